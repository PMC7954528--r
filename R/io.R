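#' @include synth.R
NULL

#' Read / write a synapse annotation table (CSV)
#'
#' The CSV carries the columns synapse_id, attach_node, partner_id, valence,
#' behavior_label.
#'
#' @param path CSV file path.
#' @param skeleton optional [Skeleton-class] to validate attachment nodes.
#' @return [SynapseTable-class] (reader); the path, invisibly (writer).
#' @export
readSynapseTable <- function(path, skeleton = NULL) {
  SynapseTable(read.csv(path, colClasses = c(synapse_id = "character",
                                             partner_id = "character")),
               skeleton = skeleton)
}

#' @rdname readSynapseTable
#' @param table a [SynapseTable-class].
#' @export
writeSynapseTable <- function(table, path) {
  stopifnot(is(table, "SynapseTable"))
  write.csv(table@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a trial recording (CSV matrix + JSON sidecar)
#'
#' The CSV holds the trace matrix (rows = samples, columns = cells, header =
#' cell ids); the JSON sidecar holds trial_id, behavior, dt and
#' reference_cell.
#'
#' @param csvPath path of the trace matrix CSV.
#' @param jsonPath path of the metadata JSON (default: csvPath with a .json
#'   extension).
#' @return [TrialRecording-class] (reader); invisible csvPath (writer).
#' @export
readTrial <- function(csvPath, jsonPath = sub("\\.csv$", ".json", csvPath)) {
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  tr <- as.matrix(read.csv(csvPath, check.names = FALSE))
  trialRecording(tr, dt = meta$dt, referenceCell = meta$reference_cell,
                 behavior = meta$behavior, trialId = meta$trial_id)
}

#' @rdname readTrial
#' @param trial a [TrialRecording-class].
#' @export
writeTrial <- function(trial, csvPath,
                       jsonPath = sub("\\.csv$", ".json", csvPath)) {
  stopifnot(is(trial, "TrialRecording"))
  write.csv(as.data.frame(trial@traces), csvPath, row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(list(trial_id = trial@trialId,
                            behavior = trial@behavior, dt = trial@dt,
                            reference_cell = trial@referenceCell),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' Read / write a per-cell coherence table (CSV)
#'
#' Columns: cell_id, trial_id, re, im, magnitude, phase, ci_magnitude,
#' f_star.
#'
#' @param path CSV path.
#' @return data.frame (reader); invisible path (writer).
#' @export
readCoherenceTable <- function(path) {
  read.csv(path, colClasses = c(cell_id = "character",
                                trial_id = "character"))
}

#' @rdname readCoherenceTable
#' @param coherence data.frame as from [coherenceMap()].
#' @export
writeCoherenceTable <- function(coherence, path) {
  write.csv(coherence, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# named complex partner -> z vector from a coherence table
coherenceToZ <- function(coherence) {
  setNames(complex(real = coherence$re, imaginary = coherence$im),
           coherence$cell_id)
}

#' Write a cluster set (long CSV + summary CSV + JSON manifest)
#'
#' @param clusters a [ClusterSet-class].
#' @param table the [SynapseTable-class] resolving partners.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "clusters").
#' @return invisibly, the paths written.
#' @export
writeClusterSet <- function(clusters, table, dir, prefix = "clusters") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- data.frame(
    cluster_id = rep(seq_along(clusters@members),
                     lengths(clusters@members)),
    synapse_id = unlist(clusters@members, use.names = FALSE))
  np <- lengths(.clusterPartners(clusters, table))
  summary <- data.frame(cluster_id = seq_along(clusters@members),
                        n_synapses = lengths(clusters@members),
                        n_partners = np, extent_um = clusters@extents)
  p1 <- file.path(dir, paste0(prefix, "_long.csv"))
  p2 <- file.path(dir, paste0(prefix, "_summary.csv"))
  p3 <- file.path(dir, paste0(prefix, "_manifest.json"))
  write.csv(long, p1, row.names = FALSE, quote = FALSE)
  write.csv(summary, p2, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(params = as.list(clusters@params),
                            n_clusters = length(clusters@members)),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

#' Write / read an F-ratio grid (long CSV + JSON manifest)
#'
#' @param fgrid an [FRatioGrid-class].
#' @param path CSV path; the manifest is written next to it.
#' @return invisible path (writer); [FRatioGrid-class] (reader).
#' @export
writeFRatioGrid <- function(fgrid, path) {
  g <- cbind(trial_id = fgrid@trialId, gridTable(fgrid))
  write.csv(g, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(trial_id = fgrid@trialId,
                            n_shuffles = fgrid@nShuffles,
                            seed = fgrid@seed),
                       sub("\\.csv$", "_manifest.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFRatioGrid
#' @export
readFRatioGrid <- function(path) {
  g <- read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", "_manifest.json", path),
                              simplifyVector = TRUE)
  new("FRatioGrid", trialId = as.character(g$trial_id[1]),
      grid = g[setdiff(names(g), "trial_id")],
      nShuffles = as.numeric(meta$n_shuffles), seed = as.numeric(meta$seed))
}

#' Write an F-ratio result as JSON
#'
#' @param result an [FRatioResult-class].
#' @param path JSON path.
#' @return invisibly, the path.
#' @export
writeFRatioResult <- function(result, path) {
  jsonlite::write_json(
    list(f = result@f, ss_total = result@ssTotal,
         ss_within = result@ssWithin, ss_between = result@ssBetween,
         p_hat = result@pHat, m = result@m, n_shuffles = result@nShuffles,
         seed = result@seed, degenerate = result@degenerate),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records input checksums, configuration and seed so any stage can be
#' re-executed without the original command line.
#'
#' @param path JSON path.
#' @param inputs character vector of input file paths (checksummed).
#' @param config list of configuration values.
#' @param seed the master seed.
#' @return invisibly, the path.
#' @export
writeRunManifest <- function(path, inputs = character(0), config = list(),
                             seed = NA) {
  files <- inputs[file.exists(inputs)]
  jsonlite::write_json(
    list(inputs = as.list(setNames(unname(tools::md5sum(files)), files)),
         config = config, seed = seed,
         r_version = as.character(getRversion()),
         package_version =
           as.character(utils::packageVersion("synarbor"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path configuration file; format chosen by extension.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (grepl("\\.(ya?ml)$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write the stage reports of a run
#'
#' Emits well-formed CSV summaries for whichever results are supplied: a
#' per-trial correlation table, the F-ratio grid, the cluster-size frequency
#' table and the significant parameter pairs (at most \code{topK} rows per
#' trial).
#'
#' @param dir output directory.
#' @param correlations optional data.frame of per-trial correlation rows.
#' @param fgrid optional [FRatioGrid-class].
#' @param clusters,table optional [ClusterSet-class] plus
#'   [SynapseTable-class] for the frequency table.
#' @param alpha,topK settings for [significantPairs()].
#' @return invisibly, the paths written.
#' @export
writeReport <- function(dir, correlations = NULL, fgrid = NULL,
                        clusters = NULL, table = NULL, alpha = 0.05,
                        topK = 10L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(correlations)) {
    p <- file.path(dir, "correlations.csv")
    write.csv(correlations, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(fgrid)) {
    p <- file.path(dir, "fratio_grid.csv")
    writeFRatioGrid(fgrid, p)
    sp <- cbind(trial_id = if (nrow(significantPairs(fgrid, alpha, topK)))
                  fgrid@trialId else character(0),
                significantPairs(fgrid, alpha, topK))
    p2 <- file.path(dir, "significant_pairs.csv")
    write.csv(sp, p2, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p, p2)
  }
  if (!is.null(clusters) && !is.null(table)) {
    p <- file.path(dir, "cluster_sizes.csv")
    write.csv(clusterSizeTable(filterMultiSynapse(clusters), table), p,
              row.names = FALSE, quote = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
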