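#' @include AllClasses.R
NULL

# core sums of squares for a vector of complex values and a cluster index;
# returns c(ssTotal, ssWithin, ssBetween)
.complexSS <- function(z, k) {
  z0 <- mean(z)
  sst <- sum(Mod(z - z0)^2)
  zk0 <- vapply(split(z, k), mean, complex(1))
  ssw <- sum(Mod(z - zk0[as.character(k)])^2)
  c(sst, ssw, sst - ssw)
}

.fratioFromSS <- function(ss) {
  sst <- ss[1]; ssw <- ss[2]
  if (sst <= 1e-300) return(list(f = 1, degenerate = "zero_total"))
  if (ssw <= sst * 1e-15) return(list(f = Inf, degenerate = "zero_within"))
  list(f = sst / ssw, degenerate = "")
}

#' Complex-coherence F-ratio over clusters
#'
#' For complex coherence values z_ki of cell i in cluster k, with cluster
#' centroids z_k0 and grand centroid z_0, the statistic is
#' F = sum |z_ki - z_0|^2 / sum |z_ki - z_k0|^2 (absolute squares of complex
#' deviations).  F >= 1 always, since the total sum of squares decomposes
#' into within plus between; F > 1 indicates that coherence values within a
#' spatial cluster are more similar to each other than across clusters.
#' Each cluster should contribute the z of each of its distinct partners
#' once.
#'
#' @param clusterValues list of complex vectors, one per cluster; at least
#'   one cluster must have two or more members.
#' @return an [FRatioResult-class] (without a permutation p-value).
#'   Degenerate inputs are flagged: all values identical gives F = 1 with
#'   flag "zero_total"; zero within-cluster scatter with nonzero total gives
#'   the F = +Inf sentinel with flag "zero_within".
#' @examples
#' complexFRatio(list(c(1 + 0i, 0 + 1i), c(-1 + 0i, 0 - 1i)))  # F = 2
#' @export
complexFRatio <- function(clusterValues) {
  stopifnot(is.list(clusterValues), length(clusterValues) >= 1)
  n <- lengths(clusterValues)
  if (any(n == 0)) stop("empty cluster in clusterValues")
  if (!any(n >= 2))
    stop("at least one cluster must contribute two or more values")
  z <- as.complex(unlist(clusterValues, use.names = FALSE))
  k <- rep(seq_along(clusterValues), n)
  ss <- .complexSS(z, k)
  fr <- .fratioFromSS(ss)
  new("FRatioResult", f = fr$f, ssTotal = ss[1], ssWithin = ss[2],
      ssBetween = ss[3], pHat = NA_real_, m = NA_real_,
      nShuffles = NA_real_, seed = NA_real_, degenerate = fr$degenerate)
}

#' Permutation p-value for the complex F-ratio
#'
#' Keeps the cluster composition (which partner slots belong to which
#' cluster) fixed and randomly shuffles the partner-to-coherence map over
#' all matched partners, recomputing F each time.  The empirical p-value is
#' (m + 1) / (nShuffles + 1), where m counts shuffles whose F is at least
#' the observed F.  In the complex-valued case the F-ratio does not follow
#' an F-distribution under the null, so only this permutation p is offered.
#'
#' @param clusterPartners list of character vectors: the distinct partner
#'   ids of each cluster (e.g. clusters from [clusterSynapses()] +
#'   [filterForFRatio()], partners via the synapse table).
#' @param zValues named complex vector: per-partner coherence, covering at
#'   least all partners appearing in \code{clusterPartners}; the shuffle
#'   permutes this entire map.
#' @param nShuffles number of random shuffles (the reference analysis used
#'   1000).
#' @param seed integer seed; results are reproducible given the seed.
#' @return an [FRatioResult-class] with pHat, m, nShuffles and seed set.
#'   A degenerate observed F keeps its flag; pHat is still returned.
#' @export
permutationP <- function(clusterPartners, zValues, nShuffles = 1000L,
                         seed = 1L) {
  stopifnot(is.list(clusterPartners), nShuffles >= 1)
  if (is.null(names(zValues))) stop("zValues must be named by partner id")
  partners <- unlist(clusterPartners, use.names = FALSE)
  missing <- setdiff(partners, names(zValues))
  if (length(missing))
    stop("no coherence value for partner(s): ",
         paste(head(missing, 5), collapse = ", "))
  idx <- match(partners, names(zValues))
  k <- rep(seq_along(clusterPartners), lengths(clusterPartners))
  z <- as.complex(zValues)
  obs <- complexFRatio(split(z[idx], k))
  P <- length(z)
  N <- length(idx)
  # all shuffles at once: columns of Zm are the permuted values at the
  # membership slots; group sums via rowsum give the within sums of squares
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nShuffles), function(s) sample.int(P), integer(P))
  })
  Zm <- matrix(z[perm], P, nShuffles)[idx, , drop = FALSE]
  Rm <- Re(Zm); Qm <- Im(Zm)
  tot2 <- colSums(Rm^2) + colSums(Qm^2)
  sst <- tot2 - N * (colMeans(Rm)^2 + colMeans(Qm)^2)
  nk <- as.vector(rowsum(rep(1, N), k))
  ssw <- tot2 - colSums((rowsum(Rm, k)^2 + rowsum(Qm, k)^2) / nk)
  fShuf <- ifelse(sst <= 1e-300, 1,
                  ifelse(ssw <= sst * 1e-15, Inf, sst / pmax(ssw, 1e-300)))
  m <- sum(fShuf >= obs@f)
  new("FRatioResult", f = obs@f, ssTotal = obs@ssTotal,
      ssWithin = obs@ssWithin, ssBetween = obs@ssBetween,
      pHat = (m + 1) / (nShuffles + 1), m = as.numeric(m),
      nShuffles = as.numeric(nShuffles), seed = as.numeric(seed),
      degenerate = obs@degenerate)
}

#' Proximity weight of a partner
#'
#' The proximity weight of a synapse is the inverse of its along-neurite
#' distance to the soma; the proximity weight of a neuron is the sum over
#' its synapses.
#'
#' @param somaDistances numeric vector of along-neurite distances (um) of
#'   one partner's synapses to the soma; all must be positive (a synapse
#'   directly on the soma needs a minimum-distance floor applied upstream).
#' @return weight in 1/um.
#' @examples
#' proximityWeight(c(10, 40))  # 0.125
#' @export
proximityWeight <- function(somaDistances) {
  if (!length(somaDistances)) stop("no distances given")
  if (any(somaDistances <= 0))
    stop("zero or negative soma distance; apply a minimum-distance floor ",
         "in the configuration before computing proximity weights")
  sum(1 / somaDistances)
}

#' Build per-partner profiles (synapse counts, proximity weights, coherence)
#'
#' @param skeleton a [Skeleton-class].
#' @param table a [SynapseTable-class].
#' @param coherence data.frame as from [coherenceMap()]; cell_id is matched
#'   against partner ids.  Partners without a row are marked unmatched.
#' @param distanceFloor minimum soma distance (um) substituted for synapses
#'   attached at the soma itself (default 1).
#' @return data.frame: partner_id, synapse_count, proximity_weight,
#'   magnitude, re, im, vsd_matched.
#' @export
buildPartnerProfiles <- function(skeleton, table, coherence,
                                 distanceFloor = 1) {
  r <- table@records
  d <- pmax(distanceToSoma(skeleton, table), distanceFloor)
  byP <- split(seq_len(nrow(r)), r$partner_id)
  prof <- data.frame(
    partner_id = names(byP),
    synapse_count = lengths(byP),
    proximity_weight = vapply(byP, function(i) proximityWeight(d[i]),
                              numeric(1)))
  j <- match(prof$partner_id, coherence$cell_id)
  prof$magnitude <- coherence$magnitude[j]
  prof$re <- coherence$re[j]
  prof$im <- coherence$im[j]
  prof$vsd_matched <- !is.na(j)
  rownames(prof) <- NULL
  prof
}

#' Correlation between an anatomical measure and coherence magnitude
#'
#' Pearson correlation (with its usual two-sided t-transform p-value)
#' between synapse count (or proximity weight) and coherence magnitude over
#' included partners: those matched to the optical record with at least two
#' synapses.
#'
#' @param profiles data.frame from [buildPartnerProfiles()].
#' @param measure "synapse_count" or "proximity_weight".
#' @param minSynapses inclusion threshold (default 2).
#' @return list with r, p, n.
#' @export
partnerCoherenceCorrelation <- function(profiles,
                                        measure = c("synapse_count",
                                                    "proximity_weight"),
                                        minSynapses = 2L) {
  measure <- match.arg(measure)
  inc <- profiles$vsd_matched & profiles$synapse_count >= minSynapses &
    !is.na(profiles$magnitude)
  x <- profiles[[measure]][inc]
  y <- profiles$magnitude[inc]
  if (length(x) < 3) stop("fewer than 3 included partners")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in ", if (sd(x) == 0) measure else "magnitude",
         "; correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Across-trial one-sample t-test of correlation coefficients
#'
#' Two-tailed test of the collected per-trial correlation coefficients
#' against zero mean: t = mean / (sd / sqrt(n)) with n - 1 degrees of
#' freedom.
#'
#' @param rValues numeric vector of per-trial correlations (n >= 2).
#' @return list with t, p, mean, sd, n and \code{degenerate} (TRUE when the
#'   values have zero spread, in which case t is +/-Inf and p is 0, or t = 0
#'   and p = 1 when all values are zero).
#' @export
trialsTTest <- function(rValues) {
  n <- length(rValues)
  if (n < 2) stop("need at least two values")
  m <- mean(rValues); s <- sd(rValues)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    return(list(t = t, p = if (m == 0) 1 else 0, mean = m, sd = s, n = n,
                degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1), mean = m, sd = s, n = n,
       degenerate = FALSE)
}

#' Cyclic greedy assignment of cells to behaviors
#'
#' Compensates for systematically different coherence-magnitude scales
#' across behaviors: within a cycle, the (cell, behavior) pair with the
#' greatest magnitude among unassigned cells and behaviors not yet used in
#' the cycle is assigned; when every behavior has been used the next cycle
#' starts.  Per-behavior counts therefore differ by at most one.  Ties are
#' broken towards the lower row, then column, index.
#'
#' @param magnitudes numeric matrix, cells x behaviors, with dimnames.
#' @return list with \code{assignment} (named character vector cell ->
#'   behavior) and \code{log} (data.frame: step, cycle, cell, behavior,
#'   magnitude, in assignment order).
#' @export
assignBehaviors <- function(magnitudes) {
  m <- as.matrix(magnitudes)
  if (!nrow(m) || !ncol(m)) stop("empty magnitude matrix")
  if (is.null(rownames(m))) rownames(m) <- paste0("cell", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("behavior", seq_len(ncol(m)))
  unassigned <- rownames(m)
  log <- list()
  assignment <- character(0)
  step <- 0L; cycle <- 1L
  while (length(unassigned)) {
    open <- colnames(m)
    while (length(open) && length(unassigned)) {
      sub <- m[unassigned, open, drop = FALSE]
      ij <- which(sub == max(sub), arr.ind = TRUE)
      ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
      cell <- unassigned[ij[1]]; beh <- open[ij[2]]
      step <- step + 1L
      assignment[cell] <- beh
      log[[step]] <- data.frame(step = step, cycle = cycle, cell = cell,
                                behavior = beh,
                                magnitude = m[cell, beh])
      unassigned <- setdiff(unassigned, cell)
      open <- setdiff(open, beh)
    }
    cycle <- cycle + 1L
  }
  list(assignment = assignment, log = do.call(rbind, log))
}

# two-sample Kolmogorov-Smirnov statistic, ties allowed
.ksStat <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(g) - ecdf(y)(g)))
}

#' Compare spatial distributions of synapse groups against 'unknown'
#'
#' Each labeled group's along-neurite distance distribution is compared
#' with the distribution of the 'unknown' group using the two-sample
#' Kolmogorov-Smirnov statistic and a label-permutation p-value
#' (m + 1)/(nPerm + 1).
#'
#' @param distanceGroups named list of numeric vectors (um); must contain an
#'   element named "unknown".
#' @param nPerm number of label shuffles (default 10000).
#' @param seed integer seed.
#' @return data.frame: group, n, statistic, p.  Groups with fewer than two
#'   samples are skipped with a warning.
#' @export
spatialGroupComparison <- function(distanceGroups, nPerm = 10000L,
                                   seed = 1L) {
  if (!"unknown" %in% names(distanceGroups))
    stop("distanceGroups must contain an element named 'unknown'")
  if (length(distanceGroups) < 2) stop("need at least two groups")
  ref <- distanceGroups[["unknown"]]
  out <- list()
  for (g in setdiff(names(distanceGroups), "unknown")) {
    x <- distanceGroups[[g]]
    if (length(x) < 2 || length(ref) < 2) {
      warning("group '", g, "' (or 'unknown') has fewer than 2 samples; skipped")
      next
    }
    stat <- .ksStat(x, ref)
    pool <- c(x, ref)
    nx <- length(x)
    m <- withr::with_seed(as.integer(seed), {
      sum(vapply(seq_len(nPerm), function(i) {
        sel <- sample.int(length(pool), nx)
        .ksStat(pool[sel], pool[-sel]) >= stat
      }, logical(1)))
    })
    out[[g]] <- data.frame(group = g, n = nx, statistic = stat,
                           p = (m + 1) / (nPerm + 1))
  }
  if (!length(out))
    return(data.frame(group = character(0), n = integer(0),
                      statistic = numeric(0), p = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
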