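#' @include clustering.R cohstats.R
NULL

#' Clustering parameter grid
#'
#' The explored ranges are 5-25 um for the maximum nearest-neighbor
#' distance and 10-100 um for the maximum cluster extent; defaults step
#' d_nn by 2.5 um and d_ext by 5 um.
#'
#' @param d_nn_values strictly increasing numeric vector (um).
#' @param d_ext_values strictly increasing numeric vector (um).
#' @return list with the two validated grids.
#' @export
parameterGrid <- function(d_nn_values = seq(5, 25, by = 2.5),
                          d_ext_values = seq(10, 100, by = 5)) {
  stopifnot(all(diff(d_nn_values) > 0), all(diff(d_ext_values) > 0),
            all(d_nn_values > 0), all(d_ext_values > 0))
  list(d_nn_values = as.numeric(d_nn_values),
       d_ext_values = as.numeric(d_ext_values))
}

# reproducible per-cell sub-seed from (master seed, d_nn index, d_ext index);
# cells are independent, so any evaluation order yields the same grid
.subSeed <- function(seed, i, j) {
  as.integer((as.numeric(seed) * 48271 + i * 1000003 + j * 7919) %%
               2147483647)
}

#' Sweep the clustering parameter space and score each cell
#'
#' For every (d_nn, d_ext) pair: cluster the synapses under the tree metric,
#' remove clusters with a single synapse or a single distinct partner,
#' evaluate the complex-coherence F-ratio over the distinct partners of each
#' cluster, and attach a permutation p-value.  Cells where no cluster
#' survives filtering (or where fewer than two coherence values remain) are
#' flagged degenerate rather than erroring.
#'
#' @param skeleton a [Skeleton-class].
#' @param table a [SynapseTable-class].
#' @param zValues named complex vector of per-partner coherence for the
#'   trial (matched partners only; synapses of unmatched partners still
#'   shape the clustering but contribute no coherence value).
#' @param grid a [parameterGrid()].
#' @param nShuffles permutation count per cell (reference analysis: 1000).
#' @param seed master seed; per-cell sub-seeds are derived from it.
#' @param trialId identifier stored in the result.
#' @return an [FRatioGrid-class].
#' @export
runSweep <- function(skeleton, table, zValues, grid = parameterGrid(),
                     nShuffles = 1000L, seed = 1L, trialId = "trial1") {
  stopifnot(is(table, "SynapseTable"))
  if (is.null(names(zValues))) stop("zValues must be named by partner id")
  D <- pairwiseDistances(skeleton, table)
  rows <- list(); r <- 0L
  for (i in seq_along(grid$d_nn_values)) {
    dnn <- grid$d_nn_values[i]
    for (j in seq_along(grid$d_ext_values)) {
      dext <- grid$d_ext_values[j]
      cs <- clusterSynapses(D, dnn, dext)
      fcs <- filterForFRatio(cs, table)
      # matched partners only; a cluster needs >= 2 of them to constrain
      # the within-cluster scatter
      cp <- lapply(.clusterPartners(fcs, table),
                   function(p) p[p %in% names(zValues)])
      cp <- cp[lengths(cp) >= 2L]
      r <- r + 1L
      if (!length(cp)) {
        rows[[r]] <- data.frame(d_nn = dnn, d_ext = dext, f = NA_real_,
                                p_hat = NA_real_, n_clusters = 0L,
                                n_values = 0L, degenerate = TRUE)
        next
      }
      fr <- permutationP(cp, zValues, nShuffles = nShuffles,
                         seed = .subSeed(seed, i, j))
      rows[[r]] <- data.frame(d_nn = dnn, d_ext = dext, f = fr@f,
                              p_hat = fr@pHat, n_clusters = length(cp),
                              n_values = sum(lengths(cp)),
                              degenerate = nzchar(fr@degenerate))
    }
  }
  new("FRatioGrid", trialId = as.character(trialId),
      grid = do.call(rbind, rows), nShuffles = as.numeric(nShuffles),
      seed = as.numeric(seed))
}

#' Best-d_nn row of a sweep and its F-vs-d_ext profile
#'
#' Finds the d_nn value at which the largest (finite, non-degenerate)
#' F-ratio in the grid was obtained; ties go to the lowest d_nn.  Returns
#' that row's F as a function of d_ext.
#'
#' @param fgrid an [FRatioGrid-class].
#' @return list with \code{d_nn_star} and \code{profile} (data.frame d_ext,
#'   f, p_hat; degenerate cells excluded).
#' @export
bestDnnProfile <- function(fgrid) {
  g <- gridTable(fgrid)
  ok <- !g$degenerate & is.finite(g$f)
  if (!any(ok)) stop("all grid cells are degenerate")
  gm <- g[ok, ]
  best <- gm[order(-gm$f, gm$d_nn), ][1, ]
  row <- g[g$d_nn == best$d_nn & !g$degenerate & is.finite(g$f), ]
  list(d_nn_star = best$d_nn,
       profile = data.frame(d_ext = row$d_ext, f = row$f,
                            p_hat = row$p_hat))
}

#' Gaussian localization of the best-corresponding cluster extent
#'
#' Fits F = 1 + A exp(-(d_ext - mu)^2 / (2 sigma^2)) to the F-vs-d_ext
#' profile by nonlinear least squares (Levenberg-Marquardt), initialized at
#' A = max(F) - 1, mu = argmax d_ext, sigma = a quarter of the grid span.
#' The standard error of mu comes from the parameter covariance at the
#' optimum.  Non-convergence and non-identifiable (flat) profiles are
#' reported via the converged flag, never as an exception.
#'
#' @param profile data.frame with columns d_ext and f (e.g. from
#'   [bestDnnProfile()]); at least four points.
#' @return a [GaussianFit-class].
#' @export
fitPeak <- function(profile) {
  d <- profile$d_ext; f <- profile$f
  keep <- is.finite(d) & is.finite(f)
  d <- d[keep]; f <- f[keep]
  if (length(d) < 4)
    return(new("GaussianFit", a = NA_real_, mu = NA_real_, sigma = NA_real_,
               seMu = NA_real_, converged = FALSE,
               message = "fewer than 4 non-degenerate points"))
  if (diff(range(f)) < 1e-9)
    return(new("GaussianFit", a = max(f) - 1, mu = NA_real_,
               sigma = NA_real_, seMu = NA_real_, converged = FALSE,
               message = "flat profile: peak location non-identifiable"))
  start <- list(a = max(f) - 1, mu = d[which.max(f)],
                sigma = diff(range(d)) / 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ 1 + a * exp(-0.5 * ((d - mu) / sigma)^2),
                      data = data.frame(d = d, f = f), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(new("GaussianFit", a = NA_real_, mu = NA_real_, sigma = NA_real_,
               seMu = NA_real_, converged = FALSE,
               message = conditionMessage(fit)))
  co <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  seMu <- if (is.null(vc)) NA_real_ else sqrt(vc["mu", "mu"])
  sig <- abs(unname(co["sigma"]))   # sign-symmetric model
  span <- diff(range(d))
  inRange <- co["mu"] >= min(d) - span && co["mu"] <= max(d) + span
  identifiable <- is.finite(seMu) && abs(co["a"]) > 1e-8 && sig > 1e-8 &&
    inRange
  new("GaussianFit", a = unname(co["a"]), mu = unname(co["mu"]),
      sigma = sig, seMu = seMu,
      converged = identifiable,
      message = if (identifiable) "converged"
        else if (!inRange)
          "fit did not identify a peak (centre far outside the profile)"
        else "fit did not identify a peak (near-zero amplitude or width)")
}

#' Significant parameter pairs of a sweep
#'
#' Grid cells with an empirical p below alpha, sorted by ascending p then
#' descending F, truncated to the top k.
#'
#' @param fgrid an [FRatioGrid-class].
#' @param alpha significance level (default 0.05).
#' @param topK maximum rows returned (default 10).
#' @return data.frame: d_nn, d_ext, f, p_hat, n_clusters (possibly empty).
#' @export
significantPairs <- function(fgrid, alpha = 0.05, topK = 10L) {
  g <- gridTable(fgrid)
  sel <- !g$degenerate & !is.na(g$p_hat) & g$p_hat < alpha
  out <- g[sel, c("d_nn", "d_ext", "f", "p_hat", "n_clusters")]
  out <- out[order(out$p_hat, -out$f), , drop = FALSE]
  rownames(out) <- NULL
  head(out, topK)
}
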