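#' @include AllClasses.R
NULL

#' Remove a polynomial trend from a trace
#'
#' Least-squares polynomial of the given order removed (order 0 = mean).
#' Used before spectral analysis to absorb dye-bleaching trends.
#'
#' @param trace numeric series.
#' @param order nonnegative integer polynomial order.
#' @return the residual series (mean approximately 0).
#' @export
detrendTrace <- function(trace, order = 2L) {
  order <- as.integer(order)
  stopifnot(order >= 0L)
  n <- length(trace)
  if (n <= order + 1L)
    stop("series too short (", n, " samples) for detrend order ", order)
  t <- seq_len(n) / n
  X <- outer(t, 0:order, `^`)
  as.numeric(trace - X %*% qr.coef(qr(X), trace))
}

# Slepian (DPSS) tapers via the symmetric tridiagonal formulation; columns
# are tapers, each normalised to unit energy.  Cached: the eigenproblem is
# the expensive step and depends only on (n, NW, K).
.dpss <- function(n, nw, k) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  hit <- .synarbor_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (k > 2 * nw - 1 + 1e-9) stop("nTapers must not exceed 2*timeBandwidth - 1")
  if (n < 2 * k) stop("series too short for ", k, " tapers")
  W <- nw / n
  t <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  od <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- dg
  A[cbind(1:(n - 1), 2:n)] <- od
  A[cbind(2:n, 1:(n - 1))] <- od
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  # fix signs: symmetric tapers positive mean, antisymmetric positive slope
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) < 1e-8) s <- sum(V[seq_len(n %/% 2), j] * -1)
    if (s < 0) V[, j] <- -V[, j]
  }
  .synarbor_cache[[key]] <- V
  V
}

# tapered eigen-FFTs at positive-frequency bins; rows = bins, cols = tapers
.taperedFFT <- function(trace, opts) {
  x <- detrendTrace(trace, opts@detrendOrder)
  n <- length(x)
  V <- .dpss(n, opts@timeBandwidth, opts@nTapers)
  nf <- n %/% 2
  X <- stats::mvfft(V * x)[1 + seq_len(nf), , drop = FALSE]
  X
}

.freqGrid <- function(n, dt) (seq_len(n %/% 2)) / (n * dt)

#' Multitaper power spectral density
#'
#' Average of the squared tapered eigen-spectra over Slepian tapers; the
#' trace is polynomial-detrended first (see [SpectralOptions-class]).
#'
#' @param trace numeric series.
#' @param dt sample interval (s).
#' @param opts a [SpectralOptions-class].
#' @return list with \code{frequency} (Hz, (0, Nyquist]) and \code{power}
#'   (nonnegative, relative units).
#' @export
multitaperPSD <- function(trace, dt, opts = spectralOptions()) {
  stopifnot(is(opts, "SpectralOptions"), dt > 0)
  validObject(opts)
  X <- .taperedFFT(trace, opts)
  list(frequency = .freqGrid(length(trace), dt),
       power = rowMeans(Mod(X)^2) * dt)
}

#' Dominant frequency of a reference trace
#'
#' The frequency of the largest multitaper-power peak within the search
#' band.  The hub neuron's dominant rhythm frequency for a behavior anchors
#' all coherence evaluations for that trial.
#'
#' @param reference numeric series of the reference cell.
#' @param dt sample interval (s).
#' @param opts a [SpectralOptions-class]; its \code{searchBand} restricts
#'   the argmax.
#' @return frequency in Hz.
#' @export
dominantFrequency <- function(reference, dt, opts = spectralOptions()) {
  psd <- multitaperPSD(reference, dt, opts)
  band <- opts@searchBand
  nyq <- 1 / (2 * dt)
  if (band[1] >= nyq)
    stop("search band (", band[1], ", ", band[2], ") Hz lies outside the ",
         "Nyquist frequency ", nyq, " Hz")
  sel <- psd$frequency >= band[1] & psd$frequency <= min(band[2], nyq)
  if (!any(sel)) stop("no frequency bins inside the search band")
  psd$frequency[sel][which.max(psd$power[sel])]
}

#' Complex coherence of a trace with a reference at one frequency
#'
#' Multitaper estimate at the frequency bin containing \code{fStar}:
#' z = sum_k conj(X_k) Y_k / sqrt(sum_k |X_k|^2 sum_k |Y_k|^2) with X the
#' tapered spectra of \code{trace} and Y of \code{reference}.  |z| <= 1 by
#' Cauchy-Schwarz.  Sign convention: a positive phase means the trace LAGS
#' the reference (a trace delayed by tau relative to the reference has phase
#' +2 pi fStar tau).  The magnitude confidence half-width is a 95% jackknife
#' over tapers on the atanh scale.
#'
#' @param trace,reference equal-length numeric series.
#' @param dt sample interval (s).
#' @param fStar analysis frequency (Hz), within the Nyquist range.
#' @param opts a [SpectralOptions-class].
#' @param cellId,trialId identifiers copied into the output row.
#' @return one-row data.frame: cell_id, trial_id, re, im, magnitude, phase,
#'   ci_magnitude, f_star.
#' @export
coherenceAt <- function(trace, reference, dt, fStar,
                        opts = spectralOptions(), cellId = NA_character_,
                        trialId = NA_character_) {
  stopifnot(length(trace) == length(reference), dt > 0)
  nyq <- 1 / (2 * dt)
  if (fStar <= 0 || fStar > nyq)
    stop("fStar must lie in (0, Nyquist = ", nyq, "] Hz")
  X <- .taperedFFT(trace, opts)
  Y <- .taperedFFT(reference, opts)
  f <- .freqGrid(length(trace), dt)
  b <- which.min(abs(f - fStar))
  xb <- X[b, ]; yb <- Y[b, ]
  px <- sum(Mod(xb)^2); py <- sum(Mod(yb)^2)
  if (px <= .Machine$double.eps * length(trace) || py == 0)
    stop("degenerate signal: no power at the analysis frequency ",
         signif(f[b], 4), " Hz")
  z <- sum(Conj(xb) * yb) / sqrt(px * py)
  # jackknife over tapers on the atanh(|z|) scale
  K <- length(xb)
  ci <- NA_real_
  if (K >= 2) {
    zjk <- vapply(seq_len(K), function(k) {
      s <- -k
      abs(sum(Conj(xb[s]) * yb[s]) /
            sqrt(sum(Mod(xb[s])^2) * sum(Mod(yb[s])^2)))
    }, numeric(1))
    zjk <- pmin(zjk, 1 - 1e-12)
    th <- atanh(zjk)
    sdj <- sqrt((K - 1) / K * sum((th - mean(th))^2))
    m0 <- min(abs(z), 1 - 1e-12)
    lo <- tanh(atanh(m0) - 1.96 * sdj)
    hi <- tanh(atanh(m0) + 1.96 * sdj)
    ci <- (hi - lo) / 2
  }
  data.frame(cell_id = cellId, trial_id = trialId,
             re = Re(z), im = Im(z), magnitude = abs(z),
             phase = Arg(z), ci_magnitude = ci, f_star = f[b])
}

#' Coherence map of a trial
#'
#' Computes the reference cell's dominant frequency within the behavior's
#' search band, then the complex coherence of every cell with the reference
#' at that frequency.  The reference's own record has magnitude 1 and phase
#' 0 exactly.
#'
#' @param trial a [TrialRecording-class].
#' @param opts a [SpectralOptions-class]; when omitted, the search band is
#'   the behavior's default ([defaultSearchBand()]).
#' @return data.frame with one row per cell (see [coherenceAt()]).
#' @export
coherenceMap <- function(trial, opts = NULL) {
  stopifnot(is(trial, "TrialRecording"))
  if (is.null(opts))
    opts <- spectralOptions(searchBand = defaultSearchBand(trial@behavior))
  tr <- trial@traces
  ref <- tr[, trial@referenceCell]
  fStar <- dominantFrequency(ref, trial@dt, opts)
  rows <- lapply(colnames(tr), function(cell)
    coherenceAt(tr[, cell], ref, trial@dt, fStar, opts,
                cellId = cell, trialId = trial@trialId))
  do.call(rbind, rows)
}
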