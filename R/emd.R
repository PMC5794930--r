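# Empirical mode decomposition by cubic-spline envelope sifting.

# indices of strict local maxima/minima, with flat runs collapsed to their
# center point
.local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  r <- rle(x)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mx <- integer(0); mn <- integer(0)
  if (k >= 3) for (i in 2:(k - 1)) {
    mid <- (starts[i] + ends[i]) %/% 2L
    if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1])
      mx <- c(mx, mid)
    if (r$values[i] < r$values[i - 1] && r$values[i] < r$values[i + 1])
      mn <- c(mn, mid)
  }
  list(max = mx, min = mn)
}

.envelope_mean <- function(x) {
  n <- length(x)
  ex <- .local_extrema(x)
  if (length(ex$max) < 2 || length(ex$min) < 2) return(NULL)
  # anchor the splines at the signal endpoints to bound boundary swings
  up <- splinefun(c(1, ex$max, n), c(x[1], x[ex$max], x[n]))(seq_len(n))
  lo <- splinefun(c(1, ex$min, n), c(x[1], x[ex$min], x[n]))(seq_len(n))
  (up + lo) / 2
}

#' Empirical mode decomposition
#'
#' Sifts a signal into intrinsic mode functions (IMFs): the envelope mean
#' (cubic splines through the local maxima and minima) is subtracted until
#' the normalized sifting criterion drops below `sd_stop`, the IMF is
#' removed, and the process repeats on the residue until it has fewer than
#' four extrema or `max_imfs` is reached.  The IMFs plus residual always sum
#' to the input exactly (up to float round-off) by construction.
#'
#' @param x numeric vector.
#' @param max_imfs maximum number of IMFs (default 10).
#' @param sd_stop sifting stop criterion (Huang's SD, default 0.2).
#' @param max_sift iteration cap per IMF; non-convergence within the cap is
#'   a warning and the current best is kept.
#' @return list with `imfs` (matrix, one IMF per column; 0 columns for
#'   signals with fewer than four extrema) and `residual`.
#' @export
emd <- function(x, max_imfs = 10, sd_stop = 0.2, max_sift = 30) {
  n <- length(x)
  imfs <- list()
  res <- x
  for (k in seq_len(max_imfs)) {
    ex <- .local_extrema(res)
    if (length(ex$max) + length(ex$min) < 4) break
    if (is.null(.envelope_mean(res))) break  # cannot form both envelopes
    h <- res
    converged <- FALSE
    for (it in seq_len(max_sift)) {
      m <- .envelope_mean(h)
      if (is.null(m)) { converged <- TRUE; break }
      h1 <- h - m
      sdc <- sum((h - h1)^2) / sum(h^2 + .Machine$double.eps)
      h <- h1
      if (sdc < sd_stop) { converged <- TRUE; break }
    }
    if (!converged)
      warning("sifting did not converge within ", max_sift,
              " iterations for IMF ", k, "; keeping best effort")
    imfs[[k]] <- h
    res <- res - h
  }
  list(imfs = if (length(imfs)) do.call(cbind, imfs)
       else matrix(numeric(0), n, 0),
       residual = res)
}

#' EMD denoising of a spectrum
#'
#' Decomposes the spectrum into IMFs, thresholds the first
#' `n_noise_imfs` (noise-dominated, highest-frequency) IMFs with the
#' universal rule (`sigma * sqrt(2 log n)`, `sigma` from the MAD of the
#' IMF), and reconstructs from the thresholded IMFs, the remaining IMFs and
#' the residual.  Spectra with fewer than four extrema (e.g. strictly
#' monotone) are returned unchanged.
#'
#' @param spectrum numeric vector.
#' @param n_noise_imfs number of leading IMFs to threshold (default 1).
#' @param mode `"soft"` (default) or `"hard"` thresholding.
#' @param max_imfs,sd_stop,max_sift forwarded to [emd()].
#' @return denoised vector, same length.
#' @export
emd_denoise <- function(spectrum, n_noise_imfs = 1, mode = c("soft", "hard"),
                        max_imfs = 10, sd_stop = 0.2, max_sift = 30) {
  mode <- match.arg(mode)
  dec <- emd(spectrum, max_imfs = max_imfs, sd_stop = sd_stop,
             max_sift = max_sift)
  p <- ncol(dec$imfs)
  if (p == 0) return(spectrum)
  n <- length(spectrum)
  out <- dec$residual
  for (j in seq_len(p)) {
    imf <- dec$imfs[, j]
    if (j <= n_noise_imfs) {
      sigma <- median(abs(imf)) / 0.6745
      t_j <- sigma * sqrt(2 * log(n))
      imf <- if (mode == "soft") .soft(imf, t_j) else imf * (abs(imf) > t_j)
    }
    out <- out + imf
  }
  out
}
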