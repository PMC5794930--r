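# Orthogonal periodized discrete wavelet transform.
# Analysis: a[k] = sum_m lo[m] x[(2(k-1)+m) mod n], detail with the
# quadrature-mirror highpass hi[m] = (-1)^m lo[L-1-m]; synthesis is the
# transpose, so perfect reconstruction follows from filter orthogonality.

.wt_filters <- function(wavelet) {
  lo <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    # Daubechies extremal-phase, 4 vanishing moments (8 taps)
    db4 = {
      h <- c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
             -0.02798376941698385, -0.18703481171888114,
             0.030841381835986965, 0.032883011666982945,
             -0.010597401784997278)
      h / sqrt(sum(h^2))  # unit-norm guard against printed truncation
    },
    stop("unknown wavelet `", wavelet, "` (db4, haar)"))
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  list(lo = lo, hi = hi, L = L)
}

.dwt_step <- function(x, f) {
  n <- length(x)
  k <- seq_len(n / 2)
  idx <- outer(2 * (k - 1), seq_len(f$L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(a = as.vector(xm %*% f$lo), d = as.vector(xm %*% f$hi))
}

.idwt_step <- function(a, d, f) {
  n <- 2 * length(a)
  x <- numeric(n)
  for (m in seq_len(f$L)) {
    idx <- (2 * (seq_along(a) - 1) + m - 1) %% n + 1
    contrib <- a * f$lo[m] + d * f$hi[m]
    # accumulate (idx may repeat when L > n)
    acc <- rowsum(contrib, idx)
    x[as.integer(rownames(acc))] <- x[as.integer(rownames(acc))] + acc[, 1]
  }
  x
}

#' Multilevel periodized DWT
#'
#' @param x numeric vector; length must be divisible by `2^level`.
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @param level decomposition depth.
#' @return list with `approx` (coarsest approximation) and `details` (list of
#'   detail coefficient vectors, finest first).
#' @seealso [wavelet_denoise()]
#' @export
dwt_periodized <- function(x, wavelet = "db4", level = 4) {
  n <- length(x)
  if (level < 1) stop("`level` must be >= 1")
  if (n %% 2^level != 0)
    stop("signal length ", n, " is not divisible by 2^level = ", 2^level)
  f <- .wt_filters(wavelet)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- .dwt_step(a, f)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, wavelet = wavelet, level = level)
}

#' @rdname dwt_periodized
#' @param w a decomposition from [dwt_periodized()].
#' @export
idwt_periodized <- function(w) {
  f <- .wt_filters(w$wavelet)
  a <- w$approx
  for (j in rev(seq_len(w$level)))
    a <- .idwt_step(a, w$details[[j]], f)
  a
}

.soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# SURE-optimal soft threshold for unit-variance coefficients
.sure_threshold <- function(d) {
  n <- length(d)
  s <- sort(d^2)
  risk <- (n - 2 * seq_len(n) + cumsum(s) + (n - seq_len(n)) * s) / n
  sqrt(s[which.min(risk)])
}

#' Wavelet soft-threshold denoising of a spectrum
#'
#' Multilevel periodized DWT, soft thresholding of all detail coefficients,
#' reconstruction.  The high-frequency part carries the noise; the universal
#' rule thresholds it at `sigma * sqrt(2 log n)` with `sigma` estimated from
#' the median absolute deviation of the finest-level details.  Signals whose
#' length is not divisible by `2^level` are symmetrically padded, transformed
#' and cropped, so any length >= `2^level` works and a zero threshold
#' reproduces the input exactly.
#'
#' @param spectrum numeric vector, length >= `2^level`.
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @param level decomposition depth (default 4).
#' @param rule `"universal"` or `"sure"` (per-level SURE-optimal threshold).
#' @param threshold fixed threshold overriding the rule (0 = reconstruction
#'   identity).
#' @return denoised vector, same length.
#' @export
wavelet_denoise <- function(spectrum, wavelet = "db4", level = 4,
                            rule = c("universal", "sure"), threshold = NULL) {
  rule <- match.arg(rule)
  n <- length(spectrum)
  if (n < 2^level)
    stop("level ", level, " too deep for a length-", n, " signal")
  block <- 2^level
  npad <- ceiling(n / block) * block
  x <- if (npad > n) c(spectrum, spectrum[n - seq_len(npad - n) + 1]) else spectrum
  w <- dwt_periodized(x, wavelet, level)
  sigma <- median(abs(w$details[[1]])) / 0.6745
  for (j in seq_len(level)) {
    t_j <- if (!is.null(threshold)) threshold
           else if (rule == "universal") sigma * sqrt(2 * log(npad))
           else if (sigma > 0) sigma * .sure_threshold(w$details[[j]] / sigma)
           else 0
    w$details[[j]] <- .soft(w$details[[j]], t_j)
  }
  idwt_periodized(w)[seq_len(n)]
}
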