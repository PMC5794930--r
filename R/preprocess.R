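#' Preprocessing configuration
#'
#' Selects one of the four preprocessing families compared for this kind of
#' data — per-pixel spectral moving average (MA), per-band spatial median
#' filter (MF), per-pixel wavelet denoising (WT), per-pixel EMD denoising —
#' or `none`.
#'
#' The conventional MA smoothing points are 7, 11, 15, 19 or 23 and MF
#' windows 3–15; any odd value >= 3 is accepted.
#'
#' @param method one of `"none"`, `"MA"`, `"MF"`, `"WT"`, `"EMD"`.
#' @param ma_points odd number of MA smoothing points.
#' @param mf_window odd MF window edge.
#' @param wt_wavelet wavelet family (`"db4"` or `"haar"`).
#' @param wt_level decomposition depth.
#' @param wt_threshold_rule `"universal"` or `"sure"`.
#' @param emd_n_noise_imfs how many leading (noise-dominated) IMFs to
#'   threshold.
#' @param emd_threshold_rule `"universal"`.
#' @param emd_mode `"soft"` (default) or `"hard"` thresholding of the noise
#'   IMFs.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(method = c("none", "MA", "MF", "WT", "EMD"),
                              ma_points = 11, mf_window = 7,
                              wt_wavelet = "db4", wt_level = 4,
                              wt_threshold_rule = c("universal", "sure"),
                              emd_n_noise_imfs = 1,
                              emd_threshold_rule = "universal",
                              emd_mode = c("soft", "hard")) {
  method <- match.arg(method)
  wt_threshold_rule <- match.arg(wt_threshold_rule)
  emd_mode <- match.arg(emd_mode)
  emd_threshold_rule <- match.arg(emd_threshold_rule)
  if (ma_points < 3 || ma_points %% 2 == 0)
    stop("`ma_points` must be odd and >= 3")
  if (mf_window < 3 || mf_window %% 2 == 0)
    stop("`mf_window` must be odd and >= 3")
  structure(as.list(environment()), class = "preprocess_config")
}

#' Moving-average smoothing of one spectrum
#'
#' Centered boxcar mean over `points` adjacent bands.  Near the edges the
#' window shrinks symmetrically (the first and last band are returned
#' unchanged), so the output length equals the input length and no values
#' are extrapolated.
#'
#' @param spectrum numeric vector.
#' @param points odd window length, `3 <= points <= length(spectrum)`.
#' @return smoothed vector, same length.
#' @examples
#' moving_average(c(0, 1, 0, 1, 0), 3)  # interior: 1/3, 2/3, 1/3
#' @export
moving_average <- function(spectrum, points) {
  n <- length(spectrum)
  if (points %% 2 == 0 || points < 3) stop("`points` must be odd and >= 3")
  if (points > n) stop("`points` (", points, ") exceeds band count (", n, ")")
  h <- (points - 1L) %/% 2L
  cs <- cumsum(c(0, spectrum))
  i <- seq_len(n)
  k <- pmin(h, i - 1L, n - i)  # symmetric shrinking half-width
  (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
}

#' Spatial median filter of every band of a cube
#'
#' Applies [median_filter_band()] independently to each band's gray-scale
#' image, then re-applies the mask so the background stays exactly 0.
#'
#' @param cube a [hypercube()].
#' @param window odd window edge.
#' @param lmap optional [bean_label_map()]; if supplied the background is
#'   re-zeroed after filtering.
#' @return filtered [hypercube()].
#' @export
median_filter_cube <- function(cube, window, lmap = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  data <- cube$data
  for (b in seq_len(dim(data)[3]))
    data[, , b] <- median_filter_cpp(data[, , b], as.integer(window))
  out <- hypercube(data, cube$wavelengths, cube$meta)
  if (!is.null(lmap)) out <- apply_mask(out, lmap)
  out
}

#' Apply a configured preprocessing method to a masked cube
#'
#' Dispatches on `pre$method`.  Spectral methods (MA, WT, EMD) act on each
#' foreground pixel's spectrum and leave the background exactly 0; the
#' spatial method (MF) filters each band image and then re-applies the mask,
#' since filtering bleeds foreground values into the background ring.
#'
#' @param cube masked reflectance [hypercube()].
#' @param lmap [bean_label_map()] of the scene.
#' @param pre a [preprocess_config()].
#' @return preprocessed [hypercube()].
#' @export
preprocess_cube <- function(cube, lmap, pre) {
  stopifnot(inherits(cube, "hypercube"), inherits(lmap, "bean_label_map"),
            inherits(pre, "preprocess_config"))
  if (pre$method == "none") return(cube)
  if (pre$method == "MF")
    return(median_filter_cube(cube, pre$mf_window, lmap))
  d <- dim(cube$data)
  data <- cube$data
  dim(data) <- c(d[1] * d[2], d[3])
  fg <- which(lmap$mask)
  fn <- switch(pre$method,
    MA = function(x) moving_average(x, pre$ma_points),
    WT = function(x) wavelet_denoise(x, wavelet = pre$wt_wavelet,
                                     level = pre$wt_level,
                                     rule = pre$wt_threshold_rule),
    EMD = function(x) emd_denoise(x, n_noise_imfs = pre$emd_n_noise_imfs,
                                  mode = pre$emd_mode))
  data[fg, ] <- t(apply(data[fg, , drop = FALSE], 1, fn))
  dim(data) <- d
  hypercube(data, cube$wavelengths, cube$meta)
}

#' Preprocess every spectrum of a dataset
#'
#' Convenience wrapper applying a spectral preprocessing method (MA, WT or
#' EMD) row-wise to a [spectra_dataset()]; `method = "MF"` is spatial and
#' must go through [preprocess_cube()].
#'
#' @param ds a [spectra_dataset()].
#' @param pre a [preprocess_config()].
#' @return preprocessed [spectra_dataset()].
#' @export
preprocess_spectra <- function(ds, pre) {
  stopifnot(inherits(ds, "spectra_dataset"), inherits(pre, "preprocess_config"))
  if (pre$method == "none") return(ds)
  if (pre$method == "MF")
    stop("MF is a spatial method; apply it to the cube with preprocess_cube()")
  fn <- switch(pre$method,
    MA = function(x) moving_average(x, pre$ma_points),
    WT = function(x) wavelet_denoise(x, wavelet = pre$wt_wavelet,
                                     level = pre$wt_level,
                                     rule = pre$wt_threshold_rule),
    EMD = function(x) emd_denoise(x, n_noise_imfs = pre$emd_n_noise_imfs,
                                  mode = pre$emd_mode))
  spectra_dataset(t(apply(ds$X, 1, fn)), ds$y, ds$meta, ds$wavelengths)
}

#' @export
print.preprocess_config <- function(x, ...) {
  detail <- switch(x$method,
    none = "",
    MA = sprintf(" (%d points)", x$ma_points),
    MF = sprintf(" (%dx%d window)", x$mf_window, x$mf_window),
    WT = sprintf(" (%s, level %d, %s threshold)", x$wt_wavelet, x$wt_level,
                 x$wt_threshold_rule),
    EMD = sprintf(" (%d noise IMF(s), %s %s threshold)", x$emd_n_noise_imfs,
                  x$emd_threshold_rule, x$emd_mode))
  cat(sprintf("<preprocess_config> %s%s\n", x$method, detail))
  invisible(x)
}
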