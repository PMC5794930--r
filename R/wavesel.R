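#' Second-derivative spectra of class means
#'
#' Savitzky–Golay second derivative (window 11, cubic polynomial by default
#' — the chemometric standard for derivative spectra on a uniform grid) of
#' one mean spectrum per class.  Second-derivative spectra sharpen absorption
#' features and suppress the baseline, which is what makes between-class
#' differences localizable to single bands.
#'
#' @param class_means [spectra_dataset()] with exactly one spectrum per
#'   class (e.g. class means of the calibration averages), or a plain matrix
#'   with one class per row plus a `wavelengths` argument.
#' @param wavelengths band grid (nm) when `class_means` is a matrix.
#' @param window Savitzky–Golay window length (odd, default 11).
#' @param polyorder polynomial order (default 3).
#' @return object of class `d2_set`: list with `d2` (K x bands matrix of
#'   second derivatives, in reflectance / nm^2), `wavelengths`, `classes`.
#' @export
second_derivative <- function(class_means, wavelengths = NULL, window = 11,
                              polyorder = 3) {
  if (inherits(class_means, "spectra_dataset")) {
    if (anyDuplicated(class_means$y))
      stop("`class_means` must hold exactly one spectrum per class")
    M <- class_means$X
    wavelengths <- class_means$wavelengths
    classes <- class_means$y
  } else {
    M <- as.matrix(class_means)
    if (is.null(wavelengths)) stop("`wavelengths` required for matrix input")
    classes <- seq_len(nrow(M))
  }
  if (ncol(M) < window)
    stop("fewer bands (", ncol(M), ") than the derivative window (", window, ")")
  step <- diff(wavelengths)
  if (any(abs(step - step[1]) > 1e-8))
    stop("second_derivative requires a uniform wavelength grid")
  d2 <- t(apply(M, 1, function(s)
    signal::sgolayfilt(s, p = polyorder, n = window, m = 2, ts = step[1])))
  structure(list(d2 = d2, wavelengths = as.numeric(wavelengths),
                 classes = as.integer(classes)),
            class = "d2_set")
}

#' Class means of a spectra dataset
#'
#' @param ds a [spectra_dataset()].
#' @return [spectra_dataset()] with one mean spectrum per class.
#' @export
class_means <- function(ds) {
  stopifnot(inherits(ds, "spectra_dataset"))
  cl <- sort(unique(ds$y))
  M <- t(vapply(cl, function(k) colMeans(ds$X[ds$y == k, , drop = FALSE]),
                numeric(ncol(ds$X))))
  spectra_dataset(M, cl, data.frame(scene_id = NA_integer_, bean_id = cl),
                  ds$wavelengths)
}

#' Select optimal wavelengths from second-derivative spectra
#'
#' Deterministic replacement for the conventional manual picking of
#' second-derivative peaks and valleys: every band where some class's
#' *class-centered* second-derivative curve (its row minus the across-class
#' mean) has a local extremum is a candidate, so only between-class
#' differences generate candidates; each candidate is scored by the
#' across-class range (max - min) of the second derivative at that band;
#' candidates are kept greedily by descending score (ties toward the lower
#' wavelength) subject to a minimum mutual separation, up to `max_k`.
#' Peaks whose classes barely differ score near zero and are dropped by
#' `score_floor`.
#'
#' @param d2set a `d2_set` from [second_derivative()].
#' @param max_k maximum number of wavelengths (default 15).
#' @param min_separation_nm minimum distance between selected wavelengths
#'   (default 10 nm).
#' @param score_floor minimum between-class range for a candidate to be
#'   eligible (default 0 keeps all extrema).
#' @return object of class `wavelength_set`: list with `selected` (nm,
#'   ascending), `indices` (band indices), `scores` (between-class range at
#'   each selected band, same order as `selected`).  Empty (with a warning)
#'   when no class differences produce extrema above the floor.
#' @export
select_wavelengths <- function(d2set, max_k = 15, min_separation_nm = 10,
                               score_floor = 0) {
  stopifnot(inherits(d2set, "d2_set"))
  if (nrow(d2set$d2) < 2) stop("need at least 2 classes")
  wl <- d2set$wavelengths
  # candidates come from the class-centered curves, so the selection depends
  # only on between-class differences (a spectrum added to every class mean
  # cancels here and cannot shift the picked bands)
  centered <- sweep(d2set$d2, 2, colMeans(d2set$d2))
  cand <- sort(unique(unlist(lapply(seq_len(nrow(centered)), function(k) {
    ex <- .local_extrema(centered[k, ])
    c(ex$max, ex$min)
  }))))
  score <- apply(d2set$d2[, cand, drop = FALSE], 2, function(v)
    max(v) - min(v))
  keep <- score > score_floor
  cand <- cand[keep]; score <- score[keep]
  if (!length(cand)) {
    warning("no second-derivative extrema with between-class differences; ",
            "empty wavelength set")
    return(structure(list(selected = numeric(0), indices = integer(0),
                          scores = numeric(0)), class = "wavelength_set"))
  }
  ord <- order(-score, wl[cand])
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= max_k) break
    if (!length(sel) || min(abs(wl[cand[i]] - wl[sel])) >= min_separation_nm)
      sel <- c(sel, cand[i])
  }
  o <- order(wl[sel])
  structure(list(selected = wl[sel][o], indices = sel[o],
                 scores = score[match(sel[o], cand)]),
            class = "wavelength_set")
}

#' @export
print.wavelength_set <- function(x, ...) {
  cat(sprintf("<wavelength_set> %d bands: %s nm\n", length(x$selected),
              paste(round(x$selected), collapse = ", ")))
  invisible(x)
}

#' Restrict a dataset to the selected wavelengths
#'
#' @param ds a [spectra_dataset()].
#' @param ws a `wavelength_set` (or an integer vector of band indices).
#' @return [spectra_dataset()] with columns restricted to the selection,
#'   ascending wavelength order preserved; provenance untouched.
#' @export
subset_bands <- function(ds, ws) {
  stopifnot(inherits(ds, "spectra_dataset"))
  idx <- if (inherits(ws, "wavelength_set")) ws$indices else as.integer(ws)
  if (!length(idx)) stop("empty wavelength selection")
  if (any(idx < 1 | idx > ncol(ds$X)))
    stop("band index out of range 1..", ncol(ds$X))
  spectra_dataset(ds$X[, idx, drop = FALSE], ds$y, ds$meta,
                  ds$wavelengths[idx])
}

#' Serialize a wavelength set as CSV
#' @param ws a `wavelength_set`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_wavelength_csv <- function(ws, path) {
  write.csv(data.frame(wavelength_nm = ws$selected, band_index = ws$indices,
                       score = ws$scores),
            path, row.names = FALSE)
  invisible(path)
}

#' Plot second-derivative spectra with selected bands marked
#'
#' One curve per class with vertical guides at the selected wavelengths —
#' the visual companion of [select_wavelengths()].
#'
#' @param d2set a `d2_set` from [second_derivative()].
#' @param ws optional `wavelength_set` to mark.
#' @param ... forwarded to [graphics::matplot()].
#' @return invisibly, `NULL`.
#' @export
plot_second_derivative <- function(d2set, ws = NULL, ...) {
  stopifnot(inherits(d2set, "d2_set"))
  graphics::matplot(d2set$wavelengths, t(d2set$d2), type = "l", lty = 1,
                    xlab = "wavelength (nm)",
                    ylab = "2nd derivative (refl / nm^2)", ...)
  if (!is.null(ws) && length(ws$selected))
    graphics::abline(v = ws$selected, col = "grey60", lty = 3)
  invisible(NULL)
}
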