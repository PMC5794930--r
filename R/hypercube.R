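#' Hyperspectral cube
#'
#' A `hypercube` wraps a 3-D reflectance (or raw-intensity) array of shape
#' `rows x cols x bands` together with its wavelength vector (nm, strictly
#' increasing, one entry per band) and free-form acquisition metadata.
#'
#' @param data numeric 3-D array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, `length(wavelengths) == dim(data)[3]`.
#' @param meta named list of acquisition metadata (optional).
#' @return An object of class `hypercube` with elements `data`,
#'   `wavelengths`, `meta`.
#' @examples
#' cube <- hypercube(array(0.5, c(4, 5, 3)), c(1000, 1005, 1010))
#' dim(cube)
#' @export
hypercube <- function(data, wavelengths, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3])
    stop("length(wavelengths) [", length(wavelengths),
         "] must equal the number of bands [", dim(data)[3], "]")
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths, meta = meta),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' White/dark reference frames
#'
#' Reference intensities used for reflectance correction.  `white` and `dark`
#' may each be a full `rows x cols x bands` array or a per-band vector
#' (length = bands) for line-scan instruments whose references are uniform
#' across the frame.
#'
#' @param white raw intensity of the white (Teflon) reference.
#' @param dark raw intensity with the light path closed.
#' @return An object of class `reference_frames`.
#' @export
reference_frames <- function(white, dark) {
  if (is.array(white) != is.array(dark) ||
      (is.array(white) && !identical(dim(white), dim(dark))) ||
      (!is.array(white) && length(white) != length(dark)))
    stop("`white` and `dark` must have identical shape")
  structure(list(white = white, dark = dark), class = "reference_frames")
}

# broadcast a reference (vector per band, or full array) against cube dims
.ref_expand <- function(ref, d) {
  if (is.array(ref)) {
    if (!identical(dim(ref), d))
      stop("reference frame shape ", paste(dim(ref), collapse = "x"),
           " does not match cube shape ", paste(d, collapse = "x"))
    ref
  } else {
    if (length(ref) != d[3])
      stop("per-band reference length ", length(ref),
           " does not match band count ", d[3])
    aperm(array(ref, c(d[3], d[1], d[2])), c(2, 3, 1))
  }
}

#' Reflectance correction with white and dark references
#'
#' Converts raw intensities to relative reflectance element-wise:
#' `R = (raw - dark) / (white - dark)`.  `white - dark` must be strictly
#' positive everywhere it is used; a zero denominator is reported with the
#' (row, col, band) location of the first offender.
#'
#' @param raw `hypercube` of raw intensities.
#' @param refs `reference_frames`.
#' @return `hypercube` of reflectance, same shape and wavelengths as `raw`.
#' @examples
#' raw <- hypercube(array(550, c(2, 2, 1)), 1000)
#' refs <- reference_frames(white = 1000, dark = 100)
#' reflectance_correct(raw, refs)$data[1, 1, 1]  # (550-100)/900 = 0.5
#' @export
reflectance_correct <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frames"))
  d <- dim(raw$data)
  if (!is.array(refs$white) && !is.array(refs$dark)) {
    # per-band references: column-scale the unfolded cube (fast path)
    if (length(refs$white) != d[3] || length(refs$dark) != d[3])
      stop("per-band reference length does not match band count ", d[3])
    denom <- refs$white - refs$dark
    if (any(denom <= 0))
      stop("white - dark is not positive at band ", which(denom <= 0)[1])
    out <- raw$data
    dim(out) <- c(d[1] * d[2], d[3])
    out <- sweep(out, 2L, refs$dark, "-")
    out <- sweep(out, 2L, denom, "/")
    dim(out) <- d
    return(hypercube(out, raw$wavelengths, raw$meta))
  }
  white <- .ref_expand(refs$white, d)
  dark <- .ref_expand(refs$dark, d)
  denom <- white - dark
  bad <- which(denom <= 0)
  if (length(bad)) {
    loc <- arrayInd(bad[1], d)
    stop(sprintf(
      "white - dark is not positive at %d element(s); first at (row %d, col %d, band %d)",
      length(bad), loc[1], loc[2], loc[3]))
  }
  out <- (raw$data - dark) / denom
  hypercube(out, raw$wavelengths, raw$meta)
}

#' Nearest band index for a requested wavelength
#'
#' Returns the index of the band whose center wavelength is closest to
#' `band_nm`; ties break toward the lower wavelength.
#'
#' @param wavelengths numeric vector of band centers (nm).
#' @param band_nm requested wavelength (nm); must lie within the grid range.
#' @return integer band index (1-based).
#' @export
nearest_band <- function(wavelengths, band_nm) {
  if (band_nm < min(wavelengths) || band_nm > max(wavelengths))
    stop("requested wavelength ", band_nm, " nm outside grid range [",
         min(wavelengths), ", ", max(wavelengths), "]")
  d <- abs(wavelengths - band_nm)
  which(d == min(d))[1]  # first match = lower wavelength on ties
}
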