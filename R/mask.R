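#' Bean label map
#'
#' Binary foreground mask plus integer instance labels: `mask` is a
#' `rows x cols` logical matrix (TRUE = sample), `labels` an integer matrix
#' with 0 on the background and `1..n_beans` on the beans.  Labels are
#' positive exactly where the mask is TRUE and each id is one 8-connected
#' component.
#'
#' @param mask logical matrix.
#' @param labels integer matrix, same shape.
#' @return An object of class `bean_label_map` with elements `mask`,
#'   `labels`, `n_beans`.
#' @export
bean_label_map <- function(mask, labels) {
  stopifnot(is.matrix(mask), is.matrix(labels),
            identical(dim(mask), dim(labels)))
  mask <- mask & TRUE  # coerce to logical
  storage.mode(labels) <- "integer"
  if (any((labels > 0L) != mask))
    stop("labels must be positive exactly where mask is TRUE")
  structure(list(mask = mask, labels = labels,
                 n_beans = max(0L, max(labels))),
            class = "bean_label_map")
}

#' @export
print.bean_label_map <- function(x, ...) {
  cat(sprintf("<bean_label_map> %d x %d, %d beans, %d foreground px\n",
              nrow(x$mask), ncol(x$mask), x$n_beans, sum(x$mask)))
  invisible(x)
}

#' Build a foreground mask and bean instance labels from one band
#'
#' Thresholds the gray-scale image at the band nearest `band_nm` (default
#' 1200 nm, the conventional masking band for NIR bean imagery): pixels with
#' reflectance above the threshold are sample, the rest background.  The
#' default threshold is Otsu's method on that band; pass a fixed value to
#' override.  Bean instances are 8-connected components of the mask;
#' components smaller than `min_area` pixels are dropped (specks).  Touching
#' beans merge into one instance (no watershed split).
#'
#' @param cube reflectance [hypercube()].
#' @param band_nm wavelength (nm) of the masking band; nearest band is used.
#' @param threshold reflectance cutoff, or `NULL` for Otsu.
#' @param min_area minimum component area in pixels (default 20).
#' @return A [bean_label_map()].  An empty mask triggers a warning, not an
#'   error.
#' @export
build_mask <- function(cube, band_nm = 1200, threshold = NULL, min_area = 20) {
  stopifnot(inherits(cube, "hypercube"))
  b <- nearest_band(cube$wavelengths, band_nm)
  gray <- cube$data[, , b]
  if (is.null(threshold)) {
    rng <- range(gray)
    if (rng[2] <= rng[1]) {
      threshold <- rng[1]  # constant image: nothing above threshold
    } else {
      threshold <- EBImage::otsu(gray, range = rng, levels = 256L)
    }
  }
  mask <- gray > threshold
  labels <- label_components_cpp(mask)
  if (min_area > 0 && max(labels) > 0) {
    area <- tabulate(labels)
    keep <- which(area >= min_area)
    relab <- integer(length(area))
    relab[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
    mask <- labels > 0L
  }
  if (!any(mask)) warning("mask is empty: no pixel above threshold ",
                          signif(threshold, 4))
  bean_label_map(mask, labels)
}

#' Zero the background of a cube
#'
#' Sets every background voxel (mask FALSE) to exactly 0 at all bands;
#' foreground values are untouched.
#'
#' @param cube a [hypercube()].
#' @param lmap a [bean_label_map()] with matching spatial shape.
#' @return masked [hypercube()].
#' @export
apply_mask <- function(cube, lmap) {
  stopifnot(inherits(cube, "hypercube"), inherits(lmap, "bean_label_map"))
  d <- dim(cube$data)
  if (!identical(d[1:2], dim(lmap$mask)))
    stop("mask shape ", paste(dim(lmap$mask), collapse = "x"),
         " does not match cube ", paste(d[1:2], collapse = "x"))
  data <- cube$data
  bg <- which(!lmap$mask)  # column-major pixel indices
  if (length(bg)) {
    dim(data) <- c(d[1] * d[2], d[3])
    data[bg, ] <- 0
    dim(data) <- d
  }
  hypercube(data, cube$wavelengths, cube$meta)
}

#' Spatial median filter of one gray-scale band image
#'
#' Replaces each pixel by the median of its odd square window, with reflect
#' padding at the borders.
#'
#' @param image numeric matrix.
#' @param window odd integer window edge (3, 5, ...).
#' @return filtered matrix, same shape.
#' @export
median_filter_band <- function(image, window) {
  if (length(window) != 1 || window < 3 || window %% 2 == 0)
    stop("`window` must be an odd integer >= 3")
  median_filter_cpp(image, as.integer(window))
}

#' Export a bean label map as CSV
#'
#' Writes the integer instance-label matrix (0 = background) as a plain CSV
#' grid, one row per image row.
#'
#' @param lmap a [bean_label_map()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_label_map_csv <- function(lmap, path) {
  stopifnot(inherits(lmap, "bean_label_map"))
  utils::write.table(lmap$labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
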