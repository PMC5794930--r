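#' Spectra dataset
#'
#' The unit of all modelling: a spectra matrix `X` (`n_spectra x n_bands`),
#' integer class labels `y` in `1..K`, a provenance table `meta` with one row
#' per spectrum (`scene_id`, `bean_id`, and for pixel spectra `row`, `col`),
#' and the wavelength grid.  Rows of `X`, `y` and `meta` are aligned.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param y integer class labels, one per row of `X`.
#' @param meta data.frame with `nrow(X)` rows; columns `scene_id`,
#'   `bean_id`, and optionally `row`, `col`.
#' @param wavelengths numeric vector, `ncol(X)` entries.
#' @return An object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(X, y, meta, wavelengths) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (nrow(meta) != nrow(X)) stop("nrow(meta) must equal nrow(X)")
  if (length(wavelengths) != ncol(X))
    stop("length(wavelengths) must equal ncol(X)")
  if (length(y) && any(y < 1L)) stop("class labels must be integers >= 1")
  structure(list(X = X, y = y, meta = as.data.frame(meta),
                 wavelengths = as.numeric(wavelengths)),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  kind <- if (is_pixel_dataset(x)) "pixel" else "sample-average"
  cat(sprintf("<spectra_dataset> %d %s spectra x %d bands, %d class(es)\n",
              nrow(x$X), kind, ncol(x$X), length(unique(x$y))))
  invisible(x)
}

#' @export
#' @rdname spectra_dataset
#' @param ds a `spectra_dataset`.
is_pixel_dataset <- function(ds) all(c("row", "col") %in% names(ds$meta))

#' Bind spectra datasets row-wise
#' @param ... `spectra_dataset` objects on a common wavelength grid.
#' @return combined `spectra_dataset`.
#' @export
bind_spectra <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "spectra_dataset")) parts <- parts[[1]]
  wl <- parts[[1]]$wavelengths
  for (p in parts) stopifnot(identical(p$wavelengths, wl))
  spectra_dataset(do.call(rbind, lapply(parts, `[[`, "X")),
                  unlist(lapply(parts, `[[`, "y")),
                  do.call(rbind, lapply(parts, `[[`, "meta")),
                  wl)
}

#' Extract one spectrum per foreground pixel
#'
#' Walks the scene in row-major order (row outer, column inner) and collects
#' the reflectance spectrum, bean id and pixel coordinates (1-based) of every
#' foreground pixel.
#'
#' @param cube reflectance [hypercube()] (masked or maskable).
#' @param lmap [bean_label_map()].
#' @param class_label integer class assigned to every spectrum.
#' @param scene_id scene identifier recorded in the provenance table.
#' @return pixel-level [spectra_dataset()].
#' @export
extract_pixel_spectra <- function(cube, lmap, class_label, scene_id = 1L) {
  stopifnot(inherits(cube, "hypercube"), inherits(lmap, "bean_label_map"))
  d <- dim(cube$data)
  if (!identical(d[1:2], dim(lmap$mask))) stop("cube/mask shape mismatch")
  idx <- which(lmap$mask)  # column-major
  rr <- ((idx - 1L) %% d[1]) + 1L
  cc <- ((idx - 1L) %/% d[1]) + 1L
  ord <- order(rr, cc)     # row-major scan
  idx <- idx[ord]; rr <- rr[ord]; cc <- cc[ord]
  data <- cube$data
  dim(data) <- c(d[1] * d[2], d[3])
  X <- data[idx, , drop = FALSE]
  meta <- data.frame(scene_id = scene_id, bean_id = lmap$labels[idx],
                     row = rr, col = cc)
  spectra_dataset(X, rep(as.integer(class_label), length(idx)), meta,
                  cube$wavelengths)
}

#' Average pixel spectra within each bean
#'
#' Collapses a pixel-level dataset to one mean spectrum per (scene, bean)
#' instance — the conventional sample-average calibration unit.  Class labels
#' are inherited; pixel coordinates are dropped.
#'
#' @param pixels pixel-level [spectra_dataset()] (needs `bean_id`).
#' @return sample-average [spectra_dataset()], one row per bean, ordered by
#'   (scene_id, bean_id).
#' @export
average_by_bean <- function(pixels) {
  stopifnot(inherits(pixels, "spectra_dataset"))
  if (!"bean_id" %in% names(pixels$meta)) stop("`bean_id` missing from meta")
  key <- paste(pixels$meta$scene_id, pixels$meta$bean_id)
  lv <- unique(key[order(pixels$meta$scene_id, pixels$meta$bean_id)])
  grp <- factor(key, levels = lv)
  n <- as.vector(table(grp))
  A <- rowsum(pixels$X, grp) / n
  first <- match(levels(grp), key)
  meta <- data.frame(scene_id = pixels$meta$scene_id[first],
                     bean_id = pixels$meta$bean_id[first],
                     n_pixels = n)
  spectra_dataset(A, pixels$y[first], meta, pixels$wavelengths)
}

#' Write / read a spectra dataset as CSV
#'
#' Column layout: `scene_id, bean_id, row, col, y`, then one reflectance
#' column per wavelength (named `nm<wavelength>`).  Sample-average datasets
#' carry `NA` in `row`/`col`.
#'
#' @param ds a [spectra_dataset()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectra_dataset"))
  m <- ds$meta
  df <- data.frame(
    scene_id = m$scene_id, bean_id = m$bean_id,
    row = if ("row" %in% names(m)) m$row else NA_integer_,
    col = if ("col" %in% names(m)) m$col else NA_integer_,
    y = ds$y)
  spec <- as.data.frame(ds$X)
  names(spec) <- paste0("nm", format(ds$wavelengths, trim = TRUE))
  write.csv(cbind(df, spec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl_cols <- grep("^nm", names(df))
  wl <- as.numeric(sub("^nm", "", names(df)[wl_cols]))
  meta <- df[, c("scene_id", "bean_id", "row", "col"), drop = FALSE]
  if (all(is.na(meta$row))) meta <- meta[, c("scene_id", "bean_id")]
  spectra_dataset(as.matrix(df[, wl_cols, drop = FALSE]), df$y, meta, wl)
}
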