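#' Read an ENVI-style hyperspectral cube
#'
#' Parses an ASCII ENVI header (`key = value`, with `wavelength = {...}`) and
#' reads the companion binary cube.  Supported layouts are band-sequential
#' (`bsq`) and band-interleaved-by-line (`bil`); supported data types are 4
#' (32-bit float) and 5 (64-bit float), little or big endian.  The binary
#' file is located by replacing the header extension with `.img`, `.raw` or
#' `.dat`, or by the header's `data file` entry.
#'
#' @param header_path path to the `.hdr` file.
#' @return A [hypercube()].
#' @seealso [write_envi()]
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  hdr <- .parse_envi_header(header_path)
  for (key in c("samples", "lines", "bands"))
    if (is.null(hdr[[key]])) stop("ENVI header missing `", key, "`")
  if (is.null(hdr$wavelength))
    stop("ENVI header has no `wavelength` list; cannot build a hypercube")
  samples <- as.integer(hdr$samples); lines <- as.integer(hdr$lines)
  bands <- as.integer(hdr$bands)
  wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1]])
  if (length(wl) != bands)
    stop("header lists ", length(wl), " wavelengths for ", bands, " bands")
  interleave <- tolower(if (is.null(hdr$interleave)) "bsq" else hdr$interleave)
  if (!interleave %in% c("bsq", "bil"))
    stop("unsupported interleave `", hdr$interleave, "` (bsq and bil only)")
  dtype <- as.integer(if (is.null(hdr[["data type"]])) 5L else hdr[["data type"]])
  if (!dtype %in% c(4L, 5L)) stop("unsupported ENVI data type ", dtype)
  size <- if (dtype == 4L) 4L else 8L
  endian <- if (!is.null(hdr[["byte order"]]) && hdr[["byte order"]] == "1")
    "big" else "little"

  bin_path <- .envi_binary_path(header_path, hdr)
  n <- samples * lines * bands
  expect_bytes <- n * size
  if (file.info(bin_path)$size != expect_bytes)
    stop(sprintf("binary cube %s is %d bytes; header implies %d (%dx%dx%d, %d-byte)",
                 bin_path, file.info(bin_path)$size, expect_bytes,
                 lines, samples, bands, size))
  con <- file(bin_path, "rb"); on.exit(close(con))
  v <- readBin(con, "double", n = n, size = size, endian = endian)

  data <- if (interleave == "bsq") {
    # [band][line][sample], sample fastest
    aperm(array(v, c(samples, lines, bands)), c(2, 1, 3))
  } else {
    # bil: [line][band][sample]
    aperm(array(v, c(samples, bands, lines)), c(3, 1, 2))
  }
  meta <- hdr[setdiff(names(hdr), c("wavelength"))]
  hypercube(data, wl, meta)
}

#' Write an ENVI-style hyperspectral cube
#'
#' Writes `<stem>.hdr` (ASCII) and `<stem>.img` (binary, 64-bit IEEE floats,
#' little endian).  Round-trips with [read_envi()] bit-exactly for both
#' interleaves.
#'
#' @param cube a [hypercube()].
#' @param header_path destination header path (`.hdr`).
#' @param interleave `"bsq"` (default) or `"bil"`.
#' @return `header_path`, invisibly.
#' @export
write_envi <- function(cube, header_path, interleave = c("bsq", "bil")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  stem <- sub("\\.hdr$", "", header_path)
  bin_path <- paste0(stem, ".img")
  hdr <- c(
    "ENVI",
    "description = {hsibean export}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = {", paste(format(cube$wavelengths, trim = TRUE),
                                   collapse = ", "), "}"))
  writeLines(hdr, header_path)
  v <- if (interleave == "bsq") {
    as.vector(aperm(cube$data, c(2, 1, 3)))
  } else {
    as.vector(aperm(cube$data, c(2, 3, 1)))
  }
  con <- file(bin_path, "wb"); on.exit(close(con))
  writeBin(v, con, size = 8L, endian = "little")
  invisible(header_path)
}

.parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # re-join continuation lines of an open { ... } block
  out <- character(); buf <- ""
  for (ln in lines) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    if (lengths(regmatches(buf, gregexpr("\\{", buf))) ==
        lengths(regmatches(buf, gregexpr("\\}", buf)))) {
      out <- c(out, buf); buf <- ""
    }
  }
  if (nzchar(buf)) out <- c(out, buf)
  hdr <- list()
  for (ln in out) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- trimws(gsub("[{}]", "", val))
    hdr[[key]] <- val
  }
  hdr
}

.envi_binary_path <- function(header_path, hdr) {
  if (!is.null(hdr[["data file"]])) {
    p <- hdr[["data file"]]
    if (!file.exists(p))
      p <- file.path(dirname(header_path), basename(p))
    if (file.exists(p)) return(p)
  }
  stem <- sub("\\.hdr$", "", header_path)
  for (ext in c(".img", ".raw", ".dat", "")) {
    p <- paste0(stem, ext)
    if (file.exists(p) && p != header_path) return(p)
  }
  stop("no binary cube found next to ", header_path)
}
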