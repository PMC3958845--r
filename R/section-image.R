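#' Multi-channel FISH section image
#'
#' A `section_image` holds the co-registered probe channels of one biofilm
#' cryosection: a reference channel labelling all bacteria (conventionally
#' `"EUB338mix"`) plus one channel per specific probe (e.g. `"Nse1472"` for
#' AOB, `"Bfu613"` for anammox). Channels are 8-bit intensity matrices on a
#' common pixel grid.
#'
#' @param channels Named list of integer matrices with values in 0..255.
#'   All matrices must share the same dimensions.
#' @param pixel_size_um Side length of one pixel in micrometres (> 0).
#' @param depth_um Depth of the section into the carrier compartment, in
#'   micrometres (z >= 0).
#' @param compartment_id Optional identifier of the carrier compartment.
#'
#' @return An object of class `section_image`.
#' @export
section_image <- function(channels, pixel_size_um, depth_um = 0,
                          compartment_id = NA_character_) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("'channels' must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("every channel must be a matrix")
  d1 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d1), logical(1))))
    stop("all channels must share identical dimensions")
  channels <- lapply(channels, function(ch) {
    ch <- round(ch)
    if (anyNA(ch) || min(ch) < 0 || max(ch) > 255)
      stop("channel intensities must lie in [0, 255]")
    storage.mode(ch) <- "integer"
    ch
  })
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  if (!is.numeric(depth_um) || length(depth_um) != 1L || depth_um < 0)
    stop("'depth_um' must be a single non-negative number")
  structure(
    list(channels = channels,
         pixel_size_um = as.numeric(pixel_size_um),
         depth_um = as.numeric(depth_um),
         compartment_id = as.character(compartment_id)),
    class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<section_image> %d x %d px, %.4g um/px, depth %g um\n",
              d[1], d[2], x$pixel_size_um, x$depth_um))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (!is.na(x$compartment_id))
    cat("  compartment:", x$compartment_id, "\n")
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$channels[[1]])

#' Binary mask of probe-labelled biomass
#'
#' Thresholded (black-and-white) image of one channel, carrying its pixel
#' scale and a provenance note recording how it was produced.
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @param pixel_size_um Pixel size in micrometres.
#' @param provenance Character note (channel and threshold used).
#'
#' @return An object of class `binary_mask`: a logical matrix with
#'   attributes `pixel_size_um` and `provenance`.
#' @export
binary_mask <- function(mask, pixel_size_um = 1, provenance = "") {
  if (is.matrix(mask) && !is.logical(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask))
    stop("'mask' must be a logical matrix without NAs")
  structure(mask, pixel_size_um = as.numeric(pixel_size_um),
            provenance = as.character(provenance),
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, %d foreground px (%.1f%%)\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"),
              sum(x), 100 * mean(x)))
  p <- attr(x, "provenance")
  if (nzchar(p)) cat("  provenance:", p, "\n")
  invisible(x)
}

pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) 1 else ps
}

# strip class/attrs down to a plain logical matrix
as_plain_mask <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(x))
  m
}

#' Read and write section images
#'
#' A section image is stored as a multi-page 8-bit TIFF (one page per
#' channel, in channel order) together with a YAML sidecar
#' (`<prefix>.yml`) recording channel names, pixel size, depth and
#' compartment id. The round trip is bit-exact.
#'
#' @param image A `section_image`.
#' @param prefix Path prefix; `<prefix>.tif` and `<prefix>.yml` are written.
#' @return `write_section_image` returns `prefix` invisibly;
#'   `read_section_image` returns a `section_image`.
#' @export
write_section_image <- function(image, prefix) {
  stopifnot(inherits(image, "section_image"))
  pages <- lapply(image$channels, function(ch) ch / 255)
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 8L)
  meta <- list(channels = as.list(names(image$channels)),
               pixel_size_um = image$pixel_size_um,
               depth_um = image$depth_um,
               compartment_id = image$compartment_id)
  # precision 17: doubles survive the text round trip bit-exactly
  yaml::write_yaml(meta, paste0(prefix, ".yml"), precision = 17L)
  invisible(prefix)
}

#' @rdname write_section_image
#' @export
read_section_image <- function(prefix) {
  prefix <- sub("\\.tif$", "", prefix)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE, as.is = TRUE)
  meta <- yaml::read_yaml(paste0(prefix, ".yml"))
  names(pages) <- unlist(meta$channels)
  cid <- meta$compartment_id
  if (is.null(cid) || length(cid) == 0L) cid <- NA_character_
  section_image(pages, pixel_size_um = meta$pixel_size_um,
                depth_um = meta$depth_um, compartment_id = cid)
}

#' Read and write 16-bit label images
#'
#' Shell and segmentation label grids (non-negative integers < 65536) are
#' stored as single-page 16-bit TIFF. `NA` labels are stored as 65535.
#'
#' @param labels Integer matrix of labels.
#' @param path Output TIFF path.
#' @return `write_label_tiff` returns `path` invisibly; `read_label_tiff`
#'   the integer matrix (65535 mapped back to `NA`).
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels))
  lab <- labels
  lab[is.na(lab)] <- 65535L
  if (min(lab) < 0 || max(lab) > 65535)
    stop("labels must lie in [0, 65535]")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  lab <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(lab) <- "integer"
  lab[lab == 65535L] <- NA_integer_
  lab
}
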