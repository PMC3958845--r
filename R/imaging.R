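#' Fixed-cutoff intensity thresholding
#'
#' Binarizes an 8-bit channel at a fixed intensity cutoff. A pixel is
#' foreground iff its intensity is greater than or equal to the cutoff
#' (inclusive, so a cutoff of 30 keeps pixels at exactly 30). The standard
#' cutoff for homogenized-sample images is 30.
#'
#' @param channel Integer matrix of 8-bit intensities, or a
#'   `section_image` (then `which` names the channel).
#' @param cutoff Intensity cutoff in 0..255. Default 30.
#' @param which Channel name when `channel` is a `section_image`.
#' @param pixel_size_um Pixel size for a bare matrix input (ignored for a
#'   `section_image`, which carries its own).
#'
#' @return A [binary_mask].
#' @export
threshold_fixed <- function(channel, cutoff = 30, which = NULL,
                            pixel_size_um = 1) {
  if (inherits(channel, "section_image")) {
    if (is.null(which)) stop("'which' channel name required for a section_image")
    pixel_size_um <- channel$pixel_size_um
    channel <- channel$channels[[which]]
    if (is.null(channel)) stop("no channel named '", which, "'")
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 255)
    stop("'cutoff' must lie in [0, 255]")
  binary_mask(channel >= cutoff, pixel_size_um,
              sprintf("fixed threshold >= %g", cutoff))
}

# gradient magnitude by central differences (forward/backward at edges)
gradient_magnitude <- function(ch) {
  ch <- ch * 1.0
  nr <- nrow(ch); nc <- ncol(ch)
  up <- ch[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- ch[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  lf <- ch[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- ch[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  sqrt((dn - up)^2 + (rt - lf)^2) / 2
}

#' Robust automatic threshold selection (RATS)
#'
#' Gradient-weighted automatic thresholding: the threshold is the
#' gradient-magnitude-weighted mean intensity, `T = sum(w * I) / sum(w)`
#' with `w` the local gradient magnitude, so that pixels near edges —
#' where intensity crosses between background and foreground — dominate
#' the estimate. Foreground is intensity `>= T`. With `tile_px` set the
#' threshold is computed per square tile instead of globally (a local
#' variant for images with uneven illumination); tiles with zero gradient
#' fall back to the global threshold.
#'
#' @inheritParams threshold_fixed
#' @param tile_px Optional tile side (pixels) for tile-local thresholding.
#'
#' @return A [binary_mask] whose provenance records the threshold used.
#' @export
threshold_rats <- function(channel, which = NULL, pixel_size_um = 1,
                           tile_px = NULL) {
  if (inherits(channel, "section_image")) {
    if (is.null(which)) stop("'which' channel name required for a section_image")
    pixel_size_um <- channel$pixel_size_um
    channel <- channel$channels[[which]]
    if (is.null(channel)) stop("no channel named '", which, "'")
  }
  w <- gradient_magnitude(channel)
  sw <- sum(w)
  if (sw == 0)
    stop("flat image: zero gradient everywhere, RATS threshold undefined")
  t_global <- sum(w * channel) / sw
  if (is.null(tile_px)) {
    out <- binary_mask(channel >= t_global, pixel_size_um,
                       sprintf("RATS threshold %.3f", t_global))
    attr(out, "threshold") <- t_global
    return(out)
  }
  stopifnot(tile_px >= 2)
  mask <- matrix(FALSE, nrow(channel), ncol(channel))
  ri <- (seq_len(nrow(channel)) - 1L) %/% as.integer(tile_px)
  ci <- (seq_len(ncol(channel)) - 1L) %/% as.integer(tile_px)
  for (i in unique(ri)) for (j in unique(ci)) {
    rows <- which(ri == i); cols <- which(ci == j)
    wt <- w[rows, cols]; cht <- channel[rows, cols]
    tt <- if (sum(wt) > 0) sum(wt * cht) / sum(wt) else t_global
    mask[rows, cols] <- cht >= tt
  }
  binary_mask(mask, pixel_size_um,
              sprintf("RATS-local threshold (tile %d px, global %.3f)",
                      as.integer(tile_px), t_global))
}

# number of foreground pixels among the 8 neighbours of each pixel
count_neighbors8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  acc <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    acc <- acc + p[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  acc
}

#' Single-pass noise reduction
#'
#' Removes speckle from a binary mask in one pass: a foreground pixel is
#' retained iff its 8-neighbourhood contains at least
#' `min_nonzero_neighbors` foreground pixels (default 1, the standard
#' setting, which deletes isolated single pixels). Background pixels are
#' never changed. All retention decisions are made against the input mask,
#' not the partially-cleaned one.
#'
#' @param mask A [binary_mask] or logical matrix.
#' @param min_nonzero_neighbors Minimum foreground neighbours required.
#'
#' @return A [binary_mask].
#' @export
noise_reduce <- function(mask, min_nonzero_neighbors = 1) {
  ps <- pixel_size(mask)
  m <- as_plain_mask(mask)
  keep <- m & (count_neighbors8(m) >= min_nonzero_neighbors)
  binary_mask(keep, ps,
              sprintf("%s + noise reduction (>= %d neighbors)",
                      attr(mask, "provenance") %||% "", min_nonzero_neighbors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# area-mean block reduction by integer factor k; partial edge blocks are
# averaged over the pixels they actually contain
block_mean <- function(m, k) {
  ri <- (seq_len(nrow(m)) - 1L) %/% k
  ci <- (seq_len(ncol(m)) - 1L) %/% k
  s <- rowsum(m * 1.0, ri, reorder = TRUE)
  s <- t(rowsum(t(s), ci, reorder = TRUE))
  cnt <- outer(tabulate(ri + 1L), tabulate(ci + 1L))
  s / cnt
}

#' Reduce image resolution to a pixel-count budget
#'
#' Downscales every channel by the same integer factor so the total pixel
#' count does not exceed `target_mp` megapixels (1 megapixel = 2^20
#' pixels; biovolume fractions are conventionally measured after reduction
#' to 1 megapixel). Resampling is area-mean, so foreground area fractions
#' are conserved. Images already within budget are returned unchanged;
#' there is no upscaling. The pixel size is rescaled by the same factor.
#'
#' @param image A `section_image`, or a numeric matrix (then
#'   `pixel_size_um` applies).
#' @param target_mp Pixel budget in megapixels (default 1).
#' @param pixel_size_um Pixel size for bare-matrix input.
#'
#' @return Object of the same kind as the input, downscaled.
#' @export
downscale_to_megapixels <- function(image, target_mp = 1, pixel_size_um = 1) {
  budget <- target_mp * 2^20
  if (inherits(image, "section_image")) {
    d <- dim(image)
    if (prod(d) <= budget) return(image)
    k <- downscale_factor(d, budget)
    chans <- lapply(image$channels, function(ch)
      pmin(255L, pmax(0L, as.integer(round(block_mean(ch, k))))))
    chans <- lapply(chans, function(ch) {
      dim(ch) <- c(ceiling(d[1] / k), ceiling(d[2] / k)); ch
    })
    return(section_image(chans, image$pixel_size_um * k, image$depth_um,
                         image$compartment_id))
  }
  stopifnot(is.matrix(image))
  if (length(image) <= budget) return(image)
  k <- downscale_factor(dim(image), budget)
  out <- block_mean(image, k)
  attr(out, "pixel_size_um") <- pixel_size_um * k
  out
}

downscale_factor <- function(d, budget) {
  k <- 2L
  while (ceiling(d[1] / k) * ceiling(d[2] / k) > budget) k <- k + 1L
  k
}

#' Assemble image tiles into a wall-to-wall mosaic
#'
#' Places tiles on a common canvas at the given pixel offsets to produce a
#' single image covering the whole carrier compartment ("wall-to-wall").
#' Overlapping pixels are resolved by maximum intensity. All tiles must
#' share the same pixel size and channel set.
#'
#' @param tiles List of `section_image` tiles.
#' @param offsets_px Two-column matrix (or list of length-2 vectors) of
#'   zero-based (row, col) offsets, one per tile.
#'
#' @return A `section_image` covering the union of the placed tiles.
#' @export
assemble_tiles <- function(tiles, offsets_px) {
  stopifnot(length(tiles) >= 1L)
  if (is.list(offsets_px)) offsets_px <- do.call(rbind, offsets_px)
  offsets_px <- matrix(as.integer(offsets_px), ncol = 2L)
  stopifnot(nrow(offsets_px) == length(tiles))
  ps <- vapply(tiles, function(t) t$pixel_size_um, numeric(1))
  if (diff(range(ps)) > 1e-9 * ps[1])
    stop("tiles have mismatched pixel sizes: ",
         paste(unique(signif(ps, 8)), collapse = ", "))
  cn <- names(tiles[[1]]$channels)
  for (t in tiles)
    if (!identical(sort(names(t$channels)), sort(cn)))
      stop("tiles have mismatched channel sets")
  ext <- t(vapply(seq_along(tiles), function(i)
    offsets_px[i, ] + dim(tiles[[i]]), integer(2)))
  canvas_dim <- c(max(ext[, 1]), max(ext[, 2]))
  chans <- lapply(cn, function(nm) {
    canvas <- matrix(0L, canvas_dim[1], canvas_dim[2])
    for (i in seq_along(tiles)) {
      d <- dim(tiles[[i]])
      rows <- offsets_px[i, 1] + seq_len(d[1])
      cols <- offsets_px[i, 2] + seq_len(d[2])
      canvas[rows, cols] <- pmax(canvas[rows, cols],
                                 tiles[[i]]$channels[[nm]])
    }
    canvas
  })
  names(chans) <- cn
  section_image(chans, tiles[[1]]$pixel_size_um, tiles[[1]]$depth_um,
                tiles[[1]]$compartment_id)
}
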