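#' Measure compartment dimensions
#'
#' Fits the minimal-area bounding rectangle (rotating calipers over the
#' convex hull of the foreground) to the reference-channel signal and
#' reports the four side lengths, the two diagonals and the enclosed area
#' in micrometres. Pixel extent is accounted for by adding one pixel size
#' to each projected width, so an axis-aligned block of 600 px at 1 um/px
#' measures 600 um.
#'
#' @param reference Reference-channel [binary_mask]; non-empty, not
#'   degenerate (line-like).
#' @param depth_um Optional section depth recorded in the result.
#'
#' @return Object of class `compartment_geometry`: list with `sides`
#'   (length 4), `diagonals` (length 2), `area_um2`, `angle_deg` of the
#'   fitted rectangle, `depth_um`.
#' @export
measure_compartment <- function(reference, depth_um = NA_real_) {
  ps <- pixel_size(reference)
  m <- as_plain_mask(reference)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty reference mask")
  pts <- cbind(idx[, 1] * ps, idx[, 2] * ps)  # pixel centres, um
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) < 3L) stop("degenerate (line-like) mask")
  best <- NULL
  nh <- nrow(hull)
  for (i in seq_len(nh)) {
    e <- hull[i %% nh + 1L, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    w <- diff(range(pu)) + ps  # + ps: pixel centres -> pixel extents
    hgt <- diff(range(pv)) + ps
    a <- w * hgt
    if (is.null(best) || a < best$area) {
      best <- list(area = a, w = w, h = hgt,
                   angle = atan2(u[2], u[1]) * 180 / pi)
    }
  }
  if (is.null(best) || best$w < 2 * ps || best$h < 2 * ps)
    stop("degenerate (line-like) mask")
  diag_len <- sqrt(best$w^2 + best$h^2)
  structure(list(sides = c(best$w, best$h, best$w, best$h),
                 diagonals = c(diag_len, diag_len),
                 area_um2 = best$area,
                 angle_deg = best$angle,
                 depth_um = depth_um),
            class = "compartment_geometry")
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat(sprintf("<compartment_geometry> sides %s um, diagonals %s um, area %.4g um^2\n",
              paste(signif(x$sides, 5), collapse = "/"),
              paste(signif(x$diagonals, 5), collapse = "/"), x$area_um2))
  invisible(x)
}

#' Estimate shrinkage against physical carrier dimensions
#'
#' Compares the measured compartment dimensions of a section with the
#' carrier compartment dimensions determined independently (e.g. by
#' brightfield microscopy of the plastic carrier), giving a linear ratio
#' (measured side / reference side) and an area ratio. Ratios near 1
#' indicate that cryosectioning and hybridization introduced no
#' significant shrinkage; a 10% linear shrink yields an area ratio of
#' 0.81. Because the carrier compartment has a slight "waist" — its area
#' decreases with depth down to the mid-point — reference dimensions
#' should be supplied per depth.
#'
#' @param measured A `compartment_geometry` (or list of them for a stack).
#' @param reference_side_um Reference compartment side length (um) at the
#'   matching depth; recycled across a list input.
#' @param reference_area_um2 Reference area; defaults to
#'   `reference_side_um^2`.
#'
#' @return data.frame with `depth_um`, `linear_ratio`, `area_ratio`.
#' @export
estimate_shrinkage <- function(measured, reference_side_um,
                               reference_area_um2 = reference_side_um^2) {
  stopifnot(all(reference_side_um > 0), all(reference_area_um2 > 0))
  if (inherits(measured, "compartment_geometry")) measured <- list(measured)
  n <- length(measured)
  ref_side <- rep_len(reference_side_um, n)
  ref_area <- rep_len(reference_area_um2, n)
  data.frame(
    depth_um = vapply(measured, `[[`, numeric(1), "depth_um"),
    linear_ratio = vapply(seq_len(n), function(i)
      mean(measured[[i]]$sides) / ref_side[i], numeric(1)),
    area_ratio = vapply(seq_len(n), function(i)
      measured[[i]]$area_um2 / ref_area[i], numeric(1)))
}

# walk along a ray from `origin` in direction `dir` (unit vector, um),
# sampling the mask; returns extent (um) of contiguous foreground from the
# wall, skipping gaps narrower than channel_skip_um, capped at max_len
ray_thickness <- function(m, ps, origin, dir, max_len, channel_skip_um) {
  step <- ps / 2
  tt <- seq(0, max_len, by = step)
  r <- pmin(pmax(as.integer(round((origin[1] + tt * dir[1]) / ps)), 1L), nrow(m))
  c <- pmin(pmax(as.integer(round((origin[2] + tt * dir[2]) / ps)), 1L), ncol(m))
  fg <- m[cbind(r, c)]
  if (!any(fg)) return(c(extent = 0, flagged = TRUE))
  # leading gap wider than the channel width means no biomass at the wall
  first <- which(fg)[1]
  if ((first - 1L) * step > channel_skip_um) return(c(extent = 0, flagged = TRUE))
  extent_i <- first
  i <- first
  n <- length(fg)
  while (i < n) {
    nxt <- i + 1L
    if (fg[nxt]) {
      i <- nxt
      extent_i <- nxt
    } else {
      # measure the gap; skip it if narrower than the channel width
      gap_end <- nxt
      while (gap_end < n && !fg[gap_end + 1L]) gap_end <- gap_end + 1L
      gap_um <- (gap_end - i) * step
      if (gap_end < n && gap_um <= channel_skip_um) {
        i <- gap_end + 1L
        extent_i <- i
      } else break
    }
  }
  c(extent = tt[extent_i], flagged = FALSE)
}

#' Measure biofilm thickness at sides and corners
#'
#' Performs the eight standard thickness measurements on a
#' reference-channel image of a mature (wall-attached) biofilm: one along
#' the inward normal from the midpoint of each compartment side, and one
#' along the inward diagonal from each corner. Each measurement is the
#' extent of contiguous foreground from the wall; gaps narrower than
#' `channel_skip_um` (biofilm channels, default 10 um) are ignored. Side
#' measurements are capped at half the side length and corner
#' measurements at half the diagonal, so a fully filled compartment
#' measures side/2. Sides with no foreground at the wall report 0 and are
#' flagged.
#'
#' @param reference Reference-channel [binary_mask].
#' @param channel_skip_um Maximum gap width treated as a biofilm channel.
#' @param geometry Optional precomputed [measure_compartment()] result;
#'   computed from `reference` when absent.
#'
#' @return Object of class `thickness_measurements`: list with `side_um`
#'   (4), `corner_um` (4), `flagged` (logical 8), `side_mean`, `side_sd`,
#'   `corner_mean`, `corner_sd`.
#' @export
measure_thickness <- function(reference, channel_skip_um = 10,
                              geometry = NULL) {
  ps <- pixel_size(reference)
  m <- as_plain_mask(reference)
  if (is.null(geometry)) geometry <- measure_compartment(reference)
  # rectangle frame: centre and half-extents along the fitted axes
  idx <- which(m, arr.ind = TRUE)
  pts <- cbind(idx[, 1] * ps, idx[, 2] * ps)
  th <- geometry$angle_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  pu <- pts %*% u; pv <- pts %*% v
  ctr <- (c(min(pu), min(pv)) + c(max(pu), max(pv))) / 2
  centre <- ctr[1] * u + ctr[2] * v
  hw <- geometry$sides[1] / 2; hh <- geometry$sides[2] / 2
  side_mid <- list(centre + hw * u, centre - hw * u,
                   centre + hh * v, centre - hh * v)
  side_dir <- list(-u, u, -v, v)
  side_cap <- c(hw, hw, hh, hh)
  corners <- list(centre + hw * u + hh * v, centre + hw * u - hh * v,
                  centre - hw * u + hh * v, centre - hw * u - hh * v)
  half_diag <- sqrt(hw^2 + hh^2)
  side_res <- t(vapply(1:4, function(i)
    ray_thickness(m, ps, side_mid[[i]], side_dir[[i]], side_cap[i],
                  channel_skip_um), numeric(2)))
  corner_res <- t(vapply(1:4, function(i) {
    dir <- centre - unlist(corners[i])
    dir <- dir / sqrt(sum(dir^2))
    ray_thickness(m, ps, corners[[i]], dir, half_diag, channel_skip_um)
  }, numeric(2)))
  structure(list(side_um = side_res[, 1], corner_um = corner_res[, 1],
                 flagged = c(side_res[, 2], corner_res[, 2]) > 0,
                 side_mean = mean(side_res[, 1]),
                 side_sd = stats::sd(side_res[, 1]),
                 corner_mean = mean(corner_res[, 1]),
                 corner_sd = stats::sd(corner_res[, 1])),
            class = "thickness_measurements")
}

#' @export
print.thickness_measurements <- function(x, ...) {
  cat(sprintf("<thickness_measurements> sides %.0f +/- %.0f um, corners %.0f +/- %.0f um\n",
              x$side_mean, x$side_sd, x$corner_mean, x$corner_sd))
  if (any(x$flagged)) cat("  flagged measurements:", sum(x$flagged), "\n")
  invisible(x)
}
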