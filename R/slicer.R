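#' Slicer parameters
#'
#' Settings for multidirectional wall-distance stratification: virtual
#' slice (shell) thickness and the baseline-smoothing fraction applied to
#' the compartment boundary before distances are measured. The standard
#' analysis uses 100 um slices with 20% baseline smoothing.
#'
#' @param slice_thickness_um Shell thickness in micrometres (> 0).
#' @param baseline_smoothing_fraction Moving-average window for the
#'   boundary polygon, as a fraction of the compartment side length, in
#'   \[0, 1).
#' @return An object of class `slicer_params`.
#' @export
slicer_params <- function(slice_thickness_um = 100,
                          baseline_smoothing_fraction = 0.20) {
  stopifnot(slice_thickness_um > 0,
            baseline_smoothing_fraction >= 0,
            baseline_smoothing_fraction < 1)
  structure(list(slice_thickness_um = slice_thickness_um,
                 baseline_smoothing_fraction = baseline_smoothing_fraction),
            class = "slicer_params")
}

# boundary pixels: foreground with a 4-neighbour outside the mask (image
# border counts as outside)
boundary_pixels <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  inner <- p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)] &
    p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)]
  m & !inner
}

# Moore-neighbour boundary trace: ordered (row, col) contour of a simply
# connected mask
trace_contour <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  start <- which(m)[1]
  s <- c((start - 1L) %% nr + 1L, (start - 1L) %/% nr + 1L)
  # neighbours clockwise starting from W
  moves <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                 c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  inside <- function(p) p[1] >= 1L && p[1] <= nr && p[2] >= 1L && p[2] <= nc
  fg <- function(p) inside(p) && m[p[1], p[2]]
  contour <- list(s)
  cur <- s
  backtrack <- 1L  # direction index pointing to where we came from (W)
  repeat {
    found <- FALSE
    for (k in 0:7) {
      dir <- (backtrack - 1L + k) %% 8L + 1L
      cand <- cur + moves[dir, ]
      if (fg(cand)) {
        # next backtrack: the neighbour just before this one, seen from cand
        prev <- cur + moves[(dir - 2L) %% 8L + 1L, ]
        rel <- prev - cand
        backtrack <- which(moves[, 1] == rel[1] & moves[, 2] == rel[2])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == s)) break
    contour[[length(contour) + 1L]] <- cur
  }
  do.call(rbind, contour)
}

# circular moving average of contour coordinates over a window of w points
smooth_contour <- function(pts, w) {
  if (w <= 1L) return(pts)
  if (w %% 2L == 0L) w <- w + 1L
  n <- nrow(pts)
  if (w >= n) w <- if (n %% 2L == 1L) n else n - 1L
  kern <- rep(1 / w, w)
  sm <- function(v) {
    ext <- c(v[(n - (w %/% 2) + 1L):n], v, v[1:(w %/% 2)])
    as.numeric(stats::filter(ext, kern, sides = 2))[(w %/% 2 + 1L):(w %/% 2 + n)]
  }
  cbind(sm(pts[, 1]), sm(pts[, 2]))
}

# rasterize a closed polygon (fractional pixel coords) to pixel set
rasterize_polygon <- function(pts, nr, nc) {
  pts <- rbind(pts, pts[1, , drop = FALSE])
  out_r <- integer(0); out_c <- integer(0)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    n <- max(2L, ceiling(max(abs(b - a)) / 0.5) + 1L)
    tt <- seq(0, 1, length.out = n)
    out_r <- c(out_r, a[1] + tt * (b[1] - a[1]))
    out_c <- c(out_c, a[2] + tt * (b[2] - a[2]))
  }
  r <- pmin(pmax(as.integer(round(out_r)), 1L), nr)
  c <- pmin(pmax(as.integer(round(out_c)), 1L), nc)
  cbind(r, c)[!duplicated(cbind(r, c)), , drop = FALSE]
}

#' Label compartment pixels by wall-distance shell
#'
#' Multidirectional ("slicer") stratification of a wall-to-wall
#' compartment footprint. The compartment boundary is extracted, optionally
#' smoothed with a moving-average window spanning
#' `baseline_smoothing_fraction` of the side length (the smoothed baseline
#' suppresses pixel-scale roughness of the traced wall), and every
#' interior pixel is labelled with
#' `shell_index = floor(distance to baseline / slice_thickness_um)`.
#' Shell 0 is the 0-100 um band at the wall; shells partition the mask.
#' Distances are exact Euclidean distances to the nearest baseline pixel,
#' computed with a distance transform.
#'
#' @param compartment_mask [binary_mask] of the filled compartment
#'   footprint; must be simply connected.
#' @param params A [slicer_params].
#'
#' @return Object of class `shell_labels`: list with `labels` (integer
#'   matrix of shell indices, `NA` outside the footprint), `distance_um`,
#'   `shells` (data.frame: `shell_index`, `d_lo_um`, `d_hi_um`,
#'   `shell_area_um2`), `pixel_size_um`, `params`.
#' @export
wall_distance_shells <- function(compartment_mask, params = slicer_params()) {
  stopifnot(inherits(params, "slicer_params"))
  ps <- pixel_size(compartment_mask)
  m <- as_plain_mask(compartment_mask)
  if (!any(m)) stop("empty compartment mask")
  ncomp <- max(label_components8(m))
  if (ncomp != 1L)
    stop(sprintf("compartment mask has %d connected components; expected 1",
                 ncomp))
  holes <- count_holes(m)
  if (holes > 0L)
    stop(sprintf("compartment mask is not simply connected: %d hole(s)",
                 holes))
  nr <- nrow(m); nc <- ncol(m)
  if (params$baseline_smoothing_fraction > 0) {
    contour <- trace_contour(m)
    side_px <- nrow(contour) / 4  # square compartment: perimeter / 4
    w <- max(1L, round(params$baseline_smoothing_fraction * side_px))
    baseline <- rasterize_polygon(smooth_contour(contour, w), nr, nc)
    base_mask <- matrix(FALSE, nr, nc)
    base_mask[baseline] <- TRUE
  } else {
    base_mask <- boundary_pixels(m)
  }
  # distance of every pixel to the nearest baseline pixel
  dist_px <- EBImage::distmap(1 - base_mask)
  dist_um <- matrix(as.numeric(dist_px), nr, nc) * ps
  labels <- matrix(NA_integer_, nr, nc)
  labels[m] <- as.integer(floor(dist_um[m] / params$slice_thickness_um))
  idx <- sort(unique(labels[m]))
  # contiguous ranges; the innermost shell is truncated at the true maximum
  shells <- data.frame(
    shell_index = idx,
    d_lo_um = idx * params$slice_thickness_um,
    d_hi_um = (idx + 1) * params$slice_thickness_um)
  shells$d_hi_um[length(idx)] <- min(shells$d_hi_um[length(idx)],
                                     max(dist_um[m]))
  shells$shell_area_um2 <- vapply(idx, function(i)
    sum(labels == i, na.rm = TRUE) * ps^2, numeric(1))
  structure(list(labels = labels, distance_um = dist_um, shells = shells,
                 pixel_size_um = ps, params = params),
            class = "shell_labels")
}

# background components (4-connected) not touching the image border
count_holes <- function(m) {
  bg <- EBImage::bwlabel((!m) * 1)
  bg <- matrix(as.integer(round(bg)), nrow(m), ncol(m))
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  length(setdiff(unique(bg[bg > 0L]), border_labels))
}

#' @export
print.shell_labels <- function(x, ...) {
  cat(sprintf("<shell_labels> %d shells of %g um (smoothing %.0f%%)\n",
              nrow(x$shells), x$params$slice_thickness_um,
              100 * x$params$baseline_smoothing_fraction))
  print(x$shells, row.names = FALSE)
  invisible(x)
}

#' Per-shell biovolume fractions
#'
#' Relative population abundance in each virtual slice: within each shell,
#' the kept specific-probe area divided by the reference area. Shells
#' where the reference is empty are reported as missing (`NA` with
#' `missing = TRUE`), never as zero.
#'
#' @param shells A `shell_labels` from [wall_distance_shells()].
#' @param kept_objects `object_set` of artifact-filtered specific objects
#'   (or a [binary_mask] of the specific signal).
#' @param reference Reference-channel [binary_mask] on the same grid.
#' @param probe Probe name recorded in the output.
#'
#' @return Object of class `shell_profile`: data.frame with `shell_index`,
#'   `d_lo_um`, `d_hi_um`, `shell_area_um2`, `probe`, `fraction`,
#'   `missing`.
#' @export
shell_biovolume_profile <- function(shells, kept_objects, reference,
                                    probe = NA_character_) {
  stopifnot(inherits(shells, "shell_labels"))
  spec_mask <- if (inherits(kept_objects, "object_set"))
    object_union_mask(kept_objects) else as_plain_mask(kept_objects)
  if (!identical(dim(spec_mask), dim(shells$labels)))
    stop("specific mask and shells are on different grids")
  ref <- as_plain_mask(reference)
  lab <- shells$labels
  out <- shells$shells
  nb <- max(out$shell_index) + 1L
  ref_in <- tabulate(lab[ref & !is.na(lab)] + 1L, nbins = nb)[out$shell_index + 1L]
  spec_in <- tabulate(lab[spec_mask & !is.na(lab)] + 1L,
                      nbins = nb)[out$shell_index + 1L]
  out$probe <- probe
  out$fraction <- ifelse(ref_in > 0, spec_in / ref_in, NA_real_)
  out$missing <- ref_in == 0
  class(out) <- c("shell_profile", "data.frame")
  out
}

#' Aggregate shell profiles across sections
#'
#' Combines per-section shell profiles into per-shell mean biovolume
#' fractions with t-based 95% confidence intervals. `n` counts the
#' sections contributing a non-missing value to a shell and may shrink
#' for the deepest shells, which not every section reaches. Shells with a
#' single contributing section report the mean with an undefined
#' (flagged, `NA`) interval.
#'
#' @param profiles List of `shell_profile` data.frames.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return data.frame with `shell_index`, `d_lo_um`, `d_hi_um`, `probe`,
#'   `n`, `mean`, `ci_lo`, `ci_hi`.
#' @export
aggregate_shell_profiles <- function(profiles, conf_level = 0.95) {
  all <- do.call(rbind, lapply(profiles, as.data.frame))
  all <- all[!all$missing & !is.na(all$fraction), , drop = FALSE]
  key <- interaction(all$shell_index, all$probe, drop = TRUE)
  res <- do.call(rbind, lapply(split(all, key), function(g) {
    n <- nrow(g)
    m <- mean(g$fraction)
    if (n >= 2L) {
      half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1L) *
        stats::sd(g$fraction) / sqrt(n)
      ci <- c(m - half, m + half)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(shell_index = g$shell_index[1],
               d_lo_um = min(g$d_lo_um), d_hi_um = max(g$d_hi_um),
               probe = g$probe[1], n = n, mean = m,
               ci_lo = ci[1], ci_hi = ci[2],
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$probe, res$shell_index), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export shell profiles as CSV
#'
#' @param profiles A `shell_profile`, list of them, or aggregated table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_shell_profiles <- function(profiles, path) {
  if (inherits(profiles, "data.frame")) profiles <- list(profiles)
  tbl <- do.call(rbind, lapply(profiles, as.data.frame))
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
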