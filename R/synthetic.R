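#' Target-fraction profile helpers
#'
#' Constructors for the target biovolume-fraction profiles used by
#' [synthetic_config()]. Profiles are functions of section depth `z` (um)
#' and wall distance `d` (um), both vectorized.
#'
#' * `constant_profile(p)` — `p` everywhere.
#' * `linear_depth_profile(from, to, z_from, z_to)` — linear in depth
#'   between `z_from` and `z_to`, clamped outside; wall-independent.
#' * `ramp_depth_profile(level, z_start, z_end)` — 0 above `z_start`,
#'   rising linearly to `level` at `z_end`, constant below (a population
#'   that only establishes below a threshold depth).
#' * `wall_modulated_profile(depth_fn, at_wall, at_center, max_distance)`
#'   — multiplies a depth profile by a linear wall-distance factor running
#'   from `at_wall` (d = 0) to `at_center` (d >= max_distance), for
#'   populations concentrated near (or away from) the compartment wall.
#'
#' @param p,from,to,level Target fractions in \[0, 1\].
#' @param z_from,z_to,z_start,z_end Depth breakpoints (um).
#' @param depth_fn A depth profile `function(z, d)`.
#' @param at_wall,at_center Multipliers at the wall and at the centre.
#' @param max_distance Wall distance (um) at which `at_center` is reached.
#' @return A vectorized `function(z, d)`.
#' @name profiles
NULL

#' @rdname profiles
#' @export
constant_profile <- function(p) {
  force(p)
  function(z, d) rep_len(p, max(length(z), length(d)))
}

#' @rdname profiles
#' @export
linear_depth_profile <- function(from, to, z_from, z_to) {
  force(from); force(to); force(z_from); force(z_to)
  function(z, d) {
    t <- pmin(pmax((z - z_from) / (z_to - z_from), 0), 1)
    rep_len(from + t * (to - from), max(length(z), length(d)))
  }
}

#' @rdname profiles
#' @export
ramp_depth_profile <- function(level, z_start, z_end) {
  force(level); force(z_start); force(z_end)
  function(z, d) {
    t <- pmin(pmax((z - z_start) / (z_end - z_start), 0), 1)
    rep_len(level * t, max(length(z), length(d)))
  }
}

#' @rdname profiles
#' @export
wall_modulated_profile <- function(depth_fn, at_wall, at_center,
                                   max_distance) {
  force(depth_fn); force(at_wall); force(at_center); force(max_distance)
  function(z, d) {
    t <- pmin(pmax(d / max_distance, 0), 1)
    depth_fn(z, d) * (at_wall + t * (at_center - at_wall))
  }
}

#' Configuration of the synthetic section-image generator
#'
#' Describes a synthetic stack of FISH section images of one square MBBR
#' carrier compartment, with known ground truth. The defaults emulate a
#' mature nitritation-anammox biofilm: a ~1 mm square compartment imaged
#' at 3.30 px/um, sections every 20 um down to 820 um (41 sections), AOB
#' decreasing linearly from 0.40 at the surface to 0.05 at 800 um,
#' anammox absent above 180 um and rising to 0.30 at 400 um, biomass
#' areal density rising with depth to 400 um, microcolony clusters of
#' varying size, colony placement densified toward the corners (biofilm
#' thicker in corners than on sides), autofluorescent artifacts appearing
#' identically in both specific channels, and isolated-pixel speckle.
#'
#' Foreground intensities are drawn around mean 180 (sd 30) and
#' background around mean 10 on the 8-bit scale, straddling the standard
#' threshold cutoff of 30.
#'
#' @param compartment_side_um Compartment side length (um).
#' @param pixel_size_um Pixel size (um/px); default 1/3.30.
#' @param grid_size_px Image side (px); default the smallest grid
#'   covering the compartment. Must satisfy
#'   `grid_size_px * pixel_size_um >= compartment_side_um`.
#' @param section_depths_um Depths (um) of the sections to generate.
#' @param aob_profile,amx_profile Target biovolume-fraction profiles
#'   `function(z, d)` for AOB (Nse1472) and anammox (Bfu613); see
#'   [profiles].
#' @param other_bacteria_fraction Minimum fraction of biomass labelled by
#'   the reference probe only, as `function(z)`. Colony classes partition
#'   the biomass with P(AOB) and P(anammox) given by the profiles and all
#'   remaining probability on "other"; this field enters the
#'   `aob + amx + other <= 1` validation.
#' @param biomass_coverage Target areal density (biomass area /
#'   compartment area) as `function(z)`.
#' @param colony_radius_um `c(mean, sd)` of colony radii (um).
#' @param corner_thickening_factor >= 1; colony placement density
#'   multiplier at the compartment corners.
#' @param artifact_rate Expected autofluorescent objects per section
#'   (Poisson).
#' @param speckle_rate Expected isolated foreground pixels per 10^4
#'   pixels in each specific channel.
#' @param foreground_mean,foreground_sd,background_mean,background_sd
#'   Intensity model on the 8-bit scale.
#' @param edge_blur_px Gaussian blur sigma (px) applied to each rendered
#'   channel (colony edges are not perfectly sharp); 0 disables.
#' @param seed Integer seed; a fixed seed makes the stack bit-identical.
#'
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(compartment_side_um = 1000,
                             pixel_size_um = 1 / 3.30,
                             grid_size_px = ceiling(compartment_side_um /
                                                      pixel_size_um),
                             section_depths_um = seq(20, 820, by = 20),
                             aob_profile = linear_depth_profile(0.40, 0.05,
                                                                0, 800),
                             amx_profile = ramp_depth_profile(0.30, 180, 400),
                             other_bacteria_fraction = function(z)
                               rep_len(0.25, length(z)),
                             biomass_coverage = function(z)
                               0.35 + 0.20 * pmin(z, 400) / 400,
                             colony_radius_um = c(mean = 12, sd = 4),
                             corner_thickening_factor = 336 / 235,
                             artifact_rate = 5,
                             speckle_rate = 2,
                             foreground_mean = 180, foreground_sd = 30,
                             background_mean = 10, background_sd = 3,
                             edge_blur_px = 0.7,
                             seed = 1L) {
  cfg <- structure(
    list(compartment_side_um = compartment_side_um,
         pixel_size_um = pixel_size_um,
         grid_size_px = as.integer(grid_size_px),
         section_depths_um = section_depths_um,
         aob_profile = aob_profile,
         amx_profile = amx_profile,
         other_bacteria_fraction = other_bacteria_fraction,
         biomass_coverage = biomass_coverage,
         colony_radius_um = colony_radius_um,
         corner_thickening_factor = corner_thickening_factor,
         artifact_rate = artifact_rate,
         speckle_rate = speckle_rate,
         foreground_mean = foreground_mean, foreground_sd = foreground_sd,
         background_mean = background_mean, background_sd = background_sd,
         edge_blur_px = edge_blur_px,
         seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$compartment_side_um > 0, cfg$pixel_size_um > 0,
            all(cfg$section_depths_um >= 0),
            cfg$corner_thickening_factor >= 1,
            cfg$artifact_rate >= 0, cfg$speckle_rate >= 0,
            cfg$edge_blur_px >= 0)
  if (cfg$grid_size_px * cfg$pixel_size_um < cfg$compartment_side_um -
      1e-9 * cfg$compartment_side_um)
    stop("grid_size_px x pixel_size_um must cover compartment_side_um")
  zs <- cfg$section_depths_um
  ds <- seq(0, cfg$compartment_side_um / 2, length.out = 26)
  for (z in zs) {
    a <- cfg$aob_profile(rep(z, length(ds)), ds)
    m <- cfg$amx_profile(rep(z, length(ds)), ds)
    o <- rep_len(cfg$other_bacteria_fraction(z), length(ds))
    cov <- cfg$biomass_coverage(z)
    if (any(a < 0 | a > 1) || any(m < 0 | m > 1) || any(o < 0 | o > 1) ||
        cov < 0 || cov > 1)
      stop(sprintf("profile outside [0,1] at z = %g um", z))
    bad <- which(a + m + o > 1 + 1e-9)
    if (length(bad))
      stop(sprintf(
        "aob + amx + other = %.3f > 1 at (z = %g um, wall distance = %g um)",
        (a + m + o)[bad[1]], z, ds[bad[1]]))
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %g um compartment, %d px grid (%.4g um/px), %d sections, seed %d\n",
    x$compartment_side_um, x$grid_size_px, x$pixel_size_um,
    length(x$section_depths_um), x$seed))
  invisible(x)
}

# analytic wall distance (um) of pixel centres; negative outside the
# compartment footprint
wall_distance_grid <- function(cfg) {
  ps <- cfg$pixel_size_um
  n <- cfg$grid_size_px
  xy <- (seq_len(n) - 0.5) * ps
  dx <- pmin(xy, cfg$compartment_side_um - xy)
  outer(dx, dx, pmin)
}

colony_mean_area <- function(cfg) {
  r <- cfg$colony_radius_um
  pi * (r[["mean"]]^2 + r[["sd"]]^2)
}

# draw colony centres: interior points (corner-weighted when the
# thickening factor exceeds 1) plus a row along the walls so the biomass
# reaches the compartment boundary, as attached biofilm does
draw_colony_centers <- function(cfg, n_interior) {
  side <- cfg$compartment_side_um
  ctf <- cfg$corner_thickening_factor
  if (n_interior > 0) {
    if (ctf > 1) {
      m <- ceiling(n_interior * ctf * 1.3)
      x <- stats::runif(m, 0, side); y <- stats::runif(m, 0, side)
      cx <- pmin(x, side - x); cy <- pmin(y, side - y)
      s_corner <- sqrt(cx^2 + cy^2)
      w <- 1 + (ctf - 1) * exp(-(s_corner / (side / 6))^2)
      keep <- stats::runif(m) < w / max(w)
      x <- x[keep][seq_len(min(n_interior, sum(keep)))]
      y <- y[keep][seq_len(min(n_interior, sum(keep)))]
      short <- n_interior - length(x)
      if (short > 0) {
        x <- c(x, stats::runif(short, 0, side))
        y <- c(y, stats::runif(short, 0, side))
      }
    } else {
      x <- stats::runif(n_interior, 0, side)
      y <- stats::runif(n_interior, 0, side)
    }
  } else {
    x <- numeric(0); y <- numeric(0)
  }
  # wall-lining colonies, evenly spaced with jitter
  spacing <- 1.5 * cfg$colony_radius_um[["mean"]]
  n_wall_side <- max(2L, ceiling(side / spacing))
  t <- (seq_len(n_wall_side) - 0.5) / n_wall_side * side +
    stats::runif(n_wall_side, -spacing / 4, spacing / 4)
  t <- pmin(pmax(t, 0), side)
  wx <- c(t, t, rep(0, n_wall_side), rep(side, n_wall_side))
  wy <- c(rep(0, n_wall_side), rep(side, n_wall_side), t, t)
  list(x = c(x, wx), y = c(y, wy), n_wall = 4L * n_wall_side)
}

# paint filled discs into an integer label matrix (later discs overwrite)
paint_discs <- function(lab, cfg, x, y, r, value) {
  ps <- cfg$pixel_size_um
  n <- cfg$grid_size_px
  side <- cfg$compartment_side_um
  for (k in seq_along(x)) {
    i0 <- max(1L, floor((x[k] - r[k]) / ps))
    i1 <- min(n, ceiling((x[k] + r[k]) / ps + 1))
    j0 <- max(1L, floor((y[k] - r[k]) / ps))
    j1 <- min(n, ceiling((y[k] + r[k]) / ps + 1))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    px <- (ii - 0.5) * ps; py <- (jj - 0.5) * ps
    inside <- outer((px - x[k])^2, (py - y[k])^2, `+`) <= r[k]^2
    # clip to the compartment footprint
    inside <- inside & outer(px >= 0 & px <= side, py >= 0 & py <= side, `&`)
    if (any(inside)) {
      block <- lab[ii, jj, drop = FALSE]
      block[inside] <- value[k]
      lab[ii, jj] <- block
    }
  }
  lab
}

draw_radii <- function(cfg, n) {
  r <- abs(stats::rnorm(n, cfg$colony_radius_um[["mean"]],
                        cfg$colony_radius_um[["sd"]]))
  pmax(r, 1.2 * cfg$pixel_size_um)
}

# class probabilities at colony centres -> 1 AOB, 2 anammox, 3 other
draw_classes <- function(cfg, z, x, y) {
  side <- cfg$compartment_side_um
  d <- pmax(pmin(pmin(x, side - x), pmin(y, side - y)), 0)
  pa <- cfg$aob_profile(rep(z, length(d)), d)
  pm <- cfg$amx_profile(rep(z, length(d)), d)
  u <- stats::runif(length(d))
  ifelse(u < pa, 1L, ifelse(u < pa + pm, 2L, 3L))
}

# draw one artifact disc at a position whose (margin-expanded) footprint
# is free of existing labels; up to 50 attempts, NULL if space is too tight
place_clear_disc <- function(lab, cfg, margin_px = 2L,
                             radius_range_um = c(3, 8)) {
  n <- cfg$grid_size_px
  for (try in 1:50) {
    x <- stats::runif(1, 0, cfg$compartment_side_um)
    y <- stats::runif(1, 0, cfg$compartment_side_um)
    r <- stats::runif(1, radius_range_um[1], radius_range_um[2])
    disc <- paint_discs(matrix(0L, n, n), cfg, x, y, r, 1L)
    idx <- which(disc == 1L)
    if (!length(idx)) next
    ij <- arrayInd(idx, c(n, n))
    i0 <- max(1L, min(ij[, 1]) - margin_px)
    i1 <- min(n, max(ij[, 1]) + margin_px)
    j0 <- max(1L, min(ij[, 2]) - margin_px)
    j1 <- min(n, max(ij[, 2]) + margin_px)
    if (all(lab[i0:i1, j0:j1] == 0L)) return(idx)
  }
  NULL
}

render_channel <- function(fg_mask, cfg) {
  n <- cfg$grid_size_px
  img <- matrix(stats::rnorm(n * n, cfg$background_mean, cfg$background_sd),
                n, n)
  nfg <- sum(fg_mask)
  if (nfg > 0)
    img[fg_mask] <- stats::rnorm(nfg, cfg$foreground_mean, cfg$foreground_sd)
  if (cfg$edge_blur_px > 0)
    img <- EBImage::gblur(img, sigma = cfg$edge_blur_px)
  matrix(pmin(pmax(round(img), 0), 255), n, n)
}

add_speckle <- function(img, cfg) {
  n2 <- length(img)
  k <- stats::rpois(1, n2 * cfg$speckle_rate / 1e4)
  if (k > 0)
    img[sample.int(n2, k)] <- round(pmin(pmax(
      stats::rnorm(k, cfg$foreground_mean, cfg$foreground_sd), 0), 255))
  img
}

#' Generate a synthetic compartment section stack with ground truth
#'
#' Renders one multi-channel section image per entry of
#' `section_depths_um`. Biomass is laid down as filled microcolony discs
#' (interior placement, corner-weighted, plus a wall-lining row so the
#' biofilm reaches the compartment walls); each colony is assigned a
#' class — AOB, anammox or other — with probabilities given by the target
#' profiles at its position. The reference channel (`EUB338mix`) covers
#' the union of all colonies; the specific channels (`Nse1472`, `Bfu613`)
#' cover their class only, plus planted autofluorescent artifacts that
#' appear with identical footprints in both specific channels (and not in
#' the reference). Isolated-pixel speckle is added to the specific
#' channels after rendering.
#'
#' Ground-truth label masks (1 AOB, 2 anammox, 3 other, 4 artifact; the
#' classes are mutually exclusive, later-painted colonies owning shared
#' pixels) are returned alongside, with exact per-depth and per-shell
#' fractions recomputed from the masks by pixel counting.
#'
#' @param config A [synthetic_config()].
#' @param truth_slice_um Shell thickness used for the ground-truth
#'   per-shell fractions (default 100).
#'
#' @return Object of class `synthetic_stack`: list with `sections` (list
#'   of [section_image]), `truth` (list: `labels`, `artifacts` (pixel
#'   index sets per section), `depth_fractions`, `shell_fractions`), and
#'   `config`.
#' @export
generate_compartment_stack <- function(config, truth_slice_um = 100) {
  validate_synthetic_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$grid_size_px
  dgrid <- wall_distance_grid(cfg)
  inside <- dgrid >= 0
  shell_grid <- matrix(NA_integer_, n, n)
  shell_grid[inside] <- as.integer(floor(dgrid[inside] / truth_slice_um))
  sections <- vector("list", length(cfg$section_depths_um))
  labels <- vector("list", length(cfg$section_depths_um))
  artifacts <- vector("list", length(cfg$section_depths_um))
  mean_area <- colony_mean_area(cfg)
  for (si in seq_along(cfg$section_depths_um)) {
    z <- cfg$section_depths_um[si]
    cov <- cfg$biomass_coverage(z)
    lab <- matrix(0L, n, n)
    art_idx <- integer(0)
    if (cov > 0) {
      spacing <- 1.5 * cfg$colony_radius_um[["mean"]]
      n_wall <- 4L * max(2L, ceiling(cfg$compartment_side_um / spacing))
      n_int <- max(0L, round((cov * cfg$compartment_side_um^2 -
                                n_wall * mean_area / 2) / mean_area))
      ctr <- draw_colony_centers(cfg, n_int)
      r <- draw_radii(cfg, length(ctr$x))
      cls <- draw_classes(cfg, z, ctr$x, ctr$y)
      ord <- sample.int(length(ctr$x))
      lab <- paint_discs(lab, cfg, ctr$x[ord], ctr$y[ord], r[ord], cls[ord])
    }
    # autofluorescent artifacts: identical footprint in both specific
    # channels, absent from the reference; placed clear of biomass (the
    # typical mineral/debris particles sit in voids, and contact would
    # merge them with genuine objects under 8-connectivity)
    if (cfg$artifact_rate > 0) {
      na <- stats::rpois(1, cfg$artifact_rate)
      for (k in seq_len(na)) {
        placed <- place_clear_disc(lab, cfg, margin_px = 2L)
        if (is.null(placed)) next
        lab[placed] <- 4L
        art_idx <- c(art_idx, placed)
      }
    }
    eub_fg <- lab %in% 1:3; dim(eub_fg) <- dim(lab)
    nse_fg <- lab == 1L | lab == 4L
    bfu_fg <- lab == 2L | lab == 4L
    chans <- list(
      EUB338mix = render_channel(eub_fg, cfg),
      Nse1472 = add_speckle(render_channel(nse_fg, cfg), cfg),
      Bfu613 = add_speckle(render_channel(bfu_fg, cfg), cfg))
    sections[[si]] <- section_image(chans, cfg$pixel_size_um, z,
                                    compartment_id = "synthetic")
    labels[[si]] <- lab
    artifacts[[si]] <- art_idx
  }
  truth <- list(labels = labels, artifacts = artifacts)
  truth$depth_fractions <- truth_depth_fractions(cfg, labels)
  truth$shell_fractions <- truth_shell_fractions(cfg, labels, shell_grid)
  structure(list(sections = sections, truth = truth, config = cfg),
            class = "synthetic_stack")
}

truth_depth_fractions <- function(cfg, labels) {
  do.call(rbind, lapply(seq_along(labels), function(si) {
    lab <- labels[[si]]
    bio <- sum(lab == 1L | lab == 2L | lab == 3L)
    data.frame(depth_um = cfg$section_depths_um[si],
               probe = c("Nse1472", "Bfu613"),
               fraction = if (bio > 0)
                 c(sum(lab == 1L), sum(lab == 2L)) / bio
               else c(NA_real_, NA_real_),
               biomass_px = bio)
  }))
}

truth_shell_fractions <- function(cfg, labels, shell_grid) {
  do.call(rbind, lapply(seq_along(labels), function(si) {
    lab <- labels[[si]]
    bio <- lab == 1L | lab == 2L | lab == 3L
    sh <- shell_grid[bio]
    if (!length(sh)) return(NULL)
    nb <- max(shell_grid, na.rm = TRUE) + 1L
    tot <- tabulate(sh + 1L, nbins = nb)
    aob <- tabulate(shell_grid[lab == 1L] + 1L, nbins = nb)
    amx <- tabulate(shell_grid[lab == 2L] + 1L, nbins = nb)
    idx <- which(tot > 0) - 1L
    data.frame(depth_um = cfg$section_depths_um[si],
               shell_index = rep(idx, 2L),
               probe = rep(c("Nse1472", "Bfu613"), each = length(idx)),
               fraction = c(aob[idx + 1L] / tot[idx + 1L],
                            amx[idx + 1L] / tot[idx + 1L]))
  }))
}

#' @export
print.synthetic_stack <- function(x, ...) {
  cat(sprintf("<synthetic_stack> %d sections, %d px grid, seed %d\n",
              length(x$sections), x$config$grid_size_px, x$config$seed))
  invisible(x)
}

#' Analytic expected profiles of a synthetic configuration
#'
#' Expected biovolume fraction per depth and per wall-distance shell,
#' computed by integrating the configuration's target-fraction functions
#' over the pixel grid (uniform area weights) — never from rendered
#' images. Used as the independent expectation in parameter-recovery
#' tests.
#'
#' @param config A [synthetic_config()].
#' @param slice_thickness_um Shell thickness for the per-shell
#'   expectation (default 100).
#'
#' @return List with `depth` (data.frame: `depth_um`, `probe`,
#'   `fraction`) and `shell` (data.frame: `depth_um`, `shell_index`,
#'   `probe`, `fraction`).
#' @export
expected_profile <- function(config, slice_thickness_um = 100) {
  validate_synthetic_config(config)
  dgrid <- wall_distance_grid(config)
  d <- dgrid[dgrid >= 0]
  sh <- as.integer(floor(d / slice_thickness_um))
  nb <- max(sh) + 1L
  cnt <- tabulate(sh + 1L, nbins = nb)
  depth <- NULL; shell <- NULL
  for (z in config$section_depths_um) {
    pa <- config$aob_profile(rep(z, length(d)), d)
    pm <- config$amx_profile(rep(z, length(d)), d)
    depth <- rbind(depth, data.frame(
      depth_um = z, probe = c("Nse1472", "Bfu613"),
      fraction = c(mean(pa), mean(pm))))
    sa <- rowsum(pa, sh)[, 1] / cnt
    sm <- rowsum(pm, sh)[, 1] / cnt
    shell <- rbind(shell, data.frame(
      depth_um = z, shell_index = rep(0:(nb - 1L), 2L),
      probe = rep(c("Nse1472", "Bfu613"), each = nb),
      fraction = c(sa, sm)))
  }
  list(depth = depth, shell = shell)
}

#' Plant autofluorescent artifacts into a section image
#'
#' Adds a Poisson-distributed number of bright objects with identical
#' footprints to both specific channels (`Nse1472` and `Bfu613`) of a
#' section image, leaving the reference channel untouched — the signature
#' of autofluorescent particles, which the dual-channel removal step must
#' eliminate.
#'
#' @param image A `section_image` with both specific channels.
#' @param rate Expected number of artifacts (Poisson mean, >= 0).
#' @param seed Integer seed.
#' @param radius_um Range of artifact radii (um).
#' @param intensity Artifact intensity (8-bit).
#'
#' @return List with `image` (modified `section_image`) and `footprints`
#'   (list of pixel index vectors, one per planted object).
#' @export
plant_artifacts <- function(image, rate, seed = 1L, radius_um = c(3, 8),
                            intensity = 200) {
  stopifnot(inherits(image, "section_image"))
  if (rate < 0) stop("artifact rate must be >= 0")
  if (!all(c("Nse1472", "Bfu613") %in% names(image$channels)))
    stop("image must have both specific channels (Nse1472, Bfu613)")
  set.seed(seed)
  d <- dim(image)
  ps <- image$pixel_size_um
  na <- stats::rpois(1, rate)
  footprints <- list()
  if (na > 0) {
    cfg <- list(pixel_size_um = ps, grid_size_px = d[1],
                compartment_side_um = d[2] * ps)
    # avoid existing specific signal so planted objects stay separable
    occupied <- (image$channels$Nse1472 >= 30 |
                   image$channels$Bfu613 >= 30) * 1L
    for (k in seq_len(na)) {
      idx <- place_clear_disc(occupied, cfg, margin_px = 2L,
                              radius_range_um = radius_um)
      if (is.null(idx)) next
      occupied[idx] <- 1L
      footprints[[length(footprints) + 1L]] <- idx
      for (ch in c("Nse1472", "Bfu613"))
        image$channels[[ch]][idx] <- as.integer(intensity)
    }
  }
  list(image = image, footprints = footprints)
}

#' Render a deterministic biofilm ring mask
#'
#' Noise-free reference mask of a mature, wall-attached biofilm band with
#' prescribed thicknesses: `side_thickness_um` measured along the inward
#' normal at the side midpoints and `corner_thickness_um` along the
#' inward diagonal at the corners. The band is the union of the
#' wall-distance band (`d <= side_thickness_um`) with quarter-discs of
#' radius `corner_thickness_um` around the corners, so both planted
#' values are recovered exactly by [measure_thickness()]. Used as a
#' deterministic geometry fixture.
#'
#' @param side_um Compartment side (um).
#' @param side_thickness_um Biofilm thickness on the sides (um).
#' @param corner_thickness_um Biofilm thickness at the corners, measured
#'   along the diagonal (um); must be >= `side_thickness_um`.
#' @param pixel_size_um Pixel size (um/px).
#' @param scale Linear scale factor applied to the rendered geometry
#'   (e.g. 0.9 for a 10% linear shrink); the mask stays on the same grid.
#'
#' @return A [binary_mask].
#' @export
render_biofilm_ring <- function(side_um = 1000, side_thickness_um = 235,
                                corner_thickness_um = 336,
                                pixel_size_um = 1, scale = 1) {
  stopifnot(corner_thickness_um >= side_thickness_um, scale > 0, scale <= 1)
  n <- ceiling(side_um / pixel_size_um)
  xy <- (seq_len(n) - 0.5) * pixel_size_um
  side <- side_um * scale
  ts <- side_thickness_um * scale
  tc <- corner_thickness_um * scale
  off <- (side_um - side) / 2  # centre the scaled compartment on the grid
  x <- xy - off
  inside <- x >= 0 & x <= side
  dx <- pmin(x, side - x)
  wall_d <- outer(dx, dx, pmin)
  in2 <- outer(inside, inside, `&`)
  ring <- in2 & wall_d <= ts
  cx <- pmin(x, side - x)  # distance to nearest wall per axis
  corner_d <- sqrt(outer(cx^2, cx^2, `+`))
  ring <- ring | (in2 & corner_d <= tc)
  binary_mask(ring, pixel_size_um, "synthetic biofilm ring")
}

# colony-sampling model of per-section fractions: same colony counts,
# positions and class draws as the renderer, but fractions are computed
# from analytic disc areas instead of rasterized images
sample_depth_fractions <- function(cfg) {
  set.seed(cfg$seed)
  mean_area <- colony_mean_area(cfg)
  out <- lapply(cfg$section_depths_um, function(z) {
    cov <- cfg$biomass_coverage(z)
    if (cov <= 0)
      return(data.frame(depth_um = z, aob = NA_real_, amx = NA_real_))
    spacing <- 1.5 * cfg$colony_radius_um[["mean"]]
    n_wall <- 4L * max(2L, ceiling(cfg$compartment_side_um / spacing))
    n_int <- max(0L, round((cov * cfg$compartment_side_um^2 -
                              n_wall * mean_area / 2) / mean_area))
    ctr <- draw_colony_centers(cfg, n_int)
    r <- draw_radii(cfg, length(ctr$x))
    cls <- draw_classes(cfg, z, ctr$x, ctr$y)
    a <- pi * r^2
    # wall colonies are clipped to roughly half their area
    a[seq(length(a) - ctr$n_wall + 1L, length(a))] <-
      a[seq(length(a) - ctr$n_wall + 1L, length(a))] / 2
    data.frame(depth_um = z,
               aob = sum(a[cls == 1L]) / sum(a),
               amx = sum(a[cls == 2L]) / sum(a))
  })
  do.call(rbind, out)
}

#' Write a synthetic stack to disk
#'
#' Writes each section as TIFF + YAML sidecar (see
#' [write_section_image()]), ground-truth label masks as 16-bit TIFF, and
#' the true per-depth and per-shell fractions as CSV.
#'
#' @param stack A `synthetic_stack`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "synthetic_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (si in seq_along(stack$sections)) {
    pref <- file.path(dir, sprintf("section_%03d", si))
    write_section_image(stack$sections[[si]], pref)
    write_label_tiff(stack$truth$labels[[si]], paste0(pref, "_truth.tif"))
  }
  utils::write.csv(stack$truth$depth_fractions,
                   file.path(dir, "truth_depth_fractions.csv"),
                   row.names = FALSE)
  utils::write.csv(stack$truth$shell_fractions,
                   file.path(dir, "truth_shell_fractions.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(seed = stack$config$seed,
                        pixel_size_um = stack$config$pixel_size_um,
                        compartment_side_um = stack$config$compartment_side_um,
                        depths_um = as.list(stack$config$section_depths_um)),
                   file.path(dir, "stack.yml"))
  invisible(dir)
}
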