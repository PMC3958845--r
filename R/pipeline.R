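#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: the sections to
#' analyze, channel roles, thresholding, artifact rejection, slicer and
#' regression parameters, and the output directory. Thresholds are
#' explicit per configuration (the cutoff actually applied to every image
#' is recorded in the run log, so no image is binarized by an
#' undocumented manual setting).
#'
#' @param sections List of `section_image` objects, or character paths
#'   (prefixes) readable by [read_section_image()].
#' @param reference_channel Name of the reference ("all bacteria")
#'   channel. Default `"EUB338mix"`.
#' @param probe_channels Named character vector of specific-probe
#'   channels; names are probe labels.
#' @param threshold Either `"fixed"` (default) or `"rats"`.
#' @param cutoff Fixed-threshold cutoff (default 30); ignored for RATS.
#' @param min_nonzero_neighbors Noise-reduction neighbour requirement.
#' @param downscale_mp Megapixel budget before measurement (NULL skips).
#' @param artifact_params An [artifact_params()].
#' @param slicer An [slicer_params()].
#' @param dual_channel_overlap Overlap rule for
#'   [remove_autofluorescent()].
#' @param windows Named list of depth windows (um) for the per-probe
#'   regressions; probes absent from the list are fitted over the full
#'   depth range.
#' @param alpha Significance level for the regressions.
#' @param compartment_side_um Physical carrier compartment side (um) used
#'   for shrinkage estimation and areal density; NULL to skip shrinkage.
#' @param out_dir Output directory (NULL: no files written).
#' @param seed Integer seed recorded in the run log (the measurement
#'   pipeline itself is deterministic).
#'
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sections,
                            reference_channel = "EUB338mix",
                            probe_channels = c(AOB = "Nse1472",
                                               anammox = "Bfu613"),
                            threshold = c("fixed", "rats"),
                            cutoff = 30,
                            min_nonzero_neighbors = 1,
                            downscale_mp = 1,
                            artifact_params = fishstrat::artifact_params(),
                            slicer = slicer_params(),
                            dual_channel_overlap = 0.5,
                            windows = list(),
                            alpha = 0.01,
                            compartment_side_um = NULL,
                            out_dir = NULL,
                            seed = 1L) {
  threshold <- match.arg(threshold)
  if (is.character(sections)) sections <- as.list(sections)
  stopifnot(length(sections) >= 1L)
  for (s in sections) {
    if (is.character(s)) {
      if (!file.exists(paste0(sub("\\.tif$", "", s), ".tif")))
        stop("section file not found: ", s)
    } else if (!inherits(s, "section_image")) {
      stop("'sections' must contain section_image objects or file paths")
    }
  }
  structure(list(sections = sections,
                 reference_channel = reference_channel,
                 probe_channels = probe_channels,
                 threshold = threshold, cutoff = cutoff,
                 min_nonzero_neighbors = min_nonzero_neighbors,
                 downscale_mp = downscale_mp,
                 artifact_params = artifact_params,
                 slicer = slicer,
                 dual_channel_overlap = dual_channel_overlap,
                 windows = windows, alpha = alpha,
                 compartment_side_um = compartment_side_um,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

threshold_channel <- function(image, channel, config) {
  if (config$threshold == "fixed")
    threshold_fixed(image, cutoff = config$cutoff, which = channel)
  else
    threshold_rats(image, which = channel)
}

#' Measure one section
#'
#' Runs the per-section measurement chain: optional downscaling to the
#' megapixel budget, thresholding of every channel, single-pass noise
#' reduction, 8-connected segmentation of the specific channels,
#' dual-channel autofluorescence removal, congruency-based artifact
#' rejection against the reference, and biovolume-fraction / shell-profile
#' / geometry measurement.
#'
#' @param image A `section_image`.
#' @param config A [pipeline_config()].
#' @param shells Optional precomputed `shell_labels` (otherwise computed
#'   from the full image footprint).
#'
#' @return List with `fractions` (named per probe), `areal_density`,
#'   `qc` (per-probe aggregate congruency + pass flags), `objects`,
#'   `shell_profiles`, `geometry`, `thickness`, `masks`, `thresholds`.
#' @export
measure_section <- function(image, config, shells = NULL) {
  if (!is.null(config$downscale_mp))
    image <- downscale_to_megapixels(image, config$downscale_mp)
  ref_name <- config$reference_channel
  if (!ref_name %in% names(image$channels))
    stop("reference channel '", ref_name, "' missing from section")
  masks <- lapply(c(stats::setNames(ref_name, "reference"),
                    config$probe_channels),
                  function(ch) noise_reduce(
                    threshold_channel(image, ch, config),
                    config$min_nonzero_neighbors))
  ref_mask <- masks[["reference"]]
  probes <- names(config$probe_channels)
  objs <- lapply(probes, function(p)
    segment(masks[[p]], channel = config$probe_channels[[p]]))
  names(objs) <- probes
  removed_dual <- NULL
  if (length(objs) == 2L) {
    rm2 <- remove_autofluorescent(objs[[1]], objs[[2]],
                                  config$dual_channel_overlap)
    objs[[1]] <- rm2$a
    objs[[2]] <- rm2$b
    removed_dual <- rm2$removed
  }
  qc <- list()
  kept <- list()
  for (p in probes) {
    rj <- reject_artifacts(congruency(objs[[p]], ref_mask), ref_mask,
                           config$artifact_params)
    kept[[p]] <- rj$kept
    qc[[p]] <- list(aggregate_congruency = rj$aggregate_congruency,
                    image_pass_flag = rj$image_pass_flag)
  }
  fractions <- vapply(probes, function(p)
    if (sum(ref_mask) > 0) biovolume_fraction(kept[[p]], ref_mask)
    else NA_real_, numeric(1))
  # slicer on the full wall-to-wall footprint
  if (is.null(shells)) {
    footprint <- binary_mask(matrix(TRUE, nrow(ref_mask), ncol(ref_mask)),
                             pixel_size(ref_mask), "image footprint")
    shells <- wall_distance_shells(footprint, config$slicer)
  }
  shell_profiles <- lapply(probes, function(p)
    shell_biovolume_profile(shells, kept[[p]], ref_mask, probe = p))
  names(shell_profiles) <- probes
  geom <- tryCatch(measure_compartment(ref_mask, depth_um = image$depth_um),
                   error = function(e) NULL)
  thick <- if (!is.null(geom))
    tryCatch(measure_thickness(ref_mask, geometry = geom),
             error = function(e) NULL) else NULL
  ad <- if (!is.null(config$compartment_side_um))
    areal_density(ref_mask, config$compartment_side_um^2) else NA_real_
  list(depth_um = image$depth_um, fractions = fractions,
       areal_density = ad, qc = qc, objects = kept,
       removed_dual = removed_dual,
       shell_profiles = shell_profiles, geometry = geom,
       thickness = thick, masks = masks,
       thresholds = vapply(masks, attr, character(1), "provenance"))
}

# per-section biovolume fractions for a list of synthetic sections, using
# the standard measurement chain with default parameters
measure_stack_fractions <- function(sections, config = NULL) {
  if (is.null(config))
    config <- pipeline_config(sections, downscale_mp = NULL)
  d1 <- dim(sections[[1]])
  footprint <- binary_mask(matrix(TRUE, d1[1], d1[2]),
                           sections[[1]]$pixel_size_um, "image footprint")
  shells_cache <- wall_distance_shells(footprint, config$slicer)
  rows <- lapply(sections, function(img) {
    m <- measure_section(img, config, shells = shells_cache)
    data.frame(depth_um = m$depth_um,
               aob = unname(m$fractions["AOB"]),
               amx = unname(m$fractions["anammox"]))
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration over a stack of sections: per-section
#' measurement (see [measure_section()]), shell-profile aggregation
#' across sections, per-probe depth-trend regressions, geometry and
#' shrinkage tables, and — when `out_dir` is set — CSV outputs plus a run
#' log (YAML: all parameters, thresholds applied per image, seed, package
#' version). Deterministic given the configuration. Any stage failure
#' aborts with the stage name and the offending section.
#'
#' @param config A [pipeline_config()].
#'
#' @return Object of class `pipeline_result`: list with `sections`
#'   (per-section measurements), `depth_profiles`, `regressions`,
#'   `shell_summary`, `geometry`, `shrinkage`, `qc`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage <- function(name, sec, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed on section %s: %s",
                   name, sec, conditionMessage(e)), call. = FALSE))
  }
  sections <- lapply(seq_along(config$sections), function(i) {
    s <- config$sections[[i]]
    if (is.character(s))
      s <- stage("read", i, read_section_image(s))
    s
  })
  # shells depend only on grid dimensions + pixel size: cache across sections
  shell_cache <- new.env(parent = emptyenv())
  shells_for <- function(img) {
    if (!is.null(config$downscale_mp))
      img <- downscale_to_megapixels(img, config$downscale_mp)
    key <- paste(dim(img)[1], dim(img)[2], signif(img$pixel_size_um, 12))
    if (is.null(shell_cache[[key]])) {
      footprint <- binary_mask(matrix(TRUE, dim(img)[1], dim(img)[2]),
                               img$pixel_size_um, "image footprint")
      shell_cache[[key]] <- wall_distance_shells(footprint, config$slicer)
    }
    shell_cache[[key]]
  }
  measured <- lapply(seq_along(sections), function(i)
    stage("measure", i,
          measure_section(sections[[i]], config,
                          shells = shells_for(sections[[i]]))))
  depths <- vapply(measured, `[[`, numeric(1), "depth_um")
  probes <- names(config$probe_channels)
  depth_profiles <- lapply(probes, function(p)
    depth_profile(config$probe_channels[[p]], depths,
                  vapply(measured, function(m) m$fractions[[p]], numeric(1))))
  names(depth_profiles) <- probes
  regressions <- lapply(probes, function(p) {
    win <- config$windows[[p]]
    stage("regression", p,
          fit_depth_regression(depth_profiles[[p]], window = win,
                               alpha = config$alpha))
  })
  names(regressions) <- probes
  shell_summary <- stage("slicer", "all", aggregate_shell_profiles(
    unlist(lapply(measured, `[[`, "shell_profiles"), recursive = FALSE)))
  geometry <- do.call(rbind, lapply(measured, function(m) {
    if (is.null(m$geometry)) return(NULL)
    data.frame(depth_um = m$depth_um,
               side_um = mean(m$geometry$sides),
               diagonal_um = mean(m$geometry$diagonals),
               area_um2 = m$geometry$area_um2,
               side_thickness_um = if (is.null(m$thickness)) NA_real_
               else m$thickness$side_mean,
               corner_thickness_um = if (is.null(m$thickness)) NA_real_
               else m$thickness$corner_mean)
  }))
  shrinkage <- if (!is.null(config$compartment_side_um) &&
                   !is.null(geometry)) {
    estimate_shrinkage(lapply(measured, `[[`, "geometry"),
                       config$compartment_side_um)
  } else NULL
  qc <- do.call(rbind, lapply(seq_along(measured), function(i)
    do.call(rbind, lapply(probes, function(p) data.frame(
      section = i, depth_um = measured[[i]]$depth_um, probe = p,
      aggregate_congruency = measured[[i]]$qc[[p]]$aggregate_congruency,
      image_pass_flag = measured[[i]]$qc[[p]]$image_pass_flag)))))
  res <- structure(list(sections = measured,
                        depth_profiles = depth_profiles,
                        regressions = regressions,
                        shell_summary = shell_summary,
                        geometry = geometry, shrinkage = shrinkage,
                        qc = qc, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

schema_header <- "# fishstrat CSV schema v1\n"

write_schema_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(schema_header, file = con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV output
#'
#' @param path CSV written by [run_pipeline()] (versioned schema header).
#' @return data.frame.
#' @export
read_pipeline_csv <- function(path)
  utils::read.csv(path, comment.char = "#")

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  probes <- names(cfg$probe_channels)
  dp <- do.call(rbind, lapply(res$depth_profiles, as.data.frame))
  write_schema_csv(dp, file.path(out_dir, "depth_profiles.csv"))
  reg <- do.call(rbind, lapply(probes, function(p) {
    r <- res$regressions[[p]]
    data.frame(probe = p, slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, n = r$n, p_value = r$p_value,
               alpha = r$alpha, significant = r$significant,
               window_lo_um = r$window[1], window_hi_um = r$window[2])
  }))
  write_schema_csv(reg, file.path(out_dir, "regressions.csv"))
  write_schema_csv(res$shell_summary, file.path(out_dir, "shell_profiles.csv"))
  if (!is.null(res$geometry))
    write_schema_csv(res$geometry, file.path(out_dir, "geometry.csv"))
  if (!is.null(res$shrinkage))
    write_schema_csv(res$shrinkage, file.path(out_dir, "shrinkage.csv"))
  write_schema_csv(res$qc, file.path(out_dir, "qc.csv"))
  obj <- do.call(rbind, lapply(seq_along(res$sections), function(i) {
    tabs <- lapply(res$sections[[i]]$objects, `[[`, "table")
    t <- do.call(rbind, tabs)
    if (is.null(t) || nrow(t) == 0L) return(NULL)
    cbind(section = i, t)
  }))
  if (!is.null(obj))
    write_schema_csv(obj, file.path(out_dir, "objects.csv"))
  for (i in seq_along(res$sections)) {
    mlist <- res$sections[[i]]$masks
    for (nm in names(mlist)) {
      tiff::writeTIFF((as_plain_mask(mlist[[nm]])) * 1,
                      file.path(out_dir,
                                sprintf("mask_%03d_%s.tif", i, nm)),
                      bits.per.sample = 8L)
    }
  }
  log <- list(
    package = "fishstrat",
    version = as.character(utils::packageVersion("fishstrat")),
    seed = cfg$seed,
    threshold = cfg$threshold, cutoff = cfg$cutoff,
    min_nonzero_neighbors = cfg$min_nonzero_neighbors,
    downscale_mp = cfg$downscale_mp,
    artifact_params = unclass(cfg$artifact_params),
    slicer = unclass(cfg$slicer),
    dual_channel_overlap = cfg$dual_channel_overlap,
    alpha = cfg$alpha,
    thresholds_applied = lapply(res$sections, function(m)
      as.list(m$thresholds)))
  yaml::write_yaml(log, file.path(out_dir, "run_log.yml"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d sections\n", length(x$sections)))
  for (p in names(x$regressions)) {
    cat(" ", p, ": ")
    print(x$regressions[[p]])
  }
  invisible(x)
}

#' Section-image I/O round trip
#'
#' Writes a section image to a temporary location and reads it back;
#' the result is bit-identical to the input (channels and metadata).
#' Primarily a self-check of the TIFF + sidecar format contract.
#'
#' @param image A `section_image`.
#' @return The re-read `section_image`.
#' @export
io_roundtrip <- function(image) {
  pref <- tempfile("section_")
  write_section_image(image, pref)
  on.exit(unlink(paste0(pref, c(".tif", ".yml"))))
  read_section_image(pref)
}
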