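#' Segment a binary mask into 8-connected objects
#'
#' Labels maximal 8-connected components of the foreground. Every
#' foreground pixel belongs to exactly one object, so object areas sum to
#' the mask area. Returns an `object_set`: the label image plus a
#' per-object table with areas in pixels and square micrometres.
#'
#' Connected-component labelling is delegated to [EBImage::bwlabel()]
#' (4-connected) and then labels that touch diagonally are merged by
#' union-find to obtain 8-connectivity, the convention used throughout
#' this package.
#'
#' @param mask A [binary_mask] or logical matrix.
#' @param channel Optional channel name recorded in the object table.
#'
#' @return An object of class `object_set`: list with `labels` (integer
#'   matrix, 0 = background), `table` (data.frame: `object_id`, `channel`,
#'   `area_px`, `area_um2`, `congruency`, `removed_reason`), and
#'   `pixel_size_um`.
#' @export
segment <- function(mask, channel = NA_character_) {
  ps <- pixel_size(mask)
  m <- as_plain_mask(mask)
  lab <- label_components8(m)
  n <- max(lab)
  area_px <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  tbl <- data.frame(
    object_id = seq_len(n),
    channel = rep(as.character(channel), n),
    area_px = area_px,
    area_um2 = area_px * ps^2,
    congruency = rep(NA_real_, n),
    removed_reason = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  structure(list(labels = lab, table = tbl, pixel_size_um = ps),
            class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat(sprintf("<object_set> %d objects, %d foreground px, %.4g um/px\n",
              nrow(x$table), sum(x$table$area_px), x$pixel_size_um))
  invisible(x)
}

# 8-connected labelling: EBImage::bwlabel (4-connected) + merge of labels
# adjacent across a diagonal, via union-find on the (small) label graph
label_components8 <- function(m) {
  lab <- EBImage::bwlabel(m * 1)
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), , drop = FALSE]
    b <- lab[-1L, , drop = FALSE]
    if (shift[2] == 1L) {
      a <- a[, seq_len(nc - 1L), drop = FALSE]
      b <- b[, -1L, drop = FALSE]
    } else {
      a <- a[, -1L, drop = FALSE]
      b <- b[, seq_len(nc - 1L), drop = FALSE]
    }
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Congruency of objects with the reference mask
#'
#' The congruency of an object is the fraction of its pixels that lie
#' inside the reference ("all bacteria") mask — the basis for rejecting
#' autofluorescent artifacts, which light up in a specific channel without
#' a matching reference signal.
#'
#' @param objects An `object_set` from [segment()].
#' @param reference A [binary_mask] on the same grid.
#'
#' @return The `object_set` with the `congruency` column filled in.
#' @export
congruency <- function(objects, reference) {
  stopifnot(inherits(objects, "object_set"))
  if (!identical(dim(objects$labels), dim(reference)))
    stop("objects and reference are on different grids")
  if (nrow(objects$table) == 0L) return(objects)
  ref <- as_plain_mask(reference)
  lab <- objects$labels
  ids <- objects$table$object_id
  inside <- tabulate(lab[lab > 0L & ref], nbins = max(ids))
  objects$table$congruency <- inside[ids] / objects$table$area_px
  objects
}

object_union_mask <- function(objects) objects$labels > 0L

#' Remove dual-channel autofluorescent objects
#'
#' Autofluorescent particles appear in both specific probe channels (here
#' conventionally Nse1472 and Bfu613), which no genuine cell does since
#' the probes target disjoint taxa. An object in channel A is removed iff
#' at least `overlap_rule` of its own area overlaps foreground of channel
#' B, and symmetrically. Removed objects are reported, not discarded
#' silently.
#'
#' @param objects_a,objects_b `object_set`s from the two specific
#'   channels, on the same grid.
#' @param overlap_rule Minimum overlap fraction of an object's own area
#'   for removal (default 0.5).
#'
#' @return List with `a`, `b` (filtered `object_set`s) and `removed`
#'   (data.frame of removed objects with their channel and overlap).
#' @export
remove_autofluorescent <- function(objects_a, objects_b, overlap_rule = 0.5) {
  stopifnot(inherits(objects_a, "object_set"), inherits(objects_b, "object_set"))
  if (!identical(dim(objects_a$labels), dim(objects_b$labels)))
    stop("object sets are on different grids")
  ov_a <- overlap_fraction(objects_a, object_union_mask(objects_b))
  ov_b <- overlap_fraction(objects_b, object_union_mask(objects_a))
  drop_a <- which(ov_a >= overlap_rule)
  drop_b <- which(ov_b >= overlap_rule)
  removed <- rbind(
    removed_frame(objects_a, drop_a, ov_a),
    removed_frame(objects_b, drop_b, ov_b))
  list(a = drop_objects(objects_a, drop_a, "autofluorescent"),
       b = drop_objects(objects_b, drop_b, "autofluorescent"),
       removed = removed)
}

overlap_fraction <- function(objects, other_mask) {
  if (nrow(objects$table) == 0L) return(numeric(0))
  lab <- objects$labels
  ids <- objects$table$object_id
  inside <- tabulate(lab[lab > 0L & other_mask], nbins = max(ids))
  inside[ids] / objects$table$area_px
}

removed_frame <- function(objects, idx, overlap) {
  df <- objects$table[idx, c("object_id", "channel", "area_px", "area_um2"),
                      drop = FALSE]
  df$overlap <- overlap[idx]
  rownames(df) <- NULL
  df
}

# drop objects by row index, keeping original object ids, and clear their
# pixels from the label image
drop_objects <- function(objects, idx, reason) {
  if (length(idx) == 0L) return(objects)
  ids <- objects$table$object_id[idx]
  objects$labels[objects$labels %in% ids] <- 0L
  objects$table <- objects$table[-idx, , drop = FALSE]
  rownames(objects$table) <- NULL
  objects
}

#' Congruency parameters for artifact rejection
#'
#' @param object_congruency_threshold Per-object congruency below which an
#'   object is rejected (default 0.50).
#' @param aggregate_congruency_requirement Minimum aggregate congruency of
#'   the kept objects with the reference for the image to pass QC
#'   (default 0.90).
#' @return An object of class `artifact_params`.
#' @export
artifact_params <- function(object_congruency_threshold = 0.50,
                            aggregate_congruency_requirement = 0.90) {
  stopifnot(object_congruency_threshold >= 0, object_congruency_threshold <= 1,
            aggregate_congruency_requirement >= 0,
            aggregate_congruency_requirement <= 1)
  structure(list(object_congruency_threshold = object_congruency_threshold,
                 aggregate_congruency_requirement =
                   aggregate_congruency_requirement),
            class = "artifact_params")
}

#' Congruency-based artifact rejection
#'
#' Removes objects whose congruency with the reference mask falls below
#' the per-object threshold (standard 50%), then checks the aggregate
#' congruency of the kept objects — the area-weighted mean, i.e. total
#' kept area inside the reference over total kept area — against the
#' aggregate requirement (standard 90%). Images failing the aggregate
#' requirement are flagged, never silently dropped: silent dropping would
#' bias stratification profiles.
#'
#' @param objects An `object_set`; congruency is computed here if absent.
#' @param reference The reference-channel [binary_mask].
#' @param params An [artifact_params].
#'
#' @return List with `kept` (`object_set`), `aggregate_congruency`, and
#'   `image_pass_flag` (TRUE iff aggregate >= requirement; TRUE vacuously
#'   for an empty object list).
#' @export
reject_artifacts <- function(objects, reference, params = artifact_params()) {
  stopifnot(inherits(params, "artifact_params"))
  if (anyNA(objects$table$congruency))
    objects <- congruency(objects, reference)
  low <- which(objects$table$congruency < params$object_congruency_threshold)
  kept <- drop_objects(objects, low, "low congruency")
  if (nrow(kept$table) == 0L) {
    return(list(kept = kept, aggregate_congruency = NA_real_,
                image_pass_flag = TRUE))
  }
  agg <- sum(kept$table$congruency * kept$table$area_px) /
    sum(kept$table$area_px)
  list(kept = kept, aggregate_congruency = agg,
       image_pass_flag = agg >= params$aggregate_congruency_requirement)
}

#' Biovolume fraction of a probe-targeted population
#'
#' Total area of the kept specific-probe objects divided by the
#' reference-channel area. Values above 1 raise an error rather than being
#' clamped — a fraction above 1 signals that congruency filtering was
#' skipped.
#'
#' @param kept_objects `object_set` of artifact-filtered specific objects.
#' @param reference Reference-channel [binary_mask]; must be non-empty.
#'
#' @return Biovolume fraction in \[0, 1\].
#' @export
biovolume_fraction <- function(kept_objects, reference) {
  ref_area <- sum(reference)
  if (ref_area == 0)
    stop("empty reference mask: biovolume fraction undefined")
  f <- sum(kept_objects$table$area_px) / ref_area
  if (f > 1)
    stop(sprintf(
      "biovolume fraction %.3f > 1: was congruency filtering skipped?", f))
  f
}

#' Biomass areal density
#'
#' Reference-channel signal area as a fraction of the total compartment
#' area — the biomass density measure used to track how densely the
#' compartment cross-section is colonized.
#'
#' @param reference Reference-channel [binary_mask].
#' @param compartment_area_um2 Compartment cross-section area in um^2.
#'
#' @return Fraction in \[0, 1\].
#' @export
areal_density <- function(reference, compartment_area_um2) {
  stopifnot(compartment_area_um2 > 0)
  a <- sum(reference) * pixel_size(reference)^2
  if (a > compartment_area_um2 * (1 + 1e-9))
    stop("reference area exceeds compartment area")
  min(a / compartment_area_um2, 1)
}

#' Export an object table as CSV
#'
#' @param objects An `object_set` (or list of them).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_object_table <- function(objects, path) {
  if (inherits(objects, "object_set")) objects <- list(objects)
  tbl <- do.call(rbind, lapply(objects, `[[`, "table"))
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
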