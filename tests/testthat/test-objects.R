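test_that("segmentation finds maximal 8-connected components", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE
  m[7:9, 6:8] <- TRUE
  os <- segment(binary_mask(m, 2))
  expect_equal(nrow(os$table), 2L)
  expect_equal(os$table$area_px, c(9L, 9L))
  expect_equal(os$table$area_um2, c(36, 36))
  # diagonal touch merges into one object
  dg <- matrix(FALSE, 4, 4); dg[1, 1] <- TRUE; dg[2, 2] <- TRUE
  expect_equal(nrow(segment(binary_mask(dg))$table), 1L)
  expect_equal(nrow(segment(binary_mask(matrix(FALSE, 3, 3)))$table), 0L)
})

test_that("segmentation agrees with the flood-fill oracle and partitions the mask", {
  for (seed in 1:5) {
    m <- rand_mask(32, 0.35, seed)
    os <- segment(binary_mask(m))
    ref <- bf_label8(m)
    expect_equal(nrow(os$table), max(ref))
    # identical partition: labelings agree up to renaming
    expect_equal(sum(os$table$area_px), sum(m))
    key <- paste(os$labels[m], ref[m])
    expect_equal(length(unique(key)), max(ref))
  }
})

test_that("congruency is the object-area fraction inside the reference", {
  m <- matrix(FALSE, 8, 8); m[2:3, 2:3] <- TRUE          # 4-px object
  ref <- matrix(FALSE, 8, 8); ref[2, 2:3] <- TRUE        # covers 2 px
  os <- congruency(segment(binary_mask(m)), binary_mask(ref))
  expect_equal(os$table$congruency, 0.5)
  full <- congruency(segment(binary_mask(m)), binary_mask(m))
  expect_equal(full$table$congruency, 1.0)
  disj <- congruency(segment(binary_mask(m)), binary_mask(matrix(FALSE, 8, 8)))
  expect_equal(disj$table$congruency, 0.0)
  # random case against a per-object pixel-count oracle
  mm <- rand_mask(24, 0.3, 7); rr <- rand_mask(24, 0.5, 8)
  os <- congruency(segment(binary_mask(mm)), binary_mask(rr))
  for (k in seq_len(nrow(os$table))) {
    pix <- os$labels == os$table$object_id[k]
    expect_equal(os$table$congruency[k], sum(pix & rr) / sum(pix))
  }
})

test_that("dual-channel autofluorescent objects are removed, disjoint ones kept", {
  a <- matrix(FALSE, 12, 12); a[2:4, 2:4] <- TRUE; a[8:10, 8:10] <- TRUE
  b <- matrix(FALSE, 12, 12); b[2:4, 2:4] <- TRUE; b[8:10, 1:3] <- TRUE
  res <- remove_autofluorescent(segment(binary_mask(a), "A"),
                                segment(binary_mask(b), "B"))
  # the shared block goes from both; the disjoint blocks stay
  expect_equal(nrow(res$a$table), 1L)
  expect_equal(nrow(res$b$table), 1L)
  expect_equal(nrow(res$removed), 2L)
  disjoint <- remove_autofluorescent(
    segment(binary_mask(a), "A"),
    segment(binary_mask(matrix(FALSE, 12, 12)), "B"))
  expect_equal(nrow(disjoint$a$table), 2L)
  expect_equal(nrow(disjoint$removed), 0L)
})

test_that("planted artifacts are fully removed and genuine objects kept", {
  cfg <- test_config(section_depths_um = 300, artifact_rate = 6,
                     foreground_sd = 0, background_sd = 0,
                     background_mean = 0, edge_blur_px = 0,
                     speckle_rate = 0, seed = 13)
  stack <- generate_compartment_stack(cfg)
  img <- stack$sections[[1]]
  lab <- stack$truth$labels[[1]]
  art <- stack$truth$artifacts[[1]]
  expect_gt(length(art), 0)
  nse <- threshold_fixed(img, which = "Nse1472")
  bfu <- threshold_fixed(img, which = "Bfu613")
  res <- remove_autofluorescent(segment(nse, "Nse1472"),
                                segment(bfu, "Bfu613"))
  # all artifact pixels cleared from both channels
  expect_false(any(res$a$labels[art] > 0))
  expect_false(any(res$b$labels[art] > 0))
  # every genuine (class) pixel retained
  expect_true(all(res$a$labels[lab == 1L] > 0))
  expect_true(all(res$b$labels[lab == 2L] > 0))
})

test_that("congruency rejection applies both thresholds and flags failures", {
  ref <- matrix(FALSE, 20, 20); ref[1:20, 1:10] <- TRUE
  # object A: 10 px fully inside; object B: 10 px with 4 inside (cong 0.4)
  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:3] <- TRUE               # 10 px inside -> congruency 1.0
  m[10:14, 9:10] <- TRUE            # partially inside
  m[10:14, 9] <- TRUE; m[10:14, 10] <- TRUE
  m2 <- matrix(FALSE, 20, 20)
  m2[2:6, 2:3] <- TRUE
  m2[10:14, 9:12] <- TRUE           # 20 px, 10 inside -> congruency 0.5
  os <- congruency(segment(binary_mask(m2)), binary_mask(ref))
  expect_setequal(round(os$table$congruency, 2), c(1, 0.5))
  kept <- reject_artifacts(os, binary_mask(ref),
                           artifact_params(0.6, 0.9))
  expect_equal(nrow(kept$kept$table), 1L)
  expect_true(kept$image_pass_flag)
  # engineered aggregate congruency below the requirement trips the flag
  os2 <- congruency(segment(binary_mask(m2)), binary_mask(ref))
  rj <- reject_artifacts(os2, binary_mask(ref), artifact_params(0.5, 0.9))
  expect_equal(rj$aggregate_congruency, (10 + 10) / (10 + 20))
  expect_false(rj$image_pass_flag)
  # all-congruent objects: kept, pass
  rj3 <- reject_artifacts(congruency(segment(binary_mask(m)),
                                     binary_mask(m)), binary_mask(m))
  expect_true(rj3$image_pass_flag)
  expect_equal(nrow(rj3$kept$table), nrow(segment(binary_mask(m))$table))
  # empty object list: vacuous pass
  e <- reject_artifacts(segment(binary_mask(matrix(FALSE, 5, 5))),
                        binary_mask(matrix(TRUE, 5, 5)))
  expect_true(e$image_pass_flag)
  expect_equal(nrow(e$kept$table), 0L)
})

test_that("artifact rejection is idempotent", {
  mm <- rand_mask(30, 0.3, 3); rr <- rand_mask(30, 0.6, 4)
  os <- congruency(segment(binary_mask(mm)), binary_mask(rr))
  r1 <- reject_artifacts(os, binary_mask(rr))
  r2 <- reject_artifacts(r1$kept, binary_mask(rr))
  expect_identical(r1$kept$table, r2$kept$table)
  expect_equal(r1$aggregate_congruency, r2$aggregate_congruency)
})

test_that("biovolume fractions behave at the boundaries and sum correctly", {
  ref <- binary_mask(matrix(TRUE, 10, 10))
  os <- segment(ref)
  expect_equal(biovolume_fraction(os, ref), 1.0)
  empty <- segment(binary_mask(matrix(FALSE, 10, 10)))
  expect_equal(biovolume_fraction(empty, ref), 0.0)
  expect_error(biovolume_fraction(os, binary_mask(matrix(FALSE, 10, 10))),
               "empty reference")
  # un-filtered specific larger than reference raises, not clamps
  big <- segment(binary_mask(matrix(TRUE, 10, 10)))
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  expect_error(biovolume_fraction(big, binary_mask(half)), "> 1")
  # disjoint probes against one reference sum to <= 1
  a <- matrix(FALSE, 10, 10); a[, 1:3] <- TRUE
  b <- matrix(FALSE, 10, 10); b[, 5:7] <- TRUE
  s <- biovolume_fraction(segment(binary_mask(a)), ref) +
    biovolume_fraction(segment(binary_mask(b)), ref)
  expect_lte(s, 1)
})

test_that("areal density is the reference area over the compartment area", {
  full <- binary_mask(matrix(TRUE, 10, 10), pixel_size_um = 2)
  expect_equal(areal_density(full, 400), 1.0)
  expect_equal(areal_density(binary_mask(matrix(FALSE, 10, 10), 2), 400), 0)
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  expect_equal(areal_density(binary_mask(half, 2), 400), 0.5)
  expect_error(areal_density(full, 100), "exceeds")
})
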