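test_that("a 1 mm square at 1 um/px yields five 100 um shells", {
  m <- binary_mask(matrix(TRUE, 1000, 1000), pixel_size_um = 1)
  sh <- wall_distance_shells(m, slicer_params(100, 0))
  expect_equal(sh$shells$shell_index, 0:4)
  expect_equal(sh$shells$d_lo_um, seq(0, 400, by = 100))
  # innermost shell is the central 200 x 200 px square
  inner <- which(sh$labels == 4L, arr.ind = TRUE)
  expect_equal(range(inner[, 1]), c(401, 600))
  expect_equal(range(inner[, 2]), c(401, 600))
  expect_equal(sum(sh$labels == 4L), 200^2)
  # shells partition the mask
  expect_equal(sum(sh$shells$shell_area_um2), sum(m) * 1)
})

test_that("shell labels equal the all-pairs boundary-distance oracle", {
  for (seed in 1:4) {
    m <- make_blob_mask(40, seed)
    sh <- wall_distance_shells(binary_mask(m, 2), slicer_params(20, 0))
    expect_identical(sh$labels, bf_shell_labels(m, 20, 2))
    expect_equal(sum(sh$shells$shell_area_um2), sum(m) * 4)
  }
})

test_that("non-simply-connected masks are rejected with a component count", {
  two <- matrix(FALSE, 20, 20); two[2:5, 2:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_error(wall_distance_shells(binary_mask(two)), "2 connected")
  holed <- matrix(TRUE, 20, 20); holed[8:12, 8:12] <- FALSE
  expect_error(wall_distance_shells(binary_mask(holed)), "hole")
})

test_that("shell profiles are invariant under rotations and flips", {
  m <- make_blob_mask(36, 9)
  spec <- m & rand_mask(36, 0.5, 10)
  p0 <- shell_biovolume_profile(
    wall_distance_shells(binary_mask(m), slicer_params(8, 0)),
    binary_mask(spec), binary_mask(m), "x")
  for (tf in list(function(x) t(x),
                  function(x) x[rev(seq_len(nrow(x))), ],
                  function(x) x[, rev(seq_len(ncol(x)))])) {
    p1 <- shell_biovolume_profile(
      wall_distance_shells(binary_mask(tf(m)), slicer_params(8, 0)),
      binary_mask(tf(spec)), binary_mask(tf(m)), "x")
    expect_equal(p1$fraction, p0$fraction)
    expect_equal(p1$shell_area_um2, p0$shell_area_um2)
  }
})

test_that("uniform masks give identical fractions in all shells; empty reference is flagged missing", {
  m <- binary_mask(matrix(TRUE, 120, 120), pixel_size_um = 5)
  sh <- wall_distance_shells(m, slicer_params(100, 0))
  p <- shell_biovolume_profile(sh, m, m, "uniform")
  expect_true(all(p$fraction == 1))
  expect_false(any(p$missing))
  # reference absent from the innermost shell -> missing, not zero
  ref <- as_logical_matrix(m)
  ref[sh$labels == max(sh$shells$shell_index)] <- FALSE
  p2 <- shell_biovolume_profile(sh, binary_mask(ref, 5), binary_mask(ref, 5),
                                "probe")
  expect_true(p2$missing[nrow(p2)])
  expect_true(is.na(p2$fraction[nrow(p2)]))
})

test_that("baseline smoothing regularizes a ragged boundary", {
  set.seed(4)
  n <- 120
  m <- matrix(FALSE, n, n)
  m[6:(n - 5), 6:(n - 5)] <- TRUE
  # roughen the boundary with single-pixel notches
  edge <- which(boundary_oracle(m), arr.ind = TRUE)
  notch <- edge[sample(nrow(edge), 40), ]
  m[notch] <- FALSE
  m <- make_simply_connected(m)
  raw <- wall_distance_shells(binary_mask(m), slicer_params(20, 0))
  smo <- wall_distance_shells(binary_mask(m), slicer_params(20, 0.2))
  # smoothing must not change the partition property
  expect_equal(sum(smo$shells$shell_area_um2), sum(m))
  expect_equal(sum(raw$shells$shell_area_um2), sum(m))
})

test_that("aggregation gives t-based confidence intervals and per-shell n", {
  mk <- function(f) data.frame(shell_index = 0L, d_lo_um = 0, d_hi_um = 100,
                               shell_area_um2 = 1, probe = "p", fraction = f,
                               missing = FALSE)
  agg <- aggregate_shell_profiles(list(mk(0.2), mk(0.4)))
  expect_equal(agg$mean, 0.3)
  half <- stats::qt(0.975, df = 1) * stats::sd(c(0.2, 0.4)) / sqrt(2)
  expect_equal(agg$ci_lo, 0.3 - half)
  expect_equal(agg$ci_hi, 0.3 + half)
  expect_equal(agg$n, 2L)
  # identical profiles -> zero-width interval
  agg2 <- aggregate_shell_profiles(list(mk(0.25), mk(0.25), mk(0.25)))
  expect_equal(agg2$ci_lo, agg2$ci_hi)
  # single contribution -> undefined CI, mean reported
  agg3 <- aggregate_shell_profiles(list(mk(0.5)))
  expect_equal(agg3$mean, 0.5)
  expect_true(is.na(agg3$ci_lo))
  # deep shell present in fewer sections reports the smaller n
  deep <- function(f) rbind(mk(f), data.frame(
    shell_index = 4L, d_lo_um = 400, d_hi_um = 500, shell_area_um2 = 1,
    probe = "p", fraction = f, missing = FALSE))
  profs <- c(lapply(c(0.1, 0.2, 0.3, 0.4), deep),
             lapply(c(0.1, 0.2, 0.3, 0.4), mk))
  agg4 <- aggregate_shell_profiles(profs)
  expect_equal(agg4$n[agg4$shell_index == 0L], 8L)
  expect_equal(agg4$n[agg4$shell_index == 4L], 4L)
})
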