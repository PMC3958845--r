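test_that("fixed thresholding matches the per-pixel oracle and handles extremes", {
  expect_true(all(threshold_fixed(matrix(255L, 8, 8), 30)))
  expect_false(any(threshold_fixed(matrix(0L, 8, 8), 30)))
  # inclusive comparison: pixels exactly at the cutoff are foreground
  expect_true(all(threshold_fixed(matrix(30L, 4, 4), 30)))
  for (seed in 1:3) {
    ch <- rand_channel(32, seed)
    expect_identical(as_logical_matrix(threshold_fixed(ch, 30)),
                     bf_threshold(ch, 30))
  }
  expect_error(threshold_fixed(matrix(0L, 2, 2), 300), "0, 255")
})

test_that("RATS thresholding separates a two-level image exactly", {
  ch <- matrix(10L, 32, 32)
  ch[10:20, 8:25] <- 200L
  bm <- threshold_rats(ch)
  t_used <- attr(bm, "threshold")
  expect_gt(t_used, 10)
  expect_lt(t_used, 200)
  # exhaustive threshold search: minimal misclassification against the
  # known level-200 region
  truth <- ch == 200L
  errs <- vapply(0:255, function(t) sum((ch >= t) != truth), numeric(1))
  best <- (0:255)[which.min(errs)]
  expect_identical(as_logical_matrix(bm), bf_threshold(ch, best))
})

test_that("RATS threshold is shift-equivariant", {
  ch <- rand_channel(24, 5) %/% 2  # leave headroom for the offset
  t1 <- attr(threshold_rats(ch), "threshold")
  t2 <- attr(threshold_rats(ch + 40L), "threshold")
  expect_equal(t2, t1 + 40, tolerance = 1e-10)
})

test_that("RATS recovers the high-mode fraction of a bimodal mixture", {
  set.seed(42)
  n <- 64
  hi <- matrix(stats::runif(n * n) < 0.35, n, n)
  ch <- matrix(0, n, n)
  ch[!hi] <- stats::rnorm(sum(!hi), 40, 10)
  ch[hi] <- stats::rnorm(sum(hi), 200, 15)
  ch <- matrix(as.integer(pmin(pmax(round(ch), 0), 255)), n, n)
  bm <- threshold_rats(ch)
  expect_lt(abs(mean(bm) - mean(hi)), 0.05)
})

test_that("flat images have no defined RATS threshold", {
  expect_error(threshold_rats(matrix(7L, 16, 16)), "flat")
})

test_that("noise reduction matches the 8-neighbour counting oracle", {
  centre <- matrix(FALSE, 3, 3); centre[2, 2] <- TRUE
  expect_false(any(noise_reduce(binary_mask(centre))))
  solid <- binary_mask(matrix(TRUE, 2, 2))
  expect_true(all(noise_reduce(solid)))
  for (seed in 1:4) {
    m <- rand_mask(16, 0.4, seed)
    expect_identical(as_logical_matrix(noise_reduce(binary_mask(m))),
                     bf_noise_reduce(m, 1))
    expect_identical(as_logical_matrix(noise_reduce(binary_mask(m), 3)),
                     bf_noise_reduce(m, 3))
  }
})

test_that("thresholding and noise reduction are idempotent where the contract says", {
  ch <- rand_channel(20, 9)
  m1 <- threshold_fixed(ch, 30)
  expect_identical(as_logical_matrix(threshold_fixed(m1 * 255L, 30)),
                   as_logical_matrix(m1))
  # solid blocks: no retained pixel can lose all its neighbours
  solid <- matrix(FALSE, 12, 12); solid[3:6, 3:9] <- TRUE; solid[9:10, 2:4] <- TRUE
  once <- noise_reduce(binary_mask(solid))
  twice <- noise_reduce(once)
  expect_identical(as_logical_matrix(once), as_logical_matrix(twice))
})

test_that("downscaling respects the megapixel budget and conserves area", {
  big <- section_image(list(EUB338mix = matrix(128L, 4096, 4096)),
                       pixel_size_um = 0.25)
  small <- downscale_to_megapixels(big, 1)
  expect_identical(dim(small), c(1024L, 1024L))
  expect_equal(small$pixel_size_um, 1.0)
  rm(big)
  unchanged <- section_image(list(EUB338mix = matrix(1L, 512, 512)),
                             pixel_size_um = 1)
  expect_identical(downscale_to_megapixels(unchanged, 1), unchanged)
  # ~50%-foreground mask (spatially coherent, as probe masks are):
  # downscale then re-threshold at 0.5 conserves the area fraction
  n <- 2048
  cc <- (seq_len(n) - n / 2)^2
  m <- outer(cc, cc, `+`) <= (n * 0.399)^2  # disc covering ~0.50
  sm <- downscale_to_megapixels(m * 1.0, 1)
  expect_identical(dim(sm), c(1024L, 1024L))
  expect_lt(abs(mean(sm >= 0.5) - mean(m)), 0.01)
  # area-mean resampling conserves the mean exactly for divisible dims
  expect_equal(mean(sm), mean(m))
})

test_that("tile assembly reproduces the unsplit image", {
  cfg <- test_config(section_depths_um = 200, seed = 21)
  img <- generate_compartment_stack(cfg)$sections[[1]]
  one <- assemble_tiles(list(img), rbind(c(0L, 0L)))
  expect_identical(one$channels, img$channels)
  # split into 2x2 tiles and reassemble
  d <- dim(img); h <- d[1] %/% 2
  tile <- function(rs, cs) section_image(
    lapply(img$channels, function(ch) ch[rs, cs, drop = FALSE]),
    img$pixel_size_um, img$depth_um, img$compartment_id)
  tiles <- list(tile(1:h, 1:h), tile(1:h, (h + 1):d[2]),
                tile((h + 1):d[1], 1:h), tile((h + 1):d[1], (h + 1):d[2]))
  offs <- rbind(c(0L, 0L), c(0L, h), c(h, 0L), c(h, h))
  back <- assemble_tiles(tiles, offs)
  expect_identical(back$channels, img$channels)
  expect_error(
    assemble_tiles(list(img, section_image(img$channels, 2)), offs[1:2, ]),
    "pixel sizes")
})
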