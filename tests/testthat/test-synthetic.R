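test_that("a fixed seed gives bit-identical stacks", {
  cfg <- test_config(section_depths_um = c(100, 300), seed = 5)
  s1 <- generate_compartment_stack(cfg)
  s2 <- generate_compartment_stack(cfg)
  expect_identical(lapply(s1$sections, `[[`, "channels"),
                   lapply(s2$sections, `[[`, "channels"))
  expect_identical(s1$truth$labels, s2$truth$labels)
})

test_that("zero density profiles produce blank channels and empty truth", {
  cfg <- test_config(section_depths_um = c(100, 300),
                     aob_profile = constant_profile(0),
                     amx_profile = constant_profile(0),
                     biomass_coverage = function(z) rep_len(0, length(z)),
                     background_mean = 0, background_sd = 0,
                     foreground_sd = 0, edge_blur_px = 0)
  s <- generate_compartment_stack(cfg)
  for (img in s$sections)
    expect_true(all(vapply(img$channels, function(ch) all(ch == 0L),
                           logical(1))))
  expect_true(all(vapply(s$truth$labels, function(l) all(l == 0L),
                         logical(1))))
})

test_that("inconsistent fraction profiles are rejected naming the location", {
  expect_error(
    test_config(aob_profile = constant_profile(0.7),
                amx_profile = constant_profile(0.2),
                other_bacteria_fraction = function(z)
                  rep_len(0.3, length(z))),
    "z = .*wall distance")
})

test_that("constant-profile configs are measured back within 0.03", {
  cfg <- test_config(
    section_depths_um = c(200, 600),
    aob_profile = constant_profile(0.30),
    amx_profile = constant_profile(0.10),
    foreground_sd = 0, background_sd = 0, background_mean = 0,
    edge_blur_px = 0, seed = 17)
  stack <- generate_compartment_stack(cfg)
  fr <- fishstrat:::measure_stack_fractions(stack$sections)
  expect_true(all(abs(fr$aob - 0.30) <= 0.03))
  expect_true(all(abs(fr$amx - 0.10) <= 0.03))
  # and the measurement agrees with the exact ground-truth pixel counts
  tr <- stack$truth$depth_fractions
  expect_true(all(abs(fr$aob - tr$fraction[tr$probe == "Nse1472"]) < 0.005))
})

test_that("reference channel structure contains every specific-class pixel", {
  cfg <- test_config(section_depths_um = 400, artifact_rate = 4,
                     speckle_rate = 2, seed = 23)
  s <- generate_compartment_stack(cfg)
  lab <- s$truth$labels[[1]]
  img <- s$sections[[1]]
  # ground-truth masks are mutually exclusive by construction (single
  # label grid); reference foreground covers all bacterial classes
  eub <- threshold_fixed(img, which = "EUB338mix")
  expect_true(all(eub[lab %in% 1:3]))
  # artifacts are absent from the reference structure
  expect_true(all(lab[s$truth$artifacts[[1]]] == 4L))
})

test_that("expected profiles integrate the target functions over the grid", {
  cfg <- test_config(section_depths_um = c(100, 400))
  flat <- test_config(section_depths_um = c(100, 400),
                      aob_profile = constant_profile(0.2),
                      amx_profile = constant_profile(0.1))
  ep <- expected_profile(flat)
  expect_true(all(abs(ep$depth$fraction[ep$depth$probe == "Nse1472"] - 0.2)
                  < 1e-12))
  expect_true(all(abs(ep$shell$fraction[ep$shell$probe == "Nse1472"] - 0.2)
                  < 1e-12))
  # linear depth profile: expectation reproduces the same line
  lin <- expected_profile(cfg)
  aob <- lin$depth[lin$depth$probe == "Nse1472", ]
  expect_equal(aob$fraction,
               cfg$aob_profile(aob$depth_um, 0), tolerance = 1e-12)
  # radial profile: per-shell expectation equals the area-weighted mean
  rad <- test_config(
    section_depths_um = 100,
    aob_profile = function(z, d) pmax(0.4 - 0.0006 * d, 0.05),
    amx_profile = constant_profile(0))
  ep2 <- expected_profile(rad, slice_thickness_um = 100)
  dgrid <- fishstrat:::wall_distance_grid(rad)
  d <- dgrid[dgrid >= 0]
  sh <- floor(d / 100)
  want <- tapply(pmax(0.4 - 0.0006 * d, 0.05), sh, mean)
  got <- ep2$shell$fraction[ep2$shell$probe == "Nse1472"]
  expect_equal(unname(got), unname(as.numeric(want)), tolerance = 1e-12)
})

test_that("planting artifacts puts identical footprints in both specific channels", {
  cfg <- test_config(section_depths_um = 300, seed = 3)
  img <- generate_compartment_stack(cfg)$sections[[1]]
  same <- plant_artifacts(img, rate = 0, seed = 1)
  expect_identical(same$image$channels, img$channels)
  planted <- plant_artifacts(img, rate = 5, seed = 9)
  expect_gt(length(planted$footprints), 0)
  for (fp in planted$footprints) {
    expect_true(all(planted$image$channels$Nse1472[fp] ==
                      planted$image$channels$Bfu613[fp]))
    expect_true(all(planted$image$channels$Nse1472[fp] >= 30))
  }
  # downstream dual-channel removal eliminates every planted object
  nse <- noise_reduce(threshold_fixed(planted$image, which = "Nse1472"))
  bfu <- noise_reduce(threshold_fixed(planted$image, which = "Bfu613"))
  res <- remove_autofluorescent(segment(nse, "Nse1472"),
                                segment(bfu, "Bfu613"))
  for (fp in planted$footprints) {
    expect_true(all(res$a$labels[fp] == 0L))
    expect_true(all(res$b$labels[fp] == 0L))
  }
  expect_error(plant_artifacts(img, rate = -1), ">= 0")
})

test_that("radial stratification shows up in the measured shell profile", {
  cfg <- test_config(
    section_depths_um = c(200, 300, 400, 500),
    aob_profile = constant_profile(0.1),
    amx_profile = function(z, d) pmax(0.45 - 0.0008 * d, 0.05),
    colony_radius_um = c(mean = 6, sd = 2),
    foreground_sd = 0, background_sd = 0, background_mean = 0,
    edge_blur_px = 0, seed = 29)
  stack <- generate_compartment_stack(cfg)
  foot <- binary_mask(matrix(TRUE, cfg$grid_size_px, cfg$grid_size_px),
                      cfg$pixel_size_um)
  sh <- wall_distance_shells(foot, slicer_params(100, 0))
  profs <- lapply(stack$sections, function(img) {
    eub <- noise_reduce(threshold_fixed(img, which = "EUB338mix"))
    bfu <- noise_reduce(threshold_fixed(img, which = "Bfu613"))
    kept <- reject_artifacts(congruency(segment(bfu, "Bfu613"), eub),
                             eub)$kept
    shell_biovolume_profile(sh, kept, eub, "Bfu613")
  })
  agg <- aggregate_shell_profiles(profs)
  ep <- expected_profile(cfg, 100)
  want <- ep$shell$fraction[ep$shell$probe == "Bfu613" &
                              ep$shell$depth_um == 200]
  expect_true(all(abs(agg$mean - want[agg$shell_index + 1L]) <= 0.05))
  # monotone decreasing away from the wall
  expect_true(all(diff(agg$mean) < 0.02))
})
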