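test_that("default field geometry reproduces the fixed evaluated area", {
  g <- default_field_geometry()
  expect_equal(g$area_um2, 1229054.6934, tolerance = 1e-9)
  img <- simulate_field(simulation_config(n_aggregates = 0), seed = 1)$image
  expect_equal(field_area_um2(img), 1229054.6934, tolerance = 1e-9)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(t_fraction = 1.2), "t_fraction")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(nucleus_radius_um = 0), "nucleus_radius_um")
  expect_error(simulation_config(n_aggregates = -1), "n_aggregates")
  expect_error(simulation_config(nuclei_per_aggregate = c(50, 10)), "increasing")
})

test_that("a field with no aggregates is truly empty", {
  f <- simulate_field(small_config(n_aggregates = 0), seed = 5)
  expect_equal(nrow(f$truth$aggregates), 0)
  expect_equal(f$truth$n_foci, 0)
  expect_equal(f$truth$true_focus_score, 0)
  expect_equal(f$truth$true_aggregate_area_fraction_pct, 0)
  expect_true(all(get_channel(f$image, "CD3") <= 200 + 0))
})

test_that("two aggregates of 80 nuclei give two foci and the formula score", {
  f <- simulate_field(
    simulation_config(n_aggregates = 2, nuclei_per_aggregate = 80),
    seed = 11
  )
  tr <- f$truth
  expect_equal(tr$n_foci, 2L)
  # recompute from stored fields with the printed formula
  expect_equal(tr$true_focus_score, (2 / tr$gland_area_mm2) * 4)
  expect_equal(tr$gland_area_mm2, 1.2290546934, tolerance = 1e-9)
})

test_that("ground truth is self-consistent across random configurations", {
  set.seed(404)
  for (k in 1:12) {
    cfg <- small_config(
      n_aggregates = sample(0:3, 1),
      nuclei_per_aggregate = sort(sample(10:90, 2)),
      t_fraction = runif(1, 0.2, 0.8),
      segregation_mode = sample(c("segregated", "mixed"), 1),
      noise_sd = sample(c(0, 100), 1)
    )
    tr <- simulate_field(cfg, seed = 7000 + k)$truth
    expect_equal(tr$n_foci, sum(tr$aggregates$nucleus_count > 50))
    expect_equal(tr$true_focus_score, tr$n_foci / tr$gland_area_mm2 * 4)
    with(tr$aggregates, {
      expect_true(all(intersection_area_um2 <=
                        pmin(t_area_um2, b_area_um2) + 1e-9))
      expect_equal(t_area_um2 + b_area_um2 - intersection_area_um2,
                   union_area_um2)
    })
    # union of per-aggregate areas never exceeds the recorded field coverage
    expect_lte(
      sum(tr$aggregates$union_area_um2) / (tr$gland_area_mm2 * 1e6) * 100,
      tr$true_aggregate_area_fraction_pct + 1e-9
    )
  }
})

test_that("identical (config, seed) reproduce bit-identical fields", {
  cfg <- small_config(n_aggregates = 2, noise_sd = 50)
  a <- simulate_field(cfg, seed = 99)
  b <- simulate_field(cfg, seed = 99)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$aggregates, b$truth$aggregates)
  c <- simulate_field(cfg, seed = 100)
  expect_false(identical(a$image$channels, c$image$channels))
})

test_that("well-separated sub-clusters have zero T/B intersection", {
  f <- simulate_field(
    simulation_config(
      field_width_px = 700, field_height_px = 700,
      n_aggregates = 2, nuclei_per_aggregate = 80,
      segregation_mode = "segregated", separation_factor = 2
    ),
    seed = 21
  )
  expect_true(all(f$truth$aggregates$intersection_area_um2 == 0))
  # oracle: pixel-count intersection of the thresholded noise-free rasters
  mt <- get_channel(f$image, "CD3") >= 2100
  mb <- get_channel(f$image, "B220") >= 2100
  expect_equal(sum(mt & mb), 0)
})

test_that("aggregate placement failure is reported with the aggregate index", {
  cfg <- simulation_config(
    field_width_px = 200, field_height_px = 200,
    n_aggregates = 12, nuclei_per_aggregate = 100
  )
  expect_error(simulate_field(cfg, seed = 1), "aggregate")
})

test_that("cohort simulation validates groups and is deterministic", {
  cfg <- small_config(n_aggregates = 1, nuclei_per_aggregate = 30)
  expect_error(
    simulate_cohort(list(a = cfg, a = cfg), 2, seed = 1),
    "duplicate"
  )
  one <- simulate_cohort(list(only = cfg), n_fields_per_group = 1, seed = 3)
  expect_equal(nrow(one), 1L)
  again <- simulate_cohort(list(only = cfg), n_fields_per_group = 1, seed = 3)
  expect_identical(one$image[[1]]$channels, again$image[[1]]$channels)
})

test_that("a halved aggregate burden lowers the mean planted focus score", {
  wt <- small_config(n_aggregates = 4, nuclei_per_aggregate = c(55, 100))
  ko <- small_config(n_aggregates = 2, nuclei_per_aggregate = c(55, 100))
  co <- simulate_cohort(list(WT = wt, KO = ko), n_fields_per_group = 6, seed = 17)
  tr <- cohort_truth(co)
  m <- tapply(tr$true_focus_score, tr$group, mean)
  expect_lt(m[["KO"]], m[["WT"]])
})

test_that("identical configs plant no group effect (null behaviour)", {
  cfg <- simulation_config(
    field_width_px = 300, field_height_px = 300,
    n_aggregates = 2, nuclei_per_aggregate = c(15, 40)
  )
  reject <- vapply(1:100, function(s) {
    co <- simulate_cohort(list(g1 = cfg, g2 = cfg), 10, seed = 5000 + s)
    tr <- cohort_truth(co)
    p <- mann_whitney(
      tr$true_aggregate_area_fraction_pct[tr$group == "g1"],
      tr$true_aggregate_area_fraction_pct[tr$group == "g2"]
    )$p_value
    p <= 0.05
  }, logical(1))
  expect_gte(mean(!reject), 0.9)
})
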