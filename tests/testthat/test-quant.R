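test_that("marker areas follow pixel counting and unit conversion", {
  expect_equal(marker_area(matrix(FALSE, 3, 3), 1), 0)
  m <- matrix(FALSE, 40, 50)
  m[1:25, 1:40] <- TRUE # 1000 px
  expect_equal(marker_area(m, 1), 1000)
  expect_equal(marker_area_mm2(m, 1), 0.001)
})

test_that("intersection area agrees with brute force in both modes", {
  a <- matrix(FALSE, 8, 8); a[1:4, ] <- TRUE
  b <- matrix(FALSE, 8, 8); b[5:8, ] <- TRUE
  expect_equal(intersection_area(a, b, 1), 0)
  expect_equal(intersection_area(a, a, 2), marker_area(a, 2))
  expect_error(intersection_area(a, matrix(FALSE, 4, 4), 1), "dimensions")

  set.seed(42)
  for (k in 1:6) {
    ma <- random_mask(64, 64, 0.45)
    mb <- random_mask(64, 64, 0.45)
    brute <- sum(ma & mb) * 1.7^2
    expect_equal(intersection_area(ma, mb, 1.7, mode = "raster"), brute)
    expect_equal(intersection_area(ma, mb, 1.7, mode = "polygon"), brute,
                 tolerance = 1e-12)
  }
})

test_that("aggregate detection finds planted components", {
  f <- simulate_field(small_config(n_aggregates = 2,
                                   nuclei_per_aggregate = 60),
                      seed = 61)
  mt <- get_channel(f$image, "CD3") >= 2100
  mb <- get_channel(f$image, "B220") >= 2100
  aggs <- detect_aggregates(mt, mb, f$image$pixel_size_um)
  expect_equal(nrow(aggs), 2)
  expect_equal(sort(aggs$union_area_um2),
               sort(f$truth$aggregates$union_area_um2))
  empty <- detect_aggregates(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4), 1)
  expect_equal(nrow(empty), 0)
})

test_that("touching T and B sub-clusters form a single aggregate", {
  # separation 1.5 keeps the stained sub-clusters in contact
  f <- simulate_field(
    simulation_config(field_width_px = 600, field_height_px = 600,
                      n_aggregates = 1, nuclei_per_aggregate = 80,
                      segregation_mode = "segregated"),
    seed = 62
  )
  mt <- get_channel(f$image, "CD3") >= 2100
  mb <- get_channel(f$image, "B220") >= 2100
  expect_gt(sum(mt), 0)
  expect_gt(sum(mb), 0)
  aggs <- detect_aggregates(mt, mb, f$image$pixel_size_um)
  expect_equal(nrow(aggs), 1)
})

test_that("nucleus counting recovers planted counts", {
  px <- default_field_geometry()$pixel_size_um
  f <- simulate_field(
    simulation_config(field_width_px = 520, field_height_px = 520,
                      n_aggregates = 1, nuclei_per_aggregate = 60,
                      segregation_mode = "mixed",
                      nucleus_separation_um = 8), # >= 3 nucleus radii apart
    seed = 63
  )
  dapi <- get_channel(f$image, "DAPI")
  mt <- get_channel(f$image, "CD3") >= 2100
  mb <- get_channel(f$image, "B220") >= 2100
  # sparse spacing can split a lone cell's halo off the main footprint, so
  # count over the union of detected footprints
  fp <- sort(unlist(detect_aggregates(mt, mb, f$image$pixel_size_um)$pixels))
  expect_equal(
    count_nuclei(dapi, fp, f$image$pixel_size_um, 2.5,
                 method = "area_ratio", dapi_threshold = 2100),
    60L
  )
  expect_equal(
    count_nuclei(dapi, fp, f$image$pixel_size_um, 2.5,
                 method = "peaks", dapi_threshold = 2100),
    60L
  )
  expect_equal(count_nuclei(dapi, integer(0), px, 2.5), 0L)
  expect_error(count_nuclei(dapi, fp, px, -1), "positive")
})

test_that("peaks counting stays within 15% on dense aggregates", {
  f <- simulate_field(
    simulation_config(field_width_px = 520, field_height_px = 520,
                      n_aggregates = 1, nuclei_per_aggregate = 120,
                      segregation_mode = "mixed"),
    seed = 64
  )
  dapi <- get_channel(f$image, "DAPI")
  mt <- get_channel(f$image, "CD3") >= 2100
  mb <- get_channel(f$image, "B220") >= 2100
  fp <- detect_aggregates(mt, mb, f$image$pixel_size_um)$pixels[[1]]
  n <- count_nuclei(dapi, fp, f$image$pixel_size_um, 2.5,
                    method = "peaks", dapi_threshold = 2100)
  expect_lt(abs(n - 120) / 120, 0.15)
})

test_that("focus calling is strictly more-than-50", {
  aggs <- tibble::tibble(aggregate_id = 1:3, nucleus_count = c(50L, 51L, 200L))
  foci <- detect_foci(aggs)
  expect_equal(foci$nucleus_count, c(51L, 200L))
  expect_equal(nrow(detect_foci(aggs[0, ])), 0)
  expect_equal(nrow(detect_foci(tibble::tibble(nucleus_count = c(10L, 50L)))), 0)
})

test_that("focus score follows the printed formula and is scale invariant", {
  expect_equal(focus_score(0, 3.7), 0)
  expect_equal(focus_score(4, 4), 4)
  expect_equal(focus_score(3, 6), 2)
  expect_error(focus_score(1, 0), "positive")
  for (k in c(2, 5, 11)) {
    expect_equal(focus_score(3 * k, 1.4 * k), focus_score(3, 1.4))
  }
})

test_that("aggregate area fraction is a guarded percentage", {
  expect_equal(aggregate_area_fraction(0, 5), 0)
  expect_equal(aggregate_area_fraction(2.5, 2.5), 100)
  expect_equal(aggregate_area_fraction(0.5, 2), 25)
  expect_error(aggregate_area_fraction(3, 2), "exceeds")
})

test_that("gland area accepts polygons, region sets and masks", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  expect_equal(gland_area_mm2(sq, 1), 1)
  expect_equal(gland_area_mm2(matrix(TRUE, 100, 200), 2), 200 * 100 * 4 / 1e6)
  rs <- region_set(list(sq), pixel_size_um = 1)
  expect_equal(gland_area_mm2(rs), 1)
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(gland_area_mm2(bow, 1), "self-intersecting")
})

test_that("gland polygon truth matches the pipeline's gland area exactly", {
  poly <- rbind(c(30, 20), c(380, 40), c(400, 390), c(25, 370))
  cfg <- small_config(n_aggregates = 1, nuclei_per_aggregate = 60,
                      gland_polygon = poly)
  f <- simulate_field(cfg, seed = 65)
  expect_equal(gland_area_mm2(poly, cfg$pixel_size_um), f$truth$gland_area_mm2)
})

test_that("segregation index covers its defined and degenerate cases", {
  expect_equal(segregation_index(10, 10, 0), 1)
  expect_equal(segregation_index(10, 10, 10), 0)
  expect_equal(segregation_index(10, 0, 0), 1)
  expect_true(is.na(segregation_index(0, 0, 0)))
  aggs <- tibble::tibble(
    t_area_um2 = c(10, 10, 0), b_area_um2 = c(10, 10, 0),
    intersection_area_um2 = c(0, 8, 0)
  )
  cl <- segregation_classify(aggs)
  expect_identical(cl$segregated, c(TRUE, FALSE, NA))
  expect_equal(segregated_prevalence_pct(cl), 50)
  expect_true(is.na(segregated_prevalence_pct(cl[3, ])))
})

test_that("union identity holds for detected aggregates", {
  f <- simulate_field(small_config(n_aggregates = 3,
                                   nuclei_per_aggregate = c(20, 70),
                                   segregation_mode = "mixed"),
                      seed = 66)
  mt <- get_channel(f$image, "CD3") >= 2100
  mb <- get_channel(f$image, "B220") >= 2100
  aggs <- detect_aggregates(mt, mb, f$image$pixel_size_um)
  with(aggs, {
    expect_equal(union_area_um2,
                 t_area_um2 + b_area_um2 - intersection_area_um2)
    expect_true(all(intersection_area_um2 <= pmin(t_area_um2, b_area_um2)))
  })
})

test_that("field cell counts classify nuclei by mask membership", {
  ma <- matrix(FALSE, 20, 20); ma[1:20, 1:10] <- TRUE  # x in [0,10)
  mb <- matrix(FALSE, 20, 20); mb[1:10, 1:20] <- TRUE  # y in [0,10)
  pos <- cbind(x = rep(c(2.5, 6.5), each = 5), y = seq(0.5, 19.5, length.out = 10))
  # all 10 in A; those with y < 10 also in B
  res <- field_cell_counts(pos, ma, mb)
  expect_equal(res$n_cells_markerA, 10)
  expect_equal(res$n_cells_markerA_and_B, sum(pos[, 2] < 10))
  expect_equal(res$pct_double_positive, 100 * res$n_cells_markerA_and_B / 10)
  none <- field_cell_counts(pos, !ma & FALSE, mb)
  expect_true(is.na(none$pct_double_positive))
})

test_that("planted double-positive fractions are recovered per field", {
  f <- simulate_field(small_config(n_aggregates = 2,
                                   nuclei_per_aggregate = 80,
                                   segregation_mode = "mixed",
                                   nucleus_separation_um = 9),
                      seed = 67)
  mt <- get_channel(f$image, "CD3") >= 2100
  md <- get_channel(f$image, "DAPI") >= 2100
  # nucleus positions recovered from the DAPI raster component centroids
  labs <- label_components(md, 8)
  nr <- nrow(md)
  cents <- do.call(rbind, lapply(seq_len(max(labs)), function(i) {
    ii <- which(labs == i)
    c(mean((ii - 1) %/% nr) + 0.5, mean((ii - 1) %% nr) + 0.5)
  }))
  res <- field_cell_counts(cents, md, mt)
  planted_t <- sum(f$truth$aggregates$t_area_um2) > 0
  expect_equal(res$n_cells_markerA, sum(f$truth$aggregates$nucleus_count))
  expect_true(res$pct_double_positive > 0 && res$pct_double_positive < 100)
})
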