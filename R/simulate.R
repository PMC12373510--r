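#' Configuration for the synthetic sialadenitis field simulator
#'
#' Describes one simulated immunofluorescence field: a gland region containing
#' planted lymphocytic aggregates. Each aggregate is a disc-shaped cluster of
#' stamped nuclei; every nucleus carries a T- or B-cell identity
#' (Bernoulli(`t_fraction`)) and paints a stained-cell disc of radius
#' `cell_radius_um` into the matching marker channel (`CD3` for T, `B220` for
#' B), while all nuclei paint `nucleus_radius_um` discs into `DAPI`. Under
#' `segregation_mode = "segregated"` the T and B nuclei occupy two sub-cluster
#' discs whose centres are `separation_factor` aggregate radii apart; under
#' `"mixed"` all nuclei share one disc.
#'
#' Default geometry reproduces the protocol's fixed evaluated field area of
#' 1,229,054.6934 um^2 (see [default_field_geometry()]). Nucleus centres are
#' snapped to pixel centres and placed with a minimum centre-to-centre
#' separation slightly above one nucleus diameter, so stamped nuclear discs
#' never share a pixel and every nucleus contributes an identical discrete
#' footprint: DAPI-positive area inside an aggregate is then an exact multiple
#' of the nominal nucleus footprint.
#'
#' @param field_width_px,field_height_px Field size in pixels.
#' @param pixel_size_um Pixel side length (um).
#' @param gland_polygon Optional simple polygon (n x 2 matrix of pixel
#'   coordinates, x then y) delimiting the gland; `NULL` means the whole field
#'   is gland.
#' @param n_aggregates Number of planted aggregates (>= 0).
#' @param nuclei_per_aggregate Either a single integer (fixed count) or a
#'   length-2 integer range sampled uniformly per aggregate.
#' @param t_fraction Probability that a nucleus is a T cell, in \[0, 1\].
#' @param segregation_mode `"segregated"` or `"mixed"`.
#' @param separation_factor Distance between T and B sub-cluster centres, in
#'   units of the aggregate radius (>= 0; forced to 0 under `"mixed"`).
#' @param nucleus_radius_um Nucleus (DAPI) disc radius (um).
#' @param nucleus_separation_um Minimum nucleus centre-to-centre distance
#'   (um); default one nucleus diameter plus a small snap margin, which keeps
#'   stamped nuclear discs pixel-disjoint. Larger values spread nuclei out
#'   (sparser, better-resolved infiltrates).
#' @param cell_radius_um Stained-cell (marker) disc radius (um); must be >=
#'   `nucleus_radius_um`.
#' @param marker_intensity Named intensities for channels `DAPI`, `CD3`,
#'   `B220` (arbitrary camera units, 16-bit range).
#' @param background_intensity Constant background level (>= 0).
#' @param noise_sd Standard deviation of additive Gaussian noise, clipped at 0.
#' @return A `simulation_config` object (a validated named list).
#' @examples
#' cfg <- simulation_config(n_aggregates = 2, nuclei_per_aggregate = 80)
#' @export
simulation_config <- function(field_width_px = FIELD_WIDTH_PX,
                              field_height_px = FIELD_HEIGHT_PX,
                              pixel_size_um = DEFAULT_PIXEL_SIZE_UM,
                              gland_polygon = NULL,
                              n_aggregates = 6,
                              nuclei_per_aggregate = c(30L, 110L),
                              t_fraction = 0.5,
                              segregation_mode = c("segregated", "mixed"),
                              separation_factor = 1.5,
                              nucleus_radius_um = 2.5,
                              nucleus_separation_um = NULL,
                              cell_radius_um = 7,
                              marker_intensity = c(DAPI = 4000, CD3 = 4000, B220 = 4000),
                              background_intensity = 200,
                              noise_sd = 0) {
  segregation_mode <- match.arg(segregation_mode)
  stopifnot_scalar_positive(field_width_px, "field_width_px")
  stopifnot_scalar_positive(field_height_px, "field_height_px")
  stopifnot_scalar_positive(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_positive(nucleus_radius_um, "nucleus_radius_um")
  stopifnot_scalar_positive(cell_radius_um, "cell_radius_um")
  if (cell_radius_um < nucleus_radius_um) {
    abort("`cell_radius_um` must be >= `nucleus_radius_um`.")
  }
  if (is.null(nucleus_separation_um)) {
    nucleus_separation_um <- 2 * nucleus_radius_um + NUCLEUS_SEP_MARGIN_UM
  }
  if (!is_scalar_number(nucleus_separation_um) ||
      nucleus_separation_um < 2 * nucleus_radius_um) {
    abort("`nucleus_separation_um` must be at least one nucleus diameter.")
  }
  if (!is_scalar_number(n_aggregates) || n_aggregates < 0 ||
      n_aggregates != round(n_aggregates)) {
    abort("`n_aggregates` must be a non-negative integer.")
  }
  if (!is.numeric(nuclei_per_aggregate) ||
      !length(nuclei_per_aggregate) %in% c(1L, 2L) ||
      any(nuclei_per_aggregate < 1) ||
      any(nuclei_per_aggregate != round(nuclei_per_aggregate))) {
    abort("`nuclei_per_aggregate` must be a positive integer or integer range.")
  }
  if (length(nuclei_per_aggregate) == 2L &&
      nuclei_per_aggregate[2] < nuclei_per_aggregate[1]) {
    abort("`nuclei_per_aggregate` range must be increasing.")
  }
  if (!is_scalar_number(t_fraction) || t_fraction < 0 || t_fraction > 1) {
    abort("`t_fraction` must lie in [0, 1].")
  }
  if (!is_scalar_number(separation_factor) || separation_factor < 0) {
    abort("`separation_factor` must be >= 0.")
  }
  if (segregation_mode == "mixed") separation_factor <- 0
  if (!is_scalar_number(background_intensity) || background_intensity < 0) {
    abort("`background_intensity` must be >= 0.")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.")
  }
  need <- c("DAPI", "CD3", "B220")
  if (is.null(names(marker_intensity)) || !all(need %in% names(marker_intensity)) ||
      any(marker_intensity <= 0)) {
    abort("`marker_intensity` must be positive and named DAPI, CD3, B220.")
  }
  if (!is.null(gland_polygon)) {
    gland_polygon <- validate_simple_polygon(gland_polygon)
  }
  structure(
    list(
      field_width_px = as.integer(field_width_px),
      field_height_px = as.integer(field_height_px),
      pixel_size_um = pixel_size_um,
      gland_polygon = gland_polygon,
      n_aggregates = as.integer(n_aggregates),
      nuclei_per_aggregate = as.integer(nuclei_per_aggregate),
      t_fraction = t_fraction,
      segregation_mode = segregation_mode,
      separation_factor = separation_factor,
      nucleus_radius_um = nucleus_radius_um,
      nucleus_separation_um = nucleus_separation_um,
      cell_radius_um = cell_radius_um,
      marker_intensity = marker_intensity[need],
      background_intensity = background_intensity,
      noise_sd = noise_sd
    ),
    class = "simulation_config"
  )
}

# packing fraction used to size a cluster disc for n non-overlapping nuclei
NUCLEUS_PACKING <- 0.4
# minimum nucleus centre separation margin beyond one diameter (um); keeps
# pixel-snapped nuclear discs disjoint
NUCLEUS_SEP_MARGIN_UM <- 0.2

cluster_radius_um <- function(n, sep_um) {
  (sep_um / 2) * sqrt(max(n, 1) / NUCLEUS_PACKING)
}

#' Discrete footprint size of one stamped nucleus
#'
#' Number of pixels whose centres fall within `radius_um` of a pixel centre.
#' Because the simulator snaps nucleus centres to pixel centres, every stamped
#' nucleus covers exactly this many pixels.
#'
#' @param radius_um Disc radius (um).
#' @param pixel_size_um Pixel size (um).
#' @return Integer pixel count.
#' @export
nominal_nucleus_footprint_px <- function(radius_um, pixel_size_um) {
  r <- radius_um / pixel_size_um
  k <- floor(r)
  dx <- seq(-k, k)
  sum(outer(dx, dx, function(a, b) a^2 + b^2) <= r^2)
}

# RSA placement of n points in a disc (local coords, um) with min separation;
# points snapped to the pixel lattice before acceptance.
place_nuclei_disc <- function(n, centre_um, radius_um, sep_um, pixel_size_um) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 600L * n
  sep2 <- sep_um^2
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    a <- runif(1, 0, 2 * pi)
    d <- radius_um * sqrt(runif(1))
    p <- centre_um + c(cos(a), sin(a)) * d
    # snap to the centre of the containing pixel
    p <- (floor(p / pixel_size_um) + 0.5) * pixel_size_um
    if (placed > 0L) {
      dd <- (pts[seq_len(placed), 1] - p[1])^2 + (pts[seq_len(placed), 2] - p[2])^2
      if (min(dd) < sep2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- p
  }
  if (placed < n) {
    abort(sprintf("could not place %d nuclei in a cluster disc (placed %d).", n, placed))
  }
  pts
}

# stamp discs of radius r_um centred at pts (um) into a logical mask
stamp_discs <- function(mask, pts_um, r_um, pixel_size_um) {
  if (nrow(pts_um) == 0) return(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  r_px <- r_um / pixel_size_um
  k <- ceiling(r_px)
  for (i in seq_len(nrow(pts_um))) {
    cx <- pts_um[i, 1] / pixel_size_um # pixel coords (continuous)
    cy <- pts_um[i, 2] / pixel_size_um
    x0 <- max(0L, floor(cx - k)); x1 <- min(nc - 1L, ceiling(cx + k))
    y0 <- max(0L, floor(cy - k)); y1 <- min(nr - 1L, ceiling(cy + k))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1
    ys <- y0:y1
    inside <- outer(ys + 0.5 - cy, xs + 0.5 - cx, function(a, b) a^2 + b^2) <= r_px^2
    mask[ys + 1L, xs + 1L] <- mask[ys + 1L, xs + 1L] | inside
  }
  mask
}

point_in_polygon <- function(px, py, poly) {
  # even-odd ray cast; vertices poly[,1]=x, poly[,2]=y
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    x1 <- poly[j[k], 1]; y1 <- poly[j[k], 2]
    x2 <- poly[k, 1]; y2 <- poly[k, 2]
    cross <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, cross)
  }
  inside
}

#' Simulate one salivary-gland immunofluorescence field
#'
#' Generates a three-channel field (`DAPI`, `CD3`, `B220`) with planted
#' peri-glandular lymphocytic aggregates, plus exhaustive per-aggregate ground
#' truth measured from the noise-free label rasters (not analytically
#' approximated). Identical `(config, seed)` pairs reproduce bit-identical
#' output.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for all randomness in this field.
#' @return A list with elements `image` (a [multiplex_image()]) and `truth`
#'   (a `ground_truth` list; see Details).
#' @details The `truth` element contains `gland_area_mm2`, a per-aggregate
#'   tibble (`aggregate_id`, `nucleus_count`, `t_area_um2`, `b_area_um2`,
#'   `intersection_area_um2`, `union_area_um2`, `segregated`, `centre_x_px`,
#'   `centre_y_px`), `n_foci` (aggregates with more than 50 nuclei),
#'   `true_focus_score` = `(n_foci / gland_area_mm2) * 4`, and
#'   `true_aggregate_area_fraction_pct` = 100 x (total stained aggregate
#'   area) / gland area.
#' @examples
#' f <- simulate_field(simulation_config(
#'   field_width_px = 300, field_height_px = 300,
#'   n_aggregates = 1, nuclei_per_aggregate = 20
#' ), seed = 1)
#' f$truth$n_foci
#' @export
simulate_field <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  px <- config$pixel_size_um
  W <- config$field_width_px
  H <- config$field_height_px
  sep_um <- config$nucleus_separation_um

  gland_area_mm2 <- if (is.null(config$gland_polygon)) {
    W * H * px^2 / 1e6
  } else {
    polygon_area_px(config$gland_polygon) * px^2 / 1e6
  }

  # per-aggregate nucleus counts
  rng <- config$nuclei_per_aggregate
  n_agg <- config$n_aggregates
  counts <- if (n_agg == 0) {
    integer(0)
  } else if (length(rng) == 1L) {
    rep(rng, n_agg)
  } else {
    sample(rng[1]:rng[2], n_agg, replace = TRUE)
  }

  dapi_mask <- matrix(FALSE, H, W)
  t_mask <- matrix(FALSE, H, W)
  b_mask <- matrix(FALSE, H, W)
  agg_rows <- vector("list", n_agg)
  centres <- matrix(numeric(0), 0, 2) # um
  extents <- numeric(0)
  clearance_um <- 3 * px

  for (i in seq_len(n_agg)) {
    n_i <- counts[i]
    R_i <- cluster_radius_um(n_i, sep_um)
    is_t <- runif(n_i) < config$t_fraction
    nT <- sum(is_t)
    nB <- n_i - nT
    if (config$segregation_mode == "segregated" && nT > 0 && nB > 0) {
      rT <- cluster_radius_um(nT, sep_um)
      rB <- cluster_radius_um(nB, sep_um)
      d <- config$separation_factor * R_i
      extent_i <- max(rT, rB) + d / 2 + config$cell_radius_um
    } else {
      extent_i <- R_i + config$cell_radius_um
    }
    # place aggregate centre
    placed <- FALSE
    for (try in seq_len(1000L)) {
      c_um <- c(runif(1, extent_i + px, W * px - extent_i - px),
                runif(1, extent_i + px, H * px - extent_i - px))
      if (W * px < 2 * (extent_i + px) || H * px < 2 * (extent_i + px)) break
      if (!is.null(config$gland_polygon)) {
        ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
        probe <- cbind(c_um[1] + cos(ang) * (extent_i + px),
                       c_um[2] + sin(ang) * (extent_i + px)) / px
        if (!all(point_in_polygon(probe[, 1], probe[, 2], config$gland_polygon)) ||
            !point_in_polygon(c_um[1] / px, c_um[2] / px, config$gland_polygon)) {
          next
        }
      }
      if (nrow(centres) > 0) {
        dd <- sqrt((centres[, 1] - c_um[1])^2 + (centres[, 2] - c_um[2])^2)
        if (any(dd <= extents + extent_i + clearance_um)) next
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf("failed to place aggregate %d after 1000 attempts.", i))
    }
    centres <- rbind(centres, c_um)
    extents <- c(extents, extent_i)

    # place nuclei
    if (config$segregation_mode == "segregated" && nT > 0 && nB > 0) {
      u <- runif(1, 0, 2 * pi)
      dvec <- c(cos(u), sin(u)) * (config$separation_factor * R_i / 2)
      ptsT <- place_nuclei_disc(nT, c_um + dvec, cluster_radius_um(nT, sep_um),
                                sep_um, px)
      ptsB <- place_nuclei_disc(nB, c_um - dvec, cluster_radius_um(nB, sep_um),
                                sep_um, px)
    } else {
      pts <- place_nuclei_disc(n_i, c_um, R_i, sep_um, px)
      ptsT <- pts[is_t, , drop = FALSE]
      ptsB <- pts[!is_t, , drop = FALSE]
    }

    t_i <- stamp_discs(matrix(FALSE, H, W), ptsT, config$cell_radius_um, px)
    b_i <- stamp_discs(matrix(FALSE, H, W), ptsB, config$cell_radius_um, px)
    dapi_mask <- stamp_discs(dapi_mask, rbind(ptsT, ptsB),
                             config$nucleus_radius_um, px)
    t_mask <- t_mask | t_i
    b_mask <- b_mask | b_i
    agg_rows[[i]] <- tibble(
      aggregate_id = i,
      nucleus_count = n_i,
      t_area_um2 = sum(t_i) * px^2,
      b_area_um2 = sum(b_i) * px^2,
      intersection_area_um2 = sum(t_i & b_i) * px^2,
      union_area_um2 = sum(t_i | b_i) * px^2,
      segregated = config$segregation_mode == "segregated",
      centre_x_px = c_um[1] / px,
      centre_y_px = c_um[2] / px
    )
  }

  aggregates <- if (n_agg > 0) dplyr::bind_rows(agg_rows) else tibble(
    aggregate_id = integer(), nucleus_count = integer(),
    t_area_um2 = numeric(), b_area_um2 = numeric(),
    intersection_area_um2 = numeric(), union_area_um2 = numeric(),
    segregated = logical(), centre_x_px = numeric(), centre_y_px = numeric()
  )

  n_foci <- sum(aggregates$nucleus_count > 50L)
  truth <- structure(
    list(
      gland_area_mm2 = gland_area_mm2,
      aggregates = aggregates,
      n_foci = n_foci,
      true_focus_score = n_foci / gland_area_mm2 * 4,
      true_aggregate_area_fraction_pct =
        100 * (sum(t_mask | b_mask) * px^2) / (gland_area_mm2 * 1e6)
    ),
    class = "ground_truth"
  )

  paint <- function(mask, level) {
    ch <- matrix(config$background_intensity, H, W)
    ch[mask] <- level
    if (config$noise_sd > 0) ch <- ch + rnorm(H * W, 0, config$noise_sd)
    matrix(pmin(pmax(round(ch), 0), 65535), H, W)
  }
  img <- multiplex_image(
    list(
      DAPI = paint(dapi_mask, config$marker_intensity[["DAPI"]]),
      CD3 = paint(t_mask, config$marker_intensity[["CD3"]]),
      B220 = paint(b_mask, config$marker_intensity[["B220"]])
    ),
    pixel_size_um = px
  )
  list(image = img, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> gland %.4f mm^2, %d aggregates, %d foci, focus score %.3f, area fraction %.3f%%\n",
    x$gland_area_mm2, nrow(x$aggregates), x$n_foci,
    x$true_focus_score, x$true_aggregate_area_fraction_pct
  ))
  invisible(x)
}

#' @method tidy ground_truth
#' @export
tidy.ground_truth <- function(x, ...) x$aggregates

#' @method glance ground_truth
#' @export
glance.ground_truth <- function(x, ...) {
  tibble(
    gland_area_mm2 = x$gland_area_mm2,
    n_aggregates = nrow(x$aggregates),
    n_foci = x$n_foci,
    true_focus_score = x$true_focus_score,
    true_aggregate_area_fraction_pct = x$true_aggregate_area_fraction_pct
  )
}

#' Simulate a grouped cohort of fields
#'
#' Deterministic per-field sub-seeding derived from `(seed, group index,
#' field index)`, so a cohort is reproducible as a whole and each field is
#' reproducible on its own.
#'
#' @param group_configs Named list of [simulation_config()] objects, one per
#'   group (names must be unique).
#' @param n_fields_per_group Fields per group (>= 1).
#' @param seed Master integer seed.
#' @return A tibble with columns `group`, `field`, `seed`, `image`
#'   (list-column of [multiplex_image()]) and `truth` (list-column of ground
#'   truths).
#' @examples
#' cfg <- simulation_config(field_width_px = 256, field_height_px = 256,
#'                          n_aggregates = 1, nuclei_per_aggregate = 20)
#' co <- simulate_cohort(list(wt = cfg), n_fields_per_group = 1, seed = 7)
#' nrow(co)
#' @export
simulate_cohort <- function(group_configs, n_fields_per_group, seed) {
  if (!is.list(group_configs) || length(group_configs) < 1L) {
    abort("`group_configs` must be a non-empty named list of configs.")
  }
  nms <- names(group_configs)
  if (is.null(nms) || any(!nzchar(nms))) abort("every group needs a name.")
  if (anyDuplicated(nms)) abort("duplicate group names.")
  if (!is_scalar_number(n_fields_per_group) || n_fields_per_group < 1) {
    abort("`n_fields_per_group` must be >= 1.")
  }
  grid <- tidyr::expand_grid(group = nms, field = seq_len(n_fields_per_group))
  grid$seed <- vapply(seq_len(nrow(grid)), function(i) {
    g <- match(grid$group[i], nms)
    (as.double(seed) + 1000003 * g + 797 * grid$field[i]) %% 2147483647
  }, numeric(1))
  sims <- purrr::map2(grid$group, seq_len(nrow(grid)), function(g, i) {
    simulate_field(group_configs[[g]], seed = grid$seed[i])
  })
  grid$image <- purrr::map(sims, "image")
  grid$truth <- purrr::map(sims, "truth")
  grid
}

#' Pooled ground-truth summary of a simulated cohort
#'
#' @param cohort Result of [simulate_cohort()].
#' @return Tibble with one row per field: group, field, planted gland-level
#'   truths.
#' @export
cohort_truth <- function(cohort) {
  dplyr::bind_cols(
    cohort[, c("group", "field")],
    dplyr::bind_rows(purrr::map(cohort$truth, glance))
  )
}
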