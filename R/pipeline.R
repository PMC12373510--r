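# Orchestration: simulate -> classify -> quantify -> compare, with logged,
# deterministic runs and figure-ready output tables.

GLAND_ENDPOINTS <- c("focus_score", "aggregate_area_fraction_pct",
                     "t_area_um2", "b_area_um2", "intersection_area_um2",
                     "segregated_prevalence_pct")

#' Write a simulated cohort to disk
#'
#' One TIFF (+ JSON sidecar) and one ground-truth JSON per field, plus a
#' pooled per-aggregate CSV and a per-field CSV.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_field%02d", cohort$group, cohort$field)
  for (i in seq_len(nrow(cohort))) {
    write_field_tiff(cohort$image[[i]], file.path(out_dir, paste0(stem[i], ".tif")))
    tr <- cohort$truth[[i]]
    jsonlite::write_json(
      list(gland_area_mm2 = tr$gland_area_mm2,
           n_foci = tr$n_foci,
           true_focus_score = tr$true_focus_score,
           true_aggregate_area_fraction_pct = tr$true_aggregate_area_fraction_pct,
           aggregates = tr$aggregates),
      file.path(out_dir, paste0(stem[i], "_truth.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  agg <- dplyr::bind_rows(purrr::pmap(
    cohort[, c("group", "field", "truth")],
    function(group, field, truth) {
      dplyr::mutate(truth$aggregates, group = group, field = field,
                    .before = 1)
    }
  ))
  write.csv(agg, file.path(out_dir, "truth_aggregates.csv"), row.names = FALSE)
  write.csv(cohort_truth(cohort), file.path(out_dir, "truth_fields.csv"),
            row.names = FALSE)
  invisible(out_dir)
}

#' Quantify a cohort of fields
#'
#' Runs [quantify_field()] over every field of a simulated cohort (or a set
#' of TIFF paths) and pools the results. With `out_dir`, writes
#' `gland_metrics.csv`, `aggregate_metrics.csv` and a run log listing every
#' resolved parameter; reruns with the same inputs are byte-identical.
#'
#' @param fields A [simulate_cohort()] tibble, a named list of
#'   [multiplex_image()]s, or a character vector of TIFF paths.
#' @param out_dir Optional output directory.
#' @param ... Passed to [quantify_field()] (thresholds, gland, limits, ...).
#' @return List with tibbles `glands` (one row per field) and `aggregates`
#'   (one row per aggregate).
#' @export
run_quantification <- function(fields, out_dir = NULL, ...) {
  if (is.character(fields)) {
    imgs <- lapply(fields, read_field_tiff)
    meta <- tibble(group = "all", field = seq_along(imgs),
                   id = basename(fields))
  } else if (is.data.frame(fields)) {
    imgs <- fields$image
    meta <- tibble(group = fields$group, field = fields$field,
                   id = sprintf("%s_field%02d", fields$group, fields$field))
  } else {
    imgs <- fields
    meta <- tibble(group = "all", field = seq_along(imgs),
                   id = names(imgs) %||% sprintf("field%02d", seq_along(imgs)))
  }
  res <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    res[[i]] <- tryCatch(
      quantify_field(imgs[[i]], ...),
      error = function(e) {
        abort(sprintf("field '%s': %s", meta$id[i], conditionMessage(e)))
      }
    )
  }
  glands <- dplyr::bind_cols(meta, dplyr::bind_rows(purrr::map(res, glance)))
  aggregates <- dplyr::bind_rows(purrr::map2(res, seq_along(res), function(r, i) {
    if (nrow(r$aggregates) == 0) return(NULL)
    dplyr::bind_cols(meta[rep(i, nrow(r$aggregates)), ], r$aggregates)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(glands, file.path(out_dir, "gland_metrics.csv"), row.names = FALSE)
    write.csv(aggregates, file.path(out_dir, "aggregate_metrics.csv"),
              row.names = FALSE)
    params <- c(list(...), res[[1]]$params[setdiff(names(res[[1]]$params),
                                                   names(list(...)))])
    writeLines(c(
      sprintf("elsquant %s quantification run", as.character(packageVersion("elsquant"))),
      sprintf("fields: %d", length(imgs)),
      vapply(names(params), function(k) {
        sprintf("%s = %s", k, paste(format(params[[k]]), collapse = ","))
      }, character(1))
    ), file.path(out_dir, "run_log.txt"))
  }
  list(glands = glands, aggregates = aggregates)
}

summary_quartiles <- function(v) {
  tibble(median = median(v), q25 = unname(quantile(v, 0.25)),
         q75 = unname(quantile(v, 0.75)), min = min(v), max = max(v))
}

#' Compare quantified endpoints between groups
#'
#' One row per endpoint per group pair, with box-plot summaries (median,
#' 25th/75th percentiles, min, max per group), the Mann-Whitney U test
#' (or Wilcoxon signed-rank when `paired = TRUE`, pairing rows by `field`),
#' and significance stars.
#'
#' @param glands Per-field metrics tibble from [run_quantification()] (needs
#'   a `group` column).
#' @param endpoints Endpoint column names (default: the gland-level panel).
#' @param paired Use the paired signed-rank test (requires equal group
#'   sizes, matched by field order).
#' @return Tibble of comparisons.
#' @export
run_comparison <- function(glands, endpoints = GLAND_ENDPOINTS, paired = FALSE) {
  stopifnot(is.data.frame(glands), "group" %in% names(glands))
  bad <- setdiff(endpoints, names(glands))
  if (length(bad)) {
    abort(sprintf("unknown endpoint(s) %s; available: %s",
                  paste(bad, collapse = ", "),
                  paste(intersect(GLAND_ENDPOINTS, names(glands)),
                        collapse = ", ")))
  }
  groups <- unique(glands$group)
  if (length(groups) < 2) abort("need at least two groups to compare.")
  pairs <- combn(groups, 2, simplify = FALSE)
  out <- list()
  for (ep in endpoints) {
    for (gp in pairs) {
      v1 <- glands[[ep]][glands$group == gp[1]]
      v2 <- glands[[ep]][glands$group == gp[2]]
      keep1 <- !is.na(v1); keep2 <- !is.na(v2)
      test <- if (paired) {
        wilcoxon_signed_rank(v1[keep1 & keep2], v2[keep1 & keep2])
      } else {
        mann_whitney(v1[keep1], v2[keep2])
      }
      q1 <- summary_quartiles(v1[keep1]); q2 <- summary_quartiles(v2[keep2])
      names(q1) <- paste0(names(q1), "_1"); names(q2) <- paste0(names(q2), "_2")
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble(endpoint = ep, group1 = gp[1], group2 = gp[2],
               n1 = sum(keep1), n2 = sum(keep2)),
        q1, q2,
        tibble(statistic = test$statistic, p.value = test$p_value,
               method = test$method, exact = test$exact,
               stars = significance_stars(test$p_value))
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate, quantify and compare a two-group demonstration cohort
#'
#' A wild-type-like group against a treated/knockout-like group with halved
#' aggregate burden, run end to end: simulation with planted truth,
#' threshold classification, quantification and group comparison.
#'
#' @param seed Master seed.
#' @param n_fields_per_group Fields per group.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @param field_width_px,field_height_px Simulated field size (defaults to
#'   a reduced 512 px field to keep the demonstration fast).
#' @param noise_sd Additive noise level (camera units).
#' @return List: `truth` (per-field planted truth), `glands`, `aggregates`,
#'   `comparison`.
#' @export
run_demo_cohort <- function(seed = 1, n_fields_per_group = 10, out_dir = NULL,
                            field_width_px = 512, field_height_px = 512,
                            noise_sd = 0) {
  wt <- simulation_config(
    field_width_px = field_width_px, field_height_px = field_height_px,
    n_aggregates = 3, nuclei_per_aggregate = c(30, 110), noise_sd = noise_sd
  )
  ko <- simulation_config(
    field_width_px = field_width_px, field_height_px = field_height_px,
    n_aggregates = 1, nuclei_per_aggregate = c(30, 110), noise_sd = noise_sd
  )
  cohort <- simulate_cohort(list(WT = wt, KO = ko), n_fields_per_group, seed)
  if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "fields"))
  q <- run_quantification(
    cohort,
    out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "metrics")
  )
  cmp <- run_comparison(q$glands)
  if (!is.null(out_dir)) {
    write.csv(cmp, file.path(out_dir, "comparison.csv"), row.names = FALSE)
  }
  list(truth = cohort_truth(cohort), glands = q$glands,
       aggregates = q$aggregates, comparison = cmp)
}

#' Read a plain-text pipeline configuration
#'
#' `key = value` lines (TOML-like; `#` comments). Numeric-looking values are
#' converted; repeated dotted keys (`threshold.CD3 = 400`) become named
#' vectors under the prefix.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort(sprintf("cannot parse config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    if (grepl(".", key, fixed = TRUE)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      sub <- out[[parts[1]]] %||% list()
      sub[[parts[2]]] <- val
      out[[parts[1]]] <- sub
    } else {
      out[[key]] <- val
    }
  }
  out
}
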