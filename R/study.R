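#' Run the full congruence study on a cohort
#'
#' For every specimen x level cloud, reconstructs the five exposure
#' configurations (A both, B left/right, C left/right), fits the three
#' symmetric primitives at the chosen tolerance, and emits one congruence
#' record per (specimen, level, group, side, shape): the observation unit of
#' the study's per-level tables and raw ITPR datasets. Normals are estimated
#' once per full cloud and carried through the reconstruction subsets so
#' cylinder fits across groups share the same local-surface estimates.
#'
#' Summaries computed from the records:
#' * `group_summary`, `region_summary` — mean +/- sample SD of ITPR by
#'   (group, shape) and (region, group, shape);
#' * `table1` — per-level Group B-A and C-B ITPR differences (mean +/- SD
#'   across specimens), three shapes wide;
#' * `reductions` — percent reduction in mean ITPR for the two study
#'   contrasts: laterality (unilateral B+C vs bilateral A) and
#'   spinous-process inclusion (C vs B), per shape.
#'
#' A failing cell (reconstruction or fit error) is logged as a warning and
#' skipped; the study aborts if more than `max_abort_frac` of cells fail.
#'
#' @param cohort A tibble from [generate_cohort()] (columns `specimen`,
#'   `level`, `region`, `seed`, `cloud`).
#' @param epsilon Maximum inlier distance in mm.
#' @param iterations RANSAC iterations per fit.
#' @param refine,normal_k Passed to [ransac_fit()].
#' @param max_abort_frac Maximum tolerated fraction of failed cells.
#' @return A `congruence_study` object: list with `records` (tibble),
#'   the summary tibbles above, `aborted`, and the configuration echo.
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
run_study <- function(cohort, epsilon = 0.5, iterations = 100,
                      refine = TRUE, normal_k = 20, max_abort_frac = 0.1) {
  stopifnot(all(c("specimen", "level", "region", "seed", "cloud") %in% names(cohort)))
  cells <- tidyr::expand_grid(
    row = seq_len(nrow(cohort)),
    config = list(list(group = "A", side = "both", offset = 10L),
                  list(group = "B", side = "left", offset = 20L),
                  list(group = "B", side = "right", offset = 30L),
                  list(group = "C", side = "left", offset = 40L),
                  list(group = "C", side = "right", offset = 50L)))
  records <- list()
  aborted <- list()
  for (ri in seq_len(nrow(cohort))) {
    cl <- cohort$cloud[[ri]]
    cl <- tryCatch(estimate_normals(cl, k = normal_k), error = function(e) cl)
    for (cfg in cells$config[cells$row == ri]) {
      base_seed <- cohort$seed[ri] + cfg$offset
      rec <- tryCatch({
        sub <- reconstruct_group(cl, cfg$group, cfg$side)
        prof <- congruence_profile(sub, epsilon = epsilon,
                                   iterations = iterations, seed = base_seed,
                                   refine = refine, normal_k = normal_k)
        tibble::tibble(
          specimen = cohort$specimen[ri], level = cohort$level[ri],
          region = cohort$region[ri], group = cfg$group, side = cfg$side,
          shape = prof$shape, epsilon = epsilon, itpr = prof$itpr,
          rmse = prof$rmse, n_points = prof$n_points, seed = prof$seed)
      }, error = function(e) {
        warn(sprintf("cell %s %s Group %s (%s) failed: %s",
                     cohort$specimen[ri], cohort$level[ri], cfg$group,
                     cfg$side, conditionMessage(e)))
        NULL
      })
      if (is.null(rec)) {
        aborted[[length(aborted) + 1]] <- tibble::tibble(
          specimen = cohort$specimen[ri], level = cohort$level[ri],
          group = cfg$group, side = cfg$side)
      } else {
        records[[length(records) + 1]] <- rec
      }
    }
  }
  aborted <- dplyr::bind_rows(aborted)
  n_cells <- nrow(cohort) * 5
  if (nrow(aborted) > max_abort_frac * n_cells) {
    abort(sprintf("study failed: %d of %d cells aborted", nrow(aborted), n_cells))
  }
  records <- dplyr::bind_rows(records)

  structure(list(
    records = records,
    group_summary = summarize_cells(records, .data$itpr, group, shape),
    region_summary = summarize_cells(records, .data$itpr, region, group, shape),
    table1 = study_table1(records),
    reductions = study_reductions(records),
    aborted = aborted,
    config = list(epsilon = epsilon, iterations = iterations,
                  refine = refine, normal_k = normal_k,
                  n_specimens = length(unique(cohort$specimen)),
                  levels = unique(cohort$level))
  ), class = "congruence_study")
}

# per-level Group B-A and C-B ITPR differences, mean +/- SD across specimens
study_table1 <- function(records) {
  per_cell <- records |>
    dplyr::group_by(.data$specimen, .data$level, .data$region, .data$group,
                    .data$shape) |>
    dplyr::summarise(itpr = mean(.data$itpr), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "itpr")
  per_cell |>
    dplyr::mutate(`Group B-A` = .data$B - .data$A,
                  `Group C-B` = .data$C - .data$B) |>
    tidyr::pivot_longer(c("Group B-A", "Group C-B"),
                        names_to = "contrast", values_to = "diff") |>
    dplyr::group_by(.data$level, .data$region, .data$shape, .data$contrast) |>
    dplyr::summarise(mean = mean(.data$diff),
                     sd = ifelse(dplyr::n() > 1, sd(.data$diff), 0),
                     n = dplyr::n(), .groups = "drop")
}

study_reductions <- function(records) {
  by_shape <- split(records, records$shape)
  purrr::map_dfr(by_shape, function(df) {
    lat_pre <- mean(df$itpr[df$group %in% c("B", "C")])
    lat_post <- mean(df$itpr[df$group == "A"])
    sp_pre <- mean(df$itpr[df$group == "C"])
    sp_post <- mean(df$itpr[df$group == "B"])
    tibble::tibble(
      shape = df$shape[1],
      contrast = c("laterality", "sp_inclusion"),
      mean_pre = round(c(lat_pre, sp_pre), 3),
      mean_post = round(c(lat_post, sp_post), 3),
      reduction_pct = c(percent_reduction(lat_pre, lat_post),
                        percent_reduction(sp_pre, sp_post)))
  })
}

#' @export
print.congruence_study <- function(x, ...) {
  cat(sprintf("Congruence study: %d records (%d specimens x %d levels), eps = %g mm\n",
              nrow(x$records), x$config$n_specimens,
              length(x$config$levels), x$config$epsilon))
  cat("\nMean ITPR by exposure group and shape:\n")
  print(x$group_summary, n = Inf)
  cat("\nPercent reductions in mean ITPR:\n")
  print(x$reductions, n = Inf)
  invisible(x)
}

#' Tidiers for congruence studies
#'
#' `tidy()` returns the full record table (one row per specimen x level x
#' group x side x shape); `glance()` a one-row study summary.
#'
#' @param x A `congruence_study`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.congruence_study <- function(x, ...) x$records

#' @rdname tidy.congruence_study
#' @export
glance.congruence_study <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records), n_aborted = nrow(x$aborted),
    n_specimens = x$config$n_specimens, n_levels = length(x$config$levels),
    epsilon = x$config$epsilon, iterations = x$config$iterations)
}

#' Cell-wise mean, SD and count of a measurement column
#'
#' The study's reporting primitive: sample SD (n - 1 denominator); cells
#' with a single observation report SD 0 and are flagged `degenerate`.
#'
#' @param data A data frame of records.
#' @param value Unquoted measurement column (e.g. `itpr`).
#' @param ... Unquoted grouping columns.
#' @return A tibble with `mean`, `sd`, `n`, `degenerate` per cell.
#' @export
summarize_cells <- function(data, value, ...) {
  if (nrow(data) == 0) abort("no records to summarise")
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(mean = mean({{ value }}),
                     sd = ifelse(dplyr::n() > 1, sd({{ value }}), 0),
                     n = dplyr::n(),
                     degenerate = dplyr::n() < 2,
                     .groups = "drop")
}
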