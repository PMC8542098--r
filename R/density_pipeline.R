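# Derivation pipeline behind the cube design: per-dataset percentage gram
# contributions, top-5 ranking, mean-rank aggregation into up-to-10
# representative foods per group, mean group density, conversion of the
# original gram cutoffs into cube volumes, and 1-D clustering of the
# resulting sides into the core cube set.

pipeline_error <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "gdqs_pipeline_error")

#' Keep only the first recall per respondent
#'
#' Multi-recall surveys contribute only their first 24-h recall to the
#' density derivation.
#' @param records Tibble with columns `dataset_id`, `respondent_id`,
#'   `recall_no` and the consumption columns.
#' @return The filtered records.
#' @export
filter_first_recall <- function(records) {
  if (!"recall_no" %in% names(records)) return(tibble::as_tibble(records))
  records |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$dataset_id, .data$respondent_id) |>
    dplyr::filter(.data$recall_no == min(.data$recall_no)) |>
    dplyr::ungroup()
}

#' Percentage gram contribution of each food to its group
#'
#' For each (dataset, group), the gram sum of each food across all
#' respondents divided by the gram sum of the whole group. Groups with zero
#' total grams are omitted; contributions sum to 1 over foods with positive
#' grams.
#'
#' @param records Tibble with `dataset_id`, `respondent_id`, `food_name`,
#'   `group_id`, `grams` (first recalls only; see [filter_first_recall()]).
#' @return Tibble with `dataset_id`, `group_id`, `food_name`, `total_grams`,
#'   `pct_contribution`.
#' @export
compute_contributions <- function(records) {
  records <- tibble::as_tibble(records)
  if (any(records$grams < 0)) pipeline_error("negative gram amounts")
  records |>
    dplyr::group_by(.data$dataset_id, .data$group_id, .data$food_name) |>
    dplyr::summarise(total_grams = sum(.data$grams), .groups = "drop_last") |>
    dplyr::mutate(group_total = sum(.data$total_grams)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$group_total > 0, .data$total_grams > 0) |>
    dplyr::mutate(pct_contribution = .data$total_grams / .data$group_total) |>
    dplyr::select("dataset_id", "group_id", "food_name", "total_grams",
                  "pct_contribution")
}

#' Rank the top contributing foods per dataset and group
#'
#' Within each (dataset, group), the `top_n` foods by percentage gram
#' contribution receive ranks 1 (largest contribution) to
#' `min(top_n, n_foods)`. Ties are broken by larger total gram
#' contribution, then lexicographically by food name.
#'
#' @param contributions Output of [compute_contributions()].
#' @param top_n Number of foods ranked per (dataset, group); default 5.
#' @return Tibble with `dataset_id`, `group_id`, `food_name`,
#'   `pct_contribution`, `rank`.
#' @export
rank_top_foods <- function(contributions, top_n = 5L) {
  contributions |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$dataset_id, .data$group_id,
                   dplyr::desc(.data$pct_contribution),
                   dplyr::desc(.data$total_grams), .data$food_name) |>
    dplyr::group_by(.data$dataset_id, .data$group_id) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("dataset_id", "group_id", "food_name", "pct_contribution", "rank")
}

#' Candidate pool of ranked foods per group
#'
#' Union of the per-dataset ranked foods: with 11 datasets and 5 ranks this
#' pool holds up to 55 foods per group.
#' @param rank_entries Output of [rank_top_foods()] across datasets.
#' @return Tibble with `group_id`, `pool_size`.
#' @export
candidate_pool_sizes <- function(rank_entries) {
  rank_entries |>
    tibble::as_tibble() |>
    dplyr::distinct(.data$group_id, .data$food_name) |>
    dplyr::count(.data$group_id, name = "pool_size")
}

#' Aggregate per-dataset ranks into representative food sets
#'
#' Computes each food's mean rank across datasets and selects, per group,
#' the `top_n` foods with the lowest mean rank (1 being the best rank) as
#' the group's globally representative foods; the group's mean density is
#' the simple mean of their individual densities.
#'
#' By default the mean rank averages over only the datasets in which the
#' food entered the top ranks; `absent_rank` optionally assigns a penalty
#' rank for every dataset in which the food is absent, in which case the
#' mean runs over all `n_datasets` datasets. Ties are broken by larger
#' total contribution, then lexicographically.
#'
#' @param rank_entries Output of [rank_top_foods()] across datasets.
#' @param densities Named numeric vector or tibble (`food_name`, `density`)
#'   giving each food's density in g/cm3.
#' @param top_n Maximum representative foods per group; default 10.
#' @param absent_rank Optional penalty rank for datasets where a food is
#'   unranked (e.g. 6); `NULL` (default) averages over ranked datasets only.
#' @param n_datasets Number of datasets (only used with `absent_rank`);
#'   defaults to the number of distinct `dataset_id`s.
#' @return A `gdqs_representatives` tibble: `group_id`, `food_name`,
#'   `mean_rank`, `density`, ordered by mean rank within group.
#' @export
aggregate_representatives <- function(rank_entries, densities, top_n = 10L,
                                      absent_rank = NULL, n_datasets = NULL) {
  rank_entries <- tibble::as_tibble(rank_entries)
  if (!nrow(rank_entries)) pipeline_error("no rank entries")
  if (is.data.frame(densities))
    densities <- stats::setNames(densities$density, densities$food_name)
  n_datasets <- n_datasets %||% dplyr::n_distinct(rank_entries$dataset_id)

  agg <- rank_entries |>
    dplyr::group_by(.data$group_id, .data$food_name) |>
    dplyr::summarise(rank_sum = sum(.data$rank), n_ranked = dplyr::n(),
                     total_contribution = sum(.data$pct_contribution),
                     .groups = "drop")
  agg$mean_rank <- if (is.null(absent_rank)) {
    agg$rank_sum / agg$n_ranked
  } else {
    (agg$rank_sum + absent_rank * (n_datasets - agg$n_ranked)) / n_datasets
  }

  reps <- agg |>
    dplyr::arrange(.data$group_id, .data$mean_rank,
                   dplyr::desc(.data$total_contribution), .data$food_name) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup()

  miss <- setdiff(reps$food_name, names(densities))
  if (length(miss))
    pipeline_error("no density available for selected food '%s'", miss[1])
  reps |>
    dplyr::mutate(density = unname(densities[.data$food_name])) |>
    dplyr::select("group_id", "food_name", "mean_rank", "density") |>
    structure(class = c("gdqs_representatives", class(tibble::tibble())))
}

#' Mean group densities from representative food sets
#' @param representatives Output of [aggregate_representatives()].
#' @return Tibble with `group_id`, `n_foods`, `mean_density` (simple mean).
#' @export
group_mean_densities <- function(representatives) {
  representatives |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(n_foods = dplyr::n(),
                     mean_density = mean(.data$density), .groups = "drop")
}

#' Convert original gram cutoffs into cube volumes and side lengths
#'
#' `volume_cm3 = grams / mean_density`, `side_mm = 10 * volume^(1/3)`. The
#' hard-cheese cutoffs are printed in milk equivalents, so they are divided
#' by [milk_equivalent_factor] before the volume conversion (this is what
#' places the cheese low/middle cutoff on the second-smallest cube).
#'
#' @param tax A `gdqs_taxonomy`.
#' @param densities Optional tibble (`group_id`, `mean_density`) overriding
#'   the taxonomy's densities, e.g. from [group_mean_densities()].
#' @return Tibble with one row per cube-assessed cutoff: `group_id`,
#'   `boundary`, `original_g`, `grams_for_volume`, `volume_cm3`, `side_mm`.
#' @export
boundaries_to_volumes <- function(tax, densities = NULL) {
  d <- if (is.null(densities)) tax$densities else tibble::as_tibble(densities)
  cheese <- intersect("hf_dairy_cheese", tax$groups$group_id)
  b <- tax$boundaries |>
    dplyr::filter(!is.na(.data$cube_index)) |>
    dplyr::left_join(d[, c("group_id", "mean_density")], by = "group_id")
  if (any(is.na(b$mean_density)))
    pipeline_error("missing density for group '%s'", b$group_id[is.na(b$mean_density)][1])
  if (any(b$mean_density <= 0))
    pipeline_error("non-positive density for group '%s'", b$group_id[b$mean_density <= 0][1])
  b |>
    dplyr::mutate(
      grams_for_volume = dplyr::if_else(.data$group_id %in% cheese,
                                        .data$original_g / milk_equivalent_factor,
                                        as.numeric(.data$original_g)),
      volume_cm3 = .data$grams_for_volume / .data$mean_density,
      side_mm = 10 * .data$volume_cm3^(1 / 3)
    ) |>
    dplyr::select("group_id", "boundary", "original_g", "grams_for_volume",
                  "volume_cm3", "side_mm")
}

#' Cluster raw cutoff cube sides into the core cube set
#'
#' One cube per cutoff (52 of them) is impractical and many differ
#' imperceptibly, so similar sides are grouped and averaged:
#' 1-D agglomerative clustering (complete linkage by default) on side
#' length into `k_core` clusters, each clustered cube taking the mean side
#' of its members. Two flank cubes carrying no cutoffs are appended at the
#' ends, giving `k_core + 2` cubes in total.
#'
#' @param raw Tibble with a `side_mm` column (see
#'   [boundaries_to_volumes()]).
#' @param k_core Number of cutoff-bearing cubes; default 8.
#' @param flank_sides Sides (mm) of the two added end cubes.
#' @param method Linkage passed to [stats::hclust()].
#' @return A `gdqs_cube_design`: list with `cubes` (tibble `cube_index`,
#'   `side_mm`, `n_boundaries`) and `assignment` (raw rows with their
#'   `cube_index`).
#' @export
cluster_cubes <- function(raw, k_core = 8L, flank_sides = c(18, 100),
                          method = "complete") {
  raw <- tibble::as_tibble(raw)
  if (k_core < 1L) pipeline_error("k_core must be >= 1")
  sides <- raw$side_mm
  if (dplyr::n_distinct(sides) < k_core)
    pipeline_error("only %d distinct side lengths for %d clusters",
                   dplyr::n_distinct(sides), k_core)
  cl <- if (k_core == 1L) rep(1L, length(sides)) else {
    stats::cutree(stats::hclust(stats::dist(sides), method = method), k = k_core)
  }
  centers <- tapply(sides, cl, mean)
  ord <- order(centers)
  core <- tibble::tibble(
    side_mm = as.numeric(centers[ord]),
    n_boundaries = as.integer(table(cl)[ord])
  )
  raw$cube_index <- match(cl, as.integer(names(centers)[ord])) + 1L

  cubes <- dplyr::bind_rows(
    tibble::tibble(side_mm = min(flank_sides), n_boundaries = 0L),
    core,
    tibble::tibble(side_mm = max(flank_sides), n_boundaries = 0L)
  )
  cubes$cube_index <- seq_len(nrow(cubes))
  if (is.unsorted(cubes$side_mm, strictly = FALSE))
    pipeline_error("flank sides must lie outside the clustered side range")
  structure(list(cubes = cubes[, c("cube_index", "side_mm", "n_boundaries")],
                 assignment = raw),
            class = "gdqs_cube_design")
}

#' @export
print.gdqs_cube_design <- function(x, ...) {
  cat(sprintf("<gdqs_cube_design> %d cubes (%d carry cutoffs)\n",
              nrow(x$cubes), sum(x$cubes$n_boundaries > 0)))
  print(x$cubes)
  invisible(x)
}

#' Cube design as a tibble
#' @param x A `gdqs_cube_design`.
#' @param ... Unused.
#' @export
tidy.gdqs_cube_design <- function(x, ...) x$cubes

#' Plot a cube design against the raw cutoff sides
#' @param object A `gdqs_cube_design`.
#' @param ... Unused.
#' @return A ggplot object: raw cutoff sides as points, clustered cube
#'   sides as vertical lines.
#' @export
autoplot.gdqs_cube_design <- function(object, ...) {
  ggplot2::ggplot(object$assignment,
                  ggplot2::aes(x = .data$side_mm, y = factor(.data$cube_index))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(data = object$cubes,
                        ggplot2::aes(xintercept = .data$side_mm),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "cube side (mm)", y = "assigned cube") +
    ggplot2::theme_minimal()
}

#' Full density-derivation pipeline over multi-dataset consumption records
#'
#' Chains [filter_first_recall()], [compute_contributions()],
#' [rank_top_foods()] and [aggregate_representatives()].
#'
#' @param records Consumption records (`dataset_id`, `respondent_id`,
#'   optional `recall_no`, `food_name`, `group_id`, `grams`).
#' @param densities Food-level density lookup (named vector or tibble
#'   `food_name`, `density`).
#' @param top_rank Per-dataset ranks; default 5.
#' @param top_set Representative foods per group; default 10.
#' @param absent_rank See [aggregate_representatives()].
#' @return A `gdqs_representatives` tibble.
#' @export
derive_densities <- function(records, densities, top_rank = 5L, top_set = 10L,
                             absent_rank = NULL) {
  records |>
    filter_first_recall() |>
    compute_contributions() |>
    rank_top_foods(top_n = top_rank) |>
    aggregate_representatives(densities, top_n = top_set,
                              absent_rank = absent_rank)
}

#' Derive a cube design from a taxonomy's original cutoffs
#'
#' Convenience wrapper: [boundaries_to_volumes()] then [cluster_cubes()].
#' @inheritParams boundaries_to_volumes
#' @inheritParams cluster_cubes
#' @return A `gdqs_cube_design`.
#' @export
derive_cube_design <- function(tax, densities = NULL, k_core = 8L,
                               flank_sides = c(18, 100), method = "complete") {
  cluster_cubes(boundaries_to_volumes(tax, densities), k_core = k_core,
                flank_sides = flank_sides, method = method)
}
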