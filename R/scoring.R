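# Point-table scoring. The numeric point values per category are
# configuration, not package constants: they belong to the validated metric
# definition and are supplied by the user. The shipped
# `example_point_table.csv` is a clearly labelled toy table for tests and
# examples, not the published values.

score_error <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "gdqs_score_error")

#' Load and validate a scoring point table
#'
#' A point table maps every reporting food group and every category valid
#' for it to a point value, and assigns each group a role: `healthy` (more
#' consumption scores higher), `unhealthy` (less scores higher), or
#' `unhealthy_in_excess` (moderate consumption scores highest).
#'
#' @param x CSV path or data frame with columns `group_id` (reporting
#'   group), `category`, `points`, `role`.
#' @param taxonomy Taxonomy defining the reporting groups to cover.
#' @return A validated `gdqs_point_table` tibble.
#' @examples
#' pt <- load_point_table(example_point_table_path())
#' @export
load_point_table <- function(x, taxonomy = load_taxonomy()) {
  pt <- if (is.character(x)) read_cfg(x) else tibble::as_tibble(x)
  miss <- setdiff(c("group_id", "category", "points", "role"), names(pt))
  if (length(miss)) score_error("point table is missing column(s): %s", paste(miss, collapse = ", "))
  rep_groups <- unique(taxonomy$groups$reporting_group_id)
  bad <- setdiff(unique(pt$group_id), rep_groups)
  if (length(bad)) score_error("point table has unknown reporting group '%s'", bad[1])
  bad_cat <- setdiff(unique(pt$category), gdqs_categories)
  if (length(bad_cat)) score_error("unknown category '%s'", bad_cat[1])
  bad_role <- setdiff(unique(pt$role), c("healthy", "unhealthy", "unhealthy_in_excess"))
  if (length(bad_role)) score_error("unknown role '%s'", bad_role[1])
  if (anyDuplicated(pt[, c("group_id", "category")]))
    score_error("duplicate (group, category) rows in point table")

  subs <- hf_dairy_subgroups(taxonomy)
  vh_group <- unique(taxonomy$groups$reporting_group_id[taxonomy$groups$group_id %in% subs])
  for (g in rep_groups) {
    cats_needed <- c("low", "middle", "high", if (g %in% vh_group) "very_high")
    have <- pt$category[pt$group_id == g]
    missing_cat <- setdiff(cats_needed, have)
    if (length(missing_cat))
      score_error("point table misses category '%s' for group '%s'", missing_cat[1], g)
    if (dplyr::n_distinct(pt$role[pt$group_id == g]) != 1L)
      score_error("conflicting roles for group '%s'", g)
  }
  class(pt) <- c("gdqs_point_table", class(pt))
  pt
}

#' Path to the shipped example point table
#'
#' A toy table for tests and examples. It is not the published GDQS point
#' assignment; supply the validated table for real scoring.
#' @export
example_point_table_path <- function() {
  config_file("example_point_table.csv")
}

#' Score per-group quantity categories into the GDQS total and submetrics
#'
#' Looks up each reporting group's category in the point table, filling
#' groups absent from `quantities` with `low` (nothing reported means the
#' lowest consumption band), and adds the liquid-oils category from the
#' inference algorithm. The positive submetric sums points over `healthy`
#' groups; the negative submetric over `unhealthy` and
#' `unhealthy_in_excess` groups; the total is their sum.
#'
#' @param quantities Tibble keyed by `reporting_group_id` with a `category`
#'   column (see [session_quantities()]); grams are carried through if
#'   present.
#' @param oil_category Category for the liquid-oils group, from
#'   [infer_oil_category()].
#' @param point_table A `gdqs_point_table`.
#' @param taxonomy A `gdqs_taxonomy`.
#' @return A `gdqs_result` with elements `total`, `submetric_plus`,
#'   `submetric_minus` and `per_group` (tibble over all 25 reporting
#'   groups).
#' @export
score_session <- function(quantities, oil_category, point_table,
                          taxonomy = load_taxonomy()) {
  rep_groups <- sort(unique(taxonomy$groups$reporting_group_id))
  oil_rep <- unique(taxonomy$groups$reporting_group_id[
    taxonomy$groups$assessment_mode == "oil_algorithm"])

  per <- tibble::tibble(reporting_group_id = rep_groups) |>
    dplyr::left_join(tibble::as_tibble(quantities), by = "reporting_group_id") |>
    dplyr::mutate(
      category = dplyr::if_else(.data$reporting_group_id == oil_rep,
                                oil_category, .data$category),
      category = dplyr::coalesce(.data$category, "low")
    )
  if (!"grams_estimate" %in% names(per)) per$grams_estimate <- NA_real_

  pt <- tibble::as_tibble(point_table)
  per <- per |>
    dplyr::left_join(pt, by = c("reporting_group_id" = "group_id", "category"))
  if (any(is.na(per$points)))
    score_error("point table has no entry for group '%s' at category '%s'",
                per$reporting_group_id[is.na(per$points)][1],
                per$category[is.na(per$points)][1])

  plus <- sum(per$points[per$role == "healthy"])
  minus <- sum(per$points[per$role != "healthy"])
  structure(
    list(total = plus + minus, submetric_plus = plus, submetric_minus = minus,
         per_group = dplyr::select(per, "reporting_group_id", "category",
                                   "grams_estimate", "points", "role")),
    class = "gdqs_result"
  )
}

#' @export
print.gdqs_result <- function(x, ...) {
  cat(sprintf("<gdqs_result> total %.1f (healthy %.1f + unhealthy %.1f) over %d groups\n",
              x$total, x$submetric_plus, x$submetric_minus, nrow(x$per_group)))
  invisible(x)
}

#' Per-group categories and points of a scored session
#' @param x A `gdqs_result`.
#' @param ... Unused.
#' @export
tidy.gdqs_result <- function(x, ...) x$per_group

#' One-row summary of a scored session
#' @param x A `gdqs_result`.
#' @param ... Unused.
#' @export
glance.gdqs_result <- function(x, ...) {
  tibble::tibble(total = x$total, submetric_plus = x$submetric_plus,
                 submetric_minus = x$submetric_minus,
                 n_groups = nrow(x$per_group))
}

#' Bar chart of per-group points for a scored session
#' @param object A `gdqs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gdqs_result <- function(object, ...) {
  df <- object$per_group
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$reporting_group_id, .data$points),
    y = .data$points, fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "points",
                  title = sprintf("GDQS total %.1f", object$total)) +
    ggplot2::theme_minimal()
}

#' Write a scored result to JSON
#' @param result A `gdqs_result`.
#' @param path Output path.
#' @export
write_result <- function(result, path) {
  jsonlite::write_json(
    list(total = result$total, submetric_plus = result$submetric_plus,
         submetric_minus = result$submetric_minus, per_group = result$per_group),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
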