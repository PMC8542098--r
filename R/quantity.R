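# Cube selections -> quantity categories and gram point estimates.
# The respondent visualizes the combined volume consumed per food group and
# picks the closest cube; the cutoff tables then place that volume into the
# low / middle / high (/ very_high for high-fat dairy) consumption band.

quantity_error <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "gdqs_quantity_error")

group_boundary_table <- function(tax, group_id) {
  b <- tax$boundaries[tax$boundaries$group_id == group_id, ]
  b[match(intersect(gdqs_boundaries, b$boundary), b$boundary), ]
}

#' Categorize grams against a vector of increasing cutoffs
#'
#' Values below the smallest cutoff are `low`; a value equal to a cutoff
#' falls in the band above it ("equal to or above" the cutoff).
#' @param grams Non-negative numeric vector.
#' @param cutoffs Strictly increasing cutoffs of length 2 (low/middle,
#'   middle/high) or 3 (plus high/very-high).
#' @return Character vector of categories.
#' @export
categorize_grams <- function(grams, cutoffs) {
  if (any(grams < 0)) quantity_error("grams must be non-negative")
  if (is.unsorted(cutoffs, strictly = TRUE))
    quantity_error("cutoffs must strictly increase")
  idx <- vapply(grams, function(g) sum(g >= cutoffs), integer(1))
  gdqs_categories[idx + 1L]
}

#' Quantity category from a cube selection
#'
#' A cube strictly below the group's low/middle cube maps to `low`, strictly
#' between the boundary cubes to `middle`, strictly above the middle/high
#' cube to `high` (above the high/very-high cube to `very_high` for the
#' high-fat dairy subgroups). When the selected cube IS a boundary cube the
#' interview asks whether the visualized amount is "as big or bigger" or
#' "smaller" than the cube; that confirmation resolves the category upward
#' or downward.
#'
#' @param tax A `gdqs_taxonomy`.
#' @param group_id A cube-assessed collection group.
#' @param cube_index Selected cube, 1--10.
#' @param borderline_answer `"bigger_or_equal"`, `"smaller"`, or
#'   `"not_applicable"` (required to be a real answer exactly when
#'   `cube_index` is a boundary cube of the group).
#' @return One of [gdqs_categories].
#' @export
categorize_from_cube <- function(tax, group_id, cube_index,
                                 borderline_answer = "not_applicable") {
  if (group_id == oil_group(tax))
    quantity_error("'%s' is assessed by the oil-inference algorithm, not cubes", group_id)
  if (!group_id %in% cube_assessed_groups(tax))
    quantity_error("unknown cube-assessed group '%s'", group_id)
  if (!cube_index %in% tax$cubes$cube_index)
    quantity_error("cube index %s out of range", cube_index)
  b <- group_boundary_table(tax, group_id)
  bc <- b$cube_index

  if (cube_index %in% bc) {
    pos <- match(cube_index, bc)
    if (identical(borderline_answer, "bigger_or_equal")) return(gdqs_categories[pos + 1L])
    if (identical(borderline_answer, "smaller")) return(gdqs_categories[pos])
    quantity_error(
      "cube %d is the %s boundary cube for '%s': a 'bigger_or_equal'/'smaller' confirmation is required",
      cube_index, b$boundary[pos], group_id)
  }
  if (!identical(borderline_answer, "not_applicable"))
    quantity_error("cube %d is not a boundary cube for '%s'; no borderline answer expected",
                   cube_index, group_id)
  gdqs_categories[sum(cube_index > bc) + 1L]
}

#' Gram point estimate for a cube selection
#'
#' The full volume of the selected cube times the group's mean density.
#' Unreported groups (`cube_index = NULL`) estimate 0 g.
#' @inheritParams categorize_from_cube
#' @return Grams (numeric scalar).
#' @examples
#' tax <- load_taxonomy()
#' estimate_grams(tax, "red_meat", 2) # ~9.26 g
#' @export
estimate_grams <- function(tax, group_id, cube_index) {
  if (is.null(cube_index)) return(0)
  if (!group_id %in% cube_assessed_groups(tax))
    quantity_error("'%s' is not a cube-assessed group", group_id)
  dens <- group_density(tax, group_id)
  if (is.na(dens)) quantity_error("no density entry for group '%s'", group_id)
  if (!cube_index %in% tax$cubes$cube_index)
    quantity_error("cube index %s out of range", cube_index)
  dens * cube_volume(tax, cube_index)
}

hf_dairy_subgroups <- function(tax) {
  rep <- tax$groups$reporting_group_id
  dup <- unique(rep[duplicated(rep)])
  tax$groups$group_id[rep %in% dup]
}

#' Merge the split high-fat dairy subgroups in the gram domain
#'
#' The instrument asks about hard cheese and other high-fat dairy
#' separately (their densities are too different for one cube scale) and
#' recombines them for reporting: cheese grams are multiplied by
#' [milk_equivalent_factor] (6.1) to convert them to milk equivalents, the
#' milk-equivalent grams are added to the other-dairy grams, and the sum is
#' categorized against the reporting group's original gram cutoffs
#' (35 / 140 / 734 g).
#'
#' @param tax A `gdqs_taxonomy`.
#' @param cheese_cube,other_cube Selected cube index for each subgroup, or
#'   `NULL` if the subgroup was not reported.
#' @param cheese_grams,other_grams Alternatively, direct gram estimates
#'   (override the cube arguments when supplied).
#' @return One-row tibble: `group_id` (the merged reporting group),
#'   `category`, `grams_estimate` (milk-equivalent grams).
#' @examples
#' tax <- load_taxonomy()
#' merge_high_fat_dairy(tax, cheese_cube = 2) # ~54.6 g -> middle
#' @export
merge_high_fat_dairy <- function(tax, cheese_cube = NULL, other_cube = NULL,
                                 cheese_grams = NULL, other_grams = NULL) {
  subs <- hf_dairy_subgroups(tax)
  if (length(subs) != 2L)
    quantity_error("taxonomy does not contain exactly two split dairy subgroups")
  # identify which subgroup is the cheese one by its density (the outlier
  # that forced the split: hard cheese is far denser-per-serving in milk
  # equivalents); by convention the shipped config names it hf_dairy_cheese
  cheese_id <- if ("hf_dairy_cheese" %in% subs) "hf_dairy_cheese" else subs[1]
  other_id <- setdiff(subs, cheese_id)
  rep_id <- unique(tax$groups$reporting_group_id[tax$groups$group_id %in% subs])

  cheese_g <- cheese_grams %||% estimate_grams(tax, cheese_id, cheese_cube)
  other_g <- other_grams %||% estimate_grams(tax, other_id, other_cube)
  if (cheese_g < 0 || other_g < 0) quantity_error("gram amounts must be non-negative")

  merged <- milk_equivalent_factor * cheese_g + other_g
  cutoffs <- group_boundary_table(tax, other_id)$original_g
  tibble::tibble(
    group_id = rep_id,
    category = categorize_grams(merged, cutoffs),
    grams_estimate = merged
  )
}

#' Per-reporting-group quantities for a finalized recall session
#'
#' Applies [categorize_from_cube()] and [estimate_grams()] to every cube
#' selection in the session, scores every unreported cube-assessed group as
#' `low` / 0 g, and merges the two high-fat dairy subgroups into their
#' reporting group. Liquid oils is excluded here; its category comes from
#' [infer_oil_category()] at scoring time.
#'
#' @param session A `gdqs_session` at step 6 or later.
#' @param tax A `gdqs_taxonomy`.
#' @return Tibble keyed by `reporting_group_id` with `category` and
#'   `grams_estimate`, one row per cube-assessed reporting group (24 rows
#'   with the shipped taxonomy).
#' @export
session_quantities <- function(session, tax = load_taxonomy()) {
  sel <- session$cube_selections
  subs <- hf_dairy_subgroups(tax)
  plain <- setdiff(cube_assessed_groups(tax), subs)

  per_group <- purrr::map_dfr(plain, function(gid) {
    row <- sel[sel$group_id == gid, ]
    if (nrow(row)) {
      tibble::tibble(
        group_id = gid,
        category = categorize_from_cube(tax, gid, row$cube_index[1], row$borderline_answer[1]),
        grams_estimate = estimate_grams(tax, gid, row$cube_index[1])
      )
    } else {
      tibble::tibble(group_id = gid, category = "low", grams_estimate = 0)
    }
  })
  pick <- function(gid) {
    row <- sel[sel$group_id == gid, ]
    if (nrow(row)) row$cube_index[1] else NULL
  }
  cheese_id <- if ("hf_dairy_cheese" %in% subs) "hf_dairy_cheese" else subs[1]
  dairy <- merge_high_fat_dairy(tax, cheese_cube = pick(cheese_id),
                                other_cube = pick(setdiff(subs, cheese_id)[1]))
  per_group |>
    dplyr::left_join(tax$groups[, c("group_id", "reporting_group_id")], by = "group_id") |>
    dplyr::select(reporting_group_id = "reporting_group_id", "category", "grams_estimate") |>
    dplyr::bind_rows(dplyr::rename(dairy, reporting_group_id = "group_id")) |>
    dplyr::arrange(.data$reporting_group_id)
}
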