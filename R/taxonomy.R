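# Food-group taxonomy: the 26 collection-time GDQS groups, the 10-cube set,
# the gram cutoff tables (original + operationalized) and the mean group
# densities that tie grams to cube volumes.

#' Quantity category levels
#'
#' Ordered consumption categories used throughout the package. `very_high`
#' exists only for the high-fat dairy group, which carries one more cutoff
#' than every other group.
#' @export
gdqs_categories <- c("low", "middle", "high", "very_high")

#' Boundary levels between adjacent quantity categories
#' @export
gdqs_boundaries <- c("low_middle", "middle_high", "high_very_high")

#' Milk-equivalent conversion factor for hard cheese
#'
#' Hard-cheese grams are multiplied by this factor to express them as milk
#' equivalents before the split high-fat dairy subgroups are recombined for
#' reporting.
#' @export
milk_equivalent_factor <- 6.1

config_file <- function(name) {
  system.file("extdata", name, package = "gdqsr", mustWork = TRUE)
}

#' Path to the shipped default configuration directory
#' @return Directory containing the group, cube, boundary and density CSVs.
#' @export
gdqs_config_dir <- function() {
  dirname(config_file("gdqs_groups.csv"))
}

read_cfg <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

taxonomy_error <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "gdqs_config_error")
}

#' Load and validate a GDQS taxonomy configuration
#'
#' Reads the food-group table, cube set, cutoff boundaries and mean group
#' densities (four CSV files) and validates them against the structural
#' constraints of the operationalized instrument: 26 collection-time groups
#' mapping onto 25 reporting groups, exactly one group assessed by the
#' liquid-oils algorithm, 10 cubes with strictly increasing side lengths,
#' two cutoffs per cube-assessed group (three for the two high-fat dairy
#' subgroups, 54 in total), grams strictly increasing and cube assignments
#' weakly increasing within a group, and one density entry per cube-assessed
#' group.
#'
#' @param dir Directory containing `gdqs_groups.csv`, `gdqs_cubes.csv`,
#'   `gdqs_boundaries.csv` and `gdqs_densities.csv`. Defaults to the
#'   configuration shipped with the package (transcribed from the published
#'   instrument tables).
#' @param groups,cubes,boundaries,densities Optional data frames overriding
#'   the corresponding file, mainly for testing variant configurations.
#' @return A `gdqs_taxonomy` object: a list of four tibbles (`groups`,
#'   `cubes`, `boundaries`, `densities`).
#' @examples
#' tax <- load_taxonomy()
#' glance(tax)
#' @export
load_taxonomy <- function(dir = gdqs_config_dir(),
                          groups = NULL, cubes = NULL,
                          boundaries = NULL, densities = NULL) {
  groups     <- tibble::as_tibble(groups %||% read_cfg(file.path(dir, "gdqs_groups.csv")))
  cubes      <- tibble::as_tibble(cubes %||% read_cfg(file.path(dir, "gdqs_cubes.csv")))
  boundaries <- tibble::as_tibble(boundaries %||% read_cfg(file.path(dir, "gdqs_boundaries.csv")))
  densities  <- tibble::as_tibble(densities %||% read_cfg(file.path(dir, "gdqs_densities.csv")))

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) taxonomy_error("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  }
  need(groups, c("group_id", "name", "assessment_mode", "reporting_group_id"), "groups table")
  need(cubes, c("cube_index", "side_mm"), "cube table")
  need(boundaries, c("group_id", "boundary", "cube_index", "original_g", "operationalized_g"), "boundary table")
  need(densities, c("group_id", "mean_density", "representative_foods"), "density table")

  tax <- structure(
    list(groups = groups, cubes = cubes,
         boundaries = boundaries, densities = densities),
    class = "gdqs_taxonomy"
  )
  validate_taxonomy(tax)
  tax
}

#' Validate a taxonomy object
#'
#' Checks every structural invariant of the operationalized instrument and
#' aborts with a `gdqs_config_error` naming the offending group or boundary.
#' @param tax A `gdqs_taxonomy`.
#' @return `tax`, invisibly, if valid.
#' @export
validate_taxonomy <- function(tax) {
  g <- tax$groups; cu <- tax$cubes; b <- tax$boundaries; d <- tax$densities

  if (anyDuplicated(g$group_id)) taxonomy_error("duplicate group_id in groups table")
  if (nrow(g) != 26L)
    taxonomy_error("expected 26 collection-time groups, found %d", nrow(g))
  if (dplyr::n_distinct(g$reporting_group_id) != 25L)
    taxonomy_error("expected 25 reporting groups, found %d",
                   dplyr::n_distinct(g$reporting_group_id))
  bad_mode <- setdiff(unique(g$assessment_mode), c("cube", "oil_algorithm"))
  if (length(bad_mode)) taxonomy_error("unknown assessment_mode: %s", bad_mode[1])
  oil <- g$group_id[g$assessment_mode == "oil_algorithm"]
  if (length(oil) != 1L)
    taxonomy_error("expected exactly one oil_algorithm group, found %d", length(oil))

  if (!identical(sort(cu$cube_index), 1:10) && !identical(sort(as.integer(cu$cube_index)), 1:10))
    taxonomy_error("cube indices must be exactly 1..10")
  cu <- dplyr::arrange(cu, .data$cube_index)
  if (any(diff(cu$side_mm) <= 0))
    taxonomy_error("cube side lengths must strictly increase with cube index")

  unknown <- setdiff(b$group_id, g$group_id)
  if (length(unknown)) taxonomy_error("boundary refers to unknown group '%s'", unknown[1])
  bad_b <- setdiff(unique(b$boundary), gdqs_boundaries)
  if (length(bad_b)) taxonomy_error("unknown boundary level '%s'", bad_b[1])

  cube_groups <- g$group_id[g$assessment_mode == "cube"]
  for (gid in cube_groups) {
    bg <- b[b$group_id == gid, ]
    bg <- bg[match(intersect(gdqs_boundaries, bg$boundary), bg$boundary), ]
    if (!all(c("low_middle", "middle_high") %in% bg$boundary))
      taxonomy_error("group '%s' must have low_middle and middle_high cutoffs", gid)
    if (anyDuplicated(bg$boundary))
      taxonomy_error("group '%s' has duplicated boundary levels", gid)
    if (any(is.na(bg$cube_index)) || any(is.na(bg$operationalized_g)))
      taxonomy_error("group '%s' has cube-assessed cutoffs with missing cube or grams", gid)
    if (!all(bg$cube_index %in% cu$cube_index))
      taxonomy_error("group '%s' references a nonexistent cube", gid)
    if (any(diff(bg$operationalized_g) <= 0))
      taxonomy_error("operationalized grams must strictly increase within group '%s'", gid)
    if (any(is.finite(bg$original_g)) && any(diff(bg$original_g) <= 0))
      taxonomy_error("original grams must strictly increase within group '%s'", gid)
    if (any(diff(bg$cube_index) < 0))
      taxonomy_error("cube assignments must not decrease within group '%s'", gid)
    if (!gid %in% d$group_id)
      taxonomy_error("cube-assessed group '%s' has no density entry", gid)
  }
  extra_vh <- b$group_id[b$boundary == "high_very_high"]
  multi_rep <- g$group_id[g$reporting_group_id %in%
                            g$reporting_group_id[duplicated(g$reporting_group_id)]]
  if (!all(extra_vh %in% multi_rep))
    taxonomy_error("high_very_high cutoff only allowed for the split dairy subgroups (got '%s')",
                   setdiff(extra_vh, multi_rep)[1])

  oil_b <- b[b$group_id == oil, ]
  if (nrow(oil_b) && any(!is.na(oil_b$cube_index)))
    taxonomy_error("the oil-algorithm group must not carry cube assignments")

  if (anyDuplicated(d$group_id)) taxonomy_error("duplicate density entries")
  if (any(!is.finite(d$mean_density)) || any(d$mean_density <= 0))
    taxonomy_error("densities must be positive: %s",
                   paste(d$group_id[!is.finite(d$mean_density) | d$mean_density <= 0], collapse = ", "))
  if (oil %in% d$group_id)
    taxonomy_error("the oil-algorithm group must not have a density entry")

  invisible(tax)
}

#' @export
print.gdqs_taxonomy <- function(x, ...) {
  cnt <- glance(x)
  cat("<gdqs_taxonomy>\n")
  cat(sprintf("  %d collection groups -> %d reporting groups\n",
              cnt$collection_groups, cnt$reporting_groups))
  cat(sprintf("  %d cutoff boundaries (%d after dairy merge), %d cubes (%d carry cutoffs)\n",
              cnt$boundaries, cnt$reporting_boundaries, cnt$cubes, cnt$boundary_cubes))
  invisible(x)
}

#' Structural summary of a taxonomy
#'
#' One-row tibble with the counts that characterize the instrument design:
#' collection-time groups, reporting groups after the dairy merge, cutoff
#' boundaries before/after the merge, cubes, and cubes that carry at least
#' one cutoff.
#' @param x A `gdqs_taxonomy`.
#' @param ... Unused.
#' @export
glance.gdqs_taxonomy <- function(x, ...) {
  b <- x$boundaries
  # after the dairy merge the split subgroups collapse to one reporting group
  # carrying the three original milk-equivalent cutoffs
  rep_b <- dplyr::distinct(
    dplyr::left_join(b, x$groups[, c("group_id", "reporting_group_id")], by = "group_id"),
    .data$reporting_group_id, .data$boundary
  )
  tibble::tibble(
    collection_groups = nrow(x$groups),
    reporting_groups = dplyr::n_distinct(x$groups$reporting_group_id),
    boundaries = nrow(b),
    reporting_boundaries = nrow(rep_b),
    cubes = nrow(x$cubes),
    boundary_cubes = dplyr::n_distinct(b$cube_index[!is.na(b$cube_index)])
  )
}

#' Boundary table in long, joined form
#'
#' @param x A `gdqs_taxonomy`.
#' @param ... Unused.
#' @return A tibble with one row per cutoff boundary, joined with cube side
#'   lengths and group densities.
#' @export
tidy.gdqs_taxonomy <- function(x, ...) {
  x$boundaries |>
    dplyr::left_join(x$groups, by = "group_id") |>
    dplyr::left_join(x$cubes, by = "cube_index") |>
    dplyr::left_join(x$densities[, c("group_id", "mean_density")], by = "group_id") |>
    dplyr::mutate(volume_cm3 = (.data$side_mm / 10)^3) |>
    dplyr::select("group_id", "name", "reporting_group_id", "boundary", "cube_index",
                  "side_mm", "volume_cm3", "original_g", "operationalized_g",
                  "mean_density")
}

cube_volume <- function(tax, cube_index) {
  side <- tax$cubes$side_mm[match(cube_index, tax$cubes$cube_index)]
  (side / 10)^3
}

group_density <- function(tax, group_id) {
  tax$densities$mean_density[match(group_id, tax$densities$group_id)]
}

cube_assessed_groups <- function(tax) {
  tax$groups$group_id[tax$groups$assessment_mode == "cube"]
}

oil_group <- function(tax) {
  tax$groups$group_id[tax$groups$assessment_mode == "oil_algorithm"]
}

#' Audit agreement between printed gram cutoffs and cube volumes
#'
#' Each operationalized gram cutoff was designed to equal mean group density
#' times the volume of its designated cube. Because the printed cube sides
#' are rounded to the millimetre, the product deviates slightly from the
#' printed grams; this report quantifies that relative deviation per cutoff.
#' The fish-and-shellfish cutoffs are known outliers (roughly 20--25%);
#' every other cutoff agrees to within 15%.
#'
#' @param tax A `gdqs_taxonomy`.
#' @return Tibble with one row per cube-assessed cutoff: predicted grams
#'   (`mean_density * volume_cm3`), printed operationalized grams, and
#'   `rel_deviation = |predicted - printed| / printed`.
#' @examples
#' rep <- cutoff_consistency_report(load_taxonomy())
#' dplyr::filter(rep, rel_deviation > 0.15)
#' @export
cutoff_consistency_report <- function(tax) {
  tt <- tidy(tax) |> dplyr::filter(!is.na(.data$cube_index))
  if (any(is.na(tt$mean_density)))
    taxonomy_error("missing density for group '%s'",
                   tt$group_id[is.na(tt$mean_density)][1])
  tt |>
    dplyr::mutate(
      predicted_g = .data$mean_density * .data$volume_cm3,
      rel_deviation = abs(.data$predicted_g - .data$operationalized_g) / .data$operationalized_g
    ) |>
    dplyr::select("group_id", "boundary", "cube_index", "side_mm", "mean_density",
                  "predicted_g", "operationalized_g", "rel_deviation")
}

#' Write a taxonomy back to its four-CSV representation
#'
#' Inverse of [load_taxonomy()]; `load_taxonomy(dir)` on the written
#' directory reproduces the taxonomy exactly.
#' @param tax A `gdqs_taxonomy`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_taxonomy <- function(tax, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tax$groups, file.path(dir, "gdqs_groups.csv"), progress = FALSE)
  readr::write_csv(tax$cubes, file.path(dir, "gdqs_cubes.csv"), progress = FALSE)
  readr::write_csv(tax$boundaries, file.path(dir, "gdqs_boundaries.csv"), progress = FALSE)
  readr::write_csv(tax$densities, file.path(dir, "gdqs_densities.csv"), progress = FALSE)
  invisible(dir)
}
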