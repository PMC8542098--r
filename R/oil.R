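# Liquid-oils inference. Respondents cannot reliably recall oil amounts, so
# the category is inferred from interview flags instead of cubes.

#' Infer the liquid-oils quantity category from session flags
#'
#' The respondent is placed in the highest oil-consumption range if any of
#' three triggers fires: (1) they consumed deep-fried foods prepared at home
#' with pourable liquid oil; (2) they consumed two or more mixed dishes; or
#' (3) they answered yes to pouring liquid oil on food or using it in food
#' preparation. With exactly one mixed dish and no trigger, the amount is
#' classified in the middle range; with no trigger and no mixed dish it
#' defaults to the low range.
#'
#' @param home_deep_fried_pourable_oil Logical, trigger 1.
#' @param mixed_dish_count Non-negative integer count of mixed dishes.
#' @param poured_or_used_oil Logical, trigger 3.
#' @return `"high"`, `"middle"`, or `"low"`.
#' @examples
#' infer_oil_category(FALSE, 1, FALSE) # "middle"
#' infer_oil_category(TRUE, 0, FALSE)  # "high"
#' @export
infer_oil_category <- function(home_deep_fried_pourable_oil,
                               mixed_dish_count,
                               poured_or_used_oil) {
  stopifnot(is.logical(home_deep_fried_pourable_oil),
            is.logical(poured_or_used_oil))
  if (is.na(mixed_dish_count) || mixed_dish_count < 0)
    rlang::abort("mixed_dish_count must be a non-negative integer",
                 class = "gdqs_quantity_error")
  if (isTRUE(home_deep_fried_pourable_oil) ||
      mixed_dish_count >= 2 ||
      isTRUE(poured_or_used_oil)) {
    "high"
  } else if (mixed_dish_count == 1) {
    "middle"
  } else {
    "low"
  }
}
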