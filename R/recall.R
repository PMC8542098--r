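# Seven-step 24-h open-recall interview, modelled as a small state machine.
# Step 1 free listing by eating occasion; 2 mixed-dish decomposition;
# 3 probe/manual classification; 4 deep-fried questions; 5 caloric-sweetener
# probe; 6 per-group read-back and cube capture; 7 finalize and score.

session_error <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "gdqs_session_error")

empty_items <- function() {
  tibble::tibble(
    item_id = integer(), raw_name = character(), occasion = character(),
    entry_id = character(), kind = character(), parent_id = integer(),
    group_id = character(), dual_group = character(), provenance = character()
  )
}

empty_selections <- function() {
  tibble::tibble(group_id = character(), cube_index = integer(),
                 borderline_answer = character())
}

#' Start a new recall session
#'
#' @param respondent_id Identifier of the respondent.
#' @param recall_date Date of the recall (the day being reported on).
#' @return A `gdqs_session` object at step 1.
#' @examples
#' s <- new_session("r001")
#' @export
new_session <- function(respondent_id, recall_date = Sys.Date()) {
  structure(
    list(
      respondent_id = as.character(respondent_id),
      recall_date = as.character(recall_date),
      step = 1L,
      items = empty_items(),
      purchased_deep_fried = FALSE,
      home_deep_fried_pourable_oil = FALSE,
      poured_or_used_oil = FALSE,
      cube_selections = empty_selections()
    ),
    class = "gdqs_session"
  )
}

require_step <- function(session, step) {
  if (session$step != step)
    session_error("operation requires step %d but session is at step %d", step, session$step)
}

#' Number of distinct mixed dishes reported in a session
#' @param session A `gdqs_session`.
#' @export
mixed_dish_count <- function(session) {
  sum(session$items$kind == "mixed_dish", na.rm = TRUE)
}

#' Advance the interview to the next step
#'
#' Steps are monotone 1 through 7. Moving past step 3 requires every leaf
#' item to have been classified into a concrete group.
#' @param session A `gdqs_session`.
#' @return The updated session.
#' @export
advance_step <- function(session) {
  if (session$step >= 7L) session_error("session is already finalized (step 7)")
  if (session$step == 3L) {
    pending <- pending_items(session)
    if (nrow(pending))
      session_error("cannot leave step 3: unclassified item(s): %s",
                    paste(pending$raw_name, collapse = ", "))
  }
  session$step <- session$step + 1L
  session
}

match_item <- function(raw_name, db, entry_id = NULL) {
  # exact (case-insensitive) name/alias match, else best fuzzy hit >= 0.8,
  # else free text requiring a manual group in step 3
  if (!is.null(entry_id)) {
    i <- match(entry_id, db$entry_id)
    if (is.na(i)) db_error("unknown entry '%s'", entry_id)
    return(list(entry_id = entry_id, kind = db$kind[i], provenance = "db_matched"))
  }
  hits <- search_foods(db, raw_name, limit = 1L, min_score = 0.8)
  if (nrow(hits)) {
    list(entry_id = hits$entry_id[1], kind = hits$kind[1], provenance = "db_matched")
  } else {
    list(entry_id = NA_character_, kind = NA_character_, provenance = "free_text_manual")
  }
}

append_item <- function(session, raw_name, occasion, match, parent_id = NA_integer_) {
  session$items <- dplyr::bind_rows(session$items, tibble::tibble(
    item_id = nrow(session$items) + 1L,
    raw_name = raw_name, occasion = occasion,
    entry_id = match$entry_id, kind = match$kind,
    parent_id = parent_id,
    group_id = NA_character_, dual_group = NA_character_,
    provenance = match$provenance
  ))
  session
}

#' Report a consumed food or beverage (step 1, free listing)
#'
#' Matches the reported name against the master database (exact or fuzzy);
#' names absent from the database become free-text items that must receive
#' a manual group in step 3. Mixed dishes are flagged from the database
#' `kind` and decomposed into ingredients in step 2.
#'
#' @param session A `gdqs_session` at step 1.
#' @param raw_name Food name as reported.
#' @param occasion Eating-occasion label (free string, e.g. "breakfast").
#' @param db A `gdqs_master_db`.
#' @param entry_id Optional explicit database choice (the drop-down pick),
#'   bypassing fuzzy matching.
#' @return The updated session.
#' @export
add_item <- function(session, raw_name, occasion, db, entry_id = NULL) {
  require_step(session, 1L)
  raw_name <- trimws(raw_name)
  if (!nzchar(raw_name)) session_error("empty food name")
  append_item(session, raw_name, occasion, match_item(raw_name, db, entry_id))
}

#' Decompose a mixed dish into its (main) ingredients (step 2)
#'
#' The dish itself contributes no food group; its ingredient items are
#' matched and classified individually. Exception foods such as bread or
#' cakes are single foods in the database and refuse decomposition.
#'
#' @param session A `gdqs_session` at step 2.
#' @param item_id Item id of the mixed dish.
#' @param ingredient_names Non-empty character vector of ingredient names.
#' @param db A `gdqs_master_db`.
#' @return The updated session with one child item per ingredient.
#' @export
decompose_mixed_dish <- function(session, item_id, ingredient_names, db) {
  require_step(session, 2L)
  i <- match(item_id, session$items$item_id)
  if (is.na(i)) session_error("unknown item id %s", item_id)
  if (!identical(session$items$kind[i], "mixed_dish"))
    session_error("'%s' is a single food, not a mixed dish; it is not decomposed",
                  session$items$raw_name[i])
  ingredient_names <- trimws(ingredient_names)
  ingredient_names <- ingredient_names[nzchar(ingredient_names)]
  if (!length(ingredient_names))
    session_error("no ingredients given for '%s'; ask for the main ingredients",
                  session$items$raw_name[i])
  occ <- session$items$occasion[i]
  for (nm in ingredient_names)
    session <- append_item(session, nm, occ, match_item(nm, db), parent_id = item_id)
  session
}

leaf_items <- function(session) {
  it <- session$items
  it[!(it$item_id %in% it$parent_id[!is.na(it$parent_id)]) &
       !(it$kind %in% "mixed_dish"), , drop = FALSE]
}

pending_items <- function(session) {
  lv <- leaf_items(session)
  lv[is.na(lv$group_id), , drop = FALSE]
}

#' Classify every reported item into its food group (step 3)
#'
#' Database-matched items take their preassigned group; ambiguous items are
#' resolved through their probe chain with the supplied answers; free-text
#' items take the enumerator's manual group. Mixed-dish parents receive no
#' group (their ingredients do). The operation is idempotent.
#'
#' @param session A `gdqs_session` at step 3.
#' @param db A `gdqs_master_db`.
#' @param probe_answers Named list: item id (as character) -> character
#'   vector of probe answers.
#' @param manual_groups Named list: item id (as character) -> concrete
#'   collection-time group for free-text items.
#' @param taxonomy Taxonomy validating manual groups.
#' @return The updated session with `group_id` set on every leaf item.
#' @export
classify_all <- function(session, db, probe_answers = list(),
                         manual_groups = list(), taxonomy = load_taxonomy()) {
  require_step(session, 3L)
  it <- session$items
  pending_probes <- character()
  for (i in seq_len(nrow(it))) {
    if (identical(it$kind[i], "mixed_dish")) next
    key <- as.character(it$item_id[i])
    if (it$provenance[i] == "db_matched") {
      ans <- probe_answers[[key]] %||% character()
      group <- tryCatch(resolve_entry(db, it$entry_id[i], ans),
                        gdqs_db_error = function(e) {
                          pending_probes <<- c(pending_probes, sprintf(
                            "'%s' (id %s): %s", it$raw_name[i], key, conditionMessage(e)))
                          NA_character_
                        })
      it$group_id[i] <- group
    } else {
      manual <- manual_groups[[key]]
      if (is.null(manual))
        session_error("free-text item '%s' (id %s) needs a manual group", it$raw_name[i], key)
      if (!manual %in% taxonomy$groups$group_id)
        session_error("manual group '%s' for item '%s' is not a collection-time group",
                      manual, it$raw_name[i])
      it$group_id[i] <- manual
    }
  }
  if (length(pending_probes))
    session_error("pending probe(s): %s", paste(pending_probes, collapse = "; "))
  session$items <- it
  pending <- it[is.na(it$group_id) & !(it$kind %in% "mixed_dish"), , drop = FALSE]
  if (nrow(pending))
    session_error("unresolved item(s): %s", paste(pending$raw_name, collapse = ", "))
  session
}

#' Record the deep-fried follow-up questions (step 4)
#'
#' Purchased deep-fried items are dual-classified: they keep their original
#' food group and are additionally tagged to the purchased-deep-fried
#' group. The home-deep-fried and poured-oil flags feed the liquid-oils
#' inference.
#'
#' @param session A `gdqs_session` at step 4.
#' @param purchased_item_ids Item ids of purchased deep-fried items.
#' @param home_deep_fried_pourable_oil Logical.
#' @param poured_or_used_oil Logical.
#' @return The updated session.
#' @export
set_deep_fried <- function(session, purchased_item_ids = integer(),
                           home_deep_fried_pourable_oil = FALSE,
                           poured_or_used_oil = FALSE) {
  require_step(session, 4L)
  bad <- setdiff(purchased_item_ids, session$items$item_id)
  if (length(bad)) session_error("unknown item id %s", bad[1])
  idx <- session$items$item_id %in% purchased_item_ids
  session$items$dual_group[idx] <- "purchased_deep_fried"
  session$purchased_deep_fried <- length(purchased_item_ids) > 0
  session$home_deep_fried_pourable_oil <- isTRUE(home_deep_fried_pourable_oil)
  session$poured_or_used_oil <- isTRUE(poured_or_used_oil)
  session
}

#' Record caloric sweeteners elicited by the sweetener probe (step 5)
#'
#' Sweeteners are easily forgotten in free listing; this probe adds them as
#' classified items of the sweets-and-ice-cream group.
#'
#' @param session A `gdqs_session` at step 5.
#' @param names Character vector of sweetener names (e.g. "sugar").
#' @param group_id Group the sweeteners are classified into.
#' @return The updated session.
#' @export
add_sweeteners <- function(session, names, group_id = "sweets_ice_cream") {
  require_step(session, 5L)
  for (nm in names) {
    session <- append_item(session, nm, "sweetener_probe",
                           list(entry_id = NA_character_, kind = "single_food",
                                provenance = "db_matched"))
    session$items$group_id[nrow(session$items)] <- group_id
  }
  session
}

#' Read back the reported foods grouped by food group
#'
#' The enumerator reads the per-group list back to the respondent before the
#' cube question, so the respondent can visualize the combined volume of
#' everything consumed in that group. Dual-classified purchased deep-fried
#' items appear under both their original and the deep-fried group.
#'
#' @param session A `gdqs_session` at step 4 or later.
#' @return Tibble with one row per group carrying at least one item:
#'   `group_id`, `n_items`, `item_names` (list-column).
#' @export
read_back_groups <- function(session) {
  if (session$step < 4L)
    session_error("read-back requires classification to be complete (step >= 4)")
  lv <- leaf_items(session)
  primary <- lv[!is.na(lv$group_id), c("group_id", "raw_name")]
  dual <- lv[!is.na(lv$dual_group), c("dual_group", "raw_name")]
  names(dual) <- c("group_id", "raw_name")
  dplyr::bind_rows(primary, dual) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(n_items = dplyr::n(),
                     item_names = list(.data$raw_name), .groups = "drop") |>
    dplyr::arrange(.data$group_id)
}

#' Record the cube selected for a food group (step 6)
#'
#' @param session A `gdqs_session` at step 6.
#' @param group_id A cube-assessed group with at least one reported item.
#' @param cube_index Selected cube, 1--10.
#' @param borderline_answer Required confirmation (`"bigger_or_equal"` or
#'   `"smaller"`) when the selected cube is a boundary cube of the group;
#'   `"not_applicable"` otherwise.
#' @param taxonomy A `gdqs_taxonomy`.
#' @return The updated session.
#' @export
record_cube_selection <- function(session, group_id, cube_index,
                                  borderline_answer = "not_applicable",
                                  taxonomy = load_taxonomy()) {
  require_step(session, 6L)
  groups_with_items <- read_back_groups(session)$group_id
  if (!group_id %in% groups_with_items)
    session_error("no reported items in group '%s'; no cube question is asked", group_id)
  # validates group/cube/borderline consistency
  categorize_from_cube(taxonomy, group_id, cube_index, borderline_answer)
  session$cube_selections <- session$cube_selections |>
    dplyr::filter(.data$group_id != !!group_id) |>
    dplyr::bind_rows(tibble::tibble(group_id = group_id,
                                    cube_index = as.integer(cube_index),
                                    borderline_answer = borderline_answer))
  session
}

#' Finalize a session: quantities, oil inference and (optionally) the score
#'
#' @param session A `gdqs_session` at step 6 (advanced to 7 on success).
#' @param taxonomy A `gdqs_taxonomy`.
#' @param point_table Optional point table (see [load_point_table()]); when
#'   supplied the GDQS total and submetrics are computed.
#' @return A list with elements `session` (at step 7), `quantities` (see
#'   [session_quantities()]), `oil_category`, and `result` (a
#'   `gdqs_result`, or `NULL` without a point table).
#' @export
finalize_session <- function(session, taxonomy = load_taxonomy(), point_table = NULL) {
  require_step(session, 6L)
  quantities <- session_quantities(session, taxonomy)
  oil <- infer_oil_category(session$home_deep_fried_pourable_oil,
                            mixed_dish_count(session),
                            session$poured_or_used_oil)
  session$step <- 7L
  result <- if (!is.null(point_table))
    score_session(quantities, oil, point_table, taxonomy)
  list(session = session, quantities = quantities, oil_category = oil,
       result = result %||% NULL)
}

#' @export
print.gdqs_session <- function(x, ...) {
  cat(sprintf("<gdqs_session> respondent %s, %s, step %d\n",
              x$respondent_id, x$recall_date, x$step))
  cat(sprintf("  %d item(s), %d mixed dish(es), %d cube selection(s)\n",
              nrow(x$items), mixed_dish_count(x), nrow(x$cube_selections)))
  invisible(x)
}

#' Serialize a session to JSON
#' @param session A `gdqs_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  jsonlite::write_json(unclass(session), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a session back from JSON
#' @param path File written by [write_session()].
#' @return A `gdqs_session`.
#' @export
read_session <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- new_session(raw$respondent_id, raw$recall_date)
  s$step <- as.integer(raw$step)
  s$purchased_deep_fried <- isTRUE(raw$purchased_deep_fried)
  s$home_deep_fried_pourable_oil <- isTRUE(raw$home_deep_fried_pourable_oil)
  s$poured_or_used_oil <- isTRUE(raw$poured_or_used_oil)
  if (length(raw$items)) {
    it <- tibble::as_tibble(raw$items)
    it$item_id <- as.integer(it$item_id)
    it$parent_id <- as.integer(it$parent_id)
    s$items <- dplyr::bind_rows(empty_items(), it)
  }
  if (length(raw$cube_selections)) {
    cs <- tibble::as_tibble(raw$cube_selections)
    cs$cube_index <- as.integer(cs$cube_index)
    s$cube_selections <- dplyr::bind_rows(empty_selections(), cs)
  }
  s
}

#' Export classified items as a flat table
#' @param session A `gdqs_session`.
#' @return Tibble with columns `item`, `occasion`, `group`, `provenance`.
#' @export
session_items <- function(session) {
  lv <- leaf_items(session)
  tibble::tibble(item = lv$raw_name, occasion = lv$occasion,
                 group = lv$group_id, provenance = lv$provenance)
}
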