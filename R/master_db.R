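# Master database of preclassified foods, beverages and mixed dishes.
# Ambiguous entries (bread, milk, ...) carry up to two probe descriptors
# whose answers decide the food group at interview time.

db_error <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "gdqs_db_error")

parse_probe_map <- function(spec) {
  # "white=refined_grains;brown=whole_grains" -> named character vector
  if (is.na(spec) || !nzchar(spec)) return(NULL)
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) db_error("malformed probe map '%s'", spec)
  stats::setNames(trimws(vapply(kv, `[[`, "", 2L)), trimws(vapply(kv, `[[`, "", 1L)))
}

#' Load and validate a master food database
#'
#' The master database holds one row per food, beverage or mixed dish with
#' its preassigned food group. Entries whose group depends on extra detail
#' (e.g. white vs brown bread) have `group_id = "ambiguous"` and one or two
#' probe columns; each probe is a question plus an `answer=group` map, with
#' a `probe1` answer optionally chaining to `probe2` via the target
#' `"probe2"`.
#'
#' @param x Path to a CSV file, or a data frame, with columns `entry_id`,
#'   `name`, `aliases` (`;`-separated, may be empty), `kind` (`single_food`,
#'   `beverage` or `mixed_dish`), `group_id` (a collection-time group or
#'   `"ambiguous"`), and optional `probe1_question`, `probe1_map`,
#'   `probe2_question`, `probe2_map`.
#' @param taxonomy Taxonomy whose collection groups are the valid targets.
#' @return A `gdqs_master_db` tibble.
#' @examples
#' db <- gen_master_db(seed = 1)
#' search_foods(db, "banana")
#' @export
load_master_db <- function(x, taxonomy = load_taxonomy()) {
  db <- if (is.character(x)) read_cfg(x) else tibble::as_tibble(x)
  required <- c("entry_id", "name", "kind", "group_id")
  miss <- setdiff(required, names(db))
  if (length(miss)) db_error("master db is missing column(s): %s", paste(miss, collapse = ", "))
  for (col in c("aliases", "probe1_question", "probe1_map", "probe2_question", "probe2_map"))
    if (!col %in% names(db)) db[[col]] <- NA_character_

  if (anyDuplicated(db$entry_id)) db_error("duplicate entry_id values")
  dup <- db$name[duplicated(tolower(db$name))]
  if (length(dup)) db_error("duplicate canonical name '%s'", dup[1])
  bad_kind <- setdiff(unique(db$kind), c("single_food", "beverage", "mixed_dish"))
  if (length(bad_kind)) db_error("unknown kind '%s'", bad_kind[1])

  valid_groups <- taxonomy$groups$group_id
  bad <- setdiff(unique(db$group_id), c(valid_groups, "ambiguous"))
  if (length(bad))
    db_error("unknown group '%s'; valid groups: %s", bad[1],
             paste(valid_groups, collapse = ", "))

  for (i in seq_len(nrow(db))) {
    m1 <- parse_probe_map(db$probe1_map[i])
    m2 <- parse_probe_map(db$probe2_map[i])
    if (db$group_id[i] == "ambiguous" && is.null(m1))
      db_error("ambiguous entry '%s' has no probe", db$name[i])
    if (!is.null(m1)) {
      bad1 <- setdiff(m1, c(valid_groups, "probe2"))
      if (length(bad1)) db_error("probe on '%s' targets unknown group '%s'", db$name[i], bad1[1])
      if (any(m1 == "probe2") && is.null(m2))
        db_error("probe1 on '%s' chains to a missing probe2", db$name[i])
    }
    if (!is.null(m2)) {
      bad2 <- setdiff(m2, valid_groups)
      if (length(bad2)) db_error("probe2 on '%s' targets unknown group '%s'", db$name[i], bad2[1])
    }
  }
  class(db) <- c("gdqs_master_db", class(db))
  db
}

entry_strings <- function(db) {
  # list of lowercase name + aliases per entry
  al <- strsplit(ifelse(is.na(db$aliases), "", db$aliases), ";", fixed = TRUE)
  purrr::map2(tolower(db$name), al, function(nm, a) unique(c(nm, tolower(trimws(a[nzchar(a)])))))
}

similarity <- function(query, strings) {
  # normalized edit-distance ratio; a prefix match scores 0.99 so that
  # prefix hits rank above non-prefix fuzzy hits but below exact matches
  q <- tolower(trimws(query))
  best <- 0
  for (s in strings) {
    if (s == q) return(1)
    full <- 1 - utils::adist(q, s)[1, 1] / max(nchar(q), nchar(s))
    pref <- if (nchar(s) >= nchar(q)) {
      0.99 * (1 - utils::adist(q, substr(s, 1, nchar(q)))[1, 1] / nchar(q))
    } else 0
    best <- max(best, full, pref)
  }
  best
}

#' Fuzzy-search the master database
#'
#' Approximate string matching over canonical names and aliases, emulating
#' the type-ahead drop-down of the collection instrument. Scoring uses a
#' normalized edit-distance ratio; an exact (case-insensitive) match scores
#' 1 and always ranks first, and entries whose name or alias starts with the
#' query rank above non-prefix fuzzy hits. Ties are broken by `entry_id`, so
#' results are deterministic and independent of the row order of `db`.
#'
#' @param db A `gdqs_master_db`.
#' @param query Non-empty search string.
#' @param limit Maximum number of results.
#' @param min_score Minimum similarity for inclusion (default 0.6).
#' @return Tibble of matches (`entry_id`, `name`, `kind`, `group_id`,
#'   `score`), sorted by descending score.
#' @export
search_foods <- function(db, query, limit = 10L, min_score = 0.6) {
  query <- trimws(query)
  if (!nzchar(query)) db_error("empty search query")
  scores <- vapply(entry_strings(db), function(s) similarity(query, s), numeric(1))
  out <- tibble::tibble(
    entry_id = db$entry_id, name = db$name, kind = db$kind,
    group_id = db$group_id, score = scores
  )
  out |>
    dplyr::filter(.data$score >= min_score) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$entry_id) |>
    utils::head(limit)
}

#' Resolve an entry to its food group through its probe chain
#'
#' Concrete entries return their preassigned group regardless of answers;
#' ambiguous entries walk their probe chain using the supplied ordered
#' answer labels.
#'
#' @param db A `gdqs_master_db`.
#' @param entry_id Entry identifier.
#' @param answers Character vector of probe answers, in probe order.
#' @return A concrete collection-time `group_id`.
#' @examples
#' db <- gen_master_db(seed = 1)
#' resolve_entry(db, "bread", c("brown"))
#' @export
resolve_entry <- function(db, entry_id, answers = character()) {
  i <- match(entry_id, db$entry_id)
  if (is.na(i)) db_error("unknown entry '%s'", entry_id)
  if (db$group_id[i] != "ambiguous") return(db$group_id[i])
  maps <- list(parse_probe_map(db$probe1_map[i]), parse_probe_map(db$probe2_map[i]))
  target <- "probe1"
  k <- 0L
  for (m in maps) {
    if (is.null(m)) break
    k <- k + 1L
    if (length(answers) < k)
      db_error("entry '%s' needs a probe answer; expected one of: %s",
               db$name[i], paste(names(m), collapse = ", "))
    ans <- answers[[k]]
    if (!ans %in% names(m))
      db_error("unknown answer '%s' for entry '%s'; expected one of: %s",
               ans, db$name[i], paste(names(m), collapse = ", "))
    target <- m[[ans]]
    if (target != "probe2") return(target)
  }
  db_error("probe chain for entry '%s' did not terminate", db$name[i])
}

#' List the probe question(s) attached to an entry
#' @param db A `gdqs_master_db`.
#' @param entry_id Entry identifier.
#' @return Tibble with columns `probe`, `question`, `answers`.
#' @export
entry_probes <- function(db, entry_id) {
  i <- match(entry_id, db$entry_id)
  if (is.na(i)) db_error("unknown entry '%s'", entry_id)
  out <- list()
  for (k in 1:2) {
    m <- parse_probe_map(db[[paste0("probe", k, "_map")]][i])
    if (!is.null(m)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        probe = k, question = db[[paste0("probe", k, "_question")]][i],
        answers = paste(names(m), collapse = ";")
      )
    }
  }
  dplyr::bind_rows(out)
}
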