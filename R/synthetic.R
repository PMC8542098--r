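# Seeded generators for every input the package consumes: a master food
# database, recall sessions, and multi-dataset consumption tables with a
# food-level density lookup. These emulate the *structure* of the real
# inputs (the authors' ~2700-entry database and the 11 survey datasets are
# not public); they make no claim of dietary realism.

#' Generate a synthetic master food database
#'
#' Builds a structurally realistic database from the representative-food
#' vocabulary of the taxonomy: at least one entry per collection-time group,
#' probed ambiguous entries (bread resolving to refined vs whole grains,
#' milk to high- vs low-fat dairy), and mixed dishes with known ingredient
#' lists. Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param foods_per_group Entries drawn per group from the vocabulary.
#' @param taxonomy A `gdqs_taxonomy`.
#' @return A validated `gdqs_master_db`.
#' @examples
#' db <- gen_master_db(seed = 1)
#' @export
gen_master_db <- function(seed = 1L, foods_per_group = 2L,
                          taxonomy = load_taxonomy()) {
  set.seed(seed)
  dens <- taxonomy$densities
  rows <- purrr::map_dfr(seq_len(nrow(dens)), function(i) {
    foods <- strsplit(dens$representative_foods[i], ";", fixed = TRUE)[[1]]
    foods <- utils::head(foods, foods_per_group)
    kind <- if (dens$group_id[i] %in% c("juice", "ssb")) "beverage" else "single_food"
    tibble::tibble(name = foods, kind = kind, group_id = dens$group_id[i])
  })
  # drop vocabulary names that collide with the probed/mixed entries below
  rows <- rows[!tolower(rows$name) %in% c("bread", "milk", "chicken stew", "vegetable curry"), ]

  special <- tibble::tibble(
    name = c("Bread", "Milk", "Chicken stew", "Vegetable curry", "Tilapia"),
    kind = c("single_food", "beverage", "mixed_dish", "mixed_dish", "single_food"),
    group_id = c("ambiguous", "ambiguous", "ambiguous", "ambiguous", "fish_shellfish"),
    probe1_question = c("Was the bread white or brown?",
                        "Was the milk full fat or low fat?",
                        "Main ingredient animal or vegetable?",
                        "Main ingredient animal or vegetable?", NA),
    probe1_map = c("white=refined_grains;brown=whole_grains",
                   "full fat=hf_dairy_other;low fat=low_fat_dairy",
                   "animal=poultry_game_meat;vegetable=other_veg",
                   "animal=poultry_game_meat;vegetable=other_veg", NA)
  )
  special <- special[!tolower(special$name) %in% tolower(rows$name), ]

  db <- dplyr::bind_rows(rows, special)
  db <- db[!duplicated(tolower(db$name)), ]
  db$entry_id <- sprintf("f%03d", seq_len(nrow(db)))
  db$aliases <- NA_character_
  db$aliases[db$name == "Banana"] <- "Ripe banana;Matoke"
  load_master_db(db, taxonomy)
}

#' Generate synthetic recall sessions
#'
#' Drives the full interview programmatically: free listing, mixed-dish
#' decomposition, probe classification, deep-fried and sweetener steps, and
#' cube selections (including borderline confirmations). Oil flags and
#' mixed-dish counts vary across sessions so all inference branches occur.
#'
#' @param seed Integer seed.
#' @param n Number of sessions.
#' @param db A `gdqs_master_db` (see [gen_master_db()]).
#' @param taxonomy A `gdqs_taxonomy`.
#' @param mixed_dish_prob Probability a session reports a mixed dish.
#' @param oil_flag_prob Probability of each oil flag being set.
#' @return List of `gdqs_session` objects at step 6 (ready to finalize).
#' @export
gen_sessions <- function(seed = 1L, n = 5L, db = gen_master_db(seed),
                         taxonomy = load_taxonomy(),
                         mixed_dish_prob = 0.5, oil_flag_prob = 0.3) {
  set.seed(seed + 1L)
  singles <- db[db$kind != "mixed_dish" & db$group_id != "ambiguous", ]
  dishes <- db[db$kind == "mixed_dish", ]
  occasions <- c("breakfast", "lunch", "dinner", "snack")

  purrr::map(seq_len(n), function(i) {
    s <- new_session(sprintf("r%03d", i))
    n_items <- sample(2:5, 1)
    picks <- singles[sample(nrow(singles), n_items), ]
    for (j in seq_len(n_items))
      s <- add_item(s, picks$name[j], sample(occasions, 1), db,
                    entry_id = picks$entry_id[j])
    use_dish <- stats::runif(1) < mixed_dish_prob && nrow(dishes) > 0
    if (use_dish) s <- add_item(s, dishes$name[1], "dinner", db,
                                entry_id = dishes$entry_id[1])
    s <- advance_step(s)
    if (use_dish) {
      dish_id <- s$items$item_id[s$items$kind == "mixed_dish"][1]
      ing <- singles$name[sample(nrow(singles), 2)]
      s <- decompose_mixed_dish(s, dish_id, ing, db)
    }
    s <- advance_step(s)
    s <- classify_all(s, db, taxonomy = taxonomy)
    s <- advance_step(s)
    s <- set_deep_fried(
      s,
      home_deep_fried_pourable_oil = stats::runif(1) < oil_flag_prob,
      poured_or_used_oil = stats::runif(1) < oil_flag_prob
    )
    s <- advance_step(s)
    if (stats::runif(1) < 0.5) s <- add_sweeteners(s, "Sugar")
    s <- advance_step(s)
    for (gid in read_back_groups(s)$group_id) {
      if (!gid %in% cube_assessed_groups(taxonomy)) next
      cube <- sample(1:10, 1)
      bc <- group_boundary_table(taxonomy, gid)$cube_index
      ans <- if (cube %in% bc) sample(c("bigger_or_equal", "smaller"), 1) else "not_applicable"
      s <- record_cube_selection(s, gid, cube, ans, taxonomy)
    }
    s
  })
}

#' Generate synthetic multi-dataset consumption records and densities
#'
#' Emulates the structure of the multi-country 24-h recall datasets used
#' for the density derivation: `n_datasets` datasets, each with
#' `n_respondents` women and `foods_per_group` distinct foods per food
#' group. Per-respondent gram amounts are log-normal; each food has a
#' dataset-independent weight so that a food's expected share of its
#' group's grams is its weight. `dominant` foods are given their target
#' share, with the remainder split evenly. Optionally a fraction of
#' respondents carries a second recall (to be dropped by
#' [filter_first_recall()]), and food names can be made pairwise disjoint
#' across datasets.
#'
#' @param seed Integer seed.
#' @param n_datasets Number of datasets; default 11.
#' @param n_respondents Respondents (women) per dataset; default 60.
#' @param foods_per_group Distinct foods per group per dataset; default 15.
#' @param groups Character vector of group ids; defaults to the shipped
#'   taxonomy's cube-assessed groups.
#' @param dominant Named numeric vector: share targeted by the designated
#'   dominant food of each group (food named `"<group>_dom"`); e.g.
#'   `c(refined_grains = 0.6)`. Shares must be in (0, 1).
#' @param second_recall_prob Fraction of respondents with a second recall.
#' @param disjoint_names If `TRUE`, food names are prefixed by dataset so
#'   no name recurs across datasets.
#' @param sdlog Log-normal sigma of per-respondent gram amounts.
#' @return List with `records` (tibble: `dataset_id`, `respondent_id`,
#'   `recall_no`, `food_name`, `group_id`, `grams`) and `densities`
#'   (tibble: `food_name`, `density`).
#' @export
gen_consumption_datasets <- function(seed = 1L, n_datasets = 11L,
                                     n_respondents = 60L,
                                     foods_per_group = 15L,
                                     groups = NULL,
                                     dominant = NULL,
                                     second_recall_prob = 0.2,
                                     disjoint_names = FALSE,
                                     sdlog = 0.4) {
  set.seed(seed)
  groups <- groups %||% cube_assessed_groups(load_taxonomy())
  stopifnot(foods_per_group >= 1L, n_datasets >= 1L, n_respondents >= 1L)
  if (!is.null(dominant) && any(dominant <= 0 | dominant >= 1))
    pipeline_error("dominant shares must lie in (0, 1)")

  base_foods <- function(gid, ds) {
    nm <- sprintf("%s_food_%02d", gid, seq_len(foods_per_group))
    if (!is.null(dominant) && gid %in% names(dominant)) nm[1] <- paste0(gid, "_dom")
    if (disjoint_names) nm <- paste0("d", ds, "_", nm)
    nm
  }
  food_weights <- function(gid) {
    # dataset-specific weights (symmetric Dirichlet): different datasets
    # favour different foods, as different countries do, so per-dataset
    # top-5 lists differ and the pooled candidate set grows
    w <- stats::rgamma(foods_per_group, shape = 1.5)
    w <- w / sum(w)
    if (!is.null(dominant) && gid %in% names(dominant)) {
      share <- dominant[[gid]]
      w <- c(share, (1 - share) * w[-1] / sum(w[-1]))
    }
    w
  }

  records <- purrr::map_dfr(seq_len(n_datasets), function(ds) {
    purrr::map_dfr(groups, function(gid) {
      foods <- base_foods(gid, ds)
      w <- food_weights(gid)
      # meanlog per food chosen so E[grams] is proportional to its weight
      meanlog <- log(w * 100) - sdlog^2 / 2
      second <- which(stats::runif(n_respondents) < second_recall_prob)
      resp <- c(rep(seq_len(n_respondents), each = foods_per_group),
                rep(second, each = foods_per_group))
      recall <- rep(c(1L, 2L), c(n_respondents, length(second)) * foods_per_group)
      n_rows <- length(resp)
      tibble::tibble(
        dataset_id = sprintf("ds%02d", ds),
        respondent_id = sprintf("ds%02d_w%03d", ds, resp),
        recall_no = recall,
        food_name = rep(foods, times = n_respondents + length(second)),
        group_id = gid,
        grams = stats::rlnorm(n_rows,
                              meanlog = rep(meanlog, times = n_respondents + length(second)),
                              sdlog = sdlog)
      )
    })
  })
  dens <- records |>
    dplyr::distinct(.data$food_name, .data$group_id) |>
    dplyr::mutate(density = stats::runif(dplyr::n(), 0.4, 1.1)) |>
    dplyr::select("food_name", "density")
  list(records = records, densities = dens)
}
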