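# Independent brute-force oracles used to cross-check the pipeline
# implementations. Deliberately naive: plain loops, no dplyr.

# per-(dataset, group, food) share of group grams, by explicit tallying
oracle_contributions <- function(records) {
  out <- list()
  for (ds in unique(records$dataset_id)) {
    rds <- records[records$dataset_id == ds, ]
    for (g in unique(rds$group_id)) {
      rg <- rds[rds$group_id == g, ]
      total <- sum(rg$grams)
      if (total <= 0) next
      for (f in unique(rg$food_name)) {
        fg <- sum(rg$grams[rg$food_name == f])
        if (fg > 0) {
          out[[length(out) + 1L]] <- data.frame(
            dataset_id = ds, group_id = g, food_name = f,
            pct_contribution = fg / total)
        }
      }
    }
  }
  do.call(rbind, out)
}

# mean rank over datasets where ranked; top_n lowest mean ranks per group
oracle_aggregate <- function(rank_entries, top_n = 10) {
  out <- list()
  for (g in unique(rank_entries$group_id)) {
    rg <- rank_entries[rank_entries$group_id == g, ]
    foods <- unique(rg$food_name)
    mr <- vapply(foods, function(f) mean(rg$rank[rg$food_name == f]), numeric(1))
    tc <- vapply(foods, function(f) sum(rg$pct_contribution[rg$food_name == f]), numeric(1))
    ord <- order(mr, -tc, foods)
    keep <- head(ord, top_n)
    out[[g]] <- data.frame(group_id = g, food_name = foods[keep],
                           mean_rank = mr[keep])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# optimal 1-D clustering into k contiguous blocks minimizing the maximum
# within-cluster diameter, by exhaustive enumeration of break positions
oracle_cluster_1d <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  stopifnot(k <= n)
  best <- NULL; best_obj <- Inf
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  for (sp in splits) {
    bounds <- c(0, sp, n)
    diam <- 0; centers <- numeric(k)
    for (j in seq_len(k)) {
      blk <- xs[(bounds[j] + 1):bounds[j + 1]]
      diam <- max(diam, max(blk) - min(blk))
      centers[j] <- mean(blk)
    }
    if (diam < best_obj) { best_obj <- diam; best <- centers }
  }
  list(centers = best, objective = best_obj)
}

# plain DP Levenshtein distance, independent of utils::adist
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(a) + 1L, length(b) + 1L)
  d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (a[i] != b[j]))
  d[length(a) + 1L, length(b) + 1L]
}

# shared small fixtures
tiny_taxonomy <- function() load_taxonomy()

tiny_db <- function() {
  load_master_db(tibble::tibble(
    entry_id = c("e1", "e2", "e3", "e4", "e5", "e6", "e7"),
    name = c("Banana", "Bread", "Tilapia", "Chicken stew", "Watermelon",
             "Fried chicken", "Breadfruit"),
    aliases = c("Ripe banana", NA, NA, NA, NA, NA, NA),
    kind = c("single_food", "single_food", "single_food", "mixed_dish",
             "single_food", "single_food", "single_food"),
    group_id = c("other_fruits", "ambiguous", "fish_shellfish", "ambiguous",
                 "other_fruits", "poultry_game_meat", "other_fruits"),
    probe1_question = c(NA, "White or brown?", NA, "Animal or vegetable?", NA, NA, NA),
    probe1_map = c(NA, "white=refined_grains;brown=whole_grains", NA,
                   "animal=poultry_game_meat;vegetable=other_veg", NA, NA, NA)
  ))
}
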