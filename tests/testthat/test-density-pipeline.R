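test_that("contributions are per-group gram shares summing to one", {
  rec <- tibble::tibble(
    dataset_id = "d1", respondent_id = rep(c("w1", "w2"), each = 3),
    food_name = rep(c("A", "B", "C"), 2), group_id = "legumes",
    grams = c(30, 20, 10, 20, 10, 10))
  cc <- compute_contributions(rec)
  expect_equal(cc$pct_contribution[match(c("A", "B", "C"), cc$food_name)],
               c(0.5, 0.3, 0.2))
  expect_equal(sum(cc$pct_contribution), 1)

  single <- tibble::tibble(dataset_id = "d1", respondent_id = "w1",
                           food_name = "A", group_id = "eggs", grams = 12)
  expect_equal(compute_contributions(single)$pct_contribution, 1)

  zero <- dplyr::mutate(single, grams = 0)
  expect_equal(nrow(compute_contributions(zero)), 0L)
})

test_that("contributions match a brute-force tally on a 200-record synthetic set", {
  set.seed(11)
  rec <- tibble::tibble(
    dataset_id = sample(c("d1", "d2"), 200, replace = TRUE),
    respondent_id = sample(sprintf("w%02d", 1:20), 200, replace = TRUE),
    food_name = sample(LETTERS[1:8], 200, replace = TRUE),
    group_id = sample(c("legumes", "red_meat", "juice"), 200, replace = TRUE),
    grams = round(stats::rlnorm(200, 3, 0.7), 2))
  got <- compute_contributions(rec)
  want <- oracle_contributions(rec)
  merged <- merge(got, want, by = c("dataset_id", "group_id", "food_name"))
  expect_equal(nrow(merged), nrow(got))
  expect_equal(nrow(merged), nrow(want))
  expect_equal(merged$pct_contribution.x, merged$pct_contribution.y, tolerance = 1e-12)
})

test_that("only the first recall per respondent is kept", {
  rec <- tibble::tibble(
    dataset_id = "d1", respondent_id = c("w1", "w1", "w2"),
    recall_no = c(1L, 2L, 1L), food_name = "A", group_id = "eggs",
    grams = c(10, 99, 5))
  kept <- filter_first_recall(rec)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$recall_no == 1L))

  all_first <- dplyr::filter(rec, recall_no == 1L)
  expect_equal(filter_first_recall(all_first), all_first)

  set.seed(5)
  mix <- tibble::tibble(
    dataset_id = sample(c("d1", "d2"), 100, replace = TRUE),
    respondent_id = sample(sprintf("w%02d", 1:10), 100, replace = TRUE),
    recall_no = sample(1:3, 100, replace = TRUE),
    food_name = "A", group_id = "eggs", grams = 1)
  kept <- filter_first_recall(mix)
  # oracle: per (dataset, respondent), rows carrying the minimum recall_no
  expected_n <- sum(vapply(split(mix, paste(mix$dataset_id, mix$respondent_id)),
                           function(d) sum(d$recall_no == min(d$recall_no)),
                           numeric(1)))
  expect_equal(nrow(kept), expected_n)
})

test_that("ranking caps at five foods with deterministic tie-breaks", {
  rec <- tibble::tibble(
    dataset_id = "d1", respondent_id = "w1",
    food_name = sprintf("food%02d", 1:8), group_id = "legumes",
    grams = c(80, 70, 60, 50, 40, 30, 20, 10))
  rk <- rank_top_foods(compute_contributions(rec))
  expect_equal(nrow(rk), 5L)
  expect_equal(rk$rank, 1:5)
  expect_equal(rk$food_name[1], "food01")

  rec3 <- dplyr::slice_head(rec, n = 3)
  expect_equal(nrow(rank_top_foods(compute_contributions(rec3))), 3L)

  # tie at the last rank: lexicographically smaller name wins
  tie <- tibble::tibble(
    dataset_id = "d1", respondent_id = "w1",
    food_name = c("apple", "fig", "date", "cherry", "banana", "elderberry"),
    group_id = "other_fruits", grams = c(60, 10, 10, 30, 40, 10))
  rk_tie <- rank_top_foods(compute_contributions(tie))
  expect_equal(rk_tie$food_name[rk_tie$rank == 4], "date")
  expect_equal(rk_tie$food_name[rk_tie$rank == 5], "elderberry")
  expect_false("fig" %in% rk_tie$food_name)
})

test_that("mean-rank aggregation selects the lowest mean ranks with densities", {
  # one dataset, five ranked foods with densities 0.5..0.9 -> mean 0.7
  rec <- tibble::tibble(
    dataset_id = "d1", respondent_id = "w1",
    food_name = letters[1:5], group_id = "legumes",
    grams = c(50, 40, 30, 20, 10))
  dens <- stats::setNames(seq(0.5, 0.9, by = 0.1), letters[1:5])
  reps <- aggregate_representatives(rank_top_foods(compute_contributions(rec)), dens)
  expect_equal(nrow(reps), 5L)
  expect_equal(group_mean_densities(reps)$mean_density, 0.7)

  # a food ranking 1 in all three datasets has mean rank 1 and is selected
  rec3 <- purrr::map_dfr(1:3, function(d) tibble::tibble(
    dataset_id = paste0("d", d), respondent_id = "w1",
    food_name = c("X", sample(letters[1:6], 3)), group_id = "eggs",
    grams = c(100, 30, 20, 10)))
  rk3 <- rank_top_foods(compute_contributions(rec3))
  dens3 <- stats::setNames(rep(0.6, 7), c("X", letters[1:6]))
  reps3 <- aggregate_representatives(rk3, dens3)
  expect_equal(reps3$mean_rank[reps3$food_name == "X"], 1)
  expect_equal(reps3$food_name[1], "X")

  expect_error(aggregate_representatives(rk3, dens3[-1]), "X",
               class = "gdqs_pipeline_error")
})

test_that("aggregation matches the brute-force oracle on a synthetic fixture", {
  set.seed(21)
  sim <- gen_consumption_datasets(seed = 21, n_datasets = 4, n_respondents = 15,
                                  foods_per_group = 12,
                                  groups = c("legumes", "red_meat"))
  rk <- rank_top_foods(compute_contributions(filter_first_recall(sim$records)))
  reps <- aggregate_representatives(rk, sim$densities)
  want <- oracle_aggregate(as.data.frame(rk))
  for (g in unique(want$group_id)) {
    expect_equal(reps$food_name[reps$group_id == g],
                 want$food_name[want$group_id == g], info = g)
    expect_equal(reps$mean_rank[reps$group_id == g],
                 want$mean_rank[want$group_id == g], info = g)
  }
})

test_that("penalizing absent datasets is exposed as an option", {
  rk <- tibble::tibble(
    dataset_id = c("d1", "d2", "d1"), group_id = "eggs",
    food_name = c("X", "X", "Y"), pct_contribution = c(0.6, 0.6, 0.4),
    rank = c(1L, 1L, 2L))
  reps <- aggregate_representatives(rk, c(X = 0.6, Y = 0.6), absent_rank = 6)
  # X: (1+1)/2 = 1; Y: (2+6)/2 = 4
  expect_equal(reps$mean_rank[reps$food_name == "X"], 1)
  expect_equal(reps$mean_rank[reps$food_name == "Y"], 4)
})

test_that("gram cutoffs convert to volumes and sides, cheese in milk equivalents", {
  tax <- load_taxonomy()
  bv <- boundaries_to_volumes(tax)
  rm <- bv[bv$group_id == "red_meat", ]
  expect_equal(rm$volume_cm3[rm$boundary == "low_middle"], 12 / 0.87, tolerance = 1e-12)
  expect_equal(rm$side_mm[rm$boundary == "low_middle"], 10 * (12 / 0.87)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(rm$volume_cm3[rm$boundary == "middle_high"], 48 / 0.87, tolerance = 1e-12)

  ch <- bv[bv$group_id == "hf_dairy_cheese" & bv$boundary == "low_middle", ]
  expect_equal(ch$grams_for_volume, 35 / 6.1, tolerance = 1e-12)
  expect_equal(ch$volume_cm3, 35 / 6.1 / 0.84, tolerance = 1e-12)

  # identity case: density 1, 1 g -> 1 cm3 -> 10 mm
  tax1 <- tax
  tax1$densities$mean_density <- 1
  tax1$boundaries$original_g[!is.na(tax1$boundaries$cube_index)] <- 1
  bv1 <- boundaries_to_volumes(tax1)
  plain <- bv1[bv1$group_id == "red_meat", ]
  expect_true(all(abs(plain$volume_cm3 - 1) < 1e-12))
  expect_true(all(abs(plain$side_mm - 10) < 1e-12))

  d0 <- dplyr::mutate(tax$densities,
                      mean_density = ifelse(group_id == "juice", 0, mean_density))
  expect_error(boundaries_to_volumes(tax, d0), class = "gdqs_pipeline_error")
})

test_that("well-separated sides cluster into singletons matching the 1-D oracle", {
  sides <- c(12, 20, 31, 44, 58, 71, 83, 96)
  raw <- tibble::tibble(side_mm = sample(sides))
  design <- cluster_cubes(raw, k_core = 8, flank_sides = c(10, 100))
  core <- design$cubes[design$cubes$n_boundaries > 0, ]
  expect_equal(core$side_mm, sort(sides))
  oracle <- oracle_cluster_1d(sides, 8)
  expect_equal(core$side_mm, oracle$centers)

  # clustered clumps: oracle and hclust agree on clearly separated clumps
  clumps <- c(10.1, 10.4, 10.2, 50.3, 50.1, 90.2, 90.5, 90.1)
  d2 <- cluster_cubes(tibble::tibble(side_mm = clumps), k_core = 3,
                      flank_sides = c(5, 100))
  expect_equal(d2$cubes$side_mm[d2$cubes$n_boundaries > 0],
               oracle_cluster_1d(clumps, 3)$centers, tolerance = 1e-12)

  expect_error(cluster_cubes(tibble::tibble(side_mm = c(1, 1, 1)), k_core = 2),
               class = "gdqs_pipeline_error")
  one <- cluster_cubes(tibble::tibble(side_mm = c(30, 40)), k_core = 1,
                       flank_sides = c(18, 100))
  expect_equal(nrow(one$cubes), 3L)
  expect_equal(one$cubes$side_mm[2], 35)
})

test_that("clustering the published cutoffs recovers the printed cube sizes loosely", {
  tax <- load_taxonomy()
  design <- derive_cube_design(tax, k_core = 8)
  expect_equal(nrow(design$cubes), 10L)
  core <- design$cubes$side_mm[design$cubes$n_boundaries > 0]
  printed <- c(22, 27, 32, 38, 46, 52, 55, 89)
  hits <- sum(abs(sort(core) - printed) <= 3)
  expect_gte(hits, 6)
})
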