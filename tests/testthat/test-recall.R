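make_classified_session <- function(db = tiny_db()) {
  s <- new_session("r1")
  s <- add_item(s, "Banana", "breakfast", db)
  s <- add_item(s, "Watermelon", "dinner", db)
  s <- add_item(s, "Chicken stew", "dinner", db)
  s <- add_item(s, "Fried chicken", "lunch", db)
  s <- advance_step(s)
  dish_id <- s$items$item_id[s$items$kind == "mixed_dish"][1]
  s <- decompose_mixed_dish(s, dish_id, c("Tilapia", "Banana"), db)
  s <- advance_step(s)
  classify_all(s, db)
}

test_that("free listing matches, flags mixed dishes, and falls back to free text", {
  db <- tiny_db()
  s <- new_session("r1")
  s <- add_item(s, "banana", "breakfast", db)
  expect_equal(s$items$provenance[1], "db_matched")
  expect_equal(s$items$kind[1], "single_food")

  s <- add_item(s, "chicken stew", "dinner", db)
  expect_equal(s$items$kind[2], "mixed_dish")
  expect_equal(mixed_dish_count(s), 1L)

  s <- add_item(s, "grandma's porridge", "snack", db)
  expect_equal(s$items$provenance[3], "free_text_manual")

  expect_error(add_item(s, "", "snack", db), "empty", class = "gdqs_session_error")
  s2 <- advance_step(s)
  expect_error(add_item(s2, "rice", "lunch", db), "step", class = "gdqs_session_error")
})

test_that("mixed-dish decomposition creates matched children and guards exceptions", {
  db <- tiny_db()
  s <- new_session("r1")
  s <- add_item(s, "Chicken stew", "dinner", db)
  s <- add_item(s, "Bread", "dinner", db)
  s <- advance_step(s)
  s2 <- decompose_mixed_dish(s, 1L, c("Tilapia", "Banana", "Watermelon"), db)
  kids <- s2$items[!is.na(s2$items$parent_id), ]
  expect_equal(nrow(kids), 3L)
  expect_true(all(kids$parent_id == 1L))
  expect_true(all(kids$provenance == "db_matched"))

  # bread is a single food in the db: never decomposed
  expect_error(decompose_mixed_dish(s, 2L, "flour", db), "single food",
               class = "gdqs_session_error")
  expect_error(decompose_mixed_dish(s, 1L, character(), db), "main ingredients",
               class = "gdqs_session_error")
})

test_that("classification resolves probes, manual groups, and dual-tags deep-fried", {
  db <- tiny_db()
  s <- new_session("r1")
  s <- add_item(s, "Bread", "breakfast", db)
  s <- add_item(s, "grandma's porridge", "snack", db)
  s <- add_item(s, "Fried chicken", "lunch", db)
  s <- advance_step(s); s <- advance_step(s)

  expect_error(classify_all(s, db), class = "gdqs_session_error")
  s <- classify_all(s, db, probe_answers = list(`1` = "white"),
                    manual_groups = list(`2` = "refined_grains"))
  expect_equal(s$items$group_id[1], "refined_grains")
  expect_equal(s$items$group_id[2], "refined_grains")

  # idempotent
  s_again <- classify_all(s, db, probe_answers = list(`1` = "white"),
                          manual_groups = list(`2` = "refined_grains"))
  expect_equal(s_again$items, s$items)

  s <- advance_step(s)
  s <- set_deep_fried(s, purchased_item_ids = 3L)
  rb <- read_back_groups(s)
  expect_true("purchased_deep_fried" %in% rb$group_id)
  expect_true("poultry_game_meat" %in% rb$group_id)
  fried_groups <- rb$group_id[vapply(rb$item_names, function(x) "Fried chicken" %in% x, logical(1))]
  expect_setequal(fried_groups, c("poultry_game_meat", "purchased_deep_fried"))
})

test_that("read-back groups items per food group with dual tags", {
  s <- make_classified_session()
  s <- advance_step(s)
  s <- set_deep_fried(s, purchased_item_ids = 4L)
  rb <- read_back_groups(s)
  fruits <- rb$item_names[[match("other_fruits", rb$group_id)]]
  expect_setequal(fruits, c("Banana", "Watermelon", "Banana"))
  # the mixed dish itself contributes no group
  expect_false(any(vapply(rb$item_names, function(x) "Chicken stew" %in% x, logical(1))))

  empty <- new_session("r0")
  empty$step <- 4L
  expect_equal(nrow(read_back_groups(empty)), 0L)
})

test_that("read-back equals resolved leaf groups plus dual tags on synthetic sessions", {
  tax <- tiny_taxonomy()
  db <- gen_master_db(seed = 2)
  for (s in gen_sessions(seed = 7, n = 4, db = db, taxonomy = tax)) {
    rb <- read_back_groups(s)
    items <- s$items
    leaves <- items[!(items$item_id %in% items$parent_id[!is.na(items$parent_id)]) &
                      !(items$kind %in% "mixed_dish"), ]
    expected <- union(leaves$group_id[!is.na(leaves$group_id)],
                      leaves$dual_group[!is.na(leaves$dual_group)])
    expect_setequal(rb$group_id, expected)
  }
})

test_that("cube capture validates group, cube and borderline confirmation", {
  tax <- tiny_taxonomy()
  s <- make_classified_session()
  s$step <- 6L
  s <- record_cube_selection(s, "other_fruits", 3, taxonomy = tax)
  expect_equal(s$cube_selections$cube_index, 3L)
  # boundary cube (other_fruits low/middle sits on cube 4) requires an answer
  expect_error(record_cube_selection(s, "other_fruits", 4, taxonomy = tax),
               "confirmation", class = "gdqs_quantity_error")
  s <- record_cube_selection(s, "other_fruits", 4, "smaller", taxonomy = tax)
  expect_equal(nrow(s$cube_selections), 1L)  # re-selection replaces
  expect_error(record_cube_selection(s, "red_meat", 3, taxonomy = tax),
               "no reported items", class = "gdqs_session_error")
})

test_that("sessions round-trip through JSON with all fields and step", {
  s <- make_classified_session()
  s <- advance_step(s)
  s <- set_deep_fried(s, purchased_item_ids = 4L, poured_or_used_oil = TRUE)
  s <- advance_step(s)
  s <- add_sweeteners(s, "Sugar")
  s <- advance_step(s)
  s <- record_cube_selection(s, "other_fruits", 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(s2$step, s$step)
  expect_equal(s2$items, s$items)
  expect_equal(s2$cube_selections, s$cube_selections)
  expect_equal(s2$poured_or_used_oil, TRUE)
  expect_equal(mixed_dish_count(s2), mixed_dish_count(s))
})
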