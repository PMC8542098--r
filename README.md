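# gdqsr

Collection and scoring tools for the **operationalized Global Diet Quality
Score (GDQS)** — a food-group-based diet quality metric designed for
population surveys in low- and middle-income countries.

The GDQS places the grams consumed from each of 25 food groups into broad
quantity bands and sums band-specific points:

```
GDQS = Σ_g points_g(band_g),   band_g = category(grams_g | cutoffs_g)
```

Collecting `grams_g` by weighed recall is impractical at survey scale, so
the operationalized instrument asks respondents to visualize the combined
volume consumed per group and pick the closest of **10 cubes** (sides
18–100 mm); a mean group density ρ_g (g/cm³) links volume and grams
(`grams = ρ_g · side³`). Because 10 cubes must carry up to 54 cutoffs, the
operationalized gram cutoffs differ slightly from the original validation
cutoffs; both are shipped. Special cases implemented in full:

* **High-fat dairy** is split at collection into *hard cheese* and *other*
  (26 groups / 54 cutoffs) and recombined for reporting (25 / 51), with
  cheese grams × 6.1 converted to milk equivalents and the sum categorized
  against the original 35 / 140 / 734 g cutoffs.
* **Liquid oils** is never asked by cube; its band is inferred from three
  interview flags (home deep-frying with pourable oil, ≥ 2 mixed dishes,
  pouring/using oil), with one mixed dish ⇒ middle.
* **Borderline cubes** (a cube that *is* a cutoff) require an
  "as big or bigger" / "smaller" confirmation.

The package also re-implements the **design pipeline** that produced the
cube set: per-dataset percentage gram contributions, top-5 ranking,
mean-rank aggregation into ≤10 representative foods per group, mean group
density, gram→volume conversion of the original cutoffs, and 1-D
agglomerative clustering of the 52 cutoff sides into the 8 core cubes.
Seeded generators provide every input (master food database, recall
sessions, multi-dataset consumption tables), so everything runs with no
external data.

## Worked example

A small interview, driven end to end (the example point table is a toy
configuration — the published point values are supplied by the user as
configuration):

```r
library(gdqsr)
tax <- load_taxonomy()
db  <- gen_master_db(seed = 1)
pt  <- load_point_table(example_point_table_path())

s <- new_session("resp-001") |>
  add_item("banana", "breakfast", db) |>
  add_item("white rice", "lunch", db) |>
  add_item("chicken stew", "dinner", db) |>      # mixed dish
  advance_step()                                 # -> step 2
dish <- s$items$item_id[s$items$kind == "mixed_dish"]
s <- decompose_mixed_dish(s, dish, c("chicken average cut", "tomato"), db) |>
  advance_step() |> classify_all(db) |>          # step 3: classification
  advance_step() |> set_deep_fried() |>          # step 4: deep-fried flags
  advance_step() |> add_sweeteners("Sugar") |>   # step 5: sweetener probe
  advance_step()                                 # -> step 6: cube capture
s <- s |>
  record_cube_selection("other_fruits", 5, taxonomy = tax) |>
  record_cube_selection("refined_grains", 5, "bigger_or_equal", taxonomy = tax) |>
  record_cube_selection("poultry_game_meat", 4, taxonomy = tax) |>
  record_cube_selection("other_veg", 3, taxonomy = tax) |>
  record_cube_selection("sweets_ice_cream", 2, taxonomy = tax)
fin <- finalize_session(s, tax, pt)

fin$oil_category
#> [1] "middle"          # one mixed dish, no oil flags
glance(fin$result)
#> # A tibble: 1 × 4
#>   total submetric_plus submetric_minus n_groups
#>   <dbl>          <dbl>           <dbl>    <int>
#> 1    15              3              12       25
dplyr::filter(tidy(fin$result), grams_estimate > 0)
#> # A tibble: 5 × 5
#>   reporting_group_id category grams_estimate points role
#>   <chr>              <chr>             <dbl>  <dbl> <chr>
#> 1 other_fruits       middle            42.8       1 healthy
#> 2 other_veg          low               13.4       0 healthy
#> 3 poultry_game_meat  middle            27.2       1 healthy
#> 4 refined_grains     high              34.0       0 unhealthy
#> 5 sweets_ice_cream   low                7.45      2 unhealthy
```

`other_fruits` cube 5 means a 38 mm cube: 0.78 g/cm³ × 3.8³ cm³ ≈ 42.8 g,
between the 27 g and 107 g cutoffs, hence *middle*. `refined_grains` cube 5
sits exactly on the middle/high cutoff; the "bigger or equal" confirmation
resolves it to *high*. One mixed dish and no oil flags infer *middle*
liquid oils. Unreported groups score at *low*, which under the toy table's
anti-monotone unhealthy points is where the 12 negative-submetric points
come from.

Design-side, `cutoff_consistency_report(tax)` audits printed grams against
ρ × cube volume, and `derive_cube_design(tax)` re-derives the cube set from
the original cutoffs (recovering 6 of the 8 printed core sides within
3 mm; the authors' exact grouping is not recoverable).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, by running the package end to end: the milk-equivalent ratio
measured from the dairy-merge output; the representative-set size per group
on a seeded 11-dataset fixture with 15 foods per group; the number of
ranked foods in a group with 8 distinct foods in one dataset; and the
per-group candidate pool size when 11 datasets share no food names.

## Command line

`inst/cli/gdqs.R` is a thin wrapper over `gdqs_cli()`:

```sh
Rscript inst/cli/gdqs.R config validate
Rscript inst/cli/gdqs.R simulate --seed 7 --out /tmp/sim
Rscript inst/cli/gdqs.R score /tmp/sim/session_01.json \
    --points inst/extdata/example_point_table.csv --out /tmp/sim/scored.json
```

Every run writes a `run_manifest.json` (command, seed, versions, output
hashes).

## Scope

Implemented: the data path of the collection instrument and the density /
cube-design derivation. Not implemented (by design): the mobile UI, the
published per-category point values (configuration), nutrient-adequacy
estimation, and the regression sensitivity analyses on external cohorts.
See `vignettes/gdqs-methods.Rmd` for the methodological choices and their
rationale.
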