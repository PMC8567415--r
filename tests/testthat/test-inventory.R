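# Event-level GHG balance, batch runs, reporting, CLI.

test_that("the reference event reproduces the published total", {
  r <- ghg_balance(worked_example_event(), worked_example_config())
  expect_equal(r$sequestration_co2e, 15000 * 0.68 * 0.79 * 44 / 12) # 29546
  expect_equal(r$n2o_co2e, 2.4 * 0.23 * 298)                        # 164.496
  expect_equal(r$ch4_co2e, 0)
  expect_equal(r$priming_co2e, 0)
  expect_equal(r$total_co2e_display, 29710)
  expect_equal(r$total_co2e,
               r$sequestration_co2e + r$n2o_co2e + r$ch4_co2e + r$priming_co2e)

  p <- r$provenance
  expect_equal(p$fc, 0.68)
  expect_equal(p$fc_source, "class_table")
  expect_equal(p$fperm_method, "exact_cell")
  expect_equal(p$gwp_n2o, 298)
  expect_true(p$n2o_eligible)            # 10.2 Mg C/ha > 10
  expect_equal(p$application_rate_c, 10.2)
  expect_equal(p$baseline_n2o_raw, 2.355)
  expect_equal(p$baseline_n2o_used, 2.4) # 2-significant-figure convention
})

test_that("disabling intermediate rounding exposes full precision", {
  r <- ghg_balance(worked_example_event(), worked_example_config(rounding = FALSE))
  expect_equal(r$n2o_co2e, 2.355 * 0.23 * 298)
  expect_equal(r$provenance$baseline_n2o_used, 2.355)
})

test_that("switching to the current GWP rescales only the N2O term", {
  r298 <- ghg_balance(worked_example_event(), worked_example_config())
  r273 <- ghg_balance(worked_example_event(), bc_config(gwp_n2o = 273))
  expect_equal(r273$sequestration_co2e, r298$sequestration_co2e)
  expect_equal(r273$n2o_co2e, r298$n2o_co2e * 273 / 298)
})

test_that("the balance is linear in mass and zero for an empty event", {
  cfg <- bc_config(include_n2o = FALSE)
  ev1 <- worked_example_event()
  ev2 <- ev1; ev2$mass <- 2 * ev1$mass
  r1 <- ghg_balance(ev1, cfg)
  r2 <- ghg_balance(ev2, cfg)
  expect_equal(r2$sequestration_co2e, 2 * r1$sequestration_co2e)

  ev0 <- application_event("zero", biochar_spec("wood"), mass = 0)
  expect_equal(ghg_balance(ev0, cfg)$total_co2e, 0)
})

test_that("organic and forest-organic soils are refused", {
  ev <- application_event("histosol", biochar_spec("wood"), mass = 100,
                          soil_kind = "organic_or_forest_organic_horizon")
  expect_error(ghg_balance(ev), "mineral")
})

test_that("the conservative chain uses class-mean F_C and low-class permanence", {
  ev <- application_event("cons", biochar_spec("maize stover"), mass = 15000,
                          area_ha = 1000, soil_temp = 10, timeframe = 100,
                          n_rate = 0.15)
  r <- ghg_balance(ev, worked_example_config())
  expect_equal(r$provenance$fc, 0.67)               # pyrolysis mean column
  expect_equal(r$provenance$fperm, 0.72)            # low class at (10, 100)
  expect_equal(r$provenance$fperm_method, "conservative")

  # never exceeds the medium- or high-class total for the same event
  for (cls in c("medium", "high")) {
    evc <- application_event("cls",
                             biochar_spec("maize stover", temp_class = cls),
                             mass = 15000, area_ha = 1000, soil_temp = 10,
                             timeframe = 100, n_rate = 0.15)
    expect_lte(r$total_co2e, ghg_balance(evc, worked_example_config())$total_co2e)
  }
})

test_that("excluding the optional N2O credit zeroes the term and flags it", {
  r <- ghg_balance(worked_example_event(), worked_example_config(include_n2o = FALSE))
  expect_equal(r$n2o_co2e, 0)
  expect_equal(r$total_co2e, r$sequestration_co2e)
  expect_true(any(grepl("optional", r$provenance$warnings)))
})

test_that("batch runs are additive and order-invariant, with row-level error capture", {
  events <- list(worked_example_event(), worked_example_event())
  run <- run_inventory(events, worked_example_config())
  single <- ghg_balance(worked_example_event(), worked_example_config())
  expect_equal(run$total_co2e, 2 * single$total_co2e)
  expect_equal(nrow(run$results), 3) # two events + TOTAL row
  expect_equal(run$results$event_id[3], "TOTAL")

  # empty input
  empty <- run_inventory(list(), worked_example_config())
  expect_equal(empty$total_co2e, 0)
  expect_equal(nrow(empty$results), 0)

  # activity table with one bad row: others still processed
  tab <- data.frame(
    event_id = c("a", "b"),
    feedstock = c("maize stover", "unobtainium"),
    pyrolysis_temp_c = c(500, 500),
    mass_mg = c(15000, 100), area_ha = c(1000, 10),
    soil_temp_c = c(10, 10), timeframe_years = c(100, 100),
    n_rate_mg_per_ha = c(0.15, 0.1),
    stringsAsFactors = FALSE
  )
  run2 <- run_inventory(tab, worked_example_config())
  expect_equal(length(run2$details), 1)
  expect_equal(nrow(run2$errors), 1)
  expect_match(run2$errors$message, "unknown feedstock")
  expect_equal(run2$total_co2e, single$total_co2e)
  expect_error(run_inventory(tab, worked_example_config(), strict = TRUE),
               "unknown feedstock")

  # order invariance of the grand total
  tab_rev <- tab[2:1, ]
  expect_equal(run_inventory(tab_rev, worked_example_config())$total_co2e,
               run2$total_co2e)
})

test_that("reports round-trip and expose provenance", {
  run <- run_inventory(list(worked_example_event()), worked_example_config())

  csv_path <- tempfile(fileext = ".csv")
  render_report(run, "csv", csv_path)
  back <- utils::read.csv(csv_path)
  expect_equal(back$total_co2e[1], run$results$total_co2e[1])

  json_path <- tempfile(fileext = ".json")
  render_report(run, "json", json_path)
  parsed <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  expect_equal(parsed$events$provenance$fperm_method, "exact_cell")
  expect_equal(parsed$events$provenance$gwp_n2o, 298)
  expect_equal(parsed$total_co2e, run$total_co2e)

  expect_error(render_report(run, "xml"))
})

test_that("kg-denominated activity columns convert to Mg with a warning", {
  tab <- data.frame(event_id = "a", feedstock = "maize stover",
                    pyrolysis_temp_c = 500, mass_kg = 15e6, area_ha = 1000,
                    soil_temp_c = 10, timeframe_years = 100,
                    n_rate_kg_per_ha = 150, stringsAsFactors = FALSE)
  w <- capture_warnings(run <- run_inventory(tab, worked_example_config()))
  expect_match(w, "converting mass_kg", all = FALSE)
  expect_match(w, "converting n_rate_kg_per_ha", all = FALSE)
  expect_equal(run$details[[1]]$total_co2e_display, 29710)
})

test_that("the command-line interface drives the full pipeline", {
  act <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    event_id = "wk", feedstock = "maize stover", pyrolysis_temp_c = 500,
    mass_mg = 15000, area_ha = 1000, soil_temp_c = 10, timeframe_years = 100,
    n_rate_mg_per_ha = 0.15
  ), act, row.names = FALSE)
  outdir <- tempfile()
  status <- suppressMessages(
    bc_cli(c("inventory", "--activity", act, "--gwp-n2o", "298",
             "--out", outdir))
  )
  expect_equal(status, 0L)
  res <- utils::read.csv(file.path(outdir, "inventory.csv"))
  expect_equal(res$total_co2e_display[1], 29710)

  out <- capture.output(suppressMessages(
    bc_cli(c("permanence", "--class", "medium", "--timeframe", "100",
             "--soil-temp", "10"))
  ))
  expect_match(paste(out, collapse = ""), "0.79")
  expect_equal(suppressMessages(bc_cli(c("definitely-not-a-subcommand"))), 1L)
})
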