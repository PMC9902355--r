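defs <- maize_defs()

height_rule <- validation_rule("range", "plant_height",
                               list(min = 0.5, max = 5))

test_that("range bounds are inclusive and violations flagged both sides", {
  mk <- function(v) records_from_df(rec_row("V1", "plant_height", v), defs)
  expect_null(check_range(mk("5.00")[1, ], height_rule))
  expect_null(check_range(mk("0.50")[1, ], height_rule))
  f_hi <- check_range(mk("5.01")[1, ], height_rule)
  expect_s3_class(f_hi, "validation_flag")
  expect_equal(f_hi$rule_type, "range")
  expect_s3_class(check_range(mk("0.30")[1, ], height_rule),
                  "validation_flag")
})

test_that("enumeration membership is trim/case-folded exact match", {
  rule <- validation_rule("enumeration", "plant_type",
                          list(allowed = c("compact", "semi-compact", "flat")))
  mk <- function(v) records_from_df(rec_row("V1", "plant_type", v), defs)
  expect_null(check_enumeration(mk("semi-compact")[1, ], rule))
  expect_null(check_enumeration(mk(" Semi-Compact ")[1, ], rule))
  expect_s3_class(check_enumeration(mk("Flat and compact")[1, ], rule),
                  "validation_flag")

  empty_rule <- validation_rule("enumeration", "plant_type",
                                list(allowed = character()))
  expect_s3_class(check_enumeration(mk("compact")[1, ], empty_rule),
                  "validation_flag")
})

test_that("date and decimal formats are enforced", {
  date_rule <- validation_rule("format", "sowing_date", list(kind = "date"))
  dec_rule <- validation_rule("format", "yield",
                              list(kind = "decimal", decimals = 2))
  mkd <- function(v) records_from_df(rec_row("V1", "sowing_date", v), defs)
  mky <- function(v) records_from_df(rec_row("V1", "yield", v), defs)
  expect_s3_class(check_format(mkd("9021.6.3")[1, ], date_rule),
                  "validation_flag")
  expect_s3_class(check_format(mkd("2021-02-30")[1, ], date_rule),
                  "validation_flag")
  expect_null(check_format(mkd("2021-06-03")[1, ], date_rule))
  expect_s3_class(check_format(mky("16.7.8")[1, ], dec_rule),
                  "validation_flag")
  expect_s3_class(check_format(mky("16.789")[1, ], dec_rule),
                  "validation_flag")
  expect_null(check_format(mky("16.78")[1, ], dec_rule))
})

test_that("consistency rule flags linear-relation violations per key", {
  rule <- validation_rule("consistency", "yield",
                          list(partner_trait_id = "grain_weight",
                               a = 1, b = 0, tolerance = 0.1))
  df <- rbind(rec_row("V1", "yield", "2.00"),
              rec_row("V1", "grain_weight", "1.00"),
              rec_row("V2", "yield", "1.05"),
              rec_row("V2", "grain_weight", "1.00"),
              rec_row("V3", "yield", "3.00"))
  r <- records_from_df(df, defs)
  res <- check_consistency(r, rule)
  expect_length(res$hits, 1L)
  expect_equal(res$hits[[1]]$row, 1L)  # y=2 vs a*x+b=1
  expect_equal(res$unverifiable, "V3/L1/1/2021")
})

test_that("statistic rule flags locations with out-of-bound CV", {
  rule <- validation_rule("statistic", "yield",
                          list(lower = 0, upper = 10))
  mkloc <- function(vals, loc) do.call(rbind, lapply(seq_along(vals),
    function(i) rec_row("V1", "yield", vals[i], loc, i)))
  df <- rbind(mkloc(c("100.00", "150.00", "200.00"), "L1"),  # CV 33.3
              mkloc(c("100.00", "104.00", "108.00"), "L2"),  # CV 3.85
              mkloc(c("50.00", "50.00", "50.00"), "L3"),     # CV 0
              rec_row("V1", "yield", "7.00", "L4"))          # n < 2: skipped
  r <- records_from_df(df, defs)
  res <- check_statistic(r, rule)
  expect_equal(unname(res$cv["L1"]), 33.33333, tolerance = 1e-6)
  expect_equal(unname(res$cv["L2"]), 3.846154, tolerance = 1e-6)
  flagged_locs <- unique(r$location[vapply(res$hits, `[[`, 1L, "row")])
  expect_equal(flagged_locs, "L1")
  expect_equal(res$skipped, "L4")
})

test_that("validate_all accepts clean input and flags seeded abnormals", {
  cfg <- read_trial_config(system.file("extdata", "maize_traits.json",
                                       package = "vtrial"))
  clean <- rbind(rec_row("V1", "yield", "12.34"),
                 rec_row("V1", "sowing_date", "2021-06-03"),
                 rec_row("V1", "plant_type", "compact"))
  res <- validate_all(records_from_df(clean, cfg$traits), cfg$rules,
                      cfg$traits)
  expect_true(all(res$records$status == "accepted"))
  expect_equal(nrow(res$summary), 0L)

  seeded <- rbind(clean,
                  rec_row("V2", "sowing_date", "9021.6.3"),
                  rec_row("V2", "yield", "16.7.8"),
                  rec_row("V2", "plant_type", "Flat and compact"))
  res2 <- validate_all(records_from_df(seeded, cfg$traits), cfg$rules,
                       cfg$traits)
  expect_equal(sum(res2$records$status == "flagged"), 3L)
})

test_that("validation is idempotent", {
  cfg <- read_trial_config(system.file("extdata", "maize_traits.json",
                                       package = "vtrial"))
  df <- rbind(rec_row("V1", "yield", "12.34"),
              rec_row("V1", "plant_height", "5.50"),
              rec_row("V2", "sowing_date", "9021.6.3"))
  r1 <- validate_all(records_from_df(df, cfg$traits), cfg$rules, cfg$traits)
  r2 <- validate_all(r1$records, cfg$rules, cfg$traits)
  expect_equal(r2$records$status, r1$records$status)
  expect_equal(r2$summary, r1$summary)
  expect_equal(vapply(r2$records$flags, length, integer(1)),
               vapply(r1$records$flags, length, integer(1)))
})

test_that("format failure precludes range and consistency flags", {
  rules <- list(validation_rule("format", "yield",
                                list(kind = "decimal", decimals = 2)),
                validation_rule("range", "yield", list(min = 0, max = 100)),
                validation_rule("consistency", "yield",
                                list(partner_trait_id = "grain_weight",
                                     a = 1, b = 0, tolerance = 0.1)))
  df <- rbind(rec_row("V1", "yield", "16.7.8"),
              rec_row("V1", "grain_weight", "20.00"))
  res <- validate_all(records_from_df(df, defs), rules, defs)
  types <- vapply(res$records$flags[[1]], `[[`, character(1), "rule_type")
  expect_true(all(types == "format"))
})

test_that("summary counts equal the flags on records (conservation)", {
  cfg <- read_trial_config(system.file("extdata", "maize_traits.json",
                                       package = "vtrial"))
  df <- rbind(rec_row("V1", "plant_height", "9.00", "L1"),
              rec_row("V2", "plant_height", "0.10", "L2"),
              rec_row("V1", "sowing_date", "bad", "L1"))
  res <- validate_all(records_from_df(df, cfg$traits), cfg$rules, cfg$traits)
  expect_equal(sum(res$summary$n_flags),
               sum(vapply(res$records$flags, length, integer(1))))
})

test_that("widening a range or enumeration never increases flags", {
  df <- rbind(rec_row("V1", "plant_height", "5.50"),
              rec_row("V2", "plant_height", "2.00"),
              rec_row("V3", "plant_type", "upright"))
  n_flags <- function(rules) {
    res <- validate_all(records_from_df(df, defs), rules, defs)
    sum(vapply(res$records$flags, length, integer(1)))
  }
  narrow <- list(validation_rule("range", "plant_height",
                                 list(min = 0.5, max = 5)),
                 validation_rule("enumeration", "plant_type",
                                 list(allowed = "compact")))
  wide <- list(validation_rule("range", "plant_height",
                               list(min = 0.5, max = 6)),
               validation_rule("enumeration", "plant_type",
                               list(allowed = c("compact", "upright"))))
  expect_true(n_flags(wide) <= n_flags(narrow))
  expect_equal(n_flags(wide), 0L)
})

test_that("strict mode promotes flag severity to error", {
  res <- validate_all(records_from_df(rec_row("V1", "plant_height", "9.00"),
                                      defs),
                      list(height_rule), defs, strict = TRUE)
  expect_equal(res$records$flags[[1]][[1]]$severity, "error")
})
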