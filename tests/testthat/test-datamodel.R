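test_that("trait definitions enforce their invariants", {
  expect_error(trait_def("h", "h", "numeric", min_value = 5, max_value = 1),
               "min_value")
  expect_error(trait_def("t", "t", "enumeration"), "allowed_values")
  expect_error(trait_def("t", "t", "text", decimals = 2), "numeric")
  expect_error(trait_set(trait_def("a", "a", "text"),
                         trait_def("a", "a", "text")),
               "duplicate")
})

test_that("well-formed rows read as entered records, row order preserved", {
  df <- rbind(rec_row("V1", "yield", "10.00"),
              rec_row("V2", "yield", "11.00"),
              rec_row("V3", "yield", "12.00"))
  r <- records_from_df(df, maize_defs())
  expect_s3_class(r, "trait_records")
  expect_equal(nrow(r), 3L)
  expect_equal(r$status, rep("entered", 3))
  expect_equal(r$variety, c("V1", "V2", "V3"))
  expect_equal(unlist(r$parsed), c(10, 11, 12))
})

test_that("parsing failures become format flags, not errors", {
  df <- rbind(rec_row("V1", "sowing_date", "9021.6.3"),
              rec_row("V1", "yield", "16.7.8"))
  r <- records_from_df(df, maize_defs())
  expect_equal(r$status, c("flagged", "flagged"))
  expect_equal(vapply(r$flags, function(f) f[[1]]$rule_type, character(1)),
               c("format", "format"))
})

test_that("empty files, missing columns and unknown traits are handled", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("variety,location,replicate,year,trait,value", f)
  expect_equal(nrow(read_records(f, maize_defs())), 0L)

  writeLines(c("variety,location,replicate,trait,value",
               "V1,L1,1,yield,5"), f)
  expect_error(read_records(f, maize_defs()), "year")

  writeLines(c("variety,location,replicate,year,trait,value",
               "V1,L1,1,2021,mystery,5"), f)
  expect_error(read_records(f, maize_defs()), "mystery")
})

test_that("empty value fields are missing values, never zero or flagged", {
  r <- records_from_df(rec_row("V1", "yield", ""), maize_defs())
  expect_true(is.na(r$parsed[[1]]))
  expect_equal(r$status, "entered")
  expect_length(r$flags[[1]], 0L)
})

test_that("write/read round trip is lossless including statuses and flags", {
  defs <- maize_defs()
  df <- rbind(rec_row("V1", "yield", "10.00"),
              rec_row("V1", "sowing_date", "9021.6.3"),
              rec_row("V2", "plant_height", "5.01"),
              rec_row("V2", "plant_type", "compact"))
  r <- records_from_df(df, defs)
  rules <- list(validation_rule("range", "plant_height",
                                list(min = 0.5, max = 5)))
  r <- validate_all(r, rules, defs)$records
  out <- withr::local_tempfile(fileext = ".csv")
  write_records(r, out)
  r2 <- read_records(out, defs)
  expect_equal(r2$status, r$status)
  expect_equal(r2$value, r$value)
  expect_equal(unlist(r2$parsed[c(1, 3)]), unlist(r$parsed[c(1, 3)]))
  f1 <- r$flags[[3]][[1]]; f2 <- r2$flags[[3]][[1]]
  expect_equal(f2$rule_type, f1$rule_type)
  expect_equal(f2$severity, f1$severity)
  expect_equal(f2$message, f1$message)

  # empty collection -> header-only file
  write_records(r[0, ], out)
  expect_equal(length(readLines(out)), 1L)
  expect_equal(nrow(read_records(out, defs)), 0L)
})

test_that("simulated records survive the round trip byte-identically", {
  tr <- simulate_trial(sim_config(n_varieties = 3, n_locations = 2, seed = 4))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records(tr$records, f1)
  write_records(read_records(f1, trait_set(yield_def())), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pivot_to_matrix aggregates replicates per variety and environment", {
  df <- do.call(rbind, lapply(1:3, function(rep) {
    rbind(rec_row("V1", "yield", "7.00", "L1", rep),
          rec_row("V1", "yield", "7.00", "L2", rep),
          rec_row("V2", "yield", "7.00", "L1", rep),
          rec_row("V2", "yield", "7.00", "L2", rep))
  }))
  r <- records_from_df(df, maize_defs())
  m <- pivot_to_matrix(r, "yield")
  expect_equal(dim(m), c(2L, 2L))
  expect_true(all(m == 7))

  df2 <- rbind(rec_row("V1", "yield", "10.00", "L1", 1),
               rec_row("V1", "yield", "11.00", "L1", 2),
               rec_row("V1", "yield", "12.00", "L1", 3))
  m2 <- pivot_to_matrix(records_from_df(df2, maize_defs()), "yield")
  expect_equal(unname(m2["V1", "L1"]), 11.0)
})

test_that("absent variety-location pairs are missing cells, not zeros", {
  df <- rbind(rec_row("V1", "yield", "10.00", "L1"),
              rec_row("V1", "yield", "12.00", "L2"),
              rec_row("V2", "yield", "11.00", "L1"))
  m <- pivot_to_matrix(records_from_df(df, maize_defs()), "yield")
  expect_true(is.na(m["V2", "L2"]))
  expect_equal(sum(!is.na(m)), 3L)
})

test_that("pivoting a non-numeric trait is a type error", {
  r <- records_from_df(rec_row("V1", "plant_type", "compact"), maize_defs())
  expect_error(pivot_to_matrix(r, "plant_type"), "numeric")
})

test_that("pivot supports max, min and interval aggregation and year keys", {
  df <- rbind(rec_row("V1", "yield", "10.00", "L1", 1, 2021),
              rec_row("V1", "yield", "14.00", "L1", 2, 2021),
              rec_row("V1", "yield", "20.00", "L1", 1, 2022))
  r <- records_from_df(df, maize_defs())
  expect_equal(unname(pivot_to_matrix(r, "yield", "max")["V1", "L1"]), 20)
  expect_equal(unname(pivot_to_matrix(r, "yield", "interval")["V1", "L1"]), 10)
  m <- pivot_to_matrix(r, "yield", by_year = TRUE)
  expect_equal(colnames(m), c("L1:2021", "L1:2022"))
  expect_equal(unname(m["V1", "L1:2021"]), 12)
})

test_that("pivot conserves data: cells account for contributing records", {
  set.seed(11)
  for (i in 1:5) {
    tr <- simulate_trial(sim_config(n_varieties = sample(2:5, 1),
                                    n_locations = sample(2:4, 1),
                                    n_replicates = 3, seed = i))
    m <- pivot_to_matrix(tr$records, "yield")
    expect_equal(sum(!is.na(m)) * 3, nrow(tr$records))
  }
})
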