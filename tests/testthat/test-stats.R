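test_that("compute_cv matches hand calculations and guards its domain", {
  expect_equal(compute_cv(c(5, 5, 5)), 0)
  expect_equal(compute_cv(c(1, 2, 3)), 50)           # sd 1, mean 2
  expect_equal(compute_cv(c(100, 104, 108)), 100 * 4 / 104, tolerance = 1e-12)
  expect_error(compute_cv(5), "at least 2")
  expect_error(compute_cv(c(-1, 1)), "zero mean")
})

test_that("compute_cv is invariant to positive rescaling", {
  set.seed(2)
  for (i in 1:10) {
    x <- abs(rnorm(6, 10))
    c <- runif(1, 0.1, 50)
    expect_equal(compute_cv(c * x), compute_cv(x), tolerance = 1e-10)
  }
})

test_that("ANOVA decomposition matches the brute-force oracle on a 2x2x2", {
  set.seed(7)
  d <- balanced_frame(2, 2, 2, rnorm(8, 100, 5))
  an <- anova_two_factor(d)
  oracle <- anova_oracle(d)
  for (src in c("variety", "environment", "interaction", "residual")) {
    expect_equal(an$ss[an$source == src], oracle[[src]], tolerance = 1e-8,
                 label = src)
  }
  expect_equal(sum(an$ss), oracle$total, tolerance = 1e-8)
  expect_equal(sum(an$df), nrow(d) - 1L)
})

test_that("constant data give zero sums of squares and NA F statistics", {
  d <- balanced_frame(2, 2, 2, rep(4, 8))
  an <- anova_two_factor(d)
  expect_equal(an$ss, rep(0, 4))
  expect_true(all(is.na(an$f)))
})

test_that("unbalanced data are rejected with the holes identified", {
  d <- balanced_frame(2, 2, 2, rnorm(8))
  expect_error(anova_two_factor(d[-1, ]), "unbalanced")
  err <- tryCatch(anova_two_factor(d[-(1:2), ]), error = function(e) e)
  expect_match(conditionMessage(err), "V1/E1")
})

test_that("single-environment trials reduce to a one-way decomposition", {
  set.seed(3)
  d <- balanced_frame(4, 1, 3, rnorm(12, 50, 2))
  an <- anova_two_factor(d)
  expect_equal(an$df[an$source == "environment"], 0L)
  expect_equal(an$df[an$source == "variety"], 3L)
  expect_equal(an$df[an$source == "residual"], 8L)
  expect_equal(sum(an$ss), sum((d$value - mean(d$value))^2),
               tolerance = 1e-8)
})

test_that("interaction-as-error switch changes the variety F denominator", {
  set.seed(8)
  d <- balanced_frame(3, 3, 2, rnorm(18, 10))
  a_res <- anova_two_factor(d, error_term = "residual")
  a_int <- anova_two_factor(d, error_term = "interaction")
  ms <- function(a, s) a$ms[a$source == s]
  expect_equal(a_int$f[1], ms(a_int, "variety") / ms(a_int, "interaction"),
               tolerance = 1e-10)
  expect_equal(a_res$f[1], ms(a_res, "variety") / ms(a_res, "residual"),
               tolerance = 1e-10)
})

test_that("LSD equals the t-quantile formula and letters separate means", {
  set.seed(5)
  d <- balanced_frame(4, 3, 2, rnorm(24, 100, 3))
  an <- anova_two_factor(d)
  means <- tapply(d$value, d$variety, mean)
  out <- lsd_comparisons(an, means, alpha = 0.05)
  ms_res <- an$ms[an$source == "residual"]
  df_res <- an$df[an$source == "residual"]
  expect_equal(attr(out, "lsd"),
               qt(0.975, df_res) * sqrt(2 * ms_res / 6), tolerance = 1e-12)
  # hand-check of the worked formula: MS=1, r=3, df=10
  toy <- structure(data.frame(source = c("variety", "environment",
                                         "interaction", "residual"),
                              df = c(2, 0, 0, 10), ss = c(2, 0, 0, 10),
                              ms = c(1, NA, NA, 1), f = NA_real_,
                              p = NA_real_),
                   class = c("anova_table", "data.frame"),
                   grand_mean = 10, n_varieties = 3, n_environments = 1,
                   n_replicates = 3)
  toy_out <- lsd_comparisons(toy, c(A = 10, B = 10), r_effective = 3)
  expect_equal(attr(toy_out, "lsd"), qt(0.975, 10) * sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(round(attr(toy_out, "lsd"), 3), 1.819)
  # equal means share a letter
  expect_equal(toy_out$letters[1], toy_out$letters[2])
  # means two LSDs apart never share one
  sep <- lsd_comparisons(toy, c(A = 10, B = 10 + 2 * attr(toy_out, "lsd")),
                         r_effective = 3)
  expect_false(grepl(sep$letters[1], sep$letters[2], fixed = TRUE))
})

test_that("varieties differing by more than LSD never share a letter", {
  set.seed(21)
  for (i in 1:20) {
    nv <- sample(3:8, 1)
    d <- balanced_frame(nv, 2, 3, rnorm(nv * 6, 100, sample(1:10, 1)))
    an <- anova_two_factor(d)
    means <- tapply(d$value, d$variety, mean)
    out <- lsd_comparisons(an, means)
    lsd <- attr(out, "lsd")
    for (a in seq_len(nrow(out) - 1)) for (b in (a + 1):nrow(out)) {
      shared <- intersect(strsplit(out$letters[a], "")[[1]],
                          strsplit(out$letters[b], "")[[1]])
      if (abs(out$mean[a] - out$mean[b]) > lsd) {
        expect_length(shared, 0L)
      } else {
        expect_gt(length(shared), 0L)
      }
    }
  }
})

test_that("GCV follows the expected-mean-square arithmetic", {
  toy <- structure(data.frame(source = c("variety", "environment",
                                         "interaction", "residual"),
                              df = c(4, 0, 0, 10), ss = 0,
                              ms = c(13, NA, NA, 1), f = NA_real_,
                              p = NA_real_),
                   class = c("anova_table", "data.frame"),
                   grand_mean = 10, n_varieties = 5, n_environments = 1,
                   n_replicates = 3)
  expect_equal(gcv(toy), 20)  # sqrt((13-1)/3) = 2 over mean 10
  toy$ms[1] <- 1
  expect_equal(gcv(toy), 0)   # negative component truncated at equality
  toy$ms[1] <- 0.5
  expect_equal(gcv(toy), 0)
})

test_that("RLSD is the LSD as a percent of the reference mean", {
  expect_equal(rlsd(0, 10), 0)
  expect_equal(rlsd(0.5, 10), 5)
  for (lsd in c(0.3, 1.7, 12)) {
    m <- 7.3
    expect_equal(rlsd(lsd, m) * m / 100, lsd, tolerance = 1e-12)
  }
  expect_error(rlsd(1, 0), "> 0")
})

test_that("CK comparison reports percent increases and a full ranking", {
  means <- c(V1 = 100, V2 = 105, V3 = 100, V4 = 92)
  out <- compare_to_ck(means, "V1")
  expect_equal(out$increase_pct[out$variety == "V1"], 0)
  expect_equal(out$increase_pct[out$variety == "V2"], 5)
  expect_equal(out$increase_pct[out$variety == "V4"], -8)
  expect_setequal(out$rank, 1:4)
  expect_equal(out$variety[1], "V2")
  expect_error(compare_to_ck(means, "V9"), "absent")
})

test_that("per-location CV separates error CV from pooled CV", {
  tr <- simulate_trial(sim_config(n_varieties = 8, n_locations = 3,
                                  sd_genotype = 40, sd_residual = 12,
                                  seed = 6))
  cvs <- location_cv(tr$records, "yield")
  expect_equal(nrow(cvs), 3L)
  # pooled CV includes genotypic spread, so it exceeds the error CV
  expect_true(all(cvs$cv_pooled > cvs$cv_error))
})
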