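#' Coefficient of variation (percent)
#'
#' The trial-precision index: 100 times the sample standard deviation
#' (n - 1 divisor) over the mean. A field test with CV below 10 percent
#' is conventionally considered well controlled.
#'
#' @param values Numeric vector, length >= 2, with non-zero mean.
#' @return CV in percent.
#' @examples
#' compute_cv(c(1, 2, 3))  # 50
#' @export
compute_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop_vt("input", "compute_cv needs at least 2 non-missing values")
  }
  m <- mean(values)
  if (m == 0) stop_vt("input", "compute_cv undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Assemble an analysis frame from records
#'
#' Extracts one numeric trait into the (variety, environment, replicate,
#' value) long form used by [anova_two_factor()]. Records carrying format
#' flags or missing values are dropped. The environment is the location,
#' or the location-year combination when `by_year = TRUE`; when several
#' years share a location key, the replicate label is extended with the
#' year so replicates stay distinct.
#'
#' @param records A `trait_records` table.
#' @param trait_id Numeric trait to extract.
#' @param by_year If `TRUE`, environments are location-year composites.
#' @return A data frame with columns `variety`, `environment`,
#'   `replicate`, `value`.
#' @export
trial_frame <- function(records, trait_id, by_year = FALSE) {
  stopifnot(inherits(records, "trait_records"))
  rec <- records[records$trait == trait_id, , drop = FALSE]
  if (nrow(rec) == 0L) stop_vt("input", "no records for trait '", trait_id, "'")
  usable <- vapply(seq_len(nrow(rec)), function(i) {
    is.numeric(rec$parsed[[i]]) && !is.na(rec$parsed[[i]]) &&
      !has_format_flag(rec$flags[[i]])
  }, logical(1))
  rec <- rec[usable, , drop = FALSE]
  env <- if (by_year) paste(rec$location, rec$year, sep = ":") else rec$location
  repl <- if (!by_year && length(unique(rec$year)) > 1L) {
    paste(rec$year, rec$replicate, sep = ":")
  } else as.character(rec$replicate)
  data.frame(variety = rec$variety, environment = env, replicate = repl,
             value = vapply(rec$parsed, as.numeric, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Two-factor ANOVA with interaction for balanced trials
#'
#' Fits the fixed-effects observation model
#' `Y_ijk = mu + g_i + e_j + theta_ij + eps_ijk` (variety effect,
#' environment effect, variety-by-environment interaction, residual) to a
#' balanced complete trial and decomposes the total sum of squares by
#' source. F statistics test each source against the residual mean square
#' by default; set `error_term = "interaction"` to test the variety
#' effect against the interaction mean square instead.
#'
#' @param data A data frame with columns `variety`, `environment`,
#'   `replicate`, `value` (see [trial_frame()]).
#' @param error_term Denominator for the variety F test: `"residual"`
#'   (default) or `"interaction"`.
#' @return An object of class `anova_table`: a data frame with one row
#'   per source (`variety`, `environment`, `interaction`, `residual`) and
#'   columns `df`, `ss`, `ms`, `f`, `p`, with attributes `grand_mean`,
#'   `n_varieties`, `n_environments`, `n_replicates`.
#' @export
anova_two_factor <- function(data, error_term = c("residual", "interaction")) {
  error_term <- match.arg(error_term)
  required <- c("variety", "environment", "replicate", "value")
  if (!all(required %in% names(data))) {
    stop_vt("schema", "data must have columns ",
            paste(required, collapse = ", "))
  }
  if (anyNA(data$value)) stop_vt("input", "missing values in 'value'")
  tab <- table(data$variety, data$environment)
  r <- unique(as.vector(tab))
  if (length(r) != 1L || r[1] == 0L) {
    holes <- which(tab != max(tab), arr.ind = TRUE)
    stop_vt("unbalanced",
            "unbalanced data: every variety x environment cell must hold ",
            "the same number of replicates; offending cells: ",
            paste(utils::head(paste(rownames(tab)[holes[, 1]],
                                    colnames(tab)[holes[, 2]], sep = "/"),
                              10L), collapse = ", "))
  }
  r <- r[1]
  d <- data.frame(variety = factor(data$variety),
                  environment = factor(data$environment),
                  value = data$value)
  # constant data: every SS is rounding noise; report zeros and NA tests
  snap_zero <- function(out) {
    if (sum(out$ss) <= 1e-10 * max(1, sum(d$value^2))) {
      out$ss <- rep(0, nrow(out))
      out$ms <- ifelse(out$df > 0, 0, NA_real_)
      out$f <- NA_real_
      out$p <- NA_real_
    }
    out
  }
  if (nlevels(d$environment) == 1L) {
    # single-location trial: one-way decomposition, no environment terms
    fit <- stats::aov(value ~ variety, data = d)
    s <- summary(fit)[[1]]
    out <- data.frame(source = c("variety", "environment", "interaction",
                                 "residual"),
                      df = c(s$Df[1], 0L, 0L, s$Df[2]),
                      ss = c(s$`Sum Sq`[1], 0, 0, s$`Sum Sq`[2]),
                      ms = c(s$`Mean Sq`[1], NA, NA, s$`Mean Sq`[2]),
                      f = c(s$`F value`[1], NA, NA, NA),
                      p = c(s$`Pr(>F)`[1], NA, NA, NA),
                      stringsAsFactors = FALSE)
    out$f[!is.finite(out$f)] <- NA_real_
    out$p[is.na(out$f)] <- NA_real_
    out <- snap_zero(out)
    return(structure(out, class = c("anova_table", "data.frame"),
                     grand_mean = mean(d$value),
                     n_varieties = nlevels(d$variety),
                     n_environments = 1L, n_replicates = r,
                     error_term = "residual"))
  }
  fit <- stats::aov(value ~ variety * environment, data = d)
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  pick <- function(nm) which(rn == nm)
  idx <- c(pick("variety"), pick("environment"),
           pick("variety:environment"), pick("Residuals"))
  out <- data.frame(source = c("variety", "environment", "interaction",
                               "residual"),
                    df = s$Df[idx], ss = s$`Sum Sq`[idx],
                    ms = s$`Mean Sq`[idx],
                    f = s$`F value`[idx], p = s$`Pr(>F)`[idx],
                    stringsAsFactors = FALSE)
  if (r == 1L) {  # no replication: residual row absent from aov output
    out$df[4] <- 0; out$ss[4] <- 0; out$ms[4] <- NA_real_
    out$f <- NA_real_; out$p <- NA_real_
  }
  if (error_term == "interaction") {
    out$f[1] <- out$ms[1] / out$ms[3]
    out$p[1] <- stats::pf(out$f[1], out$df[1], out$df[3], lower.tail = FALSE)
  }
  out$f[!is.finite(out$f)] <- NA_real_
  out$p[is.na(out$f)] <- NA_real_
  out$f[4] <- NA_real_; out$p[4] <- NA_real_
  out <- snap_zero(out)
  structure(out, class = c("anova_table", "data.frame"),
            grand_mean = mean(d$value),
            n_varieties = nlevels(d$variety),
            n_environments = nlevels(d$environment),
            n_replicates = r,
            error_term = error_term)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Two-factor ANOVA (", attr(x, "n_varieties"), " varieties x ",
      attr(x, "n_environments"), " environments x ",
      attr(x, "n_replicates"), " replicates; grand mean ",
      round(attr(x, "grand_mean"), 3), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Least significant difference and letter groupings
#'
#' Computes `LSD = t(1 - alpha/2, df_residual) * sqrt(2 * MS_residual /
#' r)` with `r` the number of observations per variety mean, sorts the
#' variety means in descending order and assigns significance letters by
#' the standard sequential method: two varieties share a letter if and
#' only if they fall in a common maximal run of means whose extremes
#' differ by at most the LSD.
#'
#' @param anova An [anova_two_factor()] result.
#' @param means Named numeric vector of variety means.
#' @param alpha Significance level (default 0.05).
#' @param r_effective Observations per variety mean; defaults to
#'   environments times replicates from `anova`.
#' @return A data frame of class `lsd_groups` with columns `variety`,
#'   `mean`, `rank`, `letters`, sorted by descending mean; attributes
#'   `lsd`, `alpha`, `df`.
#' @export
lsd_comparisons <- function(anova, means, alpha = 0.05,
                            r_effective = NULL) {
  stopifnot(inherits(anova, "anova_table"))
  if (!is_num(alpha) || alpha <= 0 || alpha >= 1) {
    stop_vt("config", "alpha must be in (0, 1)")
  }
  df_res <- anova$df[anova$source == "residual"]
  ms_res <- anova$ms[anova$source == "residual"]
  if (df_res <= 0 || !is.finite(ms_res)) {
    stop_vt("input", "residual degrees of freedom are zero; LSD undefined")
  }
  r_effective <- r_effective %||%
    (attr(anova, "n_environments") * attr(anova, "n_replicates"))
  lsd <- stats::qt(1 - alpha / 2, df_res) * sqrt(2 * ms_res / r_effective)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  n <- length(m)
  # maximal runs [i, j] with m[i] - m[j] <= LSD, one letter per run
  ends <- vapply(seq_len(n), function(i) {
    j <- i
    while (j < n && m[i] - m[j + 1L] <= lsd) j <- j + 1L
    j
  }, integer(1))
  keep <- which(!duplicated(ends))
  keep <- keep[vapply(keep, function(i) {
    !any(ends[seq_len(i - 1L)] >= ends[i])  # drop runs nested in earlier ones
  }, logical(1))]
  letter_of <- letters[seq_along(keep)]
  lab <- vapply(seq_len(n), function(i) {
    paste(letter_of[which(keep <= i & ends[keep] >= i)], collapse = "")
  }, character(1))
  out <- data.frame(variety = names(m), mean = unname(m),
                    rank = seq_len(n), letters = lab,
                    stringsAsFactors = FALSE)
  structure(out, class = c("lsd_groups", "data.frame"),
            lsd = lsd, alpha = alpha, df = df_res)
}

#' Genetic coefficient of variation (percent)
#'
#' Scores a trial's (or site's) resolving power: the genotypic standard
#' deviation relative to the grand mean. The genotypic variance component
#' is estimated from expected mean squares as `(MS_variety - MS_error) /
#' k`, where `k` is the number of observations per variety mean and the
#' error mean square is the interaction MS in multi-environment data or
#' the residual MS for a single environment; negative estimates are
#' truncated to zero.
#'
#' @param anova An [anova_two_factor()] result.
#' @param grand_mean Trait grand mean; defaults to the value stored in
#'   `anova`.
#' @param error_term `"auto"` (default: interaction when more than one
#'   environment, else residual), `"interaction"` or `"residual"`.
#' @return GCV in percent.
#' @export
gcv <- function(anova, grand_mean = NULL,
                error_term = c("auto", "interaction", "residual")) {
  stopifnot(inherits(anova, "anova_table"))
  error_term <- match.arg(error_term)
  grand_mean <- grand_mean %||% attr(anova, "grand_mean")
  if (!is_num(grand_mean) || grand_mean == 0) {
    stop_vt("input", "grand mean must be non-zero")
  }
  ms <- stats::setNames(anova$ms, anova$source)
  use_int <- switch(error_term,
                    auto = attr(anova, "n_environments") > 1L &&
                      anova$df[anova$source == "interaction"] > 0L,
                    interaction = TRUE, residual = FALSE)
  ms_err <- if (use_int) ms[["interaction"]] else ms[["residual"]]
  k <- attr(anova, "n_environments") * attr(anova, "n_replicates")
  var_g <- max(0, (ms[["variety"]] - ms_err) / k)
  100 * sqrt(var_g) / grand_mean
}

#' Relative least significant difference (percent)
#'
#' Expresses the LSD as a percent of a reference mean: the smallest
#' varietal difference the trial can resolve. The reference is the CK
#' mean when a check is present, otherwise the grand mean.
#'
#' @param lsd LSD in trait units.
#' @param reference_mean Positive reference mean (CK mean or grand mean).
#' @return RLSD in percent.
#' @export
rlsd <- function(lsd, reference_mean) {
  if (!is_num(reference_mean) || reference_mean <= 0) {
    stop_vt("input", "reference_mean must be > 0")
  }
  100 * lsd / reference_mean
}

#' Compare variety means against the check
#'
#' Production capacity is reported as the percent increase of each
#' variety's mean over the CK mean, together with the rank by descending
#' mean. The CK itself appears with a zero increase.
#'
#' @param means Named numeric vector of variety means (CK included).
#' @param ck_code Code of the check variety.
#' @return A data frame of class `ck_comparison` with columns `variety`,
#'   `mean`, `increase_pct`, `rank`, sorted by rank; attribute `ck_code`.
#' @export
compare_to_ck <- function(means, ck_code) {
  if (!ck_code %in% names(means)) {
    stop_vt("input", "CK '", ck_code, "' absent from means")
  }
  ck_mean <- means[[ck_code]]
  if (ck_mean == 0) stop_vt("input", "CK mean is zero")
  out <- data.frame(variety = names(means), mean = unname(means),
                    increase_pct = 100 * (unname(means) - ck_mean) / ck_mean,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean, out$variety), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("ck_comparison", "data.frame"), ck_code = ck_code)
}

#' Per-location trial precision
#'
#' Two CV flavours are reported for each location: the pooled CV of all
#' replicate plot values ([compute_cv()] over everything observed there)
#' and the error CV derived from a within-location one-way ANOVA
#' (residual standard deviation after removing variety effects, relative
#' to the location mean). The error CV is the usual measure of how well
#' the field test was controlled; the pooled CV also contains genetic
#' variation.
#'
#' @param records A `trait_records` table.
#' @param trait_id Numeric trait to summarize.
#' @return A data frame with columns `location`, `n`, `mean`,
#'   `cv_pooled`, `cv_error`.
#' @export
location_cv <- function(records, trait_id) {
  d <- trial_frame(records, trait_id)
  res <- lapply(split(d, d$environment), function(dl) {
    n <- nrow(dl)
    m <- mean(dl$value)
    cv_pooled <- if (n >= 2 && m != 0) compute_cv(dl$value) else NA_real_
    cv_error <- NA_real_
    if (length(unique(dl$variety)) >= 2L && n > length(unique(dl$variety)) &&
        m != 0) {
      fit <- stats::aov(value ~ factor(variety), data = dl)
      ms_res <- summary(fit)[[1]]["Residuals", "Mean Sq"]
      cv_error <- 100 * sqrt(ms_res) / m
    }
    data.frame(location = dl$environment[1], n = n, mean = m,
               cv_pooled = cv_pooled, cv_error = cv_error,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Variety means of one trait
#'
#' Arithmetic means per variety over every usable replicate value,
#' the estimator of a variety's true trait value.
#'
#' @param records A `trait_records` table.
#' @param trait_id Numeric trait.
#' @return Named numeric vector of means.
#' @export
variety_means <- function(records, trait_id) {
  d <- trial_frame(records, trait_id)
  vapply(split(d$value, d$variety), mean, numeric(1))
}
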