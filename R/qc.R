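#' Define a data verification rule
#'
#' The rule engine implements five checking types applied to trait
#' records: `range` (Min <= x <= Max), `enumeration` (x in a collection),
#' `format` (calendar date or fixed-decimal pattern), `consistency` (a
#' linear relation y = a*x + b between two traits within a tolerance) and
#' `statistic` (the per-location coefficient of variation confined to an
#' interval). Range, enumeration and format rules act on single records at
#' entry time; consistency and statistic rules act on the stored
#' collection.
#'
#' @param rule_type One of `"range"`, `"enumeration"`, `"format"`,
#'   `"consistency"`, `"statistic"`.
#' @param trait_id The trait the rule constrains (for consistency rules,
#'   the dependent trait y).
#' @param params Named list of rule parameters: range `min`, `max`;
#'   enumeration `allowed`; format `kind` ("date" or "decimal") and, for
#'   decimals, `decimals`; consistency `partner_trait_id`, `a`, `b`,
#'   `tolerance`; statistic `lower`, `upper` (CV bounds in percent,
#'   defaults 0 and 10).
#' @return A list of class `validation_rule`.
#' @export
validation_rule <- function(rule_type, trait_id, params = list()) {
  rule_type <- match.arg(rule_type, c("range", "enumeration", "format",
                                      "consistency", "statistic"))
  if (!is_string(trait_id)) stop_vt("config", "trait_id must be a string")
  switch(rule_type,
    range = {
      if (!is_num(params$min) || !is_num(params$max)) {
        stop_vt("config", "range rule needs numeric min and max")
      }
      if (params$min > params$max) stop_vt("config", "range rule: min > max")
    },
    enumeration = {
      params$allowed <- as.character(params$allowed %||% character())
    },
    format = {
      params$kind <- match.arg(params$kind, c("date", "decimal"))
      if (params$kind == "decimal" && is.null(params$decimals)) {
        params$decimals <- 2L
      }
    },
    consistency = {
      if (!is_string(params$partner_trait_id) || !is_num(params$a) ||
          !is_num(params$b) || !is_num(params$tolerance)) {
        stop_vt("config",
                "consistency rule needs partner_trait_id, a, b, tolerance")
      }
      if (params$tolerance <= 0) {
        stop_vt("config", "consistency tolerance must be > 0")
      }
    },
    statistic = {
      params$lower <- params$lower %||% 0
      params$upper <- params$upper %||% 10
      if (params$lower > params$upper) {
        stop_vt("config", "statistic rule: lower > upper")
      }
    })
  structure(list(rule_type = rule_type, trait_id = trait_id, params = params),
            class = "validation_rule")
}

has_format_flag <- function(flags) {
  any(vapply(flags, function(f) f$rule_type == "format", logical(1)))
}

#' Range check for one record
#'
#' Flags a numeric record whose parsed value lies outside the inclusive
#' interval `[min, max]` (e.g. maize plant height outside 0.5 - 5 m).
#' Records already carrying a format flag are skipped: an unparseable
#' value cannot be compared to bounds.
#'
#' @param record One row of a `trait_records` table.
#' @param rule A range [validation_rule()].
#' @param severity Severity given to emitted flags.
#' @return A [validation_flag()] or `NULL`.
#' @export
check_range <- function(record, rule, severity = "warning") {
  stopifnot(rule$rule_type == "range")
  if (has_format_flag(record$flags[[1]])) return(NULL)
  v <- record$parsed[[1]]
  if (!is.numeric(v) || is.na(v)) return(NULL)
  if (v < rule$params$min || v > rule$params$max) {
    validation_flag("range",
      paste0("value ", v, " outside [", rule$params$min, ", ",
             rule$params$max, "] for trait '", rule$trait_id, "'"),
      severity)
  } else NULL
}

#' Enumeration membership check for one record
#'
#' Flags a value that is not a member of the allowed label set; matching
#' is exact after trimming and case folding.
#'
#' @inheritParams check_range
#' @param rule An enumeration [validation_rule()].
#' @return A [validation_flag()] or `NULL`.
#' @export
check_enumeration <- function(record, rule, severity = "warning") {
  stopifnot(rule$rule_type == "enumeration")
  v <- record$value
  if (is.na(v) || !nzchar(trimws(v))) return(NULL)
  if (!(normalize_label(v) %in% normalize_label(rule$params$allowed))) {
    validation_flag("enumeration",
      paste0("'", v, "' not in allowed set {",
             paste(rule$params$allowed, collapse = ", "),
             "} for trait '", rule$trait_id, "'"),
      severity)
  } else NULL
}

#' Format check for one record
#'
#' Date kind: the raw value must be a real calendar date written
#' YYYY-MM-DD (so "9021.6.3" fails). Decimal kind: the raw value must be
#' digits, a decimal point, and exactly the configured number of decimal
#' places (so "16.7.8" fails a two-decimal rule).
#'
#' @inheritParams check_range
#' @param rule A format [validation_rule()].
#' @return A [validation_flag()] or `NULL`.
#' @export
check_format <- function(record, rule, severity = "warning") {
  stopifnot(rule$rule_type == "format")
  v <- record$value
  if (is.na(v) || !nzchar(trimws(v))) return(NULL)
  v <- trimws(v)
  bad <- if (rule$params$kind == "date") {
    !is_iso_date(v)
  } else {
    !grepl(sprintf("^[0-9]+\\.[0-9]{%d}$", rule$params$decimals), v)
  }
  if (bad) {
    validation_flag("format",
      paste0("'", v, "' violates ", rule$params$kind, " format for trait '",
             rule$trait_id, "'"),
      severity)
  } else NULL
}

record_key <- function(records) {
  paste(records$variety, records$location, records$replicate, records$year,
        sep = "\r")
}

#' Consistency check between two traits
#'
#' For every (variety, location, replicate, year) key holding both the
#' dependent trait y and the partner trait x, flags the y record when
#' |y - (a*x + b)| exceeds the tolerance. Keys missing either trait are
#' skipped and reported as unverifiable, not flagged.
#'
#' @param records A `trait_records` table.
#' @param rule A consistency [validation_rule()].
#' @param severity Severity given to emitted flags.
#' @return A list with elements `hits` (list of `list(row, flag)` where
#'   `row` indexes `records`) and `unverifiable` (character vector of
#'   keys that could not be checked).
#' @export
check_consistency <- function(records, rule, severity = "warning") {
  stopifnot(rule$rule_type == "consistency")
  p <- rule$params
  key <- record_key(records)
  usable <- function(i) {
    is.numeric(records$parsed[[i]]) && !is.na(records$parsed[[i]]) &&
      !has_format_flag(records$flags[[i]])
  }
  iy <- which(records$trait == rule$trait_id)
  ix <- which(records$trait == p$partner_trait_id)
  xmap <- ix[match(key[iy], key[ix])]
  hits <- list()
  unverifiable <- character()
  for (j in seq_along(iy)) {
    i <- iy[j]; k <- xmap[j]
    if (is.na(k) || !usable(i) || !usable(k)) {
      unverifiable <- c(unverifiable, key[i])
      next
    }
    y <- records$parsed[[i]]; x <- records$parsed[[k]]
    if (abs(y - (p$a * x + p$b)) > p$tolerance) {
      hits[[length(hits) + 1L]] <- list(row = i, flag = validation_flag(
        "consistency",
        paste0("y=", y, " deviates from ", p$a, "*x+", p$b, " (x=", x,
               ") by more than ", p$tolerance, " for trait '",
               rule$trait_id, "'"),
        severity))
    }
  }
  list(hits = hits, unverifiable = gsub("\r", "/", unverifiable))
}

#' Statistical-characteristic check (per-location CV)
#'
#' Computes the coefficient of variation of all replicate plot values of
#' one trait within each location (pooled across varieties and blocks,
#' via [compute_cv()]) and flags every record of a location whose CV
#' falls outside `[lower, upper]`. A field test is conventionally
#' considered well controlled when its CV stays below 10 percent, hence
#' the default bounds 0 and 10. Locations with fewer than two usable
#' values are skipped.
#'
#' @param records A `trait_records` table.
#' @param rule A statistic [validation_rule()].
#' @param severity Severity given to emitted flags.
#' @return A list with elements `hits` (list of `list(row, flag)`),
#'   `cv` (named numeric, per-location CV percent) and `skipped`
#'   (locations with insufficient data).
#' @export
check_statistic <- function(records, rule, severity = "warning") {
  stopifnot(rule$rule_type == "statistic")
  p <- rule$params
  sel <- which(records$trait == rule$trait_id &
                 vapply(seq_len(nrow(records)), function(i) {
                   is.numeric(records$parsed[[i]]) &&
                     !is.na(records$parsed[[i]]) &&
                     !has_format_flag(records$flags[[i]])
                 }, logical(1)))
  hits <- list(); cvs <- numeric(); skipped <- character()
  for (loc in unique(records$location[sel])) {
    idx <- sel[records$location[sel] == loc]
    vals <- vapply(records$parsed[idx], as.numeric, numeric(1))
    if (length(vals) < 2L) { skipped <- c(skipped, loc); next }
    cv <- compute_cv(vals)
    cvs[loc] <- cv
    if (cv < p$lower || cv > p$upper) {
      for (i in idx) {
        hits[[length(hits) + 1L]] <- list(row = i, flag = validation_flag(
          "statistic",
          paste0("location ", loc, " CV ", round(cv, 2),
                 " outside [", p$lower, ", ", p$upper, "] for trait '",
                 rule$trait_id, "'"),
          severity))
      }
    }
  }
  list(hits = hits, cv = cvs, skipped = skipped)
}

#' Validate a record collection against a rule set
#'
#' Recomputes every record's flags from scratch: raw values are re-parsed
#' against the trait definitions (format flags), then entry-time rules
#' (format, range, enumeration) and post-storage rules (consistency,
#' statistic) are applied. Records failing a format check never also
#' carry range or consistency flags, since an unparseable value cannot be
#' compared. Records end up `accepted` (no flags) or `flagged`; the run
#' is idempotent.
#'
#' @param records A `trait_records` table.
#' @param rules List of [validation_rule()] objects.
#' @param trait_defs The [trait_set()] used to re-parse raw values.
#' @param strict If `TRUE`, flags carry severity `"error"` (blocking
#'   analysis) instead of `"warning"`.
#' @return A list of class `qc_result`: `records` (annotated collection)
#'   and `summary` (flag counts by rule type and location).
#' @export
validate_all <- function(records, rules, trait_defs, strict = FALSE) {
  stopifnot(inherits(records, "trait_records"))
  severity <- if (strict) "error" else "warning"
  n <- nrow(records)
  flags <- vector("list", n)
  # stage 0: re-parse (format flags from data type)
  for (i in seq_len(n)) {
    p <- parse_trait_value(records$value[i], trait_defs[[records$trait[i]]])
    records$parsed[[i]] <- p$value
    flags[[i]] <- if (is.null(p$flag)) list()
                  else list(validation_flag(p$flag$rule_type, p$flag$message,
                                            severity))
  }
  records$flags <- flags
  by_type <- split(rules, vapply(rules, `[[`, character(1), "rule_type"))
  # stage 1: entry-time, format first so precedence holds within the pass
  for (rule in by_type$format %||% list()) {
    for (i in which(records$trait == rule$trait_id)) {
      f <- check_format(records[i, ], rule, severity)
      if (!is.null(f) && !has_format_flag(records$flags[[i]])) {
        records$flags[[i]] <- c(records$flags[[i]], list(f))
      }
    }
  }
  for (rule in by_type$range %||% list()) {
    for (i in which(records$trait == rule$trait_id)) {
      f <- check_range(records[i, ], rule, severity)
      if (!is.null(f)) records$flags[[i]] <- c(records$flags[[i]], list(f))
    }
  }
  for (rule in by_type$enumeration %||% list()) {
    for (i in which(records$trait == rule$trait_id)) {
      f <- check_enumeration(records[i, ], rule, severity)
      if (!is.null(f)) records$flags[[i]] <- c(records$flags[[i]], list(f))
    }
  }
  # stage 2: post-storage collection rules
  for (rule in by_type$consistency %||% list()) {
    for (h in check_consistency(records, rule, severity)$hits) {
      records$flags[[h$row]] <- c(records$flags[[h$row]], list(h$flag))
    }
  }
  for (rule in by_type$statistic %||% list()) {
    for (h in check_statistic(records, rule, severity)$hits) {
      records$flags[[h$row]] <- c(records$flags[[h$row]], list(h$flag))
    }
  }
  has_flag <- vapply(records$flags, function(f) length(f) > 0L, logical(1))
  records$status <- ifelse(has_flag, "flagged", "accepted")
  all_flags <- unlist(records$flags, recursive = FALSE)
  types <- vapply(all_flags, `[[`, character(1), "rule_type")
  locs <- rep(records$location, times = lengths(records$flags))
  summary <- if (length(all_flags)) {
    as.data.frame(table(rule_type = types, location = locs),
                  stringsAsFactors = FALSE, responseName = "n_flags")
  } else {
    data.frame(rule_type = character(), location = character(),
               n_flags = integer(), stringsAsFactors = FALSE)
  }
  summary <- summary[summary$n_flags > 0, , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> ", nrow(x$records), " records: ",
      sum(x$records$status == "accepted"), " accepted, ",
      sum(x$records$status == "flagged"), " flagged\n", sep = "")
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}
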