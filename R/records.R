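#' Create a validation flag
#'
#' Flags annotate trait records that fail a data-verification rule. The
#' rule types form a closed set: `range`, `enumeration`, `format`,
#' `consistency` and `statistic`.
#'
#' @param rule_type One of `"range"`, `"enumeration"`, `"format"`,
#'   `"consistency"`, `"statistic"`.
#' @param message Human-readable description of the problem.
#' @param severity `"warning"` (default) or `"error"`.
#' @return An object of class `validation_flag`.
#' @export
validation_flag <- function(rule_type, message, severity = "warning") {
  rule_type <- match.arg(rule_type, c("range", "enumeration", "format",
                                      "consistency", "statistic"))
  severity <- match.arg(severity, c("warning", "error"))
  structure(list(rule_type = rule_type, message = message,
                 severity = severity),
            class = "validation_flag")
}

#' @export
format.validation_flag <- function(x, ...) {
  paste0("[", x$rule_type, "/", x$severity, "] ", x$message)
}

#' @export
print.validation_flag <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# flags <-> single-cell text encoding; "~" and "|" are reserved separators
# and never appear in rule messages generated by this package.
encode_flags <- function(flags) {
  if (length(flags) == 0L) return("")
  paste(vapply(flags, function(f) {
    paste(f$rule_type, f$severity, gsub("[~|]", " ", f$message), sep = "~")
  }, character(1)), collapse = "|")
}

decode_flags <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(list())
  lapply(strsplit(txt, "|", fixed = TRUE)[[1]], function(s) {
    parts <- strsplit(s, "~", fixed = TRUE)[[1]]
    validation_flag(parts[1], paste(parts[-(1:2)], collapse = "~"),
                    severity = parts[2])
  })
}

# Construct the EAV record table. `parsed` and `flags` are list columns;
# status is derived: a record is "flagged" iff it carries flags, otherwise
# keeps the supplied status ("entered" before validation, "accepted" after).
new_trait_records <- function(variety, location, replicate, year, trait,
                              value, parsed, flags, status = "entered") {
  n <- length(variety)
  stopifnot(length(flags) == n || n == 0L)
  has_flag <- vapply(flags, function(f) length(f) > 0L, logical(1))
  status <- rep_len(status, n)
  status[has_flag] <- "flagged"
  status[!has_flag & status == "flagged"] <- "entered"
  df <- data.frame(variety = as.character(variety),
                   location = as.character(location),
                   replicate = as.integer(replicate),
                   year = as.integer(year),
                   trait = as.character(trait),
                   value = as.character(value),
                   status = status,
                   stringsAsFactors = FALSE)
  df$parsed <- parsed
  df$flags <- flags
  class(df) <- c("trait_records", "data.frame")
  df
}

#' @export
print.trait_records <- function(x, ...) {
  cat("<trait_records> ", nrow(x), " records, ",
      length(unique(x$variety)), " varieties, ",
      length(unique(x$location)), " locations, ",
      length(unique(x$trait)), " traits\n", sep = "")
  cat("  status: ", paste(names(table(x$status)), table(x$status),
                          sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read trait records from a delimited file
#'
#' Reads long-format (EAV) trait records from a UTF-8, comma-separated
#' file with header columns `variety`, `location`, `replicate`, `year`,
#' `trait`, `value`. Raw values are parsed according to each trait's
#' declared data type; parsing failures are recorded as `format` flags on
#' the record, never raised as errors. Empty value fields are missing
#' values. Files previously written by [write_records()] additionally
#' carry `status` and `flags` columns, which are restored verbatim so that
#' a write/read cycle is lossless.
#'
#' @param path Path to the records file.
#' @param trait_defs A [trait_set()] defining every trait referenced.
#' @return A `trait_records` data frame (one row per record) with list
#'   columns `parsed` and `flags`.
#' @export
read_records <- function(path, trait_defs) {
  if (!file.exists(path)) stop_vt("io", "records file not found: ", path)
  if (!inherits(trait_defs, "trait_set")) {
    stop_vt("config", "trait_defs must be a trait_set")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("variety", "location", "replicate", "year", "trait", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_vt("schema", "records file is missing required column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(unique(df$trait), names(trait_defs))
  if (length(unknown)) {
    stop_vt("schema", "unknown trait id(s): ",
            paste(unknown, collapse = ", "))
  }
  n <- nrow(df)
  parsed <- vector("list", n)
  flags <- vector("list", n)
  restore <- all(c("status", "flags") %in% names(df))
  for (i in seq_len(n)) {
    p <- parse_trait_value(df$value[i], trait_defs[[df$trait[i]]])
    parsed[[i]] <- p$value
    flags[[i]] <- if (restore) decode_flags(df$flags[i])
                  else if (is.null(p$flag)) list() else list(p$flag)
  }
  status <- if (restore) df$status else "entered"
  new_trait_records(df$variety, df$location, df$replicate, df$year,
                    df$trait, df$value, parsed, flags, status = status)
}

#' Write trait records to a delimited file
#'
#' Serializes a `trait_records` table to comma-separated text, including
#' validation status and flags, such that [read_records()] on the output
#' reproduces the input exactly (round trip).
#'
#' @param records A `trait_records` table.
#' @param path Output file path (written atomically).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(inherits(records, "trait_records"))
  out <- data.frame(variety = records$variety, location = records$location,
                    replicate = records$replicate, year = records$year,
                    trait = records$trait, value = records$value,
                    status = records$status,
                    flags = vapply(records$flags, encode_flags, character(1)),
                    stringsAsFactors = FALSE)
  con <- textConnection("csv_lines", "w", local = TRUE)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  close(con)
  write_atomic(csv_lines, path)
}

#' Pivot records into a genotype-by-environment matrix
#'
#' Aggregates replicate values of one numeric trait into a variety (rows)
#' by environment (columns) matrix. The environment key is the location by
#' default, or the location-year combination for multi-year analysis.
#' True trait values per variety and environment are estimated by the
#' arithmetic mean of replicates (default), or by the max, min or interval
#' (max minus min) aggregation. Cells with no contributing records are
#' `NA`, never zero.
#'
#' @param records A `trait_records` table.
#' @param trait_id The numeric trait to pivot.
#' @param statistic Aggregation rule: `"mean"`, `"max"`, `"min"` or
#'   `"interval"`.
#' @param by_year If `TRUE`, each location-year pair is its own
#'   environment (keys `"location:year"`); otherwise environments are
#'   locations and replicates pool across years.
#' @return A numeric matrix with variety rownames and environment
#'   colnames, of class `ge_matrix`.
#' @export
pivot_to_matrix <- function(records, trait_id, statistic = "mean",
                            by_year = FALSE) {
  stopifnot(inherits(records, "trait_records"))
  statistic <- match.arg(statistic, c("mean", "max", "min", "interval"))
  rec <- records[records$trait == trait_id, , drop = FALSE]
  if (nrow(rec) == 0L) stop_vt("input", "no records for trait '", trait_id, "'")
  vals <- vapply(rec$parsed, function(p) {
    if (is.numeric(p)) as.numeric(p) else NA_real_
  }, numeric(1))
  if (any(!is.na(rec$value) & nzchar(rec$value) &
          vapply(rec$parsed, function(p) !is.numeric(p), logical(1)))) {
    stop_vt("type", "trait '", trait_id, "' is not numeric; ",
            "pivot_to_matrix requires a numeric trait")
  }
  env <- if (by_year) paste(rec$location, rec$year, sep = ":") else rec$location
  gens <- sort(unique(rec$variety))
  envs <- sort(unique(env))
  agg <- switch(statistic,
                mean = function(x) mean(x),
                max = function(x) max(x),
                min = function(x) min(x),
                interval = function(x) max(x) - min(x))
  m <- matrix(NA_real_, length(gens), length(envs),
              dimnames = list(gens, envs))
  key <- paste(rec$variety, env, sep = "\r")
  keep <- !is.na(vals)
  cells <- split(vals[keep], key[keep])
  for (k in names(cells)) {
    ij <- strsplit(k, "\r", fixed = TRUE)[[1]]
    m[ij[1], ij[2]] <- agg(cells[[k]])
  }
  class(m) <- c("ge_matrix", class(m))
  m
}
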