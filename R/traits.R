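#' Define a standardized trait
#'
#' A trait definition is the data-element standard for one observable
#' characteristic of a crop variety: its identifier, unit of measure, data
#' type, admissible values and the rule used to aggregate replicate
#' observations into a variety-by-environment mean.
#'
#' @param trait_id Opaque identifier, unique within a crop's trait set.
#' @param name Human-readable trait name.
#' @param data_type One of `"numeric"`, `"enumeration"`, `"date"`, `"text"`.
#' @param unit Unit of measure (e.g. `"cm"`, `"g/L"`, `"%"`); empty for
#'   unitless or non-numeric traits.
#' @param crop Crop label the trait belongs to.
#' @param description Free-text description.
#' @param allowed_values Character vector of admissible labels; required for
#'   (and only allowed with) enumeration traits.
#' @param min_value,max_value Plausibility bounds in `unit`; numeric traits
#'   only.
#' @param decimals Non-negative integer display precision; numeric traits
#'   only.
#' @param aggregation How replicate values are summarized: one of `"mean"`,
#'   `"max"`, `"min"`, `"interval"` (max minus min) or `"none"`.
#' @param method Free text describing the observation protocol.
#'
#' @return An object of class `trait_def`.
#' @examples
#' trait_def("height", "Plant height", "numeric", unit = "m",
#'           min_value = 0.5, max_value = 5, decimals = 2)
#' @export
trait_def <- function(trait_id, name, data_type,
                      unit = "", crop = "", description = "",
                      allowed_values = NULL,
                      min_value = NULL, max_value = NULL,
                      decimals = NULL,
                      aggregation = "mean", method = "") {
  if (!is_string(trait_id) || !nzchar(trait_id)) {
    stop_vt("config", "trait_id must be a non-empty string")
  }
  data_type <- match.arg(data_type, c("numeric", "enumeration", "date", "text"))
  aggregation <- match.arg(aggregation,
                           c("mean", "max", "min", "interval", "none"))
  if (data_type == "enumeration") {
    if (is.null(allowed_values) || length(allowed_values) == 0L) {
      stop_vt("config", "enumeration trait '", trait_id,
              "' needs non-empty allowed_values")
    }
  } else if (!is.null(allowed_values)) {
    stop_vt("config", "allowed_values only apply to enumeration traits")
  }
  if (data_type != "numeric") {
    if (!is.null(min_value) || !is.null(max_value) || !is.null(decimals)) {
      stop_vt("config",
              "min_value/max_value/decimals only apply to numeric traits")
    }
  }
  if (!is.null(min_value) && !is.null(max_value) && min_value > max_value) {
    stop_vt("config", "trait '", trait_id, "': min_value > max_value")
  }
  if (!is.null(decimals) &&
      (!is.numeric(decimals) || decimals < 0 || decimals != trunc(decimals))) {
    stop_vt("config", "decimals must be a non-negative integer")
  }
  structure(
    list(trait_id = trait_id, crop = crop, name = name,
         description = description, unit = unit, data_type = data_type,
         allowed_values = allowed_values,
         min_value = min_value, max_value = max_value,
         decimals = if (!is.null(decimals)) as.integer(decimals),
         aggregation = aggregation, method = method),
    class = "trait_def"
  )
}

#' @export
print.trait_def <- function(x, ...) {
  cat("<trait_def> ", x$trait_id, " (", x$data_type, ")",
      if (nzchar(x$unit)) paste0(" [", x$unit, "]"), "\n", sep = "")
  invisible(x)
}

#' Bundle trait definitions into a named set
#'
#' @param ... `trait_def` objects (or a single list of them).
#' @return A named list of class `trait_set`, keyed by `trait_id`.
#' @export
trait_set <- function(...) {
  defs <- list(...)
  if (length(defs) == 1L && is.list(defs[[1]]) &&
      !inherits(defs[[1]], "trait_def")) {
    defs <- defs[[1]]
  }
  ok <- vapply(defs, inherits, logical(1), "trait_def")
  if (!all(ok)) stop_vt("config", "all elements must be trait_def objects")
  ids <- vapply(defs, `[[`, character(1), "trait_id")
  if (anyDuplicated(ids)) {
    stop_vt("config", "duplicate trait ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(defs) <- ids
  structure(defs, class = "trait_set")
}

#' @export
print.trait_set <- function(x, ...) {
  cat("<trait_set> ", length(x), " traits: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Parse one raw string according to a trait's data type.
# Returns list(value = parsed or NA, flag = NULL | validation_flag).
# Empty strings are the on-disk missing marker: parsed NA, no flag.
parse_trait_value <- function(raw, def) {
  raw <- if (is.na(raw)) "" else trimws(raw)
  if (!nzchar(raw)) return(list(value = NA, flag = NULL))
  switch(def$data_type,
    numeric = {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) {
        list(value = NA_real_,
             flag = validation_flag("format",
               paste0("'", raw, "' is not a valid number for trait '",
                      def$trait_id, "'")))
      } else list(value = v, flag = NULL)
    },
    date = {
      if (is_iso_date(raw)) list(value = raw, flag = NULL)
      else list(value = NA_character_,
                flag = validation_flag("format",
                  paste0("'", raw, "' is not a valid YYYY-MM-DD date for trait '",
                         def$trait_id, "'")))
    },
    # enumeration membership is a QC rule, not a parse failure
    list(value = raw, flag = NULL)
  )
}

# strict ISO calendar date: YYYY-MM-DD and a real date
is_iso_date <- function(x) {
  grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x) &
    !is.na(suppressWarnings(as.Date(x, format = "%Y-%m-%d")))
}

#' Read a trial configuration file
#'
#' The shared configuration file is a JSON tree with up to three top-level
#' keys: `traits` (an array of trait definitions), `rules` (an array of
#' validation rules) and `criteria` (promotion thresholds). Any subset may
#' be present.
#'
#' @param path Path to a JSON configuration file.
#' @return A list with elements `traits` (a [trait_set()]), `rules` (a list
#'   of [validation_rule()]) and `criteria` (an [evaluation_criteria()]);
#'   absent sections are `NULL`.
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) stop_vt("io", "config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list(traits = NULL, rules = NULL, criteria = NULL)
  if (!is.null(cfg$traits)) {
    out$traits <- trait_set(lapply(cfg$traits, function(tr) {
      trait_def(
        trait_id = tr$trait_id, name = tr$name %||% tr$trait_id,
        data_type = tr$data_type %||% "numeric",
        unit = tr$unit %||% "", crop = tr$crop %||% "",
        description = tr$description %||% "",
        allowed_values = if (!is.null(tr$allowed_values))
          unlist(tr$allowed_values),
        min_value = tr$min_value, max_value = tr$max_value,
        decimals = tr$decimals,
        aggregation = tr$aggregation %||% "mean",
        method = tr$method %||% ""
      )
    }))
  }
  if (!is.null(cfg$rules)) {
    out$rules <- lapply(cfg$rules, function(r) {
      params <- r$params %||% list()
      params <- lapply(params, function(p)
        if (is.list(p)) unlist(p) else p)
      validation_rule(r$rule_type, r$trait_id, params)
    })
  }
  if (!is.null(cfg$criteria)) {
    out$criteria <- do.call(evaluation_criteria, lapply(cfg$criteria,
      function(p) if (is.list(p)) unlist(p) else p))
  }
  out
}
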