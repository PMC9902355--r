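#' Configuration for the synthetic trial simulator
#'
#' The simulator draws observations from the additive trial model
#' `Y_ijk = mu + g_i + e_j + theta_ij + eps_ijk`: a grand mean plus
#' independent zero-mean normal genotype, environment, interaction and
#' residual effects. Year-to-year variation is represented by re-drawing
#' the environment and interaction effects each year (year folds into the
#' environment key downstream). Defaults emulate a maize regional yield
#' trial: grand mean 600 (plot yield units) with genotype, environment,
#' interaction and residual standard deviations 20, 30, 10 and 25, giving
#' a residual plot CV near 4 percent — a well-controlled field test.
#'
#' @param n_varieties,n_locations,n_replicates,n_years Positive trial
#'   dimensions.
#' @param grand_mean Trait grand mean, in trait units.
#' @param sd_genotype,sd_environment,sd_interaction,sd_residual Standard
#'   deviations of the four effect distributions (trait units, >= 0).
#' @param ck_index Which variety (1-based) acts as the check; its true
#'   effect is recorded so percent-increase truths are computable.
#' @param seed Integer seed; the same seed reproduces the trial exactly.
#' @param trait_id Trait identifier stamped on the records.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_varieties = 10, n_locations = 5, n_replicates = 3,
                       n_years = 1, grand_mean = 600,
                       sd_genotype = 20, sd_environment = 30,
                       sd_interaction = 10, sd_residual = 25,
                       ck_index = 1, seed = 1L, trait_id = "yield") {
  for (nm in c("n_varieties", "n_locations", "n_replicates", "n_years")) {
    if (!is_count(get(nm))) stop_vt("config", nm, " must be a positive integer")
  }
  sds <- c(sd_genotype, sd_environment, sd_interaction, sd_residual)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop_vt("config", "effect standard deviations must be >= 0")
  }
  if (!is_count(ck_index) || ck_index > n_varieties) {
    stop_vt("config", "ck_index must point at one of the varieties")
  }
  structure(list(n_varieties = as.integer(n_varieties),
                 n_locations = as.integer(n_locations),
                 n_replicates = as.integer(n_replicates),
                 n_years = as.integer(n_years),
                 grand_mean = grand_mean,
                 sd_genotype = sd_genotype, sd_environment = sd_environment,
                 sd_interaction = sd_interaction, sd_residual = sd_residual,
                 ck_index = as.integer(ck_index), seed = as.integer(seed),
                 trait_id = trait_id),
            class = "sim_config")
}

#' Simulate a multi-environment variety trial
#'
#' Generates one record per variety, location, replicate and year from
#' the additive observation model, together with a ledger of the drawn
#' true effects for parameter-recovery tests. Varieties are coded
#' `V01, V02, ...` (the CK keeps its code and is marked in the ledger),
#' locations `L1, ...`, years starting 2021.
#'
#' @param config A [sim_config()].
#' @param trait_defs Optional [trait_set()]; defaults to a single numeric
#'   trait named by `config$trait_id`.
#' @return A list of class `sim_trial`: `records` (a `trait_records`
#'   table with status `entered`), `truth` (list with `grand_mean`, `g`,
#'   and per-year `e` and `theta`), `ck_code`, `config`.
#' @export
simulate_trial <- function(config = sim_config(), trait_defs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  nv <- config$n_varieties; nl <- config$n_locations
  nr <- config$n_replicates; ny <- config$n_years
  varieties <- sprintf("V%02d", seq_len(nv))
  locations <- paste0("L", seq_len(nl))
  years <- 2020L + seq_len(ny)
  with_seed(config$seed, {
    g <- stats::rnorm(nv, 0, config$sd_genotype)
    names(g) <- varieties
    e <- list(); theta <- list()
    rows <- vector("list", ny)
    for (yi in seq_len(ny)) {
      ey <- stats::rnorm(nl, 0, config$sd_environment)
      names(ey) <- locations
      th <- matrix(stats::rnorm(nv * nl, 0, config$sd_interaction), nv, nl,
                   dimnames = list(varieties, locations))
      e[[yi]] <- ey; theta[[yi]] <- th
      idx <- expand.grid(replicate = seq_len(nr), location = seq_len(nl),
                         variety = seq_len(nv))
      eps <- stats::rnorm(nrow(idx), 0, config$sd_residual)
      rows[[yi]] <- data.frame(
        variety = varieties[idx$variety],
        location = locations[idx$location],
        replicate = idx$replicate,
        year = years[yi],
        value = config$grand_mean + g[idx$variety] + ey[idx$location] +
          th[cbind(idx$variety, idx$location)] + eps,
        stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, rows)
    names(e) <- names(theta) <- as.character(years)
    raw <- formatC(all$value, format = "f", digits = 2)
    records <- new_trait_records(
      all$variety, all$location, all$replicate, all$year,
      rep(config$trait_id, nrow(all)), raw,
      parsed = as.list(as.numeric(raw)),
      flags = rep(list(list()), nrow(all)))
    structure(list(records = records,
                   truth = list(grand_mean = config$grand_mean, g = g,
                                e = e, theta = theta),
                   ck_code = varieties[config$ck_index],
                   config = config),
              class = "sim_trial")
  })
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("<sim_trial> ", nrow(x$records), " records (",
      x$config$n_varieties, " varieties x ", x$config$n_locations,
      " locations x ", x$config$n_replicates, " reps x ",
      x$config$n_years, " year(s)); CK = ", x$ck_code,
      "; seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Inject abnormal values into clean records
#'
#' Corrupts a configurable fraction of records with the classic abnormal
#' value classes seen in manual data entry: malformed dates
#' ("9021.6.3"-style), double-decimal numbers ("16.7.8"-style),
#' out-of-range numeric values, out-of-enumeration labels, and
#' CV inflation (multiplying one replicate to blow up the location CV).
#' Every corruption is listed in a ledger keyed by record row, enabling
#' exact precision/recall scoring of the QC engine against known truth.
#'
#' @param records A clean `trait_records` table.
#' @param rates Named list of corruption rates in `[0, 1]`: any of
#'   `date`, `decimal`, `range`, `enumeration`, `cv`.
#' @param trait_defs [trait_set()] describing the traits (used to decide
#'   which records each corruption class applies to, and range bounds).
#' @param seed Integer seed.
#' @return A list of class `corrupted_trial`: `records` (with corrupted
#'   raw values re-parsed) and `ledger` (data frame: `row`, `class`,
#'   `original`, `corrupted`).
#' @export
inject_errors <- function(records, rates = list(), trait_defs = NULL,
                          seed = 1L) {
  stopifnot(inherits(records, "trait_records"))
  defaults <- list(date = 0, decimal = 0, range = 0, enumeration = 0, cv = 0)
  unknown <- setdiff(names(rates), names(defaults))
  if (length(unknown)) {
    stop_vt("config", "unknown corruption class(es): ",
            paste(unknown, collapse = ", "))
  }
  rates <- utils::modifyList(defaults, as.list(rates))
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    stop_vt("config", "corruption rates must be in [0, 1]")
  }
  dtype <- function(tr) {
    if (is.null(trait_defs) || is.null(trait_defs[[tr]])) "numeric"
    else trait_defs[[tr]]$data_type
  }
  types <- vapply(records$trait, dtype, character(1))
  ledger <- data.frame(row = integer(), class = character(),
                       original = character(), corrupted = character(),
                       stringsAsFactors = FALSE)
  corrupt <- function(idx, rate, cls, fun) {
    if (rate == 0 || length(idx) == 0L) return()
    pick <- idx[stats::runif(length(idx)) < rate]
    for (i in pick) {
      orig <- records$value[i]
      new <- fun(i)
      records$value[i] <<- new
      ledger[nrow(ledger) + 1L, ] <<- list(i, cls, orig, new)
    }
  }
  with_seed(seed, {
    num_idx <- which(types == "numeric")
    corrupt(which(types == "date"), rates$date, "date", function(i) {
      d <- records$value[i]
      if (grepl("^[0-9]{4}-", d)) {
        # year digits scrambled and dots for dashes: 2021-06-03 -> 9021.6.3
        paste0("9", substr(d, 2, 4), ".",
               as.integer(substr(d, 6, 7)), ".",
               as.integer(substr(d, 9, 10)))
      } else "9021.6.3"
    })
    corrupt(num_idx, rates$decimal, "decimal", function(i) {
      v <- records$value[i]
      paste0(sub("(\\.[0-9])[0-9]*$", "\\1", v), ".", sample.int(9, 1))
    })
    corrupt(setdiff(num_idx, which(seq_len(nrow(records)) %in% ledger$row)),
            rates$range, "range", function(i) {
      def <- if (!is.null(trait_defs)) trait_defs[[records$trait[i]]]
      hi <- if (!is.null(def) && !is.null(def$max_value)) def$max_value
            else suppressWarnings(max(as.numeric(records$value[types == "numeric"]),
                                      na.rm = TRUE))
      formatC(hi * 10 + 1, format = "f", digits = 2)
    })
    corrupt(which(types == "enumeration"), rates$enumeration, "enumeration",
            function(i) "Flat and compact")
    corrupt(setdiff(num_idx, which(seq_len(nrow(records)) %in% ledger$row)),
            rates$cv, "cv", function(i) {
      v <- suppressWarnings(as.numeric(records$value[i]))
      formatC(v * 3, format = "f", digits = 2)
    })
  })
  # re-parse corrupted rows so downstream QC sees fresh parse state
  if (!is.null(trait_defs)) {
    for (i in unique(ledger$row)) {
      p <- parse_trait_value(records$value[i], trait_defs[[records$trait[i]]])
      records$parsed[[i]] <- p$value
      records$flags[[i]] <- list()
      records$status[i] <- "entered"
    }
  }
  structure(list(records = records, ledger = ledger),
            class = "corrupted_trial")
}
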