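#' Trial design configuration
#'
#' Regional variety tests are arranged in randomized complete blocks,
#' normally with three replicates and no more than 16 varieties per
#' group; one or two approved main varieties serve as checks (CK) in
#' every block.
#'
#' @param max_group_size Maximum number of candidate varieties per group
#'   (default 16).
#' @param n_replicates Number of complete blocks per group and location
#'   (default 3).
#' @param ck_codes Character vector of check-variety codes added to every
#'   block.
#' @param locations Character vector of test location ids.
#' @param seed Integer seed making the whole design reproducible; recorded
#'   in the design output for audit.
#' @param anonymize If `TRUE`, layouts and task lists show sequential
#'   blind codes instead of variety codes.
#' @return A list of class `design_config`.
#' @export
design_config <- function(max_group_size = 16, n_replicates = 3,
                          ck_codes = character(), locations = "L1",
                          seed = 1L, anonymize = FALSE) {
  if (!is_count(max_group_size)) {
    stop_vt("config", "max_group_size must be a positive integer")
  }
  if (!is_count(n_replicates)) {
    stop_vt("config", "n_replicates must be a positive integer")
  }
  if (length(locations) == 0L) stop_vt("config", "locations must be non-empty")
  structure(list(max_group_size = as.integer(max_group_size),
                 n_replicates = as.integer(n_replicates),
                 ck_codes = as.character(ck_codes),
                 locations = as.character(locations),
                 seed = as.integer(seed),
                 anonymize = isTRUE(anonymize)),
            class = "design_config")
}

candidate_codes <- function(candidates) {
  codes <- if (is.data.frame(candidates)) {
    if (!is.null(candidates$is_check) && any(candidates$is_check)) {
      stop_vt("config", "candidates must not contain CK entries; ",
              "pass checks via design_config(ck_codes = ...)")
    }
    candidates$variety_code
  } else as.character(candidates)
  if (length(codes) == 0L) stop_vt("input", "empty candidate list")
  if (anyDuplicated(codes)) stop_vt("config", "duplicate candidate codes")
  codes
}

#' Group candidate varieties for testing
#'
#' Computes the number of groups as `ceiling(n / max_group_size)`, then
#' applies the sequential fill rule: candidates are drawn in seeded random
#' order and each is placed in the first group that is not yet full. The
#' result is a partition of the candidates with every group at most
#' `max_group_size` strong; it is deterministic for a fixed seed.
#'
#' @param candidates Character vector of candidate codes or a
#'   [variety_table()] without CK entries.
#' @param config A [design_config()].
#' @return A named list of character vectors (`G1`, `G2`, ...), one per
#'   group.
#' @examples
#' group_varieties(sprintf("V%02d", 1:60), design_config(seed = 7))
#' @export
group_varieties <- function(candidates, config = design_config()) {
  codes <- candidate_codes(candidates)
  n <- length(codes)
  n_groups <- ceiling(n / config$max_group_size)
  with_seed(config$seed, {
    order <- sample.int(n)
    groups <- vector("list", n_groups)
    g <- 1L
    for (i in order) {
      if (length(groups[[g]]) >= config$max_group_size) g <- g + 1L
      groups[[g]] <- c(groups[[g]], codes[i])
    }
    names(groups) <- paste0("G", seq_len(n_groups))
    groups
  })
}

#' Generate randomized complete block layouts
#'
#' Associates every group with each configured test location and lays out
#' `n_replicates` complete blocks per group and location. Each block is
#' an independent seeded random permutation of the group's candidates
#' plus the CK entries, so every entry (CK included) appears exactly once
#' per block. With `anonymize = TRUE`, layouts show blind codes
#' (zero-padded sequential integers prefixed by the group label) and the
#' code mapping is returned for unblinding.
#'
#' @param groups A named list of candidate-code vectors, as returned by
#'   [group_varieties()].
#' @param config A [design_config()].
#' @return A list of class `trial_design` with elements `groups`,
#'   `assignments` (group to location ids), `layouts` (nested
#'   group/location/replicate plot sequences), `anonymization_map` and
#'   `config`.
#' @export
make_layouts <- function(groups, config = design_config()) {
  stopifnot(is.list(groups), length(groups) > 0L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("G", seq_along(groups))
  }
  all_cand <- unlist(groups, use.names = FALSE)
  clash <- intersect(config$ck_codes, all_cand)
  if (length(clash)) {
    stop_vt("config", "CK code(s) collide with candidate codes: ",
            paste(clash, collapse = ", "))
  }
  anon_map <- NULL
  if (config$anonymize) {
    anon_map <- unlist(lapply(names(groups), function(g) {
      entries <- c(groups[[g]], config$ck_codes)
      stats::setNames(sprintf("%s-%02d", g, seq_along(entries)), entries)
    }))
  }
  blind <- function(x) if (is.null(anon_map)) x else unname(anon_map[x])
  layouts <- with_seed(config$seed + 1L, {
    lapply(names(groups), function(g) {
      entries <- c(groups[[g]], config$ck_codes)
      locs <- lapply(config$locations, function(loc) {
        reps <- lapply(seq_len(config$n_replicates), function(r) {
          blind(entries[sample.int(length(entries))])
        })
        names(reps) <- paste0("R", seq_len(config$n_replicates))
        reps
      })
      names(locs) <- config$locations
      locs
    })
  })
  names(layouts) <- names(groups)
  assignments <- stats::setNames(
    rep(list(config$locations), length(groups)), names(groups))
  structure(list(groups = groups, assignments = assignments,
                 layouts = layouts, anonymization_map = anon_map,
                 config = config),
            class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design> ", length(x$groups), " group(s), ",
      length(x$config$locations), " location(s), ",
      x$config$n_replicates, " replicate block(s); seed ",
      x$config$seed, "\n", sep = "")
  sizes <- vapply(x$groups, length, integer(1))
  cat("  group sizes: ", paste(sizes, collapse = ", "),
      "; CK: ", paste(x$config$ck_codes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Interval contrast layout for very small tests
#'
#' Tests with few varieties are arranged without replication: a single
#' plot sequence in which the CK is planted first and re-inserted after
#' every `k` candidates, giving each candidate an adjacent check for
#' comparison.
#'
#' @param candidates Character vector of candidate codes.
#' @param ck_code Single check-variety code.
#' @param k Number of candidates between consecutive CK plots (default 4).
#' @return Character vector: the plot sequence.
#' @export
design_interval_contrast <- function(candidates, ck_code, k = 4) {
  codes <- candidate_codes(candidates)
  if (!is_string(ck_code)) stop_vt("config", "ck_code must be one code")
  if (!is_count(k)) stop_vt("config", "k must be a positive integer")
  out <- ck_code
  for (i in seq_along(codes)) {
    out <- c(out, codes[i])
    if (i %% k == 0L && i < length(codes)) out <- c(out, ck_code)
  }
  out
}

#' Generate the per-location task list
#'
#' After the scheme design is complete, each test location receives its
#' recording tasks automatically: one task row per location, group and
#' trait to observe, listing the plot entries (blind codes when the
#' design is anonymized).
#'
#' @param design A [make_layouts()] result.
#' @param trait_defs A [trait_set()] of the traits to record.
#' @return A data frame with columns `location`, `group`, `varieties`
#'   (comma-separated entry codes) and `trait`.
#' @export
make_task_list <- function(design, trait_defs) {
  stopifnot(inherits(design, "trial_design"))
  traits <- names(trait_defs)
  rows <- list()
  blind <- function(x) {
    if (is.null(design$anonymization_map)) x
    else unname(design$anonymization_map[x])
  }
  for (g in names(design$groups)) {
    entries <- blind(c(design$groups[[g]], design$config$ck_codes))
    for (loc in design$assignments[[g]]) {
      for (tr in traits) {
        rows[[length(rows) + 1L]] <- data.frame(
          location = loc, group = g,
          varieties = paste(entries, collapse = ","),
          trait = tr, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(location = character(), group = character(),
                      varieties = character(), trait = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Serialize a trial design to JSON
#'
#' The design file records groups, location assignments, every block's
#' plot sequence, the anonymization map and the seed, so a design can be
#' audited and regenerated exactly.
#'
#' @param design A `trial_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  payload <- list(groups = design$groups,
                  assignments = design$assignments,
                  layouts = design$layouts,
                  anonymization_map = as.list(design$anonymization_map),
                  config = unclass(design$config))
  txt <- jsonlite::toJSON(payload, auto_unbox = FALSE, pretty = TRUE,
                          null = "null")
  write_atomic(txt, path)
}

#' Read a trial design from JSON
#'
#' @param path Path to a file written by [write_design()].
#' @return A `trial_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop_vt("io", "design file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- design_config(max_group_size = p$config$max_group_size,
                       n_replicates = p$config$n_replicates,
                       ck_codes = unlist(p$config$ck_codes),
                       locations = unlist(p$config$locations),
                       seed = p$config$seed,
                       anonymize = isTRUE(p$config$anonymize))
  anon <- if (length(p$anonymization_map)) unlist(p$anonymization_map)
  structure(list(groups = lapply(p$groups, unlist),
                 assignments = lapply(p$assignments, unlist),
                 layouts = p$layouts,
                 anonymization_map = anon,
                 config = cfg),
            class = "trial_design")
}
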