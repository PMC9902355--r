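## internal helpers

# Run code under a local RNG state so package functions are seed-deterministic
# without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == trunc(x)
}

is_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

stop_vt <- function(category, ..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("vtrial_", category), "vtrial_error", "error", "condition"),
    list(message = msg, call = NULL, category = category)
  )
  stop(cond)
}

# trim + case-fold normalization used for duplicate checks and enumerations
normalize_label <- function(x) tolower(trimws(x))

# Atomic write: write to a sibling temp file, then rename into place.
write_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp, useBytes = TRUE)
  if (!file.rename(tmp, path)) {
    stop_vt("io", "cannot write to '", path, "'")
  }
  invisible(path)
}

fmt_num <- function(x, decimals = 2) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = decimals))
}
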