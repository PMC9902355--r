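#' Build a table of variety entries
#'
#' Variety entries describe the candidates (and check varieties) enrolled
#' in a testing program: code, name, pedigree, applicant and CK flag.
#'
#' @param variety_code Character vector of unique variety codes.
#' @param name,parents,applicant Character vectors (recycled) describing
#'   each entry; used for duplicate-application verification.
#' @param crop Crop label.
#' @param is_check Logical vector; `TRUE` marks an approved check (CK)
#'   variety.
#' @return A data frame of class `variety_table`.
#' @export
variety_table <- function(variety_code, name = variety_code, parents = "",
                          applicant = "", crop = "", is_check = FALSE) {
  variety_code <- as.character(variety_code)
  if (anyDuplicated(variety_code)) {
    stop_vt("config", "variety codes must be unique within a program: ",
            paste(unique(variety_code[duplicated(variety_code)]),
                  collapse = ", "))
  }
  df <- data.frame(variety_code = variety_code,
                   name = as.character(rep_len(name, length(variety_code))),
                   parents = rep_len(as.character(parents), length(variety_code)),
                   applicant = rep_len(as.character(applicant), length(variety_code)),
                   crop = rep_len(as.character(crop), length(variety_code)),
                   is_check = rep_len(as.logical(is_check), length(variety_code)),
                   stringsAsFactors = FALSE)
  class(df) <- c("variety_table", "data.frame")
  df
}

#' Find duplicate variety applications
#'
#' A variety may participate in an ecological zone's test only once, so
#' applications must be screened for entries that agree on name, parents
#' and applicant. Comparison is on normalized fields (whitespace trimmed,
#' case folded). Check (CK) varieties are excluded: they are intentionally
#' repeated across tests.
#'
#' @param entries A [variety_table()] (or data frame with columns
#'   `variety_code`, `name`, `parents`, `applicant`, optionally
#'   `is_check`).
#' @return A data frame with one row per duplicate pair (columns
#'   `code_a`, `code_b`, `name`, `parents`, `applicant`); zero rows when
#'   no duplicates exist.
#' @export
check_duplicate_applications <- function(entries) {
  empty <- data.frame(code_a = character(), code_b = character(),
                      name = character(), parents = character(),
                      applicant = character(), stringsAsFactors = FALSE)
  if (is.null(entries) || nrow(entries) == 0L) return(empty)
  if (!is.null(entries$is_check)) {
    entries <- entries[!entries$is_check, , drop = FALSE]
  }
  if (nrow(entries) < 2L) return(empty)
  key <- paste(normalize_label(entries$name),
               normalize_label(entries$parents),
               normalize_label(entries$applicant), sep = "\r")
  groups <- split(seq_len(nrow(entries)), key)
  pairs <- empty
  for (idx in groups) {
    if (length(idx) < 2L) next
    cmb <- utils::combn(idx, 2L)
    pairs <- rbind(pairs, data.frame(
      code_a = entries$variety_code[cmb[1, ]],
      code_b = entries$variety_code[cmb[2, ]],
      name = entries$name[cmb[1, ]],
      parents = entries$parents[cmb[1, ]],
      applicant = entries$applicant[cmb[1, ]],
      stringsAsFactors = FALSE))
  }
  rownames(pairs) <- NULL
  pairs
}
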