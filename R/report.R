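#' Report template
#'
#' Orders the sections of the one-command trial report and controls
#' number formatting. Each section is bound to one upstream result type;
#' a section whose input is absent from the results bundle is emitted as
#' "not available", never silently dropped.
#'
#' @param sections Character vector drawn from `"design"`, `"qc"`,
#'   `"precision"`, `"ck"`, `"evaluation"`, `"topsis"`, `"gge"`.
#' @param title Report title.
#' @param decimals Decimal places for formatted numbers.
#' @param remarks Free-text remarks of the test director, appended at the
#'   end.
#' @return A list of class `report_template`.
#' @export
report_template <- function(sections = c("design", "qc", "precision", "ck",
                                         "evaluation", "topsis", "gge"),
                            title = "Variety trial report",
                            decimals = 2, remarks = "") {
  known <- c("design", "qc", "precision", "ck", "evaluation", "topsis", "gge")
  bad <- setdiff(sections, known)
  if (length(bad)) {
    stop_vt("template", "unknown section type(s): ",
            paste(bad, collapse = ", "))
  }
  structure(list(sections = sections, title = title,
                 decimals = as.integer(decimals), remarks = remarks),
            class = "report_template")
}

md_table <- function(df, decimals = 2) {
  if (nrow(df) == 0L) return("(empty table)")
  cells <- df
  for (j in seq_along(cells)) {
    if (is.numeric(cells[[j]]) && !is.integer(cells[[j]])) {
      cells[[j]] <- fmt_num(cells[[j]], decimals)
    } else cells[[j]] <- as.character(cells[[j]])
  }
  header <- paste0("| ", paste(names(cells), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(cells)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

not_avail <- "_Not available._"

#' Generate the trial report
#'
#' Assembles a deterministic Markdown document from a bundle of upstream
#' results: design summary (with the audit seed), QC summary, precision
#' statistics (CV, GCV, LSD, RLSD), CK comparisons with significance
#' letters, promotion decisions, TOPSIS ranking and GGE summaries. The
#' report's tables are formatted views of the stored results: identical
#' bundle and template produce byte-identical output.
#'
#' @param results Named list; recognized elements are `design` (a
#'   `trial_design`), `qc` (a `qc_result`), `precision` (data frame or
#'   named list of precision statistics), `ck` (a `ck_comparison`),
#'   `lsd` (an `lsd_groups`), `evaluation` (data frame with `variety`,
#'   `result`, `failed`), `topsis` (a `topsis_result`), `gge` (a
#'   `gge_model`).
#' @param template A [report_template()].
#' @param path Optional output path; when given the report is written
#'   there atomically.
#' @return Character vector of Markdown lines (invisibly when `path` is
#'   given).
#' @export
generate_report <- function(results, template = report_template(),
                            path = NULL) {
  stopifnot(inherits(template, "report_template"))
  if (length(results) == 0L) stop_vt("input", "results bundle is empty")
  dec <- template$decimals
  out <- c(paste("#", template$title), "",
           paste0("Software: vtrial ",
                  as.character(utils::packageVersion("vtrial"))), "")
  for (sec in template$sections) {
    out <- c(out, paste("##", switch(sec,
      design = "Trial design", qc = "Data quality control",
      precision = "Trial precision", ck = "Comparison with CK",
      evaluation = "Promotion decisions", topsis = "Comprehensive ranking",
      gge = "GGE analysis")), "")
    block <- switch(sec,
      design = {
        d <- results$design
        if (is.null(d)) not_avail else {
          sizes <- vapply(d$groups, length, integer(1))
          c(paste0("Seed: ", d$config$seed),
            paste0("Groups: ", length(d$groups), " (sizes ",
                   paste(sizes, collapse = ", "), ")"),
            paste0("Locations: ", paste(d$config$locations, collapse = ", ")),
            paste0("Replicates per location: ", d$config$n_replicates),
            paste0("CK: ", paste(d$config$ck_codes, collapse = ", ")))
        }
      },
      qc = {
        q <- results$qc
        if (is.null(q)) not_avail else {
          c(paste0("Records: ", nrow(q$records), " (",
                   sum(q$records$status == "accepted"), " accepted, ",
                   sum(q$records$status == "flagged"), " flagged)"), "",
            md_table(q$summary, dec))
        }
      },
      precision = {
        p <- results$precision
        if (is.null(p)) not_avail
        else if (is.data.frame(p)) md_table(p, dec)
        else md_table(data.frame(statistic = names(p),
                                 value = unlist(p),
                                 stringsAsFactors = FALSE), dec)
      },
      ck = {
        ck <- results$ck
        if (is.null(ck)) not_avail else {
          tab <- as.data.frame(ck)
          if (!is.null(results$lsd)) {
            tab$letters <- results$lsd$letters[
              match(tab$variety, results$lsd$variety)]
          }
          c(paste0("CK: ", attr(ck, "ck_code")), "", md_table(tab, dec))
        }
      },
      evaluation = {
        ev <- results$evaluation
        if (is.null(ev)) not_avail else md_table(as.data.frame(ev), dec)
      },
      topsis = {
        tp <- results$topsis
        if (is.null(tp)) not_avail else {
          c(paste0("Weights: ",
                   paste(names(tp$weights), fmt_num(tp$weights, 4),
                         sep = "=", collapse = ", ")), "",
            md_table(tp$ranking, 4))
        }
      },
      gge = {
        gg <- results$gge
        if (is.null(gg)) not_avail else {
          c(paste0("Variance explained: ",
                   paste0(fmt_num(gg$variance_explained, 1), "%",
                          collapse = ", ")), "",
            "Genotype scores:", "",
            md_table(data.frame(genotype = rownames(gg$genotype_scores),
                                as.data.frame(gg$genotype_scores)), dec), "",
            "Environment scores:", "",
            md_table(data.frame(environment = rownames(gg$environment_scores),
                                as.data.frame(gg$environment_scores)), dec))
        }
      })
    out <- c(out, block, "")
  }
  if (nzchar(template$remarks)) {
    out <- c(out, "## Remarks", "", template$remarks, "")
  }
  if (!is.null(path)) {
    write_atomic(out, path)
    return(invisible(out))
  }
  out
}
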