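#' Promotion criteria for variety evaluation
#'
#' Thresholds of the rule-based promotion algorithm. The shipped defaults
#' are the maize profile: yield increases over CK (mean at least 5.0
#' percent, each year at least 3.0 percent), grain quality floors (bulk
#' density 720 g/L, crude starch 69.0 percent, crude protein 8.0 percent,
#' crude fat 3.0 percent), lodging ceilings (lodging + folding rate at
#' most 8.0 percent, at most 20 percent of locations with that rate at or
#' above 10 percent), growth period at most 2.0 days longer than CK, and
#' a one-vote veto on highly infectious diseases. Other crops load other
#' profiles via the configuration file.
#'
#' @param min_y Minimum mean yield increase over CK, percent.
#' @param min_y1,min_y2 Minimum per-year yield increases, percent.
#' @param min_q1 Minimum grain bulk density, g/L.
#' @param min_q2,min_q3,min_q4 Minimum crude starch, protein and fat
#'   content (dry basis), percent.
#' @param max_r1 Maximum sum of lodging and folding rate, percent.
#' @param max_r2 Maximum proportion of locations whose lodging + folding
#'   rate reaches 10 percent, in percent.
#' @param max_p Maximum days longer than the CK growth period.
#' @param veto_diseases Character vector of diseases triggering the
#'   one-vote veto when observed as highly infectious.
#' @return A list of class `evaluation_criteria`.
#' @export
evaluation_criteria <- function(min_y = 5.0, min_y1 = 3.0, min_y2 = 3.0,
                                min_q1 = 720, min_q2 = 69.0, min_q3 = 8.0,
                                min_q4 = 3.0, max_r1 = 8.0, max_r2 = 20,
                                max_p = 2.0,
                                veto_diseases = c("Leaf blight", "Stem rot",
                                                  "Ear rot", "Head smut",
                                                  "Gray spot")) {
  nums <- list(min_y = min_y, min_y1 = min_y1, min_y2 = min_y2,
               min_q1 = min_q1, min_q2 = min_q2, min_q3 = min_q3,
               min_q4 = min_q4, max_r1 = max_r1, max_r2 = max_r2,
               max_p = max_p)
  bad <- names(nums)[!vapply(nums, is_num, logical(1))]
  if (length(bad)) {
    stop_vt("config", "criteria must be finite numbers: ",
            paste(bad, collapse = ", "))
  }
  structure(c(nums, list(veto_diseases = as.character(veto_diseases))),
            class = "evaluation_criteria")
}

#' Metrics of one candidate variety
#'
#' The inputs of the promotion algorithm, all relative to the trial's CK
#' where applicable.
#'
#' @param y Mean yield increase over CK, percent.
#' @param y1,y2 Yield increases over CK in the first and second year,
#'   percent.
#' @param q1 Grain bulk density, g/L.
#' @param q2,q3,q4 Crude starch, protein, fat content (dry basis),
#'   percent.
#' @param r1 Sum of lodging and folding rate, percent.
#' @param r2 Proportion of locations whose lodging + folding rate
#'   reaches 10 percent, in percent.
#' @param p Days longer than the CK growth period (negative when
#'   shorter).
#' @param highly_infectious Character vector of diseases observed as
#'   highly infectious on this variety (empty when none).
#' @return A list of class `variety_metrics`.
#' @export
variety_metrics <- function(y, y1, y2, q1, q2, q3, q4, r1, r2, p,
                            highly_infectious = character()) {
  vals <- list(y = y, y1 = y1, y2 = y2, q1 = q1, q2 = q2, q3 = q3,
               q4 = q4, r1 = r1, r2 = r2, p = p)
  bad <- names(vals)[!vapply(vals, is_num, logical(1))]
  if (length(bad)) {
    stop_vt("input", "incomplete metrics; missing or non-numeric field(s): ",
            paste(bad, collapse = ", "))
  }
  structure(c(vals, list(highly_infectious = as.character(highly_infectious))),
            class = "variety_metrics")
}

#' Rule-based promotion decision
#'
#' Applies the five-condition promotion algorithm: (1) yield increases
#' over CK, (2) grain quality floors, (3) lodging ceilings, (4) growth
#' period, (5) one-vote veto — the set of highly infectious diseases
#' observed must be disjoint from the veto list. All comparisons are
#' inclusive. The variety is promoted (1) only when every condition
#' holds; otherwise it is eliminated (0) and each failed condition is
#' named.
#'
#' @param metrics A [variety_metrics()] object.
#' @param criteria An [evaluation_criteria()] profile (defaults: maize).
#' @return A list of class `evaluation_outcome`: `result` (integer 0 or
#'   1), `failed` (character vector of failed condition labels) and
#'   `detail` (per-condition logical).
#' @examples
#' m <- variety_metrics(y = 5.5, y1 = 3.5, y2 = 3.5, q1 = 730, q2 = 70,
#'                      q3 = 8.5, q4 = 3.5, r1 = 7, r2 = 15, p = 1)
#' evaluate_variety(m)$result  # 1
#' @export
evaluate_variety <- function(metrics, criteria = evaluation_criteria()) {
  if (!inherits(metrics, "variety_metrics")) {
    metrics <- do.call(variety_metrics, as.list(metrics))
  }
  stopifnot(inherits(criteria, "evaluation_criteria"))
  veto_hit <- intersect(normalize_label(metrics$highly_infectious),
                        normalize_label(criteria$veto_diseases))
  detail <- c(
    yield = metrics$y >= criteria$min_y && metrics$y1 >= criteria$min_y1 &&
      metrics$y2 >= criteria$min_y2,
    quality = metrics$q1 >= criteria$min_q1 &&
      metrics$q2 >= criteria$min_q2 && metrics$q3 >= criteria$min_q3 &&
      metrics$q4 >= criteria$min_q4,
    lodging = metrics$r1 <= criteria$max_r1 && metrics$r2 <= criteria$max_r2,
    growth_period = metrics$p <= criteria$max_p,
    disease_veto = length(veto_hit) == 0L
  )
  structure(list(result = as.integer(all(detail)),
                 failed = names(detail)[!detail],
                 detail = detail),
            class = "evaluation_outcome")
}

#' @export
print.evaluation_outcome <- function(x, ...) {
  cat("<evaluation_outcome> ",
      if (x$result == 1L) "1 (promote)" else "0 (eliminate)", "\n", sep = "")
  if (length(x$failed)) {
    cat("  failed: ", paste(x$failed, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Entropy weights for a decision matrix
#'
#' Objective criterion weights from Shannon entropy: with column-wise
#' shares `p_ij = y_ij / sum_i y_ij`, the entropy of criterion j is
#' `E_j = -(1/ln m) * sum_i p_ij ln p_ij` (with `0 ln 0 = 0`) and the
#' weight is `alpha_j = (1 - E_j) / sum_k (1 - E_k)`. Informative
#' (low-entropy) criteria receive higher weight.
#'
#' @param y Non-negative normalized decision matrix, m alternatives by n
#'   criteria (direction-adjusted, see [topsis_rank()]).
#' @return Numeric weight vector `alpha` summing to 1.
#' @export
entropy_weights <- function(y) {
  y <- as.matrix(y)
  m <- nrow(y)
  if (m < 2L) stop_vt("input", "entropy weights need at least 2 alternatives")
  if (any(y < 0)) stop_vt("input", "decision matrix must be non-negative")
  totals <- colSums(y)
  if (any(totals == 0)) {
    stop_vt("input", "column(s) with zero total: ",
            paste(which(totals == 0), collapse = ", "))
  }
  p <- sweep(y, 2, totals, "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  E <- -colSums(plogp) / log(m)
  gap <- pmax(0, 1 - E)  # guard tiny negative rounding
  if (sum(gap) == 0) {
    warning("all criteria carry equal (zero) information; ",
            "falling back to uniform weights")
    return(rep(1 / ncol(y), ncol(y)))
  }
  gap / sum(gap)
}

#' Combine entropy and expert weights
#'
#' `w_j = alpha_j * beta_j / sum_k alpha_k * beta_k`: the comprehensive
#' indicator weight blending the objective entropy weight `alpha` with
#' the expert score `beta`.
#'
#' @param alpha Numeric entropy-weight vector.
#' @param beta Non-negative expert scores, same length.
#' @return Weight vector summing to 1.
#' @export
combine_weights <- function(alpha, beta) {
  if (length(alpha) != length(beta)) {
    stop_vt("input", "alpha and beta must have equal length")
  }
  if (any(beta < 0)) stop_vt("input", "expert scores must be >= 0")
  prod <- alpha * beta
  if (sum(prod) == 0) stop_vt("input", "all alpha*beta products are zero")
  prod / sum(prod)
}

#' TOPSIS configuration
#'
#' @param directions Character vector, one of `"benefit"` or `"cost"` per
#'   criterion.
#' @param beta Expert scores per criterion (default uniform).
#' @param alpha Optional fixed objective weights; when `NULL` they are
#'   computed by [entropy_weights()] from the normalized matrix.
#' @param normalization `"minmax"` (default) or `"vector"`.
#' @return A list of class `topsis_config`.
#' @export
topsis_config <- function(directions, beta = NULL, alpha = NULL,
                          normalization = c("minmax", "vector")) {
  directions <- match.arg(directions, c("benefit", "cost"),
                          several.ok = TRUE)
  normalization <- match.arg(normalization)
  n <- length(directions)
  beta <- beta %||% rep(1, n)
  if (length(beta) != n || any(beta < 0) || sum(beta) == 0) {
    stop_vt("config", "beta must be ", n,
            " non-negative scores, not all zero")
  }
  if (!is.null(alpha) && (length(alpha) != n || any(alpha < 0))) {
    stop_vt("config", "alpha must be ", n, " non-negative weights")
  }
  structure(list(directions = directions, beta = beta, alpha = alpha,
                 normalization = normalization),
            class = "topsis_config")
}

# Direction-adjust and normalize a raw criterion matrix. Cost columns are
# reflected as (max - x) so that larger is always better, then columns are
# scaled to [0, 1] (minmax) or unit Euclidean norm (vector). Constant
# columns map to all-ones (they carry no preference information).
normalize_decision_matrix <- function(x, directions, normalization) {
  x <- as.matrix(x)
  y <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    if (directions[j] == "cost") col <- max(col) - col
    rng <- max(col) - min(col)
    y[, j] <- if (rng == 0) {
      rep(1, nrow(x))
    } else if (normalization == "minmax") {
      (col - min(col)) / rng
    } else {
      col / sqrt(sum(col^2))
    }
  }
  y
}

#' Rank varieties by entropy-weighted TOPSIS
#'
#' The comprehensive evaluation pipeline: the raw criterion matrix is
#' direction-adjusted and normalized; objective weights come from
#' [entropy_weights()] (unless fixed in the config) and are blended with
#' expert scores by [combine_weights()]; the weighted matrix
#' `v_ij = y_ij * w_j` is compared against the positive ideal `S+`
#' (per-criterion maximum) and negative ideal `S-` (minimum) by Euclidean
#' distance, and each variety's relative closeness
#' `C_i = D_i- / (D_i+ + D_i-)` gives the comprehensive score and
#' ranking. Ties rank by input order.
#'
#' @param x Raw decision matrix: m alternatives (rows, named) by n
#'   criteria (columns, named).
#' @param config A [topsis_config()]; defaults to all-benefit criteria
#'   with uniform expert scores.
#' @return An object of class `topsis_result`: `weights`, `normalized`,
#'   `weighted`, `s_plus`, `s_minus`, `d_plus`, `d_minus`, `closeness`,
#'   and `ranking` (data frame sorted by descending closeness).
#' @export
topsis_rank <- function(x, config = NULL) {
  x <- as.matrix(x)
  m <- nrow(x); n <- ncol(x)
  if (m < 2L) {
    stop_vt("degenerate",
            "TOPSIS needs at least 2 alternatives: closeness is undefined ",
            "when D+ + D- = 0")
  }
  if (is.null(config)) config <- topsis_config(rep("benefit", n))
  if (length(config$directions) != n) {
    stop_vt("config", "config describes ", length(config$directions),
            " criteria but matrix has ", n)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("A", seq_len(m))
  y <- normalize_decision_matrix(x, config$directions, config$normalization)
  alpha <- config$alpha
  if (is.null(alpha)) {
    alpha <- withCallingHandlers(entropy_weights(y),
      warning = function(w) invokeRestart("muffleWarning"))
  } else {
    alpha <- alpha / sum(alpha)
  }
  w <- combine_weights(alpha, config$beta)
  v <- sweep(y, 2, w, "*")
  s_plus <- apply(v, 2, max)
  s_minus <- apply(v, 2, min)
  d_plus <- sqrt(rowSums(sweep(v, 2, s_plus)^2))
  d_minus <- sqrt(rowSums(sweep(v, 2, s_minus)^2))
  denom <- d_plus + d_minus
  if (any(denom == 0)) {
    # identical alternatives on every criterion: closeness defined as 0.5
    denom[denom == 0] <- 1
    d_minus[d_plus + d_minus == 0] <- 0.5
  }
  closeness <- d_minus / denom
  ord <- order(-closeness, seq_len(m))
  ranking <- data.frame(variety = rownames(x)[ord],
                        closeness = closeness[ord],
                        rank = seq_len(m), stringsAsFactors = FALSE)
  structure(list(weights = stats::setNames(w, colnames(x)),
                 alpha = alpha, beta = config$beta,
                 normalized = y, weighted = v,
                 s_plus = s_plus, s_minus = s_minus,
                 d_plus = d_plus, d_minus = d_minus,
                 closeness = stats::setNames(closeness, rownames(x)),
                 ranking = ranking),
            class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, ...) {
  cat("<topsis_result> ", length(x$closeness), " alternatives, ",
      length(x$weights), " criteria\n", sep = "")
  cat("  weights:", paste(round(x$weights, 4), collapse = ", "), "\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
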