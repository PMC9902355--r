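#' Center a genotype-by-environment matrix on environment means
#'
#' Subtracts each environment's (column) mean, removing the environment
#' main effect and leaving genotype main effects plus
#' genotype-by-environment interaction — the G + GE surface on which the
#' GGE model operates.
#'
#' @param m A complete numeric genotype-by-environment matrix (e.g. from
#'   [pivot_to_matrix()]).
#' @return A matrix of the same shape with zero column means.
#' @export
center_environments <- function(m) {
  m <- unclass(as.matrix(m))
  if (anyNA(m)) {
    holes <- which(is.na(m), arr.ind = TRUE)
    stop_vt("input",
            "matrix has missing cells (e.g. ",
            paste(rownames(m)[holes[1, 1]], colnames(m)[holes[1, 2]],
                  sep = "/"),
            "); aggregate the records to a complete matrix first ",
            "(see pivot_to_matrix)")
  }
  sweep(m, 2, colMeans(m))
}

#' Fit the GGE model by singular value decomposition
#'
#' Decomposes the environment-centered matrix as `U diag(lambda) V'` and
#' partitions the singular values between the two sides with the scaling
#' exponent `f`: genotype scores `U diag(lambda^f)`, environment scores
#' `V diag(lambda^(1-f))`. The default `f = 0.5` gives the symmetric
#' biplot suitable for judging genotypes and environments together;
#' `f = 1` is genotype-focused. Component signs follow a deterministic
#' convention: the largest-magnitude genotype score of each component is
#' made positive.
#'
#' @param centered Environment-centered matrix from
#'   [center_environments()].
#' @param n_components Number of components to retain (default 2);
#'   truncated to the matrix rank with a warning if larger.
#' @param f Singular-value partition exponent in `[0, 1]`.
#' @return An object of class `gge_model`: `genotype_scores`,
#'   `environment_scores` (matrices with `PC1..PCk` columns),
#'   `singular_values`, `variance_explained` (percent per retained
#'   component), `f`, `centered`.
#' @export
fit_gge <- function(centered, n_components = 2, f = 0.5) {
  m <- as.matrix(centered)
  if (max(abs(colMeans(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop_vt("input", "matrix is not environment-centered; ",
            "call center_environments() first")
  }
  if (!is_num(f) || f < 0 || f > 1) stop_vt("config", "f must be in [0, 1]")
  if (!is_count(n_components)) {
    stop_vt("config", "n_components must be a positive integer")
  }
  sv <- svd(m)
  tol <- max(dim(m)) * .Machine$double.eps * max(sv$d, 1)
  rank <- sum(sv$d > tol)
  k <- min(n_components, min(dim(m)))
  if (k > rank && rank > 0L) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; retaining ", rank)
    k <- rank
  }
  if (rank == 0L) k <- 1L  # zero matrix: one null component
  idx <- seq_len(k)
  u <- sv$u[, idx, drop = FALSE]
  v <- sv$v[, idx, drop = FALSE]
  d <- sv$d[idx]
  for (j in idx) {  # sign convention
    i_max <- which.max(abs(u[, j]))
    if (u[i_max, j] < 0) { u[, j] <- -u[, j]; v[, j] <- -v[, j] }
  }
  gs <- u %*% diag(d^f, k, k)
  es <- v %*% diag(d^(1 - f), k, k)
  dimnames(gs) <- list(rownames(m), paste0("PC", idx))
  dimnames(es) <- list(colnames(m), paste0("PC", idx))
  total_ss <- sum(sv$d^2)
  varexp <- if (total_ss > 0) 100 * sv$d[idx]^2 / total_ss else rep(0, k)
  structure(list(genotype_scores = gs, environment_scores = es,
                 singular_values = d,
                 variance_explained = varexp,
                 f = f, centered = m),
            class = "gge_model")
}

#' @export
print.gge_model <- function(x, ...) {
  k <- length(x$singular_values)
  cat("<gge_model> ", nrow(x$genotype_scores), " genotypes x ",
      nrow(x$environment_scores), " environments, ", k,
      " component(s), f = ", x$f, "\n", sep = "")
  cat("  variance explained:",
      paste0(round(x$variance_explained, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

# Average-environment axis: unit vector along the mean environment score.
# Works in the retained biplot plane (two components, or one when the
# model is rank one and only one component could be kept).
aea_axis <- function(model) {
  k <- min(2L, ncol(model$environment_scores))
  ctr <- colMeans(model$environment_scores[, seq_len(k), drop = FALSE])
  len <- sqrt(sum(ctr^2))
  if (len == 0) {
    stop_vt("degenerate", "mean environment vector is zero; ",
            "average-environment axis undefined")
  }
  ctr / len
}

# Project score rows onto the AEA; orthogonal deviation is zero in a
# one-component model.
aea_decompose <- function(scores, a) {
  k <- length(a)
  s <- scores[, seq_len(k), drop = FALSE]
  proj <- as.vector(s %*% a)
  orth <- if (k == 2L) as.vector(s %*% c(-a[2], a[1])) else rep(0, nrow(s))
  list(s = s, proj = proj, orth = orth)
}

#' Rank genotypes by distance to the ideal genotype
#'
#' The average-environment axis (AEA) points along the mean of the
#' environment score vectors. The ideal genotype has the largest
#' projection on the AEA among the fitted genotypes and no deviation
#' orthogonal to it (high mean performance, perfect stability);
#' genotypes are ranked by ascending Euclidean distance to that ideal
#' point in the first two components.
#'
#' @param model A two-component [fit_gge()] model.
#' @return A data frame with columns `genotype`, `projection` (onto the
#'   AEA), `stability` (signed orthogonal deviation), `distance` (to the
#'   ideal point) and `rank`, sorted by rank; attribute `ideal_point`.
#' @export
rank_ideal_genotypes <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  if (nrow(model$genotype_scores) == 1L) {
    return(structure(
      data.frame(genotype = rownames(model$genotype_scores),
                 projection = 0, stability = 0, distance = 0, rank = 1L,
                 stringsAsFactors = FALSE),
      ideal_point = c(0, 0), class = c("gge_ranking", "data.frame")))
  }
  a <- aea_axis(model)
  dec <- aea_decompose(model$genotype_scores, a)
  ideal <- max(dec$proj) * a
  dist <- sqrt(rowSums(sweep(dec$s, 2, ideal)^2))
  ord <- order(dist, rownames(dec$s))
  out <- data.frame(genotype = rownames(dec$s)[ord],
                    projection = dec$proj[ord],
                    stability = dec$orth[ord], distance = unname(dist[ord]),
                    rank = seq_len(nrow(dec$s)), stringsAsFactors = FALSE)
  structure(out, ideal_point = ideal, class = c("gge_ranking", "data.frame"))
}

#' Rank environments by distance to the ideal environment
#'
#' The ideal test environment combines maximal discriminating power along
#' the average-environment axis with perfect representativeness (no
#' orthogonal component). Environments are ranked by ascending distance
#' to that point; each environment's vector length is reported as its
#' discriminating power.
#'
#' @param model A two-component [fit_gge()] model.
#' @return A data frame with columns `environment`, `projection`,
#'   `representativeness` (signed orthogonal deviation), `vector_length`
#'   (discriminating power), `distance`, `rank`; attribute `ideal_point`.
#' @export
rank_ideal_environments <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  a <- aea_axis(model)
  dec <- aea_decompose(model$environment_scores, a)
  ideal <- max(dec$proj) * a
  dist <- sqrt(rowSums(sweep(dec$s, 2, ideal)^2))
  ord <- order(dist, rownames(dec$s))
  out <- data.frame(environment = rownames(dec$s)[ord],
                    projection = dec$proj[ord],
                    representativeness = dec$orth[ord],
                    vector_length = unname(sqrt(rowSums(dec$s^2))[ord]),
                    distance = unname(dist[ord]),
                    rank = seq_len(nrow(dec$s)), stringsAsFactors = FALSE)
  structure(out, ideal_point = ideal, class = c("gge_ranking", "data.frame"))
}

#' Which-won-where sector assignment
#'
#' For each environment, the winning genotype is the one with the
#' largest projection onto that environment's score vector (the
#' rank-two model's prediction of the centered value), the standard
#' which-won-where reading of the biplot.
#'
#' @param model A two-component [fit_gge()] model.
#' @return A data frame with columns `environment`, `winner`,
#'   `modelled_value`.
#' @export
which_won_where <- function(model) {
  stopifnot(inherits(model, "gge_model"))
  k <- min(2L, ncol(model$genotype_scores))
  g <- model$genotype_scores[, seq_len(k), drop = FALSE]
  e <- model$environment_scores[, seq_len(k), drop = FALSE]
  fitted <- g %*% t(e)
  winners <- apply(fitted, 2, which.max)
  data.frame(environment = rownames(e),
             winner = rownames(g)[winners],
             modelled_value = fitted[cbind(winners, seq_len(nrow(e)))],
             stringsAsFactors = FALSE)
}

#' Draw a GGE biplot
#'
#' Plots genotype and environment scores of the first two components on
#' one panel (base graphics): genotypes as points, environments as
#' labelled vectors from the origin, with the average-environment axis
#' drawn when it is defined.
#'
#' @param x A [fit_gge()] model.
#' @param ... Further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.gge_model <- function(x, ...) {
  pad2 <- function(s) if (ncol(s) >= 2L) s[, 1:2, drop = FALSE] else
    cbind(s[, 1, drop = FALSE], PC2 = 0)
  g <- pad2(x$genotype_scores)
  e <- pad2(x$environment_scores)
  lims <- range(c(g, e, 0)) * 1.15
  plot(g, xlim = lims, ylim = lims, pch = 19, asp = 1,
       xlab = sprintf("PC1 (%.1f%%)", x$variance_explained[1]),
       ylab = sprintf("PC2 (%.1f%%)",
                      if (length(x$variance_explained) > 1)
                        x$variance_explained[2] else 0),
       main = "GGE biplot", ...)
  graphics::text(g, labels = rownames(g), pos = 3, cex = 0.8)
  graphics::arrows(0, 0, e[, 1], e[, 2], length = 0.08, col = "blue")
  graphics::text(e, labels = rownames(e), pos = 3, cex = 0.8, col = "blue")
  axis_try <- try(aea_axis(x), silent = TRUE)
  if (!inherits(axis_try, "try-error")) {
    graphics::abline(0, axis_try[2] / axis_try[1], lty = 2, col = "grey40")
  }
  invisible(x)
}
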