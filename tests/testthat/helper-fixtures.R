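# Shared fixtures and independent oracles, all built in code.

yield_def <- function(min = 0, max = 2000) {
  trait_def("yield", "Plot yield", "numeric", unit = "kg",
            min_value = min, max_value = max, decimals = 2)
}

maize_defs <- function() {
  trait_set(
    yield_def(min = 0, max = 100),
    trait_def("plant_height", "Plant height", "numeric", unit = "m",
              min_value = 0.5, max_value = 5, decimals = 2),
    trait_def("grain_weight", "100-grain weight", "numeric", unit = "g",
              min_value = 10, max_value = 60, decimals = 2),
    trait_def("sowing_date", "Sowing date", "date", aggregation = "none"),
    trait_def("plant_type", "Plant type", "enumeration",
              allowed_values = c("compact", "semi-compact", "flat"),
              aggregation = "none")
  )
}

# Build a trait_records table from a plain data frame via file round trip,
# exercising the canonical text format.
records_from_df <- function(df, defs) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  write.csv(df, f, row.names = FALSE, quote = TRUE)
  read_records(f, defs)
}

rec_row <- function(variety, trait, value, location = "L1", replicate = 1,
                    year = 2021) {
  data.frame(variety = variety, location = location, replicate = replicate,
             year = year, trait = trait, value = value,
             stringsAsFactors = FALSE)
}

# Brute-force two-way ANOVA oracle: explicit mean-deviation sums computed
# from first principles, no model fitting.
anova_oracle <- function(d) {
  mu <- mean(d$value)
  vs <- unique(d$variety); es <- unique(d$environment)
  r <- nrow(d) / (length(vs) * length(es))
  cell <- tapply(d$value, list(d$variety, d$environment), mean)
  vm <- tapply(d$value, d$variety, mean)[vs]
  em <- tapply(d$value, d$environment, mean)[es]
  ss_v <- length(es) * r * sum((vm - mu)^2)
  ss_e <- length(vs) * r * sum((em - mu)^2)
  # interaction: sum over cells of (cell - vmean - emean + mu)^2
  ss_int <- 0
  for (v in vs) for (e in es) {
    ss_int <- ss_int + r * (cell[v, e] - vm[[v]] - em[[e]] + mu)^2
  }
  ss_res <- 0
  for (i in seq_len(nrow(d))) {
    ss_res <- ss_res + (d$value[i] - cell[d$variety[i], d$environment[i]])^2
  }
  list(variety = ss_v, environment = ss_e, interaction = ss_int,
       residual = ss_res,
       total = sum((d$value - mu)^2))
}

balanced_frame <- function(nv, ne, nr, values) {
  g <- expand.grid(replicate = seq_len(nr), environment = paste0("E", seq_len(ne)),
                   variety = paste0("V", seq_len(nv)),
                   stringsAsFactors = FALSE)
  data.frame(variety = g$variety, environment = g$environment,
             replicate = g$replicate, value = values,
             stringsAsFactors = FALSE)
}

# Step-by-step TOPSIS oracle following the weighted-ideal-distance recipe
# with plain loops; independent of the vectorized implementation.
topsis_oracle <- function(x, directions, beta) {
  m <- nrow(x); n <- ncol(x)
  y <- matrix(0, m, n)
  for (j in seq_len(n)) {
    col <- x[, j]
    if (directions[j] == "cost") col <- max(col) - col
    rng <- max(col) - min(col)
    y[, j] <- if (rng == 0) rep(1, m) else (col - min(col)) / rng
  }
  # entropy weights
  E <- numeric(n)
  for (j in seq_len(n)) {
    p <- y[, j] / sum(y[, j])
    E[j] <- -sum(ifelse(p > 0, p * log(p), 0)) / log(m)
  }
  gap <- pmax(0, 1 - E)
  alpha <- if (sum(gap) == 0) rep(1 / n, n) else gap / sum(gap)
  w <- alpha * beta / sum(alpha * beta)
  v <- y
  for (j in seq_len(n)) v[, j] <- y[, j] * w[j]
  sp <- apply(v, 2, max); sm <- apply(v, 2, min)
  dp <- dm <- numeric(m)
  for (i in seq_len(m)) {
    dp[i] <- sqrt(sum((v[i, ] - sp)^2))
    dm[i] <- sqrt(sum((v[i, ] - sm)^2))
  }
  dm / (dp + dm)
}
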