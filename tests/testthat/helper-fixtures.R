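# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default two-site field season used by several directional checks
field_dataset <- function() cached("field", simulate_field_study(seed = 301))

field_per_mille <- function() cached("field_pm", {
  normalize_per_mille(field_dataset()$table)
})

# small deterministic count matrix for io tests
tiny_counts <- function() {
  m <- matrix(c(2, 3, 0, 1, 5, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("OTU1", "OTU2", "OTU3"), c("s1", "s2")))
  otu_table(m, unit = "raw_counts")
}

# independent naive Bray-Curtis: explicit double loop over pairs
bray_curtis_oracle <- function(values) {
  n <- ncol(values)
  d <- matrix(0, n, n, dimnames = list(colnames(values), colnames(values)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(values[, i] - values[, j])) /
        sum(values[, i] + values[, j])
    }
  }
  d
}

# independent exact-test oracle: plain normalized enumeration over all splits
nb_exact_oracle <- function(counts_a, counts_b, dispersion) {
  tot <- sum(counts_a) + sum(counts_b)
  na <- length(counts_a); nb <- length(counts_b)
  # the conditional distribution is free of the mean; center it for
  # numerical stability of the enumeration
  mu <- max(tot / (na + nb), 1e-8)
  pr <- numeric(tot + 1)
  for (s in 0:tot) {
    pa <- if (dispersion == 0) stats::dpois(s, na * mu) else
      stats::dnbinom(s, size = na / dispersion, mu = na * mu)
    pb <- if (dispersion == 0) stats::dpois(tot - s, nb * mu) else
      stats::dnbinom(tot - s, size = nb / dispersion, mu = nb * mu)
    pr[s + 1] <- pa * pb
  }
  pr <- pr / sum(pr)
  p_obs <- pr[sum(counts_a) + 1]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# grid-search ML oracle for beta regression: iterative zoom over
# (b0, b1, log phi)
betareg_grid_oracle <- function(y, x, rounds = 6) {
  n <- length(y)
  if (any(y <= 0 | y >= 1)) y <- (y * (n - 1) + 0.5) / n
  ll <- function(b0, b1, lphi) {
    mu <- stats::plogis(b0 + b1 * x)
    sum(stats::dbeta(y, mu * exp(lphi), (1 - mu) * exp(lphi), log = TRUE))
  }
  ctr <- c(0, 0, log(10)); width <- c(4, 4, 4)
  for (r in seq_len(rounds)) {
    g0 <- seq(ctr[1] - width[1], ctr[1] + width[1], length.out = 13)
    g1 <- seq(ctr[2] - width[2], ctr[2] + width[2], length.out = 13)
    gp <- seq(ctr[3] - width[3], ctr[3] + width[3], length.out = 13)
    best <- -Inf
    for (a in g0) for (b in g1) for (p in gp) {
      v <- ll(a, b, p)
      if (v > best) { best <- v; ctr <- c(a, b, p) }
    }
    width <- width / 4
  }
  list(coefficients = ctr[1:2], phi = exp(ctr[3]), loglik = best)
}

# orthogonal Procrustes residual after optimal translation/rotation/reflection
procrustes_error <- function(x, y) {
  x <- scale(x, scale = FALSE); y <- scale(y, scale = FALSE)
  s <- svd(t(x) %*% y)
  rot <- s$v %*% t(s$u)
  sum((x %*% t(rot) - y)^2)
}
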