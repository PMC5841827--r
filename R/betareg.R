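#' Beta regression of a proportion on one covariate
#'
#' Maximum-likelihood fit of `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = b0 + b1 * x` and constant precision `phi`, the standard model
#' for responses confined to (0, 1) such as per-sample taxon proportions.
#' Boundary observations (exact 0 or 1) are first compressed by
#' `y' = (y * (n - 1) + 0.5) / n` (Smithson-Verkuilen); the compression is
#' applied to all observations whenever any lie on the boundary. Wald tests
#' per coefficient use standard errors from the observed information at the
#' optimum.
#'
#' @param y Proportions in `[0, 1]`, length >= 10.
#' @param x Numeric covariate of the same length.
#' @return A `betareg_fit` list: `coefficients` (intercept, slope), `phi`,
#'   `se`, `z`, `p_value`, `loglik`, `converged`, `n`.
#' @export
fit_beta_regression <- function(y, x) {
  if (length(y) != length(x)) stop("y and x lengths differ")
  n <- length(y)
  if (n < 10) stop("beta regression needs n >= 10")
  if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
  if (any(y <= 0 | y >= 1)) y <- (y * (n - 1) + 0.5) / n
  negll <- function(theta) {
    mu <- stats::plogis(theta[1] + theta[2] * x)
    phi <- exp(theta[3])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  # moment-based starting values on the logit scale
  lf <- stats::lm.fit(cbind(1, x), stats::qlogis(pmin(pmax(y, 1e-6), 1 - 1e-6)))
  mu0 <- mean(y)
  phi0 <- max(mu0 * (1 - mu0) / max(stats::var(y), 1e-8) - 1, 1)
  opt <- stats::optim(c(lf$coefficients, log(phi0)), negll, method = "BFGS",
                      hessian = TRUE, control = list(maxit = 500))
  converged <- opt$convergence == 0
  if (!converged) warning("beta regression did not converge")
  se <- rep(NA_real_, 2)
  h <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(h, "try-error") && all(diag(h)[1:2] > 0)) {
    se <- sqrt(diag(h)[1:2])
  }
  coefs <- opt$par[1:2]
  names(coefs) <- names(se) <- c("intercept", "slope")
  z <- coefs / se
  structure(list(coefficients = coefs, phi = exp(opt$par[3]), se = se, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)), loglik = -opt$value,
                 converged = converged, n = n),
            class = "betareg_fit")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat(sprintf("beta regression (n = %d, phi = %.2f, %s)\n", x$n, x$phi,
              if (x$converged) "converged" else "NOT converged"))
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                   p = x$p_value))
  invisible(x)
}

# fit one taxon's proportion trend; returns a one-row summary or NULL when
# the taxon is absent everywhere
.taxon_trend <- function(abund_pm, covar) {
  if (all(abund_pm == 0)) return(NULL)
  fit <- fit_beta_regression(abund_pm / 1000, covar)
  data.frame(estimate = unname(fit$coefficients["slope"]),
             se = unname(fit$se["slope"]), z = unname(fit$z["slope"]),
             p_value = unname(fit$p_value["slope"]),
             converged = fit$converged, stringsAsFactors = FALSE)
}

#' Spatial trends of taxon proportions across root compartments
#'
#' Fits, per taxon, a beta regression of the per-mille proportion on the
#' compartment position code (bulk soil 0, rhizosphere 1, rhizoplane 2,
#' endosphere 3); a positive slope marks root-enriched taxa. Significance is
#' Bonferroni-adjusted across the taxa tested in the call.
#'
#' @param phyla An `otu_table` keyed by taxon (per-mille), e.g. from
#'   [aggregate_taxonomy()].
#' @param metadata Metadata with `sample_id` and `position`.
#' @param alpha Family-wise significance level.
#' @return Data frame: taxon, slope estimate, se, z, p_value, p_adjusted,
#'   significant.
#' @export
spatial_phylum_trends <- function(phyla, metadata, alpha = 0.05) {
  md <- metadata[match(sample_ids(phyla), metadata$sample_id), ]
  if (length(unique(md$position)) < 2) stop("samples must span >= 2 positions")
  .trend_table(phyla, md$position, alpha)
}

#' Temporal trends of taxon proportions within each compartment
#'
#' Per compartment, fits a beta regression of each taxon's proportion on
#' plant age in days.
#'
#' @inheritParams spatial_phylum_trends
#' @return Data frame with a `compartment` column prepended.
#' @export
temporal_phylum_trends <- function(phyla, metadata, alpha = 0.05) {
  md <- metadata[match(sample_ids(phyla), metadata$sample_id), ]
  out <- lapply(unique(md$compartment), function(cp) {
    sel <- md$compartment == cp
    sub <- phyla
    sub$values <- phyla$values[, sel, drop = FALSE]
    tt <- .trend_table(sub, md$age_days[sel], alpha)
    if (nrow(tt)) cbind(compartment = cp, tt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.trend_table <- function(tab, covar, alpha) {
  rows <- list()
  for (taxon in otu_ids(tab)) {
    tr <- .taxon_trend(tab$values[taxon, ], covar)
    if (is.null(tr)) {
      message("taxon absent everywhere, skipped: ", taxon)
      next
    }
    rows[[taxon]] <- cbind(taxon = taxon, tr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  m <- nrow(out)
  out$p_adjusted <- pmin(out$p_value * m, 1)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Classify OTUs as early, late, or complex colonizers
#'
#' Ordinary least-squares slope of per-mille abundance on plant age per OTU,
#' two-sided t-test on the slope, Bonferroni correction across the supplied
#' OTU set. OTUs with a significantly negative slope are early colonizers,
#' significantly positive are late, and everything else (including
#' constant-abundance OTUs) is complex.
#'
#' @param table An `otu_table`, per-mille.
#' @param metadata Metadata with `sample_id` and `age_days`.
#' @param otus OTU ids to classify (default: all in the table).
#' @param alpha Family-wise level.
#' @return A `colonizer_calls` data frame: otu_id, slope, p_value,
#'   p_adjusted, class.
#' @export
classify_colonizers <- function(table, metadata, otus = NULL, alpha = 0.05) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(otus)) otus <- otu_ids(table)
  miss <- setdiff(otus, otu_ids(table))
  if (length(miss)) stop("OTUs absent from table: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  age <- metadata$age_days[match(sample_ids(table), metadata$sample_id)]
  if (length(unique(age)) < 3) stop("need >= 3 distinct ages")
  slope <- p <- numeric(length(otus))
  for (i in seq_along(otus)) {
    y <- table$values[otus[i], ]
    if (stats::var(y) == 0) {
      slope[i] <- 0; p[i] <- 1
      next
    }
    fit <- stats::lm(y ~ age)
    cf <- summary(fit)$coefficients
    slope[i] <- cf["age", "Estimate"]
    p[i] <- cf["age", "Pr(>|t|)"]
  }
  p_adj <- pmin(p * length(otus), 1)
  cls <- ifelse(p_adj < alpha & slope < 0, "early",
                ifelse(p_adj < alpha & slope > 0, "late", "complex"))
  out <- data.frame(otu_id = otus, slope = slope, p_value = p,
                    p_adjusted = p_adj, class = cls, stringsAsFactors = FALSE)
  class(out) <- c("colonizer_calls", class(out))
  out
}
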