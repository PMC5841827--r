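#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` over OTUs, in `[0, 1]`.
#'
#' @param x An `otu_table` (typically per-mille) or a numeric matrix with
#'   OTUs as rows and samples as columns (e.g. log2-transformed abundances).
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_table")) x$values else x
  if (!is.matrix(m)) stop("expected an otu_table or a matrix")
  if (ncol(m) < 2) stop("need at least two samples")
  tot <- colSums(m)
  if (any(tot <= 0)) {
    stop("zero-total sample(s): ", paste(colnames(m)[tot <= 0], collapse = ", "))
  }
  vegan::vegdist(t(m), method = "bray")
}

#' Log2-transform per-mille abundances
#'
#' `log2(abundance + pseudocount)` on the per-mille scale; the default
#' pseudocount of 1 per-mille makes zeros map to zero.
#'
#' @param table An `otu_table` with unit `per_mille`.
#' @param pseudocount Added before the log; default 1.
#' @return Numeric matrix, OTUs x samples.
#' @export
log2_per_mille <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "otu_table"))
  if (table$unit != "per_mille") stop("expected a per_mille table")
  log2(table$values + pseudocount)
}

#' Shannon diversity per sample
#'
#' `H = -sum p_i log p_i` over the within-sample relative abundances (natural
#' log, zero terms skipped).
#'
#' @param table An `otu_table`.
#' @return Named numeric vector of diversities.
#' @export
shannon <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (any(colSums(table$values) <= 0)) stop("zero-total sample")
  vegan::diversity(t(table$values), index = "shannon")
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-d^2/2` with the Gower operator and eigendecomposes.
#' Coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues; negative eigenvalues are reported but not embedded, and the
#' proportion explained uses the sum of positive eigenvalues as denominator.
#'
#' @param dist A `dist` object or symmetric matrix of dissimilarities.
#' @return A `pcoa_result` list: `coordinates` (samples x axes, columns
#'   `PCo1`, ...), `eigenvalues` (positive, descending),
#'   `proportion_explained`, `negative_eigenvalues`.
#' @export
pcoa <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least three samples")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                    nrow = sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values[pos],
                 proportion_explained = e$values[pos] / sum(e$values[pos]),
                 negative_eigenvalues = e$values[e$values < -tol]),
            class = "pcoa_result")
}

#' PERMANOVA variance partitioning of a dissimilarity matrix
#'
#' Sequential (type-I) partitioning of the distance-based total sum of
#' squares over the given terms, with pseudo-F significance assessed by
#' unrestricted row permutation (`vegan::adonis2`, `by = "terms"`). P-values
#' follow `(count of permuted F >= observed + 1) / (n_perm + 1)`.
#'
#' @param dist A `dist` of dissimilarities labelled by sample id.
#' @param metadata Data frame with a `sample_id` column covering the samples.
#' @param terms Character vector of metadata columns, in partitioning order.
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutations.
#' @return A `permanova_result` data frame: term, df, sum_of_squares, r2,
#'   pseudo_f, p_value (plus Residual and Total rows).
#' @export
permanova <- function(dist, metadata, terms, n_perm = 999, seed = NULL) {
  ids <- labels(dist)
  idx <- match(ids, metadata$sample_id)
  if (anyNA(idx)) stop("metadata missing sample(s): ",
                       paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  df <- metadata[idx, , drop = FALSE]
  miss <- setdiff(terms, colnames(df))
  if (length(miss)) stop("term(s) missing from metadata: ",
                         paste(miss, collapse = ", "))
  for (tm in terms) {
    if (length(unique(df[[tm]])) < 2) stop("term has fewer than two levels: ", tm)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  fml <- stats::as.formula(paste("dist ~", paste(terms, collapse = " + ")))
  fit <- vegan::adonis2(fml, data = df, permutations = n_perm, by = "terms")
  out <- data.frame(term = rownames(fit), df = fit$Df,
                    sum_of_squares = fit$SumOfSqs, r2 = fit$R2,
                    pseudo_f = fit$F, p_value = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("permanova_result", class(out))
  out
}

#' Time-point similarity z-score matrix for one compartment
#'
#' For each pair of time points, the mean similarity `(1 - Bray-Curtis)` over
#' cross-time-point sample pairs is computed and then z-scored against the
#' mean and sd of all unique cells of that compartment's matrix, so the grand
#' mean of the z-values is zero. Within-time-point cells use distinct-sample
#' pairs only.
#'
#' @param dist A `dist` over all samples.
#' @param metadata Metadata with `sample_id`, `compartment`, `age_days`.
#' @param compartment Which compartment to summarize.
#' @return A `similarity_z` list: `timepoints` and the symmetric `z` matrix.
#' @export
timepoint_similarity_z <- function(dist, metadata, compartment) {
  md <- metadata[metadata$compartment == compartment, , drop = FALSE]
  tps <- sort(unique(md$age_days))
  if (length(tps) < 2) stop("need >= 2 timepoints in compartment ", compartment)
  m <- as.matrix(dist)
  ids <- rownames(m)
  sim <- 1 - m
  cell <- matrix(NA_real_, length(tps), length(tps),
                 dimnames = list(tps, tps))
  for (i in seq_along(tps)) {
    for (j in i:length(tps)) {
      si <- intersect(ids, md$sample_id[md$age_days == tps[i]])
      sj <- intersect(ids, md$sample_id[md$age_days == tps[j]])
      block <- sim[si, sj, drop = FALSE]
      if (i == j) {
        vals <- block[upper.tri(block)]
      } else {
        vals <- as.vector(block)
      }
      if (length(vals)) cell[i, j] <- cell[j, i] <- mean(vals)
    }
  }
  uniq <- cell[upper.tri(cell, diag = TRUE)]
  s <- stats::sd(uniq, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- 1  # degenerate: all similarities equal
  z <- (cell - mean(uniq, na.rm = TRUE)) / s
  structure(list(timepoints = tps, z = z), class = "similarity_z")
}
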