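#' Stratified half split of samples into training and test sets
#'
#' Half of the samples from each time point x compartment stratum (the
#' ceiling when a stratum is odd) are drawn into the training set,
#' reproducibly under the seed.
#'
#' @param metadata Sample metadata with `sample_id`, `compartment`,
#'   `age_days`.
#' @param compartments Compartments to include (default rhizosphere and
#'   endosphere, the two modeled rhizocompartments).
#' @param seed RNG seed.
#' @return A `split_plan` list: `train`, `test` (sample ids), `strata`, `seed`.
#' @export
split_train_test <- function(metadata,
                             compartments = c("rhizosphere", "endosphere"),
                             seed = 1L) {
  md <- metadata[metadata$compartment %in% compartments, , drop = FALSE]
  if (!nrow(md)) stop("no samples in the requested compartments")
  strata <- interaction(md$age_days, md$compartment, drop = TRUE)
  set.seed(as.integer(seed))
  train <- character(0)
  for (s in levels(strata)) {
    ids <- md$sample_id[strata == s]
    if (!length(ids)) stop("empty stratum: ", s)
    train <- c(train, sample(ids, ceiling(length(ids) / 2)))
  }
  structure(list(train = sort(train), test = sort(setdiff(md$sample_id, train)),
                 strata = strata, seed = as.integer(seed)),
            class = "split_plan")
}

.resp_vector <- function(metadata, ids, response) {
  v <- metadata[[response]][match(ids, metadata$sample_id)]
  if (anyNA(v)) stop("missing ", response, " for some samples")
  v
}

#' Fit a full random-forest model and rank OTUs by permutation importance
#'
#' Regresses the response (plant age in days or developmental stage) on the
#' per-mille abundances of all OTUs over the training samples of the split.
#' Importance is the unscaled mean increase in out-of-bag squared prediction
#' error when an OTU's abundances are permuted; ties are broken by otu_id so
#' the ranking is deterministic.
#'
#' @param table Per-mille `otu_table`.
#' @param metadata Sample metadata.
#' @param response `"age_days"` or `"dev_stage"`.
#' @param split A `split_plan`; only its training samples are used.
#' @param n_trees Trees in the forest.
#' @param seed RNG seed.
#' @return List: `forest` (a `randomForest` object), `importance` (data frame
#'   otu_id, importance, rank), `oob_variance_explained`, `response`,
#'   `train`.
#' @export
fit_full_forest <- function(table, metadata, response = "age_days", split,
                            n_trees = 500, seed = 1L) {
  stopifnot(inherits(split, "split_plan"))
  train <- intersect(split$train, sample_ids(table))
  if (length(train) < 20) stop("need >= 20 training samples")
  y <- .resp_vector(metadata, train, response)
  if (stats::var(y) == 0) stop("constant response")
  x <- t(table$values[, train, drop = FALSE])
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   importance = TRUE, keep.forest = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  ord <- order(-imp, names(imp))
  ranking <- data.frame(otu_id = names(imp)[ord], importance = unname(imp[ord]),
                        rank = seq_along(imp), stringsAsFactors = FALSE)
  list(forest = rf, importance = ranking,
       oob_variance_explained = rf$rsq[n_trees], response = response,
       train = train)
}

#' Cross-validated feature elimination over an importance ranking
#'
#' Evaluates k-fold cross-validated mean squared error while successively
#' halving the number of retained OTUs (p, p/2, p/4, ..., 1), refitting a
#' forest within each training fold using only the top-ranked OTUs. The
#' selected subset size is the smallest whose CV error is within 5% of the
#' minimum, unless a fixed size (such as the 85-OTU age or 54-OTU stage
#' models) is imposed.
#'
#' @param table Per-mille `otu_table`.
#' @param metadata Sample metadata.
#' @param response Response column name.
#' @param ranking Importance data frame from [fit_full_forest()].
#' @param split A `split_plan`; CV runs over its training samples.
#' @param k Number of folds.
#' @param sizes Optional explicit subset sizes (descending); default halving.
#' @param n_trees Trees per CV forest (smaller than the final fit for speed).
#' @param fixed_size If non-NULL, forces the selection to this size.
#' @param seed RNG seed.
#' @return A `cv_curve` list: `subset_sizes`, `cv_error`, `k`, `selection`.
#' @export
cv_feature_elimination <- function(table, metadata, response, ranking, split,
                                   k = 10, sizes = NULL, n_trees = 100,
                                   fixed_size = NULL, seed = 1L) {
  train <- intersect(split$train, sample_ids(table))
  if (k > length(train)) stop("k exceeds the number of training samples")
  p <- nrow(ranking)
  if (p < 2) stop("need at least two features")
  if (is.null(sizes)) {
    sizes <- p
    while (sizes[length(sizes)] > 1) {
      sizes <- c(sizes, floor(sizes[length(sizes)] / 2))
    }
  }
  if (any(diff(sizes) >= 0)) stop("sizes must be strictly decreasing")
  y <- .resp_vector(metadata, train, response)
  x <- t(table$values[ranking$otu_id, train, drop = FALSE])
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), length(train)))
  err <- matrix(NA_real_, k, length(sizes))
  for (f in seq_len(k)) {
    tr <- fold != f
    for (s in seq_along(sizes)) {
      cols <- seq_len(sizes[s])
      rf <- randomForest::randomForest(x = x[tr, cols, drop = FALSE],
                                       y = y[tr], ntree = n_trees)
      pred <- stats::predict(rf, x[!tr, cols, drop = FALSE])
      err[f, s] <- mean((pred - y[!tr])^2)
    }
  }
  cv_error <- colMeans(err)
  selection <- if (!is.null(fixed_size)) {
    as.integer(fixed_size)
  } else {
    min(sizes[cv_error <= 1.05 * min(cv_error)])
  }
  structure(list(subset_sizes = sizes, cv_error = cv_error, k = k,
                 selection = selection),
            class = "cv_curve")
}

#' Fit a sparse maturity model on a selected OTU set
#'
#' Refits the forest on only the selected OTUs (no further
#' parameterization), recording training provenance.
#'
#' @param table Per-mille `otu_table`.
#' @param metadata Sample metadata.
#' @param response `"age_days"` or `"dev_stage"`.
#' @param otus Selected OTU ids; must all be present in the table.
#' @param split A `split_plan` (training samples are used).
#' @param compartment Optional label recorded on the model.
#' @param n_trees Trees in the forest.
#' @param seed RNG seed.
#' @return A `maturity_model` list: `response`, `compartment`, `otus`,
#'   `forest`, `training` (ids, sites, seasons), `oob_variance_explained`.
#' @export
fit_sparse_model <- function(table, metadata, response, otus, split,
                             compartment = NULL, n_trees = 500, seed = 1L) {
  if (!length(otus)) stop("selected OTU set is empty")
  miss <- setdiff(otus, otu_ids(table))
  if (length(miss)) stop("selected OTU(s) absent from table: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  train <- intersect(split$train, sample_ids(table))
  y <- .resp_vector(metadata, train, response)
  x <- t(table$values[otus, train, drop = FALSE])
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   keep.forest = TRUE)
  md <- metadata[match(train, metadata$sample_id), ]
  structure(list(response = response, compartment = compartment, otus = otus,
                 forest = rf,
                 training = list(sample_ids = train,
                                 sites = unique(md$site),
                                 seasons = unique(md$season)),
                 oob_variance_explained = rf$rsq[n_trees]),
            class = "maturity_model")
}

#' Predict microbiota maturity for new samples
#'
#' Applies a sparse maturity model to a per-mille table. Model OTUs missing
#' from the table are imputed as absent (0 per-mille) with a warning listing
#' them; if more than half the model's OTUs are missing the model is deemed
#' non-transferable and an error is raised.
#'
#' @param model A `maturity_model`.
#' @param table Per-mille `otu_table`.
#' @param metadata Optional metadata supplying the actual response for
#'   residuals.
#' @return Data frame: sample_id, predicted, actual, residual
#'   (predicted - actual).
#' @export
predict_maturity <- function(model, table, metadata = NULL) {
  stopifnot(inherits(model, "maturity_model"))
  if (table$unit != "per_mille") stop("expected a per_mille table")
  present <- intersect(model$otus, otu_ids(table))
  missing <- setdiff(model$otus, present)
  if (length(missing) > 0.5 * length(model$otus)) {
    stop(sprintf("model not transferable: %d of %d model OTUs missing",
                 length(missing), length(model$otus)))
  }
  if (length(missing)) {
    warning("imputing 0 per-mille for missing model OTU(s): ",
            paste(missing, collapse = ", "))
  }
  x <- matrix(0, ncol(table$values), length(model$otus),
              dimnames = list(sample_ids(table), model$otus))
  x[, present] <- t(table$values[present, , drop = FALSE])
  pred <- stats::predict(model$forest, x)
  actual <- if (!is.null(metadata) && model$response %in% colnames(metadata)) {
    metadata[[model$response]][match(rownames(x), metadata$sample_id)]
  } else NA_real_
  data.frame(sample_id = rownames(x), predicted = unname(pred),
             actual = actual, residual = unname(pred) - actual,
             stringsAsFactors = FALSE)
}

#' ANOVA and Tukey contrasts of maturity predictions
#'
#' Sequential ANOVA of the predicted value on the supplied factors, followed
#' by Tukey honest-significant-difference pairwise contrasts.
#'
#' @param predictions Data frame from [predict_maturity()].
#' @param metadata Metadata with the factor columns.
#' @param factors Ordered character vector of factor names.
#' @return List: `anova` (data frame with term, df, sum_sq, f, p_value) and
#'   `tukey` (named list of pairwise contrast data frames).
#' @export
maturity_contrast <- function(predictions, metadata, factors) {
  df <- merge(predictions, metadata, by = "sample_id")
  for (f in factors) {
    if (!f %in% colnames(df)) stop("factor missing from metadata: ", f)
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2) stop("factor has fewer than two levels: ", f)
  }
  fml <- stats::as.formula(paste("predicted ~", paste(factors, collapse = " + ")))
  fit <- stats::aov(fml, data = df)
  sm <- summary(fit)[[1]]
  an <- data.frame(term = trimws(rownames(sm)), df = sm$Df,
                   sum_sq = sm$`Sum Sq`, f = sm$`F value`,
                   p_value = sm$`Pr(>F)`, stringsAsFactors = FALSE)
  tk <- lapply(stats::TukeyHSD(fit), function(m) {
    data.frame(contrast = rownames(m), diff = m[, "diff"],
               lwr = m[, "lwr"], upr = m[, "upr"],
               p_adjusted = m[, "p adj"], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  list(anova = an, tukey = tk)
}

#' Total per-mille abundance of marker OTUs per colonizer class
#'
#' Sums, per sample, the per-mille abundances of the OTUs assigned to each
#' colonizer class (early / late / complex) — the aggregate trajectories
#' whose early-to-late dominance switch marks microbiota maturation.
#'
#' @param table Per-mille `otu_table`.
#' @param calls A `colonizer_calls` data frame (columns `otu_id`, `class`).
#' @return Data frame: sample_id, early, late, complex (per-mille totals).
#' @export
aggregate_marker_abundance <- function(table, calls) {
  if (!nrow(calls)) stop("no colonizer calls supplied")
  out <- data.frame(sample_id = sample_ids(table), stringsAsFactors = FALSE)
  for (cls in c("early", "late", "complex")) {
    ids <- intersect(calls$otu_id[calls$class == cls], otu_ids(table))
    out[[cls]] <- if (length(ids)) {
      colSums(table$values[ids, , drop = FALSE])
    } else 0
  }
  out
}
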