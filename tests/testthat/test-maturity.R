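.split_md <- function(n_per = 4, tps = c(7, 14, 21),
                      comps = c("rhizosphere", "endosphere")) {
  g <- expand.grid(rep = seq_len(n_per), age_days = tps, compartment = comps,
                   stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("s%03d", seq_len(nrow(g))),
             compartment = g$compartment, age_days = g$age_days)
}

test_that("train/test split halves every time point by compartment stratum", {
  md <- .split_md(4)
  sp <- split_train_test(md, seed = 5)
  expect_length(intersect(sp$train, sp$test), 0)
  for (tp in unique(md$age_days)) for (cp in unique(md$compartment)) {
    ids <- md$sample_id[md$age_days == tp & md$compartment == cp]
    expect_equal(sum(ids %in% sp$train), 2)
  }

  md3 <- .split_md(3)
  sp3 <- split_train_test(md3, seed = 5)
  for (tp in unique(md3$age_days)) for (cp in unique(md3$compartment)) {
    ids <- md3$sample_id[md3$age_days == tp & md3$compartment == cp]
    expect_equal(sum(ids %in% sp3$train), 2)  # ceil(3/2)
  }

  expect_identical(split_train_test(md, seed = 9), split_train_test(md, seed = 9))
  expect_error(split_train_test(md, compartments = "bulk_soil"), "no samples")
})

.planted_rf_data <- function(seed = 11, n_noise = 200, n_samp = 60) {
  set.seed(seed)
  age <- rep(seq(7, 140, length.out = 10), length.out = n_samp)
  noise <- matrix(rpois(n_noise * n_samp, 20), n_noise, n_samp)
  signal <- matrix(5 + 2 * age + rnorm(n_samp, 0, 5), 1, n_samp)
  m <- rbind(signal, noise)
  dimnames(m) <- list(c("signal", sprintf("noise%03d", seq_len(n_noise))),
                      sprintf("s%03d", seq_len(n_samp)))
  md <- data.frame(sample_id = colnames(m),
                   compartment = "endosphere", age_days = age)
  tab <- structure(list(values = m, unit = "per_mille"), class = "otu_table")
  list(tab = tab, md = md)
}

test_that("the full forest finds a planted age-tracking OTU among noise", {
  d <- .planted_rf_data()
  sp <- split_train_test(d$md, compartments = "endosphere", seed = 1)
  fit <- fit_full_forest(d$tab, d$md, "age_days", sp, n_trees = 300, seed = 2)
  expect_lte(fit$importance$rank[fit$importance$otu_id == "signal"], 5)
  expect_gt(fit$oob_variance_explained, 0.5)

  # out-of-bag predictions beat a constant predictor
  tr_pred <- predict(fit$forest)
  y <- d$md$age_days[match(fit$train, d$md$sample_id)]
  expect_lt(mean((tr_pred - y)^2), var(y))

  md_const <- d$md; md_const$age_days <- 50
  expect_error(fit_full_forest(d$tab, md_const, "age_days", sp, 100, 1),
               "constant response")
})

test_that("a shuffled response yields near-zero out-of-bag variance explained", {
  d <- .planted_rf_data(n_noise = 80)
  sp <- split_train_test(d$md, compartments = "endosphere", seed = 1)
  low <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    md_null <- d$md
    set.seed(s)
    md_null$age_days <- sample(md_null$age_days)
    fit <- fit_full_forest(d$tab, md_null, "age_days", sp,
                           n_trees = 150, seed = s)
    low <- low + (fit$oob_variance_explained <= 0.1)
  }
  expect_gte(low / n_seeds, 0.9)
})

test_that("cross-validated elimination halves sizes and honors fixed overrides", {
  d <- .planted_rf_data(n_noise = 499)  # p = 500
  sp <- split_train_test(d$md, compartments = "endosphere", seed = 3)
  fit <- fit_full_forest(d$tab, d$md, "age_days", sp, n_trees = 100, seed = 4)
  cv <- cv_feature_elimination(d$tab, d$md, "age_days", fit$importance, sp,
                               k = 5, n_trees = 30, seed = 5)
  expect_identical(cv$subset_sizes, c(500, 250, 125, 62, 31, 15, 7, 3, 1))
  expect_true(cv$selection %in% cv$subset_sizes)

  cv85 <- cv_feature_elimination(d$tab, d$md, "age_days", fit$importance, sp,
                                 k = 5, sizes = c(10, 5, 1), n_trees = 30,
                                 fixed_size = 85, seed = 5)
  expect_identical(cv85$selection, 85L)

  expect_error(cv_feature_elimination(d$tab, d$md, "age_days", fit$importance,
                                      sp, k = 1000, seed = 1), "k exceeds")
})

test_that("sparse models store their OTUs, refit deterministically, and guard inputs", {
  d <- .planted_rf_data()
  sp <- split_train_test(d$md, compartments = "endosphere", seed = 3)
  otus <- c("signal", "noise001", "noise002")
  m1 <- fit_sparse_model(d$tab, d$md, "age_days", otus, sp, n_trees = 100,
                         seed = 9)
  m2 <- fit_sparse_model(d$tab, d$md, "age_days", otus, sp, n_trees = 100,
                         seed = 9)
  expect_identical(m1$otus, otus)
  p1 <- predict_maturity(m1, d$tab)
  p2 <- predict_maturity(m2, d$tab)
  expect_identical(p1$predicted, p2$predicted)

  expect_error(fit_sparse_model(d$tab, d$md, "age_days", c("signal", "ghost"),
                                sp), "absent")
  expect_error(fit_sparse_model(d$tab, d$md, "age_days", character(0), sp),
               "empty")
})

test_that("prediction imputes missing model OTUs as absent and errors past half", {
  d <- .planted_rf_data()
  sp <- split_train_test(d$md, compartments = "endosphere", seed = 3)
  otus <- c("signal", "noise001", "noise002", "noise003")
  model <- fit_sparse_model(d$tab, d$md, "age_days", otus, sp, n_trees = 100,
                            seed = 9)

  drop1 <- d$tab
  drop1$values <- drop1$values[setdiff(rownames(drop1$values), "noise003"), ]
  expect_warning(p <- predict_maturity(model, drop1, d$md), "noise003")
  expect_equal(nrow(p), ncol(drop1$values))
  expect_equal(p$residual, p$predicted - p$actual)

  drop3 <- d$tab
  drop3$values <- drop3$values[setdiff(rownames(drop3$values),
                                       c("noise001", "noise002", "noise003")), ]
  expect_error(predict_maturity(model, drop3), "not transferable")

  # zeroed features collapse to the forest baseline: identical predictions
  zero <- d$tab
  zero$values[otus, ] <- 0
  pz <- suppressWarnings(predict_maturity(model, zero))
  expect_lt(diff(range(pz$predicted)), 1e-9)
})

test_that("maturity contrasts run sequential ANOVA with calibrated null F", {
  set.seed(31)
  f_vals <- replicate(30, {
    preds <- data.frame(sample_id = sprintf("s%02d", 1:20),
                        predicted = rnorm(20))
    md <- data.frame(sample_id = preds$sample_id,
                     treatment = rep(c("a", "b"), each = 10))
    ctr <- maturity_contrast(preds, md, "treatment")
    ctr$anova$f[1]
  })
  expect_gt(mean(f_vals), 0.5)
  expect_lt(mean(f_vals), 2)

  preds <- data.frame(sample_id = sprintf("s%02d", 1:20), predicted = rnorm(20))
  md1 <- data.frame(sample_id = preds$sample_id, treatment = "a")
  expect_error(maturity_contrast(preds, md1, "treatment"), "two levels")
})

test_that("marker-class aggregation sums per-mille abundance within classes", {
  pm <- field_per_mille()
  ds <- field_dataset()
  calls <- data.frame(otu_id = ds$truth$otu_id, class = ds$truth$archetype)
  agg <- aggregate_marker_abundance(pm, calls)
  expect_true(all(agg$early + agg$late + agg$complex <= 1000 + 1e-9))
  ids <- calls$otu_id[calls$class == "early"]
  expect_equal(agg$early, unname(colSums(pm$values[ids, ])))
  expect_error(aggregate_marker_abundance(pm, calls[0, ]), "no colonizer")
})
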