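test_that("design manifests enumerate the full factorial and stage the genotypes", {
  des <- simulation_design(sites = "A", timepoints_days = c(7, 70, 140),
                           replicates = 2, genotypes = c(g1 = 1.15), seed = 1)
  md <- build_design(des)
  expect_equal(nrow(md), 1 * 4 * 3 * 1 * 2)
  expect_true(all(md$dev_stage >= 1 & md$dev_stage <= 27))
  expect_identical(md$position, compartment_position(md$compartment))

  # doubling the rate can only bring panicle initiation forward
  ages <- 1:140
  first18 <- function(rate) min(ages[stage_at_age(ages, rate) >= 18])
  expect_lte(first18(2.0), first18(1.0))

  expect_error(simulation_design(sites = character(0)), "non-empty")
  expect_error(simulation_design(genotypes = c(g = -1)), "positive")
})

test_that("latent dynamics encode archetypes, site restriction, and developmental time", {
  truth <- make_otu_truth(n_otus = 40, sites = c("A", "B"), seed = 5)
  des <- simulation_design(sites = c("A", "B"), timepoints_days = c(7, 56, 140),
                           replicates = 1, genotypes = c(g = 1.0), seed = 5)
  md <- build_design(des)
  lat <- simulate_dynamics(truth, md, rates = c(g = 1.0))
  expect_true(all(abs(colSums(lat) - 1) < 1e-9))

  late <- truth$otu_id[truth$archetype == "late" & is.na(truth$site_specific_to)][1]
  for (cp in unique(md$compartment)) {
    j7 <- md$sample_id[md$compartment == cp & md$age_days == 7 & md$site == "A"]
    j140 <- md$sample_id[md$compartment == cp & md$age_days == 140 & md$site == "A"]
    expect_gt(lat[late, j140], lat[late, j7])
  }

  ss <- truth[!is.na(truth$site_specific_to), ][1, ]
  other <- setdiff(c("A", "B"), ss$site_specific_to)
  expect_true(all(lat[ss$otu_id, md$sample_id[md$site == other]] == 0))
  expect_true(any(lat[ss$otu_id, md$sample_id[md$site == ss$site_specific_to]] > 0))

  # faster development means more late-colonizer share at the same age
  md2 <- build_design(simulation_design(sites = "A", timepoints_days = 56,
                                        replicates = 1,
                                        genotypes = c(fast = 1.0, slow = 0.7),
                                        seed = 5))
  lat2 <- simulate_dynamics(truth, md2, rates = c(fast = 1.0, slow = 0.7))
  late_ids <- truth$otu_id[truth$archetype == "late"]
  endo <- md2$compartment == "endosphere"
  fast_share <- sum(lat2[late_ids, md2$sample_id[endo & md2$genotype == "fast"]])
  slow_share <- sum(lat2[late_ids, md2$sample_id[endo & md2$genotype == "slow"]])
  expect_gt(fast_share, slow_share)
})

test_that("noiseless latent slopes recover every monotone archetype", {
  truth <- make_otu_truth(n_otus = 60, sites = "A",
                          frac_early_site_specific = 0,
                          frac_static_site_specific = 0, seed = 9)
  des <- simulation_design(sites = "A", compartments = "endosphere",
                           replicates = 1, genotypes = c(g = 1.15), seed = 9)
  md <- build_design(des)
  lat <- simulate_dynamics(truth, md, rates = c(g = 1.15))
  slopes <- apply(lat, 1, function(y) coef(lm(y ~ md$age_days))[2])
  expect_true(all(slopes[truth$archetype == "early"] < 0))
  expect_true(all(slopes[truth$archetype == "late"] > 0))
})

test_that("a planted positive compartment gradient is monotone across positions", {
  truth <- make_otu_truth(n_otus = 20, sites = "A", p_early = 0, p_late = 0,
                          p_complex = 0, frac_static_site_specific = 0,
                          affinity_sd = 0, seed = 3)
  truth$affinity_slope[1] <- 1.2
  md <- build_design(simulation_design(sites = "A", timepoints_days = 56,
                                       replicates = 1, genotypes = c(g = 1),
                                       seed = 3))
  lat <- simulate_dynamics(truth, md, rates = c(g = 1))
  shares <- lat[1, md$sample_id[order(md$position)]]
  expect_true(all(diff(shares) > 0))
})

test_that("drought perturbation shifts early/late classes in the endosphere only", {
  truth <- make_otu_truth(n_otus = 50, sites = "A", seed = 4)
  des <- simulation_design(sites = "A", timepoints_days = 49, replicates = 2,
                           genotypes = c(g = 1.15), drought_arms = TRUE,
                           seed = 4)
  md <- build_design(des)
  lat <- simulate_dynamics(truth, md, rates = c(g = 1.15))

  expect_identical(apply_drought_perturbation(lat, md, truth, severity = 0),
                   lat)

  pert <- apply_drought_perturbation(lat, md, truth, severity = 1.5)
  early <- truth$otu_id[truth$archetype == "early"]
  pick <- function(l, cp, tr) {
    ids <- md$sample_id[md$compartment == cp & md$treatment == tr]
    mean(colSums(l[early, ids, drop = FALSE]))
  }
  expect_gt(pick(pert, "endosphere", "drought"),
            pick(pert, "endosphere", "well_watered"))
  bulk_ids <- md$sample_id[md$compartment == "bulk_soil"]
  expect_identical(pert[, bulk_ids], lat[, bulk_ids])
  rhizo_ids <- md$sample_id[md$compartment == "rhizosphere"]
  expect_identical(pert[, rhizo_ids], lat[, rhizo_ids])

  md_bad <- md; md_bad$treatment[1] <- "flood"
  expect_error(apply_drought_perturbation(lat, md_bad, truth, 1), "flood")
})

test_that("count sampling conserves depth, is seed-deterministic, and tightens with concentration", {
  truth <- make_otu_truth(n_otus = 30, sites = "A",
                          frac_early_site_specific = 0,
                          frac_static_site_specific = 0, seed = 6)
  md <- build_design(simulation_design(sites = "A", compartments = "endosphere",
                                       timepoints_days = 56, replicates = 30,
                                       genotypes = c(g = 1), seed = 6))
  lat <- simulate_dynamics(truth, md, rates = c(g = 1))

  t1 <- sample_counts(lat, mean_depth = 1000, seed = 11)
  t2 <- sample_counts(lat, mean_depth = 1000, seed = 11)
  expect_identical(t1$values, t2$values)
  expect_true(all(colSums(t1$values) >= 100))

  # huge concentration: mean sampled proportions converge to the latent
  tight <- sample_counts(lat, mean_depth = 50000,
                         dirichlet_concentration = 1e7, seed = 12)
  props <- rowMeans(sweep(tight$values, 2, colSums(tight$values), "/"))
  expect_lt(max(abs(props - lat[, 1])), 0.01)
  loose <- sample_counts(lat, mean_depth = 50000,
                         dirichlet_concentration = 20, seed = 12)
  dev_tight <- mean(abs(sweep(tight$values, 2, colSums(tight$values), "/") - lat[, 1]))
  dev_loose <- mean(abs(sweep(loose$values, 2, colSums(loose$values), "/") - lat[, 1]))
  expect_lt(dev_tight, dev_loose)

  expect_error(sample_counts(lat, mean_depth = 50), "mean_depth")
})

test_that("fixtures round-trip and params.json replays the identical dataset", {
  ds <- simulate_community(simulation_design(sites = "A",
                                             timepoints_days = c(7, 70, 140),
                                             replicates = 2,
                                             genotypes = c(g = 1.15),
                                             seed = 17),
                           n_otus = 40)
  dir <- withr::local_tempdir()
  write_fixture(ds, dir)
  back <- read_otu_table(file.path(dir, "otu_table.tsv"))
  expect_equal(back$values, ds$table$values, ignore_attr = FALSE)
  truth_back <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth_back), 40)
  tax_back <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_identical(tax_back$phylum, ds$taxonomy$phylum)

  replay <- simulate_from_params(file.path(dir, "params.json"))
  expect_identical(replay$table$values, ds$table$values)
  expect_equal(replay$metadata, ds$metadata)
})
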