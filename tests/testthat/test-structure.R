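test_that("Bray-Curtis matches the formula, its bounds, and a naive double loop", {
  m <- matrix(c(600, 200, 400, 800, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("o", 1:3), c("x", "y")))
  d <- bray_curtis(otu_table(m, "per_mille"))
  expect_equal(as.numeric(d), 0.4)

  same <- cbind(x = m[, 1], y = m[, 1])
  rownames(same) <- rownames(m)
  expect_equal(as.numeric(bray_curtis(same)), 0)

  disjoint <- matrix(c(500, 0, 500, 0, 0, 1000), nrow = 3, byrow = TRUE,
                     dimnames = list(paste0("o", 1:3), c("x", "y")))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)

  set.seed(8)
  r <- matrix(rpois(600, 20), 30, 20,
              dimnames = list(paste0("o", 1:30), paste0("s", 1:20)))
  pm <- normalize_per_mille(otu_table(r, "raw_counts"))
  d <- as.matrix(bray_curtis(pm))
  oracle <- bray_curtis_oracle(pm$values)
  expect_lt(max(abs(d - oracle)), 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))

  z <- r; z[, 2] <- 0
  expect_error(bray_curtis(z), "zero-total")
})

test_that("Shannon diversity matches closed forms", {
  one <- otu_table(matrix(1000, 1, 1, dimnames = list("o", "s")), "per_mille")
  expect_equal(unname(shannon(one)), 0)

  k <- 8
  unif <- otu_table(matrix(1000 / k, k, 1,
                           dimnames = list(paste0("o", 1:k), "s")), "per_mille")
  expect_equal(unname(shannon(unif)), log(k))

  mix <- otu_table(matrix(c(500, 250, 250), 3, 1,
                          dimnames = list(paste0("o", 1:3), "s")), "per_mille")
  expect_equal(unname(shannon(mix)), 1.5 * log(2))
})

test_that("PCoA recovers planar configurations and symmetric eigenstructure", {
  set.seed(21)
  pts <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  rownames(pts) <- paste0("s", 1:12)
  ord <- pcoa(dist(pts))
  expect_equal(length(ord$eigenvalues), 2)  # planar data: two positive axes
  expect_lt(procrustes_error(ord$coordinates, pts), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 0))
  expect_true(abs(sum(ord$proportion_explained) - 1) < 1e-9)

  # three equidistant points: two equal positive eigenvalues
  tri <- matrix(1, 3, 3) - diag(3)
  dimnames(tri) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord3 <- pcoa(as.dist(tri))
  expect_equal(ord3$eigenvalues[1], ord3$eigenvalues[2])

  # coincident samples land on identical coordinates
  pts2 <- rbind(pts, s13 = pts[1, ])
  ord2 <- pcoa(dist(pts2))
  expect_lt(max(abs(ord2$coordinates["s1", ] - ord2$coordinates["s13", ])), 1e-8)

  expect_error(pcoa(dist(pts[1:2, ])), "three samples")
})

test_that("PERMANOVA partitions distance sums of squares like the brute-force decomposition", {
  # two clean groups: all between-group distance 1, within 0 => R2 = 1
  m <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  m[1:2, 3:4] <- 1; m[3:4, 1:2] <- 1
  md <- data.frame(sample_id = paste0("s", 1:4), grp = c("a", "a", "b", "b"))
  res <- permanova(as.dist(m), md, "grp", n_perm = 99, seed = 1)
  expect_equal(res$r2[res$term == "grp"], 1)

  # random data: single-factor R2 equals 1 - SS_within / SS_total by brute force
  set.seed(33)
  counts <- matrix(rpois(600, 25), 30, 20,
                   dimnames = list(paste0("o", 1:30), paste0("s", 1:20)))
  pm <- normalize_per_mille(otu_table(counts, "raw_counts"))
  d <- as.matrix(bray_curtis(pm))
  grp <- rep(c("a", "b"), each = 10)
  md <- data.frame(sample_id = colnames(d), grp = grp)
  res <- permanova(as.dist(d), md, "grp", n_perm = 99, seed = 2)

  ss_total <- sum(d[upper.tri(d)]^2) / 20
  ss_within <- 0
  for (g in c("a", "b")) {
    sub <- d[grp == g, grp == g]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / 10
  }
  expect_equal(res$r2[res$term == "grp"], 1 - ss_within / ss_total,
               tolerance = 1e-9)
  expect_equal(sum(res$sum_of_squares[res$term %in% c("grp", "Residual")]),
               res$sum_of_squares[res$term == "Total"], tolerance = 1e-9)

  # reproducible permutations under a fixed seed
  res2 <- permanova(as.dist(d), md, "grp", n_perm = 99, seed = 2)
  expect_identical(res$p_value, res2$p_value)

  expect_error(permanova(as.dist(d), md, "nope", seed = 1), "missing")
})

test_that("time-point similarity z-scores center at zero and expose late-season stabilization", {
  # degenerate case: all pairwise similarities equal => z identically 0
  m <- matrix(0.3, 6, 6); diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:6), paste0("s", 1:6))
  md <- data.frame(sample_id = paste0("s", 1:6),
                   compartment = "endosphere",
                   age_days = rep(c(7, 14, 21), each = 2))
  z <- timepoint_similarity_z(as.dist(m), md, "endosphere")
  expect_true(all(abs(z$z) < 1e-12))

  # a late-stabilizing endosphere: colonizer turnover runs from germination
  # and completes by ~day 60, after which composition is static
  truth <- make_otu_truth(n_otus = 300, sites = "A", midpoint_day = 40,
                          early_midpoint_day = 18, curve_scale = 10,
                          amplitude_mean = 3.5, p_early = 0.25, p_late = 0.35,
                          frac_early_site_specific = 0,
                          frac_static_site_specific = 0, seed = 306)
  md2 <- build_design(simulation_design(sites = "A",
                                        compartments = "endosphere",
                                        replicates = 3, genotypes = c(g = 1),
                                        seed = 306))
  lat <- simulate_dynamics(truth, md2, rates = c(g = 1))
  pm2 <- normalize_per_mille(sample_counts(lat, seed = 307))
  zz <- timepoint_similarity_z(bray_curtis(log2_per_mille(pm2)), md2,
                               "endosphere")
  expect_equal(zz$z, t(zz$z))
  uniq <- zz$z[upper.tri(zz$z, diag = TRUE)]
  expect_lt(abs(mean(uniq)), 1e-9)

  # stabilization: late-late time point pairs are more similar than the
  # still-assembling early-early pairs
  tp <- zz$timepoints
  late <- outer(tp >= 63, tp >= 63, "&")
  early <- outer(tp <= 35, tp <= 35, "&")
  expect_gt(mean(zz$z[late]), mean(zz$z[early]))
})
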