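#' Define a simulated field-season design
#'
#' The design mirrors a multi-site rice field study: two sites sampled weekly
#' over ~140 days, four root-associated compartments per plant, one or more
#' genotypes that progress through the 1-27 developmental stage scale at
#' different rates, and optionally paired well-watered/drought treatment arms.
#'
#' @param sites Character vector of site names.
#' @param compartments Compartments sampled; default all four.
#' @param timepoints_days Sampling days after germination.
#' @param replicates Biological replicates per site x compartment x timepoint
#'   x genotype (x treatment) cell.
#' @param genotypes Named numeric vector: development-rate multiplier per
#'   genotype (1 = 26 stages over 140 days; faster genotypes reach panicle
#'   initiation, stage 18, earlier).
#' @param drought_arms If TRUE each cell is duplicated into well-watered and
#'   drought arms; otherwise treatment is `"none"`.
#' @param seed Master seed for the dataset built from this design.
#' @return A `sim_design` list.
#' @export
simulation_design <- function(sites = c("Arbuckle", "Jonesboro"),
                              compartments = c("bulk_soil", "rhizosphere",
                                               "rhizoplane", "endosphere"),
                              timepoints_days = seq(7, 140, by = 7),
                              replicates = 3,
                              genotypes = c(M206 = 1.5),
                              drought_arms = FALSE,
                              seed = 1L) {
  if (!length(sites) || !length(compartments) || !length(timepoints_days) ||
      !length(genotypes)) {
    stop("design factor lists must be non-empty")
  }
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes)))) {
    stop("`genotypes` must be a named vector of development rates")
  }
  if (any(genotypes <= 0)) stop("development rates must be positive")
  if (replicates < 1) stop("need at least one replicate")
  structure(list(sites = sites, compartments = compartments,
                 timepoints_days = timepoints_days, replicates = replicates,
                 genotypes = genotypes, drought_arms = drought_arms,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Developmental stage reached at a given age
#'
#' Stage runs 1 (germination) to 27 (senescence) linearly in developmental
#' time `rate * age`, clamped to the scale; panicle initiation is stage 18.
#'
#' @param age_days Age in days after germination.
#' @param rate Development-rate multiplier.
#' @return Integer stages in 1..27.
#' @export
stage_at_age <- function(age_days, rate = 1) {
  pmin(pmax(round(1 + rate * 26 * age_days / 140), 1), 27)
}

#' Build the sample manifest for a design
#'
#' @param design A `sim_design`.
#' @return Data frame of per-sample metadata (one row per site x compartment x
#'   timepoint x genotype x replicate, times treatment arm if enabled).
#' @export
build_design <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  treatments <- if (design$drought_arms) c("well_watered", "drought") else "none"
  g <- expand.grid(replicate = seq_len(design$replicates),
                   treatment = treatments,
                   genotype = names(design$genotypes),
                   age_days = design$timepoints_days,
                   compartment = design$compartments,
                   site = design$sites,
                   stringsAsFactors = FALSE)
  rate <- design$genotypes[g$genotype]
  md <- data.frame(
    sample_id = sprintf("S%05d", seq_len(nrow(g))),
    site = g$site,
    season = "sim1",
    compartment = g$compartment,
    position = compartment_position(g$compartment),
    age_days = g$age_days,
    genotype = g$genotype,
    dev_stage = stage_at_age(g$age_days, rate),
    treatment = g$treatment,
    soil = paste0(g$site, "_soil"),
    sequencing_run = "run1",
    replicate = g$replicate,
    stringsAsFactors = FALSE)
  md
}

# Host-proximity weights on the successional signal: bulk soil barely tracks
# the plant, the endosphere tracks it fully.
.POSITION_WEIGHT <- c(0.08, 0.6, 0.8, 1.0)

#' Draw per-OTU ground truth for the generator
#'
#' Each OTU gets an archetype (early / late / complex / static colonizer), a
#' log-scale baseline, a compartment-affinity slope over positions 0-3, a
#' logistic (or Gaussian, for complex) abundance curve in developmental time,
#' and possibly a site restriction. Defaults plant 15% early, 25% late, 10%
#' complex and 50% static OTUs, with 20% of early and 10% of static OTUs
#' site-specific, mirroring field observations that early colonizers are
#' largely site-specific while soils also differ statically.
#'
#' @param n_otus Number of OTUs.
#' @param sites Site names site-specific OTUs are assigned to.
#' @param p_early,p_late,p_complex Archetype proportions (rest static).
#' @param frac_early_site_specific Fraction of early OTUs restricted to one site.
#' @param frac_static_site_specific Fraction of static OTUs restricted to one site.
#' @param amplitude_mean Mean log-scale amplitude of the archetype curves.
#' @param midpoint_day Center of the late-colonizer and complex curves in
#'   developmental-time days; defaults to the stage-18 (panicle initiation)
#'   developmental time, so late colonizers finish establishing as the plant
#'   enters reproduction.
#' @param early_midpoint_day Center of the early-colonizer decline; defaults
#'   to `midpoint_day`, so the early-to-late handover is centered on panicle
#'   initiation. Set it lower to emulate early colonizers that peak at
#'   germination and are displaced throughout the vegetative phase.
#' @param midpoint_sd SD of the per-OTU midpoint jitter around its
#'   archetype's centre (days); larger values stagger colonizer turnover
#'   across the season.
#' @param curve_scale Logistic/Gaussian scale in days.
#' @param affinity_sd SD of the per-OTU compartment-affinity slope.
#' @param baseline_sd SD of log baselines.
#' @param site_specific_boost Log-scale baseline boost for site-specific
#'   early colonizers, making them dominate the early-season community in
#'   their home site (as site-specific taxa do in the field).
#' @param seed RNG seed.
#' @return Data frame of class `otu_truth`.
#' @export
make_otu_truth <- function(n_otus = 500,
                           sites = c("Arbuckle", "Jonesboro"),
                           p_early = 0.15, p_late = 0.25, p_complex = 0.10,
                           frac_early_site_specific = 0.20,
                           frac_static_site_specific = 0.10,
                           amplitude_mean = 3,
                           midpoint_day = 140 * 17 / 26,
                           early_midpoint_day = midpoint_day,
                           midpoint_sd = 10,
                           curve_scale = 14,
                           affinity_sd = 0.8,
                           baseline_sd = 1,
                           site_specific_boost = 1.5,
                           seed = 1L) {
  stopifnot(p_early + p_late + p_complex <= 1)
  set.seed(as.integer(seed))
  n_e <- round(p_early * n_otus); n_l <- round(p_late * n_otus)
  n_c <- round(p_complex * n_otus)
  archetype <- rep(c("early", "late", "complex", "static"),
                   c(n_e, n_l, n_c, n_otus - n_e - n_l - n_c))
  amplitude <- pmax(rnorm(n_otus, amplitude_mean, 0.5), 0.5)
  amplitude[archetype == "static"] <- 0
  centre <- ifelse(archetype == "early", early_midpoint_day, midpoint_day)
  midpoint <- pmin(pmax(rnorm(n_otus, centre, midpoint_sd), 20), 125)
  site_specific_to <- rep(NA_character_, n_otus)
  e_idx <- which(archetype == "early")
  s_idx <- which(archetype == "static")
  pick_e <- e_idx[seq_len(floor(frac_early_site_specific * length(e_idx)))]
  pick_s <- s_idx[seq_len(floor(frac_static_site_specific * length(s_idx)))]
  site_specific_to[pick_e] <- rep_len(sites, length(pick_e))
  site_specific_to[pick_s] <- rep_len(sites, length(pick_s))
  affinity_slope <- rnorm(n_otus, 0, affinity_sd)
  # early colonizers are root-enriched relative to bulk soil (half-normal
  # affinity); other archetypes may be enriched or depleted
  affinity_slope[e_idx] <- abs(affinity_slope[e_idx])
  baseline <- rnorm(n_otus, 0, baseline_sd)
  baseline[pick_e] <- baseline[pick_e] + site_specific_boost
  # balance total early vs late colonizer mass (endosphere-weighted, where
  # the dominance handover is read out) so the planted handover sits at the
  # curve midpoint (panicle initiation), not at a point set by the accident
  # of which group drew the larger baselines or affinities
  l_idx <- which(archetype == "late")
  if (length(e_idx) && length(l_idx)) {
    w_endo <- baseline + 3 * affinity_slope
    baseline[e_idx] <- baseline[e_idx] +
      log(sum(exp(w_endo[l_idx])) / sum(exp(w_endo[e_idx])))
  }
  truth <- data.frame(
    otu_id = sprintf("OTU%04d", seq_len(n_otus)),
    archetype = archetype,
    site_specific_to = site_specific_to,
    baseline = baseline,
    affinity_slope = affinity_slope,
    midpoint_day = midpoint,
    amplitude = amplitude,
    curve_scale = curve_scale,
    drought_multiplier = ifelse(archetype == "early", 2.5,
                                ifelse(archetype == "late", 1 / 2.5, 1)),
    stringsAsFactors = FALSE)
  for (p in 0:3) truth[[paste0("affinity_", p)]] <- affinity_slope * p
  truth$phylum <- .assign_phyla(archetype, seed)
  class(truth) <- c("otu_truth", class(truth))
  truth
}

# archetype-stratified synthetic phyla so taxonomy aggregation has realistic
# structure (Proteobacteria classes dominate, early vs late lean differently)
.assign_phyla <- function(archetype, seed) {
  pools <- list(
    early = c("Proteobacteria|Betaproteobacteria", "Verrucomicrobia",
              "Gemmatimonadetes", "Bacteroidetes", "Actinobacteria"),
    late = c("Proteobacteria|Deltaproteobacteria", "Nitrospirae",
             "Spirochaetes", "Euryarchaeota", "Proteobacteria|Epsilonproteobacteria"),
    complex = c("Proteobacteria|Alphaproteobacteria", "Chloroflexi", "Firmicutes"),
    static = c("Proteobacteria|Alphaproteobacteria", "Proteobacteria|Gammaproteobacteria",
               "Acidobacteria", "Chloroflexi", "Planctomycetes", "Firmicutes"))
  vapply(seq_along(archetype), function(i) {
    pool <- pools[[archetype[i]]]
    pool[1 + (i %% length(pool))]
  }, character(1))
}

#' Greengenes-style lineage table for a truth table
#'
#' @param truth An `otu_truth` data frame.
#' @return Taxonomy data frame (see [parse_greengenes()]).
#' @export
truth_taxonomy <- function(truth) {
  parts <- strsplit(truth$phylum, "|", fixed = TRUE)
  phy <- vapply(parts, `[`, character(1), 1)
  cls <- vapply(parts, function(p) if (length(p) > 1) p[2] else "unassigned",
                character(1))
  data.frame(otu_id = truth$otu_id, kingdom = "Bacteria", phylum = phy,
             class = cls, order = "unassigned", family = "unassigned",
             genus = "unassigned", stringsAsFactors = FALSE)
}

#' Latent expected compositions for a manifest
#'
#' Log expected abundance of OTU i in sample j is
#' `baseline_i + affinity_slope_i * position_j + w(position_j) * curve_i(t_j)`
#' where `t_j = age_j * rate(genotype_j)` is developmental time and the
#' archetype curve is a falling logistic (early), rising logistic (late),
#' Gaussian bump (complex) or zero (static), scaled by amplitude. The
#' position weight `w` (0.15, 0.6, 0.8, 1) encodes that succession is
#' host-driven and weakest in bulk soil. Site-specific OTUs are zeroed
#' outside their site. Columns are renormalized to the simplex.
#'
#' @param truth `otu_truth` data frame.
#' @param manifest Metadata from [build_design()].
#' @param rates Named development rates (as in the design's `genotypes`).
#' @return Matrix OTUs x samples of latent relative abundances (columns sum
#'   to 1).
#' @export
simulate_dynamics <- function(truth, manifest, rates = c(M206 = 1.15)) {
  curve_val <- function(t) {
    v <- numeric(nrow(truth))
    s <- (t - truth$midpoint_day) / truth$curve_scale
    e <- truth$archetype == "early"; l <- truth$archetype == "late"
    cx <- truth$archetype == "complex"
    v[e] <- truth$amplitude[e] * (1 - stats::plogis(s[e]))
    v[l] <- truth$amplitude[l] * stats::plogis(s[l])
    v[cx] <- truth$amplitude[cx] * exp(-0.5 * s[cx]^2)
    v
  }
  lat <- matrix(0, nrow(truth), nrow(manifest),
                dimnames = list(truth$otu_id, manifest$sample_id))
  for (j in seq_len(nrow(manifest))) {
    t_dev <- manifest$age_days[j] * rates[[manifest$genotype[j]]]
    w <- .POSITION_WEIGHT[manifest$position[j] + 1]
    lg <- truth$baseline + truth$affinity_slope * manifest$position[j] +
      w * curve_val(t_dev)
    x <- exp(lg)
    x[!is.na(truth$site_specific_to) &
        truth$site_specific_to != manifest$site[j]] <- 0
    lat[, j] <- x / sum(x)
  }
  lat
}

#' Perturb latent compositions with a drought treatment
#'
#' In drought-treated samples, early-colonizer abundances are inflated by
#' `(1 + severity)` and late colonizers deflated by its reciprocal in the
#' endosphere — the compartment where water deprivation reshapes the
#' community. Optionally the same factors, raised to the attenuation
#' exponent, apply in the rhizosphere; the default exponent of 0 leaves the
#' rhizosphere unperturbed, matching the observation that drought effects on
#' microbiota maturity are endosphere-specific. Bulk soil, rhizoplane, and
#' well-watered samples are unchanged. Columns are renormalized.
#'
#' @param latent Matrix from [simulate_dynamics()].
#' @param manifest Matching metadata with a `treatment` column.
#' @param truth `otu_truth` table.
#' @param severity Non-negative perturbation strength (0 = identity).
#' @param rhizosphere_attenuation Exponent applied to the drought factors in
#'   the rhizosphere (0-1).
#' @return Perturbed latent matrix.
#' @export
apply_drought_perturbation <- function(latent, manifest, truth, severity = 0.8,
                                       rhizosphere_attenuation = 0) {
  if (severity < 0) stop("severity must be non-negative")
  bad <- setdiff(unique(manifest$treatment), c("well_watered", "drought", "none"))
  if (length(bad)) stop("unknown treatment label(s): ", paste(bad, collapse = ", "))
  if (severity == 0) return(latent)
  f <- rep(1, nrow(truth))
  f[truth$archetype == "early"] <- 1 + severity
  f[truth$archetype == "late"] <- 1 / (1 + severity)
  for (j in seq_len(nrow(manifest))) {
    if (manifest$treatment[j] != "drought") next
    fac <- if (manifest$compartment[j] == "endosphere") f
           else if (manifest$compartment[j] == "rhizosphere") f^rhizosphere_attenuation
           else NULL
    if (is.null(fac)) next
    x <- latent[, j] * fac
    latent[, j] <- x / sum(x)
  }
  latent
}

#' Draw sequencing counts from latent compositions
#'
#' Per sample: depth from a discretized log-normal around `mean_depth`,
#' proportions from a Dirichlet centered on the latent composition with the
#' given concentration (the Dirichlet-multinomial overdispersion the exact
#' test assumes), counts multinomial.
#'
#' @param latent Matrix OTUs x samples, columns on the simplex.
#' @param mean_depth Mean sequencing depth (>= 100).
#' @param depth_sdlog Log-normal sd of depth.
#' @param dirichlet_concentration Total Dirichlet concentration; larger =
#'   closer to the latent composition.
#' @param seed RNG seed.
#' @return An `otu_table` of raw counts.
#' @export
sample_counts <- function(latent, mean_depth = 10000, depth_sdlog = 0.2,
                          dirichlet_concentration = 300, seed = 1L) {
  if (mean_depth < 100) stop("mean_depth must be >= 100")
  set.seed(as.integer(seed))
  n <- ncol(latent)
  counts <- matrix(0L, nrow(latent), n, dimnames = dimnames(latent))
  depths <- pmax(round(stats::rlnorm(n, log(mean_depth), depth_sdlog)), 100)
  for (j in seq_len(n)) {
    shape <- dirichlet_concentration * latent[, j]
    p <- numeric(length(shape))
    pos <- shape > 0
    p[pos] <- stats::rgamma(sum(pos), shape = shape[pos], rate = 1)
    p <- p / sum(p)
    counts[, j] <- stats::rmultinom(1, depths[j], p)[, 1]
  }
  otu_table(counts, unit = "raw_counts")
}

#' Simulate a complete successional-community dataset
#'
#' Runs [build_design()], [make_otu_truth()], [simulate_dynamics()],
#' optionally [apply_drought_perturbation()], and [sample_counts()], deriving
#' all stage seeds from the design's master seed.
#'
#' @param design A `sim_design`.
#' @param n_otus Number of OTUs.
#@KEEP@
#'   arms).
#' @param mean_depth,dirichlet_concentration,depth_sdlog See [sample_counts()].
#' @param ... Further arguments to [make_otu_truth()].
#' @return A `synthetic_dataset` list: `table` (raw counts), `metadata`,
#'   `truth`, `taxonomy`, `params`.
#' @export
simulate_community <- function(design = simulation_design(), n_otus = 500,
                               severity = 1.5, mean_depth = 10000,
                               dirichlet_concentration = 300,
                               depth_sdlog = 0.2, ...) {
  extra <- list(...)
  md <- build_design(design)
  truth <- do.call(make_otu_truth,
                   c(list(n_otus = n_otus, sites = design$sites,
                          seed = design$seed), extra))
  lat <- simulate_dynamics(truth, md, rates = design$genotypes)
  if (design$drought_arms) {
    lat <- apply_drought_perturbation(lat, md, truth, severity = severity)
  }
  tab <- sample_counts(lat, mean_depth = mean_depth,
                       depth_sdlog = depth_sdlog,
                       dirichlet_concentration = dirichlet_concentration,
                       seed = (design$seed + 1L) %% .Machine$integer.max)
  pdesign <- unclass(design)
  pdesign$genotypes <- as.list(design$genotypes)  # keep names in JSON
  params <- list(design = pdesign, n_otus = n_otus, severity = severity,
                 mean_depth = mean_depth, depth_sdlog = depth_sdlog,
                 dirichlet_concentration = dirichlet_concentration,
                 truth_args = extra)
  structure(list(table = tab, metadata = md, truth = truth,
                 taxonomy = truth_taxonomy(truth), params = params),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d OTUs x %d samples; %d sites, %d timepoints\n",
              nrow(x$table$values), ncol(x$table$values),
              length(x$params$design$sites),
              length(x$params$design$timepoints_days)))
  invisible(x)
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Writes `otu_table.tsv`, `metadata.tsv`, `taxonomy.tsv`, `truth.tsv` and
#' `params.json` into `out_dir`; the params file replays to an identical
#' dataset via [simulate_from_params()].
#'
#' @param dataset A `synthetic_dataset`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("otu_table.tsv", "metadata.tsv",
                                "taxonomy.tsv", "truth.tsv", "params.json"))
  write_otu_table(dataset$table, paths[1])
  utils::write.table(dataset$metadata, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tx <- dataset$taxonomy
  lineage <- sprintf("k__%s; p__%s; c__%s; o__; f__; g__",
                     tx$kingdom, tx$phylum,
                     ifelse(tx$class == "unassigned", "", tx$class))
  utils::write.table(data.frame(otu_id = tx$otu_id, lineage = lineage),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(as.data.frame(dataset$truth), paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$params, paths[5], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Replay a dataset from its params.json
#'
#' @param path Path to a `params.json` written by [write_fixture()].
#' @return The regenerated `synthetic_dataset` (identical under the recorded
#'   seed).
#' @export
simulate_from_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- p$design
  design <- simulation_design(sites = d$sites, compartments = d$compartments,
                              timepoints_days = d$timepoints_days,
                              replicates = d$replicates,
                              genotypes = unlist(d$genotypes),
                              drought_arms = isTRUE(d$drought_arms),
                              seed = d$seed)
  args <- c(list(design = design, n_otus = p$n_otus, severity = p$severity,
                 mean_depth = p$mean_depth, depth_sdlog = p$depth_sdlog,
                 dirichlet_concentration = p$dirichlet_concentration),
            p$truth_args)
  do.call(simulate_community, args)
}

#' Preset study designs and datasets
#'
#' Frozen configurations used throughout the package's tests and worked
#' examples:
#'
#' * `simulate_field_study()` — the default two-site weekly season
#'   ([simulation_design()] defaults): the main successional dataset.
#' * `simulate_stage_study()` — one site, four genotypes with distinct
#'   developmental rates (Kitaake 1.6, M206 1.36, M401 1.33, Nipponbare
#'   1.31; all reach panicle initiation before day 84), biweekly sampling,
#'   quadruplicate plots, sharper successional curves (scale 8 d) so every
#'   variety's community has plateaued in the late season window.
#' * `simulate_informative_benchmark()` — feature-recovery benchmark: one
#'   site, endosphere only, 12 replicates, `n_inf/2` early + `n_inf/2` late
#'   informative OTUs among noise OTUs with turnover midpoints staggered
#'   across the season (as the age-discriminant taxa are in the field), no
#'   compartment affinity and no site restriction so every planted
#'   informative OTU is observable in the modeled compartment.
#'
#' @param seed Master seed.
#' @param n_otus Number of OTUs.
#' @param n_inf Number of informative (non-static) OTUs in the benchmark.
#' @return A `synthetic_dataset`.
#' @export
simulate_field_study <- function(seed = 1L, n_otus = 500) {
  simulate_community(simulation_design(seed = seed), n_otus = n_otus)
}

#' @rdname simulate_field_study
#' @export
simulate_stage_study <- function(seed = 1L, n_otus = 500) {
  des <- simulation_design(sites = "Arbuckle",
                           timepoints_days = seq(14, 140, by = 14),
                           replicates = 4,
                           genotypes = c(Kitaake = 1.6, M206 = 1.36,
                                         M401 = 1.33, Nipponbare = 1.31),
                           seed = seed)
  simulate_community(des, n_otus = n_otus, curve_scale = 8)
}

#' @rdname simulate_field_study
#' @export
simulate_informative_benchmark <- function(seed = 1L, n_otus = 1000,
                                           n_inf = 30) {
  des <- simulation_design(sites = "Arbuckle", compartments = "endosphere",
                           replicates = 12, seed = seed)
  simulate_community(des, n_otus = n_otus,
                     p_early = n_inf / 2 / n_otus,
                     p_late = n_inf / 2 / n_otus, p_complex = 0,
                     frac_early_site_specific = 0,
                     frac_static_site_specific = 0, affinity_sd = 0,
                     midpoint_sd = 35)
}
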