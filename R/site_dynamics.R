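#' Between-site community distances over plant age
#'
#' For each compartment, collects Bray-Curtis distances between all
#' cross-site sample pairs within each common time point and fits an
#' ordinary least-squares trend of distance on age — a declining trend means
#' the two sites' communities converge as plants mature.
#'
#' @param dist A `dist` over all samples.
#' @param metadata Metadata with `sample_id`, `site`, `compartment`,
#'   `age_days` (exactly two sites expected among the samples).
#' @param baseline `"none"` fits the trend on raw cross-site distances;
#'   `"within_site"` first subtracts, per time point, the mean within-site
#'   distance, so the trend measures the excess between-site dissimilarity
#'   and is insensitive to drifts in the replicate-level noise floor.
#' @return A `convergence_series` list: `pairs` (compartment, age_days,
#'   distance) and `trends` (compartment, slope, se, p_value, n).
#' @export
between_site_distances <- function(dist, metadata,
                                   baseline = c("none", "within_site")) {
  baseline <- match.arg(baseline)
  m <- as.matrix(dist)
  md <- metadata[match(rownames(m), metadata$sample_id), ]
  sites <- unique(md$site)
  if (length(sites) != 2) stop("exactly two sites required")
  rows <- list()
  for (cp in unique(md$compartment)) {
    sel <- md$compartment == cp
    tps <- intersect(unique(md$age_days[sel & md$site == sites[1]]),
                     unique(md$age_days[sel & md$site == sites[2]]))
    if (length(tps) < 3) stop("fewer than 3 common timepoints in ", cp)
    for (tp in sort(tps)) {
      a <- which(sel & md$site == sites[1] & md$age_days == tp)
      b <- which(sel & md$site == sites[2] & md$age_days == tp)
      d <- as.vector(m[a, b, drop = FALSE])
      if (baseline == "within_site") {
        floor_at <- function(idx) {
          if (length(idx) < 2) return(NA_real_)
          sub <- m[idx, idx, drop = FALSE]
          mean(sub[upper.tri(sub)])
        }
        d <- d - mean(c(floor_at(a), floor_at(b)), na.rm = TRUE)
      }
      rows[[length(rows) + 1]] <- data.frame(compartment = cp, age_days = tp,
                                             distance = d)
    }
  }
  pairs <- do.call(rbind, rows)
  trends <- do.call(rbind, lapply(split(pairs, pairs$compartment), function(pp) {
    fit <- summary(stats::lm(distance ~ age_days, data = pp))$coefficients
    data.frame(compartment = pp$compartment[1],
               slope = fit["age_days", "Estimate"],
               se = fit["age_days", "Std. Error"],
               p_value = fit["age_days", "Pr(>|t|)"], n = nrow(pp),
               stringsAsFactors = FALSE)
  }))
  rownames(trends) <- NULL
  structure(list(pairs = pairs, trends = trends), class = "convergence_series")
}

#' Detect site-skewed OTUs per time point and compartment
#'
#' Within each compartment and each time point sampled at both sites,
#' library sizes are equalized to the median depth, moderated dispersions
#' are estimated across the OTUs of that family, and each OTU is tested with
#' the conditional exact test ([nb_exact_test()]). Bonferroni correction is
#' applied within each time point x compartment family.
#'
#' @param table Raw-counts `otu_table`.
#' @param metadata Metadata with `sample_id`, `site`, `compartment`,
#'   `age_days`.
#' @param alpha Family-wise significance level.
#' @param compartments Compartments to scan (default all present).
#' @return A `site_skew_calls` data frame: otu_id, timepoint, compartment,
#'   log2_fc, p_value, significant, skewed_to.
#' @export
site_specific_otus <- function(table, metadata, alpha = 0.05,
                               compartments = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (table$unit != "raw_counts") stop("expected a raw_counts table")
  md <- metadata[match(sample_ids(table), metadata$sample_id), ]
  sites <- unique(md$site)
  if (length(sites) != 2) stop("exactly two sites required")
  if (is.null(compartments)) compartments <- unique(md$compartment)
  rows <- list()
  for (cp in compartments) {
    for (tp in sort(unique(md$age_days[md$compartment == cp]))) {
      ia <- which(md$compartment == cp & md$age_days == tp & md$site == sites[1])
      ib <- which(md$compartment == cp & md$age_days == tp & md$site == sites[2])
      if (!length(ia) || !length(ib)) next
      cnt <- .equalize_depth(table$values[, c(ia, ib), drop = FALSE])
      grp <- rep(sites, c(length(ia), length(ib)))
      keep <- rowSums(cnt) > 0
      if (!any(keep)) next
      disp <- estimate_dispersion(cnt[keep, , drop = FALSE], grp)
      ids <- rownames(cnt)[keep]
      mfam <- length(ids)
      res <- lapply(seq_along(ids), function(i) {
        r <- nb_exact_test(cnt[ids[i], grp == sites[1]],
                           cnt[ids[i], grp == sites[2]], disp[i])
        data.frame(otu_id = ids[i], timepoint = tp, compartment = cp,
                   log2_fc = r$log2_fc, p_value = r$p_value,
                   stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, res)
      fam$significant <- fam$p_value <= alpha / mfam
      fam$skewed_to <- ifelse(!fam$significant, NA_character_,
                              ifelse(fam$log2_fc > 0, sites[2], sites[1]))
      rows[[length(rows) + 1]] <- fam
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("site_skew_calls", class(out))
  out
}

#' Aggregate abundance of site-specific OTUs and its trend on age
#'
#' Sums, per sample, the per-mille abundance of every OTU ever called
#' site-skewed (the union over time points), and fits a per-compartment OLS
#' trend of this fraction on plant age.
#'
#' @param table Per-mille `otu_table`.
#' @param calls A `site_skew_calls` data frame.
#' @param metadata Metadata with `sample_id`, `compartment`, `age_days`.
#' @return List: `samples` (sample_id, compartment, age_days, fraction in
#'   per-mille) and `trends` (compartment, slope, p_value).
#' @export
site_specific_fraction <- function(table, calls, metadata) {
  stopifnot(inherits(table, "otu_table"))
  sig <- unique(calls$otu_id[calls$significant])
  ids <- intersect(sig, otu_ids(table))
  frac <- if (length(ids)) colSums(table$values[ids, , drop = FALSE]) else
    stats::setNames(rep(0, ncol(table$values)), sample_ids(table))
  md <- metadata[match(sample_ids(table), metadata$sample_id), ]
  samples <- data.frame(sample_id = sample_ids(table),
                        compartment = md$compartment, age_days = md$age_days,
                        fraction = unname(frac), stringsAsFactors = FALSE)
  trends <- do.call(rbind, lapply(split(samples, samples$compartment),
                                  function(ss) {
    if (stats::var(ss$fraction) == 0) {
      return(data.frame(compartment = ss$compartment[1], slope = 0,
                        p_value = 1, stringsAsFactors = FALSE))
    }
    fit <- summary(stats::lm(fraction ~ age_days, data = ss))$coefficients
    data.frame(compartment = ss$compartment[1],
               slope = fit["age_days", "Estimate"],
               p_value = fit["age_days", "Pr(>|t|)"], stringsAsFactors = FALSE)
  }))
  rownames(trends) <- NULL
  list(samples = samples, trends = trends)
}

#' Genotype x age interaction along a principal coordinate
#'
#' Within each compartment and each season window (age <= `split_day`, age >
#' `split_day`), compares `coordinate ~ age` against
#' `coordinate ~ age * genotype` with a nested-model F test, and reports
#' per-genotype slope estimates with Tukey-adjusted pairwise slope
#' contrasts. A significant early-window interaction whose slope ordering
#' follows the genotypes' developmental rates indicates development-driven
#' (not merely calendar-driven) community progression.
#'
#' @param ordination A `pcoa_result`.
#' @param metadata Metadata with `sample_id`, `compartment`, `age_days`,
#'   `genotype`.
#' @param axis Which principal coordinate to model (default 2).
#' @param split_day Window boundary in days (default 84).
#' @param compartments Compartments to test (default rhizosphere and
#'   endosphere).
#' @return List: `tests` (compartment, window, p_interaction), `slopes`
#'   (compartment, window, genotype, slope, se), `pairwise` (Tukey-adjusted
#'   slope contrasts).
#' @export
pco_trend_interaction <- function(ordination, metadata, axis = 2,
                                  split_day = 84,
                                  compartments = c("rhizosphere", "endosphere")) {
  co <- ordination$coordinates
  if (axis > ncol(co)) stop("ordination has fewer than ", axis, " axes")
  df <- data.frame(sample_id = rownames(co), y = co[, axis],
                   stringsAsFactors = FALSE)
  df <- merge(df, metadata, by = "sample_id")
  if (length(unique(df$genotype)) < 2) stop("need >= 2 genotypes")
  tests <- slopes <- pairwise <- list()
  for (cp in compartments) {
    for (win in c("early", "late")) {
      sel <- df$compartment == cp &
        (if (win == "early") df$age_days <= split_day else df$age_days > split_day)
      sub <- df[sel, , drop = FALSE]
      tab <- table(sub$genotype)
      drop_g <- names(tab)[tab < 3]
      if (length(drop_g)) {
        warning("genotype(s) dropped from ", cp, "/", win, " window: ",
                paste(drop_g, collapse = ", "))
        sub <- sub[!sub$genotype %in% drop_g, , drop = FALSE]
      }
      if (length(unique(sub$age_days)) < 3 || length(unique(sub$genotype)) < 2) next
      sub$genotype <- factor(sub$genotype)
      m0 <- stats::lm(y ~ age_days, data = sub)
      m1 <- stats::lm(y ~ age_days * genotype, data = sub)
      p_int <- stats::anova(m0, m1)$`Pr(>F)`[2]
      tests[[length(tests) + 1]] <- data.frame(compartment = cp, window = win,
                                               p_interaction = p_int,
                                               stringsAsFactors = FALSE)
      emt <- emmeans::emtrends(m1, ~genotype, var = "age_days")
      st <- as.data.frame(emt)
      slopes[[length(slopes) + 1]] <- data.frame(
        compartment = cp, window = win, genotype = as.character(st$genotype),
        slope = st$age_days.trend, se = st$SE, stringsAsFactors = FALSE)
      pw <- as.data.frame(emmeans::contrast(emt, method = "pairwise",
                                            adjust = "tukey"))
      pairwise[[length(pairwise) + 1]] <- data.frame(
        compartment = cp, window = win, contrast = as.character(pw$contrast),
        estimate = pw$estimate, p_adjusted = pw$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(tests = do.call(rbind, tests), slopes = do.call(rbind, slopes),
       pairwise = do.call(rbind, pairwise))
}
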