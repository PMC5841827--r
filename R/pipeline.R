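#' Pipeline configuration
#'
#' Collects all tunables of the end-to-end analysis. Exactly one input mode
#' is used: paths to an existing OTU table / metadata / taxonomy, or a
#' simulation design to generate data in place. Every random stage derives
#' its seed from the single master `seed`.
#'
#' @param otu_table_path,metadata_path,taxonomy_path Input files (tsv
#'   dialects of [read_otu_table()], [read_sample_metadata()],
#'   [read_taxonomy()]); leave NULL to simulate.
#' @param simulate A `sim_design` (default when no paths are given).
#' @param n_otus OTUs to simulate.
#' @param stages Character vector of stages to run, in dependency order.
#' @param prevalence Prevalence filter threshold.
#' @param pseudocount Pseudocount for the log2 ordination transform.
#' @param n_perm PERMANOVA permutations.
#' @param n_trees Trees in the final forests.
#' @param sparse_size Fixed sparse-model size (NULL = CV-selected; the
#'   reference field models use 85 OTUs for age and 54 for stage).
#' @param alpha Significance level.
#' @param split_day Early/late season boundary for interaction tests.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(otu_table_path = NULL, metadata_path = NULL,
                            taxonomy_path = NULL,
                            simulate = simulation_design(),
                            n_otus = 500,
                            stages = c("normalize", "structure", "trends",
                                       "colonizers", "maturity"),
                            prevalence = 0.05, pseudocount = 1,
                            n_perm = 999, n_trees = 500, sparse_size = NULL,
                            alpha = 0.05, split_day = 84, seed = 1L) {
  has_paths <- !is.null(otu_table_path)
  if (has_paths && (is.null(metadata_path))) {
    stop("metadata_path is required with otu_table_path")
  }
  structure(list(otu_table_path = otu_table_path,
                 metadata_path = metadata_path,
                 taxonomy_path = taxonomy_path,
                 simulate = if (has_paths) NULL else simulate,
                 n_otus = n_otus, stages = stages, prevalence = prevalence,
                 pseudocount = pseudocount, n_perm = n_perm,
                 n_trees = n_trees, sparse_size = sparse_size, alpha = alpha,
                 split_day = split_day, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_seed <- function(master, k) (as.integer(master) + 1000L * k) %% 2147483647L

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order (input -> normalize and
#' filter -> community structure -> taxon trends -> colonizer classification
#' -> maturity modeling -> site dynamics), writing tab-separated and JSON
#' results plus a `manifest.json` recording the package version, the full
#' configuration, stage seeds, and an md5 checksum per output file. The
#' manifest carries no timestamps, so a fixed master seed yields
#' byte-identical manifests across runs.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, name)
  }
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, name)
  }
  run_stage <- function(name, expr) {
    message("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!length(config$stages)) warning("no stages requested; manifest only")

  # --- input ---
  if (!is.null(config$otu_table_path)) {
    counts <- read_otu_table(config$otu_table_path)
    metadata <- read_sample_metadata(config$metadata_path)
    taxonomy <- if (!is.null(config$taxonomy_path)) {
      read_taxonomy(config$taxonomy_path)
    }
    truth <- NULL
  } else {
    design <- config$simulate
    design$seed <- .stage_seed(config$seed, 0L)
    ds <- run_stage("simulate", simulate_community(design, n_otus = config$n_otus))
    counts <- ds$table; metadata <- ds$metadata
    taxonomy <- ds$taxonomy; truth <- ds$truth
    emit_tsv(metadata, "metadata.tsv")
    emit_tsv(as.data.frame(truth), "truth.tsv")
  }

  pm <- NULL
  if ("normalize" %in% config$stages) {
    pm <- run_stage("normalize", {
      filtered <- suppressMessages(filter_prevalence(counts, config$prevalence))
      normalize_per_mille(filtered)
    })
    p <- file.path(out_dir, "otu_table_per_mille.tsv")
    write_otu_table(pm, p); written <- c(written, "otu_table_per_mille.tsv")
  }

  if ("structure" %in% config$stages) {
    run_stage("structure", {
      d <- bray_curtis(log2_per_mille(pm, config$pseudocount))
      ord <- pcoa(d)
      emit_tsv(data.frame(sample_id = rownames(ord$coordinates),
                          ord$coordinates[, seq_len(min(5, ncol(ord$coordinates)))]),
               "pcoa_coordinates.tsv")
      emit_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                          eigenvalue = ord$eigenvalues,
                          proportion = ord$proportion_explained),
               "pcoa_eigenvalues.tsv")
      terms <- intersect(c("compartment", "site", "age_days"),
                         colnames(metadata))
      terms <- terms[vapply(terms,
                            function(t) length(unique(metadata[[t]])) > 1,
                            logical(1))]
      pv <- permanova(d, metadata, terms, n_perm = config$n_perm,
                      seed = .stage_seed(config$seed, 1L))
      emit_tsv(pv, "permanova.tsv")
    })
  }

  if ("trends" %in% config$stages && !is.null(taxonomy)) {
    run_stage("trends", {
      phyla <- aggregate_taxonomy(pm, taxonomy, rank = "phylum",
                                  split_proteobacteria = TRUE)
      emit_tsv(spatial_phylum_trends(phyla, metadata, config$alpha),
               "spatial_trends.tsv")
      emit_tsv(temporal_phylum_trends(phyla, metadata, config$alpha),
               "temporal_trends.tsv")
    })
  }

  calls <- NULL
  if ("colonizers" %in% config$stages) {
    calls <- run_stage("colonizers",
                       classify_colonizers(pm, metadata, alpha = config$alpha))
    emit_tsv(calls, "colonizer_calls.tsv")
  }

  if ("maturity" %in% config$stages) {
    run_stage("maturity", {
      split <- split_train_test(metadata, seed = .stage_seed(config$seed, 2L))
      full <- fit_full_forest(pm, metadata, "age_days", split,
                              n_trees = config$n_trees,
                              seed = .stage_seed(config$seed, 3L))
      cv <- cv_feature_elimination(pm, metadata, "age_days", full$importance,
                                   split, fixed_size = config$sparse_size,
                                   seed = .stage_seed(config$seed, 4L))
      sel <- full$importance$otu_id[seq_len(cv$selection)]
      model <- fit_sparse_model(pm, metadata, "age_days", sel, split,
                                n_trees = config$n_trees,
                                seed = .stage_seed(config$seed, 5L))
      preds <- predict_maturity(model, pm, metadata)
      preds$set <- ifelse(preds$sample_id %in% split$train, "train",
                          ifelse(preds$sample_id %in% split$test, "test", "other"))
      emit_tsv(data.frame(subset_size = cv$subset_sizes,
                          cv_mse = cv$cv_error), "cv_curve.tsv")
      emit_tsv(preds, "age_predictions.tsv")
      emit_json(list(response = model$response, otus = model$otus,
                     oob_variance_explained = model$oob_variance_explained),
                "age_model.json")
    })
  }

  if ("site_dynamics" %in% config$stages &&
      length(unique(metadata$site)) == 2) {
    run_stage("site_dynamics", {
      d <- bray_curtis(pm)
      conv <- between_site_distances(d, metadata)
      emit_tsv(conv$trends, "convergence_trends.tsv")
      skew <- site_specific_otus(counts, metadata, alpha = config$alpha)
      emit_tsv(skew, "site_skew_calls.tsv")
      frac <- site_specific_fraction(pm, skew, metadata)
      emit_tsv(frac$trends, "site_specific_fraction_trends.tsv")
    })
  }

  cfg <- unclass(config)
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  manifest <- list(
    package = "rhizochron",
    version = as.character(utils::packageVersion("rhizochron")),
    master_seed = config$seed,
    config = cfg,
    outputs = lapply(stats::setNames(sort(written), sort(written)), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    }))
  emit_json(manifest, "manifest.json")
  invisible(manifest)
}
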