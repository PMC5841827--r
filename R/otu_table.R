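#' Construct an OTU table
#'
#' An `otu_table` is a non-negative numeric matrix with OTUs as rows and
#' samples as columns, tagged with its unit: raw sequence counts
#' (`"raw_counts"`) or per-mille relative abundance (`"per_mille"`, every
#' column summing to 1000).
#'
#' @param values Numeric matrix, OTUs x samples, with unique row and column
#'   names.
#' @param unit `"raw_counts"` (all values integer) or `"per_mille"` (column
#'   sums 1000 within 1e-6).
#' @return An object of class `otu_table`: a list with elements `values` and
#'   `unit`.
#' @export
otu_table <- function(values, unit = c("raw_counts", "per_mille")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (OTUs x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry OTU ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate OTU ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (anyNA(values) || any(values < 0)) {
    bad <- which(is.na(values) | values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative or missing value at OTU '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (unit == "raw_counts" && any(abs(values - round(values)) > 1e-8)) {
    stop("raw_counts tables must contain integers")
  }
  if (unit == "per_mille") {
    cs <- colSums(values)
    if (any(abs(cs - 1000) > 1e-6)) {
      stop("per_mille columns must sum to 1000; offending sample: ",
           colnames(values)[which.max(abs(cs - 1000))])
    }
  }
  structure(list(values = values, unit = unit), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
otu_ids <- function(x) rownames(x$values)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x$values)

#' Normalize counts to per-mille relative abundance
#'
#' Divides each count by its sample's total sequencing depth and multiplies by
#' 1000, so abundances are expressed in units of per mille and columns sum to
#' 1000.
#'
#' @param table An `otu_table` with unit `raw_counts`.
#' @return An `otu_table` with unit `per_mille`.
#' @export
normalize_per_mille <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (table$unit != "raw_counts") stop("expected a raw_counts table")
  depth <- colSums(table$values)
  if (any(depth == 0)) {
    stop("sample(s) with zero total counts cannot be normalized: ",
         paste(colnames(table$values)[depth == 0], collapse = ", "))
  }
  v <- sweep(table$values, 2, depth, "/") * 1000
  otu_table(v, unit = "per_mille")
}

#' Filter OTUs by prevalence
#'
#' Removes OTUs present (abundance > 0) in fewer than `min_fraction` of the
#' samples; an OTU present in exactly `min_fraction` of the samples is
#' retained (removal is strictly-less-than the threshold). The number of OTUs
#' removed is reported via `message()` and attached as attribute
#' `"n_removed"`.
#'
#' @param table An `otu_table` (either unit).
#' @param min_fraction Prevalence threshold in (0, 1]; default 0.05.
#' @return The filtered `otu_table` (sample set unchanged).
#' @export
filter_prevalence <- function(table, min_fraction = 0.05) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("`min_fraction` must lie in (0, 1]")
  }
  prev <- rowMeans(table$values > 0)
  keep <- prev >= min_fraction
  n_removed <- sum(!keep)
  message(sprintf("filter_prevalence: removed %d of %d OTUs below prevalence %.3g",
                  n_removed, length(keep), min_fraction))
  if (!any(keep)) warning("all OTUs removed by prevalence filter")
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Aggregate an OTU table to a taxonomic rank
#'
#' Sums per-sample abundances of all member OTUs at the requested rank. OTUs
#' unassigned at that rank are pooled into an explicit `unclassified_<rank>`
#' row so per-sample totals are conserved. With `split_proteobacteria = TRUE`
#' and `rank = "phylum"`, rows for the phylum Proteobacteria are replaced by
#' its classes (the phylum is phylogenetically broad and typically dominant in
#' root microbiota, so its classes are more informative trend units).
#'
#' @param table An `otu_table`, typically per-mille.
#' @param taxonomy Taxonomy data frame from [read_taxonomy()] (columns
#'   `otu_id` and the six ranks).
#' @param rank One of kingdom, phylum, class, order, family, genus.
#' @param split_proteobacteria Replace the Proteobacteria phylum row with its
#'   classes (only meaningful at rank `"phylum"`).
#' @return An `otu_table` keyed by taxon (same unit as the input).
#' @export
aggregate_taxonomy <- function(table, taxonomy, rank = "phylum",
                               split_proteobacteria = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  if (!rank %in% .RANKS) stop("unknown rank: ", rank)
  idx <- match(otu_ids(table), taxonomy$otu_id)
  if (anyNA(idx)) {
    stop("OTUs missing from taxonomy: ",
         paste(utils::head(otu_ids(table)[is.na(idx)], 5), collapse = ", "))
  }
  lab <- taxonomy[[rank]][idx]
  lab[is.na(lab) | lab == "" | lab == "unassigned"] <- paste0("unclassified_", rank)
  if (split_proteobacteria && rank == "phylum") {
    is_proteo <- taxonomy$phylum[idx] %in% "Proteobacteria"
    cls <- taxonomy$class[idx]
    cls[is.na(cls) | cls == "" | cls == "unassigned"] <- "unclassified_Proteobacteria"
    lab[is_proteo] <- cls[is_proteo]
  }
  agg <- rowsum(table$values, group = lab)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  out <- table
  out$values <- agg
  # column sums conserved exactly; per-mille tag kept when input was per-mille
  if (table$unit == "per_mille") {
    cs <- colSums(agg)
    stopifnot(all(abs(cs - 1000) < 1e-6))
  }
  out
}
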