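#' Read an OTU count table
#'
#' Tab-delimited dialect: first column holds OTU ids, header row holds sample
#' ids, cells are non-negative integer counts. BIOM 1.0 JSON is supported via
#' the biomformat package.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @return An `otu_table` with unit `raw_counts`, preserving input order.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("OTU table '", path, "' is empty")
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m, unit = "raw_counts"))
  }
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse OTU table '", path, "': ", conditionMessage(e))
  )
  if (nrow(df) == 0 || ncol(df) < 2) stop("OTU table '", path, "' is empty")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate OTU id in '", path, "': ", ids[duplicated(ids)][1])
  }
  m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1,
              dimnames = list(ids, colnames(df)[-1]))
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric cell in column '%s', row '%s'",
                   colnames(df)[j], ids[which(is.na(v))[1]]))
    }
    if (any(v < 0)) {
      stop(sprintf("negative count in column '%s', row '%s'",
                   colnames(df)[j], ids[which(v < 0)[1]]))
    }
    m[, j - 1] <- v
  }
  otu_table(m, unit = "raw_counts")
}

#' Write an OTU table as tab-delimited text
#'
#' @param table An `otu_table`.
#' @param path Output path; first column `otu_id`, one column per sample.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(otu_id = otu_ids(table), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-compartment spatial position code
#'
#' Compartments are coded by distance from the root interior: bulk soil 0,
#' rhizosphere 1, rhizoplane 2, endosphere 3.
#'
#' @param compartment Character vector of compartment names.
#' @return Integer positions 0-3.
#' @export
compartment_position <- function(compartment) {
  codes <- c(bulk_soil = 0L, rhizosphere = 1L, rhizoplane = 2L, endosphere = 3L)
  bad <- setdiff(unique(compartment), names(codes))
  if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  unname(codes[compartment])
}

#' Read sample metadata
#'
#' Tab-delimited with one row per sample. Required columns: `sample_id` and
#' `compartment`; the spatial `position` (0-3) is derived from the
#' compartment. Optional columns used downstream: `site`, `season`,
#' `age_days`, `genotype`, `dev_stage` (1-27, NA allowed), `treatment`,
#' `soil`, `sequencing_run`.
#'
#' @param path Path to the metadata file.
#' @return A data frame with a `position` column added.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "compartment")
  miss <- setdiff(req, colnames(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id: ", md$sample_id[duplicated(md$sample_id)][1])
  }
  md$position <- compartment_position(md$compartment)
  if ("age_days" %in% colnames(md) && any(md$age_days <= 0, na.rm = TRUE)) {
    stop("age_days must be positive")
  }
  if ("dev_stage" %in% colnames(md)) {
    ds <- md$dev_stage
    if (any(!is.na(ds) & (ds < 1 | ds > 27))) stop("dev_stage must lie in [1, 27]")
  }
  md
}

#' Parse Greengenes-style lineage strings
#'
#' Lineages of the form `k__Bacteria; p__Proteobacteria; c__...; o__; f__;
#' g__` are split into the six ranks; empty ranks become `"unassigned"`.
#'
#' @param otu_id Character vector of OTU ids.
#' @param lineage Character vector of lineage strings, same length.
#' @return Data frame with columns `otu_id`, `kingdom` ... `genus`.
#' @export
parse_greengenes <- function(otu_id, lineage) {
  if (anyDuplicated(otu_id)) stop("duplicate otu_id in taxonomy")
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__")
  out <- data.frame(otu_id = otu_id, stringsAsFactors = FALSE)
  pieces <- strsplit(lineage, ";\\s*")
  for (r in seq_along(.RANKS)) {
    val <- vapply(pieces, function(p) {
      hit <- p[startsWith(p, prefixes[r])]
      if (length(hit) == 0) return("unassigned")
      v <- sub(prefixes[r], "", hit[1], fixed = TRUE)
      if (!nzchar(v)) "unassigned" else v
    }, character(1))
    out[[.RANKS[r]]] <- val
  }
  out
}

#' Read a two-column taxonomy file (otu_id, Greengenes lineage)
#'
#' @param path Path to the taxonomy tsv. A header row naming the first column
#'   `otu_id` is accepted and skipped.
#' @return Data frame as produced by [parse_greengenes()].
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tx <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tx) < 2) stop("taxonomy file must have two columns: otu_id, lineage")
  if (tolower(tx[1, 1]) %in% c("otu_id", "#otu id", "otu")) tx <- tx[-1, , drop = FALSE]
  parse_greengenes(tx[[1]], tx[[2]])
}
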