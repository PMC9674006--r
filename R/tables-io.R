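#' @keywords internal
"_PACKAGE"

## Canonical factor levels for the field design
.MANAGEMENTS <- c("conventional", "no_till")
.TREATMENTS <- c("control", "fungicide")
.CROPS <- c("maize", "soybean")
.COMPARTMENTS <- c("leaf", "root")
.META_COLS <- c("sample_id", "crop", "management", "treatment", "dpf",
                "replicate_plot", "compartment")

#' Validate an OTU count table
#'
#' An OTU table is a non-negative integer matrix with taxa as rows and
#' samples as columns; row and column names are the taxon and sample
#' identifiers and must be unique.
#'
#' @param x matrix to validate.
#' @param min_samples minimum number of sample columns required.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_otu_table <- function(x, min_samples = 1L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("OTU table must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("OTU table must have taxon row names and sample column names")
  dup_t <- rownames(x)[duplicated(rownames(x))]
  if (length(dup_t))
    stop("duplicate taxon id(s): ", paste(unique(dup_t), collapse = ", "))
  dup_s <- colnames(x)[duplicated(colnames(x))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(x))
    stop("OTU table contains missing values")
  bad <- which(x < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  if (nrow(x) < 1L) stop("OTU table must contain at least one taxon")
  if (ncol(x) < min_samples)
    stop("OTU table must contain at least ", min_samples, " samples")
  invisible(x)
}

#' Read an OTU table from TSV or BIOM-JSON
#'
#' TSV dialect: UTF-8, tab-separated, header row of sample ids with first
#' header cell `taxon_id`, one row per taxon. BIOM (JSON flavour) files are
#' read through the biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return validated numeric matrix, taxa x samples, file order preserved.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("biomformat package required for BIOM input")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(validate_otu_table(m))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stop("OTU table TSV needs a taxon_id column and >=1 sample")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate taxon id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric count at row %d (taxon '%s'), column '%s'",
                   bad[1, 1], ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]]))
    stop("non-numeric counts in ", path)
  }
  rownames(m) <- ids
  validate_otu_table(m)
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table()]: integer counts round-trip bit-stably.
#'
#' @param x OTU table matrix.
#' @param path output path.
#' @export
write_otu_table <- function(x, path) {
  validate_otu_table(x)
  df <- data.frame(taxon_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with a `taxon_id` column plus one column per rank (e.g. kingdom,
#' phylum, class, order, family, genus). Empty or NA rank labels are stored
#' as the explicit sentinel `"unclassified"`.
#'
#' @param path file path.
#' @return data.frame with unique `taxon_id` and character rank columns.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!"taxon_id" %in% colnames(df))
    stop("taxonomy table missing required column: taxon_id")
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon id(s) in taxonomy: ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "))
  for (cc in setdiff(colnames(df), "taxon_id")) {
    v <- as.character(df[[cc]])
    v[is.na(v) | v == ""] <- "unclassified"
    df[[cc]] <- v
  }
  df
}

#' Write a taxonomy or generic results table as TSV
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_results <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate the sample metadata table
#'
#' Required columns: sample_id, crop, management, treatment, dpf,
#' replicate_plot, compartment. Factor columns are checked against the
#' design's declared levels; `dpf` is days post fungicide with the pre-spray
#' sampling encoded as 0.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param meta metadata data.frame to validate in place.
#' @export
validate_metadata <- function(meta) {
  miss <- setdiff(.META_COLS, colnames(meta))
  if (length(miss))
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id(s) in metadata")
  chk <- function(col, levels) {
    bad <- setdiff(unique(as.character(meta[[col]])), levels)
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s (expected: %s)", col,
                   paste(bad, collapse = ", "), paste(levels, collapse = ", ")))
  }
  chk("crop", .CROPS); chk("management", .MANAGEMENTS)
  chk("treatment", .TREATMENTS); chk("compartment", .COMPARTMENTS)
  if (!is.numeric(meta$dpf) || anyNA(meta$dpf) || any(meta$dpf < 0))
    stop("dpf must be non-negative numeric (0 = pre-spray)")
  meta
}

## align metadata rows to the table's sample columns, erroring on mismatch
align_metadata <- function(x, meta) {
  miss <- setdiff(colnames(x), meta$sample_id)
  if (length(miss))
    stop("samples absent from metadata: ", paste(utils::head(miss, 5), collapse = ", "))
  meta[match(colnames(x), meta$sample_id), , drop = FALSE]
}

#' Convert counts to per-sample relative abundances
#'
#' @param x OTU table matrix (taxa x samples).
#' @return matrix of the same shape whose columns each sum to 1.
#' @export
to_relative_abundance <- function(x) {
  validate_otu_table(x)
  cs <- colSums(x)
  if (any(cs == 0))
    stop("all-zero sample(s): ", paste(colnames(x)[cs == 0], collapse = ", "))
  sweep(x, 2, cs, "/")
}

#' Abundance/occupancy pre-filter for OTU tables
#'
#' Retains taxa whose mean per-sample relative abundance is at least
#' `mean_rel_min` and whose fraction of zero-count samples is strictly below
#' `zero_sample_frac`. The boundary conventions (mean exactly at the
#' threshold kept; zero fraction exactly at the threshold dropped) follow
#' the filtering rule "mean relative abundance less than 1e-5 ... zeros
#' present in 95% of samples were discarded".
#'
#' @param x OTU table matrix.
#' @param mean_rel_min minimum mean relative abundance (default 1e-5).
#' @param zero_sample_frac zero-occupancy fraction at or above which a taxon
#'   is dropped (default 0.95).
#' @param pooled if TRUE, mean relative abundance is computed from pooled
#'   counts instead of the per-sample mean.
#' @return list with `table` (filtered matrix) and `dropped` (taxon ids).
#' @export
filter_taxa <- function(x, mean_rel_min = 1e-5, zero_sample_frac = 0.95,
                        pooled = FALSE) {
  validate_otu_table(x)
  stopifnot(mean_rel_min >= 0, mean_rel_min <= 1,
            zero_sample_frac >= 0, zero_sample_frac <= 1)
  rel <- to_relative_abundance(x)
  mean_rel <- if (pooled) rowSums(x) / sum(x) else rowMeans(rel)
  zero_frac <- rowMeans(x == 0)
  keep <- (mean_rel >= mean_rel_min) & (zero_frac < zero_sample_frac)
  if (!any(keep))
    stop("filter_taxa removed every taxon; downstream analyses undefined")
  list(table = x[keep, , drop = FALSE], dropped = rownames(x)[!keep])
}

#' Drop taxa that never occur in fungicide-treated samples
#'
#' ANCOM-specific pre-filter: taxa with zero total count across all
#' fungicide-treated samples cannot respond to the treatment and are
#' excluded before differential-abundance testing.
#'
#' @param x OTU table matrix.
#' @param meta sample metadata covering the table's samples.
#' @inherit filter_taxa return
#' @export
filter_taxa_for_ancom <- function(x, meta) {
  validate_otu_table(x)
  meta <- align_metadata(x, meta)
  fung <- meta$treatment == "fungicide"
  if (!any(fung)) stop("no fungicide-treated samples in metadata")
  keep <- rowSums(x[, fung, drop = FALSE]) > 0
  if (!any(keep))
    stop("filter_taxa_for_ancom removed every taxon")
  list(table = x[keep, , drop = FALSE], dropped = rownames(x)[!keep])
}

#' Drop an explicit list of taxa (e.g. known contaminants)
#' @param x OTU table matrix.
#' @param taxa character vector of taxon ids to remove.
#' @return filtered matrix.
#' @export
drop_taxa <- function(x, taxa) {
  validate_otu_table(x)
  x[setdiff(rownames(x), taxa), , drop = FALSE]
}
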