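## Disturbance-response classification and abundance-occupancy core
## detection.
##
## Recovery classes, from the ANCOM time series of a stratum:
##   recovered       significant at the first post-spray point but not for
##                   the remainder of the sampling (transient effect)
##   non_recovered   significant at the first post-spray point and at every
##                   later point
##   locally_extinct non-recovered taxa that were present pre-spray, have
##                   zero counts in all fungicide samples at every
##                   post-spray point, and persist in control plots
##   indirect        not significant at the first post-spray point but
##                   significant at the final one
##   unaffected      everything else

#' Pure recovery-classification rule
#'
#' Maps one taxon's evidence tuple to its disturbance-response class.
#' `sig_rest` is "significant at every post-spray point after the first"
#' (equal to `sig_last` when there are exactly two post-spray points).
#'
#' @param sig_first significant at the first post-spray dpf.
#' @param sig_rest significant at all later post-spray dpf.
#' @param sig_last significant at the final dpf.
#' @param present_pre nonzero count in >= 1 pre-spray sample.
#' @param zero_post_fungicide zero counts in all fungicide samples at every
#'   post-spray dpf.
#' @param present_control nonzero in >= 1 control sample at each post-spray
#'   dpf.
#' @return one of `"recovered"`, `"non_recovered"`, `"locally_extinct"`,
#'   `"indirect"`, `"unaffected"`.
#' @export
recovery_rule <- function(sig_first, sig_rest, sig_last, present_pre,
                          zero_post_fungicide, present_control) {
  if (sig_first && sig_rest) {
    if (present_pre && zero_post_fungicide && present_control)
      "locally_extinct" else "non_recovered"
  } else if (sig_first) {
    "recovered"
  } else if (sig_last) {
    "indirect"
  } else {
    "unaffected"
  }
}

#' Classify taxon recovery dynamics from an ANCOM time series
#'
#' Applies [recovery_rule()] to every taxon in the stratum's ANCOM taxon
#' universe, deriving the presence/absence evidence from the stratum's
#' counts: pre-spray presence uses any dpf-0 sample, the extinction
#' condition requires zero counts in all fungicide samples at every
#' post-spray dpf, and control persistence requires a nonzero count in at
#' least one control sample at each post-spray dpf.
#'
#' @param ts one stratum's `ancom_time_series` (an element of
#'   [ancom_by_stratum()] output).
#' @param x OTU table covering the stratum's samples (may be the full
#'   table; it is subset to the stratum).
#' @param meta sample metadata.
#' @return `recovery_classification`: data.frame with taxon_id, class and
#'   per-evidence columns.
#' @export
classify_recovery <- function(ts, x, meta) {
  stopifnot(inherits(ts, "ancom_time_series"))
  if (length(ts$post_dpf) < 2)
    stop("need >= 2 post-spray time points to classify recovery")
  meta <- align_metadata(x, meta)
  sel <- meta$crop == ts$crop & meta$management == ts$management
  x <- x[, sel, drop = FALSE]
  meta <- meta[sel, , drop = FALSE]
  taxa <- ts$taxa
  miss <- setdiff(taxa, rownames(x))
  if (length(miss))
    stop("taxa in time series absent from table: ",
         paste(utils::head(miss, 5), collapse = ", "))

  first <- as.character(ts$post_dpf[1])
  last <- as.character(ts$post_dpf[length(ts$post_dpf)])
  rest <- as.character(ts$post_dpf[-1])
  sig_of <- function(dd) {
    r <- ts$results[[dd]]
    stats::setNames(r$significant, r$taxon_id)[taxa]
  }
  dir_of <- function(dd) {
    r <- ts$results[[dd]]
    stats::setNames(r$direction, r$taxon_id)[taxa]
  }
  sig_first <- sig_of(first)
  sig_last <- sig_of(last)
  sig_rest <- Reduce(`&`, lapply(rest, sig_of))

  pre <- meta$dpf == 0
  present_pre <- rowSums(x[taxa, pre, drop = FALSE] > 0) > 0
  zero_post_f <- rep(TRUE, length(taxa))
  present_ctrl <- rep(TRUE, length(taxa))
  for (dd in ts$post_dpf) {
    fsel <- meta$dpf == dd & meta$treatment == "fungicide"
    csel <- meta$dpf == dd & meta$treatment == "control"
    zero_post_f <- zero_post_f &
      rowSums(x[taxa, fsel, drop = FALSE]) == 0
    present_ctrl <- present_ctrl &
      rowSums(x[taxa, csel, drop = FALSE] > 0) > 0
  }

  cls <- vapply(seq_along(taxa), function(i)
    recovery_rule(sig_first[i], sig_rest[i], sig_last[i], present_pre[i],
                  zero_post_f[i], present_ctrl[i]), "")
  out <- data.frame(taxon_id = taxa, class = cls,
                    sig_first = unname(sig_first),
                    sig_rest = unname(sig_rest),
                    sig_last = unname(sig_last),
                    dir_first = unname(dir_of(first)),
                    dir_last = unname(dir_of(last)),
                    present_pre = unname(present_pre),
                    zero_post_fungicide = unname(zero_post_f),
                    present_control = unname(present_ctrl),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("recovery_classification", "data.frame")
  out
}

#' Summarise recovery percentages
#'
#' Percentage of each disturbance class among the affected taxa. The
#' default denominator counts taxa significantly reduced at the first
#' post-spray point (recovered + non-recovered + locally extinct, with
#' direction < 0); `denominator = "all_affected"` drops the direction
#' requirement. Indirect and unaffected taxa are excluded from the
#' denominator in both variants.
#'
#' @param rc a [classify_recovery()] result.
#' @param subset optional character vector of taxon ids to restrict to
#'   (e.g. one family's taxa).
#' @param denominator `"decreased"` (default) or `"all_affected"`.
#' @return list with `n_affected`, per-class counts and `pct` percentages.
#' @export
recovery_summary <- function(rc, subset = NULL,
                             denominator = c("decreased", "all_affected")) {
  denominator <- match.arg(denominator)
  df <- as.data.frame(rc)
  if (!is.null(subset)) df <- df[df$taxon_id %in% subset, , drop = FALSE]
  affected <- df$class %in% c("recovered", "non_recovered", "locally_extinct")
  if (denominator == "decreased") affected <- affected & df$dir_first < 0
  n <- sum(affected)
  if (n == 0) stop("no affected taxa in subset; recovery percentage undefined")
  counts <- table(factor(df$class[affected],
                         levels = c("recovered", "non_recovered",
                                    "locally_extinct")))
  pct <- stats::setNames(100 * as.numeric(counts) / n, names(counts))
  list(n_affected = n, counts = as.list(counts), pct = as.list(pct),
       denominator = denominator)
}

#' Per-taxon occupancy and mean relative abundance
#'
#' Occupancy is the fraction of samples in which the taxon has count > 0.
#'
#' @param x OTU table matrix.
#' @return data.frame (taxon_id, occupancy, mean_rel_abundance).
#' @export
occupancy_abundance <- function(x) {
  validate_otu_table(x)
  rel <- to_relative_abundance(x)
  data.frame(taxon_id = rownames(x), occupancy = rowMeans(x > 0),
             mean_rel_abundance = rowMeans(rel),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Abundance-occupancy core microbiome detection
#'
#' Taxa are ranked by occupancy (ties by mean relative abundance, then
#' taxon id). Bray-Curtis similarity between two relative-abundance
#' profiles decomposes additively over taxa
#' (1 - d = sum_i min(x_i, y_i) when both profiles sum to 1), so each
#' taxon's contribution is its mean min-share over all sample pairs. The
#' core is the minimal ranked prefix beyond which the remaining cumulative
#' contribution is below `threshold` (default: the last 2%) of the total
#' similarity.
#'
#' Callers should restrict `x` to the non-disturbed samples of one
#' management before calling.
#'
#' @param x OTU table matrix (>= 2 samples).
#' @param threshold final fraction of Bray-Curtis similarity left outside
#'   the core (default 0.02).
#' @return `core_membership`: data.frame in rank order with taxon_id,
#'   occupancy, mean_rel_abundance, contribution, cumulative (normalised,
#'   non-decreasing, ending at 1) and core flag; attribute
#'   `threshold_rank`.
#' @export
core_taxa <- function(x, threshold = 0.02) {
  validate_otu_table(x, min_samples = 2L)
  stopifnot(threshold > 0, threshold < 1)
  occ <- occupancy_abundance(x)
  ord <- order(-occ$occupancy, -occ$mean_rel_abundance, occ$taxon_id)
  occ <- occ[ord, , drop = FALSE]
  rel <- to_relative_abundance(x)[occ$taxon_id, , drop = FALSE]
  n <- ncol(rel)
  contrib <- numeric(nrow(rel))
  n_pairs <- 0L
  for (p in seq_len(n - 1)) for (q in seq(p + 1, n)) {
    contrib <- contrib + pmin(rel[, p], rel[, q])
    n_pairs <- n_pairs + 1L
  }
  contrib <- contrib / n_pairs
  total <- sum(contrib)
  if (total <= 0)
    stop("zero mean Bray-Curtis similarity; core undefined")
  cumu <- cumsum(contrib) / total
  threshold_rank <- which(cumu >= 1 - threshold)[1]
  out <- data.frame(occ, contribution = contrib, cumulative = cumu,
                    core = seq_along(cumu) <= threshold_rank,
                    row.names = NULL)
  attr(out, "threshold_rank") <- threshold_rank
  attr(out, "threshold") <- threshold
  class(out) <- c("core_membership", "data.frame")
  out
}
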