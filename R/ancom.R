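## ANCOM differential abundance: for every taxon, count how many of its
## pairwise additive log-ratio tests against the other taxa reject the
## between-group null (the W statistic). A taxon is called significant when
## W exceeds a threshold fraction (default 70%) of the taxa tested.

## two-sided two-sample rank-sum p-value, normal approximation with tie
## correction and continuity correction (matches
## wilcox.test(exact = FALSE, correct = TRUE))
rank_sum_p <- function(v, idx1, n1, n2) {
  rk <- rank(v)
  nt <- n1 + n2
  u <- sum(rk[idx1]) - n1 * (n1 + 1) / 2
  z <- u - n1 * n2 / 2
  cnt <- tabulate(match(v, unique(v)))
  ties <- sum(cnt^3 - cnt)
  sigma2 <- (n1 * n2 / 12) * ((nt + 1) - ties / (nt * (nt - 1)))
  if (sigma2 <= 0) return(1)
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

#' ANCOM W statistic for a two-group comparison
#'
#' For each ordered pair of taxa (i, j), the additive log-ratio
#' log((c_i + pc) / (c_j + pc)) is tested between the two groups with the
#' two-sample rank-sum test (normal approximation, tie and continuity
#' corrected). Within each reference taxon i, its m - 1 p-values are
#' Benjamini-Hochberg adjusted at `alpha`; W_i counts the rejections.
#' A taxon is significant when W_i > `w_threshold` x (m - 1).
#'
#' The direction reported is the sign of the difference in median CLR
#' abundance (second factor level minus first); `effect_ratio` is the
#' ratio of group mean relative abundances on the same orientation.
#'
#' @param x OTU table matrix, pre-filtered (see [filter_taxa()] and
#'   [filter_taxa_for_ancom()]); needs >= 3 taxa.
#' @param groups two-level factor over samples; the second level is the
#'   "treated" orientation for direction/effect_ratio (conventionally
#'   `levels = c("control", "fungicide")`).
#' @param alpha per-reference-taxon BH level (default 0.05).
#' @param w_threshold fraction of taxa tested that W must exceed (0.70).
#' @param pseudocount added to counts before log ratios (default 1).
#' @return data.frame (taxon_id, w, w_frac, significant, direction,
#'   effect_ratio) with run metadata in attributes.
#' @export
ancom_w <- function(x, groups, alpha = 0.05, w_threshold = 0.70,
                    pseudocount = 1) {
  validate_otu_table(x, min_samples = 2L)
  stopifnot(pseudocount > 0)
  m <- nrow(x)
  if (m < 3) stop("ANCOM W needs at least 3 taxa after filtering")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  if (length(groups) != ncol(x)) stop("groups length must match samples")
  if (any(table(groups) < 3)) stop("both groups need >= 3 samples")
  if (any(colSums(x) == 0))
    stop("all-zero sample(s) in comparison: ",
         paste(colnames(x)[colSums(x) == 0], collapse = ", "))

  lc <- log(x + pseudocount)
  idx1 <- which(groups == levels(groups)[1])
  n1 <- length(idx1); n2 <- ncol(x) - n1

  pmat <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) {
    di <- sweep(lc[(i + 1):m, , drop = FALSE], 2, lc[i, ], "-")
    pv <- apply(di, 1, rank_sum_p, idx1 = idx1, n1 = n1, n2 = n2)
    pmat[(i + 1):m, i] <- pv
    pmat[i, (i + 1):m] <- pv
  }
  w <- vapply(seq_len(m), function(i)
    sum(stats::p.adjust(pmat[i, -i], "BH") <= alpha), 0L)

  clr_x <- clr(x, pseudocount)
  g2 <- groups == levels(groups)[2]
  med_diff <- apply(clr_x[, g2, drop = FALSE], 1, stats::median) -
    apply(clr_x[, !g2, drop = FALSE], 1, stats::median)
  rel <- to_relative_abundance(x)
  mean2 <- rowMeans(rel[, g2, drop = FALSE])
  mean1 <- rowMeans(rel[, !g2, drop = FALSE])
  out <- data.frame(taxon_id = rownames(x), w = w, w_frac = w / (m - 1),
                    significant = w > w_threshold * (m - 1),
                    direction = sign(med_diff),
                    effect_ratio = ifelse(mean1 > 0, mean2 / mean1, Inf),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "meta") <- list(m = m, alpha = alpha, w_threshold = w_threshold,
                            pseudocount = pseudocount,
                            group_levels = levels(groups),
                            n_per_group = as.vector(table(groups)))
  out
}

#' ANCOM time series per (crop, management) stratum
#'
#' Within each stratum, taxa are pre-filtered (abundance/occupancy plus
#' the never-in-fungicide rule) on the full stratum so every time point
#' shares one taxon universe, then fungicide vs control is tested at each
#' dpf. The pre-spray point (dpf 0) serves as a negative-control
#' comparison.
#'
#' @param x fungal OTU table.
#' @param meta sample metadata covering the table.
#' @param alpha,w_threshold,pseudocount passed to [ancom_w()].
#' @param mean_rel_min,zero_sample_frac passed to [filter_taxa()].
#' @return named list (one element per `crop.management` stratum) of
#'   `ancom_time_series` objects: list(crop, management, dpf, post_dpf,
#'   taxa, results = per-dpf [ancom_w()] tables).
#' @export
ancom_by_stratum <- function(x, meta, alpha = 0.05, w_threshold = 0.70,
                             pseudocount = 1, mean_rel_min = 1e-5,
                             zero_sample_frac = 0.95) {
  validate_otu_table(x)
  meta <- align_metadata(x, meta)
  strata <- unique(meta[, c("crop", "management")])
  out <- list()
  for (k in seq_len(nrow(strata))) {
    cr <- strata$crop[k]; mg <- strata$management[k]
    sel <- meta$crop == cr & meta$management == mg
    sub <- x[, sel, drop = FALSE]
    msub <- meta[sel, , drop = FALSE]
    filt <- filter_taxa(sub, mean_rel_min, zero_sample_frac)$table
    filt <- filter_taxa_for_ancom(filt, msub)$table
    dpfs <- sort(unique(msub$dpf))
    results <- list()
    for (dd in dpfs) {
      dsel <- msub$dpf == dd
      trt <- table(msub$treatment[dsel])
      if (length(trt) < 2 || any(trt == 0))
        stop(sprintf("stratum %s/%s dpf %s lacks both treatments", cr, mg, dd))
      grp <- factor(msub$treatment[dsel], levels = c("control", "fungicide"))
      results[[as.character(dd)]] <-
        ancom_w(filt[, dsel, drop = FALSE], grp, alpha = alpha,
                w_threshold = w_threshold, pseudocount = pseudocount)
    }
    ts <- list(crop = cr, management = mg, dpf = dpfs,
               post_dpf = dpfs[dpfs > 0], taxa = rownames(filt),
               results = results)
    class(ts) <- "ancom_time_series"
    out[[paste(cr, mg, sep = ".")]] <- ts
  }
  out
}
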