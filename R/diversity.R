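## Bray-Curtis distances, richness, PERMANOVA, multivariate dispersion and
## partial constrained analysis of principal coordinates (CAP), with
## permutation inference. Distance-based machinery is delegated to vegan
## (vegdist / adonis2 / betadisper / capscale); this module owns input
## validation, the module contracts and tidy result containers.

#' Bray-Curtis distance matrix between samples
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed on the columns of
#' an OTU or relative-abundance table. Values lie in `[0, 1]`; when given
#' relative abundances the result is invariant to per-sample rescaling.
#'
#' @param x taxa x samples matrix (counts or proportions).
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(x) {
  validate_otu_table(x, min_samples = 2L)
  if (any(colSums(x) == 0))
    stop("all-zero sample(s): ",
         paste(colnames(x)[colSums(x) == 0], collapse = ", "))
  vegan::vegdist(t(x), method = "bray")
}

#' Per-sample taxon richness, optionally split by a taxonomy rank
#'
#' Richness is the number of taxa with count > 0 in each sample. With
#' `by_rank`, a matrix of per-rank-label richness is returned (labels
#' missing from the taxonomy are counted under `"unclassified"`); its
#' column sums equal total richness.
#'
#' @param x OTU table matrix.
#' @param tax taxonomy data.frame (needed when `by_rank` is given).
#' @param by_rank rank column name (e.g. `"class"`, `"family"`) or NULL.
#' @return integer vector (total) or label x sample integer matrix.
#' @export
richness <- function(x, tax = NULL, by_rank = NULL) {
  validate_otu_table(x)
  if (is.null(by_rank)) return(colSums(x > 0))
  if (is.null(tax)) stop("taxonomy required for by_rank richness")
  lab <- tax[[by_rank]][match(rownames(x), tax$taxon_id)]
  lab[is.na(lab)] <- "unclassified"
  pres <- (x > 0) * 1L
  rowsum(pres, group = lab)
}

#' Richness of one taxonomic group per sample
#' @param x OTU table matrix.
#' @param tax taxonomy data.frame.
#' @param rank rank column name.
#' @param label group label within that rank.
#' @return integer vector of per-sample group richness.
#' @export
group_richness <- function(x, tax, rank, label) {
  ids <- tax$taxon_id[tax[[rank]] == label]
  ids <- intersect(ids, rownames(x))
  if (!length(ids)) stop(sprintf("no taxa with %s == '%s'", rank, label))
  colSums(x[ids, , drop = FALSE] > 0)
}

check_factor_terms <- function(meta, terms) {
  for (tm in terms) {
    base_vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(base_vars, colnames(meta))
    if (length(miss))
      stop("metadata missing term variable(s): ", paste(miss, collapse = ", "))
    for (v in base_vars)
      if (length(unique(meta[[v]])) < 2)
        stop(sprintf("factor '%s' is constant; PERMANOVA term undefined", v))
    if (length(base_vars) > 1) {
      tab <- table(meta[, base_vars, drop = FALSE])
      if (any(tab == 0)) {
        idx <- which(tab == 0, arr.ind = TRUE)[1, ]
        cell <- paste(mapply(function(d, i) dimnames(tab)[[d]][i],
                             seq_along(idx), idx), collapse = " x ")
        stop(sprintf("empty design cell for term '%s': %s", tm, cell))
      }
    }
  }
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the sums of
#' squares of the (Gower-centred) distance matrix by the given factor terms
#' and tests each pseudo-F against `n_perm` label permutations, with the
#' +1 convention p = (1 + #\{F* >= F\}) / (1 + n_perm).
#'
#' @param d `dist` over samples.
#' @param meta metadata data.frame with a `sample_id` column matching the
#'   distance labels.
#' @param terms character vector of term labels (may include `a:b`).
#' @param n_perm number of permutations (>= 99).
#' @param strategy `"sequential"` (Type I, default) or `"margin"`.
#' @param seed optional integer seed for reproducible permutations.
#' @param block optional metadata column restricting permutations within
#'   blocks (e.g. `"replicate_plot"`).
#' @return data.frame with term, df, sum_sq, r2, f, p; attribute `n_perm`.
#' @export
permanova <- function(d, meta, terms, n_perm = 999,
                      strategy = c("sequential", "margin"), seed = NULL,
                      block = NULL) {
  strategy <- match.arg(strategy)
  if (n_perm < 99) stop("n_perm must be >= 99")
  labs <- attr(d, "Labels")
  if (!all(labs %in% meta$sample_id))
    stop("distance labels missing from metadata")
  meta <- meta[match(labs, meta$sample_id), , drop = FALSE]
  check_factor_terms(meta, terms)
  fml <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  perm <- if (is.null(block)) n_perm else
    permute::how(nperm = n_perm, blocks = as.factor(meta[[block]]))
  run <- function() vegan::adonis2(fml, data = meta, permutations = perm,
                                   by = if (strategy == "sequential") "terms"
                                        else "margin")
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  out <- data.frame(term = rownames(res), df = res$Df, sum_sq = res$SumOfSqs,
                    r2 = res$R2, f = res$F, p = res$`Pr(>F)`,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- n_perm
  out
}

#' Multivariate dispersion (distance to group centroid) test
#'
#' Embeds the distance matrix by principal coordinates, computes each
#' sample's distance to its group spatial centroid (real and imaginary
#' axes combined in the standard way), and permutes group labels for
#' significance.
#'
#' @param d `dist` over samples.
#' @param groups grouping factor aligned with the distance labels.
#' @param n_perm number of permutations.
#' @param seed optional seed.
#' @return list with `group_means` (mean distance-to-centroid per group),
#'   `distances` (per sample), `f`, `p`, `n_perm`.
#' @export
beta_dispersion <- function(d, groups, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("need >= 2 groups for dispersion test")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  bd <- vegan::betadisper(d, groups, type = "centroid")
  run <- function() vegan::permutest(bd, permutations = n_perm)
  pt <- if (is.null(seed)) run() else with_seed(seed, run())
  list(group_means = c(tapply(bd$distances, bd$group, mean)),
       distances = bd$distances,
       f = pt$tab$F[1], p = pt$tab$`Pr(>F)`[1], n_perm = n_perm)
}

#' Partial constrained analysis of principal coordinates (CAP)
#'
#' Distance-based redundancy analysis: the distance matrix is embedded by
#' principal coordinates, the conditioning factor (if any) is partialled
#' out, and the remaining variation is regressed on the constraint.
#' `constrained_fraction` is constrained inertia divided by total inertia
#' after removing the conditioned part; significance comes from permuting
#' residuals under the conditioned model. Negative PCoA eigenvalues are
#' retained as-is by default; `correction = "lingoes"` applies the Lingoes
#' adjustment.
#'
#' @param d `dist` over samples.
#' @param meta metadata with `sample_id` matching the distance labels.
#' @param constrain metadata column to constrain on.
#' @param condition optional metadata column to partial out.
#' @param n_perm permutations for the significance test (default 1000).
#' @param seed optional seed.
#' @param correction `"none"` or `"lingoes"`.
#' @return list with `constrained_fraction`, `p`, `n_perm`, `scores`
#'   (per-sample axis scores), and the fitted vegan object as `fit`.
#' @export
cap_partial <- function(d, meta, constrain, condition = NULL, n_perm = 1000,
                        seed = NULL, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  labs <- attr(d, "Labels")
  meta <- meta[match(labs, meta$sample_id), , drop = FALSE]
  if (length(unique(meta[[constrain]])) < 2)
    stop("constraint factor is constant")
  if (!is.null(condition)) {
    ## confounding check: constraint must retain variation within
    ## condition levels
    mm <- stats::model.matrix(~., data.frame(x = factor(meta[[constrain]])))[, -1,
                                                                  drop = FALSE]
    cm <- stats::model.matrix(~., data.frame(z = factor(meta[[condition]])))
    resid <- mm - cm %*% qr.coef(qr(cm), mm)
    if (max(abs(resid)) < 1e-10)
      stop("constraint is fully confounded with condition")
  }
  fml <- if (is.null(condition))
    stats::as.formula(paste("d ~", constrain))
  else
    stats::as.formula(paste("d ~", constrain, "+ Condition(", condition, ")"))
  fit <- vegan::capscale(fml, data = meta,
                         add = if (correction == "lingoes") "lingoes" else FALSE)
  pcond <- if (is.null(fit$pCCA)) 0 else fit$pCCA$tot.chi
  frac <- fit$CCA$tot.chi / (fit$tot.chi - pcond)
  run <- function() stats::anova(fit, permutations = n_perm)
  an <- if (is.null(seed)) run() else with_seed(seed, run())
  sc <- vegan::scores(fit, display = "sites",
                      choices = seq_len(min(2, fit$CCA$rank + 1)))
  list(constrained_fraction = unname(frac), p = an$`Pr(>F)`[1],
       n_perm = n_perm, scores = sc, fit = fit)
}
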