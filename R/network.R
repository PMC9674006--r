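## Cross-domain co-occurrence networks by Meinshausen-Buhlmann (MB)
## neighborhood selection on CLR-transformed counts: each node's CLR
## profile is lasso-regressed on all others over a log-spaced lambda path
## (per-node fits via glmnet), the regularization level is chosen by StARS
## stability selection, edges are symmetrized with the OR rule and the two
## directed coefficients averaged into a signed weight. Per-sample
## subnetworks are the induced subgraphs on the taxa present in a sample.

#' Centred log-ratio transform
#'
#' Per sample: log(count + pseudocount) minus the sample mean of the same;
#' each sample's transformed values sum to zero.
#'
#' @param x OTU table matrix (taxa x samples).
#' @param pseudocount positive value added before the log (default 1).
#' @return real matrix of the same shape.
#' @export
clr <- function(x, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  lx <- log(x + pseudocount)
  sweep(lx, 2, colMeans(lx), "-")
}

## map an unordered node pair (i < j) to its upper-triangle index
## (column-major over the p x p matrix)
pair_index <- function(i, j) (j - 1) * (j - 2) / 2 + i

## one MB lasso path over all nodes; returns sparse selection indicators
## as an (n_pairs x n_lambda) logical matrix (OR rule) and, optionally,
## the directed coefficient matrix at one lambda index
mb_path <- function(X, lambda, coef_at = NULL, rule = c("or", "and")) {
  rule <- match.arg(rule)
  p <- ncol(X); L <- length(lambda)
  n_pairs <- p * (p - 1) / 2
  cnt <- matrix(0L, n_pairs, L)
  beta_dir <- if (!is.null(coef_at)) matrix(0, p, p) else NULL
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j], family = "gaussian",
                          lambda = lambda, standardize = FALSE,
                          intercept = FALSE)
    B <- as.matrix(fit$beta)
    if (ncol(B) < L)  # glmnet may stop early on saturated fits
      B <- cbind(B, matrix(B[, ncol(B)], nrow(B), L - ncol(B)))
    others <- seq_len(p)[-j]
    nzr <- which(rowSums(B != 0) > 0)
    for (k in nzr) {
      tgt <- others[k]
      idx <- pair_index(min(j, tgt), max(j, tgt))
      cnt[idx, ] <- cnt[idx, ] + (B[k, ] != 0)
    }
    if (!is.null(coef_at))
      beta_dir[j, others] <- B[, coef_at]
  }
  adj <- if (rule == "or") cnt > 0 else cnt == 2L
  list(adj = adj, beta_dir = beta_dir)
}

#' Fit a cross-domain co-occurrence meta-network
#'
#' CLR-transforms each domain's table separately (composition closure is
#' per sequencing library), stacks them, and runs MB neighborhood
#' selection over a log-spaced lambda path of length `nlambda` spanning
#' `[lambda_max * lambda_min_ratio, lambda_max]`. The regularization level
#' is chosen by StARS: `n_subsamples` subsamples of size
#' `floor(10 * sqrt(n))`, selecting the densest graph whose monotonized
#' edge instability stays at or below `stars_instability`. An edge exists
#' if either directed neighborhood selects it (OR rule; AND available);
#' its weight is the mean of the two directed standardized coefficients
#' with 0 substituted for an unselected direction.
#'
#' @param fungi,prok OTU tables over the same samples (pre-filtered;
#'   disjoint taxon ids). `prok` may be NULL for a single-domain network.
#' @param nlambda path length (default 100).
#' @param lambda_min_ratio smallest/largest lambda ratio (default 1e-2).
#' @param stars_instability StARS instability target (default 0.05).
#' @param n_subsamples number of StARS subsamples (default 20).
#' @param seed integer seed for the subsampling.
#' @param rule `"or"` (default) or `"and"` symmetrization.
#' @param pseudocount CLR pseudocount.
#' @return `meta_network`: list(nodes, edges = data.frame(node_a, node_b,
#'   weight), lambda = list(path, selected, selected_index, instability),
#'   settings).
#' @export
fit_meta_network <- function(fungi, prok = NULL, nlambda = 100,
                             lambda_min_ratio = 1e-2,
                             stars_instability = 0.05, n_subsamples = 20,
                             seed = 1, rule = c("or", "and"),
                             pseudocount = 1) {
  rule <- match.arg(rule)
  validate_otu_table(fungi, min_samples = 2L)
  if (!is.null(prok)) {
    validate_otu_table(prok, min_samples = 2L)
    if (length(intersect(rownames(fungi), rownames(prok))))
      stop("fungal and prokaryote taxon ids must be disjoint")
    shared <- intersect(colnames(fungi), colnames(prok))
    if (length(shared) == 0) stop("fungal and prokaryote sample sets are disjoint")
    fungi <- fungi[, shared, drop = FALSE]
    prok <- prok[, shared, drop = FALSE]
  }
  n <- ncol(fungi)
  if (n < 10) stop("network estimation needs >= 10 samples")
  Z <- rbind(clr(fungi, pseudocount),
             if (!is.null(prok)) clr(prok, pseudocount))
  nodes <- rownames(Z)
  ## samples in rows, standardized nodes in columns
  X <- scale(t(Z))
  X[, attr(X, "scaled:scale") == 0] <- 0
  X <- X[order(rownames(X)), , drop = FALSE]  # order-invariant w.r.t. input
  p <- ncol(X)

  S <- abs(crossprod(X) / nrow(X)); diag(S) <- 0
  lambda_max <- max(S)
  if (lambda_max == 0) stop("degenerate data: no covariance between nodes")
  path <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = nlambda))

  b <- min(nrow(X) - 1, floor(10 * sqrt(nrow(X))))
  n_pairs <- p * (p - 1) / 2
  freq <- matrix(0, n_pairs, nlambda)
  with_seed(seed, {
    for (s in seq_len(n_subsamples)) {
      rows <- sample.int(nrow(X), b)
      freq <- freq + mb_path(X[rows, , drop = FALSE], path, rule = rule)$adj
    }
  })
  theta <- freq / n_subsamples
  instab <- colMeans(2 * theta * (1 - theta))
  instab_mono <- cummax(instab)
  ok <- which(instab_mono <= stars_instability)
  sel <- if (length(ok)) max(ok) else 1L

  full <- mb_path(X, path, coef_at = sel, rule = rule)
  adj <- full$adj[, sel]
  edges <- data.frame(node_a = character(0), node_b = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (any(adj)) {
    ut <- which(upper.tri(matrix(0, p, p)))
    idx <- ut[adj]
    i <- ((idx - 1) %% p) + 1
    j <- ((idx - 1) %/% p) + 1
    w <- (full$beta_dir[cbind(i, j)] + full$beta_dir[cbind(j, i)]) / 2
    edges <- data.frame(node_a = colnames(X)[i], node_b = colnames(X)[j],
                        weight = w, stringsAsFactors = FALSE)
  }
  out <- list(nodes = nodes, edges = edges,
              lambda = list(path = path, selected = path[sel],
                            selected_index = sel, instability = instab),
              settings = list(nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio,
                              stars_instability = stars_instability,
                              n_subsamples = n_subsamples,
                              subsample_size = b, rule = rule, seed = seed))
  class(out) <- "meta_network"
  out
}

#' Graph density of a meta-network (edges / possible edges)
#' @param net a `meta_network`.
#' @return numeric in `[0, 1]`.
#' @export
network_density <- function(net) {
  p <- length(net$nodes)
  nrow(net$edges) / (p * (p - 1) / 2)
}

#' Per-sample subnetworks of a meta-network
#'
#' For each sample, the subnetwork is the induced subgraph on the taxa
#' with count > 0 in that sample: the node set is those taxa, and an edge
#' is retained iff both endpoints are present.
#'
#' @param net a `meta_network`.
#' @param counts combined taxa x samples table; every row must be a meta
#'   node.
#' @return `subnetworks`: named list per sample with sample_id, nodes,
#'   edges, n_nodes, n_edges, linkage_density.
#' @export
make_subnetworks <- function(net, counts) {
  stopifnot(inherits(net, "meta_network"))
  validate_otu_table(counts)
  unknown <- setdiff(rownames(counts), net$nodes)
  if (length(unknown))
    stop("taxa not in meta-network: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  out <- lapply(colnames(counts), function(s) {
    present <- rownames(counts)[counts[, s] > 0]
    keep <- net$edges$node_a %in% present & net$edges$node_b %in% present
    sn <- list(sample_id = s, nodes = present,
               edges = net$edges[keep, , drop = FALSE],
               n_nodes = length(present), n_edges = sum(keep))
    sn$linkage_density <- linkage_density(sn)
    class(sn) <- "subnetwork"
    sn
  })
  names(out) <- colnames(counts)
  class(out) <- c("subnetworks", class(out))
  out
}

#' Linkage density (network complexity) of a subnetwork
#'
#' Edges per node; 0 for an empty node set.
#'
#' @param s a `subnetwork` (or any list with n_edges and n_nodes).
#' @return numeric.
#' @export
linkage_density <- function(s) {
  if (s$n_nodes == 0) return(0)
  s$n_edges / s$n_nodes
}

#' Per-sample subnetwork summary table
#' @param subs a `subnetworks` list.
#' @return data.frame (sample_id, n_nodes, n_edges, linkage_density).
#' @export
subnetwork_stats <- function(subs) {
  data.frame(sample_id = vapply(subs, `[[`, "", "sample_id"),
             n_nodes = vapply(subs, `[[`, 0, "n_nodes"),
             n_edges = vapply(subs, `[[`, 0, "n_edges"),
             linkage_density = vapply(subs, `[[`, 0, "linkage_density"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cumulative cross-group edge weight within a subnetwork
#'
#' Sum of signed weights of the bipartite edges between a fungal family
#' and a prokaryote genus inside one sample's subnetwork; zero when either
#' group is absent.
#'
#' @param s a `subnetwork`.
#' @param tax combined taxonomy data.frame (family and genus columns).
#' @param family fungal family label (e.g. `"Bulleribasidiaceae"`).
#' @param genus prokaryote genus label (e.g. `"Sphingomonas"`).
#' @return list(sample_id, family, genus, cumulative_weight).
#' @export
group_edge_weight <- function(s, tax, family, genus) {
  fam_ids <- tax$taxon_id[tax$family == family]
  gen_ids <- tax$taxon_id[tax$genus == genus]
  if (!length(fam_ids)) stop("taxonomy has no taxa with family ", family)
  if (!length(gen_ids)) stop("taxonomy has no taxa with genus ", genus)
  e <- s$edges
  cross <- (e$node_a %in% fam_ids & e$node_b %in% gen_ids) |
    (e$node_b %in% fam_ids & e$node_a %in% gen_ids)
  list(sample_id = s$sample_id, family = family, genus = genus,
       cumulative_weight = if (any(cross)) sum(e$weight[cross]) else 0)
}

#' Cumulative edge weights for one family against several genera
#' @param subs a `subnetworks` list.
#' @inheritParams group_edge_weight
#' @param genera character vector of genus labels.
#' @return data.frame (sample_id, genus, cumulative_weight).
#' @export
group_edge_weights <- function(subs, tax, family, genera) {
  do.call(rbind, lapply(subs, function(s) {
    do.call(rbind, lapply(genera, function(g) {
      gw <- group_edge_weight(s, tax, family, g)
      data.frame(sample_id = gw$sample_id, genus = g,
                 cumulative_weight = gw$cumulative_weight,
                 stringsAsFactors = FALSE)
    }))
  }))
}

star_code <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "ns")))
}

#' Compare a per-sample subnetwork metric between treatments
#'
#' Within each (management, dpf) cell, the metric is compared between
#' fungicide and control samples with the two-sample rank-sum test
#' (default; `paired = TRUE` uses the signed-rank test on samples matched
#' by replicate plot and plant order). Star codes follow the usual
#' thresholds (* 0.05, ** 0.01, *** 0.001).
#'
#' @param values data.frame with `sample_id` and the metric column.
#' @param meta sample metadata.
#' @param metric metric column name (e.g. `"linkage_density"`).
#' @param paired use the paired signed-rank variant.
#' @return data.frame (management, dpf, n_control, n_fungicide, median
#'   difference, p, stars).
#' @export
compare_subnetwork_metric <- function(values, meta, metric = "linkage_density",
                                      paired = FALSE) {
  if (!metric %in% colnames(values)) stop("metric column not found: ", metric)
  meta <- meta[match(values$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metric samples missing from metadata")
  cells <- unique(meta[, c("management", "dpf")])
  cells <- cells[order(cells$management, cells$dpf), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sel <- meta$management == cells$management[k] & meta$dpf == cells$dpf[k]
    v <- values[[metric]][sel]
    trt <- meta$treatment[sel]
    ord <- order(meta$replicate_plot[sel], meta$sample_id[sel])
    vc <- v[trt == "control"][order(ord[trt == "control"])]
    vf <- v[trt == "fungicide"][order(ord[trt == "fungicide"])]
    if (length(vc) < 3 || length(vf) < 3)
      stop(sprintf("cell %s/dpf %s has < 3 samples per treatment",
                   cells$management[k], cells$dpf[k]))
    p <- if (paired) {
      if (length(vc) != length(vf)) stop("paired test needs equal group sizes")
      suppressWarnings(stats::wilcox.test(vf, vc, paired = TRUE)$p.value)
    } else {
      suppressWarnings(stats::wilcox.test(vf, vc)$p.value)
    }
    data.frame(management = cells$management[k], dpf = cells$dpf[k],
               n_control = length(vc), n_fungicide = length(vf),
               median_diff = stats::median(vf) - stats::median(vc),
               p = p, stars = star_code(p), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
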