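test_that("CLR transform matches its formula and sums to zero per sample", {
  x <- toy_table(matrix(c(4, 4, 4, 1, 10, 100), 3, 2))
  z <- clr(x, pseudocount = 1)
  expect_equal(unname(z[, 1]), c(0, 0, 0))   # uniform sample
  expect_equal(unname(colSums(z)), c(0, 0), tolerance = 1e-12)
  ## direct formula oracle
  lx <- log(x + 1)
  expect_equal(z, sweep(lx, 2, colMeans(lx), "-"))
})

test_that("linkage density follows edges per node with an empty-graph convention", {
  tri <- list(n_nodes = 3, n_edges = 3)
  expect_equal(linkage_density(tri), 1)
  expect_equal(linkage_density(list(n_nodes = 4, n_edges = 3)), 0.75)
  expect_equal(linkage_density(list(n_nodes = 0, n_edges = 0)), 0)
})

## small deterministic meta-network for subgraph tests
toy_network <- function() {
  net <- list(nodes = paste0("t", 1:5),
              edges = data.frame(node_a = c("t1", "t1", "t2", "t4"),
                                 node_b = c("t2", "t3", "t3", "t5"),
                                 weight = c(0.5, -0.2, 0.3, 0.4),
                                 stringsAsFactors = FALSE),
              lambda = list(), settings = list())
  class(net) <- "meta_network"
  net
}

test_that("per-sample subnetworks are exact induced subgraphs", {
  net <- toy_network()
  counts <- toy_table(matrix(c(1, 1, 1, 1, 1,   # all present
                               1, 1, 0, 1, 1,   # t3 absent
                               1, 0, 0, 0, 1),  # only t1, t5
                             5, 3), m = 5, n = 3)
  subs <- make_subnetworks(net, counts)
  expect_equal(subs[["s1"]]$n_edges, 4)
  expect_equal(subs[["s1"]]$linkage_density, 4 / 5)
  expect_equal(subs[["s2"]]$n_edges, 2)       # t1-t2 and t4-t5 survive
  expect_setequal(c(subs[["s2"]]$edges$node_a, subs[["s2"]]$edges$node_b),
                  c("t1", "t2", "t4", "t5"))
  expect_equal(subs[["s3"]]$n_edges, 0)
  ## brute-force oracle over random presence patterns
  set.seed(5)
  for (k in 1:20) {
    pres <- rbinom(5, 1, 0.6)
    cnt <- toy_table(matrix(pres, 5, 1), m = 5, n = 1)
    sn <- make_subnetworks(net, cnt)[[1]]
    present <- paste0("t", which(pres == 1))
    oracle <- sum(net$edges$node_a %in% present &
                    net$edges$node_b %in% present)
    expect_equal(sn$n_edges, oracle)
    expect_equal(sn$n_nodes, length(present))
  }
  bad <- toy_table(matrix(1, 6, 1), m = 6, n = 1)
  expect_error(make_subnetworks(net, bad), "not in meta-network")
})

test_that("cross-group cumulative edge weight equals the brute-force bipartite sum", {
  net <- toy_network()
  tax <- data.frame(taxon_id = paste0("t", 1:5),
                    family = c("Bulleribasidiaceae", "unclassified",
                               "unclassified", "Bulleribasidiaceae",
                               "unclassified"),
                    genus = c("Hannaella", "Sphingomonas", "Sphingomonas",
                              "Vishniacozyma", "Sphingomonas"))
  counts <- toy_table(matrix(1, 5, 1), m = 5, n = 1)
  s <- make_subnetworks(net, counts)[[1]]
  gw <- group_edge_weight(s, tax, "Bulleribasidiaceae", "Sphingomonas")
  ## edges t1-t2 (0.5), t1-t3 (-0.2), t4-t5 (0.4) cross the groups
  expect_equal(gw$cumulative_weight, 0.5 - 0.2 + 0.4)
  ## no cross edges -> 0
  s0 <- make_subnetworks(net, toy_table(matrix(c(0, 1, 1, 0, 1), 5, 1),
                                        m = 5, n = 1))[[1]]
  expect_equal(group_edge_weight(s0, tax, "Bulleribasidiaceae",
                                 "Sphingomonas")$cumulative_weight, 0)
  expect_error(group_edge_weight(s, tax, "Nosuchfamily", "Sphingomonas"),
               "no taxa with family")
})

test_that("meta-network estimation recovers strong planted dependence and is sample-order invariant", {
  set.seed(14)
  n <- 80
  ## two strongly coupled pairs within 30 otherwise independent taxa
  z <- matrix(rnorm(30 * n, 0, 0.5), 30, n)
  z[2, ] <- z[1, ] + rnorm(n, 0, 0.2)
  z[4, ] <- -z[3, ] + rnorm(n, 0, 0.2)
  cnt <- round(exp(z + 5))
  cnt <- toy_table(cnt, m = 30, n = n)
  net <- fit_meta_network(cnt[1:15, ], cnt[16:30, ], nlambda = 30, seed = 2)
  key <- paste(pmin(net$edges$node_a, net$edges$node_b),
               pmax(net$edges$node_a, net$edges$node_b))
  expect_true("t1 t2" %in% key)
  expect_true("t3 t4" %in% key)
  w12 <- net$edges$weight[key == "t1 t2"]
  w34 <- net$edges$weight[key == "t3 t4"]
  expect_gt(w12, 0)
  expect_lt(w34, 0)
  ## permuting sample order leaves the graph unchanged under the same seed
  perm <- sample(n)
  net2 <- fit_meta_network(cnt[1:15, perm], cnt[16:30, perm], nlambda = 30,
                           seed = 2)
  expect_equal(net$edges, net2$edges)
  expect_error(fit_meta_network(cnt[1:15, 1:5], cnt[16:30, 1:5]),
               ">= 10 samples")
})

test_that("treatment comparisons of subnetwork metrics respect cell structure", {
  meta <- rbind(
    toy_metadata(paste0("a", 1:8), treatment = rep(c("control", "fungicide"),
                                                   each = 4),
                 management = "conventional", dpf = 13),
    toy_metadata(paste0("b", 1:8), treatment = rep(c("control", "fungicide"),
                                                   each = 4),
                 management = "no_till", dpf = 13))
  set.seed(3)
  vals <- data.frame(sample_id = meta$sample_id,
                     linkage_density = c(rnorm(4, 2), rnorm(4, 0.2, 0.1),
                                         rnorm(8, 2)))
  cmp <- compare_subnetwork_metric(vals, meta)
  expect_equal(nrow(cmp), 2)
  conv <- cmp[cmp$management == "conventional", ]
  expect_lte(conv$p, 0.05)
  expect_true(conv$stars %in% c("*", "**", "***"))
  nt <- cmp[cmp$management == "no_till", ]
  expect_gt(nt$p, 0.05)
  expect_equal(nt$stars, "ns")
  ## fewer than 3 per group is an error
  small <- meta[c(1:2, 5:6, 9:16), ]
  expect_error(compare_subnetwork_metric(vals[vals$sample_id %in%
                                                small$sample_id, ], small),
               "< 3 samples")
})
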