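test_that("Bray-Curtis distances match the formula and its limiting cases", {
  x <- toy_table(matrix(c(1, 2, 3, 1, 2, 3, 3, 2, 1, 4, 0, 0), 3, 4))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["s1", "s2"], 0)               # identical samples
  expect_equal(d["s1", "s3"], 4 / 12)          # direct formula evaluation
  ## disjoint supports
  y <- toy_table(matrix(c(5, 0, 0, 7), 2, 2))
  expect_equal(as.matrix(bray_curtis(y))["s1", "s2"], 1)
  ## closing to proportions makes the distance invariant to per-sample
  ## rescaling of the original counts
  rel <- to_relative_abundance(x)
  scaled <- sweep(x, 2, c(1, 7, 3, 11), "*")
  expect_equal(as.matrix(bray_curtis(rel)),
               as.matrix(bray_curtis(to_relative_abundance(scaled))),
               tolerance = 1e-12)
  expect_error(bray_curtis(toy_table(matrix(c(1, 1, 0, 0), 2, 2))),
               "all-zero")
})

test_that("richness counts nonzero taxa and class splits sum to totals", {
  x <- toy_table(matrix(c(3, 1, 0, 2, 0, 0, 0, 0, 0, 0, 4, 7), 6, 2))
  expect_equal(unname(richness(x)), c(3, 2))
  tax <- data.frame(taxon_id = paste0("t", 1:6),
                    class = c("A", "A", "A", "B", "B", NA))
  by_cls <- richness(x, tax, by_rank = "class")
  expect_equal(unname(colSums(by_cls)), unname(richness(x)))
  expect_equal(by_cls["A", "s1"], 2)
  expect_true("unclassified" %in% rownames(by_cls))
  expect_equal(unname(group_richness(x, tax, "class", "A")), c(2, 0))
})

test_that("PERMANOVA partitions a toy distance matrix exactly as the hand oracle", {
  ## 4 samples, 1 two-level factor: R2 = SS_between / SS_total from the
  ## Gower-centred partition, computed by hand
  pts <- matrix(c(0, 0, 1, 0, 10, 0, 11, 0), 4, 2, byrow = TRUE)
  rownames(pts) <- paste0("s", 1:4)
  d <- dist(pts)
  meta <- toy_metadata(rownames(pts), treatment = c("control", "control",
                                                    "fungicide", "fungicide"))
  res <- permanova(d, meta, "treatment", n_perm = 99, seed = 1)
  ## hand partition: SS_total = sum d^2 / n; SS_within from group distances
  dv <- as.matrix(d)
  ss_tot <- sum(dv[upper.tri(dv)]^2) / 4
  ss_w <- (dv[1, 2]^2) / 2 + (dv[3, 4]^2) / 2
  r2_oracle <- (ss_tot - ss_w) / ss_tot
  expect_equal(res$r2[res$term == "treatment"], r2_oracle, tolerance = 1e-10)
  ## R2 sums to 1 including the residual
  expect_equal(sum(res$r2[res$term != "Total"]), 1, tolerance = 1e-10)
  expect_gt(res$p[1], 0)
})

test_that("PERMANOVA finds planted separation at the minimum attainable p", {
  set.seed(42)
  ## two well-separated clusters, n = 10 + 10
  pts <- rbind(matrix(rnorm(10 * 2, 0, 0.1), 10, 2),
               matrix(rnorm(10 * 2, 50, 0.1), 10, 2))
  rownames(pts) <- paste0("s", 1:20)
  d <- dist(pts)
  meta <- toy_metadata(rownames(pts),
                       treatment = rep(c("control", "fungicide"), each = 10))
  res <- permanova(d, meta, "treatment", n_perm = 999, seed = 7)
  expect_equal(res$p[1], 1 / (999 + 1))
  expect_error(permanova(d, toy_metadata(rownames(pts)), "treatment"),
               "constant")
})

test_that("dispersion test sees a planted scale difference and exact duplicates give zero dispersion", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(20 * 3), 20, 3),
               matrix(rnorm(20 * 3, 0, 3), 20, 3))
  rownames(pts) <- paste0("s", 1:40)
  grp <- rep(c("a", "b"), each = 20)
  res <- beta_dispersion(dist(pts), grp, n_perm = 199, seed = 1)
  expect_lt(res$p, 0.05)
  expect_gt(res$group_means[["b"]], res$group_means[["a"]])
  ## duplicated samples in a group embed at one point
  dup <- matrix(c(0, 0, 5, 5, 0, 0, 5, 5), 4, 2)
  rownames(dup) <- paste0("s", 1:4)
  res2 <- beta_dispersion(dist(dup), c("a", "a", "b", "b"), n_perm = 99)
  expect_equal(unname(res2$group_means), c(0, 0), tolerance = 1e-10)
})

test_that("CAP with Euclidean distance and no condition equals the least-squares RDA oracle", {
  set.seed(2)
  n <- 24
  Y <- matrix(rnorm(n * 6), n, 6)
  Y[1:12, 1] <- Y[1:12, 1] + 1.5
  rownames(Y) <- paste0("s", 1:n)
  meta <- toy_metadata(rownames(Y),
                       treatment = rep(c("control", "fungicide"), each = 12))
  cp <- cap_partial(dist(Y), meta, "treatment", n_perm = 99, seed = 1)
  ## direct least-squares redundancy analysis
  Yc <- scale(Y, scale = FALSE)
  X <- stats::model.matrix(~ meta$treatment)
  H <- X %*% solve(crossprod(X), t(X))
  frac_oracle <- sum((H %*% Yc)^2) / sum(Yc^2)
  expect_equal(cp$constrained_fraction, frac_oracle, tolerance = 1e-8)
})

test_that("partial CAP removes the conditioned variation and rejects full confounding", {
  set.seed(3)
  n <- 32
  block <- rep(c("conventional", "no_till"), each = n / 2)
  trt <- rep(rep(c("control", "fungicide"), each = n / 4), 2)
  Y <- matrix(rnorm(n * 5), n, 5)
  Y[block == "no_till", 2] <- Y[block == "no_till", 2] + 3
  rownames(Y) <- paste0("s", 1:n)
  meta <- toy_metadata(rownames(Y), treatment = trt, management = block)
  full <- cap_partial(dist(Y), meta, "treatment", n_perm = 99, seed = 1)
  part <- cap_partial(dist(Y), meta, "treatment", condition = "management",
                      n_perm = 99, seed = 1)
  expect_true(is.finite(part$constrained_fraction))
  ## conditioning on the constraint itself is an error
  expect_error(cap_partial(dist(Y), meta, "treatment",
                           condition = "treatment"), "confounded")
  ## empty condition reduces exactly to unconditioned CAP
  uncond <- cap_partial(dist(Y), meta, "treatment", condition = NULL,
                        n_perm = 99, seed = 1)
  expect_equal(uncond$constrained_fraction, full$constrained_fraction)
})

test_that("permutation tests are reproducible under an explicit seed", {
  set.seed(4)
  pts <- matrix(rnorm(20 * 3), 20, 3)
  rownames(pts) <- paste0("s", 1:20)
  meta <- toy_metadata(rownames(pts),
                       treatment = rep(c("control", "fungicide"), 10))
  d <- dist(pts)
  p1 <- permanova(d, meta, "treatment", n_perm = 199, seed = 5)$p[1]
  p2 <- permanova(d, meta, "treatment", n_perm = 199, seed = 5)$p[1]
  expect_identical(p1, p2)
})
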