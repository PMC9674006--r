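## hand-written rule oracle, kept deliberately independent of the
## implementation: a literal transcription of the class definitions
oracle_rule <- function(sf, sr, sl, pp, zp, pc) {
  if (sf && sr && pp && zp && pc) return("locally_extinct")
  if (sf && sr) return("non_recovered")
  if (sf && !sr) return("recovered")
  if (!sf && sl) return("indirect")
  "unaffected"
}

test_that("recovery rule matches the exhaustive truth-table oracle", {
  grid <- expand.grid(sf = c(TRUE, FALSE), sr = c(TRUE, FALSE),
                      sl = c(TRUE, FALSE), pp = c(TRUE, FALSE),
                      zp = c(TRUE, FALSE), pc = c(TRUE, FALSE))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    expect_identical(
      recovery_rule(g$sf, g$sr, g$sl, g$pp, g$zp, g$pc),
      oracle_rule(g$sf, g$sr, g$sl, g$pp, g$zp, g$pc),
      info = paste(unlist(g), collapse = ","))
  }
})

test_that("classification from a real time series honours presence evidence", {
  scn <- generate_scenario(small_scenario_config(seed = 4))
  ts <- ancom_by_stratum(scn$fungi, scn$metadata)
  one <- ts[["soybean.conventional"]]
  rc <- classify_recovery(one, scn$fungi, scn$metadata)
  expect_s3_class(rc, "recovery_classification")
  expect_setequal(rc$taxon_id, one$taxa)
  expect_true(all(rc$class %in% RECOVERY_CLASSES))
  ## classes follow the rule applied to the recorded evidence
  for (k in seq_len(nrow(rc)))
    expect_identical(rc$class[k],
                     oracle_rule(rc$sig_first[k], rc$sig_rest[k],
                                 rc$sig_last[k], rc$present_pre[k],
                                 rc$zero_post_fungicide[k],
                                 rc$present_control[k]))
  ## locally-extinct calls really have zero post-spray fungicide counts
  le <- rc$taxon_id[rc$class == "locally_extinct"]
  sel <- scn$metadata$management == "conventional" &
    scn$metadata$treatment == "fungicide" & scn$metadata$dpf > 0
  if (length(le))
    expect_true(all(scn$fungi[le, scn$metadata$sample_id[sel]] == 0))
})

test_that("recovery summary arithmetic and denominators", {
  rc <- data.frame(
    taxon_id = paste0("t", 1:7),
    class = c("recovered", "recovered", "recovered", "non_recovered",
              "locally_extinct", "indirect", "unaffected"),
    dir_first = c(-1, -1, -1, -1, -1, 1, 0))
  class(rc) <- c("recovery_classification", "data.frame")
  s <- recovery_summary(rc)
  expect_equal(s$n_affected, 5)          # indirect/unaffected excluded
  expect_equal(s$pct$recovered, 60)      # 3 of 5
  expect_equal(s$pct$locally_extinct, 20)
  ## an increased (direction +1) affected taxon only counts under
  ## the all-affected denominator
  rc$dir_first[4] <- 1
  expect_equal(recovery_summary(rc)$n_affected, 4)
  expect_equal(recovery_summary(rc, denominator = "all_affected")$n_affected, 5)
  expect_equal(recovery_summary(rc, subset = paste0("t", 1:3))$pct$recovered,
               100)
  expect_error(recovery_summary(rc, subset = "t7"), "no affected taxa")
})

test_that("occupancy/abundance matches direct counting", {
  x <- toy_table(matrix(c(5, 0, 1, 3, 0, 0, 2, 0, 1, 1, 1, 0), 3, 4))
  oa <- occupancy_abundance(x)
  expect_equal(oa$occupancy, unname(rowMeans(x > 0)))
  expect_equal(oa$occupancy[[1]], 1)
  expect_equal(oa$occupancy[[3]], 0.5)
  rel <- sweep(x, 2, colSums(x), "/")
  expect_equal(oa$mean_rel_abundance, unname(rowMeans(rel)))
})

test_that("core detection: dominance, curve shape and order invariance", {
  ## one taxon holding ~99% of every sample is the whole core
  set.seed(6)
  x <- rbind(matrix(rpois(5 * 6, 4), 5, 6), rpois(6, 2000))
  x <- toy_table(x)
  cm <- core_taxa(x, threshold = 0.02)
  expect_identical(cm$taxon_id[cm$core][1], "t6")
  ## cumulative contribution curve is non-decreasing and ends at 1
  expect_true(all(diff(cm$cumulative) >= -1e-12))
  expect_equal(cm$cumulative[nrow(cm)], 1, tolerance = 1e-12)
  ## invariant to taxon input order
  perm <- sample(nrow(x))
  cm2 <- core_taxa(x[perm, ], threshold = 0.02)
  expect_identical(cm$taxon_id, cm2$taxon_id)
  expect_identical(cm$taxon_id[cm$core], cm2$taxon_id[cm2$core])
  expect_error(core_taxa(x[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("core membership is stable under duplicating all samples", {
  set.seed(9)
  x <- toy_table(rbind(matrix(rpois(8 * 10, 500), 8, 10),
                       matrix(rbinom(12 * 10, 3, 0.3), 12, 10)))
  cm <- core_taxa(x)
  dup <- cbind(x, x)
  colnames(dup) <- paste0("s", seq_len(ncol(dup)))
  cm2 <- core_taxa(dup)
  expect_identical(cm$taxon_id[cm$core], cm2$taxon_id[cm2$core])
})

test_that("planted high-occupancy core is recovered", {
  ## 15 abundant, ubiquitous taxa among 100 sparse rare ones
  set.seed(12)
  n <- 24
  core <- matrix(rpois(15 * n, 800), 15, n)
  rare <- matrix(rpois(100 * n, 0.7), 100, n)
  x <- toy_table(rbind(core, rare))
  cm <- core_taxa(x)
  found <- cm$taxon_id[cm$core]
  recall <- length(intersect(found, paste0("t", 1:15))) / 15
  expect_gte(recall, 0.9)
})
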