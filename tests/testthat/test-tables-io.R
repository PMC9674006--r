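test_that("OTU table TSV round-trip preserves counts, ids and order", {
  x <- toy_table(matrix(c(5L, 0L, 2L, 1L, 7L, 3L), 3, 2))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(x, tf)
  y <- read_otu_table(tf)
  expect_identical(dim(y), dim(x))
  expect_identical(rownames(y), rownames(x))
  expect_identical(colnames(y), colnames(x))
  expect_true(all(y == x))
  ## write(read(.)) is bit-stable
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(y, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("malformed OTU tables are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "tA\t1\t2", "tA\t3\t4"), tf)
  expect_error(read_otu_table(tf), "tA")
  writeLines(c("taxon_id\ts1\ts2", "tA\t1\tx", "tB\t3\t4"), tf)
  expect_error(read_otu_table(tf), "non-numeric")
  x <- toy_table()
  x[2, 1] <- -1
  expect_error(validate_otu_table(x), "negative count.*t2.*s1")
  x <- toy_table()
  colnames(x) <- c("s1", "s1")
  expect_error(validate_otu_table(x), "duplicate sample")
})

test_that("metadata parsing validates factor levels and required columns", {
  meta <- toy_metadata(paste0("s", 1:4), treatment = c("control", "fungicide"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_results(meta, tf)
  parsed <- read_metadata(tf)
  expect_identical(parsed$sample_id, meta$sample_id)
  expect_identical(parsed$treatment, meta$treatment)

  bad <- meta
  bad$management <- "organic"
  write_results(bad, tf)
  expect_error(read_metadata(tf), "unknown management.*organic")

  write_results(meta[, setdiff(colnames(meta), "dpf")], tf)
  expect_error(read_metadata(tf), "dpf")
})

test_that("relative abundance closes each sample to 1", {
  x <- toy_table(matrix(c(2, 2, 4, 1, 0, 0), 3, 2))
  rel <- to_relative_abundance(x)
  expect_equal(rel[, 1], c(t1 = 0.25, t2 = 0.25, t3 = 0.5))
  expect_equal(unname(colSums(rel)), c(1, 1))
  expect_equal(unname(to_relative_abundance(toy_table(matrix(5, 1, 2)))[1, ]),
               c(1, 1))
  x[, 2] <- 0
  expect_error(to_relative_abundance(x), "all-zero sample.*s2")
})

test_that("abundance/occupancy filter matches its definition exactly", {
  set.seed(3)
  n <- 40
  ## 10 abundant taxa, 10 ultra-rare (below 1e-5 mean relative abundance)
  x <- rbind(matrix(rpois(10 * n, 2000), 10, n),
             matrix(rbinom(10 * n, 1, 0.02), 10, n))
  x <- toy_table(x)
  res <- filter_taxa(x)
  ## brute-force recompute of both criteria per taxon
  rel <- sweep(x, 2, colSums(x), "/")
  keep_oracle <- rownames(x)[rowMeans(rel) >= 1e-5 & rowMeans(x == 0) < 0.95]
  expect_identical(rownames(res$table), keep_oracle)
  expect_setequal(res$dropped, setdiff(rownames(x), keep_oracle))
  expect_identical(sort(rownames(res$table)), sort(paste0("t", 1:10)))
  ## counts of retained taxa untouched, samples unchanged
  expect_identical(res$table, x[rownames(res$table), ])
  ## idempotence
  again <- filter_taxa(res$table)
  expect_identical(again$table, res$table)
  expect_length(again$dropped, 0)
})

test_that("filter boundary conventions: occupancy >= 95% zeros drops, mean exactly at threshold keeps", {
  n <- 40
  x <- matrix(1000, 3, n)
  x[2, ] <- 0; x[2, 1] <- 5          # zeros in 97.5% of samples
  x[3, ] <- 0; x[3, 1:2] <- c(5, 5)  # zeros in exactly 95%
  x <- toy_table(x)
  res <- filter_taxa(x)
  expect_false("t2" %in% rownames(res$table))
  expect_false("t3" %in% rownames(res$table))  # boundary: dropped at >= 0.95
  ## mean relative abundance exactly at the threshold is retained
  y <- toy_table(matrix(c(99999, 1, 99999, 1), 2, 2))
  resy <- filter_taxa(y, mean_rel_min = 1e-5, zero_sample_frac = 0.95)
  expect_true("t2" %in% rownames(resy$table))
  expect_error(filter_taxa(toy_table(matrix(c(1, 0, 0, 1), 2, 2)),
                           mean_rel_min = 0.9), "every taxon")
})

test_that("ANCOM pre-filter drops taxa never seen in fungicide plots", {
  x <- toy_table(matrix(c(5, 3, 0, 6, 2, 0, 0, 1, 0, 0, 1, 1), 3, 4))
  meta <- toy_metadata(colnames(x),
                       treatment = c("control", "control",
                                     "fungicide", "fungicide"))
  res <- filter_taxa_for_ancom(x, meta)
  ## set-comprehension oracle
  fung <- meta$sample_id[meta$treatment == "fungicide"]
  oracle <- rownames(x)[rowSums(x[, fung, drop = FALSE]) > 0]
  expect_identical(rownames(res$table), oracle)
  expect_true("t1" %in% res$dropped)       # control-only taxon
  expect_true("t3" %in% rownames(res$table))  # 1 read in one fungicide sample
})

test_that("BIOM-JSON input parses to the same table as TSV", {
  x <- toy_table(matrix(c(5L, 0L, 2L, 1L, 7L, 3L), 3, 2))
  tf <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(x), tf)
  y <- read_otu_table(tf, format = "biom-json")
  expect_equal(y[rownames(x), colnames(x)], x * 1)
})

test_that("drop_taxa removes exactly the named taxa", {
  x <- toy_table(m = 4)
  expect_identical(rownames(drop_taxa(x, c("t2", "t4"))), c("t1", "t3"))
})
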