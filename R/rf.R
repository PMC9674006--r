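## Random-forest linkage of prokaryote abundance to fungal-group richness:
## all-relevant feature search (shadow-feature comparison, Boruta scheme),
## OOB-guided mtry tuning, and a permutation test of the model's
## out-of-bag variance explained.

#' Boruta-style all-relevant feature selection
#'
#' Iteratively appends "shadow" features (independent per-column
#' permutations of the real features), fits a regression forest, and
#' records a hit for every real feature whose permutation importance
#' exceeds the maximum shadow importance. After each run, cumulative hits
#' are tested against Binomial(runs, 0.5) two-sided with Bonferroni
#' correction over the still-undecided features; decisively winning
#' features are confirmed, losing ones rejected (and dropped from further
#' runs). Features still undecided at `max_runs` are tentative.
#'
#' @param X numeric feature matrix (samples x features, >= 10 samples).
#' @param y numeric response.
#' @param max_runs maximum forest iterations (default 100).
#' @param alpha decision level (default 0.01).
#' @param ntree trees per iteration forest (default 300).
#' @param seed integer seed.
#' @return `boruta_decision`: list(status = named factor in
#'   confirmed/rejected/tentative, hits, runs_used, alpha).
#' @export
boruta_select <- function(X, y, max_runs = 100, alpha = 0.01, ntree = 300,
                          seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("boruta_select needs >= 10 samples")
  if (ncol(X) < 2) stop("boruta_select needs >= 2 features")
  if (stats::sd(y) == 0) stop("constant response; selection undefined")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  feats <- colnames(X)
  with_seed(seed, {
    status <- stats::setNames(rep("tentative", length(feats)), feats)
    hits <- stats::setNames(rep(0L, length(feats)), feats)
    runs <- stats::setNames(rep(0L, length(feats)), feats)
    run <- 0L
    while (run < max_runs && any(status == "tentative")) {
      run <- run + 1L
      active <- names(status)[status != "rejected"]
      Xa <- X[, active, drop = FALSE]
      sh <- apply(Xa, 2, sample)
      colnames(sh) <- paste0(".shadow.", seq_len(ncol(sh)))
      rf <- suppressWarnings(
        randomForest::randomForest(cbind(Xa, sh), y, ntree = ntree,
                                   importance = TRUE))
      imp <- randomForest::importance(rf, type = 1)[, 1]
      shadow_max <- max(imp[colnames(sh)])
      hit <- imp[active] > shadow_max
      hits[active] <- hits[active] + hit
      runs[active] <- runs[active] + 1L
      und <- names(status)[status == "tentative"]
      if (length(und) && run >= 5) {
        n_tests <- length(und)
        p_hi <- stats::pbinom(hits[und] - 1, runs[und], 0.5,
                              lower.tail = FALSE)
        p_lo <- stats::pbinom(hits[und], runs[und], 0.5)
        status[und[p_hi * n_tests < alpha]] <- "confirmed"
        status[und[p_lo * n_tests < alpha]] <- "rejected"
      }
    }
    out <- list(status = status, hits = hits, runs_used = run, alpha = alpha)
    class(out) <- "boruta_decision"
    out
  })
}

oob_mse <- function(X, y, mtry, ntree) {
  rf <- suppressWarnings(randomForest::randomForest(X, y, mtry = mtry,
                                                    ntree = ntree))
  rf$mse[ntree]
}

#' OOB-guided mtry tuning for regression forests
#'
#' Starting from the regression default `floor(p / 3)`, searches outward
#' (multiplying and dividing by `step_factor`) while the relative OOB-MSE
#' improvement is at least `improve`, and returns the mtry with the lowest
#' OOB error seen.
#'
#' @param X feature matrix (samples x features).
#' @param y numeric response.
#' @param ntree trees per evaluation (default 500).
#' @param step_factor multiplicative step (default 2).
#' @param improve minimum relative improvement to continue (default 0.05).
#' @param seed integer seed.
#' @return selected mtry (integer).
#' @export
tune_mtry <- function(X, y, ntree = 500, step_factor = 2, improve = 0.05,
                      seed = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1) stop("need >= 1 feature")
  start <- max(1L, floor(p / 3))
  if (p == 1) return(1L)
  with_seed(seed, {
    tried <- c(start)
    errs <- c(oob_mse(X, y, start, ntree))
    for (dir in c(1, -1)) {
      cur <- start; cur_err <- errs[1]
      repeat {
        nxt <- if (dir > 0) min(p, ceiling(cur * step_factor))
               else max(1L, floor(cur / step_factor))
        if (nxt == cur || nxt %in% tried) break
        e <- oob_mse(X, y, nxt, ntree)
        tried <- c(tried, nxt); errs <- c(errs, e)
        if ((cur_err - e) / cur_err < improve) break
        cur <- nxt; cur_err <- e
      }
    }
    as.integer(tried[which.min(errs)])
  })
}

#' Random-forest regression with OOB variance explained and permutation test
#'
#' Fits a regression forest and reports the OOB percent variance explained
#' 100 x (1 - MSE_oob / Var(y)) (may be negative), the squared correlation
#' of observed vs OOB-predicted values, and permutation importances. The
#' model's significance is assessed by refitting on `n_perm`
#' label-permuted responses and comparing percent variance explained, with
#' the +1 p-value convention (so p >= 1 / (n_perm + 1)).
#'
#' @param X feature matrix (samples x features).
#' @param y numeric response.
#' @param mtry variables per split; default `floor(p / 3)`.
#' @param ntree trees (default 1000).
#' @param n_perm permutations for the significance test (0 skips it).
#' @param seed integer seed.
#' @return `rf_model_result`: list(pct_var_explained, r_squared_obs_pred,
#'   importances, mtry, ntree, permutation_p, n_perm, oob_predicted, model).
#' @export
rf_regress <- function(X, y, mtry = NULL, ntree = 1000, n_perm = 999,
                       seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("rf_regress needs >= 10 samples")
  if (stats::sd(y) == 0) stop("constant response")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  with_seed(seed, {
    rf <- suppressWarnings(
      randomForest::randomForest(X, y, mtry = mtry, ntree = ntree,
                                 importance = TRUE))
    pred <- rf$predicted
    if (anyNA(pred))
      stop("some samples never out-of-bag; increase ntree")
    vary <- mean((y - mean(y))^2)
    pct <- 100 * (1 - mean((y - pred)^2) / vary)
    r2 <- stats::cor(y, pred)^2
    perm_p <- NA_real_
    if (n_perm > 0) {
      perm_pct <- vapply(seq_len(n_perm), function(i) {
        yp <- sample(y)
        rfp <- suppressWarnings(
          randomForest::randomForest(X, yp, mtry = mtry, ntree = ntree))
        100 * (1 - mean((yp - rfp$predicted)^2) / mean((yp - mean(yp))^2))
      }, 0)
      perm_p <- (1 + sum(perm_pct >= pct)) / (1 + n_perm)
    }
    out <- list(pct_var_explained = pct, r_squared_obs_pred = r2,
                importances = randomForest::importance(rf, type = 1)[, 1],
                mtry = mtry, ntree = ntree, permutation_p = perm_p,
                n_perm = n_perm, oob_predicted = pred, model = rf)
    class(out) <- "rf_model_result"
    out
  })
}

#' Predict fungal-group richness from prokaryote abundances
#'
#' Within one management stratum, the response is per-sample richness of
#' the fungal taxa in `family` and the features are prokaryote relative
#' abundances of the fungicide-treated samples. The pipeline runs
#' [boruta_select()], then [tune_mtry()] on the confirmed features, then
#' [rf_regress()] with a permutation test; when nothing is confirmed a
#' null (non-significant) result is returned without fitting. The same selected features are
#' then refit on the stratum's control samples to test whether they
#' transfer (the expectation under a genuine fungicide-mediated coupling
#' is that they do not).
#'
#' @param prok prokaryote OTU table.
#' @param fungi fungal OTU table over the same samples.
#' @param tax combined taxonomy.
#' @param family fungal family whose richness is the response.
#' @param meta sample metadata.
#' @param management stratum to analyse.
#' @param post_only use only post-spray (dpf > 0) samples (default TRUE).
#' @param boruta_runs,ntree,n_perm,seed tuning knobs.
#' @param mean_rel_min abundance filter applied to prokaryote features.
#' @return list(fungicide, control: `rf_model_result` or NULL,
#'   selected_features, boruta).
#' @export
predict_group_richness <- function(prok, fungi, tax, family, meta,
                                   management, post_only = TRUE,
                                   boruta_runs = 100, ntree = 500,
                                   n_perm = 999, seed = 1,
                                   mean_rel_min = 1e-5) {
  meta <- align_metadata(fungi, meta)
  if (!all(colnames(prok) == colnames(fungi)))
    stop("fungal and prokaryote tables must share samples in order")
  fam_ids <- tax$taxon_id[tax$family == family]
  fam_ids <- intersect(fam_ids, rownames(fungi))
  if (!length(fam_ids)) stop("family absent from fungal table: ", family)

  in_stratum <- meta$management == management &
    (!post_only | meta$dpf > 0)
  fit_one <- function(treatment, features, do_boruta) {
    sel <- in_stratum & meta$treatment == treatment
    if (sum(sel) < 10)
      stop("fewer than 10 samples in ", management, "/", treatment)
    yy <- colSums(fungi[fam_ids, sel, drop = FALSE] > 0)
    if (stats::sd(yy) == 0)
      stop("constant ", family, " richness in ", management, "/", treatment)
    Xf <- t(to_relative_abundance(prok[, sel, drop = FALSE])[features, ,
                                                             drop = FALSE])
    list(X = Xf, y = yy)
  }

  keep <- filter_taxa(prok, mean_rel_min = mean_rel_min)$table
  features <- rownames(keep)
  dat <- fit_one("fungicide", features, TRUE)
  bor <- boruta_select(dat$X, dat$y, max_runs = boruta_runs, ntree = ntree,
                       seed = seed)
  selected <- names(bor$status)[bor$status == "confirmed"]
  if (!length(selected)) {
    ## nothing deemed relevant: report a null model, no transfer test
    return(list(fungicide = NULL, control = NULL,
                selected_features = character(0), boruta = bor,
                significant = FALSE))
  }
  Xs <- dat$X[, selected, drop = FALSE]
  mtry <- if (length(selected) >= 2)
    tune_mtry(Xs, dat$y, ntree = ntree, seed = seed + 1) else 1L
  fit_f <- rf_regress(Xs, dat$y, mtry = mtry, ntree = ntree, n_perm = n_perm,
                      seed = seed + 2)
  datc <- fit_one("control", selected, FALSE)
  fit_c <- tryCatch(
    rf_regress(datc$X, datc$y, mtry = mtry, ntree = ntree, n_perm = n_perm,
               seed = seed + 3),
    error = function(e) NULL)
  list(fungicide = fit_f, control = fit_c, selected_features = selected,
       boruta = bor, significant = !is.na(fit_f$permutation_p) &&
         fit_f$permutation_p <= 0.05)
}
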