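## Synthetic paired fungal/prokaryote OTU tables with planted ground truth.
##
## The generator emulates a factorial fungicide-disturbance field trial:
## 2 managements x 2 treatments x 3 time points x replicate plots x plants
## per plot, with latent co-occurrence structure (sparse Gaussian graphical
## model), treatment x time x recovery-class effect multipliers, and
## prokaryote taxa whose latent abundance is negatively coupled to realized
## yeast (Bulleribasidiaceae) richness.

#' Disturbance-response class labels
#' @export
RECOVERY_CLASSES <- c("recovered", "non_recovered", "locally_extinct",
                      "indirect", "unaffected")

## run expr under a temporary seed, restoring caller RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a synthetic-scenario configuration
#'
#' Defaults describe the emulated field trial: soybean leaves in a
#' long-term tillage experiment, sampled pre-spray and at 13 and 33 days
#' post fungicide (dpf) from 4 replicate plots x 3 plants under each
#' management x treatment combination (144 samples), with sequencing depth
#' drawn negative-binomially around a median of ~30,000 reads for fungi and
#' ~47,600 for prokaryotes.
#'
#' Planted structure: a sparse latent precision matrix yields true
#' co-occurrence edges (a configurable fraction of fungal-prokaryote edges
#' negative); recovery-class effect multipliers act on fungicide samples at
#' the post-spray time points; a configurable fraction of non-recovering
#' taxa instead recover under no-till management; high-abundance "core"
#' taxa are planted by boosting base log abundance; selected prokaryotes
#' gain latent abundance as realized Bulleribasidiaceae richness drops
#' below the undisturbed baseline (competition release).
#'
#' Effect-multiplier defaults per post-spray dpf:
#' recovered (0.1, 1), non_recovered (0.1, 0.1), locally_extinct (0, 0),
#' indirect (1, 4), target pathogens (0.05, 0.05).
#'
#' @param n_fungal_taxa,n_prok_taxa numbers of taxa.
#' @param crop,compartment labels for the simulated analysis cell.
#' @param managements,treatments,dpf design factor levels; `dpf` must start
#'   with the pre-spray point 0.
#' @param n_replicates,plants_per_plot replication.
#' @param depth_mean_fungi,depth_mean_prok,depth_dispersion negative
#'   binomial sequencing-depth model.
#' @param base_logabund_mean,base_logabund_sd base log-abundance
#'   distribution across taxa.
#' @param n_core,core_boost number of planted core taxa and their
#'   log-abundance boost.
#' @param fungal_class_fracs,prok_genus_fracs taxonomy composition.
#' @param network_spec list: n_edges, weight_range, frac_negative_cross,
#'   latent_sd.
#' @param effect_spec named list of per-class multiplier vectors, one value
#'   per post-spray dpf.
#' @param n_affected named counts of planted recovered / non_recovered /
#'   locally_extinct / indirect fungal taxa.
#' @param n_target number of target-pathogen (Dothideomycetes) taxa.
#' @param no_till_recovery_frac fraction of non-recovering taxa that
#'   recover under no-till (management-dependent resilience).
#' @param coupling_spec list: on, n_coupled, strength (latent log-abundance
#'   gain per unit of lost Bulleribasidiaceae richness).
#' @param seed integer seed; all randomness flows from it.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_fungal_taxa = 300, n_prok_taxa = 500,
                            crop = "soybean", compartment = "leaf",
                            managements = c("conventional", "no_till"),
                            treatments = c("control", "fungicide"),
                            dpf = c(0, 13, 33),
                            n_replicates = 4, plants_per_plot = 3,
                            depth_mean_fungi = 30000,
                            depth_mean_prok = 47600,
                            depth_dispersion = 10,
                            base_logabund_mean = 0, base_logabund_sd = 1.5,
                            n_core = 20, core_boost = 3,
                            fungal_class_fracs = c(Dothideomycetes = 0.20,
                                                   Tremellomycetes = 0.15,
                                                   Sordariomycetes = 0.15,
                                                   other = 0.50),
                            prok_genus_fracs = c(Sphingomonas = 0.08,
                                                 Hymenobacter = 0.08,
                                                 Methylobacterium = 0.04,
                                                 other = 0.80),
                            network_spec = list(n_edges = 200,
                                                weight_range = c(0.15, 0.35),
                                                frac_negative_cross = 0.6,
                                                latent_sd = 1),
                            effect_spec = list(recovered = c(0.1, 1),
                                               non_recovered = c(0.1, 0.1),
                                               locally_extinct = c(0, 0),
                                               indirect = c(1, 4),
                                               target = c(0.05, 0.05)),
                            n_affected = c(recovered = 15, non_recovered = 10,
                                           locally_extinct = 4, indirect = 5),
                            n_target = 10,
                            no_till_recovery_frac = 0.6,
                            coupling_spec = list(on = TRUE, n_coupled = 10,
                                                 strength = 0.25),
                            seed = 1) {
  cfg <- list(n_fungal_taxa = n_fungal_taxa, n_prok_taxa = n_prok_taxa,
              crop = crop, compartment = compartment,
              managements = managements, treatments = treatments, dpf = dpf,
              n_replicates = n_replicates, plants_per_plot = plants_per_plot,
              depth_mean_fungi = depth_mean_fungi,
              depth_mean_prok = depth_mean_prok,
              depth_dispersion = depth_dispersion,
              base_logabund_mean = base_logabund_mean,
              base_logabund_sd = base_logabund_sd,
              n_core = n_core, core_boost = core_boost,
              fungal_class_fracs = fungal_class_fracs,
              prok_genus_fracs = prok_genus_fracs,
              network_spec = network_spec, effect_spec = effect_spec,
              n_affected = n_affected, n_target = n_target,
              no_till_recovery_frac = no_till_recovery_frac,
              coupling_spec = coupling_spec, seed = seed)
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' @rdname scenario_config
#' @export
default_scenario_config <- function() scenario_config()

#' Validate a scenario configuration
#' @param cfg a `scenario_config`.
#' @return `cfg` invisibly, or an error.
#' @export
validate_scenario_config <- function(cfg) {
  stopifnot(cfg$n_fungal_taxa >= 2, cfg$n_prok_taxa >= 2,
            cfg$n_replicates >= 1, cfg$plants_per_plot >= 1)
  if (cfg$dpf[1] != 0)
    stop("dpf set must start with the pre-spray point (0)")
  if (length(cfg$dpf) < 2) stop("need at least one post-spray time point")
  n_post <- length(cfg$dpf) - 1L
  for (cl in names(cfg$effect_spec)) {
    v <- cfg$effect_spec[[cl]]
    if (length(v) != n_post)
      stop(sprintf("effect_spec$%s must give one multiplier per post-spray dpf (%d)",
                   cl, n_post))
    if (any(v < 0)) stop("effect multipliers must be >= 0")
  }
  need <- c("recovered", "non_recovered", "locally_extinct", "indirect", "target")
  miss <- setdiff(need, names(cfg$effect_spec))
  if (length(miss))
    stop("effect_spec missing class(es): ", paste(miss, collapse = ", "))
  if (sum(cfg$n_affected) + cfg$n_target + cfg$n_core > cfg$n_fungal_taxa)
    stop("more planted taxa than fungal taxa available")
  stopifnot(cfg$network_spec$n_edges >= 0,
            cfg$coupling_spec$n_coupled <= cfg$n_prok_taxa)
  invisible(cfg)
}

#' Write / read a scenario configuration as YAML
#' @param cfg a `scenario_config`.
#' @param path YAML file path.
#' @export
write_scenario_config <- function(cfg, path) {
  raw <- unclass(cfg)
  ## named atomic vectors must become maps to survive YAML round-trips
  for (nm in c("fungal_class_fracs", "prok_genus_fracs", "n_affected"))
    raw[[nm]] <- as.list(raw[[nm]])
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("fungal_class_fracs", "prok_genus_fracs", "n_affected"))
    raw[[nm]] <- unlist(raw[[nm]])
  raw$network_spec$weight_range <- unlist(raw$network_spec$weight_range)
  for (nm in c("effect_spec"))
    raw[[nm]] <- lapply(raw[[nm]], unlist)
  do.call(scenario_config, raw)
}

## sparse symmetric precision matrix with planted signed edges;
## returns list(sigma, edges) where edges carry the association sign
## (positive partial association <=> negative off-diagonal precision entry)
make_latent_covariance <- function(p, n_fungal, spec) {
  omega <- diag(1, p)
  edges <- NULL
  if (spec$n_edges > 0) {
    n_pairs <- p * (p - 1) / 2
    if (spec$n_edges > n_pairs) stop("more edges requested than pairs available")
    idx <- sample.int(n_pairs, spec$n_edges)
    lt <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
    ij <- lt[idx, , drop = FALSE]
    w <- stats::runif(spec$n_edges, spec$weight_range[1], spec$weight_range[2])
    cross <- (ij[, 1] <= n_fungal) != (ij[, 2] <= n_fungal)
    sgn <- ifelse(cross,
                  ifelse(stats::runif(spec$n_edges) < spec$frac_negative_cross, -1, 1),
                  ifelse(stats::runif(spec$n_edges) < 0.5, -1, 1))
    for (k in seq_len(spec$n_edges)) {
      i <- ij[k, 1]; j <- ij[k, 2]
      omega[i, j] <- omega[j, i] <- -sgn[k] * w[k]
    }
    ## strict diagonal dominance guarantees positive definiteness; a small
    ## margin keeps planted partial correlations at realistic magnitudes
    ## (~0.2-0.4) instead of attenuating them at high-degree nodes
    margin <- if (is.null(spec$dominance_margin)) 0.1 else spec$dominance_margin
    dg <- margin + rowSums(abs(omega)) - abs(diag(omega))
    dg[dg == margin] <- 1  # isolated nodes keep unit precision
    diag(omega) <- dg
    edges <- data.frame(node_a = ij[, 1], node_b = ij[, 2],
                        sign = sgn, weight = w)
  }
  ch <- tryCatch(chol(omega), error = function(e)
    stop("planted precision matrix is not positive definite"))
  sigma <- chol2inv(ch)
  sigma <- stats::cov2cor(sigma) * spec$latent_sd^2
  list(sigma = sigma, edges = edges)
}

## taxonomy assignment for fungal taxa
assign_fungal_taxonomy <- function(ids, fracs) {
  cls <- sample(names(fracs), length(ids), replace = TRUE, prob = fracs)
  cls[cls == "other"] <- "other_class"
  fam <- rep("unclassified", length(ids))
  gen <- rep("unclassified", length(ids))
  trem <- which(cls == "Tremellomycetes")
  if (length(trem)) {
    is_bulleri <- stats::runif(length(trem)) < 0.6
    fam[trem] <- ifelse(is_bulleri, "Bulleribasidiaceae", "Tremellaceae")
    gen[trem[is_bulleri]] <- sample(c("Hannaella", "Dioszegia", "Vishniacozyma"),
                                    sum(is_bulleri), replace = TRUE)
  }
  doth <- which(cls == "Dothideomycetes")
  fam[doth] <- "Mycosphaerellaceae"; gen[doth] <- "Mycosphaerella"
  sord <- which(cls == "Sordariomycetes")
  fam[sord] <- "Nectriaceae"; gen[sord] <- "Fusarium"
  data.frame(taxon_id = ids, kingdom = "Fungi", phylum = "unclassified",
             class = cls, order = "unclassified", family = fam, genus = gen,
             stringsAsFactors = FALSE)
}

assign_prok_taxonomy <- function(ids, fracs) {
  gen <- sample(names(fracs), length(ids), replace = TRUE, prob = fracs)
  gen[gen == "other"] <- "unclassified"
  fam <- unname(c(Sphingomonas = "Sphingomonadaceae",
                  Hymenobacter = "Hymenobacteraceae",
                  Methylobacterium = "Methylobacteriaceae")[gen])
  fam[is.na(fam)] <- "unclassified"
  data.frame(taxon_id = ids, kingdom = "Bacteria", phylum = "unclassified",
             class = "unclassified", order = "unclassified", family = fam,
             genus = gen, stringsAsFactors = FALSE)
}

#' Generate a synthetic paired fungal/prokaryote scenario
#'
#' Counts are produced by (i) drawing per-sample latent log-abundances from
#' a multivariate normal whose covariance is the inverse of the planted
#' sparse precision matrix, (ii) applying treatment x dpf x recovery-class
#' effect multipliers on the natural scale (a multiplier of 0 forces exact
#' zeros), (iii) for coupled prokaryotes, adding latent abundance
#' proportional to the realized deficit of Bulleribasidiaceae richness
#' below the undisturbed (control-median) baseline, (iv) closing each domain to proportions (softmax), and (v) a
#' multinomial draw at the sample's negative-binomial sequencing depth.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return list with elements `fungi`, `prok` (OTU matrices), `taxonomy`
#'   (combined data.frame), `metadata` (sample table), `truth` (planted
#'   ground truth: `classes` per management, `target_taxa`, `true_edges`,
#'   `core_taxa`, `coupled_prokaryotes`), and `config`.
#' @export
generate_scenario <- function(cfg) {
  validate_scenario_config(cfg)
  with_seed(cfg$seed, generate_scenario_impl(cfg))
}

generate_scenario_impl <- function(cfg) {
  nf <- cfg$n_fungal_taxa; np <- cfg$n_prok_taxa; p <- nf + np
  fids <- sprintf("fOTU%d", seq_len(nf))
  pids <- sprintf("pOTU%d", seq_len(np))

  tax_f <- assign_fungal_taxonomy(fids, cfg$fungal_class_fracs)
  tax_p <- assign_prok_taxonomy(pids, cfg$prok_genus_fracs)
  taxonomy <- rbind(tax_f, tax_p)

  base <- stats::rnorm(p, cfg$base_logabund_mean, cfg$base_logabund_sd)
  names(base) <- c(fids, pids)

  ## planted core: boosted fungal taxa -> high abundance and occupancy
  core_ids <- character(0)
  if (cfg$n_core > 0) {
    core_ids <- sample(fids, cfg$n_core)
    base[core_ids] <- base[core_ids] + cfg$core_boost
  }

  ## affected fungal taxa: direct classes preferentially among
  ## Bulleribasidiaceae (the non-target yeasts), extinctions never in core;
  ## drawn from the upper half of base abundance so "present pre-spray"
  ## holds by construction
  direct_classes <- c("recovered", "non_recovered", "locally_extinct")
  n_direct <- sum(cfg$n_affected[direct_classes])
  n_indirect <- cfg$n_affected[["indirect"]]
  doth_ids <- tax_f$taxon_id[tax_f$class == "Dothideomycetes"]
  bulleri_ids <- tax_f$taxon_id[tax_f$family == "Bulleribasidiaceae"]
  eligible <- setdiff(fids, doth_ids)
  by_abund <- names(sort(base[eligible], decreasing = TRUE))
  pool <- by_abund[seq_len(max(n_direct + n_indirect + cfg$n_core,
                               ceiling(length(by_abund) / 2)))]
  cls_map <- stats::setNames(rep("unaffected", nf), fids)
  if (n_direct > 0) {
    pool_b <- intersect(pool, bulleri_ids)
    pool_o <- setdiff(pool, pool_b)
    nb <- min(length(pool_b), ceiling(n_direct / 2))
    direct_pool <- sample(c(sample(pool_b, nb),
                            sample(pool_o, n_direct - nb)))
    ## extinctions first, from non-core candidates
    k_le <- cfg$n_affected[["locally_extinct"]]
    le_cand <- setdiff(direct_pool, core_ids)
    if (length(le_cand) < k_le)
      le_cand <- unique(c(le_cand, setdiff(pool, c(core_ids, direct_pool))))
    le_take <- le_cand[seq_len(k_le)]
    cls_map[le_take] <- "locally_extinct"
    rest <- setdiff(direct_pool, le_take)
    k_r <- cfg$n_affected[["recovered"]]
    cls_map[rest[seq_len(k_r)]] <- "recovered"
    cls_map[rest[seq(k_r + 1, length.out = cfg$n_affected[["non_recovered"]])]] <-
      "non_recovered"
  }
  ind_pool <- setdiff(pool, names(cls_map)[cls_map != "unaffected"])
  if (n_indirect > 0)
    cls_map[sample(ind_pool, n_indirect)] <- "indirect"
  target_ids <- if (cfg$n_target > 0)
    sample(doth_ids, min(cfg$n_target, length(doth_ids))) else character(0)
  ## target pathogens are suppressed throughout: non-recovered dynamics
  cls_map[target_ids] <- "non_recovered"

  ## management-dependent resilience: some non-recovering taxa recover
  ## under no-till
  classes <- do.call(rbind, lapply(cfg$managements, function(mg) {
    data.frame(taxon_id = fids, management = mg, class = unname(cls_map),
               stringsAsFactors = FALSE)
  }))
  if ("no_till" %in% cfg$managements && cfg$no_till_recovery_frac > 0) {
    nr_ids <- setdiff(
      names(cls_map)[cls_map %in% c("non_recovered", "locally_extinct")],
      target_ids)
    flips <- nr_ids[stats::runif(length(nr_ids)) < cfg$no_till_recovery_frac]
    classes$class[classes$management == "no_till" &
                    classes$taxon_id %in% flips] <- "recovered"
  }

  lat <- make_latent_covariance(p, nf, cfg$network_spec)
  ch <- chol(lat$sigma)
  true_edges <- lat$edges
  if (!is.null(true_edges)) {
    all_ids <- c(fids, pids)
    true_edges$node_a <- all_ids[true_edges$node_a]
    true_edges$node_b <- all_ids[true_edges$node_b]
  }

  ## coupled prokaryotes respond to lost yeast richness
  coupled <- character(0)
  if (isTRUE(cfg$coupling_spec$on) && cfg$coupling_spec$n_coupled > 0) {
    pool <- tax_p$taxon_id[tax_p$genus %in%
                             c("Sphingomonas", "Hymenobacter", "Methylobacterium")]
    if (length(pool) < cfg$coupling_spec$n_coupled) pool <- pids
    coupled <- sample(pool, cfg$coupling_spec$n_coupled)
  }

  meta <- expand.grid(plant = seq_len(cfg$plants_per_plot),
                      replicate_plot = seq_len(cfg$n_replicates),
                      dpf = cfg$dpf, treatment = cfg$treatments,
                      management = cfg$managements,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$crop <- cfg$crop; meta$compartment <- cfg$compartment
  meta$sample_id <- sprintf("%s_%s_%s_d%02d_r%d_p%d",
                            substr(cfg$crop, 1, 3),
                            ifelse(meta$management == "no_till", "nt", "ct"),
                            ifelse(meta$treatment == "fungicide", "fun", "ctl"),
                            meta$dpf, meta$replicate_plot, meta$plant)
  meta <- meta[, c("sample_id", "crop", "management", "treatment", "dpf",
                   "replicate_plot", "plant", "compartment")]
  n <- nrow(meta)

  z <- matrix(stats::rnorm(n * p), n, p) %*% ch
  post_dpf <- cfg$dpf[-1]
  mult_for <- function(taxon, mg, dpf_idx) {
    cl <- classes$class[classes$management == mg & classes$taxon_id == taxon]
    cfg$effect_spec[[cl]][dpf_idx]
  }
  ## precompute per-(management, post-dpf) multiplier vectors over fungal taxa
  mult_tab <- array(1, dim = c(nf, length(cfg$managements), length(post_dpf)),
                    dimnames = list(fids, cfg$managements, NULL))
  for (mi in seq_along(cfg$managements)) {
    mg <- cfg$managements[mi]
    clv <- classes$class[classes$management == mg]
    names(clv) <- classes$taxon_id[classes$management == mg]
    for (di in seq_along(post_dpf)) {
      m <- rep(1, nf); names(m) <- fids
      aff <- names(clv)[clv != "unaffected"]
      if (length(aff))
        m[aff] <- vapply(clv[aff], function(cl) cfg$effect_spec[[cl]][di], 0)
      if (length(target_ids))
        m[target_ids] <- cfg$effect_spec[["target"]][di]
      mult_tab[, mi, di] <- m
    }
  }

  depth_f <- pmax(500, stats::rnbinom(n, mu = cfg$depth_mean_fungi,
                                      size = cfg$depth_dispersion))
  depth_p <- pmax(500, stats::rnbinom(n, mu = cfg$depth_mean_prok,
                                      size = cfg$depth_dispersion))

  fungi <- matrix(0L, nf, n, dimnames = list(fids, meta$sample_id))
  prok <- matrix(0L, np, n, dimnames = list(pids, meta$sample_id))
  max_rich <- length(bulleri_ids)
  rich_real <- numeric(n)

  for (s in seq_len(n)) {
    la_f <- base[fids] + z[s, seq_len(nf)]
    forced_zero <- rep(FALSE, nf)
    if (meta$treatment[s] == "fungicide" && meta$dpf[s] > 0) {
      di <- match(meta$dpf[s], post_dpf)
      mi <- match(meta$management[s], cfg$managements)
      m <- mult_tab[, mi, di]
      forced_zero <- m == 0
      la_f[!forced_zero] <- la_f[!forced_zero] + log(m[!forced_zero])
    }
    pr <- exp(la_f - max(la_f[!forced_zero]))
    pr[forced_zero] <- 0
    fungi[, s] <- stats::rmultinom(1, depth_f[s], pr / sum(pr))[, 1]
    rich_real[s] <- sum(fungi[bulleri_ids, s] > 0)
  }
  ## competition release: coupled prokaryotes gain latent abundance only
  ## when realized yeast richness falls below the undisturbed baseline
  ref_rich <- stats::median(rich_real[meta$treatment == "control"])
  for (s in seq_len(n)) {
    la_p <- base[pids] + z[s, nf + seq_len(np)]
    if (length(coupled))
      la_p[match(coupled, pids)] <- la_p[match(coupled, pids)] +
        cfg$coupling_spec$strength * max(0, ref_rich - rich_real[s])
    pr <- exp(la_p - max(la_p))
    prok[, s] <- stats::rmultinom(1, depth_p[s], pr / sum(pr))[, 1]
  }

  truth <- list(classes = classes, target_taxa = target_ids,
                true_edges = true_edges,
                core_taxa = stats::setNames(
                  rep(list(core_ids), length(cfg$managements)),
                  cfg$managements),
                coupled_prokaryotes = coupled,
                bulleribasidiaceae = bulleri_ids)
  list(fungi = fungi, prok = prok, taxonomy = taxonomy,
       metadata = validate_metadata(meta), truth = truth, config = cfg)
}

#' Write all scenario artifacts to a directory
#'
#' Emits fungi.tsv, prok.tsv, taxonomy.tsv, metadata.tsv, truth.json and
#' config.yaml in the pipeline's TSV formats.
#'
#' @param scn result of [generate_scenario()].
#' @param dir output directory (created if absent).
#' @export
write_scenario <- function(scn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(scn$fungi, file.path(dir, "fungi.tsv"))
  write_otu_table(scn$prok, file.path(dir, "prok.tsv"))
  write_results(scn$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_results(scn$metadata, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(scn$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_scenario_config(scn$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
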