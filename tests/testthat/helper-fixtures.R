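## Shared fixture builders; all fixtures are generated in code.

## tiny deterministic OTU table
toy_table <- function(counts = NULL, m = 3, n = 2) {
  if (is.null(counts))
    counts <- matrix(seq_len(m * n), m, n)
  rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  counts
}

## two-group count table from a lognormal-multinomial model; `fold`
## multiplies group-2 expected abundances
sim_two_group <- function(m, n1, n2, fold = rep(1, m), depth = 10000,
                          noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  base <- exp(stats::rnorm(m, 0, 1.5))
  x <- vapply(seq_len(n1 + n2), function(s) {
    lam <- base * exp(stats::rnorm(m, 0, noise_sd))
    if (s > n1) lam <- lam * fold
    stats::rmultinom(1, depth, lam / sum(lam))[, 1]
  }, integer(m))
  rownames(x) <- paste0("t", seq_len(m))
  colnames(x) <- paste0("s", seq_len(n1 + n2))
  x
}

two_group_factor <- function(n1, n2)
  factor(rep(c("control", "fungicide"), c(n1, n2)),
         levels = c("control", "fungicide"))

## small but fully structured scenario for integration tests
small_scenario_config <- function(seed = 11, ...) {
  scenario_config(
    n_fungal_taxa = 50, n_prok_taxa = 40,
    n_replicates = 4, plants_per_plot = 3,
    depth_mean_fungi = 8000, depth_mean_prok = 8000,
    n_core = 8, core_boost = 3,
    network_spec = list(n_edges = 40, weight_range = c(0.2, 0.4),
                        frac_negative_cross = 0.6, latent_sd = 1),
    n_affected = c(recovered = 8, non_recovered = 5, locally_extinct = 3,
                   indirect = 3),
    n_target = 4,
    coupling_spec = list(on = TRUE, n_coupled = 6, strength = 0.3),
    seed = seed, ...)
}

## scenario with a rich yeast clade and strong prokaryote coupling, for the
## richness-prediction analyses
coupled_scenario_config <- function(seed = 1, coupling_on = TRUE) {
  scenario_config(
    n_fungal_taxa = 80, n_prok_taxa = 60,
    n_replicates = 4, plants_per_plot = 3,
    depth_mean_fungi = 10000, depth_mean_prok = 10000,
    n_core = 8, core_boost = 3,
    fungal_class_fracs = c(Dothideomycetes = 0.15, Tremellomycetes = 0.40,
                           Sordariomycetes = 0.10, other = 0.35),
    prok_genus_fracs = c(Sphingomonas = 0.15, Hymenobacter = 0.15,
                         Methylobacterium = 0.10, other = 0.60),
    network_spec = list(n_edges = 50, weight_range = c(0.2, 0.4),
                        frac_negative_cross = 0.6, latent_sd = 1),
    ## presence-removing disturbance so yeast richness genuinely drops
    effect_spec = list(recovered = c(0, 1), non_recovered = c(0.05, 0.05),
                       locally_extinct = c(0, 0), indirect = c(1, 4),
                       target = c(0.05, 0.05)),
    n_affected = c(recovered = 14, non_recovered = 8, locally_extinct = 4,
                   indirect = 3),
    n_target = 5,
    coupling_spec = list(on = coupling_on, n_coupled = 8, strength = 0.35),
    seed = seed)
}

## minimal metadata for hand-built tables
toy_metadata <- function(sample_ids, treatment = NULL, management = "no_till",
                         dpf = 0) {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids, crop = "soybean",
             management = rep_len(management, n),
             treatment = if (is.null(treatment))
               rep("control", n) else rep_len(treatment, n),
             dpf = rep_len(dpf, n),
             replicate_plot = seq_len(n), compartment = "leaf",
             stringsAsFactors = FALSE)
}
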