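# Synthetic-data generators emulating the statistical structure the analysis
# assumes: multi-batch expression cohorts with latent subtypes defined by
# gene-block signatures, gene sets overlapping those blocks, subtype-linked
# survival hazards, pooled-screen count matrices with planted essential
# genes, and dilution-series viability curves. Every generator is a pure
# function of (config, seed).

#' Configuration for a synthetic expression cohort
#'
#' The cohort model is Gaussian on the log2 scale: gene g in sample j of
#' subtype s has mean `delta` if g belongs to subtype s's signature block
#' and 0 otherwise; batch b then adds a location shift `gamma_b` and
#' multiplies the residual noise sd by `delta_b` (ComBat's location/scale
#' model, so adjustment is exactly identifiable).
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param k_subtypes number of latent subtypes (>= 2).
#' @param genes_per_signature size of each subtype's signature block.
#' @param signature_effect log2 shift `delta` of signature genes in their
#'   own subtype.
#' @param n_batches number of batches (samples assigned round-robin, so
#'   batches are balanced across subtypes).
#' @param batch_shift_range,batch_scale_range ranges from which per-batch
#'   location shifts and residual-sd multipliers are drawn.
#' @param noise_sd residual Gaussian noise sd (log2 units).
#' @param seed RNG seed.
#' @return config list (class `cohort_sim_config`).
#' @export
cohort_sim_config <- function(n_genes = 500, n_samples = 200, k_subtypes = 5,
                              genes_per_signature = 50, signature_effect = 1.5,
                              n_batches = 1, batch_shift_range = c(-2, 2),
                              batch_scale_range = c(0.8, 1.25),
                              noise_sd = 1, seed = 1L) {
  .assert(k_subtypes >= 2, "k_subtypes must be >= 2")
  .assert(genes_per_signature * k_subtypes <= n_genes,
          "signature blocks (%d x %d) exceed n_genes (%d)",
          genes_per_signature, k_subtypes, n_genes)
  .assert(noise_sd > 0, "noise_sd must be > 0")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 k_subtypes = k_subtypes,
                 genes_per_signature = genes_per_signature,
                 signature_effect = signature_effect, n_batches = n_batches,
                 batch_shift_range = batch_shift_range,
                 batch_scale_range = batch_scale_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a multi-batch expression cohort with latent subtypes
#'
#' @param config a [cohort_sim_config()].
#' @return list with `expr` (genes x samples log2 matrix), `subtype`
#'   (character vector `S1..Sk`), `batch` (character vector `B1..`),
#'   `signature_genes` (list of gene-id blocks per subtype), and the
#'   `config`/`seed` used.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  .assert(inherits(config, "cohort_sim_config"), "config must come from cohort_sim_config()")
  set.seed(config$seed)
  g <- config$n_genes; n <- config$n_samples; k <- config$k_subtypes
  gene_ids <- sprintf("g%04d", seq_len(g))
  sample_ids <- sprintf("s%04d", seq_len(n))
  subtype <- sprintf("S%d", rep_len(seq_len(k), n))
  subtype <- subtype[sample.int(n)]
  batch <- sprintf("B%d", rep_len(seq_len(config$n_batches), n))
  blocks <- split(gene_ids[seq_len(k * config$genes_per_signature)],
                  rep(seq_len(k), each = config$genes_per_signature))
  names(blocks) <- sprintf("S%d", seq_len(k))
  mu <- matrix(0, g, n, dimnames = list(gene_ids, sample_ids))
  for (s in names(blocks)) {
    mu[blocks[[s]], subtype == s] <- config$signature_effect
  }
  gamma_b <- stats::runif(config$n_batches, config$batch_shift_range[[1L]],
                          config$batch_shift_range[[2L]])
  delta_b <- stats::runif(config$n_batches, config$batch_scale_range[[1L]],
                          config$batch_scale_range[[2L]])
  if (config$n_batches == 1L) { gamma_b <- 0; delta_b <- 1 }
  bidx <- as.integer(sub("^B", "", batch))
  noise <- matrix(stats::rnorm(g * n, sd = config$noise_sd), g, n)
  expr <- mu + rep(gamma_b[bidx], each = g) +
    noise * rep(delta_b[bidx], each = g)
  dimnames(expr) <- list(gene_ids, sample_ids)
  list(expr = expression_matrix(expr), subtype = stats::setNames(subtype, sample_ids),
       batch = stats::setNames(batch, sample_ids), signature_genes = blocks,
       batch_shift = gamma_b, batch_scale = delta_b, config = config,
       seed = config$seed)
}

#' Simulate gene sets: one true set per subtype plus random decoys
#'
#' @param signature_genes list of signature gene blocks (from
#'   [simulate_cohort()]).
#' @param gene_universe all gene ids the decoys may draw from.
#' @param n_decoy_sets number of decoy sets.
#' @param set_size genes per set.
#' @param seed RNG seed.
#' @return a gene set collection (named list) as from [read_gmt()]; true
#'   sets are named `TRUE_<subtype>`, decoys `DECOY_<i>`.
#' @export
simulate_gene_sets <- function(signature_genes, gene_universe,
                               n_decoy_sets = 10, set_size = 25, seed = 1L) {
  .assert(set_size <= length(gene_universe),
          "set_size (%d) exceeds gene universe (%d)", set_size,
          length(gene_universe))
  set.seed(seed)
  true_sets <- lapply(signature_genes, function(gs) {
    gs[seq_len(min(set_size, length(gs)))]
  })
  names(true_sets) <- paste0("TRUE_", names(signature_genes))
  decoys <- lapply(seq_len(n_decoy_sets), function(i) {
    sample(gene_universe, set_size)
  })
  names(decoys) <- sprintf("DECOY_%02d", seq_len(n_decoy_sets))
  sets <- c(true_sets, decoys)
  attr(sets, "description") <- stats::setNames(
    c(rep("planted subtype signature subset", length(true_sets)),
      rep("random decoy set", length(decoys))), names(sets))
  sets
}

#' Simulate survival outcomes linked to subtype
#'
#' Event times are exponential with hazard `baseline_hazard * hr[subtype]`;
#' censoring is independent uniform on (0, c_max) with c_max chosen so the
#' expected censoring fraction approximates `censoring_rate`.
#'
#' @param subtype named subtype labels per sample.
#' @param baseline_hazard events per month for the reference hazard.
#' @param hazard_ratio named vector of per-subtype hazard ratios (> 0);
#'   unnamed subtypes default to 1.
#' @param censoring_rate target censoring fraction in \[0, 1).
#' @param seed RNG seed.
#' @return clinical-style data.frame with `sample_id`, `subtype`,
#'   `os_time`, `os_event`.
#' @export
simulate_survival <- function(subtype, baseline_hazard = 0.02,
                              hazard_ratio = NULL, censoring_rate = 0.3,
                              seed = 1L) {
  .assert(censoring_rate >= 0 && censoring_rate < 1,
          "censoring_rate must be in [0, 1)")
  levs <- unique(subtype)
  hr <- stats::setNames(rep(1, length(levs)), levs)
  if (!is.null(hazard_ratio)) {
    .assert(all(hazard_ratio > 0), "hazard ratios must be > 0")
    hr[names(hazard_ratio)] <- hazard_ratio
  }
  set.seed(seed)
  n <- length(subtype)
  lambda <- baseline_hazard * hr[subtype]
  t_event <- stats::rexp(n, rate = lambda)
  if (censoring_rate == 0) {
    time <- t_event; event <- rep(1, n)
  } else {
    # Uniform(0, c_max) censoring; c_max solved numerically so that
    # P(C < T) matches the requested rate at the average hazard.
    lam_bar <- mean(lambda)
    # P(C < T) for C ~ U(0, cmax), T ~ Exp(lam_bar)
    cens_frac <- function(cmax) {
      (1 - exp(-lam_bar * cmax)) / (lam_bar * cmax)
    }
    c_max <- stats::uniroot(function(x) cens_frac(x) - censoring_rate,
                            c(1e-6, 1e6))$root
    t_cens <- stats::runif(n, 0, c_max)
    event <- as.numeric(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  }
  ids <- names(subtype)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(n))
  data.frame(sample_id = ids, subtype = as.character(subtype),
             os_time = pmax(time, .Machine$double.eps), os_event = event,
             stringsAsFactors = FALSE)
}

#' Configuration for a synthetic pooled shRNA screen
#'
#' Hairpin baseline log2 abundances are Gaussian across the library; an
#' essential gene's hairpins are shifted down by a per-hairpin depletion
#' effect in the target group only (negative depletion models amplified,
#' growth-suppressing genes). Per-sample counts are multinomial over the
#' exponentiated abundances at fixed sequencing depth, with per-cell-line
#' log2 replicate noise on top (the overdispersion of real screens).
#'
#' @param n_genes genes in the library.
#' @param hairpins_per_gene hairpins per gene (>= 1).
#' @param n_cell_lines integer vector, cell lines per subtype group
#'   (first group = target group).
#' @param baseline_mean,baseline_sd log2 abundance distribution across
#'   hairpins.
#' @param n_essential_genes genes depleted in the target group.
#' @param depletion_mean,depletion_sd per-hairpin log2 depletion effect.
#' @param noise_sd per-(hairpin, sample) log2 replicate noise.
#' @param depth reads per sample (multinomial total).
#' @param seed RNG seed.
#' @return config list (class `screen_sim_config`).
#' @export
screen_sim_config <- function(n_genes = 2000, hairpins_per_gene = 5,
                              n_cell_lines = c(5, 9), baseline_mean = 0,
                              baseline_sd = 1, n_essential_genes = 100,
                              depletion_mean = 1.5, depletion_sd = 0.5,
                              noise_sd = 0.5, depth = 5e6, seed = 1L) {
  .assert(hairpins_per_gene >= 1, "hairpins_per_gene must be >= 1")
  .assert(length(n_cell_lines) >= 2 && all(n_cell_lines >= 2),
          "need >= 2 groups with >= 2 cell lines each")
  .assert(n_essential_genes <= n_genes, "too many essential genes")
  structure(list(n_genes = n_genes, hairpins_per_gene = hairpins_per_gene,
                 n_cell_lines = n_cell_lines, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 n_essential_genes = n_essential_genes,
                 depletion_mean = depletion_mean, depletion_sd = depletion_sd,
                 noise_sd = noise_sd, depth = depth, seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate a pooled shRNA screen
#'
#' @param config a [screen_sim_config()].
#' @return list with `counts` (hairpins x cell lines integer matrix),
#'   `library` (hairpin library data.frame), `group` (named group labels,
#'   target group = `G1`), `essential_genes` (character vector planted in
#'   the target group), and `config`/`seed`.
#' @export
simulate_screen <- function(config = screen_sim_config()) {
  .assert(inherits(config, "screen_sim_config"), "config must come from screen_sim_config()")
  set.seed(config$seed)
  h <- config$n_genes * config$hairpins_per_gene
  if (config$depth < 10 * h) {
    warning("sequencing depth is small relative to library size; counts will be sparse",
            call. = FALSE)
  }
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  lib <- data.frame(
    hairpin_id = sprintf("hp%05d", seq_len(h)),
    gene = rep(genes, each = config$hairpins_per_gene),
    sequence = .random_unique_seqs(h, width = 21L),
    stringsAsFactors = FALSE)
  n_per <- config$n_cell_lines
  group <- sprintf("G%d", rep(seq_along(n_per), n_per))
  samples <- sprintf("CL%02d", seq_along(group))
  names(group) <- samples
  essential <- sample(genes, config$n_essential_genes)
  base <- stats::rnorm(h, config$baseline_mean, config$baseline_sd)
  effect <- numeric(h)
  idx <- lib$gene %in% essential
  effect[idx] <- stats::rnorm(sum(idx), config$depletion_mean,
                              config$depletion_sd)
  counts <- matrix(0L, h, length(samples),
                   dimnames = list(lib$hairpin_id, samples))
  for (j in seq_along(samples)) {
    mu <- base
    if (group[[j]] == "G1") mu <- mu - effect
    mu <- mu + stats::rnorm(h, sd = config$noise_sd)
    prop <- 2^mu
    counts[, j] <- stats::rmultinom(1L, size = config$depth,
                                    prob = prop / sum(prop))[, 1L]
  }
  list(counts = counts, library = hairpin_library(lib),
       group = group, essential_genes = essential, config = config,
       seed = config$seed)
}

.random_unique_seqs <- function(n, width = 21L) {
  repeat {
    s <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
    }, "")
    if (!anyDuplicated(s)) return(s)
  }
}

#' Simulate a dilution-series viability table
#'
#' Viability follows the Hill model `100 / (1 + (c / gi50)^hill)` with
#' optional Gaussian noise.
#'
#' @param gi50_true true midpoint concentration.
#' @param hill_slope Hill coefficient (use a large value to approach a step
#'   function).
#' @param concentrations positive, geometrically increasing doses (default:
#'   nine twofold dilutions, the paper-style series; an eight-point /
#'   128-fold series is equally valid).
#' @param noise_sd Gaussian noise on viability percent (0 = exact curve).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return data.frame with `concentration` and `viability`.
#' @export
simulate_dose_response <- function(gi50_true, hill_slope = 1,
                                   concentrations = gi50_true * 2^(-4:4),
                                   noise_sd = 0, seed = 1L) {
  .assert(all(concentrations > 0), "concentrations must be positive")
  .assert(!is.unsorted(concentrations, strictly = TRUE),
          "concentrations must be strictly increasing")
  r <- concentrations[-1L] / concentrations[-length(concentrations)]
  .assert(max(r) / min(r) < 1 + 1e-6, "concentrations must form a geometric series")
  v <- 100 / (1 + (concentrations / gi50_true)^hill_slope)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  data.frame(concentration = concentrations, viability = v)
}
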