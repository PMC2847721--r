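# run code under a fixed seed without clobbering the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default reference-gene panel for simulation
#'
#' Six candidate reference genes spanning three biological-variability
#' classes (log2-scale sd 0.05 for the quiet genes, 0.3-0.5 for the
#' unstable ones), named after the blood housekeeping panel this kind of
#' stability study screens, plus a BDNF-like target with realistic
#' inter-individual variability (sd 0.8 log2 units).
#'
#' @param target_sd_log2 Biological sd of the target gene (default 0.8).
#' @param target_effect_log2 Dysregulation effect added to the target in
#'   case samples (default 0, i.e. no dysregulation).
#' @return A tibble `gene`, `mean_log2`, `bio_sd_log2`, `dysregulated`,
#'   `effect_log2`.
#' @export
default_gene_panel <- function(target_sd_log2 = 0.8, target_effect_log2 = 0) {
  tibble(
    gene = c("GNB2L1", "HPRT1", "YWHAZ", "B2M", "GAPDH", "ACTB", "BDNF"),
    mean_log2 = c(0, 0, 0, 2, 3, 3, -2),
    bio_sd_log2 = c(0.05, 0.05, 0.05, 0.3, 0.4, 0.5, target_sd_log2),
    dysregulated = c(rep(FALSE, 6L), target_effect_log2 != 0),
    effect_log2 = c(rep(0, 6L), target_effect_log2)
  )
}

#' Simulation configuration
#'
#' Describes a synthetic RT-qPCR experiment with known ground truth:
#' per-sample loading variation (log2-normal), per-gene biological
#' variability classes, optional dysregulation of flagged genes in "case"
#' samples, technical replicate noise on the Cq scale, and an aggregate EAR
#' signal pooled over many independent Alu-bearing transcripts. Biology and
#' loading act multiplicatively (noise on the log2 quantity scale);
#' technical error is additive on the cycle scale — the error structure
#' qPCR assumes.
#'
#' @param n_samples Number of samples (default 10).
#' @param genes Gene panel tibble (see [default_gene_panel()]).
#' @param n_cases Number of leading samples forming the "case" group that
#'   receives dysregulation effects (default 0).
#' @param loading_sd_log2 Per-sample loading sd, log2 units (default 0.5).
#' @param technical_sd_cq Technical replicate noise sd, cycles
#'   (default 0.15).
#' @param rt_replicates,pcr_replicates Replicate design (default 2 x 3, six
#'   measurements per sample and gene).
#' @param ear_components Number of pooled Alu-bearing transcripts behind the
#'   EAR signal (default 500).
#' @param ear_component_sd_log2 Per-sample biological sd of each pooled
#'   transcript (default 0.3).
#' @param ear_component_spread_log2 Spread of component mean abundances
#'   (default 1).
#' @param amplification_factor Per-cycle fold change used for the Cq
#'   transform (default 2).
#' @param baseline_cq Cq of a unit quantity at unit loading (default 24,
#'   placing typical Cq in the realistic 18-35 cycle window; the anchor
#'   cancels from every downstream ratio).
#' @param include_ear Emit the pooled EAR gene? Default `TRUE`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 10L,
                       genes = default_gene_panel(),
                       n_cases = 0L,
                       loading_sd_log2 = 0.5,
                       technical_sd_cq = 0.15,
                       rt_replicates = 2L,
                       pcr_replicates = 3L,
                       ear_components = 500L,
                       ear_component_sd_log2 = 0.3,
                       ear_component_spread_log2 = 1,
                       amplification_factor = 2,
                       baseline_cq = 24,
                       include_ear = TRUE) {
  genes <- as_tibble(genes)
  need <- c("gene", "mean_log2", "bio_sd_log2", "dysregulated", "effect_log2")
  if (!all(need %in% names(genes))) {
    abort_format(paste0("`genes` needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(genes$bio_sd_log2 < 0) || loading_sd_log2 < 0 || technical_sd_cq < 0 ||
      ear_component_sd_log2 < 0) {
    abort_validation("all standard deviations must be >= 0")
  }
  if (n_samples < 1L || rt_replicates < 1L || pcr_replicates < 1L || ear_components < 1L) {
    abort_validation("sample, replicate and EAR component counts must be >= 1")
  }
  if (n_cases < 0L || n_cases > n_samples) {
    abort_validation("`n_cases` must lie in [0, n_samples]")
  }
  if (amplification_factor <= 1) abort_domain("`amplification_factor` must be > 1")
  if (anyDuplicated(genes$gene) || "EAR" %in% genes$gene) {
    abort_validation("gene ids must be unique and must not include the reserved id 'EAR'")
  }
  structure(
    list(n_samples = as.integer(n_samples), genes = genes, n_cases = as.integer(n_cases),
         loading_sd_log2 = loading_sd_log2, technical_sd_cq = technical_sd_cq,
         rt_replicates = as.integer(rt_replicates), pcr_replicates = as.integer(pcr_replicates),
         ear_components = as.integer(ear_components),
         ear_component_sd_log2 = ear_component_sd_log2,
         ear_component_spread_log2 = ear_component_spread_log2,
         amplification_factor = amplification_factor, baseline_cq = baseline_cq,
         include_ear = include_ear),
    class = "sim_config"
  )
}

#' Simulate a Cq experiment with known ground truth
#'
#' Draws per-sample loading factors, per-(sample, gene) biological
#' quantities `2^(mean + biological noise + dysregulation effect)`, and —
#' when enabled — a pooled EAR quantity summing `ear_components`
#' independent transcript quantities, each with its own mean abundance and
#' biological noise. Quantities are converted to Cq via
#' `Cq = baseline - log(quantity x loading) / log(amplification_factor)`
#' with iid technical noise per replicate well. Deterministic for a fixed
#' `(config, seed)` pair; the caller's RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `cq` (a validated `cq_tbl`) and `truth`: per-sample
#'   `loading` (with `group`), per-(sample, gene) biological `quantities`
#'   (loading excluded), the gene panel, `ear_sd_log2` (sd of the log2
#'   pooled EAR quantity across samples, `NA` when EAR disabled), the seed
#'   and the config.
#' @export
simulate_experiment <- function(config, seed = 1L) {
  if (!inherits(config, "sim_config")) abort_validation("`config` must be a sim_config()")
  with_local_seed(seed, {
    n <- config$n_samples
    samples <- sprintf("s%02d", seq_len(n))
    group <- ifelse(seq_len(n) <= config$n_cases, "case", "control")
    loading <- 2^rnorm(n, 0, config$loading_sd_log2)

    panel <- config$genes
    q_gene <- purrr::pmap(panel, function(gene, mean_log2, bio_sd_log2, dysregulated, effect_log2) {
      eff <- if (isTRUE(dysregulated)) ifelse(group == "case", effect_log2, 0) else 0
      tibble(sample = samples, gene = gene,
             true_quantity = 2^(mean_log2 + rnorm(n, 0, bio_sd_log2) + eff))
    })
    quantities <- bind_rows(q_gene)

    ear_sd <- NA_real_
    if (config$include_ear) {
      k <- config$ear_components
      mu <- rnorm(k, 0, config$ear_component_spread_log2)
      eps <- matrix(rnorm(n * k, 0, config$ear_component_sd_log2), nrow = n)
      pooled <- as.numeric(2^sweep(eps, 2L, mu, "+") %*% rep(1, k)) / k
      ear_sd <- sd(log2(pooled))
      quantities <- bind_rows(quantities,
                              tibble(sample = samples, gene = "EAR", true_quantity = pooled))
    }

    design <- cq_design(config$rt_replicates, config$pcr_replicates)
    wells <- tidyr::expand_grid(
      quantities,
      rt_rep = seq_len(config$rt_replicates),
      pcr_rep = seq_len(config$pcr_replicates)
    )
    load_of <- setNames(loading, samples)
    wells <- wells %>%
      mutate(
        cq = config$baseline_cq -
          log(.data$true_quantity * load_of[.data$sample]) / log(config$amplification_factor) +
          rnorm(n(), 0, config$technical_sd_cq)
      ) %>%
      select("sample", "gene", "rt_rep", "pcr_rep", "cq")

    list(
      cq = as_cq_table(wells, design),
      truth = list(
        loading = tibble(sample = samples, group = group, loading = loading),
        quantities = quantities,
        gene_panel = panel,
        ear_sd_log2 = ear_sd,
        seed = seed,
        config = config
      )
    )
  })
}

#' Simulate a dilution-series calibration input
#'
#' `Cq = intercept + true_slope * log10(amount) + N(0, noise_sd)` per
#' replicate point, the structure a standard curve is fitted to.
#'
#' @param true_slope Underlying slope, cycles per log10 dilution.
#' @param intercept Cq of the undiluted (amount = 1) input.
#' @param amounts Positive relative input amounts (default a 10-fold series
#'   over 6 points).
#' @param noise_sd Gaussian Cq noise sd (default 0.1 cycles).
#' @param replicates Replicates per dilution point (default 1).
#' @param seed Integer seed.
#' @return A tibble `amount`, `cq` suitable for [fit_standard_curve()].
#' @export
simulate_dilution_series <- function(true_slope = -3.27, intercept = 20,
                                     amounts = 10^-(0:5), noise_sd = 0.1,
                                     replicates = 1L, seed = 1L) {
  if (any(amounts <= 0)) abort_validation("dilution amounts must be positive")
  if (noise_sd < 0) abort_validation("`noise_sd` must be >= 0")
  with_local_seed(seed, {
    pts <- tidyr::expand_grid(amount = amounts, rep = seq_len(replicates))
    tibble(
      amount = pts$amount,
      cq = intercept + true_slope * log10(pts$amount) + rnorm(nrow(pts), 0, noise_sd)
    )
  })
}

#' Simulate a melt curve from sigmoidal components
#'
#' Fluorescence is modelled as a weighted sum of sigmoidal decays, one per
#' product species, each centred at its melting temperature: the negative
#' derivative then peaks at the component Tm values. A mixture of
#' components emulates the heterogeneous pooled Alu amplicon; replicates
#' generated from the same component list share their melting profile.
#'
#' @param components Tibble `tm` (degrees C), `width` (transition width,
#'   degrees C), `weight` (positive fluorescence contribution).
#' @param grid Temperature grid (default 55 to 94 by 0.5 degrees C).
#' @param noise_sd Gaussian fluorescence noise sd (default 0).
#' @param seed Integer seed.
#' @return A tibble `temperature_c`, `fluorescence`.
#' @examples
#' simulate_melt(tibble::tibble(tm = 88.7, width = 1, weight = 1))
#' @export
simulate_melt <- function(components, grid = seq(55, 94, by = 0.5),
                          noise_sd = 0, seed = 1L) {
  components <- as_tibble(components)
  if (!all(c("tm", "width", "weight") %in% names(components))) {
    abort_format("`components` needs columns tm, width, weight")
  }
  if (any(components$weight <= 0)) abort_validation("component weights must be positive")
  if (any(components$width <= 0)) abort_validation("component widths must be positive")
  with_local_seed(seed, {
    fl <- rep(0, length(grid))
    for (i in seq_len(nrow(components))) {
      fl <- fl + components$weight[i] /
        (1 + exp((grid - components$tm[i]) / components$width[i]))
    }
    if (noise_sd > 0) fl <- fl + rnorm(length(grid), 0, noise_sd)
    tibble(temperature_c = grid, fluorescence = fl)
  })
}
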