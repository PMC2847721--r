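# tiny polynomial rolling hash; enough to fingerprint a run configuration
config_fingerprint <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run configuration for the end-to-end workflow
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed driving every stochastic stage.
#' @param cq_path Optional path to a Cq CSV; when `NULL` the experiment is
#'   simulated from `sim`.
#' @param sim A [sim_config()] used when `cq_path` is `NULL`.
#' @param design A [cq_design()] for reading `cq_path`.
#' @param target Target gene id (default `"BDNF"`).
#' @param strategy One of `"ear"` (single universal reference `"EAR"`),
#'   `"single:GENE"`, or `"nf"` (geometric-mean factor over the stability
#'   analysis' selected references).
#' @param candidate_genes Candidate reference genes for the stability
#'   analysis; default: every gene except the target and `"EAR"`.
#' @param m_threshold Stability threshold (default 0.5).
#' @param n_references Reference genes selected for the factor (default 3).
#' @param melt_path Optional melt-curve CSV for QC.
#' @param melt_tolerance_c Replicate-concordance tolerance (default 0.5).
#' @param min_prominence_fraction Peak-calling prominence (default 0.2).
#' @param amplification_factor Single factor or named per-gene vector
#'   (default 2).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, cq_path = NULL, sim = sim_config(),
                       design = cq_design(), target = "BDNF", strategy = "nf",
                       candidate_genes = NULL, m_threshold = 0.5,
                       n_references = 3L, melt_path = NULL,
                       melt_tolerance_c = 0.5, min_prominence_fraction = 0.2,
                       amplification_factor = 2) {
  if (!(identical(strategy, "ear") || identical(strategy, "nf") ||
        grepl("^single:.+$", strategy))) {
    abort_validation("`strategy` must be 'ear', 'nf' or 'single:GENE'")
  }
  if (m_threshold <= 0 || melt_tolerance_c <= 0 || min_prominence_fraction <= 0) {
    abort_validation("thresholds must be positive")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), cq_path = cq_path, sim = sim,
         design = design, target = target, strategy = strategy,
         candidate_genes = candidate_genes, m_threshold = m_threshold,
         n_references = as.integer(n_references), melt_path = melt_path,
         melt_tolerance_c = melt_tolerance_c,
         min_prominence_fraction = min_prominence_fraction,
         amplification_factor = amplification_factor),
    class = "run_config"
  )
}

#' Run the full normalization workflow
#'
#' Ingest (or simulate) a Cq experiment, aggregate replicates into
#' efficiency-corrected relative quantities, run the reference-gene
#' stability analysis, normalize the target with the configured strategy,
#' summarise the result, and (optionally) QC melt curves. Every stage's
#' output is written under `out_dir` together with a provenance manifest
#' (package version, seed, configuration fingerprint), so any stage can be
#' re-run from its written artifacts. Re-running with the same seed and
#' configuration reproduces the outputs exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `quantities`, `stability`, `normalized`,
#'   `summary`, `melt_qc` (`NULL` unless melt input was given), and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort_validation("`config` must be a run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "earnorm_error_pipeline")
    })
  }

  cq <- step("ingest", {
    if (is.null(config$cq_path)) {
      sim <- simulate_experiment(config$sim, config$seed)
      write_cq_table(sim$cq, file.path(config$out_dir, "cq_simulated.csv"))
      readr::write_csv(sim$truth$quantities, file.path(config$out_dir, "truth_quantities.csv"))
      sim$cq
    } else {
      read_cq_table(config$cq_path, config$design)
    }
  })

  quantities <- step("quantify", quantify_cq(cq, config$amplification_factor))
  readr::write_csv(quantities, file.path(config$out_dir, "quantities.csv"))

  candidates <- config$candidate_genes %||%
    setdiff(unique(quantities$gene), c(config$target, "EAR"))
  stability <- step("stability", stepwise_ranking(
    quantities, genes = candidates,
    threshold = config$m_threshold, n_references = config$n_references
  ))
  jsonlite::write_json(
    list(rounds = stability$rounds, ranking = stability$ranking,
         exclusion_order = stability$exclusion_order, final_pair = stability$final_pair,
         selected_references = stability$selected_references,
         selected_m = as.list(stability$last_m[stability$selected_references]),
         threshold = stability$threshold, log_base = stability$log_base),
    file.path(config$out_dir, "stability.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (config$strategy == "nf" && !all(stability$selected_stable)) {
    warn("normalization factor uses reference gene(s) failing the stability threshold")
  }

  normalized <- step("normalize", {
    if (config$strategy == "ear") {
      normalize_to_single(quantities, config$target, "EAR")
    } else if (config$strategy == "nf") {
      normalize_to_nf(quantities, config$target, stability$selected_references)
    } else {
      normalize_to_single(quantities, config$target, sub("^single:", "", config$strategy))
    }
  })
  readr::write_csv(normalized, file.path(config$out_dir, "normalized.csv"))

  summary_tbl <- step("stats", box_summary(normalized$normalized))
  readr::write_csv(summary_tbl, file.path(config$out_dir, "summary.csv"))

  melt_result <- NULL
  if (!is.null(config$melt_path)) {
    melt_result <- step("meltqc", {
      curves <- read_melt_curves(config$melt_path)
      melt_qc_report(melt_peaks(curves, config$min_prominence_fraction),
                     config$melt_tolerance_c)
    })
    readr::write_csv(melt_result, file.path(config$out_dir, "meltqc.csv"))
  }

  cfg_string <- jsonlite::toJSON(config[setdiff(names(config), c("sim", "design"))],
                                 auto_unbox = TRUE, force = TRUE)
  manifest <- list(
    package = "earnorm",
    version = as.character(utils::packageVersion("earnorm")),
    seed = config$seed,
    strategy = config$strategy,
    target = config$target,
    selected_references = stability$selected_references,
    config_hash = config_fingerprint(as.character(cfg_string)),
    outputs = list.files(config$out_dir)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(quantities = quantities, stability = stability,
                 normalized = normalized, summary = summary_tbl,
                 melt_qc = melt_result, manifest = manifest))
}
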