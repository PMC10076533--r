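# End-to-end orchestration: one configuration drives simulation (or file
# input), preprocessing, disproportionality, the disease signature,
# reversal scoring and integration, writing TSV outputs plus a manifest
# into a run directory.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the standard thresholds:
#' adjusted-p 0.001 with log2 fold-change cuts 1.5 / -2.0 (core +/- 2.5),
#' reversal-gene FDR 0.25, reference condition 10 uM / 24 h, and the
#' synthetic-demo generator sizes.  Any element can be overridden via
#' `...`; a YAML file with the same keys can be loaded with
#' [load_pipeline_config()].
#'
#' @param seed Master seed; per-stage seeds are derived from it by a fixed
#'   documented formula (see `stage_seed` in the sources).
#' @param out_dir Run directory.
#' @param ... Overrides of any default element.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("inversig_run"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    alpha = 0.001, up_fc = 1.5, down_fc = -2.0, core_fc = 2.5,
    fdr = 0.25, ref_dose = 10, ref_time = 24, w0 = 0.5,
    activity_method = "ror",
    # synthetic-demo generator sizes
    n_compounds = 60, n_events = 30, n_reports = 60000,
    n_genes = 300, n_planted_up = 12, n_planted_down = 8,
    n_studies = 6, n_case = 20, n_control = 20,
    effect_size_mean = 3, study_noise_sd = 0.5,
    duplicate_fraction = 0.1, combo_fraction = 0.05,
    concomitant_fraction = 0.1,
    target_event = "Psoriasis", lambda_scale = 2.5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (cfg$up_fc <= 0 || cfg$down_fc >= 0)
    stop("fold-change cuts must satisfy up_fc > 0 and down_fc < 0")
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("fdr must lie in (0, 1)")
  if (cfg$ref_dose <= 0 || cfg$ref_time <= 0)
    stop("reference dose and time must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [pipeline_config()] elements.
#' @return A validated `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  do.call(pipeline_config, yaml::read_yaml(path))
}

demo_simulation <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  planted_up <- genes[seq_len(cfg$n_planted_up)]
  planted_down <- genes[cfg$n_planted_up + seq_len(cfg$n_planted_down)]

  ecfg <- expr_sim_config(
    n_studies = cfg$n_studies, genes = genes,
    n_case = cfg$n_case, n_control = cfg$n_control,
    planted_up = planted_up, planted_down = planted_down,
    effect_size_mean = cfg$effect_size_mean,
    study_noise_sd = cfg$study_noise_sd,
    seed = stage_seed(cfg$seed, "demo"))
  esim <- simulate_expression(ecfg)

  compounds <- sprintf("CPD%04d", seq_len(cfg$n_compounds))
  events <- c(cfg$target_event, "Drug ineffective", "Medication error",
              sprintf("EVENT%04d", seq_len(cfg$n_events - 3)))
  # latent activities drive both the planted inverse reporting ratios and
  # the signature-reversal strength
  set.seed(stage_seed(cfg$seed, "demo") + 1L)
  activities <- stats::runif(cfg$n_compounds)
  lambda <- exp(-cfg$lambda_scale * activities)
  probs <- c(0.2, 0.05, 0.05, rep(0.7 / (cfg$n_events - 3),
                                  cfg$n_events - 3))
  acfg <- aer_sim_config(
    n_drugs = cfg$n_compounds, n_events = cfg$n_events,
    n_reports = cfg$n_reports, baseline_event_probs = probs,
    planted_associations = data.frame(drug = compounds,
                                      event = cfg$target_event,
                                      lambda = lambda),
    duplicate_fraction = cfg$duplicate_fraction,
    combo_fraction = cfg$combo_fraction,
    concomitant_fraction = cfg$concomitant_fraction,
    drug_names = compounds, event_names = events,
    seed = stage_seed(cfg$seed, "demo") + 2L)
  asim <- simulate_reports(acfg)

  dcfg <- drug_sim_config(cfg$n_compounds, universe = genes,
                          activities = activities,
                          seed = stage_seed(cfg$seed, "demo") + 3L)
  list(expr = esim, aer = asim, drug_cfg = dcfg,
       activities = activities, compounds = compounds,
       planted_up = planted_up, planted_down = planted_down)
}

#' Run the full pipeline on synthetic demo data
#'
#' Executes every stage in dependency order: simulate inputs, parse /
#' deduplicate / filter the report tables, build contingency cells and the
#' three disproportionality statistics, map events and select the target
#' event, build the meta-analytic disease signature, simulate and score
#' compound signatures, summarise to sRGES, and integrate (signal
#' correlations, LOOCV reversal genes, IC50 validation).  Each stage
#' writes TSV outputs into the run directory together with a deterministic
#' manifest (parameters, seed, package version, output checksums), so a
#' rerun with the same configuration is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory result and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message("[inversig] ", ...)

  log_line("stage 1/6: simulating inputs")
  sim <- demo_simulation(cfg)
  faers_dir <- file.path(cfg$out_dir, "faers")
  paths <- write_faers(sim$aer, faers_dir)
  write_tsv(sim$aer$truth, file.path(cfg$out_dir, "truth_associations.tsv"))
  write_tsv(data.frame(compound_id = sim$compounds,
                       activity = sim$activities),
            file.path(cfg$out_dir, "truth_activities.tsv"))
  write_tsv(sim$expr$truth, file.path(cfg$out_dir, "truth_genes.tsv"))

  log_line("stage 2/6: reading, deduplicating, filtering reports")
  reports <- read_reports(paths["demo"], paths["drug"], paths["reac"])
  n_raw <- nrow(reports$demo)
  reports <- deduplicate_reports(reports)
  log_line("  dedup: ", n_raw, " -> ", nrow(reports$demo), " reports")
  reports <- filter_reports(reports)
  rem <- attr(reports, "removed")
  log_line("  filters removed: role=", rem["role"], " combination=",
           rem["combination"], " excluded_pt=", rem["excluded_pt"])
  pairs <- report_pairs(reports)
  cells <- build_contingency(pairs)
  write_tsv(cells, file.path(cfg$out_dir, "contingency.tsv"))

  log_line("stage 3/6: disproportionality statistics")
  signals <- disproportionality(cells, seed = cfg$seed)
  write_tsv(signals, file.path(cfg$out_dir, "signals.tsv"))
  sc <- attr(signals, "signal_counts")
  log_line("  inverse flags: ror=", sc["ror"], " ic=", sc["ic"],
           " ebgm=", sc["ebgm"])

  mapping <- data.frame(pt = c(cfg$target_event, "Headache"),
                        icd10 = c("L40", "R51"))
  mapped <- map_events_to_icd10(unique(cells$event), mapping)
  target <- select_target_event(signals, mapped,
                                method = cfg$activity_method)
  write_tsv(target, file.path(cfg$out_dir, "target_events.tsv"))

  log_line("stage 4/6: disease signature meta-analysis")
  sig <- meta_signature(sim$expr$studies, alpha = cfg$alpha,
                        up_fc = cfg$up_fc, down_fc = cfg$down_fc,
                        core_fc = cfg$core_fc)
  write_tsv(sig$meta, file.path(cfg$out_dir, "meta_results.tsv"))
  write_tsv(data.frame(
    gene = c(sig$up_genes, sig$down_genes),
    direction = c(rep("up", length(sig$up_genes)),
                  rep("down", length(sig$down_genes)))),
    file.path(cfg$out_dir, "disease_signature.tsv"))
  log_line("  signature: ", length(sig$up_genes), " up / ",
           length(sig$down_genes), " down")

  log_line("stage 5/6: compound signatures and reversal scoring")
  dsim <- simulate_drug_signatures(sim$drug_cfg, sig)
  scored <- score_profiles(dsim$profiles, sig)
  write_tsv(scored, file.path(cfg$out_dir, "rges.tsv"))
  srges <- summarize_rges(scored, w0 = cfg$w0, ref_dose = cfg$ref_dose,
                          ref_time = cfg$ref_time)
  write_tsv(srges, file.path(cfg$out_dir, "srges.tsv"))

  log_line("stage 6/6: integration")
  tgt <- signals[signals$event == cfg$target_event, , drop = FALSE]
  activity <- merge(srges, tgt[c("drug", "ror_uci", "ic975", "ebgm95")],
                    by.x = "compound_id", by.y = "drug", all.x = TRUE)
  correlations <- correlate_signals(activity)
  write_tsv(correlations, file.path(cfg$out_dir, "signal_correlations.tsv"))

  rank_mat <- representative_ranks(dsim$profiles, cfg$ref_dose, cfg$ref_time)
  act_vec <- activity$ror_uci[match(rownames(rank_mat),
                                    activity$compound_id)]
  ok <- is.finite(act_vec)
  rev_genes <- loocv_reversal_genes(rank_mat[ok, , drop = FALSE],
                                    act_vec[ok], fdr_threshold = cfg$fdr)
  write_tsv(rev_genes$calls, file.path(cfg$out_dir, "reversal_genes.tsv"))
  write_tsv(data.frame(gene = rownames(rev_genes$norm_ranks),
                       round(rev_genes$norm_ranks, 6),
                       check.names = FALSE),
            file.path(cfg$out_dir, "normalized_ranks.tsv"))

  ic50 <- simulate_ic50(dsim$truth, sim$drug_cfg)
  write_tsv(ic50, file.path(cfg$out_dir, "ic50.tsv"))
  comp <- srges[c("compound_id", "inchikey", "srges")]
  val <- ic50_validate(comp, ic50)
  write_tsv(val$correlations, file.path(cfg$out_dir, "ic50_correlations.tsv"))

  manifest <- c(
    sprintf("package: inversig %s",
            as.character(utils::packageVersion("inversig"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("parameters: alpha=%g up_fc=%g down_fc=%g core_fc=%g fdr=%g ref=%gum/%gh w0=%g",
            cfg$alpha, cfg$up_fc, cfg$down_fc, cfg$core_fc, cfg$fdr,
            cfg$ref_dose, cfg$ref_time, cfg$w0),
    sprintf("sizes: compounds=%d genes=%d studies=%d reports=%d",
            cfg$n_compounds, cfg$n_genes, cfg$n_studies, cfg$n_reports))
  tsvs <- sort(list.files(cfg$out_dir, pattern = "\\.tsv$", recursive = TRUE))
  sums <- tools::md5sum(file.path(cfg$out_dir, tsvs))
  manifest <- c(manifest, paste0(tsvs, ": ", unname(sums)))
  writeLines(manifest, file.path(cfg$out_dir, "MANIFEST"))

  invisible(list(config = cfg, simulation = sim, signals = signals,
                 target_events = target, signature = sig,
                 drug_sim = dsim, scored = scored, srges = srges,
                 correlations = correlations, reversal_genes = rev_genes,
                 ic50_validation = val, out_dir = cfg$out_dir))
}

#' One-command synthetic demonstration run
#'
#' @param seed Master seed.
#' @param out_dir Run directory.
#' @param quiet Suppress stage logging (default TRUE).
#' @return The [run_pipeline()] result, invisibly.
#' @export
pipeline_demo <- function(seed = 7L, out_dir = tempfile("inversig_demo"),
                          quiet = TRUE) {
  cfg <- pipeline_config(seed = seed, out_dir = out_dir)
  if (quiet) suppressMessages(run_pipeline(cfg)) else run_pipeline(cfg)
}

#' Summarise a completed run directory
#'
#' Tabulates inverse-signal counts per method, signature sizes, the top 20
#' compounds by sRGES, selected reversal genes, and the correlation
#' results.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return Character vector of report lines (also written to
#'   `report.txt` in the run directory), invisibly.
#' @export
pipeline_report <- function(run_dir) {
  f <- function(x) file.path(run_dir, x)
  lines <- c("inversig run report", "===================")
  if (file.exists(f("signals.tsv"))) {
    s <- read_tsv(f("signals.tsv"))
    lines <- c(lines, "", sprintf(
      "Inverse signals: ROR %d, IC %d, EBGM %d (of %d drug-event pairs)",
      sum(s$inverse_ror), sum(s$inverse_ic), sum(s$inverse_ebgm), nrow(s)))
  } else {
    lines <- c(lines, "", "WARNING: signals.tsv missing (incomplete run)")
  }
  if (file.exists(f("disease_signature.tsv"))) {
    g <- read_tsv(f("disease_signature.tsv"))
    lines <- c(lines, sprintf("Disease signature: %d up / %d down genes",
                              sum(g$direction == "up"),
                              sum(g$direction == "down")))
  }
  if (file.exists(f("srges.tsv"))) {
    r <- read_tsv(f("srges.tsv"))
    r <- r[order(r$srges), ]
    top <- utils::head(r, 20)
    lines <- c(lines, "", "Top 20 compounds by sRGES (most reversing first):",
               sprintf("  %-10s %8.4f", top$compound_id, top$srges))
  }
  if (file.exists(f("reversal_genes.tsv"))) {
    rg <- read_tsv(f("reversal_genes.tsv"))
    sel <- rg$gene[rg$selected]
    lines <- c(lines, "",
               if (length(sel)) paste("Reversal genes:",
                                      paste(sel, collapse = ", "))
               else "Reversal genes: none selected")
  }
  if (file.exists(f("signal_correlations.tsv"))) {
    co <- read_tsv(f("signal_correlations.tsv"))
    lines <- c(lines, "", "sRGES vs inverse-signal correlations:",
               sprintf("  %-8s rho = %6.3f  p = %.3g  n = %d",
                       co$method, co$rho, co$p, co$n))
  }
  if (file.exists(f("ic50_correlations.tsv"))) {
    ic <- read_tsv(f("ic50_correlations.tsv"))
    lines <- c(lines, "", "sRGES vs IC50 correlations:",
               sprintf("  %-12s rho = %6.3f  p = %.3g  n = %d",
                       ic$stat, ic$rho, ic$p, ic$n))
  }
  writeLines(lines, f("report.txt"))
  invisible(lines)
}
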