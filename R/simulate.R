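# Synthetic-data generators: adverse-event report tables, multi-study
# expression matrices, compound rank signatures and IC50 tables, all with
# known ground truth so every downstream stage is testable offline.

#' Configuration for the adverse-event report simulator
#'
#' Reports are multinomial over (drug, event) cells: the cell probability is
#' the product of the drug and event marginals, multiplied by the planted
#' relative reporting ratio lambda for planted pairs, then renormalised.
#' With few planted cells the renormalisation constant is ~1, so the
#' expected count of a planted pair is lambda times its expectation under
#' independence — analytically computable for tests.
#'
#' @param n_drugs,n_events,n_reports Positive integers.
#' @param baseline_event_probs Probability vector over events (sums to 1);
#'   default uniform.
#' @param planted_associations Data frame with columns `drug`, `event`,
#'   `lambda` (relative reporting ratio > 0; lambda < 1 plants an inverse
#'   association).  Drug/event given as names or 1-based indices.
#' @param duplicate_fraction Proportion of cases emitted twice with a new
#'   case-version identifier and a later event date (exercises dedup).
#' @param combo_fraction Proportion of drug rows rewritten as
#'   multi-ingredient combination names (exercises the combination filter).
#' @param concomitant_fraction Proportion of reports that carry an extra
#'   non-suspect drug row (exercises the primary-suspect filter).
#' @param drug_names,event_names Optional identifier vectors.
#' @param seed Integer seed.
#' @return An object of class `aer_sim_config`.
#' @export
aer_sim_config <- function(n_drugs, n_events, n_reports,
                           baseline_event_probs = NULL,
                           planted_associations = NULL,
                           duplicate_fraction = 0,
                           combo_fraction = 0,
                           concomitant_fraction = 0,
                           drug_names = NULL, event_names = NULL,
                           seed = 1L) {
  stopifnot(n_drugs >= 1, n_events >= 1, n_reports >= 1)
  if (is.null(baseline_event_probs))
    baseline_event_probs <- rep(1 / n_events, n_events)
  if (length(baseline_event_probs) != n_events)
    stop("baseline_event_probs must have length n_events")
  if (any(baseline_event_probs < 0) ||
      abs(sum(baseline_event_probs) - 1) > 1e-9)
    stop("baseline_event_probs must be a probability vector summing to 1")
  if (duplicate_fraction < 0 || duplicate_fraction >= 1 ||
      combo_fraction < 0 || combo_fraction >= 1 ||
      concomitant_fraction < 0 || concomitant_fraction >= 1)
    stop("fractions must lie in [0, 1)")
  if (is.null(drug_names)) drug_names <- sprintf("DRUG%04d", seq_len(n_drugs))
  if (is.null(event_names)) event_names <- sprintf("EVENT%04d", seq_len(n_events))
  if (!is.null(planted_associations)) {
    pa <- planted_associations
    stopifnot(all(c("drug", "event", "lambda") %in% names(pa)))
    if (any(pa$lambda <= 0)) stop("planted lambda must be > 0")
    if (is.numeric(pa$drug)) pa$drug <- drug_names[pa$drug]
    if (is.numeric(pa$event)) pa$event <- event_names[pa$event]
    if (anyDuplicated(pa[c("drug", "event")]))
      stop("planted_associations must list each (drug, event) pair once")
    planted_associations <- pa
  }
  structure(list(
    n_drugs = n_drugs, n_events = n_events, n_reports = n_reports,
    baseline_event_probs = baseline_event_probs,
    planted_associations = planted_associations,
    duplicate_fraction = duplicate_fraction,
    combo_fraction = combo_fraction,
    concomitant_fraction = concomitant_fraction,
    drug_names = drug_names, event_names = event_names,
    seed = as.integer(seed)
  ), class = "aer_sim_config")
}

#' Simulate spontaneous adverse-event report tables
#'
#' Emits DEMO/DRUG/REAC tables in the FAERS quarterly ASCII dialect
#' (columns PRIMARYID, CASEID, EVENT_DT, ROLE_COD, DRUGNAME, PT) plus a
#' truth table of the planted (drug, event, lambda) associations.
#' Deterministic under a fixed seed.
#'
#' @param cfg An [aer_sim_config()].
#' @return A list of class `aer_sim` with elements `demo`, `drug`, `reac`
#'   (data frames), `truth` (planted associations), and `expected`
#'   (analytic expected cell counts used by tests).
#' @export
simulate_reports <- function(cfg) {
  stopifnot(inherits(cfg, "aer_sim_config"))
  set.seed(stage_seed(cfg$seed, "reports"))
  nd <- cfg$n_drugs; ne <- cfg$n_events
  p_drug <- rep(1 / nd, nd)
  P <- outer(p_drug, cfg$baseline_event_probs)
  dimnames(P) <- list(cfg$drug_names, cfg$event_names)
  if (!is.null(cfg$planted_associations)) {
    pa <- cfg$planted_associations
    P[cbind(match(pa$drug, cfg$drug_names),
            match(pa$event, cfg$event_names))] <-
      P[cbind(match(pa$drug, cfg$drug_names),
              match(pa$event, cfg$event_names))] * pa$lambda
  }
  Pn <- P / sum(P)
  counts <- stats::rmultinom(1, cfg$n_reports, as.vector(Pn))[, 1]
  idx <- rep(seq_along(counts), counts)
  drug_i <- ((idx - 1) %% nd) + 1
  event_i <- ((idx - 1) %/% nd) + 1
  n <- length(idx)
  ord <- sample.int(n)                     # shuffle report order
  drug_i <- drug_i[ord]; event_i <- event_i[ord]

  case_id <- 10000000L + seq_len(n)
  primary_id <- case_id * 10L + 1L
  dates <- sample(seq(as.Date("2015-01-01"), as.Date("2020-12-31"), by = "day"),
                  n, replace = TRUE)
  event_dt <- as.integer(format(dates, "%Y%m%d"))

  drug_name <- cfg$drug_names[drug_i]
  is_combo <- stats::runif(n) < cfg$combo_fraction
  if (any(is_combo)) {
    partner <- cfg$drug_names[(drug_i[is_combo] %% nd) + 1]
    drug_name[is_combo] <- paste(drug_name[is_combo], partner, sep = "\\")
  }

  demo <- data.frame(PRIMARYID = primary_id, CASEID = case_id,
                     EVENT_DT = event_dt, stringsAsFactors = FALSE)
  drug <- data.frame(PRIMARYID = primary_id, CASEID = case_id,
                     ROLE_COD = "PS", DRUGNAME = drug_name,
                     stringsAsFactors = FALSE)
  reac <- data.frame(PRIMARYID = primary_id, CASEID = case_id,
                     PT = cfg$event_names[event_i], stringsAsFactors = FALSE)

  # concomitant (non-suspect) extra drug rows
  is_con <- stats::runif(n) < cfg$concomitant_fraction
  if (any(is_con)) {
    con <- data.frame(
      PRIMARYID = primary_id[is_con], CASEID = case_id[is_con],
      ROLE_COD = "C",
      DRUGNAME = cfg$drug_names[sample.int(nd, sum(is_con), replace = TRUE)],
      stringsAsFactors = FALSE)
    drug <- rbind(drug, con)
  }

  # duplicate case versions: same case id, new primary id, later date
  is_dup <- stats::runif(n) < cfg$duplicate_fraction
  if (any(is_dup)) {
    k <- which(is_dup)
    dup_dates <- as.integer(format(dates[k] + sample(1:200, length(k),
                                                     replace = TRUE), "%Y%m%d"))
    dup_pid <- case_id[k] * 10L + 2L
    demo <- rbind(demo, data.frame(PRIMARYID = dup_pid, CASEID = case_id[k],
                                   EVENT_DT = dup_dates))
    drug <- rbind(drug, data.frame(PRIMARYID = dup_pid, CASEID = case_id[k],
                                   ROLE_COD = "PS", DRUGNAME = drug_name[k]))
    reac <- rbind(reac, data.frame(PRIMARYID = dup_pid, CASEID = case_id[k],
                                   PT = cfg$event_names[event_i[k]]))
  }

  truth <- cfg$planted_associations
  if (is.null(truth))
    truth <- data.frame(drug = character(), event = character(),
                        lambda = numeric())
  expected <- data.frame(
    drug = rep(cfg$drug_names, ne),
    event = rep(cfg$event_names, each = nd),
    e_independence = cfg$n_reports * as.vector(outer(p_drug,
                                                     cfg$baseline_event_probs)),
    e_planted = cfg$n_reports * as.vector(Pn),
    stringsAsFactors = FALSE)

  structure(list(demo = demo, drug = drug, reac = reac,
                 truth = truth, expected = expected, config = cfg),
            class = "aer_sim")
}

#' Write simulated report tables as FAERS-dialect `$`-delimited files
#'
#' @param sim An `aer_sim` object.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths.
#' @export
write_faers <- function(sim, dir) {
  stopifnot(inherits(sim, "aer_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"))
  for (nm in names(paths))
    utils::write.table(sim[[nm]], paths[[nm]], sep = "$", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  paths
}

#' Configuration for the multi-study expression simulator
#'
#' @param n_studies Number of studies.
#' @param genes Character vector of gene identifiers.
#' @param n_case,n_control Per-study arm sizes (>= 2).
#' @param planted_up,planted_down Disjoint gene subsets carrying the planted
#'   effect (up: cases higher; down: cases lower).
#' @param effect_size_mean Planted case-control difference in log2
#'   expression units (residual SD is 1, so this is also the standardized
#'   mean difference).
#' @param study_noise_sd SD of per-study baseline shifts (log2 units).
#' @param seed Integer seed.
#' @return An object of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_studies, genes, n_case, n_control,
                            planted_up = character(),
                            planted_down = character(),
                            effect_size_mean = 2,
                            study_noise_sd = 0.5,
                            seed = 1L) {
  stopifnot(n_studies >= 1, length(genes) >= 1, n_case >= 2, n_control >= 2)
  if (length(intersect(planted_up, planted_down)) > 0)
    stop("planted_up and planted_down must be disjoint")
  if (!all(c(planted_up, planted_down) %in% genes))
    stop("planted gene sets must be subsets of the gene universe")
  structure(list(n_studies = n_studies, genes = genes,
                 n_case = n_case, n_control = n_control,
                 planted_up = planted_up, planted_down = planted_down,
                 effect_size_mean = effect_size_mean,
                 study_noise_sd = study_noise_sd,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate per-study expression matrices with planted DEGs
#'
#' Each study is a genes x samples matrix of log2 expression: gene baseline
#' ~ N(7, 1), a per-study shift ~ N(0, study_noise_sd), residual N(0, 1),
#' and the planted effect (+/- effect_size_mean) added to case samples of
#' the planted up/down genes.  Deterministic under a fixed seed.
#'
#' @param cfg An [expr_sim_config()].
#' @return A list of class `expr_sim`: `studies` (named list, each with
#'   `matrix` and `labels`), `truth` (data frame gene/direction).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  set.seed(stage_seed(cfg$seed, "expression"))
  G <- length(cfg$genes)
  base <- stats::rnorm(G, mean = 7, sd = 1)
  delta <- numeric(G)
  names(delta) <- cfg$genes
  delta[cfg$planted_up] <- cfg$effect_size_mean
  delta[cfg$planted_down] <- -cfg$effect_size_mean
  studies <- vector("list", cfg$n_studies)
  names(studies) <- sprintf("SYN%05d", seq_len(cfg$n_studies) * 101L)
  for (s in seq_len(cfg$n_studies)) {
    nc <- cfg$n_case; nn <- cfg$n_control
    shift <- stats::rnorm(1, 0, cfg$study_noise_sd)
    m <- matrix(stats::rnorm(G * (nc + nn)), nrow = G) + base + shift
    m[, seq_len(nc)] <- m[, seq_len(nc)] + delta
    rownames(m) <- cfg$genes
    colnames(m) <- sprintf("GSM%04d%03d", s, seq_len(nc + nn))
    labels <- c(rep("case", nc), rep("control", nn))
    studies[[s]] <- list(matrix = m, labels = labels)
  }
  truth <- data.frame(
    gene = c(cfg$planted_up, cfg$planted_down),
    direction = c(rep("up", length(cfg$planted_up)),
                  rep("down", length(cfg$planted_down))),
    effect = c(rep(cfg$effect_size_mean, length(cfg$planted_up)),
               rep(-cfg$effect_size_mean, length(cfg$planted_down))),
    stringsAsFactors = FALSE)
  structure(list(studies = studies, truth = truth, config = cfg),
            class = "expr_sim")
}

# 27-character InChIKey-shaped identifier (14-10-1 uppercase blocks).
synthetic_inchikey <- function(n) {
  blk <- function(k) replicate(n, paste(sample(LETTERS, k, TRUE), collapse = ""))
  paste(blk(14), blk(10), sep = "-") |> paste("N", sep = "-")
}

#' Configuration for the compound signature / IC50 simulator
#'
#' @param n_compounds Number of compounds.
#' @param universe Gene universe for the rank signatures.
#' @param activities Optional latent activities in `[0, 1]`; default
#'   uniform draws.
#' @param conditions Data frame of (cell_line, dose_um, time_h) conditions
#'   profiled per compound; must include the 10 uM / 24 h reference.
#' @param condition_attenuation Multiplier applied to the latent activity
#'   for non-reference conditions (models weaker effects at lower dose or
#'   shorter exposure).
#' @param ic50_intercept,ic50_slope log10(nM) intercept and (positive)
#'   slope of the activity -> potency link.
#' @param ic50_noise_sd Lognormal noise SD in log10(nM) units.
#' @param ic50_replicates Max number of assay rows per compound.
#' @param seed Integer seed.
#' @return An object of class `drug_sim_config`.
#' @export
drug_sim_config <- function(n_compounds, universe,
                            activities = NULL,
                            conditions = NULL,
                            condition_attenuation = 0.6,
                            ic50_intercept = 3, ic50_slope = 2,
                            ic50_noise_sd = 0.3,
                            ic50_replicates = 3,
                            seed = 1L) {
  stopifnot(n_compounds >= 1, length(universe) >= 2)
  if (!is.null(activities)) {
    stopifnot(length(activities) == n_compounds,
              all(activities >= 0), all(activities <= 1))
  }
  if (is.null(conditions))
    conditions <- data.frame(
      cell_line = c("A375", "A375", "MCF7"),
      dose_um = c(10, 1, 10),
      time_h = c(24, 6, 24))
  stopifnot(all(c("cell_line", "dose_um", "time_h") %in% names(conditions)),
            nrow(conditions) >= 1,
            all(conditions$dose_um > 0), all(conditions$time_h > 0))
  stopifnot(ic50_slope > 0, ic50_noise_sd >= 0)
  structure(list(n_compounds = n_compounds, universe = universe,
                 activities = activities, conditions = conditions,
                 condition_attenuation = condition_attenuation,
                 ic50_intercept = ic50_intercept, ic50_slope = ic50_slope,
                 ic50_noise_sd = ic50_noise_sd,
                 ic50_replicates = as.integer(ic50_replicates),
                 seed = as.integer(seed)),
            class = "drug_sim_config")
}

# Geometric success probability for activity t on a universe of size N:
# the mean displacement from the list end is (1 - t) * N / 2, linear in
# the activity, so t = 0 gives uniform ranks (p = 0 is handled as the
# uniform limit) and t = 1 the exact extreme ranks.
geom_prob <- function(t, N) {
  if (t <= 0) return(0)
  1 / (1 + (1 - t) * N / 2)
}

# Place genes of one set near one end of 1..N by truncated-geometric
# draws without replacement; remaining genes fill the rest uniformly.
# available: logical over positions still free.
place_geometric <- function(set_n, available, p, from_top) {
  picked <- integer(set_n)
  free <- which(available)
  for (i in seq_len(set_n)) {
    d <- rtruncgeom(1, p, length(free))
    pos <- if (from_top) free[d + 1] else free[length(free) - d]
    picked[i] <- pos
    free <- free[free != pos]
  }
  picked
}

#' Simulate compound rank signatures with planted reversal
#'
#' For a compound with latent activity t, each disease up-gene's rank is
#' drawn toward the bottom of the list and each down-gene toward the top
#' via truncated-geometric displacements whose mean scale is linear in the
#' (condition-attenuated) activity: (1 - t) N / 2 positions from the list
#' end, so t = 0 gives uniform random ranks and t = 1 the exact extreme
#' ranks.  Rank 1 = most up-regulated by the
#' compound.  Deterministic under a fixed seed.
#'
#' @param cfg A [drug_sim_config()].
#' @param signature A [disease_signature] (or list with `up_genes`,
#'   `down_genes`) whose genes lie in the configured universe.
#' @return A list of class `drug_sim`: `profiles` (long data frame:
#'   compound_id, inchikey, cell_line, dose_um, time_h, gene, rank),
#'   `truth` (compound_id, inchikey, activity).
#' @export
simulate_drug_signatures <- function(cfg, signature) {
  stopifnot(inherits(cfg, "drug_sim_config"))
  up <- signature$up_genes; down <- signature$down_genes
  if (length(up) + length(down) == 0) stop("signature is empty")
  if (!all(c(up, down) %in% cfg$universe))
    stop("signature genes must lie in the configured universe")
  if (nrow(cfg$conditions) < 1) stop("at least one condition is required")
  set.seed(stage_seed(cfg$seed, "drugsig"))
  N <- length(cfg$universe)
  act <- cfg$activities
  if (is.null(act)) act <- stats::runif(cfg$n_compounds)
  keys <- synthetic_inchikey(cfg$n_compounds)
  ids <- sprintf("CPD%04d", seq_len(cfg$n_compounds))
  cond <- cfg$conditions
  is_ref <- cond$dose_um == 10 & cond$time_h == 24
  out <- vector("list", cfg$n_compounds * nrow(cond))
  k <- 0L
  up_i <- match(up, cfg$universe); down_i <- match(down, cfg$universe)
  other_i <- setdiff(seq_len(N), c(up_i, down_i))
  for (i in seq_len(cfg$n_compounds)) {
    for (j in seq_len(nrow(cond))) {
      t_eff <- act[i] * if (is_ref[j]) 1 else cfg$condition_attenuation
      p_eff <- geom_prob(t_eff, N)
      avail <- rep(TRUE, N)
      pos_down <- place_geometric(length(down_i), avail, p_eff, TRUE)
      avail[pos_down] <- FALSE
      pos_up <- place_geometric(length(up_i), avail, p_eff, FALSE)
      avail[pos_up] <- FALSE
      ranks <- integer(N)
      ranks[down_i] <- pos_down
      ranks[up_i] <- pos_up
      ranks[other_i] <- sample(which(avail))
      k <- k + 1L
      out[[k]] <- data.frame(
        compound_id = ids[i], inchikey = keys[i],
        cell_line = cond$cell_line[j], dose_um = cond$dose_um[j],
        time_h = cond$time_h[j], gene = cfg$universe, rank = ranks,
        stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, out)
  truth <- data.frame(compound_id = ids, inchikey = keys, activity = act,
                      stringsAsFactors = FALSE)
  structure(list(profiles = profiles, truth = truth, config = cfg),
            class = "drug_sim")
}

#' Simulate an IC50 activity table keyed by InChIKey-like identifiers
#'
#' log10 IC50(nM) = intercept - slope * activity + Normal(0, noise_sd),
#' with a positive slope so more active compounds are more potent.  Some
#' compounds receive multiple assay rows to exercise median/min/max
#' summarisation.
#'
#' @param truth Data frame with `compound_id`, `inchikey`, `activity`
#'   (as emitted by [simulate_drug_signatures()]).
#' @param cfg The same [drug_sim_config()].
#' @return Data frame: inchikey, ic50_nm, assay_id.
#' @export
simulate_ic50 <- function(truth, cfg) {
  stopifnot(inherits(cfg, "drug_sim_config"),
            all(truth$activity >= 0), all(truth$activity <= 1))
  set.seed(stage_seed(cfg$seed, "ic50"))
  n_rows <- sample.int(cfg$ic50_replicates, nrow(truth), replace = TRUE)
  key <- rep(truth$inchikey, n_rows)
  act <- rep(truth$activity, n_rows)
  l10 <- cfg$ic50_intercept - cfg$ic50_slope * act +
    stats::rnorm(length(act), 0, cfg$ic50_noise_sd)
  data.frame(inchikey = key,
             ic50_nm = 10^l10,
             assay_id = sprintf("ASSAY%06d", seq_along(key)),
             stringsAsFactors = FALSE)
}
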