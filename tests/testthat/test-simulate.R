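# Synthetic-data generators: determinism, planted ground truth, and the
# analytic expectations the designs promise.

test_that("report simulation is deterministic and round-trips its truth", {
  cfg <- aer_sim_config(5, 4, 2000, duplicate_fraction = 0.2,
                        planted_associations = data.frame(
                          drug = 1, event = 1, lambda = 0.5),
                        seed = 11)
  s1 <- simulate_reports(cfg)
  s2 <- simulate_reports(cfg)
  expect_identical(s1$demo, s2$demo)
  expect_identical(s1$drug, s2$drug)
  expect_identical(s1$reac, s2$reac)
  expect_equal(nrow(s1$truth), 1)
  expect_equal(s1$truth$lambda, 0.5)
  # every planted association appears exactly once in the truth table
  expect_false(anyDuplicated(s1$truth[c("drug", "event")]) > 0)
})

test_that("planted lambda scales the expected pair count", {
  cfg <- aer_sim_config(10, 10, 200000,
                        planted_associations = data.frame(
                          drug = 1, event = 1, lambda = 0.1),
                        seed = 3)
  sim <- simulate_reports(cfg)
  pairs <- merge(sim$drug[c("PRIMARYID", "DRUGNAME")],
                 sim$reac[c("PRIMARYID", "PT")], by = "PRIMARYID")
  a <- sum(pairs$DRUGNAME == cfg$drug_names[1] & pairs$PT == cfg$event_names[1])
  e_indep <- 200000 / 100            # uniform marginals
  expect_gt(a / e_indep, 0.07)
  expect_lt(a / e_indep, 0.13)
})

test_that("duplicate_fraction = 0 means deduplication removes nothing", {
  cfg <- aer_sim_config(4, 4, 500, duplicate_fraction = 0, seed = 5)
  sim <- simulate_reports(cfg)
  rep0 <- read_reports(sim$demo, sim$drug, sim$reac)
  expect_equal(nrow(deduplicate_reports(rep0)$demo), nrow(rep0$demo))
})

test_that("report config rejects invalid probability vectors and lambdas", {
  expect_error(aer_sim_config(2, 2, 10, baseline_event_probs = c(0.7, 0.7)),
               "probability")
  expect_error(aer_sim_config(2, 2, 10, planted_associations = data.frame(
    drug = 1, event = 1, lambda = 0)), "lambda")
  expect_error(aer_sim_config(2, 2, 10, duplicate_fraction = 1), "fractions")
})

test_that("expression simulation plants the stated effects", {
  genes <- sprintf("G%03d", 1:60)
  cfg <- expr_sim_config(4, genes, 15, 15,
                         planted_up = genes[1:5], planted_down = genes[6:9],
                         effect_size_mean = 2, seed = 9)
  sim <- simulate_expression(cfg)
  expect_length(sim$studies, 4)
  diffs <- sapply(sim$studies, function(s) {
    rowMeans(s$matrix[, s$labels == "case"]) -
      rowMeans(s$matrix[, s$labels == "control"])
  })
  expect_true(all(rowMeans(diffs)[1:5] > 1))      # planted up
  expect_true(all(rowMeans(diffs)[6:9] < -1))     # planted down
  expect_lt(max(abs(rowMeans(diffs)[10:60])), 1)  # null genes near zero
  expect_setequal(sim$truth$gene, genes[1:9])
  # determinism
  expect_identical(sim$studies[[1]]$matrix,
                   simulate_expression(cfg)$studies[[1]]$matrix)
})

test_that("overlapping planted gene sets are rejected", {
  expect_error(expr_sim_config(2, letters, 3, 3, planted_up = c("a", "b"),
                               planted_down = c("b", "c")), "disjoint")
})

test_that("drug signatures honour the activity extremes", {
  genes <- sprintf("G%03d", 1:50)
  sig <- make_signature(genes[1:4], genes[5:7])
  # maximal activity, noiseless link: exact extreme ranks
  cfg1 <- drug_sim_config(3, genes, activities = rep(1, 3),
                          conditions = data.frame(cell_line = "A375",
                                                  dose_um = 10, time_h = 24),
                          seed = 2)
  sim1 <- simulate_drug_signatures(cfg1, sig)
  p1 <- sim1$profiles[sim1$profiles$compound_id == "CPD0001", ]
  rk <- setNames(p1$rank, p1$gene)
  expect_setequal(rk[genes[1:4]], 47:50)   # up-genes at the exact bottom
  expect_setequal(rk[genes[5:7]], 1:3)     # down-genes at the exact top
  # zero activity: RGES centred near 0
  cfg0 <- drug_sim_config(40, genes, activities = rep(0, 40),
                          conditions = data.frame(cell_line = "A375",
                                                  dose_um = 10, time_h = 24),
                          seed = 4)
  sim0 <- simulate_drug_signatures(cfg0, sig)
  sc0 <- score_profiles(sim0$profiles, sig)
  expect_lt(abs(mean(sc0$rges)), 0.25)
  # each profile is a permutation of 1..N
  expect_setequal(p1$rank, seq_along(genes))
})

test_that("drug signature simulation rejects bad inputs", {
  genes <- letters[1:10]
  cfg <- drug_sim_config(2, genes, seed = 1)
  expect_error(simulate_drug_signatures(cfg, make_signature(character(),
                                                            character())),
               "empty")
  expect_error(simulate_drug_signatures(cfg, make_signature("zzz", "a")),
               "universe")
})

test_that("IC50 simulation is monotone in activity and keyed correctly", {
  genes <- letters[1:6]
  cfg <- drug_sim_config(30, genes, ic50_noise_sd = 0, ic50_replicates = 1,
                         seed = 8)
  truth <- data.frame(compound_id = sprintf("C%02d", 1:30),
                      inchikey = replicate(30, paste(sample(LETTERS, 27,
                                                            TRUE),
                                                     collapse = "")),
                      activity = seq(0, 1, length.out = 30))
  tab <- simulate_ic50(truth, cfg)
  expect_equal(stats::cor(truth$activity, tab$ic50_nm, method = "spearman"),
               -1)
  expect_true(all(nchar(tab$inchikey) == 27))
})

test_that("multiple IC50 rows summarise by median, min and max", {
  tab <- data.frame(inchikey = rep(strrep("A", 27), 3), ic50_nm = c(1, 2, 9))
  s <- summarize_ic50(tab)
  expect_equal(s$ic50_median, 2)
  expect_equal(s$ic50_min, 1)
  expect_equal(s$ic50_max, 9)
  expect_equal(s$n_assays, 3L)
})
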