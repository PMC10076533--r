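# Report parsing, deduplication, filtering, contingency tables and event
# mapping.

test_that("a three-row fixture parses into three case reports", {
  rep0 <- make_report_fixture()
  expect_equal(nrow(rep0$demo), 3)
  expect_equal(attr(rep0, "n_skipped"), 0L)
})

test_that("rows with empty drug names are skipped and counted", {
  rep0 <- make_report_fixture()
  drug <- rep0$drug
  drug$DRUGNAME[2] <- ""
  rep1 <- read_reports(rep0$demo, drug, rep0$reac)
  expect_equal(attr(rep1, "n_skipped"), 1L)
  expect_equal(nrow(rep1$drug), 2)
})

test_that("a missing mandatory column is a hard error naming it", {
  rep0 <- make_report_fixture()
  expect_error(read_reports(rep0$demo, rep0$drug[-4], rep0$reac), "DRUGNAME")
})

test_that("round-trip through $-delimited files preserves the tables", {
  cfg <- aer_sim_config(4, 3, 300, duplicate_fraction = 0.1,
                        combo_fraction = 0.1, seed = 21)
  sim <- simulate_reports(cfg)
  dir <- withr::local_tempdir()
  paths <- write_faers(sim, dir)
  rep0 <- read_reports(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(nrow(rep0$demo), nrow(sim$demo))
  expect_setequal(rep0$drug$DRUGNAME, sim$drug$DRUGNAME)
})

test_that("deduplication keeps the most recent case version", {
  demo <- data.frame(PRIMARYID = c(421L, 422L), CASEID = c(42L, 42L),
                     EVENT_DT = c(20190101L, 20200101L))
  drug <- data.frame(PRIMARYID = c(421L, 422L), CASEID = 42L,
                     ROLE_COD = "PS", DRUGNAME = "X")
  reac <- data.frame(PRIMARYID = c(421L, 422L), CASEID = 42L, PT = "Rash")
  out <- deduplicate_reports(read_reports(demo, drug, reac))
  expect_equal(out$demo$PRIMARYID, 422L)
})

test_that("date ties break by the larger version identifier", {
  demo <- data.frame(PRIMARYID = c(100L, 101L), CASEID = c(1L, 1L),
                     EVENT_DT = 20190101L)
  drug <- data.frame(PRIMARYID = c(100L, 101L), CASEID = 1L,
                     ROLE_COD = "PS", DRUGNAME = "X")
  reac <- data.frame(PRIMARYID = c(100L, 101L), CASEID = 1L, PT = "Rash")
  out <- deduplicate_reports(read_reports(demo, drug, reac))
  expect_equal(out$demo$PRIMARYID, 101L)
})

test_that("deduplication is idempotent and matches the distinct-case count", {
  cfg <- aer_sim_config(6, 5, 5000, duplicate_fraction = 0.2, seed = 33)
  sim <- simulate_reports(cfg)
  rep0 <- read_reports(sim$demo, sim$drug, sim$reac)
  d1 <- deduplicate_reports(rep0)
  d2 <- deduplicate_reports(d1)
  expect_identical(d1$demo, d2$demo)
  expect_equal(nrow(d1$demo), length(unique(sim$demo$CASEID)))
})

test_that("reports whose only event is an excluded term are dropped", {
  demo <- data.frame(PRIMARYID = 1:2, CASEID = 1:2, EVENT_DT = 20190101L)
  drug <- data.frame(PRIMARYID = 1:2, CASEID = 1:2, ROLE_COD = "PS",
                     DRUGNAME = c("ASPIRIN", "IBUPROFEN"))
  reac <- data.frame(PRIMARYID = 1:2, CASEID = 1:2,
                     PT = c("Drug ineffective", "Psoriasis"))
  out <- filter_reports(read_reports(demo, drug, reac))
  expect_equal(out$demo$PRIMARYID, 2L)
  expect_equal(attr(out, "removed")[["excluded_pt"]], 1L)
})

test_that("combination drug names are recognised and dropped", {
  expect_true(inversig:::is_combination_drug("AMOXICILLIN\\CLAVULANATE"))
  expect_true(inversig:::is_combination_drug("DRUG A + DRUG B"))
  expect_true(inversig:::is_combination_drug("ASPIRIN AND CAFFEINE"))
  expect_false(inversig:::is_combination_drug("ASPIRIN"))
  demo <- data.frame(PRIMARYID = 1L, CASEID = 1L, EVENT_DT = 20190101L)
  drug <- data.frame(PRIMARYID = 1L, CASEID = 1L, ROLE_COD = "PS",
                     DRUGNAME = "AMOXICILLIN\\CLAVULANATE")
  reac <- data.frame(PRIMARYID = 1L, CASEID = 1L, PT = "Rash")
  out <- filter_reports(read_reports(demo, drug, reac))
  expect_equal(nrow(out$demo), 0)
})

test_that("combo removals fall within binomial bounds of the planted rate", {
  cfg <- aer_sim_config(8, 6, 10000, combo_fraction = 0.1, seed = 12)
  sim <- simulate_reports(cfg)
  out <- filter_reports(read_reports(sim$demo, sim$drug, sim$reac))
  n_combo <- attr(out, "removed")[["combination"]]
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(n_combo, bounds[1])
  expect_lte(n_combo, bounds[2])
})

test_that("the retained set is order-independent across the three filters", {
  cfg <- aer_sim_config(6, 5, 3000, combo_fraction = 0.1,
                        concomitant_fraction = 0.2,
                        event_names = c("Drug ineffective", "Medication error",
                                        "Rash", "Psoriasis", "Nausea"),
                        seed = 44)
  sim <- simulate_reports(cfg)
  rep0 <- deduplicate_reports(read_reports(sim$demo, sim$drug, sim$reac))
  got <- filter_reports(rep0)
  # brute-force, order-free recomputation of the surviving report ids
  dn <- normalize_drug_name(rep0$drug$DRUGNAME)
  ok_drug <- rep0$drug$PRIMARYID[rep0$drug$ROLE_COD == "PS" &
                                   !inversig:::is_combination_drug(dn)]
  ok_reac <- rep0$reac$PRIMARYID[!tolower(rep0$reac$PT) %in%
                                   c("drug ineffective", "medication error")]
  expect_setequal(got$demo$PRIMARYID, intersect(ok_drug, ok_reac))
})

test_that("contingency cells follow the 2x2 construction", {
  pairs <- data.frame(
    drug = rep(c("D1", "D2"), times = c(100, 1000)),
    event = c(rep(c("E1", "E2"), times = c(10, 90)),
              rep(c("E1", "E2"), times = c(100, 900))))
  cells <- build_contingency(pairs)
  c11 <- cells[cells$drug == "D1" & cells$event == "E1", ]
  expect_equal(c(c11$a, c11$b, c11$c, c11$d), c(10, 90, 100, 900))
  expect_true(all(cells$a + cells$b + cells$c + cells$d == nrow(pairs)))
  expect_true(all(cells$d >= 0))
  # conservation: the a's sum to the total pair count
  expect_equal(sum(cells$a), nrow(pairs))
  # E matches the closed form to 1e-9
  expect_equal(cells$expected, (cells$a + cells$b) * (cells$a + cells$c) /
                 cells$n, tolerance = 1e-9)
})

test_that("degenerate contingency inputs are handled", {
  one <- build_contingency(data.frame(drug = "D", event = "E"))
  expect_equal(c(one$a, one$b, one$c, one$d), c(1, 0, 0, 0))
  expect_true(is.na(compute_ror(one$a, one$b, one$c, one$d)$ror))
  expect_error(build_contingency(data.frame(drug = character(),
                                            event = character())), "pairs")
})

test_that("ICD-10 mapping flags chapters and reports coverage", {
  mapping <- data.frame(pt = c("Psoriasis", "Headache"),
                        icd10 = c("L40", "R51"))
  events <- c("Psoriasis", "Headache", paste0("Unmapped", 1:48))
  m <- map_events_to_icd10(events, mapping)
  expect_true(m$mapped[m$event == "Psoriasis"])
  expect_false(m$excluded[m$event == "Psoriasis"])    # chapter L retained
  expect_true(m$excluded[m$event == "Headache"])      # chapter R excluded
  expect_equal(attr(m, "coverage"), 2 / 50)
  dup <- rbind(mapping, data.frame(pt = "Psoriasis", icd10 = "L41"))
  expect_error(map_events_to_icd10(events, dup), "conflicting")
})

test_that("target events rank by inversely-flagged drug counts", {
  signals <- data.frame(
    drug = c(paste0("D", 1:5), paste0("D", 1:2), "D9"),
    event = c(rep("X", 5), rep("Y", 2), "Z"),
    inverse_ror = TRUE)
  mapped <- data.frame(event = c("X", "Y", "Z"), icd10 = c("L40", "L41", "L42"),
                       chapter = "L", mapped = TRUE, excluded = FALSE)
  out <- select_target_event(signals, mapped)
  expect_equal(out$event[1], "X")
  expect_equal(out$n_inverse_drugs, c(5L, 2L, 1L))
  # ties break alphabetically
  signals2 <- data.frame(drug = paste0("D", c(1:3, 1:3)),
                         event = rep(c("B", "A"), each = 3),
                         inverse_ror = TRUE)
  mapped2 <- data.frame(event = c("A", "B"), icd10 = c("L40", "L41"),
                        chapter = "L", mapped = TRUE, excluded = FALSE)
  expect_equal(select_target_event(signals2, mapped2)$event, c("A", "B"))
  # PT grouping pools synonym counts
  out3 <- select_target_event(
    rbind(signals, data.frame(drug = "D6", event = "X2", inverse_ror = TRUE)),
    rbind(mapped, data.frame(event = "X2", icd10 = "L40", chapter = "L",
                             mapped = TRUE, excluded = FALSE)),
    groups = list(X = c("X", "X2")))
  expect_equal(out3$n_inverse_drugs[out3$event == "X"], 6L)
})
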