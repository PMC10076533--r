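# Probe collapse, the moderated t-test, fixed-effect combination and DEG
# thresholds.

test_that("probe collapse keeps the max-IQR probe with lexical tie-break", {
  m <- rbind(p1 = c(1, 2, 3, 4), p2 = c(0, 5, 10, 15),
             p3 = c(2, 2, 2, 2))
  map <- data.frame(probe = c("p1", "p2", "p3"), gene = c("g", "g", "h"))
  out <- collapse_probes(m, map)
  expect_equal(unname(out["g", ]), c(0, 5, 10, 15))   # IQR 7.5 beats 1.5
  # equal IQRs: smaller probe id wins
  m2 <- rbind(pB = 1:4, pA = 2:5)
  out2 <- collapse_probes(m2, data.frame(probe = c("pB", "pA"), gene = "g"))
  expect_equal(unname(out2["g", ]), 2:5)
  expect_error(collapse_probes(m, NULL), "empty")
})

test_that("probe collapse equals a brute-force per-gene argmax", {
  set.seed(42)
  m <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("probe%02d", 1:50), NULL))
  map <- data.frame(probe = rownames(m),
                    gene = sample(sprintf("gene%02d", 1:15), 50, TRUE))
  out <- collapse_probes(m, map)
  for (g in rownames(out)) {
    probes <- map$probe[map$gene == g]
    iqrs <- apply(m[probes, , drop = FALSE], 1, IQR)
    best <- sort(probes[iqrs == max(iqrs)])[1]
    expect_equal(unname(out[g, ]), unname(m[best, ]))
  }
})

test_that("moderated t collapses to zero when group means agree", {
  set.seed(1)
  m <- matrix(rnorm(40), 4, 10)
  m[1, ] <- rep(c(1, 2, 3, 4, 5), 2)   # identical case/control patterns
  rownames(m) <- paste0("g", 1:4)
  labels <- rep(c("case", "control"), each = 5)
  m[1, labels == "case"] <- m[1, labels == "control"]
  res <- moderated_t(m, labels)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("the d0 = 0 override equals the ordinary pooled t-test", {
  set.seed(2)
  m <- matrix(rnorm(100 * 12, sd = rep(runif(100, 0.5, 2), 12)), 100, 12)
  rownames(m) <- sprintf("g%03d", 1:100)
  labels <- rep(c("case", "control"), each = 6)
  res <- moderated_t(m, labels, d0 = 0)
  for (i in c(1, 17, 50, 100)) {
    tt <- t.test(m[i, labels == "case"], m[i, labels == "control"],
                 var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("null p-values are uniform under moderation", {
  set.seed(3)
  m <- matrix(rnorm(1000 * 20), 1000, 20)
  rownames(m) <- sprintf("g%04d", 1:1000)
  res <- moderated_t(m, rep(c("case", "control"), each = 10))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("moderated t agrees with an independent moderated-t implementation", {
  skip_if_not_installed("limma")
  set.seed(4)
  m <- matrix(rnorm(300 * 16, sd = rep(runif(300, 0.5, 2), 16)), 300, 16)
  m[1:20, 1:8] <- m[1:20, 1:8] + 2
  rownames(m) <- sprintf("g%03d", 1:300)
  labels <- rep(c("case", "control"), each = 8)
  ours <- moderated_t(m, labels)
  design <- cbind(1, labels == "case")
  lim <- limma::eBayes(limma::lmFit(m, design))
  expect_gt(cor(ours$t, lim$t[, 2]), 0.99)
  expect_gt(cor(rank(ours$p), rank(lim$p.value[, 2])), 0.99)
})

test_that("fixed-effect combination matches the closed-form oracle", {
  mk <- function(effect, se, p = 0.5) {
    data.frame(gene = "g1", effect = effect, se = se,
               log2fc = effect * 1.1, t = 0, df = 10, p = p)
  }
  # single study: identity
  one <- combine_fixed_effect(list(mk(0.8, 0.2)))
  expect_equal(one$effect, 0.8)
  expect_equal(one$se, 0.2)
  # equal standard errors: arithmetic mean
  two <- combine_fixed_effect(list(mk(1, 0.3), mk(3, 0.3)))
  expect_equal(two$effect, 2)
  # three studies: hand-coded sum(w theta)/sum(w)
  eff <- c(0.5, 1.2, -0.3); se <- c(0.1, 0.4, 0.25)
  three <- combine_fixed_effect(list(mk(eff[1], se[1]), mk(eff[2], se[2]),
                                     mk(eff[3], se[3])))
  w <- 1 / se^2
  expect_equal(three$effect, sum(w * eff) / sum(w), tolerance = 1e-12)
  expect_equal(three$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(three$log2fc, sum(w * eff * 1.1) / sum(w), tolerance = 1e-12)
  # convexity: meta-effect inside the per-study range
  expect_gte(three$effect, min(eff))
  expect_lte(three$effect, max(eff))
})

test_that("single-study meta-analysis is the identity on p too", {
  set.seed(5)
  m <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(sprintf("g%02d", 1:50),
                                                    NULL))
  res <- moderated_t(m, rep(c("case", "control"), each = 4))
  meta <- combine_fixed_effect(list(res))
  ord <- match(meta$gene, res$gene)
  expect_equal(meta$effect, res$effect[ord])
  z <- res$effect[ord] / res$se[ord]
  expect_equal(meta$p, 2 * pnorm(-abs(z)))
})

test_that("BH adjustment is monotone in the raw p-values", {
  set.seed(6)
  m <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  meta <- combine_fixed_effect(list(
    moderated_t(m, rep(c("case", "control"), each = 5))))
  ord <- order(meta$p)
  expect_true(all(diff(meta$p_adj[ord]) >= 0))
  expect_true(all(meta$p_adj >= meta$p))
})

test_that("DEG thresholds are asymmetric and strict", {
  meta <- data.frame(gene = c("up_ok", "down_miss", "down_ok", "ns"),
                     log2fc = c(1.6, -1.9, -2.1, 3),
                     p_adj = c(5e-4, 5e-4, 5e-4, 0.5))
  sig <- select_degs(meta)
  expect_equal(sig$up_genes, "up_ok")          # 1.6 > 1.5
  expect_equal(sig$down_genes, "down_ok")      # -1.9 misses the -2.0 cut
  expect_false("down_miss" %in% c(sig$up_genes, sig$down_genes))
  expect_false("ns" %in% sig$up_genes)         # fails adjusted p
  expect_error(select_degs(meta, up_fc = -1), "up_fc")
  expect_error(select_degs(meta, down_fc = 1), "down_fc")
})

test_that("the global null keeps the signature near-empty", {
  genes <- sprintf("G%03d", 1:400)
  cfg <- expr_sim_config(3, genes, 10, 10, effect_size_mean = 0, seed = 13)
  sim <- simulate_expression(cfg)
  sig <- meta_signature(sim$studies)
  expect_lte(length(sig$up_genes) + length(sig$down_genes),
             ceiling(0.001 * length(genes)) + 2)
})

test_that("planted signals are recovered through the full signature path", {
  genes <- sprintf("G%03d", 1:200)
  cfg <- expr_sim_config(5, genes, 15, 15, planted_up = genes[1:6],
                         planted_down = genes[7:10],
                         effect_size_mean = 3, seed = 14)
  sim <- simulate_expression(cfg)
  sig <- meta_signature(sim$studies)
  expect_setequal(sig$up_genes, genes[1:6])
  expect_setequal(sig$down_genes, genes[7:10])
})
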