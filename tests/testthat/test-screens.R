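test_that("tolerance enrichment needs both thresholds in stress but not control", {
  stress <- data.frame(guide_id = c("a", "b", "c"),
                       log2fc = c(2.5, 1.9, 3.0),
                       p_adj = c(1e-25, 1e-30, 1e-25))
  control <- data.frame(guide_id = c("a", "b", "c"),
                        log2fc = c(0.1, 0.1, 2.5),
                        p_adj = c(0.5, 0.5, 1e-30))
  res <- select_tolerance_enriched(stress, control)
  expect_equal(res$hits$selected, c(TRUE, FALSE, FALSE))
  # a: passes in stress only; b: fails lfc in stress; c: passes in both
})

test_that("tolerance enrichment equals the brute-force filter on random tables", {
  set.seed(17)
  n <- 500
  stress <- data.frame(guide_id = sprintf("g%03d", 1:n),
                       log2fc = rnorm(n, 0, 2),
                       p_adj = 10^-runif(n, 0, 40))
  control <- data.frame(guide_id = sprintf("g%03d", 1:n),
                        log2fc = rnorm(n, 0, 1),
                        p_adj = 10^-runif(n, 0, 25))
  res <- select_tolerance_enriched(stress, control)
  brute <- (stress$log2fc >= 2 & -log10(stress$p_adj) >= 20) &
    !(control$log2fc >= 2 & -log10(control$p_adj) >= 20)
  expect_equal(res$hits$selected, brute)
  # idempotent / order-invariant
  perm <- sample(n)
  res2 <- select_tolerance_enriched(stress[perm, ], control[perm, ])
  expect_equal(res2$hits$selected[order(res2$hits$guide_id)],
               res$hits$selected[order(res$hits$guide_id)])
})

test_that("gene-level tolerance flag requires both guides in stress only", {
  stress <- data.frame(guide_id = c("g1_1", "g1_2", "g2_1", "g2_2"),
                       gene_id = c("g1", "g1", "g2", "g2"),
                       log2fc = c(3, 2.5, 3, -1),
                       p_adj = c(1e-30, 1e-22, 1e-30, 0.9))
  control <- data.frame(guide_id = stress$guide_id, gene_id = stress$gene_id,
                        log2fc = c(-0.5, -0.5, -0.5, -0.5),
                        p_adj = rep(0.5, 4))
  res <- select_tolerance_enriched(stress, control)
  flags <- stats::setNames(res$genes$flagged, res$genes$gene_id)
  expect_true(flags[["g1"]])
  expect_false(flags[["g2"]])
})

test_that("stress-depleted selection ranks by dF and applies the both-guide rule", {
  # guide depleted under stress but not control: dF = F_control - F_stress
  F_stress <- c(x_1 = -4, x_2 = -3.5, y_1 = -4, y_2 = -0.1, z_1 = 0, z_2 = 0.2)
  F_control <- c(x_1 = -0.2, x_2 = -0.3, y_1 = -0.2, y_2 = 0, z_1 = 0, z_2 = 0.1)
  gene_of <- stats::setNames(sub("_.*", "", names(F_stress)), names(F_stress))
  res <- select_tolerance_depleted(F_stress, F_control, top_n = 3,
                                   gene_of = gene_of)
  # x_1 and y_1 tie at dF = 3.8; ties break by guide id
  expect_equal(res$top$guide_id, c("x_1", "y_1", "x_2"))
  expect_equal(res$top$dF[1], 3.8)
  expect_equal(res$genes, "x")   # both x guides in top; only one y guide

  # top-n equals a brute-force sort on a larger random table
  set.seed(23)
  Fs <- stats::setNames(rnorm(300, -1, 2), sprintf("q%03d", 1:300))
  Fc <- stats::setNames(rnorm(300, 0, 1), names(Fs))
  res2 <- select_tolerance_depleted(Fs, Fc, top_n = 200)
  dF <- Fc - Fs
  expect_equal(res2$top$guide_id,
               names(sort(-dF))[1:200])
  expect_equal(res2$top$dF, unname(sort(dF, decreasing = TRUE)[1:200]))
})

test_that("the droplet read floor removes guides per sample, boundary at 32", {
  m <- matrix(c(31, 40, 32, 5, 0, 100), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("r1", "r2")))
  f <- droplet_filter_counts(m)
  expect_true(is.na(f["a", "r1"])); expect_equal(f["a", "r2"], 40)
  expect_equal(f["b", "r1"], 32)   # "fewer than 32": 32 is kept
  expect_true(is.na(f["b", "r2"]))
  expect_true(all(is.na(f["c", "r1"])))
  # monotonicity: lowering the floor never removes a guide from a sample
  f_lo <- droplet_filter_counts(m, min_reads = 16)
  expect_true(all(is.na(f) | !is.na(f_lo)))
})

test_that("enrichment factors are ratios of relative abundances", {
  sorted <- matrix(c(20, 980), 2, 1, dimnames = list(c("a", "b"), "r1"))
  unsorted <- matrix(c(5, 995), 2, 1, dimnames = list(c("a", "b"), "r1"))
  ef <- enrichment_factors(sorted, unsorted)
  expect_equal(ef["a", "r1"], (20 / 1000) / (5 / 1000))  # EF = 4
  # equal relative abundance: EF = 1
  ef1 <- enrichment_factors(unsorted, unsorted)
  expect_equal(unname(ef1[, 1]), c(1, 1))
  # absence in either fraction: NA, never Inf
  s2 <- matrix(c(NA, 100), 2, 1, dimnames = list(c("a", "b"), "r1"))
  ef2 <- enrichment_factors(s2, unsorted)
  expect_true(is.na(ef2["a", "r1"]))
  expect_false(any(is.infinite(ef2)))
})

test_that("concordance filter drops >=10-fold discordant replicates", {
  expect_false(concordance_filter(c(0.5, 6.0))$keep)  # 12-fold
  expect_true(concordance_filter(c(2.0, 3.0))$keep)
  expect_false(concordance_filter(c(1.0, 10.0))$keep) # boundary inclusive
  single <- concordance_filter(c(NA, 4.2))
  expect_true(single$keep); expect_true(single$single)
})

test_that("clone scoring counts appearances and calls hits at 2 of 4", {
  ef <- rbind(hit1 = c(3.2, 0.8, 4.0, NA),
              miss = c(2.9, 2.5, 1.0, 2.0),
              hit2 = c(5, 4, 3.5, 3))
  colnames(ef) <- paste0("r", 1:4)
  res <- score_clones(ef)
  expect_equal(res$appearances, c(2L, 0L, 4L))
  expect_equal(res$hit, c(TRUE, FALSE, TRUE))
  # raising ef_min never adds hits
  res5 <- score_clones(ef, ef_min = 5)
  expect_true(all(res$hit | !res5$hit))
  # brute-force evaluation on a random table
  set.seed(29)
  eft <- matrix(rlnorm(400, 0, 1), 100, 4,
                dimnames = list(sprintf("c%03d", 1:100), paste0("r", 1:4)))
  res2 <- score_clones(eft)
  expect_equal(res2$appearances, unname(rowSums(eft >= 3)))
  expect_equal(res2$hit, unname(rowSums(eft >= 3) >= 2))
})

test_that("concordance groups blank discordant runs before scoring", {
  ef <- rbind(a = c(1, 1, 30, 2.9),    # runs 1/3 discordant (30x)
              b = c(4, 4, 5, 6))
  colnames(ef) <- paste0("r", 1:4)
  res <- score_clones(ef, run_groups = list(c(1, 3), c(2, 4)))
  expect_true(is.na(res$EF_run1[1]) && is.na(res$EF_run3[1]))
  expect_equal(res$appearances, c(0L, 4L))
})

test_that("variability bins honour the p-value range boundaries", {
  p_to_bin <- function(p) as.character(cut(p,
    breaks = c(0, 0.001, 0.01, 0.05, 0.1, 1),
    labels = c("<0.001", "0.01-0.001", "0.05-0.01", "0.1-0.05", "1-0.1"),
    right = TRUE, include.lowest = TRUE))
  expect_equal(p_to_bin(0.05), "0.05-0.01")   # boundary into the lower range
  expect_equal(p_to_bin(0.5), "1-0.1")

  set.seed(31)
  lvl <- rep(1:5, each = 4)                   # 5 growth rates, 4 obs each
  flat <- rep(10, 20) + rnorm(20, 0, 0.5)
  trend <- 10 + 2 * lvl + rnorm(20, 0, 0.5)
  const <- rep(3, 20)
  ab <- rbind(flat = flat, trend = trend, const = const)
  fit <- c(flat = -0.1, trend = -3, const = 0)
  res <- variability_bins(ab, lvl, fit)
  pp <- stats::setNames(res$per_protein$bin, res$per_protein$protein)
  expect_equal(as.character(pp[["trend"]]), "<0.001")  # planted strong trend
  expect_equal(as.character(pp[["const"]]), "1-0.1")   # constant -> p = 1
  expect_true(res$per_protein$p[res$per_protein$protein == "flat"] > 0.01)
  expect_equal(sum(res$per_bin$n), 3)
})

test_that("droplet screen end-to-end recovers spiked producers", {
  ids <- sprintf("c%04d", 1:2000)
  set.seed(42)
  spikes <- sample(ids, 20)
  truth <- random_truth(ids, 0.07, seed = 1, frac_depleted = 0,
                        productive_ids = spikes)
  cfg <- droplet_config(seed = 7)
  sim <- simulate_droplet_screen(ids, truth, cfg)
  ef <- enrichment_factors(droplet_filter_counts(sim$sorted),
                           droplet_filter_counts(sim$unsorted))
  hits <- score_clones(ef, run_groups = split(sim$run_meta$run,
                                              sim$run_meta$timepoint))
  is_spike <- hits$guide_id %in% spikes
  expect_gte(mean(hits$hit[is_spike]), 0.8)
  expect_lte(mean(hits$hit[!is_spike]), 0.05)
})
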