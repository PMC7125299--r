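test_that("size factors recover scaling between samples", {
  set.seed(1)
  a <- rnbinom(200, mu = 100, size = 5) + 1L
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- sprintf("g%03d", 1:200)
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = a, s2 = 2L * a)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # matches the definitional median-of-ratios computation
  m3 <- cbind(s1 = rnbinom(300, mu = 80, size = 8),
              s2 = rnbinom(300, mu = 120, size = 8),
              s3 = rnbinom(300, mu = 100, size = 8))
  rownames(m3) <- sprintf("g%03d", 1:300)
  keep <- rowSums(m3 == 0) == 0
  ref <- exp(rowMeans(log(m3[keep, ])))
  expected <- apply(m3[keep, ], 2, function(x) median(x / ref))
  expect_equal(unname(size_factors(m3)), unname(expected))
})

test_that("size factors fall back to totals without a common nonzero guide", {
  m <- cbind(s1 = c(5L, 0L), s2 = c(0L, 5L))
  rownames(m) <- c("a", "b")
  expect_warning(sf <- size_factors(m), "fallback|total")
  expect_equal(unname(sf), c(1, 1))
})

test_that("generations converts time to doublings", {
  expect_equal(generations(0.0693, 10), 0.0693 * 10 / log(2))
  expect_lt(abs(generations(0.0693, 10) - 1), 0.001)
  # 32 days at mu ~0.03/h spans ~33 generations ("over 32 cell generations")
  expect_lt(abs(generations(0.03, 768) - 33.2), 0.05)
  expect_equal(generations(0.07, 0), 0)
})

test_that("log2fc trajectories are zero for unchanged clones and track depletion", {
  ids <- sprintf("g%02d", 1:30)
  truth <- sim_truth(ids, mu_mut = rep(0.07, 30))
  cfg <- competition_config(0.07, c(0, 50, 100), replicates = 4,
                            depth = 1e6, overdispersion = Inf, seed = 2)
  sim <- simulate_competition(ids, truth, cfg, condition = "L300")
  traj <- log2fc_trajectory(sim$counts, sim$meta, "L300")
  expect_true(all(abs(traj$log2fc) < 0.05))
  expect_equal(traj$log2fc[traj$time_h == 0], rep(0, 30))

  # a clone halving its normalized abundance every generation: slope -1/gen
  n_gen <- c(0, 1, 2, 3)
  counts <- rbind(dil = 1000 * 2^-n_gen, ref = rep(1000, 4))
  counts <- matrix(as.integer(counts), 2, byrow = FALSE,
                   dimnames = list(c("dil", "ref"), paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4), condition = "C",
                     time_h = n_gen * 10, replicate = 1L, induced = TRUE,
                     mu_pop = log(2) / 10, n_gen = n_gen)
  traj2 <- log2fc_trajectory(counts, meta, "C", pseudocount = 0,
                             sf = stats::setNames(rep(1, 4), paste0("s", 1:4)))
  d <- traj2[traj2$guide_id == "dil", ]
  expect_equal(diff(d$log2fc) / diff(d$n_gen), rep(-1, 3))
})

test_that("trajectory equals the mean of per-replicate trajectories", {
  set.seed(5)
  counts <- matrix(rpois(40, 100) + 1L, 5, 8,
                   dimnames = list(sprintf("g%d", 1:5),
                                   sprintf("s%d", 1:8)))
  meta <- data.frame(sample_id = sprintf("s%d", 1:8), condition = "C",
                     time_h = rep(c(0, 24), each = 4),
                     replicate = rep(1:4, 2), induced = TRUE,
                     mu_pop = 0.05, n_gen = generations(0.05, rep(c(0, 24), each = 4)))
  sf <- stats::setNames(rep(1, 8), colnames(counts))
  traj <- log2fc_trajectory(counts, meta, "C", sf = sf)
  per_rep <- sapply(1:4, function(r) {
    log2((counts[, 4 + r] + 0.5) / (counts[, r] + 0.5))
  })
  expect_equal(traj$log2fc[traj$time_h == 24], unname(rowMeans(per_rep)))
})

test_that("missing induction samples raise an error", {
  counts <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), condition = "C",
                     time_h = c(24, 48), replicate = 1L, induced = TRUE,
                     mu_pop = 0.05, n_gen = c(1, 2))
  expect_error(log2fc_trajectory(counts, meta, "C"), "t = 0")
})

test_that("fitness score closed forms hold to machine precision", {
  gens <- c(0, 4, 8, 16, 32)
  expect_equal(fitness_score(gens, rep(-2, 5)), -2)
  expect_equal(fitness_score(c(0, 16), c(0, -8)), -4)
  expect_equal(fitness_score(gens, rep(0, 5)), 0)
  expect_error(fitness_score(5, -1), "2")
  # constant trajectories equal the constant on arbitrary grids
  set.seed(7)
  for (i in 1:20) {
    g <- sort(runif(sample(3:8, 1), 0, 40))
    g[1] <- 0
    cst <- runif(1, -8, 2)
    expect_equal(fitness_score(g, rep(cst, length(g))), cst)
  }
})

test_that("fitness score is linear in the trajectory", {
  set.seed(11)
  for (i in 1:20) {
    g <- c(0, sort(runif(5, 1, 40)))
    x <- rnorm(6); y <- rnorm(6)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(fitness_score(g, a * x + b * y),
                 a * fitness_score(g, x) + b * fitness_score(g, y))
  }
})

test_that("delta fitness subtracts, flags, and is antisymmetric", {
  d <- delta_fitness(-4, -0.5)
  expect_equal(d$delta_F, -3.5)
  expect_true(d$flagged)
  d0 <- delta_fitness(-1, -1)
  expect_equal(d0$delta_F, 0)
  expect_false(d0$flagged)
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(delta_fitness(a, b)$delta_F, -delta_fitness(b, a)$delta_F)
  # flag count equals brute-force thresholding
  dd <- delta_fitness(a, b * 4)
  expect_equal(sum(dd$flagged), sum(abs(a - 4 * b) >= 3))
})

test_that("gene fitness averages guides and applies the same-cluster rule", {
  rec <- data.frame(gene_id = "g1", guide_id = c("g1_1", "g1_2"),
                    F = c(-2, -4), cluster = c(2L, 2L))
  gf <- gene_fitness(rec)
  expect_equal(gf$F, -3)
  expect_true(gf$eligible)

  rec2 <- rec; rec2$cluster <- c(2L, 5L)
  expect_false(gene_fitness(rec2)$eligible)

  rec3 <- data.frame(gene_id = "g2", guide_id = "g2_1", F = -1, cluster = 1L)
  gf3 <- gene_fitness(rec3)
  expect_equal(gf3$F, -1)
  expect_false(gf3$eligible)
})

test_that("significance test is calibrated under the null and detects depletion", {
  set.seed(13)
  n <- 300
  mu <- rep(100, n)
  counts <- sapply(1:8, function(j) rnbinom(n, mu = mu, size = 10))
  dimnames(counts) <- list(sprintf("g%03d", 1:n), sprintf("s%d", 1:8))
  res <- significance_test(counts, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_gt(mean(res$p > 0.05), 0.85)        # roughly uniform p under null
  expect_gt(min(res$p_adj), 0.2)             # no confident calls
  # BH adjustment equals the brute-force formula
  expect_equal(res$p_adj, oracle_bh(res$p))

  # planted 8-fold depletion at ~100 reads/guide, 4 replicates
  set.seed(14)
  n <- 400; tp <- 1:4                         # 1% spike-in of true positives
  mu_b <- rep(100, n); mu_b[tp] <- 12.5
  counts2 <- cbind(sapply(1:4, function(j) rnbinom(n, mu = 100, size = 20)),
                   sapply(1:4, function(j) rnbinom(n, mu = mu_b, size = 20)))
  dimnames(counts2) <- list(sprintf("g%03d", 1:n), sprintf("s%d", 1:8))
  res2 <- significance_test(counts2, sprintf("s%d", 1:4), sprintf("s%d", 5:8))
  expect_true(all(res2$p_adj[tp] < 0.005))
  expect_lt(mean(res2$p_adj[-tp] < 0.005), 0.01)
  expect_lt(max(abs(res2$log2fc[tp] - (-3))), 1)
})

test_that("growth-rate estimation inverts the depletion model exactly", {
  tp <- c(0, 6, 12, 24)
  f <- 1e-4 * (1 - (0.07 - 0.035))^tp
  est <- estimate_growth_rate(f, tp, mu_pop = 0.07)
  expect_lt(abs(est$mu_mut - 0.035), 1e-10)
  expect_false(est$lower_bound)
  # flat fractions: mu_mut = mu_pop
  est2 <- estimate_growth_rate(rep(2e-3, 4), tp, mu_pop = 0.07)
  expect_equal(est2$mu_mut, 0.07)
  # clone vanishing after t0 is flagged lower-bound
  est3 <- estimate_growth_rate(c(1e-4, 0, 0, 0), tp, mu_pop = 0.07)
  expect_true(est3$lower_bound)
})

test_that("growth rates are recovered from sampled counts", {
  ids <- sprintf("c%04d", 1:400)
  truth <- random_truth(ids, 0.07, seed = 31, frac_depleted = 0.28)
  cfg <- competition_config(0.07, c(0, 24, 48, 96, 144, 192, 240, 317),
                            replicates = 2, depth = 4e5,
                            overdispersion = Inf, seed = 6)
  sim <- simulate_competition(ids, truth, cfg)
  est <- estimate_growth_rates(sim$counts, sim$meta, 0.07)
  err <- abs(est$mu_mut - truth$mu_mut[match(est$clone_id, truth$clone_id)])
  expect_lt(median(err, na.rm = TRUE), 0.05 * 0.07)
})
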