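#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median across guides of the
#' ratio of each sample's counts to the per-guide geometric-mean reference,
#' using only guides with nonzero counts in every sample (the standard
#' normalization for sequencing count data). When no guide is nonzero
#' everywhere, falls back to total-count scaling with a warning.
#'
#' @param counts guides x samples integer matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) {
    warning("no guide nonzero in all samples; falling back to total-count scaling")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  sub <- counts[keep, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  sf <- apply(sub, 2, function(x) stats::median(x / ref))
  stats::setNames(sf, colnames(counts))
}

#' Generations elapsed since induction
#'
#' Converts cultivation time to population doublings:
#' `n_gen = mu_pop * t / ln 2`.
#'
#' @param mu_pop population growth rate, per hour.
#' @param t time in hours.
#' @return number of cell generations.
#' @examples
#' generations(0.03, 768)   # ~33.2 generations over 32 days
#' @export
generations <- function(mu_pop, t) {
  stopifnot(all(mu_pop >= 0), all(t >= 0))
  mu_pop * t / log(2)
}

#' Log2 fold-change trajectories per guide
#'
#' For one condition, computes per-guide log2 fold-change against the t = 0
#' (induction) samples: normalized counts get a pseudocount, each
#' replicate's timepoint is compared to its own t = 0 sample, and
#' trajectories are averaged across replicates. The generation axis is taken
#' from the metadata (`n_gen`, or `mu_pop`/`time_h` when absent).
#'
#' @param counts guides x samples integer matrix.
#' @param meta sample metadata with `sample_id`, `condition`, `time_h`,
#'   `replicate` and either `n_gen` or `mu_pop`.
#' @param condition condition label to analyse.
#' @param pseudocount added to normalized counts before log (default 0.5).
#' @param sf optional precomputed size factors (named by sample).
#' @return long data.frame: `guide_id`, `condition`, `time_h`, `n_gen`,
#'   `log2fc` (replicate mean).
#' @export
log2fc_trajectory <- function(counts, meta, condition, pseudocount = 0.5,
                              sf = NULL) {
  m <- meta[meta$condition == condition, , drop = FALSE]
  if (!nrow(m)) stop("no samples for condition ", condition)
  if (!any(m$time_h == 0)) stop("missing t = 0 samples for condition ", condition)
  if (is.null(m$n_gen)) m$n_gen <- generations(m$mu_pop, m$time_h)
  counts <- counts[, m$sample_id, drop = FALSE]
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf[colnames(counts)], "/") + pseudocount
  times <- sort(unique(m$time_h))
  reps <- sort(unique(m$replicate))
  out <- vector("list", length(times))
  for (ti in seq_along(times)) {
    lfc_reps <- sapply(reps, function(r) {
      s_t <- m$sample_id[m$time_h == times[ti] & m$replicate == r]
      s_0 <- m$sample_id[m$time_h == 0 & m$replicate == r]
      if (!length(s_0)) s_0 <- m$sample_id[m$time_h == 0]
      if (!length(s_t)) return(rep(NA_real_, nrow(norm)))
      log2(rowMeans(norm[, s_t, drop = FALSE]) /
             rowMeans(norm[, s_0, drop = FALSE]))
    })
    out[[ti]] <- data.frame(
      guide_id = rownames(counts), condition = condition,
      time_h = times[ti],
      n_gen = m$n_gen[match(times[ti], m$time_h)],
      log2fc = rowMeans(as.matrix(lfc_reps), na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Negative-binomial Wald test for differential guide abundance
#'
#' Contrasts two sample groups (e.g. endpoint vs induction) with a Wald test
#' on the log fold-change of normalized means, using a method-of-moments
#' gene-wise negative-binomial dispersion pooled across both groups. With a
#' handful of replicates the raw moment estimate is unstable (a guide whose
#' sample variance happens to fall below its mean would get a Poisson
#' variance and a wildly anticonservative p-value), so per-guide dispersions
#' are floored at the library-wide median dispersion. Guides whose raw
#' estimate was degenerate (non-positive) are flagged; when the whole
#' library is degenerate the test reduces to Poisson. P-values are
#' Benjamini-Hochberg adjusted across guides.
#'
#' @param counts guides x samples integer matrix.
#' @param group_a,group_b character vectors of sample ids (reference,
#'   comparison); at least 2 samples each.
#' @param sf optional size factors for the union of samples.
#' @param pseudocount stabilises the fold-change of zero means (default 0.5).
#' @return data.frame: `guide_id`, `log2fc`, `p`, `p_adj`, `poisson_fallback`.
#' @export
significance_test <- function(counts, group_a, group_b, sf = NULL,
                              pseudocount = 0.5) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  if (is.null(sf)) sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf[colnames(sub)], "/")
  A <- norm[, group_a, drop = FALSE]
  B <- norm[, group_b, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  v_pool <- (vA * (nA - 1) + vB * (nB - 1)) / (nA + nB - 2)
  m_pool <- (mA + mB) / 2
  alpha <- (v_pool - m_pool) / m_pool^2
  fallback <- !is.finite(alpha) | alpha <= 0
  alpha_prior <- stats::median(alpha[!fallback])
  if (!is.finite(alpha_prior)) alpha_prior <- 0   # whole library ~ Poisson
  alpha[fallback] <- alpha_prior
  alpha <- pmax(alpha, alpha_prior)
  mA_s <- pmax(mA, pseudocount); mB_s <- pmax(mB, pseudocount)
  log2fc <- log2((mB + pseudocount) / (mA + pseudocount))
  ## delta-method variance of log(mean) under NB: (1/mu + alpha)/n
  se2 <- (1 / mA_s + alpha) / nA + (1 / mB_s + alpha) / nB
  z <- log(mB_s / mA_s) / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(guide_id = rownames(counts), log2fc = log2fc, p = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             poisson_fallback = fallback, stringsAsFactors = FALSE)
}

#' Fitness score: generation-normalized AUC of the log2FC trajectory
#'
#' `F = AUC(n_gen, log2FC) / max(n_gen)` with a trapezoid AUC. A clone at
#' constant log2FC `c` has `F = c`; a clone depleting linearly to `-8` over
#' the experiment has `F = -4`.
#'
#' @param n_gen non-decreasing generation grid (>= 2 points).
#' @param log2fc log2 fold-changes at those generations.
#' @return scalar fitness score.
#' @export
fitness_score <- function(n_gen, log2fc) {
  ok <- is.finite(n_gen) & is.finite(log2fc)
  n_gen <- n_gen[ok]; log2fc <- log2fc[ok]
  if (length(n_gen) < 2) stop("fitness score needs at least 2 trajectory points")
  if (is.unsorted(n_gen)) {
    o <- order(n_gen); n_gen <- n_gen[o]; log2fc <- log2fc[o]
  }
  pracma::trapz(n_gen, log2fc) / max(n_gen)
}

#' Fitness scores for all guides in a trajectory table
#'
#' @param traj long trajectory data.frame from [log2fc_trajectory()].
#' @return data.frame `guide_id`, `condition`, `F`.
#' @export
fitness_scores <- function(traj) {
  sp <- split(traj, list(traj$guide_id, traj$condition), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    guide_id = d$guide_id[1], condition = d$condition[1],
    F = fitness_score(d$n_gen, d$log2fc), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Differential fitness between two conditions
#'
#' `dF = F_a - F_b`; absolute differences at or above the threshold are
#' flagged as condition-differential.
#'
#' @param F_a,F_b fitness scores (vectors align by position).
#' @param threshold flag threshold on |dF| (default 3).
#' @return data.frame `delta_F`, `flagged`.
#' @export
delta_fitness <- function(F_a, F_b, threshold = 3) {
  dF <- F_a - F_b
  data.frame(delta_F = dF, flagged = abs(dF) >= threshold)
}

#' Gene-level fitness from guide-level records
#'
#' Gene fitness is the mean fitness of the gene's (up to two) guides. A gene
#' is eligible for condition-differential calls only when it has two guides
#' and both share a depletion-cluster label; single-guide genes and genes
#' with discordant guides are reported but ineligible.
#'
#' @param records data.frame with `gene_id`, `guide_id`, `F` and optional
#'   `cluster`.
#' @return data.frame `gene_id`, `F`, `n_guides`, `eligible`.
#' @export
gene_fitness <- function(records) {
  sp <- split(records, records$gene_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    elig <- nrow(d) == 2 &&
      (!"cluster" %in% names(d) || length(unique(d$cluster)) == 1)
    data.frame(gene_id = d$gene_id[1], F = mean(d$F), n_guides = nrow(d),
               eligible = elig, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Estimate a mutant growth rate from its abundance trajectory
#'
#' Inverts the discrete depletion model: `log f(t) = log f(0) +
#' t * log(1 - mu_diff)` is fit by least squares over points with `f > 0`,
#' and `mu_mut = mu_pop - mu_diff`. Exact (machine precision) on noiseless
#' model trajectories. When fewer than two positive points remain the
#' estimate is returned as a lower bound (`lower_bound = TRUE`, slope from
#' the last positive observation assuming depletion continued).
#'
#' @param f abundance fractions over time.
#' @param time_h times in hours.
#' @param mu_pop population growth rate, per hour.
#' @return one-row data.frame: `mu_mut`, `mu_diff`, `mu_pop`, `residual`
#'   (RMS of the log fit), `points_used`, `lower_bound`.
#' @export
estimate_growth_rate <- function(f, time_h, mu_pop) {
  stopifnot(length(f) == length(time_h), f[1] > 0)
  pos <- f > 0
  if (sum(pos) < 2) {
    ## all later points zero: the clone fell below detection by the first
    ## zero timepoint. Report the depletion rate implied by at least a
    ## halving of abundance by then, flagged as a lower bound only.
    t_zero <- time_h[which(!pos)[1]]
    mu_diff <- 1 - 0.5^(1 / max(t_zero, 1))
    return(data.frame(mu_mut = mu_pop - mu_diff, mu_diff = mu_diff,
                      mu_pop = mu_pop, residual = NA_real_,
                      points_used = sum(pos), lower_bound = TRUE))
  }
  x <- time_h[pos]; y <- log(f[pos])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  mu_diff <- 1 - exp(slope)
  data.frame(mu_mut = mu_pop - mu_diff, mu_diff = mu_diff, mu_pop = mu_pop,
             residual = sqrt(mean(fit$residuals^2)),
             points_used = sum(pos), lower_bound = FALSE,
             row.names = NULL)
}

#' Estimate growth rates for all clones in a count time course
#'
#' Converts counts to abundance fractions (replicate-averaged per
#' timepoint), then fits the depletion model per clone. Because a
#' turbidostat renormalizes fractions at every timepoint (depleting clones
#' inflate everyone else's share), the fit is iterated: after each pass the
#' population renormalization factor implied by the fitted clone models is
#' computed and divided out before refitting.
#'
#' @param counts clones x samples integer matrix.
#' @param meta metadata with `sample_id`, `time_h` (and `replicate`).
#' @param mu_pop population growth rate, per hour.
#' @param renorm_iter renormalization-correction passes (default 2; 0
#'   disables the correction).
#' @return data.frame, one row per clone, as in [estimate_growth_rate()].
#' @export
estimate_growth_rates <- function(counts, meta, mu_pop, renorm_iter = 2L) {
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  times <- sort(unique(meta$time_h))
  fr <- sapply(times, function(t) {
    s <- meta$sample_id[meta$time_h == t]
    m <- counts[, s, drop = FALSE]
    rowMeans(sweep(m, 2, colSums(m), "/"))
  })
  colnames(fr) <- as.character(times)
  S <- rep(1, length(times))
  est <- NULL
  for (it in 0:renorm_iter) {
    fr_c <- sweep(fr, 2, S, "*")
    est <- do.call(rbind, lapply(seq_len(nrow(fr_c)), function(i) {
      fi <- fr_c[i, ]
      if (fi[1] <= 0) return(data.frame(mu_mut = NA_real_, mu_diff = NA_real_,
                                        mu_pop = mu_pop, residual = NA_real_,
                                        points_used = 0L, lower_bound = NA))
      estimate_growth_rate(fi, times, mu_pop)
    }))
    if (it == renorm_iter) break
    ## renormalization factor implied by the fitted models
    md <- est$mu_diff
    f0 <- fr_c[, 1]
    ok <- is.finite(md) & md < 1 & f0 > 0
    S_new <- colSums(f0[ok] * t(sapply(md[ok], function(d) (1 - d)^times)))
    S <- S_new / sum(f0[ok])
  }
  est$clone_id <- rownames(counts)
  rownames(est) <- NULL
  est[, c("clone_id", setdiff(names(est), "clone_id"))]
}
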