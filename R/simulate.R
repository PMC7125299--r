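#' Ground-truth table for simulations
#'
#' @param clone_id character vector of clone (guide) ids.
#' @param mu_mut per-hour specific growth rate of each clone.
#' @param f0 initial abundance fractions; must sum to 1.
#' @param productivity optional per-cell product formation rate in arbitrary
#'   fluorescence units (droplet screen only).
#' @return data.frame of class `SimTruth`.
#' @export
sim_truth <- function(clone_id, mu_mut, f0 = NULL, productivity = NULL) {
  n <- length(clone_id)
  if (is.null(f0)) f0 <- rep(1 / n, n)
  stopifnot(length(mu_mut) == n, length(f0) == n,
            all(mu_mut >= 0), all(f0 >= 0),
            abs(sum(f0) - 1) < 1e-9)
  if (is.null(productivity)) productivity <- rep(NA_real_, n)
  stopifnot(all(is.na(productivity) | productivity >= 0))
  structure(data.frame(clone_id = clone_id, mu_mut = mu_mut, f0 = f0,
                       productivity = productivity, stringsAsFactors = FALSE),
            class = c("SimTruth", "data.frame"))
}

#' Random ground truth emulating a genome-wide repression library
#'
#' A configurable fraction of clones (default 0.28, the share of guides
#' significantly depleted in genome-wide cyanobacterial CRISPRi screens)
#' carries a growth defect, with mutant growth rates drawn uniformly
#' between 5% and 95% of the population rate (repression mutants span
#' near-knockout to mild defects). The rest are neutral. Initial fractions
#' are equal.
#'
#' @param clone_id clone ids.
#' @param mu_pop population growth rate, per hour.
#' @param seed integer seed.
#' @param frac_depleted fraction of clones with a growth defect.
#' @param productive_ids optional ids of high-productivity clones;
#'   productivity is `productivity_fold` for these and 1 for the rest.
#' @param productivity_fold productivity of spiked clones (default 10).
#' @return [sim_truth()] table.
#' @export
random_truth <- function(clone_id, mu_pop, seed = 1L, frac_depleted = 0.28,
                         productive_ids = NULL, productivity_fold = 10) {
  set.seed(seed)
  n <- length(clone_id)
  mu <- rep(mu_pop, n)
  dep <- sample.int(n, round(frac_depleted * n))
  mu[dep] <- stats::runif(length(dep), 0.05 * mu_pop, 0.95 * mu_pop)
  prod <- NULL
  if (!is.null(productive_ids)) {
    prod <- rep(1, n)
    prod[clone_id %in% productive_ids] <- productivity_fold
  }
  sim_truth(clone_id, mu, productivity = prod)
}

#' Competition-simulation configuration
#'
#' @param mu_pop population (turbidostat dilution) growth rate, per hour.
#' @param timepoints_h strictly increasing sampling times in hours; the
#'   first must be 0 (induction).
#' @param replicates number of replicate cultivations (default 4, as in
#'   replicated turbidostat screens).
#' @param depth sequencing reads per sample; default 75 reads per clone is
#'   set by [simulate_competition()] when `depth = NULL` (the 50-100
#'   reads/sgRNA regime of a typical pooled-screen NGS run).
#' @param overdispersion Dirichlet concentration scale; counts are
#'   Dirichlet-multinomial with concentration `overdispersion` times the
#'   expected fractions. `Inf` gives a pure multinomial. Default 200 times
#'   the clone number (mild overdispersion), set at simulation time.
#' @param seed master seed; per-sample substreams are derived by fixed
#'   offsets.
#' @export
competition_config <- function(mu_pop, timepoints_h, replicates = 4L,
                               depth = NULL, overdispersion = NULL,
                               seed = 1L) {
  stopifnot(mu_pop >= 0, length(timepoints_h) >= 2,
            timepoints_h[1] == 0, all(diff(timepoints_h) > 0),
            replicates >= 1, is.null(depth) || depth > 0)
  structure(list(mu_pop = mu_pop, timepoints_h = timepoints_h,
                 replicates = as.integer(replicates), depth = depth,
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "CompetitionSimConfig")
}

#' Expected clone fractions under the discrete depletion model
#'
#' A clone growing slower than the population washes out of a turbidostat:
#' its fraction follows `f(t) = f(0) * (1 - (mu_pop - mu_mut))^t` with `t`
#' in hours and rates per hour. Because the turbidostat holds total density
#' constant, observed fractions are the renormalized values; both are
#' returned.
#'
#' @param truth [sim_truth()] table.
#' @param mu_pop population growth rate (per hour).
#' @param timepoints_h times in hours.
#' @return list with matrices `raw` and `renorm` (clones x timepoints).
#' @export
depletion_fractions <- function(truth, mu_pop, timepoints_h) {
  mu_diff <- mu_pop - truth$mu_mut
  if (any(mu_diff >= 1))
    stop("mu_pop - mu_mut >= 1 for some clone: depletion model undefined")
  raw <- outer(seq_len(nrow(truth)), seq_along(timepoints_h),
               function(i, j) truth$f0[i] * (1 - mu_diff[i])^timepoints_h[j])
  renorm <- sweep(raw, 2, colSums(raw), "/")
  dimnames(raw) <- dimnames(renorm) <-
    list(truth$clone_id, as.character(timepoints_h))
  list(raw = raw, renorm = renorm)
}

## Dirichlet-multinomial (or multinomial) draw of one sample
rdirmultinom <- function(depth, prob, concentration = Inf) {
  if (is.finite(concentration)) {
    alpha <- prob * concentration
    g <- stats::rgamma(length(alpha), shape = alpha)
    if (sum(g) == 0) g[] <- prob
    prob <- g / sum(g)
  }
  as.integer(stats::rmultinom(1, size = depth, prob = prob))
}

#' Simulate a pooled turbidostat competition time course
#'
#' Clone fractions follow the discrete depletion model (see
#' [depletion_fractions()]), renormalized at each timepoint; reads per
#' sample are drawn (Dirichlet-)multinomially at the configured depth.
#' Replicates share expected fractions and differ only by sampling noise.
#' Bit-reproducible for a fixed seed.
#'
#' @param library `GuideLibrary`, guides data.frame, or character vector of
#'   clone ids; every clone must appear in `truth`.
#' @param truth [sim_truth()] table.
#' @param cfg [competition_config()].
#' @param condition condition label recorded in the metadata (default "SIM").
#' @return list with `counts` (clones x samples integer matrix), `meta`
#'   (sample metadata data.frame: sample_id, condition, time_h, replicate,
#'   induced, mu_pop, n_gen), and `fractions` (raw and renormalized expected
#'   fractions).
#' @export
simulate_competition <- function(library, truth, cfg, condition = "SIM") {
  ids <- if (inherits(library, "GuideLibrary")) library$guides$guide_id
         else if (is.data.frame(library)) library$guide_id
         else as.character(library)
  if (!all(ids %in% truth$clone_id))
    stop("truth table does not cover every library clone")
  truth <- truth[match(ids, truth$clone_id), ]
  n <- length(ids)
  depth <- if (is.null(cfg$depth)) 75L * n else cfg$depth
  conc <- if (is.null(cfg$overdispersion)) 200 * n else cfg$overdispersion
  fr <- depletion_fractions(truth, cfg$mu_pop, cfg$timepoints_h)
  nt <- length(cfg$timepoints_h)
  counts <- matrix(0L, n, nt * cfg$replicates,
                   dimnames = list(ids, NULL))
  meta <- expand.grid(replicate = seq_len(cfg$replicates),
                      time_h = cfg$timepoints_h, KEEP.OUT.ATTRS = FALSE)
  meta <- meta[order(meta$time_h, meta$replicate), , drop = FALSE]
  sample_id <- sprintf("%s_t%g_r%d", condition, meta$time_h, meta$replicate)
  colnames(counts) <- sample_id
  for (k in seq_len(nrow(meta))) {
    ti <- match(meta$time_h[k], cfg$timepoints_h)
    set.seed(cfg$seed + 1000L * k)
    counts[, k] <- rdirmultinom(depth, fr$renorm[, ti], conc)
  }
  meta <- data.frame(sample_id = sample_id, condition = condition,
                     time_h = meta$time_h, replicate = meta$replicate,
                     induced = TRUE, mu_pop = cfg$mu_pop,
                     n_gen = generations(cfg$mu_pop, meta$time_h),
                     stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  list(counts = counts, meta = meta, fractions = fr)
}

#' Simulate amplicon reads from a count matrix
#'
#' Each counted unit emits one read `flank5 + spacer + flank3`, truncated to
#' `read_len`, mimicking the PCR amplicon of an sgRNA expression cassette.
#' Reads within a sample are shuffled deterministically by the seed.
#'
#' @param counts clones x samples integer matrix (rownames = clone ids).
#' @param spacers named character vector mapping clone id to spacer.
#' @param flank5,flank3 constant cassette sequence around the spacer.
#' @param read_len read length; must cover `flank5` plus the longest spacer.
#' @param seed integer seed.
#' @return named list (one character vector of reads per sample).
#' @export
simulate_reads <- function(counts, spacers, flank5 = "GTTTAAGAGC",
                           flank3 = "AGGCTAGTCC", read_len = 60L, seed = 1L) {
  ids <- rownames(counts)
  stopifnot(all(ids %in% names(spacers)))
  spacers <- spacers[ids]
  if (read_len < nchar(flank5) + max(nchar(spacers)))
    stop("read_len shorter than flank5 + longest spacer")
  full <- paste0(flank5, spacers, flank3)
  full <- substr(full, 1L, read_len)
  out <- vector("list", ncol(counts))
  names(out) <- colnames(counts)
  for (k in seq_len(ncol(counts))) {
    reads <- rep(full, counts[, k])
    set.seed(seed + k)
    out[[k]] <- sample(reads)
  }
  out
}

#' Write simulated reads to FASTQ
#'
#' @param reads named list of read vectors (per sample), as from
#'   [simulate_reads()].
#' @param dir output directory; one `<sample>.fastq` per sample.
#' @return invisibly, the file paths.
#' @export
write_fastq <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(reads))
  for (k in seq_along(reads)) {
    r <- reads[[k]]
    dss <- Biostrings::DNAStringSet(r)
    names(dss) <- sprintf("read%06d", seq_along(r))
    q <- Biostrings::BStringSet(strrep("I", nchar(r)))
    paths[k] <- file.path(dir, paste0(names(reads)[k], ".fastq"))
    Biostrings::writeXStringSet(dss, paths[k], format = "fastq", qualities = q)
  }
  invisible(paths)
}

#' Droplet-screen simulation configuration
#'
#' @param n_droplets droplets generated per sorting run.
#' @param occupancy_lambda mean cells per droplet (Poisson loading).
#' @param noise_cv coefficient of variation of the multiplicative
#'   (log-normal, mean 1) per-droplet fluorescence noise.
#' @param sort_fraction fraction of cell-containing droplets sorted
#'   (default 0.02: the top 2% most fluorescent droplets).
#' @param runs number of sorting runs (default 4: two cultivation occasions
#'   times two assay timepoints).
#' @param depth reads per sequenced sample.
#' @param seed master seed; per-run substreams derived by fixed offsets.
#' @export
droplet_config <- function(n_droplets = 180000L, occupancy_lambda = 0.3,
                           noise_cv = 0.5, sort_fraction = 0.02,
                           runs = 4L, depth = 200000L, seed = 1L) {
  stopifnot(sort_fraction > 0, sort_fraction < 1, occupancy_lambda > 0,
            n_droplets > 0, runs >= 1, depth > 0, noise_cv >= 0)
  structure(list(n_droplets = as.integer(n_droplets),
                 occupancy_lambda = occupancy_lambda, noise_cv = noise_cv,
                 sort_fraction = sort_fraction, runs = as.integer(runs),
                 depth = as.integer(depth), seed = as.integer(seed)),
            class = "DropletSimConfig")
}

#' Simulate a fluorescence-activated droplet-sorting screen
#'
#' Per run: droplets are loaded with Poisson(`occupancy_lambda`) cells drawn
#' from the clone abundance distribution; droplet fluorescence is the sum of
#' its cells' productivities times a log-normal noise factor (mean 1, CV
#' `noise_cv`); the top `sort_fraction` of cell-containing droplets are
#' kept. The sorted count sample is a multinomial read sample over the cells
#' in kept droplets; the unsorted sample is a read sample of the input
#' abundances. Empty droplets have zero fluorescence and are excluded from
#' the cell-containing denominator.
#'
#' @param library `GuideLibrary`, guides data.frame or clone-id vector.
#' @param truth [sim_truth()] table with `productivity` set.
#' @param cfg [droplet_config()].
#' @return list with `sorted` and `unsorted` (clones x runs count matrices),
#'   `run_meta` (run, occasion, timepoint), and `stats` (per run: droplets,
#'   cell-containing droplets, sorted droplets).
#' @export
simulate_droplet_screen <- function(library, truth, cfg) {
  ids <- if (inherits(library, "GuideLibrary")) library$guides$guide_id
         else if (is.data.frame(library)) library$guide_id
         else as.character(library)
  truth <- truth[match(ids, truth$clone_id), ]
  if (any(is.na(truth$productivity)))
    stop("truth must provide productivity for every clone")
  n <- length(ids)
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  meanlog <- -sdlog^2 / 2   # noise factor has mean 1
  sorted <- unsorted <- matrix(0L, n, cfg$runs,
                               dimnames = list(ids, sprintf("run%d", seq_len(cfg$runs))))
  stats_df <- data.frame(run = seq_len(cfg$runs), droplets = NA_integer_,
                         cell_containing = NA_integer_, sorted = NA_integer_)
  for (r in seq_len(cfg$runs)) {
    set.seed(cfg$seed + 7919L * r)
    occ <- stats::rpois(cfg$n_droplets, cfg$occupancy_lambda)
    nonempty <- which(occ > 0L)
    ncells <- sum(occ)
    cell_clone <- sample.int(n, ncells, replace = TRUE, prob = truth$f0)
    drop_of_cell <- rep.int(seq_along(occ), occ)
    fl_cells <- rowsum(truth$productivity[cell_clone], drop_of_cell)
    noise <- if (cfg$noise_cv > 0)
      stats::rlnorm(length(nonempty), meanlog, sdlog) else 1
    fl <- as.numeric(fl_cells) * noise
    n_keep <- round(cfg$sort_fraction * length(nonempty))
    keep_droplets <- nonempty[order(fl, decreasing = TRUE)[seq_len(n_keep)]]
    kept_cells <- cell_clone[drop_of_cell %in% keep_droplets]
    sorted_tab <- tabulate(kept_cells, nbins = n)
    if (sum(sorted_tab) > 0)
      sorted[, r] <- rdirmultinom(cfg$depth, sorted_tab / sum(sorted_tab))
    unsorted[, r] <- rdirmultinom(cfg$depth, truth$f0)
    stats_df$droplets[r] <- cfg$n_droplets
    stats_df$cell_containing[r] <- length(nonempty)
    stats_df$sorted[r] <- n_keep
  }
  run_meta <- data.frame(run = seq_len(cfg$runs),
                         occasion = rep(1:2, length.out = cfg$runs),
                         timepoint = rep(1:2, each = ceiling(cfg$runs / 2),
                                         length.out = cfg$runs))
  list(sorted = sorted, unsorted = unsorted, run_meta = run_meta,
       stats = stats_df)
}
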