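#' Select guides enriched under stress but not in the control
#'
#' A guide is a tolerance hit when it passes both thresholds (log2 FC >=
#' `lfc_min` and -log10 p >= `neglogp_min`) in the stress condition and does
#' not pass both in the control. At gene level, a gene is flagged when both
#' of its guides are selected-or-above-average in stress but not in control
#' (above-average meaning log2 FC greater than the condition mean).
#'
#' @param stress,control data.frames with `guide_id`, `log2fc`, `p_adj`
#'   (same guide set; `gene_id` optional, enables the gene-level flag).
#' @param lfc_min log2 fold-change threshold (default 2).
#' @param neglogp_min -log10 adjusted p-value threshold (default 20).
#' @return list: `hits` (per-guide data.frame with `selected`), `genes`
#'   (data.frame of flagged genes, or NULL when no `gene_id` given).
#' @export
select_tolerance_enriched <- function(stress, control, lfc_min = 2,
                                      neglogp_min = 20) {
  stopifnot(identical(sort(stress$guide_id), sort(control$guide_id)))
  control <- control[match(stress$guide_id, control$guide_id), ]
  pass <- function(d) d$log2fc >= lfc_min & -log10(d$p_adj) >= neglogp_min
  sel <- pass(stress) & !pass(control)
  hits <- data.frame(guide_id = stress$guide_id,
                     log2fc_stress = stress$log2fc, p_adj_stress = stress$p_adj,
                     log2fc_control = control$log2fc, p_adj_control = control$p_adj,
                     selected = sel, stringsAsFactors = FALSE)
  genes <- NULL
  if (!is.null(stress$gene_id)) {
    up_s <- sel | stress$log2fc > mean(stress$log2fc, na.rm = TRUE)
    up_c <- pass(control) | control$log2fc > mean(control$log2fc, na.rm = TRUE)
    per_gene <- split(data.frame(up_s, up_c), stress$gene_id)
    flag <- vapply(per_gene, function(d)
      nrow(d) >= 2 && all(d$up_s) && !all(d$up_c), logical(1))
    genes <- data.frame(gene_id = names(per_gene), flagged = unname(flag),
                        stringsAsFactors = FALSE)
  }
  list(hits = hits, genes = genes)
}

#' Select guides specifically depleted under stress
#'
#' Ranks guides by differential fitness `dF = F_control - F_stress`
#' (largest first: most specifically depleted under stress) and takes the
#' top `top_n`. Ties at the cutoff are broken by guide id. Genes with both
#' guides inside the top set are reported.
#'
#' @param F_stress,F_control named numeric vectors of fitness scores
#'   (names = guide ids).
#' @param top_n size of the selected set (default 200).
#' @param gene_of optional named vector mapping guide id to gene id.
#' @return list: `top` (data.frame guide_id, dF, rank), `genes` (character
#'   vector of genes with both guides in the top set; NULL without
#'   `gene_of`).
#' @export
select_tolerance_depleted <- function(F_stress, F_control, top_n = 200,
                                      gene_of = NULL) {
  ids <- intersect(names(F_stress), names(F_control))
  dF <- F_control[ids] - F_stress[ids]
  o <- order(-dF, ids)
  top_n <- min(top_n, length(ids))
  top <- data.frame(guide_id = ids[o][seq_len(top_n)],
                    dF = unname(dF[o][seq_len(top_n)]),
                    rank = seq_len(top_n), stringsAsFactors = FALSE)
  genes <- NULL
  if (!is.null(gene_of)) {
    g_top <- gene_of[top$guide_id]
    g_all <- table(gene_of[ids])
    g_in <- table(g_top)
    genes <- names(g_in)[g_in >= 2 & g_all[names(g_in)] >= 2]
  }
  list(top = top, genes = genes)
}

#' Apply the per-sample read floor to droplet-screen counts
#'
#' Guides with fewer than `min_reads` mapped reads in a sample are removed
#' from that sample only (set to NA); the floor is "fewer than", so a guide
#' at exactly `min_reads` is kept.
#'
#' @param counts guides x samples matrix.
#' @param min_reads read floor (default 32).
#' @return numeric matrix with NA where a guide fell under the floor.
#' @export
droplet_filter_counts <- function(counts, min_reads = 32) {
  m <- as.matrix(counts) * 1.0
  m[m < min_reads] <- NA_real_
  m
}

#' Enrichment factors from sorted and unsorted fractions
#'
#' `EF = (relative abundance in sorted) / (relative abundance in unsorted)`
#' per guide per run. Relative abundances are computed after the read floor
#' (NA entries drop out of the denominator totals). Guides absent from
#' either fraction of a run get NA (no EF for that run), never Inf.
#'
#' @param sorted,unsorted guides x runs matrices (same dimensions), already
#'   floored via [droplet_filter_counts()] or raw.
#' @return guides x runs matrix of enrichment factors.
#' @export
enrichment_factors <- function(sorted, unsorted) {
  stopifnot(identical(dim(sorted), dim(unsorted)),
            identical(rownames(sorted), rownames(unsorted)))
  rel <- function(m) sweep(m, 2, colSums(m, na.rm = TRUE), "/")
  ef <- rel(sorted) / rel(unsorted)
  ef[!is.finite(ef)] <- NA_real_
  ef
}

#' Replicate-concordance filter on enrichment factors
#'
#' Guides whose enrichment factor differs by 10-fold or more between
#' replicates are unreliable and dropped. With a single replicate EF the
#' guide is kept but flagged.
#'
#' @param ef numeric vector of replicate EFs for one guide (NAs allowed).
#' @param max_ratio drop threshold on max/min (default 10, boundary
#'   inclusive).
#' @return list: `keep` (logical), `single` (TRUE when only one EF was
#'   available), `ratio`.
#' @export
concordance_filter <- function(ef, max_ratio = 10) {
  ef <- ef[is.finite(ef)]
  if (length(ef) < 2)
    return(list(keep = TRUE, single = TRUE, ratio = NA_real_))
  r <- max(ef) / min(ef)
  list(keep = r < max_ratio, single = FALSE, ratio = r)
}

#' Score clones across sorting runs and call hits
#'
#' Applies the replicate-concordance filter within each replicate group,
#' gives a clone a score of 1 for every run where its enrichment factor is
#' at least `ef_min`, and calls a hit when the summed score (appearances)
#' reaches `min_appearances` out of all runs.
#'
#' @param ef guides x runs matrix of enrichment factors.
#' @param ef_min per-run enrichment threshold (default 3).
#' @param min_appearances minimum number of scoring runs for a hit
#'   (default 2).
#' @param run_groups optional list of column-index vectors defining
#'   replicate groups for the concordance filter; runs in a failing group
#'   lose their EFs for that guide. The default NULL applies no filtering
#'   (EFs are assumed already concordance-filtered).
#' @param max_ratio concordance drop threshold (default 10).
#' @return data.frame: `guide_id`, `EF_run*`, `appearances`, `hit`,
#'   `mean_ef`.
#' @export
score_clones <- function(ef, ef_min = 3, min_appearances = 2,
                         run_groups = NULL, max_ratio = 10) {
  ef <- as.matrix(ef)
  if (is.null(run_groups)) run_groups <- list()
  for (g in run_groups) {
    if (length(g) < 2) next
    sub <- ef[, g, drop = FALSE]
    drop <- apply(sub, 1, function(v) {
      isFALSE(concordance_filter(v, max_ratio)$keep)
    })
    ef[drop, g] <- NA_real_
  }
  score <- ef >= ef_min
  appearances <- rowSums(score, na.rm = TRUE)
  out <- data.frame(guide_id = rownames(ef), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ef))) out[[paste0("EF_run", j)]] <- ef[, j]
  out$appearances <- as.integer(appearances)
  out$hit <- appearances >= min_appearances
  out$mean_ef <- rowMeans(ef, na.rm = TRUE)
  out
}

#' Bin proteins by expression variability and summarise fitness
#'
#' For each protein, tests whether abundance changes across growth-rate
#' levels (one-way ANOVA); proteins are binned by p-value into the ranges
#' 1-0.1, 0.1-0.05, 0.05-0.01, 0.01-0.001, <0.001 (right-closed intervals:
#' p = 0.05 falls in the 0.05-0.01 bin) and the fitness-score distribution
#' per bin is summarised. Constant proteins get p = 1.
#'
#' @param abundance proteins x samples numeric matrix.
#' @param growth_rate per-sample growth-rate level (factor or numeric, >= 2
#'   observations per level).
#' @param fitness named numeric vector of fitness scores per protein
#'   (names = rownames of `abundance`).
#' @return list: `per_protein` (protein, p, bin, fitness), `per_bin`
#'   (bin, n, median_F, mean_F).
#' @export
variability_bins <- function(abundance, growth_rate, fitness) {
  abundance <- as.matrix(abundance)
  lvl <- factor(growth_rate)
  stopifnot(ncol(abundance) == length(lvl), nlevels(lvl) >= 2)
  p <- apply(abundance, 1, function(a) {
    if (stats::var(a) == 0) return(1)
    stats::anova(stats::lm(a ~ lvl))[["Pr(>F)"]][1]
  })
  p[!is.finite(p)] <- 1
  bin <- cut(p, breaks = c(0, 0.001, 0.01, 0.05, 0.1, 1),
             labels = c("<0.001", "0.01-0.001", "0.05-0.01", "0.1-0.05", "1-0.1"),
             right = TRUE, include.lowest = TRUE)
  per_protein <- data.frame(protein = rownames(abundance), p = p, bin = bin,
                            fitness = unname(fitness[rownames(abundance)]),
                            stringsAsFactors = FALSE)
  per_bin <- do.call(rbind, lapply(split(per_protein, per_protein$bin, drop = TRUE),
    function(d) data.frame(bin = as.character(d$bin[1]), n = nrow(d),
                           median_F = stats::median(d$fitness, na.rm = TRUE),
                           mean_F = mean(d$fitness, na.rm = TRUE),
                           stringsAsFactors = FALSE)))
  rownames(per_bin) <- NULL
  list(per_protein = per_protein, per_bin = per_bin)
}
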