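#' Cluster depletion/enrichment trajectories
#'
#' Agglomerative clustering (Ward's minimum-variance criterion, `ward.D2`)
#' on Euclidean distances between per-guide feature vectors (log2
#' fold-changes concatenated over conditions and timepoints). The mean
#' silhouette width is reported for a range of cluster numbers; since
#' time-course screens typically separate about equally well over a broad
#' range of k, the working k is a configuration choice (default 6). A merge
#' rule then combines clusters whose centroid trajectories all stay inside a
#' near-zero band (max |centroid| < `merge_eps`) into a single "unchanged"
#' cluster, since splits within that band reflect technical variation.
#'
#' Labels are relabelled so cluster 1 has the most negative centroid mean
#' (strongest depletion) and the merged unchanged cluster comes last.
#'
#' @param x numeric matrix, guides x features; missing values are imputed
#'   as 0 (mask returned).
#' @param k number of clusters to cut (default 6).
#' @param k_range candidate k values for the silhouette report (default 3:9).
#' @param merge_eps near-zero band half-width for the merge rule
#'   (default 0.5, in log2 fold-change units).
#' @return list: `labels` (named integer vector), `k` (after merging),
#'   `k_cut`, `silhouette` (data.frame k, avg_width), `centroids` (matrix),
#'   `merged` (logical: did the merge rule fire), `na_mask`.
#' @export
cluster_trajectories <- function(x, k = 6L, k_range = 3:9, merge_eps = 0.5) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("fewer guides than clusters requested")
  na_mask <- is.na(x)
  x[na_mask] <- 0
  d <- stats::dist(x, method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  k_range <- k_range[k_range < nrow(x)]
  sil <- data.frame(k = k_range, avg_width = vapply(k_range, function(kk) {
    cl <- stats::cutree(hc, kk)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1)))
  labels <- stats::cutree(hc, k)
  cent <- rowsum(x, labels) / as.vector(table(labels))
  near_zero <- apply(abs(cent), 1, max) < merge_eps
  merged <- sum(near_zero) >= 2
  grp <- seq_len(nrow(cent))            # old label -> merge group
  if (merged) grp[near_zero] <- which(near_zero)[1]
  ## order groups: most depleted (lowest centroid mean) first, any merged
  ## "unchanged" group last
  groups <- unique(grp)
  gmean <- vapply(groups, function(g)
    mean(cent[grp == g, , drop = FALSE]), numeric(1))
  is_unchanged <- vapply(groups, function(g)
    all(near_zero[grp == g]), logical(1))
  o <- order(is_unchanged, gmean)
  new_of_group <- stats::setNames(seq_along(groups), groups[o])
  labels_out <- as.integer(new_of_group[as.character(grp[labels])])
  names(labels_out) <- rownames(x)
  cent_out <- rowsum(x, labels_out) / as.vector(table(labels_out))
  list(labels = labels_out, k = length(groups), k_cut = k,
       silhouette = sil, centroids = cent_out, merged = merged,
       na_mask = na_mask)
}

#' Build the clustering feature matrix from trajectory tables
#'
#' Concatenates replicate-averaged log2 fold-changes over all conditions and
#' timepoints into one feature vector per guide (the t = 0 anchor point is
#' dropped; it is identically zero).
#'
#' @param trajs list of (or single) trajectory data.frames from
#'   [log2fc_trajectory()].
#' @return numeric matrix, guides x (condition:timepoint) features.
#' @export
trajectory_features <- function(trajs) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  traj <- do.call(rbind, trajs)
  traj <- traj[traj$time_h > 0, , drop = FALSE]
  key <- paste(traj$condition, traj$time_h, sep = ":")
  guides <- unique(traj$guide_id)
  cols <- unique(key)
  m <- matrix(NA_real_, length(guides), length(cols),
              dimnames = list(guides, cols))
  m[cbind(match(traj$guide_id, guides), match(key, cols))] <- traj$log2fc
  m
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster labelings; 1 means identical
#' partitions up to relabelling, 0 the chance level.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
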