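#' Extract the spacer from an amplicon read
#'
#' Returns the sequence following the first exact occurrence of the 5'
#' cassette anchor, truncated at the 3' anchor when present, and capped at
#' `max_len`. Reads lacking the 5' anchor yield `NA` and are tallied as
#' unassigned downstream.
#'
#' @param reads character vector of reads.
#' @param flank5 5' anchor (non-empty).
#' @param flank3 3' anchor; "" disables truncation.
#' @param max_len maximum spacer length returned (default 25).
#' @return character vector (NA where the 5' anchor is absent).
#' @export
extract_spacer <- function(reads, flank5, flank3 = "", max_len = 25L) {
  stopifnot(nzchar(flank5))
  pos <- regexpr(flank5, reads, fixed = TRUE)
  out <- rep(NA_character_, length(reads))
  hit <- pos > 0L
  tail_seq <- substr(reads[hit], pos[hit] + nchar(flank5), nchar(reads[hit]))
  if (nzchar(flank3)) {
    p3 <- regexpr(flank3, tail_seq, fixed = TRUE)
    cut <- ifelse(p3 > 0L, p3 - 1L, nchar(tail_seq))
    tail_seq <- substr(tail_seq, 1L, cut)
  }
  out[hit] <- substr(tail_seq, 1L, max_len)
  out
}

#' Count reads per sgRNA
#'
#' Assigns each read to exactly one guide by exact spacer matching. Mixed
#' spacer lengths are resolved by the longest-match rule: the extracted
#' region is compared against library spacers from the longest length down,
#' so a spacer that is a prefix of another never shadows it. Unmatched and
#' ambiguous reads are tallied per sample; assigned + ambiguous +
#' unassigned = total.
#'
#' @param reads named list of read vectors (one per sample), or a named
#'   character vector of FASTQ paths.
#' @param library `GuideLibrary` or guides data.frame with `guide_id` and
#'   `spacer` columns; spacers must map to a unique guide id.
#' @param flank5,flank3 cassette anchors (defaults match
#'   [simulate_reads()]).
#' @param max_len maximum spacer length.
#' @return list with `counts` (guides x samples integer matrix) and `stats`
#'   (per sample: total, assigned, ambiguous, unassigned, assignment_rate).
#' @export
count_reads <- function(reads, library, flank5 = "GTTTAAGAGC",
                        flank3 = "AGGCTAGTCC", max_len = 25L) {
  g <- if (inherits(library, "GuideLibrary")) library$guides else library
  per_spacer <- tapply(g$guide_id, g$spacer, function(x) length(unique(x)))
  if (any(per_spacer > 1))
    stop("duplicate spacers mapping to different guide ids")
  if (is.character(reads))
    reads <- lapply(reads, read_fastq_seqs)
  dict <- stats::setNames(g$guide_id, g$spacer)
  lens <- sort(unique(nchar(g$spacer)), decreasing = TRUE)
  counts <- matrix(0L, nrow(g), length(reads),
                   dimnames = list(g$guide_id, names(reads)))
  stats_df <- data.frame(sample = names(reads), total = 0L, assigned = 0L,
                         ambiguous = 0L, unassigned = 0L,
                         assignment_rate = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(reads)) {
    sp <- extract_spacer(reads[[k]], flank5, flank3, max_len)
    assigned_id <- rep(NA_character_, length(sp))
    todo <- !is.na(sp)
    for (L in lens) {   # longest match first
      cand <- substr(sp, 1L, L)
      hit <- todo & !is.na(dict[cand])
      assigned_id[hit] <- dict[cand[hit]]
      todo <- todo & !hit
    }
    tab <- table(factor(assigned_id, levels = g$guide_id))
    counts[, k] <- as.integer(tab)
    n_tot <- length(sp)
    n_ass <- sum(!is.na(assigned_id))
    stats_df$total[k] <- n_tot
    stats_df$assigned[k] <- n_ass
    stats_df$unassigned[k] <- n_tot - n_ass
    stats_df$assignment_rate[k] <- if (n_tot > 0) n_ass / n_tot else NA_real_
  }
  list(counts = counts, stats = stats_df)
}

read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write / read count matrices and sample metadata as TSV
#'
#' Count tables have guides as rows (first column `guide_id`) and samples as
#' columns. Metadata tables carry one row per sample.
#'
#' @param counts guides x samples integer matrix.
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  if (any(m < 0, na.rm = TRUE)) stop("negative counts")
  m
}

#' @rdname write_counts
#' @param meta sample metadata data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_sample_meta <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
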