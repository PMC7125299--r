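#' Scan a genome for protospacer sites matching a spacer
#'
#' Finds every genomic site whose PAM-proximal 17 nt are within Hamming
#' distance `max_mismatch` of the spacer's PAM-proximal 17 nt and that is
#' flanked by an NGG or NAG PAM, on either strand. This is the site
#' definition underlying off-target counting: dCas9 binding specificity is
#' dominated by the PAM-proximal ("seed") bases, and NAG is a tolerated
#' alternative PAM. Circular replicons wrap.
#'
#' The fast path delegates the mismatch-tolerant 17-mer search to
#' [Biostrings::matchPattern()] and then verifies PAM adjacency; tests prove
#' it equivalent to a position-by-position brute-force scan.
#'
#' @param spacer spacer sequence, length >= 17 (PAM-proximal end last).
#' @param genome [AnnotatedGenome].
#' @param max_mismatch maximum mismatches in the 17-nt window (default 1,
#'   i.e. "fewer than two").
#' @return data.frame with one row per site: `replicon`, `strand`,
#'   `proto17_start` (0-based plus-strand start of the 17-mer),
#'   `pam_pos` (0-based plus-strand start of the PAM triplet),
#'   `pam` ("NGG"/"NAG"), `mismatches`.
#' @export
scan_sites <- function(spacer, genome, max_mismatch = 1L) {
  spacer <- toupper(spacer)
  stopifnot(nchar(spacer) >= 17L)
  q17 <- substr(spacer, nchar(spacer) - 16L, nchar(spacer))
  out <- vector("list", length(genome$replicons))
  for (ri in seq_along(genome$replicons)) {
    seq_chr <- as.character(genome$replicons[[ri]])
    n <- nchar(seq_chr)
    circ <- genome$circular[ri]
    ext <- if (circ) 19L else 0L
    ## extend both ends so wrap-around sites appear once in linear search
    sub_chr <- if (circ)
      paste0(substr(seq_chr, n - ext + 1L, n), seq_chr, substr(seq_chr, 1L, ext))
    else seq_chr
    sub <- Biostrings::DNAString(sub_chr)
    off <- if (circ) ext else 0L
    rows <- list()

    ## plus strand: 17-mer then PAM triplet to its right
    m <- Biostrings::matchPattern(q17, sub, max.mismatch = max_mismatch)
    if (length(m)) {
      s <- Biostrings::start(m); e <- Biostrings::end(m)
      ok <- e + 3L <= nchar(sub_chr)
      s <- s[ok]; e <- e[ok]
      if (length(s)) {
        b2 <- substring(sub_chr, e + 2L, e + 2L)
        b3 <- substring(sub_chr, e + 3L, e + 3L)
        pam_ok <- b3 == "G" & (b2 == "G" | b2 == "A")
        s <- s[pam_ok]; e <- e[pam_ok]; b2 <- b2[pam_ok]
        if (length(s)) {
          mm <- vapply(seq_along(s), function(i) {
            sum(strsplit(substring(sub_chr, s[i], e[i]), "")[[1]] !=
                  strsplit(q17, "")[[1]])
          }, integer(1))
          rows[[length(rows) + 1L]] <- data.frame(
            replicon = names(genome$replicons)[ri], strand = "+",
            proto17_start = (s - 1L - off) %% max(n, 1L),
            pam_pos = (e - off) %% max(n, 1L),
            pam = ifelse(b2 == "G", "NGG", "NAG"),
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }

    ## minus strand: search revcomp(q17) on plus; PAM triplet sits to the
    ## left of the match (plus bases C C/T N read 5'->3')
    m <- Biostrings::matchPattern(revcomp(q17), sub, max.mismatch = max_mismatch)
    if (length(m)) {
      s <- Biostrings::start(m); e <- Biostrings::end(m)
      ok <- s - 3L >= 1L
      s <- s[ok]; e <- e[ok]
      if (length(s)) {
        c1 <- substring(sub_chr, s - 3L, s - 3L)  # comp of PAM G3
        c2 <- substring(sub_chr, s - 2L, s - 2L)  # comp of PAM base 2
        pam_ok <- c1 == "C" & (c2 == "C" | c2 == "T")
        s <- s[pam_ok]; e <- e[pam_ok]; c2 <- c2[pam_ok]
        if (length(s)) {
          rcq <- strsplit(revcomp(q17), "")[[1]]
          mm <- vapply(seq_along(s), function(i) {
            sum(strsplit(substring(sub_chr, s[i], e[i]), "")[[1]] != rcq)
          }, integer(1))
          rows[[length(rows) + 1L]] <- data.frame(
            replicon = names(genome$replicons)[ri], strand = "-",
            proto17_start = (s - 1L - off) %% max(n, 1L),
            pam_pos = (s - 4L - off) %% max(n, 1L),
            pam = ifelse(c2 == "C", "NGG", "NAG"),
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(replicon = character(), strand = character(),
                 proto17_start = integer(), pam_pos = integer(),
                 pam = character(), mismatches = integer(),
                 stringsAsFactors = FALSE)
    ## extension can report a wrapped site twice; keep one
    df <- df[!duplicated(df[c("strand", "proto17_start", "pam_pos")]), ]
    out[[ri]] <- df
  }
  do.call(rbind, out)
}

#' Count off-target binding sites of a spacer
#'
#' An off-target site has fewer than two mismatches (i.e. 0 or 1) in the
#' PAM-proximal 17 nt of the spacer, next to an NGG or NAG PAM, on either
#' strand of any replicon. The on-target site itself (any site overlapping
#' the on-target protospacer on the same strand, including an overlapping
#' NAG reading) is excluded.
#'
#' @param spacer spacer sequence (length >= 17).
#' @param genome [AnnotatedGenome].
#' @param on_target optional list/row with `replicon`, `strand`,
#'   `protospacer_start`, `protospacer_end` (0-based half-open, plus-strand
#'   coordinates) identifying the intended target; `NULL` counts all sites.
#' @return non-negative integer.
#' @export
count_offtargets <- function(spacer, genome, on_target = NULL) {
  sites <- scan_sites(spacer, genome)
  if (!nrow(sites)) return(0L)
  if (!is.null(on_target)) {
    s17 <- sites$proto17_start
    e17 <- s17 + 17L
    ov <- sites$replicon == on_target$replicon &
      sites$strand == on_target$strand &
      s17 < on_target$protospacer_end &
      e17 > on_target$protospacer_start
    sites <- sites[!ov, ]
  }
  nrow(sites)
}

#' Check spacer composition filters
#'
#' A spacer passes when it has no run of six or more G, no run of four or
#' more T, and a GC content between 25 and 75% (boundaries inclusive).
#' Long G runs impede oligo synthesis and T runs act as Pol III-like
#' terminators; extreme GC correlates with poor sgRNA activity.
#'
#' @param spacer one or more spacer sequences over \{A,C,G,T\}.
#' @return data.frame with columns `spacer`, `ok`, `reason` ("G6", "T4",
#'   "GC", or NA when passing).
#' @export
spacer_composition_ok <- function(spacer) {
  spacer <- toupper(spacer)
  if (any(grepl("[^ACGT]", spacer))) stop("spacer contains non-ACGT characters")
  g6 <- has_run(spacer, "G", 6L)
  t4 <- has_run(spacer, "T", 4L)
  gc <- gc_frac(spacer)
  gc_bad <- gc < 0.25 | gc > 0.75
  reason <- rep(NA_character_, length(spacer))
  reason[gc_bad] <- "GC"
  reason[t4] <- "T4"
  reason[g6] <- "G6"
  data.frame(spacer = spacer, ok = !(g6 | t4 | gc_bad), reason = reason,
             gc = gc, stringsAsFactors = FALSE)
}

default_window_cfg <- function() list(max_tss_dist = 500L, max_gene_fraction = 0.75)

#' Enumerate sgRNA candidates for one gene
#'
#' Scans the strand opposite the gene's coding strand for the pattern
#' 5'-CCN\[20-25 bases ending in T\]-3'. The CC guarantees an NGG PAM on the
#' coding strand and the terminal T means the spacer, read on the coding
#' strand, begins with A — required for efficient transcription of the sgRNA
#' 5' end. Candidates are kept when the PAM-proximal protospacer end lies
#' within `min(max_tss_dist, ceiling(max_gene_fraction * gene length))` nt
#' downstream of the anchor (the annotated TSS when available, otherwise the
#' start codon). When one PAM admits several spacer lengths, the shortest is
#' kept.
#'
#' @param genome [AnnotatedGenome].
#' @param gene a single row of `genome$features` (or a feature id).
#' @param window_cfg list with `max_tss_dist` (default 500) and
#'   `max_gene_fraction` (default 0.75).
#' @return data.frame of candidates: `gene_id`, `spacer`, `replicon`,
#'   `pam_strand`, `protospacer_start`, `protospacer_end` (0-based half-open
#'   plus-strand), `offset_nt`, `gc_fraction`, `length`.
#' @export
enumerate_candidates <- function(genome, gene, window_cfg = default_window_cfg()) {
  if (is.character(gene) && length(gene) == 1L)
    gene <- genome$features[genome$features$id == gene, ]
  if (!nrow(gene)) stop("gene not found")
  gene <- gene[1, ]
  empty <- data.frame(gene_id = character(), spacer = character(),
                      replicon = character(), pam_strand = character(),
                      protospacer_start = integer(), protospacer_end = integer(),
                      offset_nt = integer(), gc_fraction = numeric(),
                      length = integer(), stringsAsFactors = FALSE)
  ri <- match(gene$replicon, names(genome$replicons))
  if (is.na(ri)) { warning("gene ", gene$id, " has no usable anchor/replicon"); return(empty) }
  seq_chr <- as.character(genome$replicons[[ri]])
  n <- nchar(seq_chr)
  circ <- genome$circular[ri]
  glen <- gene$end - gene$start
  maxoff <- min(window_cfg$max_tss_dist,
                ceiling(window_cfg$max_gene_fraction * glen))
  anchor <- if (!is.na(gene$tss)) gene$tss else
    if (gene$strand == "+") gene$start else gene$end - 1L

  ## coding-orientation window: 25 nt upstream of the anchor (so a
  ## protospacer ending at offset 0 fits) .. maxoff + PAM downstream
  if (gene$strand == "+") {
    w_from <- anchor - 25L; w_to <- anchor + maxoff + 4L
    if (!circ) { w_from <- max(w_from, 0L); w_to <- min(w_to, n) }
    W <- substr_circ(seq_chr, w_from, w_to, circ)
    a0 <- anchor - w_from
  } else {
    w_from <- anchor - maxoff - 4L; w_to <- anchor + 26L
    if (!circ) { w_from <- max(w_from, 0L); w_to <- min(w_to, n) }
    W <- revcomp(substr_circ(seq_chr, w_from, w_to, circ))
    a0 <- (w_to - 1L) - anchor
  }
  ch <- strsplit(W, "")[[1]]
  nW <- length(ch)
  best <- list()  # keyed by PAM position within W -> shortest-L candidate
  for (L in 20:25) {
    ## protospacer at i..i+L-1 (0-based within W), PAM at i+L..i+L+2
    imax <- nW - L - 3L
    if (imax < 0L) next
    i <- 0:imax
    ok <- ch[i + 1L] == "A" & ch[i + L + 2L] == "G" & ch[i + L + 3L] == "G"
    for (ii in i[ok]) {
      offset <- ii + L - 1L - a0
      if (offset < 0L || offset > maxoff) next
      key <- as.character(ii + L)  # PAM position within W
      if (!is.null(best[[key]])) next  # shortest L wins (L ascending)
      best[[key]] <- c(ii = ii, L = L)
    }
  }
  if (!length(best)) return(empty)
  rows <- lapply(best, function(b) {
    ii <- b[["ii"]]; L <- b[["L"]]
    spacer <- substr(W, ii + 1L, ii + L)
    if (gene$strand == "+") {
      ps <- (w_from + ii) %% n
      pe <- ps + L
    } else {
      pe_plus <- w_to - ii
      ps <- (pe_plus - L) %% n
      pe <- ps + L
    }
    data.frame(gene_id = gene$id, spacer = spacer, replicon = gene$replicon,
               pam_strand = gene$strand,
               protospacer_start = as.integer(ps),
               protospacer_end = as.integer(pe),
               offset_nt = as.integer(ii + L - 1L - a0),
               gc_fraction = gc_frac(spacer),
               length = as.integer(L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$offset_nt, out$protospacer_start), ]
}

#' Select up to two guides per gene
#'
#' Candidates are ranked by off-target count (ascending), then anchor
#' proximity (`offset_nt` ascending), then genomic position. The top
#' candidate is taken; the second is the next-ranked candidate lying at
#' least `min_separation` nt away (separation between PAM-proximal
#' protospacer ends) among those tying the best remaining off-target count,
#' falling back to the next-ranked candidate overall when none does.
#'
#' @param candidates data.frame as produced by [enumerate_candidates()] with
#'   an `offtarget_count` column.
#' @param min_separation minimum protospacer-start separation (default 10).
#' @return data.frame with 0-2 rows and a `rank` column.
#' @export
select_guides <- function(candidates, min_separation = 10L) {
  if (!nrow(candidates)) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  ord <- order(candidates$offtarget_count, candidates$offset_nt,
               candidates$protospacer_start)
  cand <- candidates[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand$spacer), , drop = FALSE]
  first <- cand[1, , drop = FALSE]
  if (nrow(cand) == 1L) {
    first$rank <- 1L
    rownames(first) <- NULL
    return(first)
  }
  rest <- cand[-1, , drop = FALSE]
  ## spacing is a preference, not a licence to accept more off-targets: only
  ## candidates tying the best remaining off-target count are considered for
  ## the >=10 nt preference
  pool <- rest$offtarget_count == rest$offtarget_count[1]
  ## separation measured between PAM-proximal protospacer ends (offset
  ## differences): invariant under reverse-complementing the genome
  far <- pool & abs(rest$offset_nt - first$offset_nt) >= min_separation
  second <- if (any(far)) rest[which(far)[1], , drop = FALSE] else rest[1, , drop = FALSE]
  out <- rbind(first, second)
  out$rank <- c(1L, 2L)
  rownames(out) <- NULL
  out
}

#' Design a genome-wide sgRNA library
#'
#' Runs the full design per gene: candidate enumeration in the TSS/gene
#' window, composition filtering (G6/T4/GC), off-target counting and
#' two-guide selection. Deterministic for a fixed genome.
#'
#' @param genome [AnnotatedGenome].
#' @param window_cfg see [enumerate_candidates()].
#' @param min_separation see [select_guides()].
#' @return A `GuideLibrary`: list with `guides` (data.frame, one row per
#'   selected guide with a `guide_id` of the form `<gene>_<rank>`) and
#'   `status` (data.frame gene_id, kind, status in \{"two","one","none"\}).
#' @export
design_library <- function(genome, window_cfg = default_window_cfg(),
                           min_separation = 10L) {
  feats <- genome$features
  guide_rows <- list()
  status <- character(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    gene <- feats[i, ]
    cand <- enumerate_candidates(genome, gene, window_cfg)
    if (nrow(cand)) {
      comp <- spacer_composition_ok(cand$spacer)
      cand <- cand[comp$ok, , drop = FALSE]
    }
    if (nrow(cand)) {
      cand$offtarget_count <- vapply(seq_len(nrow(cand)), function(j) {
        count_offtargets(cand$spacer[j], genome, on_target = list(
          replicon = cand$replicon[j], strand = cand$pam_strand[j],
          protospacer_start = cand$protospacer_start[j],
          protospacer_end = cand$protospacer_end[j]))
      }, integer(1))
      sel <- select_guides(cand, min_separation)
    } else {
      sel <- cand
      sel$offtarget_count <- integer(0)
      sel$rank <- integer(0)
    }
    status[i] <- c("none", "one", "two")[nrow(sel) + 1L]
    if (nrow(sel)) {
      sel$guide_id <- sprintf("%s_%d", sel$gene_id, sel$rank)
      guide_rows[[length(guide_rows) + 1L]] <- sel
    }
  }
  guides <- if (length(guide_rows)) do.call(rbind, guide_rows) else
    data.frame()
  rownames(guides) <- NULL
  structure(list(
    guides = guides,
    status = data.frame(gene_id = feats$id, kind = feats$kind,
                        status = status, stringsAsFactors = FALSE)),
    class = "GuideLibrary")
}

#' @export
print.GuideLibrary <- function(x, ...) {
  cat("GuideLibrary:", nrow(x$guides), "guides for",
      sum(x$status$status != "none"), "of", nrow(x$status), "genes\n")
  invisible(x)
}

#' Library composition totals
#'
#' Given the number of genes designed with two guides or one guide, split by
#' feature class, returns library totals: two-guide genes contribute two
#' sgRNAs each, one-guide genes one.
#'
#' @param two_ORF,two_ncRNA number of ORFs / ncRNAs with two sgRNAs.
#' @param one_ORF,one_ncRNA number of ORFs / ncRNAs with one sgRNA.
#' @return list with `total_sgRNAs`, `ORF_sgRNAs`, `ncRNA_sgRNAs`.
#' @examples
#' composition_summary(3526, 1555, 20, 316)$total_sgRNAs  # 10498
#' @export
composition_summary <- function(two_ORF, two_ncRNA, one_ORF, one_ncRNA) {
  stopifnot(two_ORF >= 0, two_ncRNA >= 0, one_ORF >= 0, one_ncRNA >= 0)
  list(total_sgRNAs = 2 * two_ORF + 2 * two_ncRNA + one_ORF + one_ncRNA,
       ORF_sgRNAs = 2 * two_ORF + one_ORF,
       ncRNA_sgRNAs = 2 * two_ncRNA + one_ncRNA)
}

#' Write a guide library to TSV
#' @param library `GuideLibrary` or its `guides` data.frame.
#' @param path output path.
#' @export
write_library <- function(library, path) {
  g <- if (inherits(library, "GuideLibrary")) library$guides else library
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guide library from TSV
#' @param path TSV written by [write_library()] (columns `guide_id`,
#'   `gene_id`, `spacer` at minimum).
#' @return data.frame of guides.
#' @export
read_library <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  per_spacer <- tapply(g$guide_id, g$spacer, function(x) length(unique(x)))
  if (any(per_spacer > 1))
    stop("duplicate spacers mapping to different guide ids")
  g
}
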