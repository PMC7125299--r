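# Independent brute-force oracles and shared fixtures.

# Position-by-position scan for sites whose PAM-proximal 17-mer is within
# `max_mm` mismatches of the spacer's, flanked by NGG/NAG. Works on plain
# character vectors; independent of the Biostrings-based fast path.
oracle_scan <- function(spacer, genome, max_mm = 1L) {
  q <- strsplit(toupper(substr(spacer, nchar(spacer) - 16L, nchar(spacer))),
                "")[[1]]
  res <- list()
  for (ri in seq_along(genome$replicons)) {
    seq_chr <- as.character(genome$replicons[[ri]])
    n <- nchar(seq_chr)
    circ <- genome$circular[ri]
    scan_one <- function(s) {
      v <- strsplit(s, "")[[1]]
      if (circ) v <- c(v, v[1:19])
      n_start <- length(v) - 19L
      if (n_start < 1L)
        return(data.frame(start0 = integer(0), mm = integer(0),
                          pam = character(0)))
      mm <- rep(0L, n_start)
      for (o in 0:16) mm <- mm + (v[(1:n_start) + o] != q[o + 1L])
      pam2 <- v[(1:n_start) + 17L + 1L]
      pam3 <- v[(1:n_start) + 17L + 2L]
      hits <- which(mm <= max_mm & pam3 == "G" & (pam2 == "G" | pam2 == "A"))
      data.frame(start0 = hits - 1L, mm = mm[hits],
                 pam = ifelse(pam2[hits] == "G", "NGG", "NAG"))
    }
    parts <- list()
    plus <- scan_one(seq_chr)
    if (nrow(plus)) {
      plus$strand <- "+"
      plus$proto17_start <- plus$start0 %% n
      parts$plus <- plus
    }
    rcs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq_chr)))
    minus <- scan_one(rcs)
    if (nrow(minus)) {
      minus$strand <- "-"
      # rc-coordinate b maps back to plus-strand 17-mer start n - b - 17
      minus$proto17_start <- (n - (minus$start0 %% n) - 17L) %% n
      parts$minus <- minus
    }
    df <- if (length(parts)) do.call(rbind, parts) else plus
    if (nrow(df)) {
      df$replicon <- names(genome$replicons)[ri]
      df <- df[!duplicated(df[c("strand", "proto17_start")]), ]
      res[[length(res) + 1L]] <- df[c("replicon", "strand", "proto17_start",
                                      "pam", "mm")]
    }
  }
  if (!length(res))
    return(data.frame(replicon = character(), strand = character(),
                      proto17_start = integer(), pam = character(),
                      mm = integer()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

site_keys <- function(df) {
  sort(paste(df$replicon, df$strand, df$proto17_start, df$pam, sep = ":"))
}

# brute-force Benjamini-Hochberg
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# archetype trajectory matrix: 5 depletion patterns over 3 conditions x 5
# timepoints, emulating fast / steady / condition-dependent / slow /
# unchanged washout classes
archetypes5 <- function() {
  lin <- function(end) seq(end / 5, end, length.out = 5)
  rbind(rep(c(-4, -7, -8, -8, -8), 3),
        c(lin(-8), lin(-8), lin(-8)),
        c(lin(-8), lin(-3), lin(-5)),
        c(lin(-2), lin(-1.5), lin(-2)),
        rep(0, 15))
}

make_cluster_fixture <- function(seed, copies = 100, sigma = 0.5,
                                 extra_flat = FALSE) {
  arch <- archetypes5()
  truth <- rep(seq_len(nrow(arch)), each = copies)
  if (extra_flat) {
    arch <- rbind(arch, rep(0.3, 15))
    truth <- c(truth, rep(5L, copies))  # same truth class as "unchanged"
  }
  set.seed(seed)
  X <- arch[rep(seq_len(nrow(arch)), each = copies), ] +
    matrix(stats::rnorm(nrow(arch) * copies * 15, 0, sigma),
           nrow(arch) * copies)
  rownames(X) <- sprintf("g%04d", seq_len(nrow(X)))
  list(x = X, truth = truth)
}

# small linear genome fixture with a single gene whose upstream region is
# fully controlled (for hand-checked candidate enumeration)
hand_genome <- function(seq_chr, gene_start, gene_end, strand = "+",
                        tss = NA_integer_) {
  AnnotatedGenome(
    stats::setNames(Biostrings::DNAStringSet(seq_chr), "chr"),
    data.frame(id = "gene1", kind = "ORF", replicon = "chr", strand = strand,
               start = gene_start, end = gene_end, tss = tss,
               stringsAsFactors = FALSE),
    circular = FALSE)
}
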