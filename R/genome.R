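#' Annotated genome container
#'
#' An `AnnotatedGenome` bundles one or more replicon sequences with a gene
#' feature table. Coordinates are 0-based half-open internally; the GFF3
#' reader/writer converts to and from the 1-based inclusive convention.
#'
#' @param replicons named [Biostrings::DNAStringSet] (or named character
#'   vector) of replicon sequences over \{A,C,G,T\}.
#' @param features data.frame with columns `id`, `kind` ("ORF" or "ncRNA"),
#'   `replicon`, `strand` ("+"/"-"), `start`, `end` (0-based half-open) and
#'   optional `tss` (0-based position of the transcription start site, `NA`
#'   when unknown).
#' @param circular logical, one value per replicon; circular replicons wrap
#'   in pattern and off-target scans.
#' @return An object of class `AnnotatedGenome`.
#' @export
AnnotatedGenome <- function(replicons, features, circular = TRUE) {
  if (is.character(replicons)) replicons <- Biostrings::DNAStringSet(replicons)
  stopifnot(methods::is(replicons, "DNAStringSet"), !is.null(names(replicons)))
  features <- as.data.frame(features)
  req <- c("id", "kind", "replicon", "strand", "start", "end")
  if (!all(req %in% names(features)))
    stop("features must have columns: ", paste(req, collapse = ", "))
  if (!"tss" %in% names(features)) features$tss <- NA_integer_
  if (anyDuplicated(features$id)) stop("duplicate feature ids")
  if (!all(features$replicon %in% names(replicons)))
    stop("feature replicon not found among sequences")
  lens <- stats::setNames(Biostrings::width(replicons), names(replicons))
  bad <- features$start < 0 | features$end > lens[features$replicon] |
    features$start >= features$end
  if (any(bad)) stop("feature bounds outside replicon: ",
                     paste(features$id[bad], collapse = ", "))
  structure(
    list(replicons = replicons,
         features = features,
         circular = rep_len(circular, length(replicons))),
    class = "AnnotatedGenome")
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat("AnnotatedGenome:", length(x$replicons), "replicon(s),",
      sum(Biostrings::width(x$replicons)), "nt,",
      nrow(x$features), "feature(s)\n")
  invisible(x)
}

## character sequence of one replicon (plus strand)
replicon_seq <- function(genome, replicon = 1L) {
  as.character(genome$replicons[[replicon]])
}

#' Simulate a random annotated genome
#'
#' Generates a circular replicon of random sequence at a target GC content
#' and packs `n_genes` non-overlapping gene features onto both strands.
#' Each gene receives a transcription start site (TSS) at or upstream of its
#' start codon. Output is deterministic for a fixed seed.
#'
#' @param seed integer RNG seed.
#' @param length_nt replicon length in nucleotides.
#' @param n_genes number of gene features to place.
#' @param gc_fraction target GC content in (0, 1).
#' @param ncrna_fraction fraction of features annotated as ncRNA rather than
#'   ORF (default 0.2, roughly the design-relevant mix in cyanobacterial
#'   genome annotations).
#' @param tss_fraction fraction of genes with an annotated TSS (default 0.8);
#'   the rest anchor designs at the start codon.
#' @return An [AnnotatedGenome].
#' @examples
#' g <- make_genome(seed = 1, length_nt = 20000, n_genes = 15, gc_fraction = 0.48)
#' @export
make_genome <- function(seed, length_nt, n_genes, gc_fraction,
                        ncrna_fraction = 0.2, tss_fraction = 0.8) {
  stopifnot(length_nt > 0, n_genes > 0, gc_fraction > 0, gc_fraction < 1)
  if (n_genes * 300 > length_nt)
    stop("infeasible packing: need at least 300 nt per gene (",
         n_genes * 300, " > ", length_nt, ")")
  set.seed(seed)
  base_p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
              G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq_chr <- paste(sample(names(base_p), length_nt, replace = TRUE,
                          prob = base_p), collapse = "")

  ## pack genes left-to-right with random lengths and random spare gaps
  max_len <- max(300L, min(1500L, floor(length_nt / n_genes) - 60L))
  glen <- sample(300:max_len, n_genes, replace = TRUE)
  spare <- length_nt - sum(glen) - 100L * n_genes  # >=100 nt fixed gap
  if (spare < 0) { # shrink towards the minimum to fit
    glen <- rep(300L, n_genes)
    spare <- length_nt - sum(glen) - 100L * n_genes
    if (spare < 0) stop("infeasible packing after shrink")
  }
  extra <- as.integer(stats::rmultinom(1, spare, rep(1, n_genes + 1)))
  starts <- integer(n_genes)
  pos <- extra[1]
  for (i in seq_len(n_genes)) {
    starts[i] <- pos
    pos <- pos + glen[i] + 100L + extra[i + 1L]
  }
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  kind <- ifelse(stats::runif(n_genes) < ncrna_fraction, "ncRNA", "ORF")
  has_tss <- stats::runif(n_genes) < tss_fraction
  tss_off <- sample(0:60, n_genes, replace = TRUE)
  tss <- ifelse(strand == "+", starts - tss_off, starts + glen - 1L + tss_off)
  tss[tss < 0 | tss >= length_nt] <- NA_integer_
  tss[!has_tss] <- NA_integer_
  features <- data.frame(
    id = sprintf("g%04d", seq_len(n_genes)),
    kind = kind,
    replicon = "synthetic_1",
    strand = strand,
    start = starts,
    end = starts + glen,
    tss = as.integer(tss),
    stringsAsFactors = FALSE)
  reps <- Biostrings::DNAStringSet(c(synthetic_1 = seq_chr))
  AnnotatedGenome(reps, features, circular = TRUE)
}

random_spacer <- function(n = 20L) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant a (near-)matching protospacer site into a genome
#'
#' Edits the genome sequence so that a copy of `spacer` (with a requested
#' number of mismatches confined to the PAM-proximal 17-nt window) followed
#' by the requested PAM exists at `position` on `strand`. Used to construct
#' ground-truth fixtures for off-target counting: sites with 0 or 1 mismatch
#' in the PAM-proximal 17 nt are counted as off-targets, sites with 2 or
#' more are not.
#'
#' If the edit would accidentally create additional matching sites (or
#' destroy existing ones), mismatch placement is re-randomized up to
#' `retries` times, then an error is raised.
#'
#' @param genome [AnnotatedGenome].
#' @param spacer spacer sequence (5'->3', PAM-distal to PAM-proximal).
#' @param mismatches number of mismatches to place in the PAM-proximal
#'   17-nt window.
#' @param pam "NGG" or "NAG".
#' @param strand "+" or "-": the strand carrying the protospacer + PAM.
#' @param position 0-based plus-strand start of the edited block.
#' @param seed integer seed for mismatch placement.
#' @param replicon replicon name or index (default first).
#' @param retries re-randomization attempts (default 20).
#' @return The edited [AnnotatedGenome].
#' @export
plant_site <- function(genome, spacer, mismatches = 0L, pam = c("NGG", "NAG"),
                       strand = c("+", "-"), position, seed = 1L,
                       replicon = 1L, retries = 20L) {
  pam <- match.arg(pam)
  strand <- match.arg(strand)
  spacer <- toupper(spacer)
  L <- nchar(spacer)
  stopifnot(L >= 17L, mismatches <= L)
  seq_chr <- replicon_seq(genome, replicon)
  n <- nchar(seq_chr)
  block_len <- L + 3L
  if (position < 0 || position + block_len > n)
    stop("position leaves no room for protospacer + PAM")
  rep_name <- if (is.numeric(replicon)) names(genome$replicons)[replicon] else replicon

  before <- nrow(scan_sites(spacer, genome))
  expect_hit <- if (mismatches <= 1L) 1L else 0L
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(retries)) {
    sp <- strsplit(spacer, "")[[1]]
    if (mismatches > 0L) {
      win <- (L - 16L):L  # PAM-proximal 17-nt window
      at <- sample(win, mismatches)
      for (i in at) sp[i] <- sample(setdiff(bases, sp[i]), 1L)
    }
    pam_seq <- c(sample(bases, 1L), if (pam == "NGG") "G" else "A", "G")
    site <- paste(c(sp, pam_seq), collapse = "")
    if (strand == "-") site <- revcomp(site)
    cand <- paste0(substr(seq_chr, 1L, position),
                   site,
                   substr(seq_chr, position + block_len + 1L, n))
    g2 <- genome
    reps <- as.character(g2$replicons)
    reps[[rep_name]] <- cand
    g2$replicons <- Biostrings::DNAStringSet(reps)
    after <- nrow(scan_sites(spacer, g2))
    if (after == before + expect_hit) return(g2)
  }
  stop("plant_site: could not place site without disturbing existing matches")
}

#' Write an annotated genome to FASTA + GFF3
#'
#' @param genome [AnnotatedGenome].
#' @param fasta,gff output paths. GFF3 coordinates are 1-based inclusive.
#' @return invisibly, the paths.
#' @export
write_genome <- function(genome, fasta, gff) {
  Biostrings::writeXStringSet(genome$replicons, fasta)
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$replicon,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$ID <- f$id
  S4Vectors::mcols(gr)$type <- ifelse(f$kind == "ORF", "gene", "ncRNA")
  S4Vectors::mcols(gr)$kind <- f$kind
  S4Vectors::mcols(gr)$tss <- ifelse(is.na(f$tss), NA_integer_, f$tss + 1L)
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta = fasta, gff = gff))
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Features of type `gene`, `CDS`, `ORF` are read as ORFs; `ncRNA` (and any
#' `*RNA` type) as ncRNAs. An integer `tss` attribute, when present, is
#' interpreted as a 1-based TSS position.
#'
#' @param fasta,gff input paths.
#' @param circular logical; whether replicons wrap (default TRUE).
#' @return An [AnnotatedGenome].
#' @export
read_genome <- function(fasta, gff, circular = TRUE) {
  reps <- Biostrings::readDNAStringSet(fasta)
  names(reps) <- sub("\\s.*$", "", names(reps))
  gr <- rtracklayer::import(gff, format = "gff3")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  keep <- type %in% c("gene", "CDS", "ORF") | grepl("RNA$", type)
  gr <- gr[keep]; m <- S4Vectors::mcols(gr)
  kind <- if (!is.null(m$kind)) as.character(m$kind) else
    ifelse(as.character(m$type) %in% c("gene", "CDS", "ORF"), "ORF", "ncRNA")
  id <- if (!is.null(m$ID)) as.character(m$ID) else
    sprintf("feat%05d", seq_along(gr))
  tss <- if (!is.null(m$tss)) suppressWarnings(as.integer(m$tss)) - 1L
         else rep(NA_integer_, length(gr))
  features <- data.frame(
    id = id, kind = kind,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    tss = tss,
    stringsAsFactors = FALSE)
  AnnotatedGenome(reps, features, circular = circular)
}
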