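## small sequence helpers shared across modules

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## 0-based half-open substring with optional circular wrap-around.
## `from` may be negative and `to` may exceed nchar(seq) when circular.
substr_circ <- function(seq, from, to, circular = TRUE) {
  n <- nchar(seq)
  if (!circular) {
    from <- max(from, 0L); to <- min(to, n)
    if (from >= to) return("")
    return(substr(seq, from + 1L, to))
  }
  idx <- ((from:(to - 1L)) %% n) + 1L
  paste(strsplit(seq, "")[[1]][idx], collapse = "")
}

gc_frac <- function(x) {
  v <- strsplit(toupper(x), "")
  vapply(v, function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

has_run <- function(x, base, len) {
  grepl(strrep(base, len), x, fixed = TRUE)
}
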