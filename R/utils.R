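# Shared internal helpers.  Coordinates are 0-based half-open everywhere in
# this package; conversion to 1-based happens only at FASTA/SAM/BED
# boundaries, following each format's own convention.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0

assert_count <- function(x, name, min = 0) {
  if (!is_count(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_fraction <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1)))
    stopf("`%s` must be a fraction %s", name, if (open) "in (0,1)" else "in [0,1]")
  as.numeric(x)
}

# Vectorized reverse complement for plain character DNA.
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substring extraction on 0-based half-open intervals.
seq_extract <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

gc_fraction <- function(x) {
  dna <- Biostrings::DNAStringSet(x)
  acgt <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T"))
  tot <- rowSums(acgt)
  ifelse(tot == 0, NA_real_, (acgt[, "C"] + acgt[, "G"]) / tot)
}
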