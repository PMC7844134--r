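## Small shared helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

.pkg_cache <- new.env(parent = emptyenv())

## BLOSUM62 from Biostrings, cached.
blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

## The 20 standard amino acids, in BLOSUM62 row order.
.std_aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Robinson & Robinson style background amino-acid frequencies.
.aa_freq <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
              E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
              M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
              Y = 2.92, V = 6.87) / 100

## Replace residues outside the BLOSUM62 alphabet by X (scored as weak
## mismatch), with a warning naming the offending residues.
sanitize_protein <- function(protein, locus_tag = NULL) {
  ok <- rownames(blosum62())
  chars <- strsplit(protein, "")[[1]]
  bad <- !(chars %in% ok)
  if (any(bad)) {
    warning("non-standard residues ",
            paste(unique(chars[bad]), collapse = ""),
            if (!is.null(locus_tag)) paste0(" in ", locus_tag),
            "; treated as X (mismatch)")
    chars[bad] <- "X"
    protein <- paste(chars, collapse = "")
  }
  protein
}

random_protein <- function(n) {
  paste(sample(.std_aa, n, replace = TRUE, prob = .aa_freq), collapse = "")
}

## Standard bacterial (table 11) codon table, stops excluded.
codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    gc <- gc[gc != "*"]
    .pkg_cache$codons <- split(names(gc), gc)
  }
  .pkg_cache$codons
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647
}
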