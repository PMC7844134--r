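## Independent oracles and tiny fixture builders used across the suite.
## Every oracle here is a brute-force or closed-form computation kept
## deliberately separate from the package's implementation path.

## Brute-force unsigned breakpoint count between two orderings of the
## same element set: adjacencies (unordered pairs) of `a` not present in
## `b`, counted by exhaustive pair scan.
oracle_breakpoints <- function(a, b) {
  n <- 0L
  if (length(a) < 2) return(0L)
  for (i in seq_len(length(a) - 1)) {
    x <- a[i]; y <- a[i + 1]
    adjacent_in_b <- FALSE
    for (j in seq_len(length(b) - 1))
      if ((b[j] == x && b[j + 1] == y) || (b[j] == y && b[j + 1] == x))
        adjacent_in_b <- TRUE
    if (!adjacent_in_b) n <- n + 1L
  }
  n
}

## Exhaustive architecture distance oracle on signatures with unique
## block names: breakpoints + orientation mismatches + symmetric
## difference, computed from first principles.
oracle_architecture_distance <- function(a, b) {
  na <- a$blocks$name; nb <- b$blocks$name
  shared <- intersect(na, nb)
  uniq <- length(setdiff(na, nb)) + length(setdiff(nb, na))
  oa <- na[na %in% shared]; ob <- nb[nb %in% shared]
  bp <- oracle_breakpoints(oa, ob)
  flips <- 0L
  for (s in shared)
    if (a$blocks$orientation[match(s, na)] !=
        b$blocks$orientation[match(s, nb)]) flips <- flips + 1L
  bp + flips + uniq
}

## Brute-force maximal-run segmentation over a label sequence: a new
## block starts whenever the label changes or the label is not in
## `mergeable`.
oracle_runs <- function(labels, mergeable) {
  if (!length(labels)) return(character(0))
  out <- labels[1]
  for (k in seq_along(labels)[-1]) {
    if (!(labels[k] == labels[k - 1] && labels[k] %in% mergeable))
      out <- c(out, labels[k])
  }
  out
}

## Closed-form identity for equal-length, indel-free protein pairs
## (the simulator's regime): per-position match fraction.
oracle_hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

random_aa_seq <- function(n) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

## Tiny hand-built genome: `genes` is a data.frame with start, end,
## strand, locus_tag, protein (optional).
tiny_genome <- function(genes, contig_len = max(genes$end) + 50L,
                        circular = FALSE, genome_id = "tiny",
                        seq = NULL, completeness = NA_real_) {
  contigs <- data.frame(id = "c1", length = contig_len,
                        circular = circular, stringsAsFactors = FALSE)
  genes$contig_id <- "c1"
  if (is.null(genes$symbol)) genes$symbol <- NA_character_
  if (is.null(genes$protein)) genes$protein <- NA_character_
  annotated_genome(genome_id, contigs, genes, seq = seq,
                   completeness = completeness)
}

## A fast simulation spec used when the scenario does not need large
## backgrounds (keeps alignment work small).
quick_spec <- function(seed, ...) {
  simulation_spec(seed = seed, n_background_genes = 4,
                  background_length_range = c(150, 300), ...)
}

## Mutate a protein to an approximate target identity with uniform
## random substitutions (independent of the package's BLOSUM-weighted
## mutator); used to build queries of known divergence.
mutate_uniform <- function(protein, target) {
  chars <- strsplit(protein, "")[[1]]
  L <- length(chars)
  nsub <- round((1 - target) * L)
  pos <- sample.int(L, nsub)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (p in pos) chars[p] <- sample(setdiff(aas, chars[p]), 1)
  paste(chars, collapse = "")
}
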