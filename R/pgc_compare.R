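## Pairwise PGC comparison: per-family protein identity (with the strict
## >90% high-identity flag) and nucleotide synteny blocks under the two
## cutoff dialects (PGC scale: id > 70%, length > 500 bp; genome scale:
## id > 80%, length > 2 kb).

#' Global protein identity with terminal gaps trimmed
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11 / extend 1);
#' identity = matches / alignment columns * 100, where columns lying in a
#' terminal gap of either sequence are trimmed and internal gap columns
#' count in the denominator (BLAST-style reporting).
#'
#' @param a,b Protein sequences (character).
#' @return List with `identity` (percent) and `aligned_length` (columns).
#' @export
global_protein_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
  pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  rp <- range(which(pc != "-")); rs <- range(which(sc != "-"))
  lo <- max(rp[1], rs[1]); hi <- min(rp[2], rs[2])
  if (lo > hi) return(list(identity = 0, aligned_length = 0L))
  cols <- lo:hi
  matches <- sum(pc[cols] == sc[cols] & pc[cols] != "-")
  list(identity = 100 * matches / length(cols),
       aligned_length = length(cols))
}

.member_protein <- function(cand, fam) {
  mem <- cand$members[cand$members$family == fam, , drop = FALSE]
  if (!nrow(mem)) return(NA_character_)
  if (nrow(mem) > 1 && any(mem$split)) {
    ## split fragments, in chain order, approximate the full gene
    paste(mem$protein[!is.na(mem$protein)], collapse = "")
  } else mem$protein[1]
}

#' Per-family protein identity between two PGCs
#'
#' For every family present in both clusters, computes the global-alignment
#' identity (terminal gaps trimmed) and flags pairs exceeding 90% identity
#' (strictly: exactly 90.0 is not flagged).  Families present in only one
#' cluster are reported in the `unpaired` attribute.
#'
#' @param pgc_a,pgc_b `pgc_candidate` objects carrying protein sequences.
#' @return data.frame of class `gene_pair_identity` with columns `family`,
#'   `identity`, `aligned_length`, `high_identity`; attribute `unpaired`
#'   is a list with the families unique to each cluster.
#' @export
pairwise_gene_identity <- function(pgc_a, pgc_b) {
  fa <- unique(pgc_a$members$family)
  fb <- unique(pgc_b$members$family)
  shared <- intersect(fa, fb)
  rows <- lapply(shared, function(f) {
    pa <- .member_protein(pgc_a, f); pb <- .member_protein(pgc_b, f)
    if (is.na(pa) || is.na(pb) || !nzchar(pa) || !nzchar(pb)) return(NULL)
    r <- global_protein_identity(pa, pb)
    data.frame(family = f, identity = r$identity,
               aligned_length = r$aligned_length,
               high_identity = r$identity > 90,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family = character(), identity = numeric(),
                      aligned_length = integer(),
                      high_identity = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_pair_identity", "data.frame")
  attr(out, "unpaired") <- list(a_only = setdiff(fa, fb),
                                b_only = setdiff(fb, fa))
  out
}

## ---- nucleotide synteny blocks ------------------------------------------

.dialects <- list(pgc = c(min_identity = 70, min_length = 500),
                  genome = c(min_identity = 80, min_length = 2000))

.kmer_starts <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(setNames(character(0), integer(0)))
  substring(s, 1:(n - k + 1), k:n)
}

## Exact k-mer anchoring on one strand: shared k-mers grouped by diagonal,
## chained into runs, extended outward by exact match.  No indels are
## modelled within a block; near-diagonal variation surfaces as separate
## blocks (adequate at desk scale; the simulator introduces no indels by
## default).
.blocks_one_strand <- function(a, b, k, max_anchor_gap, max_occ = 10L) {
  ka <- .kmer_starts(a, k)
  kb <- .kmer_starts(b, k)
  valid_a <- !grepl("N", ka, fixed = TRUE)
  pos_by_kmer <- split(which(valid_a), ka[valid_a])
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) <= max_occ]
  hitlist <- pos_by_kmer[kb]
  nb <- lengths(hitlist); nb[is.na(names(hitlist))] <- 0L
  j <- rep(seq_along(kb), nb)
  i <- unlist(hitlist, use.names = FALSE)
  if (!length(i)) return(NULL)
  d <- i - j
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- nchar(a); nbl <- nchar(b)
  res <- list()
  for (dd in unique(d)) {
    ii <- sort(i[d == dd])
    run <- cumsum(c(1, diff(ii) > max_anchor_gap))
    for (r in unique(run)) {
      s <- min(ii[run == r]); e <- max(ii[run == r]) + k - 1L
      ## extend outward while bases match exactly
      while (s > 1 && (s - dd) > 1 && av[s - 1] == bv[s - dd - 1]) s <- s - 1
      while (e < na && (e - dd) < nbl && av[e + 1] == bv[e - dd + 1]) e <- e + 1
      span <- s:e
      idn <- 100 * mean(av[span] == bv[span - dd])
      res[[length(res) + 1L]] <- data.frame(
        a_start = s, a_end = e, b_start = s - dd, b_end = e - dd,
        length = e - s + 1L, identity = idn, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Find conserved synteny blocks between two nucleotide sequences
#'
#' Deterministic k-mer-anchored block finding: exact 11-mer matches are
#' grouped by diagonal, chained, extended, and scored by per-base
#' identity; inverted matches are found on the reverse complement of
#' `seq_b`.  Blocks overlapping on `seq_a` are resolved greedily in favour
#' of the higher-scoring block.  Cutoffs are strict (`>`), following the
#' two reporting dialects: `pgc` (identity > 70%, length > 500 bp) for
#' cluster-scale comparisons and `genome` (identity > 80%, length > 2 kb)
#' for genome-scale ones.
#'
#' @param seq_a,seq_b Nucleotide sequences (character or
#'   [Biostrings::DNAString]), alphabet A/C/G/T/N.
#' @param dialect `"pgc"` or `"genome"`; ignored when `min_identity` and
#'   `min_length` are given explicitly.
#' @param min_identity,min_length Explicit cutoffs (percent, bp).
#' @param k Anchor k-mer size; default 11.
#' @param max_anchor_gap Maximum distance between chained anchors on one
#'   diagonal; default 200 bp.
#' @return data.frame of class `synteny_blocks`: `a_start`, `a_end`,
#'   `b_start`, `b_end` (1-based inclusive), `length`, `identity`,
#'   `orientation` (`same`/`inverted`).
#' @export
synteny_blocks <- function(seq_a, seq_b, dialect = c("pgc", "genome"),
                           min_identity = NULL, min_length = NULL,
                           k = 11, max_anchor_gap = 200) {
  dialect <- match.arg(dialect)
  cut <- .dialects[[dialect]]
  min_identity <- min_identity %||% cut[["min_identity"]]
  min_length <- min_length %||% cut[["min_length"]]
  a <- toupper(as.character(seq_a)); b <- toupper(as.character(seq_b))
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      length = integer(), identity = numeric(),
                      orientation = character(), stringsAsFactors = FALSE)
  class(empty) <- c("synteny_blocks", "data.frame")
  if (!nzchar(a) || !nzchar(b)) return(empty)
  if (grepl("[^ACGTN]", a) || grepl("[^ACGTN]", b))
    stop("sequences must be over the A/C/G/T/N alphabet")

  fwd <- .blocks_one_strand(a, b, k, max_anchor_gap)
  if (!is.null(fwd) && nrow(fwd)) fwd$orientation <- "same"
  brc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(b)))
  rev <- .blocks_one_strand(a, brc, k, max_anchor_gap)
  if (!is.null(rev) && nrow(rev)) {
    nb <- nchar(b)
    ## map coordinates on the reverse complement back to seq_b
    b_start <- nb - rev$b_end + 1L
    b_end <- nb - rev$b_start + 1L
    rev$b_start <- b_start; rev$b_end <- b_end
    rev$orientation <- "inverted"
  }
  blocks <- rbind(fwd, rev)
  if (is.null(blocks) || !nrow(blocks)) return(empty)

  ## strict dialect cutoffs
  blocks <- blocks[blocks$identity > min_identity &
                     blocks$length > min_length, , drop = FALSE]
  if (!nrow(blocks)) return(empty)

  ## greedy non-overlap on seq_a, best (identity * length) first
  blocks <- blocks[order(-(blocks$identity * blocks$length)), , drop = FALSE]
  keep <- logical(nrow(blocks))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$a_start[i]; e <- blocks$a_end[i]
    if (!any(s <= occ_e & e >= occ_s)) {
      keep[i] <- TRUE
      occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
    }
  }
  blocks <- blocks[keep, , drop = FALSE]
  blocks <- blocks[order(blocks$a_start), , drop = FALSE]
  rownames(blocks) <- NULL
  class(blocks) <- c("synteny_blocks", "data.frame")
  blocks
}
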