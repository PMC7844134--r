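## Protein family assignment by local alignment (Smith-Waterman, BLOSUM62,
## gap open 11 / extend 1) with BLAST-like Karlin-Altschul E-values.
##
## The significance/coverage rule is: a homolog call requires
## E < E_max (default 1e-5) and alignment coverage of the reference
## protein > C_min (default 0.40).

## Gapped Karlin-Altschul parameters for BLOSUM62 with gap open 11 /
## extend 1 (the standard protein-BLAST parameter set).
.ka_lambda <- 0.267
.ka_K <- 0.041

#' Bit score and E-value from a raw local-alignment score
#'
#' Karlin-Altschul statistics with the standard gapped BLOSUM62 (11/1)
#' parameters: `bits = (lambda * S - ln K) / ln 2`,
#' `E = m * n * 2^(-bits)` with search space `m * n` = query length times
#' total reference length.
#'
#' @param score Raw alignment score(s).
#' @param m Query length (residues).
#' @param n Total reference set length (residues).
#' @return data.frame with `bit_score` and `evalue`.
#' @export
ka_statistics <- function(score, m, n) {
  bits <- (.ka_lambda * score - log(.ka_K)) / log(2)
  data.frame(bit_score = bits, evalue = m * n * 2^(-bits))
}

#' Search thresholds for family assignment
#'
#' @param E_max Maximum E-value (exclusive); default `1e-5`.
#' @param C_min Minimum fraction of the reference protein covered by the
#'   alignment (exclusive); default `0.40`.
#' @param split_gap Maximum genomic gap (bp) between two same-family
#'   fragments on one contig for them to be merged as a split gene;
#'   default 3000.
#' @return A `search_thresholds` list.
#' @export
search_thresholds <- function(E_max = 1e-5, C_min = 0.40, split_gap = 3000) {
  stopifnot(E_max > 0, C_min > 0, C_min < 1, split_gap > 0)
  structure(list(E_max = E_max, C_min = C_min, split_gap = split_gap),
            class = "search_thresholds")
}

## Align one query protein against the full reference set; returns scores
## for all references plus coverage/identity for the requested indices.
.align_query <- function(protein, refs) {
  subj <- Biostrings::AAString(protein)
  Biostrings::pairwiseAlignment(
    pattern = refs, subject = subj, type = "local",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
}

.align_details <- function(protein, ref) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = ref, subject = Biostrings::AAString(protein), type = "local",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1)
  pat <- as.character(Biostrings::alignedPattern(aln))
  cov <- sum(strsplit(pat, "")[[1]] != "-") / Biostrings::width(ref)
  list(score = Biostrings::score(aln),
       coverage = cov,
       identity = Biostrings::pid(aln, type = "PID1"))
}

#' Assign proteins to photosynthesis-related gene families
#'
#' Searches every protein-bearing feature of `genome` against the family
#' reference set by local alignment and keeps, per locus, the best family
#' by bit score (ties broken by identity, then lexicographic family name).
#' A call requires `evalue < E_max` and reference coverage `> C_min`.
#'
#' MAG assemblies frequently split genes across fragments, so same-family
#' hits on one contig that individually fail the coverage rule are merged
#' when they lie within `split_gap` bp of each other and their combined
#' coverage passes `C_min`; such assignments are flagged `split = TRUE`.
#'
#' @param genome An [annotated_genome()].
#' @param refs Reference proteins ([Biostrings::AAStringSet] named by
#'   family), e.g. [default_family_refs()].
#' @param thresholds A [search_thresholds()].
#' @return A data.frame of class `family_assignments` with one row per
#'   assigned locus: `locus_tag`, `contig_id`, `start`, `end`, `strand`,
#'   `family`, `category`, `bit_score`, `evalue`, `coverage`, `identity`,
#'   `split`.
#' @export
assign_families <- function(genome, refs = default_family_refs(),
                            thresholds = search_thresholds()) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (length(refs) == 0) stop("empty reference set")
  ft <- genome$features
  ft <- ft[!is.na(ft$protein) & nzchar(ft$protein), , drop = FALSE]
  ref_total <- sum(Biostrings::width(refs))
  fams <- names(refs)

  rows <- vector("list", nrow(ft))
  for (i in seq_len(nrow(ft))) {
    protein <- sanitize_protein(ft$protein[i], ft$locus_tag[i])
    scores <- .align_query(protein, refs)
    stats <- ka_statistics(scores, nchar(protein), ref_total)
    cand <- which(stats$evalue < thresholds$E_max)
    if (!length(cand)) next
    best_score <- max(scores[cand])
    tied <- cand[scores[cand] == best_score]
    det <- lapply(tied, function(k) .align_details(protein, refs[k]))
    if (length(tied) > 1) {
      idn <- vapply(det, `[[`, 0, "identity")
      keep <- which(idn == max(idn))
      keep <- keep[order(fams[tied[keep]])][1]
    } else keep <- 1L
    k <- tied[keep]
    rows[[i]] <- data.frame(
      locus_tag = ft$locus_tag[i], contig_id = ft$contig_id[i],
      start = ft$start[i], end = ft$end[i], strand = ft$strand[i],
      family = fams[k], category = family_category(fams[k]),
      bit_score = stats$bit_score[k], evalue = stats$evalue[k],
      coverage = det[[keep]]$coverage, identity = det[[keep]]$identity,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits))
    hits <- data.frame(locus_tag = character(), contig_id = character(),
                       start = integer(), end = integer(),
                       strand = character(), family = character(),
                       category = character(), bit_score = numeric(),
                       evalue = numeric(), coverage = numeric(),
                       identity = numeric(), stringsAsFactors = FALSE)
  hits$split <- logical(nrow(hits))

  ## coverage rule + split-gene rescue
  keep <- hits$coverage > thresholds$C_min
  out <- hits[keep, , drop = FALSE]
  frag <- hits[!keep, , drop = FALSE]
  if (nrow(frag)) {
    for (key in unique(paste(frag$contig_id, frag$family))) {
      grp <- frag[paste(frag$contig_id, frag$family) == key, , drop = FALSE]
      grp <- grp[order(grp$start), , drop = FALSE]
      ## chain fragments whose genomic gap (next start - prev end) < split_gap
      gap <- grp$start[-1] - grp$end[-nrow(grp)]
      chain_id <- cumsum(c(1, gap >= thresholds$split_gap))
      for (cid in unique(chain_id)) {
        ch <- grp[chain_id == cid, , drop = FALSE]
        if (nrow(ch) >= 2 && sum(ch$coverage) > thresholds$C_min) {
          ch$split <- TRUE
          out <- rbind(out, ch)
        }
      }
    }
  }
  ## multiple same-family assignments in close proximity are fragments of
  ## one (assembly- or annotation-) split gene: flag them all
  if (nrow(out) > 1) {
    key <- paste(out$contig_id, out$family)
    for (kk in unique(key)) {
      idx <- which(key == kk)
      if (length(idx) < 2) next
      idx <- idx[order(out$start[idx])]
      gap <- out$start[idx][-1] - out$end[idx][-length(idx)]
      ch <- cumsum(c(1, gap >= thresholds$split_gap))
      for (cid in unique(ch))
        if (sum(ch == cid) >= 2) out$split[idx[ch == cid]] <- TRUE
    }
  }
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("family_assignments", "data.frame")
  attr(out, "genome_id") <- genome$genome_id
  attr(out, "thresholds") <- thresholds
  out
}

#' Build a presence/absence matrix from family assignments
#'
#' A marker named after a category (`puf`, `puh`, `bch`, `crt`) is
#' satisfied by any assigned family of that category; any other marker is
#' matched by family name (with the table aliases `RubisCO` ->
#' `RubisCO-like` and `Rho-like` -> `rhodopsin-like`).  Scanned genomes
#' never get `unknown` cells: a marker is either evidenced or absent.
#'
#' @param assignments_by_genome Named list (genome id ->
#'   `family_assignments`).
#' @param marker_set Character vector of marker names; defaults to the
#'   MAG survey marker panel.
#' @return A `presence_matrix`.
#' @export
build_presence_matrix <- function(assignments_by_genome,
                                  marker_set = default_marker_set()) {
  if (!length(marker_set)) stop("marker_set must be non-empty")
  alias <- c("RubisCO" = "RubisCO-like", "Rho-like" = "rhodopsin-like")
  cats <- c("puf", "puh", "bch", "crt")
  m <- matrix("absent", nrow = length(assignments_by_genome),
              ncol = length(marker_set),
              dimnames = list(names(assignments_by_genome), marker_set))
  for (g in names(assignments_by_genome)) {
    a <- assignments_by_genome[[g]]
    for (mk in marker_set) {
      hit <- if (mk %in% cats) any(a$category == mk)
      else any(a$family == (if (mk %in% names(alias)) alias[[mk]] else mk))
      if (isTRUE(hit)) m[g, mk] <- "present"
    }
  }
  presence_matrix(m)
}

#' Default marker panel
#'
#' The marker columns of the MAG gene-inventory survey: the three
#' category-level CGB markers plus the oxygen-lifestyle and accessory
#' phototrophy markers.
#'
#' @return Character vector of marker names.
#' @export
default_marker_set <- function() {
  c("puf", "puh", "bch", "acsF", "bchE", "hemF", "hemN", "hemJ", "hemG",
    "BphP", "BphO", "RubisCO", "Rho-like")
}

#' Reference full-matrix Smith-Waterman score
#'
#' A straightforward full dynamic-programming local-alignment score
#' (affine gaps: a gap of length k costs `open + k * ext`), implemented
#' independently in C++ as a validation reference for the package's
#' alignment engine.
#'
#' @param a,b Protein sequences (character).
#' @param open,ext Gap opening/extension penalties (positive).
#' @return The optimal local alignment score (numeric).
#' @export
sw_score_reference <- function(a, b, open = 11, ext = 1) {
  mat <- blosum62()
  ai <- match(strsplit(a, "")[[1]], rownames(mat)) - 1L
  bi <- match(strsplit(b, "")[[1]], rownames(mat)) - 1L
  if (anyNA(ai) || anyNA(bi))
    stop("sequence contains residues outside the scoring matrix alphabet")
  sw_score_dp(ai, bi, mat, as.numeric(open), as.numeric(ext))
}
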