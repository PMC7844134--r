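## Sub-cluster architecture: segmentation of a PGC into canonical blocks,
## the Gemmatimonadetes acsF/bchO placement markers, and a gene-order
## distance between architectures.

.canonical_blocks <- c("bchP2G", "bchFNBHLM", "lhaA-puhABC", "pufBALMC",
                       "crtF-bchCXYZ", "bchID")

## Maximal-run segmentation of a family/strand sequence into blocks.
## Runs are merged only for canonical block labels; every other gene is a
## singleton block.  Returned in input (genomic) order.
.segment_families <- function(family, strand) {
  blk <- family_block(family)
  n <- length(blk)
  if (n == 0)
    return(data.frame(name = character(), orientation = character(),
                      n_members = integer(), stringsAsFactors = FALSE))
  grp <- integer(n); grp[1] <- 1L
  if (n > 1) for (k in 2:n) {
    same_run <- blk[k] == blk[k - 1] && blk[k] %in% .canonical_blocks
    grp[k] <- if (same_run) grp[k - 1] else grp[k - 1] + 1L
  }
  idx <- split(seq_len(n), grp)
  name <- vapply(idx, function(i) blk[i[1]], "")
  orientation <- vapply(idx, function(i) {
    s <- strand[i]
    nf <- sum(s == "+"); nr <- sum(s == "-")
    if (nf > nr) "forward" else if (nr > nf) "reverse"
    else if (s[1] == "+") "forward" else "reverse"  # tie -> first member
  }, "")
  members <- lapply(idx, function(i) family[i])
  out <- data.frame(name = name, orientation = orientation,
                    n_members = lengths(idx), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "members") <- unname(members)
  out
}

.flip_blocks <- function(blocks) {
  out <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
  out$orientation <- ifelse(out$orientation == "forward",
                            "reverse", "forward")
  m <- attr(blocks, "members")
  ## the opposite reading also reverses gene order within each block
  if (!is.null(m)) attr(out, "members") <- lapply(rev(m), rev)
  rownames(out) <- NULL
  out
}

## Canonical reading direction: a cluster read from the opposite strand is
## the same architecture, so we pick the lexicographically smaller of the
## two serializations.  Makes signatures invariant to a uniform strand
## flip + coordinate reversal.
.canonicalize_blocks <- function(blocks) {
  if (nrow(blocks) < 1) return(blocks)
  ser <- function(b) paste(b$name, b$orientation, collapse = ";")
  flipped <- .flip_blocks(blocks)
  if (ser(flipped) < ser(blocks)) flipped else blocks
}

#' Construct an architecture signature
#'
#' An ordered, oriented list of sub-cluster blocks.  The block order is
#' canonicalized so that reading a cluster from either strand yields the
#' same signature; the two Gemmatimonadetes placement markers are
#' evaluated on construction.
#'
#' @param blocks data.frame with columns `name`, `orientation`
#'   (`forward`/`reverse`) and `n_members`.
#' @return An object of class `architecture_signature` with elements
#'   `blocks`, `acsF_marker`, `bchO_marker`, `missing`.
#' @export
architecture_signature <- function(blocks) {
  stopifnot(is.data.frame(blocks),
            all(c("name", "orientation") %in% names(blocks)))
  if (is.null(blocks$n_members)) blocks$n_members <- 1L
  blocks <- .canonicalize_blocks(blocks)
  sig <- structure(list(blocks = blocks, acsF_marker = NA,
                        bchO_marker = NA, missing = character(0)),
                   class = "architecture_signature")
  mk <- marker_test(sig)
  sig$acsF_marker <- mk$acsF_marker
  sig$bchO_marker <- mk$bchO_marker
  sig$missing <- mk$missing
  sig
}

#' @export
print.architecture_signature <- function(x, ...) {
  arrow <- ifelse(x$blocks$orientation == "forward", ">", "<")
  cat("architecture_signature:",
      paste0(arrow, x$blocks$name, collapse = " "), "\n")
  cat("  acsF marker:", x$acsF_marker, " bchO marker:", x$bchO_marker, "\n")
  if (length(x$missing)) cat("  missing:",
                             paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Segment a PGC candidate into sub-cluster blocks
#'
#' Maximal runs of consecutive member genes whose families belong to the
#' same canonical sub-cluster become one block; genes outside the
#' canonical sub-clusters (the singleton anchors acsF, bchO, puhE, ppsR,
#' aerR and anything else) each form a singleton block.  Intervening
#' hypothetical ORFs are not cluster members and are therefore transparent:
#' they never break a run.  Block orientation is the majority strand of
#' the members (ties: strand of the first member).
#'
#' @param cluster A `pgc_candidate` (from [detect_clusters()]), or `NULL`
#'   / empty for an empty signature.
#' @return An [architecture_signature()].
#' @export
segment_subclusters <- function(cluster) {
  if (is.null(cluster) || nrow(cluster$members) == 0)
    return(architecture_signature(
      data.frame(name = character(), orientation = character(),
                 n_members = integer(), stringsAsFactors = FALSE)))
  ## collapse split fragments of one gene into a single positional unit
  mem <- cluster$members
  dup <- duplicated(mem$family) & mem$split &
    c(FALSE, mem$family[-1] == mem$family[-nrow(mem)])
  mem <- mem[!dup, , drop = FALSE]
  architecture_signature(.segment_families(mem$family, mem$strand))
}

#' The packaged Gemmatimonadetes template signature
#'
#' Architecture signature of the Gemma-PGC template
#' ([gemma_pgc_template()]): six canonical multi-gene sub-clusters plus
#' the singleton anchors, with both placement markers true.
#'
#' @return An [architecture_signature()].
#' @export
gemma_template_signature <- function() {
  tmpl <- gemma_pgc_template()
  tmpl <- tmpl[!tmpl$hypothetical, , drop = FALSE]
  architecture_signature(.segment_families(tmpl$family, tmpl$strand))
}

#' Test the Gemmatimonadetes acsF / bchO placement markers
#'
#' `acsF_marker` is true iff the acsF singleton lies strictly between the
#' `bchFNBHLM` and `lhaA-puhABC` blocks (in either reading direction);
#' `bchO_marker` is the analogue for `pufBALMC` / `crtF-bchCXYZ`.  If the
#' singleton or either flanking block is absent the marker is false and
#' the element is listed in `missing`.
#'
#' @param sig An [architecture_signature()].
#' @return List with `acsF_marker`, `bchO_marker`, `missing`.
#' @export
marker_test <- function(sig) {
  nm <- sig$blocks$name
  missing <- character(0)
  one <- function(single, left, right) {
    need <- c(single, left, right)
    absent <- need[!(need %in% nm)]
    if (length(absent)) {
      missing <<- union(missing, absent)
      return(FALSE)
    }
    i <- match(single, nm); l <- match(left, nm); r <- match(right, nm)
    min(l, r) < i && i < max(l, r)
  }
  acsF <- one("acsF", "bchFNBHLM", "lhaA-puhABC")
  bchO <- one("bchO", "pufBALMC", "crtF-bchCXYZ")
  list(acsF_marker = acsF, bchO_marker = bchO, missing = missing)
}

#' Gene-order distance between two architectures
#'
#' `distance = breakpoints + orientation mismatches + symmetric
#' difference`: the number of adjacent block pairs (restricted to blocks
#' present in both signatures) that are adjacent in one order but not the
#' other, plus the number of shared blocks whose orientation differs,
#' plus the number of blocks present in exactly one signature.  The
#' distance is symmetric and zero iff the signatures are identical in
#' content, order and orientation (up to a whole-cluster flip, which
#' canonicalization removes).  The triangle inequality is not guaranteed.
#'
#' @param a,b [architecture_signature()] objects.
#' @return Non-negative integer distance.
#' @export
compare_architectures <- function(a, b) {
  ba <- a$blocks; bb <- b$blocks
  shared <- intersect(ba$name, bb$name)
  uniq <- sum(!(ba$name %in% shared)) + sum(!(bb$name %in% shared))
  if (length(shared) == 0) return(as.integer(uniq))
  oa <- ba$name[ba$name %in% shared]
  ob <- bb$name[bb$name %in% shared]
  oa <- oa[!duplicated(oa)]; ob <- ob[!duplicated(ob)]
  adj <- function(ord) {
    if (length(ord) < 2) return(character(0))
    p <- cbind(ord[-length(ord)], ord[-1])
    apply(p, 1, function(x) paste(sort(x), collapse = "\r"))
  }
  breakpoints <- sum(!(adj(oa) %in% adj(ob)))
  ori_a <- ba$orientation[match(shared, ba$name)]
  ori_b <- bb$orientation[match(shared, bb$name)]
  flips <- sum(ori_a != ori_b)
  as.integer(breakpoints + flips + uniq)
}
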