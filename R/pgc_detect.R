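## Chaining photosynthesis-family genes along contigs into PGC candidates.
##
## Two photosynthesis genes join one cluster iff their genomic gap is at
## most max_gap AND at most max_intervening consecutive non-photosynthesis
## genes sit between them.  On circular contigs the chain may wrap the
## origin.

#' Chaining parameters for PGC detection
#'
#' Defaults are tuned to the ~42 kb Gemmatimonadetes PGC: intergenic gaps
#' inside the cluster are sub-kilobase, and 6 kb / 5 intervening genes
#' tolerate the hypothetical-ORF stretch between the puh and puf operons
#' without merging distant singletons.  `min_members` suppresses isolated
#' heme-pathway or carotenoid genes from forming spurious "clusters".
#'
#' @param max_gap Maximum genomic gap between consecutive cluster genes
#'   (bp); default 6000.
#' @param max_intervening Maximum consecutive non-photosynthesis genes
#'   between cluster members; default 5.
#' @param min_members Minimum member count for a reported cluster;
#'   default 4.
#' @return A `chaining_params` list.
#' @export
chaining_params <- function(max_gap = 6000, max_intervening = 5,
                            min_members = 4) {
  stopifnot(max_gap > 0, max_intervening > 0, min_members > 0)
  structure(list(max_gap = max_gap, max_intervening = max_intervening,
                 min_members = min_members), class = "chaining_params")
}

.new_candidate <- function(genome_id, contig_id, members, wrapped, contig_len) {
  if (wrapped) {
    ## chain order crosses the origin: starts drop once at the wrap point
    brk <- which(diff(members$start) < 0)[1]
    p1 <- seq_len(brk); p2 <- seq(brk + 1, nrow(members))
    span <- data.frame(
      contig_id = contig_id,
      start = c(min(members$start[p1]), min(members$start[p2])),
      end = c(max(members$end[p1]), max(members$end[p2])))
  } else {
    span <- data.frame(contig_id = contig_id,
                       start = min(members$start), end = max(members$end))
  }
  structure(list(genome_id = genome_id, contig_id = contig_id,
                 members = members, span = span, wrapped = wrapped,
                 n_intervening = NA_integer_),
            class = "pgc_candidate")
}

#' @export
print.pgc_candidate <- function(x, ...) {
  cat("pgc_candidate:", nrow(x$members), "genes on", x$contig_id,
      if (x$wrapped) "(wraps origin)" else "",
      "\n  families:", paste(x$members$family, collapse = " "), "\n")
  invisible(x)
}

#' Detect photosynthesis gene cluster candidates
#'
#' Chains genes assigned to photosynthesis families (categories `bch`,
#' `puf`, `puh`, `crt`, `regulatory`) along each contig.  Consecutive
#' photosynthesis genes belong to one cluster iff their genomic gap is
#' `<= max_gap` bp and at most `max_intervening` non-photosynthesis genes
#' lie between them; intervening hypothetical ORFs therefore do not break
#' a cluster.  On circular contigs the chain wraps the origin, so detection
#' is invariant to the assembly's choice of origin.  Clusters with fewer
#' than `min_members` members are dropped.
#'
#' @param genome An [annotated_genome()].
#' @param assignments `family_assignments` for this genome.
#' @param params A [chaining_params()].
#' @return List of `pgc_candidate` objects.  Each carries `members` (the
#'   assigned genes, in chain order), `span` (one row, or two rows for an
#'   origin-wrapping cluster), and `n_intervening`.
#' @export
detect_clusters <- function(genome, assignments,
                            params = chaining_params()) {
  stopifnot(inherits(genome, "annotated_genome"))
  pgc <- assignments[assignments$category %in% .pgc_categories, ,
                     drop = FALSE]
  out <- list()
  for (ci in seq_len(nrow(genome$contigs))) {
    contig <- genome$contigs$id[ci]
    clen <- genome$contigs$length[ci]
    circ <- isTRUE(genome$contigs$circular[ci])
    ft <- genome$features[genome$features$contig_id == contig, ,
                          drop = FALSE]
    if (!nrow(ft)) next
    is_pgc <- ft$locus_tag %in% pgc$locus_tag
    idx <- which(is_pgc)
    if (!length(idx)) next

    ## group consecutive photosynthesis genes
    grp <- integer(length(idx))
    grp[1] <- 1L
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        gap <- ft$start[idx[k]] - ft$end[idx[k - 1]]
        between <- idx[k] - idx[k - 1] - 1L
        joined <- gap <= params$max_gap && between <= params$max_intervening
        grp[k] <- if (joined) grp[k - 1] else grp[k - 1] + 1L
      }
    }
    groups <- split(idx, grp)

    wrapped <- FALSE
    if (circ && length(groups) >= 1) {
      first <- groups[[1]]; last <- groups[[length(groups)]]
      if (!identical(first, last)) {
        gap <- (clen - ft$end[last[length(last)]]) + ft$start[first[1]]
        between <- (nrow(ft) - last[length(last)]) + (first[1] - 1L)
        if (gap <= params$max_gap && between <= params$max_intervening) {
          ## merge last and first across the origin; chain order crosses 0
          groups[[1]] <- c(last, first)
          groups[[length(groups)]] <- NULL
          wrapped <- length(groups) >= 1
          attr(groups[[1]], "wrapped") <- TRUE
        }
      }
    }

    for (g in groups) {
      if (length(g) < params$min_members) next
      mem <- ft[g, c("contig_id", "start", "end", "strand", "locus_tag",
                     "protein"), drop = FALSE]
      mi <- match(mem$locus_tag, pgc$locus_tag)
      mem$family <- pgc$family[mi]
      mem$split <- pgc$split[mi]
      rownames(mem) <- NULL
      cand <- .new_candidate(genome$genome_id, contig, mem,
                             isTRUE(attr(g, "wrapped")), clen)
      ## intervening non-photosynthesis genes inside the chain
      if (isTRUE(attr(g, "wrapped"))) {
        brk <- which(diff(g) < 0)[1]           # chain order: high idx, then low
        inside <- c(seq(min(g[1:brk]), nrow(ft)),
                    seq_len(max(g[(brk + 1):length(g)])))
      } else {
        inside <- seq(min(g), max(g))
      }
      cand$n_intervening <- sum(!is_pgc[inside])
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Probe cluster continuity via the AcsF / BchO / PuhE anchors
#'
#' The three anchor genes are the positionally flexible loci of the PGC;
#' requiring all three inside a single candidate selects complete,
#' continuous clusters over fragmented ones (the same logic as screening
#' with a fused AcsF-BchO-PuhE query).  Families merged by the split-gene
#' rule are reported in `split_flags`: a split anchor on one contig still
#' counts as found.
#'
#' @param candidates List of `pgc_candidate` from one genome.
#' @param anchors Anchor families; default `c("acsF", "bchO", "puhE")`.
#' @return List with `continuous` (TRUE iff one candidate holds all
#'   anchors), `anchors_found` (anchors seen in any candidate) and
#'   `split_flags` (families flagged as split fragments).
#' @export
probe_continuity <- function(candidates,
                             anchors = c("acsF", "bchO", "puhE")) {
  found <- character(0); splits <- character(0); continuous <- FALSE
  for (cand in candidates) {
    fams <- unique(cand$members$family)
    found <- union(found, intersect(anchors, fams))
    splits <- union(splits, unique(cand$members$family[cand$members$split]))
    if (all(anchors %in% fams)) continuous <- TRUE
  }
  list(continuous = continuous,
       anchors_found = intersect(anchors, found),
       split_flags = splits)
}

#' Export PGC candidates as BED
#'
#' Writes cluster spans in BED format (0-based half-open, matching the
#' internal coordinate convention).
#'
#' @param candidates List of `pgc_candidate`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters_bed <- function(candidates, path) {
  rows <- list()
  for (i in seq_along(candidates)) {
    sp <- candidates[[i]]$span
    for (j in seq_len(nrow(sp)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sp$contig_id[j], start = sp$start[j], end = sp$end[j],
        name = paste0("PGC_", i), score = nrow(candidates[[i]]$members),
        strand = ".", stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = integer(), strand = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
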