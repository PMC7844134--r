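## Pipeline orchestration: scan one genome end to end, compare two
## scanned genomes, and write machine-readable reports.  Every numeric
## threshold consulted by a decision is echoed in the report.

#' Scan a genome for a photosynthesis gene cluster and classify it
#'
#' Runs the full per-genome pipeline: family assignment, PGC chaining,
#' continuity probe, architecture segmentation with the Gemmatimonadetes
#' placement markers, and the CGB / oxygen-lifestyle decision rules.
#'
#' @param genome An [annotated_genome()].
#' @param refs Family reference proteins; default [default_family_refs()].
#' @param search A [search_thresholds()].
#' @param chain A [chaining_params()].
#' @param oxy An [oxygen_rules()].
#' @param marker_set Marker panel for the presence row; default
#'   [default_marker_set()].
#' @return A `pgc_scan` list: `genome_id`, `assignments`, `clusters`,
#'   `continuity`, `signature` (of the largest cluster), `presence`
#'   (named character vector), `cgb`, `oxygen`, `thresholds`, and the
#'   input `genome`.
#' @export
run_scan <- function(genome, refs = default_family_refs(),
                     search = search_thresholds(),
                     chain = chaining_params(),
                     oxy = oxygen_rules(),
                     marker_set = default_marker_set()) {
  stopifnot(inherits(genome, "annotated_genome"))
  assignments <- assign_families(genome, refs, search)
  clusters <- detect_clusters(genome, assignments, chain)
  continuity <- probe_continuity(clusters)
  main <- if (length(clusters)) {
    sizes <- vapply(clusters, function(x) nrow(x$members), 0L)
    clusters[[which.max(sizes)]]
  } else NULL
  signature <- segment_subclusters(main)
  pm <- build_presence_matrix(setNames(list(assignments), genome$genome_id),
                              marker_set)
  row <- setNames(as.vector(pm[1, ]), colnames(pm))
  cgb <- classify_cgb(row)
  oxygen <- classify_oxygen(row, genome$completeness, oxy)
  structure(list(
    genome_id = genome$genome_id,
    assignments = assignments,
    clusters = clusters,
    continuity = continuity,
    signature = signature,
    presence = row,
    cgb = cgb,
    oxygen = as.character(oxygen),
    oxygen_evidence = attr(oxygen, "evidence"),
    oxygen_downgraded = attr(oxygen, "downgraded"),
    completeness = genome$completeness,
    thresholds = list(search = unclass(search), chain = unclass(chain),
                      oxygen = unclass(oxy)),
    genome = genome
  ), class = "pgc_scan")
}

#' @export
print.pgc_scan <- function(x, ...) {
  cat("pgc_scan", x$genome_id, "--", nrow(x$assignments),
      "family assignments,", length(x$clusters), "cluster(s)\n")
  cat("  CGB:", x$cgb, " oxygen:", x$oxygen,
      " continuous PGC:", x$continuity$continuous, "\n")
  cat("  markers: acsF", x$signature$acsF_marker,
      " bchO", x$signature$bchO_marker, "\n")
  invisible(x)
}

#' Write a scan report to disk
#'
#' Emits `<genome_id>.json` (full report), `<genome_id>.assignments.tsv`
#' and `<genome_id>.clusters.bed` in `dir`.  Reports are deterministic
#' given inputs, and never mix with logging output.
#'
#' @param scan A `pgc_scan` from [run_scan()].
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
write_scan_report <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, scan$genome_id)
  rep <- list(
    genome_id = scan$genome_id,
    cgb = scan$cgb,
    oxygen = scan$oxygen,
    oxygen_downgraded = scan$oxygen_downgraded,
    completeness = scan$completeness,
    presence = as.list(scan$presence),
    continuity = scan$continuity,
    markers = list(acsF = scan$signature$acsF_marker,
                   bchO = scan$signature$bchO_marker,
                   missing = scan$signature$missing),
    architecture = scan$signature$blocks,
    n_clusters = length(scan$clusters),
    thresholds = scan$thresholds)
  jsonlite::write_json(rep, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(scan$assignments, paste0(base, ".assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_clusters_bed(scan$clusters, paste0(base, ".clusters.bed"))
  invisible(paste0(base, ".json"))
}

.span_sequence <- function(scan) {
  if (!length(scan$clusters)) return(NULL)
  sizes <- vapply(scan$clusters, function(x) nrow(x$members), 0L)
  main <- scan$clusters[[which.max(sizes)]]
  g <- scan$genome
  if (is.null(g$seq)) return(NULL)
  sp <- main$span
  paste(vapply(seq_len(nrow(sp)), function(j) {
    s <- as.character(g$seq[[sp$contig_id[j]]])
    substr(s, sp$start[j] + 1, sp$end[j])
  }, ""), collapse = "")
}

#' Compare two scanned genomes
#'
#' Computes per-family protein identities between the main detected
#' clusters (with the strict >90% flags), the architecture distance, and
#' nucleotide synteny blocks between the cluster regions (PGC dialect)
#' and whole contigs (genome dialect).
#'
#' @param scan_a,scan_b `pgc_scan` objects from [run_scan()].
#' @return A `pgc_comparison` list; if either genome lacks a detected
#'   cluster the result carries `no_pgc = TRUE` and names the genome(s).
#' @export
run_compare <- function(scan_a, scan_b) {
  stopifnot(inherits(scan_a, "pgc_scan"), inherits(scan_b, "pgc_scan"))
  lack <- c(scan_a$genome_id, scan_b$genome_id)[
    c(!length(scan_a$clusters), !length(scan_b$clusters))]
  if (length(lack))
    return(structure(list(no_pgc = TRUE, genomes_without_pgc = lack),
                     class = "pgc_comparison"))
  main_a <- scan_a$clusters[[which.max(vapply(scan_a$clusters,
                                              function(x) nrow(x$members), 0L))]]
  main_b <- scan_b$clusters[[which.max(vapply(scan_b$clusters,
                                              function(x) nrow(x$members), 0L))]]
  idents <- pairwise_gene_identity(main_a, main_b)
  dist <- compare_architectures(scan_a$signature, scan_b$signature)
  sa <- .span_sequence(scan_a); sb <- .span_sequence(scan_b)
  pgc_blocks <- if (!is.null(sa) && !is.null(sb))
    synteny_blocks(sa, sb, dialect = "pgc") else NULL
  ga <- scan_a$genome; gb <- scan_b$genome
  genome_blocks <- if (!is.null(ga$seq) && !is.null(gb$seq))
    synteny_blocks(as.character(ga$seq[[1]]), as.character(gb$seq[[1]]),
                   dialect = "genome") else NULL
  structure(list(
    no_pgc = FALSE,
    genome_ids = c(scan_a$genome_id, scan_b$genome_id),
    gene_identities = idents,
    n_high_identity = sum(idents$high_identity),
    architecture_distance = dist,
    synteny_pgc = pgc_blocks,
    synteny_genome = genome_blocks,
    dialects = .dialects
  ), class = "pgc_comparison")
}

#' @export
print.pgc_comparison <- function(x, ...) {
  if (isTRUE(x$no_pgc)) {
    cat("pgc_comparison: no PGC detected in",
        paste(x$genomes_without_pgc, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat("pgc_comparison", paste(x$genome_ids, collapse = " vs "), "\n")
  cat("  shared families:", nrow(x$gene_identities),
      " (>90% identity:", x$n_high_identity, ")\n")
  cat("  architecture distance:", x$architecture_distance, "\n")
  invisible(x)
}
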