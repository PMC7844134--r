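## Annotated-genome model and standard-format I/O.
##
## Internal coordinates are 0-based half-open; GFF3 on disk is 1-based
## inclusive.  The conversion happens exactly once, at read/write time.

#' Construct an annotated genome
#'
#' The internal genome model every pipeline stage consumes: contigs plus
#' strand-aware gene features with protein sequences.
#'
#' @param genome_id Genome identifier.
#' @param contigs data.frame with columns `id`, `length` (bp), `circular`.
#' @param features data.frame with columns `contig_id`, `start` (0-based),
#'   `end` (half-open), `strand` (`+`/`-`), `locus_tag`, `symbol`
#'   (optional, `NA` allowed), `protein` (`NA` for non-coding features).
#' @param seq Optional [Biostrings::DNAStringSet] of contig sequences,
#'   named by contig id.
#' @param completeness,contamination Optional percentages in \[0, 100\]
#'   (CheckM-style MAG quality estimates).
#' @return An object of class `annotated_genome`.  Features are sorted by
#'   (contig, start, end, locus_tag).
#' @export
annotated_genome <- function(genome_id, contigs, features, seq = NULL,
                             completeness = NA_real_,
                             contamination = NA_real_) {
  stopifnot(is.data.frame(contigs), is.data.frame(features))
  contigs$length <- as.integer(contigs$length)
  if (anyDuplicated(contigs$id))
    stop("duplicate contig id in genome ", genome_id)
  if (any(contigs$length < 0)) stop("negative contig length")
  if (!all(features$contig_id %in% contigs$id))
    stop("format error: feature references unknown contig: ",
         paste(setdiff(features$contig_id, contigs$id), collapse = ", "))
  if (is.null(features$symbol)) features$symbol <- NA_character_
  if (is.null(features$protein)) features$protein <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start < 0) || any(features$start >= features$end))
    stop("invalid feature coordinates (need 0 <= start < end)")
  clen <- setNames(contigs$length, contigs$id)
  circ <- setNames(as.logical(contigs$circular), contigs$id)
  too_long <- features$end > clen[features$contig_id] &
    !circ[features$contig_id]
  if (any(too_long))
    stop("feature end beyond linear contig length: ",
         paste(features$locus_tag[too_long], collapse = ", "))
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  o <- order(features$contig_id, features$start, features$end,
             features$locus_tag)
  features <- features[o, , drop = FALSE]
  rownames(features) <- NULL
  for (v in c(completeness, contamination))
    if (!is.na(v) && (v < 0 || v > 100))
      stop("completeness/contamination must be in [0, 100]")
  structure(list(genome_id = genome_id, contigs = contigs,
                 features = features, seq = seq,
                 completeness = completeness,
                 contamination = contamination),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome", x$genome_id, "--", nrow(x$contigs), "contig(s),",
      nrow(x$features), "feature(s)\n")
  if (!is.na(x$completeness))
    cat("  completeness:", x$completeness, "% contamination:",
        x$contamination, "%\n")
  invisible(x)
}

.read_pragmas <- function(gff_path) {
  lines <- readLines(gff_path, n = 50L)
  pr <- grep("^#!", lines, value = TRUE)
  out <- list()
  for (p in pr) {
    parts <- strsplit(sub("^#!", "", p), "[ \t]+")[[1]]
    if (length(parts) >= 2) out[[parts[1]]] <- parts[2]
  }
  out
}

#' Read an annotated genome from GFF3 + FASTA
#'
#' Reads canonical GFF3 (1-based inclusive coordinates on disk) together
#' with the genomic and protein FASTA files and builds the internal
#' 0-based half-open [annotated_genome()] model.  Proteins are joined to
#' CDS features by the GFF `ID` attribute (first whitespace-delimited token
#' of the FASTA header); a CDS without a protein record is retained with a
#' warning and excluded from family search downstream.
#'
#' @param gff_path,genome_fasta,protein_fasta File paths.
#' @param genome_id Genome identifier; defaults to the GFF basename.
#' @return An [annotated_genome()].
#' @export
read_annotated_genome <- function(gff_path, genome_fasta, protein_fasta,
                                  genome_id = NULL) {
  for (f in c(gff_path, genome_fasta, protein_fasta))
    if (!file.exists(f)) stop("file not found: ", f)
  genome_id <- genome_id %||% sub("\\.gff3?$", "", basename(gff_path))

  dna <- Biostrings::readDNAStringSet(genome_fasta)
  names(dna) <- vapply(strsplit(names(dna), "\\s+"), `[`, "", 1L)
  prot <- Biostrings::readAAStringSet(protein_fasta)
  names(prot) <- vapply(strsplit(names(prot), "\\s+"), `[`, "", 1L)

  gr <- rtracklayer::import(gff_path, format = "gff3")
  circular_ids <- character(0)
  reg <- gr[gr$type == "region"]
  if (length(reg) && !is.null(reg$Is_circular))
    circular_ids <- as.character(GenomicRanges::seqnames(
      reg[!is.na(reg$Is_circular) & reg$Is_circular == "true"]))
  cds <- gr[gr$type %in% c("CDS", "gene")]
  cds <- cds[!duplicated(cds$ID)]

  contigs <- data.frame(id = names(dna),
                        length = Biostrings::width(dna),
                        circular = names(dna) %in% circular_ids,
                        stringsAsFactors = FALSE)
  bad <- setdiff(unique(as.character(GenomicRanges::seqnames(cds))),
                 contigs$id)
  if (length(bad))
    stop("format error: GFF references contig(s) absent from FASTA: ",
         paste(bad, collapse = ", "))

  ids <- as.character(cds$ID)
  sym <- if (!is.null(cds$gene)) as.character(cds$gene) else
    rep(NA_character_, length(cds))
  pp <- rep(NA_character_, length(cds))
  hit <- ids %in% names(prot)
  pp[hit] <- as.character(prot[ids[hit]])
  if (any(!hit))
    warning("no protein record for ", sum(!hit), " feature(s): ",
            paste(utils::head(ids[!hit], 5), collapse = ", "),
            "; retained without protein")
  features <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds) - 1L,   # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds)),
    locus_tag = ids, symbol = sym, protein = pp,
    stringsAsFactors = FALSE)
  features$strand[features$strand == "*"] <- "+"

  pragmas <- .read_pragmas(gff_path)
  annotated_genome(genome_id, contigs, features, seq = dna,
                   completeness = as.numeric(pragmas$completeness %||% NA),
                   contamination = as.numeric(pragmas$contamination %||% NA))
}

#' Write an annotated genome as GFF3 + FASTA
#'
#' Emits `<prefix>.gff3`, `<prefix>.fna` and `<prefix>.faa` in `dir`.
#' Internal 0-based half-open coordinates are converted back to GFF3
#' 1-based inclusive; the round trip through
#' [read_annotated_genome()] is the identity on every feature.
#'
#' @param genome An [annotated_genome()] with sequences attached.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; defaults to the genome id.
#' @return Invisibly, a named list of the three paths.
#' @export
write_annotated_genome <- function(genome, dir, prefix = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (is.null(genome$seq)) stop("genome has no sequences attached")
  prefix <- prefix %||% genome$genome_id
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(gff = file.path(dir, paste0(prefix, ".gff3")),
                fna = file.path(dir, paste0(prefix, ".fna")),
                faa = file.path(dir, paste0(prefix, ".faa")))

  ft <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = ft$contig_id,
    ranges = IRanges::IRanges(start = ft$start + 1L, end = ft$end),
    strand = ft$strand)
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- ft$locus_tag
  gr$gene <- ft$symbol
  reg <- GenomicRanges::GRanges(
    seqnames = genome$contigs$id,
    ranges = IRanges::IRanges(start = 1L, end = genome$contigs$length),
    strand = "+")
  reg$type <- "region"
  reg$phase <- NA_integer_
  reg$ID <- paste0("region-", genome$contigs$id)
  reg$gene <- NA_character_
  reg$Is_circular <- ifelse(genome$contigs$circular, "true", NA_character_)
  gr$Is_circular <- NA_character_
  rtracklayer::export(c(reg, gr), paths$gff, format = "gff3")

  ## genome-level pragmas after the version line
  lines <- readLines(paths$gff)
  extra <- paste0("#!genome-id ", genome$genome_id)
  if (!is.na(genome$completeness))
    extra <- c(extra, paste0("#!completeness ", genome$completeness))
  if (!is.na(genome$contamination))
    extra <- c(extra, paste0("#!contamination ", genome$contamination))
  writeLines(c(lines[1], extra, lines[-1]), paths$gff)

  Biostrings::writeXStringSet(genome$seq, paths$fna)
  keep <- !is.na(ft$protein)
  aa <- Biostrings::AAStringSet(ft$protein[keep])
  names(aa) <- ft$locus_tag[keep]
  Biostrings::writeXStringSet(aa, paths$faa)
  invisible(paths)
}

#' Rotate the origin of a circular contig
#'
#' Moves the coordinate origin of a (single-contig) genome by `offset` bp:
#' the sequence is rotated and all features are shifted modulo the contig
#' length.  The cut must fall in an intergenic region; rotating through a
#' feature is an error.  Used to verify that circular-aware cluster
#' detection is invariant to the (arbitrary) assembly origin.
#'
#' @param genome An [annotated_genome()] with one circular contig.
#' @param offset Rotation in bp (new origin = old position `offset`).
#' @return The rotated [annotated_genome()].
#' @export
rotate_annotated_genome <- function(genome, offset) {
  stopifnot(inherits(genome, "annotated_genome"), nrow(genome$contigs) == 1L)
  if (!genome$contigs$circular[1]) stop("contig is not circular")
  L <- genome$contigs$length[1]
  offset <- offset %% L
  if (offset == 0) return(genome)
  ft <- genome$features
  if (any(ft$start < offset & ft$end > offset))
    stop("rotation offset cuts through a feature; pick an intergenic point")
  ns <- (ft$start - offset) %% L
  ft$start <- as.integer(ns)
  ft$end <- as.integer(ns + (genome$features$end - genome$features$start))
  seq <- genome$seq
  if (!is.null(seq)) {
    s <- as.character(seq[[1]])
    seq <- Biostrings::DNAStringSet(paste0(substr(s, offset + 1, L),
                                           substr(s, 1, offset)))
    names(seq) <- genome$contigs$id
  }
  annotated_genome(genome$genome_id, genome$contigs, ft, seq = seq,
                   completeness = genome$completeness,
                   contamination = genome$contamination)
}

#' Basic genome statistics
#'
#' Length (bp) and GC content of a genome, computed over A/C/G/T bases.
#'
#' @param x An [annotated_genome()] with sequences, a
#'   [Biostrings::DNAStringSet], or a FASTA path.
#' @return A list with `length_bp` and `gc_percent`.
#' @export
genome_stats <- function(x) {
  dna <- if (inherits(x, "annotated_genome")) x$seq
  else if (inherits(x, "DNAStringSet")) x
  else Biostrings::readDNAStringSet(x)
  if (is.null(dna)) stop("no sequence available")
  f <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T"))
  acgt <- colSums(f)
  list(length_bp = sum(Biostrings::width(dna)),
       gc_percent = 100 * (acgt["C"] + acgt["G"]) / sum(acgt))
}

## ---- presence/absence matrices ------------------------------------------

presence_levels <- c("present", "absent", "unknown")

#' Construct a presence/absence matrix
#'
#' @param m Character matrix with values in `present`/`absent`/`unknown`,
#'   rownames = genome ids, colnames = marker names.
#' @return A `presence_matrix`.
#' @export
presence_matrix <- function(m) {
  stopifnot(is.matrix(m))
  bad <- setdiff(unique(as.vector(m)), presence_levels)
  if (length(bad))
    stop("invalid presence value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(rownames(m)))
    stop("duplicate genome id: ",
         paste(rownames(m)[duplicated(rownames(m))], collapse = ", "))
  structure(m, class = c("presence_matrix", class(m)))
}

#' Read a presence/absence matrix from TSV
#'
#' Header row: `genome_id<TAB>marker1<TAB>...`.  Cell tokens: `+` =
#' present, `-` (ASCII hyphen) or `−` (Unicode minus, as printed in
#' typeset tables) = absent, blank = unknown.  Any other token is an error
#' naming the token.
#'
#' @param tsv_path Path to the TSV file.
#' @return A `presence_matrix` (one row per genome).
#' @export
read_presence_matrix <- function(tsv_path) {
  df <- utils::read.delim(tsv_path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8")
  if (ncol(df) < 1) stop("presence matrix needs a genome_id column")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate genome id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- as.matrix(df[, -1, drop = FALSE])
  tok <- trimws(as.vector(cells))
  vals <- rep(NA_character_, length(tok))
  vals[tok == "+"] <- "present"
  vals[tok %in% c("-", "−")] <- "absent"   # ASCII hyphen or typeset minus
  vals[tok == ""] <- "unknown"
  if (anyNA(vals)) {
    bad <- unique(tok[is.na(vals)])
    stop("unknown presence token: ", paste(shQuote(bad), collapse = ", "))
  }
  m <- matrix(vals, nrow = nrow(cells), ncol = ncol(cells),
              dimnames = list(ids, colnames(cells)))
  presence_matrix(m)
}

#' Write a presence/absence matrix as TSV
#'
#' Inverse of [read_presence_matrix()] (`+`/`-`/blank tokens).
#'
#' @param m A `presence_matrix`.
#' @param path Output path.
#' @param genome_col Name for the first column.
#' @return Invisibly, `path`.
#' @export
write_presence_matrix <- function(m, path, genome_col = "genome_id") {
  tok <- c(present = "+", absent = "-", unknown = "")
  out <- matrix(tok[as.vector(m)], nrow = nrow(m),
                dimnames = dimnames(m))
  df <- data.frame(rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- genome_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
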