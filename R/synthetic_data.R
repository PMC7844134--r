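## Synthetic annotated genomes with known ground truth.
##
## The generator plants the Gemma-PGC template (or a permuted variant)
## with controllable per-gene protein identity to the packaged reference
## set, intervening hypothetical ORFs, background non-photosynthesis
## genes, optional circularity, and MAG-style fragmentation with a target
## completeness.

#' Simulation specification
#'
#' @param seed Integer RNG seed; every simulation is deterministic given
#'   the spec.
#' @param target_protein_identity Target global identity of each planted
#'   protein to its packaged reference, in \[0.2, 1\]; default 0.75 (the
#'   divergence regime of environmental CGB relative to the isolates).
#' @param architecture Gene-order template (a data.frame like
#'   [gemma_pgc_template()]); default the Gemma-PGC template.
#' @param intergenic_gap_range Min/max intergenic gap (bp); default
#'   c(50, 500), the sub-kilobase spacing of a ~42 kb, ~35-gene cluster.
#' @param n_background_genes Background non-photosynthesis ORFs planted
#'   around the cluster; default 10.
#' @param background_length_range Background ORF length range (codons);
#'   default c(200, 1500).
#' @param hyp_length_range Hypothetical ORF length range (codons);
#'   default c(80, 150).
#' @param extra_families Standalone (non-cluster) marker genes planted in
#'   the flanking regions at the same target identity; default
#'   `c("BphP", "BphO")`, the aerobic oxygen-marker profile.  Use
#'   `"bchE"` for a microaerophilic profile, or `character(0)` for none.
#' @param circular Emit a circular contig; default FALSE.
#' @param split_in_place Families to plant as two adjacent half-gene ORFs
#'   (models a gene annotated as split fragments); default none.
#' @param verify_background Rejection-sample background/hypothetical ORFs
#'   until non-significant against the reference set; default TRUE.
#' @param genome_id Genome identifier; default derived from the seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed,
                            target_protein_identity = 0.75,
                            architecture = NULL,
                            intergenic_gap_range = c(50, 500),
                            n_background_genes = 10,
                            background_length_range = c(200, 1500),
                            hyp_length_range = c(80, 150),
                            extra_families = c("BphP", "BphO"),
                            circular = FALSE,
                            split_in_place = character(0),
                            verify_background = TRUE,
                            genome_id = NULL) {
  if (target_protein_identity < 0.2 || target_protein_identity > 1)
    stop("unsatisfiable identity target (must be in [0.2, 1])")
  stopifnot(length(intergenic_gap_range) == 2,
            all(intergenic_gap_range > 0),
            intergenic_gap_range[1] <= intergenic_gap_range[2])
  structure(list(
    seed = as.integer(seed),
    target_protein_identity = target_protein_identity,
    architecture = architecture,
    intergenic_gap_range = intergenic_gap_range,
    n_background_genes = n_background_genes,
    background_length_range = background_length_range,
    hyp_length_range = hyp_length_range,
    extra_families = extra_families,
    circular = circular,
    split_in_place = split_in_place,
    verify_background = verify_background,
    genome_id = genome_id %||% sprintf("SIM%06d", as.integer(seed) %% 1e6)
  ), class = "simulation_spec")
}

## BLOSUM62-positive exchange partners per residue (falling back to
## score-zero partners, then to any other residue).
.substitution_partners <- function() {
  if (!is.null(.pkg_cache$partners)) return(.pkg_cache$partners)
  mat <- blosum62()[.std_aa, .std_aa]
  partners <- lapply(.std_aa, function(a) {
    p <- .std_aa[mat[a, ] > 0 & .std_aa != a]
    if (!length(p)) p <- .std_aa[mat[a, ] >= 0 & .std_aa != a]
    if (!length(p)) p <- setdiff(.std_aa, a)
    p
  })
  names(partners) <- .std_aa
  .pkg_cache$partners <- partners
  partners
}

## Substitute round((1 - target) * L) distinct positions with accepted
## (BLOSUM62-positive) exchanges; realized global identity is then within
## rounding of the target.
mutate_protein <- function(protein, target_identity) {
  L <- nchar(protein)
  nsub <- round((1 - target_identity) * L)
  if (nsub == 0) return(list(protein = protein, identity = 1))
  chars <- strsplit(protein, "")[[1]]
  pos <- sample.int(L, nsub)
  partners <- .substitution_partners()
  for (p in pos) {
    cand <- partners[[chars[p]]]
    chars[p] <- if (length(cand) == 1) cand else sample(cand, 1)
  }
  list(protein = paste(chars, collapse = ""), identity = (L - nsub) / L)
}

## Uniform synonymous back-translation (bacterial code, table 11),
## trailing stop codon appended.
back_translate <- function(protein) {
  codons <- codon_table()
  chars <- strsplit(protein, "")[[1]]
  picked <- vapply(chars, function(a) {
    cs <- codons[[a]]
    if (length(cs) == 1) cs else sample(cs, 1)
  }, "", USE.NAMES = FALSE)
  paste0(paste(picked, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

.min_evalue_vs_refs <- function(protein, refs, ref_total) {
  scores <- .align_query(protein, refs)
  min(ka_statistics(scores, nchar(protein), ref_total)$evalue)
}

.random_orf <- function(len, refs, ref_total, verify, E_max = 1e-5) {
  for (try in 1:25) {
    p <- random_protein(len)
    if (!verify || .min_evalue_vs_refs(p, refs, ref_total) >= E_max)
      return(p)
  }
  stop("could not sample a non-significant background ORF")
}

#' Simulate an annotated genome with a planted PGC
#'
#' Builds a single-contig genome carrying the template photosynthesis
#' gene cluster (proteins mutated to the target identity against the
#' packaged references, coding sequences back-translated with the
#' bacterial codon table), hypothetical ORFs inside the cluster, and
#' random background ORFs (rejection-sampled to be non-significant
#' against the reference set) on both flanks.  Deterministic given the
#' spec.
#'
#' @param spec A [simulation_spec()].
#' @param refs Reference protein set; default [default_family_refs()].
#' @return List with `genome` (an [annotated_genome()] with sequences)
#'   and `truth` (planted gene table with families, coordinates, strands
#'   and realized identities, plus the planted architecture).
#' @export
simulate_genome <- function(spec, refs = default_family_refs()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  ref_total <- sum(Biostrings::width(refs))
  tmpl <- spec$architecture %||% gemma_pgc_template()
  gapr <- spec$intergenic_gap_range

  ## assemble the gene plan: left background, cluster, right background
  plan <- list()
  add <- function(family, strand, protein, type, identity = NA_real_,
                  forced_gap = NA_integer_) {
    plan[[length(plan) + 1L]] <<- list(family = family, strand = strand,
                                       protein = protein, type = type,
                                       identity = identity,
                                       forced_gap = forced_gap)
  }
  n_bg <- spec$n_background_genes
  n_left <- floor(n_bg / 2)
  bg_len <- function() sample(seq(spec$background_length_range[1],
                                  spec$background_length_range[2]), 1)
  for (i in seq_len(n_left))
    add(NA_character_, sample(c("+", "-"), 1),
        .random_orf(bg_len(), refs, ref_total, spec$verify_background),
        "background")
  for (r in seq_len(nrow(tmpl))) {
    fam <- tmpl$family[r]; strand <- tmpl$strand[r]
    if (isTRUE(tmpl$hypothetical[r])) {
      len <- sample(seq(spec$hyp_length_range[1], spec$hyp_length_range[2]), 1)
      add(fam, strand,
          .random_orf(len, refs, ref_total, spec$verify_background), "hyp")
    } else {
      mut <- mutate_protein(as.character(refs[[fam]]),
                            spec$target_protein_identity)
      if (fam %in% spec$split_in_place) {
        L <- nchar(mut$protein); h <- floor(L / 2)
        add(fam, strand, substr(mut$protein, 1, h), "pgc", mut$identity)
        add(fam, strand, substr(mut$protein, h + 1, L), "pgc",
            mut$identity, forced_gap = 30L)
      } else {
        add(fam, strand, mut$protein, "pgc", mut$identity)
      }
    }
  }
  for (fam in spec$extra_families) {
    mut <- mutate_protein(as.character(refs[[fam]]),
                          spec$target_protein_identity)
    add(fam, sample(c("+", "-"), 1), mut$protein, "extra", mut$identity)
  }
  for (i in seq_len(n_bg - n_left))
    add(NA_character_, sample(c("+", "-"), 1),
        .random_orf(bg_len(), refs, ref_total, spec$verify_background),
        "background")

  ## lay genes onto the contig
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  lead <- sample(seq(gapr[1], gapr[2]), 1)
  pieces <- c(pieces, random_dna(lead)); pos <- pos + lead
  for (i in seq_along(plan)) {
    g <- plan[[i]]
    if (i > 1) {
      gap <- if (!is.na(g$forced_gap)) g$forced_gap
      else sample(seq(gapr[1], gapr[2]), 1)
      pieces <- c(pieces, random_dna(gap)); pos <- pos + gap
    }
    cds <- back_translate(g$protein)
    if (g$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    len <- nchar(cds)
    feats[[i]] <- data.frame(
      start = pos, end = pos + len, strand = g$strand,
      family = g$family, type = g$type, protein = g$protein,
      realized_identity = g$identity, stringsAsFactors = FALSE)
    pieces <- c(pieces, cds); pos <- pos + len
  }
  tail_gap <- sample(seq(gapr[1], gapr[2]), 1)
  pieces <- c(pieces, random_dna(tail_gap)); pos <- pos + tail_gap

  contig_id <- paste0(spec$genome_id, "_c1")
  ftab <- do.call(rbind, feats)
  ftab$contig_id <- contig_id
  ftab$locus_tag <- sprintf("%s_%05d", spec$genome_id,
                            seq_len(nrow(ftab)) * 5L)
  ftab$symbol <- ifelse(ftab$type %in% c("pgc", "extra"), ftab$family,
                        ifelse(ftab$type == "hyp", "hyp", NA_character_))
  seq <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(seq) <- contig_id
  contigs <- data.frame(id = contig_id, length = pos,
                        circular = spec$circular, stringsAsFactors = FALSE)
  genome <- annotated_genome(
    spec$genome_id, contigs,
    ftab[, c("contig_id", "start", "end", "strand", "locus_tag",
             "symbol", "protein")],
    seq = seq)
  truth <- list(
    spec = spec,
    genes = ftab[, c("locus_tag", "contig_id", "start", "end", "strand",
                     "family", "type", "realized_identity")],
    planted_families = unique(ftab$family[ftab$type == "pgc"]),
    architecture = tmpl)
  list(genome = genome, truth = truth)
}

#' Fragment a genome into a MAG-like assembly
#'
#' Cuts the (single-contig) genome at uniform random breakpoints into
#' `n_contigs` pieces and retains each piece independently with
#' probability `completeness`, so the expected retained length fraction
#' equals the target and the retained-gene fraction is an unbiased
#' completeness estimator.  Genes cut by a breakpoint are annotated on
#' both retained halves (same family, fragment-suffixed locus tags) with
#' correspondingly truncated proteins; fragments shorter than 60 bp are
#' dropped.
#'
#' @param genome A single-contig [annotated_genome()] with sequences.
#' @param truth Ground truth from [simulate_genome()] (or `NULL`).
#' @param completeness Target completeness fraction in (0, 1\].
#' @param n_contigs Number of pieces to cut into.
#' @param seed RNG seed.
#' @return List with `genome` (the fragmented [annotated_genome()];
#'   `completeness` holds the realized retained percentage) and `truth`
#'   (with `retained_genes`, `retained_families` and
#'   `realized_completeness` added; gene retention = at least half of the
#'   gene's length retained).
#' @export
fragment_to_mag <- function(genome, truth, completeness, n_contigs, seed) {
  stopifnot(inherits(genome, "annotated_genome"),
            nrow(genome$contigs) == 1L,
            completeness > 0, completeness <= 1, n_contigs >= 1)
  set.seed(seed)
  L <- genome$contigs$length[1]
  brk <- if (n_contigs > 1) sort(sample.int(L - 1L, n_contigs - 1L))
  else integer(0)
  starts <- c(0L, brk); ends <- c(brk, L)
  retained <- stats::runif(n_contigs) < completeness
  full_seq <- as.character(genome$seq[[1]])
  ft <- genome$features

  contigs <- list(); feats <- list(); seqs <- character(0)
  kept_len <- 0L
  ci <- 0L
  for (p in which(retained)) {
    ci <- ci + 1L
    cid <- sprintf("%s_mag_c%02d", genome$genome_id, ci)
    s <- starts[p]; e <- ends[p]
    kept_len <- kept_len + (e - s)
    contigs[[ci]] <- data.frame(id = cid, length = e - s,
                                circular = FALSE, stringsAsFactors = FALSE)
    seqs <- c(seqs, substr(full_seq, s + 1, e))
    ov <- ft[ft$end > s & ft$start < e, , drop = FALSE]
    if (!nrow(ov)) next
    for (j in seq_len(nrow(ov))) {
      gs <- max(ov$start[j], s); ge <- min(ov$end[j], e)
      if (ge - gs < 60L) next
      cut <- gs > ov$start[j] || ge < ov$end[j]
      prot <- ov$protein[j]
      if (cut && !is.na(prot)) {
        glen <- ov$end[j] - ov$start[j]
        if (ov$strand[j] == "+") {
          a0 <- gs - ov$start[j]; a1 <- ge - ov$start[j]
        } else {
          a0 <- ov$end[j] - ge; a1 <- ov$end[j] - gs
        }
        aa_from <- floor(a0 / 3) + 1L
        aa_to <- min(nchar(prot), floor(a1 / 3))
        prot <- if (aa_to >= aa_from) substr(prot, aa_from, aa_to)
        else NA_character_
      }
      feats[[length(feats) + 1L]] <- data.frame(
        contig_id = cid, start = gs - s, end = ge - s,
        strand = ov$strand[j],
        locus_tag = if (cut) paste0(ov$locus_tag[j], "_f", p)
        else ov$locus_tag[j],
        symbol = ov$symbol[j], protein = prot, stringsAsFactors = FALSE)
    }
  }
  if (!ci) {  # everything dropped: emit a minimal stub contig
    cid <- sprintf("%s_mag_c01", genome$genome_id)
    contigs[[1]] <- data.frame(id = cid, length = 0L, circular = FALSE,
                               stringsAsFactors = FALSE)
    seqs <- ""
  }
  seq <- Biostrings::DNAStringSet(seqs)
  ctab <- do.call(rbind, contigs)
  names(seq) <- ctab$id
  ftab <- if (length(feats)) do.call(rbind, feats) else
    ft[0, c("contig_id", "start", "end", "strand", "locus_tag", "symbol",
            "protein")]
  realized <- kept_len / L
  mag <- annotated_genome(paste0(genome$genome_id, "_mag"), ctab, ftab,
                          seq = seq, completeness = 100 * realized)

  ## ground truth: gene retained iff >= half its length is retained
  if (!is.null(truth)) {
    genes <- truth$genes
    kept_bp <- vapply(seq_len(nrow(genes)), function(j) {
      sum(pmax(0L, pmin(genes$end[j], ends[retained]) -
                 pmax(genes$start[j], starts[retained])))
    }, 0L)
    genes$retained <- kept_bp >= (genes$end - genes$start) / 2
    truth$genes <- genes
    truth$retained_genes <- genes$locus_tag[genes$retained]
    truth$retained_families <-
      unique(genes$family[genes$retained & genes$type == "pgc"])
    truth$realized_completeness <- realized
  }
  list(genome = mag, truth = truth)
}

## ---- packaged in-paper fixtures -----------------------------------------

#' MAG gene-inventory fixture (Greenland soil and glacier bins)
#'
#' The packaged presence/absence matrix of key functional genes across
#' the six Gemmatimonadetes MAGs from Northeast Greenland soil (ES-bin)
#' and glacial ice (LF-bin) samples, plus their assembly statistics
#' (size, GC, completeness, contamination).
#'
#' @return List with `presence` (a `presence_matrix`) and `stats`
#'   (data.frame keyed by genome id).
#' @export
table3_fixture <- function() {
  p <- system.file("extdata", "greenland_mag_markers.tsv",
                   package = "pgcfinder", mustWork = TRUE)
  s <- system.file("extdata", "greenland_mag_stats.tsv",
                   package = "pgcfinder", mustWork = TRUE)
  stats <- utils::read.delim(s, sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE)
  rownames(stats) <- stats$genome_id
  list(presence = read_presence_matrix(p), stats = stats)
}

#' Isolate marker fixture (the two phototrophic Gemmatimonas species)
#'
#' Presence/absence of the oxygen-diagnostic genes (aerobic/anaerobic
#' enzyme alternatives and oxidative-stress genes) in the two sequenced
#' phototrophic Gemmatimonas isolates.
#'
#' @return A `presence_matrix` with rows `G_groenlandica_TET16` and
#'   `G_phototrophica_AP64`.
#' @export
table2_fixture <- function() {
  p <- system.file("extdata", "gemmatimonas_isolate_markers.tsv",
                   package = "pgcfinder", mustWork = TRUE)
  read_presence_matrix(p)
}

#' Copy the packaged fixture tables to a directory
#'
#' @param dir Output directory.
#' @return Character vector of the copied paths.
#' @export
package_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("greenland_mag_markers.tsv", "greenland_mag_stats.tsv",
             "gemmatimonas_isolate_markers.tsv")
  src <- vapply(files, function(f)
    system.file("extdata", f, package = "pgcfinder", mustWork = TRUE), "")
  dest <- file.path(dir, files)
  file.copy(src, dest, overwrite = TRUE)
  dest
}
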