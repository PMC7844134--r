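## Photosynthesis-related gene family metadata: the single source of truth
## for family -> category and family -> canonical sub-cluster membership.

#' Photosynthesis-related gene family table
#'
#' Metadata for every gene family the package screens for: the functional
#' category used for category-level presence calls (`puf`, `puh`, `bch`,
#' `crt`, `regulatory`, `oxygen-marker`, `other`), the canonical sub-cluster
#' block the family belongs to (or `NA` for families outside the six
#' canonical blocks), and the length of the packaged reference protein.
#'
#' The six canonical sub-clusters are `bchP2G` (bchP, idi, bchG),
#' `bchFNBHLM`, `lhaA-puhABC`, `pufBALMC`, `crtF-bchCXYZ` and `bchID`.
#' `acsF`, `bchO`, `puhE`, `ppsR` and `aerR` are treated as singleton
#' anchors: their placement within the cluster is the diagnostic signal, so
#' they are never absorbed into a neighbouring block.
#'
#' @return A data.frame with columns `family`, `category`, `block`,
#'   `ref_length`.
#' @export
#' @examples
#' head(pgc_family_table())
pgc_family_table <- function() {
  tab <- rbind(
    c("bchP",  "bch", "bchP2G",       400L),
    c("idi",   "bch", "bchP2G",       180L),
    c("bchG",  "bch", "bchP2G",       300L),
    c("bchF",  "bch", "bchFNBHLM",    170L),
    c("bchN",  "bch", "bchFNBHLM",    430L),
    c("bchB",  "bch", "bchFNBHLM",    520L),
    c("bchH",  "bch", "bchFNBHLM",    800L),
    c("bchL",  "bch", "bchFNBHLM",    290L),
    c("bchM",  "bch", "bchFNBHLM",    220L),
    c("acsF",  "bch", NA,             350L),
    c("lhaA",  "puh", "lhaA-puhABC",  390L),
    c("puhA",  "puh", "lhaA-puhABC",  250L),
    c("puhB",  "puh", "lhaA-puhABC",  210L),
    c("puhC",  "puh", "lhaA-puhABC",  160L),
    c("puhE",  "puh", NA,             230L),
    c("pufB",  "puf", "pufBALMC",      50L),
    c("pufA",  "puf", "pufBALMC",      55L),
    c("pufL",  "puf", "pufBALMC",     280L),
    c("pufM",  "puf", "pufBALMC",     310L),
    c("pufC",  "puf", "pufBALMC",     330L),
    c("bchO",  "bch", NA,             280L),
    c("crtF",  "crt", "crtF-bchCXYZ", 300L),
    c("bchC",  "bch", "crtF-bchCXYZ", 310L),
    c("bchX",  "bch", "crtF-bchCXYZ", 330L),
    c("bchY",  "bch", "crtF-bchCXYZ", 400L),
    c("bchZ",  "bch", "crtF-bchCXYZ", 480L),
    c("ppsR",  "regulatory", NA,      460L),
    c("aerR",  "regulatory", NA,      200L),
    c("bchI",  "bch", "bchID",        340L),
    c("bchD",  "bch", "bchID",        580L),
    ## families screened for but not part of the aerobic Gemma-PGC template
    c("bchE",  "bch",          NA,    550L),
    c("hemF",  "other",        NA,    300L),
    c("hemN",  "other",        NA,    450L),
    c("hemJ",  "other",        NA,    170L),
    c("hemG",  "other",        NA,    180L),
    c("BphP",  "oxygen-marker", NA,   600L),
    c("BphO",  "oxygen-marker", NA,   210L),
    c("RubisCO-like",   "other", NA,  430L),
    c("rhodopsin-like", "other", NA,  250L)
  )
  out <- data.frame(family = tab[, 1], category = tab[, 2], block = tab[, 3],
                    ref_length = as.integer(tab[, 4]),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$family
  out
}

## Singleton anchors with positional meaning inside the PGC.
.singleton_anchors <- c("acsF", "bchO", "puhE", "ppsR", "aerR")

## Categories whose members are chained into PGC candidates.
.pgc_categories <- c("bch", "puf", "puh", "crt", "regulatory")

#' Canonical sub-cluster membership
#'
#' Maps a vector of family names to the canonical sub-cluster block each
#' belongs to.  Families outside the six canonical blocks map to their own
#' name (singleton block), so every family has a well-defined block label.
#'
#' @param family Character vector of family names.
#' @return Character vector of block labels, same length as `family`.
#' @export
family_block <- function(family) {
  tab <- pgc_family_table()
  blk <- tab[family, "block"]
  blk[is.na(blk)] <- family[is.na(blk)]
  blk
}

#' Gene family category lookup
#'
#' @param family Character vector of family names.
#' @return Character vector of categories (`NA` for unknown families).
#' @export
family_category <- function(family) {
  pgc_family_table()[family, "category"]
}

#' Read a family reference protein set
#'
#' Reads a protein FASTA whose headers follow `>family|source` and returns
#' an [Biostrings::AAStringSet] named by family.  Duplicate family entries
#' are an error: the search assumes one representative per family.
#'
#' @param path Path to the reference FASTA.
#' @return An `AAStringSet` named by family.
#' @export
read_family_refs <- function(path) {
  refs <- Biostrings::readAAStringSet(path)
  fam <- vapply(strsplit(names(refs), "|", fixed = TRUE), `[`, "", 1L)
  fam <- trimws(fam)
  if (anyDuplicated(fam))
    stop("duplicate family entries in reference set: ",
         paste(unique(fam[duplicated(fam)]), collapse = ", "))
  names(refs) <- fam
  refs
}

#' Packaged family reference proteins
#'
#' Returns the reference protein set shipped with the package.  These are
#' synthetic stand-in sequences (one per family, lengths matching
#' `pgc_family_table()`), generated once with a fixed random seed; they are
#' not transcriptions of any deposited protein.  All simulations and tests
#' are expressed relative to this set, so no download is ever required.
#'
#' @return An `AAStringSet` named by family.
#' @export
default_family_refs <- function() {
  path <- system.file("extdata", "pgc_family_refs_synthetic.faa",
                      package = "pgcfinder", mustWork = TRUE)
  read_family_refs(path)
}

#' Gemmatimonadetes PGC architecture template
#'
#' The packaged Gemma-PGC gene-order template: six canonical multi-gene
#' sub-clusters plus the singleton anchors, with `acsF` between
#' `bchFNBHLM` and `lhaA-puhABC` and `bchO` between `pufBALMC` and
#' `crtF-bchCXYZ` — the two placements diagnostic for Gemmatimonadetes.
#' Rows are in genomic order; `hyp` rows mark the hypothetical-ORF stretch
#' between the puh and puf operons.
#'
#' @return A data.frame with columns `family`, `strand`, `block` and
#'   logical `hypothetical`.
#' @export
gemma_pgc_template <- function() {
  g <- function(fams, strand) data.frame(family = fams, strand = strand,
                                         stringsAsFactors = FALSE)
  tmpl <- rbind(
    g(c("bchP", "idi", "bchG"), "+"),
    g(c("bchM", "bchL", "bchH", "bchB", "bchN", "bchF"), "-"),
    g("acsF", "-"),
    g(c("lhaA", "puhA", "puhB", "puhC"), "+"),
    g("puhE", "+"),
    g(c("hyp1", "hyp2", "hyp3"), "+"),
    g(c("pufB", "pufA", "pufL", "pufM", "pufC"), "+"),
    g("bchO", "+"),
    g(c("crtF", "bchC", "bchX", "bchY", "bchZ"), "-"),
    g("ppsR", "-"),
    g("aerR", "+"),
    g(c("bchI", "bchD"), "+")
  )
  tmpl$hypothetical <- grepl("^hyp", tmpl$family)
  tmpl$block <- NA_character_
  tmpl$block[!tmpl$hypothetical] <- family_block(tmpl$family[!tmpl$hypothetical])
  rownames(tmpl) <- NULL
  tmpl
}

#' Packaged proteobacterial PGC architectures
#'
#' Reference PGC architectures for representative proteobacterial classes,
#' used as the contrast set when asserting that the Gemmatimonadetes
#' architecture is unique.  These are synthetic stand-ins encoding
#' plausible proteobacterial block orders and orientations (reconstructed
#' from the literature on purple-bacterial PGC organization), not
#' transcriptions of specific genomes.
#'
#' @return A named list of [architecture_signature()] objects.
#' @export
proteobacterial_architectures <- function() {
  path <- system.file("extdata",
                      "proteobacterial_pgc_architectures_synthetic.json",
                      package = "pgcfinder", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(raw, function(x) {
    blocks <- data.frame(
      name = vapply(x$blocks, `[[`, "", "name"),
      orientation = vapply(x$blocks, `[[`, "", "orientation"),
      n_members = vapply(x$blocks, function(b) as.integer(b$n_members), 1L),
      stringsAsFactors = FALSE
    )
    architecture_signature(blocks)
  })
  names(out) <- vapply(raw, `[[`, "", "class")
  out
}
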