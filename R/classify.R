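## Decision rules: CGB membership (>=1 puf + >=1 puh + >=1 bch gene),
## oxygen-lifestyle indication (bchE absent + BphP and BphO present =>
## aerobic-indicated), and identity-threshold taxonomic delimitation.

#' Oxygen-lifestyle rule set
#'
#' The aerobic indication requires the absence of the anaerobic cyclase
#' gene `bchE` together with the presence of the bacteriophytochrome
#' genes `BphP` and `BphO`; the presence of `bchE` indicates a
#' microaerophilic lifestyle.  Because an absence in an incomplete MAG is
#' weak evidence, any call that depends on an absence is downgraded to
#' `indeterminate` when genome completeness falls below
#' `completeness_floor`.
#'
#' @param require_absent Families that must be absent; default `bchE`.
#' @param require_present Families that must be present; default
#'   `BphP`, `BphO`.
#' @param completeness_floor Completeness (%) below which absence-based
#'   calls are not trusted; default 75.
#' @return An `oxygen_rules` list.
#' @export
oxygen_rules <- function(require_absent = "bchE",
                         require_present = c("BphP", "BphO"),
                         completeness_floor = 75) {
  if (length(intersect(require_absent, require_present)))
    stop("require_absent and require_present must be disjoint")
  structure(list(require_absent = require_absent,
                 require_present = require_present,
                 completeness_floor = completeness_floor),
            class = "oxygen_rules")
}

#' Taxonomic delimitation thresholds
#'
#' ANI 95--96% is the conventional species boundary; 16S rRNA identity
#' 95% / 98.7% are the conventional genus / species boundaries.
#'
#' @param ani_species_low,ani_species_high ANI species band (%); defaults
#'   95 and 96.
#' @param ssu_genus,ssu_species 16S identity thresholds (%); defaults 95
#'   and 98.7.
#' @return A `taxonomy_thresholds` list.
#' @export
taxonomy_thresholds <- function(ani_species_low = 95, ani_species_high = 96,
                                ssu_genus = 95, ssu_species = 98.7) {
  stopifnot(ani_species_low <= ani_species_high, ssu_genus < ssu_species)
  structure(list(ani_species_low = ani_species_low,
                 ani_species_high = ani_species_high,
                 ssu_genus = ssu_genus, ssu_species = ssu_species),
            class = "taxonomy_thresholds")
}

.get_row <- function(row, needed) {
  if (inherits(row, "presence_matrix")) {
    if (nrow(row) != 1) stop("expected a single presence-matrix row")
    row <- setNames(as.vector(row[1, ]), colnames(row))
  }
  miss <- setdiff(needed, names(row))
  if (length(miss)) stop("missing marker column(s): ",
                         paste(miss, collapse = ", "))
  row
}

#' CGB membership call
#'
#' A genome belongs to the chlorophototrophic Gemmatimonadetes bacteria
#' (CGB) iff it carries at least one `puf`, one `puh` and one `bch` gene.
#' `unknown` cells count as absent (conservative inclusion).
#'
#' @param row A named character vector of presence states (or a 1-row
#'   `presence_matrix`) covering markers `puf`, `puh`, `bch`.
#' @return `"CGB"` or `"non-CGB"`.
#' @export
classify_cgb <- function(row) {
  row <- .get_row(row, c("puf", "puh", "bch"))
  if (all(row[c("puf", "puh", "bch")] == "present")) "CGB" else "non-CGB"
}

#' Oxygen-lifestyle indication
#'
#' `aerobic-indicated` iff every `require_absent` family is absent and
#' every `require_present` family is present; `microaerophilic-indicated`
#' iff any `require_absent` family (bchE by default) is present; otherwise
#' `indeterminate`.  When `completeness < completeness_floor`, a call that
#' relies on an absence is downgraded to `indeterminate` (the absence may
#' be an assembly gap, not a biological signal); `unknown` cells are not
#' evaluable as absences.
#'
#' @param row Named presence vector (or 1-row `presence_matrix`) covering
#'   the rule's markers.
#' @param completeness Genome completeness (%), `NA` for complete
#'   genomes/isolates.
#' @param rules An [oxygen_rules()].
#' @return One of `"aerobic-indicated"`, `"microaerophilic-indicated"`,
#'   `"indeterminate"`, with attribute `evidence` listing every marker
#'   consulted and attribute `downgraded` when the completeness floor
#'   suppressed an absence-based call.
#' @export
classify_oxygen <- function(row, completeness = NA_real_,
                            rules = oxygen_rules()) {
  row <- .get_row(row, c(rules$require_absent, rules$require_present))
  evidence <- row[c(rules$require_absent, rules$require_present)]
  absent_ok <- all(row[rules$require_absent] == "absent")
  present_ok <- all(row[rules$require_present] == "present")
  any_marker_present <- any(row[rules$require_absent] == "present")
  trusted_absence <- is.na(completeness) ||
    completeness >= rules$completeness_floor
  downgraded <- FALSE
  call <- if (any_marker_present) {
    "microaerophilic-indicated"
  } else if (absent_ok && present_ok) {
    if (trusted_absence) "aerobic-indicated" else {
      downgraded <- TRUE
      "indeterminate"
    }
  } else "indeterminate"
  structure(call, evidence = evidence, downgraded = downgraded)
}

#' Threshold-based taxonomic delimitation
#'
#' Applies the conventional identity thresholds: ANI at or above the top
#' of the species band means same species; ANI below the band means a
#' different species, and 16S identity then decides whether it falls in
#' the same genus (`> ssu_genus`) or is a new genus candidate.  An ANI
#' inside the species band is reported as conflicting evidence unless the
#' 16S identity independently corroborates the same-species call.  With
#' only a 16S value, the 16S thresholds alone decide.  Without a 16S
#' value, an ANI below the species band is reported at the most
#' conservative rank change (new species, same genus).
#'
#' @param ani Average nucleotide identity (%), or `NA`.
#' @param ssu_identity 16S rRNA gene identity (%), or `NA`.
#' @param thresholds A [taxonomy_thresholds()].
#' @return One of `"same species"`, `"new species same genus"`,
#'   `"new genus candidate"`, `"conflicting evidence"`.
#' @export
delimit_taxon <- function(ani = NA_real_, ssu_identity = NA_real_,
                          thresholds = taxonomy_thresholds()) {
  if (is.na(ani) && is.na(ssu_identity))
    stop("at least one of ani and ssu_identity is required")
  th <- thresholds
  if (is.na(ani)) {
    return(if (ssu_identity > th$ssu_species) "same species"
           else if (ssu_identity > th$ssu_genus) "new species same genus"
           else "new genus candidate")
  }
  if (ani >= th$ani_species_high) return("same species")
  if (ani < th$ani_species_low) {
    if (is.na(ssu_identity)) return("new species same genus")
    return(if (ssu_identity > th$ssu_genus) "new species same genus"
           else "new genus candidate")
  }
  ## ANI inside the species band: only corroborating 16S resolves it
  if (!is.na(ssu_identity) && ssu_identity > th$ssu_species)
    return("same species")
  "conflicting evidence"
}

#' Classify every row of a presence matrix
#'
#' Convenience wrapper applying [classify_cgb()] and [classify_oxygen()]
#' to each genome of a presence matrix.
#'
#' @param m A `presence_matrix`.
#' @param completeness Optional named numeric vector of completeness (%)
#'   per genome id.
#' @param rules An [oxygen_rules()].
#' @return data.frame with columns `genome_id`, `cgb`, `oxygen`.
#' @export
classify_matrix <- function(m, completeness = NULL,
                            rules = oxygen_rules()) {
  ids <- rownames(m)
  res <- data.frame(genome_id = ids,
                    cgb = NA_character_, oxygen = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    row <- setNames(as.vector(m[i, ]), colnames(m))
    res$cgb[i] <- classify_cgb(row)
    comp <- if (!is.null(completeness) && ids[i] %in% names(completeness))
      completeness[[ids[i]]] else NA_real_
    res$oxygen[i] <- as.character(classify_oxygen(row, comp, rules))
  }
  res
}
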