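refs <- default_family_refs()

## Build a genome carrying the given proteins as consecutive genes.
protein_genome <- function(proteins, gap = 200L, ids = NULL) {
  starts <- integer(length(proteins))
  pos <- 0L
  ends <- integer(length(proteins))
  for (i in seq_along(proteins)) {
    starts[i] <- pos
    ends[i] <- pos + 3L * (nchar(proteins[i]) + 1L)
    pos <- ends[i] + gap
  }
  genes <- data.frame(start = starts, end = ends, strand = "+",
                      locus_tag = ids %||% paste0("g", seq_along(proteins)),
                      protein = proteins, stringsAsFactors = FALSE)
  tiny_genome(genes, contig_len = pos + 100L)
}

test_that("self-search of every packaged reference hits its own family at 100%", {
  g <- protein_genome(as.character(refs), ids = paste0("q_", names(refs)))
  a <- assign_families(g, refs)
  expect_equal(nrow(a), length(refs))
  expect_equal(a$family[match(paste0("q_", names(refs)), a$locus_tag)],
               names(refs))
  expect_true(all(a$identity == 100))
  expect_true(all(a$coverage == 1))
  expect_true(all(a$evalue < 1e-5))
})

test_that("a ~60% identity bchL query is assigned bchL with the oracle's exact score", {
  set.seed(101)
  q <- mutate_uniform(as.character(refs[["bchL"]]), 0.60)
  g <- protein_genome(q)
  a <- assign_families(g, refs)
  expect_equal(a$family, "bchL")
  ## bit score must correspond exactly to the independent full-DP score
  s_oracle <- sw_score_reference(as.character(refs[["bchL"]]), q)
  expect_equal(a$bit_score, (0.267 * s_oracle - log(0.041)) / log(2))
})

test_that("alignment engine scores equal the full-DP reference on random pairs", {
  set.seed(2024)
  for (i in 1:20) {
    a <- random_aa_seq(sample(30:200, 1))
    b <- random_aa_seq(sample(30:200, 1))
    s_impl <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(s_impl, sw_score_reference(a, b))
  }
})

test_that("weak homology fails E_max at defaults but passes a loose E_max", {
  set.seed(55)
  ## a short, heavily mutated fragment: real signal, weak significance
  frag <- mutate_uniform(substr(as.character(refs[["puhC"]]), 1, 40), 0.65)
  g <- protein_genome(frag)
  strict <- assign_families(g, refs, search_thresholds(E_max = 1e-12))
  loose <- assign_families(g, refs, search_thresholds(E_max = 1e-2,
                                                      C_min = 0.1))
  expect_equal(nrow(strict), 0L)
  expect_gt(nrow(loose), 0L)
})

test_that("lowering E_max or raising C_min never adds assignments", {
  sim <- simulate_genome(quick_spec(21, target_protein_identity = 0.6,
                                    verify_background = FALSE))
  base <- assign_families(sim$genome, refs, search_thresholds())
  tighter_e <- assign_families(sim$genome, refs,
                               search_thresholds(E_max = 1e-30))
  tighter_c <- assign_families(sim$genome, refs,
                               search_thresholds(C_min = 0.9))
  expect_true(all(tighter_e$locus_tag %in% base$locus_tag))
  expect_true(all(tighter_c$locus_tag %in% base$locus_tag))
  expect_lte(nrow(tighter_e), nrow(base))
  expect_lte(nrow(tighter_c), nrow(base))
})

test_that("coverage is measured against the reference length", {
  ## half of acsF aligned -> coverage ~0.5, fails the 0.40 rule only
  ## when below it; a 30% fragment must fail
  frag <- substr(as.character(refs[["acsF"]]), 1, 105)  # 30% of 350
  g <- protein_genome(frag)
  a <- assign_families(g, refs)
  expect_equal(nrow(a), 0L)
  a2 <- assign_families(g, refs, search_thresholds(C_min = 0.2))
  expect_equal(a2$family, "acsF")
  expect_lt(a2$coverage, 0.35)
})

test_that("same-family fragments within split_gap merge as a split gene", {
  p <- as.character(refs[["acsF"]])
  L <- nchar(p)
  ## thirds: each ~33% coverage, individually below the 0.40 rule
  thirds <- c(substr(p, 1, floor(L / 3)),
              substr(p, floor(L / 3) + 1, floor(2 * L / 3)),
              substr(p, floor(2 * L / 3) + 1, L))
  g <- protein_genome(thirds, gap = 500L, ids = c("f1", "f2", "f3"))
  a <- assign_families(g, refs)
  expect_equal(nrow(a), 3L)
  expect_true(all(a$split))
  expect_true(all(a$family == "acsF"))
  ## far apart: no merge possible, each fragment fails coverage alone
  g2 <- protein_genome(thirds, gap = 5000L, ids = c("f1", "f2", "f3"))
  a2 <- assign_families(g2, refs)
  expect_equal(nrow(a2), 0L)
  ## halves pass coverage individually but are still flagged as split
  ## fragments when adjacent
  h <- floor(L / 2)
  halves <- c(substr(p, 1, h), substr(p, h + 1, L))
  a3 <- assign_families(protein_genome(halves, gap = 500L), refs)
  expect_equal(nrow(a3), 2L)
  expect_true(all(a3$split))
})

test_that("non-standard residues are treated as mismatch with a warning", {
  p <- as.character(refs[["bchM"]])
  substr(p, 10, 10) <- "U"
  g <- protein_genome(p)
  expect_warning(a <- assign_families(g, refs), "non-standard")
  expect_equal(a$family, "bchM")
  expect_lt(a$identity, 100)
})

test_that("empty reference set errors", {
  g <- protein_genome("MKLV")
  expect_error(assign_families(g, refs[0]), "empty reference set")
})

test_that("presence matrix from assignments uses category-level markers", {
  sim <- simulate_genome(quick_spec(31, verify_background = FALSE))
  a <- assign_families(sim$genome, refs)
  pm <- build_presence_matrix(list(SIM = a))
  expect_equal(unname(pm["SIM", c("puf", "puh", "bch")]),
               rep("present", 3))
  expect_equal(unname(pm["SIM", "bchE"]), "absent")
  expect_equal(unname(pm["SIM", c("BphP", "BphO")]), rep("present", 2))
  ## empty assignment list -> all-absent row
  pm0 <- build_presence_matrix(list(EMPTY = a[0, ]))
  expect_true(all(pm0 == "absent"))
})

test_that("two pufM fragments alone yield puf=present and nothing else", {
  p <- as.character(refs[["pufM"]])
  h <- floor(nchar(p) / 2)
  g <- protein_genome(c(substr(p, 1, h), substr(p, h + 1, nchar(p))),
                      gap = 400L)
  a <- assign_families(g, refs)
  pm <- build_presence_matrix(list(x = a))
  expect_equal(unname(pm["x", "puf"]), "present")
  expect_true(all(pm["x", setdiff(colnames(pm), "puf")] == "absent"))
})
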