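refs <- default_family_refs()

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## copy `seq` with each base substituted with prob `p`
mutate_dna <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < p
  chars[hit] <- vapply(chars[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(chars, collapse = "")
}

test_that("identical protein pairs report 100% identity, flagged high", {
  sim <- simulate_genome(quick_spec(81, verify_background = FALSE))
  a <- assign_families(sim$genome, refs)
  cl <- detect_clusters(sim$genome, a)[[1]]
  gp <- pairwise_gene_identity(cl, cl)
  expect_true(all(gp$identity == 100))
  expect_true(all(gp$high_identity))
  expect_length(attr(gp, "unpaired")$a_only, 0L)
})

test_that("the >90% flag is strict and matches realized identities", {
  set.seed(82)
  mk_cluster <- function(target) {
    prots <- lapply(c("acsF", "bchO", "puhE"), function(f) {
      p <- as.character(refs[[f]])
      if (target < 1) mutate_uniform(p, target) else p
    })
    members <- data.frame(
      contig_id = "c", start = seq(0, by = 2000, length.out = 3),
      end = seq(0, by = 2000, length.out = 3) + 1000,
      strand = "+", locus_tag = paste0("g", 1:3),
      protein = unlist(prots), family = c("acsF", "bchO", "puhE"),
      split = FALSE, stringsAsFactors = FALSE)
    list(genome_id = "x", contig_id = "c", members = members,
         span = data.frame(contig_id = "c", start = 0, end = 7000),
         wrapped = FALSE)
  }
  ref_cl <- mk_cluster(1)
  hi <- mk_cluster(0.92)
  lo <- mk_cluster(0.88)
  gp_hi <- pairwise_gene_identity(ref_cl, hi)
  gp_lo <- pairwise_gene_identity(ref_cl, lo)
  ## realized identities verified against the closed-form oracle for
  ## indel-free pairs
  for (i in seq_len(nrow(gp_hi))) {
    f <- gp_hi$family[i]
    expect_equal(gp_hi$identity[i],
                 oracle_hamming_identity(
                   ref_cl$members$protein[ref_cl$members$family == f],
                   hi$members$protein[hi$members$family == f]))
  }
  expect_true(all(gp_hi$high_identity))
  expect_true(all(!gp_lo$high_identity))
  expect_true(all(gp_hi$identity > 90 & gp_hi$identity < 96))
  expect_true(all(gp_lo$identity > 84 & gp_lo$identity < 90.5))
})

test_that("identity exactly 90.0 is not flagged high", {
  ## 10-residue protein with exactly 9 matches = 90.0%
  a <- "ARNDCQEGHI"
  b <- "ARNDCQEGHL"
  r <- global_protein_identity(a, b)
  expect_equal(r$identity, 90)
  members <- function(p) data.frame(
    contig_id = "c", start = 0, end = 33, strand = "+", locus_tag = "g",
    protein = p, family = "acsF", split = FALSE, stringsAsFactors = FALSE)
  cl_a <- list(members = members(a))
  cl_b <- list(members = members(b))
  gp <- pairwise_gene_identity(cl_a, cl_b)
  expect_false(gp$high_identity)
})

test_that("families present in only one PGC are reported unpaired", {
  mk <- function(fams) {
    members <- data.frame(
      contig_id = "c", start = seq_along(fams) * 1000,
      end = seq_along(fams) * 1000 + 500, strand = "+",
      locus_tag = paste0("g", seq_along(fams)),
      protein = vapply(fams, function(f) as.character(refs[[f]]), ""),
      family = fams, split = FALSE, stringsAsFactors = FALSE)
    list(members = members)
  }
  gp <- pairwise_gene_identity(mk(c("acsF", "bchO")), mk(c("acsF", "puhE")))
  expect_equal(gp$family, "acsF")
  expect_equal(attr(gp, "unpaired")$a_only, "bchO")
  expect_equal(attr(gp, "unpaired")$b_only, "puhE")
})

test_that("a sequence against itself yields one full-length 100% block", {
  set.seed(83)
  s <- rand_dna(10000)
  b <- synteny_blocks(s, s, dialect = "pgc")
  expect_equal(nrow(b), 1L)
  expect_equal(b$identity, 100)
  expect_equal(b$length, 10000L)
  expect_equal(b$orientation, "same")
})

test_that("a 400 bp exact repeat is excluded under the pgc dialect", {
  set.seed(84)
  repeat_seq <- rand_dna(400)
  a <- paste0(rand_dna(3000), repeat_seq, rand_dna(3000))
  b <- paste0(rand_dna(2000), repeat_seq, rand_dna(4000))
  blocks <- synteny_blocks(a, b, dialect = "pgc")
  expect_equal(nrow(blocks), 0L)
  ## but it is found with an explicit lower length cutoff
  blocks2 <- synteny_blocks(a, b, min_identity = 70, min_length = 100)
  expect_equal(nrow(blocks2), 1L)
  expect_gte(blocks2$length, 400L)
})

test_that("two ~85% identity 3 kb islands are recovered within +/-50 bp", {
  set.seed(85)
  isl1 <- rand_dna(3000); isl2 <- rand_dna(3000)
  a <- paste0(rand_dna(1500), isl1, rand_dna(2500), isl2, rand_dna(1500))
  b <- paste0(rand_dna(1000), mutate_dna(isl1, 0.15), rand_dna(3500),
              mutate_dna(isl2, 0.15), rand_dna(2000))
  blocks <- synteny_blocks(a, b, dialect = "pgc")
  expect_equal(nrow(blocks), 2L)
  expect_true(all(blocks$identity > 80 & blocks$identity < 92))
  a_starts <- sort(blocks$a_start)
  expect_lt(abs(a_starts[1] - 1501), 50)
  expect_lt(abs(a_starts[2] - (1500 + 3000 + 2500 + 1)), 50)
  ## the genome dialect also accepts these blocks (id > 80, len > 2 kb)
  g <- synteny_blocks(a, b, dialect = "genome")
  expect_equal(nrow(g), 2L)
})

test_that("every genome-dialect block also qualifies under the pgc dialect", {
  set.seed(86)
  core <- rand_dna(8000)
  a <- paste0(rand_dna(1000), core, rand_dna(1000))
  b <- paste0(rand_dna(500), mutate_dna(core, 0.1), rand_dna(1500))
  gb <- synteny_blocks(a, b, dialect = "genome")
  pb <- synteny_blocks(a, b, dialect = "pgc")
  expect_gt(nrow(gb), 0L)
  for (i in seq_len(nrow(gb)))
    expect_true(any(pb$a_start <= gb$a_start[i] &
                      pb$a_end >= gb$a_end[i]))
})

test_that("reverse-complementing seq_b inverts orientations, keeps identity", {
  set.seed(87)
  core <- rand_dna(4000)
  a <- paste0(rand_dna(800), core, rand_dna(800))
  b <- paste0(rand_dna(400), mutate_dna(core, 0.1), rand_dna(1200))
  fwd <- synteny_blocks(a, b, dialect = "pgc")
  brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  rev <- synteny_blocks(a, brc, dialect = "pgc")
  expect_equal(nrow(fwd), nrow(rev))
  expect_true(all(fwd$orientation == "same"))
  expect_true(all(rev$orientation == "inverted"))
  expect_equal(sort(fwd$identity), sort(rev$identity))
  ## coordinates on b map back through the reverse complement
  expect_equal(sort(nchar(b) - rev$b_end + 1L), sort(fwd$b_start))
})

test_that("block count is symmetric under argument swap", {
  set.seed(88)
  core <- rand_dna(3000)
  a <- paste0(rand_dna(700), core, rand_dna(900))
  b <- paste0(rand_dna(1100), mutate_dna(core, 0.12), rand_dna(600))
  ab <- synteny_blocks(a, b, dialect = "pgc")
  ba <- synteny_blocks(b, a, dialect = "pgc")
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(sort(ab$length), sort(ba$length))
})

test_that("empty sequences give an empty block list", {
  expect_equal(nrow(synteny_blocks("", "ACGT")), 0L)
  expect_error(synteny_blocks("ACGU", "ACGT"), "alphabet")
})
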