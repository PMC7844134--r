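refs <- default_family_refs()

canonical_names <- c("bchP2G", "bchFNBHLM", "lhaA-puhABC", "pufBALMC",
                     "crtF-bchCXYZ", "bchID")

test_that("the template segments into six canonical multi-gene blocks with both markers", {
  sig <- gemma_template_signature()
  canon <- sig$blocks[sig$blocks$name %in% canonical_names, ]
  expect_equal(nrow(canon), 6L)
  expect_true(all(canon$n_members > 1))
  expect_true(sig$acsF_marker)
  expect_true(sig$bchO_marker)
  ## the singleton anchors are present as their own blocks
  expect_true(all(c("acsF", "bchO", "puhE", "ppsR", "aerR") %in%
                    sig$blocks$name))
})

test_that("segmentation of a detected cluster matches the template signature", {
  sim <- simulate_genome(quick_spec(71, verify_background = FALSE))
  a <- assign_families(sim$genome, refs)
  cl <- detect_clusters(sim$genome, a)
  sig <- segment_subclusters(cl[[1]])
  expect_equal(sig$blocks[, c("name", "orientation", "n_members")],
               gemma_template_signature()$blocks[, c("name", "orientation",
                                                     "n_members")])
  expect_equal(compare_architectures(sig, gemma_template_signature()), 0L)
})

test_that("empty clusters give an empty signature", {
  sig <- segment_subclusters(NULL)
  expect_equal(nrow(sig$blocks), 0L)
  expect_false(sig$acsF_marker)
  expect_true("acsF" %in% sig$missing)
})

test_that("segmentation equals a brute-force maximal-run oracle on shuffles", {
  tmpl <- gemma_pgc_template()
  tmpl <- tmpl[!tmpl$hypothetical, ]
  set.seed(90)
  for (i in 1:10) {
    perm <- sample(nrow(tmpl))
    fam <- tmpl$family[perm]; strand <- tmpl$strand[perm]
    sig <- architecture_signature(pgcfinder:::.segment_families(fam, strand))
    expected <- oracle_runs(family_block(fam), canonical_names)
    got_names <- sig$blocks$name
    ## the signature may be the flipped reading; compare both directions
    ok <- identical(got_names, expected) ||
      identical(got_names, rev(expected))
    expect_true(ok)
  }
})

test_that("segmentation is invariant to whole-cluster strand flip + reversal", {
  sim <- simulate_genome(quick_spec(72, verify_background = FALSE))
  a <- assign_families(sim$genome, refs)
  cl <- detect_clusters(sim$genome, a)[[1]]
  sig <- segment_subclusters(cl)
  flipped <- cl
  flipped$members <- flipped$members[rev(seq_len(nrow(flipped$members))), ]
  flipped$members$strand <- ifelse(flipped$members$strand == "+", "-", "+")
  sigf <- segment_subclusters(flipped)
  expect_equal(sig$blocks, sigf$blocks)
  expect_equal(sig$acsF_marker, sigf$acsF_marker)
})

test_that("relocating acsF breaks only the acsF marker", {
  tmpl <- gemma_pgc_template()
  tmpl <- tmpl[!tmpl$hypothetical, ]
  ## move acsF after the bchID sub-cluster
  acsF_row <- tmpl[tmpl$family == "acsF", ]
  tmpl2 <- rbind(tmpl[tmpl$family != "acsF", ], acsF_row)
  sig2 <- architecture_signature(
    pgcfinder:::.segment_families(tmpl2$family, tmpl2$strand))
  expect_false(sig2$acsF_marker)
  expect_true(sig2$bchO_marker)
})

test_that("a signature lacking acsF reports it missing", {
  tmpl <- gemma_pgc_template()
  tmpl <- tmpl[!tmpl$hypothetical & tmpl$family != "acsF", ]
  sig <- architecture_signature(
    pgcfinder:::.segment_families(tmpl$family, tmpl$strand))
  expect_false(sig$acsF_marker)
  expect_equal(sig$missing, "acsF")
})

test_that("distance is zero on self and symmetric", {
  t0 <- gemma_template_signature()
  expect_equal(compare_architectures(t0, t0), 0L)
  for (p in proteobacterial_architectures()) {
    expect_equal(compare_architectures(t0, p), compare_architectures(p, t0))
    expect_gt(compare_architectures(t0, p), 0L)
  }
})

test_that("distance matches the exhaustive oracle on all permutations of 4 blocks", {
  blocks4 <- c("bchP2G", "bchFNBHLM", "pufBALMC", "bchID")
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  mk <- function(ord, ori = rep("forward", length(ord))) {
    architecture_signature(data.frame(name = ord, orientation = ori,
                                      n_members = 2L,
                                      stringsAsFactors = FALSE))
  }
  ref <- mk(blocks4)
  for (p in perms(blocks4)) {
    sig <- mk(p)
    expect_equal(compare_architectures(ref, sig),
                 oracle_architecture_distance(ref, sig))
  }
  ## orientation flips add to the distance
  flipped <- mk(blocks4, c("reverse", "forward", "forward", "forward"))
  expect_equal(compare_architectures(ref, flipped),
               oracle_architecture_distance(ref, flipped))
  expect_gt(compare_architectures(ref, flipped), 0L)
})

test_that("blocks present in exactly one signature count toward the distance", {
  a <- architecture_signature(data.frame(
    name = c("bchP2G", "bchFNBHLM"), orientation = "forward",
    n_members = 2L, stringsAsFactors = FALSE))
  b <- architecture_signature(data.frame(
    name = c("bchP2G", "bchFNBHLM", "acsF"), orientation = "forward",
    n_members = c(2L, 2L, 1L), stringsAsFactors = FALSE))
  expect_equal(compare_architectures(a, b), 1L)
})

test_that("single-transposition permutations move away from the template and markers flip as planted", {
  tmpl <- gemma_pgc_template()
  t0 <- gemma_template_signature()
  ## block-unit sequence in template order
  units <- rle(ifelse(tmpl$hypothetical, "HYP",
                      family_block(tmpl$family)))$values
  units <- units[units != "HYP"]
  for (i in seq_len(length(units) - 1)) {
    sw <- units
    sw[c(i, i + 1)] <- sw[c(i + 1, i)]
    ## rebuild a gene-level architecture from the swapped unit order
    rows <- do.call(rbind, lapply(sw, function(u) {
      tmpl[!tmpl$hypothetical &
             family_block(tmpl$family) == u, , drop = FALSE]
    }))
    sig <- architecture_signature(
      pgcfinder:::.segment_families(rows$family, rows$strand))
    expect_gt(compare_architectures(t0, sig), 0L)
    ## markers flip exactly when the acsF / bchO slots are disturbed
    pos <- function(u, v) match(u, v)
    acsF_between <- {
      p <- pos("acsF", sw)
      l <- pos("bchFNBHLM", sw); r <- pos("lhaA-puhABC", sw)
      min(l, r) < p && p < max(l, r)
    }
    bchO_between <- {
      p <- pos("bchO", sw)
      l <- pos("pufBALMC", sw); r <- pos("crtF-bchCXYZ", sw)
      min(l, r) < p && p < max(l, r)
    }
    expect_equal(sig$acsF_marker, acsF_between)
    expect_equal(sig$bchO_marker, bchO_between)
  }
})
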