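mk_call <- function(query, species, chrom = "c1", start = 100L, end = 500L,
                    evalue = 1e-40, score = 200L) {
  tibble(query_id = query, chrom = chrom, strand = "+", start = start,
         end = end, qstart = 0L, qend = 400L, score = score,
         evalue = evalue, species = species, reciprocal = TRUE,
         syntenic = TRUE, overlapping_gene = NA_character_,
         promoted = TRUE)
}

test_that("the conservation criterion needs four species spanning lineage II", {
  tr <- fixture_tree()
  cfg <- lincphylo_config()
  # focal + A. lyrata only: 2 species
  f1 <- build_families(mk_call("q1", "Aly"), tr, cfg)
  expect_false(f1$conserved)
  expect_equal(f1$n_species, 2L)
  # focal + 3 lineage-I species, no lineage II
  f2 <- build_families(dplyr::bind_rows(
    mk_call("q2", "Aly", start = 100L),
    mk_call("q2", "Cgra", start = 1000L),
    mk_call("q2", "Crub", start = 2000L)), tr, cfg)
  expect_equal(f2$n_species, 4L)
  expect_false(f2$conserved)
  # focal + C. rubella + S. parvula + E. salsugineum
  f3 <- build_families(dplyr::bind_rows(
    mk_call("q3", "Crub", start = 100L),
    mk_call("q3", "Spa", start = 1000L),
    mk_call("q3", "Esa", start = 2000L)), tr, cfg)
  expect_true(f3$conserved)
  expect_equal(f3$depth_age, 42)
})

test_that("depth is the MRCA age of the most divergent member and is monotone", {
  tr <- fixture_tree()
  cfg <- lincphylo_config()
  f <- build_families(mk_call("q", "Aly"), tr, cfg)
  expect_equal(f$depth_age, 13)
  f <- build_families(dplyr::bind_rows(mk_call("q", "Aly", start = 1L),
                                       mk_call("q", "Crub", start = 600L)),
                      tr, cfg)
  expect_equal(f$depth_age, 18)
  f <- build_families(dplyr::bind_rows(mk_call("q", "Aly", start = 1L),
                                       mk_call("q", "Crub", start = 600L),
                                       mk_call("q", "Tha", start = 1200L)),
                      tr, cfg)
  expect_equal(f$depth_age, 65)
})

test_that("a contested interval is kept only in the lowest-E family", {
  tr <- fixture_tree()
  cfg <- lincphylo_config()
  calls <- dplyr::bind_rows(
    mk_call("q1", "Spa", start = 100L, end = 500L, evalue = 1e-50),
    mk_call("q2", "Spa", start = 300L, end = 700L, evalue = 1e-30),
    mk_call("q2", "Esa", start = 5000L, end = 5400L, evalue = 1e-45))
  fams <- build_families(calls, tr, cfg)
  m1 <- fams$members[[which(fams$query_id == "q1")]]
  m2 <- fams$members[[which(fams$query_id == "q2")]]
  expect_true("Spa" %in% m1$species)
  expect_false("Spa" %in% m2$species)
  expect_true("Esa" %in% m2$species)
  # no interval appears in more than one family
  all_mb <- dplyr::bind_rows(fams$members)
  expect_equal(anyDuplicated(all_mb[, c("species", "chrom", "start")]), 0L)
})

test_that("ORF screen applies the >100 amino-acid boundary exactly", {
  set.seed(51)
  stopless <- function(n) paste(sample(c("GCA", "GGA", "CCA", "TCA", "ACA"),
                                       n, TRUE), collapse = "")
  orf100 <- paste0("ATG", stopless(99), "TAA") # 100 aa incl. Met
  orf101 <- paste0("ATG", stopless(100), "TAA") # 101 aa
  expect_false(orf_screen(orf100, 100L))
  expect_true(orf_screen(orf101, 100L))
  # reverse-strand ORF is found too
  expect_true(orf_screen(revcomp(orf101), 100L))
})

test_that("ORF screen agrees with a six-frame enumeration oracle", {
  set.seed(52)
  for (i in 1:60) {
    s <- rand_seq(sample(150:500, 1))
    thr <- sample(c(10L, 20L, 40L), 1)
    expect_equal(orf_screen(s, thr), orf_oracle_max_aa(s) > thr, info = s)
  }
})

test_that("family alignment projects members onto ungapped query coordinates", {
  set.seed(53)
  q <- rand_seq(120)
  m1 <- mutate_seq(q, 0.9)
  # member with an internal deletion
  m2 <- paste0(substr(q, 1, 50), substr(q, 61, 120))
  aln <- family_alignment(q, c(Aly = m1, Spa = m2))
  expect_equal(nchar(aln), c(focal = 120L, Aly = 120L, Spa = 120L))
  expect_equal(aln[["focal"]], q)
  expect_equal(sum(strsplit(aln[["Spa"]], "")[[1]] == "-"), 10)
  # identical member reproduces the query
  aln2 <- family_alignment(q, c(X = q))
  expect_equal(aln2[["X"]], q)
})

test_that("the conserved-ORF permutation test behaves at its boundaries", {
  set.seed(54)
  q <- rand_seq(120)
  aln <- c(focal = q, a = q, b = q, c = q)
  res <- conserved_coding_test(aln, n_perm = 200, seed = 1)
  expect_equal(res$p_value, 1)
  expect_false(res$coding)
  # fewer than four sequences: skipped, retained
  res2 <- conserved_coding_test(aln[1:3], n_perm = 200, seed = 1)
  expect_true(is.na(res2$p_value))
  expect_false(res2$coding)
})

test_that("a planted synonymous-only signal is detected below alpha", {
  set.seed(55)
  # codons with fourfold-degenerate third positions
  base_codons <- sample(c("GCT", "GGT", "CCT", "ACT", "GTT", "TCT", "CGT"),
                        100, TRUE)
  focal <- paste(base_codons, collapse = "")
  syn_mutate <- function(codons, k) {
    idx <- sample(length(codons), k)
    for (i in idx) {
      third <- sample(c("A", "C", "G", "T"), 1)
      codons[i] <- paste0(substr(codons[i], 1, 2), third)
    }
    paste(codons, collapse = "")
  }
  aln <- c(focal = focal,
           a = syn_mutate(base_codons, 40),
           b = syn_mutate(base_codons, 40),
           c = syn_mutate(base_codons, 40))
  res <- conserved_coding_test(aln, n_perm = 1000, alpha = 0.001, seed = 2)
  expect_lt(res$p_value, 0.001)
  expect_true(res$coding)
})

test_that("the coding test keeps near-nominal size on neutral alignments", {
  set.seed(56)
  n_rep <- 60
  rejections <- 0
  for (i in seq_len(n_rep)) {
    q <- rand_seq(90)
    aln <- c(focal = q,
             a = mutate_seq(q, 0.85), b = mutate_seq(q, 0.85),
             c = mutate_seq(q, 0.85))
    p <- conserved_coding_test(aln, n_perm = 99, seed = i)$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  # Bin(60, 0.05): 99% upper bound
  expect_lte(rejections, stats::qbinom(0.995, n_rep, 0.05))
})

test_that("the known-ncRNA screen finds planted motifs and rejects noise", {
  set.seed(57)
  motif <- rand_seq(120)
  lib <- c(sno1 = paste0(rand_seq(40), motif, rand_seq(40)))
  query <- paste0(rand_seq(60), mutate_seq(motif, 0.9), rand_seq(60))
  expect_true(known_ncrna_screen(query, lib, 1e-5))
  expect_false(known_ncrna_screen(rand_seq(240), lib, 1e-5))
  expect_false(known_ncrna_screen(rand_seq(240), character(0), 1e-5))
  # 80%-identity motif: decision agrees with the Smith-Waterman oracle
  q80 <- paste0(rand_seq(50), mutate_seq(motif, 0.8), rand_seq(50))
  sc <- scoring_scheme()
  s_oracle <- sw_oracle_score(q80, lib[[1]])
  e_oracle <- karlin_evalue(s_oracle, nchar(q80), nchar(lib[[1]]), sc)
  expect_equal(known_ncrna_screen(q80, lib, 1e-5), e_oracle <= 1e-5)
})
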