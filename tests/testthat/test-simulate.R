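test_that("expected_divergence follows the Jukes-Cantor forward formula", {
  expect_equal(expected_divergence(0, 0.002), 0)
  expect_equal(expected_divergence(1e9, 0.002), 0.75, tolerance = 1e-9)
  expect_equal(expected_divergence(84, 0.002), 0.1505136, tolerance = 1e-6)
  expect_error(expected_divergence(-1, 0.002), "negative")
})

test_that("a null process yields byte-identical copies in every species", {
  tr <- fixture_tree4()
  p <- sim_params(tree = tr, n_loci = 6, locus_len = 120,
                  birth_weights = c("15" = 1), subst_rate = 0,
                  indel_rate = 0, loss_prob = 0, decay_prob = 0,
                  dup_prob = 0, te_insert_prob = 0, rng_seed = 3)
  sim <- simulate_lincrna_cohort(p)
  expect_true(all(sim$truth$state[sim$truth$primary] == "present"))
  for (li in sim$queries$locus_id) {
    rows <- dplyr::filter(sim$truth, locus_id == li, primary)
    seqs <- vapply(seq_len(nrow(rows)), function(i)
      get_sequence(sim$genomes[[rows$species[i]]],
                   rows[i, c("chrom", "start", "end", "strand")]), "")
    expect_length(unique(seqs), 1)
  }
})

test_that("forced deletion removes loci but keeps flanking anchor genes", {
  tr <- fixture_tree4()
  p <- sim_params(tree = tr, n_loci = 8, locus_len = 100,
                  birth_weights = c("15" = 1), loss_prob = 1,
                  decay_prob = 0, dup_prob = 0, te_insert_prob = 0,
                  rng_seed = 5)
  sim <- simulate_lincrna_cohort(p)
  expect_true(all(sim$truth$state[sim$truth$primary] == "lost"))
  expect_true(all(is.na(sim$truth$start[sim$truth$primary])))
  expect_equal(nrow(sim$queries), 0)
  # anchors still present in every species for every locus
  expect_equal(nrow(sim$anchors), 8 * 2 * 4)
  a1 <- sim$anchors[1, ]
  s <- get_sequence(sim$genomes[[a1$species]],
                    a1[, c("chrom", "start", "end", "strand")])
  expect_equal(nchar(s), 900)
})

test_that("per-branch loss frequency is within the binomial 99% CI", {
  tr <- fixture_tree2(10)
  p <- sim_params(tree = tr, n_loci = 200, locus_len = 100,
                  birth_weights = c("10" = 1), subst_rate = 0.001,
                  loss_prob = 0.1, decay_prob = 0, dup_prob = 0,
                  te_insert_prob = 0, rng_seed = 42)
  sim <- simulate_lincrna_cohort(p)
  # one branch from root to each tip: per-species lost count ~ Bin(200, 0.1)
  for (sp in c("A", "B")) {
    lost <- sum(sim$truth$state[sim$truth$primary &
                                  sim$truth$species == sp] == "lost")
    ci <- stats::qbinom(c(0.005, 0.995), 200, 0.1)
    expect_gte(lost, ci[1])
    expect_lte(lost, ci[2])
  }
})

test_that("per-branch duplication frequency matches its binomial law", {
  tr <- fixture_tree2(10)
  p <- sim_params(tree = tr, n_loci = 200, locus_len = 100,
                  birth_weights = c("10" = 1), subst_rate = 0.001,
                  loss_prob = 0, decay_prob = 0, dup_prob = 0.05,
                  max_copies = 2, te_insert_prob = 0, rng_seed = 42)
  sim <- simulate_lincrna_cohort(p)
  # single copy enters each of the two terminal branches; the copy cap
  # allows at most one event per branch: total events ~ Bin(400, 0.05)
  n_events <- nrow(sim$dup_events)
  ci <- stats::qbinom(c(0.005, 0.995), 400, 0.05)
  expect_gte(n_events, ci[1])
  expect_lte(n_events, ci[2])
})

test_that("realized divergence matches the Jukes-Cantor expectation", {
  tr <- fixture_tree2(25)
  rate <- 0.002
  p <- sim_params(tree = tr, n_loci = 120, locus_len = 300,
                  birth_weights = c("25" = 1), subst_rate = rate,
                  indel_rate = 0, loss_prob = 0, decay_prob = 0,
                  dup_prob = 0, te_insert_prob = 0,
                  cns_prob_shallow = 0, cns_prob_deep = 0, rng_seed = 11)
  sim <- simulate_lincrna_cohort(p)
  pd <- vapply(sim$queries$locus_id, function(li) {
    rows <- dplyr::filter(sim$truth, locus_id == li, primary)
    seqs <- vapply(seq_len(nrow(rows)), function(i)
      get_sequence(sim$genomes[[rows$species[i]]],
                   rows[i, c("chrom", "start", "end", "strand")]), "")
    mean(strsplit(seqs[1], "")[[1]] != strsplit(seqs[2], "")[[1]])
  }, 0, USE.NAMES = FALSE)
  p_exp <- expected_divergence(50, rate)
  se <- stats::sd(pd) / sqrt(length(pd))
  expect_lt(abs(mean(pd) - p_exp), 3 * se + 1e-12)
})

test_that("WGD doubles copy number before fractionation is applied", {
  p <- sim_params(n_loci = 30, locus_len = 120, rng_seed = 9,
                  post_wgd_loss = 0.3)
  sim <- simulate_lincrna_cohort(p)
  expect_gt(nrow(sim$wgd_log), 0)
  expect_true(all(sim$wgd_log$copies_after_dup ==
                    2L * sim$wgd_log$copies_before))
  expect_true(all(sim$wgd_log$copies_retained <=
                    sim$wgd_log$copies_after_dup))
})

test_that("truth intervals, queries and annotation tracks are consistent", {
  sim <- simulate_lincrna_cohort(sim_params(n_loci = 25, rng_seed = 13))
  # every emitted primary interval slices to a sequence of that length
  pres <- dplyr::filter(sim$truth, !is.na(start))
  for (i in sample(nrow(pres), min(40, nrow(pres)))) {
    s <- get_sequence(sim$genomes[[pres$species[i]]],
                      pres[i, c("chrom", "start", "end", "strand")])
    expect_equal(nchar(s), pres$end[i] - pres$start[i])
  }
  # CNS islands lie inside their locus interval
  if (nrow(sim$cns)) {
    j <- dplyr::inner_join(
      dplyr::mutate(sim$cns, locus_id = sub("_cns$", "", name)),
      dplyr::filter(sim$truth, primary, !is.na(start)),
      by = c("locus_id", "species", "chrom"), suffix = c("", ".loc"))
    expect_true(all(j$start >= j$start.loc & j$end <= j$end.loc))
  }
  # duplication events only at or below the birth node
  if (nrow(sim$dup_events)) {
    bn <- sim$truth %>%
      dplyr::distinct(locus_id, birth_node)
    ls <- lincphylo:::st_leafsets(sim$tree)
    j <- dplyr::left_join(sim$dup_events, bn, by = "locus_id")
    ok <- vapply(seq_len(nrow(j)), function(i)
      all(ls[[j$node[i]]] %in% ls[[j$birth_node[i]]]), TRUE)
    expect_true(all(ok))
  }
  # write/read round trip of the emitted files
  dir <- tempfile()
  write_sim(sim, dir)
  g <- read_genome(file.path(dir, "Ath.fa"))
  expect_equal(g, sim$genomes$Ath)
  bed <- read_bed(file.path(dir, "lincrna.bed"))
  expect_equal(bed$start, sim$queries$start)
  gff <- read_gff_genes(file.path(dir, "Spa.genes.gff3"))
  asp <- dplyr::filter(sim$anchors, species == "Spa")
  expect_equal(gff$start, asp$start)
  expect_equal(gff$name, asp$name)
})
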