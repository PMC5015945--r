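test_that("Karlin-Altschul lambda solves its defining equation", {
  sc <- scoring_scheme()
  lhs <- 0.25 * exp(sc$lambda * 1) + 0.75 * exp(-sc$lambda * 2)
  expect_equal(lhs, 1, tolerance = 1e-8)
  # E-values are monotone decreasing in the score
  e <- karlin_evalue(c(30, 40, 50), 400, 1e6, sc)
  expect_true(all(diff(e) < 0))
})

test_that("a verbatim planted query is found with score equal to its length", {
  set.seed(21)
  q <- rand_seq(80)
  genome <- c(c1 = paste0(rand_seq(300), q, rand_seq(300)))
  h <- search_genome(c(query = q), genome, scoring_scheme(), 1)
  expect_gt(nrow(h), 0)
  expect_equal(h$score[1], 80)
  expect_equal(h$start[1], 300)
  expect_equal(h$end[1], 380)
  expect_equal(h$strand[1], "+")
  # and on the reverse strand
  genome2 <- c(c1 = paste0(rand_seq(200), revcomp(q), rand_seq(200)))
  h2 <- search_genome(c(query = q), genome2, scoring_scheme(), 1)
  expect_equal(h2$strand[1], "-")
  expect_equal(h2$score[1], 80)
})

test_that("no shared word means no hit; short queries warn and are dropped", {
  genome <- c(c1 = strrep("T", 400))
  h <- search_genome(c(q = "ACGTACGTACGT"), genome, scoring_scheme(), 10)
  expect_equal(nrow(h), 0)
  expect_warning(h2 <- search_genome(c(q = "ACGT"), genome,
                                     scoring_scheme(), 10), "shorter")
  expect_equal(nrow(h2), 0)
})

test_that("best-hit score equals the full Smith-Waterman oracle", {
  set.seed(31)
  for (rep in 1:8) {
    q <- rand_seq(60)
    copy <- mutate_seq(q, 0.85)
    genome <- c(c1 = paste0(rand_seq(150), copy, rand_seq(190)))
    h <- search_genome(c(q = q), genome, scoring_scheme(), 1e3)
    oracle <- sw_oracle_score(q, genome[[1]])
    expect_gt(nrow(h), 0)
    expect_equal(max(h$score), oracle)
  }
})

test_that("close hits merge by the query-length gap rule and idempotently", {
  h <- tibble(query_id = "q", chrom = "c1", strand = "+",
              start = c(100L, 250L), end = c(200L, 350L),
              qstart = c(0L, 0L), qend = c(100L, 100L),
              score = c(50L, 60L), evalue = c(1e-30, 1e-35))
  m <- merge_hits(h, c(q = 300L))
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 350L)
  expect_equal(m$score, 60L)
  expect_equal(m$evalue, 1e-35)
  h2 <- dplyr::mutate(h, start = c(100L, 600L), end = c(200L, 700L))
  m2 <- merge_hits(h2, c(q = 300L))
  expect_equal(nrow(m2), 2)

  # idempotence over random small hit sets
  set.seed(5)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    starts <- sort(sample(0:2000, n))
    hh <- tibble(query_id = "q", chrom = "c1", strand = "+",
                 start = as.integer(starts),
                 end = as.integer(starts + sample(50:200, n, TRUE)),
                 qstart = 0L, qend = 50L,
                 score = sample(30:90, n, TRUE),
                 evalue = 10^-sample(20:60, n, TRUE))
    ql <- c(q = sample(100:400, 1))
    once <- merge_hits(hh, ql)
    twice <- merge_hits(once, ql)
    expect_equal(as.data.frame(once), as.data.frame(twice))
    # no overlapping same-strand hits remain
    o <- dplyr::arrange(once, start)
    if (nrow(o) > 1) expect_true(all(o$start[-1] >= head(o$end, -1)))
  }
})

test_that("top_hit breaks ties by score then coordinates, deterministically", {
  h <- tibble(query_id = "q", chrom = c("c2", "c1"), strand = "+",
              start = c(10L, 10L), end = c(60L, 60L), qstart = 0L,
              qend = 50L, score = c(50L, 50L), evalue = c(1e-30, 1e-30))
  expect_equal(top_hit(h)$chrom, "c1")
  h$score <- c(60L, 50L)
  expect_equal(top_hit(h)$chrom, "c2")
  h$evalue <- c(1e-25, 1e-30)
  expect_equal(top_hit(h)$chrom, "c1")
})

test_that("reciprocity distinguishes orthologs from paralogs", {
  set.seed(41)
  anc <- rand_seq(200)
  ortho <- mutate_seq(anc, 0.92)
  # focal genome: the true locus plus a diverged paralog
  paralog <- mutate_seq(anc, 0.80)
  focal <- c(f1 = paste0(rand_seq(100), anc, rand_seq(100), paralog,
                         rand_seq(100)))
  subject <- c(s1 = paste0(rand_seq(120), ortho, rand_seq(120)))
  qint <- tibble(chrom = "f1", start = 100L, end = 300L)
  hit <- tibble(chrom = "s1", start = 120L, end = 320L, strand = "+")
  expect_true(check_reciprocity(hit, subject, focal, qint,
                                e_cutoff = 1e-5))
  # a paralog-derived subject sequence that back-maps to the paralog locus
  par_sub <- c(s1 = paste0(rand_seq(120), mutate_seq(paralog, 0.95),
                           rand_seq(120)))
  hit2 <- tibble(chrom = "s1", start = 120L, end = 320L, strand = "+")
  expect_false(check_reciprocity(hit2, par_sub, focal, qint,
                                 e_cutoff = 1e-5))
  # no back-hit at all
  empty_focal <- c(f1 = rand_seq(400))
  expect_false(check_reciprocity(hit, subject, empty_focal, qint,
                                 e_cutoff = 1e-5))
})

test_that("synteny requires an anchor hit near the candidate", {
  cfg <- lincphylo_config()
  hit <- tibble(chrom = "s1", start = 100000L, end = 100400L)
  near <- tibble(chrom = "s1", start = 90000L, end = 90900L)
  far <- tibble(chrom = "s1", start = 100000L + 60000L,
                end = 100900L + 60000L)
  other <- tibble(chrom = "s2", start = 100000L, end = 100900L)
  expect_true(check_synteny(hit, near, cfg))
  expect_false(check_synteny(hit, far, cfg))
  expect_false(check_synteny(hit, other, cfg))
  expect_false(check_synteny(hit, near[0, ], cfg))
})

test_that("homolog promotion works end to end on a small simulated cohort", {
  sim <- simulate_lincrna_cohort(
    sim_params(n_loci = 15, rng_seed = 19, decay_prob = 0, dup_prob = 0))
  cfg <- lincphylo_config(rng_seed = 19)
  hom <- call_homologs(sim$queries, sim$genomes, "Ath", sim$anchors_focal,
                       config = cfg)
  calls <- dplyr::filter(hom$calls, promoted)
  expect_gt(nrow(calls), 0)
  # promoted calls land on a planted copy of their locus (the top hit may
  # be a surviving whole-genome-duplication copy rather than the primary)
  j <- dplyr::inner_join(calls,
                         dplyr::filter(sim$truth, !is.na(start),
                                       state == "present"),
                         by = c(query_id = "locus_id", species = "species",
                                chrom = "chrom"), suffix = c("", ".t"))
  per_call <- j %>%
    dplyr::group_by(query_id, species, start) %>%
    dplyr::summarise(ok = any(start < end.t & end > start.t),
                     .groups = "drop")
  expect_true(all(per_call$ok))
  expect_equal(nrow(dplyr::distinct(j, query_id, species)),
               nrow(dplyr::distinct(calls, query_id, species)))
  expect_true(all(calls$evalue <= cfg$strict_evalue))
})
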