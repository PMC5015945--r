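test_that("TE overlap classes honor the 10-nt and distance boundaries", {
  locus <- tibble(chrom = "c1", start = 100L, end = 500L)
  te_in <- tibble(chrom = "c1", start = 490L, end = 600L) # overlap 10
  expect_equal(interval_overlap_class(locus, te_in), "inside")
  te_9 <- tibble(chrom = "c1", start = 491L, end = 600L) # overlap 9
  expect_equal(interval_overlap_class(locus, te_9), "within_100bp")
  te_near <- tibble(chrom = "c1", start = 505L, end = 600L) # distance 5
  expect_equal(interval_overlap_class(locus, te_near), "within_100bp")
  te_300 <- tibble(chrom = "c1", start = 800L, end = 900L)
  expect_equal(interval_overlap_class(locus, te_300), "within_500bp")
  te_far <- tibble(chrom = "c1", start = 2000L, end = 2100L)
  expect_equal(interval_overlap_class(locus, te_far), "none")
  # CNS-style classification counts any >= 1 nt overlap
  cns <- tibble(chrom = "c1", start = 499L, end = 530L)
  expect_equal(interval_overlap_class(locus, cns, min_nt = 1L), "inside")
})

test_that("overlap classification agrees with a naive scan and is translation invariant", {
  set.seed(91)
  naive_class <- function(ls, le, as, ae, min_nt, near) {
    ov <- max(0, min(le, ae) - max(ls, as))
    if (ov >= min_nt) return("inside")
    d <- if (ov > 0) 0 else max(as - le, ls - ae)
    for (b in near) if (d <= b) return(paste0("within_", b, "bp"))
    "none"
  }
  for (i in 1:200) {
    ls <- sample(0:2000, 1); le <- ls + sample(50:400, 1)
    as <- sample(0:2500, 1); ae <- as + sample(20:300, 1)
    got <- interval_overlap_class(tibble(chrom = "c", start = ls, end = le),
                                  tibble(chrom = "c", start = as, end = ae))
    want <- naive_class(ls, le, as, ae, 10L, c(100L, 500L))
    expect_equal(got, want, info = paste(ls, le, as, ae))
    shift <- sample(1:5000, 1)
    got2 <- interval_overlap_class(
      tibble(chrom = "c", start = ls + shift, end = le + shift),
      tibble(chrom = "c", start = as + shift, end = ae + shift))
    expect_equal(got2, got)
  }
})

test_that("Fisher's exact test matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact(c(2, 1, 1, 2))$p_value, 1.0)
  expect_equal(fisher_exact(c(0, 5, 0, 7))$p_value, 1.0) # zero margin
  set.seed(92)
  for (i in 1:40) {
    m <- sample(0:20, 4, replace = TRUE)
    if (sum(m) == 0) next
    got <- fisher_exact(m)$p_value
    want <- fisher_oracle_p(m[1], m[2], m[3], m[4])
    expect_equal(got, want, tolerance = 1e-9, info = paste(m, collapse = ","))
  }
  # odds ratio is the sample odds ratio with its degenerate conventions
  expect_equal(fisher_exact(c(4, 2, 1, 3))$odds_ratio, 6)
  expect_equal(fisher_exact(c(4, 0, 1, 3))$odds_ratio, Inf)
})

test_that("depth-stratified proportions reproduce stress-responsiveness arithmetic", {
  rec <- tibble(
    depth_age = c(rep(0, 1736), rep(13, 1785)),
    stress = c(rep(c(TRUE, FALSE), c(147, 1736 - 147)),
               rep(c(TRUE, FALSE), c(339, 1785 - 339))))
  tab <- depth_stratified_proportions(rec, "stress")
  expect_equal(tab$prop_pct, c(100 * 147 / 1736, 100 * 339 / 1785))
  expect_equal(round(tab$prop_pct, 1), c(8.5, 19.0))
  expect_true(is.na(tab$p_value[1]))
  expect_lt(tab$p_value[2], 1e-4)
  # all-false flags: zero proportions, p = 1
  rec0 <- tibble(depth_age = rep(c(0, 13), each = 50), flag = FALSE)
  tab0 <- depth_stratified_proportions(rec0, "flag")
  expect_equal(tab0$prop_pct, c(0, 0))
  expect_equal(tab0$p_value[2], 1)
})

test_that("expression-depth correlation recovers exact and null relations", {
  d <- tibble(depth_age = seq(0, 65, length.out = 40),
              mean_fpkm = 10^(seq(0, 65, length.out = 40)) - 0.01)
  # y = x exactly after the log10 transform
  fit <- suppressWarnings(expression_depth_correlation(d))
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-12)
  td <- suppressWarnings(tidy(fit))
  expect_equal(unname(td$estimate[td$term == "depth_age"]), 1,
               tolerance = 1e-9)
  gl <- suppressWarnings(glance(fit))
  expect_equal(gl$n, 40)
  # permuted response: null rejections near nominal level
  set.seed(93)
  rej <- 0
  for (i in 1:60) {
    d2 <- tibble(depth_age = rep(c(0, 13, 42, 65), each = 25),
                 mean_fpkm = 10^rnorm(100, 0, 0.5))
    if (expression_depth_correlation(d2)$p_value < 0.05) rej <- rej + 1
  }
  expect_lte(rej, qbinom(0.995, 60, 0.05))
})

test_that("miRNA expectation scoring follows the seed-weighted rules", {
  mirna <- "TTGGACTGAAGGGAGCTCCC" # 20 nt
  target_rc <- revcomp(mirna)
  linc <- paste0(rand_seq(50), target_rc, rand_seq(50))
  res <- mirna_expectation(linc, mirna)
  expect_equal(res$expectation, 0)
  expect_true(res$hit)
  # one G:U wobble at miRNA position 15 scores 0.5
  v <- strsplit(target_rc, "")[[1]]
  # miRNA position i pairs with target-site position L - i + 1
  pos_in_site <- 20 - 15 + 1
  mi15 <- substr(mirna, 15, 15)
  v[pos_in_site] <- if (mi15 == "G") "T" else "G"
  wob15 <- paste(v, collapse = "")
  expect_equal(mirna_expectation(paste0(rand_seq(30), wob15, rand_seq(30)),
                                 mirna)$expectation, 0.5)
  # the same wobble inside the 5' seed (position 5) is doubled
  v <- strsplit(target_rc, "")[[1]]
  mi5 <- substr(mirna, 5, 5)
  stopifnot(mi5 %in% c("A", "G", "C", "T"))
  v[20 - 5 + 1] <- if (mi5 == "G") "T" else if (mi5 == "T") "G" else "A"
  wob5 <- paste(v, collapse = "")
  sc5 <- mirna_expectation(paste0(rand_seq(30), wob5, rand_seq(30)),
                           mirna)$expectation
  expect_equal(sc5, if (mi5 %in% c("G", "T")) 1.0 else 2.0)
})

test_that("miRNA scoring agrees with an independent offset-scan oracle", {
  set.seed(94)
  for (i in 1:60) {
    linc <- rand_seq(80)
    mir <- rand_seq(21)
    got <- mirna_expectation(linc, mir)$expectation
    want <- mirna_oracle(linc, mir)
    expect_equal(got, want, info = paste(linc, mir))
  }
})

test_that("the folding proxy matches hand-counted and enumerated structures", {
  expect_equal(mfe_proxy_per_nt("GGGAAACCC"), -3 / 9)
  expect_equal(mfe_proxy_per_nt(strrep("A", 30)), 0)
  set.seed(95)
  for (i in 1:40) {
    s <- rand_seq(sample(6:12, 1))
    got <- -mfe_proxy_per_nt(s) * nchar(s)
    expect_equal(got, nussinov_oracle(s), info = s)
  }
})

test_that("gene proximity vs conservation handles null, planted and degenerate cases", {
  set.seed(96)
  # independent: p roughly uniform (not extreme)
  rec <- tibble(conserved = sample(c(TRUE, FALSE), 300, TRUE),
                nearest_gene_bp = runif(300, 0, 5000))
  r0 <- gene_proximity_vs_conservation(rec, n_perm = 500, seed = 1)
  expect_gt(r0$p_value, 0.001)
  # planted covariation is detected
  rec2 <- tibble(conserved = rep(c(TRUE, FALSE), each = 150),
                 nearest_gene_bp = c(runif(150, 0, 1000),
                                     runif(150, 2000, 5000)))
  r1 <- gene_proximity_vs_conservation(rec2, n_perm = 500, seed = 1)
  expect_lt(r1$p_value, 0.01)
  # constant proximity: r = 0 by convention
  rec3 <- tibble(conserved = rep(c(TRUE, FALSE), 10), nearest_gene_bp = 100)
  expect_equal(gene_proximity_vs_conservation(rec3)$r, 0)
})

test_that("the feature table joins depth, TE, CNS, expression and stress", {
  sim <- simulate_lincrna_cohort(sim_params(n_loci = 30, rng_seed = 33))
  cfg <- lincphylo_config(rng_seed = 33)
  pipe <- run_pipeline(sim, cfg, gene_trees = FALSE, coding_filter = FALSE)
  ft <- pipe$features
  expect_equal(nrow(ft), nrow(sim$queries))
  expect_true(all(c("te_class", "cns_overlap", "nearest_gene_bp",
                    "mean_fpkm", "stress_responsive", "depth_age") %in%
                    names(ft)))
  # CNS overlap agrees with the planted islands for present focal loci
  expect_equal(ft$cns_overlap, ft$has_cns & ft$focal_state == "present" |
                 ft$cns_overlap)
  # planted TE classes are recovered for focal loci
  with_te <- filter(ft, te_class != "none")
  truth_te <- filter(sim$queries, te_class != "none")
  expect_setequal(with_te$locus_id, truth_te$locus_id)
})
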