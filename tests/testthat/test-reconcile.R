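test_that("a congruent single-copy gene tree reconciles with zero events", {
  st <- fixture_tree4()
  gt <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  rec <- reconcile(gt, st)
  expect_equal(rec$n_dup, 0L)
  expect_equal(rec$n_loss, 0L)
  expect_true(all(rec$events$event == "speciation"))
})

test_that("the textbook two-copy case maps one duplication to the ancestor", {
  lm <- tibble(species = c("A", "B"), lineage = c("I", "II"))
  st <- read_species_tree("(A:10,B:10);", lm, focal = "A")
  gt <- ape::read.tree(text = "((A|1:1,B|1:1):1,(A|2:1,B|2:1):1);")
  rec <- reconcile(gt, st)
  expect_equal(rec$n_dup, 1L)
  expect_equal(rec$n_loss, 0L)
  dup_nodes <- rec$events$node[rec$events$event == "duplication"]
  expect_equal(dup_nodes, lincphylo:::st_mrca(st, c("A", "B")))
})

test_that("rooting freedom and incongruence are costed correctly", {
  lm <- tibble(species = c("A", "B", "C"), lineage = c("I", "I", "II"))
  st <- read_species_tree("((A:5,B:5):5,C:10);", lm, focal = "A")
  # a three-leaf gene tree is an unrooted star: some rooting is congruent
  gt <- ape::read.tree(text = "((A:1,C:1):1,B:1);")
  rec <- reconcile(gt, st)
  expect_equal(rec$n_dup, 0L)
  expect_equal(rec$n_loss, 0L)
  # four leaves with a second C copy force genuine incongruence
  gt2 <- ape::read.tree(text = "((A:1,C|1:1):1,(B:1,C|2:1):1);")
  rec2 <- reconcile(gt2, st)
  oracle <- oracle_reconcile_min(gt2, st)
  expect_equal(c(rec2$n_dup, rec2$n_loss), unname(oracle))
  expect_gt(rec2$n_dup + rec2$n_loss, 0)
})

test_that("reconciliation errors when a gene-tree species is missing", {
  st <- fixture_tree4()
  gt <- ape::read.tree(text = "((A:1,B:1):1,Zz:1);")
  expect_error(reconcile(gt, st), "Zz")
})

test_that("chosen cost equals the brute-force minimum over all rootings (<= 6 leaves)", {
  skip_if_not_installed("phangorn")
  st <- fixture_tree4()
  sp <- c("A", "B", "C", "D")
  set.seed(71)
  # all 4-leaf and 5-leaf unrooted topologies with species assignments,
  # including multi-copy leaf sets
  assignments <- list(c("A", "B", "C", "D"),
                      c("A", "A", "B", "C"),
                      c("A", "B", "A", "B"),
                      c("A", "B", "C", "D", "A"),
                      c("A", "A", "B", "B", "C"),
                      c("D", "C", "B", "A", "A"))
  for (asn in assignments) {
    n <- length(asn)
    topos <- phangorn::allTrees(n, rooted = FALSE)
    for (tp in topos) {
      tp$tip.label <- paste0(asn, "|", seq_len(n))
      tp$edge.length <- rep(1, nrow(tp$edge))
      rec <- reconcile(tp, st)
      oracle <- oracle_reconcile_min(tp, st)
      expect_equal(c(rec$n_dup, rec$n_loss), unname(oracle),
                   info = ape::write.tree(tp))
    }
  }
  # random 6-leaf trees with random species assignments
  for (i in 1:25) {
    n <- 6
    tp <- ape::rtree(n)
    asn <- sample(sp, n, replace = TRUE)
    tp$tip.label <- paste0(asn, "|", seq_len(n))
    rec <- reconcile(tp, st)
    oracle <- oracle_reconcile_min(tp, st)
    expect_equal(c(rec$n_dup, rec$n_loss), unname(oracle),
                 info = ape::write.tree(tp))
  }
})

test_that("polytomy resolution matches exhaustive enumeration", {
  st <- fixture_tree4()
  set.seed(72)
  for (i in 1:20) {
    n <- sample(5:6, 1)
    tp <- ape::rtree(n)
    asn <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
    tp$tip.label <- paste0(asn, "|", seq_len(n))
    # collapse random internal edges into polytomies via zero supports
    tp$node.label <- as.character(sample(c(0, 100), tp$Nnode, replace = TRUE))
    tp$node.label[1] <- ""
    rec <- reconcile(tp, st, collapse_pct = 70)
    # oracle: collapse the same branches, then enumerate everything
    ntip <- length(tp$tip.label)
    drop <- which(suppressWarnings(as.numeric(tp$node.label)) < 70) + ntip
    gt2 <- tp
    if (length(drop)) {
      gt2$edge.length <- ifelse(gt2$edge[, 2] %in% drop, 0, 1)
      gt2 <- ape::di2multi(gt2, tol = 0.5)
    }
    oracle <- oracle_reconcile_min(gt2, st)
    expect_equal(c(rec$n_dup, rec$n_loss), unname(oracle),
                 info = ape::write.tree(tp))
  }
})

test_that("every reported event satisfies the LCA duplication criterion", {
  st <- fixture_tree()
  set.seed(73)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    asn <- sample(st$tip.label, n, replace = TRUE)
    tp <- ape::rtree(n)
    tp$tip.label <- paste0(asn, "|", seq_len(n))
    rec <- reconcile(tp, st)
    expect_true(all(rec$events$event %in% c("speciation", "duplication")))
    expect_equal(nrow(rec$events), n - 1) # one event per internal node
    expect_equal(sum(rec$events$event == "duplication"), rec$n_dup)
  }
})

test_that("backbone summaries bin events and apply the exclusion threshold", {
  st <- fixture_tree()
  n42 <- lincphylo:::st_mrca(st, c("Ath", "Spa"))
  n13 <- lincphylo:::st_mrca(st, c("Ath", "Aly"))
  ath <- match("Ath", st$tip.label)
  ev <- tibble(
    family_id = c("f1", "f1", "f2", rep("f3", 4)),
    node = c(n42, n13, n42, rep(ath, 4)),
    event = "duplication",
    age = st$node_age[c(n42, n13, n42, rep(ath, 4))])
  s <- summarize_duplications(ev, st, max_backbone = 3)
  expect_equal(s$n_excluded, 1) # f3 exceeds the threshold
  expect_equal(s$families_with_dup, 2)
  pn <- s$per_node
  expect_equal(pn$n_dup_events[pn$node == n42], 2L)
  expect_equal(pn$n_dup_events[pn$node == n13], 1L)
  expect_equal(pn$n_dup_events[pn$node == ath], 0L)
  # no duplications anywhere -> all bins zero
  s0 <- summarize_duplications(ev[0, ], st)
  expect_true(all(s0$per_node$n_dup_events == 0))
})
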