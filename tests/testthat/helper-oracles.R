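# Independent oracles used by the tests. These deliberately re-derive
# results by brute force / closed form, separate from the package's own
# algorithms.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate a sequence to a target identity (substitutions only)
mutate_seq <- function(seq, identity) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  k <- round((1 - identity) * n)
  idx <- sample(n, k)
  bases <- c("A", "C", "G", "T")
  for (i in idx) v[i] <- sample(setdiff(bases, v[i]), 1)
  paste(v, collapse = "")
}

# Full Smith-Waterman with affine gaps (gap of length L costs
# open + L * extend), both strands; plain O(mn) R implementation.
sw_oracle_score <- function(query, subject, match = 1, mismatch = 2,
                            gap_open = 5, gap_extend = 2) {
  one <- function(q, s) {
    qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
    m <- length(qv); n <- length(sv)
    NEG <- -1e9
    H <- matrix(0, m + 1, n + 1)
    E <- matrix(NEG, m + 1, n + 1)
    F <- matrix(NEG, m + 1, n + 1)
    best <- 0
    for (i in 2:(m + 1)) {
      for (j in 2:(n + 1)) {
        sub <- if (qv[i - 1] == sv[j - 1]) match else -mismatch
        E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                       E[i, j - 1] - gap_extend)
        F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                       F[i - 1, j] - gap_extend)
        H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
        best <- max(best, H[i, j])
      }
    }
    best
  }
  max(one(query, subject),
      one(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(query))), subject))
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
fisher_oracle_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# maximum base pairs by plain recursion (exponential, len <= 12)
nussinov_oracle <- function(seq, min_loop = 3) {
  s <- chartr("Tt", "Uu", toupper(seq))
  v <- strsplit(s, "")[[1]]
  can_pair <- function(a, b)
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (t in (i + min_loop + 1):j) {
      if (can_pair(v[i], v[t]))
        best <- max(best, 1 + rec(i + 1, t - 1) + rec(t + 1, j))
    }
    best
  }
  if (length(v) < min_loop + 2) return(0)
  rec(1, length(v))
}

# --- reconciliation brute-force oracle ------------------------------------

# species-tree lookup tables
oracle_st_prep <- function(st) {
  ntip <- length(st$tip.label)
  n <- ntip + st$Nnode
  parent <- rep(NA_integer_, n)
  parent[st$edge[, 2]] <- st$edge[, 1]
  root <- setdiff(st$edge[, 1], st$edge[, 2])[1]
  depth <- rep(NA_integer_, n); depth[root] <- 0L
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(st$edge))) {
      a <- st$edge[e, 1]; b <- st$edge[e, 2]
      if (!is.na(depth[a]) && is.na(depth[b])) { depth[b] <- depth[a] + 1L; done <- FALSE }
    }
    if (done) break
  }
  list(parent = parent, depth = depth,
       leaf = stats::setNames(seq_len(ntip), st$tip.label))
}

oracle_lca <- function(pp, u, v) {
  while (u != v) {
    if (pp$depth[u] >= pp$depth[v]) u <- pp$parent[u] else v <- pp$parent[v]
  }
  u
}

# cost of a rooted nested-list gene tree (leaves = species names)
oracle_cost <- function(tree, pp) {
  walk <- function(node) {
    if (!is.list(node))
      return(list(map = pp$leaf[[node]], dups = 0L, losses = 0L))
    stopifnot(length(node) == 2)
    L <- walk(node[[1]]); R <- walk(node[[2]])
    M <- oracle_lca(pp, L$map, R$map)
    dup <- (M == L$map) || (M == R$map)
    dl <- max(pp$depth[L$map] - pp$depth[M] - (if (dup) 0 else 1), 0)
    dr <- max(pp$depth[R$map] - pp$depth[M] - (if (dup) 0 else 1), 0)
    list(map = M, dups = L$dups + R$dups + as.integer(dup),
         losses = L$losses + R$losses + dl + dr)
  }
  r <- walk(tree)
  c(dups = r$dups, losses = r$losses)
}

# all binary resolutions of a multifurcating nested list (children list)
oracle_resolutions <- function(children) {
  k <- length(children)
  if (k == 1) return(children)
  if (k == 2) return(list(list(children[[1]], children[[2]])))
  smaller <- oracle_resolutions(children[-k])
  out <- list()
  attach_everywhere <- function(node, leaf) {
    res <- list(list(node, leaf))
    if (is.list(node) && length(node) == 2) {
      for (l in attach_everywhere(node[[1]], leaf))
        res <- c(res, list(list(l, node[[2]])))
      for (r in attach_everywhere(node[[2]], leaf))
        res <- c(res, list(list(node[[1]], r)))
    }
    res
  }
  for (s in smaller) out <- c(out, attach_everywhere(s, children[[k]]))
  out
}

# adjacency of an unrooted phylo (degree-2 storage root contracted)
oracle_graph <- function(gt) {
  ntip <- length(gt$tip.label)
  edges <- gt$edge
  deg <- table(factor(c(edges[, 1], edges[, 2]),
                      levels = seq_len(ntip + gt$Nnode)))
  root2 <- as.integer(names(deg)[deg == 2 & as.integer(names(deg)) > ntip])
  edges_l <- lapply(seq_len(nrow(edges)), function(i) edges[i, ])
  for (v in root2) {
    inc <- which(vapply(edges_l, function(e) v %in% e, TRUE))
    nb <- setdiff(unique(unlist(edges_l[inc])), v)
    edges_l <- edges_l[-inc]
    edges_l <- c(edges_l, list(nb))
  }
  list(edges = do.call(rbind, edges_l), ntip = ntip,
       species = sub("\\|.*$", "", gt$tip.label))
}

# fully enumerated minimum (dups, losses) over all rootings and all
# resolutions of any multifurcations
oracle_reconcile_min <- function(gt, st) {
  pp <- oracle_st_prep(st)
  g <- oracle_graph(gt)
  adj <- lapply(seq_len(max(g$edges)), function(v) {
    nb <- c(g$edges[g$edges[, 1] == v, 2], g$edges[g$edges[, 2] == v, 1])
    unique(nb)
  })
  build <- function(node, from) {
    kids <- setdiff(adj[[node]], from)
    if (!length(kids)) return(g$species[node])
    lapply(kids, build, from = node)
  }
  expand <- function(node) {
    # returns list of fully binary alternatives for this subtree
    if (!is.list(node)) return(list(node))
    alt_children <- lapply(node, expand)
    combos <- list(list())
    for (ac in alt_children) {
      combos <- do.call(c, lapply(combos, function(cm)
        lapply(ac, function(a) c(cm, list(a)))))
    }
    out <- list()
    for (cm in combos) out <- c(out, oracle_resolutions(cm))
    out
  }
  best <- NULL
  for (e in seq_len(nrow(g$edges))) {
    u <- g$edges[e, 1]; v <- g$edges[e, 2]
    for (L in expand(build(u, v))) for (R in expand(build(v, u))) {
      cost <- oracle_cost(list(L, R), pp)
      if (is.null(best) || cost[1] < best[1] ||
          (cost[1] == best[1] && cost[2] < best[2]))
        best <- cost
    }
  }
  best
}

# small species-tree fixture shaped like the default chronogram
fixture_tree <- function() default_species_tree()

# minimal two-taxon tree for process calibration
fixture_tree2 <- function(height = 10) {
  lm <- tibble::tibble(species = c("A", "B"), lineage = c("I", "II"))
  read_species_tree(sprintf("(A:%g,B:%g);", height, height), lm, focal = "A")
}

# small 4-taxon tree
fixture_tree4 <- function() {
  lm <- tibble::tibble(species = c("A", "B", "C", "D"),
                       lineage = c("I", "I", "II", "outgroup"))
  read_species_tree("(((A:5,B:5):5,C:10):5,D:15);", lm, focal = "A")
}

# independent ungapped miRNA expectation scan (vector arithmetic route)
mirna_oracle <- function(lincrna, mirna, score_len = 20) {
  t_seq <- chartr("Uu", "Tt", toupper(lincrna))
  m_seq <- chartr("Uu", "Tt", toupper(mirna))
  L <- min(nchar(m_seq), score_len)
  tv <- strsplit(t_seq, "")[[1]]
  mv <- strsplit(m_seq, "")[[1]][1:L]
  n <- length(tv)
  if (n < L) return(Inf)
  best <- Inf
  for (s in 1:(n - L + 1)) {
    win <- rev(tv[s:(s + L - 1)])
    sc <- 0
    for (i in 1:L) {
      pair <- paste0(mv[i], win[i])
      penalty <- if (pair %in% c("AT", "TA", "CG", "GC")) 0
      else if (pair %in% c("GT", "TG")) 0.5 else 1
      if (i >= 2 && i <= 13) penalty <- 2 * penalty
      sc <- sc + penalty
    }
    best <- min(best, sc)
  }
  best
}

# six-frame ORF scan oracle: longest ATG..stop ORF in amino acids
orf_oracle_max_aa <- function(seq) {
  best <- 0
  for (s in c(seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))))) {
    v <- strsplit(toupper(s), "")[[1]]
    for (f in 0:2) {
      i <- f + 1
      codons <- character(0)
      while (i + 2 <= length(v)) {
        codons <- c(codons, paste(v[i:(i + 2)], collapse = ""))
        i <- i + 3
      }
      aa <- Biostrings::GENETIC_CODE[codons]
      aa[is.na(aa)] <- "X"
      open <- NA
      for (ci in seq_along(aa)) {
        if (is.na(open) && codons[ci] == "ATG") open <- ci
        if (!is.na(open) && aa[ci] == "*") {
          best <- max(best, ci - open)
          open <- NA
        }
      }
    }
  }
  best
}
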