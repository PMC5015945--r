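#' Jukes-Cantor distance between two aligned sequences
#'
#' Columns with a gap or ambiguous base in either sequence are excluded;
#' `d = -3/4 ln(1 - 4p/3)` with `p` the mismatch proportion. Saturated
#' pairs (`p >= 0.75`) are assigned the saturation cap.
#'
#' @param a,b aligned sequences of equal length.
#' @param cap distance assigned at saturation.
#' @return distance (substitutions/site).
#' @export
jc_distance <- function(a, b, cap = 5.0) {
  stopifnot(nchar(a) == nchar(b))
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) return(cap)
  p <- mean(x[ok] != y[ok])
  jc_transform(p, cap)
}

jc_transform <- function(p, cap = 5.0) {
  d <- ifelse(p >= 0.75, cap, -0.75 * log(pmax(1 - 4 * p / 3, 1e-12)))
  pmin(d, cap)
}

# Pairwise mismatch/valid column counts for an alignment (rows = sequences).
# Returns list(mism, valid): n_pairs x L 0/1 matrices, plus the pair index.
aln_pair_columns <- function(aln) {
  M <- do.call(rbind, strsplit(toupper(aln), ""))
  okM <- matrix(M %in% c("A", "C", "G", "T"), nrow = nrow(M))
  n <- nrow(M)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  mism <- matrix(0, np, ncol(M)); valid <- matrix(0, np, ncol(M))
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    v <- okM[i, ] & okM[j, ]
    valid[k, ] <- as.numeric(v)
    mism[k, ] <- as.numeric(v & M[i, ] != M[j, ])
  }
  list(mism = mism, valid = valid, pairs = pairs, labels = names(aln))
}

pair_dist_matrix <- function(pc, w = NULL, cap = 5.0) {
  nv <- if (is.null(w)) rowSums(pc$valid) else as.vector(pc$valid %*% w)
  nm <- if (is.null(w)) rowSums(pc$mism) else as.vector(pc$mism %*% w)
  p <- ifelse(nv > 0, nm / nv, 1)
  d <- jc_transform(p, cap)
  n <- length(pc$labels)
  D <- matrix(0, n, n, dimnames = list(pc$labels, pc$labels))
  for (k in seq_len(ncol(pc$pairs)))
    D[pc$pairs[1, k], pc$pairs[2, k]] <- D[pc$pairs[2, k], pc$pairs[1, k]] <- d[k]
  D
}

#' Jukes-Cantor distance matrix for a family alignment
#' @param aln named character vector of aligned sequences.
#' @param cap saturation cap.
#' @return symmetric distance matrix.
#' @export
jc_distance_matrix <- function(aln, cap = 5.0) {
  pair_dist_matrix(aln_pair_columns(aln), NULL, cap)
}

#' Neighbor joining
#'
#' Standard Saitou-Nei agglomeration on a symmetric distance matrix.
#' Negative branch lengths are clamped to zero; ties in the Q criterion are
#' broken by the lexicographically lowest index pair, so the result is
#' deterministic.
#'
#' @param D symmetric distance matrix with row/col names (n >= 3).
#' @return an unrooted `phylo`.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 3,
            isTRUE(all.equal(unname(D), unname(t(D)), tolerance = 1e-8)),
            all(diag(D) == 0), all(D >= 0))
  labs <- rownames(D)
  sub <- as.list(labs) # newick fragments
  D <- unname(D)
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    qmin <- min(Q)
    tied <- which(Q <= qmin + 1e-9, arr.ind = TRUE)
    tied <- tied[order(tied[, 1], tied[, 2]), , drop = FALSE]
    i <- tied[1, 1]; j <- tied[1, 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    newd <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    merged <- sprintf("(%s:%.10g,%s:%.10g)", sub[[i]], bi, sub[[j]], bj)
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    D <- D2
    sub <- c(sub[keep], merged)
  }
  b1 <- max(0.5 * (D[1, 2] + D[1, 3] - D[2, 3]), 0)
  b2 <- max(0.5 * (D[1, 2] + D[2, 3] - D[1, 3]), 0)
  b3 <- max(0.5 * (D[1, 3] + D[2, 3] - D[1, 2]), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", sub[[1]], b1, sub[[2]], b2,
                 sub[[3]], b3)
  ape::read.tree(text = nwk)
}

# canonical split keys (internal, non-trivial) of a phylo; side not
# containing the first (alphabetical) tip label. Splits on zero-length
# internal branches are treated as unresolved and skipped.
tree_splits <- function(tr, min_len = 1e-10) {
  tips <- sort(tr$tip.label)
  anchor <- tips[1]
  ntip <- length(tr$tip.label)
  ls <- st_leafsets(tr)
  nodes <- setdiff(seq_len(ntip + tr$Nnode), seq_len(ntip))
  elen <- stats::setNames(tr$edge.length, tr$edge[, 2])
  keys <- character(0)
  for (v in nodes) {
    bl <- elen[as.character(v)]
    if (!is.na(bl) && bl <= min_len) next
    set <- ls[[v]]
    if (anchor %in% set) set <- setdiff(tips, set)
    if (length(set) >= 2 && length(set) <= ntip - 2)
      keys <- c(keys, paste(sort(set), collapse = "|"))
  }
  unique(keys)
}

#' Gene tree with bootstrap supports
#'
#' Infers the neighbor-joining tree from Jukes-Cantor distances on a family
#' alignment and attaches internal-branch supports from column-resampling
#' bootstrap replicates (percentage of replicate trees containing the same
#' bipartition).
#'
#' @param aln named character vector of aligned sequences (>= 3).
#' @param reps bootstrap replicates.
#' @param seed RNG seed for the resampling stream.
#' @param cap saturation cap for distances.
#' @return a `phylo` with `node.label` holding supports (root label empty).
#' @export
bootstrap_supports <- function(aln, reps = 100L, seed = 1L, cap = 5.0) {
  stopifnot(length(aln) >= 3)
  pc <- aln_pair_columns(aln)
  L <- ncol(pc$valid)
  ref <- neighbor_joining(pair_dist_matrix(pc, NULL, cap))
  counts <- stats::setNames(numeric(0), character(0))
  with_stage_seed(seed, "bootstrap", {
    for (b in seq_len(reps)) {
      w <- tabulate(sample.int(L, L, replace = TRUE), L)
      bt <- neighbor_joining(pair_dist_matrix(pc, w, cap))
      for (k in tree_splits(bt))
        counts[k] <- if (is.na(counts[k])) 1 else counts[k] + 1
    }
  })
  ntip <- length(ref$tip.label)
  ls <- st_leafsets(ref)
  tips <- sort(ref$tip.label); anchor <- tips[1]
  lab <- character(ref$Nnode)
  for (v in (ntip + 1):(ntip + ref$Nnode)) {
    set <- ls[[v]]
    if (anchor %in% set) set <- setdiff(tips, set)
    if (length(set) >= 2 && length(set) <= ntip - 2) {
      k <- paste(sort(set), collapse = "|")
      cnt <- counts[k]
      lab[v - ntip] <- sprintf("%g", round(100 * (if (is.na(cnt)) 0 else cnt) / reps))
    } else lab[v - ntip] <- ""
  }
  ref$node.label <- lab
  ref
}
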