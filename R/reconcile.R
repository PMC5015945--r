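# Gene-tree / species-tree reconciliation with duplication dating.
#
# The gene tree is taken as unrooted; internal branches below the bootstrap
# support threshold are collapsed into polytomies; every rooting on a
# remaining branch is scored; polytomies are resolved to minimize
# duplications then losses (exact per-polytomy enumeration for small
# polytomies, species-guided greedy joining beyond that); the rooting with
# the fewest duplications (then losses, then the lexicographically smallest
# canonical form) wins. Events follow from the standard LCA mapping:
# a node is a duplication iff its mapping equals a child's mapping, and the
# loss count on a child edge is the number of species-tree edges skipped,
# minus one at speciation nodes.

# --- species-tree helpers -------------------------------------------------

st_prep <- function(st) {
  ntip <- length(st$tip.label)
  n <- ntip + st$Nnode
  parent <- st_parents(st)
  depth <- integer(n)
  # depth via BFS from root
  root <- setdiff(st$edge[, 1], st$edge[, 2])[1]
  ord <- c(root)
  i <- 1
  kids <- vector("list", n)
  for (e in seq_len(nrow(st$edge)))
    kids[[st$edge[e, 1]]] <- c(kids[[st$edge[e, 1]]], st$edge[e, 2])
  while (i <= length(ord)) {
    v <- ord[i]
    for (k in kids[[v]]) { depth[k] <- depth[v] + 1L; ord <- c(ord, k) }
    i <- i + 1
  }
  list(ntip = ntip, parent = parent, depth = depth, root = root,
       leaf_id = stats::setNames(seq_len(ntip), st$tip.label),
       age = st$node_age)
}

st_lca <- function(prep, u, v) {
  while (u != v) {
    if (prep$depth[u] >= prep$depth[v]) u <- prep$parent[u]
    else v <- prep$parent[v]
  }
  u
}

# --- polytomy resolution --------------------------------------------------

# all binary join structures over k items (nested lists of indices)
enum_resolutions <- function(k) {
  if (k == 1) return(list(1L))
  if (k == 2) return(list(list(1L, 2L)))
  prev <- enum_resolutions(k - 1L)
  out <- list()
  insert_at <- function(node, path_id, newleaf) {
    # returns list of structures with newleaf attached on every edge
    res <- list(list(node, newleaf)) # attach above this subtree
    if (is.list(node)) {
      for (l in insert_at(node[[1]], path_id, newleaf))
        res <- c(res, list(list(l, node[[2]])))
      for (r in insert_at(node[[2]], path_id, newleaf))
        res <- c(res, list(list(node[[1]], r)))
    }
    res
  }
  for (s in prev) out <- c(out, insert_at(s, NULL, as.integer(k)))
  out
}

resolution_cache <- new.env(parent = emptyenv())
get_resolutions <- function(k) {
  key <- as.character(k)
  if (is.null(resolution_cache[[key]]))
    resolution_cache[[key]] <- enum_resolutions(k)
  resolution_cache[[key]]
}

# evaluate one join structure; maps = children species mappings;
# returns list(map, dups, losses, events = list of c(node, is_dup))
eval_join <- function(struct, maps, prep) {
  if (!is.list(struct))
    return(list(map = maps[[struct]], dups = 0L, losses = 0L,
                events = list()))
  L <- eval_join(struct[[1]], maps, prep)
  R <- eval_join(struct[[2]], maps, prep)
  M <- st_lca(prep, L$map, R$map)
  dup <- (M == L$map) || (M == R$map)
  dl <- max(prep$depth[L$map] - prep$depth[M] - (if (dup) 0L else 1L), 0L)
  dr <- max(prep$depth[R$map] - prep$depth[M] - (if (dup) 0L else 1L), 0L)
  list(map = M, dups = L$dups + R$dups + as.integer(dup),
       losses = L$losses + R$losses + dl + dr,
       events = c(L$events, R$events, list(c(M, as.integer(dup)))))
}

lex_less <- function(a, b) {
  for (t in seq_along(a)) {
    if (a[t] < b[t]) return(TRUE)
    if (a[t] > b[t]) return(FALSE)
  }
  FALSE
}

greedy_join_struct <- function(maps, prep) {
  items <- as.list(seq_along(maps))
  cur <- maps
  while (length(items) > 2) {
    n <- length(items)
    best <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      M <- st_lca(prep, cur[[i]], cur[[j]])
      is_spec <- (M != cur[[i]]) && (M != cur[[j]])
      # prefer speciation joins, then the most recent LCA, then low indices
      key <- c(as.numeric(!is_spec), -prep$depth[M], i, j)
      if (is.null(best) || lex_less(key, best$key))
        best <- list(key = key, i = i, j = j, M = M)
    }
    merged <- list(items[[best$i]], items[[best$j]])
    keep <- setdiff(seq_along(items), c(best$i, best$j))
    M <- best$M
    items <- c(items[keep], list(merged))
    cur <- c(cur[keep], M)
  }
  if (length(items) == 2) list(items[[1]], items[[2]]) else items[[1]]
}

resolve_polytomy <- function(maps, prep, max_enum = 6L) {
  k <- length(maps)
  if (k == 2) {
    return(eval_join(list(1L, 2L), maps, prep))
  }
  if (k <= max_enum) {
    best <- NULL
    for (s in get_resolutions(k)) {
      ev <- eval_join(s, maps, prep)
      if (is.null(best) || ev$dups < best$dups ||
          (ev$dups == best$dups && ev$losses < best$losses))
        best <- ev
    }
    best
  } else {
    eval_join(greedy_join_struct(maps, prep), maps, prep)
  }
}

# --- gene-tree graph ------------------------------------------------------

# Build the collapsed unrooted graph of a gene tree. Returns adjacency,
# species per leaf node, edge list.
gt_graph <- function(gt, st, collapse_pct) {
  ntip <- length(gt$tip.label)
  n <- ntip + gt$Nnode
  species <- sub("\\|.*$", "", gt$tip.label)
  missing <- setdiff(unique(species), st$tip.label)
  if (length(missing))
    stop("gene-tree species absent from species tree: ",
         paste(missing, collapse = ", "))
  supp <- rep(NA_real_, n)
  if (!is.null(gt$node.label)) {
    sv <- suppressWarnings(as.numeric(gt$node.label))
    supp[ntip + seq_len(gt$Nnode)] <- sv
  }
  parent <- rep(NA_integer_, n)
  parent[gt$edge[, 2]] <- gt$edge[, 1]
  # union-find contraction of weak internal edges
  rep_of <- seq_len(n)
  find <- function(x) { while (rep_of[x] != x) x <- rep_of[x]; x }
  root <- setdiff(gt$edge[, 1], gt$edge[, 2])[1]
  for (v in (ntip + 1):n) {
    if (v == root || is.na(parent[v])) next
    s <- supp[v]
    if (!is.na(s) && s < collapse_pct) rep_of[find(v)] <- find(parent[v])
  }
  edges <- unique(t(apply(gt$edge, 1, function(e) {
    a <- find(e[1]); b <- find(e[2]); sort(c(a, b))
  })))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  # contract a degree-2 storage root
  repeat {
    deg <- table(factor(c(edges[, 1], edges[, 2]),
                        levels = unique(c(edges[, 1], edges[, 2]))))
    d2 <- as.integer(names(deg)[deg == 2])
    d2 <- d2[d2 > ntip]
    if (!length(d2)) break
    v <- d2[1]
    inc <- which(edges[, 1] == v | edges[, 2] == v)
    nb <- setdiff(unique(c(edges[inc, ])), v)
    edges <- edges[-inc, , drop = FALSE]
    if (length(nb) == 2) edges <- rbind(edges, sort(nb))
  }
  list(ntip = ntip, edges = edges, species = species,
       labels = gt$tip.label)
}

# orient graph away from a root placed on edge (u, v)
orient_from_edge <- function(graph, u, v) {
  adj <- list()
  add_edge <- function(a, b) {
    adj[[as.character(a)]] <<- c(adj[[as.character(a)]], b)
    adj[[as.character(b)]] <<- c(adj[[as.character(b)]], a)
  }
  for (e in seq_len(nrow(graph$edges))) add_edge(graph$edges[e, 1], graph$edges[e, 2])
  kids_of <- function(node, from) setdiff(adj[[as.character(node)]], from)
  list(adj = adj, kids_of = kids_of, u = u, v = v)
}

# recursive reconciliation of the subtree rooted at `node`, entered from
# `from`; returns map, counts, events, canonical newick
reconcile_subtree <- function(node, from, orient, graph, prep, st,
                              leaf_species_id) {
  kids <- setdiff(orient$adj[[as.character(node)]], from)
  if (!length(kids)) { # leaf
    return(list(map = leaf_species_id[node], dups = 0L, losses = 0L,
                events = list(), nwk = graph$labels[node]))
  }
  subs <- lapply(kids, function(k)
    reconcile_subtree(k, node, orient, graph, prep, st, leaf_species_id))
  maps <- lapply(subs, function(s) s$map)
  res <- resolve_polytomy(maps, prep)
  nwk <- paste0("(", paste(sort(vapply(subs, function(s) s$nwk, "")),
                           collapse = ","), ")")
  list(map = res$map,
       dups = res$dups + sum(vapply(subs, function(s) s$dups, 0L)),
       losses = res$losses + sum(vapply(subs, function(s) s$losses, 0L)),
       events = c(do.call(c, lapply(subs, function(s) s$events)), res$events),
       nwk = nwk)
}

#' Reconcile a gene tree with the species tree
#'
#' Collapses weakly supported internal branches, scores every rooting, and
#' maps the best rooted tree onto the species tree via LCA mapping,
#' labeling each internal node as a speciation or duplication and counting
#' implied losses (see the file header for the exact criteria).
#'
#' @param gene_tree a `phylo`; tip labels are `species` or `species|copy`;
#'   `node.label` may carry bootstrap supports (0-100).
#' @param st a `species_tree`.
#' @param collapse_pct internal branches with support below this are
#'   collapsed before rooting (default 70).
#' @return an object of class `reconciled_tree`: list with `n_dup`,
#'   `n_loss`, `events` (tibble of internal-node events with species-tree
#'   node and age), `backbone_dups`, and the canonical rooted `newick`.
#' @export
reconcile <- function(gene_tree, st, collapse_pct = 70) {
  prep <- st_prep(st)
  graph <- gt_graph(gene_tree, st, collapse_pct)
  leaf_species_id <- prep$leaf_id[graph$species]
  best <- NULL
  for (e in seq_len(nrow(graph$edges))) {
    u <- graph$edges[e, 1]; v <- graph$edges[e, 2]
    orient <- orient_from_edge(graph, u, v)
    L <- reconcile_subtree(u, v, orient, graph, prep, st, leaf_species_id)
    R <- reconcile_subtree(v, u, orient, graph, prep, st, leaf_species_id)
    M <- st_lca(prep, L$map, R$map)
    dup <- (M == L$map) || (M == R$map)
    dl <- max(prep$depth[L$map] - prep$depth[M] - (if (dup) 0L else 1L), 0L)
    dr <- max(prep$depth[R$map] - prep$depth[M] - (if (dup) 0L else 1L), 0L)
    total <- list(
      dups = L$dups + R$dups + as.integer(dup),
      losses = L$losses + R$losses + dl + dr,
      events = c(L$events, R$events, list(c(M, as.integer(dup)))),
      nwk = paste0("(", paste(sort(c(L$nwk, R$nwk)), collapse = ","), ");"))
    if (is.null(best) || total$dups < best$dups ||
        (total$dups == best$dups && total$losses < best$losses) ||
        (total$dups == best$dups && total$losses == best$losses &&
         total$nwk < best$nwk))
      best <- total
  }
  ev <- best$events
  events <- tibble::tibble(
    node = vapply(ev, function(x) x[1], 1L),
    event = ifelse(vapply(ev, function(x) x[2], 1L) == 1, "duplication",
                   "speciation"))
  events$age <- st$node_age[events$node]
  bb <- c(backbone_nodes(st), match(st$focal, st$tip.label))
  backbone_dups <- sum(events$event == "duplication" & events$node %in% bb)
  structure(list(n_dup = best$dups, n_loss = best$losses, events = events,
                 backbone_dups = backbone_dups, newick = best$nwk),
            class = "reconciled_tree")
}

#' @export
print.reconciled_tree <- function(x, ...) {
  cat("reconciled_tree:", x$n_dup, "duplication(s),", x$n_loss,
      "loss(es),", x$backbone_dups, "on the backbone\n")
  invisible(x)
}

#' Summarize duplication events across families
#'
#' Excludes highly duplicated families (more than `max_backbone`
#' duplications on the root-to-focal backbone), then bins the remaining
#' duplication events by their mapped backbone node.
#'
#' @param events tibble with columns `family_id`, `node`, `age`, `event`
#'   (one row per reconciled internal node; combine across families), e.g.
#'   from binding `reconcile()$events` per family.
#' @param st a `species_tree`.
#' @param max_backbone exclusion threshold.
#' @return a list: `per_node` tibble (`node`, `age`, `n_dup_events`,
#'   `n_families`), `n_excluded`, `n_included`, `families_with_dup`.
#' @export
summarize_duplications <- function(events, st, max_backbone = 3L) {
  bb <- c(backbone_nodes(st), match(st$focal, st$tip.label))
  dups <- dplyr::filter(events, .data$event == "duplication",
                        .data$node %in% bb)
  per_fam <- dups %>% dplyr::count(.data$family_id, name = "n_backbone")
  excluded <- per_fam$family_id[per_fam$n_backbone > max_backbone]
  all_fams <- unique(events$family_id)
  kept <- dplyr::filter(dups, !.data$family_id %in% excluded)
  per_node <- tibble::tibble(node = bb, age = st$node_age[bb]) %>%
    dplyr::left_join(
      kept %>% dplyr::group_by(.data$node) %>%
        dplyr::summarise(n_dup_events = dplyr::n(),
                         n_families = dplyr::n_distinct(.data$family_id),
                         .groups = "drop"),
      by = "node") %>%
    tidyr::replace_na(list(n_dup_events = 0L, n_families = 0L)) %>%
    dplyr::arrange(dplyr::desc(.data$age))
  list(per_node = per_node,
       n_excluded = length(excluded),
       n_included = length(setdiff(all_fams, excluded)),
       families_with_dup = dplyr::n_distinct(kept$family_id))
}
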