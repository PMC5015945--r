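#' Classify species missing from conserved families as loss or decay
#'
#' For each conserved family and each species lacking a strict homolog, the
#' query is re-searched at the relaxed E-value cutoff and so are the focal
#' flanking anchor genes. The locus is `decayed` when a relaxed query hit
#' lies on the same chromosome as an anchor-gene hit within the effective
#' linkage distance — the larger of the 10-kb baseline and the observed
#' query-to-anchor distance in the focal genome — and `lost` otherwise
#' (no relaxed hit, or a hit unlinked to the anchor region).
#'
#' @param families output of [build_families()].
#' @param homology output of [call_homologs()] (uses `relaxed_hits` and
#'   `anchor_hits`).
#' @param queries focal query tibble (for focal anchor distances).
#' @param anchors_focal focal anchor tibble with intervals.
#' @param tree a `species_tree`.
#' @param config a [lincphylo_config()].
#' @param which_families `"conserved"` (default) restricts to conserved
#'   families; `"all"` classifies every family.
#' @return tibble of loss/decay calls: `family_id`, `species`, `state`
#'   (present/decayed/lost), evidence columns (relaxed-hit interval,
#'   anchor-hit interval, link distance, effective linkage threshold).
#'   Only species in lineages I and II are classified: a conserved family
#'   implies presence in their common ancestor, so absence there is loss
#'   or decay, whereas nothing follows for more basal taxa.
#' @export
classify_loss_decay <- function(families, homology, queries, anchors_focal,
                                tree, config = lincphylo_config(),
                                which_families = c("conserved", "all")) {
  which_families <- match.arg(which_families)
  fams <- if (which_families == "conserved")
    dplyr::filter(families, .data$conserved) else families
  if (!nrow(fams)) return(empty_loss_decay())
  ingroup <- names(tree$lineage)[tree$lineage %in% c("I", "II")]
  subjects <- setdiff(intersect(tree$tip.label, ingroup), tree$focal)
  # focal anchor distance per query (distance from locus to nearest anchor)
  qa <- anchors_focal %>%
    dplyr::left_join(queries[, c("locus_id", "start", "end")],
                     by = "locus_id", suffix = c("", ".q")) %>%
    dplyr::mutate(dist = pmax(.data$start - .data$end.q,
                              .data$start.q - .data$end, 0L)) %>%
    dplyr::group_by(.data$locus_id) %>%
    dplyr::summarise(anchor_dist = min(.data$dist), .groups = "drop")
  anchor_dist <- stats::setNames(qa$anchor_dist, qa$locus_id)
  rows <- list()
  for (fi in seq_len(nrow(fams))) {
    q <- fams$query_id[fi]
    mb <- fams$members[[fi]]
    eff_link <- max(config$decay_link_bp,
                    anchor_dist[[q]] %||% 0L)
    for (sp in subjects) {
      if (sp %in% mb$species) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          family_id = q, species = sp, state = "present",
          hit_chrom = NA_character_, hit_start = NA_integer_,
          hit_end = NA_integer_, anchor_chrom = NA_character_,
          anchor_start = NA_integer_, anchor_end = NA_integer_,
          link_bp = NA_integer_, effective_link_bp = eff_link)
        next
      }
      rel <- dplyr::filter(homology$relaxed_hits, .data$species == sp,
                           .data$query_id == q)
      anc <- dplyr::filter(homology$anchor_hits, .data$species == sp,
                           .data$locus_id == q)
      state <- "lost"
      hit <- anchor <- NULL; link <- NA_integer_
      if (nrow(rel) && nrow(anc)) {
        cand <- dplyr::inner_join(rel, anc, by = "chrom",
                                  suffix = c("", ".a"), relationship = "many-to-many") %>%
          dplyr::mutate(link = pmax(.data$start - .data$end.a,
                                    .data$start.a - .data$end, 0L)) %>%
          dplyr::filter(.data$link <= eff_link) %>%
          dplyr::arrange(.data$evalue, .data$link)
        if (nrow(cand)) {
          state <- "decayed"
          hit <- cand[1, c("chrom", "start", "end")]
          anchor <- cand[1, c("chrom", "start.a", "end.a")]
          link <- cand$link[1]
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family_id = q, species = sp, state = state,
        hit_chrom = if (!is.null(hit)) hit$chrom else NA_character_,
        hit_start = if (!is.null(hit)) hit$start else NA_integer_,
        hit_end = if (!is.null(hit)) hit$end else NA_integer_,
        anchor_chrom = if (!is.null(anchor)) anchor$chrom else NA_character_,
        anchor_start = if (!is.null(anchor)) anchor$start.a else NA_integer_,
        anchor_end = if (!is.null(anchor)) anchor$end.a else NA_integer_,
        link_bp = link, effective_link_bp = eff_link)
    }
  }
  dplyr::bind_rows(rows)
}

empty_loss_decay <- function() {
  tibble::tibble(family_id = character(), species = character(),
                 state = character(), hit_chrom = character(),
                 hit_start = integer(), hit_end = integer(),
                 anchor_chrom = character(), anchor_start = integer(),
                 anchor_end = integer(), link_bp = integer(),
                 effective_link_bp = integer())
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Score test for a difference of two binomial proportions
#'
#' Pooled-variance z statistic with a two-sided normal p-value; a degenerate
#' pooled proportion (0 or 1) yields `z = 0`, `p = 1`.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return tibble with `z` and `p_value`.
#' @export
proportion_score_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1)
    return(tibble::tibble(z = 0, p_value = 1))
  z <- (x1 / n1 - x2 / n2) /
    sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  tibble::tibble(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Group species by indistinguishable loss or decay proportions
#'
#' Runs all pairwise proportion score tests among species for the chosen
#' state, applies a Bonferroni threshold of `alpha / choose(n, 2)`, links
#' species whose corrected test is non-significant, and reports the
#' connected components with their proportion ranges. When a component is
#' not a clique (some internal pair is significant) it is flagged.
#'
#' @param calls loss/decay call tibble from [classify_loss_decay()].
#' @param metric `"lost"` or `"decayed"`.
#' @param alpha family-wise significance level.
#' @return list with `species` (per-species proportions and group id),
#'   `groups` (group summary with min/max percent and clique flag), and
#'   `pairs` (all pairwise tests with Bonferroni-corrected significance).
#' @export
group_species <- function(calls, metric = c("lost", "decayed"), alpha = 0.01) {
  metric <- match.arg(metric)
  tab <- calls %>%
    dplyr::group_by(.data$species) %>%
    dplyr::summarise(x = sum(.data$state == metric), n = dplyr::n(),
                     prop = .data$x / .data$n, .groups = "drop") %>%
    dplyr::arrange(.data$species)
  ns <- nrow(tab)
  if (ns < 2)
    return(list(species = dplyr::mutate(tab, group = 1L),
                groups = tibble::tibble(), pairs = tibble::tibble()))
  n_tests <- choose(ns, 2)
  thr <- alpha / n_tests
  prs <- utils::combn(ns, 2)
  pair_rows <- purrr::map(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    t <- proportion_score_test(tab$x[i], tab$n[i], tab$x[j], tab$n[j])
    tibble::tibble(species1 = tab$species[i], species2 = tab$species[j],
                   z = t$z, p_value = t$p_value,
                   significant = t$p_value < thr)
  })
  pairs <- dplyr::bind_rows(pair_rows)
  # connected components over non-significant edges
  group <- seq_len(ns)
  find <- function(x) { while (group[x] != x) x <- group[x]; x }
  for (k in seq_len(nrow(pairs))) {
    if (!pairs$significant[k]) {
      i <- match(pairs$species1[k], tab$species)
      j <- match(pairs$species2[k], tab$species)
      group[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(ns), find, 1L)
  comp <- match(comp, unique(comp))
  tab$group <- comp
  groups <- tab %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(members = paste(.data$species, collapse = ","),
                     n_species = dplyr::n(),
                     min_pct = 100 * min(.data$prop),
                     max_pct = 100 * max(.data$prop), .groups = "drop")
  # clique check: any significant pair inside a component?
  groups$is_clique <- vapply(groups$group, function(g) {
    mem <- tab$species[tab$group == g]
    inpair <- pairs$species1 %in% mem & pairs$species2 %in% mem
    !any(pairs$significant[inpair])
  }, TRUE)
  list(species = tab, groups = groups, pairs = pairs)
}
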