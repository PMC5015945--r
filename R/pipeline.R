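#' Run the full comparative pipeline on a simulated cohort
#'
#' Chains the stages: homology search with reciprocity and synteny checks,
#' family construction with the two-lineage conservation criterion, query
#' ORF screening and the conserved-ORF permutation filter, gene-tree
#' inference and reconciliation for conserved families, loss-vs-decay
#' classification, and the per-locus feature table.
#'
#' @param sim a `linc_sim` from [simulate_lincrna_cohort()] (or a list with
#'   the same elements read from disk).
#' @param config a [lincphylo_config()].
#' @param gene_trees infer gene trees and reconcile (the slowest stage).
#' @param coding_filter run the conserved-ORF permutation test on conserved
#'   families with at least four members.
#' @param ncrna_library optional named character vector of known noncoding
#'   RNAs for the similarity screen.
#' @return a list of class `linc_pipeline` with elements `homology`,
#'   `families`, `loss_decay`, `features`, `events` (reconciliation events
#'   per family), `dup_summary`, and `config`.
#' @export
run_pipeline <- function(sim, config = lincphylo_config(),
                         gene_trees = TRUE, coding_filter = TRUE,
                         ncrna_library = NULL) {
  tree <- sim$tree
  focal <- tree$focal
  gene_annot <- dplyr::select(sim$anchors, "species", "chrom", "start",
                              "end", "name")
  hom <- call_homologs(sim$queries, sim$genomes, focal, sim$anchors_focal,
                       subject_genes = gene_annot, config = config)
  fams <- build_families(hom$calls, tree, config,
                         query_ids = sim$queries$locus_id)

  # focal-genome self-search for extra (paralogous) focal copies
  self_hits <- search_genome(stats::setNames(sim$queries$seq,
                                             sim$queries$locus_id),
                             sim$genomes[[focal]], config$scoring,
                             config$strict_evalue)
  self_hits <- merge_hits(self_hits, nchar(
    stats::setNames(sim$queries$seq, sim$queries$locus_id)))
  qint <- sim$queries[match(self_hits$query_id, sim$queries$locus_id), ]
  self_extra <- self_hits[!(self_hits$chrom == qint$chrom &
                              interval_overlaps(self_hits$start,
                                                self_hits$end,
                                                qint$start, qint$end)), ] %>%
    dplyr::mutate(species = focal)

  # query ORF screen
  fams$orf_flag <- vapply(fams$query_id, function(q) {
    orf_screen(sim$queries$seq[sim$queries$locus_id == q],
               config$orf_aa_threshold)
  }, TRUE, USE.NAMES = FALSE)
  # known-ncRNA screen
  fams$ncrna_flag <- if (is.null(ncrna_library)) FALSE else
    vapply(fams$query_id, function(q) {
      known_ncrna_screen(sim$queries$seq[sim$queries$locus_id == q],
                         ncrna_library, config$relaxed_evalue,
                         config$scoring)
    }, TRUE, USE.NAMES = FALSE)

  # family alignments (members projected on the query)
  aln_of <- function(fi) {
    q <- fams$query_id[fi]
    mb <- fams$members[[fi]]
    if (!nrow(mb)) return(NULL)
    seqs <- vapply(seq_len(nrow(mb)), function(i)
      get_sequence(sim$genomes[[mb$species[i]]], mb[i, ]), "")
    names(seqs) <- mb$species
    family_alignment(sim$queries$seq[sim$queries$locus_id == q], seqs,
                     config$scoring)
  }

  fams$coding_flag <- FALSE
  fams$coding_p <- NA_real_
  if (coding_filter) {
    idx <- which(fams$conserved & vapply(fams$members, nrow, 1L) >= 3)
    for (fi in idx) {
      aln <- aln_of(fi)
      ct <- conserved_coding_test(aln, n_perm = 1000L, alpha = 0.001,
                                  seed = stage_seed(config$rng_seed,
                                                    paste0("coding", fi)))
      fams$coding_p[fi] <- ct$p_value
      fams$coding_flag[fi] <- isTRUE(ct$coding)
    }
  }
  fams$conserved_final <- fams$conserved & !fams$orf_flag &
    !fams$ncrna_flag & !fams$coding_flag

  # loss / decay on conserved families
  ld <- classify_loss_decay(fams, hom, sim$queries, sim$anchors_focal, tree,
                            config)

  # gene trees + reconciliation on conserved families
  events <- tibble::tibble(family_id = character(), node = integer(),
                           event = character(), age = double())
  dup_summary <- NULL
  if (gene_trees) {
    strict_hits <- dplyr::filter(hom$relaxed_hits,
                                 .data$evalue <= config$strict_evalue)
    events <- family_reconciliations(fams, strict_hits, self_extra, sim,
                                     config)
    dup_summary <- summarize_duplications(events, tree,
                                          config$max_backbone_dups)
  }

  feats <- build_feature_table(sim$queries, fams, sim$te, sim$cns,
                               dplyr::filter(gene_annot,
                                             .data$species == focal),
                               sim$expression, sim$stress, config)
  structure(list(homology = hom, families = fams, loss_decay = ld,
                 features = feats, events = events,
                 dup_summary = dup_summary, config = config),
            class = "linc_pipeline")
}

#' @export
print.linc_pipeline <- function(x, ...) {
  cat("linc_pipeline:", nrow(x$families), "families (",
      sum(x$families$conserved), "conserved ),",
      nrow(x$loss_decay), "loss/decay calls\n")
  invisible(x)
}

# Gene trees with multi-copy leaves: the focal query, the family member per
# species, extra strict hits (paralogs), and extra focal copies; NJ +
# bootstrap + reconciliation. Returns the event table across families.
family_reconciliations <- function(fams, strict_hits, self_extra, sim,
                                   config, max_extra_per_species = 2L) {
  tree <- sim$tree
  focal <- tree$focal
  out <- list()
  idx <- which(fams$conserved)
  for (fi in idx) {
    q <- fams$query_id[fi]
    mb <- fams$members[[fi]]
    if (nrow(mb) < 2) next
    seqs <- stats::setNames(
      vapply(seq_len(nrow(mb)), function(i)
        get_sequence(sim$genomes[[mb$species[i]]], mb[i, ]), ""),
      paste0(mb$species, "|m"))
    # extra strict hits not overlapping the member
    extra <- dplyr::filter(strict_hits, .data$query_id == q)
    extra <- dplyr::bind_rows(extra,
                              dplyr::filter(self_extra, .data$query_id == q))
    if (nrow(extra)) {
      keep <- vapply(seq_len(nrow(extra)), function(i) {
        mrow <- mb[mb$species == extra$species[i], ]
        !nrow(mrow) || !(mrow$chrom == extra$chrom[i] &&
                           interval_overlaps(mrow$start, mrow$end,
                                             extra$start[i], extra$end[i]))
      }, TRUE)
      extra <- extra[keep, ]
      extra <- extra %>%
        dplyr::group_by(.data$species) %>%
        dplyr::arrange(.data$evalue, .by_group = TRUE) %>%
        dplyr::slice(seq_len(max_extra_per_species)) %>%
        dplyr::ungroup()
      if (nrow(extra)) {
        es <- stats::setNames(
          vapply(seq_len(nrow(extra)), function(i)
            get_sequence(sim$genomes[[extra$species[i]]], extra[i, ]), ""),
          paste0(extra$species, "|x", seq_len(nrow(extra))))
        seqs <- c(seqs, es)
      }
    }
    qseq <- sim$queries$seq[sim$queries$locus_id == q]
    aln <- family_alignment(qseq, seqs, config$scoring)
    names(aln)[1] <- paste0(focal, "|q")
    if (length(aln) < 3) next
    gt <- bootstrap_supports(aln, reps = config$bootstrap_reps,
                             seed = stage_seed(config$rng_seed,
                                               paste0("boot", q)))
    rec <- reconcile(gt, tree, config$support_collapse_pct)
    ev <- rec$events
    ev$family_id <- q
    out[[length(out) + 1L]] <- ev
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(node = integer(), event = character(), age = double(),
                      family_id = character())
}

#' Expected reconciliation node of each planted duplication
#'
#' Given survivorship, the LCA mapping of a duplication node in a correct
#' gene tree is the species-tree LCA of all species carrying a surviving
#' descendant of either daughter copy. Events with an extinct daughter
#' lineage are unrecoverable (`expected_node = NA`).
#'
#' @param sim a `linc_sim`.
#' @return tibble `locus_id`, `node` (planted), `expected_node`.
#' @export
expected_duplication_nodes <- function(sim) {
  tr <- sim$tree
  clades <- st_leafsets(tr)
  tips <- sim$truth %>% dplyr::filter(!is.na(.data$copy_id),
                                      .data$state != "lost")
  purrr::pmap_dfr(sim$dup_events, function(locus_id, node, type,
                                           parent_copy, new_copy) {
    # both daughter lineages live inside the clade of the planted node
    tc <- dplyr::filter(tips, .data$locus_id == !!locus_id,
                        .data$species %in% clades[[node]])
    in_lineage <- function(ids, anc)
      ids == anc | startsWith(ids, paste0(anc, "."))
    new_sp <- tc$species[in_lineage(tc$copy_id, new_copy)]
    par_sp <- tc$species[in_lineage(tc$copy_id, parent_copy) &
                           !in_lineage(tc$copy_id, new_copy)]
    exp_node <- if (length(new_sp) && length(par_sp))
      st_mrca(tr, c(new_sp, par_sp)) else NA_integer_
    tibble::tibble(locus_id = locus_id, node = node,
                   expected_node = exp_node)
  })
}

#' Compare pipeline output with the simulator's planted truth
#'
#' Computes the planted-history recovery metrics: homolog recall and
#' precision (restricted to species within `max_recall_age` Myr of the focal
#' species), agreement of the conserved flag with the truth-derived flag,
#' loss/decay state accuracy over the classified (family, species) pairs
#' (species outside the birth clade are excluded), the fraction of
#' recovered duplication events mapped to a planted duplication node, and
#' whether the whole-genome-duplication species are isolated by
#' [group_species()] on the lost metric.
#'
#' @param pipe a `linc_pipeline`.
#' @param sim the `linc_sim` it was run on.
#' @param max_recall_age recall/precision divergence limit (Myr).
#' @return a one-row tibble of metrics (percentages in 0-100).
#' @export
evaluate_recovery <- function(pipe, sim, max_recall_age = 42) {
  tree <- sim$tree
  focal <- tree$focal
  age_vs_focal <- vapply(tree$tip.label, function(sp)
    if (sp == focal) 0 else mrca_age(tree, c(focal, sp)), 0)
  in_range <- names(age_vs_focal)[age_vs_focal <= max_recall_age &
                                    names(age_vs_focal) != focal]
  truth <- sim$truth
  queries <- sim$queries$locus_id
  # recall/precision are judged on intact queries: a query whose own focal
  # copy is in decay mode is hyper-mutated and cannot seed recovery of its
  # (normally evolving) homologs by construction
  intact <- if ("focal_state" %in% names(sim$queries))
    sim$queries$locus_id[sim$queries$focal_state == "present"] else queries
  tp <- truth %>%
    dplyr::filter(.data$primary, .data$species %in% in_range,
                  .data$locus_id %in% intact)
  calls <- dplyr::filter(pipe$homology$calls, .data$promoted,
                         .data$species %in% in_range,
                         .data$query_id %in% intact)
  t_present <- dplyr::filter(tp, .data$state == "present")
  found <- dplyr::semi_join(
    t_present,
    dplyr::inner_join(calls, truth %>% dplyr::filter(!is.na(.data$start)),
                      by = c(query_id = "locus_id", species = "species",
                             chrom = "chrom"),
                      suffix = c("", ".t"), relationship = "many-to-many") %>%
      dplyr::filter(interval_overlaps(.data$start, .data$end,
                                      .data$start.t, .data$end.t)) %>%
      dplyr::distinct(.data$query_id, .data$species) %>%
      dplyr::rename(locus_id = "query_id"),
    by = c("locus_id", "species"))
  recall <- nrow(found) / max(nrow(t_present), 1)
  correct_calls <- dplyr::inner_join(
    calls, truth %>% dplyr::filter(!is.na(.data$start)),
    by = c(query_id = "locus_id", species = "species", chrom = "chrom"),
    suffix = c("", ".t"), relationship = "many-to-many") %>%
    dplyr::filter(interval_overlaps(.data$start, .data$end, .data$start.t,
                                    .data$end.t)) %>%
    dplyr::distinct(.data$query_id, .data$species)
  precision <- nrow(correct_calls) / max(nrow(dplyr::distinct(
    calls, .data$query_id, .data$species)), 1)

  # conserved-flag agreement vs truth-derived conservation
  lin2 <- names(tree$lineage)[tree$lineage == "II"]
  tflag <- truth %>%
    dplyr::filter(.data$primary, .data$state == "present",
                  .data$locus_id %in% queries,
                  .data$species != focal) %>%
    dplyr::group_by(.data$locus_id) %>%
    dplyr::summarise(n_sp = dplyr::n() + 1L,
                     lin2 = any(.data$species %in% lin2),
                     .groups = "drop") %>%
    dplyr::mutate(truth_conserved = .data$n_sp >=
                    pipe$config$min_family_species & .data$lin2)
  fcomp <- pipe$families %>%
    dplyr::left_join(tflag, by = c(query_id = "locus_id")) %>%
    dplyr::mutate(truth_conserved = dplyr::coalesce(.data$truth_conserved,
                                                    FALSE))
  conserved_agree <- mean(fcomp$conserved == fcomp$truth_conserved)

  # loss/decay accuracy over classified pairs (truth state known)
  ld <- pipe$loss_decay %>%
    dplyr::inner_join(truth %>% dplyr::filter(.data$primary) %>%
                        dplyr::select("locus_id", "species", truth_state = "state"),
                      by = c(family_id = "locus_id", species = "species")) %>%
    dplyr::filter(.data$truth_state != "absent")
  ld_acc <- if (nrow(ld)) mean(ld$state == ld$truth_state) else NA_real_

  # duplication node accuracy among recovered events, judged against the
  # survivorship-aware expected LCA mapping of each planted event
  dup_acc <- NA_real_
  if (!is.null(pipe$events) && nrow(pipe$events)) {
    rec_d <- dplyr::filter(pipe$events, .data$event == "duplication")
    if (nrow(rec_d)) {
      td <- expected_duplication_nodes(sim)
      td <- dplyr::filter(td, !is.na(.data$expected_node))
      matched <- dplyr::semi_join(rec_d, td,
                                  by = c(family_id = "locus_id",
                                         node = "expected_node"))
      dup_acc <- nrow(matched) / nrow(rec_d)
    }
  }

  # WGD species isolated on the lost metric
  wgd_sp <- character(0)
  if (length(tree$wgd_nodes)) {
    ls <- st_leafsets(tree)
    wgd_sp <- unique(unlist(ls[tree$wgd_nodes]))
  }
  wgd_isolated <- NA
  if (length(wgd_sp) && nrow(pipe$loss_decay)) {
    gs <- group_species(pipe$loss_decay, "lost")
    gmap <- stats::setNames(gs$species$group, gs$species$species)
    wgd_groups <- unique(gmap[intersect(names(gmap), wgd_sp)])
    other_groups <- unique(gmap[setdiff(names(gmap), wgd_sp)])
    wgd_isolated <- !any(wgd_groups %in% other_groups)
  }

  tibble::tibble(
    homolog_recall_pct = 100 * recall,
    homolog_precision_pct = 100 * precision,
    conserved_agreement_pct = 100 * conserved_agree,
    loss_decay_accuracy_pct = 100 * ld_acc,
    duplication_node_accuracy_pct = 100 * dup_acc,
    wgd_isolated_on_loss = wgd_isolated,
    n_queries = length(queries),
    n_conserved = sum(pipe$families$conserved))
}
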