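#' Cluster homolog calls into per-query families
#'
#' Each query lincRNA forms a family with its promoted homologs (at most one
#' member per subject species). A genomic interval may not belong to more
#' than one family: when members of different families overlap, the
#' contested locus is kept in the family where it has the lowest E-value
#' (ties: higher score, then lexicographically smallest query id) and
#' removed from the others. A family is `conserved` when it spans at least
#' `min_family_species` species (including the focal species) with at least
#' one member from lineage II; its conservation depth is the age of the most
#' recent common ancestor of the focal species and the most divergent member.
#'
#' @param calls candidate tibble from [call_homologs()] (uses rows with
#'   `promoted = TRUE`).
#' @param tree a `species_tree`.
#' @param config a [lincphylo_config()].
#' @param query_ids optional character vector of all query ids; queries
#'   without any candidate become singleton (focal-only, depth 0) families.
#' @return a tibble with one row per query: `query_id`, `n_species`,
#'   `lineage2_present`, `conserved`, `depth_node`, `depth_age`, and a
#'   `members` list-column of member tibbles.
#' @export
build_families <- function(calls, tree, config = lincphylo_config(),
                           query_ids = NULL) {
  members <- dplyr::filter(calls, .data$promoted)
  # interval-conflict resolution across families
  if (nrow(members)) {
    members <- members %>%
      dplyr::group_by(.data$species, .data$chrom) %>%
      dplyr::arrange(.data$start, .by_group = TRUE) %>%
      dplyr::mutate(cluster = cumsum(is.na(cummax_lag_end(.data$end)) |
                                       .data$start >= cummax_lag_end(.data$end))) %>%
      dplyr::group_by(.data$cluster, .add = TRUE) %>%
      dplyr::arrange(.data$evalue, dplyr::desc(.data$score), .data$query_id,
                     .by_group = TRUE) %>%
      dplyr::slice(1) %>%
      dplyr::ungroup() %>%
      dplyr::select(-"cluster")
  }
  focal <- tree$focal
  age_vs_focal <- vapply(tree$tip.label, function(sp)
    if (sp == focal) 0 else mrca_age(tree, c(focal, sp)), 0)
  lin2 <- names(tree$lineage)[tree$lineage == "II"]
  queries <- sort(unique(c(calls$query_id, query_ids)))
  fam <- purrr::map(queries, function(q) {
    mb <- dplyr::filter(members, .data$query_id == q)
    depth_age <- if (nrow(mb)) max(age_vs_focal[mb$species]) else 0
    depth_node <- if (nrow(mb)) st_mrca(tree, c(focal, mb$species))
                  else match(focal, tree$tip.label)
    tibble::tibble(
      query_id = q,
      n_species = nrow(mb) + 1L,
      lineage2_present = any(mb$species %in% lin2),
      conserved = (nrow(mb) + 1L) >= config$min_family_species &&
        any(mb$species %in% lin2),
      depth_node = depth_node,
      depth_age = depth_age,
      members = list(mb))
  })
  dplyr::bind_rows(fam)
}

#' Flatten a family table for reporting
#'
#' One row per family with the member list serialized as
#' `species:chrom:start-end:strand` strings.
#' @param families output of [build_families()].
#' @return a flat tibble suitable for [write_report()].
#' @export
families_report <- function(families) {
  families %>%
    dplyr::mutate(member_list = purrr::map_chr(.data$members, function(mb) {
      if (!nrow(mb)) return("")
      paste(sprintf("%s:%s:%d-%d:%s", mb$species, mb$chrom, mb$start, mb$end,
                    mb$strand), collapse = ",")
    })) %>%
    dplyr::select(-"members")
}

GENETIC_CODE_1 <- NULL # populated at load time from Biostrings

translate_nt <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0) return("")
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Screen a sequence for a long open reading frame
#'
#' Scans all six reading frames for an `ATG ... stop` open reading frame
#' longer than `threshold_aa` amino acids (the ATG methionine counts, the
#' stop does not). Sequences with such an ORF do not qualify as lincRNAs.
#'
#' @param seq a DNA string.
#' @param threshold_aa ORF length threshold in amino acids (default 100; an
#'   ORF of exactly 100 aa does not trigger).
#' @return `TRUE` if a qualifying ORF exists.
#' @export
orf_screen <- function(seq, threshold_aa = 100L) {
  pat <- sprintf("M[^*]{%d,}\\*", threshold_aa)
  for (s in c(seq, revcomp(seq))) {
    for (f in 0:2) {
      aa <- translate_nt(substring(s, f + 1, nchar(s)))
      if (grepl(pat, aa)) return(TRUE)
    }
  }
  FALSE
}

#' Focal-anchored progressive family alignment
#'
#' Aligns every member globally to the focal query (affine costs from the
#' scoring scheme, free end gaps) and stacks the alignments on query
#' coordinates; member insertions relative to the query are dropped. The
#' result is a fixed-width alignment (width = query length) with the
#' ungapped query as its first row.
#'
#' @param focal_seq the query sequence.
#' @param member_seqs named character vector of member sequences.
#' @param scheme a [scoring_scheme()].
#' @return named character vector: `focal` first, then one row per member.
#' @export
family_alignment <- function(focal_seq, member_seqs,
                             scheme = scoring_scheme()) {
  out <- c(focal = toupper(focal_seq))
  if (!length(member_seqs)) return(out)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                                  mismatch = -scheme$mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(toupper(member_seqs)),
    subject = Biostrings::DNAString(toupper(focal_seq)),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  L <- nchar(focal_seq)
  proj <- vapply(seq_along(member_seqs), function(i) {
    pa <- as.character(Biostrings::alignedPattern(aln[i]))
    sa <- as.character(Biostrings::alignedSubject(aln[i]))
    pchars <- strsplit(pa, "")[[1]]
    schars <- strsplit(sa, "")[[1]]
    row <- rep("-", L)
    # subject (focal) positions before the aligned block are left as gaps
    spos <- Biostrings::start(Biostrings::subject(aln[i])) - 1L
    keep <- schars != "-"
    row[spos + seq_len(sum(keep))] <- pchars[keep]
    paste(row, collapse = "")
  }, "")
  c(out, stats::setNames(proj, names(member_seqs)))
}

#' Permutation test for a conserved open reading frame
#'
#' Tests whether substitutions in a family alignment preserve an encoded
#' peptide. Over the best-scoring common reading frame the statistic is
#' `T = (# synonymous column substitutions) - (# nonsynonymous) - 3 * (#
#' frame-disrupting gaps or in-frame stops)`; its null distribution is
#' obtained by shuffling alignment columns. Requires at least four
#' sequences; with fewer the test is skipped (`p = NA`, family retained).
#'
#' @param aln character vector alignment (focal first; equal widths; the
#'   focal row must be ungapped, as produced by [family_alignment()]).
#' @param n_perm number of column permutations.
#' @param alpha significance level for the coding flag.
#' @param seed RNG seed for the permutation stream.
#' @return a list with `p_value`, `t_obs`, and `coding` (`p < alpha`).
#' @export
conserved_coding_test <- function(aln, n_perm = 1000L, alpha = 0.001,
                                  seed = 1L) {
  if (length(aln) < 4)
    return(list(p_value = NA_real_, t_obs = NA_real_, coding = FALSE))
  stopifnot(length(unique(nchar(aln))) == 1)
  res <- cpp_coding_test(unname(aln), as.integer(n_perm), as.integer(seed))
  p <- (1 + sum(res$t_perm >= res$t_obs)) / (1 + n_perm)
  list(p_value = p, t_obs = res$t_obs, coding = p < alpha)
}

#' Screen a query against a library of known noncoding RNAs
#'
#' @param query a DNA string.
#' @param library named character vector of known ncRNA sequences.
#' @param e_cutoff E-value cutoff (relaxed by default).
#' @param scheme a [scoring_scheme()].
#' @return `TRUE` iff the query hits the library at or below the cutoff.
#' @export
known_ncrna_screen <- function(query, library, e_cutoff = 1e-5,
                               scheme = scoring_scheme()) {
  if (!length(library)) return(FALSE)
  hits <- search_genome(c(q = query), library, scheme, e_cutoff)
  nrow(hits) > 0
}
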