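#' Alignment scoring scheme with Karlin-Altschul statistics
#'
#' The default scheme is the classic short-nucleotide setup: match reward
#' +1, mismatch penalty 2, gap open 5, gap extend 2 (as costs), word size 8.
#' The ungapped Karlin-Altschul `lambda` is solved from
#' `sum_ij p_i p_j exp(lambda s_ij) = 1` under uniform base frequencies; `K`
#' is fixed at 0.46 as a calibration constant. E-values are
#' `E = K m n exp(-lambda S)` with `m` the query length and `n` the total
#' searched length.
#'
#' @param match match reward (positive).
#' @param mismatch mismatch penalty (positive cost).
#' @param gap_open,gap_extend affine gap costs; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param word_size seed k-mer length.
#' @param K Karlin-Altschul K.
#' @param xdrop ungapped extension X-drop.
#' @param trigger minimum ungapped seed-extension score that triggers gapped
#'   extension.
#' @return a list of class `scoring_scheme` with a computed `lambda`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = 2L, gap_open = 5L,
                           gap_extend = 2L, word_size = 8L, K = 0.46,
                           xdrop = 20L, trigger = 22L) {
  stopifnot(match > 0, mismatch > 0, K > 0)
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(-l * mismatch) - 1
  lambda <- stats::uniroot(f, c(1e-4, 10), tol = 1e-12)$root
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size), K = K, lambda = lambda,
                 xdrop = as.integer(xdrop), trigger = as.integer(trigger)),
            class = "scoring_scheme")
}

#' Karlin-Altschul E-value
#' @param score raw alignment score(s).
#' @param m query length.
#' @param n total searched length.
#' @param scheme a [scoring_scheme()].
#' @return E-value(s).
#' @export
karlin_evalue <- function(score, m, n, scheme) {
  scheme$K * as.double(m) * as.double(n) * exp(-scheme$lambda * score)
}

as_query_vector <- function(queries) {
  if (is.data.frame(queries)) {
    stopifnot(all(c("locus_id", "seq") %in% names(queries)))
    stats::setNames(queries$seq, queries$locus_id)
  } else {
    stopifnot(!is.null(names(queries)))
    queries
  }
}

empty_hits <- function() {
  tibble::tibble(query_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 qstart = integer(), qend = integer(), score = integer(),
                 evalue = double())
}

#' Seeded local-alignment search of queries against a genome
#'
#' Finds exact word-size seeds on both strands, extends them ungapped with
#' an X-drop, and polishes candidate regions with a local affine-gap
#' dynamic-programming alignment. Hits with E-value at or below `e_cutoff`
#' are returned sorted by ascending E-value.
#'
#' @param queries named character vector of query sequences, or a tibble
#'   with `locus_id`/`seq` columns.
#' @param genome named character vector of chromosome sequences.
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff maximum E-value.
#' @return a tibble of hits (`query_id`, `chrom`, `strand`, subject
#'   `start`/`end` 0-based half-open, aligned query span `qstart`/`qend`,
#'   `score`, `evalue`).
#' @export
search_genome <- function(queries, genome, scheme = scoring_scheme(),
                          e_cutoff = 1e-20) {
  q <- as_query_vector(queries)
  short <- nchar(q) < scheme$word_size
  if (any(short)) {
    warning("dropping ", sum(short), " query(ies) shorter than word size")
    q <- q[!short]
  }
  if (!length(q) || !length(genome)) return(empty_hits())
  raw <- cpp_search(unname(q), unname(genome), scheme$word_size,
                    scheme$match, scheme$mismatch, scheme$gap_open,
                    scheme$gap_extend, scheme$xdrop, scheme$trigger)
  if (!nrow(raw)) return(empty_hits())
  n_total <- sum(nchar(genome))
  out <- tibble::tibble(
    query_id = names(q)[raw$qidx],
    chrom = names(genome)[raw$cidx],
    strand = raw$strand,
    start = raw$sstart, end = raw$send,
    qstart = raw$qstart, qend = raw$qend,
    score = raw$score,
    evalue = karlin_evalue(raw$score, nchar(q)[raw$qidx], n_total,
                           scheme))
  out <- dplyr::filter(out, .data$evalue <= e_cutoff)
  dplyr::arrange(out, .data$evalue, dplyr::desc(.data$score), .data$chrom,
                 .data$start)
}

#' Merge close hits of the same query
#'
#' Hits on the same chromosome and strand whose gap is smaller than the
#' original query length are unioned into one interval; the merged hit keeps
#' the maximum score and minimum E-value of its members. Idempotent.
#'
#' @param hits hit tibble from [search_genome()] (one or more queries).
#' @param query_len named integer vector of query lengths (names =
#'   `query_id`), or a single length when `hits` holds one query.
#' @return merged hit tibble.
#' @export
merge_hits <- function(hits, query_len) {
  if (!nrow(hits)) return(hits)
  if (is.null(names(query_len))) {
    stopifnot(length(query_len) == 1)
    query_len <- stats::setNames(rep(query_len, length(unique(hits$query_id))),
                                 unique(hits$query_id))
  }
  hits %>%
    dplyr::group_by(.data$query_id, .data$chrom, .data$strand) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::mutate(
      gap = .data$start - cummax_lag_end(.data$end),
      cluster = cumsum(is.na(.data$gap) |
                         .data$gap >= query_len[.data$query_id])) %>%
    dplyr::group_by(.data$cluster, .add = TRUE) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     qstart = min(.data$qstart), qend = max(.data$qend),
                     score = max(.data$score), evalue = min(.data$evalue),
                     .groups = "drop") %>%
    dplyr::select(-"cluster") %>%
    dplyr::relocate("query_id", "chrom", "strand", "start", "end", "qstart",
                    "qend", "score", "evalue") %>%
    dplyr::arrange(.data$evalue, dplyr::desc(.data$score), .data$chrom,
                   .data$start)
}

# lagged running maximum of interval ends (NA for the first row of a group)
cummax_lag_end <- function(end) {
  if (!length(end)) return(integer(0))
  c(NA_integer_, cummax(end)[-length(end)])
}

#' Top hit per query
#'
#' Minimal E-value; ties broken by higher score, then lowest
#' (chromosome, start) lexicographically — deterministic across runs.
#'
#' @param hits hit tibble.
#' @return one row per `query_id`.
#' @export
top_hit <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits %>%
    dplyr::group_by(.data$query_id) %>%
    dplyr::arrange(.data$evalue, dplyr::desc(.data$score), .data$chrom,
                   .data$start, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()
}

#' Reciprocity check
#'
#' A candidate hit is reciprocal when the top hit of its subject sequence,
#' searched back against the focal genome, overlaps the original query
#' interval by at least 1 bp.
#'
#' @param hit one-row hit tibble (subject interval).
#' @param subject_genome genome the hit lives in.
#' @param focal_genome the focal genome searched back.
#' @param query_interval one-row tibble with `chrom`, `start`, `end` of the
#'   original query locus.
#' @param scheme,e_cutoff back-search parameters (strict cutoff by default).
#' @return logical.
#' @export
check_reciprocity <- function(hit, subject_genome, focal_genome,
                              query_interval, scheme = scoring_scheme(),
                              e_cutoff = 1e-20) {
  seq <- get_sequence(subject_genome,
                      tibble::tibble(chrom = hit$chrom, start = hit$start,
                                     end = hit$end, strand = hit$strand))
  back <- search_genome(stats::setNames(seq, "back"), focal_genome, scheme,
                        e_cutoff)
  if (!nrow(back)) return(FALSE)
  tb <- top_hit(back)
  tb$chrom == query_interval$chrom &&
    tb$start < query_interval$end && tb$end > query_interval$start
}

#' Synteny check
#'
#' A candidate hit is syntenic when at least one of the query's flanking
#' anchors (nearest protein-coding genes, or 5-kb flanks when genes are
#' absent) has its top hit in the subject genome on the hit's chromosome
#' within the synteny window.
#'
#' @param hit one-row hit tibble.
#' @param anchor_top_hits tibble of the anchors' top hits in the subject
#'   genome (columns `chrom`, `start`, `end`).
#' @param config a [lincphylo_config()].
#' @return logical.
#' @export
check_synteny <- function(hit, anchor_top_hits, config = lincphylo_config()) {
  if (is.null(anchor_top_hits) || !nrow(anchor_top_hits)) return(FALSE)
  same <- anchor_top_hits$chrom == hit$chrom
  if (!any(same)) return(FALSE)
  a <- anchor_top_hits[same, , drop = FALSE]
  gap <- pmax(a$start - hit$end, hit$start - a$end, 0L)
  any(gap <= config$synteny_window_bp)
}

interval_overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

#' Run the homology stage across all subject genomes
#'
#' For every query and every non-focal genome: relaxed-threshold seeded
#' search, merging of close hits, strict top-hit selection, reciprocal
#' back-search against the focal genome, and synteny verification against
#' the query's flanking anchor genes. Hits overlapping an annotated gene of
#' the subject species carry that gene id as an annotation (not a filter).
#'
#' @param queries focal query tibble (`locus_id`, `seq`, `chrom`, `start`,
#'   `end`).
#' @param genomes named list of genomes (must include the focal genome).
#' @param focal focal species name.
#' @param anchors_focal tibble of focal anchor genes with `locus_id`,
#'   `side`, `seq`.
#' @param subject_genes optional tibble of gene annotations across species
#'   (`species`, `chrom`, `start`, `end`, `name`) for the gene-overlap
#'   annotation.
#' @param config a [lincphylo_config()].
#' @return a list with `calls` (per query x species candidate with
#'   `reciprocal`, `syntenic`, `promoted` flags), `relaxed_hits` (all merged
#'   relaxed-threshold hits) and `anchor_hits` (top anchor-gene hits per
#'   species), for reuse by the loss-vs-decay stage.
#' @export
call_homologs <- function(queries, genomes, focal, anchors_focal,
                          subject_genes = NULL, config = lincphylo_config()) {
  scheme <- config$scoring
  qvec <- stats::setNames(queries$seq, queries$locus_id)
  qlen <- nchar(qvec)
  avec <- stats::setNames(anchors_focal$seq,
                          paste(anchors_focal$locus_id, anchors_focal$side,
                                sep = "|"))
  focal_genome <- genomes[[focal]]
  subjects <- setdiff(names(genomes), focal)
  calls <- list(); relaxed_all <- list(); anchor_all <- list()
  for (sp in subjects) {
    g <- genomes[[sp]]
    fw <- search_genome(qvec, g, scheme, config$relaxed_evalue)
    fw <- merge_hits(fw, qlen)
    relaxed_all[[sp]] <- dplyr::mutate(fw, species = sp)
    # anchor top hits in this genome (relaxed cutoff: anchors may decay too)
    ah <- search_genome(avec, g, scheme, config$relaxed_evalue)
    ah <- top_hit(ah) %>%
      tidyr::separate_wider_delim("query_id", "|",
                                  names = c("locus_id", "side"))
    anchor_all[[sp]] <- dplyr::mutate(ah, species = sp)
    # strict candidates: top hit per query
    cand <- top_hit(dplyr::filter(fw, .data$evalue <= config$strict_evalue))
    if (!nrow(cand)) next
    # batched reciprocal back-search
    cand_seq <- get_sequence(g, cand[, c("chrom", "start", "end", "strand")])
    back <- search_genome(stats::setNames(cand_seq, cand$query_id),
                          focal_genome, scheme, config$strict_evalue)
    back_top <- top_hit(back)
    qint <- queries[match(cand$query_id, queries$locus_id), ]
    bt <- back_top[match(cand$query_id, back_top$query_id), ]
    reciprocal <- !is.na(bt$chrom) & bt$chrom == qint$chrom &
      interval_overlaps(bt$start, bt$end, qint$start, qint$end)
    # synteny: any of the two anchors' top hits near the candidate
    syntenic <- vapply(seq_len(nrow(cand)), function(i) {
      a <- dplyr::filter(anchor_all[[sp]], .data$locus_id == cand$query_id[i])
      isTRUE(check_synteny(cand[i, ], a, config))
    }, TRUE)
    gene_overlap <- rep(NA_character_, nrow(cand))
    if (!is.null(subject_genes)) {
      sg <- dplyr::filter(subject_genes, .data$species == sp)
      for (i in seq_len(nrow(cand))) {
        ov <- sg$chrom == cand$chrom[i] &
          interval_overlaps(sg$start, sg$end, cand$start[i], cand$end[i])
        if (any(ov)) gene_overlap[i] <- sg$name[which(ov)[1]]
      }
    }
    calls[[sp]] <- dplyr::mutate(cand, species = sp, reciprocal = reciprocal,
                                 syntenic = syntenic,
                                 overlapping_gene = gene_overlap,
                                 promoted = reciprocal & syntenic &
                                   .data$evalue <= config$strict_evalue)
  }
  list(calls = if (length(calls)) dplyr::bind_rows(calls) else
         dplyr::mutate(empty_hits(), species = character(0),
                       reciprocal = logical(0), syntenic = logical(0),
                       overlapping_gene = character(0), promoted = logical(0)),
       relaxed_hits = if (length(relaxed_all)) dplyr::bind_rows(relaxed_all)
         else dplyr::mutate(empty_hits(), species = character(0)),
       anchor_hits = if (length(anchor_all)) dplyr::bind_rows(anchor_all)
         else tibble::tibble())
}
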