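#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one list. Defaults
#' follow the analysis the package implements: a strict E-value of 1e-20 for
#' homolog promotion and a relaxed 1e-5 for the loss-vs-decay re-search,
#' nearest flanking protein-coding genes (or a 5-kb flank when genes are
#' absent) as synteny anchors, a 10-kb syntenic-linkage rule for decay calls,
#' a minimum of four species spanning both lineages for a family to count as
#' conserved, a 100-amino-acid open-reading-frame screen, a 10-nt minimum
#' transposable-element overlap, 100 bootstrap replicates with branches under
#' 70% support collapsed, exclusion of families with more than 3 backbone
#' duplications, and a miRNA target expectation cutoff of 2.0 scored over
#' 20 nt.
#'
#' @param strict_evalue E-value at or below which a hit may be promoted to
#'   homolog.
#' @param relaxed_evalue E-value for the loss-vs-decay re-search and for
#'   anchor-gene searches.
#' @param synteny_window_bp maximum distance (bp) between a candidate homolog
#'   and an anchor-gene hit for the candidate to count as syntenic.
#' @param flank_bp_when_no_gene flank length used as a synteny anchor when no
#'   annotated gene is present near the query.
#' @param decay_link_bp baseline maximum distance between a relaxed query hit
#'   and an anchor-gene hit for a decay call.
#' @param min_family_species minimum number of species (including the focal
#'   species) for a conserved family.
#' @param orf_aa_threshold open reading frames longer than this many amino
#'   acids disqualify a query as a lincRNA.
#' @param te_min_overlap_nt minimum overlap (nt) for a transposable element
#'   to count as inside a locus.
#' @param te_near_bp distances (bp) defining the "near" TE classes.
#' @param bootstrap_reps bootstrap replicates for gene-tree supports.
#' @param support_collapse_pct internal branches below this bootstrap
#'   percentage are collapsed before reconciliation.
#' @param max_backbone_dups families with more backbone duplications are
#'   excluded from duplication summaries.
#' @param mirna_expectation_cutoff maximum expectation score for a reported
#'   miRNA target site.
#' @param mirna_score_len number of miRNA 5' positions scored.
#' @param scoring alignment scoring scheme, see [scoring_scheme()].
#' @param rng_seed integer seed from which all stochastic stages derive
#'   their streams.
#'
#' @return a list of class `lincphylo_config`.
#' @export
lincphylo_config <- function(strict_evalue = 1e-20,
                             relaxed_evalue = 1e-5,
                             synteny_window_bp = 50000L,
                             flank_bp_when_no_gene = 5000L,
                             decay_link_bp = 10000L,
                             min_family_species = 4L,
                             orf_aa_threshold = 100L,
                             te_min_overlap_nt = 10L,
                             te_near_bp = c(100L, 500L),
                             bootstrap_reps = 100L,
                             support_collapse_pct = 70,
                             max_backbone_dups = 3L,
                             mirna_expectation_cutoff = 2.0,
                             mirna_score_len = 20L,
                             scoring = scoring_scheme(),
                             rng_seed = 1L) {
  stopifnot(strict_evalue < relaxed_evalue,
            synteny_window_bp > 0, flank_bp_when_no_gene > 0,
            decay_link_bp > 0, min_family_species >= 1,
            orf_aa_threshold > 0, te_min_overlap_nt > 0,
            all(te_near_bp > 0), bootstrap_reps >= 1,
            support_collapse_pct > 0, support_collapse_pct <= 100)
  structure(list(
    strict_evalue = strict_evalue, relaxed_evalue = relaxed_evalue,
    synteny_window_bp = as.integer(synteny_window_bp),
    flank_bp_when_no_gene = as.integer(flank_bp_when_no_gene),
    decay_link_bp = as.integer(decay_link_bp),
    min_family_species = as.integer(min_family_species),
    orf_aa_threshold = as.integer(orf_aa_threshold),
    te_min_overlap_nt = as.integer(te_min_overlap_nt),
    te_near_bp = sort(as.integer(te_near_bp)),
    bootstrap_reps = as.integer(bootstrap_reps),
    support_collapse_pct = support_collapse_pct,
    max_backbone_dups = as.integer(max_backbone_dups),
    mirna_expectation_cutoff = mirna_expectation_cutoff,
    mirna_score_len = as.integer(mirna_score_len),
    scoring = scoring,
    rng_seed = as.integer(rng_seed)
  ), class = "lincphylo_config")
}

# Derive a reproducible integer sub-seed for a named pipeline stage from the
# master seed, so each stochastic stage has its own stream.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% .Machine$integer.max)
}

with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  force(code)
}
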