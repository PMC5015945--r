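#' Classify loci by overlap with an annotation track
#'
#' A locus is `inside` when it overlaps an annotation interval by at least
#' `min_nt` nucleotides; otherwise it falls in the smallest `within_<d>bp`
#' class whose distance bound `d` it satisfies; otherwise `none`. For
#' conserved-noncoding-sequence overlap use `min_nt = 1`.
#'
#' @param loci interval tibble (`chrom`, `start`, `end`).
#' @param annot interval tibble of the annotation track.
#' @param min_nt minimum overlap for `inside`.
#' @param near_bp increasing distance bounds for the near classes.
#' @return character vector of classes, one per locus.
#' @export
interval_overlap_class <- function(loci, annot, min_nt = 10L,
                                   near_bp = c(100L, 500L)) {
  near_bp <- sort(as.integer(near_bp))
  if (!nrow(loci)) return(character(0))
  out <- rep("none", nrow(loci))
  if (!nrow(annot)) return(out)
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    ai <- which(annot$chrom == ch)
    if (!length(ai)) next
    lr <- IRanges::IRanges(start = loci$start[li] + 1L, end = loci$end[li])
    ar <- IRanges::IRanges(start = annot$start[ai] + 1L, end = annot$end[ai])
    # max overlap width per locus
    ov <- IRanges::findOverlaps(lr, ar)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(lr[S4Vectors::queryHits(ov)],
                                              ar[S4Vectors::subjectHits(ov)]))
      best <- tapply(w, S4Vectors::queryHits(ov), max)
      idx <- as.integer(names(best))
      out[li[idx]][best >= min_nt] <- "inside"
    }
    d <- IRanges::distance(lr, ar[IRanges::nearest(lr, ar)])
    for (k in seq_along(li)) {
      if (out[li[k]] == "inside") next
      dk <- d[k]
      if (is.na(dk)) next
      cls <- near_bp[which(dk <= near_bp)[1]]
      if (!is.na(cls) && dk > 0) out[li[k]] <- paste0("within_", cls, "bp")
      if (dk == 0) { # overlapping but under min_nt: still the nearest class
        out[li[k]] <- paste0("within_", near_bp[1], "bp")
      }
    }
  }
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by conditional enumeration (sum of hypergeometric
#' probabilities not exceeding the observed table's); the odds ratio is the
#' sample odds ratio `(a d) / (b c)` (`Inf` when `b c = 0` and `a d > 0`,
#' `NaN` for 0/0).
#'
#' @param table a 2x2 matrix or vector `c(a, b, c, d)` filled by row.
#' @return tibble with `p_value`, `odds_ratio`.
#' @export
fisher_exact <- function(table) {
  m <- if (is.matrix(table)) table else matrix(table, 2, 2, byrow = TRUE)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  p <- stats::fisher.test(m)$p.value
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  tibble::tibble(p_value = p, odds_ratio = or)
}

#' Proportions of a flag stratified by conservation depth
#'
#' Bins loci by the age of their conservation depth node, computes the
#' per-bin proportion of the flag, and tests each deeper bin against the
#' shallowest (species-specific) bin with Fisher's exact test.
#'
#' @param records tibble with a `depth_age` column and a logical/0-1 flag
#'   column.
#' @param flag name of the flag column.
#' @return tibble per depth bin: `depth_age`, `n`, `n_flag`, `prop_pct`,
#'   `p_value` (NA for the reference bin).
#' @export
depth_stratified_proportions <- function(records, flag) {
  f <- as.logical(records[[flag]])
  tab <- tibble::tibble(depth_age = records$depth_age, flag = f) %>%
    dplyr::group_by(.data$depth_age) %>%
    dplyr::summarise(n = dplyr::n(), n_flag = sum(.data$flag),
                     .groups = "drop") %>%
    dplyr::arrange(.data$depth_age) %>%
    dplyr::mutate(prop_pct = 100 * .data$n_flag / .data$n)
  ref <- tab[1, ]
  tab$p_value <- c(NA_real_, vapply(seq_len(nrow(tab) - 1) + 1, function(i) {
    fisher_exact(c(tab$n_flag[i], tab$n[i] - tab$n_flag[i],
                   ref$n_flag, ref$n - ref$n_flag))$p_value
  }, 0))
  tab
}

#' Correlation between expression and conservation depth
#'
#' Ordinary least squares of log10(mean FPKM + 0.01) on depth-node age, with
#' the Pearson correlation. Records without expression are excluded.
#'
#' @param records tibble with `depth_age` and `mean_fpkm` columns.
#' @return an object of class `linc_depth_fit` (supports [tidy()],
#'   [glance()] and [autoplot][ggplot2::autoplot]).
#' @export
expression_depth_correlation <- function(records) {
  d <- records %>%
    dplyr::filter(!is.na(.data$mean_fpkm)) %>%
    dplyr::mutate(log_fpkm = log10(.data$mean_fpkm + 0.01))
  fit <- stats::lm(log_fpkm ~ depth_age, data = d)
  ct <- stats::cor.test(d$depth_age, d$log_fpkm)
  structure(list(fit = fit, r = unname(ct$estimate),
                 slope = unname(stats::coef(fit)[2]),
                 p_value = summary(fit)$coefficients[2, 4],
                 n = nrow(d), data = d),
            class = "linc_depth_fit")
}

#' @export
print.linc_depth_fit <- function(x, ...) {
  cat("expression ~ conservation depth: r =", round(x$r, 3),
      " slope =", signif(x$slope, 3), "log10-FPKM/Myr, p =",
      signif(x$p_value, 3), " (n =", x$n, ")\n")
  invisible(x)
}

#' @rdname expression_depth_correlation
#' @param x a `linc_depth_fit`.
#' @param ... unused.
#' @export
tidy.linc_depth_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std_error = co[, 2], statistic = co[, 3],
                 p_value = co[, 4])
}

#' @rdname expression_depth_correlation
#' @export
glance.linc_depth_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = summary(x$fit)$r.squared,
                 slope = x$slope, p_value = x$p_value, n = x$n)
}

#' miRNA target expectation score
#'
#' Slides the reverse complement of the miRNA along the transcript and
#' scores each ungapped window over the first `score_len` miRNA positions:
#' perfect complement 0, G:U wobble 0.5, mismatch 1, penalties doubled in
#' the 5' seed (miRNA positions 2-13). Reports the minimum expectation and
#' its transcript position; a target requires expectation <= the cutoff.
#'
#' @param lincrna transcript sequence (DNA).
#' @param mirna mature miRNA sequence (RNA or DNA alphabet).
#' @param cutoff expectation cutoff for a hit.
#' @param score_len number of miRNA positions scored.
#' @return tibble with `expectation`, `position` (0-based transcript offset
#'   of the site), `hit`.
#' @export
mirna_expectation <- function(lincrna, mirna, cutoff = 2.0, score_len = 20L) {
  t_seq <- chartr("Uu", "Tt", toupper(lincrna))
  m_seq <- chartr("Uu", "Tt", toupper(mirna))
  L <- min(nchar(m_seq), score_len)
  n <- nchar(t_seq)
  if (n < L) return(tibble::tibble(expectation = Inf, position = NA_integer_,
                                   hit = FALSE))
  tv <- strsplit(t_seq, "")[[1]]
  # miRNA position i pairs with target position (site_end - i + 1); walking
  # the site 3'->5' on the target corresponds to miRNA 5'->3'.
  mv <- strsplit(m_seq, "")[[1]][seq_len(L)]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  weight <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  best <- Inf; best_pos <- NA_integer_
  for (s in seq_len(n - L + 1)) {
    site <- tv[(s + L - 1):s] # 3'->5' along target = miRNA 5'->3'
    sc <- 0
    for (i in seq_len(L)) {
      ti <- site[i]; mi <- mv[i]
      if (ti == comp[[mi]]) next
      wob <- (mi == "G" && ti == "T") || (mi == "T" && ti == "G")
      sc <- sc + weight[i] * (if (wob) 0.5 else 1)
      if (sc >= best) break
    }
    if (sc < best) { best <- sc; best_pos <- s - 1L }
  }
  tibble::tibble(expectation = best, position = best_pos,
                 hit = best <= cutoff)
}

#' Folding proxy: base-pair maximization per nucleotide
#'
#' Nussinov dynamic programming (minimum loop 3; AU, GC and GU pairs);
#' the maximal pair count is negated and divided by sequence length, giving
#' a minimum-free-energy-like score per nucleotide.
#'
#' @param seq RNA/DNA sequence.
#' @return negative pairs-per-nucleotide (0 for unfoldable sequences).
#' @export
mfe_proxy_per_nt <- function(seq) {
  n <- nchar(seq)
  if (n == 0) return(0)
  -cpp_nussinov(seq, 3L) / n
}

#' Gene proximity versus conservation
#'
#' Point-biserial correlation between the conserved flag and the distance
#' to the nearest gene, with a permutation p-value.
#'
#' @param records tibble with logical `conserved` and numeric
#'   `nearest_gene_bp`.
#' @param n_perm permutation count.
#' @param seed RNG stream seed.
#' @return tibble with `r`, `p_value`, `n`.
#' @export
gene_proximity_vs_conservation <- function(records, n_perm = 10000L,
                                           seed = 1L) {
  x <- as.numeric(records$conserved)
  y <- records$nearest_gene_bp
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(tibble::tibble(r = 0, p_value = 1, n = length(x)))
  r <- stats::cor(x, y)
  with_stage_seed(seed, "gene_proximity", {
    null_r <- vapply(seq_len(n_perm), function(i) stats::cor(sample(x), y), 0)
  })
  tibble::tibble(r = r,
                 p_value = (1 + sum(abs(null_r) >= abs(r))) / (1 + n_perm),
                 n = length(x))
}

#' Assemble the per-locus feature table
#'
#' Joins conservation depth with TE class, CNS overlap, nearest-gene
#' distance, expression, stress-responsiveness and the folding proxy.
#'
#' @param queries focal query tibble (`locus_id`, intervals, `seq`).
#' @param families family tibble from [build_families()].
#' @param te,cns focal-species interval tibbles (repeats / conserved
#'   noncoding sequences).
#' @param genes focal-species gene interval tibble.
#' @param expression tibble `locus_id` + four FPKM columns.
#' @param stress tibble with `locus_id` and `stress_responsive`.
#' @param config a [lincphylo_config()].
#' @param with_mfe compute the folding proxy (O(n^3) per locus).
#' @return a feature tibble, one row per query locus.
#' @export
build_feature_table <- function(queries, families, te, cns, genes,
                                expression = NULL, stress = NULL,
                                config = lincphylo_config(),
                                with_mfe = FALSE) {
  fam <- families %>% dplyr::select("query_id", "conserved", "depth_age")
  rec <- queries %>%
    dplyr::left_join(fam, by = c(locus_id = "query_id")) %>%
    dplyr::mutate(conserved = dplyr::coalesce(.data$conserved, FALSE),
                  depth_age = dplyr::coalesce(.data$depth_age, 0))
  rec$te_class <- interval_overlap_class(rec, te,
                                         min_nt = config$te_min_overlap_nt,
                                         near_bp = config$te_near_bp)
  rec$cns_overlap <- interval_overlap_class(rec, cns, min_nt = 1L,
                                            near_bp = config$te_near_bp) == "inside"
  rec$nearest_gene_bp <- nearest_distance(rec, genes)
  if (!is.null(expression)) {
    fp <- expression
    fcols <- setdiff(names(fp), "locus_id")
    fp$mean_fpkm <- rowMeans(as.matrix(fp[, fcols]))
    rec <- dplyr::left_join(rec, fp[, c("locus_id", "mean_fpkm")],
                            by = "locus_id")
  } else rec$mean_fpkm <- NA_real_
  if (!is.null(stress)) {
    rec <- dplyr::left_join(
      rec, dplyr::select(stress, "locus_id", "stress_responsive"),
      by = "locus_id")
  } else rec$stress_responsive <- NA_integer_
  if (with_mfe)
    rec$mfe_proxy_per_nt <- vapply(rec$seq, mfe_proxy_per_nt, 0,
                                   USE.NAMES = FALSE)
  rec
}

# distance to nearest annotation interval per locus (NA if none on chrom)
nearest_distance <- function(loci, annot) {
  out <- rep(NA_real_, nrow(loci))
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    ai <- which(annot$chrom == ch)
    if (!length(ai)) next
    lr <- IRanges::IRanges(start = loci$start[li] + 1L, end = loci$end[li])
    ar <- IRanges::IRanges(start = annot$start[ai] + 1L, end = annot$end[ai])
    out[li] <- IRanges::distance(lr, ar[IRanges::nearest(lr, ar)])
  }
  out
}
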