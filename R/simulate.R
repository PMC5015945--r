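#' Default chronogram used by the simulator
#'
#' An ultrametric 11-taxon species tree shaped like the crucifer phylogeny
#' the pipeline was designed around: a focal species `Ath` with a 13-Myr
#' sister (`Aly`), a lineage-I clade completed by a 9-Myr `Cgra`/`Crub` pair
#' (joining at 18 Myr) and `Lal` (30 Myr), a lineage-II clade (`Bra`, `Bol`,
#' `Spa`, `Esa`) splitting from lineage I at 42 Myr, a basal ingroup taxon
#' `Aar` at 54 Myr, and an outgroup `Tha` at 65 Myr. Nodes carrying a
#' whole-genome duplication are flagged: the `Bra`/`Bol` ancestor and the
#' `Lal` terminal branch (mesopolyploid lineages).
#'
#' @return a `species_tree` (see [read_species_tree()]) with a `wgd_nodes`
#'   element of species-tree node ids.
#' @export
default_species_tree <- function() {
  nwk <- paste0("(Tha:65,(Aar:54,((((Ath:13,Aly:13):5,(Cgra:9,Crub:9):9):12,",
                "Lal:30):12,((Bra:20,Bol:20):15,(Spa:25,Esa:25):10):7):12):11);")
  lm <- tibble::tibble(
    species = c("Ath", "Aly", "Cgra", "Crub", "Lal", "Bra", "Bol", "Spa",
                "Esa", "Aar", "Tha"),
    lineage = c("I", "I", "I", "I", "I", "II", "II", "II", "II",
                "outgroup", "outgroup"))
  tr <- read_species_tree(nwk, lm, focal = "Ath")
  tr$wgd_nodes <- c(st_mrca(tr, c("Bra", "Bol")), st_mrca(tr, "Lal"))
  tr
}

#' Simulation parameters
#'
#' Defines the generative model for planted lincRNA histories: loci are born
#' at backbone nodes of the chronogram, evolve by a Jukes-Cantor
#' single-nucleotide substitution process with branch-length-proportional
#' divergence plus short indels, and are subject to per-branch deletion
#' (loss), switching to a hyper-mutating decay mode, local duplication, and
#' whole-genome duplication at flagged nodes followed by fractionation.
#' Conserved noncoding sequence (CNS) islands inside a subset of loci evolve
#' at a strongly reduced rate; flanking protein-coding anchor genes are
#' always retained and collinear. Expression and stress covariates are drawn
#' from models whose linear predictors depend on birth-node age.
#'
#' @param tree a `species_tree`; default [default_species_tree()].
#' @param n_loci number of ancestral loci to plant.
#' @param locus_len ancestral locus length (nt).
#' @param birth_weights named numeric of birth probabilities, names are
#'   backbone node ages in Myr (`"0"` = focal-terminal birth).
#' @param subst_rate substitutions/site/Myr.
#' @param indel_rate indel events as a fraction of substitution events.
#' @param loss_prob per-branch per-copy deletion probability.
#' @param decay_prob per-branch probability of switching to decay mode.
#' @param decay_multiplier rate multiplier while in decay mode.
#' @param dup_prob per-branch local duplication probability.
#' @param post_wgd_loss per-copy retention failure probability right after a
#'   whole-genome duplication (fractionation).
#' @param max_copies cap on copies per locus per lineage.
#' @param te_library character vector of TE sequences (generated if `NULL`).
#' @param te_insert_prob probability a shallow-born focal locus receives a TE.
#' @param cns_prob_shallow,cns_prob_deep probability a locus born below /
#'   at-or-above the lineage-split age carries a CNS island.
#' @param cns_len CNS island length (nt).
#' @param cns_rate_multiplier substitution-rate multiplier inside the island.
#' @param flank_gene_len anchor gene length (nt).
#' @param flank_rate_multiplier substitution-rate multiplier for anchors.
#' @param spacer_range min/max intergenic spacer length (bp).
#' @param anchor_gap_range min/max anchor-to-locus distance (bp).
#' @param dup_offset_bp distance between tandem copies (bp); chosen larger
#'   than `locus_len` so tandem copies are not merged by the hit-merging rule.
#' @param loci_per_chrom loci per simulated chromosome.
#' @param synteny_break_prob per-(locus, species) probability the locus is
#'   translocated away from its anchors.
#' @param expr_mu0,expr_beta,expr_sigma log10-FPKM model: intercept, slope on
#'   birth age (per Myr), residual sd.
#' @param stress_alpha0,stress_alpha1 logit model for stress-responsiveness.
#' @param max_genome_len error guard on expected genome length (bp).
#' @param rng_seed master seed.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(tree = default_species_tree(),
                       n_loci = 200L,
                       locus_len = 400L,
                       birth_weights = c("0" = 0.30, "13" = 0.20, "18" = 0.12,
                                         "30" = 0.08, "42" = 0.12, "54" = 0.10,
                                         "65" = 0.08),
                       subst_rate = 0.002,
                       indel_rate = 0.1,
                       loss_prob = 0.02,
                       decay_prob = 0.02,
                       decay_multiplier = 8,
                       dup_prob = 0.05,
                       post_wgd_loss = 0.35,
                       max_copies = 4L,
                       te_library = NULL,
                       te_insert_prob = 0.15,
                       cns_prob_shallow = 0.25,
                       cns_prob_deep = 0.8,
                       cns_len = 36L,
                       cns_rate_multiplier = 0.05,
                       flank_gene_len = 900L,
                       flank_rate_multiplier = 0.2,
                       spacer_range = c(200L, 600L),
                       anchor_gap_range = c(300L, 800L),
                       dup_offset_bp = 1500L,
                       loci_per_chrom = 50L,
                       synteny_break_prob = 0,
                       expr_mu0 = -0.5,
                       expr_beta = 0.01,
                       expr_sigma = 0.4,
                       stress_alpha0 = -2.4,
                       stress_alpha1 = 0.035,
                       max_genome_len = 5e7,
                       rng_seed = 42L) {
  probs <- c(loss_prob, decay_prob, dup_prob, post_wgd_loss, te_insert_prob,
             cns_prob_shallow, cns_prob_deep, indel_rate, synteny_break_prob)
  stopifnot(all(probs >= 0), all(probs <= 1),
            subst_rate >= 0, decay_multiplier >= 0,
            cns_rate_multiplier >= 0, flank_rate_multiplier >= 0,
            cns_len < locus_len, n_loci >= 1,
            abs(sum(birth_weights) - 1) < 1e-8)
  rm(probs)
  structure(as.list(environment()), class = "sim_params")
}

#' Expected Jukes-Cantor divergence
#'
#' Forward formula for the expected proportion of differing sites after
#' evolving for a total path time `t` at rate `rate`:
#' `p = 3/4 (1 - exp(-4/3 rate t))`.
#'
#' @param branch_path_myr total path length in Myr.
#' @param rate substitutions/site/Myr.
#' @return expected p-distance.
#' @export
expected_divergence <- function(branch_path_myr, rate) {
  if (any(branch_path_myr < 0)) stop("negative time")
  0.75 * (1 - exp(-4 / 3 * rate * branch_path_myr))
}

BASE_INT <- c(65L, 67L, 71L, 84L) # A C G T

rand_dna_int <- function(n) sample(BASE_INT, n, replace = TRUE)
rand_dna <- function(n) intToUtf8(rand_dna_int(n))

# Evolve an integer-coded sequence for t Myr at the given per-site rates.
# cns is c(start, end) (0-based half-open, relative) or NULL; indels are
# kept out of the island so it stays a contiguous low-divergence block.
evolve_seq <- function(iv, cns, t, rate, cns_rate, indel_rate) {
  L <- length(iv)
  if (L == 0 || t <= 0) return(list(iv = iv, cns = cns))
  r <- rep(rate, L)
  if (!is.null(cns) && cns[2] > cns[1]) r[(cns[1] + 1):cns[2]] <- cns_rate
  p <- 0.75 * (1 - exp(-4 / 3 * r * t))
  hit <- which(stats::runif(L) < p)
  if (length(hit)) {
    cur <- match(iv[hit], BASE_INT)
    iv[hit] <- BASE_INT[((cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  n_ind <- stats::rpois(1, indel_rate * rate * t * L)
  for (dummy in seq_len(n_ind)) {
    L <- length(iv)
    len <- sample.int(5L, 1)
    if (stats::runif(1) < 0.5) { # deletion
      ok <- seq_len(max(L - len, 0))
      if (!is.null(cns)) ok <- ok[ok > cns[2] | (ok + len - 1) <= cns[1]]
      if (!length(ok)) next
      pos <- ok[sample.int(length(ok), 1)]
      iv <- iv[-(pos:(pos + len - 1))]
      if (!is.null(cns) && pos <= cns[1]) cns <- cns - len
    } else { # insertion after position pos (0..L)
      ok <- 0:L
      if (!is.null(cns)) ok <- ok[ok <= cns[1] | ok >= cns[2]]
      pos <- ok[sample.int(length(ok), 1)]
      iv <- append(iv, rand_dna_int(len), after = pos)
      if (!is.null(cns) && pos <= cns[1]) cns <- cns + len
    }
  }
  list(iv = iv, cns = cns)
}

# Tree bookkeeping for the simulator.
sim_tree_info <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  kids <- vector("list", n)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  list(ntip = ntip, kids = kids, age = tree$node_age,
       labels = tree$tip.label, focal_id = match(tree$focal, tree$tip.label),
       wgd = if (is.null(tree$wgd_nodes)) integer(0) else tree$wgd_nodes)
}

#' Simulate a multi-species lincRNA cohort with full ground truth
#'
#' Runs the generative model of [sim_params()] and assembles per-species
#' genomes in which every surviving locus copy sits between two collinear
#' anchor genes. Returns genomes, the focal query annotation, anchor-gene
#' annotations, covariates, and a complete truth table.
#'
#' @param params a `sim_params` list.
#' @return an object of class `linc_sim`; see Details.
#' @details The returned list has elements `genomes` (named list of named
#'   chromosome vectors), `queries` (focal locus tibble with sequences),
#'   `anchors` (anchor-gene intervals for every species, with sequences for
#'   the focal species), `truth` (per locus x species: state
#'   present/decayed/lost, primary-copy interval, copy count, CNS and TE
#'   placement), `dup_events` (planted duplications with species-tree node),
#'   `wgd_log` (copy counts before/after each WGD), `expression` and
#'   `stress` covariate tibbles, `cns` and `te` interval tibbles, plus the
#'   `tree` and `params` used.
#' @export
simulate_lincrna_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  info <- sim_tree_info(p$tree)
  with_stage_seed(p$rng_seed, "simulate", {
    exp_len <- length(info$labels) * p$n_loci *
      (p$locus_len + 2 * p$flank_gene_len + 2 * mean(p$spacer_range) +
         2 * mean(p$anchor_gap_range))
    if (exp_len > p$max_genome_len)
      stop("expected genome length ", round(exp_len), " exceeds cap")

    # birth nodes: map weight names (ages) to backbone node ids
    bb <- backbone_nodes(p$tree)
    node_of_age <- stats::setNames(bb, as.character(round(info$age[bb])))
    node_of_age <- c(node_of_age, stats::setNames(info$focal_id, "0"))
    w_ages <- names(p$birth_weights)
    if (!all(w_ages %in% names(node_of_age)))
      stop("birth_weights ages not matching backbone node ages: ",
           paste(setdiff(w_ages, names(node_of_age)), collapse = ", "))
    lineage_split_age <- mrca_age(p$tree, names(p$tree$lineage)[p$tree$lineage %in% c("I", "II")])

    if (is.null(p$te_library))
      p$te_library <- vapply(1:3, function(i) rand_dna(200L), "")

    locus_ids <- sprintf("L%04d", seq_len(p$n_loci))
    birth_nodes <- node_of_age[sample(w_ages, p$n_loci, replace = TRUE,
                                      prob = p$birth_weights)]
    birth_ages <- info$age[birth_nodes]

    # covariates from birth age
    mu <- p$expr_mu0 + p$expr_beta * birth_ages
    tissue_log <- matrix(stats::rnorm(4 * p$n_loci, mean = rep(mu, each = 4),
                                      sd = p$expr_sigma), ncol = 4, byrow = TRUE)
    expression <- tibble::tibble(locus_id = locus_ids,
                                 fpkm_flower = 10^tissue_log[, 1],
                                 fpkm_leaf = 10^tissue_log[, 2],
                                 fpkm_silique = 10^tissue_log[, 3],
                                 fpkm_root = 10^tissue_log[, 4])
    p_stress <- stats::plogis(p$stress_alpha0 + p$stress_alpha1 * birth_ages)
    stress_flag <- stats::runif(p$n_loci) < p_stress
    stress <- tibble::tibble(locus_id = locus_ids)
    smat <- matrix(0L, p$n_loci, 4)
    for (i in which(stress_flag)) {
      row <- stats::rbinom(4, 1, 0.5)
      if (!any(row == 1)) row[sample.int(4, 1)] <- 1L
      smat[i, ] <- row
    }
    stress$stress_aba <- smat[, 1]; stress$stress_cold <- smat[, 2]
    stress$stress_drought <- smat[, 3]; stress$stress_salt <- smat[, 4]
    stress$stress_responsive <- as.integer(stress_flag)

    # CNS carriage and TE class per locus
    deep <- birth_ages >= lineage_split_age
    has_cns <- stats::runif(p$n_loci) <
      ifelse(deep, p$cns_prob_deep, p$cns_prob_shallow)
    te_class <- rep("none", p$n_loci)
    shallow_idx <- which(!deep & stats::runif(p$n_loci) < p$te_insert_prob)
    te_class[shallow_idx] <- sample(c("inside", "within_100bp", "within_500bp"),
                                    length(shallow_idx), replace = TRUE)

    # evolve each locus along the tree
    leafsets <- st_leafsets(p$tree)
    tips <- vector("list", p$n_loci)      # per locus: list(species -> copies)
    dup_rows <- list(); wgd_rows <- list()
    for (li in seq_len(p$n_loci)) {
      anc <- rand_dna_int(p$locus_len)
      cns <- NULL
      if (has_cns[li]) {
        s0 <- sample.int(p$locus_len - p$cns_len - 20L, 1) + 10L
        cns <- c(s0, s0 + p$cns_len)
      }
      gA <- rand_dna_int(p$flank_gene_len)
      gB <- rand_dna_int(p$flank_gene_len)
      res <- new.env(parent = emptyenv())
      res$tips <- list(); res$dups <- list(); res$wgd <- list()

      descend <- function(node, copies) {
        # copies: list of list(id, iv, cns, decay)
        if (node <= info$ntip) {
          res$tips[[info$labels[node]]] <- copies
          return(invisible(NULL))
        }
        for (child in info$kids[[node]]) {
          bl <- info$age[node] - info$age[child]
          # per-branch loss and decay switching
          cur <- list()
          for (cp in copies) {
            if (stats::runif(1) < p$loss_prob) next
            if (!cp$decay && stats::runif(1) < p$decay_prob) cp$decay <- TRUE
            cur <- c(cur, list(cp))
          }
          # whole-genome duplication on the stem branch of a flagged node:
          # the event sits at the branch midpoint (strictly between the two
          # speciations, so copy divergence is dateable), then fractionation
          if (child %in% info$wgd) {
            half <- bl / 2
            evolved <- list()
            for (cp in cur) {
              mult <- if (cp$decay) p$decay_multiplier else 1
              ev <- evolve_seq(cp$iv, cp$cns, half, p$subst_rate * mult,
                               p$subst_rate * mult * p$cns_rate_multiplier,
                               p$indel_rate)
              cp$iv <- ev$iv; cp$cns <- ev$cns
              evolved <- c(evolved, list(cp))
            }
            before <- length(evolved)
            doubled <- list()
            for (cp in evolved) {
              dup <- cp
              dup$id <- paste0(cp$id, ".w", length(res$dups) + 1L)
              keep1 <- stats::runif(1) >= p$post_wgd_loss
              keep2 <- stats::runif(1) >= p$post_wgd_loss
              if (keep1 && keep2) {
                res$dups[[length(res$dups) + 1L]] <-
                  list(node = child, parent_copy = cp$id, new_copy = dup$id,
                       type = "wgd")
                doubled <- c(doubled, list(cp), list(dup))
              } else if (keep1 || keep2) {
                doubled <- c(doubled, list(cp))
              }
            }
            res$wgd[[length(res$wgd) + 1L]] <-
              list(node = child, before = before, after_dup = 2L * before,
                   retained = length(doubled))
            surv <- list()
            for (cp in doubled) {
              mult <- if (cp$decay) p$decay_multiplier else 1
              ev <- evolve_seq(cp$iv, cp$cns, bl - half, p$subst_rate * mult,
                               p$subst_rate * mult * p$cns_rate_multiplier,
                               p$indel_rate)
              cp$iv <- ev$iv; cp$cns <- ev$cns
              surv <- c(surv, list(cp))
            }
            if (length(surv)) descend(child, surv)
            next
          }
          # evolve along the branch; a local duplication forks at a uniform
          # point within the branch so copy divergence predates the child
          # node but postdates the parent
          surv <- list()
          for (cp in cur) {
            dup_here <- length(cur) < p$max_copies &&
              stats::runif(1) < p$dup_prob
            mult <- if (cp$decay) p$decay_multiplier else 1
            rate <- p$subst_rate * mult
            crate <- rate * p$cns_rate_multiplier
            if (dup_here) {
              t1 <- stats::runif(1) * bl
              ev <- evolve_seq(cp$iv, cp$cns, t1, rate, crate, p$indel_rate)
              cp$iv <- ev$iv; cp$cns <- ev$cns
              dup <- cp
              dup$id <- paste0(cp$id, ".d", length(res$dups) + 1L)
              res$dups[[length(res$dups) + 1L]] <-
                list(node = child, parent_copy = cp$id, new_copy = dup$id,
                     type = "local")
              for (z in list(cp, dup)) {
                ev <- evolve_seq(z$iv, z$cns, bl - t1, rate, crate,
                                 p$indel_rate)
                z$iv <- ev$iv; z$cns <- ev$cns
                surv <- c(surv, list(z))
              }
            } else {
              ev <- evolve_seq(cp$iv, cp$cns, bl, rate, crate, p$indel_rate)
              cp$iv <- ev$iv; cp$cns <- ev$cns
              surv <- c(surv, list(cp))
            }
          }
          if (length(surv)) descend(child, surv)
        }
        invisible(NULL)
      }

      root_copy <- list(id = locus_ids[li], iv = anc, cns = cns, decay = FALSE)
      if (birth_nodes[li] <= info$ntip) {
        res$tips[[info$labels[birth_nodes[li]]]] <- list(root_copy)
      } else {
        descend(birth_nodes[li], list(root_copy))
      }
      tips[[li]] <- as.list(res$tips)
      if (length(res$dups))
        dup_rows[[length(dup_rows) + 1L]] <- tibble::tibble(
          locus_id = locus_ids[li],
          node = vapply(res$dups, function(d) d$node, 1L),
          type = vapply(res$dups, function(d) d$type, ""),
          parent_copy = vapply(res$dups, function(d) d$parent_copy, ""),
          new_copy = vapply(res$dups, function(d) d$new_copy, ""))
      if (length(res$wgd))
        wgd_rows[[length(wgd_rows) + 1L]] <- tibble::tibble(
          locus_id = locus_ids[li],
          node = vapply(res$wgd, function(d) d$node, 1L),
          copies_before = vapply(res$wgd, function(d) d$before, 1L),
          copies_after_dup = vapply(res$wgd, function(d) d$after_dup, 1L),
          copies_retained = vapply(res$wgd, function(d) d$retained, 1L))

      tips[[li]]$...anchors <- list(gA = gA, gB = gB)
    }

    # assemble genomes
    genomes <- list(); truth_rows <- list(); anchor_rows <- list()
    cns_rows <- list(); te_rows <- list(); query_rows <- list()
    for (sp_id in seq_len(info$ntip)) {
      sp <- info$labels[sp_id]
      chrom_seqs <- list(); chrom_names <- character(0)
      chunks <- list(); pos <- 0L; cur_chrom <- ""
      flush <- function() {
        if (length(chunks)) {
          chrom_seqs[[cur_chrom]] <<- paste(unlist(chunks), collapse = "")
          chrom_names <<- c(chrom_names, cur_chrom)
        }
        chunks <<- list(); pos <<- 0L
      }
      add <- function(s) { chunks[[length(chunks) + 1L]] <<- s; pos <<- pos + nchar(s) }
      for (li in seq_len(p$n_loci)) {
        chrom_i <- (li - 1L) %/% p$loci_per_chrom + 1L
        nm <- paste0("chr", chrom_i)
        if (nm != cur_chrom) { flush(); cur_chrom <- nm }
        copies <- tips[[li]][[sp]]
        anc_pair <- tips[[li]]$...anchors
        # anchors evolve by total path from the locus birth node (or root
        # for the anchors, which predate all loci): use species root path,
        # i.e. tree height, scaled by flank multiplier; deterministic per
        # species x locus via local evolution here.
        ha <- evolve_seq(anc_pair$gA, NULL, max(info$age),
                         p$subst_rate * p$flank_rate_multiplier,
                         p$subst_rate, 0)$iv
        hb <- evolve_seq(anc_pair$gB, NULL, max(info$age),
                         p$subst_rate * p$flank_rate_multiplier,
                         p$subst_rate, 0)$iv
        add(rand_dna(sample(p$spacer_range[1]:p$spacer_range[2], 1)))
        gA_start <- pos
        add(intToUtf8(ha))
        gA_end <- pos
        gapA <- sample(p$anchor_gap_range[1]:p$anchor_gap_range[2], 1)
        gapB <- sample(p$anchor_gap_range[1]:p$anchor_gap_range[2], 1)
        primary <- NULL; extra <- list()
        if (!is.null(copies) && length(copies)) {
          primary <- copies[[1]]
          if (length(copies) > 1) extra <- copies[-1]
        }
        te_here <- if (sp_id == info$focal_id) te_class[li] else "none"
        # left gap, with possible near-TE upstream of locus
        loc_start <- NA_integer_; loc_end <- NA_integer_
        cns_abs <- NULL
        if (!is.null(primary)) {
          if (te_here %in% c("within_100bp", "within_500bp")) {
            d <- if (te_here == "within_100bp") sample(10:100, 1) else sample(101:500, 1)
            te_seq <- p$te_library[[sample.int(length(p$te_library), 1)]]
            add(rand_dna(max(gapA - d - nchar(te_seq), 10L)))
            te_start <- pos
            add(te_seq)
            te_rows[[length(te_rows) + 1L]] <- tibble::tibble(
              species = sp, chrom = nm, start = te_start, end = pos,
              strand = "+", name = paste0(locus_ids[li], "_te"))
            add(rand_dna(d))
          } else {
            add(rand_dna(gapA))
          }
          loc_start <- pos
          seq_iv <- primary$iv
          cns_rel <- primary$cns
          if (te_here == "inside" && length(seq_iv) >= 60) {
            te_seq <- p$te_library[[sample.int(length(p$te_library), 1)]]
            okpos <- setdiff(10:(length(seq_iv) - 10L),
                             if (!is.null(cns_rel)) (cns_rel[1] - 5L):(cns_rel[2] + 5L) else integer(0))
            ipos <- okpos[sample.int(length(okpos), 1)]
            seq_iv <- append(seq_iv, utf8ToInt(te_seq), after = ipos)
            if (!is.null(cns_rel) && ipos <= cns_rel[1])
              cns_rel <- cns_rel + nchar(te_seq)
            te_rows[[length(te_rows) + 1L]] <- tibble::tibble(
              species = sp, chrom = nm, start = loc_start + ipos,
              end = loc_start + ipos + nchar(te_seq), strand = "+",
              name = paste0(locus_ids[li], "_te"))
          }
          add(intToUtf8(seq_iv))
          loc_end <- pos
          if (!is.null(cns_rel)) {
            cns_abs <- c(loc_start + cns_rel[1], loc_start + cns_rel[2])
            cns_rows[[length(cns_rows) + 1L]] <- tibble::tibble(
              species = sp, chrom = nm, start = cns_abs[1], end = cns_abs[2],
              strand = "+", name = paste0(locus_ids[li], "_cns"))
          }
          for (xc in extra) {
            add(rand_dna(p$dup_offset_bp))
            xs <- pos
            add(intToUtf8(xc$iv))
            truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
              locus_id = locus_ids[li], species = sp, copy_id = xc$id,
              primary = FALSE,
              state = ifelse(xc$decay, "decayed", "present"),
              chrom = nm, start = xs, end = pos, strand = "+")
          }
          add(rand_dna(gapB))
        } else {
          add(rand_dna(gapA + gapB))
        }
        gB_start <- pos
        add(intToUtf8(hb))
        gB_end <- pos
        add(rand_dna(sample(p$spacer_range[1]:p$spacer_range[2], 1)))
        anchor_rows[[length(anchor_rows) + 1L]] <- tibble::tibble(
          locus_id = locus_ids[li], species = sp,
          side = c("up", "down"), chrom = nm,
          start = c(gA_start, gB_start), end = c(gA_end, gB_end),
          strand = "+",
          name = paste0(locus_ids[li], c("_gA", "_gB")))
        # "absent" = species not descended from the birth node
        st <- if (is.null(copies) || !length(copies)) {
          if (sp %in% leafsets[[birth_nodes[li]]]) "lost" else "absent"
        } else if (any(!vapply(copies, function(z) z$decay, TRUE))) "present"
        else "decayed"
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          locus_id = locus_ids[li], species = sp,
          copy_id = if (!is.null(primary)) primary$id else NA_character_,
          primary = TRUE, state = st, chrom = if (!is.null(primary)) nm else NA_character_,
          start = loc_start, end = loc_end,
          strand = if (!is.null(primary)) "+" else NA_character_)
        if (sp_id == info$focal_id && !is.null(primary)) {
          query_rows[[length(query_rows) + 1L]] <- tibble::tibble(
            locus_id = locus_ids[li], chrom = nm, start = loc_start,
            end = loc_end, strand = "+",
            birth_node = unname(birth_nodes[li]), birth_age = birth_ages[li],
            has_cns = has_cns[li], te_class = te_here,
            focal_state = st)
        }
      }
      flush()
      genomes[[sp]] <- unlist(chrom_seqs)
    }

    truth <- dplyr::bind_rows(truth_rows) %>%
      dplyr::left_join(tibble::tibble(locus_id = locus_ids,
                                      birth_node = unname(birth_nodes),
                                      birth_age = birth_ages,
                                      has_cns = has_cns,
                                      te_class = te_class),
                       by = "locus_id")
    queries <- if (length(query_rows)) dplyr::bind_rows(query_rows) else
      tibble::tibble(locus_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     birth_node = integer(), birth_age = double(),
                     has_cns = logical(), te_class = character(),
                     focal_state = character())
    queries$seq <- if (nrow(queries))
      get_sequence(genomes[[p$tree$focal]],
                   queries[, c("chrom", "start", "end", "strand")])
    else character(0)
    anchors <- dplyr::bind_rows(anchor_rows)
    anchors_focal <- dplyr::filter(anchors, .data$species == p$tree$focal)
    anchors_focal$seq <- get_sequence(genomes[[p$tree$focal]],
                                      anchors_focal[, c("chrom", "start", "end", "strand")])
    out <- list(genomes = genomes, queries = queries, anchors = anchors,
                anchors_focal = anchors_focal, truth = truth,
                dup_events = if (length(dup_rows)) dplyr::bind_rows(dup_rows) else
                  tibble::tibble(locus_id = character(), node = integer(),
                                 type = character(), parent_copy = character(),
                                 new_copy = character()),
                wgd_log = if (length(wgd_rows)) dplyr::bind_rows(wgd_rows) else
                  tibble::tibble(locus_id = character(), node = integer(),
                                 copies_before = integer(),
                                 copies_after_dup = integer(),
                                 copies_retained = integer()),
                expression = expression, stress = stress,
                cns = if (length(cns_rows)) dplyr::bind_rows(cns_rows) else
                  tibble::tibble(species = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character(), name = character()),
                te = if (length(te_rows)) dplyr::bind_rows(te_rows) else
                  tibble::tibble(species = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character(), name = character()),
                tree = p$tree, params = p)
    class(out) <- "linc_sim"
    out
  })
}

#' @export
print.linc_sim <- function(x, ...) {
  cat("linc_sim:", nrow(x$queries), "focal queries /", x$params$n_loci,
      "planted loci across", length(x$genomes), "genomes\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits per-species FASTA genomes, anchor-gene GFF3, BED files for lincRNA
#' loci, repeats and CNS, covariate TSVs, the truth table, and a JSON
#' sidecar of the simulation parameters.
#'
#' @param sim a `linc_sim`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes)) {
    write_genome(sim$genomes[[sp]], file.path(dir, paste0(sp, ".fa")))
    write_gff_genes(dplyr::filter(sim$anchors, .data$species == sp),
                    file.path(dir, paste0(sp, ".genes.gff3")))
  }
  write_bed(sim$queries, file.path(dir, "lincrna.bed"))
  write_bed(sim$te, file.path(dir, "repeats.bed"))
  write_bed(sim$cns, file.path(dir, "cns.bed"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$stress, file.path(dir, "stress.tsv"))
  pj <- sim$params
  pj$tree <- ape::write.tree(sim$tree)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(pj[!vapply(pj, is.function, TRUE)],
                         file.path(dir, "params.json"),
                         auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}
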