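#' Genomic intervals
#'
#' All coordinates inside the package are 0-based half-open (BED convention);
#' conversion to the 1-based inclusive GFF3 convention happens only at
#' serialization. An interval tibble has columns `chrom`, `start`, `end`,
#' `strand` (one of `+`, `-`, `.`) and optionally `species` and `name`.
#'
#' @param chrom,start,end,strand,species,name interval fields, recycled to a
#'   common length.
#' @return a tibble with one row per interval.
#' @export
genome_interval <- function(chrom, start, end, strand = ".", species = NA_character_,
                            name = NA_character_) {
  x <- tibble::tibble(species = species, chrom = chrom,
                      start = as.integer(start), end = as.integer(end),
                      strand = strand, name = name)
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(all(x$start >= 0), all(x$start < x$end),
            all(x$strand %in% c("+", "-", ".")))
  invisible(x)
}

#' Read a genome FASTA into an indexed in-memory genome
#'
#' @param path path to a FASTA file of chromosome sequences.
#' @return a named character vector, one uppercased sequence per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate chromosome names in ", path)
  g <- toupper(as.character(ss))
  names(g) <- nm
  g
}

#' Write a genome to FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract sequences for intervals from a genome
#'
#' Returns the uppercased subsequence for each interval; minus-strand
#' intervals are reverse-complemented.
#'
#' @param genome named character vector of chromosomes.
#' @param intervals interval tibble (see [genome_interval()]).
#' @return character vector of sequences.
#' @export
get_sequence <- function(genome, intervals) {
  validate_intervals(intervals)
  miss <- setdiff(unique(intervals$chrom), names(genome))
  if (length(miss)) stop("unknown chromosome(s): ", paste(miss, collapse = ", "))
  lens <- nchar(genome)[intervals$chrom]
  if (any(intervals$end > lens)) stop("interval end beyond chromosome length")
  out <- substr(genome[intervals$chrom], intervals$start + 1L, intervals$end)
  rc <- intervals$strand == "-"
  if (any(rc)) out[rc] <- revcomp(out[rc])
  unname(toupper(out))
}

#' Reverse-complement DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a dated species tree with lineage labels
#'
#' The newick string must carry branch lengths in Myr and be ultrametric;
#' node ages are computed as root height minus root-to-node path length.
#' The lineage map assigns each leaf to lineage `I`, `II` or `outgroup`, and
#' names the focal species whose annotated loci seed every query.
#'
#' @param newick a newick string or path to a newick file.
#' @param lineage_map a tibble/data.frame with columns `species`, `lineage`
#'   (`I`, `II` or `outgroup`), or a path to such a TSV.
#' @param focal the focal species (a leaf label).
#' @param tol ultrametricity tolerance (Myr).
#' @return an object of class `species_tree`: an ape `phylo` with elements
#'   `node_age` (ages for nodes `1..(n + Nnode)`), `lineage` (named by leaf),
#'   and `focal`.
#' @export
read_species_tree <- function(newick, lineage_map, focal, tol = 1e-6) {
  tr <- if (file.exists(newick[1]) && !grepl("\\(", newick[1])) ape::read.tree(newick)
        else ape::read.tree(text = newick)
  if (is.null(tr)) stop("could not parse newick")
  if (is.character(lineage_map) && length(lineage_map) == 1)
    lineage_map <- readr::read_tsv(lineage_map, show_col_types = FALSE)
  ntip <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  height <- max(depth[seq_len(ntip)])
  if (max(abs(depth[seq_len(ntip)] - height)) > tol)
    stop("species tree is not ultrametric within tolerance")
  age <- height - depth
  age[seq_len(ntip)] <- 0
  lin <- stats::setNames(as.character(lineage_map$lineage), lineage_map$species)
  if (!all(tr$tip.label %in% names(lin)))
    stop("lineage map missing species: ",
         paste(setdiff(tr$tip.label, names(lin)), collapse = ", "))
  if (!focal %in% tr$tip.label) stop("focal species not a leaf: ", focal)
  tr$node_age <- age
  tr$lineage <- lin[tr$tip.label]
  tr$focal <- focal
  class(tr) <- c("species_tree", class(tr))
  tr
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", length(x$tip.label), "leaves, root age",
      round(max(x$node_age), 2), "Myr, focal", x$focal, "\n")
  invisible(x)
}

# MRCA node of a set of leaves; returns the species-tree node id.
st_mrca <- function(tree, species) {
  species <- unique(species)
  if (length(species) == 1) return(match(species, tree$tip.label))
  ape::getMRCA(tree, species)
}

#' Age (Myr) of the most recent common ancestor of a set of species
#' @param tree a `species_tree`.
#' @param species character vector of leaf labels.
#' @return age in Myr (0 for a single species).
#' @export
mrca_age <- function(tree, species) {
  tree$node_age[st_mrca(tree, species)]
}

# Node ids on the path from the root to the focal leaf (the "backbone"),
# root first, excluding the focal leaf itself.
backbone_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  node <- match(tree$focal, tree$tip.label)
  path <- integer(0)
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parent) == 0) break
    path <- c(parent, path)
    node <- parent
  }
  path
}

# parent lookup: parent[node] = parent id (NA for root)
st_parents <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- rep(NA_integer_, n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# leaves under each node (list indexed by node id)
st_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    out[[a]] <- c(out[[a]], out[[b]])
  }
  out
}

#' Convert internal intervals to BED / GFF3 coordinate tables
#'
#' Internal coordinates are 0-based half-open. `as_bed` is the identity on
#' coordinates; `as_gff` shifts starts to 1-based inclusive.
#' @param x interval tibble.
#' @return tibble with serialization coordinates.
#' @export
as_bed_coords <- function(x) {
  validate_intervals(x)
  dplyr::select(x, dplyr::any_of(c("chrom", "start", "end", "name", "score", "strand")))
}

#' @rdname as_bed_coords
#' @export
as_gff_coords <- function(x) {
  validate_intervals(x)
  dplyr::mutate(x, start = .data$start + 1L)
}

#' @rdname as_bed_coords
#' @param g a tibble in GFF3 coordinates (1-based inclusive `start`).
#' @export
from_gff_coords <- function(g) {
  dplyr::mutate(g, start = as.integer(.data$start) - 1L,
                end = as.integer(.data$end))
}

#' Write pipeline report tables to TSV
#'
#' Writes each table with a deterministic column order; an empty table yields
#' a header-only file. `read_report` round-trips what `write_report` wrote.
#'
#' @param tables named list of tibbles (e.g. `families`, `duplications`,
#'   `loss_decay`, `features`).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(tables, function(tb, nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tb, p)
    p
  })
  invisible(paths)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  out <- purrr::map(paths, readr::read_tsv, show_col_types = FALSE,
                    progress = FALSE)
  names(out) <- sub("\\.tsv$", "", basename(paths))
  out
}

#' Write / read interval tables as BED6
#' @param x interval tibble with optional `name`, `score` columns.
#' @param path file path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  b <- tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                      name = if ("name" %in% names(x)) x$name else ".",
                      score = if ("score" %in% names(x)) x$score else 0,
                      strand = x$strand)
  readr::write_tsv(b, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                           "score", "strand"),
                       show_col_types = FALSE, progress = FALSE)
  tibble::as_tibble(b) %>%
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Write / read gene annotations as GFF3
#'
#' Emits `gene` features (with nested `mRNA`/`CDS` spanning the gene) in
#' 1-based inclusive coordinates; `read_gff_genes` returns the gene records
#' in internal 0-based half-open coordinates.
#' @param genes interval tibble with a `name` column of gene ids.
#' @param path file path.
#' @export
write_gff_genes <- function(genes, path) {
  validate_intervals(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    g <- as_gff_coords(genes)
    lines <- character(0)
    for (i in seq_len(nrow(g))) {
      id <- g$name[i]
      f <- function(type, attr) paste(g$chrom[i], "lincphylo", type, g$start[i],
                                      g$end[i], ".", g$strand[i], ".", attr,
                                      sep = "\t")
      lines <- c(lines,
                 f("gene", paste0("ID=", id)),
                 f("mRNA", paste0("ID=", id, ".1;Parent=", id)),
                 f("CDS", paste0("ID=", id, ".1.cds;Parent=", id, ".1")))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_gff_genes
#' @export
read_gff_genes <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln))
    return(tibble::tibble(species = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), name = character()))
  parts <- strsplit(ln, "\t", fixed = TRUE)
  g <- tibble::tibble(
    chrom = purrr::map_chr(parts, 1),
    type = purrr::map_chr(parts, 3),
    start = as.integer(purrr::map_chr(parts, 4)),
    end = as.integer(purrr::map_chr(parts, 5)),
    strand = purrr::map_chr(parts, 7),
    attr = purrr::map_chr(parts, 9)
  ) %>%
    dplyr::filter(.data$type == "gene") %>%
    dplyr::mutate(name = sub("^ID=([^;]+).*$", "\\1", .data$attr)) %>%
    dplyr::select("chrom", "start", "end", "strand", "name")
  from_gff_coords(g)
}
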