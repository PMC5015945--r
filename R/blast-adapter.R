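#' Read blastn tabular (format 6) output
#'
#' Parses the default 12-column tabular layout (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) into
#' the package's hit table: subject coordinates become 0-based half-open
#' with an explicit strand (a subject start greater than the end denotes a
#' minus-strand hit), and the bit score is kept as the hit score.
#'
#' @param path path to a tabular output file, or a character vector of
#'   tabular lines.
#' @return a hit tibble compatible with [merge_hits()]/[top_hit()].
#' @export
read_blast_tab6 <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits())
  f <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(f) >= 12))
  get <- function(i) vapply(f, `[[`, "", i)
  sstart <- as.integer(get(9)); send <- as.integer(get(10))
  minus <- sstart > send
  tibble::tibble(
    query_id = get(1),
    chrom = get(2),
    strand = ifelse(minus, "-", "+"),
    start = pmin(sstart, send) - 1L,
    end = pmax(sstart, send),
    qstart = as.integer(get(7)) - 1L,
    qend = as.integer(get(8)),
    score = as.numeric(get(12)),
    evalue = as.numeric(get(11))) %>%
    dplyr::arrange(.data$evalue, dplyr::desc(.data$score), .data$chrom,
                   .data$start)
}

#' Search a genome with an external blastn binary
#'
#' Optional adapter around a system `blastn` (task `blastn`, reward 1,
#' penalty -2, gap open 5, gap extend 2, word size 8), returning the same
#' hit table as [search_genome()]. The internal engine remains the default
#' throughout the pipeline; this adapter exists for cross-checking against
#' a reference aligner.
#'
#' @inheritParams search_genome
#' @return a hit tibble.
#' @export
search_genome_blastn <- function(queries, genome, scheme = scoring_scheme(),
                                 e_cutoff = 1e-20) {
  if (Sys.which("blastn") == "")
    stop("no blastn binary on the PATH")
  q <- as_query_vector(queries)
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  of <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(qf, sf, of)))
  write_genome(q, qf)
  write_genome(genome, sf)
  status <- system2("blastn",
                    c("-task", "blastn", "-query", qf, "-subject", sf,
                      "-reward", scheme$match,
                      "-penalty", -scheme$mismatch,
                      "-gapopen", scheme$gap_open,
                      "-gapextend", scheme$gap_extend,
                      "-word_size", scheme$word_size,
                      "-evalue", format(e_cutoff, scientific = TRUE),
                      "-outfmt", "6", "-out", of),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("blastn exited with status ", status)
  dplyr::filter(read_blast_tab6(of), .data$evalue <= e_cutoff)
}
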