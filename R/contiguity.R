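#' NG(x): contig length at x% of an external genome-size estimate
#'
#' Contigs are sorted in descending order and the length of the first
#' contig at which the cumulative sum reaches `x`% of `genome_size` is
#' returned (ties at the threshold resolved by `>=`). Unlike [nxx()], the
#' threshold is taken against an external genome-size estimate, so the
#' value is `NA` when the assembly total falls short of it.
#'
#' @param contig_lengths numeric multiset of contig lengths (bp).
#' @param genome_size external genome-size estimate (bp).
#' @param x percentage in (0, 100].
#' @return Length in bp, or `NA` when total contig length < `x`% of
#'   `genome_size` (including an empty contig list).
#' @examples
#' ngx(c(500, 400, 300), 1000, 50)  # 500
#' ngx(c(500, 400, 300), 1000, 90)  # 400
#' @export
ngx <- function(contig_lengths, genome_size, x) {
  assert_scalar_number(genome_size, "genome_size", min = 1)
  assert_scalar_number(x, "x", min = .Machine$double.eps, max = 100)
  s <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  thresh <- x / 100 * genome_size
  if (length(s) == 0L || sum(s) < thresh) return(NA_real_)
  s[which(cumsum(s) >= thresh)[1L]]
}

#' Assembled percentage of the genome
#'
#' @param total_contig_bp total contig length (bp).
#' @param genome_size genome-size estimate (bp).
#' @return `100 * total / genome_size`, rounded to one decimal as
#'   conventionally reported.
#' @examples
#' assembled_pct(1.60e9, 2.2724e9)  # 70.4
#' @export
assembled_pct <- function(total_contig_bp, genome_size) {
  assert_scalar_number(total_contig_bp, "total_contig_bp", min = 1)
  assert_scalar_number(genome_size, "genome_size", min = 1)
  round(100 * total_contig_bp / genome_size, 1)
}

#' Fold coverage of a base total over a genome size
#'
#' @param total_bases total sequenced/corrected bases (bp).
#' @param genome_size genome-size estimate (bp).
#' @return `total / genome_size` rounded to the nearest integer fold.
#' @examples
#' coverage_fold(25.11e9, 2.2724e9)  # 11
#' @export
coverage_fold <- function(total_bases, genome_size) {
  assert_scalar_number(total_bases, "total_bases", min = 1)
  assert_scalar_number(genome_size, "genome_size", min = 1)
  round(total_bases / genome_size)
}

#' Gap percentage of an assembly
#'
#' Percentage of N bases over the scaffolds as given (gap content of a
#' scaffolded assembly), not over re-split contigs.
#'
#' @param asm an [assembly()].
#' @return `100 * N bases / total scaffold bp`.
#' @export
gap_pct <- function(asm) {
  stopifnot(inherits(asm, "Assembly"))
  n_bases <- sum(Biostrings::letterFrequency(asm$seq, "N")[, 1L])
  100 * n_bases / sum(Biostrings::width(asm$seq))
}

#' Effective assembly size by unique k-mers
#'
#' The number of distinct k-mers occurring exactly once across the whole
#' assembly, a proxy for the uniquely mappable sequence length. Windows
#' containing N (or any non-ACGT letter) are excluded. By default k-mers
#' are counted in the given orientation only, as a k-mer counter with
#' default parameters would; `canonical = TRUE` collapses each k-mer with
#' its reverse complement.
#'
#' @param asm an [assembly()] (or `DNAStringSet`/character vector).
#' @param k k-mer length (default 150).
#' @param canonical collapse reverse complements? (default `FALSE`)
#' @return Integer count of unique k-mers (0 when `k` exceeds every
#'   scaffold).
#' @export
effective_size <- function(asm, k = 150, canonical = FALSE) {
  seqs <- if (inherits(asm, "Assembly")) asm$seq else asm
  if (!is.character(seqs)) seqs <- as.character(seqs)
  assert_scalar_number(k, "k", min = 1)
  count_unique_kmers_cpp(toupper(seqs), as.integer(k), isTRUE(canonical))
}

#' Full contiguity report for an assembly
#'
#' Computes the assembly-level statistics used to compare titration
#' conditions: contig count and N50 (after splitting scaffolds at N-gap
#' runs), an NG(x) curve against the genome-size estimate, assembled and
#' gap percentages, and the effective assembly size by unique k-mers.
#'
#' @param asm an [assembly()].
#' @param genome_size external genome-size estimate (defaults to the
#'   assembly's own).
#' @param k k-mer length for [effective_size()].
#' @param ngx_x percentages for the NG(x) curve.
#' @param min_gap_run N-run threshold for contig splitting.
#' @param canonical passed to [effective_size()].
#' @return An object of class `ContiguityReport` (a list of the named
#'   statistics; `ngx_curve` is a named numeric vector, `NA` where the
#'   assembly total falls short).
#' @export
contiguity_report <- function(asm, genome_size = NULL, k = 150,
                              ngx_x = c(25, 50, 75, 90), min_gap_run = 10,
                              canonical = FALSE) {
  stopifnot(inherits(asm, "Assembly"))
  genome_size <- genome_size %||% asm$genome_size_estimate
  ctg <- split_into_contigs(asm, min_gap_run = min_gap_run)$contig_lengths
  total <- sum(ctg)
  structure(list(
    contig_count = length(ctg),
    total_bp = total,
    longest_bp = if (length(ctg)) max(ctg) else 0,
    n50 = if (length(ctg)) nxx(ctg, 50) else NA_real_,
    ngx_curve = stats::setNames(
      vapply(ngx_x, function(x) ngx(ctg, genome_size, x), 0), ngx_x),
    assembled_pct = assembled_pct(total, genome_size),
    gap_pct = gap_pct(asm),
    effective_size_bp = effective_size(asm, k = k, canonical = canonical),
    genome_size = genome_size, k = k
  ), class = "ContiguityReport")
}

#' @export
print.ContiguityReport <- function(x, ...) {
  cat(sprintf(paste0(
    "ContiguityReport: %d contigs, %.0f bp (%.1f%% of %.0f bp), ",
    "N50 %.0f, gaps %.2f%%, effective size %.0f (k=%d)\n"),
    x$contig_count, x$total_bp, x$assembled_pct, x$genome_size,
    x$n50, x$gap_pct, x$effective_size_bp, x$k))
  ng <- paste(sprintf("NG%s=%s", names(x$ngx_curve),
                      ifelse(is.na(x$ngx_curve), "NA",
                             format(x$ngx_curve, big.mark = ","))),
              collapse = "  ")
  cat(" ", ng, "\n")
  invisible(x)
}
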