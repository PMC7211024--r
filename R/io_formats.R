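#' Construct a ReadSet
#'
#' A `ReadSet` holds identified long reads, either with their sequences (a
#' [Biostrings::DNAStringSet]) or in length-only mode. Reads produced by
#' clipping carry provenance: the id of the original read and the 0-based
#' offset of the clip within it.
#'
#' @param ids character vector of unique read ids.
#' @param lengths integer vector of read lengths in bp (all >= 1).
#' @param sequences optional `DNAStringSet` (or character vector) whose
#'   widths must equal `lengths`; omit for length-only sets.
#' @param source_id,source_offset optional provenance vectors; both must be
#'   given together. `source_offset` is 0-based.
#' @return An object of class `ReadSet` with elements `reads` (a data.frame
#'   with columns `id`, `length`, `source_id`, `source_offset`), `seq`
#'   (`DNAStringSet` or `NULL`) and `total_bases`.
#' @export
read_set <- function(ids, lengths, sequences = NULL,
                     source_id = NULL, source_offset = NULL) {
  ids <- as.character(ids)
  lengths <- as.numeric(lengths)
  if (anyDuplicated(ids)) stop("read ids must be unique")
  if (length(ids) != length(lengths)) stop("ids and lengths differ in length")
  if (length(lengths) && any(lengths < 1)) stop("read lengths must be >= 1")
  if (xor(is.null(source_id), is.null(source_offset)))
    stop("source_offset must be present iff source_id is present")
  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet"))
      sequences <- Biostrings::DNAStringSet(sequences)
    if (length(sequences) != length(ids))
      stop("sequences and ids differ in length")
    if (length(ids) && any(Biostrings::width(sequences) != lengths))
      stop("sequence widths must equal declared lengths")
    names(sequences) <- ids
  }
  reads <- data.frame(
    id = ids,
    length = lengths,
    source_id = if (is.null(source_id)) rep(NA_character_, length(ids))
                else as.character(source_id),
    source_offset = if (is.null(source_offset)) rep(NA_real_, length(ids))
                    else as.numeric(source_offset),
    stringsAsFactors = FALSE
  )
  structure(
    list(reads = reads, seq = sequences, total_bases = sum(lengths)),
    class = "ReadSet"
  )
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads, %.0f bp total%s\n",
              nrow(x$reads), x$total_bases,
              if (is.null(x$seq)) " (length-only)" else ""))
  invisible(x)
}

#' @export
length.ReadSet <- function(x) nrow(x$reads)

#' Subset a ReadSet by read index
#'
#' @param rs a `ReadSet`.
#' @param idx integer indices into the read table.
#' @return A `ReadSet` holding the selected reads (order preserved).
#' @export
subset_reads <- function(rs, idx) {
  stopifnot(inherits(rs, "ReadSet"))
  r <- rs$reads[idx, , drop = FALSE]
  read_set(r$id, r$length,
           sequences = if (is.null(rs$seq)) NULL else rs$seq[idx],
           source_id = r$source_id, source_offset = r$source_offset)
}

#' Construct an Assembly
#'
#' An `Assembly` is an ordered set of named scaffold (or contig) sequences
#' plus an external genome-size estimate used by NG(x) and assembled-%
#' statistics. Lower-case letters are uppercased; only `N` participates in
#' gap logic downstream.
#'
#' @param sequences named `DNAStringSet` or named character vector of
#'   non-empty nucleotide sequences with unique names.
#' @param genome_size_estimate genome size in bp; defaults to the total
#'   assembly length.
#' @return An object of class `Assembly` with elements `seq` and
#'   `genome_size_estimate`.
#' @export
assembly <- function(sequences, genome_size_estimate = NULL) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("scaffold names must be present and unique")
  if (any(Biostrings::width(sequences) == 0))
    stop("scaffold sequences must be non-empty")
  sequences <- Biostrings::DNAStringSet(toupper(sequences))
  gs <- genome_size_estimate %||% sum(Biostrings::width(sequences))
  assert_scalar_number(gs, "genome_size_estimate", min = 1)
  structure(list(seq = sequences, genome_size_estimate = gs),
            class = "Assembly")
}

#' @export
print.Assembly <- function(x, ...) {
  cat(sprintf("Assembly: %d scaffolds, %.0f bp (genome size estimate %.0f bp)\n",
              length(x$seq), sum(Biostrings::width(x$seq)),
              x$genome_size_estimate))
  invisible(x)
}

#' Build a table of genomic intervals
#'
#' Internal convention is 0-based half-open (BED-style); 1-based inclusive
#' coordinates appear only in human-facing locus reports.
#'
#' @param chrom,start,end,label,strand interval columns; `strand` one of
#'   `+`, `-`, `.`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `label`,
#'   `strand`.
#' @export
intervals <- function(chrom, start, end, label = ".", strand = ".") {
  n <- length(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (n && any(start < 0 | start >= end))
    stop("intervals require 0 <= start < end")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             label = rep_len(as.character(label), n),
             strand = rep_len(as.character(strand), n),
             stringsAsFactors = FALSE)
}

#' Read long reads from FASTA or FASTQ
#'
#' @param path file path; gzip-compressed input is handled transparently.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by file extension).
#' @param length_only if `TRUE`, sequences are discarded and only read
#'   lengths are retained (useful for titration of large sets).
#' @return A [read_set()]; an empty file yields an empty `ReadSet` with a
#'   warning.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           length_only = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  seqs <- tryCatch(
    {
      if (format == "fastq") {
        con <- gzfile(path, "r")
        lines <- readLines(con, warn = FALSE)
        close(con)
        if (length(lines) %% 4L != 0L)
          stop("truncated FASTQ (line count not a multiple of 4)")
        if (length(lines)) {
          bad <- which(nchar(lines[seq(2L, length(lines), by = 4L)]) !=
                         nchar(lines[seq(4L, length(lines), by = 4L)]))
          if (length(bad))
            stop(sprintf("sequence/quality length mismatch at record %d",
                         bad[1L]))
        }
        Biostrings::readDNAStringSet(path, format = "fastq")
      } else {
        Biostrings::readDNAStringSet(path, format = "fasta")
      }
    },
    error = function(e) {
      if (grepl("no line|nothing to read|empty", conditionMessage(e),
                ignore.case = TRUE)) {
        warning(sprintf("empty %s file: %s", format, path))
        return(Biostrings::DNAStringSet())
      }
      stop(sprintf("malformed %s record in %s: %s",
                   format, path, conditionMessage(e)), call. = FALSE)
    })
  if (length(seqs) == 0L) {
    if (file.size(path) == 0) warning(sprintf("empty %s file: %s", format, path))
    return(read_set(character(0), numeric(0)))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (length_only) {
    read_set(ids, Biostrings::width(seqs))
  } else {
    read_set(ids, Biostrings::width(seqs), sequences = unname(seqs))
  }
}

#' Read a length-only ReadSet from a TSV of integer lengths
#'
#' @param path file with one integer read length per line (no header).
#' @return A length-only [read_set()] with synthetic ids `L000001`, ...
#' @export
read_length_tsv <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  if (any(v != floor(v) | v < 1)) stop("lengths must be positive integers")
  read_set(sprintf("L%06d", seq_along(v)), v)
}

#' Write reads to FASTA or FASTQ
#'
#' @param rs a `ReadSet` with sequences.
#' @param path output path (`.gz` compresses).
#' @param format `"fasta"` or `"fastq"` (FASTQ writes uniform dummy
#'   qualities).
#' @export
write_reads <- function(rs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(rs, "ReadSet"))
  if (is.null(rs$seq)) stop("ReadSet is length-only; nothing to write")
  compress <- grepl("\\.gz$", path)
  if (format == "fasta") {
    Biostrings::writeXStringSet(rs$seq, path, compress = compress)
  } else {
    # written directly: the Biostrings FASTQ writer caps record width well
    # below long-read lengths
    s <- as.character(rs$seq)
    con <- if (compress) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", names(rs$seq), "\n", s, "\n+\n",
                      vapply(nchar(s), function(w) strrep("I", w), "")),
               con)
  }
  invisible(path)
}

#' Split scaffolds into contigs at N-gap runs
#'
#' Every run of at least `min_gap_run` consecutive `N` splits a scaffold;
#' shorter N runs are retained inside contigs. The default threshold of 10
#' always splits the 13-bp N gaps that optical-map hybrid scaffolding
#' writes at contig joins.
#'
#' @param asm an [assembly()].
#' @param min_gap_run minimum N-run length (bp) treated as a gap.
#' @return A list with `contig_lengths` (numeric vector over all
#'   scaffolds), `gaps` (an [intervals()] table of qualifying N runs,
#'   0-based half-open), and `contigs_per_scaffold` (named list of length
#'   vectors).
#' @export
split_into_contigs <- function(asm, min_gap_run = 10) {
  stopifnot(inherits(asm, "Assembly"))
  assert_scalar_number(min_gap_run, "min_gap_run", min = 1)
  gap_chrom <- character(0); gap_start <- numeric(0); gap_end <- numeric(0)
  per <- vector("list", length(asm$seq))
  names(per) <- names(asm$seq)
  for (i in seq_along(asm$seq)) {
    s <- asm$seq[[i]]
    L <- length(s)
    nruns <- IRanges::reduce(methods::as(Biostrings::matchPattern("N", s),
                                         "IRanges"))
    nruns <- nruns[IRanges::width(nruns) >= min_gap_run]
    ctg <- IRanges::setdiff(IRanges::IRanges(1L, L), nruns)
    per[[i]] <- IRanges::width(ctg)
    if (length(nruns)) {
      gap_chrom <- c(gap_chrom, rep(names(asm$seq)[i], length(nruns)))
      gap_start <- c(gap_start, IRanges::start(nruns) - 1)
      gap_end <- c(gap_end, IRanges::end(nruns))
    }
  }
  list(
    contig_lengths = as.numeric(unlist(per, use.names = FALSE)),
    gaps = intervals(gap_chrom, gap_start, gap_end, label = "gap"),
    contigs_per_scaffold = per
  )
}

#' Read a BED3+ file as an interval table
#'
#' Coordinates are kept 0-based half-open. Column 4 (if present) becomes
#' `label`, column 6 `strand`.
#'
#' @param path BED file path.
#' @return An [intervals()] data.frame.
#' @export
read_bed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  colClasses = "character", quote = "",
                  comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("BED requires at least 3 columns")
  start <- suppressWarnings(as.numeric(d[[2L]]))
  end <- suppressWarnings(as.numeric(d[[3L]]))
  if (anyNA(start) || anyNA(end) || any(start != floor(start)) ||
      any(end != floor(end)))
    stop("BED coordinates must be integers")
  intervals(d[[1L]], start, end,
            label = if (ncol(d) >= 4L) d[[4L]] else ".",
            strand = if (ncol(d) >= 6L) d[[6L]] else ".")
}

#' Write an interval table as BED
#'
#' @param iv an [intervals()] data.frame.
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  out <- data.frame(iv$chrom, format(iv$start, scientific = FALSE, trim = TRUE),
                    format(iv$end, scientific = FALSE, trim = TRUE),
                    iv$label, 0L, iv$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
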