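#' Build a monomer library
#'
#' A named set of repeat monomer consensus sequences (e.g. knob180, TR-1,
#' CentC, subtelomere units). The telomere 7-mer is fixed biology and is
#' handled by [count_telomere_motifs()], not by the library.
#'
#' @param monomers named character vector (or `DNAStringSet`) of monomer
#'   sequences, each at least 5 bp of A/C/G/T.
#' @return A named uppercase character vector of class `MonomerLibrary`.
#' @export
monomer_library <- function(monomers) {
  if (methods::is(monomers, "DNAStringSet"))
    monomers <- stats::setNames(as.character(monomers), names(monomers))
  monomers <- toupper(monomers)
  if (is.null(names(monomers)) || any(!nzchar(names(monomers))))
    stop("monomers must be named by repeat class")
  if (any(nchar(monomers) < 5)) stop("monomer lengths must be >= 5")
  if (any(grepl("[^ACGT]", monomers)))
    stop("monomers must contain only A/C/G/T")
  structure(monomers, class = "MonomerLibrary")
}

#' Scan an assembly for tandem monomer hits
#'
#' Detection is rotation-aware Hamming scanning: every window of monomer
#' length is scored against all cyclic rotations of the monomer and of its
#' reverse complement (N never matches), windows at identity >=
#' `min_identity` are merged into maximal runs, and each run is emitted as
#' consecutive monomer-length hits (the final hit absorbs a remainder
#' shorter than half a monomer; a longer remainder becomes a partial hit).
#' Externally produced hits (e.g. from blast) can be substituted anywhere
#' a hit table is accepted, via [read_bed()].
#'
#' @param asm an [assembly()].
#' @param monomer a single monomer sequence (character, >= 5 bp).
#' @param class label recorded for the hits (default `"repeat"`).
#' @param min_identity minimum fraction of matching bases over the window,
#'   default 0.8 to tolerate the ~5-10% per-copy divergence typical of
#'   satellite arrays.
#' @return An [intervals()] table (0-based half-open) with columns
#'   `chrom`, `start`, `end`, `label`, `strand` and `identity`.
#' @export
scan_monomer_hits <- function(asm, monomer, class = "repeat",
                              min_identity = 0.8) {
  stopifnot(inherits(asm, "Assembly"))
  monomer <- toupper(as.character(monomer))
  if (nchar(monomer) < 5) stop("monomer length must be >= 5")
  assert_scalar_number(min_identity, "min_identity", min = 0, max = 1)
  m <- nchar(monomer)
  mrc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(monomer)))
  out <- list()
  for (ci in seq_along(asm$seq)) {
    s <- as.character(asm$seq[[ci]])
    if (nchar(s) < m) next
    best <- tandem_best_match_cpp(s, monomer, mrc)
    ok <- which(best / m >= min_identity)   # candidate window starts (1-based)
    if (!length(ok)) next
    # maximal runs of candidate starts -> spans [first, last + m)
    brk <- c(0L, which(diff(ok) > 1L), length(ok))
    for (r in seq_len(length(brk) - 1L)) {
      run <- ok[(brk[r] + 1L):brk[r + 1L]]
      span_start <- run[1L] - 1L            # 0-based
      span_end <- run[length(run)] - 1L + m
      span_len <- span_end - span_start
      n_full <- span_len %/% m
      rem <- span_len %% m
      starts <- span_start + (seq_len(n_full) - 1L) * m
      ends <- starts + m
      if (rem >= m / 2) {                   # long remainder: partial hit
        starts <- c(starts, span_start + n_full * m)
        ends <- c(ends, span_end)
      } else if (rem > 0L) {                # short remainder: extend last
        ends[length(ends)] <- span_end
      }
      idw <- pmin(starts + 1L, length(best))
      out[[length(out) + 1L]] <- data.frame(
        chrom = names(asm$seq)[ci], start = starts, end = ends,
        label = class, strand = ".",
        identity = best[idw] / m, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(cbind(intervals(character(0), numeric(0), numeric(0)),
                 identity = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster repeat hits into arrays
#'
#' Single-linkage clustering along each chromosome, per repeat class:
#' consecutive hits whose interspace is less than `max_interspace` join
#' one array; the array span runs from the first hit start to the last
#' hit end. Idempotent and independent of hit input order.
#'
#' @param hits a hit table from [scan_monomer_hits()] (or [read_bed()]).
#' @param max_interspace maximum gap between consecutive elements of one
#'   array, default 100 kb (gaps >= this split arrays).
#' @return A data.frame with columns `chrom`, `start`, `end`, `label`,
#'   `hit_count`.
#' @export
cluster_arrays <- function(hits, max_interspace = 100000) {
  assert_scalar_number(max_interspace, "max_interspace", min = 1)
  if (nrow(hits) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), label = character(0),
                      hit_count = integer(0)))
  hits <- hits[order(hits$chrom, hits$label, hits$start), , drop = FALSE]
  out <- list()
  for (key in unique(paste(hits$chrom, hits$label, sep = "\r"))) {
    h <- hits[paste(hits$chrom, hits$label, sep = "\r") == key, ,
              drop = FALSE]
    # running maximum end guards against nested/overlapping hits
    hi_end <- cummax(h$end)
    gap <- h$start[-1L] - hi_end[-nrow(h)]
    grp <- cumsum(c(0, as.integer(gap >= max_interspace)))
    for (g in unique(grp)) {
      hg <- h[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = hg$chrom[1L], start = min(hg$start), end = max(hg$end),
        label = hg$label[1L], hit_count = nrow(hg),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Quantify repeat, gap and other bases inside an array span
#'
#' Accounts every base of the span to exactly one of three categories:
#' `repeat_bp` (union of hit bases, N positions excluded), `gap_bp` (N
#' bases) and `other_bp` (the remainder), so the three always sum to the
#' span length. When a truth size is supplied, completeness is
#' `100 * repeat_bp / truth_size`.
#'
#' @param span one row of a [cluster_arrays()] result (or a list with
#'   `chrom`, `start`, `end`, `label`).
#' @param hits the hit table the span was clustered from.
#' @param asm the [assembly()] scanned.
#' @param truth_size optional true array size in bp (e.g. from the
#'   synthetic-genome truth table, or an external size estimate).
#' @return An object of class `RepeatArrayReport`.
#' @export
quantify_array <- function(span, hits, asm, truth_size = NULL) {
  stopifnot(inherits(asm, "Assembly"))
  s0 <- as.numeric(span$start); e0 <- as.numeric(span$end)
  span_len <- e0 - s0
  h <- hits[hits$chrom == span$chrom & hits$label == span$label &
              hits$end > s0 & hits$start < e0, , drop = FALSE]
  hit_u <- IRanges::reduce(IRanges::IRanges(pmax(h$start, s0) + 1,
                                            pmin(h$end, e0)))
  seq_span <- Biostrings::subseq(asm$seq[[span$chrom]], s0 + 1, e0)
  nruns <- IRanges::reduce(methods::as(
    Biostrings::matchPattern("N", seq_span), "IRanges"))
  nruns <- IRanges::shift(nruns, s0)       # back to chromosome coordinates
  gap_bp <- sum(IRanges::width(nruns))
  repeat_bp <- sum(IRanges::width(IRanges::setdiff(hit_u, nruns)))
  completeness <- if (!is.null(truth_size)) {
    if (truth_size <= 0) NA_real_ else 100 * repeat_bp / truth_size
  } else NA_real_
  structure(list(chrom = span$chrom, start = s0, end = e0,
                 label = span$label, hit_count = nrow(h),
                 repeat_bp = repeat_bp, gap_bp = gap_bp,
                 other_bp = span_len - repeat_bp - gap_bp,
                 completeness_pct = completeness,
                 truth_size = truth_size %||% NA_real_),
            class = "RepeatArrayReport")
}

#' @export
print.RepeatArrayReport <- function(x, ...) {
  cat(sprintf(paste0("RepeatArrayReport %s %s:%.0f-%.0f: %d hits, ",
                     "repeat %.0f bp, gap %.0f bp, other %.0f bp"),
              x$label, x$chrom, x$start, x$end, x$hit_count,
              x$repeat_bp, x$gap_bp, x$other_bp))
  if (!is.na(x$completeness_pct))
    cat(sprintf(", completeness %.1f%%", x$completeness_pct))
  cat("\n")
  invisible(x)
}

#' Scan, cluster and quantify all repeat arrays of an assembly
#'
#' @param asm an [assembly()].
#' @param monomers a [monomer_library()].
#' @param min_identity,max_interspace see [scan_monomer_hits()] and
#'   [cluster_arrays()].
#' @param truth_sizes optional named vector of per-class true sizes (bp);
#'   completeness is reported per class against these.
#' @return A list with `hits` (combined hit table), `arrays` (data.frame,
#'   one row per array with repeat/gap/other accounting) and `by_class`
#'   (data.frame of per-class totals and completeness).
#' @export
repeat_report <- function(asm, monomers, min_identity = 0.8,
                          max_interspace = 100000, truth_sizes = NULL) {
  monomers <- monomer_library(monomers)
  hits <- do.call(rbind, lapply(names(monomers), function(cls)
    scan_monomer_hits(asm, monomers[[cls]], class = cls,
                      min_identity = min_identity)))
  arrays <- cluster_arrays(hits, max_interspace = max_interspace)
  rows <- lapply(seq_len(nrow(arrays)), function(i) {
    q <- quantify_array(arrays[i, ], hits, asm)
    data.frame(chrom = q$chrom, start = q$start, end = q$end,
               label = q$label, hit_count = q$hit_count,
               repeat_bp = q$repeat_bp, gap_bp = q$gap_bp,
               other_bp = q$other_bp, stringsAsFactors = FALSE)
  })
  arr_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               label = character(0), hit_count = integer(0),
               repeat_bp = numeric(0), gap_bp = numeric(0),
               other_bp = numeric(0))
  cls_rep <- vapply(names(monomers), function(cls)
    sum(arr_df$repeat_bp[arr_df$label == cls]), 0)
  by_class <- data.frame(
    label = names(monomers), repeat_bp = cls_rep,
    truth_bp = if (is.null(truth_sizes)) NA_real_ else
      as.numeric(truth_sizes[names(monomers)]),
    stringsAsFactors = FALSE)
  by_class$completeness_pct <- 100 * by_class$repeat_bp / by_class$truth_bp
  rownames(by_class) <- NULL
  list(hits = hits, arrays = arr_df, by_class = by_class)
}

#' Count telomere repeat motifs
#'
#' Counts positions where the telomere 7-mer `TTTAGGG` or its reverse
#' complement `CCCTAAA` occurs, scanning every offset (these motifs cannot
#' self-overlap, so overlapping and non-overlapping counts agree). N never
#' matches. The count is invariant under reverse complementation of the
#' input.
#'
#' @param x character scalar/vector, `DNAString`, or `DNAStringSet`.
#' @return Total motif count over all supplied sequences.
#' @export
count_telomere_motifs <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (methods::is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  sum(Biostrings::vcountPattern(TELOMERE_MOTIF, x, fixed = TRUE)) +
    sum(Biostrings::vcountPattern(TELOMERE_MOTIF_RC, x, fixed = TRUE))
}

#' Locate the subtelomere boundary at a chromosome end
#'
#' The terminal subtelomere array is the hit cluster that starts within
#' `terminal_window` of the chromosome end; the boundary is its innermost
#' edge, and the telomere region is what remains between the cluster's
#' outer edge and the chromosome end (reported with its telomere-motif
#' count). Returns `NULL` when no terminal cluster exists — chromosomes
#' genuinely lacking a subtelomere at that end report as absent.
#'
#' @param asm an [assembly()].
#' @param chrom chromosome (scaffold) name.
#' @param hits subtelomere hit table from [scan_monomer_hits()].
#' @param end `"left"` or `"right"`.
#' @param terminal_window how close (bp) to the chromosome end a cluster
#'   must start to count as terminal (default 2 Mb; scale down for small
#'   genomes).
#' @param max_interspace clustering gap, as in [cluster_arrays()].
#' @return `NULL`, or a list with `boundary` (0-based innermost cluster
#'   edge), `subtelomere` and `telomere` intervals, `telomere_bp` and
#'   `motif_count`.
#' @export
detect_subtelomere_boundary <- function(asm, chrom, hits,
                                        end = c("left", "right"),
                                        terminal_window = 2e6,
                                        max_interspace = 100000) {
  stopifnot(inherits(asm, "Assembly"))
  end <- match.arg(end)
  L <- as.numeric(Biostrings::width(asm$seq)[match(chrom, names(asm$seq))])
  if (is.na(L)) stop(sprintf("unknown chromosome: %s", chrom))
  h <- hits[hits$chrom == chrom, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  cl <- cluster_arrays(h, max_interspace = max_interspace)
  if (end == "left") {
    cl <- cl[cl$start < terminal_window, , drop = FALSE]
    if (nrow(cl) == 0L) return(NULL)
    c1 <- cl[which.min(cl$start), ]
    telo <- c(0, c1$start)
    boundary <- c1$end
  } else {
    cl <- cl[cl$end > L - terminal_window, , drop = FALSE]
    if (nrow(cl) == 0L) return(NULL)
    c1 <- cl[which.max(cl$end), ]
    telo <- c(c1$end, L)
    boundary <- c1$start
  }
  telo_seq <- if (telo[2L] > telo[1L])
    Biostrings::subseq(asm$seq[[chrom]], telo[1L] + 1, telo[2L]) else NULL
  list(boundary = boundary,
       subtelomere = intervals(chrom, c1$start, c1$end, "subtelomere"),
       telomere = if (telo[2L] > telo[1L])
         intervals(chrom, telo[1L], telo[2L], "telomere") else NULL,
       telomere_bp = telo[2L] - telo[1L],
       motif_count = if (is.null(telo_seq)) 0L else
         count_telomere_motifs(telo_seq))
}

#' Per-end telomere/subtelomere report for an assembly
#'
#' @param asm an [assembly()].
#' @param subtelomere_monomer subtelomere monomer sequence (scanned with
#'   [scan_monomer_hits()]), or `NULL` if `hits` is supplied.
#' @param hits optional precomputed subtelomere hit table.
#' @param min_identity,terminal_window,max_interspace see
#'   [scan_monomer_hits()] and [detect_subtelomere_boundary()].
#' @return A data.frame with one row per chromosome end: `chrom`, `end`,
#'   `has_subtelomere`, `subtelomere_bp`, `telomere_bp`, `motif_count`.
#' @export
telomere_report <- function(asm, subtelomere_monomer = NULL, hits = NULL,
                            min_identity = 0.8, terminal_window = 2e6,
                            max_interspace = 100000) {
  stopifnot(inherits(asm, "Assembly"))
  if (is.null(hits)) {
    if (is.null(subtelomere_monomer))
      stop("supply subtelomere_monomer or hits")
    hits <- scan_monomer_hits(asm, subtelomere_monomer,
                              class = "subtelomere",
                              min_identity = min_identity)
  }
  rows <- list()
  for (chrom in names(asm$seq)) {
    for (side in c("left", "right")) {
      b <- detect_subtelomere_boundary(asm, chrom, hits, end = side,
                                       terminal_window = terminal_window,
                                       max_interspace = max_interspace)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, end = side,
        has_subtelomere = !is.null(b),
        subtelomere_bp = if (is.null(b)) 0 else
          b$subtelomere$end - b$subtelomere$start,
        telomere_bp = if (is.null(b)) NA_real_ else b$telomere_bp,
        motif_count = if (is.null(b)) NA_integer_ else b$motif_count,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Construct a 1-based locus report
#'
#' Human-facing locus coordinates are 1-based inclusive, so the length is
#' `end - start + 1`.
#'
#' @param chrom chromosome name.
#' @param start_1based,end_1based 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `LocusMatch` with `length_bp` computed from
#'   the coordinates.
#' @examples
#' locus_match("chr9", 11625031, 11914133)$length_bp  # 289103
#' @export
locus_match <- function(chrom, start_1based, end_1based, strand = "+") {
  assert_scalar_number(start_1based, "start_1based", min = 1)
  assert_scalar_number(end_1based, "end_1based", min = start_1based)
  structure(list(chrom = chrom, start_1based = start_1based,
                 end_1based = end_1based,
                 length_bp = end_1based - start_1based + 1,
                 strand = strand, found = TRUE),
            class = "LocusMatch")
}

#' @export
print.LocusMatch <- function(x, ...) {
  if (isTRUE(x$found)) {
    cat(sprintf("LocusMatch %s:%.0f-%.0f (%s), %.0f bp\n", x$chrom,
                x$start_1based, x$end_1based, x$strand, x$length_bp))
  } else {
    cat("LocusMatch: not found\n")
    if (!is.null(x$diagnostics)) print(x$diagnostics)
  }
  invisible(x)
}

flank_matches <- function(asm, flank, max_mismatch) {
  f <- Biostrings::DNAString(toupper(as.character(flank)))
  rows <- list()
  for (orient in c("+", "-")) {
    pat <- if (orient == "+") f else Biostrings::reverseComplement(f)
    m <- Biostrings::vmatchPattern(pat, asm$seq, max.mismatch = max_mismatch,
                                   fixed = TRUE)
    for (ci in seq_along(m)) {
      r <- m[[ci]]
      if (!length(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = names(asm$seq)[ci], start = IRanges::start(r),
        end = IRanges::end(r), strand = orient, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  do.call(rbind, rows)
}

#' Locate a locus by its flanking sequences
#'
#' Finds matches of both ~2 kb flanks on either strand and reports the
#' same-chromosome, consistent-orientation pair spanning the locus: on the
#' plus strand the left flank precedes the right; on the minus strand the
#' reverse-complemented right flank precedes the reverse-complemented
#' left. Coordinates are reported 1-based inclusive, so the length is
#' `end - start + 1`.
#'
#' @param asm an [assembly()].
#' @param left_flank,right_flank flanking sequences (character or
#'   `DNAString`), each at least 100 bp.
#' @param restrict_chrom optional chromosome name to search.
#' @param max_mismatch mismatches tolerated per flank match (default 0).
#' @return A [locus_match()] when a consistent pair exists (smallest
#'   spanning interval if several); otherwise a `LocusMatch` with
#'   `found = FALSE` and a `diagnostics` table of the per-flank matches.
#' @export
locate_locus_by_flanks <- function(asm, left_flank, right_flank,
                                   restrict_chrom = NULL, max_mismatch = 0) {
  stopifnot(inherits(asm, "Assembly"))
  if (nchar(as.character(left_flank)) < 100 ||
      nchar(as.character(right_flank)) < 100)
    stop("flanks must be at least 100 bp")
  lm <- flank_matches(asm, left_flank, max_mismatch)
  rm_ <- flank_matches(asm, right_flank, max_mismatch)
  if (!is.null(restrict_chrom)) {
    lm <- lm[lm$chrom == restrict_chrom, , drop = FALSE]
    rm_ <- rm_[rm_$chrom == restrict_chrom, , drop = FALSE]
  }
  best <- NULL
  for (i in seq_len(nrow(lm))) for (j in seq_len(nrow(rm_))) {
    if (lm$chrom[i] != rm_$chrom[j] || lm$strand[i] != rm_$strand[j]) next
    if (lm$strand[i] == "+") {
      if (lm$start[i] > rm_$start[j]) next
      cand <- c(lm$start[i], rm_$end[j])
    } else {
      if (rm_$start[j] > lm$start[i]) next
      cand <- c(rm_$start[j], lm$end[i])
    }
    if (is.null(best) || diff(cand) < diff(best$range))
      best <- list(chrom = lm$chrom[i], range = cand,
                   strand = lm$strand[i])
  }
  if (is.null(best)) {
    return(structure(list(
      found = FALSE,
      diagnostics = rbind(
        if (nrow(lm)) cbind(flank = "left", lm) else NULL,
        if (nrow(rm_)) cbind(flank = "right", rm_) else NULL)),
      class = "LocusMatch"))
  }
  locus_match(best$chrom, best$range[1L], best$range[2L],
              strand = best$strand)
}
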