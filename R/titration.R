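#' Read/contig length statistics
#'
#' `N(x)` is the length of the element at which the descending-sorted
#' cumulative sum first reaches `x`% of the total.
#'
#' @param lengths non-empty numeric vector of lengths in bp.
#' @return An object of class `LengthStats`: `count`, `total`, `max`,
#'   `n25`, `n50`.
#' @examples
#' length_stats(c(2, 2, 2, 3, 3))$n50  # 3
#' @export
length_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stop("length_stats requires a non-empty input")
  structure(list(count = length(lengths), total = sum(lengths),
                 max = max(lengths),
                 n25 = nxx(lengths, 25), n50 = nxx(lengths, 50)),
            class = "LengthStats")
}

#' @export
print.LengthStats <- function(x, ...) {
  cat(sprintf("LengthStats: n=%d total=%.0f max=%.0f N25=%.0f N50=%.0f\n",
              x$count, x$total, x$max, x$n25, x$n50))
  invisible(x)
}

#' N(x) of a length multiset
#'
#' @param lengths numeric vector of lengths.
#' @param x percentage of total, in (0, 100].
#' @return The length at which the descending cumulative sum first reaches
#'   `x`% of the total.
#' @export
nxx <- function(lengths, x) {
  assert_scalar_number(x, "x", min = .Machine$double.eps, max = 100)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  thresh <- x / 100 * sum(s)
  s[which(cumsum(s) >= thresh)[1L]]
}

#' Serial depth titration of a read set
#'
#' Downsamples a read set to a descending ladder of fold-coverages so that
#' each depth subset is a superset of the next smaller one: the largest
#' subset is drawn from the full set by seeded uniform sampling of reads
#' without replacement, accumulating reads until the base total crosses
#' `depth * genome_size` (the crossing read included); every subsequent
#' subset is drawn the same way from the previous subset. Because reads
#' are sampled uniformly, each subset keeps the length distribution of the
#' full set.
#'
#' @param reads a [read_set()].
#' @param depths strictly descending fold-coverages.
#' @param genome_size genome size in bp used to convert depth to bases.
#' @param seed integer RNG seed.
#' @param tolerance maximum allowed relative overshoot of each subset's
#'   base total past its target (default 0.005).
#' @return An object of class `TitrationSeries`: `depths`, `genome_size`,
#'   `seed`, `tolerance`, `subsets` (list of `ReadSet`, one per depth) and
#'   `stats` (list of [length_stats()]).
#' @export
serial_downsample <- function(reads, depths, genome_size, seed,
                              tolerance = 0.005) {
  stopifnot(inherits(reads, "ReadSet"))
  assert_scalar_number(genome_size, "genome_size", min = 1)
  depths <- as.numeric(depths)
  if (length(depths) == 0L || any(diff(depths) >= 0) || any(depths <= 0))
    stop("depths must be strictly descending and positive")
  full_depth <- reads$total_bases / genome_size
  if (depths[1L] > full_depth)
    stop(sprintf("requested depth %gx exceeds available %.2fx",
                 depths[1L], full_depth))
  local_seed(seed, {
    subsets <- vector("list", length(depths))
    cur_idx <- seq_len(nrow(reads$reads))
    for (d in seq_along(depths)) {
      target <- depths[d] * genome_size
      perm <- sample(cur_idx)
      csum <- cumsum(reads$reads$length[perm])
      k <- which(csum >= target)[1L]
      if (is.na(k))
        stop(sprintf("requested depth %gx exceeds available data", depths[d]))
      if (csum[k] > target * (1 + tolerance))
        stop(sprintf("depth %gx subset overshoots target by more than %.1f%%",
                     depths[d], 100 * tolerance))
      cur_idx <- sort(perm[seq_len(k)])
      subsets[[d]] <- subset_reads(reads, cur_idx)
    }
    structure(list(depths = depths, genome_size = genome_size, seed = seed,
                   tolerance = tolerance, subsets = subsets,
                   stats = lapply(subsets,
                                  function(s) length_stats(s$reads$length))),
              class = "TitrationSeries")
  })
}

#' @export
print.TitrationSeries <- function(x, ...) {
  cat("TitrationSeries over depths:", paste0(x$depths, "x"), "\n")
  for (i in seq_along(x$depths))
    cat(sprintf("  %4gx: %d reads, %.0f bp, N50 %.0f\n", x$depths[i],
                x$stats[[i]]$count, x$stats[[i]]$total, x$stats[[i]]$n50))
  invisible(x)
}

#' Shift a read set onto a target length distribution
#'
#' Reproduces an empirical read-length distribution by sample-and-clip:
#' target lengths are processed in descending order; for each target `L`
#' one pool read of length >= `L` is chosen uniformly at random, clipped
#' to its first `L` bases, and the unused suffix is returned to the pool
#' for further use (if at least `min_remnant` bp). Remnants can themselves
#' be clipped again. Targets with no eligible pool read are skipped and
#' reported, not fatal.
#'
#' @param source a [read_set()] (with or without sequences).
#' @param target_lengths numeric multiset of desired read lengths in bp.
#' @param seed integer RNG seed.
#' @param min_remnant smallest clipped-off suffix worth returning to the
#'   pool (default 1000 bp).
#' @return A list of class `LengthShiftResult`: `reads` (a `ReadSet` whose
#'   length multiset equals the fulfilled subset of `target_lengths`, with
#'   `source_id`/`source_offset` provenance), `skipped_lengths` (targets
#'   with no eligible read) and `pool_lengths` (lengths left in the pool).
#' @export
match_length_distribution <- function(source, target_lengths, seed,
                                      min_remnant = 1000) {
  stopifnot(inherits(source, "ReadSet"))
  if (nrow(source$reads) == 0L) stop("source ReadSet is empty")
  assert_scalar_number(min_remnant, "min_remnant", min = 1)
  targets <- sort(as.numeric(target_lengths), decreasing = TRUE)
  if (length(targets) && any(targets < 1)) stop("target lengths must be >= 1")

  local_seed(seed, {
    # pool kept sorted ascending by length for binary eligibility search;
    # off is the 0-based offset of each pool fragment in its original read
    o <- order(source$reads$length)
    pool_len <- source$reads$length[o]
    pool_src <- source$reads$id[o]
    pool_off <- rep(0, length(o))

    out_len <- numeric(0); out_src <- character(0); out_off <- numeric(0)
    skipped <- numeric(0)
    for (L in targets) {
      lo <- findInterval(L - 0.5, pool_len) + 1L   # first pool index >= L
      n <- length(pool_len)
      if (lo > n) { skipped <- c(skipped, L); next }
      pick <- lo - 1L + sample.int(n - lo + 1L, 1L)
      out_len <- c(out_len, L)
      out_src <- c(out_src, pool_src[pick])
      out_off <- c(out_off, pool_off[pick])
      remnant <- pool_len[pick] - L
      r_src <- pool_src[pick]; r_off <- pool_off[pick] + L
      pool_len <- pool_len[-pick]; pool_src <- pool_src[-pick]
      pool_off <- pool_off[-pick]
      if (remnant >= min_remnant) {
        at <- findInterval(remnant, pool_len)
        pool_len <- append(pool_len, remnant, after = at)
        pool_src <- append(pool_src, r_src, after = at)
        pool_off <- append(pool_off, r_off, after = at)
      }
    }
    ids <- if (length(out_len))
      sprintf("%s:%.0f-%.0f", out_src, out_off, out_off + out_len)
    else character(0)
    seqs <- NULL
    if (!is.null(source$seq) && length(out_len)) {
      src_i <- match(out_src, source$reads$id)
      seqs <- Biostrings::subseq(source$seq[src_i], start = out_off + 1,
                                 width = out_len)
    }
    structure(list(
      reads = read_set(ids, out_len, sequences = seqs,
                       source_id = out_src, source_offset = out_off),
      skipped_lengths = skipped,
      pool_lengths = pool_len
    ), class = "LengthShiftResult")
  })
}

#' @export
print.LengthShiftResult <- function(x, ...) {
  cat(sprintf("LengthShiftResult: %d reads fulfilled, %d targets skipped\n",
              nrow(x$reads$reads), length(x$skipped_lengths)))
  invisible(x)
}
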