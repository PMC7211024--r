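#' Configure assembly degradation
#'
#' Models the preferential collapse of repeats in low-depth assemblies:
#' breakpoints follow a Poisson process whose intensity is higher inside
#' repeat-class truth intervals than in unique sequence, and each break
#' deletes a segment whose expected size is `drop_fraction` times the
#' length of the local feature.
#'
#' @param breaks_per_mb_unique breakpoint intensity in unique sequence
#'   (breaks per Mb).
#' @param breaks_per_mb_repeat breakpoint intensity inside repeat truth
#'   intervals; must be >= the unique rate.
#' @param drop_fraction expected deleted fraction of the local feature per
#'   break, in \[0, 1\].
#' @param gap_policy `"ngap"` writes `gap_fill` N's in place of each
#'   deletion (producing scaffolds); `"remove"` splits at deletions into
#'   separate contigs (no N is ever written).
#' @param gap_fill N-run length written under the `ngap` policy
#'   (default 13, the N run an optical-map hybrid scaffold writes).
#' @param seed integer RNG seed.
#' @return An object of class `DegradeConfig`.
#' @export
degrade_config <- function(breaks_per_mb_unique = 1,
                           breaks_per_mb_repeat = 4,
                           drop_fraction = 0.3,
                           gap_policy = c("ngap", "remove"),
                           gap_fill = 13, seed = 1L) {
  assert_scalar_number(breaks_per_mb_unique, "breaks_per_mb_unique", min = 0)
  assert_scalar_number(breaks_per_mb_repeat, "breaks_per_mb_repeat", min = 0)
  if (breaks_per_mb_repeat < breaks_per_mb_unique)
    stop("repeat break rate must be >= unique break rate")
  assert_scalar_number(drop_fraction, "drop_fraction", min = 0, max = 1)
  assert_scalar_number(gap_fill, "gap_fill", min = 1)
  structure(list(breaks_per_mb_unique = breaks_per_mb_unique,
                 breaks_per_mb_repeat = breaks_per_mb_repeat,
                 drop_fraction = drop_fraction,
                 gap_policy = match.arg(gap_policy),
                 gap_fill = gap_fill, seed = seed),
            class = "DegradeConfig")
}

# feature classes whose truth intervals receive the repeat break rate
REPEAT_CLASSES <- c("knob180", "tr1", "centc", "rdna", "subtelomere",
                    "telomere", "ltr")

# candidate-break ceiling intensity (breaks/Mb). Candidates are generated
# at this fixed rate and thinned to the requested rate, so for a fixed
# seed the breakpoint set at a higher rate is a superset of the set at a
# lower rate: degradation is monotone in the rates by construction.
BREAK_CEILING_PER_MB <- 512

#' Degrade a simulated genome into a fragmented assembly
#'
#' Places breakpoints by a seeded Poisson process (repeat truth intervals
#' get the repeat intensity, everything else the unique intensity); each
#' break deletes an exponentially sized segment with expected size
#' `drop_fraction * local feature length`. Under the `ngap` policy each
#' deletion is replaced by a `gap_fill`-bp N run, yielding scaffolds;
#' under `remove` the sequence is split into separate contigs. Candidate
#' breaks are generated at a fixed ceiling intensity and thinned, so
#' increasing either rate (same seed) only adds breakpoints.
#'
#' @param genome a [build_genome()] result.
#' @param config a [degrade_config()]; both rates must be <=
#'   `BREAK_CEILING_PER_MB` (512/Mb).
#' @return A list of class `DegradedAssembly`: `assembly` (the fragmented
#'   [assembly()], genome-size estimate inherited from the truth genome),
#'   `retained` (data.frame per truth feature: `chrom`, `label`, `start`,
#'   `end`, `original_bp`, `retained_bp`), and `deletions` (an
#'   [intervals()] table in original-genome coordinates).
#' @export
degrade_assembly <- function(genome, config) {
  stopifnot(inherits(genome, "SimulatedGenome"),
            inherits(config, "DegradeConfig"))
  if (max(config$breaks_per_mb_unique, config$breaks_per_mb_repeat) >
      BREAK_CEILING_PER_MB)
    stop(sprintf("break rates above the candidate ceiling (%d/Mb) are not supported",
                 BREAK_CEILING_PER_MB))
  asm <- genome$assembly
  truth <- genome$truth
  rep_truth <- truth[truth$label %in% REPEAT_CLASSES, , drop = FALSE]

  del_rows <- list()
  out_seqs <- list()
  local_seed(config$seed, {
    for (ci in seq_along(asm$seq)) {
      cname <- names(asm$seq)[ci]
      L <- as.numeric(Biostrings::width(asm$seq)[ci])
      tr <- rep_truth[rep_truth$chrom == cname, , drop = FALSE]
      tf <- truth[truth$chrom == cname, , drop = FALSE]

      # candidate breaks at the ceiling rate, with per-candidate thinning
      # mark and deletion-size draw (couples realizations across configs)
      n_cand <- rpois(1L, BREAK_CEILING_PER_MB * L / 1e6)
      if (n_cand == 0L) { next }
      pos <- sort(floor(runif(n_cand) * L))
      u <- runif(n_cand)
      esize <- rexp(n_cand)

      in_repeat <- rep(FALSE, n_cand)
      feat_len <- rep(NA_real_, n_cand)
      if (nrow(tf)) {
        for (j in seq_len(nrow(tf))) {
          hit <- pos >= tf$start[j] & pos < tf$end[j]
          feat_len[hit] <- tf$end[j] - tf$start[j]
          if (tf$label[j] %in% REPEAT_CLASSES) in_repeat[hit] <- TRUE
        }
      }
      # local feature length for breaks in unique sequence: length of the
      # containing inter-feature segment
      if (any(is.na(feat_len))) {
        bounds <- sort(unique(c(0, tf$start, tf$end, L)))
        seg <- findInterval(pos, bounds)
        feat_len[is.na(feat_len)] <-
          (bounds[pmin(seg + 1L, length(bounds))] - bounds[seg])[is.na(feat_len)]
      }
      rate <- ifelse(in_repeat, config$breaks_per_mb_repeat,
                     config$breaks_per_mb_unique)
      keep <- u < rate / BREAK_CEILING_PER_MB
      if (!any(keep)) next
      pos <- pos[keep]; esize <- esize[keep]; feat_len <- feat_len[keep]

      dlen <- floor(esize * config$drop_fraction * feat_len)
      dstart <- pos
      dend <- pmin(pos + pmax(dlen, 0), L)
      real <- dend > dstart
      dr <- IRanges::reduce(IRanges::IRanges(dstart[real] + 1, dend[real]))
      # zero-length deletions are pure breaks; represent as width-0 cuts,
      # dropping any that fall inside (or on the edge of) a real deletion
      cuts0 <- unique(dstart[dend == dstart])
      if (length(cuts0) && length(dr)) {
        st0 <- IRanges::start(dr) - 1; en <- IRanges::end(dr)
        cuts0 <- cuts0[!vapply(cuts0, function(p) any(p >= st0 & p <= en),
                               logical(1))]
      }
      del_rows[[length(del_rows) + 1L]] <- data.frame(
        chrom = cname,
        start = c(IRanges::start(dr) - 1, cuts0),
        end = c(IRanges::end(dr), cuts0), stringsAsFactors = FALSE)
    }
  })
  del <- if (length(del_rows)) do.call(rbind, del_rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))

  # apply deletions / cuts chromosome by chromosome
  for (ci in seq_along(asm$seq)) {
    cname <- names(asm$seq)[ci]
    s <- asm$seq[[ci]]
    L <- length(s)
    d <- del[del$chrom == cname, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) == 0L) {
      out_seqs[[cname]] <- stats::setNames(as.character(s), cname)
      next
    }
    # kept segments between consecutive deletions/cuts
    keep_start <- c(0, d$end)
    keep_end <- c(d$start, L)
    w <- keep_end - keep_start
    segs <- as.character(Biostrings::extractAt(
      s, IRanges::IRanges(keep_start + 1, width = w)))
    if (config$gap_policy == "ngap") {
      joined <- paste(segs, collapse = strrep("N", config$gap_fill))
      out_seqs[[cname]] <- stats::setNames(joined, cname)
    } else {
      segs <- segs[nzchar(segs)]
      out_seqs[[cname]] <- stats::setNames(
        segs, sprintf("%s_ctg%03d", cname, seq_along(segs)))
    }
  }
  out <- unlist(unname(out_seqs))
  degraded <- assembly(out, genome_size_estimate = asm$genome_size_estimate)

  # retained bases per truth feature
  retained <- truth[, c("chrom", "label", "start", "end")]
  retained$original_bp <- retained$end - retained$start
  retained$retained_bp <- retained$original_bp
  if (nrow(del)) {
    for (i in seq_len(nrow(retained))) {
      d <- del[del$chrom == retained$chrom[i] & del$end > del$start, ,
               drop = FALSE]
      if (!nrow(d)) next
      ov <- pmin(d$end, retained$end[i]) - pmax(d$start, retained$start[i])
      retained$retained_bp[i] <- retained$original_bp[i] - sum(pmax(ov, 0))
    }
  }
  rownames(retained) <- NULL
  structure(list(assembly = degraded, retained = retained,
                 deletions = del, config = config),
            class = "DegradedAssembly")
}

#' @export
print.DegradedAssembly <- function(x, ...) {
  cat(sprintf("DegradedAssembly: %d sequences, %.0f bp, %d deletions (%s policy)\n",
              length(x$assembly$seq), sum(Biostrings::width(x$assembly$seq)),
              nrow(x$deletions), x$config$gap_policy))
  invisible(x)
}

#' Write the retained-truth table as TSV
#'
#' @param deg a [degrade_assembly()] result.
#' @param path output path.
#' @export
write_retained_tsv <- function(deg, path) {
  write.table(deg$retained, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
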