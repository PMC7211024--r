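#' Telomere repeat motif
#'
#' The plant telomere 7-mer, written for the G-rich strand; the C-rich
#' strand carries its reverse complement.
#' @export
TELOMERE_MOTIF <- "TTTAGGG"

#' @rdname TELOMERE_MOTIF
#' @export
TELOMERE_MOTIF_RC <- "CCCTAAA"

default_array_plan <- function() {
  # monomer length (bp) and copies per array; classes emulate the maize
  # non-TE repeat space: 180-bp knob, 350-bp TR-1 knob, 156-bp CentC,
  # ~11-kb rDNA-like NOR unit, and 300-1300 bp subtelomere monomers
  list(
    knob180     = list(monomer_len = 180,  copies = 120, arrays = 1),
    tr1         = list(monomer_len = 350,  copies = 60,  arrays = 1),
    centc       = list(monomer_len = 156,  copies = 150, arrays = 1),
    rdna        = list(monomer_len = 11000, copies = 4,  arrays = 1)
  )
}

#' Specify a synthetic genome
#'
#' Plans a genome of seeded random background carrying the feature classes
#' whose assembly completeness the package measures: single-copy gene-like
#' segments, LTR elements with two terminal repeats, tandem monomer arrays
#' (knob180, TR-1, CentC, rDNA-like), subtelomere arrays adjacent to the
#' telomeres, and telomere 7-mer runs touching both chromosome ends (left
#' ends carry `CCCTAAA` copies, right ends `TTTAGGG`).
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param genes list(count, min_len, max_len) of gene-like unique segments
#'   per chromosome.
#' @param ltr list(count, tr_len, internal_len): LTR elements per
#'   chromosome; each element is terminal repeat + internal + terminal
#'   repeat.
#' @param arrays named list per monomer class:
#'   list(monomer_len, copies, arrays). Defaults to maize-like classes.
#' @param subtelomere list(monomer_min, monomer_max, copies); one array
#'   inside each chromosome end. `copies = 0` disables.
#' @param telomere_units tandem copies of the 7-bp telomere motif at each
#'   chromosome end.
#' @param divergence per-copy substitution rate applied to array copies
#'   and LTR terminal repeats, in \[0, 0.2\].
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @return An object of class `GenomeSpec`.
#' @export
genome_spec <- function(chromosomes = data.frame(name = c("chr1", "chr2"),
                                                 length = c(1e6, 1e6)),
                        genes = list(count = 20, min_len = 2000,
                                     max_len = 6000),
                        ltr = list(count = 5, tr_len = 1000,
                                   internal_len = 5000),
                        arrays = default_array_plan(),
                        subtelomere = list(monomer_min = 300,
                                           monomer_max = 1300, copies = 20),
                        telomere_units = 50,
                        divergence = 0.05,
                        seed = 1L) {
  assert_scalar_number(divergence, "divergence", min = 0, max = 0.2)
  assert_scalar_number(telomere_units, "telomere_units", min = 0)
  if (anyDuplicated(chromosomes$name)) stop("chromosome names must be unique")
  structure(list(chromosomes = chromosomes, genes = genes, ltr = ltr,
                 arrays = arrays, subtelomere = subtelomere,
                 telomere_units = telomere_units, divergence = divergence,
                 seed = seed),
            class = "GenomeSpec")
}

# one tandem array: copies of monomer, each with per-copy substitutions
make_array <- function(monomer, copies, divergence) {
  m <- nchar(monomer)
  paste(vapply(seq_len(copies), function(i) {
    mutate_dna(monomer, rbinom(1L, m, divergence))
  }, ""), collapse = "")
}

#' Build a synthetic genome with ground truth
#'
#' Deterministically (per seed) realizes a [genome_spec()]: monomer
#' sequences are generated once per genome from the seed (the telomere
#' 7-mer excepted, which is the fixed biological motif), arrays are tandem
#' monomer copies with per-copy substitutions at the divergence rate, and
#' every planted feature is recorded in a truth interval table (0-based
#' half-open) that downstream metrics use as their evaluation oracle.
#'
#' @param spec a [genome_spec()].
#' @return An object of class `SimulatedGenome`: `assembly` (an
#'   [assembly()]), `truth` (an [intervals()] table; LTR elements
#'   additionally emit per-terminal-repeat `ltr_tr` rows), and `monomers`
#'   (named character vector of the monomer sequences used).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  local_seed(spec$seed, {
    telo_len <- spec$telomere_units * nchar(TELOMERE_MOTIF)
    monomers <- c(
      vapply(spec$arrays, function(a) random_dna(a$monomer_len), ""),
      subtelomere = if (spec$subtelomere$copies > 0)
        random_dna(sample(seq(spec$subtelomere$monomer_min,
                              spec$subtelomere$monomer_max), 1L)) else "",
      telomere = TELOMERE_MOTIF
    )
    monomers <- monomers[nzchar(monomers)]

    seqs <- character(nrow(spec$chromosomes))
    truth <- list()
    for (ci in seq_len(nrow(spec$chromosomes))) {
      cname <- spec$chromosomes$name[ci]
      clen <- spec$chromosomes$length[ci]

      # features placed in the interior (between telomere/subtelomere ends)
      feats <- list()   # list of (label, seq, extra truth offset rows)
      for (i in seq_len(spec$genes$count)) {
        feats[[length(feats) + 1L]] <-
          list(label = "gene",
               seq = random_dna(sample(spec$genes$min_len:spec$genes$max_len,
                                       1L)))
      }
      for (i in seq_len(spec$ltr$count)) {
        tr0 <- random_dna(spec$ltr$tr_len)
        tr1 <- mutate_dna(tr0, rbinom(1L, nchar(tr0), spec$divergence))
        tr2 <- mutate_dna(tr0, rbinom(1L, nchar(tr0), spec$divergence))
        feats[[length(feats) + 1L]] <-
          list(label = "ltr",
               seq = paste0(tr1, random_dna(spec$ltr$internal_len), tr2),
               tr_len = spec$ltr$tr_len)
      }
      for (cls in names(spec$arrays)) {
        a <- spec$arrays[[cls]]
        for (i in seq_len(a$arrays)) {
          feats[[length(feats) + 1L]] <-
            list(label = cls,
                 seq = make_array(monomers[[cls]], a$copies, spec$divergence))
        }
      }

      # per-end realizations: same monomer, independent per-copy divergence
      sub_left <- if (spec$subtelomere$copies > 0)
        make_array(monomers[["subtelomere"]], spec$subtelomere$copies,
                   spec$divergence) else ""
      sub_right <- if (spec$subtelomere$copies > 0)
        make_array(monomers[["subtelomere"]], spec$subtelomere$copies,
                   spec$divergence) else ""
      telo_left <- strrep(TELOMERE_MOTIF_RC, spec$telomere_units)
      telo_right <- strrep(TELOMERE_MOTIF, spec$telomere_units)

      fixed_len <- 2 * telo_len + nchar(sub_left) + nchar(sub_right)
      feat_len <- sum(vapply(feats, function(f) nchar(f$seq), 0))
      free <- clen - fixed_len - feat_len
      if (free < length(feats) + 1L)
        stop(sprintf("planned features overfill chromosome %s (%d bp short)",
                     cname, (length(feats) + 1L) - free))

      # random non-overlapping layout: shuffle features, split the free
      # background into random gaps around them
      ord <- sample(seq_along(feats))
      feats <- feats[ord]
      w <- runif(length(feats) + 1L)
      gaps <- floor(w / sum(w) * free)
      gaps[length(gaps)] <- free - sum(gaps[-length(gaps)])

      pieces <- character(0)
      rows <- list()
      pos <- 0
      push <- function(seqpart, label = NULL, extra_tr = NULL) {
        pieces[[length(pieces) + 1L]] <<- seqpart
        if (!is.null(label))
          rows[[length(rows) + 1L]] <<-
            data.frame(chrom = cname, start = pos, end = pos + nchar(seqpart),
                       label = label, strand = ".")
        if (!is.null(extra_tr)) {
          rows[[length(rows) + 1L]] <<-
            data.frame(chrom = cname,
                       start = c(pos, pos + nchar(seqpart) - extra_tr),
                       end = c(pos + extra_tr, pos + nchar(seqpart)),
                       label = "ltr_tr", strand = ".")
        }
        pos <<- pos + nchar(seqpart)
      }
      if (telo_len > 0) push(telo_left, "telomere")
      if (nzchar(sub_left)) push(sub_left, "subtelomere")
      for (i in seq_along(feats)) {
        push(random_dna(gaps[i]))
        push(feats[[i]]$seq, feats[[i]]$label,
             extra_tr = feats[[i]]$tr_len)
      }
      push(random_dna(gaps[length(gaps)]))
      if (nzchar(sub_right)) push(sub_right, "subtelomere")
      if (telo_len > 0) push(telo_right, "telomere")

      seqs[ci] <- paste(pieces, collapse = "")
      stopifnot(nchar(seqs[ci]) == clen)
      truth[[ci]] <- do.call(rbind, rows)
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(match(truth$chrom, spec$chromosomes$name),
                         truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    asm <- assembly(stats::setNames(seqs, spec$chromosomes$name))
    structure(list(assembly = asm, truth = truth, monomers = monomers,
                   spec = spec),
              class = "SimulatedGenome")
  })
}

#' @export
print.SimulatedGenome <- function(x, ...) {
  cat(sprintf("SimulatedGenome: %d chromosomes, %.0f bp, %d truth features\n",
              length(x$assembly$seq), sum(Biostrings::width(x$assembly$seq)),
              nrow(x$truth)))
  invisible(x)
}

#' Write a simulated genome to FASTA + truth BED
#'
#' @param genome a [build_genome()] result.
#' @param fasta,bed output paths.
#' @export
write_genome <- function(genome, fasta, bed) {
  stopifnot(inherits(genome, "SimulatedGenome"))
  Biostrings::writeXStringSet(genome$assembly$seq, fasta)
  write_bed(genome$truth, bed)
  invisible(genome)
}
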