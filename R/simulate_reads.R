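#' Configure long-read simulation
#'
#' Read lengths follow a log-normal truncated below at `min_read`, whose
#' location parameter is numerically calibrated (root finding on the
#' closed-form tail-mass equation) so the distribution-level N50 equals
#' `target_n50`. The default shape `lognormal_sigma = 0.52` reproduces the
#' N25/N50 ratio (~1.42) typical of PacBio Sequel subread sets.
#'
#' @param depth target fold-coverage (> 0).
#' @param target_n50 desired read N50 in bp (>= `min_read`).
#' @param lognormal_sigma log-scale standard deviation of read lengths.
#' @param min_read minimum read length in bp.
#' @param substitution_rate per-base substitution error rate in \[0, 0.15\].
#' @param seed integer RNG seed.
#' @return An object of class `ReadSimConfig`.
#' @export
read_sim_config <- function(depth, target_n50, lognormal_sigma = 0.52,
                            min_read = 500, substitution_rate = 0,
                            seed = 1L) {
  assert_scalar_number(depth, "depth", min = .Machine$double.eps)
  assert_scalar_number(target_n50, "target_n50", min = 1)
  assert_scalar_number(lognormal_sigma, "lognormal_sigma", min = 0.01, max = 3)
  assert_scalar_number(min_read, "min_read", min = 1)
  assert_scalar_number(substitution_rate, "substitution_rate",
                       min = 0, max = 0.15)
  if (target_n50 < min_read)
    stop("target_n50 must be >= min_read")
  structure(list(depth = depth, target_n50 = target_n50,
                 lognormal_sigma = lognormal_sigma, min_read = min_read,
                 substitution_rate = substitution_rate, seed = seed),
            class = "ReadSimConfig")
}

# For lengths ~ LogNormal(mu, sigma) truncated at tmin, the N50 is the t*
# with E[X 1(X >= t*)] = 0.5 E[X 1(X >= tmin)], and
# E[X 1(X >= t)] = exp(mu + sigma^2/2) * pnorm((mu + sigma^2 - log t)/sigma).
# Solve for mu such that t* = target.
calibrate_meanlog <- function(target_n50, sigma, min_read) {
  f <- function(mu) {
    stats::pnorm((mu + sigma^2 - log(target_n50)) / sigma) -
      0.5 * stats::pnorm((mu + sigma^2 - log(min_read)) / sigma)
  }
  uniroot(f, lower = log(target_n50) - 6 * sigma^2 - 5,
          upper = log(target_n50) + 5, tol = 1e-10)$root
}

#' Simulate read lengths and positions over a genome
#'
#' Length-only workhorse behind [simulate_reads()]: start positions are
#' uniform over the genome, lengths are drawn from the calibrated
#' truncated log-normal, and reads are truncated at chromosome ends.
#' Reads accumulate until the base total crosses `depth * genome_size`
#' (crossing read included), so the total is within a read length of the
#' target.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param config a [read_sim_config()].
#' @return A length-only [read_set()]; each read's true origin is kept in
#'   attribute `origin` (data.frame `chrom`, `start` 0-based).
#' @export
simulate_read_lengths <- function(chrom_lengths, config) {
  stopifnot(inherits(config, "ReadSimConfig"))
  gsize <- sum(chrom_lengths)
  if (gsize < 1) stop("genome is empty")
  mu <- calibrate_meanlog(config$target_n50, config$lognormal_sigma,
                          config$min_read)
  target_bases <- config$depth * gsize
  local_seed(config$seed, {
    lens <- numeric(0); chrom <- integer(0); start <- numeric(0)
    total <- 0
    mean_len <- exp(mu + config$lognormal_sigma^2 / 2)
    while (total < target_bases) {
      n_chunk <- max(1000L, ceiling((target_bases - total) / mean_len * 1.1))
      l <- rlnorm(n_chunk, mu, config$lognormal_sigma)
      l <- round(l[l >= config$min_read])
      if (!length(l)) next
      ci <- sample.int(length(chrom_lengths), length(l), replace = TRUE,
                       prob = chrom_lengths / gsize)
      st <- floor(runif(length(l)) * chrom_lengths[ci])
      l <- pmin(l, chrom_lengths[ci] - st)   # truncate at chromosome end
      cs <- total + cumsum(l)
      k <- which(cs >= target_bases)[1L]
      if (!is.na(k)) { l <- l[seq_len(k)]; ci <- ci[seq_len(k)]
                       st <- st[seq_len(k)] }
      lens <- c(lens, l); chrom <- c(chrom, ci); start <- c(start, st)
      total <- total + sum(l)
    }
    rs <- read_set(sprintf("read%07d", seq_along(lens)), lens)
    attr(rs, "origin") <- data.frame(
      chrom = names(chrom_lengths)[chrom] %||% as.character(chrom),
      start = start, stringsAsFactors = FALSE)
    rs
  })
}

#' Simulate a long-read set from a genome
#'
#' Draws reads as uniform substrings of the genome with log-normal lengths
#' calibrated to the target N50 (see [read_sim_config()]); substitution
#' errors are applied at the configured rate. With `sequences = FALSE`
#' only ids/lengths/origins are materialized, which is much cheaper for
#' titration experiments where only the length distribution matters.
#'
#' @param genome a [build_genome()] result or an [assembly()].
#' @param config a [read_sim_config()].
#' @param sequences materialize read sequences? (default `TRUE`)
#' @return A [read_set()].
#' @export
simulate_reads <- function(genome, config, sequences = TRUE) {
  asm <- if (inherits(genome, "SimulatedGenome")) genome$assembly else genome
  stopifnot(inherits(asm, "Assembly"))
  cl <- stats::setNames(as.numeric(Biostrings::width(asm$seq)),
                        names(asm$seq))
  rs <- simulate_read_lengths(cl, config)
  if (!sequences) return(rs)
  origin <- attr(rs, "origin")
  n <- nrow(rs$reads)
  seqs <- vector("list", length(asm$seq))
  # extract all reads of one chromosome at once
  for (ci in seq_along(asm$seq)) {
    sel <- which(origin$chrom == names(asm$seq)[ci])
    if (!length(sel)) next
    v <- Biostrings::extractAt(
      asm$seq[[ci]],
      IRanges::IRanges(start = origin$start[sel] + 1,
                       width = rs$reads$length[sel]))
    seqs[[ci]] <- stats::setNames(as.character(v), rs$reads$id[sel])
  }
  flat <- unlist(seqs)
  flat <- flat[rs$reads$id]
  if (config$substitution_rate > 0) {
    local_seed(config$seed + 1L, {
      nmut <- rbinom(n, rs$reads$length, config$substitution_rate)
      idx <- which(nmut > 0)
      for (i in idx) flat[i] <- mutate_dna(flat[i], nmut[i])
    })
  }
  out <- read_set(rs$reads$id, rs$reads$length,
                  sequences = Biostrings::DNAStringSet(unname(flat)))
  attr(out, "origin") <- origin
  out
}
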