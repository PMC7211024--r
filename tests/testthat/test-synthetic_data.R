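test_that("planted arrays and telomeres appear with exact truth sizes", {
  spec <- genome_spec(
    chromosomes = data.frame(name = "c1", length = 1e5),
    genes = list(count = 0, min_len = 100, max_len = 200),
    ltr = list(count = 0, tr_len = 100, internal_len = 100),
    arrays = list(centc = list(monomer_len = 156, copies = 100, arrays = 1)),
    subtelomere = list(monomer_min = 300, monomer_max = 400, copies = 0),
    telomere_units = 50, divergence = 0, seed = 2L)
  g <- build_genome(spec)
  tr <- g$truth
  centc <- tr[tr$label == "centc", ]
  expect_equal(centc$end - centc$start, 100 * 156)

  s <- as.character(g$assembly$seq[[1]])
  expect_equal(substr(s, 1, 350), strrep("CCCTAAA", 50))
  expect_equal(substr(s, nchar(s) - 349, nchar(s)), strrep("TTTAGGG", 50))
  telo <- tr[tr$label == "telomere", ]
  expect_equal(telo$start, c(0, 1e5 - 350))
  expect_equal(telo$end, c(350, 1e5))

  # divergence 0: array is exact monomer copies
  arr_seq <- substr(s, centc$start + 1, centc$end)
  expect_equal(arr_seq, strrep(g$monomers[["centc"]], 100))
})

test_that("genome generation is deterministic and validates overfill", {
  fa1 <- tempfile(fileext = ".fa"); bed1 <- tempfile(fileext = ".bed")
  fa2 <- tempfile(fileext = ".fa"); bed2 <- tempfile(fileext = ".bed")
  write_genome(build_genome(small_spec(seed = 9L)), fa1, bed1)
  write_genome(build_genome(small_spec(seed = 9L)), fa2, bed2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(bed1), readLines(bed2))
  expect_false(identical(
    as.character(build_genome(small_spec(seed = 1L))$assembly$seq),
    as.character(build_genome(small_spec(seed = 2L))$assembly$seq)))

  spec <- small_spec()
  spec$chromosomes$length <- c(3e4, 3e4)   # too small for the plan
  expect_error(build_genome(spec), "overfill")
})

test_that("truth intervals respect chromosome bounds and LTR structure", {
  g <- build_genome(small_spec(seed = 4L))
  lens <- setNames(Biostrings::width(g$assembly$seq), names(g$assembly$seq))
  expect_true(all(g$truth$start >= 0))
  expect_true(all(g$truth$end <= lens[g$truth$chrom]))

  # at divergence 0 the two terminal repeats of each LTR are identical
  g0 <- build_genome(small_spec(seed = 5L, divergence = 0))
  trs <- g0$truth[g0$truth$label == "ltr_tr", ]
  expect_equal(nrow(trs), 2 * 2 * 2)  # 2 per element, 2 elements, 2 chroms
  for (i in seq(1, nrow(trs), by = 2)) {
    s <- as.character(g0$assembly$seq[[trs$chrom[i]]])
    expect_equal(substr(s, trs$start[i] + 1, trs$end[i]),
                 substr(s, trs$start[i + 1] + 1, trs$end[i + 1]))
  }
})

test_that("simulated reads meet depth, substring and N50 contracts", {
  g <- build_genome(genome_spec(
    chromosomes = data.frame(name = "c1", length = 1e6),
    seed = 3L))
  cfg <- read_sim_config(depth = 20, target_n50 = 12000, seed = 8L)
  rs <- simulate_reads(g, cfg, sequences = FALSE)
  expect_gte(rs$total_bases, 19.6e6)
  expect_lte(rs$total_bases, 20.4e6)

  # substitution_rate 0: every read is an exact substring of the genome
  small <- assembly(c(x = random_dna_str(50000)))
  cfg2 <- read_sim_config(depth = 3, target_n50 = 3000, min_read = 300,
                          seed = 2L)
  rs2 <- simulate_reads(small, cfg2)
  origin <- attr(rs2, "origin")
  xs <- as.character(small$seq[[1]])
  for (i in seq_len(nrow(rs2$reads))) {
    expect_identical(as.character(rs2$seq[[i]]),
                     substr(xs, origin$start[i] + 1,
                            origin$start[i] + rs2$reads$length[i]))
  }

  # substitutions change about the right number of bases
  cfg3 <- read_sim_config(depth = 3, target_n50 = 3000, min_read = 300,
                          substitution_rate = 0.1, seed = 2L)
  rs3 <- simulate_reads(small, cfg3)
  expect_identical(rs3$reads, rs2$reads)  # same lengths/positions
  mism <- sum(vapply(seq_len(nrow(rs3$reads)), function(i)
    Biostrings::neditAt(rs2$seq[[i]], rs3$seq[[i]]), 0L))
  expect_gt(mism / rs3$total_bases, 0.08)
  expect_lt(mism / rs3$total_bases, 0.12)
})

test_that("read-length calibration hits the target N50 within 5%", {
  cfg <- read_sim_config(depth = 30, target_n50 = 20000, seed = 21L)
  rs <- simulate_read_lengths(c(g = 1e7), cfg)
  realized <- oracle_n50(rs$reads$length)
  expect_gte(realized, 19000)
  expect_lte(realized, 21000)
})

test_that("zero-rate degradation is the identity", {
  g <- build_genome(small_spec(seed = 6L))
  deg <- degrade_assembly(g, degrade_config(0, 0, seed = 3L))
  expect_identical(as.character(deg$assembly$seq),
                   as.character(g$assembly$seq))
  expect_true(all(deg$retained$retained_bp == deg$retained$original_bp))
})

test_that("remove policy yields N-free contigs; ngap conserves bases", {
  g <- build_genome(small_spec(seed = 6L))
  cfg <- degrade_config(4, 30, drop_fraction = 0.3, gap_policy = "remove",
                        seed = 5L)
  deg <- degrade_assembly(g, cfg)
  expect_equal(sum(Biostrings::letterFrequency(deg$assembly$seq, "N")), 0)

  cfg_n <- degrade_config(4, 30, drop_fraction = 0.3, gap_policy = "ngap",
                          seed = 5L)
  deg_n <- degrade_assembly(g, cfg_n)
  # per scaffold: retained (non-N) bases + deleted bases = original length
  for (cn in names(g$assembly$seq)) {
    kept <- sum(Biostrings::width(deg_n$assembly$seq[cn])) -
      sum(Biostrings::letterFrequency(deg_n$assembly$seq[cn], "N"))
    d <- deg_n$deletions[deg_n$deletions$chrom == cn, ]
    expect_equal(kept + sum(d$end - d$start),
                 Biostrings::width(g$assembly$seq)[[
                   match(cn, names(g$assembly$seq))]])
  }
})

test_that("repeat-biased breaks remove more array than gene sequence", {
  g <- build_genome(small_spec(seed = 7L))
  arr_classes <- c("knob180", "tr1", "centc")
  frac <- function(deg, classes) {
    r <- deg$retained[deg$retained$label %in% classes, ]
    sum(r$retained_bp) / sum(r$original_bp)
  }
  arr_fr <- gene_fr <- numeric(20)
  for (s in 1:20) {
    deg <- degrade_assembly(g, degrade_config(
      breaks_per_mb_unique = 2, breaks_per_mb_repeat = 60,
      drop_fraction = 0.4, seed = 100L + s))
    arr_fr[s] <- frac(deg, arr_classes)
    gene_fr[s] <- frac(deg, "gene")
  }
  expect_lt(mean(arr_fr), mean(gene_fr))
})

test_that("raising the repeat break rate never raises retained array bp", {
  g <- build_genome(small_spec(seed = 8L))
  arr_classes <- c("knob180", "tr1", "centc")
  for (s in 1:5) {
    prev <- Inf
    for (rate in c(5, 20, 80)) {
      deg <- degrade_assembly(g, degrade_config(
        breaks_per_mb_unique = 2, breaks_per_mb_repeat = rate,
        drop_fraction = 0.4, seed = 200L + s))
      cur <- sum(deg$retained$retained_bp[deg$retained$label %in% arr_classes])
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})
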