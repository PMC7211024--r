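test_that("exact tandem copies yield contiguous full-identity hits", {
  set.seed(41)
  mono <- random_dna_str(156)
  asm <- assembly(c(c1 = strrep(mono, 10)))
  hits <- scan_monomer_hits(asm, mono, class = "centc")
  expect_equal(nrow(hits), 10)
  expect_true(all(hits$identity == 1))
  expect_equal(hits$start, seq(0, 9) * 156)
  expect_equal(hits$end, seq(1, 10) * 156)

  # monomer absent
  expect_equal(nrow(scan_monomer_hits(asm, random_dna_str(156))), 0)
})

test_that("diverged copies are found with bounded identity loss", {
  set.seed(43)
  mono <- random_dna_str(156)
  # exactly 7 substitutions per copy: any monomer-length window overlaps
  # at most 2 copies, so identity >= 1 - 14/156 = 0.910
  asm <- assembly(c(c1 = noisy_array(mono, 10, 7)))
  hits <- scan_monomer_hits(asm, mono, class = "centc")
  expect_equal(nrow(hits), 10)
  expect_true(all(hits$identity >= 0.9))
})

test_that("rotated and reverse-complemented arrays are detected", {
  set.seed(47)
  mono <- random_dna_str(180)
  rot <- paste0(substr(mono, 61, 180), substr(mono, 1, 60))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mono)))
  asm <- assembly(c(f = strrep(rot, 5), r = strrep(rc, 5)))
  hits <- scan_monomer_hits(asm, mono)
  expect_equal(sum(hits$chrom == "f"), 5)
  expect_equal(sum(hits$chrom == "r"), 5)
  expect_true(all(hits$identity == 1))
})

test_that("array clustering brackets the 100-kb interspace threshold", {
  h2 <- intervals(c("c", "c"), c(0, 180), c(180, 360), label = "knob180")
  h2$identity <- 1
  cl <- cluster_arrays(h2)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(0, 360))

  # interspace 99,640 (< 100 kb) merges
  hm <- intervals(c("c", "c"), c(0, 100000), c(360, 100180), "knob180")
  expect_equal(nrow(cluster_arrays(hm)), 1)
  # interspace 100,140 (>= 100 kb) splits
  hs <- intervals(c("c", "c"), c(0, 100500), c(360, 100680), "knob180")
  expect_equal(nrow(cluster_arrays(hs)), 2)
  # exactly 100,000 splits (rule is "less than 100 kb" joins)
  he <- intervals(c("c", "c"), c(0, 100360), c(360, 100540), "knob180")
  expect_equal(nrow(cluster_arrays(he)), 2)

  # different chromosomes never merge
  hc <- intervals(c("c1", "c2"), c(0, 0), c(180, 180), "knob180")
  expect_equal(nrow(cluster_arrays(hc)), 2)

  # idempotent and order-independent
  set.seed(3)
  hr <- intervals("c", seq(0, 40) * 200, seq(0, 40) * 200 + 180, "knob180")
  shuf <- hr[sample(nrow(hr)), ]
  expect_equal(cluster_arrays(hr), cluster_arrays(shuf))
})

test_that("array quantification conserves span bases", {
  # constructed accounting: 10-kb span, 6,000 hit bp, 1,300 N
  set.seed(53)
  seqs <- paste0(random_dna_str(4000), strrep("N", 1300),
                 random_dna_str(4700))
  asm <- assembly(c(c1 = seqs))
  hits <- intervals("c1", c(0, 7000), c(3000, 10000), label = "x")
  span <- list(chrom = "c1", start = 0, end = 10000, label = "x")
  q <- quantify_array(span, hits, asm)
  expect_equal(q$repeat_bp, 6000)
  expect_equal(q$gap_bp, 1300)
  expect_equal(q$other_bp, 2700)

  # completeness on a synthetic analog of a partly assembled 5-Mb knob
  q2 <- quantify_array(span, intervals("c1", 0, 325000 / 100, "x"),
                       assembly(c(c1 = random_dna_str(10000))),
                       truth_size = 50000)
  expect_equal(q2$completeness_pct, 6.5)

  # conservation on scanned fixtures
  g <- build_genome(small_spec(seed = 11L))
  deg <- degrade_assembly(g, degrade_config(4, 40, 0.3, "ngap", seed = 3L))
  hits_k <- scan_monomer_hits(deg$assembly, g$monomers[["knob180"]],
                              class = "knob180")
  arr <- cluster_arrays(hits_k)
  for (i in seq_len(nrow(arr))) {
    qq <- quantify_array(arr[i, ], hits_k, deg$assembly)
    expect_equal(qq$repeat_bp + qq$gap_bp + qq$other_bp,
                 arr$end[i] - arr$start[i])
  }
})

test_that("telomere motifs are counted exactly, both strands, N excluded", {
  expect_equal(count_telomere_motifs(strrep("TTTAGGG", 10)), 10)
  expect_equal(count_telomere_motifs("CCCTAAA"), 1)
  expect_equal(count_telomere_motifs("TTTAGGGNTTTAGGG"), 2)
  expect_equal(count_telomere_motifs("ACGTACGTACGT"), 0)
  # mixed-strand fixture
  expect_equal(count_telomere_motifs(paste0(strrep("TTTAGGG", 3), "AC",
                                            strrep("CCCTAAA", 2))), 5)
})

test_that("telomere counting is reverse-complement symmetric", {
  set.seed(59)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T", "N", "TTTAGGG", "CCCTAAA"),
                      sample(5:30, 1), replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    expect_identical(count_telomere_motifs(s), count_telomere_motifs(rc))
  }
})

test_that("subtelomere boundaries sit at the terminal cluster edge", {
  set.seed(61)
  mono <- random_dna_str(400)
  sub_arr <- strrep(mono, 12)                    # 4,800 bp subtelomere
  telo <- strrep("TTTAGGG", 150)                 # 1,050 bp telomere
  chrom <- paste0(random_dna_str(10000), sub_arr, telo)   # right end
  asm <- assembly(c(c1 = chrom))
  hits <- scan_monomer_hits(asm, mono, class = "subtelomere")
  b <- detect_subtelomere_boundary(asm, "c1", hits, end = "right",
                                   terminal_window = 8000)
  expect_false(is.null(b))
  # innermost edge of the terminal cluster, within one monomer of 10,000
  expect_lte(abs(b$boundary - 10000), 400)
  # telomere region = cluster outer edge to chromosome end
  expect_lte(abs(b$telomere_bp - 1050), 400)
  expect_equal(b$motif_count, count_telomere_motifs(
    substr(chrom, nchar(chrom) - b$telomere_bp + 1, nchar(chrom))))

  # no subtelomere near the left end: absent
  expect_null(detect_subtelomere_boundary(asm, "c1", hits, end = "left",
                                          terminal_window = 8000))
  # hits only in the middle: absent at both ends
  mid <- paste0(random_dna_str(20000), strrep(mono, 5), random_dna_str(20000))
  asm_mid <- assembly(c(c1 = mid))
  hits_mid <- scan_monomer_hits(asm_mid, mono, class = "subtelomere")
  expect_null(detect_subtelomere_boundary(asm_mid, "c1", hits_mid,
                                          end = "left",
                                          terminal_window = 5000))
  expect_null(detect_subtelomere_boundary(asm_mid, "c1", hits_mid,
                                          end = "right",
                                          terminal_window = 5000))
})

test_that("flank-located loci reproduce 1-based coordinate arithmetic", {
  set.seed(67)
  chrom <- random_dna_str(400000)
  # plant a 289,103-bp locus: 1-based [50,001 .. 339,103]
  lf <- substr(chrom, 50001, 52000)
  rf <- substr(chrom, 337104, 339103)
  asm <- assembly(c(chr9 = chrom))
  lm <- locate_locus_by_flanks(asm, lf, rf)
  expect_true(lm$found)
  expect_equal(lm$start_1based, 50001)
  expect_equal(lm$end_1based, 339103)
  expect_equal(lm$length_bp, 289103)
  expect_equal(lm$strand, "+")

  # reverse-complemented assembly: same locus length on the minus strand
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chrom)))
  lm_rc <- locate_locus_by_flanks(assembly(c(chr9 = rc)), lf, rf)
  expect_true(lm_rc$found)
  expect_equal(lm_rc$strand, "-")
  expect_equal(lm_rc$length_bp, 289103)

  # missing right flank: not-found with diagnostics
  lm_na <- locate_locus_by_flanks(asm, lf, random_dna_str(2000))
  expect_false(lm_na$found)
  expect_true(any(lm_na$diagnostics$flank == "left"))
})

test_that("locus_match computes 1-based inclusive lengths", {
  expect_equal(locus_match("chr9", 11625031, 11914133)$length_bp, 289103)
  expect_error(locus_match("c", 10, 5))
})

test_that("monomer library validates its entries", {
  expect_error(monomer_library(c("ACGTT")), "named")
  expect_error(monomer_library(c(x = "ACG")), ">= 5")
  expect_error(monomer_library(c(x = "ACGNN")), "A/C/G/T")
  ml <- monomer_library(c(centc = "acgtacgt"))
  expect_equal(unname(ml["centc"]), "ACGTACGT")
})
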