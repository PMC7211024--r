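test_that("NG(x) takes the contig at x% of the genome-size estimate", {
  expect_equal(ngx(c(500, 400, 300), 1000, 50), 500)
  expect_equal(ngx(c(500, 400, 300), 1000, 90), 400)
  expect_true(is.na(ngx(c(500, 400, 300), 2000, 90)))  # total short of 90%
  expect_true(is.na(ngx(numeric(0), 1000, 50)))

  # NG50 against the assembly total is exactly N50
  set.seed(5)
  for (i in 1:20) {
    l <- sample(1e3:1e6, sample(4:100, 1), replace = TRUE)
    expect_equal(ngx(l, sum(l), 50), oracle_n50(l))
  }
})

test_that("assembled percentage and coverage folds match printed arithmetic", {
  expect_equal(assembled_pct(1.60e9, 2.2724e9), 70.4)
  expect_equal(assembled_pct(2.13e9, 2.2724e9), 93.7)
  expect_equal(assembled_pct(5e6, 5e6), 100.0)

  expect_equal(coverage_fold(25.11e9, 2.2724e9), 11)
  expect_equal(coverage_fold(45.62e9, 2.2724e9), 20)
  expect_equal(coverage_fold(7e7, 7e7), 1)
})

test_that("gap percentage pools N bases over scaffolds", {
  a1 <- assembly(c(s = paste0(random_dna_str(87), strrep("N", 13))))
  expect_equal(gap_pct(a1), 13.0)
  expect_equal(gap_pct(assembly(c(s = random_dna_str(100)))), 0.0)
  a2 <- assembly(c(s1 = paste0(random_dna_str(75), strrep("N", 25)),
                   s2 = random_dna_str(100)))
  expect_equal(gap_pct(a2), 12.5)
})

test_that("effective size counts k-mers occurring exactly once", {
  set.seed(31)
  s <- random_dna_str(200)
  a <- assembly(c(s = s))
  expect_equal(effective_size(a, k = 150), oracle_unique_kmers(s, 150))
  expect_equal(effective_size(a, k = 150), 51)  # all 51 windows distinct

  hp <- assembly(c(s = strrep("A", 200)))
  expect_equal(effective_size(hp, k = 150), 0)

  dup <- assembly(c(s = paste0(s, s)))        # S+S: nothing inside S unique
  expect_equal(effective_size(dup, k = 150),
               oracle_unique_kmers(paste0(s, s), 150))
})

test_that("effective size agrees with the exhaustive oracle incl. N and rc", {
  set.seed(37)
  scaf1 <- paste0(random_dna_str(400), strrep("N", 13), random_dna_str(300))
  core <- random_dna_str(250)
  scaf2 <- paste0(core, random_dna_str(50), core)  # internal duplication
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(core)))
  scaf3 <- paste0(rc, random_dna_str(120))
  a <- assembly(c(a = scaf1, b = scaf2, c = scaf3))
  for (k in c(5, 31, 150)) {
    expect_equal(effective_size(a, k = k),
                 oracle_unique_kmers(c(scaf1, scaf2, scaf3), k),
                 info = sprintf("k=%d", k))
    expect_equal(effective_size(a, k = k, canonical = TRUE),
                 oracle_unique_kmers(c(scaf1, scaf2, scaf3), k,
                                     canonical = TRUE),
                 info = sprintf("canonical k=%d", k))
  }
  expect_equal(effective_size(assembly(c(s = random_dna_str(60))), 150), 0)
})

test_that("contiguity report assembles the per-condition statistics", {
  g <- build_genome(small_spec(seed = 10L))
  deg <- degrade_assembly(g, degrade_config(4, 30, 0.3, "ngap", seed = 2L))
  cr <- contiguity_report(deg$assembly, k = 31)
  ctg <- split_into_contigs(deg$assembly)$contig_lengths
  expect_equal(cr$contig_count, length(ctg))
  expect_equal(cr$n50, oracle_n50(ctg))
  expect_gte(cr$longest_bp, cr$n50)
  expect_lte(cr$effective_size_bp, cr$total_bp)
  expect_equal(cr$assembled_pct, assembled_pct(sum(ctg), 4e5))
})
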