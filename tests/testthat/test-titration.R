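test_that("length statistics follow the descending-cumulative definition", {
  st <- length_stats(c(2, 2, 2, 3, 3))
  expect_equal(st$n50, 3)   # cumulative 3, 6 >= 6 (half of 12)
  expect_equal(st$total, 12)

  st1 <- length_stats(77)
  expect_equal(c(st1$n25, st1$n50, st1$max), c(77, 77, 77))

  expect_equal(length_stats(c(10, 10, 10, 10))$n50, 10)
  expect_error(length_stats(numeric(0)), "non-empty")

  set.seed(3)
  for (i in 1:20) {
    l <- sample(1e3:1e5, sample(5:200, 1), replace = TRUE)
    st <- length_stats(l)
    expect_gte(st$n25, st$n50)
    expect_gte(st$max, st$n25)
    expect_equal(st$n50, oracle_n50(l))
  }
})

test_that("serial titration nests subsets and hits exact counts on equal lengths", {
  rs <- read_set(sprintf("r%04d", 1:1000), rep(1000, 1000))
  tit <- serial_downsample(rs, c(2, 1), genome_size = 1e5, seed = 5L)
  expect_equal(nrow(tit$subsets[[1]]$reads), 200)
  expect_equal(nrow(tit$subsets[[2]]$reads), 100)
  expect_true(all(tit$subsets[[2]]$reads$id %in% tit$subsets[[1]]$reads$id))

  # repeated seeded run is identical
  tit2 <- serial_downsample(rs, c(2, 1), genome_size = 1e5, seed = 5L)
  expect_identical(tit$subsets[[1]]$reads, tit2$subsets[[1]]$reads)
  expect_identical(tit$subsets[[2]]$reads, tit2$subsets[[2]]$reads)

  # requesting the full depth returns the entire set
  full <- serial_downsample(rs, 10, genome_size = 1e5, seed = 1L)
  expect_setequal(full$subsets[[1]]$reads$id, rs$reads$id)
})

test_that("serial titration validates its preconditions", {
  rs <- read_set(c("a", "b"), c(100, 100))
  expect_error(serial_downsample(rs, c(1, 2), 100, seed = 1),
               "descending")
  expect_error(serial_downsample(rs, 5, 100, seed = 1), "exceeds")
})

test_that("distribution shifting fulfils a feasible target multiset exactly", {
  set.seed(13)
  lens <- round(rlnorm(400, log(8000), 0.5))
  rs <- read_set(sprintf("r%03d", seq_along(lens)), lens)

  # source lengths equal the target multiset: zero-clip identity
  sh <- match_length_distribution(rs, lens, seed = 2L)
  expect_equal(length(sh$skipped_lengths), 0)
  expect_equal(sort(sh$reads$reads$length), sort(lens))

  # feasible shrunken targets fulfilled exactly, N50 matched exactly
  targets <- round(sample(lens, 200) * 0.6)
  sh2 <- match_length_distribution(rs, targets, seed = 3L)
  expect_equal(length(sh2$skipped_lengths), 0)
  expect_equal(sort(sh2$reads$reads$length), sort(targets))
  expect_equal(length_stats(sh2$reads$reads$length)$n50,
               length_stats(targets)$n50)
})

test_that("single-read clipping trace reuses the remnant", {
  rs <- read_set("big", 100000)
  sh <- match_length_distribution(rs, c(60000, 30000), seed = 1L,
                                  min_remnant = 1000)
  expect_equal(sh$reads$reads$length, c(60000, 30000))
  expect_equal(sh$reads$reads$source_id, c("big", "big"))
  expect_equal(sh$reads$reads$source_offset, c(0, 60000))
  expect_equal(sh$pool_lengths, 10000)
  expect_equal(length(sh$skipped_lengths), 0)
})

test_that("infeasible targets are skipped and reported", {
  rs <- read_set("only", 50000)
  sh <- match_length_distribution(rs, c(60000, 40000), seed = 1L)
  expect_equal(sh$reads$reads$length, 40000)
  expect_equal(sh$skipped_lengths, 60000)
})

test_that("every shifted read is a contiguous substring of its source", {
  set.seed(17)
  n <- 60
  lens <- round(rlnorm(n, log(3000), 0.5))
  seqs <- vapply(lens, random_dna_str, "")
  rs <- read_set(sprintf("s%02d", 1:n), lens, sequences = seqs)
  targets <- round(sample(lens, 30) * 0.5)
  sh <- match_length_distribution(rs, targets, seed = 4L, min_remnant = 200)
  expect_equal(length(sh$skipped_lengths), 0)
  r <- sh$reads$reads
  for (i in seq_len(nrow(r))) {
    src <- seqs[match(r$source_id[i], rs$reads$id)]
    expect_identical(as.character(sh$reads$seq[[i]]),
                     substr(src, r$source_offset[i] + 1,
                            r$source_offset[i] + r$length[i]))
  }
  expect_lte(sh$reads$total_bases, rs$total_bases)
})

test_that("feasible log-normal shifts rarely skip targets across seeds", {
  set.seed(23)
  lens <- round(rlnorm(2000, log(9000), 0.5))
  rs <- read_set(sprintf("r%04d", seq_along(lens)), lens)
  # target total ~60% of source total, target max below source max
  skipped <- vapply(1:20, function(s) {
    targets <- round(sample(lens, 1500) * 0.8)
    length(match_length_distribution(rs, targets,
                                     seed = 1000L + s)$skipped_lengths)
  }, 0)
  expect_gte(mean(skipped == 0), 0.95)
})
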