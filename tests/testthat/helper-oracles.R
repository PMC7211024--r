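# Independent oracles used to freeze expected values; deliberately naive.

# brute-force unique k-mer count: hash every window as a string
oracle_unique_kmers <- function(seqs, k, canonical = FALSE) {
  seqs <- toupper(as.character(seqs))
  kmers <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    w <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    w <- w[!grepl("[^ACGT]", w)]
    if (canonical) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(w)))
      w <- pmin(w, rc)
    }
    kmers <- c(kmers, w)
  }
  sum(table(kmers) == 1L)
}

# descending-cumulative N50 by direct enumeration
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= sum(s) / 2)[1]]
}

# two-sample Kolmogorov-Smirnov distance on raw values
ks_distance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tandem array of a monomer with exactly n_sub substitutions per copy
noisy_array <- function(monomer, copies, n_sub) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(copies), function(i) {
    ch <- strsplit(monomer, "")[[1]]
    for (p in sample(length(ch), n_sub)) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
    paste(ch, collapse = "")
  }, ""), collapse = "")
}

# small genome spec used across tests: two 200-kb chromosomes with all
# feature classes at reduced copy numbers
small_spec <- function(seed = 1L, divergence = 0.05) {
  genome_spec(
    chromosomes = data.frame(name = c("chrA", "chrB"),
                             length = c(2e5, 2e5)),
    genes = list(count = 6, min_len = 2000, max_len = 5000),
    ltr = list(count = 2, tr_len = 600, internal_len = 2000),
    arrays = list(
      knob180 = list(monomer_len = 180, copies = 40, arrays = 1),
      tr1 = list(monomer_len = 350, copies = 20, arrays = 1),
      centc = list(monomer_len = 156, copies = 50, arrays = 1)),
    subtelomere = list(monomer_min = 300, monomer_max = 500, copies = 10),
    telomere_units = 30,
    divergence = divergence,
    seed = seed)
}
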