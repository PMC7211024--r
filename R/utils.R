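# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so generators are pure
# functions of (arguments, seed).
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Random DNA as a single string; intToUtf8 avoids a per-base character vector.
random_dna <- function(n) {
  if (n <= 0L) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# Substitute `n_sub` random positions of `seq` (a character scalar) with a
# different base; positions sampled without replacement.
mutate_dna <- function(seq, n_sub) {
  if (n_sub <= 0L) return(seq)
  n <- nchar(seq)
  n_sub <- min(n_sub, n)
  pos <- sample.int(n, n_sub)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(bases, chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(min), format(max)), call. = FALSE)
  invisible(x)
}
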