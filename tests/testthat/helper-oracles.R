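# Independent brute-force oracles. These deliberately use different code
# paths (character vectors, explicit loops, enumeration) from the package.

# naive shift-by-one motif scan: 0-based offsets of exact matches
oracle_scan <- function(sequence, motif) {
  m <- nchar(motif)
  L <- nchar(sequence)
  if (L < m) return(integer(0))
  starts <- seq_len(L - m + 1)
  hits <- starts[substring(sequence, starts, starts + m - 1) == motif]
  as.integer(hits) - 1L
}

# naive promoter window by character indexing; tss0 is 0-based
oracle_window <- function(src, tss0, strand, upstream = 1000,
                          downstream = 100) {
  chars <- strsplit(src, "")[[1]]
  if (strand == "+") {
    idx <- (tss0 - upstream):(tss0 + downstream)
  } else {
    idx <- (tss0 - downstream):(tss0 + upstream)
  }
  idx <- idx[idx >= 0 & idx < length(chars)]
  win <- chars[idx + 1]
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    win <- rev(unname(comp[win]))
  }
  paste(win, collapse = "")
}

# ordinary pooled-variance two-sample t (independently coded)
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  tt <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

# exhaustive enumeration of the one-sided hypergeometric tail:
# population of fg_total + bg_total sequences of which `carriers` carry
# the motif; draw fg_total; p = P[carriers in draw >= fg_with]
oracle_hyper_enum <- function(fg_with, fg_total, bg_with, bg_total) {
  N <- fg_total + bg_total
  K <- fg_with + bg_with
  draws <- utils::combn(N, fg_total)
  carriers_in_draw <- colSums(draws <= K)  # items 1..K are the carriers
  mean(carriers_in_draw >= fg_with)
}

# random DNA string
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
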