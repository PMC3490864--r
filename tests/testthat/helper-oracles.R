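# Independent oracles used by the tests. These deliberately re-derive
# results through different code paths (pure R, regexes, enumeration)
# than the package implementation.

# Pure-R three-state affine-gap global alignment score (end gaps
# penalised; gap of length L costs open + (L-1)*extend). Score only, no
# traceback; independent of the compiled implementation.
align_score_dp <- function(a, b, sub = gonnet250(), open = 10, ext = 0.05) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1)
  Ia <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  Ib <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  M[1, 1] <- 0
  if (m > 0) Ia[1, 2:(m + 1)] <- -(open + (seq_len(m) - 1) * ext)
  if (n > 0) Ib[2:(n + 1), 1] <- -(open + (seq_len(n) - 1) * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[A[i], B[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], Ia[i, j], Ib[i, j])
      Ia[i + 1, j + 1] <- max(M[i + 1, j] - open, Ia[i + 1, j] - ext,
                              Ib[i + 1, j] - open)
      Ib[i + 1, j + 1] <- max(M[i, j + 1] - open, Ib[i, j + 1] - ext,
                              Ia[i, j + 1] - open)
    }
  }
  max(M[n + 1, m + 1], Ia[n + 1, m + 1], Ib[n + 1, m + 1])
}

# Literal exhaustive enumeration over every gapped alignment (for tiny
# sequences): recurses over the three moves, scoring gaps by whether the
# previous move was the same gap type.
align_score_enum <- function(a, b, sub = gonnet250(), open = 10, ext = 0.05) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      best <- max(best, sub[A[i], B[j]] + rec(i + 1, j + 1, "M"))
    }
    if (j <= length(B)) {  # gap in a
      cost <- if (identical(prev, "Ia")) ext else open
      best <- max(best, -cost + rec(i, j + 1, "Ia"))
    }
    if (i <= length(A)) {  # gap in b
      cost <- if (identical(prev, "Ib")) ext else open
      best <- max(best, -cost + rec(i + 1, j, "Ib"))
    }
    best
  }
  rec(1, 1, "start")
}

# Double-regex sequon oracle: overlapping matches via lookahead.
sequon_oracle <- function(seq) {
  count <- function(pattern) {
    hits <- gregexpr(pattern, seq, perl = TRUE)[[1]]
    sum(hits > 0)
  }
  list(n_sequons = count("N(?=[^P][ST])"), n_NP = count("N(?=P)"),
       total_N = count("N"), total_P = count("P"),
       total_residues = nchar(seq))
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                      "I", "K", "L", "M", "N", "P", "Q",
                                      "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small fixture helpers ------------------------------------------------------

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

write_tmp_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

make_linker_set <- function(seqs, label = "test",
                            ids = paste0("L", seq_along(seqs))) {
  linker_set(id = ids, seq = seqs, label = label)
}
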