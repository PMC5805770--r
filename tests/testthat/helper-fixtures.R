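# Shared fixture builders. Everything is generated in code at test time.

rand_reads <- function(n, L, distinct = TRUE) {
  out <- replicate(n, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                            collapse = ""))
  if (distinct) out <- unique(out)
  out
}

# Fully naive rep(v) oracle: nested loops over pairs and overlap lengths,
# independent of both the builder and the vectorised brute_rep_table.
naive_rep_table <- function(reads, K) {
  n <- length(reads)
  L <- nchar(reads[1])
  out <- integer(n)
  for (v in seq_len(n)) {
    best <- 0L
    for (u in seq_len(n)) {
      if (u == v) next
      if (K > L - 1) next
      for (l in (L - 1):K) {
        if (l <= best) break
        if (substring(reads[u], L - l + 1, L) == substring(reads[v], 1, l)) {
          best <- l
          break
        }
      }
    }
    out[v] <- if (best > 0) L - best else L
  }
  out
}

# Inject N symbols into randomly chosen reads (for codec fixtures).
inject_ns <- function(reads, n_reads = 5L, max_per_read = 3L) {
  L <- nchar(reads[1])
  idx <- sample(length(reads), min(n_reads, length(reads)))
  for (i in idx) {
    pos <- sample(L, sample.int(max_per_read, 1))
    x <- strsplit(reads[i], "")[[1]]
    x[pos] <- "N"
    reads[i] <- paste0(x, collapse = "")
  }
  reads
}
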