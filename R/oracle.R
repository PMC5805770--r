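#' Brute-force per-read representation costs
#'
#' For each distinct read `v`, computes `rep(v)`: the minimum achievable
#' edge weight over all candidate parents, i.e. `L` minus the longest exact
#' suffix-prefix overlap (of length at least `K`) between any other read
#' and `v`, or `L` when no such overlap exists. The sum of `rep(v)` over
#' all reads is a lower bound on the total weight of any read forest with
#' minimum overlap `K`, and the greedy builder attains it on error-free
#' reads.
#'
#' This is a deliberately naive reference implementation, independent of
#' the forest builder's indexed search: every overlap length from `L-1`
#' down to `K` is scanned directly by substring equality over all reads.
#'
#' @param reads character vector of *distinct* equal-length reads.
#' @param K minimum overlap length.
#' @return integer vector of `rep(v)`, named by read.
#' @export
brute_rep_table <- function(reads, K) {
  if (anyDuplicated(reads)) stop("reads must be distinct")
  n <- length(reads)
  if (n == 0) return(integer(0))
  L <- nchar(reads[1])
  if (any(nchar(reads) != L)) stop("reads must have equal length")
  if (K < 1 || K > L) stop("K must satisfy 1 <= K <= L")
  best <- integer(n)
  for (l in seq(L - 1L, K)) { # l = L needs u == v, excluded by distinctness
    if (l < K) break
    pre <- substring(reads, 1L, l)
    suf <- substring(reads, L - l + 1L, L)
    lev <- unique(suf)
    cnt <- tabulate(match(suf, lev), nbins = length(lev))
    hits <- cnt[match(pre, lev)]
    hits[is.na(hits)] <- 0L
    hits <- hits - as.integer(suf == pre) # a read's own suffix does not count
    sel <- best == 0L & hits >= 1L
    best[sel] <- l
  }
  out <- ifelse(best > 0L, L - best, L)
  names(out) <- reads
  out
}

perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- perms(n - 1L)
  out <- matrix(0L, nrow(p) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    out[r + seq_len(nrow(p)), ] <- cbind(rep(i, nrow(p)), p + (p >= i))
    r <- r + nrow(p)
  }
  out
}

#' Brute-force shortest common superstring length
#'
#' Exact minimum superstring length by enumerating all permutations of the
#' reads and merging consecutive reads with their maximal exact overlap.
#' Reads contained in another read are removed first (required for the
#' permutation-merge formulation to be exact); distinct equal-length reads
#' are automatically substring-free. Limited to `n <= 8` reads.
#'
#' @param reads character vector of distinct reads.
#' @return integer superstring length.
#' @export
brute_scs_length <- function(reads) {
  if (anyDuplicated(reads)) stop("reads must be distinct")
  n <- length(reads)
  if (n > 8) stop("brute_scs_length enumerates permutations; n must be <= 8")
  if (n == 0) return(0L)
  # containment pruning (distinct equal-length reads are substring-free,
  # but strictly shorter reads contained in a longer one must be removed)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (keep[i] && nchar(reads[i]) < nchar(reads[j]) &&
        grepl(reads[i], reads[j], fixed = TRUE))
      keep[i] <- FALSE
  reads <- reads[keep]
  n <- length(reads)
  if (n == 1) return(nchar(reads))
  max_overlap <- function(a, b) {
    la <- nchar(a)
    lmax <- min(la, nchar(b)) - 1L
    if (lmax >= 1L)
      for (l in lmax:1L)
        if (substring(a, la - l + 1L, la) == substring(b, 1L, l)) return(l)
    0L
  }
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) ov[i, j] <- max_overlap(reads[i], reads[j])
  pm <- perms(n)
  saved <- rep(0L, nrow(pm))
  for (t in seq_len(n - 1L))
    saved <- saved + ov[cbind(pm[, t], pm[, t + 1L])]
  sum(nchar(reads)) - max(saved)
}

#' Multiset equality of two read sets
#'
#' `TRUE` iff the two sequence multisets are identical irrespective of
#' order.
#'
#' @param a,b [read_set()] objects or character vectors.
#' @return logical.
#' @export
multiset_equal <- function(a, b) {
  a <- as_read_set(a)$reads
  b <- as_read_set(b)$reads
  length(a) == length(b) && identical(sort(a), sort(b))
}
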