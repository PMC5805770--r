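#' Binary entropy function
#'
#' `h2(p) = -p log2(p) - (1-p) log2(1-p)` in bits, with the endpoints
#' returning 0 by continuity.
#'
#' @param p probability in `[0, 1]`.
#' @return bits.
#' @export
binary_entropy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = FALSE) || anyNA(p))
    stop("p must lie in [0, 1]")
  ifelse(p == 0 | p == 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))
}

#' Per-base entropy of the substitution-error process
#'
#' For reads corrupted independently per base with probability `p` (the
#' corrupted base replaced uniformly by one of the other three), the error
#' process contributes `N * L * log2(3) * h2(p)` bits to the entropy of the
#' read collection; this returns the per-base value `log2(3) * h2(p)`.
#'
#' @param p substitution error probability per base, `0 <= p < 1`.
#' @return bits per base.
#' @examples
#' error_entropy_per_base(0.003) # ~0.047
#' @export
error_entropy_per_base <- function(p) {
  if (any(p < 0 | p >= 1) || anyNA(p)) stop("p must lie in [0, 1)")
  log2(3) * binary_entropy(p)
}

#' Entropy of a Poisson random variable
#'
#' Direct series evaluation of `sum_k -P(k) log2 P(k)` for
#' `Poisson(lam)`, truncated where the remaining tail is far below 1e-12
#' bits. `poisson_entropy(0)` is 0 (degenerate distribution).
#'
#' @param lam mean, `>= 0`.
#' @return bits.
#' @export
poisson_entropy <- function(lam) {
  if (length(lam) != 1 || is.na(lam) || lam < 0) stop("lam must be a single value >= 0")
  if (lam == 0) return(0)
  kmax <- ceiling(lam + 15 * sqrt(lam + 1) + 60)
  pk <- dpois(0:kmax, lam)
  pk <- pk[pk > 0]
  -sum(pk * log2(pk))
}

#' Descriptive complexity of a genome via a universal compressor
#'
#' Estimates `H(G)` by the description length of `G` under a DEFLATE-class
#' (LZ77) compressor: the size in bits of a gzip file of the genome text at
#' the maximum compression setting. Deterministic for a fixed zlib backend.
#'
#' @param G genome string over A, C, G, T (non-empty).
#' @return bits.
#' @export
lz_genome_bits <- function(G) {
  if (!is.character(G) || length(G) != 1 || nchar(G) == 0)
    stop("G must be a single non-empty genome string")
  tmp <- tempfile(fileext = ".gz")
  on.exit(unlink(tmp), add = TRUE)
  con <- gzfile(tmp, "wb", compression = 9L)
  writeBin(charToRaw(G), con)
  close(con)
  8 * file.size(tmp)
}

#' Entropy approximation for a collection of sampled reads
#'
#' Approximates the minimum number of bits any algorithm needs to describe
#' `N` reads of length `L` sampled uniformly at random from genome `G` with
#' i.i.d. per-base substitution errors at rate `p`:
#'
#' `H(R) ~ N*L*log2(3)*h2(p) + |G| * H(Poisson(N/|G|)) + LZ(G)`
#'
#' i.e. an error term, a read-sampling (coverage) term, and a genome
#' descriptive-complexity term. The remaining conditional terms of the
#' exact decomposition are treated as negligible (zero).
#'
#' @param G genome string.
#' @param N number of reads.
#' @param L read length, `1 <= L <= nchar(G)`.
#' @param p per-base substitution error rate, `0 <= p < 1`.
#' @return an object of class `entropy_estimate`: list with `lz_genome_bits`,
#'   `sampling_bits`, `error_bits`, `total_bits` and `per_base` (each term
#'   divided by `N*L`).
#' @export
estimate_read_set_entropy <- function(G, N, L, p = 0) {
  if (N < 1) stop("N must be >= 1")
  if (L < 1 || L > nchar(G)) stop("L must satisfy 1 <= L <= |G|")
  lz <- lz_genome_bits(G)
  glen <- nchar(G)
  sampling <- glen * poisson_entropy(N / glen)
  err <- N * L * error_entropy_per_base(p)
  total <- lz + sampling + err
  per_base <- c(lz_genome = lz, sampling = sampling, error = err,
                total = total) / (N * L)
  structure(list(lz_genome_bits = lz, sampling_bits = sampling,
                 error_bits = err, total_bits = total, per_base = per_base,
                 N = N, L = L, p = p, genome_length = glen),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat("Read-set entropy approximation (bits/base):\n")
  cat(sprintf("  genome (LZ):   %.3f\n", x$per_base[["lz_genome"]]))
  cat(sprintf("  sampling:      %.3f\n", x$per_base[["sampling"]]))
  cat(sprintf("  errors:        %.3f\n", x$per_base[["error"]]))
  cat(sprintf("  total:         %.3f\n", x$per_base[["total"]]))
  invisible(x)
}
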