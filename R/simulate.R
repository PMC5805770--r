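#' Parameters for read-set simulation
#'
#' Bundles the simulation parameters: reads are sampled independently and
#' uniformly from all start positions of a linear genome, corrupted per
#' base with probability `p` (substitution by one of the other three bases,
#' uniformly), and emitted as the reverse complement with probability
#' `flip_prob`. All randomness comes from R's Mersenne-Twister stream
#' seeded with `seed`, so fixtures are byte-reproducible.
#'
#' @param N number of reads.
#' @param L read length.
#' @param p per-base substitution error probability, `0 <= p < 1`.
#' @param flip_prob probability a read is emitted reverse-complemented.
#' @param seed integer RNG seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(N, L, p = 0, flip_prob = 0, seed = 1L) {
  if (N < 1) stop("N must be >= 1")
  if (L < 1) stop("L must be >= 1")
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)")
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must lie in [0, 1]")
  structure(list(N = as.integer(N), L = as.integer(L), p = p,
                 flip_prob = flip_prob, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a uniform i.i.d. genome
#'
#' Each base drawn independently and uniformly from A, C, G, T.
#' Deterministic given `seed`.
#'
#' @param length genome length in bases, `>= 1`.
#' @param seed integer RNG seed.
#' @return a single genome string.
#' @export
simulate_genome <- function(length, seed = 1L) {
  if (length < 1) stop("length must be >= 1")
  withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
     .rng_sample_kind = "Rejection")
}

#' Sample reads uniformly from a genome
#'
#' `N` start positions are drawn uniformly from `[1, |G| - L + 1]` (linear
#' genome), then substitution errors and strand flips are applied per the
#' spec. Deterministic given `spec$seed`.
#'
#' @param G genome string.
#' @param spec a [simulation_spec()].
#' @return a [read_set()].
#' @export
sample_reads <- function(G, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  glen <- nchar(G)
  if (spec$L > glen) stop("read length L exceeds the genome length")
  withr::with_seed(spec$seed, {
    starts <- sample.int(glen - spec$L + 1L, spec$N, replace = TRUE)
    reads <- substring(G, starts, starts + spec$L - 1L)
    if (spec$p > 0) {
      big <- charToRaw(paste0(reads, collapse = ""))
      hit <- which(runif(length(big)) < spec$p)
      if (length(hit) > 0) {
        bases <- charToRaw("ACGT")
        cur <- match(big[hit], bases) - 1L
        shift <- sample.int(3L, length(hit), replace = TRUE)
        big[hit] <- bases[((cur + shift) %% 4L) + 1L]
        all <- rawToChar(big)
        reads <- substring(all, (seq_len(spec$N) - 1L) * spec$L + 1L,
                           seq_len(spec$N) * spec$L)
      }
    }
    if (spec$flip_prob > 0) {
      flip <- runif(spec$N) < spec$flip_prob
      if (any(flip)) reads[flip] <- revcomp(reads[flip])
    }
    read_set(reads)
  }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
     .rng_sample_kind = "Rejection")
}
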