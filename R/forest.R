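#' Default minimum overlap length
#'
#' The default K-mer seed / minimum overlap length used by the forest
#' builder: `floor(L / 5)` for reads of length `L` (never below 1).
#'
#' @param L read length in bases.
#' @return integer overlap length.
#' @examples
#' default_overlap_k(100)
#' @export
default_overlap_k <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1) stop("L must be a positive integer")
  max(1L, L %/% 5L)
}

#' Seeded suffix-prefix overlap between two reads
#'
#' Returns the largest `l` with `K <= l <= L` such that the prefix of
#' length `l` of `v_seq` matches the suffix of length `l` of `u_seq`,
#' where the last `K` overlap positions (the seed window) must match
#' exactly and the remaining `l - K` positions may disagree in at most
#' `eps` places. Scanning slides the seed window right-to-left (`l` from
#' `L` down to `K`) and the first validated window wins.
#'
#' @param u_seq,v_seq two strings of equal length `L` (the potential parent
#'   `u` and child `v`).
#' @param K seed / minimum overlap length, `1 <= K <= L`.
#' @param eps maximum number of mismatches outside the seed window.
#' @return the overlap length, or `NA_integer_` if no overlap of length at
#'   least `K` validates.
#' @examples
#' suffix_prefix_overlap("AACGT", "CGTTT", K = 2, eps = 0) # 3
#' @export
suffix_prefix_overlap <- function(u_seq, v_seq, K, eps = 0L) {
  if (nchar(u_seq) != nchar(v_seq))
    stop("u_seq and v_seq must have equal length")
  if (K > nchar(u_seq)) stop("K must satisfy K <= L")
  if (K < 1) stop("K must be >= 1")
  .spov_cpp(u_seq, v_seq, as.integer(K), as.integer(eps))[1]
}

new_read_forest <- function(built, L, K, eps, strand_correct) {
  nodes <- data.frame(id = seq_along(built$seq),
                      seq = built$seq,
                      parent = built$parent,
                      weight = built$weight,
                      fwd_mult = built$fwd_mult,
                      rev_mult = built$rev_mult,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 n_offsets = built$n_offsets,
                 L = as.integer(L), K = as.integer(K), eps = as.integer(eps),
                 strand_correct = isTRUE(strand_correct),
                 N_total = sum(built$fwd_mult) + sum(built$rev_mult)),
            class = "read_forest")
}

#' Build the greedy minimum-weight read forest
#'
#' Iterates over the reads in input order. Exact duplicate reads (and, with
#' strand correction, exact reverse-complement duplicates) are collapsed
#' into one node with multiplicity counts. Each new distinct read searches
#' its parent by sliding a length-`K` window right-to-left over its sequence
#' against a suffix K-mer index (longest validated overlap wins; candidate
#' hits are tried in ascending node id), then searches left-to-right against
#' a prefix K-mer index for existing nodes that would be better off with the
#' new read as their parent, reassigning them. With `strand_correct = TRUE`
#' the parent search runs for both orientations and the orientation with
#' the longer validated overlap is committed permanently.
#'
#' `N` symbols are substituted by the placeholder base `A` for matching
#' purposes; their true positions are carried on the node and restored
#' losslessly by the codec.
#'
#' On error-free reads (`eps = 0`) the resulting forest attains the minimum
#' possible total weight, which equals the sum of per-node representation
#' costs computed independently by [brute_rep_table()].
#'
#' @param rs a [read_set()] or character vector of reads.
#' @param K minimum overlap / seed length; defaults to [default_overlap_k()].
#' @param eps maximum mismatches tolerated outside the exact seed window
#'   when extending a candidate overlap (default 2).
#' @param strand_correct logical; enable the greedy strand synchronisation
#'   heuristic (default `FALSE`).
#' @return an object of class `read_forest`: a list with a `nodes` data
#'   frame (`id`, `seq` — the committed-orientation sequence with N
#'   placeholders applied, `parent` — node id or `NA` for roots, `weight`,
#'   `fwd_mult`, `rev_mult`), per-node N offsets, and the parameters.
#' @examples
#' f <- build_read_forest(c("ACGT", "CGTA", "GTAC", "TACG", "ACGG"),
#'                        K = 2, eps = 0)
#' total_weight(f)  # 5
#' @export
build_read_forest <- function(rs, K = NULL, eps = 2L, strand_correct = FALSE) {
  rs <- as_read_set(rs)
  if (rs$N_total == 0) {
    built <- list(seq = character(0), parent = integer(0), weight = integer(0),
                  fwd_mult = integer(0), rev_mult = integer(0), n_offsets = list())
    return(new_read_forest(built, 0L, if (is.null(K)) 0L else K, eps, strand_correct))
  }
  if (is.null(K)) K <- default_overlap_k(rs$L)
  K <- as.integer(K); eps <- as.integer(eps)
  if (K < 1) stop("K must be >= 1")
  if (K > rs$L) stop("K must satisfy K <= L")
  if (eps < 0) stop("eps must be >= 0")
  built <- .integrate_reads_cpp(rs$reads, K, eps, isTRUE(strand_correct),
                                character(0), integer(0), integer(0),
                                integer(0), integer(0), list())
  new_read_forest(built, rs$L, K, eps, strand_correct)
}

#' Integrate additional reads into an existing forest
#'
#' Runs the same parent search / children reassignment / index insertion
#' step as [build_read_forest()] for each new read, against the state of an
#' already-built forest. Committed orientations of existing nodes never
#' change, but their parent edges may be reassigned to a new node providing
#' a longer overlap.
#'
#' @param forest a `read_forest`.
#' @param reads character vector of new reads (same length `L`).
#' @return the updated `read_forest`.
#' @export
forest_insert <- function(forest, reads) {
  stopifnot(inherits(forest, "read_forest"))
  reads <- as_read_set(reads)
  if (reads$N_total == 0) return(forest)
  if (nrow(forest$nodes) == 0)
    return(build_read_forest(reads, K = if (forest$K >= 1) forest$K else NULL,
                             eps = forest$eps, strand_correct = forest$strand_correct))
  if (reads$L != forest$L) stop("new reads must have length L = ", forest$L)
  built <- .integrate_reads_cpp(reads$reads, forest$K, forest$eps,
                                forest$strand_correct,
                                forest$nodes$seq, forest$nodes$parent,
                                forest$nodes$weight, forest$nodes$fwd_mult,
                                forest$nodes$rev_mult, forest$n_offsets)
  new_read_forest(built, forest$L, forest$K, forest$eps, forest$strand_correct)
}

#' Total weight of a read forest
#'
#' The sum of edge weights over all nodes: each non-root node contributes
#' its overlap deficit against its parent, each root contributes `L`.
#' Multiplicity does not multiply weight (duplicates are one node). This is
#' exactly the number of consensus symbols the codec stores.
#'
#' @param forest a `read_forest`.
#' @return integer symbol count.
#' @export
total_weight <- function(forest) {
  stopifnot(inherits(forest, "read_forest"))
  sum(forest$nodes$weight)
}

#' @export
print.read_forest <- function(x, ...) {
  n <- nrow(x$nodes)
  cat("read_forest: ", n, " distinct reads (", x$N_total, " total), L = ",
      x$L, ", K = ", x$K, ", eps = ", x$eps,
      if (x$strand_correct) ", strand-corrected" else "", "\n", sep = "")
  if (n > 0)
    cat("  total weight: ", total_weight(x), " symbols; roots: ",
        sum(is.na(x$nodes$parent)), "\n", sep = "")
  invisible(x)
}
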