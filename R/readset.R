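#' Construct a fixed-length read set
#'
#' A `read_set` is the package's in-memory representation of a multiset of
#' fixed-length DNA reads: an ordered character vector over the alphabet
#' A, C, G, T, N in which every element has the same length `L`. Order is
#' preserved from the source, but the compressor treats the collection as a
#' multiset (decompression does not restore the original order).
#'
#' @param reads character vector of reads (upper- or lowercase; folded to
#'   uppercase). Any character outside A, C, G, T, N is an error.
#' @return an object of class `read_set`: a list with elements `reads`
#'   (uppercase character vector), `L` (read length) and `N_total`
#'   (number of reads, duplicates included).
#' @examples
#' rs <- read_set(c("ACGT", "acgn"))
#' rs$L
#' rs$N_total
#' @export
read_set <- function(reads) {
  reads <- toupper(as.character(reads))
  if (length(reads) > 0) {
    bad <- grepl("[^ACGTN]", reads)
    if (any(bad))
      stop("read ", which(bad)[1], " contains characters outside {A,C,G,T,N}")
    L <- nchar(reads[1])
    if (any(nchar(reads) != L))
      stop("fixed-length violation: reads have differing lengths (",
           "expected L = ", L, ", first offender is read ",
           which(nchar(reads) != L)[1], ")")
  } else {
    L <- 0L
  }
  structure(list(reads = reads, L = as.integer(L), N_total = length(reads)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set: ", x$N_total, " reads of length ", x$L, "\n", sep = "")
  if (x$N_total > 0)
    cat("  first: ", x$reads[1], "\n", sep = "")
  invisible(x)
}

as_read_set <- function(x) {
  if (inherits(x, "read_set")) return(x)
  if (is.character(x)) return(read_set(x))
  stop("expected a read_set or a character vector of reads")
}

#' Read fixed-length reads from a FASTA or FASTQ file
#'
#' Parses a FASTA or 4-line FASTQ file (gzip-compressed input is accepted
#' transparently) and returns the sequences only: identifiers and quality
#' strings are discarded, lowercase is folded to uppercase, and the file
#' order is preserved. The compression model is defined only for fixed-length
#' reads, so files with unequal sequence lengths are rejected.
#'
#' @param path path to a FASTA/FASTQ file, optionally gzip-compressed.
#' @param format `"auto"` (detect from the first record marker), `"fasta"`
#'   or `"fastq"`.
#' @return a [read_set()].
#' @export
read_fastx <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- readLines(con, n = 1L)
    if (length(first) == 0)
      stop("empty input: no records in ", path)
    format <- if (startsWith(first, ">")) "fasta"
    else if (startsWith(first, "@")) "fastq"
    else stop("parse error at line 1: expected '>' or '@', found ",
              substr(first, 1, 1))
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0) stop("empty input: no records in ", path)
  read_set(as.character(seqs))
}

#' Write a read set to FASTA
#'
#' Writes the reads with synthetic sequential identifiers `read_1`,
#' `read_2`, ... Decompressed output is a multiset: record order is not
#' guaranteed to match the originally compressed input.
#'
#' @param rs a [read_set()] (or character vector of reads).
#' @param path output file path; a `.gz` suffix writes gzip-compressed.
#' @return (invisibly) the number of records written.
#' @export
write_fastx <- function(rs, path) {
  rs <- as_read_set(rs)
  compress <- grepl("\\.gz$", path)
  if (rs$N_total == 0) {
    if (compress) { con <- gzfile(path, "wb"); close(con) } else file.create(path)
    return(invisible(0L))
  }
  x <- Biostrings::DNAStringSet(rs$reads)
  names(x) <- paste0("read_", seq_len(rs$N_total))
  Biostrings::writeXStringSet(x, filepath = path, compress = compress)
  invisible(rs$N_total)
}
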