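bitwidth <- function(n) {
  # bits needed to address n values (0 .. n-1)
  if (n <= 1) return(0L)
  as.integer(ceiling(log2(n)))
}

#' Decompose a read forest into contigs
#'
#' Breaks the forest into disjoint contigs, the unit of encoding. Each
#' decomposition step starts at an unprocessed leaf and walks parent links
#' until hitting an already-processed node, a root, or a node already on
#' the current path (which closes a cycle). A closed cycle is emitted as
#' its own contig (parent = itself) and the tail below the entry node as a
#' separate contig referencing it; pure cycles with no attached trees are
#' picked up afterwards. Contigs are ordered so that every parent reference
#' points to an earlier contig (or to the contig itself for cycles).
#'
#' @param forest a `read_forest`.
#' @return a list of contigs; each is a list with `nodes` (node ids in
#'   root-to-leaf order), `deltas` (per-read edge weights; their sum is the
#'   contig consensus length), `is_cycle`, `parent_contig` (contig index,
#'   `NA` for roots, self for cycles) and `parent_index` (1-based read
#'   index of the attachment read within the parent contig).
#' @export
decompose_forest <- function(forest) {
  stopifnot(inherits(forest, "read_forest"))
  parent <- forest$nodes$parent
  weight <- forest$nodes$weight
  n <- length(parent)
  contigs <- vector("list", 0L)
  if (n == 0) return(contigs)
  ccount <- tabulate(parent[!is.na(parent)], nbins = n)
  processed <- logical(n)
  stamp <- integer(n)
  contig_of <- integer(n)
  pos_in <- integer(n)

  emit <- function(nodes_rtl, is_cycle, pc, pidx) {
    ci <- length(contigs) + 1L
    contigs[[ci]] <<- list(nodes = nodes_rtl,
                           deltas = weight[nodes_rtl],
                           is_cycle = is_cycle,
                           parent_contig = if (is_cycle) ci else pc,
                           parent_index = pidx)
    processed[nodes_rtl] <<- TRUE
    contig_of[nodes_rtl] <<- ci
    pos_in[nodes_rtl] <<- seq_along(nodes_rtl)
    ci
  }

  walk <- function(start) {
    path <- integer(0)
    cur <- start
    repeat {
      path <- c(path, cur)
      stamp[cur] <<- start
      p <- parent[cur]
      if (is.na(p)) {
        emit(rev(path), FALSE, NA_integer_, NA_integer_)
        return(invisible())
      }
      if (processed[p]) {
        emit(rev(path), FALSE, contig_of[p], pos_in[p])
        return(invisible())
      }
      if (stamp[p] == start) { # cycle closure at p
        pos <- match(p, path)
        cyc <- emit(rev(path[pos:length(path)]), TRUE, NA_integer_, NA_integer_)
        if (pos > 1L)
          emit(rev(path[seq_len(pos - 1L)]), FALSE, cyc, pos_in[p])
        return(invisible())
      }
      cur <- p
    }
  }

  for (leaf in which(ccount == 0L)) if (!processed[leaf]) walk(leaf)
  for (v in seq_len(n)) if (!processed[v]) walk(v) # pure cycles
  contigs
}

# Derived (consensus-implied) strings for the reads of one contig, given the
# actual node sequences. Encoder and decoder share this geometry: read i
# occupies consensus positions (P_i - L) .. (P_i - 1), P = cumsum(deltas),
# negative positions borrowing from the parent read's string; cycle contigs
# index modulo the consensus length.
contig_derived <- function(seqs, deltas, is_cycle, parent_str, L) {
  k <- length(seqs)
  P <- cumsum(deltas)
  contrib <- substring(seqs, L - deltas + 1L, L)
  if (is_cycle) {
    cons <- paste0(contrib, collapse = "")
    C <- P[k]
    s <- (P - L) %% C
    big <- strrep(cons, ceiling((C - 1L + L) / C) + 1L)
    derived <- substring(big, s + 1L, s + L)
  } else {
    prev <- c(parent_str, seqs[-k])
    derived <- paste0(substring(prev, deltas + 1L, L), contrib)
  }
  derived
}

apply_errors <- function(s, offsets, bases) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  x[offsets + 1L] <- bases
  paste0(x, collapse = "")
}

BASES <- c("A", "C", "G", "T")

#' Compress a read multiset into a binary container
#'
#' Builds the greedy read forest, decomposes it into contigs and serialises
#' everything into a self-contained byte-exact archive: a fixed header;
#' a bit-packed contig metadata stream (per contig: read count, parent
#' pointer, fixed-codebook Huffman differential offsets whose sum is the
#' contig consensus length, and per-read mismatch records); the main
#' consensus stream and the singleton stream (reads for which neither a
#' parent nor a child was found), both 2-bit packed and post-compressed
#' with DEFLATE; an Elias-gamma multiplicity stream; and an N-position
#' stream restoring true `N` symbols. The container decodes with no
#' information beyond its own bytes, and the consensus + singleton streams
#' together hold exactly [total_weight()] symbols.
#'
#' @param x a [read_set()], character vector of reads, or path handled by
#'   [read_fastx()] if a length-1 string naming an existing file.
#' @inheritParams build_read_forest
#' @return a raw vector (the container).
#' @seealso [decompress_reads()], [container_stats()]
#' @export
compress_reads <- function(x, K = NULL, eps = 2L, strand_correct = FALSE) {
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !inherits(x, "read_set")) x <- read_fastx(x)
  rs <- as_read_set(x)
  forest <- build_read_forest(rs, K = K, eps = eps, strand_correct = strand_correct)
  encode_container(forest)
}

#' Serialise a read forest into the binary container
#'
#' Lower-level interface used by [compress_reads()]; see there for the
#' container layout.
#'
#' @param forest a `read_forest`.
#' @return a raw vector.
#' @export
encode_container <- function(forest) {
  stopifnot(inherits(forest, "read_forest"))
  L <- forest$L
  nd <- forest$nodes
  n_nodes <- nrow(nd)
  contigs <- decompose_forest(forest)

  singleton <- vapply(contigs, function(cg) {
    length(cg$nodes) == 1L && !cg$is_cycle && is.na(cg$parent_contig)
  }, logical(1))
  main <- contigs[!singleton]
  sing_nodes <- vapply(contigs[singleton], function(cg) cg$nodes, integer(1))
  main_index <- cumsum(!singleton) # full contig index -> index among main

  wL <- bitwidth(L)
  emission <- c(unlist(lapply(main, `[[`, "nodes"), use.names = FALSE), sing_nodes)
  emission <- as.integer(emission)
  n_main_reads <- length(emission) - length(sing_nodes)

  # ---- derived strings and error records for main-contig reads ----
  derived_all <- character(n_main_reads)
  actual_all <- character(n_main_reads)
  cons_parts <- character(length(main))
  at <- 0L
  for (ci in seq_along(main)) {
    cg <- main[[ci]]
    seqs <- nd$seq[cg$nodes]
    pstr <- ""
    if (!cg$is_cycle && !is.na(cg$parent_contig)) {
      pnode <- contigs[[cg$parent_contig]]$nodes[cg$parent_index]
      pstr <- nd$seq[pnode]
    }
    k <- length(seqs)
    derived_all[at + seq_len(k)] <- contig_derived(seqs, cg$deltas, cg$is_cycle, pstr, L)
    actual_all[at + seq_len(k)] <- seqs
    cons_parts[ci] <- paste0(substring(seqs, L - cg$deltas + 1L, L), collapse = "")
    at <- at + k
  }
  if (n_main_reads > 0) {
    a <- charToRaw(paste0(derived_all, collapse = ""))
    b <- charToRaw(paste0(actual_all, collapse = ""))
    diff <- which(a != b)
  } else {
    b <- raw(0)
    diff <- integer(0)
  }
  err_read <- as.integer((diff - 1L) %/% L + 1L)
  err_off <- as.integer((diff - 1L) %% L)
  err_base <- if (length(diff))
    match(rawToChar(b[diff], multiple = TRUE), BASES) - 1L else integer(0)
  err_counts <- tabulate(err_read, nbins = n_main_reads)

  # ---- metadata stream ----
  bw <- .bw_new()
  read_at <- 0L
  err_at <- 0L
  for (ci in seq_along(main)) {
    cg <- main[[ci]]
    k <- length(cg$nodes)
    .bw_gamma(bw, k)
    if (cg$is_cycle) {
      .bw_gamma(bw, 1L)
    } else if (is.na(cg$parent_contig)) {
      .bw_gamma(bw, 2L)
    } else {
      pm <- main_index[cg$parent_contig]
      .bw_gamma(bw, 2L + (ci - pm))
      w <- bitwidth(length(main[[pm]]$nodes))
      if (w > 0) .bw_fixed(bw, cg$parent_index - 1L, w)
    }
    .bw_huff(bw, cg$deltas, L)
    ec <- err_counts[read_at + seq_len(k)]
    .bw_gamma(bw, ec + 1L)
    ne <- sum(ec)
    if (ne > 0) {
      sel <- err_at + seq_len(ne)
      if (wL > 0) .bw_fixed(bw, err_off[sel], wL)
      .bw_fixed(bw, err_base[sel], 2L)
      err_at <- err_at + ne
    }
    read_at <- read_at + k
  }
  meta <- .bw_raw(bw)

  # ---- consensus and singleton streams (2-bit packed + DEFLATE) ----
  main_gz <- memCompress(.pack_bases_cpp(paste0(cons_parts, collapse = "")), "gzip")
  sing_gz <- memCompress(.pack_bases_cpp(paste0(nd$seq[sing_nodes], collapse = "")), "gzip")

  # ---- multiplicity stream ----
  bw <- .bw_new()
  if (n_nodes > 0) {
    if (forest$strand_correct) {
      .bw_gamma(bw, as.integer(rbind(nd$fwd_mult[emission] + 1L,
                                     nd$rev_mult[emission] + 1L)))
    } else {
      .bw_gamma(bw, nd$fwd_mult[emission] + nd$rev_mult[emission])
    }
  }
  mult <- .bw_raw(bw)

  # ---- N-position stream ----
  bw <- .bw_new()
  noff <- forest$n_offsets[emission]
  cnt <- lengths(noff)
  nrec <- sum(cnt)
  .bw_gamma(bw, nrec + 1L)
  if (nrec > 0) {
    idx <- rep.int(seq_along(emission), cnt)
    .bw_gamma(bw, diff(c(0L, idx)) + 1L)
    if (wL > 0) .bw_fixed(bw, unlist(noff, use.names = FALSE), wL)
  }
  npos <- .bw_raw(bw)

  # ---- assemble container ----
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("ATRF"), con)
  writeBin(as.raw(c(1L, as.integer(forest$strand_correct))), con)
  writeBin(as.integer(c(L, forest$K, forest$eps, forest$N_total, n_nodes,
                        length(main), length(sing_nodes))),
           con, size = 4L, endian = "little")
  for (s in list(meta, main_gz, sing_gz, mult, npos)) {
    writeBin(length(s), con, size = 4L, endian = "little")
    writeBin(as.raw(s), con)
  }
  rawConnectionValue(con)
}

parse_container <- function(container) {
  if (!is.raw(container)) stop("format error: expected a raw container")
  if (length(container) < 4 || rawToChar(container[1:4]) != "ATRF")
    stop("format error: bad magic (not a readforest container)")
  con <- rawConnection(container[-(1:4)], "rb")
  on.exit(close(con), add = TRUE)
  ver <- as.integer(readBin(con, "raw", n = 1L))
  if (length(ver) == 0) stop("corruption error: truncated container")
  if (ver != 1L) stop("format error: unsupported container version ", ver)
  strand <- isTRUE(as.integer(readBin(con, "raw", n = 1L)) == 1L)
  hdr <- readBin(con, "integer", n = 7L, size = 4L, endian = "little")
  if (length(hdr) < 7L) stop("corruption error: truncated container")
  names(hdr) <- c("L", "K", "eps", "N_total", "n_nodes", "n_contigs", "n_singletons")
  streams <- vector("list", 5L)
  names(streams) <- c("meta", "main_gz", "sing_gz", "mult", "npos")
  for (i in 1:5) {
    len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(len) == 0 || len < 0) stop("corruption error: truncated container header")
    s <- readBin(con, "raw", n = len)
    if (length(s) != len) stop("corruption error: truncated stream ", names(streams)[i])
    streams[[i]] <- s
  }
  list(version = ver, strand_correct = strand, header = as.list(hdr),
       streams = streams)
}

#' Decode a container back to the read multiset
#'
#' Reconstructs each contig's reads root-to-leaf (borrowing cross-contig
#' prefixes through the parent pointers and indexing modulo the consensus
#' length for cycles), reapplies mismatch records, N positions, orientation
#' counts and multiplicities. The result equals the compressed input as a
#' multiset; record order is not preserved.
#'
#' @param container a raw vector produced by [compress_reads()] /
#'   [encode_container()].
#' @return a [read_set()].
#' @export
decompress_reads <- function(container) {
  pc <- parse_container(container)
  h <- pc$header
  L <- h$L
  if (h$N_total == 0) return(read_set(character(0)))
  wL <- bitwidth(L)

  # ---- metadata ----
  br <- .br_new(pc$streams$meta)
  ctg <- vector("list", h$n_contigs)
  for (ci in seq_len(h$n_contigs)) {
    k <- .br_gamma(br, 1L)
    kind <- .br_gamma(br, 1L)
    is_cycle <- kind == 1L
    pctg <- NA_integer_
    pidx <- NA_integer_
    if (kind > 2L) {
      pctg <- ci - (kind - 2L)
      if (pctg < 1L) stop("corruption error: contig parent pointer out of range")
      w <- bitwidth(length(ctg[[pctg]]$deltas))
      pidx <- (if (w > 0) .br_fixed(br, 1L, w) else 0L) + 1L
    }
    deltas <- .br_huff(br, k, L)
    ec <- .br_gamma(br, k) - 1L
    ne <- sum(ec)
    off <- integer(0); bs <- integer(0)
    if (ne > 0) {
      off <- if (wL > 0) .br_fixed(br, ne, wL) else integer(ne)
      bs <- .br_fixed(br, ne, 2L)
    }
    ctg[[ci]] <- list(deltas = deltas, is_cycle = is_cycle, parent_contig = pctg,
                      parent_index = pidx, err_counts = ec, err_off = off,
                      err_base = bs)
  }

  # ---- consensus streams ----
  tot_syms <- sum(vapply(ctg, function(cg) sum(cg$deltas), numeric(1)))
  consensus <- .unpack_bases_cpp(memDecompress(pc$streams$main_gz, "gzip"), tot_syms)
  sing_seqs <- character(0)
  if (h$n_singletons > 0) {
    s <- .unpack_bases_cpp(memDecompress(pc$streams$sing_gz, "gzip"),
                           h$n_singletons * L)
    sing_seqs <- substring(s, (seq_len(h$n_singletons) - 1L) * L + 1L,
                           seq_len(h$n_singletons) * L)
  }

  # ---- reconstruct contig reads ----
  reads_by_ctg <- vector("list", h$n_contigs)
  cons_at <- 0L
  for (ci in seq_len(h$n_contigs)) {
    cg <- ctg[[ci]]
    k <- length(cg$deltas)
    clen <- sum(cg$deltas)
    cons <- substr(consensus, cons_at + 1L, cons_at + clen)
    cons_at <- cons_at + clen
    P <- cumsum(cg$deltas)
    contrib <- substring(cons, P - cg$deltas + 1L, P)
    eP <- cumsum(cg$err_counts)
    recon <- character(k)
    if (cg$is_cycle) {
      C <- clen
      s <- (P - L) %% C
      big <- strrep(cons, ceiling((C - 1L + L) / C) + 1L)
      derived <- substring(big, s + 1L, s + L)
      for (i in seq_len(k)) {
        recon[i] <- if (cg$err_counts[i] > 0) {
          sel <- (eP[i] - cg$err_counts[i] + 1L):eP[i]
          apply_errors(derived[i], cg$err_off[sel], BASES[cg$err_base[sel] + 1L])
        } else derived[i]
      }
    } else {
      pstr <- if (!is.na(cg$parent_contig))
        reads_by_ctg[[cg$parent_contig]][cg$parent_index] else ""
      for (i in seq_len(k)) {
        prev <- if (i == 1L) pstr else recon[i - 1L]
        der <- paste0(substring(prev, cg$deltas[i] + 1L, L), contrib[i])
        recon[i] <- if (cg$err_counts[i] > 0) {
          sel <- (eP[i] - cg$err_counts[i] + 1L):eP[i]
          apply_errors(der, cg$err_off[sel], BASES[cg$err_base[sel] + 1L])
        } else der
      }
    }
    if (any(nchar(recon) != L))
      stop("corruption error: delta sum inconsistent with consensus length")
    reads_by_ctg[[ci]] <- recon
  }

  node_seqs <- c(unlist(reads_by_ctg, use.names = FALSE), sing_seqs)
  n_nodes <- length(node_seqs)
  if (n_nodes != h$n_nodes)
    stop("corruption error: node count mismatch")

  # ---- multiplicities ----
  br <- .br_new(pc$streams$mult)
  if (pc$strand_correct) {
    v <- .br_gamma(br, 2L * n_nodes) - 1L
    fwd <- v[seq(1L, length(v), by = 2L)]
    rev_ <- v[seq(2L, length(v), by = 2L)]
  } else {
    fwd <- .br_gamma(br, n_nodes)
    rev_ <- integer(n_nodes)
  }

  # ---- N positions ----
  br <- .br_new(pc$streams$npos)
  nrec <- .br_gamma(br, 1L) - 1L
  if (nrec > 0) {
    idx <- cumsum(.br_gamma(br, nrec) - 1L)
    off <- if (wL > 0) .br_fixed(br, nrec, wL) else integer(nrec)
    for (u in unique(idx)) {
      sel <- idx == u
      node_seqs[u] <- apply_errors(node_seqs[u], off[sel],
                                   rep("N", sum(sel)))
    }
  }

  out <- c(rep.int(node_seqs, fwd),
           if (any(rev_ > 0)) rep.int(revcomp(node_seqs[rev_ > 0]), rev_[rev_ > 0])
           else character(0))
  if (length(out) != h$N_total)
    stop("corruption error: multiplicity sum does not match read count")
  read_set(out)
}

#' Container summary statistics
#'
#' @param container a raw container, or the path of a container file.
#' @return a list with total size in bits, bits per base, contig / singleton
#'   / distinct-read counts, and per-stream byte sizes.
#' @export
container_stats <- function(container) {
  if (is.character(container)) container <- read_container(container)
  pc <- parse_container(container)
  h <- pc$header
  bits <- 8 * length(container)
  list(bits = bits,
       bits_per_base = if (h$N_total > 0) bits / (h$N_total * h$L) else NA_real_,
       L = h$L, K = h$K, eps = h$eps,
       N_total = h$N_total, n_distinct = h$n_nodes,
       n_contigs = h$n_contigs, n_singletons = h$n_singletons,
       strand_correct = pc$strand_correct,
       stream_bytes = vapply(pc$streams, length, integer(1)))
}

#' @rdname compress_reads
#' @param input input FASTA/FASTQ path.
#' @param output output path.
#' @export
compress_file <- function(input, output, K = NULL, eps = 2L,
                          strand_correct = FALSE) {
  container <- compress_reads(read_fastx(input), K = K, eps = eps,
                              strand_correct = strand_correct)
  writeBin(container, output)
  invisible(container_stats(container))
}

#' @rdname decompress_reads
#' @param input container file path.
#' @param output output FASTA path.
#' @export
decompress_file <- function(input, output) {
  rs <- decompress_reads(read_container(input))
  write_fastx(rs, output)
  invisible(rs$N_total)
}

read_container <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readBin(path, "raw", n = file.size(path))
}

#' Fixed-codebook Huffman coding of differential offsets
#'
#' The per-read differential offsets (edge weights, in `[1, L]`) are coded
#' with a canonical Huffman code over the alphabet `{1..L}` built from a
#' truncated geometric weight profile `P(d) proportional to 0.85^(d-1)`.
#' Encoder and decoder derive the identical codebook from `L` alone, so no
#' codebook is transmitted.
#'
#' @param deltas integer vector of values in `[1, L]`.
#' @param L read length (alphabet size).
#' @return `encode_deltas()`: a raw vector with attribute `nbits`;
#'   `decode_deltas()`: the integer vector of decoded values;
#'   `delta_codebook()`: a data frame with `symbol`, `length` and `code`
#'   (the canonical codeword as a 0/1 string).
#' @examples
#' decode_deltas(encode_deltas(c(1, 1, 5), 8), 3, 8)
#' @export
encode_deltas <- function(deltas, L) {
  bw <- .bw_new()
  .bw_huff(bw, as.integer(deltas), as.integer(L))
  .bw_raw(bw)
}

#' @rdname encode_deltas
#' @param bits raw vector from [encode_deltas()].
#' @param count number of values to decode.
#' @export
decode_deltas <- function(bits, count, L) {
  br <- .br_new(bits)
  .br_huff(br, as.integer(count), as.integer(L))
}

#' @rdname encode_deltas
#' @export
delta_codebook <- function(L) {
  as.data.frame(.huff_codebook_cpp(as.integer(L)), stringsAsFactors = FALSE)
}
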