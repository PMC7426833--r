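# k-mer seed-and-chain local alignment.  Anchors are maximal runs of shared
# exact k-mers; chains are found by sparse dynamic programming with a linear
# gap penalty.  SNP-level divergence is handled by chaining across broken
# anchors, not by inexact seeds.

DEFAULT_K <- 15L
DEFAULT_GAP_PENALTY <- 0.01
DEFAULT_MAX_GAP <- 20000L
# The source study's BLAST thresholds (e <= 1e-150, score >= 1000) map to a
# minimum chain score of 1000 matched bp wherever a BLAST search is emulated.
BLAST_EQUIV_MIN_SCORE <- 1000

#' Build a reusable k-mer index over an assembly
#'
#' Indexing a target once and querying many sequences against it is the fast
#' path used by the PAP genotyper and the orthology confirmation step.
#'
#' @param assembly A \code{genome_assembly} (or named character vector).
#' @param k k-mer size (>= 8).
#' @param max_occ k-mers seen more than this many times in the target are
#'   ignored as repetitive.
#' @return An opaque index object.
#' @export
kmer_index <- function(assembly, k = DEFAULT_K, max_occ = 64L) {
  if (k < 8L) stop("k < 8 enters the spurious-anchor regime")
  seqs <- if (inherits(assembly, "genome_assembly")) assembly$sequences
          else assembly
  ptr <- cpp_build_index(seqs, as.integer(k), as.integer(max_occ))
  structure(list(ptr = ptr, k = as.integer(k),
                 seq_names = names(seqs),
                 seq_lens = vapply(seqs, nchar, integer(1))),
            class = "kmer_index")
}

# Raw anchors of `query` against every sequence of the index, both strands.
# Returns a data.frame: seqid, q_start, q_end, t_start, t_end, strand
# (0-based half-open, query coordinates always on the forward query axis).
query_anchors <- function(index, query) {
  k <- index$k
  qlen <- nchar(query)
  collect <- function(res, strand) {
    out <- vector("list", length(res))
    for (i in seq_along(res)) {
      a <- res[[i]]
      if (!length(a$q_start)) next
      qs <- a$q_start; ls <- a$len
      if (strand == "-") qs <- qlen - (a$q_start + ls)
      out[[i]] <- data.frame(seqid = names(res)[i], q_start = qs,
                             q_end = qs + ls, t_start = a$t_start,
                             t_end = a$t_start + ls, strand = strand,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  fw <- collect(cpp_query_index(index$ptr, query), "+")
  rv <- if (qlen >= k) collect(cpp_query_index(index$ptr, cpp_revcomp(query)), "-")
        else NULL
  res <- rbind(fw, rv)
  if (is.null(res))
    res <- data.frame(seqid = character(), q_start = integer(),
                      q_end = integer(), t_start = integer(),
                      t_end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  res
}

make_chain <- function(blocks, score, seqid, strand) {
  blocks <- blocks[order(blocks$t_start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks$identity <- 1.0  # blocks are maximal exact matches
  structure(list(blocks = blocks, score = score, seqid = seqid,
                 strand = strand,
                 matched_bp = sum(blocks$q_end - blocks$q_start)),
            class = "alignment_chain")
}

#' @export
print.alignment_chain <- function(x, ...) {
  cat(sprintf("<alignment_chain> %s(%s): %d block(s), %d bp matched, score %.1f\n",
              x$seqid, x$strand, nrow(x$blocks), x$matched_bp, x$score))
  invisible(x)
}

# Trim chance overlaps (<= k bp) between consecutive blocks of a chain so
# blocks are strictly non-overlapping on both axes; blocks arrive sorted by
# target start.
trim_blocks <- function(blocks, strand) {
  if (nrow(blocks) < 2L) return(blocks)
  for (j in 2:nrow(blocks)) {
    ot <- blocks$t_end[j - 1] - blocks$t_start[j]
    oq <- if (strand == "+") blocks$q_end[j - 1] - blocks$q_start[j]
          else blocks$q_end[j] - blocks$q_start[j - 1]
    o <- max(0L, ot, oq)
    if (o > 0L) {
      blocks$t_start[j] <- blocks$t_start[j] + o
      if (strand == "+") blocks$q_start[j] <- blocks$q_start[j] + o
      else blocks$q_end[j] <- blocks$q_end[j] - o
    }
  }
  blocks
}

# Iteratively extract chains from an anchor set of ONE (seqid, strand):
# best chain by DP, then drop anchors whose overlap with the chain's query
# or target span exceeds k (smaller overlaps are chance k-mer extensions).
extract_chains <- function(anc, seqid, strand, gap_penalty, max_gap,
                           min_chain_bp, k = DEFAULT_K, max_chains = 50L) {
  chains <- list()
  # chain in a monotone coordinate frame: q_start on '-' was already mapped
  # to the forward axis, so target increases as query DEcreases; flip the
  # query sign for the DP instead.
  qs <- if (strand == "+") anc$q_start else -anc$q_end
  dp_frame <- data.frame(qs = qs, ts = anc$t_start,
                         len = anc$q_end - anc$q_start)
  keep <- rep(TRUE, nrow(anc))
  while (sum(keep) > 0 && length(chains) < max_chains) {
    idx <- which(keep)
    ch <- cpp_chain(dp_frame$qs[idx], dp_frame$ts[idx], dp_frame$len[idx],
                    gap_penalty, max_gap, max_overlap = k)
    sel <- idx[ch$idx]
    blocks <- anc[sel, c("q_start", "q_end", "t_start", "t_end"),
                  drop = FALSE]
    blocks <- trim_blocks(blocks[order(blocks$t_start), , drop = FALSE],
                          strand)
    matched <- sum(blocks$q_end - blocks$q_start)
    if (matched < min_chain_bp) break
    chains[[length(chains) + 1L]] <-
      make_chain(blocks, ch$score, seqid, strand)
    qlo <- min(blocks$q_start); qhi <- max(blocks$q_end)
    tlo <- min(blocks$t_start); thi <- max(blocks$t_end)
    ov_q <- pmin(anc$q_end, qhi) - pmax(anc$q_start, qlo)
    ov_t <- pmin(anc$t_end, thi) - pmax(anc$t_start, tlo)
    keep <- keep & !(ov_q > k | ov_t > k)
  }
  chains
}

#' Seed-and-chain local alignment of two DNA sequences
#'
#' Anchors are maximal runs of shared exact k-mers on both strands; colinear
#' chains are scored as matched bp minus \code{gap_penalty} per gapped bp
#' (gaps capped at \code{max_gap_bp} per join).  Secondary chains are
#' reported after masking the anchors used by better ones.
#'
#' @param query,target DNA strings (length >= k).
#' @param k k-mer size; \code{k < 8} is an error.
#' @param min_block_bp Chains with fewer total matched bp are dropped.
#' @param max_gap_bp Maximum per-join gap.
#' @param gap_penalty Penalty per gap bp.
#' @return List of \code{alignment_chain} objects, best first.
#' @export
seed_and_chain <- function(query, target, k = DEFAULT_K, min_block_bp = 50L,
                           max_gap_bp = DEFAULT_MAX_GAP,
                           gap_penalty = DEFAULT_GAP_PENALTY) {
  if (k < 8L) stop("k < 8 enters the spurious-anchor regime")
  stopifnot(nchar(query) >= k, nchar(target) >= k)
  idx <- kmer_index(c(target = target), k = k)
  anc <- query_anchors(idx, query)
  chains <- list()
  for (st in c("+", "-")) {
    a <- anc[anc$strand == st, , drop = FALSE]
    if (!nrow(a)) next
    chains <- c(chains, extract_chains(a, "target", st, gap_penalty,
                                       max_gap_bp, min_block_bp, k = k))
  }
  chains[order(vapply(chains, `[[`, numeric(1), "score"),
               decreasing = TRUE)]
}

chain_q_span <- function(chain) {
  c(min(chain$blocks$q_start), max(chain$blocks$q_end))
}
chain_t_span <- function(chain) {
  c(min(chain$blocks$t_start), max(chain$blocks$t_end))
}

# Aligned-length-weighted identity of a chain: matched bp / spanned bp.
chain_identity <- function(chain) {
  span <- max(diff(chain_q_span(chain)), diff(chain_t_span(chain)))
  chain$matched_bp / span
}

#' Best-matching target region for a query sequence
#'
#' Scans every sequence of the target assembly (both strands), chains
#' anchors, and returns the target interval spanned by the highest-scoring
#' chain, padded and clipped.  Ties are broken by longer aligned length,
#' then lexicographic sequence id, then smaller target start.
#'
#' @param query DNA string.
#' @param target A \code{genome_assembly}, or a prebuilt \code{kmer_index}.
#' @param pad_bp Padding added to each side of the chain's target span.
#' @param min_score Chains scoring below this are ignored; \code{NULL}
#'   result means no region qualified.
#' @param k,max_gap_bp,gap_penalty Chaining parameters.
#' @return \code{list(interval = <seqid,start,end,strand df>, chain = ...)}
#'   or \code{NULL}.
#' @export
best_matching_region <- function(query, target, pad_bp = 1000L,
                                 min_score = 100, k = DEFAULT_K,
                                 max_gap_bp = DEFAULT_MAX_GAP,
                                 gap_penalty = DEFAULT_GAP_PENALTY) {
  if (nchar(query) == 0L) stop("empty query")
  idx <- if (inherits(target, "kmer_index")) target
         else kmer_index(target, k = k)
  anc <- query_anchors(idx, query)
  if (!nrow(anc)) return(NULL)
  best <- NULL
  for (sid in unique(anc$seqid)) for (st in c("+", "-")) {
    a <- anc[anc$seqid == sid & anc$strand == st, , drop = FALSE]
    if (!nrow(a)) next
    ch <- extract_chains(a, sid, st, gap_penalty, max_gap_bp,
                         min_chain_bp = 1L, k = idx$k, max_chains = 1L)
    if (!length(ch)) next
    ch <- ch[[1]]
    if (ch$score < min_score) next
    if (is.null(best)) { best <- ch; next }
    better <- ch$score > best$score ||
      (ch$score == best$score &&
         (ch$matched_bp > best$matched_bp ||
            (ch$matched_bp == best$matched_bp &&
               (ch$seqid < best$seqid ||
                  (ch$seqid == best$seqid &&
                     chain_t_span(ch)[1] < chain_t_span(best)[1])))))
    if (better) best <- ch
  }
  if (is.null(best)) return(NULL)
  tl <- idx$seq_lens[[best$seqid]]
  sp <- chain_t_span(best)
  list(interval = genomic_interval(best$seqid,
                                   max(0L, sp[1] - pad_bp),
                                   min(tl, sp[2] + pad_bp),
                                   best$strand),
       chain = best)
}

merge_intervals <- function(starts, ends) {
  if (!length(starts)) return(cbind(start = integer(), end = integer()))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  outs <- c(); oute <- c()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { outs <- c(outs, ms); oute <- c(oute, me); ms <- starts[i]; me <- ends[i] }
  }
  cbind(start = c(outs, ms), end = c(oute, me))
}

#' Alignment ratio of a query span
#'
#' Fraction of a query sub-interval covered by the union of aligned block
#' query-intervals; 1.0 means the span is completely present in the target,
#' 0 means it is absent.
#'
#' @param chains List of \code{alignment_chain} from one query/target
#'   comparison (a single chain is also accepted).
#' @param query_span Numeric length-2 \code{c(start, end)} in query
#'   coordinates (0-based half-open).
#' @return Ratio in [0, 1].
#' @export
alignment_ratio <- function(chains, query_span) {
  if (inherits(chains, "alignment_chain")) chains <- list(chains)
  if (length(query_span) != 2L || query_span[2] <= query_span[1])
    stop("empty query span")
  s0 <- query_span[1]; e0 <- query_span[2]
  starts <- integer(); ends <- integer()
  for (ch in chains) {
    starts <- c(starts, ch$blocks$q_start)
    ends <- c(ends, ch$blocks$q_end)
  }
  m <- merge_intervals(starts, ends)
  cov <- sum(pmax(0, pmin(m[, "end"], e0) - pmax(m[, "start"], s0)))
  cov / (e0 - s0)
}

#' Dot-plot points of a chain set
#'
#' One row per aligned block (query midpoint, target midpoint, strand);
#' forward blocks fall on diagonals, reverse blocks on anti-diagonals.
#'
#' @param chains List of \code{alignment_chain}.
#' @return data.frame with \code{q_mid}, \code{t_mid}, \code{strand}.
#' @export
dotplot_points <- function(chains) {
  if (inherits(chains, "alignment_chain")) chains <- list(chains)
  out <- lapply(chains, function(ch)
    data.frame(q_mid = (ch$blocks$q_start + ch$blocks$q_end) / 2,
               t_mid = (ch$blocks$t_start + ch$blocks$t_end) / 2,
               strand = ch$strand, stringsAsFactors = FALSE))
  if (!length(out))
    return(data.frame(q_mid = numeric(), t_mid = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
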