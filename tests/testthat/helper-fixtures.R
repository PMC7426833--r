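# Shared fixtures: all synthetic, generated in code at test time.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small-genome study conditions used by the fast unit tests (the acceptance
# tests run the full-size defaults).
tiny_cfg <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_chromosomes = 1L,
                   chromosome_length_bp = 300000L, n_genes = 40L,
                   n_elements = 8L,
                   accession_tree = default_accession_tree(4L),
                   assembly_n50_target_bp = 60000L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Brute-force shared k-mer matches between two sequences: every (q, t)
# position pair whose k-mers are equal.  Oracle for the anchor finder.
brute_kmer_matches <- function(query, target, k = 15L) {
  qk <- substring(query, seq_len(nchar(query) - k + 1L),
                  seq_len(nchar(query) - k + 1L) + k - 1L)
  tk <- substring(target, seq_len(nchar(target) - k + 1L),
                  seq_len(nchar(target) - k + 1L) + k - 1L)
  tmap <- split(seq_along(tk), tk)
  out <- list()
  for (q in seq_along(qk)) {
    hits <- tmap[[qk[q]]]
    if (!is.null(hits))
      out[[length(out) + 1L]] <- data.frame(q = q - 1L, t = hits - 1L)
  }
  if (!length(out)) return(data.frame(q = integer(), t = integer()))
  do.call(rbind, out)
}

# (q, t) k-mer pairs implied by a set of chains' ungapped blocks.
chain_kmer_pairs <- function(chains, k = 15L) {
  out <- list()
  for (ch in chains) for (i in seq_len(nrow(ch$blocks))) {
    b <- ch$blocks[i, ]
    n <- b$q_end - b$q_start - k + 1L
    if (n <= 0) next
    out[[length(out) + 1L]] <-
      data.frame(q = b$q_start + seq_len(n) - 1L,
                 t = b$t_start + seq_len(n) - 1L)
  }
  if (!length(out)) return(data.frame(q = integer(), t = integer()))
  unique(do.call(rbind, out))
}

# A hand-built alignment chain for ratio tests.
fake_chain <- function(q_starts, q_ends, t_starts = q_starts,
                       t_ends = q_ends, strand = "+") {
  structure(list(blocks = data.frame(q_start = q_starts, q_end = q_ends,
                                     t_start = t_starts, t_end = t_ends,
                                     identity = 1),
                 score = sum(q_ends - q_starts), seqid = "t",
                 strand = strand,
                 matched_bp = sum(q_ends - q_starts)),
            class = "alignment_chain")
}
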