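# The two bespoke assembly-editing rules: depth-based chimeric-contig
# splitting and hint-guided scaffold joining.

#' Split contigs at low-depth positions
#'
#' Maximal runs with per-bp depth >= \code{min_depth} become new contigs
#' named \code{<id>_partN}; runs shorter than \code{min_run_bp} are
#' discarded, as is all sequence outside retained runs.  A contig whose
#' depth never reaches the threshold is removed entirely.
#'
#' @param assembly A \code{genome_assembly}.
#' @param depths Named list (one integer vector per contig, length equal to
#'   the contig) of read depths.
#' @param min_depth Positions with depth below this are split points
#'   (default 4: split where depth is less than four).
#' @param min_run_bp Minimal retained run.
#' @param rename If FALSE and a contig is kept whole, its name is kept.
#' @return A new \code{genome_assembly}.
#' @export
split_low_depth <- function(assembly, depths, min_depth = 4L,
                            min_run_bp = 100L, rename = TRUE) {
  out <- character(); anchored <- logical()
  for (sid in names(assembly$sequences)) {
    dep <- depths[[sid]]
    if (is.null(dep)) stop("missing depth track for contig ", sid)
    L <- nchar(assembly$sequences[[sid]])
    if (length(dep) != L)
      stop("depth track length mismatch for ", sid)
    r <- rle(dep >= min_depth)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= min_run_bp)
    if (length(ok) == 1L && r$lengths[ok] == L && !rename) {
      out[[sid]] <- assembly$sequences[[sid]]
      anchored[[sid]] <- assembly$anchored[[sid]]
      next
    }
    for (j in seq_along(ok)) {
      nm <- sprintf("%s_part%d", sid, j)
      out[[nm]] <- substr(assembly$sequences[[sid]], starts[ok[j]],
                          ends[ok[j]])
      anchored[[nm]] <- assembly$anchored[[sid]]
    }
  }
  if (!length(out)) stop("no sequence survives depth splitting")
  genome_assembly(assembly$accession_id, out, anchored)
}

#' Read a per-contig depth TSV (position, depth)
#' @param path Two-column TSV (1-based position, depth), one file per
#'   contig, or a three-column (contig, position, depth) combined file.
#' @return Named list of integer depth vectors (only for the combined
#'   layout) or a single vector.
#' @export
read_depth_tsv <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(d) == 2L) {
    v <- integer(max(d[[1]]))
    v[d[[1]]] <- d[[2]]
    return(v)
  }
  lapply(split(d, d[[1]]), function(x) {
    v <- integer(max(x[[2]]))
    v[x[[2]]] <- x[[3]]
    v
  })
}

# Align one terminal window of a hint against the primary assembly and
# return the qualifying hit, or NULL.
hint_end_hit <- function(win_seq, primary_idx, min_identity, min_len_bp,
                         min_score) {
  reg <- best_matching_region(win_seq, primary_idx, pad_bp = 0L,
                              min_score = min_score)
  if (is.null(reg)) return(NULL)
  ch <- reg$chain
  if (ch$matched_bp < min_len_bp) return(NULL)
  if (chain_identity(ch) < min_identity) return(NULL)
  list(seqid = ch$seqid, strand = ch$strand, score = ch$score)
}

#' Join primary scaffolds using hint sequences
#'
#' For each hint sequence the two terminal windows are aligned against the
#' primary scaffolds; when the two ends hit two distinct scaffolds with
#' chains passing the identity / length / score thresholds, those scaffolds
#' are joined in hint-implied order and orientation with an N gap.  Each
#' scaffold end is used at most once; candidate joins are applied greedily
#' by descending combined score, and a conflicting lower-score join is
#' skipped with a warning.
#'
#' @param primary Assembly to be joined.
#' @param hints Assembly providing the joining sequences.
#' @param min_identity,min_len_bp,min_score Alignment thresholds for each
#'   end hit (identity >= 0.99, aligned length >= 5000 bp, chain score >=
#'   1000 by default).
#' @param end_window_bp Terminal window length per hint end.
#' @param gap_n Number of N characters inserted at each junction.
#' @return A new \code{genome_assembly} with joined scaffolds.
#' @export
hint_join <- function(primary, hints, min_identity = 0.99,
                      min_len_bp = 5000L, min_score = BLAST_EQUIV_MIN_SCORE,
                      end_window_bp = 50000L, gap_n = 100L) {
  stopifnot(length(primary$sequences) >= 1L, length(hints$sequences) >= 1L)
  idx <- kmer_index(primary)
  cand <- list()
  for (hid in names(hints$sequences)) {
    hs <- hints$sequences[[hid]]
    L <- nchar(hs)
    w <- min(end_window_bp, floor(L / 2))
    if (w < 15L) next
    left <- substr(hs, 1L, w)
    right <- substr(hs, L - w + 1L, L)
    hl <- hint_end_hit(left, idx, min_identity, min_len_bp, min_score)
    hr <- hint_end_hit(right, idx, min_identity, min_len_bp, min_score)
    if (is.null(hl) || is.null(hr)) next
    if (hl$seqid == hr$seqid) next  # both ends on one scaffold: no join
    # junction side of each scaffold in its original orientation:
    # a '+' left-end hit continues rightwards out of the scaffold's right
    # end; '-' flips that.
    e1 <- if (hl$strand == "+") "R" else "L"
    e2 <- if (hr$strand == "+") "L" else "R"
    cand[[length(cand) + 1L]] <- data.frame(
      hint = hid, s1 = hl$seqid, e1 = e1, s2 = hr$seqid, e2 = e2,
      score = hl$score + hr$score, stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(primary)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$hint), , drop = FALSE]

  used <- character()           # "scaffold:end" keys already consumed
  comp <- setNames(names(primary$sequences), names(primary$sequences))
  find <- function(x) { while (comp[[x]] != x) x <- comp[[x]]; x }
  edges <- list()
  for (i in seq_len(nrow(cand))) {
    k1 <- paste0(cand$s1[i], ":", cand$e1[i])
    k2 <- paste0(cand$s2[i], ":", cand$e2[i])
    if (k1 %in% used || k2 %in% used) {
      warning("conflicting join via hint ", cand$hint[i], " skipped")
      next
    }
    if (find(cand$s1[i]) == find(cand$s2[i])) {
      warning("cyclic join via hint ", cand$hint[i], " skipped")
      next
    }
    comp[find(cand$s1[i])] <- find(cand$s2[i])
    used <- c(used, k1, k2)
    edges[[length(edges) + 1L]] <- cand[i, ]
  }
  if (!length(edges)) return(primary)
  edges <- do.call(rbind, edges)

  # walk each connected component into one oriented path
  gap <- strrep("N", gap_n)
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges$s1[i]]] <- c(adj[[edges$s1[i]]], i)
    adj[[edges$s2[i]]] <- c(adj[[edges$s2[i]]], i)
  }
  in_path <- character()
  out <- character(); anchored <- logical()
  for (sid in names(primary$sequences)) {
    if (sid %in% in_path) next
    deg <- length(adj[[sid]])
    if (deg == 0L) {
      out[[sid]] <- primary$sequences[[sid]]
      anchored[[sid]] <- primary$anchored[[sid]]
      next
    }
    if (deg == 2L) next  # interior scaffold; reached from an endpoint
    # endpoint: orient the first scaffold so its used end faces right,
    # then walk; every subsequent scaffold is oriented so the end it is
    # entered at faces left.
    ei <- adj[[sid]][1]
    e <- edges[ei, ]
    here <- sid
    here_end <- if (e$s1 == sid) e$e1 else e$e2
    s <- primary$sequences[[here]]
    if (here_end == "L") s <- cpp_revcomp(s)
    seqs <- list(s); members <- here
    repeat {
      e <- edges[ei, ]
      other <- if (e$s1 == here) e$s2 else e$s1
      other_end <- if (e$s1 == here) e$e2 else e$e1
      s2 <- primary$sequences[[other]]
      if (other_end == "R") s2 <- cpp_revcomp(s2)
      seqs[[length(seqs) + 1L]] <- s2
      members <- c(members, other)
      nxt <- setdiff(adj[[other]], ei)
      if (!length(nxt)) break
      ei <- nxt[1]
      here <- other
    }
    nm <- paste(members, collapse = "_")
    out[[nm]] <- paste(unlist(seqs), collapse = gap)
    anchored[[nm]] <- any(unlist(primary$anchored[members]))
    in_path <- c(in_path, members)
  }
  genome_assembly(primary$accession_id, out, anchored)
}
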