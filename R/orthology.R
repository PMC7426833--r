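# Cross-genome gene-partner classification: reciprocal best hits on
# transcript (DNA 15-mers) and protein (4-mers) channels, transcript-to-
# genome confirmation, CNV/PAP candidate calling, and consensus-ID
# assignment.

PARTNER_CATEGORIES <- c("one_to_one", "homologue_partner", "tandem_dup_cnv",
                        "non_tandem_cnv_pap", "unanchored", "no_call")

#' Directed best hits by k-mer containment
#'
#' Similarity is shared-k-mer containment |shared| / |query k-mers| over
#' k-mer sets (transcript channel: DNA k = 15; protein channel: amino-acid
#' k = 4).  The best hit per query is reported with a deterministic
#' tie-break (higher containment, longer subject, lexicographic id); hits
#' below the minimum containment are dropped.  Queries whose top containment
#' is shared by several subjects (within 1e-9) are flagged \code{tied}.
#'
#' @param genes_a Query gene table (with \code{transcript_seq} /
#'   \code{protein_seq}).
#' @param genes_b Subject gene table.
#' @param channel \code{"transcript"} or \code{"protein"}.
#' @param min_containment Hits below this are dropped.
#' @return data.frame: query, subject, containment, tied.
#' @export
similarity_best_hits <- function(genes_a, genes_b,
                                 channel = c("transcript", "protein"),
                                 min_containment = 0.3) {
  channel <- match.arg(channel)
  empty <- data.frame(query = character(), subject = character(),
                      containment = numeric(), tied = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(genes_a) || !nrow(genes_b)) return(empty)
  col <- if (channel == "transcript") "transcript_seq" else "protein_seq"
  k <- if (channel == "transcript") 15L else 4L
  m <- cpp_containment(genes_a[[col]], genes_b[[col]], k,
                       channel == "transcript")
  sub_len <- nchar(genes_b[[col]])
  out <- vector("list", nrow(genes_a))
  for (i in seq_len(nrow(genes_a))) {
    v <- m[i, ]
    top <- max(v)
    if (top < min_containment) next
    cand <- which(v >= top - 1e-9)
    tied <- length(cand) > 1L
    o <- cand[order(-v[cand], -sub_len[cand], genes_b$gene_id[cand])]
    out[[i]] <- data.frame(query = genes_a$gene_id[i],
                           subject = genes_b$gene_id[o[1]],
                           containment = v[o[1]], tied = tied,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

reciprocal_pairs <- function(bh_ab, bh_ba) {
  if (!nrow(bh_ab) || !nrow(bh_ba)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      containment = numeric(), stringsAsFactors = FALSE))
  }
  ba_subject <- setNames(bh_ba$subject, bh_ba$query)
  ba_untied <- setNames(!bh_ba$tied, bh_ba$query)
  keep <- !bh_ab$tied &
    bh_ab$subject %in% bh_ba$query &
    ba_untied[bh_ab$subject] &
    ba_subject[bh_ab$subject] == bh_ab$query
  keep[is.na(keep)] <- FALSE
  data.frame(gene_a = bh_ab$query[keep], gene_b = bh_ab$subject[keep],
             containment = bh_ab$containment[keep], stringsAsFactors = FALSE)
}

#' One-to-one orthologue and homologue-partner calls
#'
#' A pair is one-to-one iff it is reciprocal best (untied) in BOTH the
#' transcript and the protein channel AND the best-matching genomic region
#' of the A transcript in genome B overlaps the locus of the B gene by at
#' least 1 bp (the transcript-to-genome confirmation).  Pairs reciprocal in
#' exactly one channel (or failing confirmation) are homologue partners.
#' Remaining genes of either side get \code{no_call} rows.
#'
#' @param genes_a,genes_b Gene tables with sequences.
#' @param genome_b Genome assembly of side B (or a \code{kmer_index} plus
#'   \code{genes_b} coordinates).
#' @param min_containment Channel threshold.
#' @param min_region_score Minimum chain score for the genomic confirmation.
#' @return data.frame of partner calls: gene_a, gene_b, category,
#'   containment_t, containment_p, overlap_bp.
#' @export
call_one_to_one <- function(genes_a, genes_b, genome_b,
                            min_containment = 0.3, min_region_score = 100) {
  bt_ab <- similarity_best_hits(genes_a, genes_b, "transcript", min_containment)
  bt_ba <- similarity_best_hits(genes_b, genes_a, "transcript", min_containment)
  bp_ab <- similarity_best_hits(genes_a, genes_b, "protein", min_containment)
  bp_ba <- similarity_best_hits(genes_b, genes_a, "protein", min_containment)
  rt <- reciprocal_pairs(bt_ab, bt_ba)
  rp <- reciprocal_pairs(bp_ab, bp_ba)
  key <- function(df) paste(df$gene_a, df$gene_b, sep = "\r")
  both <- intersect(key(rt), key(rp))
  one <- setdiff(union(key(rt), key(rp)), both)

  idx_b <- if (inherits(genome_b, "kmer_index")) genome_b
           else kmer_index(genome_b)
  cont_t <- setNames(bt_ab$containment, paste(bt_ab$query, bt_ab$subject,
                                              sep = "\r"))
  cont_p <- setNames(bp_ab$containment, paste(bp_ab$query, bp_ab$subject,
                                              sep = "\r"))
  calls <- list()
  used_a <- character(); used_b <- character()
  for (kp in both) {
    ab <- strsplit(kp, "\r", fixed = TRUE)[[1]]
    a <- ab[1]; b <- ab[2]
    tx <- genes_a$transcript_seq[genes_a$gene_id == a]
    reg <- best_matching_region(tx, idx_b, min_score = min_region_score)
    ov <- 0L
    if (!is.null(reg)) {
      gb <- genes_b[genes_b$gene_id == b, ]
      if (reg$interval$seqid == gb$seqid)
        ov <- max(0L, min(reg$interval$end, gb$end) -
                    max(reg$interval$start, gb$start))
    }
    cat_ <- if (ov >= 1L) "one_to_one" else "homologue_partner"
    calls[[length(calls) + 1L]] <- data.frame(
      gene_a = a, gene_b = b, category = cat_,
      containment_t = unname(cont_t[kp]), containment_p = unname(cont_p[kp]),
      overlap_bp = ov, stringsAsFactors = FALSE)
    used_a <- c(used_a, a); used_b <- c(used_b, b)
  }
  for (kp in one) {
    ab <- strsplit(kp, "\r", fixed = TRUE)[[1]]
    if (ab[1] %in% used_a || ab[2] %in% used_b) next
    calls[[length(calls) + 1L]] <- data.frame(
      gene_a = ab[1], gene_b = ab[2], category = "homologue_partner",
      containment_t = unname(cont_t[kp]), containment_p = unname(cont_p[kp]),
      overlap_bp = NA_integer_, stringsAsFactors = FALSE)
    used_a <- c(used_a, ab[1]); used_b <- c(used_b, ab[2])
  }
  for (a in setdiff(genes_a$gene_id, used_a))
    calls[[length(calls) + 1L]] <- data.frame(
      gene_a = a, gene_b = NA_character_, category = "no_call",
      containment_t = NA_real_, containment_p = NA_real_,
      overlap_bp = NA_integer_, stringsAsFactors = FALSE)
  for (b in setdiff(genes_b$gene_id, used_b))
    calls[[length(calls) + 1L]] <- data.frame(
      gene_a = NA_character_, gene_b = b, category = "no_call",
      containment_t = NA_real_, containment_p = NA_real_,
      overlap_bp = NA_integer_, stringsAsFactors = FALSE)
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

count_intervening <- function(genes, seqid, lo, hi) {
  sum(genes$seqid == seqid & genes$start >= lo & genes$end <= hi)
}

# Classify the no_call genes of ONE side.  `genes_self` is that side's gene
# table, `genes_other`/`genome_other` the opposite side.
classify_side <- function(ids, genes_self, assembly_self, genes_other,
                          genome_other_idx, tandem_window_bp,
                          tandem_max_intervening, within_containment,
                          cross_containment, min_region_score) {
  if (!length(ids)) {
    return(data.frame(gene = character(), category = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  m_self <- cpp_containment(
    genes_self$transcript_seq[match(ids, genes_self$gene_id)],
    genes_self$transcript_seq, 15L, TRUE)
  m_cross <- if (nrow(genes_other))
    cpp_containment(
      genes_self$transcript_seq[match(ids, genes_self$gene_id)],
      genes_other$transcript_seq, 15L, TRUE)
  else matrix(0, length(ids), 0)

  out <- list()
  for (j in seq_along(ids)) {
    gid <- ids[j]
    gi <- match(gid, genes_self$gene_id)
    anchored <- assembly_self$anchored[[genes_self$seqid[gi]]]
    if (isFALSE(anchored)) {
      out[[j]] <- data.frame(gene = gid, category = "unanchored",
                             evidence = "sequence_not_anchored",
                             stringsAsFactors = FALSE)
      next
    }
    v <- m_self[j, ]
    v[gi] <- -1  # exclude self
    best_within <- which.max(v)
    tandem <- FALSE
    if (v[best_within] >= within_containment &&
        genes_self$seqid[best_within] == genes_self$seqid[gi]) {
      lo <- min(genes_self$end[gi], genes_self$end[best_within])
      hi <- max(genes_self$start[gi], genes_self$start[best_within])
      gap <- max(0L, hi - lo)
      if (gap <= tandem_window_bp &&
          count_intervening(genes_self, genes_self$seqid[gi], lo, hi) <=
            tandem_max_intervening)
        tandem <- TRUE
    }
    if (tandem) {
      out[[j]] <- data.frame(gene = gid, category = "tandem_dup_cnv",
                             evidence = sprintf("within_genome_homologue=%s",
                                                genes_self$gene_id[best_within]),
                             stringsAsFactors = FALSE)
      next
    }
    reg <- best_matching_region(genes_self$transcript_seq[gi],
                                genome_other_idx,
                                min_score = min_region_score)
    if (is.null(reg)) {
      out[[j]] <- data.frame(gene = gid, category = "non_tandem_cnv_pap",
                             evidence = "no_genomic_hit",
                             stringsAsFactors = FALSE)
      next
    }
    has_homologue <- v[best_within] >= within_containment ||
      (ncol(m_cross) > 0 && max(m_cross[j, ]) >= cross_containment)
    out[[j]] <- data.frame(
      gene = gid,
      category = if (has_homologue) "non_tandem_cnv_pap" else "no_call",
      evidence = if (has_homologue) "homologue_elsewhere" else "none",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classify CNV / PAP candidates among unpartnered genes
#'
#' A gene without a one-to-one partner becomes \code{tandem_dup_cnv} when
#' its best within-genome homologue lies on the same sequence within the
#' tandem window with few intervening genes; \code{non_tandem_cnv_pap} when
#' it has homologues elsewhere or no cross-genome genomic hit at all (the
#' PAP signature); \code{unanchored} when its sequence is not
#' chromosome-anchored.
#'
#' @param calls Output of \code{\link{call_one_to_one}}.
#' @param genes_a,genes_b,assembly_a,assembly_b Gene tables and assemblies.
#' @param tandem_window_bp,tandem_max_intervening Tandem definition.
#' @param within_containment,cross_containment Homologue thresholds.
#' @param min_region_score Genomic-hit threshold.
#' @return \code{calls} with no_call rows reclassified where possible; the
#'   classification is reported in \code{category} and \code{evidence}.
#' @export
classify_cnv_pap <- function(calls, genes_a, genes_b, assembly_a, assembly_b,
                             tandem_window_bp = 100000L,
                             tandem_max_intervening = 5L,
                             within_containment = 0.5,
                             cross_containment = 0.3,
                             min_region_score = 100) {
  idx_a <- kmer_index(assembly_a)
  idx_b <- kmer_index(assembly_b)
  una <- calls$gene_a[calls$category == "no_call" & !is.na(calls$gene_a)]
  unb <- calls$gene_b[calls$category == "no_call" & !is.na(calls$gene_b)]
  ca <- classify_side(una, genes_a, assembly_a, genes_b, idx_b,
                      tandem_window_bp, tandem_max_intervening,
                      within_containment, cross_containment, min_region_score)
  cb <- classify_side(unb, genes_b, assembly_b, genes_a, idx_a,
                      tandem_window_bp, tandem_max_intervening,
                      within_containment, cross_containment, min_region_score)
  calls$evidence <- calls$evidence %||% NA_character_
  if (nrow(ca)) {
    i <- match(ca$gene, calls$gene_a)
    calls$category[i] <- ca$category
    calls$evidence[i] <- ca$evidence
  }
  if (nrow(cb)) {
    i <- match(cb$gene, calls$gene_b)
    calls$category[i] <- cb$category
    calls$evidence[i] <- cb$evidence
  }
  calls
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign consensus gene ids from one-to-one partners
#'
#' Every one-to-one gene of side A receives the partner-derived id
#' \code{<partner_id><suffix>}; all other genes keep their native ids.
#' The mapping must be injective; the operation is idempotent on its
#' inputs.
#'
#' @param calls Partner calls.
#' @param suffix Consensus suffix (default \code{".jh1"}).
#' @return Named character vector: native id -> consensus id.
#' @export
assign_consensus_ids <- function(calls, suffix = ".jh1") {
  oto <- calls[calls$category == "one_to_one", , drop = FALSE]
  ids <- calls$gene_a[!is.na(calls$gene_a)]
  map <- setNames(ids, ids)
  map[oto$gene_a] <- paste0(oto$gene_b, suffix)
  if (anyDuplicated(map)) stop("consensus-id collision after suffixing")
  map
}
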