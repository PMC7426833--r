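# Assembly-based PAP genotyping: extract each element with its flanking
# region from the reference, locate the best-matching region in each target
# assembly, re-align, and score the alignment ratio over the element span
# only.  1.0 means complete presence, 0 absence.

#' Extract an element with flanking sequence from the reference
#'
#' The window is the element span extended by \code{flank_bp} on each side,
#' clipped to the sequence bounds; the element span is re-expressed in
#' window coordinates.
#'
#' @param element One element row (or an element table plus \code{i}).
#' @param reference Reference \code{genome_assembly}.
#' @param flank_bp Flank size, 0--100000 (the study used approx. 50--100 kb).
#' @return \code{list(query = DNA, span = c(start, end) in the window,
#'   window = interval)}.
#' @export
extract_flank <- function(element, reference, flank_bp = 50000L) {
  if (flank_bp < 0 || flank_bp > 100000L)
    stop("flank_bp must lie in [0, 100000]")
  sid <- element$seqid
  if (!sid %in% names(reference$sequences))
    stop("element sequence absent from reference: ", sid)
  L <- nchar(reference$sequences[[sid]])
  ws <- max(0L, element$start - flank_bp)
  we <- min(L, element$end + flank_bp)
  list(query = interval_seq(reference, sid, ws, we),
       span = c(element$start - ws, element$end - ws),
       window = genomic_interval(sid, ws, we))
}

#' Genotype one element in one target assembly
#'
#' The flank query is located in the target (best-matching region, BLAST-n
#' analog with a 1000-matched-bp score floor), the query is re-aligned
#' against that region, and the alignment ratio is measured over the element
#' span only.  \code{present} if ratio >= \code{present_min}, \code{absent}
#' if <= \code{absent_max}, otherwise \code{ambiguous}; if no flank region
#' is found at all the cell is \code{missing} (ratio NA).
#'
#' @param query,element_span From \code{\link{extract_flank}}.
#' @param target Target \code{genome_assembly}.
#' @param target_index Optional prebuilt \code{kmer_index} of the target.
#' @param present_min,absent_max Call thresholds.
#' @param flank_min_score Minimum chain score for locating the region.
#' @return \code{list(ratio, call)}.
#' @export
genotype_element <- function(query, element_span, target,
                             target_index = NULL,
                             present_min = 0.8, absent_max = 0.2,
                             flank_min_score = BLAST_EQUIV_MIN_SCORE) {
  idx <- target_index %||% kmer_index(target)
  reg <- best_matching_region(query, idx, pad_bp = 1000L,
                              min_score = flank_min_score)
  if (is.null(reg)) return(list(ratio = NA_real_, call = "missing"))
  region_seq <- interval_seq(target, reg$interval$seqid,
                             reg$interval$start, reg$interval$end)
  chains <- seed_and_chain(query, region_seq)
  ratio <- alignment_ratio(chains, element_span)
  call <- if (ratio >= present_min) "present"
          else if (ratio <= absent_max) "absent"
          else "ambiguous"
  list(ratio = ratio, call = call)
}

#' Build the element x accession PAP matrix
#'
#' The reference column is filled with ratio 1.0 / present by construction;
#' every other cell is genotyped from the assemblies.
#'
#' @param elements Element table on the reference.
#' @param reference Reference assembly.
#' @param targets Named list of target assemblies (names = accession ids).
#' @param flank_bp Flank size.
#' @param present_min,absent_max Call thresholds.
#' @param flank_min_score Region-location score floor.
#' @return A \code{pap_matrix}: list(ratio, call) matrices with elements as
#'   rows and accessions (reference first) as columns.
#' @export
build_pap_matrix <- function(elements, reference, targets,
                             flank_bp = 50000L, present_min = 0.8,
                             absent_max = 0.2,
                             flank_min_score = BLAST_EQUIV_MIN_SCORE) {
  accs <- c(reference$accession_id,
            vapply(targets, `[[`, character(1), "accession_id"))
  if (anyDuplicated(accs)) stop("duplicate accession ids")
  ne <- nrow(elements)
  ratio <- matrix(NA_real_, ne, length(accs),
                  dimnames = list(elements$element_id, accs))
  call <- matrix("missing", ne, length(accs),
                 dimnames = list(elements$element_id, accs))
  ratio[, 1L] <- 1.0
  call[, 1L] <- "present"
  flanks <- lapply(seq_len(ne), function(i)
    extract_flank(elements[i, ], reference, flank_bp))
  for (j in seq_along(targets)) {
    idx <- kmer_index(targets[[j]])
    for (i in seq_len(ne)) {
      g <- genotype_element(flanks[[i]]$query, flanks[[i]]$span,
                            targets[[j]], target_index = idx,
                            present_min = present_min,
                            absent_max = absent_max,
                            flank_min_score = flank_min_score)
      ratio[i, j + 1L] <- g$ratio
      call[i, j + 1L] <- g$call
    }
  }
  structure(list(ratio = ratio, call = call,
                 element_ids = elements$element_id, accession_ids = accs),
            class = "pap_matrix")
}

#' @export
print.pap_matrix <- function(x, ...) {
  cat(sprintf("<pap_matrix> %d elements x %d accessions\n",
              nrow(x$ratio), ncol(x$ratio)))
  tab <- apply(x$call, 2, function(cc) table(factor(
    cc, levels = c("present", "absent", "ambiguous", "missing"))))
  print(tab)
  invisible(x)
}

#' Hierarchically cluster accessions on the PAP ratio matrix
#'
#' Accession rows of the numeric ratio matrix are clustered with
#' \code{stats::hclust} (complete linkage, Euclidean distance by default,
#' matching plain R hclust usage).  Missing ratios are imputed by the
#' element (column) mean for clustering only; rows are ordered
#' lexicographically first so the result is independent of input order.
#'
#' @param pap A \code{pap_matrix} (or a plain accessions x elements matrix).
#' @param linkage,distance \code{hclust}/\code{dist} methods.
#' @return \code{list(hclust, phylo)} of class \code{pap_dendrogram}.
#' @export
cluster_accessions <- function(pap, linkage = "complete",
                               distance = "euclidean") {
  m <- if (inherits(pap, "pap_matrix")) t(pap$ratio) else pap
  if (nrow(m) < 2L) stop("need at least two accessions")
  m <- m[order(rownames(m)), , drop = FALSE]
  if (anyNA(m)) {
    message("imputing ", sum(is.na(m)), " missing ratio(s) by element mean")
    for (j in which(colSums(is.na(m)) > 0)) {
      mu <- mean(m[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      m[is.na(m[, j]), j] <- mu
    }
  }
  h <- hclust(dist(m, method = distance), method = linkage)
  structure(list(hclust = h,
                 phylo = ape::read.tree(text = write_newick(h))),
            class = "pap_dendrogram")
}

#' @export
print.pap_dendrogram <- function(x, ...) {
  cat("<pap_dendrogram>\n")
  print(x$hclust)
  invisible(x)
}

#' Is a set of accessions monophyletic in the dendrogram?
#' @param dend A \code{pap_dendrogram} (or \code{phylo}).
#' @param tips Accession labels.
#' @return Logical.
#' @export
is_clade <- function(dend, tips) {
  phy <- if (inherits(dend, "pap_dendrogram")) dend$phylo else dend
  ape::is.monophyletic(phy, tips)
}

#' Per-accession presence counts (PAP summary)
#' @param pap A \code{pap_matrix}.
#' @return data.frame: accession, present, absent, ambiguous, missing.
#' @export
pap_summary <- function(pap) {
  lv <- c("present", "absent", "ambiguous", "missing")
  tab <- t(apply(pap$call, 2, function(cc) table(factor(cc, levels = lv))))
  data.frame(accession = rownames(tab), as.data.frame(tab),
             row.names = NULL, check.names = FALSE)
}

#' Write / read a PAP matrix as TSV (ratio and call layers)
#' @param pap A \code{pap_matrix}.
#' @param ratio_path,call_path Output files.
#' @return Invisibly the paths.
#' @export
write_pap_tsv <- function(pap, ratio_path, call_path) {
  write.table(data.frame(element_id = rownames(pap$ratio), pap$ratio,
                         check.names = FALSE),
              ratio_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(element_id = rownames(pap$call), pap$call,
                         check.names = FALSE),
              call_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ratio_path, call_path))
}
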