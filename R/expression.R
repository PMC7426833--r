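# Expression filtering, ripening-inducible classification, and Pearson
# co-expression of elements with their flanking genes.

#' Filter non-expressed features
#'
#' Default mode \code{"any"} keeps features whose FPKM reaches the
#' threshold in at least one sample; mode \code{"all"} keeps only features
#' at or above it in every sample (the stricter reading of removing genes
#' that dip below the threshold anywhere).
#'
#' @param mat An \code{expression_matrix}.
#' @param min_fpkm Threshold (default 0.1).
#' @param mode \code{"any"} or \code{"all"}.
#' @return Filtered \code{expression_matrix} (order preserved).
#' @export
filter_expressed <- function(mat, min_fpkm = 0.1, mode = c("any", "all")) {
  mode <- match.arg(mode)
  stat <- if (mode == "any") apply(mat$values, 1, max)
          else apply(mat$values, 1, min)
  keep <- stat >= min_fpkm
  if (!any(keep)) {
    warning("no feature passes the expression filter")
    keep <- rep(FALSE, nrow(mat$values))
  }
  expression_matrix(mat$values[keep, , drop = FALSE], mat$sample_groups,
                    mat$ripening_group)
}

#' Pearson product-moment correlation
#'
#' Standard coefficient on two equal-length vectors; a constant vector has
#' no defined correlation and yields \code{NA}.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return Correlation in [-1, 1], or NA.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y, method = "pearson")
}

#' Classify fruit-ripening-inducible features
#'
#' A feature is ripening-inducible iff its ripening-group mean FPKM is
#' strictly the maximum over all group means and at least \code{min_fold}
#' times the next-highest group mean (the default 1.0 is a pure argmax
#' rule); ties are not inducible.
#'
#' @param mat An \code{expression_matrix} (usually filtered).
#' @param ripening_group Ripening group label (defaults to the matrix's).
#' @param min_fold Fold requirement over the runner-up group.
#' @return data.frame: feature_id, one column per group mean,
#'   is_ripening_inducible.
#' @export
call_ripening_inducible <- function(mat, ripening_group = NULL,
                                    min_fold = 1.0) {
  ripening_group <- ripening_group %||% mat$ripening_group
  groups <- unique(mat$sample_groups)
  if (length(groups) < 2L) stop("need at least two tissue groups")
  if (!ripening_group %in% groups)
    stop("ripening group absent: ", ripening_group)
  gm <- sapply(groups, function(g)
    rowMeans(mat$values[, mat$sample_groups == g, drop = FALSE]))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1,
                                     dimnames = list(rownames(mat$values),
                                                     groups))
  ri <- match(ripening_group, groups)
  other_max <- apply(gm[, -ri, drop = FALSE], 1, max)
  inducible <- gm[, ri] > other_max & gm[, ri] >= min_fold * other_max
  out <- data.frame(feature_id = rownames(mat$values), gm,
                    is_ripening_inducible = unname(inducible),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Element-to-neighbor co-expression
#'
#' For each query locus the nearest annotated gene on each side within
#' \code{window_bp} (edge-to-edge) defines a neighbor pair; Pearson r is
#' computed on the raw FPKM sample vectors.  Three query sets mirror the
#' histogram contrast of the assay: all genes (control), ripening-inducible
#' elements, and the remaining elements.  Fractions count pairs with
#' r > \code{r_cutoff} among pairs with a defined r.
#'
#' @param elements Element table with reference coordinates.
#' @param genes Gene table with reference coordinates.
#' @param mat \code{expression_matrix} containing genes and elements.
#' @param ripening_ids Ids of ripening-inducible elements (from
#'   \code{\link{call_ripening_inducible}}).
#' @param window_bp Neighbor window.
#' @param r_cutoff Co-expression cutoff (r > cutoff counts).
#' @param log2p1 If TRUE, correlate log2(FPKM+1) instead of raw FPKM.
#' @return \code{list(pairs, fractions, histogram)}: the per-pair table
#'   (with query set), the per-set fraction with its denominator, and the
#'   binned histogram (width 0.1 over [-1, 1]).
#' @export
neighbor_coexpression <- function(elements, genes, mat, ripening_ids,
                                  window_bp = 50000L, r_cutoff = 0.8,
                                  log2p1 = FALSE) {
  vals <- if (log2p1) log2(mat$values + 1) else mat$values
  feature_ok <- rownames(vals)

  build_pairs <- function(queries, set_name, id_col) {
    np <- find_neighbor_genes(queries, genes, window_bp, id_col)
    if (!nrow(np)) return(NULL)
    np$set <- set_name
    np
  }
  rip_el <- elements[elements$element_id %in% ripening_ids, , drop = FALSE]
  oth_el <- elements[!elements$element_id %in% ripening_ids, , drop = FALSE]
  gene_q <- genes
  pairs <- rbind(
    build_pairs(gene_q, "all_genes", "gene_id"),
    build_pairs(rip_el, "ripening_elements", "element_id"),
    build_pairs(oth_el, "other_elements", "element_id"))
  if (is.null(pairs))
    return(list(pairs = data.frame(), fractions = data.frame(),
                histogram = data.frame()))

  skip <- !(pairs$query_id %in% feature_ok) |
          !(pairs$gene_id %in% feature_ok)
  if (any(skip))
    message(sum(skip), " neighbor pair(s) skipped: feature not in matrix")
  pairs <- pairs[!skip, , drop = FALSE]
  pairs$r <- vapply(seq_len(nrow(pairs)), function(i)
    pearson_r(vals[pairs$query_id[i], ], vals[pairs$gene_id[i], ]),
    numeric(1))

  fractions <- do.call(rbind, lapply(split(pairs, pairs$set), function(p) {
    def <- !is.na(p$r)
    data.frame(set = p$set[1], n_pairs = sum(def),
               n_coexpressed = sum(p$r[def] > r_cutoff),
               fraction = if (any(def)) sum(p$r[def] > r_cutoff) / sum(def)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(fractions) <- NULL

  breaks <- seq(-1, 1, by = 0.1)
  histogram <- do.call(rbind, lapply(split(pairs, pairs$set), function(p) {
    r <- pmin(pmax(p$r[!is.na(p$r)], -1), 1)
    cnt <- table(cut(r, breaks = breaks, include.lowest = TRUE))
    data.frame(set = p$set[1], bin_lo = utils::head(breaks, -1),
               bin_hi = breaks[-1], count = as.integer(cnt),
               stringsAsFactors = FALSE)
  }))
  rownames(histogram) <- NULL
  list(pairs = pairs, fractions = fractions, histogram = histogram)
}

#' Co-expression edge list
#'
#' All feature pairs with |r| >= cutoff on raw FPKM, as an edge table.
#' @param mat An \code{expression_matrix}.
#' @param r_cutoff Absolute-correlation cutoff.
#' @param features Optional subset of feature ids.
#' @return data.frame: feature_a, feature_b, r.
#' @export
coexpression_edges <- function(mat, r_cutoff = 0.8, features = NULL) {
  v <- mat$values
  if (!is.null(features)) v <- v[rownames(v) %in% features, , drop = FALSE]
  cc <- suppressWarnings(cor(t(v)))
  cc[lower.tri(cc, diag = TRUE)] <- NA
  idx <- which(abs(cc) >= r_cutoff, arr.ind = TRUE)
  data.frame(feature_a = rownames(cc)[idx[, 1]],
             feature_b = colnames(cc)[idx[, 2]],
             r = cc[idx], stringsAsFactors = FALSE)
}
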