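# Term enrichment by two-sided Fisher's exact test with Benjamini-Hochberg
# control.  The two-sided p is computed directly from the hypergeometric
# distribution: the sum over all tables with the observed margins whose
# probability does not exceed that of the observed table.

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' @param a,b,c,d Non-negative integer counts laid out as
#'   (term & foreground, no-term & foreground, term & background,
#'   no-term & background); the margins are held fixed.
#' @return Two-sided p-value.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative counts")
  if (a + b + c + d < 1) stop("empty table")
  m <- a + c      # term carriers
  n <- b + d      # non-carriers
  k <- a + b      # foreground size
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up false-discovery-rate control with monotonicity enforcement;
#' input order is preserved.  This is the Storey q-value with the null
#' proportion fixed at 1, i.e. a conservative upper bound on it.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Term enrichment of a foreground gene set
#'
#' One row per term observed in the background.  By default the background
#' cells exclude the foreground (set \code{bg_includes_fg} to keep the
#' foreground inside the background universe).  Rows are sorted by p-value,
#' then term id.
#'
#' @param foreground Character vector of ids (subset of background).
#' @param background Character vector of ids (the universe).
#' @param term_table data.frame with columns \code{id}, \code{term} (one
#'   row per id-term assignment); ids without rows count as term-free.
#' @param bg_includes_fg Background convention switch.
#' @return data.frame: term_id, a, b, c, d, odds_ratio, p, q.
#' @export
enrich <- function(foreground, background, term_table,
                   bg_includes_fg = FALSE) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!length(foreground)) stop("empty foreground")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of the background")
  bg <- if (bg_includes_fg) background else setdiff(background, foreground)
  tt <- term_table[term_table$id %in% background, , drop = FALSE]
  terms <- sort(unique(tt$term))
  if (!length(terms)) {
    return(data.frame(term_id = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE))
  }
  nf <- length(foreground); nb <- length(bg)
  rows <- lapply(terms, function(tm) {
    carriers <- unique(tt$id[tt$term == tm])
    a <- sum(foreground %in% carriers)
    b <- nf - a
    cc <- sum(bg %in% carriers)
    d <- nb - cc
    or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    if (a == 0) or <- 0
    data.frame(term_id = tm, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = fisher_two_sided(a, b, cc, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjust_bh(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a term-assignment TSV (id, term_id per row)
#' @param path Two-column TSV with a header.
#' @return data.frame with columns \code{id}, \code{term}.
#' @export
read_term_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  names(d)[1:2] <- c("id", "term")
  d
}
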