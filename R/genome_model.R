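#' @useDynLib retropap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom runif setNames cor dist hclust dhyper
#'   p.adjust
#' @importFrom utils write.table read.delim
NULL

# -- coordinate convention -----------------------------------------------
# All internal coordinates are 0-based half-open [start, end) on the forward
# genomic axis; strand is metadata.  GFF3 on disk is 1-based inclusive, BED
# 0-based half-open.

#' Construct a genome assembly
#'
#' A genome assembly is the named, ordered set of sequences (chromosomes or
#' unanchored contigs) of one accession; all coordinates in the package refer
#' to it.  Sequences are case-folded to upper case and any symbol outside
#' A/C/G/T/N is replaced by N.
#'
#' @param accession_id Accession name.
#' @param sequences Named character vector of DNA strings; names are the
#'   sequence ids and must be unique.
#' @param anchored Logical vector (recycled) flagging chromosome-anchored
#'   sequences; unanchored contigs carry \code{FALSE}.
#' @return An object of class \code{genome_assembly}.
#' @export
genome_assembly <- function(accession_id, sequences, anchored = TRUE) {
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named")
  up <- toupper(sequences)
  bad <- sum(vapply(gregexpr("[^ACGTN]", up), function(m)
    if (m[1] == -1L) 0L else length(m), integer(1)))
  if (bad > 0) {
    warning(sprintf("%d non-ACGTN symbols replaced by N", bad))
    up <- gsub("[^ACGTN]", "N", up)
  }
  if (any(nchar(up) == 0L)) stop("empty sequence in assembly")
  anchored <- rep_len(as.logical(anchored), length(up))
  names(anchored) <- names(up)
  structure(list(accession_id = accession_id, sequences = up,
                 anchored = anchored),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s: %d sequence(s), %.3f Mb total\n",
              x$accession_id, length(x$sequences),
              sum(nchar(x$sequences)) / 1e6))
  invisible(x)
}

#' Sequence lengths of an assembly
#' @param assembly A \code{genome_assembly}.
#' @return Named integer vector of lengths.
#' @export
seq_lengths <- function(assembly) {
  vapply(assembly$sequences, nchar, integer(1))
}

#' Read a multi-record FASTA file into a genome assembly
#'
#' Record order is preserved; sequences are upper-cased and non-ACGTN symbols
#' are mapped to N with a warning giving the count.
#'
#' @param path FASTA file.
#' @param accession_id Accession label; defaults to the file base name.
#' @param anchored Logical flag(s) for the sequences.
#' @return A \code{genome_assembly}.
#' @export
read_fasta <- function(path, accession_id = NULL, anchored = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence ids in ", path)
  if (is.null(accession_id))
    accession_id <- sub("\\.(fa|fasta|fna)$", "", basename(path))
  genome_assembly(accession_id, setNames(as.character(ss), nm),
                  anchored = anchored)
}

#' Write a genome assembly to FASTA
#' @param assembly A \code{genome_assembly}.
#' @param path Output file.
#' @param width Line width.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(assembly$sequences)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

# -- intervals -----------------------------------------------------------

#' Create a genomic interval record
#'
#' @param sequence_id Sequence the interval lives on.
#' @param start,end 0-based half-open coordinates, \code{0 <= start < end}.
#' @param strand One of \code{"+"}, \code{"-"}, \code{"."}.
#' @return A one-row data.frame (seqid, start, end, strand).
#' @export
genomic_interval <- function(sequence_id, start, end, strand = ".") {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-", "."))
  data.frame(seqid = sequence_id, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Extract the DNA of an interval from an assembly
#' @param assembly A \code{genome_assembly}.
#' @param seqid,start,end Interval (0-based half-open).
#' @param strand If \code{"-"}, the reverse complement is returned.
#' @return DNA string.
#' @export
interval_seq <- function(assembly, seqid, start, end, strand = "+") {
  s <- assembly$sequences[[seqid]]
  if (is.null(s)) stop("sequence not in assembly: ", seqid)
  stopifnot(start >= 0, end <= nchar(s), start < end)
  out <- substr(s, start + 1L, end)
  if (strand == "-") out <- cpp_revcomp(out) else out
}

#' Reverse-complement a DNA string
#' @param x DNA string (ACGTN).
#' @return Reverse complement.
#' @export
revcomp <- function(x) cpp_revcomp(toupper(x))

translate_dna <- function(x) {
  if (nchar(x) %% 3L != 0L) stop("CDS length not a multiple of 3")
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X"))
}

# -- gene / element tables -----------------------------------------------

empty_gene_table <- function() {
  data.frame(gene_id = character(), seqid = character(), start = integer(),
             end = integer(), strand = character(), coding = logical(),
             stringsAsFactors = FALSE)
}

# Genes are a data.frame with one row per gene and list-columns holding the
# exon/CDS sub-intervals (0-based half-open, genomic forward axis, sorted):
#   gene_id seqid start end strand coding exon_starts exon_ends cds_starts
#   cds_ends transcript_seq protein_seq
make_gene_table <- function(gene_id, seqid, start, end, strand,
                            exon_starts, exon_ends, cds_starts, cds_ends) {
  df <- data.frame(gene_id = gene_id, seqid = seqid,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, coding = TRUE, stringsAsFactors = FALSE)
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  df$cds_starts <- cds_starts
  df$cds_ends <- cds_ends
  df
}

# Splice exon (or CDS) pieces; minus-strand genes get the reverse complement
# of the forward-axis concatenation.
splice_seq <- function(assembly, seqid, starts, ends, strand) {
  o <- order(starts)
  pieces <- mapply(function(s, e) interval_seq(assembly, seqid, s, e, "+"),
                   starts[o], ends[o])
  s <- paste0(pieces, collapse = "")
  if (strand == "-") cpp_revcomp(s) else s
}

#' Attach transcript and protein sequences to a gene table
#'
#' The transcript is the spliced exon sequence (reverse-complemented for
#' minus-strand genes); the protein is the standard-code translation of the
#' spliced CDS.  Genes whose spliced CDS length is not a multiple of three
#' are flagged non-coding with a warning and get an empty protein.
#'
#' @param genes Gene table (see \code{\link{read_gff3}}).
#' @param assembly The assembly the coordinates refer to.
#' @return The gene table with \code{transcript_seq}/\code{protein_seq}.
#' @export
add_gene_seqs <- function(genes, assembly) {
  n <- nrow(genes)
  tx <- character(n); cds <- character(n); coding <- rep(TRUE, n)
  for (i in seq_len(n)) {
    tx[i] <- splice_seq(assembly, genes$seqid[i], genes$exon_starts[[i]],
                        genes$exon_ends[[i]], genes$strand[i])
    cds[i] <- splice_seq(assembly, genes$seqid[i], genes$cds_starts[[i]],
                         genes$cds_ends[[i]], genes$strand[i])
  }
  bad <- nchar(cds) %% 3L != 0L
  if (any(bad)) {
    warning("CDS not a multiple of 3 after splicing for: ",
            paste(genes$gene_id[bad], collapse = ", "),
            "; marked non-coding")
    coding[bad] <- FALSE
  }
  pr <- character(n)
  if (any(!bad)) {
    # translate all coding genes in one call
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds[!bad]), if.fuzzy.codon = "X"))
    pr[!bad] <- sub("\\*$", "", aa)
  }
  genes$transcript_seq <- tx
  genes$protein_seq <- pr
  genes$coding <- coding
  genes
}

#' Build a Gag-like element table
#'
#' @param element_id,seqid,start,end,strand Vectors of equal length
#'   (coordinates 0-based half-open).
#' @param class_label Element class (e.g. \code{"LTR/gypsy"}).
#' @param term_ids List (one character vector per element) of term ids; must
#'   contain the Gag-domain term used for selection.
#' @param gag_term The Gag-domain term id.
#' @return data.frame with a \code{term_ids} list-column.
#' @export
gag_element_table <- function(element_id, seqid, start, end, strand = "+",
                              class_label = "LTR/gypsy",
                              term_ids = NULL, gag_term = "IPR005162") {
  n <- length(element_id)
  if (is.null(term_ids)) term_ids <- rep(list(gag_term), n)
  ok <- vapply(term_ids, function(t) gag_term %in% t, logical(1))
  if (!all(ok)) stop("every element must carry the Gag-domain term ", gag_term)
  df <- data.frame(element_id = element_id, seqid = seqid,
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(strand, n),
                   class_label = rep_len(class_label, n),
                   stringsAsFactors = FALSE)
  df$term_ids <- term_ids
  df
}

# -- GFF3 ----------------------------------------------------------------

#' Read gene models and Gag-like elements from GFF3
#'
#' Reads gene/mRNA/exon/CDS features plus element rows distinguished by an
#' attribute key (default \code{gag_like=1}).  GFF3 1-based inclusive
#' coordinates are converted to internal 0-based half-open; minus-strand
#' features keep forward genomic coordinates with the strand flag.
#'
#' @param path GFF3 file.
#' @param assembly Assembly providing the sequences (used to splice
#'   transcript and protein sequences).
#' @param element_key Attribute marking element rows.
#' @return \code{list(genes = <gene table>, elements = <element table>)}.
#' @export
read_gff3 <- function(path, assembly, element_key = "gag_like") {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  seqid <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L   # GFF3 1-based incl -> 0-based ho
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  type <- as.character(md$type)

  is_elem <- if (is.null(md[[element_key]])) rep(FALSE, length(gr))
             else !is.na(md[[element_key]]) & md[[element_key]] == "1"
  elements <- if (any(is_elem)) {
    terms <- if ("term_ids" %in% names(md)) {
      lapply(md$term_ids[is_elem], function(x)
        strsplit(as.character(x), ",", fixed = TRUE)[[1]])
    } else rep(list("IPR005162"), sum(is_elem))
    gag_element_table(as.character(md$ID[is_elem]), seqid[is_elem],
                      start0[is_elem], end0[is_elem], strand[is_elem],
                      class_label = if ("class_label" %in% names(md))
                        as.character(md$class_label[is_elem]) else "LTR/gypsy",
                      term_ids = terms)
  } else gag_element_table(character(), character(), integer(), integer())

  gi <- which(type == "gene" & !is_elem)
  genes <- empty_gene_table()
  if (length(gi)) {
    ids <- as.character(md$ID[gi])
    parent <- as.character(md$Parent)  # NA for parentless rows
    # map exon/CDS rows to their gene via the mRNA layer (or directly)
    mrna <- which(type == "mRNA")
    mrna_gene <- setNames(parent[mrna], as.character(md$ID[mrna]))
    owner <- function(i) {
      p <- parent[i]
      if (is.na(p)) return(NA_character_)
      if (p %in% names(mrna_gene)) unname(mrna_gene[[p]]) else p
    }
    exo <- which(type == "exon"); cdsr <- which(type == "CDS")
    exg <- vapply(exo, owner, character(1))
    cdg <- vapply(cdsr, owner, character(1))
    es <- el <- cs <- cl <- vector("list", length(gi))
    for (j in seq_along(gi)) {
      gid <- ids[j]
      ei <- exo[!is.na(exg) & exg == gid]
      ci <- cdsr[!is.na(cdg) & cdg == gid]
      if (!length(ei)) { ei <- gi[j] }     # exonless gene: locus = one exon
      o <- order(start0[ei])
      ei <- ei[o]
      if (any(start0[ei] < start0[gi[j]] | end0[ei] > end0[gi[j]]))
        stop("exon outside parent span for gene ", gid)
      if (any(utils::head(end0[ei], -1) > utils::tail(start0[ei], -1)))
        stop("overlapping exons in gene ", gid)
      es[[j]] <- start0[ei]; el[[j]] <- end0[ei]
      if (length(ci)) {
        o <- order(start0[ci])
        cs[[j]] <- start0[ci][o]; cl[[j]] <- end0[ci][o]
      } else { cs[[j]] <- es[[j]]; cl[[j]] <- el[[j]] }
    }
    genes <- make_gene_table(ids, seqid[gi], start0[gi], end0[gi], strand[gi],
                             es, el, cs, cl)
    genes <- add_gene_seqs(genes, assembly)
  }
  list(genes = genes, elements = elements)
}

gff3_attr_escape <- function(x) gsub("([;=,%])", "", x)

#' Write gene models and elements to GFF3
#'
#' Inverse of \code{\link{read_gff3}}: internal 0-based half-open coordinates
#' become 1-based inclusive columns; elements are emitted as \code{gene} rows
#' carrying \code{gag_like=1} and their term ids.
#'
#' @param genes Gene table (may be empty).
#' @param elements Element table (may be empty).
#' @param path Output file.
#' @param source_label Column 2 value.
#' @return Invisibly, \code{path}.
#' @export
write_gff3 <- function(genes, elements, path, source_label = "retropap") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(seqid, type, s, e, strand, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, source_label, type, s + 1L, e, strand, attrs)
  if (nrow(genes)) for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- gff3_attr_escape(g$gene_id)
    writeLines(fmt(g$seqid, "gene", g$start, g$end, g$strand,
                   paste0("ID=", gid)), con)
    mid <- paste0(gid, ".t1")
    writeLines(fmt(g$seqid, "mRNA", g$start, g$end, g$strand,
                   paste0("ID=", mid, ";Parent=", gid)), con)
    for (j in seq_along(g$exon_starts[[1]]))
      writeLines(fmt(g$seqid, "exon", g$exon_starts[[1]][j],
                     g$exon_ends[[1]][j], g$strand,
                     paste0("ID=", mid, ".e", j, ";Parent=", mid)), con)
    for (j in seq_along(g$cds_starts[[1]]))
      writeLines(fmt(g$seqid, "CDS", g$cds_starts[[1]][j],
                     g$cds_ends[[1]][j], g$strand,
                     paste0("ID=", mid, ".c", j, ";Parent=", mid)), con)
  }
  if (nrow(elements)) for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    writeLines(fmt(e$seqid, "gene", e$start, e$end, e$strand,
                   paste0("ID=", gff3_attr_escape(e$element_id),
                          ";gag_like=1;class_label=", e$class_label,
                          ";term_ids=",
                          paste(e$term_ids[[1]], collapse = ","))), con)
  }
  invisible(path)
}

#' Read/write a BED4 element sidecar
#'
#' BED is 0-based half-open on disk, matching the internal convention.
#' @param path BED file.
#' @param gag_term Term attached to every element read.
#' @return Element table.
#' @export
read_bed_elements <- function(path, gag_term = "IPR005162") {
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gag_element_table(b[[4]], b[[1]], b[[2]], b[[3]], gag_term = gag_term)
}

#' @rdname read_bed_elements
#' @param elements Element table to write.
#' @export
write_bed_elements <- function(elements, path) {
  write.table(elements[, c("seqid", "start", "end", "element_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# -- expression matrix ---------------------------------------------------

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, features x samples, non-negative FPKM.
#' @param sample_groups Named character vector mapping every sample (column)
#'   to one tissue-group label.
#' @param ripening_group The post-harvest-ripening group label.
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, sample_groups,
                              ripening_group = "ripening_fruit") {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0))
  if (is.null(colnames(values)) ||
      (nrow(values) > 0L && is.null(rownames(values))))
    stop("values must have feature rownames and sample colnames")
  if (!all(colnames(values) %in% names(sample_groups)))
    stop("every sample needs a group assignment")
  sample_groups <- sample_groups[colnames(values)]
  if (!ripening_group %in% sample_groups)
    stop("ripening group '", ripening_group, "' absent from sample groups")
  structure(list(values = values, sample_groups = sample_groups,
                 ripening_group = ripening_group),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples, %d groups\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_groups))))
  invisible(x)
}

#' Read an expression TSV plus sample-group table
#'
#' The matrix TSV has a header row of sample ids and feature ids in the
#' first column; the group TSV has columns \code{sample_id}, \code{group}.
#'
#' @param path Matrix TSV.
#' @param groups_path Sample-group TSV.
#' @param ripening_group Ripening group label.
#' @return An \code{expression_matrix}.
#' @export
read_expression_tsv <- function(path, groups_path,
                                ripening_group = "ripening_fruit") {
  m <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(m[, -1, drop = FALSE])
  rownames(vals) <- m[[1]]
  g <- read.delim(groups_path, stringsAsFactors = FALSE)
  expression_matrix(vals, setNames(g$group, g$sample_id), ripening_group)
}

#' @rdname read_expression_tsv
#' @param mat An \code{expression_matrix} to write.
#' @export
write_expression_tsv <- function(mat, path, groups_path = NULL) {
  df <- data.frame(feature_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path))
    write.table(data.frame(sample_id = names(mat$sample_groups),
                           group = unname(mat$sample_groups)),
                groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- Newick --------------------------------------------------------------

#' Serialize a dendrogram to Newick
#'
#' Accepts an \code{hclust} (leaf branch lengths are the merge heights, so
#' two leaves merged at height 1 give \code{"(A:1,B:1);"}), an ape
#' \code{phylo}, or a single leaf label.
#'
#' @param tree \code{hclust}, \code{phylo}, or one leaf label.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  if (is.character(tree) && length(tree) == 1L)
    return(paste0(tree, ";"))
  if (inherits(tree, "phylo")) {
    if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
    return(ape::write.tree(tree))
  }
  if (inherits(tree, "hclust")) {
    if (anyDuplicated(tree$labels)) stop("duplicate leaf labels")
    node <- function(i, parent_h) {
      if (i < 0) {  # leaf
        sprintf("%s:%s", tree$labels[-i], format(parent_h, digits = 15))
      } else {
        h <- tree$height[i]
        sprintf("(%s,%s):%s", node(tree$merge[i, 1], h),
                node(tree$merge[i, 2], h),
                format(parent_h - h, digits = 15))
      }
    }
    k <- nrow(tree$merge)
    h <- tree$height[k]
    return(sprintf("(%s,%s);", node(tree$merge[k, 1], h),
                   node(tree$merge[k, 2], h)))
  }
  stop("unsupported tree object")
}

#' Parse a Newick string
#' @param text Newick text.
#' @return An ape \code{phylo} (or the leaf label for a single-leaf tree).
#' @export
read_newick <- function(text) {
  if (grepl("^[^(),;]+;?$", trimws(text)))
    return(sub(";$", "", trimws(text)))
  ape::read.tree(text = text)
}
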