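# Synthetic-genome simulator with ground truth.  One integer seed drives
# everything; each stage reseeds at seed + a fixed offset so stages can be
# re-run in isolation (offsets: reference 0, accessions 1, fragmentation 2,
# expression 3).

SEED_OFF_REFERENCE <- 0L
SEED_OFF_ACCESSIONS <- 1L
SEED_OFF_FRAGMENT <- 2L
SEED_OFF_EXPRESSION <- 3L

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                c("A","C","G","T")), 1, paste0, collapse = "")
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

random_dna <- function(n) {
  if (n <= 0L) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

#' Default accession tree
#'
#' A caterpillar tree whose last three leaves form a single tight clade of
#' recently diverged accessions (short internal branches, mimicking a
#' cultivar group of common recent origin) among otherwise ladder-like
#' accessions with unit branch lengths.  Branch lengths scale the per-branch
#' presence-flip probability (a length-1 branch flips at exactly the
#' configured rate).
#'
#' @param n Number of accessions (>= 4).
#' @param clade_branch Branch length inside the planted clade.
#' @return Newick string.
#' @export
default_accession_tree <- function(n = 10L, clade_branch = 0.1) {
  stopifnot(n >= 4L)
  labs <- sprintf("acc%02d", seq_len(n))
  clade <- sprintf("((%s:%g,%s:%g):%g,%s:%g)", labs[n - 2], clade_branch,
                   labs[n - 1], clade_branch, clade_branch, labs[n],
                   2 * clade_branch)
  sub <- clade
  for (i in rev(seq_len(n - 3L)))
    sub <- sprintf("(%s:1,%s:1)", labs[i], sub)
  paste0(sub, ";")
}

#' Simulation configuration
#'
#' Defaults are the study conditions exercised throughout the test suite:
#' 10 accessions on a fixed tree, two 1-Mb chromosomes, 200 genes, 40
#' Gag-like elements of 2--7 kb, per-branch presence flips at 0.15, 0.5\%
#' SNPs, a ripening-inducible element fraction of 0.386 and a neighbor
#' co-expression fraction of 0.594.
#'
#' @param seed Integer master seed.
#' @param n_chromosomes,chromosome_length_bp Genome shape.
#' @param n_genes,n_elements Feature counts.
#' @param element_length_range_bp Uniform range of element lengths.
#' @param accession_tree Newick over the accessions.
#' @param pap_flip_prob_per_branch Per-branch presence flip probability.
#' @param snp_rate,small_indel_rate Per-bp mutation rates.
#' @param assembly_n50_target_bp Target contig N50 for fragmentation.
#' @param tandem_dup_prob,gene_loss_prob Per-gene event probabilities.
#' @param tissue_groups Tissue-group labels (must include
#'   \code{ripening_group}).
#' @param ripening_group Post-harvest-ripening label.
#' @param samples_per_group Replicates per group.
#' @param p_ripening_inducible Fraction of elements made ripening-inducible.
#' @param p_neighbor_coexpressed Fraction of flanking genes of ripening
#'   elements made co-expressed with their element.
#' @param expression_noise_sd Per-sample log-scale noise SD.
#' @param neighbor_window_bp Edge-to-edge window defining a flanking gene.
#' @param ragged_breakpoints If TRUE, element excisions erode up to
#'   \code{ragged_margin_bp} beyond/inside the true span.
#' @param ragged_margin_bp Maximal breakpoint jitter.
#' @param min_feature_gap_bp Minimal gap enforced between placed features.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length_bp = 1000000L,
                       n_genes = 200L,
                       n_elements = 40L,
                       element_length_range_bp = c(2000L, 7000L),
                       accession_tree = default_accession_tree(10L),
                       pap_flip_prob_per_branch = 0.15,
                       snp_rate = 0.005,
                       small_indel_rate = 0.0005,
                       assembly_n50_target_bp = 200000L,
                       tandem_dup_prob = 0.02,
                       gene_loss_prob = 0.02,
                       tissue_groups = c("root", "leaf", "stem", "flower",
                                         "young_fruit", "mature_fruit",
                                         "seed", "ripening_fruit"),
                       ripening_group = "ripening_fruit",
                       samples_per_group = 3L,
                       p_ripening_inducible = 0.386,
                       p_neighbor_coexpressed = 0.594,
                       expression_noise_sd = 0.25,
                       neighbor_window_bp = 50000L,
                       ragged_breakpoints = FALSE,
                       ragged_margin_bp = 200L,
                       min_feature_gap_bp = 300L) {
  cfg <- as.list(environment())
  probs <- c(cfg$pap_flip_prob_per_branch, cfg$snp_rate, cfg$small_indel_rate,
             cfg$tandem_dup_prob, cfg$gene_loss_prob,
             cfg$p_ripening_inducible, cfg$p_neighbor_coexpressed)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$chromosome_length_bp > 0, cfg$n_chromosomes >= 1,
            cfg$ripening_group %in% cfg$tissue_groups,
            cfg$element_length_range_bp[1] <= cfg$element_length_range_bp[2])
  structure(cfg, class = "sim_config")
}

# One gene: coding sequence of whole codons (ATG ... stop, no internal
# stops) with an optional single intron; returns the genomic piece plus
# exon/CDS offsets relative to the gene start on the forward axis.
random_gene_piece <- function() {
  n_codons <- sample(100:400, 1L)
  coding <- paste0("ATG",
                   paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                         collapse = ""), "TAA")
  strand <- sample(c("+", "-"), 1L)
  has_intron <- runif(1) < 0.5
  clen <- nchar(coding)
  if (has_intron) {
    p <- sample(seq(60L, clen - 60L), 1L)
    intron <- random_dna(sample(100:500, 1L))
    sense <- paste0(substr(coding, 1L, p), intron,
                    substr(coding, p + 1L, clen))
    ilen <- nchar(intron)
    # forward-axis exon offsets within the gene span
    if (strand == "+") {
      ex_s <- c(0L, p + ilen); ex_e <- c(p, clen + ilen)
    } else {
      lenB <- clen - p
      ex_s <- c(0L, lenB + ilen); ex_e <- c(lenB, clen + ilen)
    }
    gseq <- if (strand == "+") sense else cpp_revcomp(sense)
  } else {
    gseq <- if (strand == "+") coding else cpp_revcomp(coding)
    ex_s <- 0L; ex_e <- clen
  }
  list(seq = gseq, strand = strand, exon_starts = ex_s, exon_ends = ex_e)
}

# Place feature pieces on a chromosome of length L without overlap, with a
# minimal gap; gap slack is spread by sorted-uniform spacings.
place_features <- function(lens, L, min_gap) {
  n <- length(lens)
  slack <- L - sum(lens) - (n + 1L) * min_gap
  if (slack < 0)
    stop("infeasible packing: ", n, " features of total ", sum(lens),
         " bp do not fit in ", L,
         " bp; reduce n_genes/n_elements or increase chromosome_length_bp")
  cuts <- sort(runif(n))
  gaps <- min_gap + floor(diff(c(0, cuts, 1)) * slack)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  starts
}

#' Simulate the reference genome with genes and Gag-like elements
#'
#' Genes (single- or two-exon, coding, both strands) and elements are placed
#' without overlap on random chromosomes; every element is checked to have
#' at least one gene within the neighbor window on at least one side.
#' Deterministic for a fixed \code{config$seed}.
#'
#' @param config A \code{sim_config}.
#' @return \code{list(reference, genes, elements, truth)} where truth is a
#'   partial truth-table list.
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed + SEED_OFF_REFERENCE)
  nc <- config$n_chromosomes
  chrom_names <- sprintf("chr%02d", seq_len(nc))

  n_genes <- config$n_genes; n_elem <- config$n_elements
  gene_pieces <- lapply(seq_len(n_genes), function(i) random_gene_piece())
  elens <- if (n_elem > 0)
    sample(seq(config$element_length_range_bp[1],
               config$element_length_range_bp[2]), n_elem, replace = TRUE)
  else integer()
  elem_seqs <- vapply(elens, random_dna, character(1))
  gene_ids <- sprintf("MELO3C%06d", seq_len(n_genes))
  elem_ids <- sprintf("MELO.jh9%04d.1", seq_len(n_elem))
  feat_len <- c(vapply(gene_pieces, function(g) nchar(g$seq), integer(1)),
                elens)
  feat_kind <- c(rep("gene", n_genes), rep("element", n_elem))

  # lay features out; redraw the arrangement (not the features) until every
  # element has a gene within the neighbor window on at least one side
  layout <- NULL
  for (attempt in seq_len(20L)) {
    perm <- sample(length(feat_kind))
    feat_chrom <- rep_len(seq_len(nc), length(feat_kind))
    cand <- list()
    ok <- TRUE
    for (ci in seq_len(nc)) {
      sel <- perm[feat_chrom == ci]
      starts <- tryCatch(
        place_features(feat_len[sel], config$chromosome_length_bp,
                       config$min_feature_gap_bp),
        error = function(e) stop(e))
      cand[[ci]] <- data.frame(feat = sel, chrom = ci, start = starts,
                               end = starts + feat_len[sel])
    }
    cand <- do.call(rbind, cand)
    if (n_elem > 0) {
      ce <- cand[feat_kind[cand$feat] == "element", , drop = FALSE]
      cg <- cand[feat_kind[cand$feat] == "gene", , drop = FALSE]
      for (i in seq_len(nrow(ce))) {
        g <- cg[cg$chrom == ce$chrom[i], , drop = FALSE]
        near <- any(abs(ifelse(g$end <= ce$start[i], ce$start[i] - g$end,
                               pmax(0L, g$start - ce$end[i]))) <=
                      config$neighbor_window_bp)
        if (!near) { ok <- FALSE; break }
      }
    }
    if (ok) { layout <- cand; break }
  }
  if (is.null(layout))
    stop("element without any gene inside the neighbor window; ",
         "increase n_genes or neighbor_window_bp")

  seqs <- character(nc); names(seqs) <- chrom_names
  grows <- list(); erows <- list()
  for (ci in seq_len(nc)) {
    here <- layout[layout$chrom == ci, , drop = FALSE]
    here <- here[order(here$start), , drop = FALSE]
    lens <- feat_len[here$feat]
    pieces <- vapply(here$feat, function(f)
      if (f <= n_genes) gene_pieces[[f]]$seq else elem_seqs[f - n_genes],
      character(1))
    bounds <- c(0L, as.vector(rbind(here$start, here$end)),
                config$chromosome_length_bp)
    parts <- character(2L * nrow(here) + 1L)
    for (j in seq_len(nrow(here))) parts[2L * j] <- pieces[j]
    for (j in seq_len(nrow(here) + 1L))
      parts[2L * j - 1L] <- random_dna(bounds[2L * j] - bounds[2L * j - 1L])
    seqs[ci] <- paste(parts, collapse = "")
    for (j in seq_len(nrow(here))) {
      f <- here$feat[j]
      if (feat_kind[f] == "gene") {
        gp <- gene_pieces[[f]]
        grows[[length(grows) + 1L]] <- list(
          gene_id = gene_ids[f], seqid = chrom_names[ci],
          start = here$start[j], end = here$end[j], strand = gp$strand,
          exon_starts = here$start[j] + gp$exon_starts,
          exon_ends = here$start[j] + gp$exon_ends)
      } else {
        erows[[length(erows) + 1L]] <- list(
          element_id = elem_ids[f - n_genes], seqid = chrom_names[ci],
          start = here$start[j], end = here$end[j])
      }
    }
  }

  reference <- genome_assembly("ref", seqs, anchored = TRUE)
  genes <- if (length(grows)) {
    make_gene_table(
      vapply(grows, `[[`, character(1), "gene_id"),
      vapply(grows, `[[`, character(1), "seqid"),
      vapply(grows, `[[`, numeric(1), "start"),
      vapply(grows, `[[`, numeric(1), "end"),
      vapply(grows, `[[`, character(1), "strand"),
      lapply(grows, `[[`, "exon_starts"), lapply(grows, `[[`, "exon_ends"),
      lapply(grows, `[[`, "exon_starts"), lapply(grows, `[[`, "exon_ends"))
  } else empty_gene_table()
  if (nrow(genes)) genes <- add_gene_seqs(genes, reference)
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  elements <- gag_element_table(
    vapply(erows, `[[`, character(1), "element_id"),
    vapply(erows, `[[`, character(1), "seqid"),
    vapply(erows, `[[`, numeric(1), "start"),
    vapply(erows, `[[`, numeric(1), "end"))
  elements <- elements[order(elements$element_id), , drop = FALSE]
  rownames(elements) <- NULL

  if (nrow(elements)) {
    np <- find_neighbor_genes(elements, genes, config$neighbor_window_bp)
    has <- tapply(rep(TRUE, nrow(np)), np$query_id, any)
    if (!all(elements$element_id %in% names(has)))
      stop("element without any gene inside the neighbor window; ",
           "increase n_genes or neighbor_window_bp")
  }

  truth <- list(element_presence = NULL, element_ripening = NULL,
                neighbor_coexpressed = NULL, ortho_pairs = NULL)
  list(reference = reference, genes = genes, elements = elements,
       truth = truth, config = config)
}

# Presence states along the accession tree: root carries every element,
# each edge flips each element independently.  Branch lengths scale the
# flip probability as 1 - (1 - p)^len, so a unit branch flips at p.
simulate_presence <- function(elements, tree, flip_prob) {
  n_elem <- nrow(elements)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  state <- matrix(NA, n_elem, nnode)
  root <- ntip + 1L
  state[, root] <- TRUE
  # edges in preorder
  eo <- ape::reorder.phylo(tree, "cladewise")
  elen <- if (is.null(eo$edge.length)) rep(1, nrow(eo$edge))
          else eo$edge.length
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1]; child <- eo$edge[i, 2]
    p_edge <- 1 - (1 - flip_prob)^elen[i]
    flip <- runif(n_elem) < p_edge
    state[, child] <- xor(state[, par], flip)
  }
  pres <- state[, seq_len(ntip), drop = FALSE]
  colnames(pres) <- tree$tip.label
  rownames(pres) <- elements$element_id
  pres
}

# Build one accession genome + annotation from the reference by applying
# element excisions, gene losses, tandem duplications, SNPs and intergenic
# indels.  Guard zones of >= 50 bp around every feature boundary are kept
# mutation-free so truth coordinates stay exact.
derive_one_accession <- function(acc, ref_sim, presence, config) {
  ref <- ref_sim$reference
  genes <- ref_sim$genes
  elements <- ref_sim$elements
  guard <- 50L
  rag <- config$ragged_breakpoints
  ragm <- config$ragged_margin_bp

  lost <- runif(nrow(genes)) < config$gene_loss_prob
  dup <- !lost & runif(nrow(genes)) < config$tandem_dup_prob

  new_seqs <- character(length(ref$sequences))
  names(new_seqs) <- names(ref$sequences)
  new_genes <- list(); new_elems <- list(); ortho <- list()

  for (sid in names(ref$sequences)) {
    L <- nchar(ref$sequences[[sid]])
    g_here <- which(genes$seqid == sid)
    e_here <- which(elements$seqid == sid)

    # structural edits: pos, ref_len, alt, kind
    edits <- list()
    del_mask_s <- integer(); del_mask_e <- integer()
    for (i in e_here) {
      if (presence[elements$element_id[i]]) next
      s <- elements$start[i]; e <- elements$end[i]
      if (rag) {
        s <- s + sample(seq(-ragm, ragm), 1L)
        e <- e + sample(seq(-ragm, ragm), 1L)
        s <- max(0L, s); e <- min(L, e)
        if (e <= s) next
      }
      edits[[length(edits) + 1L]] <- list(pos = s, ref_len = e - s, alt = "")
      del_mask_s <- c(del_mask_s, elements$start[i] - ragm - guard)
      del_mask_e <- c(del_mask_e, elements$end[i] + ragm + guard)
    }
    for (i in g_here[lost[g_here]]) {
      s <- genes$start[i]; e <- genes$end[i]
      edits[[length(edits) + 1L]] <- list(pos = s, ref_len = e - s, alt = "")
      del_mask_s <- c(del_mask_s, s - guard); del_mask_e <- c(del_mask_e, e + guard)
    }
    for (i in g_here[dup[g_here]]) {
      s <- genes$start[i]; e <- genes$end[i]
      edits[[length(edits) + 1L]] <- list(
        pos = e, ref_len = 0L,
        alt = substr(ref$sequences[[sid]], s + 1L, e))
    }

    # allowed positions for point mutations
    feat_s <- c(genes$start[g_here], elements$start[e_here])
    feat_e <- c(genes$end[g_here], elements$end[e_here])
    snp_ok <- rep(TRUE, L)
    for (b in c(feat_s, feat_e))
      snp_ok[max(1L, b - guard + 1L):min(L, b + guard)] <- FALSE
    for (j in seq_along(del_mask_s))
      snp_ok[max(1L, del_mask_s[j] + 1L):min(L, del_mask_e[j])] <- FALSE
    indel_ok <- snp_ok
    for (j in seq_along(feat_s))
      indel_ok[max(1L, feat_s[j] + 1L):min(L, feat_e[j])] <- FALSE

    ok_pos <- which(snp_ok)
    n_snp <- rbinom(1L, length(ok_pos), config$snp_rate)
    snp_pos <- sort(sample(ok_pos, min(n_snp, length(ok_pos))))
    if (length(snp_pos)) {
      refc <- substring(ref$sequences[[sid]], snp_pos, snp_pos)
      altc <- vapply(refc, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      for (j in seq_along(snp_pos))
        edits[[length(edits) + 1L]] <- list(pos = snp_pos[j] - 1L,
                                            ref_len = 1L, alt = altc[j])
    }

    iok_pos <- which(indel_ok)
    n_ind <- rbinom(1L, length(iok_pos), config$small_indel_rate)
    ind_pos <- sort(sample(iok_pos, min(n_ind, length(iok_pos))))
    for (p in ind_pos) {
      ilen <- sample(1:10, 1L)
      if (runif(1) < 0.5) {
        if (p + ilen - 1L <= L && all(indel_ok[p:(p + ilen - 1L)]))
          edits[[length(edits) + 1L]] <- list(pos = p - 1L, ref_len = ilen,
                                              alt = "")
      } else {
        edits[[length(edits) + 1L]] <- list(pos = p - 1L, ref_len = 0L,
                                            alt = random_dna(ilen))
      }
    }

    # apply edits left to right, dropping any overlapping a previous one
    pos <- vapply(edits, `[[`, numeric(1), "pos")
    rl <- vapply(edits, `[[`, numeric(1), "ref_len")
    alt <- vapply(edits, `[[`, character(1), "alt")
    o <- order(pos, -rl)
    pos <- pos[o]; rl <- rl[o]; alt <- alt[o]
    keep <- rep(TRUE, length(pos))
    last_end <- -1
    for (j in seq_along(pos)) {
      if (pos[j] < last_end) { keep[j] <- FALSE; next }
      last_end <- max(last_end, pos[j] + rl[j])
    }
    pos <- pos[keep]; rl <- rl[keep]; alt <- alt[keep]

    pieces <- character(2L * length(pos) + 1L)
    prev <- 0L
    for (j in seq_along(pos)) {
      pieces[2L * j - 1L] <- substr(ref$sequences[[sid]], prev + 1L, pos[j])
      pieces[2L * j] <- alt[j]
      prev <- pos[j] + rl[j]
    }
    pieces[length(pieces)] <- substr(ref$sequences[[sid]], prev + 1L, L)
    new_seqs[[sid]] <- paste(pieces, collapse = "")

    # coordinate lift-over: offset(p) = net length change of edits whose
    # reference footprint lies at or before p (insertions count at pos)
    delta <- nchar(alt) - rl
    thr <- ifelse(rl == 0L, pos, pos + rl)
    off <- function(p) {
      if (!length(thr)) return(rep(0L, length(p)))
      idx <- findInterval(p, sort(thr))
      o2 <- order(thr)
      cs <- cumsum(delta[o2])
      ifelse(idx == 0L, 0L, cs[pmax(idx, 1L)])
    }

    for (i in e_here) {
      if (!presence[elements$element_id[i]]) next
      sh <- off(elements$start[i])
      new_elems[[length(new_elems) + 1L]] <- list(
        element_id = elements$element_id[i], seqid = sid,
        start = elements$start[i] + sh, end = elements$end[i] + sh)
    }
    for (i in g_here) {
      rid <- genes$gene_id[i]
      if (lost[i]) {
        ortho[[length(ortho) + 1L]] <- list(ref_gene = rid,
                                            acc_gene = NA_character_,
                                            event = "lost")
        next
      }
      sh <- off(genes$start[i])
      aid <- sprintf("%s.g%04d", acc, i)
      new_genes[[length(new_genes) + 1L]] <- list(
        gene_id = aid, seqid = sid, start = genes$start[i] + sh,
        end = genes$end[i] + sh, strand = genes$strand[i],
        exon_starts = genes$exon_starts[[i]] + sh,
        exon_ends = genes$exon_ends[[i]] + sh)
      ortho[[length(ortho) + 1L]] <- list(
        ref_gene = rid, acc_gene = aid,
        event = if (dup[i]) "tandem_dup" else "one_to_one")
      if (dup[i]) {
        # the inserted ancestral copy sits immediately right of the parent
        glen <- genes$end[i] - genes$start[i]
        cstart <- genes$end[i] + off(genes$end[i]) - glen
        cid <- sprintf("%s.g%04d.d", acc, i)
        new_genes[[length(new_genes) + 1L]] <- list(
          gene_id = cid, seqid = sid, start = cstart, end = cstart + glen,
          strand = genes$strand[i],
          exon_starts = genes$exon_starts[[i]] - genes$start[i] + cstart,
          exon_ends = genes$exon_ends[[i]] - genes$start[i] + cstart)
        ortho[[length(ortho) + 1L]] <- list(ref_gene = rid, acc_gene = cid,
                                            event = "tandem_dup")
      }
    }
  }

  assembly <- genome_assembly(acc, new_seqs, anchored = TRUE)
  gdf <- if (length(new_genes)) {
    make_gene_table(
      vapply(new_genes, `[[`, character(1), "gene_id"),
      vapply(new_genes, `[[`, character(1), "seqid"),
      vapply(new_genes, `[[`, numeric(1), "start"),
      vapply(new_genes, `[[`, numeric(1), "end"),
      vapply(new_genes, `[[`, character(1), "strand"),
      lapply(new_genes, `[[`, "exon_starts"),
      lapply(new_genes, `[[`, "exon_ends"),
      lapply(new_genes, `[[`, "exon_starts"),
      lapply(new_genes, `[[`, "exon_ends"))
  } else empty_gene_table()
  if (nrow(gdf)) gdf <- add_gene_seqs(gdf, assembly)
  edf <- if (length(new_elems)) gag_element_table(
    vapply(new_elems, `[[`, character(1), "element_id"),
    vapply(new_elems, `[[`, character(1), "seqid"),
    vapply(new_elems, `[[`, numeric(1), "start"),
    vapply(new_elems, `[[`, numeric(1), "end"))
  else gag_element_table(character(), character(), integer(), integer())
  odf <- data.frame(
    ref_gene = vapply(ortho, `[[`, character(1), "ref_gene"),
    acc_gene = vapply(ortho, `[[`, character(1), "acc_gene"),
    event = vapply(ortho, `[[`, character(1), "event"),
    accession = acc, stringsAsFactors = FALSE)
  list(assembly = assembly, genes = gdf, elements = edf, ortho = odf)
}

#' Derive accession genomes from the simulated reference
#'
#' Walks the accession tree flipping element presence per branch, then
#' builds each accession genome by exact-span element excision (optionally
#' ragged), gene loss, adjacent tandem duplication, SNPs and intergenic
#' small indels, with 50-bp mutation-free guards around feature boundaries.
#'
#' @param ref_sim Result of \code{\link{simulate_reference}}.
#' @param config The same \code{sim_config}.
#' @return \code{list(accessions = named list of per-accession
#'   list(assembly, genes, elements, ortho), truth = truth tables)}.
#' @export
derive_accessions <- function(ref_sim, config = ref_sim$config) {
  set.seed(config$seed + SEED_OFF_ACCESSIONS)
  tree <- ape::read.tree(text = config$accession_tree)
  pres <- simulate_presence(ref_sim$elements, tree,
                            config$pap_flip_prob_per_branch)
  accs <- sort(tree$tip.label)
  out <- list()
  ortho_all <- list()
  for (acc in accs) {
    out[[acc]] <- derive_one_accession(acc, ref_sim, pres[, acc], config)
    ortho_all[[acc]] <- out[[acc]]$ortho
  }
  truth <- ref_sim$truth
  truth$element_presence <- pres
  truth$ortho_pairs <- do.call(rbind, unname(ortho_all))
  list(accessions = out, truth = truth, tree = tree)
}

#' Fragment a chromosome-level genome into contigs
#'
#' Chromosomes are cut at random positions into pieces of roughly the N50
#' target; contig order is shuffled and about half are reverse-complemented.
#' No sequence is gained or lost; cut positions are returned for testing.
#'
#' @param genome A chromosome-level \code{genome_assembly}.
#' @param config A \code{sim_config} (uses \code{assembly_n50_target_bp}).
#' @param seed Optional reseed; \code{NULL} continues the current RNG.
#' @return \code{list(assembly, truth)} where truth maps every contig to
#'   (chrom, start, end, revcomp).
#' @export
fragment_assembly <- function(genome, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed + SEED_OFF_FRAGMENT)
  target <- config$assembly_n50_target_bp
  rows <- list()
  for (sid in names(genome$sequences)) {
    L <- nchar(genome$sequences[[sid]])
    pos <- 0L
    while (pos < L) {
      len <- if (target >= L) L else
        as.integer(round(runif(1, 0.5 * target, 1.5 * target)))
      len <- min(len, L - pos)
      rows[[length(rows) + 1L]] <- list(chrom = sid, start = pos,
                                        end = pos + len)
      pos <- pos + len
    }
  }
  ord <- sample(seq_along(rows))
  rc <- runif(length(rows)) < 0.5
  seqs <- character(length(rows))
  tr <- list()
  for (j in seq_along(ord)) {
    r <- rows[[ord[j]]]
    s <- substr(genome$sequences[[r$chrom]], r$start + 1L, r$end)
    if (rc[j]) s <- cpp_revcomp(s)
    seqs[j] <- s
    tr[[j]] <- data.frame(contig = sprintf("ctg%04d", j), chrom = r$chrom,
                          start = r$start, end = r$end, revcomp = rc[j],
                          stringsAsFactors = FALSE)
  }
  names(seqs) <- sprintf("ctg%04d", seq_along(seqs))
  list(assembly = genome_assembly(paste0(genome$accession_id, "_contigs"),
                                  seqs, anchored = FALSE),
       truth = do.call(rbind, tr))
}

# Nearest annotated gene on each side of each query locus, edge-to-edge
# distance <= window.  Queries and genes are coordinate tables.
find_neighbor_genes <- function(queries, genes, window_bp,
                                query_id_col = "element_id") {
  out <- list()
  for (i in seq_len(nrow(queries))) {
    qs <- queries$start[i]; qe <- queries$end[i]
    qid <- queries[[query_id_col]][i]
    same <- genes[genes$seqid == queries$seqid[i] &
                    genes$gene_id != qid, , drop = FALSE]
    if (!nrow(same)) next
    up <- same[same$end <= qs, , drop = FALSE]
    if (nrow(up)) {
      j <- which.max(up$end)
      d <- qs - up$end[j]
      if (d <= window_bp)
        out[[length(out) + 1L]] <- data.frame(
          query_id = qid, gene_id = up$gene_id[j], side = "upstream",
          distance_bp = d, stringsAsFactors = FALSE)
    }
    dn <- same[same$start >= qe, , drop = FALSE]
    if (nrow(dn)) {
      j <- which.min(dn$start)
      d <- dn$start[j] - qe
      if (d <= window_bp)
        out[[length(out) + 1L]] <- data.frame(
          query_id = qid, gene_id = dn$gene_id[j], side = "downstream",
          distance_bp = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(query_id = character(), gene_id = character(),
                      side = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Simulate the tissue-wide expression matrix
#'
#' Log-scale group-mean model: each feature draws a baseline mean
#' Normal(2,1) plus a Normal(0,1) per-group effect; ripening-inducible
#' elements get a fixed +3 bump in the ripening group (and are guaranteed
#' not to peak there otherwise); a co-expressed flanking gene inherits its
#' element's group-mean profile plus Normal(0, noise) per group.  Per-sample
#' values add Normal(0, noise); FPKM = max(exp(x) - 0.05, 0).
#'
#' @param ref_sim Result of \code{\link{simulate_reference}}.
#' @param truth Truth list; \code{element_ripening} and
#'   \code{neighbor_coexpressed} are drawn here if absent.
#' @param config A \code{sim_config}.
#' @return \code{list(matrix = expression_matrix, truth = updated truth)}.
#' @export
simulate_expression <- function(ref_sim, truth = ref_sim$truth,
                                config = ref_sim$config) {
  set.seed(config$seed + SEED_OFF_EXPRESSION)
  if (!config$ripening_group %in% config$tissue_groups)
    stop("ripening group label missing from tissue_groups")
  genes <- ref_sim$genes; elements <- ref_sim$elements
  groups <- config$tissue_groups
  rip <- config$ripening_group
  feats <- c(genes$gene_id, elements$element_id)
  nf <- length(feats); ng <- length(groups)

  if (is.null(truth$element_ripening)) {
    er <- runif(nrow(elements)) < config$p_ripening_inducible
    names(er) <- elements$element_id
    truth$element_ripening <- er
  }
  if (is.null(truth$neighbor_coexpressed)) {
    np <- find_neighbor_genes(elements, genes, config$neighbor_window_bp)
    np$coexpressed <- FALSE
    is_rip <- truth$element_ripening[np$query_id]
    # one draw per flanking GENE: a gene flanking several ripening elements
    # shares the dominant ripening spike with all of them, so a per-pair
    # label could not be recovered coherently from correlations
    rip_genes <- unique(np$gene_id[is_rip])
    gene_coex <- setNames(runif(length(rip_genes)) <
                            config$p_neighbor_coexpressed, rip_genes)
    np$coexpressed[is_rip] <- unname(gene_coex[np$gene_id[is_rip]])
    truth$neighbor_coexpressed <- np
  }

  base <- rnorm(nf, 2, 1)
  mu <- base + matrix(rnorm(nf * ng, 0, 1), nf, ng)
  dimnames(mu) <- list(feats, groups)

  ripcol <- match(rip, groups)
  for (eid in elements$element_id) {
    if (isTRUE(truth$element_ripening[[eid]])) {
      mu[eid, ripcol] <- base[match(eid, feats)] + 3
    } else if (which.max(mu[eid, ]) == ripcol) {
      # keep non-ripening elements from peaking in the ripening group
      o <- order(mu[eid, ], decreasing = TRUE)
      tmp <- mu[eid, ripcol]
      mu[eid, ripcol] <- mu[eid, o[2]]
      mu[eid, o[2]] <- tmp
    }
  }
  nc <- truth$neighbor_coexpressed
  coex_genes <- unique(nc$gene_id[nc$coexpressed])
  if (nrow(nc)) for (j in seq_len(nrow(nc))) {
    gid <- nc$gene_id[j]
    if (!gid %in% feats) next
    if (!nc$coexpressed[j] && gid %in% coex_genes) next
    if (nc$coexpressed[j]) {
      mu[gid, ] <- mu[nc$query_id[j], ] +
        rnorm(ng, 0, config$expression_noise_sd)
    } else if (isTRUE(truth$element_ripening[[nc$query_id[j]]]) &&
               which.max(mu[gid, ]) == ripcol) {
      # a flanking gene labelled NOT co-expressed must not peak in the
      # ripening group by accident, or the truth label would be blurred
      o <- order(mu[gid, ], decreasing = TRUE)
      tmp <- mu[gid, ripcol]
      mu[gid, ripcol] <- mu[gid, o[2]]
      mu[gid, o[2]] <- tmp
    }
  }

  spg <- config$samples_per_group
  samples <- paste0(rep(groups, each = spg), "_", seq_len(spg))
  sample_groups <- setNames(rep(groups, each = spg), samples)
  vals <- matrix(0, nf, length(samples), dimnames = list(feats, samples))
  for (s in seq_along(samples)) {
    g <- match(sample_groups[s], groups)
    vals[, s] <- pmax(exp(mu[, g] + rnorm(nf, 0, config$expression_noise_sd))
                      - 0.05, 0)
  }
  list(matrix = expression_matrix(vals, sample_groups, rip), truth = truth)
}

#' Write a simulation to disk
#'
#' Emits per-accession FASTA, the reference FASTA/GFF3/BED, expression and
#' sample-group TSVs, truth tables as TSV, and a JSON echo of the config.
#'
#' @param ref_sim,acc_sim,expr_sim Results of the three simulation stages.
#' @param outdir Output directory (created).
#' @return Invisibly, \code{outdir}.
#' @export
write_simulation <- function(ref_sim, acc_sim, expr_sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(ref_sim$reference, file.path(outdir, "reference.fa"))
  write_gff3(ref_sim$genes, ref_sim$elements,
             file.path(outdir, "reference.gff3"))
  write_bed_elements(ref_sim$elements, file.path(outdir, "elements.bed"))
  for (acc in names(acc_sim$accessions))
    write_fasta(acc_sim$accessions[[acc]]$assembly,
                file.path(outdir, paste0(acc, ".fa")))
  pres <- acc_sim$truth$element_presence
  write.table(data.frame(element_id = rownames(pres), pres + 0L,
                         check.names = FALSE),
              file.path(outdir, "truth_presence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(acc_sim$truth$ortho_pairs,
              file.path(outdir, "truth_ortho.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(expr_sim)) {
    write_expression_tsv(expr_sim$matrix, file.path(outdir, "expression.tsv"),
                         file.path(outdir, "sample_groups.tsv"))
    er <- expr_sim$truth$element_ripening
    write.table(data.frame(element_id = names(er), ripening = er + 0L),
                file.path(outdir, "truth_ripening.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(expr_sim$truth$neighbor_coexpressed,
                file.path(outdir, "truth_neighbors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  cfg <- ref_sim$config
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
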