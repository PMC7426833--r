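# End-to-end synthetic experiment: simulate -> genotype PAPs -> cluster ->
# orthology -> expression -> enrichment -> report, with every threshold
# echoed into a JSON manifest and recovered quantities compared to truth.

#' Pipeline run configuration
#'
#' Bundles the simulation config with every downstream threshold so the
#' manifest can echo all of them verbatim.
#'
#' @param seed Master seed (drives the simulation substreams).
#' @param sim A \code{\link{sim_config}}; defaults to one built from
#'   \code{seed}.
#' @param flank_bp,present_min,absent_max PAP genotyping parameters.
#' @param linkage,distance Accession clustering parameters.
#' @param min_containment,within_containment,tandem_window_bp,
#'   tandem_max_intervening Orthology parameters.
#' @param min_fpkm,filter_mode,min_fold,window_bp,r_cutoff Expression
#'   parameters.
#' @param ortho_targets Accessions to compare against the reference in the
#'   orthology stage (default: the first accession, the single-pair
#'   comparison the partner-link analysis is built on).
#' @param stages Character vector of stages to run.
#' @return A \code{run_config} list.
#' @export
run_config <- function(seed = 1L, sim = sim_config(seed = seed),
                       flank_bp = 50000L, present_min = 0.8,
                       absent_max = 0.2, linkage = "complete",
                       distance = "euclidean", min_containment = 0.3,
                       within_containment = 0.5, tandem_window_bp = 100000L,
                       tandem_max_intervening = 5L, min_fpkm = 0.1,
                       filter_mode = "any", min_fold = 1.0,
                       window_bp = 50000L, r_cutoff = 0.8,
                       ortho_targets = 1L,
                       stages = c("simulate", "pap", "cluster", "orthology",
                                  "expression", "enrichment")) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

log_stage <- function(con, stage, ...) {
  line <- sprintf("[%s] %s", stage, paste(sprintf(...), collapse = " "))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full synthetic experiment
#'
#' Simulates the reference and accession genomes, genotypes element PAPs,
#' clusters accessions, classifies gene partners against an accession,
#' classifies ripening-inducible expression and neighbor co-expression,
#' runs term enrichment on the CNV/PAP candidate set, and writes all stage
#' tables, a JSON manifest and a plain-text report comparing recovered
#' quantities to truth.
#'
#' @param config A \code{\link{run_config}}.
#' @param outdir Output directory.
#' @return Invisibly, a list with every stage result plus the summary.
#' @export
run_end_to_end <- function(config = run_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(outdir, "run.log"), "w")
  on.exit(close(logf))
  res <- list(config = config)
  simc <- config$sim

  log_stage(logf, "simulate", "seed=%d accessions=%d", simc$seed,
            length(ape::read.tree(text = simc$accession_tree)$tip.label))
  ref_sim <- simulate_reference(simc)
  acc_sim <- derive_accessions(ref_sim, simc)
  expr_sim <- if ("expression" %in% config$stages)
    simulate_expression(ref_sim, acc_sim$truth, simc) else NULL
  truth <- if (is.null(expr_sim)) acc_sim$truth else expr_sim$truth
  write_simulation(ref_sim, acc_sim, expr_sim, file.path(outdir, "sim"))
  res$ref_sim <- ref_sim; res$acc_sim <- acc_sim; res$expr_sim <- expr_sim
  log_stage(logf, "simulate", "genes=%d elements=%d", nrow(ref_sim$genes),
            nrow(ref_sim$elements))

  summary <- list(seed = simc$seed)

  if ("pap" %in% config$stages) {
    targets <- lapply(acc_sim$accessions, `[[`, "assembly")
    pap <- build_pap_matrix(ref_sim$elements, ref_sim$reference, targets,
                            flank_bp = config$flank_bp,
                            present_min = config$present_min,
                            absent_max = config$absent_max)
    write_pap_tsv(pap, file.path(outdir, "pap_ratio.tsv"),
                  file.path(outdir, "pap_call.tsv"))
    write.table(pap_summary(pap), file.path(outdir, "pap_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$pap <- pap
    conc <- pap_concordance(pap, truth$element_presence)
    summary$pap_concordance <- conc$concordance
    summary$pap_sign_errors <- conc$sign_errors
    log_stage(logf, "pap", "cells=%d concordance=%.4f sign_errors=%d",
              conc$n_cells, conc$concordance, conc$sign_errors)

    if ("cluster" %in% config$stages) {
      dend <- cluster_accessions(pap, linkage = config$linkage,
                                 distance = config$distance)
      writeLines(write_newick(dend$hclust),
                 file.path(outdir, "accessions.nwk"))
      res$dendrogram <- dend
      ntip <- length(ape::read.tree(text = simc$accession_tree)$tip.label)
      clade <- sprintf("acc%02d", (ntip - 2):ntip)
      summary$clade_recovered <- is_clade(dend, clade)
      log_stage(logf, "cluster", "planted_clade_recovered=%s",
                summary$clade_recovered)
    }
  }

  if ("orthology" %in% config$stages) {
    accs <- names(acc_sim$accessions)[config$ortho_targets]
    ortho_all <- list()
    for (acc in accs) {
      accx <- acc_sim$accessions[[acc]]
      calls <- call_one_to_one(ref_sim$genes, accx$genes, accx$assembly,
                               min_containment = config$min_containment)
      calls <- classify_cnv_pap(calls, ref_sim$genes, accx$genes,
                                ref_sim$reference, accx$assembly,
                                tandem_window_bp = config$tandem_window_bp,
                                tandem_max_intervening =
                                  config$tandem_max_intervening,
                                within_containment =
                                  config$within_containment)
      calls$accession <- acc
      ortho_all[[acc]] <- calls
      perf <- ortho_performance(calls, truth$ortho_pairs, acc)
      summary[[paste0("ortho_recall_", acc)]] <- perf$recall
      summary[[paste0("ortho_false_pairs_", acc)]] <- perf$false_pairs
      log_stage(logf, "orthology", "%s recall=%.4f false_pairs=%d", acc,
                perf$recall, perf$false_pairs)
    }
    ortho <- do.call(rbind, unname(ortho_all))
    write.table(ortho, file.path(outdir, "ortho_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$ortho <- ortho
  }

  if ("expression" %in% config$stages) {
    mat <- filter_expressed(expr_sim$matrix, min_fpkm = config$min_fpkm,
                            mode = config$filter_mode)
    rip <- call_ripening_inducible(mat, min_fold = config$min_fold)
    write.table(rip, file.path(outdir, "ripening_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    el_ids <- ref_sim$elements$element_id
    rip_el <- rip$feature_id[rip$is_ripening_inducible &
                               rip$feature_id %in% el_ids]
    n_el_in <- sum(el_ids %in% rip$feature_id)
    summary$ripening_fraction <- length(rip_el) / n_el_in
    coex <- neighbor_coexpression(ref_sim$elements, ref_sim$genes, mat,
                                  rip_el, window_bp = config$window_bp,
                                  r_cutoff = config$r_cutoff)
    write.table(coex$pairs, file.path(outdir, "neighbor_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(coex$fractions, file.path(outdir, "neighbor_fractions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(coex$histogram, file.path(outdir, "neighbor_histogram.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$ripening <- rip; res$coexpression <- coex
    fr <- coex$fractions
    summary$neighbor_coexpr_fraction <-
      fr$fraction[fr$set == "ripening_elements"]
    log_stage(logf, "expression",
              "ripening_fraction=%.4f neighbor_coexpr=%.4f",
              summary$ripening_fraction,
              summary$neighbor_coexpr_fraction %||% NA_real_)
  }

  if ("enrichment" %in% config$stages && !is.null(res$ortho)) {
    # candidate CNV/PAP set vs all reference records, Gag term vs a generic
    # term per gene; element-derived records dominate the candidate set
    term_table <- rbind(
      data.frame(id = ref_sim$genes$gene_id, term = "IPR000000",
                 stringsAsFactors = FALSE),
      data.frame(id = ref_sim$elements$element_id, term = "IPR005162",
                 stringsAsFactors = FALSE))
    cand <- unique(res$ortho$gene_a[res$ortho$category %in%
                                      c("tandem_dup_cnv",
                                        "non_tandem_cnv_pap")])
    cand <- cand[!is.na(cand)]
    # elements absent from any accession are PAP records by construction
    pres <- truth$element_presence
    cand <- c(cand, rownames(pres)[rowSums(!pres) > 0])
    bg <- c(ref_sim$genes$gene_id, ref_sim$elements$element_id)
    if (length(cand)) {
      enr <- enrich(cand, bg, term_table)
      write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res$enrichment <- enr
      over <- enr[enr$odds_ratio > 1, , drop = FALSE]
      summary$top_enriched_term <- over$term_id[1]
      log_stage(logf, "enrichment", "top_term=%s p=%.3g", over$term_id[1],
                over$p[1])
    }
  }

  res$summary <- summary
  manifest <- list(seed = simc$seed, package_version =
                     as.character(utils::packageVersion("retropap")),
                   parameters = unclass(config)[setdiff(names(config),
                                                        "sim")],
                   sim_parameters = unclass(simc),
                   counts = list(genes = nrow(ref_sim$genes),
                                 elements = nrow(ref_sim$elements),
                                 accessions = length(acc_sim$accessions)))
  manifest$parameters$stages <- config$stages
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report <- c(
    "retropap end-to-end synthetic run",
    sprintf("seed: %d", simc$seed),
    sprintf("PAP concordance vs truth: %s (sign errors: %s)",
            fmt_or_na(summary$pap_concordance),
            summary$pap_sign_errors %||% "NA"),
    sprintf("planted clade recovered: %s", summary$clade_recovered %||% NA),
    sprintf("ripening fraction recovered: %s (simulated %.3f)",
            fmt_or_na(summary$ripening_fraction), simc$p_ripening_inducible),
    sprintf("neighbor co-expression recovered: %s (simulated %.3f)",
            fmt_or_na(summary$neighbor_coexpr_fraction),
            simc$p_neighbor_coexpressed))
  writeLines(report, file.path(outdir, "report.txt"))
  invisible(res)
}

fmt_or_na <- function(x) if (is.null(x) || !length(x)) "NA" else
  sprintf("%.4f", x)

#' PAP call concordance against the truth presence table
#'
#' Concordance counts cells whose call matches the truth state
#' (present/absent); ambiguous and missing cells count as discordant but
#' not as sign errors.  A sign error is a truth-present element called
#' absent or vice versa.
#'
#' @param pap A \code{pap_matrix}.
#' @param presence Truth element x accession logical matrix.
#' @return list(n_cells, concordance, sign_errors, ambiguous).
#' @export
pap_concordance <- function(pap, presence) {
  accs <- intersect(colnames(pap$call), colnames(presence))
  el <- intersect(rownames(pap$call), rownames(presence))
  calls <- pap$call[el, accs, drop = FALSE]
  tr <- presence[el, accs, drop = FALSE]
  expected <- ifelse(tr, "present", "absent")
  n <- length(calls)
  ok <- calls == expected
  sign_err <- (calls == "present" & expected == "absent") |
              (calls == "absent" & expected == "present")
  list(n_cells = n, concordance = sum(ok) / n,
       sign_errors = sum(sign_err), ambiguous = sum(calls == "ambiguous"))
}

#' Orthology recall / false-pair performance against truth
#'
#' Recall is measured over truth one-to-one pairs of one accession; false
#' pairs are called one-to-one pairs whose genes are NOT homologous in
#' truth (i.e. not related by any truth record).
#'
#' @param calls Partner-call table.
#' @param truth_ortho Truth ortho_pairs table.
#' @param acc Accession id.
#' @return list(recall, n_truth, false_pairs).
#' @export
ortho_performance <- function(calls, truth_ortho, acc) {
  tr <- truth_ortho[truth_ortho$accession == acc, , drop = FALSE]
  oto_truth <- tr[tr$event == "one_to_one", , drop = FALSE]
  called <- calls[calls$category == "one_to_one", , drop = FALSE]
  key <- function(a, b) paste(a, b, sep = "\r")
  hit <- key(oto_truth$ref_gene, oto_truth$acc_gene) %in%
    key(called$gene_a, called$gene_b)
  related <- key(tr$ref_gene, tr$acc_gene)
  false_pairs <- sum(!key(called$gene_a, called$gene_b) %in% related)
  list(recall = if (nrow(oto_truth)) mean(hit) else NA_real_,
       n_truth = nrow(oto_truth), false_pairs = false_pairs)
}

#' Summarize a completed run directory
#'
#' Re-reads the stage TSVs and recomputes the headline fractions; warns on
#' missing stage outputs and returns what is available.
#'
#' @param outdir Run directory.
#' @return data.frame of quantity / value rows.
#' @export
report_summary <- function(outdir) {
  rows <- list()
  addrow <- function(q, v) rows[[length(rows) + 1L]] <<-
    data.frame(quantity = q, value = v, stringsAsFactors = FALSE)
  f <- file.path(outdir, "pap_summary.tsv")
  if (file.exists(f)) {
    ps <- read.delim(f, check.names = FALSE)
    for (i in seq_len(nrow(ps)))
      addrow(paste0("pap_present_", ps$accession[i]), ps$present[i])
  } else warning("missing pap_summary.tsv")
  f <- file.path(outdir, "neighbor_fractions.tsv")
  if (file.exists(f)) {
    nf <- read.delim(f)
    for (i in seq_len(nrow(nf)))
      addrow(paste0("coexpr_fraction_", nf$set[i]),
             sprintf("%.4f (n=%d)", nf$fraction[i], nf$n_pairs[i]))
  } else warning("missing neighbor_fractions.tsv")
  f <- file.path(outdir, "ripening_calls.tsv")
  if (file.exists(f)) {
    rc <- read.delim(f)
    addrow("ripening_inducible_features", sum(rc$is_ripening_inducible))
  }
  do.call(rbind, rows)
}
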