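test_that("simulation is byte-identical under a fixed seed", {
  cfg <- tiny_cfg(seed = 11)
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(a$reference$sequences, b$reference$sequences)
  expect_identical(a$genes$transcript_seq, b$genes$transcript_seq)
  da <- derive_accessions(a, cfg)
  db <- derive_accessions(b, cfg)
  expect_identical(da$accessions$acc01$assembly$sequences,
                   db$accessions$acc01$assembly$sequences)
  expect_identical(da$truth$element_presence, db$truth$element_presence)
  ea <- simulate_expression(a, da$truth, cfg)
  eb <- simulate_expression(b, db$truth, cfg)
  expect_identical(ea$matrix$values, eb$matrix$values)
})

test_that("feature counts follow the configuration", {
  cfg <- tiny_cfg(seed = 2)
  rs <- simulate_reference(cfg)
  expect_equal(nrow(rs$genes), 40L)
  expect_equal(nrow(rs$elements), 8L)
  cfg0 <- tiny_cfg(seed = 2, n_elements = 0L)
  rs0 <- simulate_reference(cfg0)
  expect_equal(nrow(rs0$elements), 0L)
})

test_that("infeasible packing errors with a config suggestion", {
  cfg <- tiny_cfg(seed = 1, chromosome_length_bp = 20000L)
  expect_error(simulate_reference(cfg), "infeasible packing")
})

test_that("no mutations and no flips reproduce the reference exactly", {
  cfg <- tiny_cfg(seed = 4, pap_flip_prob_per_branch = 0, snp_rate = 0,
                  small_indel_rate = 0, tandem_dup_prob = 0,
                  gene_loss_prob = 0)
  rs <- simulate_reference(cfg)
  ac <- derive_accessions(rs, cfg)
  expect_true(all(ac$truth$element_presence))
  for (acc in ac$accessions)
    expect_identical(unname(acc$assembly$sequences),
                     unname(rs$reference$sequences))
  expect_true(all(ac$truth$ortho_pairs$event == "one_to_one"))
})

test_that("element excision removes exactly the element span", {
  cfg <- tiny_cfg(seed = 6, snp_rate = 0, small_indel_rate = 0,
                  tandem_dup_prob = 0, gene_loss_prob = 0,
                  pap_flip_prob_per_branch = 0.5)
  rs <- simulate_reference(cfg)
  ac <- derive_accessions(rs, cfg)
  pres <- ac$truth$element_presence
  acc <- names(which(colSums(!pres) > 0))[1]
  expect_false(is.na(acc))
  absent <- rownames(pres)[!pres[, acc]]
  el <- rs$elements[rs$elements$element_id %in% absent, ]
  # removing absent element spans from the reference reproduces the genome
  for (sid in names(rs$reference$sequences)) {
    s <- rs$reference$sequences[[sid]]
    here <- el[el$seqid == sid, , drop = FALSE]
    here <- here[order(-here$start), , drop = FALSE]
    for (i in seq_len(nrow(here)))
      s <- paste0(substr(s, 1, here$start[i]),
                  substr(s, here$end[i] + 1L, nchar(s)))
    expect_identical(ac$accessions[[acc]]$assembly$sequences[[sid]], s)
  }
})

test_that("accession gene annotations lift over to the mutated genomes", {
  cfg <- tiny_cfg(seed = 8)
  rs <- simulate_reference(cfg)
  ac <- derive_accessions(rs, cfg)
  for (acc in names(ac$accessions)[1:2]) {
    g <- ac$accessions[[acc]]$genes
    # transcripts re-extracted at lifted coordinates start with ATG and
    # translate cleanly (SNP-only interiors keep the frame)
    expect_true(all(substr(g$transcript_seq, 1, 1) %in% c("A", "C", "G", "T")))
    expect_true(all(g$coding))
    expect_true(all(nchar(g$protein_seq) > 0))
  }
})

test_that("sister leaves share more presence states than distant leaves", {
  # averaged over seeds, the tight trio agrees more with itself than with
  # the far end of the caterpillar
  share_sis <- share_far <- 0
  for (s in 1:20) {
    cfg <- tiny_cfg(seed = s)
    set.seed(cfg$seed + 1L)
    tree <- ape::read.tree(text = cfg$accession_tree)
    el <- data.frame(element_id = sprintf("e%02d", 1:30))
    pres <- retropap:::simulate_presence(el, tree,
                                         cfg$pap_flip_prob_per_branch)
    sis <- tree$tip.label[c(length(tree$tip.label) - 2L,
                            length(tree$tip.label) - 1L)]
    share_sis <- share_sis + mean(pres[, sis[1]] == pres[, sis[2]])
    share_far <- share_far + mean(pres[, sis[1]] == pres[, "acc01"])
  }
  expect_gt(share_sis, share_far)
})

test_that("per-branch flip frequency is calibrated", {
  # unit-length pendant edge of acc01: flips at the configured rate
  p <- 0.15
  flips <- 0L; n <- 0L
  for (s in 1:50) {
    set.seed(s)
    tree <- ape::read.tree(text = "(acc01:1,(acc02:1,acc03:1):1);")
    el <- data.frame(element_id = sprintf("e%02d", 1:40))
    pres <- retropap:::simulate_presence(el, tree, p)
    # acc01 hangs straight off the root: its state IS the pendant flips
    flips <- flips + sum(!pres[, "acc01"])
    n <- n + nrow(el)
  }
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(flips / n - p), 3 * se)
})

test_that("fragmentation conserves sequence and approximates the N50", {
  cfg <- tiny_cfg(seed = 9)
  rs <- simulate_reference(cfg)
  fr <- fragment_assembly(rs$reference, cfg, seed = 9)
  lens <- seq_lengths(fr$assembly)
  expect_equal(sum(lens), sum(seq_lengths(rs$reference)))
  # reconstruct each chromosome from the truth table
  tr <- fr$truth
  for (sid in names(rs$reference$sequences)) {
    here <- tr[tr$chrom == sid, ]
    here <- here[order(here$start), ]
    got <- paste(vapply(seq_len(nrow(here)), function(i) {
      s <- fr$assembly$sequences[[here$contig[i]]]
      if (here$revcomp[i]) revcomp(s) else s
    }, character(1)), collapse = "")
    expect_identical(got, rs$reference$sequences[[sid]])
  }
  # realized N50 within +/-50% of target
  sl <- sort(lens, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= sum(sl) / 2)[1]]
  expect_gt(n50, 0.5 * cfg$assembly_n50_target_bp)
  expect_lt(n50, 1.5 * cfg$assembly_n50_target_bp)
})

test_that("fragmentation with an oversized target yields one contig per chromosome", {
  cfg <- tiny_cfg(seed = 10, assembly_n50_target_bp = 10000000L)
  rs <- simulate_reference(cfg)
  fr <- fragment_assembly(rs$reference, cfg, seed = 10)
  expect_equal(length(fr$assembly$sequences),
               length(rs$reference$sequences))
})

test_that("expression truth fraction of ripening elements is calibrated", {
  # observed truth fraction across seeds sits inside the exact binomial
  # 99% CI around the configured 0.386
  hits <- 0L; n <- 0L
  for (s in 1:10) {
    cfg <- tiny_cfg(seed = s, n_elements = 8L)
    rs <- simulate_reference(cfg)
    ex <- simulate_expression(rs, rs$truth, cfg)
    hits <- hits + sum(ex$truth$element_ripening)
    n <- n + length(ex$truth$element_ripening)
  }
  ci <- stats::binom.test(hits, n, 0.386, conf.level = 0.99)$conf.int
  expect_gte(0.386, ci[1])
  expect_lte(0.386, ci[2])
})

test_that("a co-expressed neighbor approaches r = 1 as noise vanishes", {
  cfg <- tiny_cfg(seed = 12, expression_noise_sd = 1e-6,
                  p_ripening_inducible = 1, p_neighbor_coexpressed = 1)
  rs <- simulate_reference(cfg)
  ex <- simulate_expression(rs, rs$truth, cfg)
  np <- ex$truth$neighbor_coexpressed
  pair <- np[np$coexpressed, ][1, ]
  r <- pearson_r(ex$matrix$values[pair$query_id, ],
                 ex$matrix$values[pair$gene_id, ])
  expect_gt(r, 0.999)
})

test_that("zero ripening probability yields zero classified elements", {
  cfg <- tiny_cfg(seed = 13, p_ripening_inducible = 0)
  rs <- simulate_reference(cfg)
  ex <- simulate_expression(rs, rs$truth, cfg)
  rip <- call_ripening_inducible(ex$matrix)
  el <- rs$elements$element_id
  expect_equal(sum(rip$is_ripening_inducible[rip$feature_id %in% el]), 0L)
})

test_that("simulation files round trip through the writers", {
  cfg <- tiny_cfg(seed = 14)
  rs <- simulate_reference(cfg)
  ac <- derive_accessions(rs, cfg)
  ex <- simulate_expression(rs, ac$truth, cfg)
  out <- file.path(tempdir(), "simout")
  write_simulation(rs, ac, ex, out)
  expect_true(file.exists(file.path(out, "reference.fa")))
  back <- read_fasta(file.path(out, "acc01.fa"))
  expect_identical(unname(back$sequences),
                   unname(ac$accessions$acc01$assembly$sequences))
  pres <- read.delim(file.path(out, "truth_presence.tsv"),
                     check.names = FALSE)
  expect_equal(nrow(pres), nrow(rs$elements))
  cfg_echo <- jsonlite::read_json(file.path(out, "config.json"))
  expect_equal(cfg_echo$seed, cfg$seed)
  expect_equal(cfg_echo$p_ripening_inducible, cfg$p_ripening_inducible)
})
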