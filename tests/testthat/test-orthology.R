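# Build a small two-genome pair with controlled events via the simulator.
make_pair <- function(seed = 21, ...) {
  cfg <- tiny_cfg(seed = seed, ...)
  rs <- simulate_reference(cfg)
  ac <- derive_accessions(rs, cfg)
  list(rs = rs, acc = ac$accessions[[1]],
       truth = ac$truth$ortho_pairs[
         ac$truth$ortho_pairs$accession == names(ac$accessions)[1], ])
}

test_that("identical gene sets map one-to-one with containment 1", {
  p <- make_pair(seed = 21, snp_rate = 0, small_indel_rate = 0,
                 tandem_dup_prob = 0, gene_loss_prob = 0,
                 pap_flip_prob_per_branch = 0)
  bh <- similarity_best_hits(p$rs$genes, p$acc$genes, "transcript")
  expect_equal(nrow(bh), nrow(p$rs$genes))
  expect_true(all(bh$containment == 1))
  expect_false(any(bh$tied))
  bhp <- similarity_best_hits(p$rs$genes, p$acc$genes, "protein")
  expect_true(all(bhp$containment == 1))
})

test_that("a randomized sequence finds no hit", {
  p <- make_pair(seed = 22)
  g <- p$rs$genes[1, ]
  g$transcript_seq <- rand_dna(nchar(g$transcript_seq), seed = 99)
  bh <- similarity_best_hits(g, p$acc$genes, "transcript")
  expect_equal(nrow(bh), 0L)
})

test_that("containment under SNPs equals the brute-force k-mer ratio", {
  set.seed(23)
  tx <- rand_dna(1200)
  mut <- tx
  for (pos in sample(1200, 12))
    substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(mut, pos, pos))[sample(3, 1)]
  ga <- data.frame(gene_id = "a", transcript_seq = tx,
                   stringsAsFactors = FALSE)
  gb <- data.frame(gene_id = "b", transcript_seq = mut,
                   stringsAsFactors = FALSE)
  bh <- similarity_best_hits(ga, gb, "transcript")
  km <- function(s) unique(substring(s, 1:(nchar(s) - 14), 15:nchar(s)))
  expect_equal(bh$containment,
               length(intersect(km(tx), km(mut))) / length(km(tx)),
               tolerance = 1e-12)
})

test_that("clean single-copy genes are called one-to-one", {
  p <- make_pair(seed = 24, tandem_dup_prob = 0, gene_loss_prob = 0)
  calls <- call_one_to_one(p$rs$genes, p$acc$genes, p$acc$assembly)
  oto <- calls[calls$category == "one_to_one", ]
  expect_equal(nrow(oto), nrow(p$rs$genes))
  # one-to-one calls form a bijection
  expect_false(anyDuplicated(oto$gene_a) > 0)
  expect_false(anyDuplicated(oto$gene_b) > 0)
  expect_true(all(oto$overlap_bp >= 1))
})

test_that("identical duplicated copies break reciprocal best by the tie rule", {
  p <- make_pair(seed = 25, snp_rate = 0, small_indel_rate = 0,
                 tandem_dup_prob = 0, gene_loss_prob = 0)
  genes_b <- p$acc$genes
  # duplicate one accession gene verbatim (same sequences, new id) and
  # append its copy next to the parent in the genome
  parent <- genes_b[5, ]
  copy <- parent
  copy$gene_id <- paste0(parent$gene_id, ".d")
  glen <- parent$end - parent$start
  copy$start <- parent$end; copy$end <- parent$end + glen
  copy$exon_starts <- list(parent$exon_starts[[1]] - parent$start + copy$start)
  copy$exon_ends <- list(parent$exon_ends[[1]] - parent$start + copy$start)
  copy$cds_starts <- copy$exon_starts; copy$cds_ends <- copy$exon_ends
  genes_b <- rbind(genes_b, copy)
  sid <- parent$seqid
  seqs <- p$acc$assembly$sequences
  seqs[[sid]] <- paste0(substr(seqs[[sid]], 1, parent$end),
                        substr(seqs[[sid]], parent$start + 1, parent$end),
                        substr(seqs[[sid]], parent$end + 1, nchar(seqs[[sid]])))
  asm_b <- genome_assembly("accdup", seqs)
  # shift downstream gene coordinates past the insertion
  shift <- genes_b$start >= parent$end & genes_b$gene_id != copy$gene_id
  genes_b$start[shift] <- genes_b$start[shift] + glen
  genes_b$end[shift] <- genes_b$end[shift] + glen
  genes_b$exon_starts[shift] <- lapply(genes_b$exon_starts[shift], `+`, glen)
  genes_b$exon_ends[shift] <- lapply(genes_b$exon_ends[shift], `+`, glen)

  calls <- call_one_to_one(p$rs$genes, genes_b, asm_b)
  ref_partner <- p$truth$ref_gene[p$truth$acc_gene == parent$gene_id]
  cat_ref <- calls$category[!is.na(calls$gene_a) & calls$gene_a == ref_partner]
  expect_false(identical(cat_ref, "one_to_one"))

  calls <- classify_cnv_pap(calls, p$rs$genes, genes_b, p$rs$reference, asm_b)
  expect_equal(calls$category[!is.na(calls$gene_b) &
                                calls$gene_b == copy$gene_id],
               "tandem_dup_cnv")
  expect_equal(calls$category[!is.na(calls$gene_b) &
                                calls$gene_b == parent$gene_id],
               "tandem_dup_cnv")
})

test_that("a gene deleted from the partner genome becomes a PAP candidate", {
  p <- make_pair(seed = 26, gene_loss_prob = 0.15, tandem_dup_prob = 0)
  lost <- p$truth$ref_gene[p$truth$event == "lost"]
  expect_gt(length(lost), 0L)
  calls <- call_one_to_one(p$rs$genes, p$acc$genes, p$acc$assembly)
  expect_true(all(calls$category[match(lost, calls$gene_a)] == "no_call"))
  calls <- classify_cnv_pap(calls, p$rs$genes, p$acc$genes,
                            p$rs$reference, p$acc$assembly)
  got <- calls[match(lost, calls$gene_a), ]
  expect_true(all(got$category == "non_tandem_cnv_pap"))
  expect_true(all(got$evidence == "no_genomic_hit"))
})

test_that("genes on unanchored contigs are classified unanchored", {
  p <- make_pair(seed = 27, gene_loss_prob = 0.2, tandem_dup_prob = 0)
  lost <- p$truth$ref_gene[p$truth$event == "lost"]
  expect_gt(length(lost), 0L)
  # mark the reference chromosome unanchored: lost genes land there
  ref2 <- p$rs$reference
  ref2$anchored[] <- FALSE
  calls <- call_one_to_one(p$rs$genes, p$acc$genes, p$acc$assembly)
  calls <- classify_cnv_pap(calls, p$rs$genes, p$acc$genes,
                            ref2, p$acc$assembly)
  expect_true(all(calls$category[match(lost, calls$gene_a)] == "unanchored"))
})

test_that("every gene receives exactly one category or no_call", {
  p <- make_pair(seed = 28)
  calls <- call_one_to_one(p$rs$genes, p$acc$genes, p$acc$assembly)
  calls <- classify_cnv_pap(calls, p$rs$genes, p$acc$genes,
                            p$rs$reference, p$acc$assembly)
  a_seen <- calls$gene_a[!is.na(calls$gene_a)]
  b_seen <- calls$gene_b[!is.na(calls$gene_b)]
  expect_setequal(a_seen, p$rs$genes$gene_id)
  expect_setequal(b_seen, p$acc$genes$gene_id)
  expect_false(anyDuplicated(a_seen) > 0)
  expect_false(anyDuplicated(b_seen) > 0)
  expect_true(all(calls$category %in%
                    c("one_to_one", "homologue_partner", "tandem_dup_cnv",
                      "non_tandem_cnv_pap", "unanchored", "no_call")))
})

test_that("consensus ids derive from the partner with the suffix", {
  calls <- data.frame(
    gene_a = c("MELO.jh102711.1", "NEWG2"),
    gene_b = c("MELO3C019694", "MELO3C000002"),
    category = c("one_to_one", "no_call"), stringsAsFactors = FALSE)
  map <- assign_consensus_ids(calls)
  expect_equal(unname(map["MELO.jh102711.1"]), "MELO3C019694.jh1")
  expect_equal(unname(map["NEWG2"]), "NEWG2")
  # idempotent: same inputs, same mapping
  expect_identical(map, assign_consensus_ids(calls))
  # collision detection
  calls2 <- data.frame(gene_a = c("x", "y"), gene_b = c("z", "z"),
                       category = "one_to_one", stringsAsFactors = FALSE)
  expect_error(assign_consensus_ids(calls2), "collision")
})
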