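test_that("FASTA read-back preserves record order, lengths and content", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1 first", rand_dna(10, seed = 1), ">s2", rand_dna(20)),
             fa)
  asm <- read_fasta(fa, accession_id = "x")
  expect_equal(length(asm$sequences), 2L)
  expect_equal(unname(seq_lengths(asm)), c(10L, 20L))
  expect_equal(names(asm$sequences), c("s1", "s2"))

  out <- tempfile(fileext = ".fa")
  write_fasta(asm, out)
  back <- read_fasta(out, accession_id = "x")
  expect_identical(back$sequences, asm$sequences)
})

test_that("non-ACGTN symbols are uppercased and mapped to N with a warning", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgtR"), fa)
  expect_warning(asm <- read_fasta(fa), "replaced by N")
  expect_identical(unname(asm$sequences), "ACGTN")
})

test_that("empty files and duplicate ids are hard errors", {
  fa <- tempfile(fileext = ".fa")
  file.create(fa)
  expect_error(read_fasta(fa))
  writeLines(c(">a", "ACGTACGT", ">a", "ACGTACGT"), fa)
  expect_error(read_fasta(fa), "duplicate")
})

test_that("GFF3 coordinates convert 1-based inclusive to 0-based half-open", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", rand_dna(400, seed = 7)), fa)
  asm <- read_fasta(fa, accession_id = "t")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t101\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\tx\texon\t101\t200\t.\t+\t.\tID=g1.e1;Parent=g1.t1"),
             gff)
  # the 100 bp CDS is not a codon multiple: warned and marked non-coding
  expect_warning(got <- read_gff3(gff, asm), "multiple of 3")
  expect_equal(got$genes$start, 100L)
  expect_equal(got$genes$end, 200L)
  expect_false(got$genes$coding)
})

test_that("minus-strand two-exon gene splices to the reverse complement", {
  cfg <- tiny_cfg(seed = 3)
  rs <- simulate_reference(cfg)
  g <- rs$genes[rs$genes$strand == "-" &
                  lengths(rs$genes$exon_starts) == 2L, ][1, ]
  expect_false(is.na(g$gene_id))
  fwd <- paste0(
    interval_seq(rs$reference, g$seqid, g$exon_starts[[1]][1],
                 g$exon_ends[[1]][1]),
    interval_seq(rs$reference, g$seqid, g$exon_starts[[1]][2],
                 g$exon_ends[[1]][2]))
  expect_identical(g$transcript_seq, revcomp(fwd))
  # and the protein is the translation of the spliced CDS
  expect_identical(substr(g$transcript_seq, 1, 3), "ATG")
  expect_false(grepl("\\*", g$protein_seq))
})

test_that("GFF3 round trip is lossless for genes and element rows", {
  cfg <- tiny_cfg(seed = 5)
  rs <- simulate_reference(cfg)
  gff <- tempfile(fileext = ".gff3")
  write_gff3(rs$genes, rs$elements, gff)
  got <- read_gff3(gff, rs$reference)
  o <- order(got$genes$gene_id)
  expect_equal(got$genes$gene_id[o], rs$genes$gene_id)
  expect_equal(got$genes$start[o], rs$genes$start)
  expect_equal(got$genes$end[o], rs$genes$end)
  expect_equal(got$genes$strand[o], rs$genes$strand)
  expect_equal(got$genes$transcript_seq[o], rs$genes$transcript_seq)
  expect_equal(got$genes$protein_seq[o], rs$genes$protein_seq)
  oe <- order(got$elements$element_id)
  expect_equal(got$elements$element_id[oe], rs$elements$element_id)
  expect_equal(got$elements$start[oe], rs$elements$start)
  expect_equal(got$elements$end[oe], rs$elements$end)
  expect_true(all(vapply(got$elements$term_ids,
                         function(t) "IPR005162" %in% t, logical(1))))
})

test_that("element rows are emitted as elements, not gene models", {
  cfg <- tiny_cfg(seed = 5)
  rs <- simulate_reference(cfg)
  gff <- tempfile(fileext = ".gff3")
  write_gff3(rs$genes, rs$elements, gff)
  got <- read_gff3(gff, rs$reference)
  expect_false(any(got$elements$element_id %in% got$genes$gene_id))
  expect_equal(nrow(got$elements), nrow(rs$elements))
})

test_that("BED element sidecar round trips", {
  cfg <- tiny_cfg(seed = 5)
  rs <- simulate_reference(cfg)
  bed <- tempfile(fileext = ".bed")
  write_bed_elements(rs$elements, bed)
  got <- read_bed_elements(bed)
  expect_equal(got$element_id, rs$elements$element_id)
  expect_equal(got$start, rs$elements$start)
  expect_equal(got$end, rs$elements$end)
})

test_that("expression TSV round trips with sample groups", {
  vals <- matrix(abs(rnorm(12)), 3, 4,
                 dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  gr <- setNames(c("a", "a", "ripening_fruit", "ripening_fruit"),
                 colnames(vals))
  m <- expression_matrix(vals, gr)
  p1 <- tempfile(); p2 <- tempfile()
  write_expression_tsv(m, p1, p2)
  back <- read_expression_tsv(p1, p2)
  expect_equal(back$values, m$values, tolerance = 1e-12)
  expect_identical(back$sample_groups, m$sample_groups)
})

test_that("newick serialization handles leaves, pairs and round trips", {
  expect_identical(write_newick("A"), "A;")
  h <- hclust(dist(c(0, 1)), method = "complete")
  h$labels <- c("A", "B")
  expect_identical(write_newick(h), "(A:1,B:1);")

  m <- matrix(rnorm(40), 8, 5)
  rownames(m) <- paste0("acc", 1:8)
  h2 <- hclust(dist(m), method = "complete")
  phy <- read_newick(write_newick(h2))
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, rownames(m))
  # round trip again: branch lengths preserved to float tolerance
  phy2 <- read_newick(write_newick(phy))
  expect_equal(sort(phy2$edge.length), sort(phy$edge.length),
               tolerance = 1e-9)
  # cophenetic distances match the merge heights
  cp <- ape::cophenetic.phylo(phy)
  expect_equal(max(cp) / 2, max(h2$height), tolerance = 1e-9)
})

test_that("duplicate leaf labels are rejected", {
  h <- hclust(dist(c(a = 0, b = 2)))
  h$labels <- c("A", "A")
  expect_error(write_newick(h), "duplicate")
})

test_that("interval invariants are enforced", {
  expect_error(genomic_interval("c", 5, 5))
  expect_error(genomic_interval("c", -1, 5))
  asm <- genome_assembly("a", c(s = "ACGTACGTAC"))
  expect_equal(interval_seq(asm, "s", 0, 4), "ACGT")
  expect_equal(interval_seq(asm, "s", 0, 4, "-"), "ACGT")  # palindromic
  expect_equal(interval_seq(asm, "s", 2, 6, "-"), revcomp("GTAC"))
  expect_error(interval_seq(asm, "s", 0, 11))
})
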