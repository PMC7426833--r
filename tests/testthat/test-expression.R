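mk_mat <- function(vals, groups = NULL) {
  if (is.null(groups))
    groups <- setNames(c("a", "a", "ripening_fruit", "ripening_fruit"),
                       colnames(vals))
  expression_matrix(vals, groups)
}

test_that("the expression filter keeps features reaching the threshold", {
  vals <- rbind(zero = c(0, 0, 0, 0),
                edge = c(0, 0, 0.1, 0),
                low = c(0.01, 0.02, 0.01, 0.05),
                ok = c(1, 2, 3, 4),
                ok2 = c(0.5, 0, 0, 0))
  colnames(vals) <- paste0("s", 1:4)
  m <- mk_mat(vals)
  f <- filter_expressed(m)
  expect_equal(rownames(f$values), c("edge", "ok", "ok2"))
  # a feature with exactly one sample at 0.1 is kept
  expect_true("edge" %in% rownames(f$values))
  # idempotent
  expect_identical(filter_expressed(f)$values, f$values)
  # strict mode keeps only features at/above threshold everywhere
  fa <- filter_expressed(m, mode = "all")
  expect_equal(rownames(fa$values), "ok")
  expect_warning(filter_expressed(mk_mat(vals * 0 + 0.01)), "no feature")
})

test_that("pearson_r matches the closed-form oracle and handles edge cases", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  n <- 4
  r_oracle <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(pearson_r(x, y), r_oracle, tolerance = 1e-12)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_true(is.na(pearson_r(x, rep(2, 4))))
  expect_error(pearson_r(x, c(1, 2)))
  # random-vector agreement with the oracle
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    ro <- (sum(a * b) - 10 * mean(a) * mean(b)) /
      sqrt((sum(a^2) - 10 * mean(a)^2) * (sum(b^2) - 10 * mean(b)^2))
    expect_equal(pearson_r(a, b), ro, tolerance = 1e-12)
  }
})

test_that("ripening classification is a strict argmax with fold support", {
  groups <- setNames(rep(c("root", "leaf", "ripening_fruit"), each = 2),
                     paste0("s", 1:6))
  vals <- rbind(up = c(1, 1, 2, 2, 50, 52),
                flat = rep(3, 6),
                leafy = c(1, 1, 60, 58, 5, 5),
                tie = c(4, 4, 5, 5, 5, 5))
  colnames(vals) <- names(groups)
  m <- expression_matrix(vals, groups)
  rc <- call_ripening_inducible(m)
  got <- setNames(rc$is_ripening_inducible, rc$feature_id)
  expect_true(got[["up"]])
  expect_false(got[["flat"]])
  expect_false(got[["leafy"]])
  expect_false(got[["tie"]])
  # fold requirement
  rc2 <- call_ripening_inducible(m, min_fold = 30)
  expect_false(setNames(rc2$is_ripening_inducible, rc2$feature_id)[["up"]])
  # single tissue group is an error
  m1 <- expression_matrix(vals[, 5:6],
                          setNames(rep("ripening_fruit", 2),
                                   colnames(vals)[5:6]))
  expect_error(call_ripening_inducible(m1), "two tissue groups")
})

test_that("neighbor pairing takes the nearest gene per side within the window", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    seqid = "chr1",
    start = c(1000L, 20000L, 52000L, 300000L),
    end = c(2000L, 21000L, 53000L, 301000L), stringsAsFactors = FALSE)
  els <- data.frame(element_id = c("e1", "e2"), seqid = "chr1",
                    start = c(30000L, 200000L), end = c(31000L, 201000L),
                    stringsAsFactors = FALSE)
  np <- retropap:::find_neighbor_genes(els, genes, 50000L)
  e1 <- np[np$query_id == "e1", ]
  expect_setequal(e1$gene_id, c("g2", "g3"))  # nearest per side, not g1
  expect_equal(e1$distance_bp[e1$gene_id == "g2"], 9000L)
  # e2: no gene within 50 kb on either side
  expect_equal(nrow(np[np$query_id == "e2", ]), 0L)
})

test_that("co-expression fractions count defined pairs above the cutoff", {
  # constructed matrix: 5 element-gene pairs, 3 above r = 0.8
  groups <- setNames(rep(c("a", "b", "c", "ripening_fruit"), each = 3),
                     paste0("s", 1:12))
  base <- c(rep(1, 9), 30, 31, 29)
  anti <- rev(base)
  flat <- jitter(rep(5, 12), amount = 0.01)
  vals <- rbind(e1 = base, e2 = base, e3 = base, e4 = base, e5 = base,
                g1 = base + rnorm(12, 0, 0.1),   # r ~ 1
                g2 = base * 2,                   # r = 1
                g3 = base + rnorm(12, 0, 0.2),   # r ~ 1
                g4 = anti,                       # r < 0
                g5 = flat + rnorm(12, 0, 1))     # r ~ 0
  vals <- pmax(vals, 0)
  colnames(vals) <- names(groups)
  m <- expression_matrix(vals, groups)
  genes <- data.frame(gene_id = paste0("g", 1:5), seqid = "chr1",
                      start = seq(1000L, by = 20000L, length.out = 5),
                      end = seq(2000L, by = 20000L, length.out = 5),
                      stringsAsFactors = FALSE)
  els <- data.frame(element_id = paste0("e", 1:5), seqid = "chr1",
                    start = genes$start + 5000L, end = genes$start + 6000L,
                    stringsAsFactors = FALSE)
  set.seed(42)
  cx <- neighbor_coexpression(els, genes, m, ripening_ids = paste0("e", 1:5),
                              window_bp = 6000L)
  fr <- cx$fractions[cx$fractions$set == "ripening_elements", ]
  expect_equal(fr$n_pairs, 5L)
  expect_equal(fr$fraction, 0.6)
  # histogram counts sum to the number of defined pairs
  h <- cx$histogram[cx$histogram$set == "ripening_elements", ]
  expect_equal(sum(h$count), 5L)
})

test_that("elements missing from the matrix are skipped with a log entry", {
  groups <- setNames(rep(c("a", "ripening_fruit"), each = 2), paste0("s", 1:4))
  vals <- matrix(runif(8, 1, 2), 2, 4,
                 dimnames = list(c("e1", "g1"), paste0("s", 1:4)))
  m <- expression_matrix(vals, groups)
  genes <- data.frame(gene_id = "g1", seqid = "c", start = 100L, end = 200L,
                      stringsAsFactors = FALSE)
  els <- data.frame(element_id = c("e1", "e2"), seqid = "c",
                    start = c(1000L, 5000L), end = c(2000L, 6000L),
                    stringsAsFactors = FALSE)
  expect_message(
    cx <- neighbor_coexpression(els, genes, m, ripening_ids = c("e1", "e2")),
    "skipped")
  expect_true(all(cx$pairs$query_id != "e2"))
})

test_that("co-expression edges report symmetric high-|r| pairs once", {
  groups <- setNames(rep(c("a", "ripening_fruit"), each = 3),
                     paste0("s", 1:6))
  x <- c(1, 2, 3, 10, 11, 12)
  vals <- rbind(f1 = x, f2 = x + 0.01, f3 = rev(x))
  colnames(vals) <- names(groups)
  m <- expression_matrix(vals, groups)
  e <- coexpression_edges(m, r_cutoff = 0.9)
  expect_equal(nrow(e), 3L)  # f1-f2 (+), f1-f3 (-), f2-f3 (-)
  expect_false(any(duplicated(t(apply(e[, 1:2], 1, sort)))))
})
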