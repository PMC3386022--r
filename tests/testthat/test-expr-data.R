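# Loading, validation, batch mean-centring and probeset subsetting of the
# treatment-instance expression matrix.

write_expr_fixture <- function(values, meta, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  expr_path <- file.path(dir, "expr.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  tab <- data.frame(probeset_id = colnames(values), t(values),
                    check.names = FALSE)
  write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = expr_path, meta = meta_path)
}

test_that("TSV round-trip preserves values, ids and metadata join", {
  values <- matrix(c(1.5, 2, 3, -1, 0.25, 4), nrow = 3,
                   dimnames = list(c("i1", "i2", "i3"), c("p1", "p2")))
  meta <- data.frame(instance_id = c("i1", "i2", "i3"),
                     compound_id = c("cA", "cA", "cB"),
                     batch_id = "b1")
  paths <- write_expr_fixture(values, meta)
  m <- load_expression(paths$expr, paths$meta)
  expect_s3_class(m, "ExpressionMatrix")
  expect_false(m$centred)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$values, values)
  expect_equal(m$instances$compound_id, c("cA", "cA", "cB"))

  # the transposed orientation auto-detects via the metadata ids
  dir2 <- withr::local_tempdir()
  flipped <- data.frame(probeset_id = rownames(values), values,
                        check.names = FALSE)
  names(flipped)[1] <- "instance_id"
  write.table(flipped, file.path(dir2, "expr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  m2 <- load_expression(file.path(dir2, "expr.tsv"), paths$meta)
  expect_equal(m2$values, values)
})

test_that("loader rejects malformed input", {
  values <- matrix(1:4, 2, dimnames = list(c("i1", "i2"), c("p1", "p2")))
  meta <- data.frame(instance_id = c("i1", "i2"), compound_id = "cA",
                     batch_id = "b1")
  paths <- write_expr_fixture(values, meta)

  # duplicate probeset row
  writeLines(c("probeset_id\ti1\ti2", "p1\t1\t2", "p1\t3\t4"), paths$expr)
  expect_error(load_expression(paths$expr, paths$meta), "duplicate probeset")

  # non-numeric cell
  writeLines(c("probeset_id\ti1\ti2", "p1\t1\tx", "p2\t3\t4"), paths$expr)
  expect_error(load_expression(paths$expr, paths$meta), "non-numeric")

  # instance missing from metadata (orientation forced so the join fails)
  writeLines(c("probeset_id\ti1\ti9", "p1\t1\t2", "p2\t3\t4"), paths$expr)
  expect_error(load_expression(paths$expr, paths$meta,
                               orientation = "instances_in_columns"),
               "lacking metadata")
  # under auto-detection the same file is simply unidentifiable
  expect_error(load_expression(paths$expr, paths$meta), "orientation")

  expect_error(load_expression(file.path(tempdir(), "nope.tsv"), paths$meta),
               "not found")
})

test_that("GCT 1.2 is parsed and dimension mismatches are rejected", {
  dir <- withr::local_tempdir()
  gct <- file.path(dir, "m.gct")
  meta <- data.frame(instance_id = c("s1", "s2"), compound_id = c("cA", "cB"),
                     batch_id = "b1")
  meta_path <- file.path(dir, "meta.tsv")
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(c("#1.2", "3\t2", "Name\tDescription\ts1\ts2",
               "p1\tna\t1\t2", "p2\tna\t3\t4", "p3\tna\t5\t6"), gct)
  m <- load_expression(gct, meta_path)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m$values["s2", "p3"], 6)

  # declared 4 rows, body has 3
  writeLines(c("#1.2", "4\t2", "Name\tDescription\ts1\ts2",
               "p1\tna\t1\t2", "p2\tna\t3\t4", "p3\tna\t5\t6"), gct)
  expect_error(load_expression(gct, meta_path), "declares 4 rows")
})

test_that("batch mean-centring zeroes within-batch probeset means and drops small batches", {
  # one batch of 6: textbook centring
  v <- matrix(1:6, ncol = 1, dimnames = list(sprintf("i%d", 1:6), "p1"))
  m <- make_em(v, compounds = sprintf("c%d", 1:6), batches = rep("b1", 6))
  centred <- batch_mean_center(m)
  expect_true(centred$centred)
  expect_equal(unname(centred$values[, 1]), c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5))
  expect_equal(mean(centred$values[, 1]), 0)

  # identical rows centre to zero
  v2 <- matrix(7, nrow = 6, ncol = 3)
  m2 <- make_em(v2, batches = rep("b1", 6))
  expect_true(all(batch_mean_center(m2)$values == 0))

  # a 6-instance batch survives, a 3-instance batch is excluded
  v3 <- matrix(rnorm(9 * 2), nrow = 9)
  m3 <- make_em(v3, batches = c(rep("big", 6), rep("small", 3)))
  expect_message(c3 <- batch_mean_center(m3), "excluded 3")
  expect_equal(nrow(c3$values), 6L)
  expect_true(all(c3$instances$batch_id == "big"))

  expect_error(batch_mean_center(c3), "already centred")
})

test_that("centring is idempotent in effect and preserves within-batch correlations", {
  set.seed(1)
  v <- matrix(rnorm(14 * 5), nrow = 14)
  m <- make_em(v, batches = rep(c("b1", "b2"), each = 7))
  c1 <- batch_mean_center(m)
  c1_reset <- expression_matrix(c1$values, c1$instances, centred = FALSE)
  c2 <- batch_mean_center(c1_reset)
  expect_lt(max(abs(c2$values - c1$values)), 1e-9)
  # per-batch means are zero
  for (b in c("b1", "b2")) {
    sub <- c1$values[c1$instances$batch_id == b, ]
    expect_lt(max(abs(colMeans(sub))), 1e-9)
  }
  # Pearson is invariant to a constant added to one whole instance, so a
  # per-probeset batch offset is all that centring needs to remove: on a
  # 2-batch fixture where batch 2 repeats batch 1 shifted by a probeset-
  # wise offset, raw cross-batch correlations are depressed but centred
  # replicates become identical again
  base <- matrix(rnorm(6 * 8), nrow = 6)
  offset <- rnorm(8, sd = 3)
  v2 <- rbind(base, sweep(base, 2, offset, `+`))
  m2 <- make_em(v2, batches = rep(c("b1", "b2"), each = 6))
  expect_equal(pearson(v2[1, ] + 42, v2[2, ]), pearson(v2[1, ], v2[2, ]))
  expect_lt(cor(v2[1, ], v2[7, ]), 1) # raw: batch offset breaks the match
  c2b <- batch_mean_center(m2)
  expect_lt(max(abs(c2b$values[7, ] - c2b$values[1, ])), 1e-9)
  expect_equal(cor(c2b$values[1, ], c2b$values[7, ]), 1)
})

test_that("subset_probesets restricts columns in signature order", {
  v <- matrix(1:12, nrow = 3,
              dimnames = list(c("i1", "i2", "i3"), c("pa", "pb", "pc", "pd")))
  m <- make_em(v)
  # identity
  expect_equal(subset_probesets(m, gene_signature(colnames(v)))$values, v)
  # single column, signature order respected
  s <- subset_probesets(m, gene_signature(c("pc", "pa")))
  expect_equal(colnames(s$values), c("pc", "pa"))
  expect_equal(unname(s$values[, "pc"]), 7:9)
  # unknown probeset is named in the error
  expect_error(subset_probesets(m, gene_signature("nope")), "nope")
  # subset of subset == composed subset
  s2 <- subset_probesets(subset_probesets(m, gene_signature(c("pd", "pb", "pa"))),
                         gene_signature(c("pb", "pa")))
  expect_equal(s2$values, subset_probesets(m, gene_signature(c("pb", "pa")))$values)
})

test_that("constructor enforces the container invariants", {
  v <- matrix(1:4, 2, dimnames = list(c("i1", "i2"), c("p1", "p2")))
  meta <- data.frame(instance_id = c("i1", "i2"), compound_id = "cA",
                     batch_id = "b1")
  expect_error(expression_matrix(v, meta[1, ]), "dimension mismatch")
  meta_dup <- meta; meta_dup$instance_id <- c("i1", "i1")
  v_dup <- v; rownames(v_dup) <- c("i1", "i1")
  expect_error(expression_matrix(v_dup, meta_dup), "duplicate instance_id")
  v_na <- v; v_na[1] <- NA
  expect_error(expression_matrix(v_na, meta), "missing values")
})
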