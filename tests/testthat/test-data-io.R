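test_that("dense CSV spot matrices round-trip bit-identically", {
  m <- spot_matrix(matrix(c(0, 1, 2, 3.5, 4, 0), 3, 2),
                   c("s1", "s2", "s3"), c("gA", "gB"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spot_matrix(m, path, "csv")
  back <- read_spot_matrix(path)
  expect_identical(dim(back), c(3L, 2L))
  expect_identical(unname(as.matrix(back$values)), unname(as.matrix(m$values)))
  expect_identical(back$spot_ids, m$spot_ids)
  expect_identical(back$gene_ids, m$gene_ids)
})

test_that("MTX triplets parse to the listed nonzeros, genes-in-rows convention", {
  dir <- withr::local_tempdir()
  # 2 genes x 3 spots, 4 nonzeros, written by hand
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 4", "1 1 5", "2 1 1", "1 3 2", "2 2 7"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB"), file.path(dir, "genes.tsv"))
  writeLines(c("b1", "b2", "b3"), file.path(dir, "barcodes.tsv"))
  m <- read_spot_matrix(file.path(dir, "matrix.mtx"))
  dense <- as.matrix(m$values)
  # independent brute-force parse of the triplet body
  trip <- read.table(file.path(dir, "matrix.mtx"), skip = 2)
  expected <- matrix(0, 3, 2)  # spots x genes after orientation flip
  for (r in seq_len(nrow(trip))) expected[trip[r, 2], trip[r, 1]] <- trip[r, 3]
  expect_equal(unname(dense), expected)
  expect_identical(sum(dense != 0), 4L)
  # round trip through the writer
  out <- file.path(dir, "rt")
  write_spot_matrix(m, out, "mtx")
  back <- read_spot_matrix(file.path(out, "matrix.mtx"))
  expect_equal(as.matrix(back$values), dense)
})

test_that("negative entries are rejected with their coordinates", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 1", "2 1 -1"), file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB"), file.path(dir, "genes.tsv"))
  writeLines(c("b1", "b2", "b3"), file.path(dir, "barcodes.tsv"))
  expect_error(read_spot_matrix(file.path(dir, "matrix.mtx")), "negative entry")
  expect_error(read_spot_matrix(file.path(dir, "missing.mtx")), "not found")
})

test_that("coordinates parse verbatim in file order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("s1,0,0", "s2,3,4"), path)
  co <- read_coordinates(path)
  expect_equal(co$x, c(0, 3))
  expect_equal(co$y, c(0, 4))
  expect_identical(co$spot_id, c("s1", "s2"))

  writeLines(c("s1,0,0", "s1,3,4"), path)
  expect_error(read_coordinates(path), "duplicated")

  writeLines(c("s1,0,zero"), path)
  expect_error(read_coordinates(path), "line 1")
})

test_that("shuffling the coordinate file preserves the id -> (x, y) pairs", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- sprintf("s%d,%g,%g", 1:8, (1:8) * 2, (8:1) * 3)
  writeLines(rows, path)
  co1 <- read_coordinates(path)
  writeLines(sample(rows), path)
  co2 <- read_coordinates(path)
  co2 <- co2[match(co1$spot_id, co2$spot_id), ]
  expect_equal(co1$x, co2$x)
  expect_equal(co1$y, co2$y)
})

test_that("gene alignment takes the ordered intersection and errors when empty", {
  a <- spot_matrix(matrix(1:6, 2, 3), c("s1", "s2"), c("a", "b", "c"))
  b <- spot_matrix(matrix(1:6, 2, 3), c("t1", "t2"), c("b", "c", "d"))
  al <- align_genes(a, b)
  expect_identical(al$simulated$gene_ids, c("b", "c"))
  expect_identical(al$real$gene_ids, c("b", "c"))
  d <- spot_matrix(matrix(1:4, 2, 2), c("t1", "t2"), c("x", "y"))
  expect_error(align_genes(a, d), "no shared genes")
})

test_that("top-N gene selection matches an exhaustive variance ranking", {
  set.seed(42)
  vals <- sapply(c(0.1, 5, 0.5, 3, 1), function(s) rnorm(20, 0, s))
  sim <- spot_matrix(abs(vals), paste0("s", 1:20), paste0("g", 1:5))
  real <- spot_matrix(matrix(1, 4, 5), paste0("t", 1:4), paste0("g", 1:5))
  al <- align_genes(sim, real, n_top = 2)
  vr <- apply(abs(vals), 2, var)
  expected <- paste0("g", sort(order(vr, decreasing = TRUE)[1:2]))
  expect_identical(al$simulated$gene_ids, expected)
  # idempotence: realigning the aligned pair changes nothing
  al2 <- align_genes(al$simulated, al$real, n_top = 2)
  expect_identical(al2$simulated$values, al$simulated$values)
  expect_identical(al2$real$values, al$real$values)
})

test_that("normalisation scales rows to the target then applies log1p", {
  m <- spot_matrix(matrix(c(1, 1, 2), 1, 3), "s1", c("a", "b", "c"))
  out <- normalize_expression(m, target_sum = 4)
  expect_equal(as.vector(out$values), c(log(2), log(2), log(3)))
  expect_identical(out$layer, "normalized")

  # row already at the target: output is log1p of the input
  m2 <- spot_matrix(matrix(c(3, 7), 1, 2), "s1", c("a", "b"))
  expect_equal(as.vector(normalize_expression(m2, 10)$values), log1p(c(3, 7)))

  # all-zero rows pass through without NaN
  m3 <- spot_matrix(matrix(c(0, 0, 1, 3), 2, 2, byrow = TRUE),
                    c("s1", "s2"), c("a", "b"))
  out3 <- normalize_expression(m3, 4)
  expect_equal(as.vector(out3$values[1, ]), c(0, 0))
  expect_false(anyNA(out3$values))

  expect_error(normalize_expression(m, target_sum = 0), "target_sum")
  expect_error(normalize_expression(out, 4), "counts")
})

test_that("post-scaling row totals all equal the target (non-zero rows)", {
  set.seed(1)
  m <- spot_matrix(matrix(rpois(50 * 8, 3), 50, 8),
                   paste0("s", 1:50), paste0("g", 1:8))
  out <- normalize_expression(m, 1e4)
  sums <- rowSums(expm1(as.matrix(out$values)))
  nz <- rowSums(as.matrix(m$values)) > 0
  expect_true(all(abs(sums[nz] - 1e4) < 1e-9 * 1e4))
})

test_that("proportion CSVs round-trip to at least 8 significant digits", {
  set.seed(3)
  raw <- matrix(rexp(100 * 5), 100, 5)
  p <- proportion_matrix(raw / rowSums(raw), paste0("t", 1:5),
                         paste0("s", 1:100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_proportions(p, path)
  back <- read_proportions(path)
  expect_lt(max(abs(unclass(back) - unclass(p))), 1e-8)
  expect_true(all(abs(rowSums(unclass(back)) - 1) < 1e-6))

  single <- proportion_matrix(matrix(1, 1, 1), "only", "s1")
  write_proportions(single, path)
  expect_equal(as.numeric(unclass(read_proportions(path))), 1)
})

test_that("proportion and pathology invariants are enforced", {
  expect_error(proportion_matrix(matrix(c(0.5, 0.4), 1, 2)), "sums to")
  expect_error(proportion_matrix(matrix(c(-0.1, 1.1), 1, 2)), "negative")
  expect_error(pathology_labels(matrix(c(1, 1, 0, 1), 2, 2)), "exactly one")
  oh <- pathology_labels(c("a", "b", "a"))
  expect_equal(unname(rowSums(unclass(oh))), c(1, 1, 1))
})

test_that("dataset assembly requires consistent spot ids", {
  expr <- spot_matrix(matrix(1:4, 2, 2), c("s1", "s2"), c("g1", "g2"))
  good <- spot_coords(c("s1", "s2"), c(0, 1), c(0, 1))
  bad <- spot_coords(c("s2", "s1"), c(0, 1), c(0, 1))
  expect_s3_class(st_dataset(expr, good), "st_dataset")
  expect_error(st_dataset(expr, bad), "do not match")
})
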