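test_that("edge lists parse into first-appearance-ordered binary matrices", {
  p <- write_edge_file(c("L1\tD1", "L1\tD2", "L2\tD2"))
  am <- load_association_edges(p)
  expect_s3_class(am, "assoc_matrix")
  expect_identical(rownames(am), c("L1", "L2"))
  expect_identical(colnames(am), c("D1", "D2"))
  expect_identical(unclass(am)[, ], matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                           dimnames = list(c("L1", "L2"),
                                                           c("D1", "D2"))))

  # headers and comments are skipped
  p2 <- write_edge_file(c("lncRNA_id\tdisease_id", "# a comment",
                          "L1\tD1", "", "L2\tD1"))
  expect_equal(sum(load_association_edges(p2)), 2)
})

test_that("duplicate edges collapse with a warning; bad inputs error", {
  p <- write_edge_file(c("L1\tD1", "L1\tD1"))
  expect_warning(am <- load_association_edges(p), "duplicate")
  expect_identical(dim(am), c(1L, 1L))
  expect_equal(sum(am), 1)

  expect_error(load_association_edges(write_edge_file(character())),
               "no associations")
  expect_error(load_association_edges(write_edge_file(c("# only comments"))),
               "no associations")
  expect_error(load_association_edges(write_edge_file(c("L1\tD1", "orphan"))),
               "line 2")
  expect_error(load_association_edges(tempfile()), "not found")
})

test_that("matrix construction enforces its invariants", {
  expect_error(assoc_matrix(matrix(0L, 2, 2)), "no associations")
  expect_error(assoc_matrix(matrix(c(1, 2), 1, 2)), "0 or 1")
  expect_error(assoc_matrix(matrix(1L, 2, 1), lnc_ids = c("a", "a")),
               "duplicate")
})

test_that("edge-list round trip reproduces matrix and identifier order", {
  sim <- small_sim()
  # scramble so the orderings are not trivially sorted, and include a
  # zero-degree column ordering case via the original simulated matrix
  p <- tempfile(fileext = ".tsv")
  write_association_edges(sim$am, p)
  am2 <- load_association_edges(p)
  expect_identical(unclass(am2)[, ], unclass(sim$am)[, ])
  expect_identical(rownames(am2), rownames(sim$am))
  expect_identical(colnames(am2), colnames(sim$am))

  # a matrix whose column first-appearance order (row-major) differs from
  # its stored order still round-trips exactly
  Y <- matrix(c(0L, 1L, 1L, 1L), 2, 2)  # edge scan meets D2 before D1
  am3 <- assoc_matrix(Y, c("La", "Lb"), c("Da", "Db"))
  p3 <- tempfile(fileext = ".tsv")
  write_association_edges(am3, p3)
  am4 <- load_association_edges(p3)
  expect_identical(colnames(am4), c("Da", "Db"))
  expect_identical(unclass(am4)[, ], unclass(am3)[, ])
})

test_that("all-pairs assembly enumerates every cell", {
  am <- tiny_am()
  ds <- assemble_dataset(am, mode = "all_pairs", seed = 1)
  expect_equal(length(ds$y), 4)
  expect_equal(sum(ds$y), 3)
  expect_false(anyDuplicated(ds$pairs) > 0)
  # labels match the matrix at each pair
  expect_equal(ds$y, as.integer(unclass(am)[ds$pairs]))
})

test_that("balanced assembly draws the requested negatives or errors", {
  am <- tiny_am()   # 3 positives, one zero cell at (2, 1)
  # floor(neg_ratio * #positives) = 1 forces the single zero cell
  ds <- assemble_dataset(am, mode = "balanced", neg_ratio = 1 / 3, seed = 1)
  expect_equal(sum(ds$y == 1), 3)
  expect_equal(sum(ds$y == 0), 1)
  expect_equal(ds$pairs[ds$y == 0, , drop = FALSE],
               cbind(row = 2L, col = 1L))

  # more negatives than zero cells is a hard error, never silently clamped
  expect_error(assemble_dataset(am, mode = "balanced", neg_ratio = 1),
               "insufficient zero cells")
  expect_error(assemble_dataset(am, mode = "balanced", neg_ratio = 2),
               "insufficient zero cells")
  expect_error(assemble_dataset(am, mode = "balanced", neg_ratio = 0),
               "positive")
})

test_that("assembly is seed-deterministic and seed-sensitive", {
  am <- small_sim()$am
  a <- assemble_dataset(am, neg_ratio = 1, seed = 11)
  b <- assemble_dataset(am, neg_ratio = 1, seed = 11)
  c <- assemble_dataset(am, neg_ratio = 1, seed = 12)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$y, b$y)
  neg_set <- function(d) sort(d$pairs[d$y == 0, 1] * 1000 + d$pairs[d$y == 0, 2])
  expect_false(identical(neg_set(a), neg_set(c)))
  # exact class balance at neg_ratio = 1
  expect_equal(sum(a$y == 1), sum(a$y == 0))
})
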