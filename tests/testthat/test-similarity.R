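test_that("constructor validates entries against the score range", {
  v <- matrix(c(0, 0.5, 1, 0.25, 0.75, 0.1, 0.9, 0.3, 0.6), 3, 3)
  sm <- similarity_matrix(v, paste0("a", 1:3), paste0("b", 1:3),
                          rep("X", 3), rep("X", 3), score_range = c(0, 1))
  expect_equal(unclass(sm)[2, 1], 0.5, ignore_attr = TRUE)
  v[2, 2] <- 2.5
  expect_error(
    similarity_matrix(v, paste0("a", 1:3), paste0("b", 1:3),
                      rep("X", 3), rep("X", 3), score_range = c(0, 2)),
    "outside")
  expect_error(
    similarity_matrix(matrix(0.1, 2, 2), c("a", "b"), c("a", "b"),
                      "X", c("X", "X")),
    "class labels")
})

test_that("write/read round trip reproduces entries at printed precision", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    v <- matrix(runif(100, 0, 2), 10, 10)
    ids <- sprintf("m%02d", 1:10)
    cls <- rep(c("P", "Q"), 5)
    sm <- similarity_matrix(v, ids, ids, cls, cls)
    mpath <- withr::local_tempfile(fileext = ".csv")
    apath <- withr::local_tempfile(fileext = ".csv")
    write_similarity_matrix(sm, mpath, apath, digits = 6)
    back <- read_similarity_matrix(mpath, apath)
    expect_equal(unclass(back), round(unclass(sm), 6),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_identical(attr(back, "row_class"), attr(sm, "row_class"))
  }
})

test_that("reading rejects malformed cells and unannotated ligands", {
  mpath <- withr::local_tempfile(fileext = ".csv")
  apath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,a,b", "a,1.0,0.5", "b,oops,1.0"), mpath)
  writeLines(c("ligand_id,class_label", "a,X", "b,X"), apath)
  expect_error(read_similarity_matrix(mpath, apath), "non-numeric")
  writeLines(c("id,a,b", "a,1.0,0.5", "b,0.4,1.0"), mpath)
  writeLines(c("ligand_id,class_label", "a,X"), apath)
  expect_error(read_similarity_matrix(mpath, apath), "missing from")
  writeLines(c("ligand_id,class_label", "a,X", "b,Y"), apath)
  expect_error(read_similarity_matrix(mpath, apath, score_range = c(0, 0.8)),
               "outside")
})

test_that("class_block matches a brute-force pair filter", {
  sm <- tiny_matrix()
  blk <- class_block(sm, "A")
  expect_equal(dim(blk), c(3L, 3L))
  expect_equal(length(intra_class_values(blk)), 3 * 2)

  # brute force: all (i, j) with both classes A, i != j
  v <- unclass(sm)
  cls <- attr(sm, "row_class")
  brute <- c()
  for (i in 1:6) for (j in 1:6) {
    if (cls[i] == "A" && cls[j] == "A" && i != j) brute <- c(brute, v[i, j])
  }
  expect_equal(sort(intra_class_values(blk)), sort(brute))

  with_diag <- class_block(sm, "A", include_diagonal = TRUE)
  expect_equal(length(intra_class_values(with_diag)), 9)
  expect_error(class_block(sm, "Z"), "unknown class")
  one <- similarity_matrix(matrix(0.5, 1, 1), "x", "x", "S", "S",
                           score_range = c(0, 1))
  expect_error(class_block(one, "S"), "fewer than 2")
})

test_that("extract_query_vector matches brute-force lookup and excludes self", {
  sm <- tiny_matrix()
  v <- unclass(sm)
  cls <- attr(sm, "row_class")

  cross <- extract_query_vector(sm, "L01", "B")   # query in A vs class B
  expect_length(cross, 3)
  expect_equal(as.numeric(cross), unname(v[which(cls == "B"), 1]))

  self <- extract_query_vector(sm, "L02", "A")    # query in A vs own class
  expect_length(self, 2)
  expect_equal(as.numeric(self),
               unname(v[setdiff(which(cls == "A"), 2), 2]))

  expect_error(extract_query_vector(sm, "nope", "A"), "unknown query")
  expect_error(extract_query_vector(sm, "L01", "Z"), "unknown class")
})

test_that("duplicate conformer ids are kept distinct and need an index", {
  v <- matrix(runif(16, 0.2, 0.8), 4, 4); diag(v) <- 1
  ids <- c("cpd1", "cpd1", "cpd2", "cpd2")   # two conformers each
  cls <- c("A", "A", "B", "B")
  sm <- similarity_matrix(v, ids, ids, cls, cls, score_range = c(0, 1))
  expect_error(extract_query_vector(sm, "cpd1", "B"), "column index")
  byidx <- extract_query_vector(sm, 2, "B")
  expect_equal(as.numeric(byidx), v[3:4, 2])
})

test_that("symmetrize averages the two overlay directions", {
  sm <- tiny_matrix()
  sym <- symmetrize(sm)
  expect_equal(unclass(sym), (unclass(sm) + t(unclass(sm))) / 2,
               ignore_attr = TRUE)
  expect_equal(unclass(sym), t(unclass(sym)), ignore_attr = TRUE)
})
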