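test_that("reading a delimited Cq table preserves shape, ids and missing cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "miR-a\t24.5\t25.1\tNA\t24.9",
               "miR-b\t30.0\t29.8\t30.2\t30.1",
               "miR-c\t27.3\t27.0\t27.6\t27.2"), path)
  m <- read_cq_table(path)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(rownames(m), c("miR-a", "miR-b", "miR-c"))
  expect_identical(colnames(m), paste0("s", 1:4))
  expect_identical(which(is.na(m)), which(row(m) == 1 & col(m) == 3))
  expect_equal(m["miR-b", "s3"], 30.2)
})

test_that("write/read round trip is bit-identical and keeps id order", {
  set.seed(42)
  m <- mk_mat(matrix(runif(20, 20, 40), 5, 4),
              genes = c("z", "a", "m", "q", "b"))
  m[2, 3] <- NA
  for (ext in c(".tsv", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_cq_table(m, path)
    back <- read_cq_table(path)
    expect_identical(unclass(back)[, ], unclass(m)[, ])
  }
})

test_that("malformed tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "a\t24\t25", "a\t30\t31"), path)
  expect_error(read_cq_table(path), "duplicate gene ids.*a")

  writeLines(c("gene\ts1\ts2", "a\t24\t25", "b\t30"), path)
  expect_error(read_cq_table(path), "ragged.*row 3")

  writeLines(c("gene\ts1\ts2", "a\t24\tundet", "b\t30\t31"), path)
  expect_error(read_cq_table(path), "'undet'.*row 'a'.*column 's2'")

  writeLines(c("gene\ts1\ts2", "a\t24\t", "b\t30\t31"), path)
  expect_true(is.na(read_cq_table(path)["a", "s2"]))  # empty cell = undetected
})

test_that("cq_matrix enforces its invariants", {
  base <- matrix(25, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_s3_class(cq_matrix(base), "cq_matrix")
  bad <- base; bad[1, 1] <- 46
  expect_error(cq_matrix(bad), "outside")
  bad <- base; bad[1, 1] <- Inf
  expect_error(cq_matrix(bad), "non-finite")
  dup <- base; colnames(dup) <- c("s1", "s1")
  expect_error(cq_matrix(dup), "duplicate sample ids")
  expect_error(cq_matrix(unname(base)), "rownames")
})

test_that("group tables parse, preserve label order, and reject conflicts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tHCC", "s2\thealthy", "s3\tHCC", "s4\thealthy"), path)
  g <- read_groups(path)
  expect_length(g, 4)
  expect_identical(levels(g), c("HCC", "healthy"))
  expect_identical(names(g), paste0("s", 1:4))

  writeLines(c("sample\tgroup", "s1\tHCC", "s1\thealthy"), path)
  expect_error(read_groups(path), "conflicting")

  writeLines(character(0), path)
  expect_error(read_groups(path), "empty")
})

test_that("a four-arm cohort file reproduces the 33/21/23/28 design", {
  sim <- generate_cq(default_panel(), seed = 7)
  prefix <- withr::local_tempfile()
  write_synthetic(sim, prefix)
  g <- read_groups(paste0(prefix, "_groups.tsv"))
  expect_identical(levels(g), c("HCC", "CHB", "cirrhosis", "healthy"))
  expect_identical(as.integer(table(g)), c(33L, 21L, 23L, 28L))
  back <- read_cq_table(paste0(prefix, "_cq.tsv"))
  expect_identical(unclass(back)[, ], unclass(sim$cq)[, ])
})

test_that("relative expression follows the 2^-dCq closed form", {
  m <- mk_mat(rbind(c(25, 26, 28.5, 24, 31),
                    c(22, 26, 30.0, 25, 29)), genes = c("t", "r"))
  re <- relative_expression(m, "t", "r")
  expect_equal(unname(re$values[1]), 0.125)
  expect_equal(unname(re$values), oracle_rel_expr(m["t", ], m["r", ]))
  expect_equal(re$n_used, 5L)
  expect_false(re$degenerate)
})

test_that("self-normalization is flagged degenerate with all values 1", {
  m <- mk_mat(rbind(c(25, 26), c(22, 23)), genes = c("t", "r"))
  re <- relative_expression(m, "t", "t")
  expect_true(re$degenerate)
  expect_true(all(re$values == 1))
})

test_that("relative expression is antisymmetric and shift invariant", {
  for (seed in 1:5) {
    m <- random_cq(2, 8, seed)
    rownames(m) <- c("t", "r")
    fwd <- relative_expression(m, "t", "r")$values
    bwd <- relative_expression(m, "r", "t")$values
    expect_equal(unname(fwd * bwd), rep(1, 8))
    shifted <- cq_matrix(unclass(m) + 2.5)
    expect_equal(relative_expression(shifted, "t", "r")$values, fwd)
  }
})

test_that("missing samples are dropped and recorded, empty overlap errors", {
  m <- mk_mat(rbind(c(25, NA, 27), c(22, 23, NA)), genes = c("t", "r"))
  re <- relative_expression(m, "t", "r")
  expect_equal(re$n_used, 1L)
  expect_setequal(re$dropped_samples, c("s2", "s3"))
  m2 <- mk_mat(rbind(c(25, NA), c(NA, 23)), genes = c("t", "r"))
  expect_error(relative_expression(m2, "t", "r"), "no samples")
})

test_that("spike normalization equals per-gene relative expression", {
  m <- mk_mat(matrix(c(24, 28, 31, 20), 4, 3),
              genes = c("a", "b", "c", "cel-miR-67"))
  out <- spike_normalize(m, "cel-miR-67")
  expect_named(out, c("a", "b", "c"))
  expect_true(all(out$a$values == 2^-4))

  set.seed(11)
  m2 <- random_cq(4, 6, 11)
  rownames(m2)[4] <- "spike"
  out2 <- spike_normalize(m2, "spike")
  for (g in names(out2))
    expect_equal(out2[[g]]$values, relative_expression(m2, g, "spike")$values)
  expect_error(spike_normalize(m2, "nope"), "not in matrix")
})

test_that("technical replicates collapse by the mean of detected wells", {
  m <- mk_mat(rbind(c(24, 25, 30), c(NA, 26, 28)),
              genes = c("a", "b"), samples = c("w1", "w2", "w3"))
  coll <- collapse_replicates(m, c("p1", "p1", "p2"))
  expect_equal(unname(coll["a", ]), c(24.5, 30))
  expect_equal(unname(coll["b", ]), c(26, 28))
})
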