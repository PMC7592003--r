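grp4 <- function(mat, sizes = c(HCC = 33, CHB = 21, cirrhosis = 23,
                                healthy = 28)) {
  sample_groups(setNames(rep(names(sizes), times = sizes), colnames(mat)))
}

test_that("combined Cq is the arithmetic mean of member rows", {
  m <- mk_mat(rbind(c(24, 25, 26), c(30, 29, 28), c(27, 27, 27)),
              genes = c("a", "b", "c"))
  expect_equal(unname(combine_refs(m, c("a", "b"))$cq[1]), 27)
  expect_equal(combine_refs(m, c("a", "b", "c"))$cq,
               colMeans(unclass(m)[c("a", "b", "c"), ]))
  # singleton: identical to the member; duplicates collapse
  expect_equal(combine_refs(m, "a")$cq, unclass(m)["a", ])
  expect_identical(combine_refs(m, c("a", "a"))$members, "a")
  expect_error(combine_refs(m, c("a", "nope")), "not in matrix")
  expect_error(combine_refs(m, character(0)), "nonempty")
})

test_that("a sample missing any member is missing in the combination", {
  m <- mk_mat(rbind(c(24, NA, 26), c(30, 29, 28)), genes = c("a", "b"))
  cb <- combine_refs(m, c("a", "b"))
  expect_true(is.na(cb$cq[["s2"]]))
  expect_equal(unname(cb$cq[c("s1", "s3")]), c(27, 27))
})

test_that("averaging two independent equal-variance genes shrinks the SD", {
  ratios <- vapply(1:30, function(seed) {
    set.seed(600 + seed)
    m <- mk_mat(rbind(26 + rnorm(80, 0, 1), 29 + rnorm(80, 0, 1)))
    sd(combine_refs(m, c("g1", "g2"))$cq) / 1
  }, numeric(1))
  expect_equal(mean(ratios), 1 / sqrt(2), tolerance = 0.05)
  # and never exceeds the noisier member by construction
  set.seed(12)
  m <- mk_mat(rbind(25 + rnorm(60, 0, 0.4), 28 + rnorm(60, 0, 1.8)))
  cb <- combine_refs(m, c("g1", "g2"))
  expect_lte(var(cb$cq), max(apply(unclass(m), 1, var)))
})

test_that("a group-shifted target is declared unstable against a flat reference", {
  set.seed(71)
  n <- 105
  flat <- 25 + rnorm(n, 0, 0.5)
  shifted <- 28 + rnorm(n, 0, 0.5)
  shifted[1:33] <- shifted[1:33] + 2          # +2 Cq in the first group
  m <- mk_mat(rbind(shifted, flat), genes = c("target", "ref"))
  rep <- cross_normalize(m, grp4(m), list("target", "ref"))
  row <- rep$pairs[rep$pairs$target == "target", ]
  expect_lt(row$p_parametric, 0.05)
  expect_identical(row$verdict, "unstable")
})

test_that("constant expression is reported degenerate, never a silent p", {
  m <- mk_mat(rbind(rep(25, 105), rep(22, 105)), genes = c("a", "b"))
  w <- capture_warnings(rep <- cross_normalize(m, grp4(m), list("a", "b")))
  expect_match(w, "degenerate", all = TRUE)
  expect_length(w, 2)  # one per ordered pair
  expect_true(all(rep$pairs$verdict == "degenerate"))
  expect_true(all(is.na(rep$pairs$p_parametric)))
})

test_that("two-group candidates use t and Mann-Whitney tests", {
  set.seed(81)
  m <- mk_mat(rbind(25 + rnorm(40, 0, 0.5), 28 + rnorm(40, 0, 0.5)),
              genes = c("a", "b"))
  g <- sample_groups(setNames(rep(c("HCC", "healthy"), each = 20),
                              colnames(m)))
  rep <- cross_normalize(m, g, list("a", "b"))
  row <- rep$pairs[1, ]
  expr <- relative_expression(m, "a", "b")$values
  expect_equal(row$p_parametric,
               t.test(expr[1:20], expr[21:40], var.equal = TRUE)$p.value)
  expect_equal(row$p_nonparametric,
               wilcox.test(expr[1:20], expr[21:40])$p.value)
})

test_that("a singleton combination behaves exactly like the bare gene", {
  set.seed(5)
  m <- random_cq(3, 60, 5)
  g <- sample_groups(setNames(rep(c("A", "B", "C"), each = 20), colnames(m)))
  bare <- cross_normalize(m, g, list("g1", "g2"))
  single <- cross_normalize(m, g, list(combine_refs(m, "g1", label = "g1"),
                                       "g2"))
  expect_equal(single$pairs$p_parametric, bare$pairs$p_parametric)
  expect_equal(single$pairs$p_nonparametric, bare$pairs$p_nonparametric)
})

test_that("pairs sharing a gene are skipped unless overlap is allowed", {
  set.seed(6)
  m <- random_cq(3, 60, 6)
  g <- sample_groups(setNames(rep(c("A", "B", "C"), each = 20), colnames(m)))
  cb <- combine_refs(m, c("g1", "g2"))
  rep <- cross_normalize(m, g, list("g1", cb))
  expect_true(all(rep$pairs$verdict == "skipped"))
  expect_match(rep$pairs$reason[1], "shared gene")
  rep2 <- cross_normalize(m, g, list("g1", cb), allow_overlap = TRUE)
  expect_true(all(rep2$pairs$partial_overlap))
  expect_true(all(rep2$pairs$verdict %in% c("stable", "unstable")))
})

test_that("combination scoring excludes members and recovers design order", {
  hits <- vapply(1:25, function(seed) {
    sim <- generate_cq(default_panel(), seed = 700 + seed)
    m <- sim$cq
    combos <- list(combine_refs(m, c("miR-S", "miR-I1")),
                   combine_refs(m, c("miR-S", "miR-I4")),
                   combine_refs(m, c("miR-S", "U6-like")))
    ev <- evaluate_combinations(m, combos)
    all(ev$table[1, c("genorm_rank", "normfinder_rank", "deltacq_rank")] == 1)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # members of any combination never appear as comparators
  sim <- generate_cq(default_panel(), seed = 701)
  ev <- evaluate_combinations(sim$cq,
                              list(combine_refs(sim$cq, c("miR-S", "miR-I1")),
                                   combine_refs(sim$cq, c("miR-S", "miR-I2"))))
  expect_identical(ev$table$combination, c("miR-S+miR-I1", "miR-S+miR-I2"))
})

test_that("a self-combination scores exactly like the gene it copies", {
  m <- random_cq(4, 30, 9)
  ev <- evaluate_combinations(m, list(combine_refs(m, "g1", label = "copy1"),
                                      combine_refs(m, "g2", label = "copy2")))
  expect_equal(ev$table$genorm[1], unname(m_values(m)["g1"]))
  expect_equal(ev$table$deltacq[1],
               unname(deltacq_stability(m)$stability["g1"]))
})

test_that("fewer than two combinations cannot be ranked", {
  m <- random_cq(4, 20, 10)
  expect_error(evaluate_combinations(m, list(combine_refs(m, c("g1", "g2")))),
               "at least 2")
})

test_that("a combination consuming the whole panel has no comparators", {
  m <- random_cq(3, 20, 11)
  expect_error(
    evaluate_combinations(m, list(combine_refs(m, c("g1", "g2", "g3")),
                                  combine_refs(m, c("g1", "g2")))),
    "no comparators")
})
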