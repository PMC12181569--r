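make_matrix <- function(values, dataset = "DS01", shared = rownames(values)) {
  expr_matrix(values, dataset = dataset, shared_probes = shared)
}

test_that("scale normalization hits the target mean exactly", {
  # hand oracle: shared probes are 2 of 3; factors from shared probes only
  v <- matrix(c(100, 300, 7,
                50, 150, 13), nrow = 3,
              dimnames = list(c("pA", "pB", "pC"), c("s1", "s2")))
  m <- make_matrix(v, shared = c("pA", "pB"))
  out <- scale_normalize(m, target_mean = 1000)
  f1 <- 1000 / mean(c(100, 300))   # = 5
  f2 <- 1000 / mean(c(50, 150))    # = 10
  expect_equal(unname(out$values[, "s1"]), c(100, 300, 7) * f1)
  expect_equal(unname(out$values[, "s2"]), c(50, 150, 13) * f2)
  expect_equal(unname(colMeans(out$values[c("pA", "pB"), ])), c(1000, 1000))
})

test_that("normalization is idempotent, ratio-preserving, identity at target", {
  set.seed(2)
  v <- matrix(rlnorm(60, log(500), 1), 10, 6,
              dimnames = list(sprintf("p%02d", 1:10), sprintf("s%d", 1:6)))
  m <- make_matrix(v, shared = sprintf("p%02d", 1:8))
  once <- scale_normalize(m)
  twice <- scale_normalize(once)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  # within-sample probe ratios preserved
  expect_equal(once$values[2, ] / once$values[5, ], v[2, ] / v[5, ])
  # sample already at the target mean is unchanged
  v1 <- v
  v1[, 1] <- v1[, 1] * 1000 / mean(v1[1:8, 1])
  out <- scale_normalize(make_matrix(v1, shared = sprintf("p%02d", 1:8)))
  expect_equal(out$values[, 1], v1[, 1], tolerance = 1e-12)
  # constant matrix collapses to the target value everywhere
  vc <- matrix(37, 4, 3, dimnames = list(sprintf("p%d", 1:4), sprintf("s%d", 1:3)))
  expect_true(all(scale_normalize(make_matrix(vc))$values == 1000))
})

test_that("normalization refuses all-zero shared probes by name", {
  v <- matrix(c(0, 0, 5, 1, 2, 3), 3, 2,
              dimnames = list(c("p1", "p2", "p3"), c("bad", "good")))
  m <- make_matrix(v, shared = c("p1", "p2"))
  expect_error(scale_normalize(m), "bad")
})

test_that("duplicate removal keeps the earliest-priority dataset copy", {
  set.seed(3)
  v <- matrix(rlnorm(40, log(500), 1), 8, 5,
              dimnames = list(sprintf("p%d", 1:8),
                              c("a1", "a2", "b1", "b2", "b3")))
  v[, "b2"] <- v[, "a1"]            # exact copy in a later dataset
  m <- expr_matrix(v, dataset = c("GSE1", "GSE1", "GSE2", "GSE2", "GSE2"))
  out <- remove_duplicates(m, priority = c("GSE1", "GSE2"))
  expect_equal(out$removed,
               data.frame(removed_id = "b2", retained_id = "a1",
                          stringsAsFactors = FALSE))
  expect_setequal(colnames(out$matrix$values), c("a1", "a2", "b1", "b3"))

  # no duplicates: identity, empty removal list
  out2 <- remove_duplicates(expr_matrix(v[, c(1, 2, 3, 5)],
                                        dataset = c("GSE1", "GSE1", "GSE2", "GSE2")),
                            priority = c("GSE1", "GSE2"))
  expect_equal(nrow(out2$removed), 0L)
  expect_equal(ncol(out2$matrix$values), 4L)
})

test_that("three-way duplicate groups leave exactly one survivor", {
  set.seed(4)
  v <- matrix(rlnorm(30, log(500), 1), 6, 5,
              dimnames = list(sprintf("p%d", 1:6),
                              c("x1", "y1", "z1", "y2", "z2")))
  v[, "y1"] <- v[, "z1"] <- v[, "x1"]
  m <- expr_matrix(v, dataset = c("A", "B", "C", "B", "C"))
  out <- remove_duplicates(m, priority = c("A", "B", "C"))
  expect_equal(nrow(out$removed), 2L)
  expect_setequal(out$removed$removed_id, c("y1", "z1"))
  expect_true(all(out$removed$retained_id == "x1"))
  # brute-force pairwise comparison agrees on who is duplicated
  key <- apply(signif(v, 4), 2, paste, collapse = ",")
  expect_equal(sum(duplicated(key)), nrow(out$removed))
})

test_that("duplicate survivor is stable under within-dataset permutation", {
  set.seed(5)
  v <- matrix(rlnorm(24, log(500), 1), 4, 6,
              dimnames = list(sprintf("p%d", 1:4), sprintf("s%d", 1:6)))
  v[, "s5"] <- v[, "s2"]
  ds <- c("A", "A", "A", "B", "B", "B")
  out1 <- remove_duplicates(expr_matrix(v, dataset = ds),
                            priority = c("A", "B"))
  perm <- c("s3", "s1", "s2", "s6", "s5", "s4")   # permute within datasets
  out2 <- remove_duplicates(expr_matrix(v[, perm], dataset = ds),
                            priority = c("A", "B"))
  expect_equal(out1$removed$removed_id, out2$removed$removed_id)
  expect_equal(out1$removed$retained_id, out2$removed$retained_id)
})

test_that("QC filter applies the banded rule and partitions the batch", {
  set.seed(6)
  n <- 40
  qc <- data.frame(
    sample_id = sprintf("s%02d", 1:n),
    background_signal = rnorm(n, 60, 8), raw_q = rnorm(n, 2.2, 0.25),
    percent_present = rnorm(n, 45, 4), biob_detected = TRUE,
    ratio_3to5 = rnorm(n, 1.4, 0.15))
  # force the controls near the batch mean so band checks are deterministic
  qc[1, 2:4] <- c(60, 2.2, 45); qc$ratio_3to5[1] <- 1.4
  # s2: three metrics displaced far beyond any 95% band plus no bioB
  qc$background_signal[2] <- 60 + 5 * 8 * 3
  qc$raw_q[2] <- 2.2 + 5 * 0.25 * 3
  qc$biob_detected[2] <- FALSE
  res <- qc_filter(qc)
  expect_true("s01" %in% res$passed)
  expect_true("s02" %in% res$excluded)
  # partition: disjoint and exhaustive
  all_ids <- c(res$passed, res$flagged, res$excluded)
  expect_setequal(all_ids, qc$sample_id)
  expect_equal(length(all_ids), n)
})

test_that("a single failing metric flags but does not exclude by default", {
  qc <- data.frame(
    sample_id = sprintf("s%d", 1:20),
    background_signal = rep(60, 20), raw_q = rep(2.2, 20),
    percent_present = rep(45, 20), biob_detected = TRUE,
    ratio_3to5 = c(rep(1.4, 10), rnorm(9, 1.4, 0.01), 5))
  res <- qc_filter(qc)
  expect_true("s20" %in% res$flagged)
  expect_false("s20" %in% res$excluded)
  # the strict any-failure reading is one configuration flag away
  strict <- qc_filter(qc, exclude_min_failures = 1L)
  expect_true("s20" %in% strict$excluded)
})

test_that("QC filter needs a spread estimate and complete columns", {
  qc <- data.frame(sample_id = c("a", "b"), background_signal = c(1, 2),
                   raw_q = c(1, 2), percent_present = c(1, 2),
                   biob_detected = TRUE, ratio_3to5 = c(1, 2))
  expect_error(qc_filter(qc), "at least 3")
  qc3 <- rbind(qc, qc[1, ])
  qc3$sample_id <- c("a", "b", "c")
  expect_error(qc_filter(qc3[, -2]), "background_signal")
})
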