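test_that("multi-class IoU matches the worked example and edge conventions", {
  expect_equal(iou_multiclass(matrix(c(1, 1, 0, 2), 2),
                              matrix(c(1, 0, 0, 2), 2)), 0.75)
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_equal(iou_multiclass(m, m), 1.0)
  expect_equal(iou_multiclass(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), 0.0)
  zeros <- matrix(0L, 3, 3)
  expect_equal(iou_multiclass(zeros, zeros), 1.0)
  expect_error(iou_multiclass(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("multi-class IoU agrees exactly with the pixel-counting oracle", {
  set.seed(802)
  for (i in 1:200) {
    pred <- random_label_mat(8, 3)
    truth <- random_label_mat(8, 3)
    expect_identical(iou_multiclass(pred, truth), iou_oracle(pred, truth))
  }
})

test_that("group means are plain arithmetic means per group", {
  meta <- data.frame(sample_id = c("a1", "a2", "b1"),
                     group = c("A", "A", "B"))
  scores <- c(a1 = 0.6, a2 = 1.0, b1 = 0.8)
  gm <- group_mean_ious(scores, meta)
  expect_equal(gm[["A"]], 0.8)
  expect_equal(gm[["B"]], 0.8)
  expect_error(group_mean_ious(c(zz = 0.5), meta), "without metadata")

  meta4 <- data.frame(sample_id = sprintf("s%d", 1:8),
                      race = rep(c("White", "Black"), each = 4),
                      gender = rep(c("Male", "Female"), 4))
  meta4$group <- paste(meta4$race, meta4$gender, sep = "-")
  sc <- stats::setNames(rep(0.8, 8), meta4$sample_id)
  expect_length(group_mean_ious(sc, meta4, by = "gender"), 2)
  expect_true(all(group_mean_ious(sc, meta4) == 0.8))
})

test_that("SER and MMD match hand evaluations", {
  expect_equal(ser(c(0.9, 0.8)), 2.0)
  expect_equal(ser(c(0.95, 0.90, 0.85)), 3.0)
  expect_equal(ser(c(a = 0.7, b = 0.7, c = 0.7)), 1.0)
  expect_equal(ser(0.5), 1.0)
  expect_error(ser(numeric(0)))
  expect_equal(mmd(c(0.9, 0.8)), 0.1)
  expect_equal(mmd(c(0.95, 0.90, 0.85)), 0.10)
  expect_equal(mmd(c(0.5, 0.5)), 0.0)
  expect_equal(mmd(0.42), 0.0)
  expect_error(mmd(numeric(0)))
})

test_that("SER denominator clamp handles a perfect group", {
  expect_equal(ser(c(1.0, 0.9)), 0.1 / 1e-6)
})

test_that("SER/MMD invariances hold on random group means", {
  set.seed(17)
  for (i in 1:50) {
    gm <- runif(4, 0.2, 0.99)
    perm <- sample(gm)
    expect_equal(ser(perm), ser(gm))
    expect_equal(mmd(perm), mmd(gm))
    # shifting all error rates up by a constant moves SER toward 1
    shift <- runif(1, 0.01, 0.3)
    shifted <- 1 - ((1 - gm) + shift)
    expect_lte(ser(shifted), ser(gm))
    expect_gte(ser(shifted), 1)
    # MMD dominates the population SD of four group means
    expect_gte(mmd(gm), sqrt(mean((gm - mean(gm))^2)))
  }
  expect_equal(mmd(rep(0.7, 4)), 0)
  expect_equal(sqrt(mean((rep(0.7, 4) - 0.7)^2)), 0)
})

test_that("paired t-test reproduces the closed-form worked example", {
  r <- paired_iou_test(c(0.5, 0.7, 0.9), c(0.4, 0.7, 0.8))
  expect_equal(r$t, 2.0)
  expect_equal(r$df, 2L)
  expect_false(r$significant)  # p ~ 0.18 at the 0.05 threshold
  same <- paired_iou_test(c(0.3, 0.4), c(0.3, 0.4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1.0)
  # constant nonzero shift: unambiguous difference by convention
  shifted <- paired_iou_test(c(0.5, 0.6), c(0.4, 0.5))
  expect_equal(shifted$p, 0.0)
  expect_error(paired_iou_test(1:3, 1:2), "length")
  expect_error(paired_iou_test(0.5, 0.4), "at least 2")
})

test_that("paired t-test agrees with the reference implementation", {
  set.seed(31)
  for (i in 1:20) {
    a <- runif(10)
    b <- a + rnorm(10, 0, 0.1)
    mine <- paired_iou_test(a, b)
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value)
  }
})

test_that("fairness report assembles the table columns correctly", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:8),
                     race = rep(c("White", "White", "Black", "Black"), 2),
                     gender = rep(c("Male", "Female"), 4))
  meta$group <- paste(meta$race, meta$gender, sep = "-")
  # group means WM 0.9, WF 0.9, BM 0.8, BF 0.8
  scores <- stats::setNames(
    ifelse(meta$race == "White", 0.9, 0.8), meta$sample_id)
  rep1 <- fairness_report(scores, meta)
  expect_equal(rep1$ser_race, 2.0)
  expect_equal(rep1$ser_gender, 1.0)
  expect_equal(rep1$rg_mean_ser, 1.5)
  expect_equal(rep1$mmd, 0.1)
  expect_equal(rep1$iou_sd, 0.05)  # population SD of (.9, .9, .8, .8)

  flat <- fairness_report(stats::setNames(rep(0.75, 8), meta$sample_id), meta)
  expect_equal(flat$iou_sd, 0)
  expect_equal(flat$rg_mean_ser, 1.0)
  expect_equal(flat$mmd, 0)

  single <- suppressWarnings(fairness_report(c(s1 = 0.42), meta[1, ]))
  expect_equal(single$mean_iou, 0.42)
})

test_that("a one-group dataset yields default SER with a warning", {
  meta <- data.frame(sample_id = c("s1", "s2"), race = "White",
                     gender = "Male", group = "White-Male")
  expect_warning(r <- fairness_report(c(s1 = 0.5, s2 = 0.7), meta),
                 "fewer than 2")
  expect_equal(r$rg_mean_ser, 1.0)
})
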