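test_that("shuffled orders are deterministic permutations, uniform over positions", {
  expect_equal(order_shuffled("only", 1), "only")
  ids <- sprintf("s%02d", 1:10)
  expect_identical(order_shuffled(ids, 7), order_shuffled(ids, 7))
  expect_setequal(order_shuffled(ids, 7), ids)
  # Monte-Carlo uniformity of the first position
  first <- vapply(1:1000, function(i) order_shuffled(ids, i)[1], character(1))
  freq <- table(first) / 1000
  expect_true(all(abs(freq - 0.1) < 0.04))
  expect_error(order_shuffled(character(0), 1))
})

test_that("interleaving cycles the groups and skips exhausted ones", {
  ids <- c("a1", "a2", "b1")
  groups <- c(a1 = "White-Male", a2 = "White-Male", b1 = "Black-Male")
  ord <- order_interleaved(ids, groups, 5)
  expect_setequal(ord, ids)
  # round-robin: one from each group in the first cycle, then the leftover
  # from the larger group once the smaller is exhausted
  expect_setequal(unname(groups[ord[1:2]]), c("Black-Male", "White-Male"))
  expect_equal(unname(groups[ord[3]]), "White-Male")
})

test_that("full-cycle windows cover all four groups", {
  ids <- sprintf("s%02d", 1:20)
  groups <- stats::setNames(rep(group_levels(), each = 5), ids)
  ord <- order_interleaved(ids, groups, 3)
  expect_setequal(ord, ids)
  for (w in seq(1, 17, by = 4))
    expect_setequal(unname(groups[ord[w:(w + 3)]]), group_levels())
})

test_that("ease scores order samples easiest-first within each group", {
  ids <- c("a1", "a2", "a3")
  groups <- stats::setNames(rep("White-Male", 3), ids)
  ease <- c(a1 = 0.9, a2 = 0.5, a3 = 0.7)
  expect_equal(order_interleaved(ids, groups, 1, ease = ease),
               c("a1", "a3", "a2"))
  # ties broken by sample id
  tied <- c(a1 = 0.5, a2 = 0.5, a3 = 0.5)
  expect_equal(order_interleaved(ids, groups, 1, ease = tied), ids)
  expect_error(order_interleaved(ids, c(a1 = "White-Male"), 1), "without group")
})

test_that("interleaved orders are permutations on randomized inputs", {
  set.seed(90)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    ids <- sprintf("x%03d", seq_len(n))
    groups <- stats::setNames(sample(group_levels(), n, replace = TRUE), ids)
    ease <- stats::setNames(runif(n), ids)
    for (ord in list(order_interleaved(ids, groups, i),
                     order_interleaved(ids, groups, i, ease = ease),
                     order_shuffled(ids, i))) {
      expect_equal(sort(ord), sort(ids))
    }
    # with ease: each group's stream is non-increasing in ease
    ord <- order_interleaved(ids, groups, i, ease = ease)
    for (g in unique(groups)) {
      stream <- ease[ord[groups[ord] == g]]
      expect_true(all(diff(stream) <= 1e-12))
    }
  }
})

test_that("self-paced scores are the previous epoch's IoU", {
  prev <- c(x = 0.9, y = 0.4)
  e <- score_self_paced(prev, c("x", "y"))
  expect_gt(e[["x"]], e[["y"]])
  expect_error(score_self_paced(prev, c("x", "y", "z")), "missing")
})

test_that("teacher-student ease uses the signed gap", {
  teacher <- c(s1 = 0.95, s2 = 0.90, s3 = 0.95)
  student <- c(s1 = 0.95, s2 = 0.50, s3 = 0.97)
  e <- score_teacher_student(teacher, student)
  expect_equal(e[["s1"]], 0)          # converged sample
  expect_equal(e[["s2"]], -0.40)      # large gap: hard
  expect_gt(e[["s3"]], e[["s1"]])     # student above teacher: easier still
  expect_gt(e[["s1"]], e[["s2"]])
  expect_error(score_teacher_student(teacher, student[1:2]), "different ids")
})

test_that("balanced curriculum grows linearly and balances the start", {
  expect_equal(bcl_schedule(100, 5), c(20L, 40L, 60L, 80L, 100L))
  expect_equal(bcl_schedule(10, 1), 10L)

  ids <- sprintf("s%03d", 1:100)
  groups <- stats::setNames(rep(group_levels(), each = 25), ids)
  st <- bcl_init(ids, groups, total_epochs = 5, seed = 8)
  expect_length(st$active, 20)
  expect_equal(as.integer(table(groups[st$active])), rep(5L, 4))
  expect_setequal(c(st$active, st$pool), ids)
  expect_length(intersect(st$active, st$pool), 0)

  sizes <- length(st$active)
  for (e in 2:5) {
    ease <- stats::setNames(runif(length(st$pool)), st$pool)
    st <- bcl_update(st, ease, e)
    sizes <- c(sizes, length(st$active))
  }
  expect_equal(sizes, c(20L, 40L, 60L, 80L, 100L))
  expect_true(all(diff(sizes) >= 0))
  expect_length(st$pool, 0)
})

test_that("admission takes the easiest pool samples first", {
  ids <- sprintf("s%02d", 1:10)
  groups <- stats::setNames(rep(group_levels(), length.out = 10), ids)
  st <- bcl_init(ids, groups, total_epochs = 2, seed = 3)
  ease <- stats::setNames(seq(0.1, by = 0.1, length.out = length(st$pool)),
                          st$pool)
  st2 <- bcl_update(st, ease, 2)
  expect_setequal(st2$active, ids)  # final epoch: full set

  st3 <- bcl_init(ids, groups, total_epochs = 4, seed = 3)
  pool1 <- st3$pool
  ease3 <- stats::setNames(seq_along(pool1) / 10, pool1)  # later = easier
  # without a group map, admission is globally easiest-first
  st4 <- bcl_update(st3, ease3, 2)
  admitted <- setdiff(st4$active, st3$active)
  expect_setequal(admitted,
                  pool1[order(-ease3[pool1])][seq_along(admitted)])
  # with a group map, each group's quota is filled by its own easiest
  st5 <- bcl_update(st3, ease3, 2, groups = groups)
  adm5 <- setdiff(st5$active, st3$active)
  for (g in unique(groups[adm5])) {
    members <- pool1[groups[pool1] == g]
    took <- adm5[groups[adm5] == g]
    expect_setequal(took,
                    members[order(-ease3[members])][seq_along(took)])
  }
})

test_that("degenerate schedules collapse to the full set", {
  ids <- c("a", "b", "c")
  groups <- stats::setNames(rep("White-Male", 3), ids)
  st <- bcl_init(ids, groups, total_epochs = 1, seed = 1)
  expect_setequal(st$active, ids)
})
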