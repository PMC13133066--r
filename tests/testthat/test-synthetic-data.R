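spec16 <- generation_spec(n_samples = 8, image_size = 16, seed = 4)

test_that("rendering is deterministic and respects the zero-noise case", {
  a <- render_sample(spec16, "White", "Male", 123)
  b <- render_sample(spec16, "White", "Male", 123)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_true(any(a$mask > 0))
  expect_true(all(a$image >= 0 & a$image <= 1))

  clean <- generation_spec(n_samples = 4, image_size = 16, seed = 4,
                           noise_sd = 0, contrast = 1)
  s <- render_sample(clean, "Black", "Female", 55)
  expect_identical(s$image, fairseg:::render_structures(clean, 55)$image0)
})

test_that("different sample seeds give different phantoms", {
  a <- render_sample(spec16, "White", "Male", 1)
  b <- render_sample(spec16, "White", "Male", 2)
  expect_false(identical(a$mask, b$mask))
})

test_that("group noise levels shape the empirical pixel residual SD", {
  lo <- generation_spec(n_samples = 4, image_size = 16, seed = 4,
                        noise_sd = 0.02, contrast = 1, jitter = 0)
  hi <- generation_spec(n_samples = 4, image_size = 16, seed = 4,
                        noise_sd = 0.20, contrast = 1, jitter = 0)
  res_sd <- function(spec) {
    mean(vapply(1:50, function(i) {
      s <- render_sample(spec, "White", "Male", i)
      clean <- fairseg:::render_structures(spec, i)$image0
      sd(s$image - clean)
    }, numeric(1)))
  }
  expect_gt(res_sd(hi), res_sd(lo))
})

test_that("image_size below the placement minimum errors", {
  expect_error(generation_spec(image_size = 8), "too small")
})

test_that("custom generation balances the four groups and is reproducible", {
  d <- generate_dataset(spec16)
  expect_equal(as.integer(table(d$meta$group)), rep(2L, 4))
  d2 <- generate_dataset(spec16)
  expect_identical(lapply(d$samples, `[[`, "image"),
                   lapply(d2$samples, `[[`, "image"))
  expect_identical(d$meta, d2$meta)
})

test_that("fixture-mode generation reproduces the cohort tables exactly", {
  spec <- generation_spec(dataset = "hip", image_size = 16, seed = 2)
  d <- generate_dataset(spec)
  expect_equal(nrow(d$meta), 761)
  expect_equal(sum(d$meta$gender == "Male"), 324)
  expect_equal(sum(d$meta$race == "White"), 443)
  tab <- demographic_table("hip")
  got <- tapply(rep(1L, nrow(d$meta)),
                list(d$meta$group, d$meta$site), sum)
  for (r in seq_len(nrow(tab))) {
    g <- paste(tab$race[r], tab$gender[r], sep = "-")
    expect_equal(unname(got[g, tab$site[r]]), tab$count[r])
  }
})

test_that("stratified splitting hits per-group targets to within one sample", {
  meta1 <- data.frame(sample_id = sprintf("s%03d", 1:100),
                      group = rep("White-Male", 100))
  sp <- stratified_split(meta1, c(train = 0.7, val = 0.1, test = 0.2), 1)
  expect_equal(as.integer(table(sp)[c("train", "val", "test")]),
               c(70L, 10L, 20L))

  sp_all <- stratified_split(meta1, c(train = 1, val = 0, test = 0), 1)
  expect_true(all(sp_all == "train"))

  meta4 <- data.frame(sample_id = sprintf("s%03d", 1:80),
                      group = rep(group_levels(), each = 20))
  sp4 <- stratified_split(meta4, c(train = 0.7, val = 0.1, test = 0.2), 3)
  for (g in group_levels()) {
    tg <- table(sp4[meta4$group == g])
    expect_equal(as.integer(tg[c("train", "val", "test")]), c(14L, 2L, 4L))
  }
  expect_error(stratified_split(meta1, c(0.5, 0.6)), "sum to 1")
  expect_error(stratified_split(meta1, c(1.2, -0.2)), "\\[0, 1\\]")
  # determinism
  expect_identical(sp4, stratified_split(meta4, c(train = 0.7, val = 0.1,
                                                  test = 0.2), 3))
})

test_that("site partitioning matches table cells exactly", {
  tab <- demographic_table("hip")
  meta <- do.call(rbind, lapply(seq_len(nrow(tab)), function(r)
    if (tab$count[r] == 0) NULL else
      data.frame(race = tab$race[r], gender = tab$gender[r])[
        rep(1, tab$count[r]), , drop = FALSE]))
  meta$sample_id <- sprintf("s%04d", seq_len(nrow(meta)))
  part <- partition_by_site(meta, tab, 1)
  ids_a <- part[["A"]]
  black_a <- sum(meta$race[match(ids_a, meta$sample_id)] == "Black")
  expect_equal(black_a, 157)
  fb_a <- sum(meta$race[match(ids_a, meta$sample_id)] == "Black" &
                meta$gender[match(ids_a, meta$sample_id)] == "Female")
  expect_equal(fb_a, 112)
  # every sample at most once
  expect_false(anyDuplicated(unlist(part)) > 0)

  knee <- demographic_table("knee")
  meta_k <- do.call(rbind, lapply(seq_len(nrow(knee)), function(r)
    data.frame(race = knee$race[r], gender = knee$gender[r])[
      rep(1, knee$count[r]), , drop = FALSE]))
  meta_k$sample_id <- sprintf("k%04d", seq_len(nrow(meta_k)))
  part_k <- partition_by_site(meta_k, knee, 1)
  male_total <- sum(vapply(part_k, function(ids)
    sum(meta_k$gender[match(ids, meta_k$sample_id)] == "Male"), numeric(1)))
  expect_equal(male_total, 280)
})

test_that("degenerate and infeasible site tables behave", {
  one_site <- data.frame(race = rep(c("White", "Black"), each = 2),
                         gender = rep(c("Male", "Female"), 2),
                         site = "A", count = 2)
  meta <- data.frame(race = rep(c("White", "Black"), each = 4),
                     gender = rep(rep(c("Male", "Female"), each = 2), 2),
                     sample_id = sprintf("s%d", 1:8))
  part <- partition_by_site(meta, one_site, 1)
  expect_equal(sort(part[["A"]]), sort(meta$sample_id))

  short <- one_site
  short$count[1] <- 5
  expect_error(partition_by_site(meta, short, 1), "infeasible")
})

test_that("datasets round-trip through PNG + CSV", {
  d <- tiny_data(n = 4, seed = 12)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  d2 <- read_dataset(dir)
  expect_identical(d2$meta$sample_id, d$meta$sample_id)
  expect_identical(d2$meta$split, d$meta$split)
  for (id in d$meta$sample_id) {
    expect_identical(d2$samples[[id]]$mask, d$samples[[id]]$mask)
    expect_lt(max(abs(d2$samples[[id]]$image - d$samples[[id]]$image)),
              1 / 255)
  }
})
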