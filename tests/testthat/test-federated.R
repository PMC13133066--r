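test_that("proximal penalty matches its closed form", {
  expect_equal(fedprox_penalty(c(1, 2), c(1, 2), 5), 0)
  expect_equal(fedprox_penalty(c(9, 9), c(1, 2), 0), 0)
  expect_equal(fedprox_penalty(c(4, 6), c(1, 2), 2), 25)  # (2/2)*(9+16)
  expect_error(fedprox_penalty(1:3, 1:2, 1), "mismatch")
})

test_that("DP perturbation is seeded Gaussian noise of the right scale", {
  par <- rep(0.5, 1e5)
  expect_identical(dp_perturb(par, 0, 1), par)
  a <- dp_perturb(par, 0.1, 9)
  b <- dp_perturb(par, 0.1, 9)
  expect_identical(a, b)
  noise <- a - par
  expect_lt(abs(sd(noise) - 0.1) / 0.1, 0.02)
  expect_lt(abs(mean(noise)), 0.002)
  expect_error(dp_perturb(par, -1, 1), "sigma")
})

test_that("client weights follow each strategy's rule and normalize", {
  ups <- data.frame(n_k = c(1, 3), iou_k = c(0.5, 0.5), ser_k = c(1.0, 2.0))
  expect_equal(client_weights(ups, "fedavg"), c(0.25, 0.75))
  expect_equal(client_weights(ups, "feddpfair"), c(2 / 3, 1 / 3))
  expect_equal(client_weights(ups, "fediou"), c(0.5, 0.5))
  set.seed(4)
  for (s in c("fedavg", "fedprox", "feddp", "feddpfair", "fediou",
              "fediou_outlier")) {
    ups_r <- data.frame(n_k = sample(1:50, 5), iou_k = runif(5),
                        ser_k = 1 + runif(5))
    expect_equal(sum(client_weights(ups_r, s)), 1, tolerance = 1e-12)
  }
  zero <- data.frame(n_k = 1, iou_k = 0, ser_k = 1)
  expect_warning(w <- client_weights(zero, "fediou"), "uniform")
  expect_equal(w, 1)
})

test_that("the IQR filter prunes exactly the anomalous client", {
  scores <- c(0.90, 0.91, 0.92, 0.93, 0.20)
  kept <- iqr_filter(scores)
  expect_setequal(kept, 1:4)
  # quartile convention check: Q1 = 0.90, Q3 = 0.92, threshold 0.87
  expect_equal(unname(quantile(scores, 0.25, type = 7)), 0.90)
  expect_equal(unname(quantile(scores, 0.75, type = 7)), 0.92)
  expect_setequal(iqr_filter(rep(0.7, 4)), 1:4)
  expect_setequal(iqr_filter(c(0.5, 0.9)), 1:2)  # threshold 0.3
  expect_gte(length(iqr_filter(runif(7))), 1)
})

test_that("aggregation is a convex combination of client parameters", {
  expect_equal(aggregate_params(list(c(1, 2)), 1), c(1, 2))
  expect_equal(aggregate_params(list(2, 4), c(1, 3)), 3.5)
  expect_equal(aggregate_params(list(c(1, 3), c(3, 5)), c(0.5, 0.5)),
               c(2, 4))
  set.seed(12)
  for (i in 1:20) {
    ps <- lapply(1:4, function(j) rnorm(6))
    w <- runif(4)
    agg <- aggregate_params(ps, w)
    lo <- do.call(pmin, ps); hi <- do.call(pmax, ps)
    expect_true(all(agg >= lo - 1e-12 & agg <= hi + 1e-12))
  }
  expect_error(aggregate_params(list(), numeric(0)), "empty")
})

make_fed_data <- function(n = 40, seed = 21, sites = c("A", "B")) {
  generate_dataset(generation_spec(n_samples = n, image_size = 16,
                                   seed = seed, sites = sites))
}

test_that("a zero-epoch local update returns the global parameters", {
  d <- make_fed_data()
  clients <- fairseg:::build_clients(d, seed = 1)
  cfg <- unet_config(16, 6, 2, 2)
  global <- build_model(cfg, 7)
  u <- local_update(global$par, clients[[1]], local_epochs = 0,
                    base_channels = 2, depth = 2, seed = 3)
  expect_identical(u$params, global$par)
  expect_true(u$iou_k >= 0 && u$iou_k <= 1)
  expect_gte(u$ser_k, 1)
})

test_that("a single-group client reports SER 1 by convention", {
  d <- make_fed_data(n = 24, sites = "A")
  keep <- d$meta$group == "White-Male" & d$meta$split != "test"
  d$samples <- d$samples[keep]
  d$meta <- d$meta[keep, , drop = FALSE]
  clients <- fairseg:::build_clients(d, seed = 2)
  global <- build_model(unet_config(16, 6, 2, 2), 7)
  u <- suppressWarnings(local_update(global$par, clients[[1]],
                                     local_epochs = 0, base_channels = 2,
                                     depth = 2, seed = 3))
  expect_equal(u$ser_k, 1.0)
})

test_that("federation history keeps normalized weights each round", {
  d <- make_fed_data()
  fed <- suppressWarnings(  # untrained clients may report IoU 0
    fairseg_federate(d, strategy = "fediou", rounds = 2, local_epochs = 1,
                     base_channels = 2, depth = 2, seed = 5))
  for (h in fed$history) {
    expect_equal(sum(h$weights), 1, tolerance = 1e-9)
    expect_true(all(h$excluded %in% fed$clients))
    expect_s3_class(h$report, "fairness_report")
  }
})

test_that("excluded clients keep participating in later rounds", {
  d <- make_fed_data(n = 50, sites = c("A", "B", "C", "D", "E"))
  # fix the reported scores so the outlier decision is deterministic: C is
  # an anomalous client, the others report tightly clustered scores
  fixed_iou <- c(A = 0.90, B = 0.91, C = 0.20, D = 0.92, E = 0.93)
  tamper <- function(u, id, round) {
    u$iou_k <- fixed_iou[[id]]
    if (id == "C")
      u$params <- with_seed(round, rnorm(length(u$params), 0, 5))
    u
  }
  fed <- fairseg_federate(d, strategy = "fediou_outlier", rounds = 3,
                          local_epochs = 1, base_channels = 2, depth = 2,
                          seed = 5, tamper = tamper)
  for (h in fed$history) {
    # C is pruned every round...
    expect_identical(h$excluded, "C")
    # ...but its local update is still computed from the new broadcast
    expect_true("C" %in% names(h$client_iou))
    # and the aggregation weights cover exactly the retained clients
    expect_setequal(names(h$weights), c("A", "B", "D", "E"))
  }
})
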