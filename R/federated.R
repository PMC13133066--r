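#' Proximal penalty between local and global parameters
#'
#' The heterogeneity-control term added to the local objective in the
#' proximal federated variant: `(mu / 2) * ||theta - theta_global||^2`.
#'
#' @param local,global flat parameter vectors of equal length.
#' @param mu proximal coefficient (`>= 0`).
#' @return the scalar penalty.
#' @export
fedprox_penalty <- function(local, global, mu) {
  if (length(local) != length(global)) stop("parameter length mismatch")
  (mu / 2) * sum((local - global)^2)
}

#' Differential-privacy perturbation of a parameter vector
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma` to
#' every parameter, deterministic given the seed.  With `sigma = 0` the
#' vector is returned bit-identical.
#'
#' @param par flat parameter vector.
#' @param sigma noise standard deviation (`>= 0`).
#' @param seed integer seed.
#' @return the perturbed vector.
#' @export
dp_perturb <- function(par, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(par)
  par + with_seed(seed, rnorm(length(par), 0, sigma))
}

#' Client aggregation weights
#'
#' Raw scores by strategy — sample count `n_k` for size-weighted averaging
#' (plain, proximal and DP variants); inverse local skewed error ratio
#' `1 / SER_k` for the fairness-weighted variant; local IoU for the
#' IoU-weighted variants — normalized to sum to 1.  If every raw score is 0
#' the weights fall back to uniform with a warning.
#'
#' @param updates data.frame (or list of client updates) with columns/fields
#'   `n_k`, `iou_k`, `ser_k`.
#' @param strategy one of `"fedavg"`, `"fedprox"`, `"feddp"`,
#'   `"feddpfair"`, `"fediou"`, `"fediou_outlier"`.
#' @return numeric weight vector summing to 1.
#' @export
client_weights <- function(updates, strategy = c("fedavg", "fedprox",
                                                 "feddp", "feddpfair",
                                                 "fediou", "fediou_outlier")) {
  strategy <- match.arg(strategy)
  if (!is.data.frame(updates))
    updates <- do.call(rbind, lapply(updates, function(u)
      data.frame(n_k = u$n_k, iou_k = u$iou_k, ser_k = u$ser_k)))
  if (nrow(updates) == 0) stop("no client updates")
  raw <- switch(strategy,
                fedavg = , fedprox = , feddp = updates$n_k,
                feddpfair = 1 / updates$ser_k,
                fediou = , fediou_outlier = updates$iou_k)
  if (all(raw == 0)) {
    warning("all raw client scores are 0; falling back to uniform weights")
    raw <- rep(1, nrow(updates))
  }
  raw / sum(raw)
}

#' Interquartile-range outlier filter over client IoU scores
#'
#' Quartiles by linear interpolation between closest ranks; clients whose
#' local IoU falls below `Q1 - 1.5 * IQR` are treated as outliers and
#' excluded from the round's aggregation.  The boundary is retained and the
#' retained set is never empty (the maximum cannot fall below the
#' threshold).
#'
#' @param iou_scores numeric vector of local client IoU scores.
#' @return integer indices of the retained clients.
#' @export
iqr_filter <- function(iou_scores) {
  if (length(iou_scores) == 0) stop("no scores to filter")
  q <- unname(quantile(iou_scores, c(0.25, 0.75), type = 7))
  threshold <- q[1] - 1.5 * (q[2] - q[1])
  which(iou_scores >= threshold)
}

#' Weighted aggregation of client parameter vectors
#'
#' Coordinate-wise convex combination of the retained clients' parameters;
#' weights are re-normalized over the retained subset.
#'
#' @param params list of flat parameter vectors.
#' @param weights numeric weights (same length; re-normalized internally).
#' @return the aggregated parameter vector.
#' @export
aggregate_params <- function(params, weights) {
  if (length(params) == 0) stop("cannot aggregate an empty client set")
  if (length(params) != length(weights)) stop("weights misaligned")
  w <- weights / sum(weights)
  out <- numeric(length(params[[1]]))
  for (i in seq_along(params)) out <- out + w[i] * params[[i]]
  out
}

# Build the per-site client list: each client gets the non-test samples of
# one site, re-split 90/10 (stratified) into a local train and local
# validation set used for iou_k / ser_k.
build_clients <- function(data, seed, val_frac = 0.1) {
  meta <- data$meta[data$meta$split != "test", , drop = FALSE]
  clients <- list()
  for (s in sort(unique(meta$site))) {
    sub <- meta[meta$site == s, , drop = FALSE]
    if (nrow(sub) == 0) next
    local_split <- stratified_split(sub, c(train = 1 - val_frac,
                                           val = val_frac),
                                    substream_seed(seed, "clientsplit", s))
    sub$split <- local_split
    cd <- structure(list(samples = data$samples[sub$sample_id], meta = sub,
                         spec = data$spec), class = "fairseg_data")
    if (sum(local_split == "train") == 0) {
      message("client ", s, " has no training samples; skipped")
      next
    }
    clients[[s]] <- cd
  }
  if (length(clients) == 0) stop("no nonempty clients")
  clients
}

#' One client's local training pass
#'
#' Initializes from the broadcast global parameters, trains locally for
#' `local_epochs` with the configured curriculum and loss (optionally with a
#' proximal pull toward the global model), and scores the result on the
#' client's local validation split.
#'
#' @param global_par broadcast flat parameter vector.
#' @param client a `fairseg_data` with local `train`/`val` splits.
#' @param local_epochs local epochs per round (0 = no training; scores are
#'   computed from the global model).
#' @param curriculum,loss,loss_mode,alpha,lr,weight_decay,batch_size,base_channels,depth
#'   as in [fairseg()].
#' @param mu proximal coefficient (0 disables the proximal term).
#' @param seed seed for this client-round.
#' @return a client update: list with `params`, `n_k`, `iou_k`, `ser_k`.
#' @export
local_update <- function(global_par, client, local_epochs = 1,
                         curriculum = "base", loss = "ce",
                         loss_mode = "reweight", alpha = 1, lr = 0.01,
                         weight_decay = 1e-6, batch_size = 2,
                         base_channels = 8, depth = 3, mu = 0, seed = 1L) {
  n_k <- sum(client$meta$split == "train")
  if (local_epochs > 0) {
    fit <- fairseg(client, curriculum = curriculum, loss = loss,
                   loss_mode = loss_mode, alpha = alpha,
                   epochs = local_epochs, lr = lr,
                   weight_decay = weight_decay, batch_size = batch_size,
                   base_channels = base_channels, depth = depth,
                   seed = seed, init_par = global_par,
                   allow_any_epochs = TRUE, evaluate_test = FALSE,
                   prox_mu = mu)
    par <- fit$model$par
    model <- fit$model
  } else {
    cfg <- unet_config(nrow(client$samples[[1]]$image),
                       n_classes = max(vapply(client$samples,
                                              function(s) max(s$mask),
                                              numeric(1))),
                       base_channels = base_channels, depth = depth)
    model <- set_model_params(build_model(cfg, seed), global_par)
    par <- global_par
  }
  val <- subset_data(client, split = "val")
  if (nrow(val$meta) > 0) {
    scores <- evaluate_model(model, val$samples)
    iou_k <- mean(scores)
    rep <- suppressWarnings(fairness_report(scores, val$meta))
    ser_k <- rep$rg_mean_ser
  } else {
    iou_k <- mean(evaluate_model(model,
                                 subset_data(client, split = "train")$samples))
    ser_k <- 1.0
  }
  list(params = par, n_k = n_k, iou_k = iou_k, ser_k = ser_k)
}

#' Simulate federated training over non-IID sites
#'
#' Runs `rounds` global communication rounds: broadcast the global model,
#' train every client locally ([local_update()]), optionally perturb each
#' update with Gaussian noise (DP variants), optionally prune clients whose
#' local IoU is an interquartile-range outlier, weight the retained updates
#' by the strategy's rule ([client_weights()]), aggregate, and score the new
#' global model on the pooled test split.  Excluded clients still receive
#' the next broadcast — exclusion is per-round, never permanent.
#'
#' @param data a `fairseg_data` whose `site` column defines the clients; the
#'   `test` split is held out as the pooled evaluation set.
#' @param strategy aggregation rule (see [client_weights()]).
#' @param rounds number of global communication rounds.
#' @param local_epochs local epochs per round.
#' @param sigma DP noise SD (used by `"feddp"` and `"feddpfair"`).
#' @param mu proximal coefficient (used by `"fedprox"`).
#' @param curriculum,loss,loss_mode,alpha,lr,weight_decay,batch_size,base_channels,depth
#'   local-training settings, as in [fairseg()].
#' @param seed master seed.
#' @param init_par optional flat parameter vector for the initial global
#'   model (e.g. a centrally pretrained warm start for federated
#'   fine-tuning); defaults to a fresh seeded initialization.
#' @param tamper optional `function(update, client_id, round)` applied to
#'   every client update before transmission; intended for robustness
#'   experiments (e.g. simulating an anomalous client).
#' @return an object of class `fairseg_fed`: final `model`, per-round
#'   `history` (weights, exclusions, pooled-test fairness reports),
#'   `config`.
#' @export
fairseg_federate <- function(data,
                             strategy = c("fedavg", "fedprox", "feddp",
                                          "feddpfair", "fediou",
                                          "fediou_outlier"),
                             rounds = 20, local_epochs = 1, sigma = 0.001,
                             mu = 0.01, curriculum = "base", loss = "ce",
                             loss_mode = "reweight", alpha = 1, lr = 0.01,
                             weight_decay = 1e-6, batch_size = 2,
                             base_channels = 8, depth = 3, seed = 1L,
                             init_par = NULL, tamper = NULL,
                             verbose = FALSE) {
  strategy <- match.arg(strategy)
  if (rounds < 1) stop("rounds must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (mu < 0) stop("mu must be >= 0")
  clients <- build_clients(data, seed)
  test <- subset_data(data, split = "test")
  image_size <- nrow(data$samples[[1]]$image)
  n_fg <- max(vapply(data$samples, function(s) max(s$mask), numeric(1)))
  cfg <- unet_config(image_size, n_classes = max(n_fg, 1),
                     base_channels = base_channels, depth = depth)
  global <- build_model(cfg, substream_seed(seed, "model"))
  if (!is.null(init_par)) global <- set_model_params(global, init_par)
  use_mu <- if (strategy == "fedprox") mu else 0
  use_noise <- strategy %in% c("feddp", "feddpfair")

  history <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    updates <- lapply(names(clients), function(id) {
      u <- local_update(global$par, clients[[id]],
                        local_epochs = local_epochs,
                        curriculum = curriculum, loss = loss,
                        loss_mode = loss_mode, alpha = alpha, lr = lr,
                        weight_decay = weight_decay,
                        batch_size = batch_size,
                        base_channels = base_channels, depth = depth,
                        mu = use_mu,
                        seed = substream_seed(seed, "round", r, "client", id))
      u$client_id <- id
      if (!is.null(tamper)) u <- tamper(u, id, r)
      u
    })
    names(updates) <- names(clients)
    if (use_noise && sigma > 0) {
      for (id in names(updates))
        updates[[id]]$params <- dp_perturb(updates[[id]]$params, sigma,
                                           substream_seed(seed, "noise", r, id))
    }
    retained <- if (strategy == "fediou_outlier")
      iqr_filter(vapply(updates, `[[`, numeric(1), "iou_k"))
    else seq_along(updates)
    excluded <- setdiff(names(updates), names(updates)[retained])
    w <- client_weights(updates[retained], strategy)
    global$par <- aggregate_params(lapply(updates[retained], `[[`, "params"), w)
    report <- if (nrow(test$meta) > 0)
      fairness_report(evaluate_model(global, test$samples), test$meta)
    else NULL
    history[[r]] <- list(round = r,
                         weights = stats::setNames(w, names(updates)[retained]),
                         excluded = excluded,
                         global_params = global$par,
                         client_iou = vapply(updates, `[[`, numeric(1), "iou_k"),
                         client_ser = vapply(updates, `[[`, numeric(1), "ser_k"),
                         report = report)
    if (verbose)
      message(sprintf("round %2d  test IoU %.4f  excluded: %s", r,
                      if (is.null(report)) NA else report$mean_iou,
                      if (length(excluded)) paste(excluded, collapse = ",")
                      else "-"))
  }
  structure(list(model = global, history = history, clients = names(clients),
                 config = list(strategy = strategy, rounds = rounds,
                               local_epochs = local_epochs, sigma = sigma,
                               mu = mu, curriculum = curriculum, loss = loss,
                               seed = seed)),
            class = "fairseg_fed")
}

#' @export
print.fairseg_fed <- function(x, ...) {
  cat(sprintf("Federated fit: %s, %d rounds x %d local epoch(s), %d clients\n",
              x$config$strategy, x$config$rounds, x$config$local_epochs,
              length(x$clients)))
  last <- x$history[[length(x$history)]]$report
  if (!is.null(last))
    cat(sprintf("Final pooled test: mean IoU %.4f, R&G mean SER %.4f, MMD %.4f\n",
                last$mean_iou, last$rg_mean_ser, last$mmd))
  invisible(x)
}

#' @export
coef.fairseg_fed <- function(object, ...) object$model$par

#' @export
plot.fairseg_fed <- function(x, ...) {
  iou <- vapply(x$history, function(h)
    if (is.null(h$report)) NA_real_ else h$report$mean_iou, numeric(1))
  graphics::plot(seq_along(iou), iou, type = "b", xlab = "round",
                 ylab = "pooled test mean IoU",
                 main = x$config$strategy, ...)
  invisible(x)
}
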