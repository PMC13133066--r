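#' Compact U-Net model descriptor
#'
#' The backbone is a miniature U-Net: one 3x3 convolution + ReLU per stage,
#' 2x2 max pooling between encoder stages, nearest-neighbour upsampling with
#' skip concatenation in the decoder, and a 1x1 output convolution to
#' per-class scores.  It is deliberately small so that the full
#' curriculum/federated pipeline runs on one CPU; larger backbones can be
#' plugged in by reimplementing the forward/gradient pair behind the same
#' flat-parameter interface.
#'
#' @param image_size input side length; must be divisible by
#'   `2^(depth - 1)`.
#' @param n_classes number of *foreground* classes (the network predicts
#'   `n_classes + 1` labels including background).
#' @param base_channels channels at the first stage (doubled per stage).
#' @param depth number of resolution levels.
#' @return a `unet_config`: named integer vector
#'   `(H, W, base, depth, K)`.
#' @export
unet_config <- function(image_size = 96, n_classes = 6, base_channels = 8,
                        depth = 3) {
  f <- 2^(depth - 1)
  if (image_size %% f != 0)
    stop("image_size must be divisible by 2^(depth-1)")
  structure(c(H = as.integer(image_size), W = as.integer(image_size),
              base = as.integer(base_channels), depth = as.integer(depth),
              K = as.integer(n_classes + 1)),
            class = "unet_config")
}

# layer shapes in parameter order; mirrors the C++ layout
unet_layers <- function(cfg) {
  depth <- cfg[["depth"]]; base <- cfg[["base"]]; K <- cfg[["K"]]
  ch <- base * 2^(seq_len(depth) - 1)
  layers <- list()
  for (l in seq_len(depth))
    layers[[length(layers) + 1]] <-
      list(cin = if (l == 1) 1L else ch[l - 1], cout = ch[l], k2 = 9L)
  for (l in rev(seq_len(depth - 1)))
    layers[[length(layers) + 1]] <-
      list(cin = ch[l + 1] + ch[l], cout = ch[l], k2 = 9L)
  layers[[length(layers) + 1]] <- list(cin = ch[1], cout = K, k2 = 1L)
  layers
}

#' Build and initialize a segmentation model
#'
#' Weights use He initialization (`N(0, 2 / fan_in)`), biases start at zero;
#' initialization is deterministic given the seed.
#'
#' @param config a [unet_config()].
#' @param seed integer seed.
#' @return a `fairseg_model`: list with `config`, flat parameter vector
#'   `par`, and optimizer `step` counter.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  layers <- unet_layers(config)
  par <- with_seed(seed, {
    unlist(lapply(layers, function(l) {
      nw <- l$cout * l$k2 * l$cin
      c(rnorm(nw, 0, sqrt(2 / (l$k2 * l$cin))), rep(0, l$cout))
    }))
  })
  expected <- cpp_unet_n_params(as.integer(config))
  stopifnot(length(par) == expected)
  structure(list(config = config, par = par, step = 0L),
            class = "fairseg_model")
}

#' @export
print.fairseg_model <- function(x, ...) {
  cat(sprintf("Compact U-Net: %dx%d input, depth %d, base %d channels, %d classes, %d parameters\n",
              x$config[["H"]], x$config[["W"]], x$config[["depth"]],
              x$config[["base"]], x$config[["K"]], length(x$par)))
  invisible(x)
}

#' Flatten / restore model parameters
#'
#' The flat vector view is the unit of exchange in federated aggregation;
#' the round trip is exact.
#'
#' @param model a `fairseg_model`.
#' @return numeric parameter vector.
#' @export
model_params <- function(model) model$par

#' @rdname model_params
#' @param par replacement flat parameter vector.
#' @export
set_model_params <- function(model, par) {
  if (length(par) != length(model$par))
    stop("parameter vector has wrong length")
  model$par <- as.numeric(par)
  model
}

#' Forward pass returning per-class scores
#' @param model a `fairseg_model`.
#' @param image numeric matrix matching the configured input size.
#' @return array `H x W x K` of unnormalized class scores.
#' @export
model_forward <- function(model, image) {
  cpp_unet_forward(model$par, as.integer(model$config), image)
}

#' Predicted label mask for one image
#' @inheritParams model_forward
#' @return integer label matrix (argmax over classes, 0 = background).
#' @export
model_predict <- function(model, image) {
  cpp_unet_predict(model$par, as.integer(model$config), image)$labels
}

#' Per-sample IoU of a model over a set of samples
#'
#' Pure evaluation: an argmax forward pass per sample scored with
#' [iou_multiclass()]; no state is mutated and no gradients are involved.
#'
#' @param model a `fairseg_model` (or `fairseg` fit), or a plain function
#'   `image -> label matrix` (a pluggable predictor, e.g. a stub in tests).
#' @param data a `fairseg_data` or list of sample records.
#' @return named numeric vector of per-sample IoU.
#' @export
evaluate_model <- function(model, data) {
  if (inherits(model, "fairseg")) model <- model$model
  samples <- if (inherits(data, "fairseg_data")) data$samples else data
  if (length(samples) == 0) stop("no samples to evaluate")
  predictor <- if (is.function(model)) model
               else function(img) model_predict(model, img)
  out <- vapply(samples, function(s) {
    iou_multiclass(predictor(s$image), s$mask)
  }, numeric(1))
  names(out) <- vapply(samples, `[[`, character(1), "sample_id")
  out
}

epoch_performance <- function(iou, epoch) {
  structure(list(iou = iou, mean = mean(iou), epoch = as.integer(epoch)),
            class = "epoch_performance")
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  state$delta <- lr * mh / (sqrt(vh) + eps)
  state
}

#' One training epoch over a fixed curriculum order
#'
#' Samples are visited exactly in `order` (which may cycle ids, as the
#' balanced curriculum does to keep a full-epoch step budget), batched
#' sequentially without reshuffling; one Adam step is taken per batch.  The loss is pixelwise
#' cross-entropy, optionally modulated by a progressive term (see
#' `loss_ctx`).  After the pass, per-sample hard IoU over the order's samples
#' is recorded with gradients disabled.
#'
#' @param model a `fairseg_model`.
#' @param samples named list of sample records covering `order`.
#' @param order character vector of sample ids (the curriculum order).
#' @param opt Adam optimizer state from `adam_init()`.
#' @param lr,weight_decay,batch_size optimizer settings.
#' @param loss_ctx list describing the progressive term for this epoch:
#'   `type` ("ce", "spl", "tpl"), `mode`, `schedule` (a [loss_schedule()]),
#'   `deltas` (named, previous-epoch performance deviations; reweight mode),
#'   `ref_mean` (detached epoch-mean reference; additive mode), `active`
#'   (whether the progressive term is active this epoch).
#' @param prox optional list `(mu, ref)` adding the proximal gradient
#'   `mu * (par - ref)` each step (federated heterogeneity control).
#' @return list with updated `model`, `opt`, `perf` (an
#'   `epoch_performance`), `mean_ce`, `mean_w`.
#' @export
train_epoch <- function(model, samples, order, opt, lr = 1e-3,
                        weight_decay = 0, batch_size = 8,
                        loss_ctx = list(type = "ce"), prox = NULL,
                        epoch = 1L) {
  if (length(order) == 0) stop("empty curriculum order")
  if (!all(order %in% names(samples))) stop("order references unknown ids")
  desc <- as.integer(model$config)
  type <- loss_ctx$type %||% "ce"
  mode <- loss_ctx$mode %||% "reweight"
  active <- isTRUE(loss_ctx$active)
  n_batches <- ceiling(length(order) / batch_size)
  ces <- numeric(0)
  ws <- numeric(0)
  for (b in seq_len(n_batches)) {
    ids <- order[((b - 1) * batch_size + 1):min(b * batch_size, length(order))]
    w <- if (type != "ce")
      weight_at(loss_ctx$schedule, min(model$step, loss_ctx$schedule$total_steps))
    else 0
    ws <- c(ws, w)
    grad <- numeric(length(model$par))
    for (id in ids) {
      s <- samples[[id]]
      if (type != "ce" && active && mode == "reweight") {
        coef <- reweight_multipliers(loss_ctx$deltas[[id]], w, type)
        variant <- 0L; ref <- 0
      } else if (type != "ce" && active && mode == "additive") {
        coef <- 1
        variant <- if (type == "spl") 1L else 2L
        ref <- loss_ctx$ref_mean
      } else {
        coef <- 1; variant <- 0L; ref <- 0
      }
      r <- cpp_unet_loss_grad(model$par, desc, s$image,
                              matrix(as.integer(s$mask), nrow(s$mask)),
                              coef, variant, w, ref)
      grad <- grad + as.numeric(r$grad)
      ces <- c(ces, r$ce)
    }
    grad <- grad / length(ids)
    if (weight_decay > 0) grad <- grad + weight_decay * model$par
    if (!is.null(prox) && prox$mu > 0)
      grad <- grad + prox$mu * (model$par - prox$ref)
    opt <- adam_step(opt, grad, lr)
    model$par <- model$par - opt$delta
    model$step <- model$step + 1L
  }
  perf <- epoch_performance(evaluate_model(model, samples[unique(order)]),
                            epoch)
  list(model = model, opt = opt, perf = perf,
       mean_ce = mean(ces), mean_w = mean(ws))
}
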