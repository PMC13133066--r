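#' Fit a fairness-aware segmentation model
#'
#' The central fitting function.  Trains the compact U-Net on the training
#' split of a synthetic (or loaded) dataset under one of five sample-ordering
#' strategies and one of three loss functions, then evaluates the result on
#' the test split and summarizes subgroup fairness.
#'
#' Orderings (`curriculum`):
#' * `"base"` — fresh uniform shuffle every epoch;
#' * `"ri"` — demographic round-robin interleaving, random within group;
#' * `"scl"` — self-paced: from epoch 2, samples ordered easiest-first by
#'   the previous epoch's per-sample IoU, interleaved by group;
#' * `"tcl"` — teacher-student: ease is the negated gap between a frozen,
#'   fully trained teacher's IoU and the student's previous-epoch IoU;
#' * `"bcl"` — balanced curriculum: training starts from a demographically
#'   balanced 20% subset and grows linearly to the full set by the final
#'   epoch, admitting the easiest unseen samples first (scored by a
#'   gradient-free forward pass), the epoch set re-sorted easiest-first and
#'   interleaved.
#'
#' Losses (`loss`): `"ce"` — pixelwise cross-entropy; `"spl"` / `"tpl"` —
#' cross-entropy plus a progressive term whose weight sweeps from `+alpha`
#' to `-alpha` over the optimizer steps, shifting emphasis from easy to hard
#' samples (see [progressive_term()]).  The per-sample difficulty signal is
#' the deviation of the sample's IoU from the previous epoch's mean; epoch 1
#' trains on the plain loss.
#'
#' @param data a `fairseg_data` from [generate_dataset()] or
#'   [read_dataset()].
#' @param curriculum,loss see above.
#' @param loss_mode `"reweight"` (default; per-sample loss multipliers) or
#'   `"additive"` (literal penalty with a differentiable soft-IoU term).
#' @param alpha progressive sweep amplitude.
#' @param epochs,lr,weight_decay,batch_size optimizer settings.  Unless
#'   `allow_any_epochs` is set, `epochs` must lie in `[25, 200]`, `lr` in
#'   `[1e-4, 0.01]` and `weight_decay` in `[1e-8, 1e-3]` (0 allowed).
#' @param base_channels,depth backbone size (see [unet_config()]).
#' @param teacher a fitted `fairseg` object (or `fairseg_model`) used as the
#'   frozen teacher for `curriculum = "tcl"`.
#' @param seed master seed; model init, epoch shuffles and the balanced
#'   subset draw all derive named sub-streams from it.
#' @param init_par optional flat parameter vector to start from (used by the
#'   federated simulator to broadcast a global model).
#' @param prox_mu proximal coefficient: adds the gradient of
#'   `(prox_mu / 2) * ||par - init||^2` each step, pulling the local model
#'   toward its starting point (0 disables).
#' @param allow_any_epochs lift the epoch-range validation.
#' @param evaluate_test whether to score the test split and attach a
#'   [fairness_report()].
#' @param verbose print one line per epoch.
#' @return an object of class `fairseg` with components `model`, `history`
#'   (per-epoch data.frame), `train_perf`, `test_scores`, `report`,
#'   `config`, `call`.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`, `residuals`.
#' @examples
#' \donttest{
#' d <- generate_dataset(generation_spec(n_samples = 16, image_size = 32,
#'                                       seed = 7))
#' fit <- fairseg(d, curriculum = "bcl", epochs = 4, allow_any_epochs = TRUE,
#'                seed = 7)
#' summary(fit)
#' }
#' @export
fairseg <- function(data,
                    curriculum = c("base", "ri", "scl", "tcl", "bcl"),
                    loss = c("ce", "spl", "tpl"),
                    loss_mode = c("reweight", "additive"),
                    alpha = 1, epochs = 50, lr = 0.01, weight_decay = 1e-6,
                    batch_size = 2, base_channels = 8, depth = 3,
                    teacher = NULL, seed = 1L, init_par = NULL,
                    prox_mu = 0, allow_any_epochs = FALSE,
                    evaluate_test = TRUE, verbose = FALSE) {
  curriculum <- match.arg(curriculum)
  loss <- match.arg(loss)
  loss_mode <- match.arg(loss_mode)
  stopifnot(inherits(data, "fairseg_data"))
  if (!allow_any_epochs && (epochs < 25 || epochs > 200))
    stop("epochs must lie in [25, 200]; set allow_any_epochs = TRUE to override")
  if (lr < 1e-4 || lr > 0.01) stop("lr must lie in [1e-4, 0.01]")
  if (weight_decay != 0 && (weight_decay < 1e-8 || weight_decay > 1e-3))
    stop("weight_decay must be 0 or in [1e-8, 1e-3]")
  if (curriculum == "tcl" && is.null(teacher))
    stop("curriculum = 'tcl' requires a trained 'teacher'")

  train <- subset_data(data, split = "train")
  ids <- train$meta$sample_id
  if (length(ids) == 0) stop("dataset has no training samples")
  groups <- stats::setNames(train$meta$group, ids)
  image_size <- nrow(train$samples[[1]]$image)
  n_fg <- max(vapply(train$samples, function(s) max(s$mask), numeric(1)))
  cfg <- unet_config(image_size, n_classes = max(n_fg, 1),
                     base_channels = base_channels, depth = depth)
  model <- build_model(cfg, substream_seed(seed, "model"))
  if (!is.null(init_par)) model <- set_model_params(model, init_par)
  # proximal pull toward the starting point (the broadcast global model when
  # called from the federated simulator)
  prox <- if (prox_mu > 0) list(mu = prox_mu, ref = model$par) else NULL
  opt <- adam_init(length(model$par))

  # planned optimizer steps for the progressive weight sweep; every epoch
  # consumes a full pass worth of steps (the balanced curriculum cycles its
  # active subset up to that budget, so ordering is decoupled from the
  # optimization budget)
  total_steps <- epochs * ceiling(length(ids) / batch_size)
  schedule <- if (loss != "ce")
    loss_schedule(loss, alpha = alpha, total_steps = total_steps,
                  mode = loss_mode) else NULL

  teacher_iou <- if (curriculum == "tcl") {
    tm <- if (inherits(teacher, "fairseg")) teacher$model else teacher
    evaluate_model(tm, train$samples)
  } else NULL

  bcl <- NULL
  prev <- NULL
  latest_iou <- NULL  # most recent per-sample IoU seen for each id
  history <- vector("list", epochs)
  for (e in seq_len(epochs)) {
    eseed <- substream_seed(seed, "epoch", e)
    if (curriculum == "bcl") {
      if (e == 1) {
        bcl <- bcl_init(ids, groups, epochs, substream_seed(seed, "bcl"))
        ord <- order_interleaved(bcl$active, groups, eseed)
      } else {
        pool_ease <- if (length(bcl$pool) > 0)
          evaluate_model(model, train$samples[bcl$pool]) else numeric(0)
        latest_iou[names(pool_ease)] <- pool_ease
        bcl <- bcl_update(bcl, pool_ease, e, groups = groups)
        # veterans use previous-epoch IoU, new admissions their admission ease
        ease <- prev$iou[intersect(names(prev$iou), bcl$active)]
        fresh <- setdiff(bcl$active, names(ease))
        ease <- c(ease, latest_iou[fresh])
        ord <- order_interleaved(bcl$active, groups, eseed, ease = ease)
      }
    } else if (curriculum == "base") {
      ord <- order_shuffled(ids, eseed)
    } else if (curriculum == "ri") {
      ord <- order_interleaved(ids, groups, eseed)
    } else if (curriculum == "scl") {
      ord <- if (e == 1) order_interleaved(ids, groups, eseed)
             else order_interleaved(ids, groups, eseed,
                                    ease = score_self_paced(prev, ids))
    } else { # tcl
      ord <- if (e == 1) order_interleaved(ids, groups, eseed)
             else order_interleaved(ids, groups, eseed,
                                    ease = score_teacher_student(
                                      teacher_iou, prev$iou[names(teacher_iou)]))
    }

    loss_ctx <- if (loss == "ce" || e == 1 || is.null(prev)) {
      list(type = loss, mode = loss_mode, schedule = schedule, active = FALSE)
    } else {
      # difficulty signal: most recent IoU per sample (covers BCL admissions
      # via their admission-time score) against the previous epoch's mean
      list(type = loss, mode = loss_mode, schedule = schedule, active = TRUE,
           deltas = latest_iou[ord] - prev$mean, ref_mean = prev$mean)
    }

    # the balanced curriculum trains on its active subset only, but keeps
    # the full-epoch step budget by cycling the curriculum order
    epoch_ord <- if (curriculum == "bcl" && length(ord) < length(ids))
      rep(ord, length.out = length(ids)) else ord
    step <- train_epoch(model, train$samples, epoch_ord, opt, lr = lr,
                        weight_decay = weight_decay, batch_size = batch_size,
                        loss_ctx = loss_ctx, prox = prox, epoch = e)
    model <- step$model
    opt <- step$opt
    # performance cache over this epoch's trained samples (drives curricula
    # and the progressive-term reference mean)
    prev <- step$perf
    latest_iou[names(prev$iou)] <- prev$iou
    history[[e]] <- data.frame(epoch = e, n_active = length(unique(ord)),
                               mean_ce = step$mean_ce,
                               mean_train_iou = step$perf$mean,
                               mean_w = step$mean_w)
    if (verbose)
      message(sprintf("epoch %3d  n=%4d  ce=%.4f  train IoU=%.4f", e,
                      length(ord), step$mean_ce, step$perf$mean))
  }

  out <- structure(list(
    model = model,
    history = do.call(rbind, history),
    train_perf = prev,
    config = list(curriculum = curriculum, loss = loss,
                  loss_mode = loss_mode, alpha = alpha, epochs = epochs,
                  lr = lr, weight_decay = weight_decay,
                  batch_size = batch_size, seed = seed,
                  total_steps = total_steps),
    call = match.call()
  ), class = "fairseg")
  if (evaluate_test && any(data$meta$split == "test")) {
    test <- subset_data(data, split = "test")
    out$test_scores <- evaluate_model(model, test$samples)
    out$report <- fairness_report(out$test_scores, test$meta)
  }
  out
}

#' @export
print.fairseg <- function(x, ...) {
  cat(sprintf("fairseg fit: curriculum '%s', loss '%s', %d epochs\n",
              x$config$curriculum, x$config$loss, x$config$epochs))
  print(x$model)
  cat(sprintf("Final mean training IoU: %.4f\n",
              x$history$mean_train_iou[nrow(x$history)]))
  if (!is.null(x$report))
    cat(sprintf("Test: mean IoU %.4f, R&G mean SER %.4f, MMD %.4f\n",
                x$report$mean_iou, x$report$rg_mean_ser, x$report$mmd))
  invisible(x)
}

#' @export
summary.fairseg <- function(object, ...) {
  print(object)
  if (!is.null(object$report)) {
    cat("\n")
    print(object$report)
  }
  invisible(object)
}

#' @export
coef.fairseg <- function(object, ...) object$model$par

#' Predict segmentation masks
#' @param object a fitted `fairseg` model.
#' @param newdata a `fairseg_data`, a list of sample records, or a single
#'   image matrix.
#' @param ... unused.
#' @return a named list of integer label matrices (or a single matrix for a
#'   single image).
#' @export
predict.fairseg <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(model_predict(object$model, newdata))
  samples <- if (inherits(newdata, "fairseg_data")) newdata$samples
             else newdata
  out <- lapply(samples, function(s) model_predict(object$model, s$image))
  names(out) <- vapply(samples, `[[`, character(1), "sample_id")
  out
}

#' @export
residuals.fairseg <- function(object, ...) {
  if (is.null(object$test_scores))
    return(1 - object$train_perf$iou)
  1 - object$test_scores
}

#' @export
plot.fairseg <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$mean_ce, type = "l", xlab = "epoch",
                 ylab = "mean cross-entropy", main = "Training loss", ...)
  graphics::plot(h$epoch, h$mean_train_iou, type = "l", xlab = "epoch",
                 ylab = "mean train IoU", main = "Training IoU", ...)
  invisible(x)
}

#' Train four demographically tailored models
#'
#' One model per race-gender group, each trained only on that group's
#' training samples; prediction routes every sample to its group's model.
#' Evaluation pools the routed test predictions.
#'
#' @inheritParams fairseg
#' @param ... further arguments passed to [fairseg()].
#' @return an object of class `fairseg_ds`: list of per-group fits plus a
#'   pooled test report.
#' @export
fairseg_ds <- function(data, seed = 1L, ...) {
  fits <- list()
  scores <- numeric(0)
  for (g in intersect(group_levels(), unique(data$meta$group))) {
    sub <- data
    keep <- data$meta$group == g
    sub$samples <- data$samples[keep]
    sub$meta <- data$meta[keep, , drop = FALSE]
    fits[[g]] <- fairseg(sub, curriculum = "base",
                         seed = substream_seed(seed, "ds", g), ...)
    if (!is.null(fits[[g]]$test_scores))
      scores <- c(scores, fits[[g]]$test_scores)
  }
  test_meta <- data$meta[data$meta$split == "test", , drop = FALSE]
  report <- if (length(scores) > 0)
    fairness_report(scores[test_meta$sample_id], test_meta) else NULL
  structure(list(fits = fits, test_scores = scores, report = report),
            class = "fairseg_ds")
}

#' @export
print.fairseg_ds <- function(x, ...) {
  cat(sprintf("Demographically tailored models (%d groups)\n",
              length(x$fits)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
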