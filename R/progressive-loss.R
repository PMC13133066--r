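#' Progressive loss schedule
#'
#' Holds the configuration of the progressive loss term: the variant
#' (`"spl"`, selective — the per-sample over-performance terms are summed and
#' then weighted; or `"tpl"`, tiered — each term is weighted before the
#' rectification, so that negative weights flip emphasis onto
#' under-performers), the gradient mode, and the sweep amplitude `alpha`.
#' The weight `w` interpolates linearly from `+alpha` at the first optimizer
#' step to `-alpha` at the last, shifting emphasis from easy to hard samples
#' over the course of training.
#'
#' @param variant `"spl"` or `"tpl"`.
#' @param alpha positive sweep amplitude (the weight runs `+alpha` to
#'   `-alpha`).
#' @param total_steps total number of optimizer steps in the run.
#' @param mode `"reweight"` (per-sample loss multipliers, difficulty signal
#'   detached) or `"additive"` (the literal penalty term, differentiable
#'   through a soft IoU surrogate).
#' @return a `loss_schedule` object.
#' @export
loss_schedule <- function(variant = c("spl", "tpl"), alpha = 1,
                          total_steps = 1L,
                          mode = c("reweight", "additive")) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  if (alpha <= 0) stop("alpha must be positive")
  if (total_steps < 1) stop("total_steps must be >= 1")
  structure(list(variant = variant, alpha = alpha,
                 total_steps = as.integer(total_steps), mode = mode),
            class = "loss_schedule")
}

#' Progressive weight at a given optimizer step
#'
#' Linear interpolation: `w = alpha - 2 * alpha * step / total_steps`, so
#' `w(0) = +alpha`, `w(total_steps) = -alpha`, and the midpoint gives 0.
#'
#' @param schedule a [loss_schedule()].
#' @param step optimizer step in `[0, total_steps]`.
#' @return the weight `w`.
#' @export
weight_at <- function(schedule, step) {
  stopifnot(inherits(schedule, "loss_schedule"))
  if (step < 0 || step > schedule$total_steps)
    stop("step out of range [0, total_steps]")
  schedule$alpha - 2 * schedule$alpha * step / schedule$total_steps
}

#' Differentiable soft IoU
#'
#' Probabilistic relaxation of the hard IoU used so the progressive penalty
#' can carry gradient: per foreground class,
#' `softIoU = sum(p * y) / sum(p + y - p * y)`, macro-averaged over classes
#' with positive soft union.  Equals the hard multi-class IoU when the
#' probabilities are one-hot.
#'
#' @param pred_probs array `H x W x K` of per-class probabilities (classes
#'   summing to 1 per pixel; class 1 is background).
#' @param truth integer label matrix (`0` = background).
#' @return score in `[0, 1]`.
#' @export
soft_iou <- function(pred_probs, truth) {
  d <- dim(pred_probs)
  if (length(d) != 3 || d[1] != nrow(truth) || d[2] != ncol(truth))
    stop("shape mismatch between probabilities and mask")
  sums <- apply(pred_probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) stop("class probabilities must sum to 1")
  K <- d[3]
  vals <- c()
  for (k in 2:K) {           # foreground classes; slice k is class k-1
    p <- pred_probs[, , k]
    y <- (truth == (k - 1)) * 1
    inter <- sum(p * y)
    union <- sum(p + y - p * y)
    if (union > 0) vals <- c(vals, inter / union)
  }
  if (length(vals) == 0) return(1.0)
  mean(vals)
}

#' Progressive loss term at batch scale
#'
#' Combines per-sample standard losses with the per-sample performance
#' deviations `dP_i = IoU_i - IoU_epoch_mean` under the current progressive
#' weight.  In `additive` mode the batch loss is
#' `mean(losses) + penalty / batch_size` with
#' `penalty = w * sum(max(dP, 0))` (selective) or
#' `penalty = sum(max(w * dP, 0))` (tiered) — the population-level sum
#' estimated on the batch and normalized by batch size so the term is
#' invariant to batching.  In `reweight` mode each sample's loss is scaled by
#' `1 + w * max(dP, 0)` (selective) or `1 + max(w * dP, 0)` (tiered),
#' floored at 0, and the mean is returned.
#'
#' @param batch_losses numeric vector of per-sample standard losses.
#' @param deltas numeric vector of per-sample performance deviations, aligned
#'   with `batch_losses`.
#' @param w current progressive weight.
#' @param variant `"spl"` or `"tpl"`.
#' @param mode `"additive"` or `"reweight"`.
#' @return the scalar batch loss.
#' @export
progressive_term <- function(batch_losses, deltas, w,
                             variant = c("spl", "tpl"),
                             mode = c("reweight", "additive")) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  if (length(batch_losses) != length(deltas))
    stop("batch losses and deltas are misaligned")
  b <- length(batch_losses)
  if (mode == "additive") {
    pen <- if (variant == "spl") w * sum(pmax(deltas, 0))
           else sum(pmax(w * deltas, 0))
    mean(batch_losses) + pen / b
  } else {
    mult <- if (variant == "spl") 1 + w * pmax(deltas, 0)
            else 1 + pmax(w * deltas, 0)
    mean(batch_losses * pmax(mult, 0))
  }
}

# per-sample loss multipliers for reweight mode (shared with the trainer)
reweight_multipliers <- function(deltas, w, variant) {
  mult <- if (variant == "spl") 1 + w * pmax(deltas, 0)
          else 1 + pmax(w * deltas, 0)
  pmax(mult, 0)
}
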