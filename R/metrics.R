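#' Multi-class intersection over union
#'
#' For every non-background class present in the reference mask (and, for
#' classes absent there, present in the prediction), the binary IoU
#' (pixel intersection over pixel union) is computed and the unweighted mean
#' over those classes is returned.  A class with empty union is skipped.  If
#' neither mask contains any foreground the score is 1 by convention (the
#' prediction of "nothing" is exactly right).
#'
#' @param pred,truth integer label matrices of equal shape; 0 is background.
#' @return a score in `[0, 1]`.
#' @examples
#' iou_multiclass(matrix(c(1, 1, 0, 2), 2), matrix(c(1, 0, 0, 2), 2))  # 0.75
#' @export
iou_multiclass <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch between masks")
  classes <- sort(unique(c(truth[truth > 0], pred[pred > 0])))
  if (length(classes) == 0) return(1.0)
  per <- vapply(classes, function(k) {
    p <- pred == k
    t <- truth == k
    u <- sum(p | t)
    if (u == 0) return(NA_real_)
    sum(p & t) / u
  }, numeric(1))
  per <- per[!is.na(per)]
  if (length(per) == 0) return(1.0)
  mean(per)
}

#' Per-group mean scores
#'
#' @param scores named numeric vector of per-sample scores.
#' @param meta data.frame with `sample_id` and grouping columns.
#' @param by grouping attribute: `"group"` (race-gender), `"race"` or
#'   `"gender"`.
#' @return named numeric vector of arithmetic group means; empty groups are
#'   omitted.
#' @export
group_mean_ious <- function(scores, meta, by = "group") {
  idx <- match(names(scores), meta$sample_id)
  if (anyNA(idx)) stop("scored sample without metadata: ",
                       paste(names(scores)[is.na(idx)][1]))
  key <- meta[[by]][idx]
  means <- tapply(scores, key, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}

#' Skewed error ratio
#'
#' Ratio of the maximum to the minimum group error rate (`1 - IoU`) across
#' protected groups; 1 means no skew, larger values mean one group's errors
#' dominate another's.  The denominator is clamped at `eps` so a group that
#' reaches IoU 1 does not divide by zero.  A single group yields 1.
#'
#' @param group_means named numeric vector of group mean IoU.
#' @param eps denominator clamp.
#' @return SER value `>= 1` (up to the clamp).
#' @export
ser <- function(group_means, eps = 1e-6) {
  if (length(group_means) == 0) stop("empty group means")
  if (length(group_means) == 1) return(1.0)
  err <- 1 - group_means
  max(err) / max(min(err), eps)
}

#' Min-max disparity
#'
#' Difference between the best and worst group mean IoU; 0 means parity.
#'
#' @inheritParams ser
#' @return MMD value `>= 0`.
#' @export
mmd <- function(group_means) {
  if (length(group_means) == 0) stop("empty group means")
  max(group_means) - min(group_means)
}

#' Two-tailed paired t-test on per-sample scores
#'
#' Implements the textbook closed form: `t = mean(d) / (sd(d) / sqrt(n))`
#' with the sample SD (n-1 denominator) and a two-tailed p-value from the t
#' distribution with `n - 1` degrees of freedom.  Vectors are aligned by
#' name when both are named.  If the paired differences have zero variance
#' the convention is `p = 1` when the mean difference is 0 (identical
#' performance) and `p = 0` otherwise (a constant, hence unambiguous, shift).
#'
#' @param a,b numeric score vectors of equal length (n >= 2).
#' @return list with `t`, `df`, `p`, `mean_diff`, and `significant`
#'   (`p < 0.05`).
#' @export
paired_iou_test <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors differ in length")
  if (length(a) < 2) stop("need at least 2 paired scores")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("score names do not match")
    b <- b[names(a)]
  }
  d <- a - b
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    t_stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1.0 else 0.0
  } else {
    t_stat <- mean(d) / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  list(t = t_stat, df = n - 1L, p = p, mean_diff = mean(d),
       significant = p < 0.05)
}

#' Subgroup fairness report
#'
#' Summarizes per-sample IoU scores the way the package's experiment tables
#' report them: overall mean IoU; the population SD over the four race-gender
#' group mean IoUs ("IoU SD"); the race-wise and gender-wise skewed error
#' ratios and their arithmetic mean ("R&G mean SER"); and the min-max
#' disparity over the race-gender group means ("MMD").
#'
#' @param scores named numeric vector of per-sample IoU.
#' @param meta metadata data.frame covering every scored sample.
#' @return an object of class `fairness_report`.
#' @export
fairness_report <- function(scores, meta) {
  if (length(scores) == 0) stop("no scores to report on")
  gm <- group_mean_ious(scores, meta, by = "group")
  if (length(gm) < 2) {
    warning("fewer than 2 race-gender groups present; SER defaults to 1")
    ser_race <- ser_gender <- 1.0
  } else {
    ser_race <- ser(group_mean_ious(scores, meta, by = "race"))
    ser_gender <- ser(group_mean_ious(scores, meta, by = "gender"))
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(
    mean_iou = mean(scores),
    iou_sd = pop_sd(gm),
    group_means = gm,
    ser_race = ser_race,
    ser_gender = ser_gender,
    rg_mean_ser = (ser_race + ser_gender) / 2,
    mmd = mmd(gm),
    n = length(scores)
  ), class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, digits = 4, ...) {
  cat(sprintf("Fairness report over %d samples\n", x$n))
  cat(sprintf("  Mean IoU:      %.*f\n", digits, x$mean_iou))
  cat(sprintf("  IoU SD:        %.*f   (over group means)\n", digits, x$iou_sd))
  cat(sprintf("  R&G mean SER:  %.*f   (race %.4f, gender %.4f)\n",
              digits, x$rg_mean_ser, x$ser_race, x$ser_gender))
  cat(sprintf("  MMD:           %.*f\n", digits, x$mmd))
  cat("  Group means:\n")
  for (g in names(x$group_means))
    cat(sprintf("    %-14s %.*f\n", g, digits, x$group_means[[g]]))
  invisible(x)
}

#' @export
as.data.frame.fairness_report <- function(x, row.names = NULL, optional = FALSE,
                                          label = NA_character_, ...) {
  data.frame(model = label, mean_iou = x$mean_iou, iou_sd = x$iou_sd,
             rg_mean_ser = x$rg_mean_ser, mmd = x$mmd,
             stringsAsFactors = FALSE)
}

#' Serialize a fairness report to JSON
#' @param x a `fairness_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
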