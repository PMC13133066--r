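#' Uniformly shuffled training order
#'
#' The plain baseline ordering: a fresh uniform permutation of the training
#' ids before every epoch.
#'
#' @param ids character vector of sample ids.
#' @param seed integer seed.
#' @return character vector: a permutation of `ids`.
#' @export
order_shuffled <- function(ids, seed) {
  if (length(ids) == 0) stop("empty id set")
  with_seed(seed, sample(ids))
}

#' Demographically interleaved training order
#'
#' Round-robin over the race-gender groups in a fixed canonical order,
#' skipping groups as they exhaust, so that (until any group runs out) every
#' window of four consecutive positions contains all four groups.  Within
#' each group the next sample is drawn uniformly at random when no ease
#' scores are supplied, or in descending ease (easiest first, ties broken by
#' sample id) when they are.
#'
#' @param ids sample ids to order.
#' @param groups named character vector mapping id to race-gender group.
#' @param seed integer seed (used only for the random within-group order).
#' @param ease optional named numeric vector of ease scores (higher =
#'   easier).
#' @return character vector: a permutation of `ids`.
#' @export
order_interleaved <- function(ids, groups, seed, ease = NULL) {
  if (length(ids) == 0) stop("empty id set")
  g <- groups[ids]
  if (anyNA(g)) stop("sample id without group: ",
                     ids[is.na(g)][1])
  streams <- lapply(intersect(group_levels(), unique(g)), function(lev) {
    members <- ids[g == lev]
    if (is.null(ease)) {
      with_seed(substream_seed(seed, "interleave", lev), sample(members))
    } else {
      e <- ease[members]
      if (anyNA(e)) stop("missing ease score for some ids in group ", lev)
      members[order(-e, members)]
    }
  })
  out <- character(length(ids))
  pos <- rep(1L, length(streams))
  k <- 0L
  while (k < length(ids)) {
    for (s in seq_along(streams)) {
      if (pos[s] <= length(streams[[s]])) {
        k <- k + 1L
        out[k] <- streams[[s]][pos[s]]
        pos[s] <- pos[s] + 1L
      }
    }
  }
  out
}

#' Self-paced ease scores
#'
#' The self-paced curriculum uses the model's own per-sample IoU from the
#' immediately preceding epoch as the ease signal: samples the model already
#' segments well are deemed easy and scheduled first.
#'
#' @param prev an `epoch_performance` (or named numeric vector of per-sample
#'   IoU) covering all training ids.
#' @param ids training ids that must be covered.
#' @return named numeric vector of ease scores.
#' @export
score_self_paced <- function(prev, ids = names(prev)) {
  scores <- if (inherits(prev, "epoch_performance")) prev$iou else prev
  missing <- setdiff(ids, names(scores))
  if (length(missing) > 0)
    stop("previous epoch performance missing ids: ", missing[1])
  scores[ids]
}

#' Teacher-student ease scores
#'
#' Ease is the negated performance gap between a fully trained teacher and
#' the current student: a small (or negative) gap means the student is close
#' to the best attainable accuracy on that sample, so the sample is easy.
#' The gap is recomputed after every epoch, so difficulty tracks the evolving
#' student rather than a fixed benchmark.
#'
#' @param teacher,student named numeric vectors of per-sample IoU over the
#'   same ids.
#' @return named numeric vector of ease scores (`-(teacher - student)`).
#' @export
score_teacher_student <- function(teacher, student) {
  if (!setequal(names(teacher), names(student)))
    stop("teacher and student scores cover different ids")
  student <- student[names(teacher)]
  -(teacher - student)
}

#' Initialize the balanced growing-subset curriculum
#'
#' The balanced curriculum starts from a demographically balanced random
#' subset holding `start_frac` of the training data (equal per-group quotas,
#' largest-remainder rounding, ties broken by canonical group order) and
#' grows linearly to the full set by the final epoch.
#'
#' @param ids full training id set.
#' @param groups named group map over `ids`.
#' @param total_epochs number of training epochs `E`.
#' @param seed integer seed for the initial balanced draw.
#' @param start_frac initial fraction of the data (default 0.2).
#' @return a `bcl_state` list: `active`, `pool`, `epoch`, `total_epochs`,
#'   `start_frac`, `n`.
#' @export
bcl_init <- function(ids, groups, total_epochs, seed, start_frac = 0.2) {
  if (length(ids) == 0) stop("empty id set")
  n <- length(ids)
  if (total_epochs <= 1) {
    return(structure(list(active = ids, pool = character(0), epoch = 1L,
                          total_epochs = as.integer(total_epochs),
                          start_frac = start_frac, n = n),
                     class = "bcl_state"))
  }
  g <- groups[ids]
  levs <- intersect(group_levels(), unique(g))
  target <- ceiling(n * start_frac)
  quota <- largest_remainder(target, rep(1 / length(levs), length(levs)))
  active <- character(0)
  for (i in seq_along(levs)) {
    members <- ids[g == levs[i]]
    k <- min(quota[i], length(members))
    picked <- with_seed(substream_seed(seed, "bcl", levs[i]),
                        sample(members, k))
    active <- c(active, picked)
  }
  structure(list(active = active, pool = setdiff(ids, active), epoch = 1L,
                 total_epochs = as.integer(total_epochs),
                 start_frac = start_frac, n = n),
            class = "bcl_state")
}

#' Advance the balanced curriculum to the next epoch
#'
#' The target active-set size at epoch `e` of `E` is
#' `ceiling(N * (f + (1 - f) * (e - 1) / (E - 1)))` with `f` the starting
#' fraction, i.e. linear growth that reaches the full set exactly at the
#' final epoch.  Admission stays demographically balanced, mirroring the
#' balanced start: the new slots are shared equally among the groups that
#' still hold pool samples (largest-remainder rounding, canonical group
#' order), each group's quota is filled easiest-first (ties by sample id),
#' and any shortfall from exhausted groups is refilled globally
#' easiest-first.  Without `groups`, admission is globally easiest-first.
#'
#' @param state a `bcl_state`.
#' @param pool_ease named numeric vector of ease scores covering the pool
#'   (the model's IoU on the unseen samples, from a gradient-free forward
#'   pass).
#' @param epoch epoch index to advance to (`state$epoch + 1`).
#' @param groups optional named group map over the ids.
#' @return the updated `bcl_state`.
#' @export
bcl_update <- function(state, pool_ease, epoch, groups = NULL) {
  stopifnot(inherits(state, "bcl_state"))
  if (epoch > state$total_epochs) stop("epoch exceeds total_epochs")
  E <- state$total_epochs
  f <- state$start_frac
  target <- if (E <= 1) state$n else
    ceiling(state$n * (f + (1 - f) * (epoch - 1) / (E - 1)) - 1e-9)
  target <- min(target, state$n)
  need <- target - length(state$active)
  if (need > 0) {
    pool <- state$pool
    if (need >= length(pool)) {
      admitted <- pool
    } else {
      e <- pool_ease[pool]
      if (anyNA(e)) stop("pool_ease must cover the whole pool")
      easiest_first <- function(ids) ids[order(-e[ids], ids)]
      if (is.null(groups)) {
        admitted <- easiest_first(pool)[seq_len(need)]
      } else {
        g <- groups[pool]
        levs <- intersect(group_levels(), unique(g))
        quota <- largest_remainder(need, rep(1 / length(levs), length(levs)))
        admitted <- character(0)
        for (i in seq_along(levs)) {
          members <- easiest_first(pool[g == levs[i]])
          admitted <- c(admitted, members[seq_len(min(quota[i],
                                                      length(members)))])
        }
        short <- need - length(admitted)
        if (short > 0) {
          rest <- easiest_first(setdiff(pool, admitted))
          admitted <- c(admitted, rest[seq_len(short)])
        }
      }
    }
    state$active <- c(state$active, admitted)
    state$pool <- setdiff(state$pool, admitted)
  }
  state$epoch <- as.integer(epoch)
  state
}

#' Expected balanced-curriculum active-set sizes
#' @param n training-set size.
#' @param total_epochs number of epochs.
#' @param start_frac starting fraction.
#' @return integer vector of length `total_epochs`.
#' @export
bcl_schedule <- function(n, total_epochs, start_frac = 0.2) {
  if (total_epochs <= 1) return(as.integer(n))
  e <- seq_len(total_epochs)
  pmin(as.integer(ceiling(n * (start_frac + (1 - start_frac) *
                                 (e - 1) / (total_epochs - 1)) - 1e-9)), n)
}
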