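#' @useDynLib fairseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile pt sd
#' @importFrom utils read.csv write.csv
NULL

# Canonical protected-group machinery. The four race-gender subgroups are the
# finest partition reported; a fixed ordering keeps interleaving and quota
# tie-breaks deterministic.
RACES   <- c("White", "Black")
GENDERS <- c("Male", "Female")
SITES   <- c("A", "B", "C", "D", "E")

group_levels <- function() {
  as.vector(outer(RACES, GENDERS, function(r, g) paste(r, g, sep = "-")))
}

group_key <- function(race, gender) paste(race, gender, sep = "-")

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed through named
#' sub-streams so that components (generation, splitting, site assignment,
#' per-round client training, ...) can be re-seeded independently without
#' interfering with each other.
#'
#' @param seed master integer seed.
#' @param ... character or integer labels naming the sub-stream.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, ...) {
  labels <- unlist(list(...), use.names = FALSE)
  h <- as.double(seed) %% 2147483647
  for (lab in labels) {
    codes <- if (is.character(lab)) utf8ToInt(lab) else as.integer(lab)
    for (v in codes) h <- (h * 69069 + as.double(v) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the previous RNG state, so seeded
#' helpers do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# largest-remainder apportionment of n into shares proportional to `frac`;
# ties broken by position order.
largest_remainder <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  left <- round(n - sum(base))
  if (left > 0) {
    rem <- raw - base
    ord <- order(-rem, seq_along(frac))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
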