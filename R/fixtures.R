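#' Bundled multi-site demographic tables
#'
#' Returns the per-site demographic composition of the two radiograph cohorts
#' whose acquisition-site structure the package's simulations replicate: 761
#' hip patients and 707 knee patients spread over five clinical sites (A-E),
#' with strongly non-IID race-gender mixes (site A is dominated by Black
#' female patients, sites B and C by White patients).  Each row gives the
#' number of patients of one race-gender subgroup contributed by one site.
#'
#' @param dataset `"hip"` or `"knee"`.
#' @return A `demographic_table`: a data.frame with columns
#'   `race`, `gender`, `site`, `count` and attributes `dataset` and `total`.
#' @examples
#' tab <- demographic_table("hip")
#' sum(tab$count)                      # 761 patients
#' xtabs(count ~ gender, tab)          # 324 male / 437 female
#' @export
demographic_table <- function(dataset = c("hip", "knee")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0(dataset, "_sites.csv"),
                      package = "fairseg", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_demographic_table(tab)
  structure(tab, class = c("demographic_table", "data.frame"),
            dataset = dataset, total = sum(tab$count))
}

validate_demographic_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("race", "gender", "site", "count") %in% names(tab)))
  if (any(tab$count < 0)) stop("demographic counts must be non-negative")
  if (!all(tab$race %in% RACES)) stop("unknown race level in table")
  if (!all(tab$gender %in% GENDERS)) stop("unknown gender level in table")
  if (anyDuplicated(tab[c("race", "gender", "site")]))
    stop("duplicate race-gender-site cell in table")
  invisible(tab)
}

#' Marginal counts of a demographic table
#'
#' @param tab a `demographic_table` (or any data.frame with the same columns).
#' @param by one of `"race"`, `"gender"`, `"group"`, `"site"`.
#' @return named integer vector of counts.
#' @export
table_marginals <- function(tab, by = c("race", "gender", "group", "site")) {
  by <- match.arg(by)
  key <- switch(by,
                race = tab$race,
                gender = tab$gender,
                site = tab$site,
                group = group_key(tab$race, tab$gender))
  out <- tapply(tab$count, key, sum)
  stats::setNames(as.vector(out), names(out))
}

#' @export
print.demographic_table <- function(x, ...) {
  cat(sprintf("Demographic table '%s': %d patients, %d sites\n",
              attr(x, "dataset"), attr(x, "total"),
              length(unique(x$site))))
  wide <- xtabs(count ~ paste(x$race, x$gender, sep = "-") + site, data = x)
  names(dimnames(wide)) <- c("group", "site")
  print(wide)
  invisible(x)
}
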