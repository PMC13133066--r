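#' Specification for a synthetic segmentation dataset
#'
#' The generator emulates a radiograph-like segmentation task: each image
#' contains `n_classes` foreground structures drawn as three left/right pairs
#' of soft-edged ellipses (mirroring paired anatomy such as left/right femur
#' and acetabulum), over a darker background.  Difficulty has two axes:
#'
#' * a *group-level* appearance shift — per race-gender group noise level,
#'   contrast and blur — which induces a controllable performance disparity
#'   between demographic subgroups, and
#' * a *per-sample* jitter on the noise amplitude, which gives curricula a
#'   within-group difficulty signal.
#'
#' The default appearance parameters are chosen so that a plainly trained
#' baseline model shows a clear subgroup disparity (skewed error ratio well
#' above 1) while the task remains learnable on a desktop CPU.
#'
#' @param dataset `"custom"` (counts from `n_samples`, balanced across the
#'   four race-gender groups) or `"hip"`/`"knee"` (counts and site assignment
#'   replicate the bundled multi-site demographic tables exactly).
#' @param n_samples total sample count (custom mode only).
#' @param image_size side length in pixels (square images).
#' @param n_classes number of foreground classes; must be even (left/right
#'   pairs), at most 6.
#' @param noise_sd,contrast,blur named numeric vectors over the four groups
#'   (`"White-Male"`, `"White-Female"`, `"Black-Male"`, `"Black-Female"`):
#'   additive Gaussian pixel noise SD, multiplicative contrast, and box-blur
#'   radius in pixels (0 = none).
#' @param jitter half-width of the uniform per-sample multiplier on the noise
#'   SD (multiplier drawn from `[1 - jitter, 1 + jitter]`).
#' @param fractions train/validation/test fractions (must sum to 1).
#' @param sites sites to cycle through in custom mode.
#' @param seed master seed; all sub-streams derive from it.
#' @return an object of class `generation_spec`.
#' @export
generation_spec <- function(dataset = "custom", n_samples = 200,
                            image_size = 96, n_classes = 6,
                            noise_sd = c("White-Male" = 0.04,
                                         "White-Female" = 0.06,
                                         "Black-Male" = 0.12,
                                         "Black-Female" = 0.16),
                            contrast = c("White-Male" = 1.00,
                                         "White-Female" = 1.00,
                                         "Black-Male" = 0.90,
                                         "Black-Female" = 0.85),
                            blur = c("White-Male" = 0,
                                     "White-Female" = 0,
                                     "Black-Male" = 0,
                                     "Black-Female" = 0),
                            jitter = 0.25,
                            fractions = c(train = 0.7, val = 0.1, test = 0.2),
                            sites = "A", seed = 1L) {
  dataset <- match.arg(dataset, c("custom", "hip", "knee"))
  gl <- group_levels()
  fill_groups <- function(v, what) {
    if (is.null(names(v)) && length(v) == 1) v <- stats::setNames(rep(v, 4), gl)
    if (!all(gl %in% names(v)))
      stop("'", what, "' must be named over all four race-gender groups")
    v[gl]
  }
  noise_sd <- fill_groups(noise_sd, "noise_sd")
  contrast <- fill_groups(contrast, "contrast")
  blur <- fill_groups(blur, "blur")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (any(contrast <= 0)) stop("contrast must be > 0")
  if (n_classes < 2 || n_classes %% 2 != 0 || n_classes > 6)
    stop("n_classes must be 2, 4 or 6 (left/right pairs)")
  if (image_size < 16) stop("image_size too small to place structures (min 16)")
  if (any(fractions < 0) || any(fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(list(dataset = dataset, n_samples = as.integer(n_samples),
                 image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 noise_sd = noise_sd, contrast = contrast, blur = blur,
                 jitter = jitter, fractions = fractions, sites = sites,
                 seed = as.integer(seed)),
            class = "generation_spec")
}

# Noiseless rendering of the paired-structure phantom for one sample seed.
# Returns list(image0, mask): intensities before contrast/noise, and labels.
render_structures <- function(spec, sample_seed) {
  S <- spec$image_size
  C <- spec$n_classes
  with_seed(sample_seed, {
    # background: dark tissue with a mild lateral exposure gradient (also a
    # positional cue, so left/right structures of a pair are separable)
    img <- matrix(rep(0.06 + 0.08 * (seq_len(S) - 1) / (S - 1), each = S),
                  S, S)
    mask <- matrix(0L, S, S)
    xs <- matrix(rep(seq_len(S), S), S, S)          # row coordinate
    ys <- matrix(rep(seq_len(S), each = S), S, S)   # col coordinate
    n_pairs <- C / 2
    row_centers <- S * (seq_len(n_pairs) + 0.5) / (n_pairs + 1)
    for (p in seq_len(n_pairs)) {
      for (side in 1:2) {                            # 1 = left, 2 = right
        cls <- 2L * (p - 1L) + side
        # distinct radiodensity per structure class
        base_int <- 0.35 + 0.09 * (cls - 1)
        cx <- row_centers[p] + runif(1, -0.04, 0.04) * S
        cy <- S * (if (side == 1) 0.28 else 0.72) + runif(1, -0.04, 0.04) * S
        rx <- S * runif(1, 0.10, 0.16)
        ry <- S * runif(1, 0.09, 0.13)
        inten <- base_int + runif(1, -0.03, 0.03)
        inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
        img[inside] <- inten
        mask[inside] <- cls
      }
    }
    list(image0 = img, mask = mask)
  })
}

box_blur <- function(img, radius) {
  if (radius <= 0) return(img)
  k <- 2L * as.integer(radius) + 1L
  pad <- as.integer(radius)
  n <- nrow(img); m <- ncol(img)
  # separable box filter with edge replication
  ext <- img[c(rep(1, pad), seq_len(n), rep(n, pad)), , drop = FALSE]
  h <- apply(ext, 2, function(col) as.numeric(stats::filter(col, rep(1 / k, k))))
  h <- h[pad + seq_len(n), , drop = FALSE]
  ext2 <- h[, c(rep(1, pad), seq_len(m), rep(m, pad)), drop = FALSE]
  v <- t(apply(ext2, 1, function(row) as.numeric(stats::filter(row, rep(1 / k, k)))))
  v[, pad + seq_len(m), drop = FALSE]
}

#' Render one synthetic sample
#'
#' Deterministic given `(spec, race, gender, sample_seed)`.  The image equals
#' the noiseless structure rendering scaled by the group contrast, optionally
#' blurred, plus Gaussian pixel noise with SD `noise_sd[group] * jitter`,
#' clipped to `[0, 1]`.
#'
#' @param spec a [generation_spec()].
#' @param race,gender the sample's protected-group attributes.
#' @param sample_seed integer seed for this sample's sub-stream.
#' @return a list with `image` (matrix in \[0,1\]), `mask` (integer matrix,
#'   0 = background), `race`, `gender`, `group`.
#' @export
render_sample <- function(spec, race, gender, sample_seed) {
  stopifnot(inherits(spec, "generation_spec"))
  race <- match.arg(race, RACES)
  gender <- match.arg(gender, GENDERS)
  g <- group_key(race, gender)
  base <- render_structures(spec, sample_seed)
  img <- base$image0 * spec$contrast[[g]]
  if (spec$blur[[g]] > 0) img <- box_blur(img, spec$blur[[g]])
  with_seed(substream_seed(sample_seed, "noise"), {
    mult <- runif(1, 1 - spec$jitter, 1 + spec$jitter)
    if (spec$noise_sd[[g]] > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd[[g]] * mult),
                          nrow(img), ncol(img))
    }
  })
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = base$mask, race = race, gender = gender, group = g)
}

#' Generate a synthetic segmentation dataset
#'
#' In custom mode the four race-gender groups receive equal quotas
#' (largest-remainder rounding) and sites are cycled round-robin within each
#' group.  In fixture mode (`dataset = "hip"` or `"knee"`) the per-group,
#' per-site counts replicate the bundled demographic tables exactly.  Splits
#' are assigned by [stratified_split()] so that each group's train/val/test
#' proportions match the requested fractions to within one sample.
#'
#' @param spec a [generation_spec()].
#' @return a `fairseg_data` object: list of sample records plus a metadata
#'   data.frame (`sample_id, race, gender, group, site, split`).
#' @examples
#' d <- generate_dataset(generation_spec(n_samples = 8, image_size = 32))
#' table(d$meta$group)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generation_spec"))
  gl <- group_levels()
  if (spec$dataset == "custom") {
    quota <- largest_remainder(spec$n_samples, rep(1 / 4, 4))
    plan <- do.call(rbind, lapply(seq_along(gl), function(i) {
      if (quota[i] == 0) return(NULL)
      rg <- strsplit(gl[i], "-")[[1]]
      data.frame(race = rg[1], gender = rg[2],
                 site = spec$sites[(seq_len(quota[i]) - 1) %%
                                     length(spec$sites) + 1],
                 stringsAsFactors = FALSE)
    }))
  } else {
    tab <- demographic_table(spec$dataset)
    plan <- tab[rep(seq_len(nrow(tab)), tab$count),
                c("race", "gender", "site")]
  }
  n <- nrow(plan)
  if (n < 1) stop("requested counts infeasible: no samples to generate")
  ids <- sprintf("%s_%05d", spec$dataset, seq_len(n))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    s <- render_sample(spec, plan$race[i], plan$gender[i],
                       substream_seed(spec$seed, "generation", i))
    s$sample_id <- ids[i]
    s$site <- plan$site[i]
    samples[[i]] <- s
  }
  meta <- data.frame(sample_id = ids, race = plan$race, gender = plan$gender,
                     group = group_key(plan$race, plan$gender),
                     site = plan$site, stringsAsFactors = FALSE)
  meta$split <- stratified_split(meta, spec$fractions,
                                 substream_seed(spec$seed, "split"))
  for (i in seq_len(n)) samples[[i]]$split <- meta$split[i]
  names(samples) <- ids
  structure(list(samples = samples, meta = meta, spec = spec),
            class = "fairseg_data")
}

#' @export
print.fairseg_data <- function(x, ...) {
  cat(sprintf("fairseg_data: %d samples, %dx%d px, %d foreground classes\n",
              nrow(x$meta), x$spec$image_size, x$spec$image_size,
              x$spec$n_classes))
  print(table(group = x$meta$group, split = x$meta$split))
  invisible(x)
}

#' Demographically stratified split assignment
#'
#' Within every race-gender group the requested fractions are apportioned by
#' largest-remainder rounding (so per-group proportions deviate from the
#' target by less than one sample) and samples are assigned by a seeded
#' shuffle.  Groups with zero samples are skipped.
#'
#' @param meta data.frame with columns `sample_id` and `group`.
#' @param fractions named numeric vector of split fractions summing to 1;
#'   names become the split labels.
#' @param seed integer seed.
#' @return character vector of split labels aligned with `meta` rows.
#' @export
stratified_split <- function(meta, fractions = c(train = 0.7, val = 0.1,
                                                 test = 0.2), seed = 1L) {
  if (any(fractions < 0) || any(fractions > 1))
    stop("fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  labs <- names(fractions) %||% paste0("s", seq_along(fractions))
  out <- character(nrow(meta))
  for (g in sort(unique(meta$group))) {
    idx <- which(meta$group == g)
    if (length(idx) == 0) next
    sizes <- largest_remainder(length(idx), fractions)
    perm <- with_seed(substream_seed(seed, "split", g), sample(idx))
    assign_labels <- rep(labs, times = sizes)
    out[perm] <- assign_labels
  }
  out
}

#' Assign samples to acquisition sites following a demographic table
#'
#' @param meta data.frame with `sample_id`, `race`, `gender`.
#' @param tab a [demographic_table()] (or compatible data.frame).
#' @param seed integer seed for the within-group shuffle.
#' @return named list mapping site to a character vector of sample ids; each
#'   per-(group, site) count equals the corresponding table cell.
#' @export
partition_by_site <- function(meta, tab, seed = 1L) {
  validate_demographic_table(tab)
  out <- stats::setNames(vector("list", length(unique(tab$site))),
                         sort(unique(tab$site)))
  for (g in unique(group_key(tab$race, tab$gender))) {
    have <- meta$sample_id[group_key(meta$race, meta$gender) == g]
    cells <- tab[group_key(tab$race, tab$gender) == g, ]
    need <- sum(cells$count)
    if (length(have) < need)
      stop(sprintf("infeasible counts for group %s: need %d, have %d",
                   g, need, length(have)))
    pool <- with_seed(substream_seed(seed, "site", g), sample(have))
    pos <- 0L
    for (r in seq_len(nrow(cells))) {
      k <- cells$count[r]
      if (k == 0) next
      out[[cells$site[r]]] <- c(out[[cells$site[r]]],
                                pool[pos + seq_len(k)])
      pos <- pos + k
    }
  }
  out
}

#' Subset a dataset by split, site or explicit ids
#' @param data a `fairseg_data`.
#' @param split,site optional filters.
#' @param ids optional explicit sample ids.
#' @return a `fairseg_data` containing the matching samples.
#' @export
subset_data <- function(data, split = NULL, site = NULL, ids = NULL) {
  keep <- rep(TRUE, nrow(data$meta))
  if (!is.null(split)) keep <- keep & data$meta$split %in% split
  if (!is.null(site)) keep <- keep & data$meta$site %in% site
  if (!is.null(ids)) keep <- keep & data$meta$sample_id %in% ids
  structure(list(samples = data$samples[keep],
                 meta = data$meta[keep, , drop = FALSE], spec = data$spec),
            class = "fairseg_data")
}

#' Write a dataset to disk as PNG pairs plus CSV metadata
#'
#' Images are stored as 8-bit grayscale PNG (intensities quantized to 1/255),
#' masks as 8-bit single-channel PNG holding the raw integer labels, and
#' metadata as `metadata.csv` with header
#' `sample_id,race,gender,site,split`.
#'
#' @param data a `fairseg_data`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in data$samples) {
    png::writePNG(s$image, file.path(dir, "images", paste0(s$sample_id, ".png")))
    png::writePNG(s$mask / 255, file.path(dir, "masks", paste0(s$sample_id, ".png")))
  }
  write.csv(data$meta[, c("sample_id", "race", "gender", "site", "split")],
            file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset previously written with [write_dataset()]
#' @param dir dataset directory.
#' @return a `fairseg_data` (with `spec = NULL`; appearance parameters are not
#'   stored in the on-disk format).
#' @export
read_dataset <- function(dir) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE,
                   colClasses = "character")
  meta$group <- group_key(meta$race, meta$gender)
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$sample_id[i]
    img <- png::readPNG(file.path(dir, "images", paste0(id, ".png")))
    if (length(dim(img)) == 3) img <- img[, , 1]
    msk <- png::readPNG(file.path(dir, "masks", paste0(id, ".png")))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    list(sample_id = id, image = img,
         mask = matrix(as.integer(round(msk * 255)), nrow(msk), ncol(msk)),
         race = meta$race[i], gender = meta$gender[i],
         group = meta$group[i], site = meta$site[i], split = meta$split[i])
  })
  names(samples) <- meta$sample_id
  spec <- NULL
  structure(list(samples = samples, meta = meta, spec = spec),
            class = "fairseg_data")
}
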