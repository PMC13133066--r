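# Shared fixtures, all built in code at test time.

# small, fast dataset: 16x16 images, balanced groups, one or more sites
tiny_data <- function(n = 12, image_size = 16, seed = 99, sites = "A",
                      noise = 0.05) {
  generate_dataset(generation_spec(
    n_samples = n, image_size = image_size, seed = seed, sites = sites,
    noise_sd = c("White-Male" = noise, "White-Female" = noise,
                 "Black-Male" = noise, "Black-Female" = noise)))
}

# brute-force multi-class IoU oracle: explicit pixel loops, no set ops
iou_oracle <- function(pred, truth) {
  classes <- sort(unique(c(truth[truth > 0], pred[pred > 0])))
  if (length(classes) == 0) return(1.0)
  vals <- c()
  for (k in classes) {
    inter <- 0; uni <- 0
    for (i in seq_len(nrow(pred))) {
      for (j in seq_len(ncol(pred))) {
        p <- pred[i, j] == k
        t <- truth[i, j] == k
        if (p && t) inter <- inter + 1
        if (p || t) uni <- uni + 1
      }
    }
    if (uni > 0) vals <- c(vals, inter / uni)
  }
  if (length(vals) == 0) return(1.0)
  mean(vals)
}

random_label_mat <- function(n = 8, k = 3) {
  matrix(sample(0:k, n * n, replace = TRUE), n, n)
}

# predictor stubs for evaluate_model
stub_oracle <- function(truths) {
  i <- 0
  function(img) { i <<- i + 1; truths[[i]] }
}
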