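# shared fixtures: all synthetic, generated in code at test time

# a small fast cohort written once per test run and reused
tiny_cohort_dir <- local({
  cache <- new.env()
  function(n = 30, image_size = 48, interval = 360, seed = 101, ...) {
    key <- paste(n, image_size, interval, seed, ...)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("cohort_", gsub("\\W", "_", key)))
      if (!file.exists(file.path(dir, "manifest.csv"))) {
        cfg <- synth_config(n_embryos = n, image_size = image_size,
                            frame_interval_minutes = interval,
                            transfer_fraction = 0.5, seed = seed, ...)
        generate_cohort(cfg, dir)
      }
      cache[[key]] <- dir
    }
    cache[[key]]
  }
})

# independent scalar-loop soft hinge (oracle; no vectorization shared with
# the implementation)
oracle_soft_hinge <- function(s, y, m = 1, gamma = 1) {
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    out[i] <- log(1 + exp(gamma * (m - y[i] * s[i])))
  }
  out
}

# brute-force weighted segmentation loss, one pixel at a time
oracle_segmentation_loss <- function(s, y, m = 1, gamma = 1) {
  total <- 0
  for (i in seq_along(s)) {
    denom <- 0
    for (j in seq_along(s)) {
      if (y[j] == y[i]) denom <- denom + exp(-s[j] * y[j])
    }
    w <- exp(-s[i] * y[i]) / denom
    total <- total + w * log(1 + exp(gamma * (m - y[i] * s[i])))
  }
  total
}

# exhaustive threshold sweep (every score value and beyond-range sentinels)
oracle_threshold <- function(scores, labels) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  objs <- sapply(cand, function(th) {
    sum(labels == -1 & scores >= th) + sum(labels == 1 & scores < th)
  })
  min(objs)
}

# closed-form first-order ARMA with first-score initialization
oracle_arma_end <- function(x, alpha) {
  n <- length(x)
  if (n == 1) return(x)
  (1 - alpha)^(n - 1) * x[1] + sum(alpha * (1 - alpha)^((n - 1):1 - 1) * x[2:n])
}
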