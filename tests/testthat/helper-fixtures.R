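# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures are stored.

`%||%` <- function(a, b) if (is.null(a)) b else a

# homogeneous "body": the whole grid is tissue at `mean_suv` + N(0, sigma).
# No anatomical borders, so every macro pixel samples pure noise.
homogeneous_volume <- function(dims = c(64, 64, 24), mean_suv = 1,
                               sigma = 0.2, seed = 1, spacing = c(3, 3, 3)) {
  set.seed(seed)
  vox <- array(mean_suv + rnorm(prod(dims), sd = sigma), dim = dims)
  suv_volume(vox, spacing = spacing)
}

small_phantom_spec <- function(...) {
  phantom_spec(grid_size = c(96, 96, 48), ...)
}

# Independent brute-force noise-map oracle: enumerates blocks by explicit
# index arithmetic (implementation-independent tiling) and evaluates the
# n-1 SD definition on the in-mask pixels of each block.
oracle_noise_map <- function(slice, mask, block_size, min_valid_fraction) {
  nbr <- floor(nrow(slice) / block_size)
  nbc <- floor(ncol(slice) / block_size)
  vals <- matrix(NA_real_, nbr, nbc)
  valid <- matrix(FALSE, nbr, nbc)
  for (bi in seq_len(nbr)) {
    for (bj in seq_len(nbc)) {
      picks <- c()
      for (i in seq_len(block_size)) {
        for (j in seq_len(block_size)) {
          r <- (bi - 1) * block_size + i
          cc <- (bj - 1) * block_size + j
          if (mask[r, cc]) picks <- c(picks, slice[r, cc])
        }
      }
      n <- length(picks)
      if (n / block_size^2 >= min_valid_fraction && n >= 2) {
        m <- sum(picks) / n
        vals[bi, bj] <- sqrt(sum((picks - m)^2) / (n - 1))
        valid[bi, bj] <- TRUE
      }
    }
  }
  list(values = vals, valid = valid)
}

# blob-like random mask with spatial structure (union of random discs)
random_blob_mask <- function(nr, nc, n_blobs = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  for (b in seq_len(n_blobs)) {
    ci <- runif(1, 1, nr); cj <- runif(1, 1, nc); r <- runif(1, 3, nr / 2)
    d2 <- outer((seq_len(nr) - ci)^2, (seq_len(nc) - cj)^2, `+`)
    m <- m | (d2 <= r^2)
  }
  m
}

# brute-force AUC: proportion of (positive, negative) pairs won (+ half ties)
oracle_auc <- function(scores, pos) {
  xp <- scores[pos]; xn <- scores[!pos]
  tot <- 0
  for (a in xp) for (b in xn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xp) * length(xn))
}
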