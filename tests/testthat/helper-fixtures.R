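# Shared fixtures and independent oracles for the test suite.

# Small, fast synthetic series: DSS at 0 ppm plus caller-specified peaks on a
# coarse axis. Defaults keep unit tests well under a second.
tiny_series <- function(peaks = list(), ppm_range = c(-0.5, 4),
                        n_points = 600L, duration_h = 1, spacing_min = 6,
                        noise_sd = 0, dss_amplitude = 1, seed = 42L) {
  spec <- synthetic_series_spec(peaks = peaks, ppm_range = ppm_range,
                                n_points = n_points, duration_h = duration_h,
                                spacing_min = spacing_min,
                                dss_amplitude = dss_amplitude,
                                noise_sd = noise_sd, seed = seed)
  simulate_series(spec)
}

const_peak <- function(name, ppm, value, fwhm = 0.02) {
  synthetic_peak(name, center = list(type = "constant", ppm = ppm),
                 amplitude = list(type = "constant", value = value),
                 fwhm = fwhm)
}

# Bruker acqus snippets
acqus_text <- function(date = 1500000000, ns = 64, ds = 8, extra = character()) {
  c(sprintf("##$DATE= %d", date), sprintf("##$NS= %d", ns),
    sprintf("##$DS= %d", ds), extra)
}

# block-wise mean of a ground-truth trajectory, matching block_sum timing
block_mean <- function(x, block = 3L) {
  nb <- length(x) %/% block
  tapply(x[seq_len(nb * block)], rep(seq_len(nb), each = block), mean)
}

# Exhaustive single-linkage agglomeration by repeated pairwise minimum
# merging (Lance-Williams with pmin), independent of stats::hclust.
# Returns labels after cutting to k clusters.
oracle_single_linkage <- function(coords, k) {
  n <- nrow(coords)
  if (n == 1L) return(1L)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  labels <- seq_len(n)
  n_active <- n
  while (n_active > k) {
    # rows/cols of merged-away clusters are held at Inf, so the global
    # minimum is always between two active clusters
    ij <- arrayInd(which.min(D), dim(D))
    i <- min(ij); j <- max(ij)
    merged <- pmin(D[i, ], D[j, ])
    D[i, ] <- merged; D[, i] <- merged
    D[i, i] <- Inf
    D[j, ] <- Inf; D[, j] <- Inf
    labels[labels == j] <- i
    n_active <- n_active - 1L
  }
  match(labels, unique(labels))
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  identical(outer(a, a, `==`), outer(b, b, `==`))
}

# dense 2-D Gaussian convolution with edge replication, direct quadruple
# loop on small inputs; oracle for gaussian_smooth_2d
dense_gauss_2d <- function(mat, sigma_ppm, sigma_time, ppm_step, t_step) {
  kern <- function(sigma, step) {
    r <- max(0L, as.integer(ceiling(4 * sigma / step)))
    k <- exp(-((-r:r) * step)^2 / (2 * sigma^2))
    k / sum(k)
  }
  kp <- kern(sigma_ppm, ppm_step)
  kt <- kern(sigma_time, t_step)
  rp <- (length(kp) - 1L) %/% 2L
  rt <- (length(kt) - 1L) %/% 2L
  Tn <- nrow(mat); P <- ncol(mat)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, Tn, P)
  for (t in seq_len(Tn)) for (p in seq_len(P)) {
    acc <- 0
    for (a in -rt:rt) for (b in -rp:rp) {
      acc <- acc + kt[a + rt + 1L] * kp[b + rp + 1L] *
        mat[clampi(t + a, Tn), clampi(p + b, P)]
    }
    out[t, p] <- acc
  }
  out
}
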