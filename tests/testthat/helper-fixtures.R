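# Small in-code fixtures shared across test files.

# A uniform-density CT with a rectangular "lesion" block of known density in
# the low-index hemisphere. Grid 9 x 7 x 5, midline at x = 5.
lesion_block_ct <- function(d_ischemic, d_normal, spacing = 1) {
  vox <- array(d_normal, c(9, 7, 5))
  mask <- array(FALSE, c(9, 7, 5))
  mask[2:3, 3:4, 2:3] <- TRUE
  vox[mask] <- d_ischemic
  list(ct = ct_volume(vox, spacing), mask = mask)
}

# Perfusion maps over an all-brain grid with uniform rCBF / Tmax values.
uniform_maps <- function(rcbf = 100, tmax = 0, dims = c(10, 10, 10),
                         spacing = 1) {
  perfusion_maps(array(rcbf, dims), array(tmax, dims),
                 array(TRUE, dims), spacing)
}

# A random one-hemisphere mask on an odd grid, for mirroring properties.
random_hemisphere_mask <- function(dims = c(11, 9, 7), n = 12) {
  mask <- array(FALSE, dims)
  mid <- (dims[1] + 1) %/% 2
  idx <- cbind(sample(seq_len(mid - 1), n, replace = TRUE),
               sample(seq_len(dims[2]), n, replace = TRUE),
               sample(seq_len(dims[3]), n, replace = TRUE))
  mask[idx] <- TRUE
  mask
}

# Independent log-binomial maximum likelihood by direct optimisation; the
# oracle against which fit_rr is checked.
brute_force_logbin <- function(data, outcome, predictors) {
  X <- cbind(1, as.matrix(data[predictors]))
  y <- as.numeric(data[[outcome]])
  nll <- function(beta) {
    p <- exp(drop(X %*% beta))
    if (any(p >= 1) || any(p <= 0)) {
      return(1e8 + 1e6 * sum(pmax(p - 1, 0)))
    }
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  start <- c(log(mean(y)), rep(0, length(predictors)))
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  exp(fit$par[-1])
}

# Single-effect generative configs used in recovery tests.
single_effect_config <- function(n, seed, rr_nwu = 1, rr_pcore = 1,
                                 rr_aspects = 1) {
  effect_config(n_subjects = n, baseline_risk = 0.16,
                rr_nwu_per_pct = rr_nwu, rr_pcore_per_ml = rr_pcore,
                rr_aspects_per_point = rr_aspects, seed = seed)
}
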