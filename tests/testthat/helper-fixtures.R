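# Shared fixtures, all generated in code.

# small noiseless cohort with an even receptive/delayed mix
noiseless_cohort <- function(n_patients = 20, n_genes = 60, n_markers = 10,
                             receptive_fraction = 0.5, seed = 7) {
  generate_cohort(cohort_config(
    n_patients = n_patients, n_genes = n_genes, n_markers = n_markers,
    receptive_fraction = receptive_fraction, noise_sd = 0, seed = seed))
}

# smooth 1-feature regression problem for forest behavior checks
smooth_fixture <- function(n = 120, noise_sd = 3, seed = 11) {
  withr::with_seed(seed, {
    x <- runif(n, -2, 2)
    y <- 40 * tanh(x) + rnorm(n, sd = noise_sd)
  })
  list(X = matrix(x, ncol = 1), y = y)
}

# direct (unvectorized) infinitesimal-jackknife oracle over stored
# membership counts and per-tree predictions
ij_oracle <- function(N, t_vec, correct = TRUE) {
  B <- length(t_vec)
  n <- nrow(N)
  tbar <- mean(t_vec)
  v <- 0
  for (i in seq_len(n)) {
    cv <- 0
    for (b in seq_len(B)) {
      cv <- cv + (N[i, b] - mean(N[i, ])) * (t_vec[b] - tbar)
    }
    v <- v + (cv / B)^2
  }
  if (correct) v <- v - (n / B^2) * sum((t_vec - tbar)^2)
  max(v, 0)
}

# brute-force enumeration of consistent grid-label triplets
enumeration_oracle <- function(phases, halfwidth = 12) {
  g <- hour_label_grid()
  all3 <- expand.grid(l1 = g, l2 = g, l3 = g)
  ok <- all3$l1 - all3$l2 == 48 & all3$l2 - all3$l3 == 48 &
    as.character(phase_from_label(all3$l1, halfwidth)) == phases[1] &
    as.character(phase_from_label(all3$l2, halfwidth)) == phases[2] &
    as.character(phase_from_label(all3$l3, halfwidth)) == phases[3]
  m <- matrix(as.integer(as.matrix(all3[ok, , drop = FALSE])), ncol = 3,
              dimnames = list(NULL, c("l1", "l2", "l3")))
  m[order(m[, 1]), , drop = FALSE]
}
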