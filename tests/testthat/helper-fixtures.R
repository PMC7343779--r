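# Shared fixtures built in code at test time.

# Random symmetric positive-definite tensor with eigenvalues in a
# cortex-plausible range (mm^2/s).
random_tensor <- function() {
  evals <- sort(runif(3, 0.2e-3, 2e-3), decreasing = TRUE)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  R %*% diag(evals) %*% t(R)
}

# Rotation matrix about a random axis.
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3))) * sample(c(-1, 1), 1)
}

# One-voxel DwiSet from a single tensor.
single_voxel_dwi <- function(D, grad = gradient_scheme(16, 1000), s0 = 1000) {
  sig <- simulate_dwi_signal(D, grad$bvals, grad$bvecs, s0 = s0)
  dwi_set(array(sig, c(1, 1, 1, length(sig))), grad$bvals, grad$bvecs)
}

# Brute-force BH step-up, written as the sort-free double loop so it shares
# nothing with p.adjust.
bh_bruteforce <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i])
    # running minimum over all hypotheses with p >= p[i]
    cand <- Inf
    for (j in seq_len(m)) {
      rank_j <- sum(p <= p[j])
      if (p[j] >= p[i]) cand <- min(cand, p[j] * m / rank_j)
    }
    adj[i] <- min(cand, 1)
  }
  adj
}

# Brute-force per-class confusion tally from raw label vectors.
confusion_bruteforce <- function(pred, truth, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(pred)) {
    m[match(pred[i], classes), match(truth[i], classes)] <-
      m[match(pred[i], classes), match(truth[i], classes)] + 1L
  }
  m
}

# The printed 4x4 test-cohort confusion counts (rows predicted, columns
# true; order HS, svPPA, bvFTD, nfvPPA).
published_confusion <- function() {
  matrix(c(21, 1, 1, 1,
           2, 13, 2, 1,
           1, 2, 10, 2,
           1, 1, 1, 6),
         nrow = 4, byrow = FALSE,
         dimnames = list(predicted = c("HS", "svPPA", "bvFTD", "nfvPPA"),
                         true = c("HS", "svPPA", "bvFTD", "nfvPPA")))
}
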