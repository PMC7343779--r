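#' Diffusion-weighted image set
#'
#' Bundles a 4-D diffusion-weighted signal array with its gradient table,
#' affine and voxel mask, validating the acquisition geometry: at least one
#' b~0 baseline volume, at least six non-collinear diffusion-weighted
#' directions, and unit-norm gradient vectors for every weighted volume.
#'
#' @param signals 4-D numeric array (x, y, z, volume) of non-negative signals.
#' @param bvals Numeric vector of per-volume b-factors in s/mm^2.
#' @param bvecs 3 x n matrix of per-volume gradient directions (image axes).
#' @param affine 4 x 4 voxel-to-world affine (RAS+). Defaults to identity.
#' @param mask Logical array of voxels to fit; defaults to all voxels.
#' @param b0_threshold b-values below this count as baseline volumes
#'   (default 50 s/mm^2, matching common vendor rounding of nominal b = 0).
#' @return A `dwi_set` object.
#' @export
dwi_set <- function(signals, bvals, bvecs, affine = diag(4), mask = NULL,
                    b0_threshold = 50) {
  stopifnot(length(dim(signals)) == 4L)
  n_vol <- dim(signals)[4L]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (length(bvals) != n_vol || ncol(bvecs) != n_vol) {
    abort(sprintf(
      "volume count mismatch: %d signal volumes, %d bvals, %d bvecs",
      n_vol, length(bvals), ncol(bvecs)
    ), class = "cortexdti_format_error")
  }
  if (any(signals < 0, na.rm = TRUE)) {
    abort("negative signal intensities", class = "cortexdti_contract_error")
  }
  is_b0 <- bvals < b0_threshold
  if (!any(is_b0)) {
    abort("no b~0 baseline volume in the acquisition",
          class = "cortexdti_missing_baseline_error")
  }
  dw <- which(!is_b0)
  if (length(dw) > 0) {
    norms <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
    if (any(abs(norms - 1) > 1e-3)) {
      abort("gradient directions for b > 0 volumes must be unit norm (within 1e-3)",
            class = "cortexdti_contract_error")
    }
  }
  if (design_rank(bvals, bvecs, b0_threshold) < 6L) {
    abort(paste0(
      "fewer than 6 non-collinear diffusion-weighted directions: ",
      "the tensor is not identifiable"
    ), class = "cortexdti_unfittable_design_error")
  }
  if (is.null(mask)) mask <- array(TRUE, dim(signals)[1:3]) else mask <- array(as.logical(mask), dim(signals)[1:3])
  structure(
    list(signals = signals, bvals = bvals, bvecs = bvecs, affine = affine,
         mask = mask, b0_threshold = b0_threshold),
    class = "dwi_set"
  )
}

#' @export
print.dwi_set <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf(
    "<dwi_set> %d x %d x %d grid, %d volumes (%d b~0, %d weighted), %d masked voxels\n",
    d[1], d[2], d[3], d[4], sum(x$bvals < x$b0_threshold),
    sum(x$bvals >= x$b0_threshold), sum(x$mask)
  ))
  invisible(x)
}

# Rank of the diffusion-weighting part of the log-linear design.
design_rank <- function(bvals, bvecs, b0_threshold = 50) {
  dw <- which(bvals >= b0_threshold)
  if (length(dw) == 0L) return(0L)
  X <- tensor_design(bvals[dw], bvecs[, dw, drop = FALSE])[, -1L, drop = FALSE]
  qr(X)$rank
}

# Design matrix of ln S = ln S0 - b g' D g with D stored lower-triangular
# (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
tensor_design <- function(bvals, bvecs) {
  gx <- bvecs[1L, ]; gy <- bvecs[2L, ]; gz <- bvecs[3L, ]
  cbind(
    1,
    -bvals * gx * gx,
    -2 * bvals * gx * gy,
    -bvals * gy * gy,
    -2 * bvals * gx * gz,
    -2 * bvals * gy * gz,
    -bvals * gz * gz
  )
}

#' Per-voxel diffusion tensor field
#'
#' @param D 4-D array (x, y, z, 6) of tensor components in lower-triangular
#'   order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), mm^2/s.
#' @param S0 3-D array of fitted non-diffusion-weighted signal.
#' @param affine 4 x 4 voxel-to-world affine.
#' @param mask Logical array of fitted voxels.
#' @param degenerate Logical array flagging voxels whose fitted tensor is not
#'   positive definite (or whose fit failed). Degenerate voxels are retained
#'   but excluded from profile sampling.
#' @return A `tensor_field` object.
#' @export
tensor_field <- function(D, S0, affine = diag(4), mask = NULL, degenerate = NULL) {
  stopifnot(length(dim(D)) == 4L, dim(D)[4L] == 6L)
  dims <- dim(D)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (is.null(degenerate)) degenerate <- array(FALSE, dims)
  structure(
    list(D = D, S0 = S0, affine = affine, mask = mask, degenerate = degenerate),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("<tensor_field> %d x %d x %d grid, %d fitted voxels, %d degenerate\n",
              d[1], d[2], d[3], sum(x$mask), sum(x$degenerate & x$mask)))
  invisible(x)
}

# 6-component lower-triangular vector <-> symmetric 3x3 matrix.
tensor6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[2], d6[4],
           d6[2], d6[3], d6[5],
           d6[4], d6[5], d6[6]), 3L, 3L)
}

mat_to_tensor6 <- function(D) {
  c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
}

#' Fit the diffusion tensor model
#'
#' Fits ln S_i = ln S0 - b_i g_i' D g_i per masked voxel by ordinary or
#' weighted (signal^2 weights) linear least squares on the log signal, the
#' standard log-linear tensor fit. Non-positive signals are clamped to a small
#' floor relative to the voxel's baseline signal before taking logs. Voxels
#' whose fitted tensor has a negative eigenvalue are flagged degenerate rather
#' than discarded.
#'
#' @param dwi A [dwi_set()].
#' @param method `"ols"` (default) or `"wls"` (weights = squared signal, one
#'   reweighting from the OLS prediction).
#' @param signal_floor Signals below `signal_floor` times the voxel's mean
#'   baseline signal are clamped to that floor before the log transform.
#' @return A [tensor_field()] with fitted `D`, `S0` and a `degenerate` mask.
#' @export
#' @examples
#' grad <- gradient_scheme(n_dirs = 12, bval = 1000)
#' D <- diag(c(1.7, 0.3, 0.2)) * 1e-3
#' sig <- simulate_dwi_signal(D, grad$bvals, grad$bvecs, s0 = 1000)
#' dwi <- dwi_set(array(sig, c(1, 1, 1, length(sig))), grad$bvals, grad$bvecs)
#' tf <- fit_tensor(dwi)
#' eigensystem(tf$D[1, 1, 1, ])$evals  # recovers (1.7, 0.3, 0.2) x 1e-3
fit_tensor <- function(dwi, method = c("ols", "wls"), signal_floor = 1e-6) {
  stopifnot(inherits(dwi, "dwi_set"))
  method <- match.arg(method)
  n_vol <- length(dwi$bvals)
  if (n_vol < 7L) {
    abort("tensor fit needs at least 7 usable volumes (1 baseline + 6 directions)",
          class = "cortexdti_unfittable_design_error")
  }
  dims <- dim(dwi$signals)[1:3]
  X <- tensor_design(dwi$bvals, dwi$bvecs)

  vox <- which(dwi$mask)
  S <- matrix(aperm(dwi$signals, c(4L, 1L, 2L, 3L)), nrow = n_vol)[, vox, drop = FALSE]

  # Floor relative to each voxel's mean baseline signal (clamp before log).
  is_b0 <- dwi$bvals < dwi$b0_threshold
  s0_est <- colMeans(S[is_b0, , drop = FALSE])
  s0_est[s0_est <= 0] <- 1
  floors <- matrix(signal_floor * s0_est, nrow = n_vol, ncol = length(vox), byrow = TRUE)
  S <- pmax(S, floors)
  logS <- log(S)

  if (method == "ols") {
    beta <- qr.coef(qr(X), logS)
  } else {
    beta_ols <- qr.coef(qr(X), logS)
    pred <- exp(X %*% beta_ols)
    beta <- matrix(NA_real_, 7L, ncol(logS))
    for (v in seq_len(ncol(logS))) {
      w <- pred[, v]^2
      Xw <- X * w
      beta[, v] <- tryCatch(
        solve(crossprod(X, Xw), crossprod(Xw, logS[, v, drop = FALSE]))[, 1L],
        error = function(e) beta_ols[, v]
      )
    }
  }

  D <- array(0, c(dims, 6L))
  S0 <- array(NA_real_, dims)
  degenerate <- array(FALSE, dims)
  Dmat <- matrix(0, prod(dims), 6L)
  Dmat[vox, ] <- t(beta[-1L, , drop = FALSE])
  D <- array(Dmat, c(dims, 6L))
  S0v <- rep(NA_real_, prod(dims))
  S0v[vox] <- exp(beta[1L, ])
  S0 <- array(S0v, dims)

  # Flag non-positive-definite fits.
  deg <- vapply(seq_along(vox), function(i) {
    ev <- eigen(tensor6_to_mat(Dmat[vox[i], ]), symmetric = TRUE, only.values = TRUE)$values
    min(ev) < 0 || anyNA(ev)
  }, logical(1))
  degv <- rep(FALSE, prod(dims))
  degv[vox] <- deg
  degenerate <- array(degv, dims)

  tensor_field(D, S0, affine = dwi$affine, mask = dwi$mask, degenerate = degenerate)
}

#' Eigensystem of a symmetric diffusion tensor
#'
#' Returns eigenvalues sorted descending with orthonormal eigenvectors.
#' Eigenvector signs are fixed deterministically (non-negative dot product
#' with +x, then +y, then +z), so repeated calls and near-degenerate tensors
#' give reproducible output. When the two largest eigenvalues are nearly
#' equal the principal direction is geometrically meaningless, and
#' `degenerate_direction` is set.
#'
#' @param D Symmetric 3 x 3 matrix, or length-6 lower-triangular vector
#'   (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).
#' @param sym_tol Maximum allowed asymmetry |D - t(D)|.
#' @param direction_tol `degenerate_direction` is set when
#'   lambda1 - lambda2 < `direction_tol` * lambda1.
#' @return List with `evals` (length 3, descending), `evecs` (3 x 3, columns
#'   are unit eigenvectors) and `degenerate_direction` (logical).
#' @export
eigensystem <- function(D, sym_tol = 1e-8, direction_tol = 1e-6) {
  if (length(D) == 6L) D <- tensor6_to_mat(D)
  stopifnot(is.matrix(D), all(dim(D) == c(3L, 3L)))
  asym <- max(abs(D - t(D)))
  if (asym > sym_tol * max(1, max(abs(D)))) {
    abort(sprintf("tensor not symmetric (max asymmetry %.3g)", asym),
          class = "cortexdti_contract_error")
  }
  es <- eigen((D + t(D)) / 2, symmetric = TRUE)
  evals <- es$values           # eigen() returns descending for symmetric
  evecs <- es$vectors
  # Deterministic sign convention.
  for (j in 1:3) {
    v <- evecs[, j]
    pick <- if (abs(v[1]) > 1e-12) 1L else if (abs(v[2]) > 1e-12) 2L else 3L
    if (v[pick] < 0) evecs[, j] <- -v
  }
  degdir <- (evals[1] - evals[2]) < direction_tol * max(evals[1], .Machine$double.eps)
  list(evals = evals, evecs = evecs, degenerate_direction = degdir)
}

#' Mean diffusivity
#'
#' @param evals Numeric vector of 3 eigenvalues, or an n x 3 matrix.
#' @return (lambda1 + lambda2 + lambda3) / 3, in the eigenvalues' units.
#' @export
mean_diffusivity <- function(evals) {
  if (is.matrix(evals)) rowMeans(evals) else mean(evals)
}

#' Fractional anisotropy
#'
#' Standard FA: sqrt(3/2) * ||lambda - MD|| / ||lambda||, clipped to \[0, 1\].
#' All-zero eigenvalues leave FA undefined; a configurable sentinel is
#' returned there instead of an error.
#'
#' @param evals Numeric vector of 3 eigenvalues, or an n x 3 matrix.
#' @param sentinel Value returned for all-zero eigenvalues (default `NA`).
#' @return FA in \[0, 1\] (or `sentinel`).
#' @export
fractional_anisotropy <- function(evals, sentinel = NA_real_) {
  m <- if (is.matrix(evals)) evals else matrix(evals, nrow = 1L)
  md <- rowMeans(m)
  num <- sqrt(rowSums((m - md)^2))
  den <- sqrt(rowSums(m^2))
  fa <- pmin(pmax(sqrt(1.5) * num / den, 0), 1)
  fa[den == 0] <- sentinel
  if (is.matrix(evals)) fa else fa[[1L]]
}
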