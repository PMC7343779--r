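#' Rotate unit vectors (Rodrigues formula), rowwise
#' @noRd
rotate_about <- function(v, axis, angle) {
  ca <- cos(angle); sa <- sin(angle)
  dot <- rowSums(axis * v)
  cross <- cbind(
    axis[, 2] * v[, 3] - axis[, 3] * v[, 2],
    axis[, 3] * v[, 1] - axis[, 1] * v[, 3],
    axis[, 1] * v[, 2] - axis[, 2] * v[, 1]
  )
  v * ca + cross * sa + axis * dot * (1 - ca)
}

# Unit vectors perpendicular to each row of n (deterministic given RNG state).
random_perpendicular <- function(n) {
  r <- matrix(rnorm(3 * nrow(n)), ncol = 3L)
  r <- r - n * rowSums(r * n)
  nr <- sqrt(rowSums(r^2))
  small <- nr < 1e-8
  if (any(small)) {
    # fall back to a coordinate axis not parallel to n
    alt <- cbind(-n[small, 2], n[small, 1], 0)
    altn <- sqrt(rowSums(alt^2))
    alt[altn < 1e-8, ] <- matrix(c(0, -1, 0), sum(altn < 1e-8), 3, byrow = TRUE)
    r[small, ] <- alt
    nr <- sqrt(rowSums(r^2))
  }
  r / nr
}

#' Synthetic cortical-ribbon phantom with controlled tensor orientation
#'
#' Builds a slab or spherical-shell grey-matter ribbon whose per-voxel
#' principal eigenvector is the local surface normal tilted by a controlled
#' angle `theta_deg` about a random in-tangent-plane axis, then perturbed by
#' Gaussian angular noise `sigma_deg` about a random axis perpendicular to
#' the tilted direction. The phantom ships the matching [ribbon_labels()]
#' (two synthetic "hemisphere" parcels), the ground-truth [tensor_field()],
#' and a truth record with the per-voxel normals and realised deviation
#' angles, so downstream profile metrics can be validated against the
#' generating parameters.
#'
#' @param geometry `"slab"` or `"shell"`.
#' @param dim Grid dimensions (voxels). Defaults: slab 24 x 24 x 16, shell
#'   32^3.
#' @param voxel_size Isotropic voxel size in mm (default 1).
#' @param thickness Slab GM thickness in mm (default 5; >= 3 voxels).
#' @param n_white Slab white-matter layers in voxels (default 3).
#' @param r_inner,r_outer Shell inner/outer GM radii in mm (defaults 6, 11).
#' @param lambdas Tensor eigenvalues (mm^2/s), descending, all > 0.
#'   Default c(1.2, 0.4, 0.3) * 1e-3, a cortex-like prolate tensor.
#' @param theta_deg True radial-deviation angle in degrees, in \[0, 90\].
#' @param sigma_deg Angular noise SD in degrees (>= 0).
#' @param seed RNG seed; the phantom is bit-reproducible under it.
#' @return List with `ribbon`, `tensors` and `truth` (theta/sigma, per-GM
#'   voxel normals, principal directions and deviation angles).
#' @export
#' @examples
#' ph <- make_phantom("slab", theta_deg = 30, sigma_deg = 0, seed = 1)
#' ph$ribbon
make_phantom <- function(geometry = c("slab", "shell"), dim = NULL,
                         voxel_size = 1, thickness = 5, n_white = 3,
                         r_inner = 6, r_outer = 11,
                         lambdas = c(1.2, 0.4, 0.3) * 1e-3,
                         theta_deg = 0, sigma_deg = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  if (theta_deg < 0 || theta_deg > 90) {
    abort("theta_deg must lie in [0, 90]", class = "cortexdti_parameter_error")
  }
  if (sigma_deg < 0) abort("sigma_deg must be >= 0", class = "cortexdti_parameter_error")
  if (!(lambdas[1] >= lambdas[2] && lambdas[2] >= lambdas[3] && lambdas[3] > 0)) {
    abort("lambdas must be descending and positive", class = "cortexdti_parameter_error")
  }
  if (geometry == "shell" && !(r_outer > r_inner && r_inner > 0)) {
    abort("need r_outer > r_inner > 0", class = "cortexdti_parameter_error")
  }
  if (geometry == "slab" && thickness / voxel_size < 3) {
    abort("slab GM must be >= 3 voxels thick", class = "cortexdti_parameter_error")
  }
  if (is.null(dim)) {
    dim <- if (geometry == "slab") c(24L, 24L, 16L) else rep(32L, 3L)
  }
  set.seed(seed)

  tissue <- array(0L, dim)
  if (geometry == "slab") {
    gm_vox <- round(thickness / voxel_size)
    z <- slice.index(tissue, 3L)           # 1-based
    tissue[z <= n_white] <- 1L
    tissue[z > n_white & z <= n_white + gm_vox] <- 2L
    tissue[z > n_white + gm_vox] <- 3L
  } else {
    ctr <- (dim - 1) / 2
    ii <- slice.index(tissue, 1L) - 1; jj <- slice.index(tissue, 2L) - 1
    kk <- slice.index(tissue, 3L) - 1
    r <- sqrt(((ii - ctr[1]))^2 + ((jj - ctr[2]))^2 + ((kk - ctr[3]))^2) * voxel_size
    tissue[r < r_inner] <- 1L
    tissue[r >= r_inner & r < r_outer] <- 2L
    tissue[r >= r_outer] <- 3L
  }

  # Two synthetic parcels: left/right half of the grid.
  parcel <- array(0L, dim)
  half <- slice.index(parcel, 1L) <= dim[1] / 2
  parcel[tissue == 2L & half] <- 1L
  parcel[tissue == 2L & !half] <- 2L
  lookup <- tibble(region_code = 1:2, hemi = c("left", "right"),
                   region = c("left hemisphere", "right hemisphere"))
  affine <- diag(c(rep(voxel_size, 3), 1))
  ribbon <- ribbon_labels(tissue, parcel, affine, region_lookup = lookup)

  gm <- which(tissue == 2L)
  gm_ijk <- which(tissue == 2L, arr.ind = TRUE)
  n_gm <- length(gm)
  normals <- if (geometry == "slab") {
    matrix(rep(c(0, 0, 1), each = n_gm), ncol = 3L)
  } else {
    ctr <- (dim - 1) / 2
    d <- sweep(gm_ijk - 1, 2L, ctr)
    d / sqrt(rowSums(d^2))
  }

  theta <- theta_deg * pi / 180
  axis1 <- random_perpendicular(normals)
  e1 <- rotate_about(normals, axis1, theta)
  if (sigma_deg > 0) {
    eps <- rnorm(n_gm, 0, sigma_deg * pi / 180)
    axis2 <- random_perpendicular(e1)
    e1 <- rotate_about(e1, axis2, eps)
  }
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- random_perpendicular(e1)
  e3 <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )

  l1 <- lambdas[1]; l2 <- lambdas[2]; l3 <- lambdas[3]
  d6 <- function(a, b) l1 * e1[, a] * e1[, b] + l2 * e2[, a] * e2[, b] + l3 * e3[, a] * e3[, b]
  nvox <- prod(dim)
  Dflat <- matrix(0, nvox, 6L)
  Dflat[gm, ] <- cbind(d6(1, 1), d6(1, 2), d6(2, 2), d6(1, 3), d6(2, 3), d6(3, 3))
  # Isotropic background diffusivity elsewhere keeps the field defined.
  bg <- tissue != 2L
  iso <- mean(lambdas)
  Dflat[bg, c(1, 3, 6)] <- iso
  D <- array(Dflat, c(dim, 6L))
  S0 <- array(1000, dim)
  mask <- array(TRUE, dim)
  tensors <- tensor_field(D, S0, affine = affine, mask = mask)

  dev_angle <- acos(pmin(pmax(abs(rowSums(e1 * normals)), 0), 1))
  truth <- list(
    geometry = geometry, theta_deg = theta_deg, sigma_deg = sigma_deg,
    lambdas = lambdas, seed = seed, gm_index = gm,
    normals = normals, e1 = e1, deviation_rad = dev_angle
  )
  list(ribbon = ribbon, tensors = tensors, truth = truth)
}

#' Forward-simulate the diffusion signal of a single tensor
#'
#' @param D Symmetric 3 x 3 tensor (mm^2/s) or length-6 lower-triangular
#'   vector.
#' @param bvals Per-volume b-values (s/mm^2).
#' @param bvecs 3 x n gradient directions.
#' @param s0 Baseline signal.
#' @return Numeric vector of noise-free signals s0 * exp(-b g' D g).
#' @export
simulate_dwi_signal <- function(D, bvals, bvecs, s0 = 1000) {
  if (length(D) == 6L) D <- tensor6_to_mat(D)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L) bvecs <- t(bvecs)
  gDg <- colSums(bvecs * (D %*% bvecs))
  s0 * exp(-bvals * gDg)
}

#' Forward-simulate a DWI acquisition from a tensor field
#'
#' S_i = S0 exp(-b_i g_i' D g_i) per voxel and volume, with Rician noise at
#' the requested signal-to-noise ratio (noise SD = mean S0 / snr on each of
#' the two quadrature channels; `snr = Inf` gives noise-free magnitudes).
#'
#' @param tensors A [tensor_field()].
#' @param bvals,bvecs Gradient table (see [gradient_scheme()]).
#' @param snr Signal-to-noise ratio (> 0 or Inf).
#' @param seed RNG seed for the noise draw.
#' @return A [dwi_set()].
#' @export
simulate_dwi <- function(tensors, bvals, bvecs, snr = Inf, seed = 1L) {
  stopifnot(inherits(tensors, "tensor_field"))
  if (!(snr > 0)) abort("snr must be > 0 (use Inf for noise-free)",
                        class = "cortexdti_parameter_error")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L) bvecs <- t(bvecs)
  dims <- dim(tensors$D)[1:3]
  nvox <- prod(dims)
  Dflat <- matrix(tensors$D, nrow = nvox)
  gx <- bvecs[1, ]; gy <- bvecs[2, ]; gz <- bvecs[3, ]
  Q <- rbind(gx^2, 2 * gx * gy, gy^2, 2 * gx * gz, 2 * gy * gz, gz^2)  # 6 x nvol
  gDg <- Dflat %*% Q                                  # nvox x nvol
  S0v <- as.vector(tensors$S0)
  S0v[is.na(S0v)] <- 0
  S <- S0v * exp(-sweep(gDg, 2L, bvals, "*"))
  if (is.finite(snr)) {
    set.seed(seed)
    sig <- mean(S0v[as.vector(tensors$mask)]) / snr
    n1 <- matrix(rnorm(length(S), 0, sig), nrow(S))
    n2 <- matrix(rnorm(length(S), 0, sig), nrow(S))
    S <- sqrt((S + n1)^2 + n2^2)
  }
  dwi_set(array(S, c(dims, length(bvals))), bvals, bvecs,
          affine = tensors$affine, mask = tensors$mask)
}

#' Deterministic diffusion gradient scheme
#'
#' Baseline volumes followed by `n_dirs` directions spread over the sphere
#' by the Fibonacci spiral — evenly distributed and non-collinear, mirroring
#' a single-shell clinical scheme (e.g. 1 b0 + 64 directions at
#' b = 2000 s/mm^2).
#'
#' @param n_dirs Number of diffusion-weighted directions (>= 6).
#' @param bval Shell b-value in s/mm^2.
#' @param n_b0 Number of baseline volumes (default 1).
#' @return List with `bvals` (length n_b0 + n_dirs) and `bvecs` (3 x n).
#' @export
gradient_scheme <- function(n_dirs = 64L, bval = 2000, n_b0 = 1L) {
  if (n_dirs < 6L) abort("need >= 6 directions", class = "cortexdti_parameter_error")
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(1 - z^2, 0))
  dirs <- rbind(r * cos(phi), r * sin(phi), z, deparse.level = 0)
  bvecs <- cbind(matrix(0, 3L, n_b0), dirs)
  bvals <- c(rep(0, n_b0), rep(bval, n_dirs))
  list(bvals = bvals, bvecs = bvecs)
}

#' Synthetic realignment time-series
#'
#' Linear per-channel drift plus optional instantaneous jumps, giving a
#' series whose displacement index is computable from the recipe: with
#' drift d on all six channels and no jumps the index is d (raw pooling);
#' a single jump of magnitude m on one channel adds m / (6 (n - 1)).
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param drift Per-transition drift, recycled over the 6 channels.
#' @param jump_magnitude Magnitude of each jump (same channel units).
#' @param n_jumps Number of jumps placed at seeded random transitions and
#'   channels.
#' @param seed RNG seed.
#' @return Tibble with columns tx, ty, tz (mm), rx, ry, rz (rad).
#' @export
make_realignment_series <- function(n_volumes, drift = 0, jump_magnitude = 0,
                                    n_jumps = 0L, seed = 1L) {
  if (n_volumes < 2L) {
    abort("need >= 2 volumes", class = "cortexdti_parameter_error")
  }
  set.seed(seed)
  drift <- rep_len(drift, 6L)
  m <- outer(0:(n_volumes - 1L), drift)
  if (n_jumps > 0L && jump_magnitude != 0) {
    for (j in seq_len(n_jumps)) {
      tr <- sample(2:n_volumes, 1L)
      ch <- sample(1:6, 1L)
      m[tr:n_volumes, ch] <- m[tr:n_volumes, ch] + jump_magnitude
    }
  }
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  as_tibble(m)
}

#' Specification of a synthetic multi-cohort study
#'
#' Defines the group structure the cohort generator emulates: per-cohort
#' group sizes mirroring the study design (selection 30 HS + 30 FTD, training
#' 30 HS + 5/13/6 bvFTD/svPPA/nfvPPA, test 24 HS + 15/18/9), a regional
#' AngleR baseline, and group-specific regional elevations placed in the
#' regions each subtype is expected to disrupt (svPPA: left fusiform and
#' entorhinal, right temporal pole and inferior temporal; bvFTD: left caudal
#' anterior cingulate and right lingual; nfvPPA: left pars opercularis; all
#' patient groups: bilateral precentral).
#'
#' @param n Named list of per-cohort group sizes; see default.
#' @param baseline_mean,baseline_sd Regional AngleR baseline (radians).
#' @param elevation Elevation added to affected regions (radians).
#' @param shared_elevation Elevation in bilateral precentral for every
#'   patient group (radians).
#' @param elevations Named list group -> (named numeric of region ->
#'   elevation); overrides the defaults built from `elevation` and
#'   `shared_elevation` if supplied.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = list(
                          selection = c(HS = 30, bvFTD = 10, svPPA = 10, nfvPPA = 10),
                          training = c(HS = 30, bvFTD = 5, svPPA = 13, nfvPPA = 6),
                          test = c(HS = 24, bvFTD = 15, svPPA = 18, nfvPPA = 9)
                        ),
                        baseline_mean = 0.64, baseline_sd = 0.04,
                        elevation = 0.10, shared_elevation = 0.05,
                        elevations = NULL) {
  stopifnot(baseline_sd > 0)
  if (any(unlist(n) < 0)) abort("group sizes must be >= 0",
                                class = "cortexdti_parameter_error")
  if (is.null(elevations)) {
    shared <- setNames(rep(shared_elevation, 2),
                       c("precentral left", "precentral right"))
    elevations <- list(
      HS = setNames(numeric(0), character(0)),
      svPPA = c(setNames(rep(elevation, 4),
                         c("fusiform left", "entorhinal left",
                           "temporalpole right", "inferiortemporal right")), shared),
      bvFTD = c(setNames(rep(elevation, 2),
                         c("caudalanteriorcingulate left", "lingual right")), shared),
      nfvPPA = c(setNames(rep(elevation, 1), "parsopercularis left"), shared)
    )
  }
  all_regions <- dk_regions()$region
  for (g in names(elevations)) {
    bad <- setdiff(names(elevations[[g]]), all_regions)
    if (length(bad)) {
      abort(paste("unknown regions in elevation map:", paste(bad, collapse = ", ")),
            class = "cortexdti_parameter_error")
    }
  }
  structure(list(n = n, baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 elevations = elevations),
            class = "cohort_spec")
}

#' Names of the regional AngleR feature columns
#'
#' @return Character vector of 68 column names, e.g.
#'   `"angle_r_fusiform_left"`.
#' @export
regional_feature_names <- function() {
  paste0("angle_r_", gsub(" ", "_", dk_regions()$region))
}

#' Generate the synthetic selection / training / test cohorts
#'
#' Draws per-subject regional AngleR values as baseline + group elevation +
#' Gaussian noise, derives the whole-brain AngleR as the regional mean, and
#' adds the whole-brain diffusion, volumetric and clinical features with
#' group-dependent distributions patterned on the study demographics
#' (healthy MMSE ~ 29, patients ~ 21; lower grey-matter fraction and higher
#' MD/PerpPD in patients). Cohort membership is disjoint by construction
#' and the output is bit-reproducible under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed.
#' @return A tibble with one row per subject: `id`, `cohort`
#'   (selection/training/test), `diagnosis` (HS/bvFTD/svPPA/nfvPPA), `group`
#'   (HS/FTD), demographics (`age`, `sex`, `education`, `mmse`, `cdr`,
#'   `scanner`), whole-brain features (`angle_r_wb`, `perp_pd_wb`,
#'   `parl_pd_wb`, `md_wb`, `gm_fr`) and the 68 regional AngleR columns
#'   ([regional_feature_names()]).
#' @export
#' @examples
#' cohorts <- make_cohorts(seed = 1)
#' dplyr::count(cohorts, cohort, diagnosis)
make_cohorts <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  regions <- dk_regions()$region
  reg_cols <- regional_feature_names()
  # selection and test cohorts share a scanner; the training cohort uses a
  # second site, as in multi-site study designs
  scanner_of <- c(selection = "scanner_A", training = "scanner_B",
                  test = "scanner_A")

  rows <- list()
  sid <- 0L
  for (coh in names(spec$n)) {
    for (g in names(spec$n[[coh]])) {
      ng <- spec$n[[coh]][[g]]
      if (ng == 0) next
      elev <- rep(0, length(regions))
      emap <- spec$elevations[[g]]
      if (length(emap)) elev[match(names(emap), regions)] <- emap
      is_hs <- g == "HS"
      reg <- matrix(rnorm(ng * length(regions),
                          mean = rep(spec$baseline_mean + elev, each = ng),
                          sd = spec$baseline_sd),
                    nrow = ng)
      colnames(reg) <- reg_cols
      df <- tibble(
        id = sprintf("S%04d", sid + seq_len(ng)),
        cohort = coh,
        diagnosis = g,
        group = if (is_hs) "HS" else "FTD",
        age = rnorm(ng, 67.5, 6),
        sex = sample(c("F", "M"), ng, replace = TRUE),
        education = pmax(rnorm(ng, 14, 3), 5),
        mmse = pmin(pmax(rnorm(ng, if (is_hs) 28.8 else 21.2,
                               if (is_hs) 1.2 else 5.9), 0), 30),
        cdr = if (is_hs) rep(0, ng) else pmax(rnorm(ng, 0.75, 0.47), 0),
        scanner = scanner_of[[coh]],
        gm_fr = rnorm(ng, if (is_hs) 0.42 else 0.39, if (is_hs) 0.015 else 0.02),
        md_wb = rnorm(ng, if (is_hs) 0.85 else 0.92, if (is_hs) 0.04 else 0.05),
        perp_pd_wb = rnorm(ng, if (is_hs) 0.55 else 0.62, if (is_hs) 0.04 else 0.05),
        parl_pd_wb = rnorm(ng, if (is_hs) 0.95 else 0.93, 0.05),
        angle_r_wb = rowMeans(reg)
      )
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(df, as_tibble(reg))
      sid <- sid + ng
    }
  }
  if (!length(rows)) {
    cols <- c("id", "cohort", "diagnosis", "group", "age", "sex", "education",
              "mmse", "cdr", "scanner", "gm_fr", "md_wb", "perp_pd_wb",
              "parl_pd_wb", "angle_r_wb", reg_cols)
    return(as_tibble(setNames(rep(list(logical(0)), length(cols)), cols)))
  }
  dplyr::bind_rows(rows)
}
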