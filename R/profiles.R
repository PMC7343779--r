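#' Grey-matter ribbon label volume
#'
#' Holds the tissue segmentation and cortical parcellation the profile
#' generator works on. Tissue codes: 0 = other/background, 1 = white matter
#' (inner boundary), 2 = cortical grey matter, 3 = pial/outside (outer
#' boundary). GM voxels additionally carry an integer parcel code.
#'
#' @param tissue Integer 3-D array of tissue codes (0/1/2/3).
#' @param parcel Integer 3-D array of parcel codes (> 0 on GM voxels).
#' @param affine 4 x 4 voxel-to-world affine; the rotational part must be
#'   axis-aligned (diagonal up to sign), which covers phantom and
#'   conformed-space volumes.
#' @param region_lookup Tibble mapping `region_code` to `region` names;
#'   defaults to [dk_regions()].
#' @return A `ribbon_labels` object.
#' @export
ribbon_labels <- function(tissue, parcel, affine = diag(4),
                          region_lookup = dk_regions()) {
  stopifnot(length(dim(tissue)) == 3L, all(dim(parcel) == dim(tissue)))
  if (!all(tissue %in% 0:3)) {
    abort("tissue codes must be 0 (other), 1 (white), 2 (GM), 3 (pial)",
          class = "cortexdti_contract_error")
  }
  R <- affine[1:3, 1:3]
  if (any(abs(R[upper.tri(R)]) > 1e-8) || any(abs(R[lower.tri(R)]) > 1e-8)) {
    abort("ribbon affine must be axis-aligned (diagonal rotation part)",
          class = "cortexdti_contract_error")
  }
  gm <- tissue == 2L
  bad <- gm & (parcel <= 0L | is.na(parcel))
  if (any(bad)) {
    abort(sprintf("%d GM voxels lack a parcel code", sum(bad)),
          class = "cortexdti_contract_error")
  }
  structure(
    list(tissue = tissue, parcel = parcel, affine = affine,
         voxel_size = abs(diag(R)), region_lookup = region_lookup),
    class = "ribbon_labels"
  )
}

#' @export
print.ribbon_labels <- function(x, ...) {
  cat(sprintf("<ribbon_labels> %s grid, %d GM voxels, %d parcels, voxel %s mm\n",
              paste(dim(x$tissue), collapse = " x "), sum(x$tissue == 2L),
              length(unique(x$parcel[x$tissue == 2L])),
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Solve the Laplace potential across the cortical ribbon
#'
#' Solves Laplace's equation on the grey-matter shell with Dirichlet
#' boundary conditions 0 at the white interface and 1 at the pial interface
#' (Gauss-Seidel with over-relaxation). The resulting potential increases
#' monotonically from the inner to the outer boundary and its gradient
#' streamlines realise columnar trajectories through the cortex.
#'
#' GM voxels with no 6-connected path to both boundaries are flagged
#' unreachable and excluded; if more than `max_unreachable` of GM is
#' unreachable a topology warning is raised (escalated to an error when
#' `strict = TRUE`).
#'
#' @param ribbon A [ribbon_labels()] volume.
#' @param tol Convergence tolerance on the maximum per-sweep update.
#' @param max_iter Maximum Gauss-Seidel sweeps.
#' @param omega Over-relaxation factor in (0, 2).
#' @param max_unreachable Tolerated unreachable GM fraction (default 0.05).
#' @param strict Escalate the topology warning to an error.
#' @return A `ribbon_potential` object with the potential array (NA outside
#'   the solved domain), the unreachable mask, and solver diagnostics.
#' @export
solve_ribbon_potential <- function(ribbon, tol = 1e-6, max_iter = 20000L,
                                   omega = 1.8, max_unreachable = 0.05,
                                   strict = FALSE) {
  stopifnot(inherits(ribbon, "ribbon_labels"))
  if (tol <= 0) abort("tol must be > 0", class = "cortexdti_parameter_error")
  n_gm <- sum(ribbon$tissue == 2L)
  if (n_gm == 0L) {
    abort("no GM voxels in ribbon", class = "cortexdti_topology_error")
  }
  if (!any(ribbon$tissue == 1L) || !any(ribbon$tissue == 3L)) {
    abort("ribbon lacks white and/or pial boundary labels",
          class = "cortexdti_topology_error")
  }
  res <- .laplace_solve_cpp(as.integer(ribbon$tissue), dim(ribbon$tissue),
                            tol, as.integer(max_iter), omega)
  frac_unreachable <- sum(res$unreachable) / n_gm
  if (frac_unreachable > max_unreachable) {
    msg <- sprintf("%.1f%% of GM voxels cannot reach both boundaries",
                   100 * frac_unreachable)
    if (strict) abort(msg, class = "cortexdti_topology_error") else warn(msg)
  }
  if (frac_unreachable == 1) {
    abort("no GM voxel connects the white and pial boundaries",
          class = "cortexdti_topology_error")
  }
  structure(
    list(potential = res$potential, unreachable = res$unreachable,
         iterations = res$iterations, converged = res$converged,
         tol = tol, frac_unreachable = frac_unreachable),
    class = "ribbon_potential"
  )
}

#' @export
print.ribbon_potential <- function(x, ...) {
  cat(sprintf("<ribbon_potential> %d iterations, converged: %s, %.2f%% unreachable GM\n",
              x$iterations, x$converged, 100 * x$frac_unreachable))
  invisible(x)
}

#' Trace cortical profiles through the ribbon
#'
#' Follows the normalised gradient of the ribbon potential from every GM
#' voxel adjacent to the white boundary up to the pial surface with a fixed
#' physical step, giving one columnar profile per white-boundary voxel.
#' Profiles shorter than two steps, terminating at a zero gradient, or
#' exiting the volume are dropped (counts retained in the `dropped`
#' attribute). Each profile carries the parcel code of the majority of GM
#' voxels it traverses (ties broken toward the seed voxel's parcel).
#'
#' @param potential A `ribbon_potential` from [solve_ribbon_potential()].
#' @param ribbon The matching [ribbon_labels()].
#' @param step_h Step length in mm (default 0.5).
#' @param max_steps Safety cap on steps per profile.
#' @return A `cortical_profiles` object: `points` tibble (profile, step,
#'   world coordinates x/y/z in mm, unit tangent tx/ty/tz) and `info` tibble
#'   (profile, region_code, n_steps, length_mm).
#' @export
trace_profiles <- function(potential, ribbon, step_h = 0.5, max_steps = NULL) {
  stopifnot(inherits(potential, "ribbon_potential"), inherits(ribbon, "ribbon_labels"))
  if (step_h <= 0) abort("step_h must be > 0", class = "cortexdti_parameter_error")
  dims <- dim(ribbon$tissue)
  vs <- ribbon$voxel_size
  if (is.null(max_steps)) {
    max_steps <- ceiling(4 * sqrt(sum((dims * vs)^2)) / step_h)
  }

  # Seeds: reachable GM voxels 6-adjacent to white matter.
  gm_idx <- which(ribbon$tissue == 2L & !potential$unreachable, arr.ind = TRUE)
  if (nrow(gm_idx) == 0L) {
    abort("no seedable GM voxels", class = "cortexdti_topology_error")
  }
  adj_white <- vapply(seq_len(nrow(gm_idx)), function(r) {
    i <- gm_idx[r, 1]; j <- gm_idx[r, 2]; k <- gm_idx[r, 3]
    nb <- rbind(c(i + 1, j, k), c(i - 1, j, k), c(i, j + 1, k),
                c(i, j - 1, k), c(i, j, k + 1), c(i, j, k - 1))
    keep <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    any(ribbon$tissue[nb[keep, , drop = FALSE]] == 1L)
  }, logical(1))
  seeds_vox <- gm_idx[adj_white, , drop = FALSE]
  if (nrow(seeds_vox) == 0L) {
    abort("no GM voxel is adjacent to the white boundary",
          class = "cortexdti_topology_error")
  }

  tr <- .trace_streamlines_cpp(potential$potential, as.integer(ribbon$tissue),
                               dims, seeds_vox - 1, vs, step_h,
                               as.integer(max_steps))

  dropped <- c(short = 0L, zero_gradient = 0L, left_domain = 0L, truncated = 0L)
  keep <- logical(length(tr$flags))
  for (s in seq_along(tr$flags)) {
    np <- nrow(tr$paths[[s]])
    if (tr$flags[s] == 1L) dropped["zero_gradient"] <- dropped["zero_gradient"] + 1L
    else if (tr$flags[s] == 2L) dropped["left_domain"] <- dropped["left_domain"] + 1L
    else if (tr$flags[s] == 3L) dropped["truncated"] <- dropped["truncated"] + 1L
    else if (np < 2L) dropped["short"] <- dropped["short"] + 1L
    else keep[s] <- TRUE
  }

  kept_idx <- which(keep)
  pts_list <- vector("list", length(kept_idx))
  info_list <- vector("list", length(kept_idx))
  A <- ribbon$affine
  for (q in seq_along(kept_idx)) {
    s <- kept_idx[q]
    pv <- tr$paths[[s]]           # 0-based voxel coords
    world <- cbind(pv, 1) %*% t(A)
    world <- world[, 1:3, drop = FALSE]
    segs <- diff(world)
    seglen <- sqrt(rowSums(segs^2))
    tang <- segs / pmax(seglen, 1e-12)
    tang <- rbind(tang, tang[nrow(tang), , drop = FALSE])  # repeat last
    np <- nrow(world)

    # Majority parcel over traversed GM voxels, ties toward the seed's parcel.
    vox <- round(pv) + 1
    vox[, 1] <- pmin(pmax(vox[, 1], 1), dims[1])
    vox[, 2] <- pmin(pmax(vox[, 2], 1), dims[2])
    vox[, 3] <- pmin(pmax(vox[, 3], 1), dims[3])
    lin <- vox[, 1] + dims[1] * (vox[, 2] - 1) + dims[1] * dims[2] * (vox[, 3] - 1)
    is_gm <- ribbon$tissue[lin] == 2L
    parcels <- ribbon$parcel[lin[is_gm]]
    seed_parcel <- ribbon$parcel[lin[1]]
    if (length(parcels) == 0L) {
      region_code <- seed_parcel
    } else {
      tab <- table(parcels)
      winners <- as.integer(names(tab)[tab == max(tab)])
      region_code <- if (seed_parcel %in% winners) seed_parcel else winners[1L]
    }

    pts_list[[q]] <- tibble(
      profile = q, step = seq_len(np) - 1L,
      x = world[, 1], y = world[, 2], z = world[, 3],
      tx = tang[, 1], ty = tang[, 2], tz = tang[, 3]
    )
    info_list[[q]] <- tibble(
      profile = q, region_code = as.integer(region_code),
      n_steps = np, length_mm = sum(seglen)
    )
  }

  structure(
    list(points = dplyr::bind_rows(pts_list), info = dplyr::bind_rows(info_list),
         step_h = step_h, dropped = dropped,
         region_lookup = ribbon$region_lookup),
    class = "cortical_profiles"
  )
}

#' @export
print.cortical_profiles <- function(x, ...) {
  cat(sprintf("<cortical_profiles> %d profiles, step %.2f mm, mean length %.2f mm (%d dropped)\n",
              nrow(x$info), x$step_h, mean(x$info$length_mm), sum(x$dropped)))
  invisible(x)
}

#' Radiality angle between principal diffusion direction and profile tangent
#'
#' AngleR = arccos(|e1 . p|): the angle between the tensor's principal
#' eigenvector and the local profile tangent, folded into \[0, pi/2\] so the
#' eigenvector's arbitrary sign cannot matter. Inputs are recycled row-wise.
#'
#' @param e1 Unit principal eigenvector (length-3 vector or n x 3 matrix).
#' @param tangent Unit profile tangent (length-3 vector or n x 3 matrix).
#' @return Angle(s) in radians in \[0, pi/2\].
#' @export
#' @examples
#' angle_r(c(1, 0, 0), c(0, 1, 0))  # pi/2
angle_r <- function(e1, tangent) {
  e1 <- if (is.matrix(e1)) e1 else matrix(e1, ncol = 3L, byrow = TRUE)
  tangent <- if (is.matrix(tangent)) tangent else matrix(tangent, ncol = 3L, byrow = TRUE)
  n1 <- sqrt(rowSums(e1^2)); n2 <- sqrt(rowSums(tangent^2))
  if (any(n1 < 1e-12) || any(n2 < 1e-12)) {
    abort("zero-length direction passed to angle_r", class = "cortexdti_contract_error")
  }
  if (any(abs(n1 - 1) > 1e-6) || any(abs(n2 - 1) > 1e-6)) {
    abort("angle_r expects unit-norm inputs", class = "cortexdti_contract_error")
  }
  d <- abs(rowSums(e1 * tangent))
  out <- acos(pmin(pmax(d, 0), 1))
  if (length(out) == 1L) out[[1L]] else out
}

#' Perpendicular and parallel components of the principal diffusion component
#'
#' Decomposes the principal diffusion component lambda1 * e1 relative to the
#' profile tangent: PerpPD = lambda1 * sin(angle) onto the perpendicular
#' plane, ParlPD = lambda1 * cos(angle) onto the profile. Values are
#' reported on the conventional 1e-3 mm^2/s scale.
#'
#' @param lambda1 Principal eigenvalue(s) in mm^2/s (>= 0).
#' @param angle Radiality angle(s) in radians, in \[0, pi/2\].
#' @return Tibble with columns `perp_pd` and `parl_pd` (units 1e-3 mm^2/s);
#'   at every sample perp_pd^2 + parl_pd^2 = (1e3 * lambda1)^2.
#' @export
#' @examples
#' perp_parl(1e-3, pi / 4)  # both components 0.7071
perp_parl <- function(lambda1, angle) {
  if (any(lambda1 < 0)) {
    abort("negative principal eigenvalue: degenerate voxel",
          class = "cortexdti_degenerate_voxel_error")
  }
  if (any(angle < -1e-12 | angle > pi / 2 + 1e-12)) {
    abort("angle outside [0, pi/2]", class = "cortexdti_contract_error")
  }
  s <- 1e3 * lambda1
  tibble(perp_pd = s * sin(angle), parl_pd = s * cos(angle))
}

#' Sample tensor metrics along cortical profiles
#'
#' At each profile point the tensor is looked up (nearest voxel by default,
#' optional component-wise trilinear interpolation), its eigensystem taken,
#' and AngleR/PerpPD/ParlPD/MD/FA evaluated against the local tangent. Each
#' metric is averaged over the profile's usable samples: voxels flagged
#' degenerate in the tensor fit are skipped entirely, and samples whose
#' principal direction is numerically degenerate (lambda1 ~ lambda2)
#' contribute to MD/FA but are excluded from the angle-derived metrics.
#'
#' @param profiles A `cortical_profiles` object.
#' @param tensors A [tensor_field()] covering the profile extent.
#' @param lookup `"nearest"` (default) or `"trilinear"` tensor lookup;
#'   nearest avoids blending orientations across tissue boundaries.
#' @param keep_samples Also return the per-sample table (for auditing).
#' @return A `profile_metrics` tibble: one row per profile with columns
#'   `profile`, `region_code`, `angle_r` (radians), `perp_pd`, `parl_pd`,
#'   `md` (all 1e-3 mm^2/s), `fa`, `n_samples` (usable samples) and
#'   `n_angle_samples`. Profiles with no usable samples carry NA metrics.
#' @export
sample_profile_metrics <- function(profiles, tensors,
                                   lookup = c("nearest", "trilinear"),
                                   keep_samples = FALSE) {
  stopifnot(inherits(profiles, "cortical_profiles"), inherits(tensors, "tensor_field"))
  lookup <- match.arg(lookup)
  dims <- dim(tensors$D)[1:3]
  Ainv <- solve(tensors$affine)
  pts <- profiles$points
  vox <- cbind(pts$x, pts$y, pts$z, 1) %*% t(Ainv)  # 0-based voxel coords

  if (lookup == "nearest") {
    iv <- round(vox[, 1]) + 1; jv <- round(vox[, 2]) + 1; kv <- round(vox[, 3]) + 1
    inside <- iv >= 1 & jv >= 1 & kv >= 1 & iv <= dims[1] & jv <= dims[2] & kv <= dims[3]
    lin <- rep(NA_integer_, nrow(pts))
    lin[inside] <- iv[inside] + dims[1] * (jv[inside] - 1) + dims[1] * dims[2] * (kv[inside] - 1)
    nvox <- prod(dims)
    Dflat <- matrix(tensors$D, nrow = nvox)
    ok <- inside & !is.na(lin) & tensors$mask[pmax(lin, 1)] & !tensors$degenerate[pmax(lin, 1)]
    ok[!inside] <- FALSE
    D6 <- matrix(NA_real_, nrow(pts), 6L)
    D6[ok, ] <- Dflat[lin[ok], , drop = FALSE]
  } else {
    D6 <- trilinear_tensor(tensors, vox[, 1:3, drop = FALSE])
    ok <- !is.na(D6[, 1])
  }

  # Eigensystem per usable sample; cache by voxel for the nearest lookup.
  n <- nrow(pts)
  lam <- matrix(NA_real_, n, 3L)
  e1 <- matrix(NA_real_, n, 3L)
  degdir <- rep(FALSE, n)
  if (lookup == "nearest") {
    ulin <- unique(lin[ok])
    cache_ev <- matrix(NA_real_, length(ulin), 3L)
    cache_e1 <- matrix(NA_real_, length(ulin), 3L)
    cache_dd <- logical(length(ulin))
    for (u in seq_along(ulin)) {
      es <- eigensystem(Dflat[ulin[u], ])
      cache_ev[u, ] <- es$evals
      cache_e1[u, ] <- es$evecs[, 1]
      cache_dd[u] <- es$degenerate_direction
    }
    pos <- match(lin, ulin)
    sel <- ok & !is.na(pos)
    lam[sel, ] <- cache_ev[pos[sel], , drop = FALSE]
    e1[sel, ] <- cache_e1[pos[sel], , drop = FALSE]
    degdir[sel] <- cache_dd[pos[sel]]
  } else {
    for (r in which(ok)) {
      es <- eigensystem(D6[r, ])
      lam[r, ] <- es$evals
      e1[r, ] <- es$evecs[, 1]
      degdir[r] <- es$degenerate_direction
    }
  }

  usable <- ok & !is.na(lam[, 1]) & lam[, 3] >= 0
  tang <- cbind(pts$tx, pts$ty, pts$tz)
  ang <- rep(NA_real_, n)
  if (any(usable)) {
    d <- abs(rowSums(e1[usable, , drop = FALSE] * tang[usable, , drop = FALSE]))
    ang[usable] <- acos(pmin(pmax(d, 0), 1))
  }
  md <- rep(NA_real_, n); fa <- rep(NA_real_, n)
  md[usable] <- 1e3 * mean_diffusivity(lam[usable, , drop = FALSE])
  fa[usable] <- fractional_anisotropy(lam[usable, , drop = FALSE])
  perp <- 1e3 * lam[, 1] * sin(ang)
  parl <- 1e3 * lam[, 1] * cos(ang)

  samples <- tibble(
    profile = pts$profile, step = pts$step,
    usable = usable, angle_usable = usable & !degdir,
    lambda1 = lam[, 1], angle_r = ang, perp_pd = perp, parl_pd = parl,
    md = md, fa = fa
  )

  per_profile <- samples |>
    dplyr::group_by(.data$profile) |>
    dplyr::summarise(
      angle_r = mean(.data$angle_r[.data$angle_usable]),
      perp_pd = mean(.data$perp_pd[.data$angle_usable]),
      parl_pd = mean(.data$parl_pd[.data$angle_usable]),
      md = mean(.data$md[.data$usable]),
      fa = mean(.data$fa[.data$usable]),
      n_samples = sum(.data$usable),
      n_angle_samples = sum(.data$angle_usable),
      .groups = "drop"
    ) |>
    dplyr::left_join(profiles$info[, c("profile", "region_code")], by = "profile") |>
    dplyr::relocate("region_code", .after = "profile")

  out <- tibble::new_tibble(per_profile, class = "profile_metrics")
  attr(out, "region_lookup") <- profiles$region_lookup
  if (keep_samples) attr(out, "samples") <- samples
  out
}

# Component-wise trilinear tensor interpolation; NA where any needed voxel is
# unfitted or degenerate.
trilinear_tensor <- function(tensors, vox) {
  dims <- dim(tensors$D)[1:3]
  nvox <- prod(dims)
  Dflat <- matrix(tensors$D, nrow = nvox)
  okvox <- as.vector(tensors$mask & !tensors$degenerate)
  out <- matrix(NA_real_, nrow(vox), 6L)
  i0 <- floor(vox[, 1]); j0 <- floor(vox[, 2]); k0 <- floor(vox[, 3])
  fx <- vox[, 1] - i0; fy <- vox[, 2] - j0; fz <- vox[, 3] - k0
  acc <- matrix(0, nrow(vox), 6L); wsum <- rep(0, nrow(vox))
  bad <- rep(FALSE, nrow(vox))
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    i <- i0 + di + 1; j <- j0 + dj + 1; k <- k0 + dk + 1
    inb <- i >= 1 & j >= 1 & k >= 1 & i <= dims[1] & j <= dims[2] & k <= dims[3]
    w <- (if (di == 1) fx else 1 - fx) *
      (if (dj == 1) fy else 1 - fy) *
      (if (dk == 1) fz else 1 - fz)
    lin <- ifelse(inb, i + dims[1] * (j - 1) + dims[1] * dims[2] * (k - 1), 1L)
    use <- inb & w > 0 & okvox[lin]
    use[is.na(use)] <- FALSE
    bad <- bad | (inb & w > 1e-12 & !use)
    if (any(use)) {
      acc[use, ] <- acc[use, , drop = FALSE] + w[use] * Dflat[lin[use], , drop = FALSE]
      wsum[use] <- wsum[use] + w[use]
    }
  }
  sel <- wsum > 0 & !bad
  out[sel, ] <- acc[sel, , drop = FALSE] / wsum[sel]
  out
}

#' Aggregate profile metrics to regional and whole-brain values
#'
#' Region value = unweighted mean over the region's per-profile means;
#' whole-brain value = by default the unweighted mean over all per-profile
#' means (a flag switches to averaging the region means instead). Regions
#' present in the lookup but hit by no profile are reported with NA values,
#' never silently imputed.
#'
#' @param metrics A `profile_metrics` tibble from [sample_profile_metrics()].
#' @param subject Subject identifier stamped into the output (default NA).
#' @param region_lookup Region code/name table; defaults to the lookup
#'   carried by `metrics`, falling back to [dk_regions()].
#' @param whole_brain `"profiles"` (mean of all profile means, default) or
#'   `"regions"` (mean of region means).
#' @return A `region_features` tibble in long format: `subject`, `metric`
#'   (angle_r/perp_pd/parl_pd/md/fa), `region` (including `"whole brain"`),
#'   `value`, `n_profiles`.
#' @export
aggregate_regions <- function(metrics, subject = NA_character_,
                              region_lookup = NULL,
                              whole_brain = c("profiles", "regions")) {
  whole_brain <- match.arg(whole_brain)
  if (nrow(metrics) == 0L) {
    abort("no profile metrics to aggregate", class = "cortexdti_empty_table_error")
  }
  region_lookup <- region_lookup %||% attr(metrics, "region_lookup") %||% dk_regions()

  long <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(c("angle_r", "perp_pd", "parl_pd", "md", "fa")),
                        names_to = "metric", values_to = "value")

  by_region <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$metric, .data$region_code) |>
    dplyr::summarise(value = mean(.data$value), n_profiles = dplyr::n(), .groups = "drop")

  full <- tidyr::expand_grid(
    metric = c("angle_r", "perp_pd", "parl_pd", "md", "fa"),
    region_code = region_lookup$region_code
  ) |>
    dplyr::left_join(by_region, by = c("metric", "region_code")) |>
    dplyr::mutate(
      region = region_name(.data$region_code, region_lookup),
      n_profiles = dplyr::coalesce(.data$n_profiles, 0L)
    )

  wb <- long |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$metric)
  wb <- if (whole_brain == "profiles") {
    dplyr::summarise(wb, value = mean(.data$value), n_profiles = dplyr::n(), .groups = "drop")
  } else {
    by_region |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(value = mean(.data$value), n_profiles = sum(.data$n_profiles),
                       .groups = "drop")
  }
  wb$region <- "whole brain"
  wb$region_code <- NA_integer_

  out <- dplyr::bind_rows(full, wb) |>
    dplyr::mutate(subject = subject) |>
    dplyr::select("subject", "metric", "region", "region_code", "value", "n_profiles") |>
    dplyr::arrange(.data$metric, !is.na(.data$region_code), .data$region_code)
  tibble::new_tibble(out, class = "region_features")
}
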