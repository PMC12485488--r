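#' Radial density profile about the helical axis
#'
#' Averages voxel values in cylindrical shells of one-voxel width around
#' the central axis, over all slices. The profile is the basis for the
#' radius estimate that scales the vector comparison metric and positions
#' the unwrapping band.
#'
#' @param map Axis-normalized [density_map()] with the helix on Z.
#' @return data.frame with columns `radius` (A, shell centers starting at
#'   0) and `mean_density`.
#' @export
radial_profile <- function(map) {
  stopifnot(inherits(map, "density_map"))
  .assert_standard_axes(map)
  d <- dim(map$data)
  cx <- d[1] / 2; cy <- d[2] / 2
  x <- seq_len(d[1]) - 1 - cx
  y <- seq_len(d[2]) - 1 - cy
  rv <- round(sqrt(outer(x^2, y^2, `+`)))     # shell index per (x, y) column
  L <- floor(min(d[1], d[2]) / 2)
  keep <- rv <= L - 1
  shell <- factor(rv[keep] + 1L, levels = seq_len(L))
  flat <- matrix(map$data, d[1] * d[2], d[3])[keep, , drop = FALSE]
  sums_xy <- rowSums(flat, na.rm = TRUE)
  cnt_xy <- rowSums(!is.na(flat))
  sums <- as.vector(tapply(sums_xy, shell, sum, default = 0))
  cnts <- as.vector(tapply(cnt_xy, shell, sum, default = 0))
  data.frame(radius = (seq_len(L) - 1) * map$voxel_size,
             mean_density = ifelse(cnts > 0, sums / cnts, 0))
}

#' Estimate the helical radius from a radial profile
#'
#' Density-weighted mean radius over the shells whose mean density exceeds
#' half of the profile maximum. This estimator is robust to the difference
#' between hollow tubes and solid filaments and is invariant to positive
#' intensity rescaling.
#'
#' @param profile Output of [radial_profile()].
#' @param threshold Fraction of the profile maximum defining the
#'   contributing shells (default 0.5).
#' @return Radius in Angstrom.
#' @export
estimate_radius <- function(profile, threshold = 0.5) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0)
  v <- profile$mean_density
  if (max(v, na.rm = TRUE) <= 0)
    stop("empty map: radial profile has no positive density")
  keep <- !is.na(v) & v >= threshold * max(v, na.rm = TRUE)
  sum(profile$radius[keep] * v[keep]) / sum(v[keep])
}

#' Cylindrical projection (unwrapping) of a helical map
#'
#' Samples the map on a band of cylinders around the helical axis and
#' averages over the band, producing a 2D (azimuth x height) image in
#' which the helical structure appears as a 2D lattice. Default sampling
#' is 1 degree / 1 Angstrom; for amyloid-like symmetries with small twist
#' and rise a finer 0.5 degree / 0.2 Angstrom sampling is used.
#'
#' @param map Axis-normalized [density_map()].
#' @param radius_band Length-2 numeric, inner and outer radius in A; must
#'   lie inside the grid.
#' @param angular_step Azimuthal sampling in degrees.
#' @param axial_step Axial sampling in Angstrom.
#' @return Object of class `cylindrical_projection`: list with `image`
#'   (matrix, azimuth x height), the steps, and the band.
#' @export
cylindrical_projection <- function(map, radius_band, angular_step = 1,
                                   axial_step = 1) {
  stopifnot(inherits(map, "density_map"),
            length(radius_band) == 2L, all(radius_band > 0),
            diff(radius_band) >= 0, angular_step > 0, axial_step > 0)
  .assert_standard_axes(map)
  d <- dim(map$data)
  vox <- map$voxel_size
  max_r <- (min(d[1], d[2]) / 2 - 1) * vox
  if (radius_band[2] > max_r)
    stop("radius band extends outside the grid (max ", signif(max_r, 4), " A)")
  nphi <- round(360 / angular_step)
  phi <- (seq_len(nphi) - 1) * 360 / nphi
  nz <- floor((d[3] - 1) * vox / axial_step) + 1L
  z <- (seq_len(nz) - 1) * axial_step
  nr <- max(3L, round(diff(radius_band) / vox) + 1L)
  radii <- seq(radius_band[1], radius_band[2], length.out = nr)
  cx <- d[1] / 2; cy <- d[2] / 2
  img <- matrix(0, nphi, nz)
  cnt <- matrix(0, nphi, nz)
  cp <- cospi(phi / 180); sp <- sinpi(phi / 180)
  zi <- rep(z / vox, each = nphi)
  for (r in radii) {
    xi <- rep(cx + r / vox * cp, times = nz)
    yi <- rep(cy + r / vox * sp, times = nz)
    v <- .interp_trilinear(map$data, xi, yi, zi)
    ok <- !is.na(v)
    img <- img + matrix(ifelse(ok, v, 0), nphi, nz)
    cnt <- cnt + matrix(as.numeric(ok), nphi, nz)
  }
  img <- ifelse(cnt > 0, img / cnt, 0)
  structure(list(image = img, angular_step = 360 / nphi,
                 axial_step = axial_step, radius_band = radius_band),
            class = "cylindrical_projection")
}

#' Normalized 2D autocorrelation of a cylindrical projection
#'
#' Mean-subtracted autocorrelation, periodic (wrap-around) in azimuth and
#' zero-padded along the axis, normalized per axial lag by the overlap
#' length so that the value at the origin is exactly 1. Axial lags are
#' restricted to half the axial extent, where the overlap is at least 50%.
#'
#' @param proj A [cylindrical_projection()].
#' @return Object of class `lattice_autocorrelation`: `surface` (matrix
#'   indexed by azimuth lag x axial lag), `phi_lags` (deg, ascending,
#'   spanning (-180, 180]), `z_lags` (A, ascending), and the sampling
#'   steps.
#' @export
autocorrelate <- function(proj) {
  stopifnot(inherits(proj, "cylindrical_projection"))
  A <- proj$image - mean(proj$image)
  nphi <- nrow(A); nz <- ncol(A)
  P <- matrix(0, nphi, 2L * nz)
  P[, seq_len(nz)] <- A
  F <- stats::fft(P)
  ac <- Re(stats::fft(Mod(F)^2, inverse = TRUE)) / length(P)
  zl <- floor(nz / 2)
  dz <- seq.int(-zl, zl)
  zcols <- ifelse(dz >= 0, dz + 1L, 2L * nz + dz + 1L)
  overlap <- nz - abs(dz)
  cov0 <- ac[1, 1] / (nphi * nz)
  surf <- sweep(ac[, zcols, drop = FALSE], 2, nphi * overlap, `/`) / cov0
  lag_deg <- wrap_twist((seq_len(nphi) - 1) * proj$angular_step)
  ord <- order(lag_deg)
  structure(list(surface = surf[ord, , drop = FALSE],
                 phi_lags = lag_deg[ord],
                 z_lags = dz * proj$axial_step,
                 angular_step = proj$angular_step,
                 axial_step = proj$axial_step),
            class = "lattice_autocorrelation")
}

# Quadratic (3-point parabola) sub-grid refinement of a peak position.
.refine_parabolic <- function(vm, v0, vp) {
  den <- vm - 2 * v0 + vp
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
}

#' Find lattice peaks on an autocorrelation surface
#'
#' Local maxima (8-neighborhood; azimuth wraps) above a relative score
#' floor, excluding the origin cell, with greedy non-maximum suppression
#' and sub-grid parabolic refinement of position and score. Peaks are
#' sorted by |axial lag| then |azimuth lag|.
#'
#' @param acf A [autocorrelate()] surface.
#' @param score_floor Minimum score relative to the origin value
#'   (default 0.25).
#' @param min_separation Minimum peak separation in grid cells (default 2).
#' @return data.frame with columns `phi` (deg), `z` (A), `score`. Empty if
#'   nothing qualifies; downstream callers treat that as "not validated".
#' @export
find_lattice_peaks <- function(acf, score_floor = 0.25, min_separation = 2L) {
  stopifnot(inherits(acf, "lattice_autocorrelation"))
  S <- acf$surface
  nphi <- nrow(S); nzc <- ncol(S)
  up <- S[c(nphi, seq_len(nphi - 1L)), , drop = FALSE]
  dn <- S[c(2:nphi, 1L), , drop = FALSE]
  shift_z <- function(M, by) {
    out <- matrix(-Inf, nphi, nzc)
    if (by > 0) out[, (1 + by):nzc] <- M[, seq_len(nzc - by)]
    else out[, seq_len(nzc + by)] <- M[, (1 - by):nzc]
    out
  }
  is_max <- S > up & S >= dn
  for (bz in c(-1L, 1L)) {
    is_max <- is_max & S >= shift_z(S, bz) & S >= shift_z(up, bz) &
      S >= shift_z(dn, bz)
  }
  is_max[, c(1L, nzc)] <- FALSE
  origin_phi <- which.min(abs(acf$phi_lags))
  origin_z <- which.min(abs(acf$z_lags))
  is_max[origin_phi, origin_z] <- FALSE
  is_max <- is_max & S >= score_floor
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(phi = numeric(0), z = numeric(0), score = numeric(0)))
  sc <- S[idx]
  ord <- order(-sc)
  idx <- idx[ord, , drop = FALSE]; sc <- sc[ord]
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    prev <- idx[keep, , drop = FALSE]
    dphi <- abs(prev[, 1] - idx[i, 1])
    dphi <- pmin(dphi, nphi - dphi)
    keep[i] <- all(pmax(dphi, abs(prev[, 2] - idx[i, 2])) >= min_separation)
  }
  idx <- idx[keep, , drop = FALSE]; sc <- sc[keep]
  phi <- numeric(nrow(idx)); z <- numeric(nrow(idx)); val <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    ip <- idx[i, 1]; iz <- idx[i, 2]
    ipm <- if (ip == 1L) nphi else ip - 1L
    ipp <- if (ip == nphi) 1L else ip + 1L
    dp <- .refine_parabolic(S[ipm, iz], S[ip, iz], S[ipp, iz])
    dzz <- if (iz > 1L && iz < nzc)
      .refine_parabolic(S[ip, iz - 1L], S[ip, iz], S[ip, iz + 1L]) else 0
    phi[i] <- wrap_twist(acf$phi_lags[ip] + dp * acf$angular_step)
    z[i] <- acf$z_lags[iz] + dzz * acf$axial_step
    val[i] <- min(1, max(-1, sc[i]))  # overlap renormalization can overshoot
  }
  out <- data.frame(phi = phi, z = z, score = val)
  out[order(abs(out$z), abs(out$phi)), , drop = FALSE]
}

#' Detect the axial (cyclic) symmetry order of a map
#'
#' Correlates the cylindrical projection with azimuthally rotated copies
#' of itself at the candidate Cn angles (all multiples of 360/n) and
#' accepts the largest order whose mean rotational self-correlation
#' clearly exceeds the generic decorrelation baseline. Returns 1 when no
#' order qualifies. Invariant to intensity scaling of the map.
#'
#' @param map Axis-normalized [density_map()].
#' @param max_csym Largest order searched (default 12).
#' @param min_score Absolute acceptance floor on the mean rotational
#'   correlation (default 0.5).
#' @param margin Required excess over the baseline, the median correlation
#'   across all tested rotations (default 0.25).
#' @param proj Optional precomputed [cylindrical_projection()] to reuse.
#' @return Integer symmetry order (>= 1).
#' @export
detect_csym <- function(map, max_csym = 12L, min_score = 0.5,
                        margin = 0.25, proj = NULL) {
  if (is.null(proj)) {
    prof <- radial_profile(map)
    r <- estimate_radius(prof)
    proj <- cylindrical_projection(map, c(0.7 * r, 1.3 * r))
  }
  # center each slice so that empty or azimuthally uniform slices do not
  # inflate the correlation at every rotation angle
  A <- sweep(proj$image, 2, colMeans(proj$image))
  nphi <- nrow(A)
  rot_cor <- local({
    cache <- new.env()
    function(deg) {
      key <- sprintf("%.6f", deg %% 360)
      if (!is.null(cache[[key]])) return(cache[[key]])
      sh <- (deg %% 360) / proj$angular_step
      s0 <- floor(sh); f <- sh - s0
      roll <- function(by) A[((seq_len(nphi) - 1 - by) %% nphi) + 1L, ,
                             drop = FALSE]
      B <- (1 - f) * roll(s0) + f * roll(s0 + 1)
      v <- stats::cor(as.vector(A), as.vector(B))
      cache[[key]] <- v
      v
    }
  })
  ns <- 2:max_csym
  scores <- vapply(ns, function(n) {
    mean(vapply(seq_len(n - 1L), function(k) rot_cor(k * 360 / n), 0))
  }, 0)
  all_angles <- unique(unlist(lapply(ns, function(n)
    (seq_len(n - 1L) * 360 / n) %% 360)))
  baseline <- stats::median(vapply(all_angles, rot_cor, 0))
  ok <- scores >= pmax(min_score, baseline + margin)
  if (!any(ok)) return(1L)
  best <- max(scores[ok])
  max(ns[ok & scores >= best - 0.05])
}

#' Determine helical parameters from a density map
#'
#' The full map-driven indexing chain: radius estimate, cylindrical
#' unwrapping over a band around the estimated radius, 2D lattice
#' autocorrelation, and selection of the lattice point closest to the
#' equator (excluding a band of one axial step, or one voxel if larger,
#' around it) as the optimal
#' twist/rise. Ties in axial distance are broken by the higher correlation
#' score, then by the smaller azimuthal lag; a candidate is only accepted
#' when its low-order harmonics are also present on the surface, which
#' rejects spurious cross-correlation peaks that do not belong to the
#' lattice. The selected parameters are then sharpened against the
#' farthest peak on the same lattice line. The twist sign is read from
#' the peak in the positive axial half-plane. Axial symmetry is detected
#' separately by [detect_csym()].
#'
#' @param map Axis-normalized [density_map()] with the helix on Z.
#' @param angular_step Azimuthal sampling, degrees (default 1; use 0.5 for
#'   amyloid-like maps).
#' @param axial_step Axial sampling, Angstrom (default 1; use 0.2 for
#'   amyloid-like maps).
#' @param radius_band Optional explicit unwrapping band (A); by default
#'   `[0.7, 1.3] *` the estimated radius.
#' @param score_floor Relative peak score floor (default 0.25).
#' @param with_csym Also run the Cn search (default TRUE).
#' @return Object of class `indexing_result`: `params`
#'   ([helical_params()]), `peak` (azimuth deg, height A), `peak_score`,
#'   `lattice` (all detected peaks), `radius` (A), and the sampling steps.
#'   Throws an error of class `helixvalid_indexing_failed` when no lattice
#'   peak qualifies.
#' @export
index_helical_params <- function(map, angular_step = 1, axial_step = 1,
                                 radius_band = NULL, score_floor = 0.25,
                                 with_csym = TRUE) {
  stopifnot(inherits(map, "density_map"))
  .assert_standard_axes(map)
  prof <- radial_profile(map)
  r <- estimate_radius(prof)
  if (is.null(radius_band)) {
    max_r <- (min(dim(map$data)[1:2]) / 2 - 1) * map$voxel_size
    radius_band <- c(0.7 * r, min(1.3 * r, max_r))
  }
  proj <- cylindrical_projection(map, radius_band, angular_step, axial_step)
  acf <- autocorrelate(proj)
  peaks <- find_lattice_peaks(acf, score_floor = score_floor)
  # a rise below one voxel is not resolvable regardless of the sampling
  excl <- max(axial_step, map$voxel_size)
  cand <- peaks[abs(peaks$z) > excl, , drop = FALSE]
  if (nrow(cand) == 0L) {
    stop(structure(
      class = c("helixvalid_indexing_failed", "error", "condition"),
      list(message = "indexing failed: no lattice peak off the equator",
           call = sys.call())))
  }
  # candidate order: closest to the equator first; peaks within one axial
  # step of each other are unresolvable ties, broken by score then |phi|
  step_group <- round(abs(cand$z) / axial_step)
  cand <- cand[order(step_group, -cand$score, abs(cand$phi)), , drop = FALSE]
  zwin <- max(abs(acf$z_lags))
  # a genuine fundamental has its low-order harmonics (i*twist, i*rise) on
  # the surface, and cannot score clearly below them: at a true lattice
  # vector the full pattern overlaps, while at a spurious sub-period only
  # part of it does
  lattice_supported <- function(t, z, score) {
    for (i in 2:3) {
      if (i * z > zwin) break
      tol_z <- i * axial_step / 2 + axial_step
      tol_p <- i * angular_step / 2 + angular_step
      hit <- abs(abs(cand$z) - i * z) <= tol_z &
        abs(wrap_twist(sign(cand$z) * cand$phi - i * t)) <= tol_p
      if (!any(hit)) return(FALSE)
      if (max(cand$score[hit]) > score + 0.1) return(FALSE)
    }
    TRUE
  }
  best <- NULL
  for (j in seq_len(nrow(cand))) {
    p <- cand[j, ]
    if (p$z < 0) { p$phi <- -p$phi; p$z <- -p$z }
    if (lattice_supported(p$phi, p$z, p$score)) { best <- p; break }
  }
  if (is.null(best)) {
    best <- cand[1, ]
    if (best$z < 0) { best$phi <- -best$phi; best$z <- -best$z }
  }
  # sharpen twist/rise against the farthest peak on the same lattice line:
  # the quantization error of a peak at level i shrinks i-fold on division
  twist <- best$phi; rise <- best$z
  ii <- round(cand$z / rise)
  pred_err <- abs(wrap_twist(cand$phi - ii * twist))
  match_ok <- ii >= 2 &
    abs(cand$z - ii * rise) <= abs(ii) * axial_step / 2 + axial_step &
    pred_err <= abs(ii) * angular_step / 2 + angular_step &
    cand$score >= best$score / 2
  if (any(match_ok)) {
    far <- cand[match_ok, , drop = FALSE][which.max(ii[match_ok]), ]
    i <- round(far$z / rise)
    k <- round((i * twist - far$phi) / 360)
    twist <- (far$phi + 360 * k) / i
    rise <- far$z / i
  }
  csym <- if (with_csym) detect_csym(map, proj = proj) else 1L
  structure(
    list(params = helical_params(wrap_twist(twist), rise, csym),
         peak = c(azimuth = best$phi, height = best$z),
         peak_score = best$score,
         lattice = peaks, radius = r,
         angular_step = angular_step, axial_step = axial_step),
    class = "indexing_result")
}

#' @export
print.indexing_result <- function(x, ...) {
  cat("map-derived helical parameters", format(x$params), "\n")
  cat(sprintf("  lattice peak at (%.3f deg, %.3f A), score %.3f; radius %.1f A\n",
              x$peak[1], x$peak[2], x$peak_score, x$radius))
  cat(sprintf("  sampling: %.2f deg / %.2f A; %d peaks detected\n",
              x$angular_step, x$axial_step, nrow(x$lattice)))
  invisible(x)
}
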