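#' Normalized twist and rise differences
#'
#' The first of the three comparison metrics between a deposited and a
#' map-derived parameter set: each parameter difference normalized by the
#' larger of the two magnitudes, so that e.g. a sign-flipped twist of
#' identical magnitude yields a twist difference of exactly 2. Treats
#' twist and rise separately and ignores the helix radius, so it is mainly
#' a screening quantity.
#'
#' @param p_dep,p_val Two [helical_params()] objects (the metric is
#'   symmetric in its arguments).
#' @param eps Guard for near-zero twists (degrees, default 1e-3).
#' @return List with `delta_twist` and `delta_rise`, both dimensionless
#'   and >= 0.
#' @export
normalized_difference <- function(p_dep, p_val, eps = 1e-3) {
  stopifnot(inherits(p_dep, "helical_params"), inherits(p_val, "helical_params"))
  list(
    delta_twist = abs(wrap_twist(p_dep$twist - p_val$twist)) /
      max(abs(p_dep$twist), abs(p_val$twist), eps),
    delta_rise = abs(p_dep$rise - p_val$rise) / max(p_dep$rise, p_val$rise)
  )
}

#' Radius-aware vector difference between parameter sets
#'
#' Embeds each helical parameter set as the 3D displacement of a point at
#' radius `r` under one symmetry step — the chord
#' `(r cos(theta) - r, r sin(theta), z)` — and reports the Euclidean
#' distance between the two displacement vectors, in Angstrom. Two sets
#' are flagged `similar` when the distance is smaller than the reported
#' resolution: differences below the resolution are not resolvable in the
#' map. Note the documented insensitivity to the twist sign at small
#' twists: +0.4 vs -0.4 degrees at r = 50 A differ by only ~0.7 A.
#'
#' @param p_dep,p_val Two [helical_params()] objects.
#' @param radius Helix radius in Angstrom (> 0), typically from
#'   [estimate_radius()] of the actual map.
#' @param resolution Reported resolution in Angstrom used for the
#'   `similar` flag; `NULL` leaves the flag `NA`.
#' @return List with `distance` (A), `radius_used`, and `similar`.
#' @export
vector_difference <- function(p_dep, p_val, radius, resolution = NULL) {
  stopifnot(inherits(p_dep, "helical_params"), inherits(p_val, "helical_params"),
            is.numeric(radius), radius > 0)
  embed <- function(p) {
    th <- p$twist / 180
    c(radius * cospi(th) - radius, radius * sinpi(th), p$rise)
  }
  dist <- sqrt(sum((embed(p_dep) - embed(p_val))^2))
  list(distance = dist, radius_used = radius,
       similar = if (is.null(resolution)) NA else dist < resolution)
}

#' Central axial slab of a map
#'
#' Retains the slab of height `3 * rise` about the axial midpoint and
#' marks everything outside it invalid. Symmetrizing such a slab with the
#' correct parameters regenerates the full-length helix, which is the
#' basis of the symmetrize-and-correlate comparison: a slab covering three
#' rise levels carries the full asymmetric content while forcing the
#' symmetry operations to actually reconstruct the rest of the map.
#'
#' @param map Axis-normalized [density_map()].
#' @param rise Helical rise in Angstrom; `3 * rise` must not exceed the
#'   axial extent (callers fall back to the full map when it does).
#' @return A `density_map` with voxels outside the slab invalidated.
#' @export
central_slab <- function(map, rise) {
  stopifnot(inherits(map, "density_map"), is.numeric(rise), rise > 0)
  .assert_standard_axes(map)
  d <- dim(map$data)
  extent <- d[3] * map$voxel_size
  if (3 * rise > extent * (1 + 1e-9))
    stop("slab of 3 * rise (", signif(3 * rise, 4),
         " A) exceeds the axial extent (", signif(extent, 4), " A)")
  zc <- (d[3] - 1) / 2
  z <- (seq_len(d[3]) - 1 - zc) * map$voxel_size
  outside <- abs(z) > 1.5 * rise
  out <- map
  out$data[, , outside] <- NA_real_
  out
}

#' Symmetrize a map under a helical parameter set
#'
#' Averages the map over every symmetry transform that fits the axial
#' extent (see [symmetry_transforms()]): the symmetrized density is
#' `x' = (1/N) sum_i T_i(x)`. Voxels receiving no valid contribution are
#' invalid in the output. When the input is a [central_slab()], the output
#' is the slab re-propagated into a full-length helical density.
#'
#' @param map Axis-normalized [density_map()] (possibly a slab).
#' @param params A [helical_params()] object; the rise must be at least
#'   one voxel.
#' @return Object of class `symmetrized_map`: a `density_map` with extra
#'   fields `params_used` and `n_transforms`.
#' @export
symmetrize <- function(map, params) {
  stopifnot(inherits(map, "density_map"), inherits(params, "helical_params"))
  .assert_standard_axes(map)
  if (params$rise < map$voxel_size)
    stop("degenerate parameters: rise below one voxel")
  d <- dim(map$data)
  tr <- symmetry_transforms(params, axial_extent = d[3] * map$voxel_size)
  acc <- array(0, dim = d)
  cnt <- array(0L, dim = d)
  for (j in seq_len(nrow(tr))) {
    t_map <- apply_transform(map, tr$rotation_deg[j], tr$translation[j])
    ok <- !is.na(t_map$data)
    acc[ok] <- acc[ok] + t_map$data[ok]
    cnt <- cnt + ok
  }
  vals <- ifelse(cnt > 0L, acc / cnt, NA_real_)
  out <- density_map(array(vals, dim = d), voxel_size = map$voxel_size,
                     origin = map$origin)
  out$params_used <- params
  out$n_transforms <- nrow(tr)
  class(out) <- c("symmetrized_map", class(out))
  out
}

#' Masked cross-correlation between two maps
#'
#' Pearson correlation (mean-subtracted) over the jointly valid voxels of
#' two maps on the same grid.
#'
#' @param a,b Two [density_map()]s with identical grids.
#' @return Correlation in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("maps must share an identical grid")
  .masked_cor(a$data, b$data)
}

#' Symmetrize-and-correlate comparison of two parameter sets
#'
#' The decisive of the three metrics: the map is central-sliced at three
#' times the (larger) rise, the slab is symmetrized separately under the
#' deposited and the candidate parameters, and each symmetrized map is
#' correlated with the original over one shared valid mask. The parameter
#' set yielding the clearly higher score is the better description of the
#' map; two high and similar scores with very different parameters are the
#' signature of a partial symmetry.
#'
#' @param map Axis-normalized [density_map()].
#' @param p_dep,p_val The deposited and candidate [helical_params()];
#'   `p_dep` may be `NULL` (score reported as `NA`).
#' @return Object of class `correlation_scores`: `cc_deposited`,
#'   `cc_validated`, `n_transforms_deposited`, `n_transforms_validated`.
#' @export
compare_by_symmetrization <- function(map, p_dep, p_val) {
  stopifnot(inherits(map, "density_map"), inherits(p_val, "helical_params"))
  .assert_standard_axes(map)
  extent <- dim(map$data)[3] * map$voxel_size
  slab_rise <- max(p_val$rise, if (!is.null(p_dep)) p_dep$rise else 0)
  slab <- if (3 * slab_rise <= extent) central_slab(map, slab_rise) else map
  sym_val <- symmetrize(slab, p_val)
  if (is.null(p_dep)) {
    mask <- !is.na(sym_val$data) & !is.na(map$data)
    cc_v <- .masked_cor(ifelse(mask, map$data, NA), sym_val$data)
    return(structure(list(cc_deposited = NA_real_, cc_validated = cc_v,
                          n_transforms_deposited = NA_integer_,
                          n_transforms_validated = sym_val$n_transforms),
                     class = "correlation_scores"))
  }
  sym_dep <- symmetrize(slab, p_dep)
  mask <- !is.na(sym_val$data) & !is.na(sym_dep$data) & !is.na(map$data)
  if (!any(mask)) stop("no jointly valid voxels across the two symmetrizations")
  ref <- ifelse(mask, map$data, NA)
  structure(list(
    cc_deposited = .masked_cor(ref, ifelse(mask, sym_dep$data, NA)),
    cc_validated = .masked_cor(ref, ifelse(mask, sym_val$data, NA)),
    n_transforms_deposited = sym_dep$n_transforms,
    n_transforms_validated = sym_val$n_transforms),
    class = "correlation_scores")
}

#' @export
print.correlation_scores <- function(x, ...) {
  cat(sprintf("symmetrize-and-correlate: cc(deposited) = %s, cc(candidate) = %.3f\n",
              if (is.na(x$cc_deposited)) "NA" else sprintf("%.3f", x$cc_deposited),
              x$cc_validated))
  invisible(x)
}
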