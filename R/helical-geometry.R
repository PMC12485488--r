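#' Helical symmetry parameters
#'
#' A helical symmetry is the screw operation relating consecutive asymmetric
#' units: a rotation (`twist`, degrees) about the helical axis combined with
#' a translation (`rise`, Angstrom) along it, optionally composed with an
#' n-fold rotational symmetry (`csym`) about the same axis.
#'
#' The twist is stored wrapped to the interval (-180, 180]. The sign
#' convention used throughout the package: positive twist corresponds to a
#' right-handed helix when the helical axis points toward increasing slice
#' index. Whether a map's apparent handedness matches the true molecular
#' chirality is not adjudicated here.
#'
#' @param twist Rotation per asymmetric unit in degrees. Any finite value is
#'   accepted and wrapped to (-180, 180].
#' @param rise Translation per asymmetric unit in Angstrom; must be > 0.
#' @param csym Axial (cyclic) symmetry order, integer >= 1.
#' @return An object of class `helical_params`.
#' @examples
#' helical_params(twist = 65.42, rise = 5.07)
#' helical_params(-1.2, 4.8, csym = 1)  # an amyloid-like symmetry
#' @export
helical_params <- function(twist, rise, csym = 1L) {
  stopifnot(is.numeric(twist), length(twist) == 1L, is.finite(twist))
  stopifnot(is.numeric(rise), length(rise) == 1L, is.finite(rise))
  if (rise <= 0) stop("rise must be positive (Angstrom)")
  csym <- as.integer(csym)
  if (is.na(csym) || csym < 1L) stop("csym must be an integer >= 1")
  structure(
    list(twist = wrap_twist(twist), rise = as.numeric(rise), csym = csym),
    class = "helical_params"
  )
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("helical symmetry: twist %.4g deg, rise %.4g A, C%d\n",
              x$twist, x$rise, x$csym))
  invisible(x)
}

#' @export
format.helical_params <- function(x, ...) {
  sprintf("(%.4g deg, %.4g A, C%d)", x$twist, x$rise, x$csym)
}

#' Wrap an angle into (-180, 180] degrees
#'
#' Twist angles are reported on the principal interval; wrapping is needed
#' whenever multiples of the twist are formed (e.g. by [n_fold()]).
#'
#' @param angle Angle(s) in degrees.
#' @return Angle(s) congruent to the input modulo 360, in (-180, 180].
#' @examples
#' wrap_twist(57)       # 57
#' wrap_twist(1439.24)  # -0.76
#' wrap_twist(-180)     # 180
#' @export
wrap_twist <- function(angle) {
  stopifnot(is.numeric(angle), all(is.finite(angle)))
  w <- angle %% 360
  ifelse(w > 180, w - 360, w)
}

#' Enumerate the symmetry transforms spanning an axial window
#'
#' Generates every screw-plus-Cn transform whose axial translation fits
#' within `axial_extent / 2` of the origin: rotations
#' `i * twist + k * 360 / csym` paired with translations `i * rise`, for all
#' integers `i` (both signs) and `k = 0 .. csym - 1`.
#'
#' @param params A [helical_params()] object.
#' @param axial_extent Axial window in Angstrom (typically the map height).
#' @return A data.frame with columns `rotation_deg` and `translation` (A);
#'   the number of transforms is `nrow()`.
#' @export
symmetry_transforms <- function(params, axial_extent) {
  stopifnot(inherits(params, "helical_params"),
            is.numeric(axial_extent), axial_extent > 0)
  m <- floor(axial_extent / 2 / params$rise)
  i <- seq.int(-m, m)
  k <- seq_len(params$csym) - 1L
  grid <- expand.grid(i = i, k = k)
  data.frame(
    rotation_deg = grid$i * params$twist + grid$k * 360 / params$csym,
    translation  = grid$i * params$rise
  )
}

#' Apply one symmetry transform to a density map
#'
#' Rotates the map by `rotation_deg` about the central axis (the grid
#' center in the two transverse axes) and shifts it by `translation`
#' Angstrom along the helical axis, using trilinear interpolation. Voxels
#' whose source position falls outside the grid are marked invalid (`NA`)
#' and are excluded from any subsequent averaging or correlation.
#'
#' @param map A [density_map()] with standard axis order.
#' @param rotation_deg Rotation about the helical axis, degrees.
#' @param translation Translation along the helical axis, Angstrom.
#' @return A `density_map` of the same geometry.
#' @export
apply_transform <- function(map, rotation_deg, translation) {
  stopifnot(inherits(map, "density_map"))
  .assert_standard_axes(map)
  d <- dim(map$data)
  cx <- d[1] / 2; cy <- d[2] / 2
  # inverse mapping: output voxel v takes the value at R(-theta) (v - t)
  th <- -rotation_deg / 180  # units of pi for cospi/sinpi (exact at multiples of 90)
  ct <- cospi(th); st <- sinpi(th)
  x <- seq_len(d[1]) - 1 - cx
  y <- seq_len(d[2]) - 1 - cy
  z <- seq_len(d[3]) - 1 - translation / map$voxel_size
  xg <- rep(x, times = d[2])
  yg <- rep(y, each = d[1])
  xs <- ct * xg - st * yg + cx
  ys <- st * xg + ct * yg + cy
  n_xy <- d[1] * d[2]
  xi <- rep(xs, times = d[3])
  yi <- rep(ys, times = d[3])
  zi <- rep(z, each = n_xy)
  out <- .interp_trilinear(map$data, xi, yi, zi)
  dim(out) <- d
  density_map(out, voxel_size = map$voxel_size, origin = map$origin)
}

#' Integer multiple of a helical symmetry
#'
#' For a true symmetry (twist, rise), the pair (n * twist mod 360, n * rise)
#' is also a valid — but partial — symmetry of the same assembly: it relates
#' every n-th asymmetric unit and therefore averages n-fold fewer copies.
#'
#' @param params A [helical_params()] object.
#' @param n Integer multiplier >= 1.
#' @return The n-fold partial symmetry as a `helical_params` object.
#' @examples
#' n_fold(helical_params(65.42, 5.07), 22)  # twist -0.76, rise 111.54
#' @export
n_fold <- function(params, n) {
  stopifnot(inherits(params, "helical_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1")
  helical_params(wrap_twist(n * params$twist), n * params$rise, params$csym)
}

#' Exchange the numeric twist and rise values
#'
#' Models the deposition error in which twist (degrees) and rise (Angstrom)
#' were entered in each other's fields. The exchange is purely numeric.
#'
#' @param params A [helical_params()] object with `twist > 0` (the twist
#'   value becomes the rise and must remain positive).
#' @return A `helical_params` with the two values exchanged.
#' @export
swap_twist_rise <- function(params) {
  stopifnot(inherits(params, "helical_params"))
  if (params$twist <= 0)
    stop("swap would produce a non-positive rise; twist must be > 0")
  helical_params(params$rise, params$twist, params$csym)
}

#' Negate the twist sign
#'
#' Models the most common deposition error: a twist entered with the wrong
#' sign (equivalently, a map whose handedness is mirrored relative to the
#' deposited parameters). Rise and axial symmetry are untouched.
#'
#' @param params A [helical_params()] object.
#' @return A `helical_params` with negated twist.
#' @export
flip_twist_sign <- function(params) {
  stopifnot(inherits(params, "helical_params"))
  helical_params(wrap_twist(-params$twist), params$rise, params$csym)
}
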