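#' Pseudo-atom model of one asymmetric unit
#'
#' A small set of 3D Gaussians, given in cylindrical coordinates about the
#' helical axis, that plays the role of the asymmetric unit when building
#' synthetic helical maps. The default is a 3-Gaussian unit at distinct
#' radii, which breaks spurious rotational symmetries and gives the radial
#' profile a well-defined band.
#'
#' The `"amyloid"` preset uses a finer 1 A grid and sharper 1.2 A
#' Gaussians at protofilament-scale radii, so that sub-5-Angstrom rises
#' (the cross-beta stacking distance) are resolved as separate rungs
#' rather than blurring into a continuous spiral.
#'
#' @param atoms data.frame with columns `radius` (A), `azimuth` (deg),
#'   `height` (A, relative to the box center), `amplitude`, `sigma` (A,
#'   Gaussian width; must be >= the voxel size).
#' @param box_size Voxels per axis (cubic grid).
#' @param voxel_size Angstrom per voxel.
#' @param preset `"default"` (tube at ~16-27 A radius, 2 A voxels) or
#'   `"amyloid"` (see above); ignored when `atoms` is given.
#' @return An object of class `pseudo_atom_model`.
#' @export
pseudo_atom_model <- function(atoms = NULL, box_size = 64L, voxel_size = 2,
                              preset = c("default", "amyloid")) {
  preset <- match.arg(preset)
  if (is.null(atoms) && preset == "amyloid") {
    if (missing(voxel_size)) voxel_size <- 1
    atoms <- data.frame(
      radius    = c(8, 11, 14),
      azimuth   = c(0, 55, 145),
      height    = c(0, 0, 0),
      amplitude = c(1, 0.8, 1.2),
      sigma     = c(1.2, 1.4, 1.2)
    )
  }
  if (is.null(atoms)) {
    atoms <- data.frame(
      radius    = c(16, 22, 27),
      azimuth   = c(0, 55, 145),
      height    = c(0, 0, 0),
      amplitude = c(1, 0.8, 1.2),
      sigma     = c(2, 2.4, 2)
    )
  }
  stopifnot(is.data.frame(atoms),
            all(c("radius", "azimuth", "height", "amplitude", "sigma")
                %in% names(atoms)))
  half_width <- box_size * voxel_size / 2
  if (any(atoms$radius >= half_width))
    stop("atom radius must be smaller than the box half-width (",
         half_width, " A)")
  if (any(atoms$sigma < voxel_size))
    stop("gaussian sigma must be >= voxel_size (no sub-voxel spikes)")
  structure(list(atoms = atoms, box_size = as.integer(box_size),
                 voxel_size = as.numeric(voxel_size)),
            class = "pseudo_atom_model")
}

#' Build a synthetic helical density map
#'
#' Places the asymmetric unit at every helical-symmetry image — rotations
#' `i * twist + k * 360 / csym`, translations `i * rise` — whose Gaussian
#' centers fall inside the box, and sums the (4-sigma truncated) Gaussians.
#' The resulting map is exactly invariant under the generating screw
#' transform, up to interpolation/truncation error.
#'
#' @param model A [pseudo_atom_model()].
#' @param params A [helical_params()] object; `rise` must be at least half
#'   a voxel or the lattice is unresolvable.
#' @return A [density_map()] with the helical axis on Z.
#' @export
make_helical_map <- function(model, params) {
  stopifnot(inherits(model, "pseudo_atom_model"),
            inherits(params, "helical_params"))
  if (params$rise < model$voxel_size / 2)
    stop("rise smaller than voxel_size / 2: lattice unresolvable on this grid")
  n <- model$box_size
  vox <- model$voxel_size
  extent <- n * vox
  arr <- array(0, dim = c(n, n, n))
  cx <- n / 2; cz <- (n - 1) / 2
  m <- ceiling(extent / params$rise) + 1L
  ks <- seq_len(params$csym) - 1L
  for (i in seq.int(-m, m)) {
    for (k in ks) {
      rot <- i * params$twist + k * 360 / params$csym
      dz  <- i * params$rise
      for (a in seq_len(nrow(model$atoms))) {
        at <- model$atoms[a, ]
        phi <- (at$azimuth + rot) / 180       # units of pi
        xc <- cx + at$radius / vox * cospi(phi)
        yc <- cx + at$radius / vox * sinpi(phi)
        zc <- cz + (at$height + dz) / vox
        s  <- at$sigma / vox
        r4 <- ceiling(4 * s)
        rng <- function(c0) {
          lo <- max(0, floor(c0 - r4)); hi <- min(n - 1, ceiling(c0 + r4))
          if (lo > hi) NULL else lo:hi
        }
        ix <- rng(xc); iy <- rng(yc); iz <- rng(zc)
        if (is.null(ix) || is.null(iy) || is.null(iz)) next
        gx <- exp(-(ix - xc)^2 / (2 * s^2))
        gy <- exp(-(iy - yc)^2 / (2 * s^2))
        gz <- exp(-(iz - zc)^2 / (2 * s^2))
        blk <- at$amplitude * (gx %o% gy %o% gz)
        arr[ix + 1L, iy + 1L, iz + 1L] <-
          array(arr[ix + 1L, iy + 1L, iz + 1L], dim = dim(blk)) + blk
      }
    }
  }
  density_map(arr, voxel_size = vox)
}

#' Simulate a half-map pair
#'
#' Adds two independent Gaussian noise realizations to the same signal map,
#' mimicking the two half-set reconstructions deposited alongside a final
#' map. Noise is scaled relative to the signal RMS and drawn from a private
#' RNG stream, so the global RNG state is untouched and the pair is fully
#' determined by `seed`.
#'
#' @param map Signal [density_map()].
#' @param noise_sigma Noise standard deviation as a fraction of the map
#'   RMS (>= 0).
#' @param seed Integer seed.
#' @return List of two `density_map`s (`half1`, `half2`).
#' @export
make_half_maps <- function(map, noise_sigma, seed) {
  stopifnot(inherits(map, "density_map"), noise_sigma >= 0)
  d <- dim(map$data)
  rms <- sqrt(mean(map$data^2, na.rm = TRUE))
  noise <- .with_seed(seed, list(
    array(stats::rnorm(prod(d), sd = noise_sigma * rms), dim = d),
    array(stats::rnorm(prod(d), sd = noise_sigma * rms), dim = d)
  ))
  h1 <- map; h1$data <- map$data + noise[[1]]
  h2 <- map; h2$data <- map$data + noise[[2]]
  list(half1 = h1, half2 = h2)
}

#' Unwrapped 2D lattice of a helical symmetry
#'
#' Enumerates the symmetry images of a reference point (azimuth 0, height
#' 0) on a cylinder of the given radius: the 2D lattice one obtains by
#' unwrapping the helix. Used both for plotting and as the ground-truth
#' lattice in tests of the autocorrelation indexing.
#'
#' @param params A [helical_params()] object.
#' @param radius Cylinder radius, A (> 0; recorded on the output).
#' @param length Axial length, A; points with |height| <= length / 2 are
#'   kept.
#' @return data.frame with columns `azimuth` (deg, wrapped to (-180, 180])
#'   and `height` (A).
#' @export
make_lattice_points <- function(params, radius, length) {
  stopifnot(inherits(params, "helical_params"), radius > 0, length > 0)
  m <- floor(length / 2 / params$rise)
  i <- seq.int(-m, m)
  k <- seq_len(params$csym) - 1L
  grid <- expand.grid(i = i, k = k)
  out <- data.frame(
    azimuth = wrap_twist(grid$i * params$twist + grid$k * 360 / params$csym),
    height  = grid$i * params$rise
  )
  attr(out, "radius") <- radius
  out[order(out$height, out$azimuth), , drop = FALSE]
}
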