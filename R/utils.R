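# Internal numeric helpers shared across modules.

# Vectorized trilinear interpolation of a 3D array at fractional 0-based
# voxel coordinates. Points outside the grid, or touching an invalid (NA)
# voxel, yield NA.
.interp_trilinear <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  out <- rep(NA_real_, length(xi))
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  ok <- x0 >= 0 & x0 <= d[1] - 1 & y0 >= 0 & y0 <= d[2] - 1 &
        z0 >= 0 & z0 <= d[3] - 1 &
        xi >= 0 & xi <= d[1] - 1 & yi >= 0 & yi <= d[2] - 1 &
        zi >= 0 & zi <= d[3] - 1
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- xi[ok] - x0; fy <- yi[ok] - y0; fz <- zi[ok] - z0
  # clamp the upper neighbor onto the grid edge; its weight is then zero
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  g <- function(ix, iy, iz) arr[cbind(ix + 1L, iy + 1L, iz + 1L)]
  v <-
    g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    g(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    g(x1, y1, z0) * fx       * fy       * (1 - fz) +
    g(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    g(x1, y0, z1) * fx       * (1 - fy) * fz +
    g(x0, y1, z1) * (1 - fx) * fy       * fz +
    g(x1, y1, z1) * fx       * fy       * fz
  out[ok] <- v
  out
}

.assert_standard_axes <- function(map) {
  if (!identical(as.integer(map$axes_order), 1:3))
    stop("map must be in standard axis order; call normalize_axes() first")
  invisible(TRUE)
}

# Pearson correlation over jointly valid (non-NA) voxels of two equal grids.
.masked_cor <- function(a, b) {
  m <- !is.na(a) & !is.na(b)
  if (!any(m)) stop("no jointly valid voxels")
  av <- a[m]; bv <- b[m]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("correlation undefined: constant input on the valid mask")
  stats::cor(av, bv)
}

# Run code with a private RNG stream, leaving the caller's RNG state alone.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
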