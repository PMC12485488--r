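#' Fourier shell correlation between two maps
#'
#' Shell-wise normalized complex correlation of the two maps' Fourier
#' transforms, with shells one voxel wide in frequency index. No masking
#' or curve correction is applied; invalid voxels are treated as zero
#' density before transforming.
#'
#' @param a,b Two [density_map()]s with identical grids and voxel size.
#' @return Object of class `fsc_curve`: data.frame with
#'   `spatial_frequency` (1/A, from 0 to Nyquist) and `correlation`.
#' @export
fsc <- function(a, b) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!identical(dim(a$data), dim(b$data)))
    stop("maps must share an identical grid")
  if (abs(a$voxel_size - b$voxel_size) > 1e-9)
    stop("maps must share the voxel size")
  d <- dim(a$data)
  A <- a$data; A[is.na(A)] <- 0
  B <- b$data; B[is.na(B)] <- 0
  FA <- stats::fft(A)
  FB <- stats::fft(B)
  wrap_idx <- function(n) { k <- 0:(n - 1); ifelse(k > n / 2, k - n, k) }
  kx <- wrap_idx(d[1]); ky <- wrap_idx(d[2]); kz <- wrap_idx(d[3])
  # radius in index units of the smallest dimension's frequency step
  n0 <- min(d)
  r <- sqrt(outer(outer((kx / d[1])^2, (ky / d[2])^2, `+`),
                  (kz / d[3])^2, `+`)) * n0
  shell <- round(r)
  smax <- floor(n0 / 2)
  keep <- shell <= smax
  sh <- factor(shell[keep], levels = 0:smax)
  num <- as.vector(tapply(Re(FA[keep] * Conj(FB[keep])), sh, sum, default = 0))
  da <- as.vector(tapply(Mod(FA[keep])^2, sh, sum, default = 0))
  db <- as.vector(tapply(Mod(FB[keep])^2, sh, sum, default = 0))
  corr <- ifelse(da > 0 & db > 0, num / sqrt(da * db), 0)
  out <- data.frame(spatial_frequency = (0:smax) / (n0 * a$voxel_size),
                    correlation = corr)
  class(out) <- c("fsc_curve", class(out))
  attr(out, "voxel_size") <- a$voxel_size
  out
}

#' Resolution at an FSC threshold
#'
#' Reads the resolution as 1 / frequency at the first crossing of the
#' curve below the threshold (0.143 is the half-map convention), linearly
#' interpolated between shells. A curve that never crosses is reported at
#' the Nyquist resolution with attribute `never_crossed = TRUE`.
#'
#' @param curve An [fsc()] curve.
#' @param threshold Correlation threshold (default 0.143).
#' @return Resolution in Angstrom (attribute `never_crossed` flags
#'   Nyquist-limited curves).
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  stopifnot(inherits(curve, "fsc_curve"))
  f <- curve$spatial_frequency
  cc <- curve$correlation
  below <- which(cc < threshold)
  below <- below[below > 1L]
  if (length(below) == 0L) {
    res <- 1 / f[length(f)]
    attr(res, "never_crossed") <- TRUE
    return(res)
  }
  i <- below[1]
  f_cross <- f[i - 1] +
    (cc[i - 1] - threshold) / (cc[i - 1] - cc[i]) * (f[i] - f[i - 1])
  res <- 1 / f_cross
  attr(res, "never_crossed") <- FALSE
  res
}

#' Resolution with partial versus full helical symmetry
#'
#' Symmetrizes the two half-maps with both the partial (e.g. deposited)
#' and the full (validated) parameter sets, computes the FSC between
#' like-symmetrized halves, and reports the 0.143 resolutions. Averaging
#' over the larger number of asymmetric units of the full symmetry can
#' only help if the parameters are truly a symmetry of the signal, so
#' `res_full <= res_partial` is the expected signature of a genuine
#' partial-symmetry deposition.
#'
#' @param half1,half2 Half-map [density_map()]s on identical grids.
#' @param p_partial,p_full The partial and full [helical_params()];
#'   a warning is issued when they are not related by an integer
#'   multiplier (see [find_multiplier()]).
#' @param threshold FSC threshold (default 0.143).
#' @return List with `res_partial`, `res_full` (A), the two `fsc_curve`s,
#'   and the multiplier relation (or `NULL`).
#' @export
partial_vs_full <- function(half1, half2, p_partial, p_full,
                            threshold = 0.143) {
  stopifnot(inherits(half1, "density_map"), inherits(half2, "density_map"),
            inherits(p_partial, "helical_params"),
            inherits(p_full, "helical_params"))
  rel <- find_multiplier(p_partial, p_full)
  if (is.null(rel))
    warning("parameter sets are not related by an integer multiplier; ",
            "comparing anyway")
  sym <- function(h, p) symmetrize(h, p)
  curve_partial <- fsc(sym(half1, p_partial), sym(half2, p_partial))
  curve_full <- fsc(sym(half1, p_full), sym(half2, p_full))
  list(res_partial = resolution_at(curve_partial, threshold),
       res_full = resolution_at(curve_full, threshold),
       fsc_partial = curve_partial, fsc_full = curve_full,
       relation = rel)
}
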