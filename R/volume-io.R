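#' 3D density map container
#'
#' Wraps a 3D voxel grid together with the metadata needed by the helical
#' validation pipeline: the (isotropic) voxel size in Angstrom, the physical
#' origin, and the storage axis order. In standard order the first array
#' index is the fastest-varying X axis and the third index the slowest Z
#' axis; the helical axis convention throughout the package is Z after
#' [normalize_axes()] / [orient_helical_axis()].
#'
#' Invalid voxels (e.g. regions that fell outside the grid during a
#' symmetry transform) are represented as `NA` and excluded from averages
#' and correlations.
#'
#' @param data 3D numeric array; every dimension must be >= 8.
#' @param voxel_size Voxel edge length in Angstrom (> 0, isotropic).
#' @param origin Physical origin in Angstrom, length-3.
#' @param axes_order Integer permutation of 1:3 giving, for each storage
#'   dimension (fastest to slowest), the physical axis (1 = X, 2 = Y,
#'   3 = Z) it carries. `c(1, 2, 3)` is the standard order.
#' @return An object of class `density_map`.
#' @export
density_map <- function(data, voxel_size, origin = c(0, 0, 0),
                        axes_order = 1:3) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  if (any(dim(data) < 8L))
    stop("all grid dimensions must be >= 8")
  stopifnot(is.numeric(voxel_size), length(voxel_size) == 1L)
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be a positive scalar (Angstrom)")
  axes_order <- as.integer(axes_order)
  if (!identical(sort(axes_order), 1:3))
    stop("axes_order must be a permutation of 1:3")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), axes_order = axes_order,
         oriented_from = NULL),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("density map: %d x %d x %d voxels, %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  axes order (fast->slow): %s\n",
              paste(c("X", "Y", "Z")[x$axes_order], collapse = " ")))
  cat(sprintf("  origin: (%.4g, %.4g, %.4g) A;  %d invalid voxels\n",
              x$origin[1], x$origin[2], x$origin[3], sum(is.na(x$data))))
  invisible(x)
}

.MRC_HEADER_BYTES <- 1024L

.parse_mrc_header <- function(raw, endian) {
  int_at  <- function(w, n = 1L)
    readBin(raw[((w - 1L) * 4L + 1L):((w + n - 1L) * 4L)], "integer",
            n = n, size = 4L, endian = endian)
  num_at  <- function(w, n = 1L)
    readBin(raw[((w - 1L) * 4L + 1L):((w + n - 1L) * 4L)], "numeric",
            n = n, size = 4L, endian = endian)
  list(
    nxyz   = int_at(1L, 3L),
    mode   = int_at(4L),
    mxyz   = int_at(8L, 3L),
    cella  = num_at(11L, 3L),
    mapcrs = int_at(17L, 3L),
    ispg   = int_at(23L),
    nsymbt = int_at(24L),
    origin = num_at(50L, 3L),
    magic  = rawToChar(raw[209:212]),
    machst = raw[213:214]
  )
}

#' Read an MRC/CCP4 density map
#'
#' Parses the MRC2014 1024-byte header and the voxel block. Mode 2
#' (32-bit float) data are supported; both byte orders are handled via the
#' machine-stamp/plausibility check, and gzip-compressed files are read
#' transparently. The header's axis-correspondence fields (`MAPC`, `MAPR`,
#' `MAPS`) populate `axes_order`; call [normalize_axes()] to obtain standard
#' storage order.
#'
#' @param path Path to a `.mrc`/`.map` file (optionally gzipped).
#' @return A [density_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = .MRC_HEADER_BYTES)
  if (length(hdr_raw) < .MRC_HEADER_BYTES)
    stop("malformed MRC header: file shorter than 1024 bytes")
  h <- .parse_mrc_header(hdr_raw, "little")
  endian <- "little"
  plausible <- function(h) all(h$nxyz > 0L) && all(h$nxyz < 1e5) &&
    h$mode %in% 0:6
  if (identical(as.integer(h$machst[1]), 0x11L) || !plausible(h)) {
    h2 <- .parse_mrc_header(hdr_raw, "big")
    if (plausible(h2)) { h <- h2; endian <- "big" }
  }
  if (h$magic != "MAP " || !plausible(h))
    stop("malformed MRC header (missing MAP stamp or implausible fields)")
  if (h$mode != 2L)
    stop("unsupported MRC data mode ", h$mode, " (only mode 2 float)")
  if (!identical(sort(h$mapcrs), 1:3))
    stop("malformed MRC header: MAPC/MAPR/MAPS is not a permutation of 1:3")
  if (h$nsymbt > 0L) invisible(readBin(con, "raw", n = h$nsymbt))
  nvox <- prod(h$nxyz)
  vals <- readBin(con, "numeric", n = nvox, size = 4L, endian = endian)
  if (length(vals) < nvox) stop("truncated MRC data block")
  vox <- h$cella / h$mxyz
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop("malformed MRC header: invalid cell dimensions")
  if (diff(range(vox)) > 1e-3 * mean(vox))
    stop("anisotropic voxel size (", paste(signif(vox, 5), collapse = ", "),
         " A); only isotropic maps are supported")
  vals[is.nan(vals)] <- NA_real_
  density_map(array(vals, dim = h$nxyz), voxel_size = mean(vox),
              origin = h$origin, axes_order = h$mapcrs)
}

#' Write a density map as an MRC2014 file
#'
#' The map must be in standard axis order. Invalid voxels are stored as
#' NaN. Mode 2 (32-bit float), little-endian.
#'
#' @param map A [density_map()] in standard axis order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  .assert_standard_axes(map)
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  vals <- map$data
  ok <- !is.na(vals)
  wi(d)                                 # NX NY NZ
  wi(2L)                                # MODE 2: float32
  wi(c(0L, 0L, 0L))                     # NXSTART..NZSTART
  wi(d)                                 # MX MY MZ
  wf(d * map$voxel_size)                # CELLA
  wf(c(90, 90, 90))                     # CELLB
  wi(1:3)                               # MAPC MAPR MAPS
  wf(c(min(vals[ok]), max(vals[ok]), mean(vals[ok])))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))                         # ISPG, NSYMBT
  wi(integer(25L))                      # EXTRA
  wf(map$origin)                        # ORIGIN
  writeBin(charToRaw("MAP "), con)      # map stamp
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(vals[ok]))               # RMS
  wi(0L)                                # NLABL
  writeBin(raw(800L), con)              # labels
  vals[!ok] <- NaN
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  invisible(path)
}

#' Reorder voxels to standard axis order
#'
#' Physically transposes the grid so that storage order is X fastest, Z
#' slowest, as declared by a standard MRC header. Maps already in standard
#' order are returned unchanged; the physical location of every voxel is
#' preserved.
#'
#' @param map A [density_map()].
#' @return A `density_map` with `axes_order = c(1, 2, 3)`.
#' @export
normalize_axes <- function(map) {
  stopifnot(inherits(map, "density_map"))
  p <- map$axes_order
  if (identical(p, 1:3)) return(map)
  # storage dim i carries physical axis p[i]; put physical axis j on dim j
  perm <- match(1:3, p)
  density_map(aperm(map$data, perm), voxel_size = map$voxel_size,
              origin = map$origin, axes_order = 1:3)
}

#' Make a chosen grid axis the helical axis
#'
#' Cyclically permutes the (already axis-normalized) grid so that the named
#' axis becomes the canonical helical axis (the slowest, Z). A cyclic
#' permutation is used so that handedness — and hence the twist sign — is
#' preserved. Calling the function again with the same declaration is a
#' no-op.
#'
#' @param map A [density_map()] in standard axis order.
#' @param axis Which grid axis currently carries the helix: 1/2/3 or
#'   "X"/"Y"/"Z".
#' @return A `density_map` whose third axis is the helical axis.
#' @export
orient_helical_axis <- function(map, axis = 3L) {
  stopifnot(inherits(map, "density_map"))
  .assert_standard_axes(map)
  if (is.character(axis)) axis <- match(toupper(axis), c("X", "Y", "Z"))
  axis <- as.integer(axis)
  if (is.na(axis) || !axis %in% 1:3) stop("axis must be 1, 2, 3 or X/Y/Z")
  if (axis == 3L) return(map)
  if (identical(map$oriented_from, axis)) return(map)
  perm <- if (axis == 1L) c(2L, 3L, 1L) else c(3L, 1L, 2L)
  out <- density_map(aperm(map$data, perm), voxel_size = map$voxel_size,
                     origin = map$origin[perm], axes_order = 1:3)
  out$oriented_from <- axis
  out
}
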