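make_tiny_map <- function(seed = 3, n = 8L, vox = 1.5) {
  set.seed(seed)
  density_map(array(stats::rnorm(n^3), dim = c(n, n, n)), voxel_size = vox,
              origin = c(1, -2, 3.5))
}

test_that("write_map / read_map round-trips grid, voxel size and origin", {
  m <- make_tiny_map()
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, path)
  r1 <- read_map(path)
  expect_equal(dim(r1$data), dim(m$data))
  expect_equal(r1$voxel_size, 1.5, tolerance = 1e-6)
  expect_equal(r1$origin, m$origin, tolerance = 1e-6)
  expect_equal(r1$data, m$data, tolerance = 1e-6)      # float32 precision
  # a second round trip of float32 data is bitwise
  path2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(r1, path2)
  r2 <- read_map(path2)
  expect_identical(r2$data, r1$data)
  # degenerate content: an all-zero volume
  z <- density_map(array(0, dim = c(8, 8, 8)), voxel_size = 2)
  pz <- withr::local_tempfile(fileext = ".mrc")
  write_map(z, pz)
  expect_true(all(read_map(pz)$data == 0))
})

# round numbers through float32 like the file does
single_to_double <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  writeBin(as.numeric(x), con, size = 4L)
  close(con)
  con <- file(tmp, "rb")
  out <- readBin(con, "numeric", n = length(x), size = 4L)
  close(con)
  out
}

# independent byte-level writer used as an oracle for header parsing
write_raw_mrc <- function(path, arr, vox, mapcrs) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(arr)
  hdr <- integer(0)
  writeBin(as.integer(d), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")
  writeBin(integer(3), con, size = 4L, endian = "little")
  writeBin(as.integer(d), con, size = 4L, endian = "little")
  writeBin(as.numeric(d * vox), con, size = 4L, endian = "little")
  writeBin(c(90, 90, 90), con, size = 4L, endian = "little")
  writeBin(as.integer(mapcrs), con, size = 4L, endian = "little")
  writeBin(c(min(arr), max(arr), mean(arr)), con, size = 4L, endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")
  writeBin(integer(25), con, size = 4L, endian = "little")
  writeBin(c(0, 0, 0), con, size = 4L, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  writeBin(stats::sd(arr), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
}

test_that("axis-correspondence header fields populate axes_order", {
  set.seed(5)
  arr <- array(stats::rnorm(8^3), dim = c(8, 8, 8))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_raw_mrc(path, arr, vox = 2, mapcrs = c(2L, 1L, 3L))
  m <- read_map(path)
  expect_identical(m$axes_order, c(2L, 1L, 3L))        # Y fastest
  norm <- normalize_axes(m)
  expect_identical(norm$axes_order, 1:3)
  expect_equal(norm$data, aperm(array(as.vector(single_to_double(arr)),
                                      dim = dim(arr)), c(2, 1, 3)))
})

test_that("malformed headers and unsupported modes are rejected", {
  path <- withr::local_tempfile(fileext = ".mrc")
  con <- file(path, "wb")
  writeBin(raw(100), con)
  close(con)
  expect_error(read_map(path), "malformed")
  set.seed(6)
  arr <- array(stats::rnorm(8^3), dim = c(8, 8, 8))
  path2 <- withr::local_tempfile(fileext = ".mrc")
  write_raw_mrc(path2, arr, vox = 2, mapcrs = c(1L, 2L, 3L))
  raw_all <- readBin(path2, "raw", n = file.size(path2))
  raw_all[13:16] <- writeBin(1L, raw(), size = 4L, endian = "little")  # mode 1
  writeBin(raw_all, path2)
  expect_error(read_map(path2), "unsupported")
})

test_that("normalize_axes preserves voxel values and physical positions", {
  m <- std_map()
  # single-marker check under a full axis reversal of storage order
  arr <- array(0, dim = c(8, 10, 12))
  arr[3, 5, 9] <- 7                                    # physical (x=3,y=5,z=9)
  std <- density_map(arr, voxel_size = 2)
  permuted <- density_map(aperm(arr, c(3, 2, 1)), voxel_size = 2,
                          axes_order = c(3L, 2L, 1L))
  back <- normalize_axes(permuted)
  expect_identical(back$data, arr)
  expect_equal(back$data[3, 5, 9], 7)
  # multiset of values is untouched for a generic permutation
  p2 <- density_map(aperm(m$data, c(2, 3, 1)), voxel_size = 2,
                    axes_order = c(2L, 3L, 1L))
  n2 <- normalize_axes(p2)
  expect_identical(n2$data, m$data)
  expect_identical(normalize_axes(n2), n2)             # idempotent
})

test_that("orient_helical_axis brings a helix built along X back to Z", {
  m <- std_map()
  mx <- density_map(aperm(m$data, c(3, 1, 2)), voxel_size = m$voxel_size)
  back <- orient_helical_axis(mx, axis = 1)
  expect_identical(back$data, m$data)
  idx <- index_helical_params(back, with_csym = FALSE)
  expect_twist_close(idx$params$twist, 57, 1)
  expect_lt(abs(idx$params$rise - 20), 1)
  expect_identical(orient_helical_axis(back, axis = 3), back)
  twice <- orient_helical_axis(orient_helical_axis(mx, 1), 1)
  expect_identical(twice$data, back$data)
})

test_that("write_map output is readable by an independent MRC parser", {
  m <- make_tiny_map(seed = 9)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, path)
  script <- sprintf(paste0(
    "import gemmi, json; g = gemmi.read_ccp4_map('%s');",
    "import numpy as np; a = np.array(g.grid, copy=False);",
    "print(json.dumps({'shape': list(a.shape),",
    " 'spacing': round(g.grid.spacing[0], 6),",
    " 'v000': float(a[0,0,0]), 'sum': float(a.sum())}))"), path)
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  expect_true(length(out) > 0 && nzchar(out[length(out)]))
  got <- jsonlite::fromJSON(out[length(out)])
  expect_equal(sort(unlist(got$shape)), c(8, 8, 8))
  expect_equal(got$spacing, 1.5, tolerance = 1e-4)
  expect_equal(got$sum, sum(m$data), tolerance = 1e-4)
})

test_that("anisotropic voxel sizes are rejected", {
  set.seed(10)
  arr <- array(stats::rnorm(8^3), dim = c(8, 8, 8))
  path <- withr::local_tempfile(fileext = ".mrc")
  con <- file(path, "wb")
  writeBin(as.integer(c(8, 8, 8)), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")
  writeBin(integer(3), con, size = 4L, endian = "little")
  writeBin(as.integer(c(8, 8, 8)), con, size = 4L, endian = "little")
  writeBin(c(16, 16, 24), con, size = 4L, endian = "little")  # 2,2,3 A/voxel
  writeBin(c(90, 90, 90), con, size = 4L, endian = "little")
  writeBin(1:3, con, size = 4L, endian = "little")
  writeBin(c(0, 1, 0.5), con, size = 4L, endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")
  writeBin(integer(25), con, size = 4L, endian = "little")
  writeBin(c(0, 0, 0), con, size = 4L, endian = "little")
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  writeBin(1, con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_map(path), "anisotropic")
})
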