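# Shared synthetic fixtures, built once per test run and memoised.

.fixtures <- new.env()

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 64^3, 2 A/voxel tube with twist 57 deg / rise 20 A, C1
std_params <- function() helical_params(57, 20)

std_map <- function() fixture("std_map",
  make_helical_map(pseudo_atom_model(), std_params()))

c3_map <- function() fixture("c3_map",
  make_helical_map(pseudo_atom_model(), helical_params(57, 20, csym = 3)))

amyloid_params <- function() helical_params(-1.2, 4.8)

amyloid_map <- function() fixture("amyloid_map",
  make_helical_map(pseudo_atom_model(preset = "amyloid"), amyloid_params()))

# compact fixture for the classification fault matrix: 48^3, 2 A/voxel
fault_model <- function() pseudo_atom_model(box_size = 48L, voxel_size = 2)

# strongly band-limited map (sigma ~ 1.75 voxels) for interpolation-
# tolerance checks
smooth_map <- function() fixture("smooth_map",
  make_helical_map(pseudo_atom_model(
    atoms = data.frame(radius = c(16, 22, 27), azimuth = c(0, 55, 145),
                       height = c(0, 0, 0), amplitude = c(1, 0.8, 1.2),
                       sigma = c(3.5, 4, 3.5))),
    std_params()))

expect_twist_close <- function(actual, expected, tol) {
  expect_lte(abs(wrap_twist(actual - expected)), tol)
}
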