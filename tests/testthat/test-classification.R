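test_that("find_multiplier recovers exact and published multiples", {
  # the published 22-fold partial symmetry example
  rel <- find_multiplier(helical_params(-0.3, 111.12),
                         helical_params(65.42, 5.07))
  expect_equal(rel$n, 22L)
  expect_lt(rel$rise_error, 0.02)
  expect_lt(rel$twist_error, 1)
  expect_equal(rel$rise_error, abs(111.12 - 22 * 5.07) / 111.12,
               tolerance = 1e-9)
  expect_equal(rel$twist_error, abs(wrap_twist(22 * 65.42 + 0.3)),
               tolerance = 1e-9)
  # exact multiples at zero error
  p <- helical_params(31.7, 6.2)
  rel3 <- find_multiplier(n_fold(p, 3), p)
  expect_equal(rel3$n, 3L)
  expect_equal(rel3$rise_error, 0, tolerance = 1e-12)
  expect_equal(rel3$twist_error, 0, tolerance = 1e-9)
  # roles exchange when the validated set is the multiple
  rel_rev <- find_multiplier(p, n_fold(p, 3))
  expect_equal(rel_rev$n, 3L)
  expect_equal(rel_rev$direction, "validated_is_multiple")
  # non-multiples are rejected
  expect_null(find_multiplier(helical_params(50, 10),
                              helical_params(21, 7.3)))
})

test_that("find_multiplier(n_fold(p, n), p) = n exhaustively for n <= 50", {
  p <- helical_params(65.42, 5.07)
  for (n in 2:50) {
    rel <- find_multiplier(n_fold(p, n), p)
    expect_equal(rel$n, n)
  }
})

test_that("the rounding shortcut agrees with a brute-force multiplier search", {
  brute <- function(p_dep, p_val, n_max = 100, tol_rise = 0.02,
                    tol_twist = 1.0) {
    coarse <- p_dep; fine <- p_val
    if (p_dep$rise < p_val$rise) { coarse <- p_val; fine <- p_dep }
    best <- NULL; best_err <- Inf
    for (n in 2:n_max) {
      re <- abs(coarse$rise - n * fine$rise) / coarse$rise
      te <- abs(wrap_twist(n * fine$twist - coarse$twist))
      if (re <= tol_rise && te <= tol_twist) {
        err <- re / tol_rise + te / tol_twist
        if (err < best_err) { best <- n; best_err <- err }
      }
    }
    best
  }
  set.seed(19)
  n_checked <- 0
  for (k in 1:1000) {
    p <- helical_params(stats::runif(1, -179, 179), stats::runif(1, 2, 10))
    n <- sample(2:40, 1)
    dep <- helical_params(
      wrap_twist(n * p$twist + stats::runif(1, -0.3, 0.3)),
      n * p$rise * (1 + stats::runif(1, -0.005, 0.005)))
    got <- find_multiplier(dep, p)
    want <- brute(dep, p)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$n, want)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 800)                            # the oracle mostly accepts
})

test_that("taxonomy prevalences recompute from counts and the survey total", {
  tab <- error_taxonomy()
  total <- attr(tab, "total_entries")
  expect_identical(total, 2025L)
  expect_equal(round(100 * tab$count / total, 2), tab$percent)
})

test_that("classify follows the decision cascade on the worked examples", {
  cfg <- validation_config()
  fake_metrics <- function(cc_dep, cc_val, radius = 50) {
    list(radius = radius, voxel_size = 1, box_height = 400,
         scores = list(cc_deposited = cc_dep, cc_validated = cc_val))
  }
  det <- function(p) structure(list(params = p), class = "indexing_result")
  # missing parameters
  r <- classify(NULL, det(helical_params(22.03, 1.41)),
                fake_metrics(NA, 0.9), 3.5, cfg)
  expect_equal(r$error_class, "no_values")
  expect_equal(r$corrected$twist, 22.03)
  # the published swapped pair: deposited (rise 130.78, twist 9.68)
  r <- classify(helical_params(9.68, 130.78), det(helical_params(130.78, 9.68)),
                fake_metrics(0.9, 0.95), 4, cfg)
  expect_equal(r$error_class, "twist_rise_swapped")
  # the published sign-flip pair: deposited twist +75.13, map says -75.13
  r <- classify(helical_params(75.13, 11.54),
                det(helical_params(-75.13, 11.54)),
                fake_metrics(0.2, 0.95), 4, cfg)
  expect_equal(r$error_class, "incorrect_twist_sign")
  # the published partial-symmetry pair
  r <- classify(helical_params(-0.3, 111.12), det(helical_params(65.42, 5.07)),
                fake_metrics(0.93, 0.97), 4.54, cfg)
  expect_equal(r$error_class, "partial_symmetry")
  expect_equal(r$multiplier, 22L)
  # consistent parameters
  r <- classify(helical_params(65.4, 5.08), det(helical_params(65.42, 5.07)),
                fake_metrics(0.95, 0.95), 4.54, cfg)
  expect_equal(r$error_class, "consistent")
  # both correlations low: manual-validation territory
  r <- classify(helical_params(100, 30), det(helical_params(65.42, 5.07)),
                fake_metrics(0.1, 0.2), 4, cfg)
  expect_equal(r$error_class, "not_validated")
  # clear win for the candidate parameters
  r <- classify(helical_params(-16.82, 3.49), det(helical_params(-26.83, 3.5)),
                fake_metrics(0.04, 0.82), 3.2, cfg)
  expect_equal(r$error_class, "incorrect_values")
})

test_that("classify is stable under modest tolerance changes", {
  det <- function(p) structure(list(params = p), class = "indexing_result")
  fake_metrics <- list(radius = 50, voxel_size = 1, box_height = 400,
                       scores = list(cc_deposited = 0.93, cc_validated = 0.97))
  for (f in c(0.8, 1, 1.2)) {
    cfg <- validation_config(tol_rise = 0.02 * f, tol_twist = 1.0 * f,
                             cc_delta = 0.1 * f)
    r <- classify(helical_params(-0.3, 111.12),
                  det(helical_params(65.42, 5.07)), fake_metrics, 4.54, cfg)
    expect_equal(r$error_class, "partial_symmetry")
  }
})

test_that("validate_entry runs the full pipeline on clean fixtures", {
  m <- std_map()
  p <- std_params()
  r <- validate_entry(m, p, reported_resolution = 5)
  expect_equal(r$error_class, "consistent")
  r_swap <- validate_entry(m, swap_twist_rise(p), reported_resolution = 5)
  expect_equal(r_swap$error_class, "twist_rise_swapped")
  expect_twist_close(r_swap$corrected$twist, p$twist, 1)
  expect_lte(abs(r_swap$corrected$rise - p$rise), 1)
  r_part <- validate_entry(m, n_fold(p, 5), reported_resolution = 5)
  expect_equal(r_part$error_class, "partial_symmetry")
  expect_equal(r_part$multiplier, 5L)
  r_none <- validate_entry(m, NULL)
  expect_equal(r_none$error_class, "no_values")
})

test_that("write_report round-trips records as CSV", {
  m <- std_map()
  recs <- list(
    validate_entry(m, std_params(), reported_resolution = 5,
                   entry_id = "SYN-0001"),
    validate_entry(m, NULL, entry_id = "SYN-0002"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(recs, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), 2L)
  expect_equal(df$entry_id, c("SYN-0001", "SYN-0002"))
  expect_equal(df$error_class, c("consistent", "no_values"))
  expect_equal(round(df$deposited_twist[1], 2), 57)
  expect_true(is.na(df$deposited_twist[2]))
  expect_equal(round(df$cc_validated[1], 2),
               round(recs[[1]]$metrics$scores$cc_validated, 2))
  # empty input: header-only file
  path0 <- withr::local_tempfile(fileext = ".csv")
  write_report(list(), path0)
  df0 <- utils::read.csv(path0)
  expect_equal(nrow(df0), 0L)
  expect_true(all(c("entry_id", "error_class", "multiplier") %in% names(df0)))
})
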