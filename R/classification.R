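#' Reference taxonomy of helical-parameter deposition errors
#'
#' The error classes observed in a 2025 survey of the helical entries of
#' the EMDB, with the reported number of affected entries, the reported
#' prevalence, and one published example entry per class (deposited versus
#' validated rise/twist). Used as the worked-example input for the
#' classification logic and for prevalence arithmetic.
#'
#' @return data.frame with columns `error_class`, `count`, `percent`
#'   (reported, in %), `example_id`, `deposited_rise`, `deposited_twist`,
#'   `validated_rise`, `validated_twist`; the total number of surveyed
#'   entries is in attribute `total_entries`.
#' @export
error_taxonomy <- function() {
  out <- data.frame(
    error_class = c("no_values", "incorrect_values", "twist_rise_swapped",
                    "incorrect_twist_sign", "partial_symmetry"),
    count = c(58L, 13L, 10L, 151L, 50L),
    percent = c(2.86, 0.64, 0.49, 7.46, 2.47),
    example_id = c("EMD-5185", "EMD-31367", "EMD-25211", "EMD-60656",
                   "EMD-43868"),
    deposited_rise = c(NA, 3.49, 130.78, 11.54, 111.12),
    deposited_twist = c(NA, -16.82, 9.68, 75.13, -0.3),
    validated_rise = c(1.41, 3.5, 9.68, 11.54, 5.07),
    validated_twist = c(22.03, -26.83, 130.78, -75.13, 65.42)
  )
  attr(out, "total_entries") <- 2025L
  out
}

#' Tolerances and sampling defaults for the validation pipeline
#'
#' One place for every tunable of [validate_entry()] and [classify()].
#'
#' @param angular_step,axial_step Default indexing sampling (1 deg, 1 A).
#' @param amyloid_angular_step,amyloid_axial_step Finer sampling for
#'   amyloid-like symmetries (0.5 deg, 0.2 A).
#' @param amyloid_rise_max,amyloid_twist_max Deposited rise (A) and |twist|
#'   (deg) below which the amyloid sampling is auto-selected.
#' @param score_floor Relative lattice peak floor (0.25).
#' @param cc_low Correlation below which a symmetrization is considered
#'   uninformative (0.5).
#' @param cc_delta Correlation margin defining "significantly higher" and
#'   "similar" scores (0.1).
#' @param tol_rise Fractional rise tolerance of the multiplier test (0.02).
#' @param tol_twist Twist tolerance of the multiplier test, degrees (1.0).
#' @param n_max Largest multiplier searched (100).
#' @param max_csym Largest axial symmetry searched (12).
#' @param retry_grid Sampling combinations retried when indexing fails:
#'   data.frame over \{1, 0.5\} deg x \{1, 0.5, 0.2\} A.
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(angular_step = 1, axial_step = 1,
                              amyloid_angular_step = 0.5,
                              amyloid_axial_step = 0.2,
                              amyloid_rise_max = 10,
                              amyloid_twist_max = 10,
                              score_floor = 0.25,
                              cc_low = 0.5, cc_delta = 0.1,
                              tol_rise = 0.02, tol_twist = 1.0,
                              n_max = 100L, max_csym = 12L,
                              retry_grid = expand.grid(
                                angular_step = c(1, 0.5),
                                axial_step = c(1, 0.5, 0.2))) {
  structure(as.list(environment()), class = "validation_config")
}

#' Integer-multiplier relation between two parameter sets
#'
#' Tests whether the coarser parameter set is (close to) an integer
#' multiple of the finer one — the signature of a deposition that used
#' only partial helical symmetry. The candidate multiplier is
#' `n = round(rise_coarse / rise_fine)`; it is accepted when the residual
#' rise error is within `tol_rise` (fractional) and the wrapped twist
#' residual within `tol_twist` degrees.
#'
#' @param p_dep,p_val Two [helical_params()] objects. Roles are exchanged
#'   automatically when `p_dep` has the smaller rise; the `direction`
#'   field records which set was the multiple.
#' @param n_max Largest multiplier considered (default 100).
#' @param tol_rise Fractional rise tolerance (default 0.02).
#' @param tol_twist Twist tolerance in degrees (default 1.0).
#' @return `NULL` when no multiplier is accepted, otherwise a list with
#'   `n`, `rise_error` (fraction), `twist_error` (degrees) and
#'   `direction` ("deposited_is_multiple" or "validated_is_multiple").
#' @examples
#' # coarse deposited symmetry that is 22 x the true one
#' find_multiplier(helical_params(-0.3, 111.12), helical_params(65.42, 5.07))
#' @export
find_multiplier <- function(p_dep, p_val, n_max = 100L,
                            tol_rise = 0.02, tol_twist = 1.0) {
  stopifnot(inherits(p_dep, "helical_params"), inherits(p_val, "helical_params"))
  direction <- "deposited_is_multiple"
  coarse <- p_dep; fine <- p_val
  if (p_dep$rise < p_val$rise) {
    coarse <- p_val; fine <- p_dep
    direction <- "validated_is_multiple"
  }
  n <- round(coarse$rise / fine$rise)
  if (n < 2 || n > n_max) return(NULL)
  rise_error <- abs(coarse$rise - n * fine$rise) / coarse$rise
  twist_error <- abs(wrap_twist(n * fine$twist - coarse$twist))
  if (rise_error > tol_rise || twist_error > tol_twist) return(NULL)
  list(n = as.integer(n), rise_error = rise_error,
       twist_error = twist_error, direction = direction)
}

.similar_threshold <- function(reported_resolution, voxel_size) {
  if (!is.null(reported_resolution) && is.finite(reported_resolution))
    reported_resolution
  else 2 * voxel_size
}

#' Assign an entry to the deposition-error taxonomy
#'
#' The decision cascade over the metric bundle, first match wins:
#' \enumerate{
#'   \item deposited parameters absent: `no_values` (corrected = detected);
#'   \item indexing failed, or both symmetrization scores below `cc_low`:
#'     `not_validated`;
#'   \item deposited and detected similar under the vector metric:
#'     `consistent`;
#'   \item swapped deposited similar (and the swap physically plausible):
#'     `twist_rise_swapped`;
#'   \item sign-flipped deposited similar: `incorrect_twist_sign`;
#'   \item an integer multiplier relates the two sets and both scores are
#'     high and close: `partial_symmetry` (with the multiplier);
#'   \item candidate score significantly higher: `incorrect_values`;
#'     otherwise `not_validated`.
#' }
#' "Similar" means a vector difference below the reported resolution
#' (below two voxels when no resolution was reported).
#'
#' @param deposited Deposited [helical_params()] or `NULL`.
#' @param detected An `indexing_result`, or `NULL` when indexing failed.
#' @param metrics List with fields `radius` (A), `voxel_size` (A),
#'   `box_height` (A) and `scores` (a `correlation_scores`); as assembled
#'   by [validate_entry()].
#' @param reported_resolution Reported resolution in A (or `NULL`).
#' @param config A [validation_config()].
#' @return Object of class `validation_record`.
#' @export
classify <- function(deposited, detected, metrics,
                     reported_resolution = NULL,
                     config = validation_config()) {
  record <- function(class, corrected = NULL, multiplier = NA_integer_) {
    structure(list(
      error_class = class,
      deposited = deposited,
      detected = if (!is.null(detected)) detected$params else NULL,
      corrected = corrected,
      multiplier = multiplier,
      metrics = metrics,
      reported_resolution = reported_resolution),
      class = "validation_record")
  }
  det <- if (!is.null(detected)) detected$params else NULL
  if (is.null(deposited))
    return(record("no_values", corrected = det))
  sc <- metrics$scores
  if (is.null(detected) ||
      (!is.na(sc$cc_deposited) && sc$cc_deposited < config$cc_low &&
       sc$cc_validated < config$cc_low))
    return(record("not_validated"))
  thr <- .similar_threshold(reported_resolution, metrics$voxel_size)
  sim <- function(p) vector_difference(p, det, metrics$radius)$distance < thr
  if (sim(deposited))
    return(record("consistent", corrected = det))
  if (deposited$twist > metrics$voxel_size &&
      deposited$twist < metrics$box_height &&
      deposited$rise > 0 && sim(swap_twist_rise(deposited)))
    return(record("twist_rise_swapped", corrected = det))
  if (sim(flip_twist_sign(deposited)))
    return(record("incorrect_twist_sign", corrected = det))
  rel <- find_multiplier(deposited, det, n_max = config$n_max,
                         tol_rise = config$tol_rise,
                         tol_twist = config$tol_twist)
  both_high <- !is.na(sc$cc_deposited) &&
    sc$cc_deposited >= config$cc_low && sc$cc_validated >= config$cc_low &&
    abs(sc$cc_validated - sc$cc_deposited) <= config$cc_delta
  if (!is.null(rel) && both_high)
    return(record("partial_symmetry", corrected = det, multiplier = rel$n))
  if (!is.na(sc$cc_deposited) &&
      sc$cc_validated - sc$cc_deposited > config$cc_delta)
    return(record("incorrect_values", corrected = det))
  record("not_validated")
}

#' @export
print.validation_record <- function(x, ...) {
  cat("validation verdict:", x$error_class, "\n")
  if (!is.null(x$deposited)) cat("  deposited:", format(x$deposited), "\n")
  if (!is.null(x$detected)) cat("  detected: ", format(x$detected), "\n")
  if (!is.na(x$multiplier)) cat("  partial-symmetry multiplier n =",
                                x$multiplier, "\n")
  sc <- x$metrics$scores
  if (!is.null(sc))
    cat(sprintf("  cc deposited/candidate: %s / %.3f\n",
                if (is.na(sc$cc_deposited)) "NA"
                else sprintf("%.3f", sc$cc_deposited), sc$cc_validated))
  invisible(x)
}

#' Validate one entry end to end
#'
#' The full pipeline for a single map: axis normalization and orientation,
#' map-driven indexing (with a retry over finer sampling grids when the
#' default fails), the three comparison metrics, and classification into
#' the error taxonomy. Amyloid sampling (0.5 deg / 0.2 A) is selected
#' automatically when the deposited rise and twist are both small.
#'
#' @param map A [density_map()] (any axis order).
#' @param deposited Deposited [helical_params()] or `NULL`.
#' @param reported_resolution Reported resolution in A (or `NULL`).
#' @param config A [validation_config()].
#' @param entry_id Optional identifier carried into the record.
#' @param helical_axis Grid axis carrying the helix after axis
#'   normalization (default 3).
#' @return A `validation_record` with the metric bundle attached.
#' @export
validate_entry <- function(map, deposited = NULL, reported_resolution = NULL,
                           config = validation_config(), entry_id = NA_character_,
                           helical_axis = 3L) {
  stopifnot(inherits(map, "density_map"))
  map <- orient_helical_axis(normalize_axes(map), helical_axis)
  amyloid <- !is.null(deposited) &&
    deposited$rise < config$amyloid_rise_max &&
    abs(deposited$twist) < config$amyloid_twist_max
  steps <- if (amyloid)
    c(config$amyloid_angular_step, config$amyloid_axial_step)
  else c(config$angular_step, config$axial_step)
  try_index <- function(ang, axi) {
    tryCatch(index_helical_params(map, angular_step = ang, axial_step = axi,
                                  score_floor = config$score_floor),
             helixvalid_indexing_failed = function(e) NULL)
  }
  detected <- try_index(steps[1], steps[2])
  if (is.null(detected)) {
    for (j in seq_len(nrow(config$retry_grid))) {
      g <- config$retry_grid[j, ]
      if (g$angular_step == steps[1] && g$axial_step == steps[2]) next
      detected <- try_index(g$angular_step, g$axial_step)
      if (!is.null(detected)) break
    }
  }
  d <- dim(map$data)
  metrics <- list(voxel_size = map$voxel_size,
                  box_height = d[3] * map$voxel_size)
  if (!is.null(detected)) {
    metrics$radius <- detected$radius
    if (!is.null(deposited)) {
      metrics$normalized <- normalized_difference(deposited, detected$params)
      metrics$vector <- vector_difference(deposited, detected$params,
                                          metrics$radius,
                                          reported_resolution)
    }
    metrics$scores <- tryCatch(
      compare_by_symmetrization(map, p_dep = deposited,
                                p_val = detected$params),
      error = function(e) list(cc_deposited = NA_real_,
                               cc_validated = NA_real_,
                               n_transforms_deposited = NA_integer_,
                               n_transforms_validated = NA_integer_))
  } else {
    metrics$scores <- list(cc_deposited = NA_real_, cc_validated = NA_real_,
                           n_transforms_deposited = NA_integer_,
                           n_transforms_validated = NA_integer_)
  }
  rec <- classify(deposited, detected, metrics, reported_resolution, config)
  rec$entry_id <- entry_id
  rec$indexing <- detected
  rec
}

#' Write validation records as a CSV report
#'
#' One row per entry with the deposited and validated parameters, the
#' error class, the multiplier, and the supporting metric values.
#'
#' @param records List of `validation_record`s (possibly empty).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  row1 <- function(rec) {
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    dep <- rec$deposited; det <- rec$detected
    sc <- rec$metrics$scores
    data.frame(
      entry_id = if (is.null(rec$entry_id)) NA_character_ else rec$entry_id,
      deposited_twist = num(dep$twist), deposited_rise = num(dep$rise),
      deposited_csym = num(dep$csym),
      validated_twist = num(det$twist), validated_rise = num(det$rise),
      validated_csym = num(det$csym),
      error_class = rec$error_class,
      multiplier = num(rec$multiplier),
      delta_twist = num(rec$metrics$normalized$delta_twist),
      delta_rise = num(rec$metrics$normalized$delta_rise),
      vector_distance = num(rec$metrics$vector$distance),
      cc_deposited = num(sc$cc_deposited),
      cc_validated = num(sc$cc_validated),
      reported_resolution = num(rec$reported_resolution)
    )
  }
  cols <- c("entry_id", "deposited_twist", "deposited_rise", "deposited_csym",
            "validated_twist", "validated_rise", "validated_csym",
            "error_class", "multiplier", "delta_twist", "delta_rise",
            "vector_distance", "cc_deposited", "cc_validated",
            "reported_resolution")
  df <- if (length(records) == 0L) {
    empty <- as.data.frame(lapply(cols, function(x) character(0)))
    names(empty) <- cols
    empty
  } else do.call(rbind, lapply(records, row1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
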