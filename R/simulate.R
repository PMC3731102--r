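# Synthetic landmark cohorts with known ground truth.
#
# The template is an exactly mirror-symmetric adult skull: right landmarks
# at +x, left at -x, midline landmarks on the x = 0 plane; y anterior, z
# superior. Coordinates are fixed artifact constants chosen so all 21
# registry distances fall in plausible adult ranges (about 41-128 mm).
# Asymmetry is injected as a parametric deformation (lateral chin
# deviation, condylar displacement, unilateral ramus scaling), then
# isotropic Gaussian noise emulates landmark digitization error on the
# order of the scanner voxel (0.4 mm).

.TEMPLATE_POINTS <- local({
  m <- rbind(
    CdR = c( 60,  0,   0),
    CdL = c(-60,  0,   0),
    GoR = c( 55, 12, -55),
    GoL = c(-55, 12, -55),
    FzR = c( 50, 40,  45),
    FzL = c(-50, 40,  45),
    KrR = c( 57, 40,  10),
    KrL = c(-57, 40,  10),
    Me  = c(  0, 75, -60),
    N   = c(  0, 70,  45),
    Gl  = c(  0, 72,  55),
    DB  = c(  0, 70, -10))
  colnames(m) <- c("x", "y", "z")
  m
})

#' The mirror-symmetric skull template
#'
#' @param subject_id subject identifier (default `"template"`).
#' @return A complete [landmark_set()] with exact mirror symmetry across
#'   the x = 0 midsagittal plane: semiangle difference 0, all left/right
#'   ratios 1, all discrepancies 0 mm.
#' @examples
#' semiangle_symmetry(symmetric_template())$difference
#' @export
symmetric_template <- function(subject_id = "template") {
  landmark_set(subject_id, .TEMPLATE_POINTS)
}

#' Specification of a parametric asymmetry
#'
#' Describes one subject's deterministic deviation from the symmetric
#' template, applied before any digitization noise.
#'
#' @param me_lateral_shift lateral (x) chin deviation of Me, mm.
#' @param cd_shift_right,cd_shift_left length-3 displacement of each
#'   condyle, mm.
#' @param ramus_scale_right,ramus_scale_left positive factor rescaling the
#'   Kr and Go offsets from the same-side condyle (values below 1 shorten
#'   that ramus).
#' @param noise_sd isotropic Gaussian digitization noise sd, mm
#'   (applied by [generate_cohort()], not by [apply_asymmetry()]).
#' @return A list of class `asymmetry_spec`.
#' @export
asymmetry_spec <- function(me_lateral_shift = 0,
                           cd_shift_right = c(0, 0, 0),
                           cd_shift_left = c(0, 0, 0),
                           ramus_scale_right = 1,
                           ramus_scale_left = 1,
                           noise_sd = 0) {
  stopifnot(length(cd_shift_right) == 3L, length(cd_shift_left) == 3L,
            ramus_scale_right > 0, ramus_scale_left > 0, noise_sd >= 0)
  structure(list(me_lateral_shift = as.numeric(me_lateral_shift),
                 cd_shift_right = as.numeric(cd_shift_right),
                 cd_shift_left = as.numeric(cd_shift_left),
                 ramus_scale_right = as.numeric(ramus_scale_right),
                 ramus_scale_left = as.numeric(ramus_scale_left),
                 noise_sd = as.numeric(noise_sd)),
            class = "asymmetry_spec")
}

#' Apply a deterministic asymmetric deformation
#'
#' Deforms a complete landmark set according to an [asymmetry_spec()]:
#' translates Me along +x by `me_lateral_shift`, displaces each condyle by
#' its `cd_shift`, and rescales each side's Kr and Go offsets from the
#' (displaced) condyle by `ramus_scale`. No noise is added.
#'
#' @param s a complete [landmark_set()].
#' @param spec an [asymmetry_spec()].
#' @return The deformed `landmark_set` (same subject id). A deformation
#'   that collapses any landmark pair below the degeneracy tolerance is
#'   an error.
#' @export
apply_asymmetry <- function(s, spec) {
  stopifnot(inherits(s, "landmark_set"), inherits(spec, "asymmetry_spec"))
  .require_complete(s)
  pts <- s$points
  pts["Me", "x"] <- pts["Me", "x"] + spec$me_lateral_shift
  pts["CdR", ] <- pts["CdR", ] + spec$cd_shift_right
  pts["CdL", ] <- pts["CdL", ] + spec$cd_shift_left
  for (side in c("R", "L")) {
    sc <- if (side == "R") spec$ramus_scale_right else spec$ramus_scale_left
    cd <- pts[paste0("Cd", side), ]
    for (lm in paste0(c("Kr", "Go"), side))
      pts[lm, ] <- cd + sc * (pts[lm, ] - cd)
  }
  out <- landmark_set(s$subject_id, pts, age = if (is.na(s$age)) NULL else s$age)
  v <- validate_landmark_set(out)
  if (nrow(v$degenerate_pairs) > 0L)
    stop("asymmetry spec collapses landmark pair(s): ",
         paste(paste0(v$degenerate_pairs$a, "/", v$degenerate_pairs$b),
               collapse = ", "))
  out
}

.add_noise <- function(s, sd) {
  if (sd <= 0) return(s)
  pts <- s$points + matrix(stats::rnorm(length(s$points), sd = sd),
                           nrow = nrow(s$points))
  rownames(pts) <- rownames(s$points)
  landmark_set(s$subject_id, pts, age = if (is.na(s$age)) NULL else s$age)
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n` subjects from the symmetric template. A fraction
#' `symmetric_fraction` (count rounded to the nearest integer) is left
#' undeformed; the rest receive a hemimandibular-elongation deformation of
#' magnitude `m` drawn uniformly from `asym_magnitude_range`, randomly to
#' the right or left: the chin point Me deviates laterally by `m` toward
#' the affected side and the contralateral condyle is elongated by `m`
#' along its ray from Me (the pattern of unilateral condylar overgrowth).
#' Ground-truth semiangle differences and discrepancies are computed on
#' the noise-free deformed geometry; isotropic Gaussian digitization noise
#' of sd `noise_sd` is then added independently per landmark per axis.
#' The default magnitude range (8-14 mm) produces semiangle differences of
#' roughly 5-8.5 degrees and discrepancies of 16-29 mm, so both symmetry
#' criteria separate cleanly from their thresholds (4 degrees, 5 mm)
#' relative to the angular scatter induced by voxel-scale noise
#' (sd about 0.14 degrees at 0.4 mm noise).
#'
#' @param n number of subjects (>= 1).
#' @param symmetric_fraction proportion of truly symmetric subjects in
#'   \[0, 1\] (default 0.7).
#' @param asym_magnitude_range length-2 `(lo, hi)` range in mm of the
#'   deformation magnitude for asymmetric subjects (default `c(8, 14)`).
#' @param noise_sd digitization noise sd in mm (default 0.4, one voxel).
#' @param seed integer random seed; fixed seed gives identical cohorts.
#' @return An object of class `labeled_cohort`: list with `subjects`
#'   (list of `landmark_set`), `truth` (data.frame: `subject_id`,
#'   `true_semiangle_diff_deg`, `true_max_discrepancy_mm`, `label` in
#'   `{"symmetric", "asymmetric"}` from the noise-free geometry under the
#'   default 4 degree / 5 mm thresholds), and `params`.
#' @examples
#' cohort <- generate_cohort(10, symmetric_fraction = 1, noise_sd = 0,
#'                           seed = 7)
#' table(cohort$truth$label)
#' @export
generate_cohort <- function(n, symmetric_fraction = 0.7,
                            asym_magnitude_range = c(8, 14),
                            noise_sd = 0.4, seed = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  if (symmetric_fraction < 0 || symmetric_fraction > 1)
    stop("symmetric_fraction must be in [0, 1]")
  if (length(asym_magnitude_range) != 2L ||
      asym_magnitude_range[1] > asym_magnitude_range[2] ||
      asym_magnitude_range[1] < 0)
    stop("asym_magnitude_range must be a non-negative (lo, hi) pair")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(as.integer(seed))
  template <- symmetric_template()
  n_sym <- round(n * symmetric_fraction)
  is_sym <- rep(FALSE, n)
  if (n_sym > 0) is_sym[sample.int(n, n_sym)] <- TRUE

  subjects <- vector("list", n)
  truth <- data.frame(subject_id = sprintf("sim%04d", seq_len(n)),
                      true_semiangle_diff_deg = NA_real_,
                      true_max_discrepancy_mm = NA_real_,
                      label = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sid <- truth$subject_id[i]
    base <- landmark_set(sid, template$points)
    if (is_sym[i]) {
      clean <- base
    } else {
      mag <- stats::runif(1, asym_magnitude_range[1], asym_magnitude_range[2])
      dir <- if (stats::runif(1) < 0.5) 1 else -1
      # chin deviates toward the +dir side; the contralateral condyle is
      # elongated by the same magnitude along its ray from Me
      cd_code <- if (dir > 0) "CdL" else "CdR"
      u <- base$points[cd_code, ] - base$points["Me", ]
      u <- u / sqrt(sum(u^2))
      spec <- if (dir > 0)
        asymmetry_spec(me_lateral_shift = mag, cd_shift_left = mag * u)
      else
        asymmetry_spec(me_lateral_shift = -mag, cd_shift_right = mag * u)
      clean <- apply_asymmetry(base, spec)
    }
    sa <- semiangle_symmetry(clean)
    disc <- lr_discrepancy(compute_measurements(clean))
    truth$true_semiangle_diff_deg[i] <- sa$difference
    truth$true_max_discrepancy_mm[i] <- disc$max_discrepancy
    truth$label[i] <- if (sa$symmetric && disc$within_threshold)
      "symmetric" else "asymmetric"
    subjects[[i]] <- .add_noise(clean, noise_sd)
  }
  structure(list(subjects = subjects, truth = truth,
                 params = list(n = n, symmetric_fraction = symmetric_fraction,
                               asym_magnitude_range = asym_magnitude_range,
                               noise_sd = noise_sd, seed = as.integer(seed))),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("<labeled_cohort> n =", length(x$subjects),
      "| symmetric:", sum(x$truth$label == "symmetric"),
      "| noise_sd:", x$params$noise_sd, "mm | seed:", x$params$seed, "\n")
  invisible(x)
}

#' Write a labeled cohort to disk
#'
#' Emits `cohort.csv` (landmark CSV dialect), `truth.csv`
#' (`subject_id,true_semiangle_diff_deg,true_max_discrepancy_mm,label`)
#' and `params.json` (generator parameters including the seed).
#'
#' @param cohort a `labeled_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landmarks(cohort$subjects, file.path(dir, "cohort.csv"), "csv")
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
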