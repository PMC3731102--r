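# Per-subject craniofacial symmetry analysis: 21 distances, 7 triangles,
# the condylar semiangle test, facial and mandibular ratio systems, and the
# left-right millimetric discrepancy classification.

#' Analysis configuration
#'
#' Collects the tunable parameters of the analysis. Thresholds are
#' inclusive: a subject exactly at the threshold is classified symmetric.
#'
#' @param semiangle_threshold_deg maximum semiangle difference (degrees)
#'   still called symmetric; default 4.
#' @param discrepancy_threshold_mm maximum left-right distance discrepancy
#'   (mm) still called within-threshold; default 5.
#' @param ratio_tolerance deviation from 1 beyond which a facial ratio is
#'   flagged; default 0.10. An artifact parameter, not a clinical norm.
#' @param sd_estimator `"sample"` (n-1 denominator, default) or
#'   `"population"` for cohort standard deviations.
#' @return A list of class `ceph_config`.
#' @export
ceph_config <- function(semiangle_threshold_deg = 4,
                        discrepancy_threshold_mm = 5,
                        ratio_tolerance = 0.10,
                        sd_estimator = c("sample", "population")) {
  stopifnot(semiangle_threshold_deg > 0, discrepancy_threshold_mm > 0,
            ratio_tolerance > 0)
  structure(list(semiangle_threshold_deg = semiangle_threshold_deg,
                 discrepancy_threshold_mm = discrepancy_threshold_mm,
                 ratio_tolerance = ratio_tolerance,
                 sd_estimator = match.arg(sd_estimator)),
            class = "ceph_config")
}

#' Compute the 21 registry distances for one subject
#'
#' @param s a complete [landmark_set()].
#' @return An object of class `measurement_vector`: list with
#'   `subject_id` and `values`, a named numeric vector of the 21
#'   inter-landmark Euclidean distances in mm, in registry order.
#' @examples
#' m <- compute_measurements(symmetric_template())
#' m$values[c("CdR-Me", "CdL-Me")]
#' @export
compute_measurements <- function(s) {
  stopifnot(inherits(s, "landmark_set"))
  .require_complete(s)
  reg <- measurement_registry()
  vals <- vapply(seq_len(nrow(reg)), function(i) {
    point_distance(s$points[reg$end1[i], ], s$points[reg$end2[i], ])
  }, numeric(1))
  names(vals) <- reg$code
  structure(list(subject_id = s$subject_id, values = vals),
            class = "measurement_vector")
}

#' Condylar semiangle symmetry test
#'
#' The apex angle of the condyle-menton triangle (angle CdR-Me-CdL) is
#' split by the ray from Me to CdM, the midpoint of the inter-condylar
#' segment CdR-CdL, into two semiangles. The median from the apex bisects
#' the apex angle exactly when the triangle is isosceles
#' (|CdR-Me| = |CdL-Me|), so the semiangle difference is a direct index
#' of left-right mandibular symmetry.
#'
#' @param s a [landmark_set()] containing at least CdR, CdL and Me.
#' @param threshold_deg inclusive symmetry threshold in degrees
#'   (default 4).
#' @return An object of class `semiangle_result`: list with `full_angle`,
#'   `semi_right` (CdR-Me-CdM), `semi_left` (CdL-Me-CdM), `difference`
#'   (all degrees), `symmetric` (difference <= threshold), `threshold`,
#'   and `degenerate` (TRUE when Me is collinear with CdR-CdL, in which
#'   case the semiangles are ill-conditioned and the result is flagged
#'   rather than trusted).
#' @examples
#' semiangle_symmetry(symmetric_template())$difference  # 0
#' @export
semiangle_symmetry <- function(s, threshold_deg = 4) {
  stopifnot(inherits(s, "landmark_set"), threshold_deg > 0)
  .require_landmarks(s, c("CdR", "CdL", "Me"))
  cdr <- s$points["CdR", ]; cdl <- s$points["CdL", ]; me <- s$points["Me", ]
  cdm <- midpoint(cdr, cdl)
  # collinearity: height of Me over line CdR-CdL via the cross product
  u <- cdl - cdr
  w <- me - cdr
  cr <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  nu <- sqrt(sum(u^2))
  degenerate <- nu < .DEGENERACY_TOL_MM ||
    sqrt(sum(cr^2)) / nu < .DEGENERACY_TOL_MM
  full <- vertex_angle(cdr, me, cdl)
  if (sqrt(sum((me - cdm)^2)) < .DEGENERACY_TOL_MM) {
    # Me sits on the inter-condylar midpoint: the bisecting ray is
    # undefined; report the flag with NA semiangles rather than failing
    semi_r <- semi_l <- diff <- NA_real_
    symmetric <- NA
  } else {
    semi_r <- vertex_angle(cdr, me, cdm)
    semi_l <- vertex_angle(cdl, me, cdm)
    diff <- abs(semi_r - semi_l)
    symmetric <- diff <= threshold_deg
  }
  structure(list(full_angle = full,
                 semi_right = semi_r,
                 semi_left = semi_l,
                 difference = diff,
                 symmetric = symmetric,
                 threshold = threshold_deg,
                 degenerate = degenerate),
            class = "semiangle_result")
}

#' @export
print.semiangle_result <- function(x, ...) {
  cat(sprintf("<semiangle> full %.3f deg; R %.3f / L %.3f; diff %.3f deg -> %s%s\n",
              x$full_angle, x$semi_right, x$semi_left, x$difference,
              if (isTRUE(x$symmetric)) "symmetric"
              else if (isFALSE(x$symmetric)) "asymmetric" else "undetermined",
              if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

#' Facial 1:1 ratio table
#'
#' All 45 unordered-pair ratios among the 10 distances of the three facial
#' triangles (CdR-Me-CdL, FzR-Me-FzL, GoR-N-GoL) and the Gl-Me height.
#' Perfect craniofacial proportionality would put every ratio at 1:1.
#' The numerator is the earlier distance in registry order, so the table
#' is deterministic and each ratio's inverse is recoverable exactly.
#'
#' @param m a `measurement_vector` from [compute_measurements()].
#' @param tolerance deviation from 1 beyond which a ratio is flagged
#'   (default 0.10).
#' @return A data.frame of class `ratio_table` with columns `numerator`,
#'   `denominator`, `ratio`, `deviates` (logical, |ratio - 1| > tolerance).
#' @export
facial_ratios <- function(m, tolerance = 0.10) {
  stopifnot(inherits(m, "measurement_vector"), tolerance > 0)
  d <- m$values[.FACIAL_RATIO_DISTANCES]
  if (any(d < .DEGENERACY_TOL_MM))
    stop("degenerate (zero) distance among facial ratio inputs: ",
         paste(names(d)[d < .DEGENERACY_TOL_MM], collapse = ", "))
  idx <- utils::combn(length(d), 2)
  out <- data.frame(
    numerator = names(d)[idx[1, ]],
    denominator = names(d)[idx[2, ]],
    ratio = as.numeric(d[idx[1, ]] / d[idx[2, ]]),
    stringsAsFactors = FALSE)
  out$deviates <- abs(out$ratio - 1) > tolerance
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' The nine mandibular ramus/body ratios
#'
#' Left/right homologue ratios of the four mandibular triangles (two ramus
#' Kr-Cd-Go, two body DB-Me-Go) plus within-body and base ratios, named
#' exactly as reported: `R_Kr_Cd`, `R_Kr_Go`, `R_Cd_Go`, `R_DB_Go`,
#' `R_Go_Me` (left over right), `R_DB_GoL_Me`, `R_DB_GoR_Me` (DB side over
#' Me side), `R_KrL_CdL_DB_Me`, `R_KrR_CdR_DB_Me` (ramus base over DB-Me).
#'
#' @param m a `measurement_vector` from [compute_measurements()].
#' @return A named numeric vector of length 9, class `mandible_ratios`.
#' @examples
#' mandible_ratios(compute_measurements(symmetric_template()))
#' @export
mandible_ratios <- function(m) {
  stopifnot(inherits(m, "measurement_vector"))
  reg <- mandible_ratio_registry()
  den <- m$values[reg$denominator]
  if (any(den < .DEGENERACY_TOL_MM))
    stop("degenerate (zero) denominator distance: ",
         paste(reg$denominator[den < .DEGENERACY_TOL_MM], collapse = ", "))
  r <- as.numeric(m$values[reg$numerator] / den)
  names(r) <- reg$code
  class(r) <- "mandible_ratios"
  r
}

#' @export
print.mandible_ratios <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Left-right millimetric discrepancy classification
#'
#' Compares right and left homologues of three facial distances
#' (FzR-Me vs FzL-Me, GoR-N vs GoL-N, CdR-Me vs CdL-Me) and classifies the
#' subject by whether the largest absolute difference stays within the
#' threshold (inclusive).
#'
#' @param m a `measurement_vector` from [compute_measurements()].
#' @param threshold_mm inclusive threshold in mm (default 5).
#' @return An object of class `discrepancy_result`: list with `d_Fz`,
#'   `d_Go`, `d_Cd`, `max_discrepancy` (mm), `within_threshold` (logical)
#'   and `threshold`.
#' @export
lr_discrepancy <- function(m, threshold_mm = 5) {
  stopifnot(inherits(m, "measurement_vector"), threshold_mm > 0)
  d <- vapply(.DISCREPANCY_PAIRS, function(pp) {
    abs(m$values[[pp[1]]] - m$values[[pp[2]]])
  }, numeric(1))
  structure(list(d_Fz = d[["d_Fz"]], d_Go = d[["d_Go"]], d_Cd = d[["d_Cd"]],
                 max_discrepancy = max(d),
                 within_threshold = max(d) <= threshold_mm,
                 threshold = threshold_mm),
            class = "discrepancy_result")
}

#' @export
print.discrepancy_result <- function(x, ...) {
  cat(sprintf("<discrepancy> Fz %.2f, Go %.2f, Cd %.2f mm; max %.2f -> %s\n",
              x$d_Fz, x$d_Go, x$d_Cd, x$max_discrepancy,
              if (x$within_threshold) "within threshold" else "beyond threshold"))
  invisible(x)
}

#' Full per-subject analysis
#'
#' Runs every stage of the analysis on one subject: the 21 distances, the
#' 7 triangles, the condylar semiangle test, the 45 facial ratios, the 9
#' mandibular ratios and the left-right discrepancy classification.
#'
#' @param s a complete [landmark_set()].
#' @param config a [ceph_config()].
#' @return An object of class `patient_report`: list with `subject_id`,
#'   `measurements`, `triangles` (named list of 7 `triangle_metrics`),
#'   `semiangle`, `facial_ratios`, `mandible_ratios`, `discrepancy`.
#' @examples
#' rep <- analyze_patient(symmetric_template())
#' rep$semiangle$symmetric
#' @export
analyze_patient <- function(s, config = ceph_config()) {
  stopifnot(inherits(s, "landmark_set"), inherits(config, "ceph_config"))
  .require_complete(s)
  m <- compute_measurements(s)
  tris <- lapply(triangle_registry(), function(v)
    triangle_metrics(v[1], v[2], v[3], s))
  structure(list(
    subject_id = s$subject_id,
    measurements = m,
    triangles = tris,
    semiangle = semiangle_symmetry(s, config$semiangle_threshold_deg),
    facial_ratios = facial_ratios(m, config$ratio_tolerance),
    mandible_ratios = mandible_ratios(m),
    discrepancy = lr_discrepancy(m, config$discrepancy_threshold_mm),
    config = config),
    class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report> subject '", x$subject_id, "'\n", sep = "")
  print(x$semiangle)
  print(x$discrepancy)
  cat(sprintf("  facial ratios flagged (|r-1| > %.2f): %d of %d\n",
              x$config$ratio_tolerance, sum(x$facial_ratios$deviates),
              nrow(x$facial_ratios)))
  invisible(x)
}

#' Flatten patient reports to one row per subject
#'
#' @param reports a list of `patient_report` objects (or a single one).
#' @return A data.frame with one row per subject: the 21 measurements
#'   (columns named by distance code), the semiangle fields, the 9
#'   mandibular ratios (registry codes verbatim), the three discrepancies
#'   and classification flags.
#' @export
patient_table <- function(reports) {
  if (inherits(reports, "patient_report")) reports <- list(reports)
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, logical(1), "patient_report")))
  rows <- lapply(reports, function(r) {
    out <- c(list(subject_id = r$subject_id),
             as.list(r$measurements$values),
             list(full_angle_deg = r$semiangle$full_angle,
                  semi_right_deg = r$semiangle$semi_right,
                  semi_left_deg = r$semiangle$semi_left,
                  semiangle_diff_deg = r$semiangle$difference,
                  semiangle_symmetric = r$semiangle$symmetric,
                  semiangle_degenerate = r$semiangle$degenerate),
             as.list(unclass(r$mandible_ratios)),
             list(d_Fz_mm = r$discrepancy$d_Fz,
                  d_Go_mm = r$discrepancy$d_Go,
                  d_Cd_mm = r$discrepancy$d_Cd,
                  max_discrepancy_mm = r$discrepancy$max_discrepancy,
                  within_discrepancy_threshold = r$discrepancy$within_threshold))
    as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize patient reports to JSON
#'
#' @param reports list of `patient_report` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patient_reports <- function(reports, path) {
  if (inherits(reports, "patient_report")) reports <- list(reports)
  recs <- lapply(reports, function(r) {
    list(subject_id = r$subject_id,
         measurements = as.list(r$measurements$values),
         triangles = lapply(r$triangles, function(t)
           list(vertices = t$vertices,
                side_lengths = as.list(t$side_lengths),
                vertex_angles = as.list(t$vertex_angles),
                perimeter = t$perimeter)),
         semiangle = unclass(r$semiangle),
         facial_ratios = as.data.frame(r$facial_ratios),
         mandible_ratios = as.list(unclass(r$mandible_ratios)),
         discrepancy = unclass(r$discrepancy))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
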