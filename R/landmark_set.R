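# The per-subject landmark container and its validation.

.DEGENERACY_TOL_MM <- 1e-9

#' Construct a landmark set
#'
#' A landmark set holds one subject's named 3D landmark coordinates in
#' millimetres, in an arbitrary right-handed scanner frame. No axis
#' orientation convention is imposed: every quantity the analysis reports
#' is invariant under rigid motion.
#'
#' @param subject_id single character subject identifier.
#' @param points named list of numeric length-3 vectors `(x, y, z)` in mm,
#'   or a numeric matrix with 3 columns and landmark codes as row names.
#'   Names must come from [landmark_codes()]; duplicates are an error.
#' @param age optional age in years.
#' @return An object of class `landmark_set`: a list with elements
#'   `subject_id`, `age`, and `points` (matrix, rows in registry order of
#'   the landmarks present, columns `x`, `y`, `z`).
#' @examples
#' s <- symmetric_template()
#' s$points["Me", ]
#' @export
landmark_set <- function(subject_id, points, age = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id))
    stop("subject_id must be a single character string")
  if (is.list(points)) {
    if (is.null(names(points)))
      stop("points must be named by landmark code")
    m <- do.call(rbind, lapply(points, function(p) {
      p <- as.numeric(p)
      if (length(p) != 3L) stop("each point must have exactly 3 coordinates")
      p
    }))
    rownames(m) <- names(points)
    points <- m
  }
  if (!is.matrix(points) || ncol(points) != 3L || is.null(rownames(points)))
    stop("points must be a 3-column matrix with landmark codes as row names")
  codes <- rownames(points)
  bad <- setdiff(codes, .LANDMARK_CODES)
  if (length(bad) > 0L)
    stop("unknown landmark code(s): ", paste(unique(bad), collapse = ", "))
  dup <- codes[duplicated(codes)]
  if (length(dup) > 0L)
    stop("duplicate landmark code(s) for subject '", subject_id, "': ",
         paste(unique(dup), collapse = ", "))
  storage.mode(points) <- "double"
  # registry order, keeping only landmarks present
  ord <- .LANDMARK_CODES[.LANDMARK_CODES %in% codes]
  points <- points[ord, , drop = FALSE]
  colnames(points) <- c("x", "y", "z")
  structure(list(subject_id = subject_id,
                 age = if (is.null(age)) NA_real_ else as.numeric(age),
                 points = points),
            class = "landmark_set")
}

#' Test whether a landmark set has all 12 landmarks
#' @param s a `landmark_set`.
#' @return `TRUE` if every registry landmark is present.
#' @export
is_complete <- function(s) {
  stopifnot(inherits(s, "landmark_set"))
  all(.LANDMARK_CODES %in% rownames(s$points))
}

.missing_codes <- function(s) setdiff(.LANDMARK_CODES, rownames(s$points))

.require_landmarks <- function(s, codes) {
  miss <- setdiff(codes, rownames(s$points))
  if (length(miss) > 0L)
    stop("subject '", s$subject_id, "' is missing landmark(s): ",
         paste(miss, collapse = ", "))
  invisible(s)
}

.require_complete <- function(s) .require_landmarks(s, .LANDMARK_CODES)

#' Validate a landmark set
#'
#' Reports (never raises) every structural problem with a subject's
#' landmarks: missing registry codes, non-finite coordinates, and
#' degenerate (coincident) landmark pairs closer than 1e-9 mm.
#'
#' @param s a `landmark_set`.
#' @return An object of class `ceph_validation`: a list with elements
#'   `subject_id`, `missing` (character), `nonfinite` (character codes
#'   with any non-finite coordinate), `degenerate_pairs` (data.frame with
#'   columns `a`, `b`), and `ok` (logical: no problems found).
#' @examples
#' validate_landmark_set(symmetric_template())$ok
#' @export
validate_landmark_set <- function(s) {
  stopifnot(inherits(s, "landmark_set"))
  pts <- s$points
  nonfinite <- rownames(pts)[!apply(is.finite(pts), 1L, all)]
  codes <- rownames(pts)
  deg_a <- character(0); deg_b <- character(0)
  if (nrow(pts) >= 2L) {
    for (i in seq_len(nrow(pts) - 1L)) {
      for (j in seq((i + 1L), nrow(pts))) {
        d2 <- sum((pts[i, ] - pts[j, ])^2)
        if (is.finite(d2) && d2 < .DEGENERACY_TOL_MM^2) {
          deg_a <- c(deg_a, codes[i]); deg_b <- c(deg_b, codes[j])
        }
      }
    }
  }
  res <- list(subject_id = s$subject_id,
              missing = .missing_codes(s),
              nonfinite = nonfinite,
              degenerate_pairs = data.frame(a = deg_a, b = deg_b,
                                            stringsAsFactors = FALSE))
  res$ok <- length(res$missing) == 0L && length(res$nonfinite) == 0L &&
    nrow(res$degenerate_pairs) == 0L
  class(res) <- "ceph_validation"
  res
}

#' @export
print.ceph_validation <- function(x, ...) {
  cat("Landmark validation for subject '", x$subject_id, "'\n", sep = "")
  if (x$ok) {
    cat("  OK: complete, finite, non-degenerate\n")
  } else {
    if (length(x$missing) > 0L)
      cat("  missing:", paste(x$missing, collapse = ", "), "\n")
    if (length(x$nonfinite) > 0L)
      cat("  non-finite coordinates:", paste(x$nonfinite, collapse = ", "), "\n")
    if (nrow(x$degenerate_pairs) > 0L)
      cat("  coincident pairs:",
          paste(paste0(x$degenerate_pairs$a, "/", x$degenerate_pairs$b),
                collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> subject '", x$subject_id, "': ",
      nrow(x$points), "/12 landmarks",
      if (!is.na(x$age)) paste0(", age ", x$age) else "", "\n", sep = "")
  print(round(x$points, 3))
  invisible(x)
}
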