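# Readers and writers for subject landmark data.
#
# Three formats:
#   csv  - the package dialect: header `subject_id,landmark,x_mm,y_mm,z_mm`,
#          comma separated, UTF-8, '.' decimal; many subjects per file.
#   fcsv - 3D Slicer markups fiducial file; one subject per file, labels
#          mapped onto landmark codes case-insensitively.
#   json - array of {"subject_id": ..., "age": ..., "points": {code: [x,y,z]}}.
#
# Coordinates are carried through unchanged, in millimetres; writing uses
# full double precision ("%.17g") so a write/load round trip is exact.

.CSV_HEADER <- c("subject_id", "landmark", "x_mm", "y_mm", "z_mm")

.check_format <- function(format) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("csv", "fcsv", "json"))
    stop("unsupported format '", paste(format, collapse = ","),
         "'; must be one of: csv, fcsv, json")
  format
}

#' Load landmark sets from a file
#'
#' @param path path to the input file.
#' @param format one of `"csv"` (package dialect), `"fcsv"` (3D Slicer
#'   fiducials, one subject per file) or `"json"`.
#' @param subject_id subject identifier for `fcsv` input, which carries
#'   none; defaults to the file name without extension.
#' @return A list of [landmark_set()] objects, one per subject, in file
#'   order. Malformed rows, unknown landmark codes (except in `fcsv`,
#'   where unknown labels are skipped with a warning) and duplicate
#'   (subject, landmark) rows are errors naming the offending line.
#' @examples
#' f <- system.file("extdata", "synthetic_cohort.csv", package = "ceph3d")
#' cohort <- load_landmarks(f, "csv")
#' length(cohort)
#' @export
load_landmarks <- function(path, format = c("csv", "fcsv", "json"),
                           subject_id = NULL) {
  format <- .check_format(match.arg(format))
  if (!file.exists(path)) stop("input file not found: ", path)
  switch(format,
    csv = .load_csv(readLines(path, encoding = "UTF-8")),
    fcsv = .load_fcsv(readLines(path, encoding = "UTF-8"),
                      subject_id = if (is.null(subject_id))
                        sub("\\.[^.]*$", "", basename(path)) else subject_id),
    json = .load_json(path))
}

.parse_num <- function(txt, line_no, what) {
  x <- suppressWarnings(as.numeric(txt))
  if (any(is.na(x)))
    stop("line ", line_no, ": non-numeric ", what, " '", txt[is.na(x)][1], "'")
  x
}

.load_csv <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty landmark CSV: no header")
  hdr <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  if (!identical(hdr, .CSV_HEADER))
    stop("bad landmark CSV header; expected '",
         paste(.CSV_HEADER, collapse = ","), "'")
  recs <- list()
  for (i in seq_along(lines)[-1]) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(f) != 5L)
      stop("line ", i, ": expected 5 comma-separated fields, found ", length(f))
    f <- trimws(f)
    code <- f[2]
    if (!code %in% .LANDMARK_CODES)
      stop("line ", i, ": unknown landmark code '", code, "'")
    xyz <- .parse_num(f[3:5], i, "coordinate")
    recs[[length(recs) + 1L]] <- list(subject = f[1], code = code,
                                      xyz = xyz, line = i)
  }
  .assemble_subjects(recs)
}

.assemble_subjects <- function(recs) {
  if (length(recs) == 0L) return(list())
  subjects <- unique(vapply(recs, `[[`, character(1), "subject"))
  out <- vector("list", length(subjects))
  names(out) <- subjects
  for (sid in subjects) {
    rr <- Filter(function(r) r$subject == sid, recs)
    codes <- vapply(rr, `[[`, character(1), "code")
    dup <- duplicated(codes)
    if (any(dup)) {
      r <- rr[[which(dup)[1]]]
      stop("line ", r$line, ": duplicate landmark '", r$code,
           "' for subject '", sid, "'")
    }
    pts <- do.call(rbind, lapply(rr, `[[`, "xyz"))
    rownames(pts) <- codes
    out[[sid]] <- landmark_set(sid, pts)
  }
  unname(out)
}

.load_fcsv <- function(lines, subject_id) {
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  codes <- character(0)
  pts <- list()
  lut <- stats::setNames(.LANDMARK_CODES, tolower(.LANDMARK_CODES))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("fcsv line ", i, ": expected >= 12 fields, found ", length(f))
    label <- trimws(f[12])
    code <- lut[tolower(label)]
    if (is.na(code)) {
      warning("fcsv: skipping unknown fiducial label '", label, "'")
      next
    }
    codes <- c(codes, code)
    pts[[length(pts) + 1L]] <- .parse_num(f[2:4], i, "coordinate")
  }
  if (length(pts) == 0L)
    return(list())
  m <- do.call(rbind, pts)
  rownames(m) <- codes
  list(landmark_set(subject_id, m))
}

.load_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(obj$subject_id)) obj <- list(obj)  # single-subject file
  lapply(obj, function(rec) {
    if (is.null(rec$subject_id) || is.null(rec$points))
      stop("JSON record must have 'subject_id' and 'points'")
    pts <- lapply(rec$points, function(p) as.numeric(unlist(p)))
    landmark_set(as.character(rec$subject_id), pts,
                 age = rec$age)
  })
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write landmark sets to a file
#'
#' Output is deterministic: subjects in input order, landmarks in registry
#' order, coordinates at full double precision so
#' `load_landmarks(write_landmarks(x))` reproduces `x` exactly.
#'
#' @param cohort a list of [landmark_set()] objects (or a single one).
#' @param path output file path.
#' @param format one of `"csv"`, `"fcsv"` (single subject only), `"json"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(cohort, path, format = c("csv", "fcsv", "json")) {
  format <- .check_format(match.arg(format))
  if (inherits(cohort, "landmark_set")) cohort <- list(cohort)
  if (!all(vapply(cohort, inherits, logical(1), "landmark_set")))
    stop("cohort must be a list of landmark_set objects")
  if (any(vapply(cohort, function(s) nrow(s$points) == 0L, logical(1))))
    stop("cannot write a landmark set with no points")
  lines <- switch(format,
    csv = .write_csv(cohort),
    fcsv = .write_fcsv(cohort),
    json = .write_json_lm(cohort))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.write_csv <- function(cohort) {
  rows <- character(0)
  for (s in cohort) {
    pts <- s$points
    for (code in rownames(pts)) {
      rows <- c(rows, paste(s$subject_id, code,
                            .fmt_num(pts[code, 1]), .fmt_num(pts[code, 2]),
                            .fmt_num(pts[code, 3]), sep = ","))
    }
  }
  c(paste(.CSV_HEADER, collapse = ","), rows)
}

.write_fcsv <- function(cohort) {
  if (length(cohort) != 1L)
    stop("fcsv holds one subject per file; got ", length(cohort), " subjects")
  s <- cohort[[1]]
  pts <- s$points
  hdr <- c("# Markups fiducial file version = 4.11",
           "# CoordinateSystem = LPS",
           paste0("# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,",
                  "label,desc,associatedNodeID"))
  rows <- vapply(seq_len(nrow(pts)), function(i) {
    paste(paste0("F", i),
          .fmt_num(pts[i, 1]), .fmt_num(pts[i, 2]), .fmt_num(pts[i, 3]),
          "0", "0", "0", "1", "1", "1", "0",
          rownames(pts)[i], s$subject_id, "", sep = ",")
  }, character(1))
  c(hdr, rows)
}

.write_json_lm <- function(cohort) {
  recs <- lapply(cohort, function(s) {
    pts <- lapply(seq_len(nrow(s$points)),
                  function(i) as.numeric(s$points[i, ]))
    names(pts) <- rownames(s$points)
    rec <- list(subject_id = s$subject_id, points = pts)
    if (!is.na(s$age)) rec$age <- s$age
    rec
  })
  # I(17) significant digits: enough to reproduce any double exactly
  jsonlite::toJSON(recs, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}
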