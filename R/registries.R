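# Landmark, measurement and triangle registries.
#
# The vocabulary is closed: 12 cephalometric landmarks, 21 inter-landmark
# distances, 7 diagnostic triangles (3 facial, 4 mandibular). All analysis
# code keys into these tables; nothing outside them is ever measured.

.LANDMARK_CODES <- c("CdR", "CdL", "GoR", "GoL", "FzR", "FzL",
                     "KrR", "KrL", "Me", "N", "Gl", "DB")

.LANDMARK_SIDE <- c(CdR = "right", CdL = "left",
                    GoR = "right", GoL = "left",
                    FzR = "right", FzL = "left",
                    KrR = "right", KrL = "left",
                    Me = "midline", N = "midline",
                    Gl = "midline", DB = "midline")

# distance codes in registry order; the first 10 are the facial-ratio set
.MEASUREMENT_CODES <- c(
  "CdR-Me", "CdL-Me", "CdR-CdL",
  "FzR-Me", "FzL-Me", "FzR-FzL",
  "GoR-N",  "GoL-N",  "GoR-GoL",
  "Gl-Me",
  "KrR-CdR", "KrR-GoR", "CdR-GoR",
  "KrL-CdL", "KrL-GoL", "CdL-GoL",
  "DB-Me",  "DB-GoR", "Me-GoR",
  "DB-GoL", "Me-GoL"
)

.TRIANGLES <- list(
  "CdR-Me-CdL"  = c("CdR", "Me", "CdL"),
  "FzR-Me-FzL"  = c("FzR", "Me", "FzL"),
  "GoR-N-GoL"   = c("GoR", "N", "GoL"),
  "KrR-CdR-GoR" = c("KrR", "CdR", "GoR"),
  "KrL-CdL-GoL" = c("KrL", "CdL", "GoL"),
  "DB-Me-GoR"   = c("DB", "Me", "GoR"),
  "DB-Me-GoL"   = c("DB", "Me", "GoL")
)

.MANDIBULAR_TRIANGLES <- c("KrR-CdR-GoR", "KrL-CdL-GoL",
                           "DB-Me-GoR", "DB-Me-GoL")

# the 10 distances entering the facial 1:1 ratio analysis, registry order
.FACIAL_RATIO_DISTANCES <- .MEASUREMENT_CODES[1:10]

# mandibular ratios: numerator / denominator, named exactly as reported
.MANDIBLE_RATIO_DEFS <- list(
  R_Kr_Cd         = c("KrL-CdL", "KrR-CdR"),
  R_Kr_Go         = c("KrL-GoL", "KrR-GoR"),
  R_Cd_Go         = c("CdL-GoL", "CdR-GoR"),
  R_DB_Go         = c("DB-GoL",  "DB-GoR"),
  R_Go_Me         = c("Me-GoL",  "Me-GoR"),
  R_DB_GoL_Me     = c("DB-GoL",  "Me-GoL"),
  R_DB_GoR_Me     = c("DB-GoR",  "Me-GoR"),
  R_KrL_CdL_DB_Me = c("KrL-CdL", "DB-Me"),
  R_KrR_CdR_DB_Me = c("KrR-CdR", "DB-Me")
)

# distances entering the left-right millimetric discrepancy check
.DISCREPANCY_PAIRS <- list(
  d_Fz = c("FzR-Me", "FzL-Me"),
  d_Go = c("GoR-N",  "GoL-N"),
  d_Cd = c("CdR-Me", "CdL-Me")
)

#' Landmark registry
#'
#' The 12 cephalometric landmarks of the analysis: paired condyle (Cd),
#' gonion (Go), frontozygomatic (Fz) and coronoid/ramus (Kr) points on the
#' right (R) and left (L) sides, and four midline points: menton (Me),
#' nasion (N), glabella (Gl) and the mandibular-body midline point (DB).
#'
#' @return A data.frame with columns `code` and `laterality`
#'   (`"right"`, `"left"` or `"midline"`), one row per landmark, in
#'   registry order.
#' @examples
#' landmark_registry()
#' @export
landmark_registry <- function() {
  data.frame(code = .LANDMARK_CODES,
             laterality = unname(.LANDMARK_SIDE[.LANDMARK_CODES]),
             stringsAsFactors = FALSE)
}

#' Landmark codes in registry order
#' @return Character vector of the 12 landmark codes.
#' @export
landmark_codes <- function() .LANDMARK_CODES

#' Mirror partner of a landmark
#'
#' Lateral landmarks map to their contralateral homologue (`CdR` to `CdL`
#' and vice versa); midline landmarks map to themselves. The map restricted
#' to lateral landmarks is an involution with no fixed points.
#'
#' @param code character vector of landmark codes.
#' @return Character vector of partner codes.
#' @examples
#' mirror_partner(c("CdR", "Me", "KrL"))
#' @export
mirror_partner <- function(code) {
  bad <- setdiff(code, .LANDMARK_CODES)
  if (length(bad) > 0L)
    stop("unknown landmark code(s): ", paste(bad, collapse = ", "))
  vapply(code, function(cc) {
    side <- .LANDMARK_SIDE[[cc]]
    if (side == "midline") return(cc)
    stem <- substr(cc, 1L, nchar(cc) - 1L)
    paste0(stem, if (side == "right") "L" else "R")
  }, character(1), USE.NAMES = FALSE)
}

#' Measurement registry
#'
#' The 21 inter-landmark linear distances, each an unordered pair of
#' distinct landmarks. Their union is exactly the sides of the 7 diagnostic
#' triangles plus the midline height Gl-Me.
#'
#' @return A data.frame with columns `code`, `end1`, `end2`, in registry
#'   order.
#' @export
measurement_registry <- function() {
  ends <- strsplit(.MEASUREMENT_CODES, "-", fixed = TRUE)
  # lateral codes contain "-" only as the pair separator: split yields
  # exactly the two endpoint codes for every registry entry
  data.frame(code = .MEASUREMENT_CODES,
             end1 = vapply(ends, `[`, character(1), 1L),
             end2 = vapply(ends, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Measurement codes in registry order
#' @return Character vector of the 21 distance codes.
#' @export
measurement_codes <- function() .MEASUREMENT_CODES

#' Triangle registry
#'
#' The 7 diagnostic triangles: three facial/cranial (condyle-menton,
#' frontozygomatic-menton, gonion-nasion) and four mandibular (left and
#' right ramus Kr-Cd-Go, left and right body DB-Me-Go).
#'
#' @return A named list of length 7; each element the ordered character
#'   triple of vertex landmark codes. Names are the triangle codes.
#' @export
triangle_registry <- function() .TRIANGLES

#' Names of the four mandibular triangles
#' @return Character vector of length 4 (two ramus, two body triangles).
#' @export
mandibular_triangle_names <- function() .MANDIBULAR_TRIANGLES

#' Mandibular ratio definitions
#'
#' The nine ramus/body ratios: five left/right homologue ratios
#' (`R_Kr_Cd`, `R_Kr_Go`, `R_Cd_Go`, `R_DB_Go`, `R_Go_Me`, each left side
#' over right side), two within-body ratios (`R_DB_GoL_Me`, `R_DB_GoR_Me`,
#' DB-side over Me-side), and two base ratios (`R_KrL_CdL_DB_Me`,
#' `R_KrR_CdR_DB_Me`, ramus base over body base DB-Me).
#'
#' @return A data.frame with columns `code`, `numerator`, `denominator`.
#' @export
mandible_ratio_registry <- function() {
  data.frame(code = names(.MANDIBLE_RATIO_DEFS),
             numerator = vapply(.MANDIBLE_RATIO_DEFS, `[`, character(1), 1L),
             denominator = vapply(.MANDIBLE_RATIO_DEFS, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}
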