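# Exact 3D Euclidean primitives used by every analysis stage.

.pt <- function(s, code) {
  .require_landmarks(s, code)
  s$points[code, ]
}

#' Euclidean distance between two 3D points
#'
#' @param p,q numeric length-3 coordinate vectors in mm.
#' @return Distance in mm.
#' @examples
#' point_distance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
point_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 3L, length(q) == 3L,
            all(is.finite(p)), all(is.finite(q)))
  sqrt(sum((p - q)^2))
}

#' Midpoint of two 3D points
#'
#' @param p,q numeric length-3 coordinate vectors in mm.
#' @return The componentwise mean, equidistant from `p` and `q`.
#' @export
midpoint <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 3L, length(q) == 3L,
            all(is.finite(p)), all(is.finite(q)))
  (p + q) / 2
}

#' Interior angle at a vertex
#'
#' The angle in degrees between the rays `vertex -> a` and `vertex -> b`.
#' The cosine is clamped to \[-1, 1\] before `acos` so that near-collinear
#' configurations return 0 or 180 degrees rather than NaN.
#'
#' @param a,vertex,b numeric length-3 coordinate vectors in mm.
#' @return Angle in degrees, in \[0, 180\].
#' @examples
#' vertex_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
vertex_angle <- function(a, vertex, b) {
  a <- as.numeric(a); vertex <- as.numeric(vertex); b <- as.numeric(b)
  u <- a - vertex
  v <- b - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < .DEGENERACY_TOL_MM || nv < .DEGENERACY_TOL_MM)
    stop("degenerate ray: a point coincides with the vertex ",
         "(separation < ", .DEGENERACY_TOL_MM, " mm)")
  cs <- sum(u * v) / (nu * nv)
  cs <- max(-1, min(1, cs))
  acos(cs) * 180 / pi
}

#' Triangle metrics from three named landmarks
#'
#' Builds the full metric description of one diagnostic triangle: side
#' lengths keyed by the opposite vertex, interior angles at each vertex,
#' and the perimeter.
#'
#' @param a_name,v_name,b_name landmark codes of the three vertices
#'   (order follows the triangle's name, e.g. `"CdR"`, `"Me"`, `"CdL"`).
#' @param s a complete-enough [landmark_set()] containing the three.
#' @return An object of class `triangle_metrics`: list with `name`,
#'   `vertices`, `side_lengths` (named by opposite vertex, mm),
#'   `vertex_angles` (named by vertex, degrees), `perimeter` (mm).
#' @examples
#' tri <- triangle_metrics("CdR", "Me", "CdL", symmetric_template())
#' sum(tri$vertex_angles)  # 180
#' @export
triangle_metrics <- function(a_name, v_name, b_name, s) {
  stopifnot(inherits(s, "landmark_set"))
  verts <- c(a_name, v_name, b_name)
  .require_landmarks(s, verts)
  P <- lapply(verts, function(cc) s$points[cc, ])
  names(P) <- verts
  # side opposite each vertex
  sides <- c(point_distance(P[[2]], P[[3]]),
             point_distance(P[[1]], P[[3]]),
             point_distance(P[[1]], P[[2]]))
  names(sides) <- verts
  if (any(sides < .DEGENERACY_TOL_MM))
    stop("degenerate triangle ", paste(verts, collapse = "-"),
         ": coincident vertices")
  angles <- c(vertex_angle(P[[2]], P[[1]], P[[3]]),
              vertex_angle(P[[1]], P[[2]], P[[3]]),
              vertex_angle(P[[1]], P[[3]], P[[2]]))
  names(angles) <- verts
  structure(list(name = paste(verts, collapse = "-"),
                 vertices = verts,
                 side_lengths = sides,
                 vertex_angles = angles,
                 perimeter = sum(sides)),
            class = "triangle_metrics")
}

#' @export
print.triangle_metrics <- function(x, ...) {
  cat("<triangle> ", x$name, "\n", sep = "")
  cat("  sides (mm, opposite vertex): ",
      paste(sprintf("%s=%.2f", names(x$side_lengths), x$side_lengths),
            collapse = ", "), "\n", sep = "")
  cat("  angles (deg): ",
      paste(sprintf("%s=%.2f", names(x$vertex_angles), x$vertex_angles),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  perimeter: %.2f mm\n", x$perimeter))
  invisible(x)
}
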