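#' Parametric stenosis specification
#'
#' Describes a single axisymmetric narrowing of the lumen as a fraction of
#' diameter reduction at the throat, an axial extent and a throat position.
#' The default (and currently only) profile family is a smooth cosine bump,
#' the standard idealization in stenosis CFD.
#'
#' @param degree Fraction of diameter reduction at the throat,
#'   `0 <= degree < 1`. A healthy vessel has `degree = 0`.
#' @param length Axial extent of the narrowing (m), `> 0`.
#' @param center Axial position of the throat (m).
#' @param shape Profile family tag; only `"cosine"` is implemented.
#' @return An object of class `stenosis_spec`.
#' @seealso [lumen_geometry()], [radius_profile()]
#' @export
stenosis_spec <- function(degree, length, center, shape = "cosine") {
  stopifnot(is.numeric(degree), length(degree) == 1L, is.finite(degree))
  if (degree < 0 || degree >= 1)
    stop("stenosis degree must satisfy 0 <= degree < 1", call. = FALSE)
  if (!is.numeric(length) || length <= 0)
    stop("stenosis length must be > 0", call. = FALSE)
  shape <- match.arg(shape, "cosine")
  structure(list(degree = degree, length = length, center = center,
                 shape = shape),
            class = "stenosis_spec")
}

#' Parametric lumen geometry
#'
#' A straight arterial segment of length `L` and base radius `R0`, optionally
#' narrowed by a [stenosis_spec()] and optionally with an elliptic
#' cross-section of axis ratio `ellipse_ratio` (minor/major). Elliptic and
#' circular lumens are compared at equal cross-sectional area: the semi-axes
#' at axial position `z` are `a = r(z)/sqrt(kappa)`, `b = r(z)*sqrt(kappa)`
#' so that `pi*a*b = pi*r(z)^2` for every `kappa`.
#'
#' @param base_radius Unnarrowed lumen radius R0 (m), `> 0`.
#' @param segment_length Axial length L of the segment (m), `> 0`.
#' @param ellipse_ratio Minor/major axis ratio `kappa` in `(0, 1]`;
#'   `1` is a circle.
#' @param stenosis A [stenosis_spec()] or `NULL` for a healthy vessel.
#' @return An object of class `lumen_geometry`.
#' @export
lumen_geometry <- function(base_radius, segment_length, ellipse_ratio = 1,
                           stenosis = NULL) {
  stopifnot(is.numeric(base_radius), base_radius > 0,
            is.numeric(segment_length), segment_length > 0)
  if (!is.numeric(ellipse_ratio) || ellipse_ratio <= 0 || ellipse_ratio > 1)
    stop("ellipse_ratio must lie in (0, 1]", call. = FALSE)
  if (!is.null(stenosis)) {
    if (!inherits(stenosis, "stenosis_spec"))
      stop("stenosis must be a stenosis_spec or NULL", call. = FALSE)
    lo <- stenosis$center - stenosis$length / 2
    hi <- stenosis$center + stenosis$length / 2
    if (lo < 0 || hi > segment_length)
      stop("stenotic window [", signif(lo, 4), ", ", signif(hi, 4),
           "] must lie inside [0, L]", call. = FALSE)
  }
  structure(list(base_radius = base_radius,
                 segment_length = segment_length,
                 ellipse_ratio = ellipse_ratio,
                 stenosis = stenosis),
            class = "lumen_geometry")
}

#' @export
print.lumen_geometry <- function(x, ...) {
  cat("Lumen geometry: R0 =", x$base_radius, "m, L =", x$segment_length,
      "m, kappa =", x$ellipse_ratio, "\n")
  if (is.null(x$stenosis)) {
    cat("  healthy (no stenosis)\n")
  } else {
    cat(sprintf("  stenosis: %.0f%% diameter reduction, length %g m at z = %g m\n",
                100 * x$stenosis$degree, x$stenosis$length, x$stenosis$center))
  }
  invisible(x)
}

#' Local equivalent lumen radius
#'
#' Evaluates the axial radius profile r(z). Outside the stenotic window the
#' vessel keeps its base radius R0; inside, a smooth cosine bump narrows it to
#' `R0 * (1 - degree)` at the throat:
#' `r(z) = R0 - (s*R0/2) * (1 + cos(2*pi*(z - zc)/Ls))` for `|z - zc| <= Ls/2`.
#' The profile is C1-smooth and symmetric about the throat.
#'
#' @param z Axial positions (m), all within `[0, L]`.
#' @param geom A [lumen_geometry()].
#' @return Numeric vector of local equivalent radii (m).
#' @export
radius_profile <- function(z, geom) {
  stopifnot(inherits(geom, "lumen_geometry"), is.numeric(z))
  L <- geom$segment_length
  tol <- 1e-12 * L
  if (any(z < -tol | z > L + tol))
    stop("axial position z outside segment [0, L]", call. = FALSE)
  r <- rep(geom$base_radius, length(z))
  st <- geom$stenosis
  if (!is.null(st) && st$degree > 0) {
    inside <- abs(z - st$center) <= st$length / 2
    if (any(inside)) {
      bump <- (st$degree * geom$base_radius / 2) *
        (1 + cos(2 * pi * (z[inside] - st$center) / st$length))
      r[inside] <- geom$base_radius - bump
    }
  }
  r
}

#' Elliptic cross-section semi-axes
#'
#' Semi-axes of the lumen cross-section at axial position `z`, under the
#' equal-area convention: `a = r(z)/sqrt(kappa)`, `b = r(z)*sqrt(kappa)`,
#' so `pi*a*b = pi*r(z)^2` exactly for every axis ratio.
#'
#' @inheritParams radius_profile
#' @return A list with numeric components `a` (major, along x) and `b`
#'   (minor, along y), each the length of `z`.
#' @export
ellipse_section <- function(z, geom) {
  stopifnot(inherits(geom, "lumen_geometry"))
  kappa <- geom$ellipse_ratio
  if (kappa <= 0) stop("ellipse ratio must be positive", call. = FALSE)
  r <- radius_profile(z, geom)
  list(a = r / sqrt(kappa), b = r * sqrt(kappa))
}

#' Ellipse containment test
#'
#' Whether points `(x, y)` in the cross-section at axial position `z` lie
#' inside (or on) the lumen boundary, via `x^2/a^2 + y^2/b^2 <= 1`.
#'
#' @param x,y Transverse coordinates (m), recycled together.
#' @inheritParams radius_profile
#' @return Logical vector.
#' @export
ellipse_contains <- function(x, y, z, geom) {
  ab <- ellipse_section(z, geom)
  x^2 / ab$a^2 + y^2 / ab$b^2 <= 1
}
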