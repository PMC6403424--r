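#' Toroid geometry
#'
#' Geometric description of one toroidal subunit and of the helix it
#' polymerizes into. Only the 12 nm external diameter is an observed
#' quantity; tube diameter and pitch (close-packed turns, pitch = tube
#' diameter) are documented assumptions, exposed for configuration.
#'
#' @param external_diameter External toroid/helix diameter, nm.
#' @param tube_diameter Diameter of the supramolecular tube, nm.
#' @param pitch Helix rise per turn, nm (default: tube diameter,
#'   close-packed turns).
#' @param chirality +1 for the S enantiomer (right-handed helices), -1
#'   for R (left-handed), 0 for the racemic mixture (cannot polymerize).
#' @return An object of class \code{"toroid_geometry"}.
#' @export
toroid_geometry <- function(external_diameter = 12, tube_diameter = 3,
                            pitch = tube_diameter, chirality = 1L) {
  if (!(external_diameter > tube_diameter && tube_diameter > 0)) {
    stop("need external_diameter > tube_diameter > 0", call. = FALSE)
  }
  if (pitch <= 0) stop("pitch must be > 0", call. = FALSE)
  if (!chirality %in% c(-1L, 0L, 1L)) {
    stop("chirality must be +1 (S), -1 (R) or 0 (racemic)", call. = FALSE)
  }
  structure(list(external_diameter = external_diameter,
                 tube_diameter = tube_diameter, pitch = pitch,
                 chirality = as.integer(chirality)),
            class = "toroid_geometry")
}

#' Build a helical chain centerline
#'
#' Concatenates \code{n_units} one-turn spirals of the toroid's
#' centerline radius into a continuous helix along the z axis
#' (right-handed Cartesian frame; right-handedness = positive torsion).
#' The helix external diameter equals the generating toroid's for any
#' number of units: the helix retains the toroidal curvature.
#'
#' @param geometry A [toroid_geometry()] with chirality +1 or -1.
#' @param n_units Number of toroid units (>= 1, one turn each).
#' @param points_per_turn Sampling density of the centerline.
#' @return An object of class \code{"helix_model"}: \code{centerline}
#'   (matrix of xyz points, nm), \code{n_turns}, \code{handedness},
#'   \code{external_diameter}, \code{pitch}, \code{axial_length},
#'   \code{contour_length}.
#' @export
#' @examples
#' h <- build_helix(toroid_geometry(chirality = 1), 10)
#' h$external_diameter
build_helix <- function(geometry = toroid_geometry(), n_units,
                        points_per_turn = 64) {
  if (n_units < 1) stop("n_units must be >= 1", call. = FALSE)
  if (geometry$chirality == 0L) {
    stop("racemic toroids (chirality 0) are unable to polymerize: ",
         "no one-directional disc tilt, no spiral opening, no helix",
         call. = FALSE)
  }
  n_units <- as.integer(n_units)
  Rc <- (geometry$external_diameter - geometry$tube_diameter) / 2
  h <- geometry$chirality
  theta <- seq(0, n_units * 2 * pi, length.out = n_units * points_per_turn + 1)
  pts <- cbind(x = Rc * cos(theta),
               y = h * Rc * sin(theta),
               z = geometry$pitch * theta / (2 * pi))
  seglen <- sqrt(rowSums(diff(pts)^2))
  structure(list(centerline = pts, n_turns = n_units,
                 handedness = as.integer(h),
                 external_diameter = 2 * Rc + geometry$tube_diameter,
                 pitch = geometry$pitch,
                 axial_length = n_units * geometry$pitch,
                 contour_length = sum(seglen),
                 geometry = geometry),
            class = "helix_model")
}

#' @export
print.helix_model <- function(x, ...) {
  cat(sprintf("helix_model: %d turn(s), %s-handed, external diameter %.3g nm, axial length %.4g nm\n",
              x$n_turns, if (x$handedness > 0) "right" else "left",
              x$external_diameter, x$axial_length))
  invisible(x)
}

#' Handedness of a helix centerline
#'
#' Sign of the mean discrete torsion of the centerline, computed from
#' triple products of consecutive difference vectors: +1 for
#' right-handed helices (S enantiomer), -1 for left-handed (R).
#'
#' @param helix A \code{"helix_model"} (or a 3-column point matrix) with
#'   at least 2 turns' worth of points.
#' @return +1 or -1.
#' @export
handedness_of <- function(helix) {
  pts <- if (inherits(helix, "helix_model")) helix$centerline else helix
  if (nrow(pts) < 4) stop("need at least 4 centerline points", call. = FALSE)
  v <- diff(pts)
  n <- nrow(v)
  cr <- cbind(v[1:(n - 2), 2] * v[2:(n - 1), 3] - v[1:(n - 2), 3] * v[2:(n - 1), 2],
              v[1:(n - 2), 3] * v[2:(n - 1), 1] - v[1:(n - 2), 1] * v[2:(n - 1), 3],
              v[1:(n - 2), 1] * v[2:(n - 1), 2] - v[1:(n - 2), 2] * v[2:(n - 1), 1])
  trip <- rowSums(cr * v[3:n, , drop = FALSE])
  s <- sign(mean(trip))
  if (s == 0) stop("degenerate (planar) centerline has no handedness",
                   call. = FALSE)
  as.integer(s)
}

#' Mirror image of a helix
#'
#' Point-wise reflection through the xz plane; flips handedness.
#'
#' @param helix A \code{"helix_model"}.
#' @export
reflect_helix <- function(helix) {
  helix$centerline[, 2] <- -helix$centerline[, 2]
  helix$handedness <- -helix$handedness
  helix$geometry$chirality <- -helix$geometry$chirality
  helix
}

#' Spherocylinder shape of a vesicle deformed by an internal rod
#'
#' A spherical vesicle (radius \code{sphere_diameter / 2}) containing a
#' growing helical chain elongates into a spherocylinder (cylinder of
#' length \code{L_c} capped by two hemispheres of radius \code{r}) whose
#' total length equals the rod length. Under the default
#' \code{fixed_area} constraint the membrane area
#' \code{A = 4 pi r^2 + 2 pi r L_c} is conserved (lipid area is nearly
#' inextensible on these timescales; water permeates, so volume is
#' free), giving the closed form \code{r = A0 / (2 pi L)}. The
#' \code{fixed_volume} mode conserves the enclosed volume instead.
#'
#' @param rod_length Length of the encapsulated chain, nm (>= 0). The
#'   tubule length is equated with it.
#' @param sphere_diameter Resting vesicle diameter, nm (default 500, the
#'   extrusion pore size).
#' @param constraint \code{"fixed_area"} (default) or \code{"fixed_volume"}.
#' @param min_radius Smallest physically meaningful cap radius, nm
#'   (membrane tubes cannot be thinner than the bilayer); rods that
#'   would require \code{r < min_radius} raise an infeasibility error
#'   reporting the maximum supportable rod length.
#' @return An object of class \code{"vesicle_shape"} with fields
#'   \code{cap_radius}, \code{cylinder_length}, \code{total_length},
#'   \code{area}, \code{volume}, \code{aspect_ratio}, \code{constraint}.
#' @export
#' @examples
#' v <- vesicle_shape(1000, sphere_diameter = 500)
#' c(v$cap_radius, v$aspect_ratio)  # 125 nm, aspect 4
vesicle_shape <- function(rod_length, sphere_diameter = 500,
                          constraint = c("fixed_area", "fixed_volume"),
                          min_radius = 5) {
  constraint <- match.arg(constraint)
  if (rod_length < 0) stop("rod_length must be >= 0", call. = FALSE)
  if (sphere_diameter <= 0) stop("sphere_diameter must be > 0", call. = FALSE)
  R0 <- sphere_diameter / 2
  A0 <- 4 * pi * R0^2
  V0 <- 4 / 3 * pi * R0^3

  if (rod_length <= sphere_diameter) {
    return(new_vesicle_shape(R0, 0, constraint))
  }
  L <- rod_length
  if (constraint == "fixed_area") {
    r <- A0 / (2 * pi * L)
    if (r < min_radius) {
      stop(sprintf(paste0("rod too long for the available membrane area: ",
                          "r = %.3g nm < min_radius = %.3g nm; maximum ",
                          "supportable rod length is %.4g nm"),
                   r, min_radius, A0 / (2 * pi * min_radius)), call. = FALSE)
    }
  } else {
    g <- function(r) pi * r^2 * L - 2 / 3 * pi * r^3 - V0
    r <- stats::uniroot(g, c(1e-9, L / 2), tol = 1e-12)$root
    if (r < min_radius) {
      Lmax <- (V0 + 2 / 3 * pi * min_radius^3) / (pi * min_radius^2)
      stop(sprintf(paste0("rod too long for the enclosed volume: r = %.3g nm ",
                          "< min_radius = %.3g nm; maximum supportable rod ",
                          "length is %.4g nm"), r, min_radius, Lmax),
           call. = FALSE)
    }
  }
  new_vesicle_shape(r, L - 2 * r, constraint)
}

#' @keywords internal
new_vesicle_shape <- function(r, Lc, constraint) {
  total <- Lc + 2 * r
  structure(list(cap_radius = r, cylinder_length = Lc, total_length = total,
                 area = 4 * pi * r^2 + 2 * pi * r * Lc,
                 volume = 4 / 3 * pi * r^3 + pi * r^2 * Lc,
                 aspect_ratio = total / (2 * r),
                 constraint = constraint),
            class = "vesicle_shape")
}

#' @export
print.vesicle_shape <- function(x, ...) {
  cat(sprintf("vesicle_shape (%s): cap radius %.4g nm, cylinder %.4g nm, total %.4g nm, aspect %.3g\n",
              x$constraint, x$cap_radius, x$cylinder_length, x$total_length,
              x$aspect_ratio))
  invisible(x)
}

#' Recovery of a deformed vesicle to a sphere
#'
#' When the internal chain depolymerizes (e.g. under a UV quench) the
#' tubular vesicle relaxes back to the area-equivalent sphere.
#'
#' @param shape A \code{"vesicle_shape"}.
#' @return The spherical \code{"vesicle_shape"} of equal membrane area.
#' @export
vesicle_recovery <- function(shape) {
  r <- sqrt(shape$area / (4 * pi))
  new_vesicle_shape(r, 0, shape$constraint)
}

#' Export a helix centerline
#'
#' Writes the centerline as XYZ (one pseudo-atom per point) or CSV.
#'
#' @param helix A \code{"helix_model"}.
#' @param path Output file path.
#' @param format \code{"xyz"} or \code{"csv"}.
#' @export
write_helix <- function(helix, path, format = c("xyz", "csv")) {
  format <- match.arg(format)
  pts <- helix$centerline
  if (format == "csv") {
    utils::write.csv(as.data.frame(pts), path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(as.character(nrow(pts)),
                 sprintf("helix centerline, %d turns, handedness %+d, nm",
                         helix$n_turns, helix$handedness)), con)
    writeLines(sprintf("C %.6f %.6f %.6f", pts[, 1], pts[, 2], pts[, 3]), con)
  }
  invisible(path)
}
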