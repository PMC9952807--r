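# Strain-avoidance orientation rule.
#
# Cells are taken to align along the spatial direction in which their
# stress fibers experience the least compression. Each solved strain field
# contributes a directional elongation e(u) = 1 + u' eps u (linearised
# stretch ratio of a fiber along unit direction u). The cyclic-stretch cue
# is evaluated on the negated peak strain — the release half of the stretch
# cycle is the compressive phase that reorients cells — and the static
# self-condensation cue on the contraction field itself. The two cues
# combine through the nonlinear addition law
#
#     e_tot = (e_cyclic^-n + e_self^-n)^(-1/n),   n = 4 by default,
#
# which weights compression (e < 1) more than extension (e > 1); the
# predicted orientation is the direction maximising e_tot.

#' Parameters of the strain-avoidance combination law
#'
#' @param n positive exponent of the addition law (default 4).
#' @param angle_grid angular step of the in-plane direction search in
#'   degrees; must divide 180 (default 0.5).
#' @param search_space `"in_plane"` (substrate x-y plane, the plane in
#'   which image-based orientation is measured) or `"full_3d"`.
#' @return an object of class `combination_params`.
#' @export
combination_params <- function(n = 4, angle_grid = 0.5,
                               search_space = c("in_plane", "full_3d")) {
  search_space <- match.arg(search_space)
  if (!is.finite(n) || n <= 0) stopf("n must be > 0")
  if (!is.finite(angle_grid) || angle_grid <= 0 ||
      abs(180 / angle_grid - round(180 / angle_grid)) > 1e-9)
    stopf("angle_grid must be positive and divide 180 degrees")
  structure(list(n = n, angle_grid = angle_grid,
                 search_space = search_space),
            class = "combination_params")
}

#' Directional stress-fiber elongation
#'
#' Linearised relative length change of a material fiber along a unit
#' direction: `1 + t(u) %*% eps %*% u`. Values below 1 indicate
#' compression, above 1 extension.
#'
#' @param strain 3 x 3 symmetric strain tensor.
#' @param direction unit vector (length 3, or length 2 in-plane).
#' @return elongation (dimensionless, 1 = no length change).
#' @export
directional_elongation <- function(strain, direction) {
  u <- as.numeric(direction)
  if (length(u) == 2) u <- c(u, 0)
  if (length(u) != 3 || abs(sqrt(sum(u^2)) - 1) > 1e-8)
    stopf("direction must be a unit vector")
  strain <- as.matrix(strain)
  if (max(abs(strain - t(strain))) > 1e-10)
    stopf("strain tensor must be symmetric")
  1 + as.numeric(t(u) %*% strain %*% u)
}

#' Nonlinear strain-avoidance addition law
#'
#' Combines two directional elongations as
#' `(e_a^-n + e_b^-n)^(-1/n)`. The law is symmetric, strictly increasing in
#' each argument, homogeneous (`combine(k a, k b) = k combine(a, b)`),
#' bounded above by `min(e_a, e_b)`, and tends to `min(e_a, e_b)` as
#' `n -> Inf`; negative powers give compressive values (e < 1) more weight
#' than extensional ones.
#'
#' @param e_a,e_b positive elongations.
#' @param n positive exponent (default 4).
#' @return the combined elongation.
#' @examples
#' combine_elongations(1, 1)          # 2^(-1/4) ~ 0.841
#' combine_elongations(1.15, 0.85)    # ~ 0.796, dominated by compression
#' @export
combine_elongations <- function(e_a, e_b, n = 4) {
  if (any(!is.finite(n)) || n <= 0) stopf("n must be > 0")
  if (any(e_a <= 0) || any(e_b <= 0))
    stopf("elongations must be positive (the law is undefined otherwise)")
  (e_a^(-n) + e_b^(-n))^(-1 / n)
}

# In-plane elongation curve e(theta) for a tensor on the angle grid.
elongation_curve <- function(tensor, angles_deg) {
  th <- angles_deg * pi / 180
  c2 <- cos(th)^2; s2 <- sin(th)^2; cs <- cos(th) * sin(th)
  1 + tensor[1, 1] * c2 + tensor[2, 2] * s2 + 2 * tensor[1, 2] * cs
}

#' Directional elongation profiles of the two alignment cues
#'
#' `cyclic_elongation()` evaluates the cyclic-stretch cue: the directional
#' elongation of the negated peak strain tensor, so that the compressive
#' release half-cycle of a pure uniaxial stretch yields e < 1 along the
#' stretch axis and a maximum perpendicular to it. `self_elongation()`
#' evaluates the static self-condensation cue on the contraction field
#' directly.
#'
#' @param field a [solve_elasticity()] result of the matching load kind.
#' @param probe probe point (mm); default the representative location.
#' @param params a [combination_params()].
#' @return numeric vector of elongations over the angle grid (degrees in
#'   `[0, 180)`, angle 0 = stretch axis), with the grid as the `angles`
#'   attribute.
#' @export
cyclic_elongation <- function(field, probe = NULL,
                              params = combination_params()) {
  stopifnot(inherits(field, "strain_field"))
  if (field$load$kind != "applied_stretch")
    stopf("cyclic_elongation expects an applied_stretch field")
  if (is.null(probe)) probe <- representative_probe(field$mesh$geometry)
  tensor <- -probe_strain(field, probe)
  angles <- seq(0, 180 - params$angle_grid, by = params$angle_grid)
  structure(elongation_curve(tensor, angles), angles = angles,
            tensor = tensor)
}

#' @rdname cyclic_elongation
#' @export
self_elongation <- function(field, probe = NULL,
                            params = combination_params()) {
  stopifnot(inherits(field, "strain_field"))
  if (field$load$kind != "self_condensation")
    stopf("self_elongation expects a self_condensation field")
  if (is.null(probe)) probe <- representative_probe(field$mesh$geometry)
  tensor <- probe_strain(field, probe)
  angles <- seq(0, 180 - params$angle_grid, by = params$angle_grid)
  structure(elongation_curve(tensor, angles), angles = angles,
            tensor = tensor)
}

#' Predict the preferred cell orientation from the combined cues
#'
#' Combines the cyclic-stretch and self-condensation elongation profiles
#' through the addition law and reports the angle (relative to the stretch
#' axis, folded to `[0, 90]` by axial symmetry) that maximises the combined
#' elongation — the direction of least effective compression. Either field
#' may be `NULL`, in which case that cue is the neutral profile e = 1.
#'
#' @param stretch_field applied-stretch [solve_elasticity()] result or
#'   `NULL`.
#' @param condensation_field self-condensation result or `NULL`.
#' @param params a [combination_params()].
#' @param probe probe point (mm); default representative location of
#'   whichever field is present.
#' @param label optional scenario label carried into the result.
#' @return an object of class `orientation_prediction` with the predicted
#'   `angle` (degrees), the full `profile` (angle, e_cyclic, e_self, e_tot),
#'   and a `no_preferred_direction` flag for isotropic profiles. Ties are
#'   broken toward the smaller angle.
#' @export
predict_orientation <- function(stretch_field = NULL,
                                condensation_field = NULL,
                                params = combination_params(),
                                probe = NULL, label = NULL) {
  if (is.null(stretch_field) && is.null(condensation_field))
    stopf("at least one of the two fields is required")
  ref <- stretch_field %||% condensation_field
  if (is.null(probe)) probe <- representative_probe(ref$mesh$geometry)
  angles <- seq(0, 180 - params$angle_grid, by = params$angle_grid)
  e_cyc <- if (is.null(stretch_field)) rep(1, length(angles))
           else as.numeric(cyclic_elongation(stretch_field, probe, params))
  e_self <- if (is.null(condensation_field)) rep(1, length(angles))
            else as.numeric(self_elongation(condensation_field, probe,
                                            params))
  if (any(e_cyc <= 0) || any(e_self <= 0))
    stopf("non-positive elongation encountered; strains too large for the ",
          "linearised model")
  e_tot <- combine_elongations(e_cyc, e_self, params$n)
  profile <- data.frame(angle = angles, e_cyclic = e_cyc, e_self = e_self,
                        e_tot = e_tot)
  class(profile) <- c("elongation_profile", "data.frame")

  iso <- diff(range(e_tot)) < 1e-12 * max(e_tot)
  if (iso) {
    angle <- NA_real_
  } else {
    folded <- fold_angle(angles)
    best <- which(e_tot > max(e_tot) - 1e-15)
    angle <- min(folded[best])
  }
  structure(list(angle = angle, profile = profile, probe = probe,
                 params = params, scenario = label,
                 no_preferred_direction = iso),
            class = "orientation_prediction")
}

#' @export
print.orientation_prediction <- function(x, ...) {
  cat("Strain-avoidance orientation prediction")
  if (!is.null(x$scenario)) cat(" [", x$scenario, "]", sep = "")
  cat("\n")
  if (x$no_preferred_direction) {
    cat("  no preferred direction (isotropic combined profile)\n")
  } else {
    cat(sprintf("  preferred angle: %.1f deg from the stretch axis\n",
                x$angle))
  }
  rng <- range(x$profile$e_tot)
  cat(sprintf("  combined elongation range: [%.4f, %.4f] (n = %g)\n",
              rng[1], rng[2], x$params$n))
  invisible(x)
}

#' Polar plot of an elongation profile
#'
#' Draws e_cyclic, e_self and e_tot as polar curves over the axial angle
#' range (mirrored to the full circle), the standard way to visualise the
#' deformation of a unit circle probe under the two cues.
#'
#' @param x an `elongation_profile` (the `profile` element of an
#'   [predict_orientation()] result).
#' @param ... ignored.
#' @export
plot.elongation_profile <- function(x, ...) {
  th <- c(x$angle, x$angle + 180) * pi / 180
  op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit(graphics::par(op))
  rmax <- max(x$e_cyclic, x$e_self, x$e_tot)
  plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax), axes = FALSE,
       xlab = "", ylab = "", main = "directional elongation", asp = 1)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey70", lty = 2)
  for (i in seq_along(c("e_cyclic", "e_self", "e_tot"))) {
    comp <- c("e_cyclic", "e_self", "e_tot")[i]
    r <- rep(x[[comp]], 2)
    graphics::lines(r * cos(th), r * sin(th),
                    col = c("steelblue", "seagreen", "firebrick")[i],
                    lwd = c(1, 1, 2)[i])
  }
  graphics::legend("topright", c("cyclic", "self", "combined"), bty = "n",
                   col = c("steelblue", "seagreen", "firebrick"),
                   lwd = c(1, 1, 2), cex = 0.8)
  invisible(x)
}
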