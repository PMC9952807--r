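# Canonical culture scenarios and their orchestration.
#
# The orientation study crosses seeding (2D layer on the elastomer vs 3D
# cell-laden hydrogel in the grooves) with groove orientation (parallel or
# perpendicular to the stretch axis), plus ungrooved controls; appending
# "_static" drops the cyclic stretch. Each scenario meshes the groove unit
# cell, runs the applied-stretch and self-condensation solves, and feeds
# the probed strain tensors to the strain-avoidance combination law.

.sa_cache <- new.env(parent = emptyenv())

#' Canonical scenario names
#' @return character vector of recognised scenario names.
#' @export
canonical_scenarios <- function() {
  base <- c("flat_2d", "2d_parallel", "2d_perpendicular",
            "flat_3d", "3d_parallel", "3d_perpendicular")
  c(base, paste0(base, "_static"))
}

scenario_geometry <- function(base, resolution = NULL, ...) {
  seeding <- if (grepl("^flat", base)) {
    if (grepl("2d", base)) "layer_2d" else "hydrogel_3d"
  } else if (grepl("^2d", base)) "layer_2d" else "hydrogel_3d"
  axis <- if (grepl("parallel", base)) "parallel_to_stretch"
          else if (grepl("perpendicular", base)) "perpendicular_to_stretch"
          else "none"
  chamber_geometry(domain = "unit_cell", groove_axis = axis,
                   seeding = seeding, ...)
}

# groove-transverse in-plane strain component at the probe
transverse_strain <- function(field, probe) {
  g <- field$mesh$geometry$grooves
  eps <- probe_strain(field, probe)
  if (is.null(g) || g$trans_axis == "y") eps[2, 2] else eps[1, 1]
}

#' Calibrate the groove sidewall spring stiffness
#'
#' The hydrogel partially detaches from the groove sidewalls in extended 3D
#' culture; the detachment is lumped into a distributed elastic spring. The
#' default stiffness is chosen such that the groove-transverse hydrogel
#' contraction at the probe reaches a set fraction (default 50%) of its
#' fully detached (free-sidewall) value.
#'
#' @param mesh a grooved 3D unit-cell mesh.
#' @param fraction target ratio of transverse contraction to the
#'   free-sidewall value, in (0, 1).
#' @param materials material map.
#' @param probe probe point; default representative location.
#' @return spring stiffness in Pa/m.
#' @export
calibrate_sidewall_stiffness <- function(mesh, fraction = 0.5,
                                         materials = material_presets(),
                                         probe = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(probe)) probe <- representative_probe(mesh$geometry)
  ld <- function(k) load_case("self_condensation",
                              contraction_magnitude = 0.2,
                              sidewall_spring_stiffness = k,
                              seeding_mode = "hydrogel_3d")
  e_free <- transverse_strain(solve_elasticity(mesh, materials, ld(0)),
                              probe)
  if (abs(e_free) < 1e-12)
    stopf("free-sidewall transverse contraction is zero; cannot calibrate")
  fn <- function(log10k)
    transverse_strain(solve_elasticity(mesh, materials, ld(10^log10k)),
                      probe) / e_free - fraction
  lo <- 3; hi <- 12
  flo <- fn(lo); fhi <- fn(hi)
  if (flo * fhi > 0)
    stopf("sidewall calibration failed to bracket the target fraction")
  r <- stats::uniroot(fn, c(lo, hi), f.lower = flo, f.upper = fhi,
                      tol = 0.01)
  10^r$root
}

#' Calibrate the cellular contraction magnitude
#'
#' The governing observation is that in the soft 3D hydrogel, cellular
#' contraction produces local strains of the same order as the applied
#' stretch. The contraction eigenstrain is therefore scaled so that the
#' peak in-plane compressive self-elongation magnitude `|1 - e_self|` at
#' the probe equals the applied strain amplitude. The solve is linear in
#' the eigenstrain, so a single reference solve suffices. The calibrated
#' value is a property of the cells and is reused across scenarios
#' (on stiff elastomer the same contraction produces only negligible
#' strain, which is what lets the applied stretch dominate in 2D).
#'
#' @param mesh grooved 3D unit-cell mesh (the calibration reference).
#' @param target peak in-plane `|1 - e_self|` to match (default 0.15, the
#'   cyclic stretch amplitude).
#' @param sidewall_spring_stiffness spring stiffness (Pa/m).
#' @param materials material map.
#' @param probe probe point; default representative location.
#' @return contraction eigenstrain magnitude (dimensionless).
#' @export
calibrate_contraction <- function(mesh, target = 0.15,
                                  sidewall_spring_stiffness,
                                  materials = material_presets(),
                                  probe = NULL) {
  if (is.null(probe)) probe <- representative_probe(mesh$geometry)
  c0 <- 0.2
  fld <- solve_elasticity(mesh, materials, load_case(
    "self_condensation", contraction_magnitude = c0,
    sidewall_spring_stiffness = sidewall_spring_stiffness,
    seeding_mode = "hydrogel_3d"))
  eps <- probe_strain(fld, probe)[1:2, 1:2]
  peak <- -min(eigen(eps, symmetric = TRUE)$values)
  if (peak <= 1e-12)
    stopf("no in-plane compression at the probe; cannot calibrate")
  c0 * target / peak
}

scenario_calibration <- function(resolution, refine_grooves, fraction,
                                 target, unit_cell_length, materials) {
  key <- paste("cal", resolution, refine_grooves, fraction, target,
               unit_cell_length,
               paste(vapply(materials, function(m)
                 paste(m$young_modulus, m$poisson_ratio), ""),
                 collapse = "|"))
  hit <- .sa_cache[[fnv1a(key)]]
  if (!is.null(hit)) return(hit)
  geo <- scenario_geometry("3d_parallel",
                           unit_cell_length = unit_cell_length)
  mesh <- mesh_geometry(geo, resolution, refine_grooves)
  k <- calibrate_sidewall_stiffness(mesh, fraction, materials)
  cm <- calibrate_contraction(mesh, target, k, materials)
  out <- list(sidewall_spring_stiffness = k, contraction_magnitude = cm)
  .sa_cache[[fnv1a(key)]] <- out
  out
}

#' Run a canonical alignment scenario
#'
#' Meshes the groove unit cell for the scenario, solves the peak-amplitude
#' applied-stretch case (unless `_static`) and the self-condensation case,
#' and predicts the preferred cell orientation via the strain-avoidance
#' addition law. The sidewall spring stiffness and the cellular contraction
#' magnitude default to their calibrated values (see
#' [calibrate_sidewall_stiffness()] and [calibrate_contraction()],
#' calibrated once on the 3D parallel-groove unit cell and shared across
#' scenarios); both can be overridden.
#'
#' @param scenario one of [canonical_scenarios()].
#' @param applied_strain peak engineering strain of the cyclic stretch
#'   (default 0.15).
#' @param params a [combination_params()].
#' @param resolution,refine_grooves meshing controls, see
#'   [mesh_geometry()].
#' @param materials material map (defaults to the measured presets).
#' @param sidewall_fraction target transverse-contraction fraction for the
#'   spring calibration.
#' @param sidewall_spring_stiffness override the calibrated stiffness
#'   (Pa/m).
#' @param contraction_magnitude override the calibrated contraction
#'   eigenstrain.
#' @param unit_cell_length unit-cell extent along the groove axis (mm).
#' @param probe_offset additive probe offset (mm, length 3).
#' @return an object of class `scenario_result`: the
#'   [predict_orientation()] result, the probed strain tensors, the
#'   effective axial strain, and the calibration actually used.
#' @examples
#' \donttest{
#' res <- run_scenario("3d_parallel", resolution = 0.35)
#' res$prediction$angle   # oblique angle, between 0 and 90 degrees
#' }
#' @export
run_scenario <- function(scenario, applied_strain = 0.15,
                         params = combination_params(),
                         resolution = 0.25, refine_grooves = TRUE,
                         materials = material_presets(),
                         sidewall_fraction = 0.5,
                         sidewall_spring_stiffness = NULL,
                         contraction_magnitude = NULL,
                         unit_cell_length = 1.4,
                         probe_offset = c(0, 0, 0)) {
  if (!scenario %in% canonical_scenarios())
    stopf("unknown scenario '%s'; canonical names: %s", scenario,
          paste(canonical_scenarios(), collapse = ", "))
  static <- grepl("_static$", scenario)
  base <- sub("_static$", "", scenario)
  geo <- scenario_geometry(base, unit_cell_length = unit_cell_length)
  mesh <- mesh_geometry(geo, resolution, refine_grooves)
  probe <- representative_probe(geo, probe_offset)
  grooved3d <- geo$seeding == "hydrogel_3d" && geo$groove_axis != "none"

  if (is.null(sidewall_spring_stiffness) || is.null(contraction_magnitude)) {
    cal <- scenario_calibration(resolution, refine_grooves,
                                sidewall_fraction, applied_strain,
                                unit_cell_length, materials)
    sidewall_spring_stiffness <- sidewall_spring_stiffness %||%
      cal$sidewall_spring_stiffness
    contraction_magnitude <- contraction_magnitude %||%
      cal$contraction_magnitude
  }

  stretch_field <- NULL
  if (!static) {
    stretch_field <- solve_elasticity(mesh, materials, load_case(
      "applied_stretch", applied_strain = applied_strain,
      seeding_mode = geo$seeding))
  }
  condensation_field <- solve_elasticity(mesh, materials, load_case(
    "self_condensation", contraction_magnitude = contraction_magnitude,
    sidewall_spring_stiffness = if (grooved3d) sidewall_spring_stiffness
                                else Inf,
    seeding_mode = geo$seeding))

  pred <- predict_orientation(stretch_field, condensation_field, params,
                              probe, label = scenario)
  structure(list(
    scenario = scenario, prediction = pred, probe = probe,
    stretch_field = stretch_field, condensation_field = condensation_field,
    stretch_tensor = if (!static) probe_strain(stretch_field, probe),
    condensation_tensor = probe_strain(condensation_field, probe),
    effective_axial_strain_pct =
      if (!static) effective_axial_strain(stretch_field, probe),
    applied_strain = if (!static) applied_strain else 0,
    calibration = list(
      sidewall_spring_stiffness = sidewall_spring_stiffness,
      contraction_magnitude = contraction_magnitude,
      sidewall_fraction = sidewall_fraction),
    mesh = mesh), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", x$scenario, "\n")
  if (!is.null(x$stretch_field))
    cat(sprintf("  applied stretch %.0f%% -> effective axial strain %.1f%%\n",
                100 * x$applied_strain, x$effective_axial_strain_pct))
  print(x$prediction)
  invisible(x)
}

#' Strain-transmission campaign across seeding and topography
#'
#' Reproduces the strain-transmission study design: the cross of three
#' seeding approaches (unseeded, 2D layer, 3D hydrogel) with three
#' topographies (unstructured, grooves parallel and perpendicular to
#' stretch), each solved at the same applied stretch and probed at the
#' representative location. The unseeded unstructured case runs on the
#' full (coarse) chamber; all other cases use the periodic unit cell.
#'
#' @param applied_strain applied engineering strain (default 0.36).
#' @param resolution unit-cell element size (mm).
#' @param chamber_resolution full-chamber element size (mm).
#' @param materials material map.
#' @return a data frame of class `strain_transmission` with the effective
#'   axial strain (percent) and the concentration ratio for each case.
#' @export
strain_transmission <- function(applied_strain = 0.36, resolution = 0.25,
                                chamber_resolution = 1,
                                materials = material_presets()) {
  seedings <- c("none", "layer_2d", "hydrogel_3d")
  topos <- c(none = "none", parallel = "parallel_to_stretch",
             perpendicular = "perpendicular_to_stretch")
  rows <- list()
  for (sd in seedings) for (tp in names(topos)) {
    if (sd == "none" && tp == "none") {
      geo <- chamber_geometry(domain = "chamber", groove_axis = "none")
      mesh <- mesh_geometry(geo, chamber_resolution,
                            refine_grooves = FALSE)
    } else {
      geo <- chamber_geometry(domain = "unit_cell", groove_axis = topos[[tp]],
                              seeding = sd)
      mesh <- mesh_geometry(geo, resolution)
    }
    fld <- solve_elasticity(mesh, materials, load_case(
      "applied_stretch", applied_strain = applied_strain,
      seeding_mode = sd))
    eff <- effective_axial_strain(fld)
    rows[[paste(sd, tp)]] <- data.frame(
      seeding = sd, topography = tp,
      applied_pct = 100 * applied_strain, effective_pct = eff,
      ratio = eff / (100 * applied_strain))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("strain_transmission", "data.frame")
  out
}

#' Anticipated elongation of a region of interest
#'
#' The analytic expectation against which image-correlation elongation
#' measurements are judged: a region of length `roi_length` under an
#' intended strain elongates by their product (e.g. a 15 mm region at 5%
#' intended strain is expected to elongate by 0.75 mm).
#'
#' @param roi_length region-of-interest length (mm).
#' @param intended_strain intended engineering strain (fraction, e.g. 0.05).
#' @return expected elongation (mm).
#' @export
expected_elongation <- function(roi_length, intended_strain) {
  if (any(roi_length < 0) || any(intended_strain < 0))
    stopf("roi_length and intended_strain must be non-negative")
  roi_length * intended_strain
}
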