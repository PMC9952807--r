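# Parametric grooved-chamber geometry.
#
# Coordinate convention: x = stretch axis, y = transverse in-plane,
# z = height. All lengths in mm. The microgrooves are square channels carved
# into the top surface of the chamber's bottom wall (the culture membrane),
# so the membrane is locally thinner underneath each groove.

#' Parametric grooved stretch-chamber geometry
#'
#' Describes the flexible elastomer culture chamber: a trough with a thick
#' and a thin sidewall, a bottom culture membrane, and an optional array of
#' square microgrooves carved into the membrane surface. Two domains are
#' supported: the full chamber (`domain = "chamber"`), used for coarse
#' whole-device solves, and a reduced periodic groove unit cell
#' (`domain = "unit_cell"`) spanning one groove pitch, used for the
#' groove-local strain analysis that drives the orientation model.
#'
#' Default dimensions are the chamber presets (20 x 10 x 10 mm, sidewalls
#' 0.1 / 5 mm, bottom wall 2 mm) with 350 x 350 um grooves spaced 350 um
#' apart. `groove_axis` is expressed relative to the stretch axis x.
#'
#' @param chamber_length,chamber_width,chamber_height outer chamber
#'   dimensions (mm); length is along the stretch axis.
#' @param thin_sidewall,thick_sidewall,bottom_wall wall thicknesses (mm).
#' @param groove_width,groove_depth,groove_spacing groove cross-section and
#'   pitch gap (mm); defaults 0.35 mm each.
#' @param groove_axis one of `"none"`, `"parallel_to_stretch"`,
#'   `"perpendicular_to_stretch"`.
#' @param seeding one of `"none"`, `"layer_2d"` (thin cell film on the
#'   culture surface) or `"hydrogel_3d"` (cell-laden hydrogel filling the
#'   grooves, or a slab of `groove_depth` thickness when ungrooved).
#' @param film_thickness 2D cell-layer film thickness (mm); default 0.01
#'   (10 um, a typical monolayer height).
#' @param domain `"chamber"` or `"unit_cell"`.
#' @param unit_cell_length extent of the unit cell along the groove axis
#'   (mm); cut faces carry mirror-symmetry conditions, so this only needs to
#'   be a few groove widths.
#' @return an object of class `chamber_geometry`.
#' @examples
#' geo <- chamber_geometry()                      # plain chamber
#' geo$bbox                                       # 20 x 10 x 10 mm
#' gc <- chamber_geometry(groove_axis = "parallel_to_stretch")
#' gc$n_grooves                                   # grooves fitting the cavity
#' @export
chamber_geometry <- function(chamber_length = 20, chamber_width = 10,
                             chamber_height = 10, thin_sidewall = 0.1,
                             thick_sidewall = 5, bottom_wall = 2,
                             groove_width = 0.35, groove_depth = 0.35,
                             groove_spacing = 0.35,
                             groove_axis = c("none", "parallel_to_stretch",
                                             "perpendicular_to_stretch"),
                             seeding = c("none", "layer_2d", "hydrogel_3d"),
                             film_thickness = 0.01,
                             domain = c("chamber", "unit_cell"),
                             unit_cell_length = 1.4) {
  groove_axis <- match.arg(groove_axis)
  seeding <- match.arg(seeding)
  domain <- match.arg(domain)

  lens <- c(chamber_length = chamber_length, chamber_width = chamber_width,
            chamber_height = chamber_height, thin_sidewall = thin_sidewall,
            thick_sidewall = thick_sidewall, bottom_wall = bottom_wall,
            groove_width = groove_width, groove_depth = groove_depth,
            groove_spacing = groove_spacing, film_thickness = film_thickness,
            unit_cell_length = unit_cell_length)
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad)) stopf("all lengths must be strictly positive; bad: %s",
                         paste(bad, collapse = ", "))
  if (groove_depth >= bottom_wall)
    stopf("groove_depth (%g mm) must be smaller than the bottom wall (%g mm)",
          groove_depth, bottom_wall)
  if (thin_sidewall + thick_sidewall >= chamber_width)
    stopf("sidewalls exceed the chamber width")
  if (bottom_wall >= chamber_height)
    stopf("bottom wall exceeds the chamber height")

  cavity_width <- chamber_width - thin_sidewall - thick_sidewall
  pitch <- groove_width + groove_spacing

  n_grooves <- 0L
  if (groove_axis != "none") {
    avail <- if (groove_axis == "parallel_to_stretch") cavity_width
             else chamber_length
    if (groove_width > avail)
      stopf("grooves (%g mm) are wider than the available span (%g mm)",
            groove_width, avail)
    n_grooves <- as.integer(floor(avail / pitch))
    if (n_grooves < 1L)
      stopf("no full groove fits the available span (%g mm)", avail)
  }

  geo <- list(chamber_length = chamber_length, chamber_width = chamber_width,
              chamber_height = chamber_height, thin_sidewall = thin_sidewall,
              thick_sidewall = thick_sidewall, bottom_wall = bottom_wall,
              groove_width = groove_width, groove_depth = groove_depth,
              groove_spacing = groove_spacing, groove_axis = groove_axis,
              seeding = seeding, film_thickness = film_thickness,
              domain = domain, unit_cell_length = unit_cell_length,
              cavity_width = cavity_width, pitch = pitch,
              n_grooves = n_grooves)
  geo$bbox <- geometry_bbox(geo)
  geo$grooves <- geometry_grooves(geo)
  class(geo) <- "chamber_geometry"
  geo
}

# Bounding box (3 x 2 matrix, rows x/y/z) of the solid domain.
geometry_bbox <- function(geo) {
  if (geo$domain == "chamber") {
    b <- rbind(x = c(0, geo$chamber_length),
               y = c(0, geo$chamber_width),
               z = c(0, geo$chamber_height))
  } else {
    # One groove pitch transverse to the groove axis; groove centred.
    lz <- geo$bottom_wall +
      if (geo$seeding == "hydrogel_3d" && geo$groove_axis == "none")
        geo$groove_depth
      else if (geo$seeding == "layer_2d" && geo$groove_axis == "none")
        geo$film_thickness else 0
    if (geo$groove_axis == "perpendicular_to_stretch") {
      b <- rbind(x = c(0, geo$pitch), y = c(0, geo$unit_cell_length),
                 z = c(0, lz))
    } else {
      b <- rbind(x = c(0, geo$unit_cell_length), y = c(0, geo$pitch),
                 z = c(0, lz))
    }
  }
  colnames(b) <- c("min", "max")
  b
}

# Groove layout: transverse axis name and the transverse intervals
# [lo, hi] of each groove, plus the ligament height z_lig (groove floor) and
# groove top z_top. NULL when ungrooved.
geometry_grooves <- function(geo) {
  if (geo$groove_axis == "none") return(NULL)
  trans <- if (geo$groove_axis == "parallel_to_stretch") "y" else "x"
  z_top <- geo$bottom_wall
  z_lig <- z_top - geo$groove_depth
  if (geo$domain == "unit_cell") {
    lo <- geo$groove_spacing / 2
    spans <- cbind(lo = lo, hi = lo + geo$groove_width)
  } else {
    avail0 <- if (trans == "y") geo$thick_sidewall else 0
    avail <- if (trans == "y") geo$cavity_width else geo$chamber_length
    span_tot <- geo$n_grooves * geo$pitch - geo$groove_spacing
    start <- avail0 + (avail - span_tot) / 2
    lo <- start + (seq_len(geo$n_grooves) - 1L) * geo$pitch
    spans <- cbind(lo = lo, hi = lo + geo$groove_width)
  }
  list(trans_axis = trans, spans = spans, z_lig = z_lig, z_top = z_top)
}

# Analytic volume of the solid (elastomer + any seeded material), mm^3.
geometry_volume <- function(geo) {
  g <- geo$grooves
  if (geo$domain == "chamber") {
    v <- geo$chamber_length * geo$chamber_width * geo$bottom_wall +
      geo$chamber_length * (geo$thick_sidewall + geo$thin_sidewall) *
        (geo$chamber_height - geo$bottom_wall)
    groove_len <- if (is.null(g)) 0 else
      if (g$trans_axis == "y") geo$chamber_length else geo$cavity_width
  } else {
    bb <- geo$bbox
    v <- prod(bb[, 2] - bb[, 1])
    # slab volume includes any flat seeded layer already via bbox height
    groove_len <- if (is.null(g)) 0 else
      if (g$trans_axis == "y") geo$unit_cell_length else geo$unit_cell_length
  }
  if (!is.null(g)) {
    notch <- nrow(g$spans) * geo$groove_width * geo$groove_depth * groove_len
    if (geo$seeding != "hydrogel_3d") v <- v - notch
    # grooved layer_2d: film on the groove floor
    if (geo$seeding == "layer_2d")
      v <- v + nrow(g$spans) * geo$groove_width * geo$film_thickness *
        groove_len
  }
  v
}

# Region classifier: maps a point (element centre) to a region name or NA
# (void). Vectorised over points.
geometry_classify <- function(geo, x, y, z) {
  reg <- rep(NA_character_, length(x))
  g <- geo$grooves
  if (geo$domain == "chamber") {
    in_bottom <- z < geo$bottom_wall
    in_walls <- !in_bottom & (y < geo$thick_sidewall |
                              y > geo$chamber_width - geo$thin_sidewall) &
      z < geo$chamber_height
    reg[in_bottom | in_walls] <- "pdms"
  } else {
    reg[z < geo$bottom_wall] <- "pdms"
    if (is.null(g)) {
      # flat unit cell: optional seeded layer on top of the membrane
      if (geo$seeding == "hydrogel_3d")
        reg[z >= geo$bottom_wall &
              z < geo$bottom_wall + geo$groove_depth] <- "hydrogel"
      if (geo$seeding == "layer_2d")
        reg[z >= geo$bottom_wall &
              z < geo$bottom_wall + geo$film_thickness] <- "cell_layer"
    }
  }
  if (!is.null(g)) {
    tau <- if (g$trans_axis == "y") y else x
    in_groove_t <- rep(FALSE, length(x))
    for (k in seq_len(nrow(g$spans)))
      in_groove_t <- in_groove_t | (tau > g$spans[k, "lo"] &
                                    tau < g$spans[k, "hi"])
    notch <- in_groove_t & z > g$z_lig & z < g$z_top
    if (geo$domain == "chamber") {
      # restrict to the cavity span along the groove axis
      along_ok <- if (g$trans_axis == "y") rep(TRUE, length(x)) else
        (y > geo$thick_sidewall & y < geo$chamber_width - geo$thin_sidewall)
      notch <- notch & along_ok
    }
    reg[notch] <- NA_character_
    if (geo$seeding == "hydrogel_3d") reg[notch] <- "hydrogel"
    if (geo$seeding == "layer_2d")
      reg[notch & z < g$z_lig + geo$film_thickness] <- "cell_layer"
  }
  reg
}

#' @export
print.chamber_geometry <- function(x, ...) {
  bb <- x$bbox
  cat("Grooved stretch-chamber geometry (", x$domain, " domain)\n", sep = "")
  cat(sprintf("  bounding box: %.3g x %.3g x %.3g mm\n",
              diff(bb[1, ]), diff(bb[2, ]), diff(bb[3, ])))
  cat("  groove axis:", x$groove_axis)
  if (x$groove_axis != "none")
    cat(sprintf(" (%g x %g um cross-section, %g um spacing, n = %d)",
                1e3 * x$groove_width, 1e3 * x$groove_depth,
                1e3 * x$groove_spacing,
                if (x$domain == "chamber") x$n_grooves else 1L))
  cat("\n  seeding:", x$seeding, "\n")
  invisible(x)
}
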