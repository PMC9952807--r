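# Tagged hexahedral meshing of the chamber geometry family.
#
# Meshes are graded tensor-product grids of axis-aligned hexahedra: grid
# lines are placed exactly on every material / feature boundary, so region
# interfaces are conforming and the meshed volume matches the parametric
# solid exactly. Elements carry a region tag (pdms / hydrogel / cell_layer);
# exterior facets carry exactly one boundary tag (clamped_end, moving_end,
# groove_sidewall, groove_bottom, free) and material interfaces at groove
# walls are recorded separately for the spring-supported sidewall condition.

# Subdivide [features] intervals with per-interval target size h.
axis_lines <- function(features, sizes) {
  out <- features[1]
  for (i in seq_len(length(features) - 1L)) {
    a <- features[i]; b <- features[i + 1L]
    n <- max(1L, ceiling((b - a) / sizes[i] - 1e-9))
    out <- c(out, a + (b - a) * seq_len(n) / n)
  }
  out
}

# Per-axis features and sizes for a geometry.
mesh_axis_plan <- function(geo, resolution, refine_grooves) {
  bb <- geo$bbox
  g <- geo$grooves
  fine <- if (refine_grooves) min(0.1, resolution) else resolution
  plan <- list()
  for (ax in c("x", "y", "z")) {
    f <- bb[ax, ]
    s <- resolution
    if (geo$domain == "chamber") {
      if (ax == "y") {
        f <- c(f[1], geo$thick_sidewall,
               geo$chamber_width - geo$thin_sidewall, f[2])
      } else if (ax == "z") {
        f <- c(f[1], geo$bottom_wall, f[2])
      }
    }
    if (!is.null(g)) {
      if (ax == g$trans_axis) {
        f <- sort(unique(c(f, as.vector(g$spans))))
      } else if (ax == "z") {
        f <- sort(unique(c(f, g$z_lig, g$z_top,
                           if (geo$seeding == "layer_2d")
                             g$z_lig + geo$film_thickness)))
      }
    } else if (geo$domain == "unit_cell" && geo$seeding != "none" &&
               ax == "z") {
      top <- geo$bottom_wall +
        if (geo$seeding == "hydrogel_3d") geo$groove_depth else
          geo$film_thickness
      f <- sort(unique(c(f, geo$bottom_wall, top)))
    }
    f <- sort(unique(f))
    # per-interval sizes
    mid <- (f[-1] + f[-length(f)]) / 2
    len <- diff(f)
    s <- rep(resolution, length(mid))
    if (!is.null(g)) {
      in_groove <- switch(ax,
        x = if (g$trans_axis == "x")
              vapply(mid, function(m) any(m > g$spans[, 1] &
                                          m < g$spans[, 2]), TRUE)
            else rep(TRUE, length(mid)),
        y = if (g$trans_axis == "y")
              vapply(mid, function(m) any(m > g$spans[, 1] &
                                          m < g$spans[, 2]), TRUE)
            else rep(TRUE, length(mid)),
        z = mid > g$z_lig & mid < g$z_top)
      s[in_groove] <- fine
    } else if (geo$domain == "unit_cell") {
      s <- rep(fine, length(mid))
      if (length(mid) > 1 && max(f) > geo$bottom_wall && "z" == ax)
        s[mid < geo$bottom_wall] <- resolution
      if (ax == "z") s[mid < geo$bottom_wall - 1e-12] <-
        pmin(resolution, geo$bottom_wall / 3)
    }
    # never split a thin film: one element through its thickness
    s <- pmax(pmin(s, len), ifelse(len <= 2 * geo$film_thickness + 1e-12,
                                   len, 0))
    plan[[ax]] <- axis_lines(f, s)
  }
  plan
}

# VTK hexahedron local node order; faces by side 1..6 = x-,x+,y-,y+,z-,z+.
hex_face_local <- list(c(1, 4, 8, 5), c(2, 3, 7, 6), c(1, 2, 6, 5),
                       c(3, 4, 8, 7), c(1, 2, 3, 4), c(5, 6, 7, 8))

#' Mesh a chamber geometry into a tagged hexahedral grid
#'
#' Generates a conforming, graded mesh of axis-aligned trilinear hexahedra.
#' Grid lines coincide with all material boundaries, so every element lies
#' in exactly one region and the meshed volume equals the parametric solid
#' volume. With `refine_grooves`, elements inside groove regions are at most
#' 0.1 mm across.
#'
#' @param geometry a [chamber_geometry()].
#' @param resolution target element size (mm) outside groove regions.
#' @param refine_grooves refine groove regions to a 0.1 mm maximum element
#'   size (default `TRUE`).
#' @return an object of class `fe_mesh` with fields `nodes` (n x 3, mm),
#'   `elems` (ne x 8 connectivity, VTK ordering), `region` (per element),
#'   `boundary` (tagged exterior facets), `interfaces` (tagged material
#'   interface facets) and the generating grid.
#' @examples
#' m <- mesh_geometry(chamber_geometry(domain = "unit_cell",
#'                                     groove_axis = "parallel_to_stretch",
#'                                     seeding = "hydrogel_3d"),
#'                    resolution = 0.3)
#' table(m$region)
#' @export
mesh_geometry <- function(geometry, resolution = 0.25,
                          refine_grooves = TRUE) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  if (!is.finite(resolution) || resolution <= 0)
    stopf("resolution must be > 0")
  plan <- mesh_axis_plan(geometry, resolution, refine_grooves)
  gx <- plan$x; gy <- plan$y; gz <- plan$z
  ncx <- length(gx) - 1L; ncy <- length(gy) - 1L; ncz <- length(gz) - 1L
  if (min(ncx, ncy, ncz) < 1L)
    stopf("mesher failure: degenerate grid for geometry (%d x %d x %d cells)",
          ncx, ncy, ncz)

  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  cz <- (gz[-1] + gz[-length(gz)]) / 2
  cc <- expand.grid(ix = seq_len(ncx), iy = seq_len(ncy), iz = seq_len(ncz))
  reg <- geometry_classify(geometry, cx[cc$ix], cy[cc$iy], cz[cc$iz])
  solid <- !is.na(reg)
  if (!any(solid))
    stopf("mesher failure: geometry produced no solid elements")

  A <- array(0L, dim = c(ncx, ncy, ncz))
  A[cbind(cc$ix, cc$iy, cc$iz)[solid, , drop = FALSE]] <-
    seq_len(sum(solid))
  ec <- cc[solid, , drop = FALSE]
  region <- reg[solid]
  ne <- nrow(ec)

  ngx <- length(gx); ngy <- length(gy)
  nid <- function(ix, iy, iz) ix + (iy - 1L) * ngx + (iz - 1L) * ngx * ngy
  elems_full <- cbind(
    nid(ec$ix,     ec$iy,     ec$iz),
    nid(ec$ix + 1L, ec$iy,     ec$iz),
    nid(ec$ix + 1L, ec$iy + 1L, ec$iz),
    nid(ec$ix,     ec$iy + 1L, ec$iz),
    nid(ec$ix,     ec$iy,     ec$iz + 1L),
    nid(ec$ix + 1L, ec$iy,     ec$iz + 1L),
    nid(ec$ix + 1L, ec$iy + 1L, ec$iz + 1L),
    nid(ec$ix,     ec$iy + 1L, ec$iz + 1L))
  used <- sort(unique(as.vector(elems_full)))
  renum <- integer(ngx * ngy * length(gz))
  renum[used] <- seq_along(used)
  elems <- matrix(renum[elems_full], nrow = ne)
  ui <- used - 1L
  nodes <- cbind(x = gx[ui %% ngx + 1L],
                 y = gy[(ui %/% ngx) %% ngy + 1L],
                 z = gz[ui %/% (ngx * ngy) + 1L])

  # --- facet extraction -----------------------------------------------
  shift <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  hdim <- c(1L, 1L, 2L, 2L, 3L, 3L)   # normal axis per side
  hsgn <- c(-1L, 1L, -1L, 1L, -1L, 1L)
  bnd <- list(); ifc <- list()
  hx <- diff(gx)[ec$ix]; hy <- diff(gy)[ec$iy]; hz <- diff(gz)[ec$iz]
  face_area <- cbind(hy * hz, hy * hz, hx * hz, hx * hz, hx * hy, hx * hy)
  for (s in seq_len(6L)) {
    nx2 <- ec$ix + shift[[s]][1]; ny2 <- ec$iy + shift[[s]][2]
    nz2 <- ec$iz + shift[[s]][3]
    inside <- nx2 >= 1L & nx2 <= ncx & ny2 >= 1L & ny2 <= ncy &
      nz2 >= 1L & nz2 <= ncz
    nb <- integer(ne)
    nb[inside] <- A[cbind(nx2[inside], ny2[inside], nz2[inside])]
    ext <- nb == 0L
    if (any(ext)) {
      e <- which(ext)
      fc <- facet_centers(ec[e, , drop = FALSE], s, gx, gy, gz)
      bnd[[s]] <- data.frame(elem = e, side = s,
                             naxis = hdim[s], nsign = hsgn[s],
                             cx = fc[, 1], cy = fc[, 2], cz = fc[, 3],
                             area = face_area[e, s])
    }
    difr <- !ext & region[pmax(nb, 1L)] != region
    if (any(difr)) {
      e <- which(difr)
      fc <- facet_centers(ec[e, , drop = FALSE], s, gx, gy, gz)
      ifc[[s]] <- data.frame(elem = e, other = nb[e], side = s,
                             naxis = hdim[s], nsign = hsgn[s],
                             cx = fc[, 1], cy = fc[, 2], cz = fc[, 3],
                             area = face_area[e, s])
    }
  }
  boundary <- do.call(rbind, bnd)
  interfaces <- if (length(ifc)) do.call(rbind, ifc) else NULL
  boundary$tag <- tag_facets(geometry, boundary, exterior = TRUE)
  if (!is.null(interfaces)) {
    # keep each interface once, from the cell-bearing side
    soft <- region[interfaces$elem] %in% c("hydrogel", "cell_layer")
    interfaces <- interfaces[soft, , drop = FALSE]
    if (nrow(interfaces)) {
      interfaces$tag <- tag_facets(geometry, interfaces, exterior = FALSE)
    } else interfaces <- NULL
  }

  mesh <- list(nodes = nodes, elems = elems, region = region,
               boundary = boundary, interfaces = interfaces,
               grid = list(x = gx, y = gy, z = gz, index = A),
               cell_index = ec, geometry = geometry)
  class(mesh) <- "fe_mesh"
  mesh
}

facet_centers <- function(ec, side, gx, gy, gz) {
  cx <- (gx[ec$ix] + gx[ec$ix + 1L]) / 2
  cy <- (gy[ec$iy] + gy[ec$iy + 1L]) / 2
  cz <- (gz[ec$iz] + gz[ec$iz + 1L]) / 2
  if (side == 1L) cx <- gx[ec$ix]
  if (side == 2L) cx <- gx[ec$ix + 1L]
  if (side == 3L) cy <- gy[ec$iy]
  if (side == 4L) cy <- gy[ec$iy + 1L]
  if (side == 5L) cz <- gz[ec$iz]
  if (side == 6L) cz <- gz[ec$iz + 1L]
  cbind(cx, cy, cz)
}

# Assign boundary / interface tags from facet position and normal.
tag_facets <- function(geo, f, exterior = TRUE) {
  bb <- geo$bbox
  tol <- 1e-9
  tag <- rep(if (exterior) "free" else "bonded", nrow(f))
  if (exterior) {
    tag[f$naxis == 1L & abs(f$cx - bb["x", 1]) < tol] <- "clamped_end"
    tag[f$naxis == 1L & abs(f$cx - bb["x", 2]) < tol] <- "moving_end"
  }
  g <- geo$grooves
  if (!is.null(g)) {
    tau <- if (g$trans_axis == "y") f$cy else f$cx
    taxis <- if (g$trans_axis == "y") 2L else 1L
    in_span <- rep(FALSE, nrow(f)); at_edge <- rep(FALSE, nrow(f))
    for (k in seq_len(nrow(g$spans))) {
      in_span <- in_span | (tau > g$spans[k, 1] + tol &
                            tau < g$spans[k, 2] - tol)
      at_edge <- at_edge | abs(tau - g$spans[k, 1]) < tol |
        abs(tau - g$spans[k, 2]) < tol
    }
    in_z <- f$cz > g$z_lig + tol & f$cz < g$z_top - tol
    side_wall <- f$naxis == taxis & at_edge & in_z & tag %in%
      c("free", "bonded")
    tag[side_wall] <- "groove_sidewall"
    bottomf <- f$naxis == 3L & in_span & abs(f$cz - g$z_lig) < tol
    tag[bottomf] <- "groove_bottom"
  } else if (!exterior) {
    # flat seeded layer: substrate interface acts as the adhesion plane
    tag[f$naxis == 3L & abs(f$cz - geo$bottom_wall) < 1e-9] <- "groove_bottom"
  }
  tag
}

# Facet corner node ids (rows of mesh$nodes) for facet table rows.
facet_nodes <- function(mesh, f) {
  loc <- hex_face_local
  t(vapply(seq_len(nrow(f)),
           function(i) mesh$elems[f$elem[i], loc[[f$side[i]]]],
           integer(4)))
}

#' Total mesh volume
#' @param mesh an `fe_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  ec <- mesh$cell_index
  sum(diff(mesh$grid$x)[ec$ix] * diff(mesh$grid$y)[ec$iy] *
        diff(mesh$grid$z)[ec$iz])
}

# Element sizes (hx, hy, hz) for all elements.
elem_sizes <- function(mesh) {
  ec <- mesh$cell_index
  cbind(hx = diff(mesh$grid$x)[ec$ix], hy = diff(mesh$grid$y)[ec$iy],
        hz = diff(mesh$grid$z)[ec$iz])
}

# Locate the element containing a point; error if outside the solid.
locate_element <- function(mesh, point) {
  g <- mesh$grid
  pt <- as.numeric(point)
  ii <- integer(3)
  for (d in 1:3) {
    gl <- g[[d]]
    if (pt[d] < gl[1] - 1e-9 || pt[d] > gl[length(gl)] + 1e-9)
      stopf("probe point (%g, %g, %g) is outside the mesh",
            pt[1], pt[2], pt[3])
    ii[d] <- min(max(findInterval(pt[d], gl, rightmost.closed = TRUE), 1L),
                 length(gl) - 1L)
  }
  el <- g$index[ii[1], ii[2], ii[3]]
  if (el == 0L)
    stopf("probe point (%g, %g, %g) lies in a void region",
          pt[1], pt[2], pt[3])
  el
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat("Hexahedral FE mesh:", nrow(x$nodes), "nodes,", nrow(x$elems),
      "elements\n")
  cat("  regions:", paste(sprintf("%s (%d)", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  cat("  boundary facets:",
      paste(sprintf("%s (%d)", names(table(x$boundary$tag)),
                    table(x$boundary$tag)), collapse = ", "), "\n")
  if (!is.null(x$interfaces))
    cat("  interface facets:",
        paste(sprintf("%s (%d)", names(table(x$interfaces$tag)),
                      table(x$interfaces$tag)), collapse = ", "), "\n")
  invisible(x)
}

#' Simple box mesh for solver verification
#'
#' A single-region rectangular block meshed with `n` uniform hexahedra per
#' axis. The two x-faces are tagged `clamped_end` / `moving_end`, all other
#' exterior facets `free`. Used for patch tests and analytic checks.
#'
#' @param l box edge lengths (mm), length 3.
#' @param n element counts per axis, length 3.
#' @param region region tag for all elements.
#' @return an `fe_mesh`.
#' @export
box_mesh <- function(l = c(1, 1, 1), n = c(4, 4, 4), region = "pdms") {
  stopifnot(all(l > 0), all(n >= 1))
  geo <- structure(list(domain = "unit_cell", groove_axis = "none",
                        seeding = "none", grooves = NULL,
                        film_thickness = 0.01, bottom_wall = l[3],
                        bbox = {
                          b <- rbind(x = c(0, l[1]), y = c(0, l[2]),
                                     z = c(0, l[3]))
                          colnames(b) <- c("min", "max"); b
                        }),
                   class = "chamber_geometry")
  gx <- seq(0, l[1], length.out = n[1] + 1)
  gy <- seq(0, l[2], length.out = n[2] + 1)
  gz <- seq(0, l[3], length.out = n[3] + 1)
  mesh_from_grid(geo, gx, gy, gz, function(x, y, z)
    rep(region, length(x)))
}

# Build an fe_mesh from explicit grid lines and a classifier; shared by
# mesh_geometry and box_mesh.
mesh_from_grid <- function(geo, gx, gy, gz, classify) {
  ncx <- length(gx) - 1L; ncy <- length(gy) - 1L; ncz <- length(gz) - 1L
  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  cz <- (gz[-1] + gz[-length(gz)]) / 2
  cc <- expand.grid(ix = seq_len(ncx), iy = seq_len(ncy), iz = seq_len(ncz))
  reg <- classify(cx[cc$ix], cy[cc$iy], cz[cc$iz])
  solid <- !is.na(reg)
  A <- array(0L, dim = c(ncx, ncy, ncz))
  A[cbind(cc$ix, cc$iy, cc$iz)[solid, , drop = FALSE]] <- seq_len(sum(solid))
  ec <- cc[solid, , drop = FALSE]
  region <- reg[solid]
  ne <- nrow(ec)
  ngx <- length(gx); ngy <- length(gy)
  nid <- function(ix, iy, iz) ix + (iy - 1L) * ngx + (iz - 1L) * ngx * ngy
  elems_full <- cbind(
    nid(ec$ix, ec$iy, ec$iz), nid(ec$ix + 1L, ec$iy, ec$iz),
    nid(ec$ix + 1L, ec$iy + 1L, ec$iz), nid(ec$ix, ec$iy + 1L, ec$iz),
    nid(ec$ix, ec$iy, ec$iz + 1L), nid(ec$ix + 1L, ec$iy, ec$iz + 1L),
    nid(ec$ix + 1L, ec$iy + 1L, ec$iz + 1L),
    nid(ec$ix, ec$iy + 1L, ec$iz + 1L))
  used <- sort(unique(as.vector(elems_full)))
  renum <- integer(ngx * ngy * length(gz))
  renum[used] <- seq_along(used)
  elems <- matrix(renum[elems_full], nrow = ne)
  ui <- used - 1L
  nodes <- cbind(x = gx[ui %% ngx + 1L], y = gy[(ui %/% ngx) %% ngy + 1L],
                 z = gz[ui %/% (ngx * ngy) + 1L])
  shift <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  hdim <- c(1L, 1L, 2L, 2L, 3L, 3L); hsgn <- c(-1L, 1L, -1L, 1L, -1L, 1L)
  bnd <- list()
  hx <- diff(gx)[ec$ix]; hy <- diff(gy)[ec$iy]; hz <- diff(gz)[ec$iz]
  face_area <- cbind(hy * hz, hy * hz, hx * hz, hx * hz, hx * hy, hx * hy)
  for (s in seq_len(6L)) {
    nx2 <- ec$ix + shift[[s]][1]; ny2 <- ec$iy + shift[[s]][2]
    nz2 <- ec$iz + shift[[s]][3]
    inside <- nx2 >= 1L & nx2 <= ncx & ny2 >= 1L & ny2 <= ncy &
      nz2 >= 1L & nz2 <= ncz
    nb <- integer(ne)
    nb[inside] <- A[cbind(nx2[inside], ny2[inside], nz2[inside])]
    ext <- which(nb == 0L)
    if (length(ext)) {
      fc <- facet_centers(ec[ext, , drop = FALSE], s, gx, gy, gz)
      bnd[[s]] <- data.frame(elem = ext, side = s, naxis = hdim[s],
                             nsign = hsgn[s], cx = fc[, 1], cy = fc[, 2],
                             cz = fc[, 3], area = face_area[ext, s])
    }
  }
  boundary <- do.call(rbind, bnd)
  boundary$tag <- tag_facets(geo, boundary, exterior = TRUE)
  mesh <- list(nodes = nodes, elems = elems, region = region,
               boundary = boundary, interfaces = NULL,
               grid = list(x = gx, y = gy, z = gz, index = A),
               cell_index = ec, geometry = geo)
  class(mesh) <- "fe_mesh"
  mesh
}
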