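# Static linear elasticity on tagged chamber meshes.
#
# Two load families are supported: externally applied uniaxial stretch
# (prescribed end displacement) and cellular self-condensation, encoded as a
# stress-free contraction eigenstrain over the cell-bearing region, with an
# elastic-spring (Robin) condition on the groove sidewalls representing the
# partial detachment of the hydrogel observed in extended 3D culture.
# Internal units: mm for lengths, Pa for moduli; spring stiffness is
# exposed in Pa/m and converted internally.

#' Material properties
#'
#' Isotropic linear-elastic material. Presets carry the measured moduli of
#' the three constituents: cardiac cells (30 kPa, nu 0.49), dECM-fibrin
#' hydrogel (21 kPa, nu 0.2) and PDMS elastomer (0.98 MPa, nu 0.49). The
#' near-incompressible constituents are tabulated at nu = 0.5 and computed
#' at 0.49.
#'
#' @param young_modulus Young's modulus (Pa).
#' @param poisson_ratio Poisson's ratio, in (0, 0.5).
#' @param density density (kg/m^3); informational (solves are static).
#' @return an object of class `material_props`.
#' @export
material <- function(young_modulus, poisson_ratio, density = NA_real_) {
  if (!is.finite(young_modulus) || young_modulus <= 0)
    stopf("young_modulus must be positive")
  if (!is.finite(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stopf("poisson_ratio must lie strictly between 0 and 0.5")
  structure(list(young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio, density = density),
            class = "material_props")
}

#' @rdname material
#' @export
material_presets <- function() {
  list(pdms = material(0.98e6, 0.49, 965),
       hydrogel = material(21e3, 0.2),
       cell_layer = material(30e3, 0.49, 1060))
}

#' Load case for a chamber solve
#'
#' @param kind `"applied_stretch"` or `"self_condensation"`.
#' @param applied_strain engineering strain of the applied stretch
#'   (e.g. 0.15); exactly one of `applied_strain` / `applied_displacement`
#'   for stretch loads.
#' @param applied_displacement prescribed end displacement (mm),
#'   alternative to `applied_strain`.
#' @param contraction_magnitude isotropic contraction eigenstrain of the
#'   cell-bearing material (> 0 shrinks); required for self-condensation.
#' @param sidewall_spring_stiffness distributed spring stiffness (Pa/m) of
#'   the groove sidewall support; 0 = fully detached, `Inf` = bonded.
#' @param seeding_mode `"none"`, `"layer_2d"` or `"hydrogel_3d"`. In
#'   `layer_2d` mode the contraction is in-plane biaxial (cells contract
#'   isometrically within the substrate plane); in `hydrogel_3d` it is
#'   isotropic and the sidewall spring condition is active.
#' @return an object of class `load_case`.
#' @export
load_case <- function(kind = c("applied_stretch", "self_condensation"),
                      applied_strain = NULL, applied_displacement = NULL,
                      contraction_magnitude = NULL,
                      sidewall_spring_stiffness = Inf,
                      seeding_mode = c("none", "layer_2d", "hydrogel_3d")) {
  kind <- match.arg(kind)
  seeding_mode <- match.arg(seeding_mode)
  if (kind == "applied_stretch") {
    if (is.null(applied_strain) == is.null(applied_displacement))
      stopf("give exactly one of applied_strain / applied_displacement")
  } else {
    if (is.null(contraction_magnitude) || contraction_magnitude <= 0)
      stopf("self_condensation requires contraction_magnitude > 0")
  }
  if (sidewall_spring_stiffness < 0)
    stopf("sidewall_spring_stiffness must be >= 0")
  structure(list(kind = kind, applied_strain = applied_strain,
                 applied_displacement = applied_displacement,
                 contraction_magnitude = contraction_magnitude,
                 sidewall_spring_stiffness = sidewall_spring_stiffness,
                 seeding_mode = seeding_mode),
            class = "load_case")
}

#' Boundary-condition primitives
#'
#' `bc_dirichlet()` constrains displacement components on a node set
#' selected either by a boundary tag or by a predicate on node coordinates;
#' `bc_robin()` adds a distributed spring (traction = -k u) on a tagged
#' facet set. `default_bcs()` builds the canonical condition set for a load
#' case: for the full chamber, one end fully clamped and the other end
#' displaced axially (stretch) or traction-free (condensation); for the
#' periodic groove unit cell, mirror-symmetry conditions on the cut faces
#' with the stretch applied as a symmetric end displacement pair.
#'
#' @param where a boundary tag (e.g. `"clamped_end"`) or a function
#'   `f(nodes)` returning a logical selector over mesh nodes (`nodes` is the
#'   n x 3 coordinate matrix).
#' @param comp displacement components to constrain (subset of 1:3).
#' @param value prescribed value (mm): a scalar or a function of the node
#'   coordinate matrix.
#' @param stiffness spring stiffness (Pa/m) for `bc_robin`.
#' @return a condition object consumed by [solve_elasticity()].
#' @export
bc_dirichlet <- function(where, comp = 1:3, value = 0) {
  structure(list(type = "dirichlet", where = where, comp = comp,
                 value = value), class = "fe_bc")
}

#' @rdname bc_dirichlet
#' @export
bc_robin <- function(where, stiffness) {
  structure(list(type = "robin", where = where, stiffness = stiffness),
            class = "fe_bc")
}

#' @rdname bc_dirichlet
#' @export
bc_tie <- function(where, comp) {
  # ties the selected displacement component of all selected nodes to one
  # common unknown: a relaxed-periodic face that stays planar but carries
  # zero net traction (the constant is part of the solution)
  structure(list(type = "tie", where = where, comp = comp),
            class = "fe_bc")
}

node_selector <- function(mesh, where, facets = NULL) {
  if (is.function(where)) return(which(where(mesh$nodes)))
  f <- rbind(
    if (!is.null(mesh$boundary)) mesh$boundary[mesh$boundary$tag == where,
                                               names(mesh$boundary) !=
                                                 "other", drop = FALSE],
    if (!is.null(mesh$interfaces))
      mesh$interfaces[mesh$interfaces$tag == where,
                      names(mesh$interfaces) != "other", drop = FALSE])
  if (is.null(f) || !nrow(f)) return(integer(0))
  sort(unique(as.vector(facet_nodes(mesh, f))))
}

facet_selector <- function(mesh, where) {
  out <- list()
  if (!is.null(mesh$boundary)) {
    b <- mesh$boundary[mesh$boundary$tag == where, , drop = FALSE]
    if (nrow(b)) out <- c(out, list(b[, c("elem", "side", "area")]))
  }
  if (!is.null(mesh$interfaces)) {
    b <- mesh$interfaces[mesh$interfaces$tag == where, , drop = FALSE]
    if (nrow(b)) out <- c(out, list(b[, c("elem", "side", "area")]))
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' @rdname bc_dirichlet
#' @param mesh an `fe_mesh`.
#' @param load a [load_case()].
#' @export
default_bcs <- function(mesh, load) {
  geo <- mesh$geometry
  bb <- geo$bbox
  tol <- 1e-9
  on_plane <- function(d, v) {
    force(d); force(v)
    function(nodes) abs(nodes[, d] - v) < tol
  }
  bcs <- list()
  if (load$kind == "applied_stretch") {
    L <- diff(bb["x", ])
    delta <- load$applied_displacement %||% (load$applied_strain * L)
    if (geo$domain == "chamber") {
      bcs <- list(bc_dirichlet("clamped_end", 1:3, 0),
                  bc_dirichlet("moving_end", 1, delta))
    } else {
      # symmetric end-displacement pair; mirror symmetry on y cut faces;
      # two point constraints remove the residual rigid modes
      xc <- mean(bb["x", ])
      bcs <- list(
        bc_dirichlet(on_plane(1, bb["x", 1]), 1, -delta / 2),
        bc_dirichlet(on_plane(1, bb["x", 2]), 1, delta / 2),
        bc_dirichlet(on_plane(2, bb["y", 1]), 2, 0),
        bc_tie(on_plane(2, bb["y", 2]), 2),
        bc_dirichlet(function(n) (abs(n[, 1] - bb["x", 1]) < tol |
                                    abs(n[, 1] - bb["x", 2]) < tol) &
                       abs(n[, 3] - bb["z", 1]) < tol &
                       abs(n[, 2] - min(n[, 2])) < tol, 3, 0))
    }
  } else {
    if (geo$domain == "chamber") {
      bcs <- list(bc_dirichlet("clamped_end", 1:3, 0))
    } else if (load$seeding_mode == "hydrogel_3d" &&
               !is.null(facet_selector(mesh, "groove_sidewall")) &&
               is.finite(load$sidewall_spring_stiffness)) {
      # groove-confined hydrogel: solve on the gel with the far stiffer
      # elastomer wall as rigid support; bonded floor, spring sidewalls
      bcs <- list(
        bc_dirichlet("groove_bottom", 1:3, 0),
        bc_robin("groove_sidewall", load$sidewall_spring_stiffness),
        bc_dirichlet(on_plane(1, bb["x", 1]), 1, 0),
        bc_dirichlet(on_plane(1, bb["x", 2]), 1, 0),
        bc_dirichlet(on_plane(2, bb["y", 1]), 2, 0),
        bc_dirichlet(on_plane(2, bb["y", 2]), 2, 0))
    } else {
      bcs <- list(
        bc_dirichlet(on_plane(1, bb["x", 1]), 1, 0),
        bc_dirichlet(on_plane(1, bb["x", 2]), 1, 0),
        bc_dirichlet(on_plane(2, bb["y", 1]), 2, 0),
        bc_tie(on_plane(2, bb["y", 2]), 2),
        bc_dirichlet(on_plane(3, bb["z", 1]), 3, 0))
    }
  }
  bcs
}

#' Solve a static linear-elasticity load case
#'
#' Assembles and solves the discrete equilibrium for a tagged chamber mesh.
#' Applied stretch is imposed through Dirichlet end conditions; cellular
#' contraction through an isotropic (3D hydrogel) or in-plane biaxial (2D
#' layer) eigenstrain over the cell-bearing region. For groove-confined
#' hydrogel condensation with a finite sidewall spring stiffness, the solve
#' is restricted to the hydrogel subdomain with the groove floor bonded and
#' distributed springs on the sidewall facets (the elastomer wall, ~50x
#' stiffer than the gel, acts as rigid support for this load).
#'
#' @param mesh an [mesh_geometry()] result.
#' @param materials named list mapping each region to a [material()];
#'   `material_presets()` by default.
#' @param load a [load_case()].
#' @param bcs list of boundary conditions ([bc_dirichlet()] / [bc_robin()]);
#'   `NULL` uses [default_bcs()].
#' @return an object of class `strain_field`: nodal `displacement` (mm),
#'   per-element centre `strain` (Voigt, dimensionless), `energy`
#'   (elastic strain energy), the active element set, and the provenance
#'   `load`.
#' @export
solve_elasticity <- function(mesh, materials = material_presets(), load,
                             bcs = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(load, "load_case"))
  regions <- unique(mesh$region)
  missing_m <- setdiff(regions, names(materials))
  if (length(missing_m))
    stopf("no material for region(s): %s", paste(missing_m, collapse = ", "))
  for (r in regions) {
    m <- materials[[r]]
    if (!inherits(m, "material_props")) stopf("materials$%s is not a material", r)
  }
  if (is.null(bcs)) bcs <- default_bcs(mesh, load)

  # active subdomain
  sub_gel <- load$kind == "self_condensation" &&
    load$seeding_mode == "hydrogel_3d" &&
    !is.null(facet_selector(mesh, "groove_sidewall")) &&
    is.finite(load$sidewall_spring_stiffness) &&
    mesh$geometry$domain == "unit_cell"
  active <- if (sub_gel) which(mesh$region == "hydrogel")
            else seq_len(nrow(mesh$elems))
  if (!length(active)) stopf("no active elements for this load")

  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  hs <- elem_sizes(mesh)

  # eigenstrain per element (Voigt) for condensation loads
  eps0 <- NULL
  if (load$kind == "self_condensation") {
    c0 <- load$contraction_magnitude
    eps0 <- matrix(0, nrow(mesh$elems), 6)
    gel <- mesh$region == "hydrogel"
    lay <- mesh$region == "cell_layer"
    if (load$seeding_mode == "hydrogel_3d" && any(gel))
      eps0[gel, 1:3] <- -c0
    else if (load$seeding_mode == "layer_2d" && any(lay))
      eps0[lay, 1:2] <- -c0
    else if (any(gel)) eps0[gel, 1:3] <- -c0
    else if (any(lay)) eps0[lay, 1:2] <- -c0
    else stopf("self_condensation needs a cell-bearing region in the mesh")
  }

  # group elements by (size, region) and assemble triplets
  key <- paste(signif(hs[, 1], 12), signif(hs[, 2], 12),
               signif(hs[, 3], 12), mesh$region)
  edof <- matrix(0L, nrow(mesh$elems), 24)
  edof[, seq(1, 24, 3)] <- 3L * (mesh$elems - 1L) + 1L
  edof[, seq(2, 24, 3)] <- 3L * (mesh$elems - 1L) + 2L
  edof[, seq(3, 24, 3)] <- 3L * mesh$elems

  ii <- list(); jj <- list(); xx <- list()
  f <- numeric(ndof)
  rtile <- rep(1:24, times = 24)
  ctile <- rep(1:24, each = 24)
  for (k in unique(key[active])) {
    els <- active[key[active] == k]
    e1 <- els[1]
    m <- materials[[mesh$region[e1]]]
    D <- elastic_D(m$young_modulus, m$poisson_ratio)
    ke <- hex8_ke(hs[e1, 1], hs[e1, 2], hs[e1, 3], D)
    ed <- edof[els, , drop = FALSE]
    ii[[k]] <- as.vector(ed[, rtile])
    jj[[k]] <- as.vector(ed[, ctile])
    xx[[k]] <- rep(as.vector(ke), each = length(els))
    if (!is.null(eps0)) {
      # eigenstrain is uniform within the cell-bearing region
      e0 <- eps0[e1, ]
      if (any(e0 != 0)) {
        fe <- hex8_fe_eigen(hs[e1, 1], hs[e1, 2], hs[e1, 3], D, e0)
        # on a structured grid a fixed local corner maps distinct elements
        # to distinct global nodes, so no index collisions per column
        for (q in 1:24) f[ed[, q]] <- f[ed[, q]] + fe[q]
      }
    }
  }
  active_nodes <- sort(unique(as.vector(mesh$elems[active, ])))
  active_dofs <- as.vector(t(outer(3L * (active_nodes - 1L), 1:3, `+`)))

  # Robin springs (facet mass matrices, all components)
  for (bc in bcs) {
    if (bc$type != "robin") next
    fac <- facet_selector(mesh, bc$where)
    if (is.null(fac)) next
    fac <- fac[fac$elem %in% active, , drop = FALSE]
    if (!nrow(fac)) next
    k_mm <- bc$stiffness / 1000   # Pa/m -> Pa/mm
    if (k_mm == 0) next
    fn <- facet_nodes(mesh, fac)
    M4 <- facet_mass(1)
    for (a in 1:4) for (b in 1:4) {
      for (cmp in 1:3) {
        key <- paste("robin", bc$where, a, b, cmp)
        ii[[key]] <- 3L * (fn[, a] - 1L) + cmp
        jj[[key]] <- 3L * (fn[, b] - 1L) + cmp
        xx[[key]] <- k_mm * M4[a, b] * fac$area
      }
    }
  }

  # tied faces: slave dofs share one master unknown (a relaxed-periodic
  # plane face with zero net traction)
  dof_map <- seq_len(ndof)
  for (bc in bcs) {
    if (bc$type != "tie") next
    nsel <- intersect(node_selector(mesh, bc$where), active_nodes)
    if (length(nsel) < 2) next
    for (cmp in bc$comp) {
      dofs <- 3L * (nsel - 1L) + cmp
      dof_map[dofs] <- dofs[1]
    }
  }
  tied <- any(dof_map != seq_len(ndof))
  K <- Matrix::sparseMatrix(i = dof_map[unlist(ii)], j = dof_map[unlist(jj)],
                            x = unlist(xx), dims = c(ndof, ndof))
  if (tied) {
    slaves <- which(dof_map != seq_len(ndof))
    acc <- rowsum(f[slaves], dof_map[slaves])
    f[as.integer(rownames(acc))] <- f[as.integer(rownames(acc))] + acc[, 1]
    f[slaves] <- 0
  }

  # Dirichlet constraints
  fixed_dof <- integer(0); fixed_val <- numeric(0)
  for (bc in bcs) {
    if (bc$type != "dirichlet") next
    nsel <- node_selector(mesh, bc$where)
    nsel <- intersect(nsel, active_nodes)
    if (!length(nsel)) next
    vals <- if (is.function(bc$value)) bc$value(mesh$nodes[nsel, , drop = FALSE])
            else rep(bc$value, length(nsel))
    for (cmp in bc$comp) {
      fixed_dof <- c(fixed_dof, dof_map[3L * (nsel - 1L) + cmp])
      fixed_val <- c(fixed_val, vals)
    }
  }
  if (anyDuplicated(fixed_dof)) {
    keep <- !duplicated(fixed_dof)
    fixed_dof <- fixed_dof[keep]; fixed_val <- fixed_val[keep]
  }

  free <- setdiff(unique(dof_map[active_dofs]), fixed_dof)
  if (!length(free) && !length(fixed_dof))
    stopf("singular system: no constraints")
  u <- numeric(ndof)
  u[fixed_dof] <- fixed_val
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    rhs <- f[free]
    if (length(fixed_dof) && any(fixed_val != 0))
      rhs <- rhs - as.numeric(K[free, fixed_dof, drop = FALSE] %*% fixed_val)
    sol <- tryCatch(
      Matrix::solve(Matrix::forceSymmetric(Kff), rhs),
      error = function(e) stopf(
        "singular system (insufficient constraints or bad material): %s",
        conditionMessage(e)))
    u[free] <- as.numeric(sol)
  }
  if (tied) u <- u[dof_map]

  U <- matrix(u, ncol = 3, byrow = TRUE)
  strain <- element_strains(mesh, U, active)
  energy <- 0.5 * sum(u * as.numeric(K %*% u)) -
    if (!is.null(eps0)) sum(u * f) else 0

  structure(list(displacement = U, strain = strain, active = active,
                 mesh = mesh, load = load, energy = energy,
                 stiffness_energy = 0.5 * sum(u * as.numeric(K %*% u))),
            class = "strain_field")
}

# Per-element centre strains (Voigt) for active elements; NA elsewhere.
element_strains <- function(mesh, U, active = seq_len(nrow(mesh$elems))) {
  hs <- elem_sizes(mesh)
  strain <- matrix(NA_real_, nrow(mesh$elems), 6)
  colnames(strain) <- c("xx", "yy", "zz", "yz", "xz", "xy")
  ukey <- paste(signif(hs[, 1], 12), signif(hs[, 2], 12), signif(hs[, 3], 12))
  for (k in unique(ukey[active])) {
    els <- active[ukey[active] == k]
    e1 <- els[1]
    B <- hex8_B(0, 0, 0, hs[e1, 1], hs[e1, 2], hs[e1, 3])
    ue <- matrix(0, length(els), 24)
    for (a in 1:8) {
      ue[, 3 * a - 2] <- U[mesh$elems[els, a], 1]
      ue[, 3 * a - 1] <- U[mesh$elems[els, a], 2]
      ue[, 3 * a] <- U[mesh$elems[els, a], 3]
    }
    strain[els, ] <- ue %*% t(B)
  }
  strain
}

#' Interpolate the strain tensor at a point
#'
#' Evaluates the symmetric small-strain tensor of a solved field at an
#' arbitrary point inside the mesh, using the element's trilinear
#' displacement interpolant at that point.
#'
#' @param field a [solve_elasticity()] result.
#' @param point numeric length-3 coordinates (mm).
#' @return a 3 x 3 symmetric strain tensor (dimensionless).
#' @export
probe_strain <- function(field, point) {
  stopifnot(inherits(field, "strain_field"))
  mesh <- field$mesh
  el <- locate_element(mesh, point)
  if (!(el %in% field$active))
    stopf("probe point lies outside the active (solved) subdomain")
  ec <- mesh$cell_index[el, ]
  g <- mesh$grid
  h <- c(diff(g$x)[ec$ix], diff(g$y)[ec$iy], diff(g$z)[ec$iz])
  lo <- c(g$x[ec$ix], g$y[ec$iy], g$z[ec$iz])
  loc <- 2 * (as.numeric(point) - lo) / h - 1
  loc <- pmin(pmax(loc, -1), 1)
  B <- hex8_B(loc[1], loc[2], loc[3], h[1], h[2], h[3])
  ue <- as.vector(t(field$displacement[mesh$elems[el, ], ]))
  v <- as.numeric(B %*% ue)
  matrix(c(v[1], v[6] / 2, v[5] / 2,
           v[6] / 2, v[2], v[4] / 2,
           v[5] / 2, v[4] / 2, v[3]), 3, 3)
}

#' Effective axial strain at a representative location
#'
#' The axial (stretch-direction) normal strain at the probe point,
#' expressed in percent, as used for the strain-transmission campaign
#' across the seeding-by-topography cases.
#'
#' @param field an applied-stretch [solve_elasticity()] result.
#' @param probe point coordinates (mm); defaults to the representative
#'   location: near the chamber/cell centre, on the groove midline, at
#'   groove half-height for 3D hydrogel seeding.
#' @return axial strain in percent.
#' @export
effective_axial_strain <- function(field, probe = NULL) {
  stopifnot(inherits(field, "strain_field"))
  if (field$load$kind != "applied_stretch")
    stopf("effective_axial_strain expects an applied_stretch solve")
  if (is.null(probe)) probe <- representative_probe(field$mesh$geometry)
  100 * probe_strain(field, probe)[1, 1]
}

#' Representative probe location for a geometry
#'
#' Near the chamber centre, on the groove midline; at groove half-height in
#' 3D hydrogel seeding, at film mid-thickness for a 2D layer, and just below
#' the groove floor inside the elastomer when unseeded.
#'
#' @param geo a [chamber_geometry()].
#' @param offset optional additive offset (mm, length 3).
#' @return length-3 coordinates (mm).
#' @export
representative_probe <- function(geo, offset = c(0, 0, 0)) {
  bb <- geo$bbox
  p <- c(mean(bb["x", ]), mean(bb["y", ]), NA)
  g <- geo$grooves
  if (!is.null(g)) {
    mid_span <- g$spans[ceiling(nrow(g$spans) / 2), ]
    tau <- mean(mid_span)
    if (g$trans_axis == "y") p[2] <- tau else p[1] <- tau
    p[3] <- switch(geo$seeding,
                   hydrogel_3d = (g$z_lig + g$z_top) / 2,
                   layer_2d = g$z_lig + geo$film_thickness / 2,
                   none = g$z_lig - min(0.05, geo$groove_depth / 4))
  } else {
    p[3] <- switch(geo$seeding,
                   hydrogel_3d = geo$bottom_wall + geo$groove_depth / 2,
                   layer_2d = geo$bottom_wall + geo$film_thickness / 2,
                   none = geo$bottom_wall / 2)
    if (geo$domain == "chamber" && geo$seeding == "none")
      p[2] <- geo$thick_sidewall + geo$cavity_width / 2
  }
  p + offset
}

#' @export
print.strain_field <- function(x, ...) {
  cat("Strain field (", x$load$kind, ")\n", sep = "")
  cat("  active elements:", length(x$active), "of", nrow(x$mesh$elems), "\n")
  cat(sprintf("  max |u| = %.4g mm, elastic energy = %.4g\n",
              max(abs(x$displacement)), x$energy))
  invisible(x)
}
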