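# Mesh and field export: legacy VTK unstructured grid and Gmsh MSH 2.2
# (ASCII). VTK carries optional point data (displacement) and cell data
# (region, strain components); MSH round-trips the mesh with region tags.

#' Export a mesh (and optional field) as legacy VTK
#'
#' Writes an ASCII VTK unstructured grid with hexahedral cells, the region
#' tag as cell data and, when a [solve_elasticity()] field is given, nodal
#' displacement vectors and element-centre strain components.
#'
#' @param mesh an `fe_mesh`.
#' @param file output path (.vtk).
#' @param field optional `strain_field` on the same mesh.
#' @return the file path, invisibly.
#' @export
write_vtk <- function(mesh, file, field = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "grooved chamber mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  writeLines(apply(cbind(8L, mesh$elems - 1L), 1, paste, collapse = " "),
             con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$region))), con)
  if (!is.null(field)) {
    comps <- colnames(field$strain)
    for (j in seq_along(comps)) {
      writeLines(c(sprintf("SCALARS strain_%s double 1", comps[j]),
                   "LOOKUP_TABLE default"), con)
      v <- field$strain[, j]
      v[is.na(v)] <- 0
      writeLines(sprintf("%.10g", v), con)
    }
    writeLines(sprintf("POINT_DATA %d", nn), con)
    writeLines("VECTORS displacement double", con)
    writeLines(apply(field$displacement, 1, function(r)
      paste(sprintf("%.10g", r), collapse = " ")), con)
  }
  invisible(file)
}

#' Gmsh MSH 2.2 export / import
#'
#' Writes the mesh as Gmsh MSH 2.2 ASCII with the region index as the
#' physical tag of each hexahedron; `read_msh` reads such a file back
#' (hexahedral elements only).
#'
#' @param mesh an `fe_mesh`.
#' @param file path (.msh).
#' @return `read_msh` returns a list with `nodes`, `elems` and `region`.
#' @export
write_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  regions <- sort(unique(mesh$region))
  rid <- match(mesh$region, regions)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", as.character(length(regions)),
               sprintf("3 %d \"%s\"", seq_along(regions), regions),
               "$EndPhysicalNames",
               "$Nodes", as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]),
             con)
  writeLines(c("$EndNodes", "$Elements",
               as.character(nrow(mesh$elems))), con)
  writeLines(paste(seq_len(nrow(mesh$elems)), 5, 2, rid, rid,
                   mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
                   mesh$elems[, 4], mesh$elems[, 5], mesh$elems[, 6],
                   mesh$elems[, 7], mesh$elems[, 8]), con)
  writeLines("$EndElements", con)
  invisible(file)
}

#' @rdname write_msh
#' @export
read_msh <- function(file) {
  ln <- readLines(file)
  sect <- function(name) {
    a <- match(paste0("$", name), ln)
    b <- match(paste0("$End", name), ln)
    if (is.na(a) || is.na(b)) stopf("MSH file lacks section %s", name)
    ln[(a + 1):(b - 1)]
  }
  pn <- sect("PhysicalNames")
  nmap <- NULL
  if (length(pn) > 1) {
    parts <- strsplit(pn[-1], " ")
    nmap <- vapply(parts, function(p)
      gsub('"', "", paste(p[-(1:2)], collapse = " ")), "")
    names(nmap) <- vapply(parts, function(p) p[2], "")
  }
  nd <- sect("Nodes")
  nmat <- do.call(rbind, lapply(strsplit(nd[-1], " +"), as.numeric))
  nodes <- nmat[order(nmat[, 1]), 2:4, drop = FALSE]
  colnames(nodes) <- c("x", "y", "z")
  el <- sect("Elements")
  emat <- do.call(rbind, lapply(strsplit(el[-1], " +"), as.numeric))
  hex <- emat[emat[, 2] == 5, , drop = FALSE]
  ntags <- hex[1, 3]
  elems <- hex[, (4 + ntags):(3 + ntags + 8), drop = FALSE]
  phys <- as.character(hex[, 4])
  region <- if (!is.null(nmap)) unname(nmap[phys]) else phys
  list(nodes = nodes, elems = elems, region = region)
}

#' Write a probe report as CSV
#'
#' One row per probed case: scenario/case label, probe location, the six
#' strain tensor components and the effective axial strain in percent.
#'
#' @param cases named list of `strain_field`s, or a single field.
#' @param file output CSV path.
#' @param probes optional list/vector of probe points matching `cases`.
#' @return the report data frame, invisibly.
#' @export
write_probe_report <- function(cases, file, probes = NULL) {
  if (inherits(cases, "strain_field")) cases <- list(case = cases)
  rows <- lapply(seq_along(cases), function(i) {
    fld <- cases[[i]]
    p <- if (is.null(probes)) representative_probe(fld$mesh$geometry)
         else probes[[i]]
    eps <- probe_strain(fld, p)
    data.frame(case = names(cases)[i] %||% as.character(i),
               x = p[1], y = p[2], z = p[3],
               exx = eps[1, 1], eyy = eps[2, 2], ezz = eps[3, 3],
               eyz = eps[2, 3], exz = eps[1, 3], exy = eps[1, 2],
               effective_axial_pct = 100 * eps[1, 1])
  })
  rep_df <- do.call(rbind, rows)
  utils::write.csv(rep_df, file, row.names = FALSE)
  invisible(rep_df)
}
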