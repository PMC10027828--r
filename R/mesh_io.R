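# Mesh file I/O: Gmsh MSH 4.1 (ASCII) with physical groups, and legacy
# VTK unstructured-grid export for visualization.
#
# The MSH writer emits one curve entity per boundary tag and one surface
# entity per cell region, named through $PhysicalNames; the reader
# accepts any ASCII MSH 4.1 file whose physical names include the four
# boundary groups and the two region groups used here.

.tag_order <- c("INLET", "OUTLET", "WALL_VESSEL", "WALL_SAC")
.region_order <- c("LUMEN", "SAC")

#' Write a mesh to Gmsh MSH 4.1
#'
#' Boundary tags and cell regions are preserved as physical groups
#' (`INLET`, `OUTLET`, `WALL_VESSEL`, `WALL_SAC`; `LUMEN`, `SAC`).
#'
#' @param mesh An `aneu_mesh`.
#' @param path Output path (conventionally `.msh`).
#' @return `path` invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "aneu_mesh"))
  tags <- .tag_order[.tag_order %in% unique(mesh$boundary$tag)]
  regs <- .region_order[.region_order %in% unique(mesh$region)]
  n <- nrow(mesh$nodes)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  w("$PhysicalNames", as.character(length(tags) + length(regs)))
  for (i in seq_along(tags)) w(sprintf('1 %d "%s"', i, tags[i]))
  for (i in seq_along(regs)) w(sprintf('2 %d "%s"', length(tags) + i, regs[i]))
  w("$EndPhysicalNames")
  bb <- apply(mesh$nodes, 2, range)
  w("$Entities", sprintf("0 %d %d 0", length(tags), length(regs)))
  for (i in seq_along(tags))
    w(sprintf("%d %.17g %.17g 0 %.17g %.17g 0 1 %d 0",
              i, bb[1, 1], bb[1, 2], bb[2, 1], bb[2, 2], i))
  for (i in seq_along(regs))
    w(sprintf("%d %.17g %.17g 0 %.17g %.17g 0 1 %d 0",
              i, bb[1, 1], bb[1, 2], bb[2, 1], bb[2, 2], length(tags) + i))
  w("$EndEntities")
  w("$Nodes", sprintf("1 %d 1 %d", n, n),
    sprintf("2 1 0 %d", n),
    as.character(seq_len(n)),
    sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]))
  w("$EndNodes")
  eb <- split(seq_len(nrow(mesh$boundary)), mesh$boundary$tag)
  tb <- split(seq_len(nrow(mesh$tri)), mesh$region)
  n_el <- nrow(mesh$boundary) + nrow(mesh$tri)
  w("$Elements", sprintf("%d %d 1 %d", length(eb) + length(tb), n_el, n_el))
  el <- 0L
  for (i in seq_along(tags)) {
    idx <- eb[[tags[i]]]
    w(sprintf("1 %d 1 %d", i, length(idx)),
      sprintf("%d %d %d", el + seq_along(idx),
              mesh$boundary$n1[idx], mesh$boundary$n2[idx]))
    el <- el + length(idx)
  }
  for (i in seq_along(regs)) {
    idx <- tb[[regs[i]]]
    w(sprintf("2 %d 2 %d", i, length(idx)),
      sprintf("%d %d %d %d", el + seq_along(idx),
              mesh$tri[idx, 1], mesh$tri[idx, 2], mesh$tri[idx, 3]))
    el <- el + length(idx)
  }
  w("$EndElements")
  invisible(path)
}

#' Read a mesh from Gmsh MSH 4.1
#'
#' Accepts ASCII MSH 4.1 files whose physical groups name the boundary
#' segments `INLET`, `OUTLET`, `WALL_VESSEL`, `WALL_SAC` and the cell
#' regions `LUMEN` and/or `SAC`.  Unknown physical names raise an error
#' listing the offending groups; boundary edges and triangle orientation
#' are rebuilt so the result satisfies the `aneu_mesh` invariants.
#'
#' @param path Path to a `.msh` file.
#' @param require_sac Require the SAC region and WALL_SAC group.
#' @return An `aneu_mesh`.
#' @export
read_mesh_msh <- function(path, require_sac = TRUE) {
  lines <- readLines(path, warn = FALSE)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1))
      stop("MSH file is missing the $", name, " section: ", path)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sect("MeshFormat")[1]), "\\s+")[[1]]
  if (!startsWith(fmt[1], "4"))
    stop("unsupported MSH version ", fmt[1], " (need 4.x ASCII)")
  if (fmt[2] != "0") stop("binary MSH files are not supported")

  pn <- sect("PhysicalNames")
  n_pn <- as.integer(pn[1])
  phys <- do.call(rbind, lapply(pn[1L + seq_len(n_pn)], function(l) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    data.frame(dim = as.integer(parts[1]), tag = as.integer(parts[2]),
               name = gsub('"', "", paste(parts[-(1:2)], collapse = " ")))
  }))
  known <- c(.tag_order, .region_order)
  bad <- setdiff(phys$name, known)
  if (length(bad))
    stop("unknown physical group name(s) in ", path, ": ",
         paste(bad, collapse = ", "))

  # entity (dim, tag) -> physical tag
  en <- sect("Entities")
  cnt <- as.integer(strsplit(trimws(en[1]), "\\s+")[[1]])
  ent <- list()
  row <- 2L
  for (d in 0:3) {
    for (k in seq_len(cnt[d + 1L])) {
      parts <- as.numeric(strsplit(trimws(en[row]), "\\s+")[[1]])
      row <- row + 1L
      if (d == 0L) next  # points carry 4 leading fields; unused here
      nphys <- parts[8L]
      if (nphys >= 1)
        ent[[paste(d, parts[1L])]] <- as.integer(parts[9L])
    }
  }

  nd <- sect("Nodes")
  hdr <- as.integer(strsplit(trimws(nd[1]), "\\s+")[[1]])
  n_blocks <- hdr[1]; n_nodes <- hdr[2]
  row <- 2L
  node_tag <- integer(n_nodes); xy <- matrix(0, n_nodes, 2L)
  got <- 0L
  for (blk in seq_len(n_blocks)) {
    bh <- as.integer(strsplit(trimws(nd[row]), "\\s+")[[1]])
    nb <- bh[4L]; row <- row + 1L
    if (nb == 0L) next
    tags_b <- as.integer(nd[row:(row + nb - 1L)]); row <- row + nb
    for (k in seq_len(nb)) {
      p <- as.numeric(strsplit(trimws(nd[row]), "\\s+")[[1]])
      got <- got + 1L
      node_tag[got] <- tags_b[k]
      xy[got, ] <- p[1:2]
      row <- row + 1L
    }
  }
  remap <- integer(max(node_tag)); remap[node_tag] <- seq_len(n_nodes)

  el <- sect("Elements")
  hdr <- as.integer(strsplit(trimws(el[1]), "\\s+")[[1]])
  row <- 2L
  edges <- list(); etags <- character(0)
  tris <- list(); rtags <- character(0)
  for (blk in seq_len(hdr[1])) {
    bh <- as.integer(strsplit(trimws(el[row]), "\\s+")[[1]])
    dim_b <- bh[1]; ent_b <- bh[2]; type_b <- bh[3]; nb <- bh[4]
    row <- row + 1L
    if (nb == 0L) next
    dat <- do.call(rbind, lapply(el[row:(row + nb - 1L)], function(l)
      as.integer(strsplit(trimws(l), "\\s+")[[1]])))
    row <- row + nb
    ptag <- ent[[paste(dim_b, ent_b)]]
    pname <- if (!is.null(ptag)) phys$name[phys$tag == ptag &
                                             phys$dim == dim_b] else NA
    if (type_b == 1L && dim_b == 1L) {         # 2-node line
      if (is.na(pname) || !length(pname))
        stop("boundary elements without a physical group in ", path)
      edges[[length(edges) + 1L]] <- dat[, 2:3, drop = FALSE]
      etags <- c(etags, rep(pname, nb))
    } else if (type_b == 2L && dim_b == 2L) {  # 3-node triangle
      if (is.na(pname) || !length(pname))
        stop("surface elements without a physical group in ", path)
      tris[[length(tris) + 1L]] <- dat[, 2:4, drop = FALSE]
      rtags <- c(rtags, rep(pname, nb))
    }
  }
  if (!length(tris)) stop("no triangles found in ", path)
  tri <- matrix(remap[do.call(rbind, tris)], ncol = 3L)
  region <- rtags
  if (require_sac && !any(region == "SAC"))
    stop("mesh file has no SAC region: ", path)

  a <- .tri_signed_area(xy, tri)
  if (any(a == 0)) stop("degenerate triangle in ", path)
  tri[a < 0, ] <- tri[a < 0, c(1L, 3L, 2L)]

  tag_map <- new.env(parent = emptyenv())
  if (length(edges)) {
    ed <- matrix(remap[do.call(rbind, edges)], ncol = 2L)
    for (k in seq_len(nrow(ed)))
      assign(paste(min(ed[k, ]), max(ed[k, ])), etags[k], envir = tag_map)
  }
  mesh <- .finalize_mesh(xy, tri, region, function(mx, my) NA_character_)
  key <- paste(pmin(mesh$boundary$n1, mesh$boundary$n2),
               pmax(mesh$boundary$n1, mesh$boundary$n2))
  looked <- vapply(key, function(k)
    if (exists(k, envir = tag_map)) get(k, envir = tag_map) else
      NA_character_, character(1))
  if (anyNA(looked))
    stop("mesh boundary edges without a tagged physical group in ", path)
  mesh$boundary$tag <- unname(looked)
  validate_mesh(mesh, require_sac = require_sac)
  mesh
}

#' Write a mesh (and optional fields) as legacy VTK
#'
#' ASCII legacy VTK unstructured grid with the cell region as cell data;
#' nodal fields (velocity components, pressure, ...) can be attached as
#' point data for visualization in ParaView and friends.
#'
#' @param mesh An `aneu_mesh`.
#' @param path Output path (conventionally `.vtk`).
#' @param point_data Named list of per-node numeric vectors.
#' @return `path` invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "aneu_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# vtk DataFile Version 3.0", "aneuflow mesh", "ASCII",
    "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n),
    sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]),
    sprintf("CELLS %d %d", m, 4L * m),
    sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
            mesh$tri[, 3] - 1L),
    sprintf("CELL_TYPES %d", m), rep("5", m),
    sprintf("CELL_DATA %d", m), "SCALARS region int 1",
    "LOOKUP_TABLE default", as.character(as.integer(mesh$region == "SAC")))
  if (length(point_data)) {
    w(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      stopifnot(length(point_data[[nm]]) == n)
      w(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
        sprintf("%.17g", point_data[[nm]]))
    }
  }
  invisible(path)
}

#' Read or write a mesh, dispatching on file extension
#'
#' `.msh` reads/writes Gmsh MSH 4.1; `.vtk` writes legacy VTK
#' (write-only).
#'
#' @param mesh An `aneu_mesh` (for writing).
#' @param path File path.
#' @param ... Passed to the format-specific functions.
#' @return `read_mesh`: an `aneu_mesh`.  `write_mesh`: `path` invisibly.
#' @export
read_mesh <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "msh") return(read_mesh_msh(path, ...))
  stop("unsupported mesh input format: .", ext)
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "msh") return(write_mesh_msh(mesh, path))
  if (ext == "vtk") return(write_mesh_vtk(mesh, path, ...))
  stop("unsupported mesh output format: .", ext)
}
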