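#' Read a tetrahedral mesh from VTK legacy or Gmsh MSH
#'
#' VTK legacy ASCII unstructured grids carry region tags as an integer
#' `region_id` cell-data array and node sets as a single integer point-data
#' bit-field array (`node_sets`); both name mappings live in the file's title
#' line, so a mesh round-trips through one standard file. Gmsh MSH 4.1 files
#' carry regions as physical names / element blocks and node sets as a
#' `node_sets` bit-field `$NodeData` record.
#'
#' @param path file path.
#' @param format "vtk" or "msh"; guessed from the extension when missing.
#' @return a [tet_mesh].
#' @export
read_tet_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read mesh: file not found: ", path)
  format <- resolve_mesh_format(path, format)
  switch(format,
    vtk = read_vtk_tet(path),
    msh = read_msh_tet(path)
  )
}

#' Write a tetrahedral mesh to VTK legacy or Gmsh MSH
#'
#' @param mesh a [tet_mesh].
#' @param path output path.
#' @param format "vtk" or "msh"; guessed from the extension when missing.
#' @param point_data optional named list of per-node numeric vectors or
#'   n x 3 matrices written as additional point-data arrays (VTK only).
#' @return `path`, invisibly.
#' @export
write_tet_mesh <- function(mesh, path, format = NULL, point_data = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  format <- resolve_mesh_format(path, format)
  switch(format,
    vtk = write_vtk_tet(mesh, path, point_data),
    msh = write_msh_tet(mesh, path)
  )
  invisible(path)
}

resolve_mesh_format <- function(path, format) {
  if (is.null(format)) format <- tolower(sub(".*\\.", "", path))
  format <- tolower(format)
  if (!format %in% c("vtk", "msh")) {
    stop("tet-mesh format must be vtk or msh (got '", format, "')")
  }
  format
}

node_set_bitfield <- function(mesh) {
  bits <- numeric(nrow(mesh$nodes))
  for (i in seq_along(mesh$node_sets)) {
    bits[mesh$node_sets[[i]]] <- bits[mesh$node_sets[[i]]] + 2^(i - 1)
  }
  bits
}

bitfield_to_node_sets <- function(bits, set_names) {
  sets <- list()
  for (i in seq_along(set_names)) {
    sets[[set_names[i]]] <- which(bits %% 2^i >= 2^(i - 1))
  }
  sets
}

# ---- VTK legacy ASCII ----

write_vtk_tet <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  regions <- unique(mesh$region)
  title <- sprintf("bramax regions=%s sets=%s",
                   paste(regions, collapse = ","),
                   paste(names(mesh$node_sets), collapse = ","))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  t0 <- mesh$tets - 1L
  writeLines(paste(4, t0[, 1], t0[, 2], t0[, 3], t0[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS region_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$region, regions) - 1L), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS node_sets int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(node_set_bitfield(mesh))), con)
  for (nm in names(point_data)) {
    v <- point_data[[nm]]
    if (is.matrix(v)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(v, 1, function(r)
        paste(sprintf("%.17g", r), collapse = " ")), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.17g", v), con)
    }
  }
}

read_vtk_tet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  title <- if (length(lines) >= 2) lines[2] else ""
  regions <- sets <- character(0)
  if (grepl("regions=", title)) {
    regions <- strsplit(sub(".*regions=(\\S*).*", "\\1", title), ",")[[1]]
  }
  if (grepl("sets=", title)) {
    sets <- strsplit(sub(".*sets=(\\S*).*", "\\1", title), ",")[[1]]
    sets <- sets[nzchar(sets)]
  }
  ipts <- grep("^POINTS ", lines)[1]
  if (is.na(ipts)) stop("not a VTK legacy unstructured grid: ", path)
  n <- as.integer(strsplit(lines[ipts], "\\s+")[[1]][2])
  nodes <- do.call(rbind, lapply(strsplit(trimws(lines[ipts + seq_len(n)]),
                                          "\\s+"), as.numeric))
  icel <- grep("^CELLS ", lines)[1]
  m <- as.integer(strsplit(lines[icel], "\\s+")[[1]][2])
  crows <- lapply(strsplit(trimws(lines[icel + seq_len(m)]), "\\s+"),
                  as.integer)
  sizes <- vapply(crows, `[`, integer(1), 1L)
  ityp <- grep("^CELL_TYPES ", lines)[1]
  types <- as.integer(trimws(lines[ityp + seq_len(m)]))
  if (any(types != 10L) || any(sizes != 4L)) {
    stop("mixed or non-tetrahedral element types in VTK file: ", path)
  }
  tets <- do.call(rbind, lapply(crows, function(r) r[2:5])) + 1L
  region <- rep(if (length(regions)) regions[1] else "soft_tissue", m)
  ird <- grep("^SCALARS region_id", lines)[1]
  if (!is.na(ird)) {
    ids <- as.integer(trimws(lines[ird + 1 + seq_len(m)]))
    if (length(regions)) region <- regions[ids + 1L]
  }
  node_sets <- list()
  ins <- grep("^SCALARS node_sets", lines)[1]
  if (!is.na(ins) && length(sets)) {
    bits <- as.numeric(trimws(lines[ins + 1 + seq_len(n)]))
    node_sets <- bitfield_to_node_sets(bits, sets)
  }
  tet_mesh(nodes, tets, region, node_sets)
}

# ---- Gmsh MSH 4.1 ASCII ----

write_msh_tet <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  regions <- unique(mesh$region)
  n <- nrow(mesh$nodes)
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat"), con)
  writeLines(c("$PhysicalNames", as.character(length(regions)),
               sprintf("3 %d \"%s\"", seq_along(regions), regions),
               "$EndPhysicalNames"), con)
  writeLines(c("$Nodes", sprintf("1 %d 1 %d", n, n),
               sprintf("3 1 0 %d", n),
               as.character(seq_len(n)),
               apply(mesh$nodes, 1, function(r)
                 paste(sprintf("%.17g", r), collapse = " "))), con)
  writeLines("$EndNodes", con)
  m <- nrow(mesh$tets)
  writeLines(c("$Elements", sprintf("%d %d 1 %d", length(regions), m, m)), con)
  eid <- 0L
  for (k in seq_along(regions)) {
    idx <- which(mesh$region == regions[k])
    writeLines(sprintf("3 %d 4 %d", k, length(idx)), con)
    t <- mesh$tets[idx, , drop = FALSE]
    writeLines(paste(eid + seq_along(idx), t[, 1], t[, 2], t[, 3], t[, 4]),
               con)
    eid <- eid + length(idx)
  }
  writeLines("$EndElements", con)
  if (length(mesh$node_sets)) {
    bits <- node_set_bitfield(mesh)
    writeLines(c("$NodeData", "2",
                 "\"node_sets\"",
                 sprintf("\"%s\"", paste(names(mesh$node_sets),
                                         collapse = ",")),
                 "1", "0", "3", "0", "1", as.character(n),
                 paste(seq_len(n), sprintf("%.17g", bits))), con)
    writeLines("$EndNodeData", con)
  }
}

read_msh_tet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1):(i1 - 1)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt) || !startsWith(fmt[1], "4.1")) {
    stop("not a Gmsh MSH 4.1 file: ", path)
  }
  phys <- sec("PhysicalNames")
  region_names <- character(0)
  if (!is.null(phys)) {
    np <- as.integer(phys[1])
    for (i in seq_len(np)) {
      tok <- strsplit(trimws(phys[1 + i]), "\\s+")[[1]]
      region_names[as.integer(tok[2])] <- gsub('"', "", tok[3])
    }
  }
  nl <- sec("Nodes")
  hdr <- as.numeric(strsplit(trimws(nl[1]), "\\s+")[[1]])
  nblocks <- hdr[1]; ntot <- hdr[2]
  nodes <- matrix(0, ntot, 3)
  tag_row <- integer(0)
  pos <- 2L
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(nl[pos]), "\\s+")[[1]])
    nb <- bh[4]
    tags <- as.integer(nl[pos + seq_len(nb)])
    coords <- do.call(rbind, lapply(
      strsplit(trimws(nl[pos + nb + seq_len(nb)]), "\\s+"), as.numeric))
    row0 <- length(tag_row)
    nodes[row0 + seq_len(nb), ] <- coords[, 1:3]
    tag_row[tags] <- row0 + seq_len(nb)
    pos <- pos + 1L + 2L * nb
  }
  el <- sec("Elements")
  hdr <- as.integer(strsplit(trimws(el[1]), "\\s+")[[1]])
  nblocks <- hdr[1]
  tets <- NULL; region <- character(0)
  pos <- 2L
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(el[pos]), "\\s+")[[1]])
    etype <- bh[3]; nb <- bh[4]
    if (etype != 4L) {
      stop("mixed element types in MSH file (only 4-node tets supported): ",
           path)
    }
    rows <- do.call(rbind, lapply(
      strsplit(trimws(el[pos + seq_len(nb)]), "\\s+"), as.integer))
    conn <- matrix(tag_row[rows[, 2:5]], ncol = 4)
    tets <- rbind(tets, conn)
    rname <- if (!is.na(region_names[bh[2]])) region_names[bh[2]] else
      paste0("region", bh[2])
    region <- c(region, rep(rname, nb))
    pos <- pos + 1L + nb
  }
  node_sets <- list()
  nd <- sec("NodeData")
  if (!is.null(nd)) {
    set_names <- strsplit(gsub('"', "", nd[3]), ",")[[1]]
    nvals <- as.integer(nd[9])
    rows <- strsplit(trimws(nd[9 + seq_len(nvals)]), "\\s+")
    bits <- numeric(nrow(nodes))
    for (r in rows) {
      bits[tag_row[as.integer(r[1])]] <- as.numeric(r[2])
    }
    node_sets <- bitfield_to_node_sets(bits, set_names)
  }
  tet_mesh(nodes, tets, region, node_sets)
}
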