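## Mesh container and mesh I/O.
##
## A `pf_mesh` is a plain list: nodes (N x dim), elems (E x nen, 1-based),
## etype ("quad4" plane strain or "tet4"), region (integer tag per element),
## sets (named node-index sets), facets (named F x 3 triangle lists for
## surface loads, 3-D only), plus, after material assignment, `materials`
## (tag-keyed list) and per-element fibre matrices `fibM`, `fibMp`.

#' Construct a finite element mesh
#'
#' @param nodes Numeric matrix of node coordinates (mm), one row per node;
#'   2 columns for plane-strain quadrilaterals, 3 for tetrahedra.
#' @param elems Integer connectivity matrix, 1-based, one row per element
#'   (4 columns for both supported element types).
#' @param etype `"quad4"` (plane strain) or `"tet4"`.
#' @param region Integer region tag per element (layer id); default all 1.
#' @param sets Named list of node-index vectors (boundary/Dirichlet sets).
#' @param facets Named list of F x 3 node-index matrices describing oriented
#'   surface triangles (pressure surfaces), 3-D only.
#' @return An object of class `"pf_mesh"`.
#' @export
pf_mesh <- function(nodes, elems, etype = c("quad4", "tet4"),
                    region = NULL, sets = list(), facets = list()) {
  etype <- match.arg(etype)
  nodes <- as.matrix(nodes)
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  dim <- if (etype == "quad4") 2L else 3L
  stopifnot(ncol(nodes) == dim, ncol(elems) == 4L,
            max(elems) <= nrow(nodes), min(elems) >= 1L)
  if (is.null(region)) region <- rep(1L, nrow(elems))
  stopifnot(length(region) == nrow(elems))
  m <- structure(list(nodes = nodes, elems = elems, etype = etype, dim = dim,
                      region = as.integer(region), sets = sets,
                      facets = facets),
                 class = "pf_mesh")
  vol <- element_volumes(m)
  if (any(vol <= 0))
    stop("non-positive element Jacobian in element(s) ",
         paste(utils::head(which(vol <= 0), 5), collapse = ", "))
  m
}

#' @method print pf_mesh
#' @export
print.pf_mesh <- function(x, ...) {
  cat(sprintf("pf_mesh: %d nodes, %d %s elements, %d region(s)\n",
              nrow(x$nodes), nrow(x$elems), x$etype,
              length(unique(x$region))))
  if (length(x$sets)) cat("  node sets:", paste(names(x$sets), collapse = ", "), "\n")
  if (length(x$facets)) cat("  facet sets:", paste(names(x$facets), collapse = ", "), "\n")
  invisible(x)
}

#' Element volumes (areas for plane strain)
#'
#' @param mesh A [pf_mesh()].
#' @return Numeric vector, mm^3 (mm^2 for quadrilaterals).
#' @export
element_volumes <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  if (mesh$etype == "quad4") {
    x <- matrix(nd[el, 1], ncol = 4); y <- matrix(nd[el, 2], ncol = 4)
    0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
           (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
           (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
           (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
  } else {
    a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    c_ <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
    (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
     a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
     a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  }
}

#' Characteristic mesh size
#'
#' Minimum edge length over all elements, used for the resolution rule
#' `l > 2 h` of the diffusive crack zone.
#'
#' @param mesh A [pf_mesh()].
#' @return Minimum element edge length, mm.
#' @export
mesh_h <- function(mesh) {
  el <- mesh$elems; nd <- mesh$nodes
  pairs <- if (mesh$etype == "quad4")
    rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  else
    rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  h <- Inf
  for (k in seq_len(nrow(pairs))) {
    d <- nd[el[, pairs[k, 1]], , drop = FALSE] - nd[el[, pairs[k, 2]], , drop = FALSE]
    h <- min(h, sqrt(rowSums(d^2)))
  }
  h
}

#' Element centroids
#' @param mesh A [pf_mesh()].
#' @return E x dim matrix of centroids.
#' @export
element_centroids <- function(mesh) {
  out <- matrix(0, nrow(mesh$elems), mesh$dim)
  for (a in 1:4) out <- out + mesh$nodes[mesh$elems[, a], , drop = FALSE]
  out / 4
}

#' Assign layer materials and fibre frames to mesh regions
#'
#' Attaches one (`material_params`, `phase_field_params`) pair to every region
#' tag and builds per-element unit fibre vectors.  For cylindrical meshes
#' (attribute `frame_type == "cylindrical"`, as built by
#' [make_tube_segment()]) the two families lie at `+/- alpha` to the local
#' circumferential direction in each element's theta--z tangent plane; for
#' planar meshes a fixed [fiber_frame()] per region is used.
#'
#' @param mesh A [pf_mesh()].
#' @param table Named list keyed by region tag (as character); each entry a
#'   list with elements `material` ([material_params()]), `phase_field`
#'   ([phase_field_params()]), and either `frame` (a [fiber_frame()]) or
#'   nothing (cylindrical meshes derive the frame from `material$alpha`);
#'   optional `two_families = FALSE` keeps only the `+alpha` family.
#' @return The mesh with `materials`, `fibM`, `fibMp` attached.
#' @export
assign_layers <- function(mesh, table) {
  tags <- sort(unique(mesh$region))
  missing <- setdiff(as.character(tags), names(table))
  if (length(missing))
    stop("no material entry for region tag(s) ", paste(missing, collapse = ", "),
         "; table has: ", paste(names(table), collapse = ", "))
  E <- nrow(mesh$elems)
  fibM <- matrix(0, E, 3); fibMp <- matrix(0, E, 3)
  cyl <- identical(attr(mesh, "frame_type"), "cylindrical")
  cent <- element_centroids(mesh)
  for (tg in tags) {
    idx <- which(mesh$region == tg)
    entry <- table[[as.character(tg)]]
    two <- !isFALSE(entry$two_families)
    if (!is.null(entry$frame)) {
      fr <- entry$frame
      fibM[idx, ] <- matrix(fr$M, length(idx), 3, byrow = TRUE)
      if (!is.null(fr$Mp) && two)
        fibMp[idx, ] <- matrix(fr$Mp, length(idx), 3, byrow = TRUE)
    } else if (cyl) {
      a <- entry$material$alpha * pi / 180
      th <- atan2(cent[idx, 2], cent[idx, 1])
      et <- cbind(-sin(th), cos(th), 0)        # circumferential
      ez <- matrix(rep(c(0, 0, 1), each = length(idx)), ncol = 3)
      fibM[idx, ] <- cos(a) * et + sin(a) * ez
      if (two) fibMp[idx, ] <- cos(a) * et - sin(a) * ez
    } else {
      stop("region ", tg, ": no fibre frame given and mesh is not cylindrical")
    }
  }
  mesh$materials <- table
  mesh$fibM <- fibM
  mesh$fibMp <- fibMp
  mesh
}

## Flatten assigned materials into the matrices the compiled kernels take.
flatten_materials <- function(mesh) {
  if (is.null(mesh$materials))
    stop("mesh has no materials; call assign_layers() first")
  tags <- sort(unique(mesh$region))
  mats <- matrix(0, length(tags), 6,
                 dimnames = list(NULL, c("mu", "k1", "k2", "kappa", "a_iso", "a_ani")))
  pf_mats <- matrix(0, length(tags), 3,
                    dimnames = list(NULL, c("l", "omega_M", "omega_Mp")))
  gc_iso <- gc_ani <- eta <- numeric(length(tags))
  for (i in seq_along(tags)) {
    e <- mesh$materials[[as.character(tags[i])]]
    m <- e$material; pf <- e$phase_field
    mats[i, ] <- c(m$mu, m$k1, m$k2, m$kappa, pf$a_iso, pf$a_ani)
    pf_mats[i, ] <- c(pf$l, pf$omega_M, pf$omega_Mp)
    gc_iso[i] <- pf$gc_iso_over_l; gc_ani[i] <- pf$gc_ani_over_l
    eta[i] <- pf$eta
  }
  mat_row <- match(mesh$region, tags)
  list(mats = mats, pf_mats = pf_mats, mat_id0 = mat_row - 1L,
       gc_iso = gc_iso[mat_row], gc_ani = gc_ani[mat_row],
       eta = max(eta), tags = tags)
}

# ---------------------------------------------------------------------------
# Native JSON mesh and Gmsh MSH 4.1 exchange

#' Write / read the native JSON mesh format
#'
#' Lossless round trip of nodes, connectivity, region tags, node sets and
#' facet sets via JSON.
#'
#' @param mesh A [pf_mesh()].
#' @param path Output file.
#' @return `write_mesh_json` returns `path` invisibly; `read_mesh_json`
#'   returns the mesh.
#' @export
write_mesh_json <- function(mesh, path) {
  obj <- list(etype = mesh$etype,
              nodes = unclass(mesh$nodes),
              elems = unclass(mesh$elems),
              region = mesh$region,
              sets = mesh$sets,
              facets = mesh$facets)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pf_mesh(nodes = obj$nodes, elems = obj$elems, etype = obj$etype,
          region = obj$region,
          sets = lapply(obj$sets, as.integer),
          facets = lapply(obj$facets, function(f) {
            f <- as.matrix(f); storage.mode(f) <- "integer"; f
          }))
}

#' Write / read a Gmsh MSH 4.1 (ASCII) mesh
#'
#' Minimal MSH 4.1 support: one entity per region tag, nodes and elements.
#' Node sets and facet sets are not representable in plain MSH and are
#' dropped; use the JSON format for a lossless round trip.
#'
#' @param mesh A [pf_mesh()].
#' @param path File path.
#' @return `write_msh` returns `path` invisibly; `read_msh` returns a
#'   [pf_mesh()].
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dim <- mesh$dim
  etype_code <- if (mesh$etype == "quad4") 3L else 4L
  tags <- sort(unique(mesh$region))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$Entities")
  w("0 0 %d %d", if (dim == 2) length(tags) else 0L,
    if (dim == 3) length(tags) else 0L)
  for (tg in tags)
    w("%d 0 0 0 0 0 0 1 %d 0", tg, tg)
  w("$EndEntities")
  N <- nrow(mesh$nodes)
  w("$Nodes")
  w("1 %d 1 %d", N, N)
  w("%d %d 0 %d", dim, tags[1], N)
  writeLines(as.character(seq_len(N)), con)
  xyz <- cbind(mesh$nodes, matrix(0, N, 3 - dim))
  writeLines(paste(xyz[, 1], xyz[, 2], xyz[, 3]), con)
  w("$EndNodes")
  w("$Elements")
  E <- nrow(mesh$elems)
  w("%d %d 1 %d", length(tags), E, E)
  eid <- 0L
  for (tg in tags) {
    idx <- which(mesh$region == tg)
    w("%d %d %d %d", dim, tg, etype_code, length(idx))
    lines <- paste(eid + seq_along(idx),
                   apply(mesh$elems[idx, , drop = FALSE], 1, paste, collapse = " "))
    writeLines(lines, con)
    eid <- eid + length(idx)
  }
  w("$EndElements")
  invisible(path)
}

#' @rdname write_msh
#' @export
read_msh <- function(path) {
  txt <- readLines(path)
  fmt <- strsplit(txt[grep("^\\$MeshFormat$", txt) + 1L], " ")[[1]]
  if (!startsWith(fmt[1], "4"))
    stop("only MSH format 4.x is supported (file says ", fmt[1], ")")
  i <- grep("^\\$Nodes$", txt)
  hdr <- as.integer(strsplit(txt[i + 1L], " ")[[1]])
  nblocks <- hdr[1]; ntot <- hdr[2]
  pos <- i + 2L
  ids <- integer(0); coords <- NULL
  for (b in seq_len(nblocks)) {
    bh <- as.numeric(strsplit(txt[pos], " ")[[1]])
    nb <- bh[4]
    ids <- c(ids, as.integer(txt[pos + seq_len(nb)]))
    cc <- do.call(rbind, lapply(txt[pos + nb + seq_len(nb)],
                                function(s) as.numeric(strsplit(trimws(s), " +")[[1]])))
    coords <- rbind(coords, cc[, 1:3, drop = FALSE])
    pos <- pos + 2L * nb + 1L
  }
  ord <- order(ids)
  coords <- coords[ord, , drop = FALSE]
  remap <- integer(max(ids)); remap[ids[ord]] <- seq_along(ids)
  i <- grep("^\\$Elements$", txt)
  hdr <- as.integer(strsplit(txt[i + 1L], " ")[[1]])
  nblocks <- hdr[1]
  pos <- i + 2L
  elems <- NULL; region <- integer(0); etype <- NULL
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(txt[pos], " ")[[1]])
    tag <- bh[2]; code <- bh[3]; nb <- bh[4]
    rows <- do.call(rbind, lapply(txt[pos + seq_len(nb)],
                                  function(s) as.integer(strsplit(trimws(s), " +")[[1]])))
    if (code %in% c(3L, 4L)) {
      etype <- if (code == 3L) "quad4" else "tet4"
      conn <- matrix(remap[rows[, -1, drop = FALSE]], ncol = 4)
      elems <- rbind(elems, conn)
      region <- c(region, rep(tag, nb))
    }
    pos <- pos + nb + 1L
  }
  dim <- if (etype == "quad4") 2L else 3L
  pf_mesh(nodes = coords[, seq_len(dim), drop = FALSE], elems = elems,
          etype = etype, region = region)
}
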