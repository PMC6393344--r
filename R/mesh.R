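# VTK hexahedron corner ordering: voxel-corner offsets (di, dj, dk).
hex_corner_offsets <- matrix(c(
  0L, 0L, 0L,
  1L, 0L, 0L,
  1L, 1L, 0L,
  0L, 1L, 0L,
  0L, 0L, 1L,
  1L, 0L, 1L,
  1L, 1L, 1L,
  0L, 1L, 1L), ncol = 3, byrow = TRUE)

#' Build an 8-node hexahedral mesh from the solid voxels
#'
#' One cuboid element per solid voxel; nodes shared between adjacent voxels
#' are referenced by the same index (no duplication). Air voxels are not
#' meshed: they carry zero stiffness in the binary material mapping.
#' Element ordering is the lexicographic (column-major) voxel order; node
#' corner ordering follows the VTK hexahedron convention.
#'
#' @param seg a [SegmentedVolume-class].
#' @return a [HexMesh-class].
#' @export
buildMesh <- function(seg) {
  assert_two_phase(seg)
  g <- voxelData(seg)
  vs <- voxelSize(seg)
  d <- dim(g)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  idx <- which(as.vector(g) == 255L)
  if (!length(idx)) stop("empty solid phase: nothing to mesh", call. = FALSE)
  i0 <- (idx - 1L) %% nx
  j0 <- ((idx - 1L) %/% nx) %% ny
  k0 <- (idx - 1L) %/% (nx * ny)
  gx <- nx + 1L; gy <- ny + 1L
  gid <- matrix(0L, length(idx), 8L)
  for (a in seq_len(8L)) {
    o <- hex_corner_offsets[a, ]
    gid[, a] <- (i0 + o[1]) + gx * ((j0 + o[2]) + gy * (k0 + o[3]))
  }
  used <- sort(unique(as.vector(gid)))
  lookup <- integer(gx * gy * (nz + 1L))
  lookup[used + 1L] <- seq_along(used)
  elems <- matrix(lookup[gid + 1L], ncol = 8L)
  ui <- used %% gx
  uj <- (used %/% gx) %% gy
  uk <- used %/% (gx * gy)
  nodes <- cbind(x = ui, y = uj, z = uk) * vs
  new("HexMesh", nodes = nodes, elems = elems,
      voxelIndex = as.integer(idx), dims = as.integer(d), voxelSize = vs)
}

#' Attach elastic material properties to a mesh
#'
#' Binary gray-level mapping: solid voxels (gray 255) receive the solid
#' constants (E0, nu0); air voxels (gray 0) are not meshed and contribute
#' zero stiffness. Damaged elements are later reassigned the ground-level
#' stiffness `groundFactor * E0` by [applyDamage()] while keeping nu0.
#'
#' @param mesh a [HexMesh-class].
#' @param gray the two-valued [VoxelVolume-class] the mesh came from.
#' @param E0 solid Young's modulus, MPa.
#' @param nu0 solid Poisson ratio, in (0, 0.5).
#' @param groundFactor stiffness knock-down factor for damaged elements.
#' @return a [MaterialField-class].
#' @export
assignMaterials <- function(mesh, gray, E0 = 20000, nu0 = 0.3,
                            groundFactor = 1e-6) {
  assert_two_phase(gray, "gray volume")
  gv <- voxelData(gray)[mesh@voxelIndex]
  if (!all(gv == 255L))
    stop("mesh elements must map to solid (gray 255) voxels", call. = FALSE)
  m <- nrow(mesh@elems)
  new("MaterialField", E = rep(E0, m), nu0 = nu0, E0 = E0,
      groundFactor = groundFactor, damaged = rep(FALSE, m))
}

#' Face-connected components of the mesh elements
#'
#' Elements sharing only an edge or a corner are connected for meshing (they
#' share nodes) but are treated as separate for load-path analysis, where
#' face connectivity is required. Components not attached to both loading
#' ends carry no load; they are retained in the mesh but flagged.
#'
#' @param mesh a [HexMesh-class].
#' @param subset optional logical per-element mask restricting the analysis
#'   (e.g. the intact elements during a damage run).
#' @return list with `labels` (integer per element, 0 for elements outside
#'   `subset`) and `report` (data.frame: component, size, spansEnds).
#' @export
meshComponents <- function(mesh, subset = NULL) {
  d <- mesh@dims
  m <- nrow(mesh@elems)
  if (is.null(subset)) subset <- rep(TRUE, m)
  mask <- logical(prod(d))
  mask[mesh@voxelIndex[subset]] <- TRUE
  lab <- cpp_label3d(mask, d)
  labElem <- integer(m)
  labElem[subset] <- lab[mesh@voxelIndex[subset]]
  ncomp <- max(labElem, 0L)
  if (ncomp == 0L)
    return(list(labels = labElem,
                report = data.frame(component = integer(), size = integer(),
                                    spansEnds = logical())))
  nx <- d[1]
  i1 <- ((mesh@voxelIndex - 1L) %% nx) + 1L
  # loading ends are those of the whole mesh, not of the subset: a subset
  # that has retreated from an end face no longer spans
  imin <- min(i1); imax <- max(i1)
  size <- tabulate(labElem, nbins = ncomp)
  spans <- vapply(seq_len(ncomp), function(cc) {
    ic <- i1[labElem == cc]
    any(ic == imin) && any(ic == imax)
  }, logical(1))
  list(labels = labElem,
       report = data.frame(component = seq_len(ncomp), size = size,
                           spansEnds = spans))
}
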