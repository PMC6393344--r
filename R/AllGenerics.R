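#' Accessors for fibrekin S4 classes
#'
#' `voxelData()` returns the raw 3D gray array, `voxelSize()` the voxel edge
#' length in micrometers, `nElements()`/`nNodes()` the mesh sizes,
#' `historyTable()` the per-increment record of a damage run, and
#' `damageRatio()` the cumulative damage-ratio vector.
#'
#' @param x an object of the appropriate class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("historyTable", function(x) standardGeneric("historyTable"))

#' @rdname accessors
#' @export
setGeneric("damageRatio", function(x) standardGeneric("damageRatio"))

#' @rdname accessors
#' @export
setMethod("voxelData", "VoxelVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSize", "VoxelVolume", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "HexMesh", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("nElements", "HexMesh", function(x) nrow(x@elems))

#' @rdname accessors
#' @export
setMethod("nNodes", "HexMesh", function(x) nrow(x@nodes))

#' @rdname accessors
#' @export
setMethod("historyTable", "DamageHistory", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("damageRatio", "DamageHistory", function(x) x@table$ratio)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(class(object), sprintf("%d x %d x %d voxels", d[1], d[2], d[3]),
      sprintf("(%.3g um/voxel)", object@voxelSize), "\n")
  cat("  physical volume:",
      format(prod(d) * object@voxelSize^3, digits = 4), "um^3\n")
  vals <- unique(as.vector(object@data))
  if (length(vals) <= 4) cat("  gray values:", sort(vals), "\n")
  else cat("  gray range:", paste(range(vals), collapse = " - "), "\n")
})

setMethod("show", "FiberSpec", function(object) {
  cat("FiberSpec: d =", object@diameter, "um, shape factor",
      object@shapeFactor, ", L =", object@length, "um\n")
  if (object@lumen)
    cat("  lumen: area fraction", object@lumenFraction, ", aspect",
        object@lumenAspect, "\n")
  else cat("  no lumen\n")
  cat("  roughness RMS", object@roughnessAmplitude, "um, voxel size",
      object@voxelSize, "um\n")
})

setMethod("show", "NotchGeometry", function(object) {
  cat(sprintf("%s-notch: w = %g um, h = %g um (theta = %.1f deg)\n",
              object@type, object@width, object@depth,
              notchAngle(object@width, object@depth)))
})

setMethod("show", "HexMesh", function(object) {
  cat("HexMesh:", nrow(object@elems), "hexahedral elements,",
      nrow(object@nodes), "nodes",
      sprintf("(%d dof)\n", 3L * nrow(object@nodes)))
})

setMethod("show", "MaterialField", function(object) {
  cat("MaterialField: E0 =", object@E0, "MPa, nu0 =", object@nu0,
      sprintf("; %d/%d elements damaged (ground %g)\n",
              sum(object@damaged), length(object@damaged),
              object@groundFactor))
})

setMethod("show", "DamageHistory", function(object) {
  n <- nrow(object@table)
  cat("DamageHistory:", object@criterion, "criterion,", n, "increments\n")
  if (n) cat(sprintf("  final damage ratio %.4f (%d / %d elements)\n",
                     object@table$ratio[n], object@table$nDamaged[n],
                     object@nDamageable))
})

setMethod("show", "StageBoundaries", function(object) {
  cat(sprintf("Stages: onset %s, growth [%s, %s], saturation %s\n",
              object@onset, object@growth[1], object@growth[2],
              object@saturation))
})

setMethod("show", "LumenStats", function(object) {
  cat("LumenStats over", nrow(object@perSlice), "slices (",
      object@skippedSlices, "skipped )\n")
  s <- object@summary
  cat(sprintf("  area  mean %.3g / median %.3g um^2\n", s$meanArea,
              s$medianArea))
  cat(sprintf("  aspect mean %.3g / median %.3g\n", s$meanAspect,
              s$medianAspect))
  if (!is.na(object@porosity))
    cat(sprintf("  porosity %.3f\n", object@porosity))
})
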