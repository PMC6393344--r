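#' @import methods
NULL

#' VoxelVolume: a 3D gray-level image with isotropic voxel size
#'
#' The central image container of the package. The first array dimension is
#' the fiber longitudinal axis X, which is also the loading axis of the
#' tensile simulation; Y and Z are the transverse axes. Gray values are
#' integers in \[0, 255\]. Physical edge length of a voxel is `voxelSize`
#' micrometers, so the physical volume of the image is
#' `prod(dim(x)) * voxelSize^3`.
#'
#' @slot data 3D integer array of gray values in \[0, 255\].
#' @slot voxelSize isotropic voxel edge length in micrometers.
#'
#' @seealso [VoxelVolume()], [SegmentedVolume-class]
#' @export
setClass("VoxelVolume",
  representation(data = "array", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0)
      msg <- c(msg, "voxelSize must be a single positive number")
    rng <- suppressWarnings(range(object@data))
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
      msg <- c(msg, "gray values must lie in [0, 255]")
    if (length(msg)) msg else TRUE
  }
)

#' SegmentedVolume: a two-phase (air/solid) voxel volume
#'
#' A [VoxelVolume-class] whose gray values are restricted to the two phase
#' labels 0 (air) and 255 (solid). Produced by [segmentVolume()]; consumed by
#' the morphometric and meshing stages.
#'
#' @seealso [segmentVolume()], [buildMesh()]
#' @export
setClass("SegmentedVolume", contains = "VoxelVolume",
  validity = function(object) {
    vals <- unique(as.vector(object@data))
    if (!all(vals %in% c(0, 255)))
      "segmented volumes may only contain gray values 0 (air) and 255 (solid)"
    else TRUE
  }
)

#' FiberSpec: geometric description of a synthetic bast fiber
#'
#' Parameters of the synthetic tomogram generator. The solid cross-section
#' is an ellipse of area-equivalent diameter `diameter` whose major/minor
#' semi-axis ratio is `shapeFactor`; an optional lumen (the tubular cell
#' cavity) spans the full fiber length with cross-section area
#' `lumenFraction` times the solid envelope area and its own elliptical
#' aspect ratio.
#'
#' @slot diameter area-equivalent fiber diameter, micrometers.
#' @slot shapeFactor major/minor semi-axis ratio of the solid cross-section
#'   (>= 1).
#' @slot length fiber length along X, micrometers.
#' @slot lumen logical; is a lumen present?
#' @slot lumenFraction lumen area fraction of the cross-section, in
#'   \[0, 0.2\].
#' @slot lumenAspect major/minor ratio of the lumen ellipse (>= 1).
#' @slot lumenWaviness relative axial modulation of the lumen cross-section
#'   (log-scale standard deviation; 0 = constant tube). Real lumina vary
#'   strongly along the fiber (mean area far above median area), and the
#'   modulation is what lets the tubular cavity concentrate axial stress.
#' @slot roughnessAmplitude RMS radial surface-roughness amplitude,
#'   micrometers (0 = smooth).
#' @slot roughnessCorrelation axial correlation length of the roughness
#'   field, micrometers.
#' @slot voxelSize voxel edge length, micrometers.
#' @slot grayAir,graySolid the two gray levels of the generated two-phase
#'   volume.
#'
#' @seealso [fiberSpec()], [generateFiber()], [fiberPreset()]
#' @export
setClass("FiberSpec",
  representation(diameter = "numeric", shapeFactor = "numeric",
                 length = "numeric", lumen = "logical",
                 lumenFraction = "numeric", lumenAspect = "numeric",
                 lumenWaviness = "numeric",
                 roughnessAmplitude = "numeric",
                 roughnessCorrelation = "numeric", voxelSize = "numeric",
                 grayAir = "numeric", graySolid = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@diameter <= 0) msg <- c(msg, "diameter must be positive")
    if (object@shapeFactor < 1) msg <- c(msg, "shapeFactor must be >= 1")
    if (object@length <= 0) msg <- c(msg, "length must be positive")
    if (object@lumenFraction < 0 || object@lumenFraction > 0.2)
      msg <- c(msg, "lumenFraction must lie in [0, 0.2]")
    if (object@lumenAspect < 1) msg <- c(msg, "lumenAspect must be >= 1")
    if (object@lumenWaviness < 0) msg <- c(msg, "lumenWaviness must be >= 0")
    if (object@roughnessAmplitude < 0)
      msg <- c(msg, "roughnessAmplitude must be >= 0")
    if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
    if (object@grayAir == object@graySolid)
      msg <- c(msg, "air and solid gray levels must differ")
    if (length(msg)) msg else TRUE
  }
)

#' NotchGeometry: a machined V- or U-notch
#'
#' A V-notch removes a triangular prism (surface opening `width`, depth
#' `depth`); a U-notch removes a semi-elliptical prism with semi-axes
#' `width/2` (axial) and `depth` (radial). The opening angle follows
#' tan(theta/2) = w / (2 h); see [notchAngle()].
#'
#' @slot type `"V"` or `"U"`.
#' @slot width notch opening w along the fiber axis, micrometers.
#' @slot depth notch depth h into the fiber, micrometers.
#' @slot axialPosition offset of the notch center from fiber mid-length,
#'   micrometers.
#' @slot azimuth azimuthal position of the notch around the fiber axis,
#'   degrees (0 = +Y direction).
#'
#' @seealso [notchGeometry()], [carveNotch()]
#' @export
setClass("NotchGeometry",
  representation(type = "character", width = "numeric", depth = "numeric",
                 axialPosition = "numeric", azimuth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@type %in% c("V", "U")) msg <- c(msg, "type must be 'V' or 'U'")
    if (!is.finite(object@width) || object@width <= 0)
      msg <- c(msg, "notch width must be positive")
    if (!is.finite(object@depth) || object@depth <= 0)
      msg <- c(msg, "notch depth must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' LumenStats: per-slice lumen ellipse statistics
#'
#' Result of [sliceEllipseStats()]: per transverse slice, the lumen
#' cross-section area and the aspect ratio of a moment-fitted ellipse, plus
#' summary statistics and the global porosity of the volume the labels were
#' extracted from.
#'
#' @slot perSlice data.frame with columns `slice`, `area` (square
#'   micrometers) and `aspect`.
#' @slot summary named list: mean/median area, mean/median aspect.
#' @slot porosity internal air fraction of the fiber, in \[0, 1\] (NA when
#'   not supplied).
#' @slot skippedSlices number of slices with fewer than 5 lumen voxels.
#' @export
setClass("LumenStats",
  representation(perSlice = "data.frame", summary = "list",
                 porosity = "numeric", skippedSlices = "integer"))

#' HexMesh: 8-node cuboid element mesh built from solid voxels
#'
#' One trilinear hexahedral element per solid voxel; nodes on shared faces
#' are shared (no duplication). Element ordering follows the lexicographic
#' (column-major) order of the source voxels; node corner ordering follows
#' the VTK hexahedron convention.
#'
#' @slot nodes numeric n x 3 matrix of node coordinates, micrometers.
#' @slot elems integer m x 8 connectivity (1-based node indices).
#' @slot voxelIndex integer m vector: linear index of each element's source
#'   voxel in the original array.
#' @slot dims integer dimensions (nx, ny, nz) of the source volume.
#' @slot voxelSize voxel edge length, micrometers.
#' @seealso [buildMesh()], [assignMaterials()]
#' @export
setClass("HexMesh",
  representation(nodes = "matrix", elems = "matrix", voxelIndex = "integer",
                 dims = "integer", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be n x 3")
    if (ncol(object@elems) != 8L) msg <- c(msg, "elems must be m x 8")
    if (nrow(object@elems) != length(object@voxelIndex))
      msg <- c(msg, "voxelIndex length must equal element count")
    if (length(msg)) msg else TRUE
  }
)

#' MaterialField: per-element elastic properties
#'
#' Binary material mapping: every meshed (solid) element carries the solid
#' Young's modulus `E0` and Poisson ratio `nu0` until it is damaged, after
#' which its modulus is the ground level `groundFactor * E0` (the element
#' stays in the mesh so the system matrix remains well posed). Air voxels
#' are never meshed, which realizes the zero-stiffness branch of the binary
#' gray-level mapping.
#'
#' @slot E numeric per-element Young's modulus, MPa.
#' @slot nu0 Poisson ratio of the solid phase (shared by all elements).
#' @slot E0 solid-phase Young's modulus, MPa.
#' @slot groundFactor stiffness knock-down factor applied to damaged
#'   elements (default 1e-6).
#' @slot damaged logical per-element damage state.
#' @seealso [assignMaterials()], [applyDamage()]
#' @export
setClass("MaterialField",
  representation(E = "numeric", nu0 = "numeric", E0 = "numeric",
                 groundFactor = "numeric", damaged = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@E) != length(object@damaged))
      msg <- c(msg, "E and damaged must have the same length")
    if (object@nu0 <= 0 || object@nu0 >= 0.5)
      msg <- c(msg, "nu0 must lie in (0, 0.5)")
    if (object@E0 <= 0) msg <- c(msg, "E0 must be positive")
    if (object@groundFactor <= 0 || object@groundFactor >= 1)
      msg <- c(msg, "groundFactor must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' DamageHistory: record of an iterative damage simulation
#'
#' One row per load increment: applied end displacement, reaction force,
#' cumulative damage ratio (damaged elements over all damageable elements),
#' and the maximum criterion value over intact elements. The identities of
#' newly damaged elements are kept per increment.
#'
#' @slot table data.frame with columns `increment`, `U` (micrometers), `F`
#'   (micronewtons), `ratio`, `maxCriterion` (MPa), `nNew`, `nDamaged`,
#'   `iterations`.
#' @slot newlyDamaged list of integer vectors (element ids per increment).
#' @slot criterion the damage criterion name.
#' @slot nDamageable total number of damageable elements.
#' @slot schedule the loading schedule used.
#' @seealso [runDamageSimulation()], [detectStages()]
#' @export
setClass("DamageHistory",
  representation(table = "data.frame", newlyDamaged = "list",
                 criterion = "character", nDamageable = "integer",
                 schedule = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@table) != length(object@newlyDamaged))
      msg <- c(msg, "one newlyDamaged entry per increment required")
    r <- object@table$ratio
    if (length(r) && (any(r < 0 | r > 1) || any(diff(r) < 0)))
      msg <- c(msg, "damage ratio must be non-decreasing in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' StageBoundaries: three-stage damage-kinetics decomposition
#'
#' Onset, growth and saturation stages of a damage-ratio curve. `onset` is
#' the first increment where the ratio exceeds `onsetThreshold` times the
#' final ratio; `saturation` the first increment where it reaches
#' `saturationThreshold` times the final ratio; growth is the interval in
#' between. All-zero curves yield NA boundaries (no onset).
#'
#' @slot onset,saturation increment indices (NA when undefined).
#' @slot growth integer pair (start, end) of the growth interval.
#' @slot onsetThreshold,saturationThreshold fractions of the final ratio.
#' @seealso [detectStages()]
#' @export
setClass("StageBoundaries",
  representation(onset = "integer", saturation = "integer",
                 growth = "integer", onsetThreshold = "numeric",
                 saturationThreshold = "numeric"))
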