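# Labels of the air components forming the exterior. mode "faces" seeds the
# flood from the four LATERAL boundary faces (robust when the fiber touches
# the volume edge); the two X end faces are never seeds, because the fiber
# is cut there and an open-ended tubular lumen would otherwise be flooded
# as exterior. mode "corners" is the strict corner-seeded variant.
boundary_labels <- function(lab, mode = c("faces", "corners")) {
  mode <- match.arg(mode)
  d <- dim(lab)
  if (mode == "corners") {
    ii <- c(1L, d[1]); jj <- c(1L, d[2]); kk <- c(1L, d[3])
    vals <- lab[as.matrix(expand.grid(ii, jj, kk))]
  } else {
    vals <- c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]])
  }
  setdiff(unique(vals), 0L)
}

#' Segment a gray-level volume into air and solid phases
#'
#' Gray-level thresholding followed by morphological opening (speckle
#' removal) and closing (pinhole filling) with a Euclidean ball structuring
#' element. When `threshold` is omitted, Otsu's method picks it from the
#' gray histogram.
#'
#' @param volume a [VoxelVolume-class].
#' @param threshold optional gray threshold in (0, 255); voxels strictly
#'   above it become solid.
#' @param openingRadius structuring-element radius in voxels for the
#'   morphological opening and closing (0 disables both).
#' @return a [SegmentedVolume-class] with gray levels 0 (air) and 255
#'   (solid).
#' @export
segmentVolume <- function(volume, threshold = NULL, openingRadius = 1) {
  g <- voxelData(volume)
  if (is.null(threshold)) {
    if (length(unique(as.vector(g))) < 2L)
      stop("constant volume: supply an explicit threshold", call. = FALSE)
    threshold <- 255 * EBImage::otsu(
      EBImage::Image(as.numeric(g) / 255, dim = c(length(g), 1L)),
      range = c(0, 1), levels = 256)
  }
  d <- dim(g)
  mask <- as.vector(g > threshold)
  if (openingRadius > 0) {
    off <- ball_offsets(openingRadius)
    mask <- cpp_morph3d(mask, d, off, FALSE)  # erode
    mask <- cpp_morph3d(mask, d, off, TRUE)   # dilate: opening done
    mask <- cpp_morph3d(mask, d, off, TRUE)   # dilate
    mask <- cpp_morph3d(mask, d, off, FALSE)  # erode: closing done
  }
  SegmentedVolume(array(ifelse(mask, 255L, 0L), dim = d),
                  voxelSize(volume))
}

#' Extract and label the lumen (internal cavities)
#'
#' Floods the exterior air from the volume boundary and labels the
#' remaining air in 3D with 6-connectivity; each label is one internal
#' cavity. For a bast fiber the dominant cavity is the tubular lumen
#' spanning the fiber length.
#'
#' @param seg a [SegmentedVolume-class].
#' @param mode `"faces"` seeds the exterior flood from all six boundary
#'   faces (default, robust to fibers touching the edge); `"corners"` is
#'   the strict corner-seeded variant.
#' @return integer array of the input dimensions: 0 outside the lumen,
#'   1..k for the k internal cavities (largest first).
#' @export
extractLumen <- function(seg, mode = c("faces", "corners")) {
  mode <- match.arg(mode)
  assert_two_phase(seg)
  d <- dim(voxelData(seg))
  air <- !solid_mask(seg)
  lab <- array(cpp_label3d(as.vector(air), d), dim = d)
  ext <- boundary_labels(lab, mode)
  lab[lab %in% ext] <- 0L
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids)) {
    sizes <- tabulate(lab, nbins = max(ids))[ids]
    remap <- integer(max(ids))
    remap[ids[order(sizes, decreasing = TRUE)]] <- seq_along(ids)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Porosity of a segmented fiber
#'
#' Internal air voxels divided by internal air plus solid voxels. Exterior
#' air is excluded: the porosity is a property of the fiber, not the field
#' of view.
#'
#' @param seg a [SegmentedVolume-class].
#' @param lumenLabels label array from [extractLumen()]; computed when
#'   omitted.
#' @return porosity fraction in \[0, 1\].
#' @export
porosityFraction <- function(seg, lumenLabels = NULL) {
  assert_two_phase(seg)
  if (is.null(lumenLabels)) lumenLabels <- extractLumen(seg)
  ns <- sum(solid_mask(seg))
  if (ns == 0L) stop("porosity undefined: no solid voxels", call. = FALSE)
  nl <- sum(lumenLabels > 0L)
  nl / (nl + ns)
}

# Moment-based ellipse fit of a set of voxel centers in a slice; returns
# semi-axes in voxel units. The vs^2/12 term is the second moment of the
# unit voxel footprint, which debiases small rasterized shapes.
fit_ellipse_moments <- function(jj, kk) {
  n <- length(jj)
  cy <- mean(jj); cz <- mean(kk)
  syy <- mean((jj - cy)^2) + 1 / 12
  szz <- mean((kk - cz)^2) + 1 / 12
  syz <- mean((jj - cy) * (kk - cz))
  tr <- syy + szz
  det <- syy * szz - syz^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  c(major = 2 * sqrt(l1), minor = 2 * sqrt(l2))
}

#' Per-slice lumen ellipse statistics
#'
#' For every transverse slice, fits an ellipse to the pooled lumen voxels
#' by second-order moments. The cross-section area comes from the voxel
#' count times the voxel footprint; the aspect ratio is the fitted
#' major/minor semi-axis ratio. Slices with fewer than `minVoxels` lumen
#' voxels are skipped and counted.
#'
#' @param lumenLabels label array from [extractLumen()].
#' @param voxelSize voxel edge length, micrometers.
#' @param minVoxels minimum lumen voxels per slice (default 5).
#' @param porosity optional porosity fraction to carry in the result.
#' @return a [LumenStats-class].
#' @export
sliceEllipseStats <- function(lumenLabels, voxelSize, minVoxels = 5,
                              porosity = NA_real_) {
  d <- dim(lumenLabels)
  if (sum(lumenLabels > 0L) == 0L)
    stop("no lumen voxels present", call. = FALSE)
  rows <- vector("list", d[1])
  skipped <- 0L
  jj_all <- rep(seq_len(d[2]), d[3])
  kk_all <- rep(seq_len(d[3]), each = d[2])
  for (i in seq_len(d[1])) {
    w <- which(lumenLabels[i, , ] > 0L)
    if (!length(w)) next
    if (length(w) < minVoxels) { skipped <- skipped + 1L; next }
    ax <- fit_ellipse_moments(jj_all[w], kk_all[w])
    rows[[i]] <- data.frame(slice = i,
                            area = length(w) * voxelSize^2,
                            aspect = ax[["major"]] / ax[["minor"]])
  }
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per)) per <- data.frame(slice = integer(), area = numeric(),
                                      aspect = numeric())
  new("LumenStats", perSlice = per,
      summary = list(meanArea = mean(per$area),
                     medianArea = stats::median(per$area),
                     meanAspect = mean(per$aspect),
                     medianAspect = stats::median(per$aspect)),
      porosity = porosity, skippedSlices = skipped)
}

#' Global descriptors of a segmented fiber
#'
#' Per-slice moment ellipse fit of the solid cross-section, averaged along
#' the axis: area-equivalent diameter, transverse shape factor (mean
#' major/minor ratio) and axial length of the solid phase.
#'
#' @param seg a [SegmentedVolume-class].
#' @return named list: `diameter` (um), `shapeFactor`, `length` (um),
#'   `slices` (number of non-empty slices used).
#' @export
fiberDescriptors <- function(seg) {
  assert_two_phase(seg)
  vs <- voxelSize(seg)
  solid <- solid_mask(seg)
  d <- dim(solid)
  jj_all <- rep(seq_len(d[2]), d[3])
  kk_all <- rep(seq_len(d[3]), each = d[2])
  diam <- asp <- numeric(0)
  occ <- integer(0)
  for (i in seq_len(d[1])) {
    w <- which(solid[i, , ])
    if (length(w) < 3L) next
    occ <- c(occ, i)
    ax <- fit_ellipse_moments(jj_all[w], kk_all[w])
    diam <- c(diam, 2 * sqrt(length(w) * vs^2 / pi))
    asp <- c(asp, ax[["major"]] / ax[["minor"]])
  }
  if (!length(occ)) stop("no solid phase present", call. = FALSE)
  list(diameter = mean(diam), shapeFactor = mean(asp),
       length = (max(occ) - min(occ) + 1L) * vs, slices = length(occ))
}
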