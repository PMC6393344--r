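#' Construct a VoxelVolume
#'
#' @param data 3D numeric/integer array of gray values in \[0, 255\]. The
#'   first dimension is the fiber longitudinal (loading) axis X.
#' @param voxelSize isotropic voxel edge length, micrometers.
#' @return a [VoxelVolume-class] object.
#' @export
VoxelVolume <- function(data, voxelSize) {
  storage.mode(data) <- "integer"
  new("VoxelVolume", data = data, voxelSize = as.numeric(voxelSize))
}

#' Construct a SegmentedVolume
#'
#' @inheritParams VoxelVolume
#' @return a [SegmentedVolume-class]; `data` may only contain 0 and 255.
#' @export
SegmentedVolume <- function(data, voxelSize) {
  storage.mode(data) <- "integer"
  new("SegmentedVolume", data = data, voxelSize = as.numeric(voxelSize))
}

#' Opening angle of a notch
#'
#' The opening angle theta of a notch of surface opening `w` and depth `h`
#' satisfies tan(theta / 2) = w / (2 h).
#'
#' @param w notch opening, micrometers.
#' @param h notch depth, micrometers.
#' @return opening angle in degrees, in (0, 180).
#' @examples
#' notchAngle(40, 15)  # the V-notched bundle geometry, ~106.3 degrees
#' notchAngle(2, 1)    # equal opening and twice-depth: 90 degrees
#' @export
notchAngle <- function(w, h) {
  if (any(!is.finite(w)) || any(!is.finite(h)) || any(w <= 0) || any(h <= 0))
    stop("invalid notch geometry: w and h must be positive", call. = FALSE)
  2 * atan(w / (2 * h)) * 180 / pi
}

#' Specify a synthetic fiber
#'
#' Builds a [FiberSpec-class] after validation. Warnings (not errors) are
#' raised when the geometry falls outside the ranges typical of imaged hemp
#' fibers: diameters 13-224 um and lumen porosities up to ~10%.
#'
#' @param diameter area-equivalent fiber diameter, micrometers.
#' @param shapeFactor major/minor semi-axis ratio of the elliptical solid
#'   cross-section (>= 1).
#' @param length fiber length along the loading axis, micrometers.
#' @param lumen logical, include a tubular lumen cavity.
#' @param lumenFraction lumen area fraction of the cross-section in
#'   \[0, 0.2\].
#' @param lumenAspect major/minor ratio of the lumen ellipse.
#' @param lumenWaviness log-scale standard deviation of the axial
#'   modulation of the lumen cross-section (0 = constant tube). Imaged
#'   lumina vary strongly along the fiber -- their mean cross-section area
#'   sits far above the median -- and the local widenings are what make
#'   the axially aligned cavity act as a stress concentrator.
#' @param roughnessAmplitude RMS radial roughness amplitude, micrometers.
#' @param roughnessCorrelation axial correlation length of the roughness,
#'   micrometers.
#' @param voxelSize voxel edge length, micrometers (default 0.28, the
#'   resolution of the synchrotron tomograms this generator emulates).
#' @param grayAir,graySolid gray levels of the two phases.
#' @return a [FiberSpec-class].
#' @export
fiberSpec <- function(diameter, shapeFactor = 1, length = 4 * diameter,
                      lumen = FALSE, lumenFraction = 0, lumenAspect = 2,
                      lumenWaviness = 0.25, roughnessAmplitude = 0,
                      roughnessCorrelation = diameter,
                      voxelSize = 0.28, grayAir = 0, graySolid = 255) {
  if (diameter < 13 || diameter > 224)
    warning("diameter ", diameter,
            " um is outside the 13-224 um range of imaged hemp fibers")
  if (lumen && (lumenFraction <= 0))
    stop("lumen = TRUE requires a positive lumenFraction", call. = FALSE)
  if (!lumen) lumenFraction <- 0
  new("FiberSpec", diameter = diameter, shapeFactor = shapeFactor,
      length = length, lumen = lumen, lumenFraction = lumenFraction,
      lumenAspect = lumenAspect, lumenWaviness = lumenWaviness,
      roughnessAmplitude = roughnessAmplitude,
      roughnessCorrelation = roughnessCorrelation, voxelSize = voxelSize,
      grayAir = grayAir, graySolid = graySolid)
}

#' Specify a notch
#'
#' @param type `"V"` (triangular prism) or `"U"` (semi-elliptical prism).
#' @param width notch opening w along the fiber axis, micrometers.
#' @param depth notch depth h, micrometers.
#' @param axialPosition notch center offset from mid-length, micrometers.
#' @param azimuth azimuth of the notched side, degrees.
#' @param diameter optional fiber diameter; when given, warnings are issued
#'   outside the machined ranges w in \[4, 108\] um and h/d in \[0.1, 0.6\].
#' @return a [NotchGeometry-class].
#' @export
notchGeometry <- function(type = c("V", "U"), width, depth,
                          axialPosition = 0, azimuth = 0, diameter = NULL) {
  type <- match.arg(type)
  if (!is.finite(width) || width <= 0 || !is.finite(depth) || depth <= 0)
    stop("invalid notch geometry: width and depth must be positive",
         call. = FALSE)
  if (width < 4 || width > 108)
    warning("notch width ", width, " um is outside the machined 4-108 um range")
  if (!is.null(diameter)) {
    hd <- depth / diameter
    if (hd < 0.1 || hd > 0.6)
      warning("relative notch depth h/d = ", signif(hd, 3),
              " is outside the machined (0.1, 0.6) range")
  }
  new("NotchGeometry", type = type, width = width, depth = depth,
      axialPosition = axialPosition, azimuth = azimuth)
}

# Per-slice transverse coordinates (in um, relative to the volume center)
# for every voxel of a (ny, nz) slice.
slice_coords <- function(ny, nz, voxelSize) {
  cy <- (ny + 1) / 2
  cz <- (nz + 1) / 2
  list(dy = (rep(seq_len(ny), nz) - cy) * voxelSize,
       dz = (rep(seq_len(nz), each = ny) - cz) * voxelSize)
}

#' Generate a synthetic fiber tomogram
#'
#' Rasterizes a two-phase fiber volume: an elliptical solid cross-section
#' of the requested equivalent diameter and shape factor, extruded along X,
#' with an optional elliptical lumen spanning the full length (the tubular
#' porosity characteristic of bast fibers) and optional correlated surface
#' roughness. Output is exactly two-valued.
#'
#' @param spec a [FiberSpec-class].
#' @param seed integer seed for the roughness field (required even for
#'   smooth fibers, for reproducibility bookkeeping).
#' @param dims optional integer (nx, ny, nz); when omitted the volume is
#'   sized to fit the fiber with a small margin. An explicit `dims` that
#'   cannot contain the fiber is an error.
#' @return a [VoxelVolume-class] with gray values `grayAir`/`graySolid`.
#' @export
generateFiber <- function(spec, seed = 1, dims = NULL) {
  validObject(spec)
  vs <- spec@voxelSize
  a <- spec@diameter / 2 * sqrt(spec@shapeFactor)  # major semi-axis (Y), um
  b <- spec@diameter / 2 / sqrt(spec@shapeFactor)  # minor semi-axis (Z), um
  margin <- ceiling((3 * spec@roughnessAmplitude + 2 * vs) / vs)
  nxw <- max(2L, as.integer(round(spec@length / vs)))
  nyw <- as.integer(2 * ceiling(a / vs) + 2 * margin + 1)
  nzw <- as.integer(2 * ceiling(b / vs) + 2 * margin + 1)
  if (is.null(dims)) {
    dims <- c(nxw, nyw, nzw)
  } else {
    dims <- as.integer(dims)
    if (length(dims) != 3L || any(dims < c(nxw, nyw - 2L * margin + 2L,
                                           nzw - 2L * margin + 2L)))
      stop("fiber does not fit in the requested volume dimensions",
           call. = FALSE)
  }
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  co <- slice_coords(ny, nz, vs)
  rho2 <- (co$dy / a)^2 + (co$dz / b)^2
  solid2d <- rho2 <= 1
  g <- array(rep(ifelse(solid2d, spec@graySolid, spec@grayAir),
                 each = nx),
             dim = c(nx, ny, nz))
  if (spec@lumen) {
    p <- spec@lumenFraction
    al <- sqrt(p * a * b * spec@lumenAspect)
    bl <- sqrt(p * a * b / spec@lumenAspect)
    # axial modulation of the lumen scale: smoothed log-normal field,
    # normalized so the realized mean cross-section area hits the target
    sfac <- rep(1, nx)
    if (spec@lumenWaviness > 0) {
      wav <- with_seed(seed + 1L,
                       matrix(stats::rnorm(nx), nx, 1))
      wav <- smooth_gauss(wav, sd = spec@diameter / vs)
      wav <- wav / max(stats::sd(wav), 1e-12) * spec@lumenWaviness
      sfac <- exp(as.vector(wav))
      sfac <- sfac / sqrt(mean(sfac^2))
    }
    if (max(sfac) * al >= a - vs || max(sfac) * bl >= b - vs)
      stop("lumen does not fit inside the solid cross-section; reduce ",
           "lumenFraction, lumenAspect or lumenWaviness", call. = FALSE)
    # one correction pass against the rasterized areas, so the realized
    # porosity hits the requested fraction despite discretization bias
    scale <- 1
    for (pass in 1:2) {
      gi <- g
      nl <- 0L
      for (i in seq_len(nx)) {
        lum2d <- (co$dy / (scale * sfac[i] * al))^2 +
                 (co$dz / (scale * sfac[i] * bl))^2 <= 1
        gi[i, , ][lum2d] <- spec@grayAir
        nl <- nl + sum(lum2d)
      }
      if (pass == 1) {
        phat <- nl / (nx * sum(solid2d))
        if (phat > 0) scale <- sqrt(p / phat)
      }
    }
    g <- gi
  }
  vol <- VoxelVolume(g, vs)
  if (spec@roughnessAmplitude > 0)
    vol <- addSurfaceRoughness(vol, spec@roughnessAmplitude,
                               spec@roughnessCorrelation, seed = seed)
  vol
}

# Per-(slice, azimuth-bin) maximum radius of a mask, in voxel units, around
# the per-slice solid centroid. Returns list(R = nx x nbins matrix,
# bin/r per-voxel assignments for one slice layout).
radial_profile <- function(mask, nbins) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  jj <- rep(seq_len(ny), nz)
  kk <- rep(seq_len(nz), each = ny)
  R <- matrix(NA_real_, nx, nbins)
  cys <- numeric(nx); czs <- numeric(nx)
  for (i in seq_len(nx)) {
    sl <- mask[i, , ]
    w <- which(sl)
    if (!length(w)) next
    cy <- mean(jj[w]); cz <- mean(kk[w])
    cys[i] <- cy; czs[i] <- cz
    dy <- jj[w] - cy; dz <- kk[w] - cz
    r <- sqrt(dy^2 + dz^2)
    bin <- pmin(nbins, 1L + as.integer((atan2(dz, dy) + pi) / (2 * pi) * nbins))
    R[i, ] <- vapply(split(r, factor(bin, levels = seq_len(nbins))),
                     function(v) if (length(v)) max(v) else NA_real_,
                     numeric(1))
  }
  list(R = R, cy = cys, cz = czs)
}

#' Add correlated surface roughness to a two-phase volume
#'
#' Perturbs the outer solid boundary radially with a correlated Gaussian
#' field of the requested RMS amplitude: per axial slice and azimuth bin,
#' the boundary radius is moved in or out by the local field value. The
#' field is white noise smoothed along the axis with a Gaussian kernel of
#' the given correlation length (and circularly over azimuth with a kernel
#' matched to the same arc length), then scaled to unit RMS. Interior air
#' (the lumen) is never breached: erosion is clipped to keep at least one
#' voxel of wall.
#'
#' @param volume two-phase [VoxelVolume-class].
#' @param amplitude RMS radial amplitude, micrometers; 0 is the identity.
#' @param correlation axial correlation length, micrometers.
#' @param seed integer seed; identical seeds give identical output.
#' @param nAzimuth number of azimuth bins of the perturbation field.
#' @return the perturbed volume (same class as the input).
#' @export
addSurfaceRoughness <- function(volume, amplitude, correlation, seed = 1,
                                nAzimuth = 72) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (amplitude == 0) return(volume)
  assert_two_phase(volume)
  g <- voxelData(volume)
  vs <- voxelSize(volume)
  d <- dim(g)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  solid <- g == 255
  air <- !solid
  lab <- array(cpp_label3d(as.vector(air), d), dim = d)
  ext_labels <- boundary_labels(lab, "faces")
  lumen <- air & !(array(lab %in% ext_labels, dim = d))

  # one-voxel shell around the lumen: never eroded, so the wall cannot
  # be breached whatever the roughness field does
  shell <- if (any(lumen))
    array(cpp_morph3d(as.vector(lumen), d, ball_offsets(1), TRUE),
          dim = d) & solid
  else array(FALSE, dim = d)

  prof <- radial_profile(solid, nAzimuth)
  lprof <- if (any(lumen)) radial_profile_centered(lumen, nAzimuth,
                                                   prof$cy, prof$cz)
           else matrix(0, nx, nAzimuth)
  lprof[is.na(lprof)] <- 0

  delta <- with_seed(seed, matrix(stats::rnorm(nx * nAzimuth), nx, nAzimuth))
  delta <- smooth_gauss(delta, sd = correlation / vs, circular = FALSE)
  rbar <- mean(prof$R, na.rm = TRUE)  # voxels
  sd_bins <- (correlation / vs) / max(1e-9, 2 * pi * rbar / nAzimuth)
  sd_bins <- min(max(sd_bins, 0.5), nAzimuth / 4)
  delta <- t(smooth_gauss(t(delta), sd = sd_bins, circular = TRUE))
  delta <- delta - mean(delta)  # pure roughness: no net erosion or growth
  delta <- delta / stats::sd(as.vector(delta)) * (amplitude / vs)  # voxels

  # clip so the new radius never dips below the lumen radius + 1 voxel wall
  floorR <- lprof + 1
  newR <- prof$R + delta
  newR[!is.na(prof$R)] <- pmax(newR[!is.na(prof$R)],
                               floorR[!is.na(prof$R)])

  jj <- rep(seq_len(ny), nz)
  kk <- rep(seq_len(nz), each = ny)
  out <- g
  for (i in seq_len(nx)) {
    Ri <- newR[i, ]
    if (all(is.na(Ri))) next
    dy <- jj - prof$cy[i]
    dz <- kk - prof$cz[i]
    r <- sqrt(dy^2 + dz^2)
    bin <- pmin(nAzimuth, 1L + as.integer((atan2(dz, dy) + pi) /
                                          (2 * pi) * nAzimuth))
    Rv <- Ri[bin]
    sl_solid <- as.vector(solid[i, , ])
    sl_lumen <- as.vector(lumen[i, , ])
    sl_shell <- as.vector(shell[i, , ])
    newsl <- (ifelse(is.na(Rv), sl_solid, r <= Rv) | sl_shell) & !sl_lumen
    out[i, , ] <- ifelse(newsl, 255L, 0L)
  }
  # a surface perturbation must not create cavities: air pockets enclosed
  # by the dilation (internal air that was not lumen) revert to solid
  air2 <- out == 0L
  lab2 <- array(cpp_label3d(as.vector(air2), d), dim = d)
  ext2 <- boundary_labels(lab2, "faces")
  trapped <- air2 & !(array(lab2 %in% ext2, dim = d)) & !lumen
  out[trapped] <- 255L
  initialize(volume, data = out)
}

# radial profile of a mask around externally supplied per-slice centers
radial_profile_centered <- function(mask, nbins, cy, cz) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  jj <- rep(seq_len(ny), nz)
  kk <- rep(seq_len(nz), each = ny)
  R <- matrix(NA_real_, nx, nbins)
  for (i in seq_len(nx)) {
    w <- which(mask[i, , ])
    if (!length(w)) next
    dy <- jj[w] - cy[i]; dz <- kk[w] - cz[i]
    r <- sqrt(dy^2 + dz^2)
    bin <- pmin(nbins, 1L + as.integer((atan2(dz, dy) + pi) / (2 * pi) * nbins))
    R[i, ] <- vapply(split(r, factor(bin, levels = seq_len(nbins))),
                     function(v) if (length(v)) max(v) else NA_real_,
                     numeric(1))
  }
  R
}

#' Carve a notch into a fiber volume
#'
#' Removes solid voxels in a prism across the fiber at the requested
#' azimuth: a V-notch removes a triangular prism (surface opening `width`
#' along the axis, apex at depth `depth`), a U-notch a semi-elliptical prism
#' with semi-axes `width/2` (axial) and `depth` (radial). Removal only
#' converts solid to air; air voxels are untouched.
#'
#' @param volume two-phase [VoxelVolume-class].
#' @param notch a [NotchGeometry-class].
#' @return the notched volume (same class as the input).
#' @export
carveNotch <- function(volume, notch) {
  validObject(notch)
  assert_two_phase(volume)
  g <- voxelData(volume)
  vs <- voxelSize(volume)
  d <- dim(g)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  L <- nx * vs
  x0 <- L / 2 + notch@axialPosition
  w <- notch@width; h <- notch@depth
  if (x0 - w / 2 < 0 || x0 + w / 2 > L)
    stop("notch footprint extends beyond the volume", call. = FALSE)
  alpha <- notch@azimuth * pi / 180

  solid <- g == 255
  idx <- which(solid)
  if (!length(idx)) stop("volume has no solid phase", call. = FALSE)
  ii <- ((idx - 1) %% nx) + 1L
  jj <- (((idx - 1) %/% nx) %% ny) + 1L
  kk <- ((idx - 1) %/% (nx * ny)) + 1L
  cy <- mean(jj); cz <- mean(kk)
  pcoord <- ((jj - cy) * cos(alpha) + (kk - cz) * sin(alpha)) * vs
  xc <- (ii - 0.5) * vs
  infoot <- abs(xc - x0) <= w / 2
  if (!any(infoot)) stop("notch footprint contains no solid voxels",
                         call. = FALSE)
  B <- max(pcoord[infoot])
  chord <- B - min(pcoord[infoot])
  if (h >= chord)
    stop("notch depth ", h, " um reaches through the local fiber width (",
         signif(chord, 4), " um)", call. = FALSE)
  t <- abs(xc - x0)
  remove <- if (notch@type == "V") {
    infoot & (pcoord >= B - h * (1 - 2 * t / w))
  } else {
    (t / (w / 2))^2 + ((B - pcoord) / h)^2 <= 1
  }
  out <- g
  out[idx[remove]] <- 0L
  initialize(volume, data = out)
}

#' Preset fiber and notch descriptors
#'
#' Four named configurations matching the fibers whose descriptors the
#' study reports: `FXU4`, a large U-notched bundle with the largest lumen
#' (porosity 9%), shape factor 3.23 and lateral dimension 232 um; `FU`, a
#' nearly round (shape factor 1.28) U-notched fiber of 44 um diameter and
#' 4% porosity; `FIV15`, the smallest fiber (18 um) with a V-notch and no
#' lumen; and `FU19`, a 23 um U-notched fiber without lumen and shape
#' factor 1.78. Notch dimensions are not part of the printed descriptors;
#' the defaults here sit inside the machined ranges (w 4-108 um, h/d
#' 0.1-0.6).
#'
#' @param name one of `"FXU4"`, `"FU"`, `"FIV15"`, `"FU19"`.
#' @param targetDiameterVoxels optional; rescale the voxel size so the
#'   fiber diameter spans this many voxels (used to run desk-scale
#'   simulations of the same geometry).
#' @param lengthDiameters optional; override the fiber length as a multiple
#'   of the diameter.
#' @param minRoughnessVoxels optional floor on the roughness amplitude in
#'   voxel units (default 0). Rescaled desk-scale fibers can end up with a
#'   nominal roughness below the voxel size, which rasterizes to a smooth
#'   surface; a floor of ~1 voxel keeps the surface-defect population
#'   resolvable.
#' @return list with elements `spec` ([FiberSpec-class]) and `notch`
#'   ([NotchGeometry-class]).
#' @export
fiberPreset <- function(name = c("FXU4", "FU", "FIV15", "FU19"),
                        targetDiameterVoxels = NULL,
                        lengthDiameters = NULL,
                        minRoughnessVoxels = 0) {
  name <- match.arg(name)
  par <- switch(name,
    FXU4 = list(d = 232, shape = 3.23, L = 573, lumen = TRUE, p = 0.09,
                notch = list(type = "U", w = 40, h = 30)),
    FU = list(d = 44, shape = 1.28, L = 240, lumen = TRUE, p = 0.04,
              notch = list(type = "U", w = 25, h = 9.5)),
    FIV15 = list(d = 18, shape = 1.15, L = 580, lumen = FALSE, p = 0,
                 notch = list(type = "V", w = 7.7, h = 2.8)),
    FU19 = list(d = 23, shape = 1.78, L = 160, lumen = FALSE, p = 0,
                notch = list(type = "U", w = 8, h = 4)))
  vs <- 0.28
  if (!is.null(targetDiameterVoxels))
    vs <- par$d / targetDiameterVoxels
  L <- if (!is.null(lengthDiameters)) lengthDiameters * par$d else par$L
  spec <- suppressWarnings(fiberSpec(
    diameter = par$d, shapeFactor = par$shape, length = L,
    lumen = par$lumen, lumenFraction = par$p, lumenAspect = 2,
    lumenWaviness = 0.25,
    roughnessAmplitude = max(0.02 * par$d, minRoughnessVoxels * vs),
    roughnessCorrelation = par$d / 2, voxelSize = vs))
  notch <- suppressWarnings(notchGeometry(
    type = par$notch$type, width = par$notch$w, depth = par$notch$h,
    diameter = par$d))
  list(spec = spec, notch = notch)
}

#' RMS radial boundary deviation between two two-phase volumes
#'
#' Extracts per-slice, per-azimuth-bin outer boundary radii of both volumes
#' about the reference volume's slice centroids and returns the RMS of
#' their difference, in micrometers. Used to verify the roughness
#' generator's amplitude.
#'
#' @param reference,perturbed two-phase [VoxelVolume-class] objects of
#'   identical dimensions.
#' @param nAzimuth number of azimuth bins.
#' @return RMS radial deviation, micrometers.
#' @export
boundaryDeviationRMS <- function(reference, perturbed, nAzimuth = 72) {
  stopifnot(identical(dim(voxelData(reference)), dim(voxelData(perturbed))))
  p0 <- radial_profile(solid_mask(reference), nAzimuth)
  R1 <- radial_profile_centered(solid_mask(perturbed), nAzimuth,
                                p0$cy, p0$cz)
  dR <- R1 - p0$R
  sqrt(mean(dR^2, na.rm = TRUE)) * voxelSize(reference)
}
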