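# Shared fixtures built in code. All seeds fixed: they are part of the
# test conditions, like any other fixture parameter.

# homogeneous solid bar, voxel size 1 um
bar_volume <- function(nx = 48, ny = 4, nz = 4) {
  SegmentedVolume(array(255L, c(nx, ny, nz)), 1)
}

# bar with a V-notch carved at mid-length (voxel units)
notched_bar <- function(nx = 40, ny = 12, nz = 6, w = 10, h = 4,
                        type = "V") {
  seg <- SegmentedVolume(array(255L, c(nx, ny, nz)), 1)
  carveNotch(seg, suppressWarnings(
    notchGeometry(type, width = w, depth = h)))
}

# rescaled preset fixture: generate, notch, segment, mesh
preset_fixture <- function(name, dvox, ld, seed, minRough = 0) {
  pre <- fiberPreset(name, targetDiameterVoxels = dvox,
                     lengthDiameters = ld, minRoughnessVoxels = minRough)
  vol <- carveNotch(generateFiber(pre$spec, seed = seed), pre$notch)
  seg <- segmentVolume(vol, openingRadius = 0)
  list(spec = pre$spec, notch = pre$notch, vol = vol, seg = seg,
       mesh = buildMesh(seg))
}

# the damage-sweep study conditions: strength rule at the critical stress
# of 200 MPa, log displacement ramp from 0.1% to epsBreak nominal strain
sweep_run <- function(fx, criterion, n = 40, epsBreak = 0.08,
                      strength = 200) {
  L <- max(fx$mesh@nodes[, 1])
  mat <- assignMaterials(fx$mesh, fx$seg)
  suppressWarnings(runDamageSimulation(
    fx$mesh, mat, criterion,
    schedule = list(U0 = 0.001 * L, Ubreak = epsBreak * L,
                    nIncrements = n, strength = strength, ramp = "log"),
    tol = 1e-5, maxit = 1000))
}

# element ids adjacent (6-neighborhood) to lumen voxels
lumen_adjacent_elements <- function(fx) {
  lum <- extractLumen(fx$seg)
  d <- dim(lum)
  li <- which(lum > 0L)
  nb <- unique(c(li - 1, li + 1, li - d[1], li + d[1],
                 li - d[1] * d[2], li + d[1] * d[2]))
  a <- match(nb, fx$mesh@voxelIndex)
  a[!is.na(a)]
}

# dense direct solve of the tensile problem (oracle for small meshes)
dense_tension_solve <- function(mesh, materials, U) {
  Ke <- hexStiffness(1, materials@nu0, rep(mesh@voxelSize, 3))
  nd <- 3L * nrow(mesh@nodes)
  K <- matrix(0, nd, nd)
  dofm <- fibrekin:::elem_dofs(mesh@elems)
  for (e in seq_len(nrow(mesh@elems))) {
    dd <- dofm[e, ]
    K[dd, dd] <- K[dd, dd] + materials@E[e] * Ke
  }
  sol <- solveTension(mesh, materials, U, tol = 1e-12)
  fixed <- sol$fixed
  free <- !fixed
  rhs <- -K[free, fixed, drop = FALSE] %*% sol$ufix[fixed]
  uref <- sol$ufix
  uref[free] <- solve(K[free, free], rhs)
  list(uref = uref, pcg = sol)
}
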