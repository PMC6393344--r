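test_that("hexahedral stiffness matrix has the textbook structure", {
  K <- hexStiffness(20000, 0.3, c(1, 1, 1))
  expect_equal(K, t(K))
  # six rigid-body modes: translations give zero force
  for (c0 in 1:3) {
    u <- rep(0, 24); u[seq(c0, 24, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-8 * max(abs(K)))
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-8 * max(ev)), 6L)
  expect_true(all(ev > -1e-8 * max(ev)))
  # linear in E
  expect_equal(hexStiffness(40000, 0.3, c(1, 1, 1)), 2 * K)
  # incompressible limit rejected
  expect_error(hexStiffness(1, 0.5, c(1, 1, 1)), "incompressib")
})

test_that("homogeneous bar under grip tension matches the closed form", {
  seg <- bar_volume(48, 4, 4)
  mesh <- buildMesh(seg)
  E0 <- 20000; nu0 <- 0.3
  mat <- assignMaterials(mesh, seg, E0 = E0, nu0 = nu0)
  U <- 0.48                          # 1% nominal strain
  sol <- solveTension(mesh, mat, U)
  # interior Ux varies linearly in x
  x <- mesh@nodes[, 1]
  mid <- x > 12 & x < 36
  fit <- stats::lm(sol$u[mid, 1] ~ x[mid])
  expect_equal(unname(coef(fit)[2]), 0.01, tolerance = 0.01)
  # mid-span sigma_xx = E0 * eps within 1%
  st <- elementStresses(mesh, mat, sol)
  xe <- mesh@nodes[mesh@elems[, 1], 1]
  span <- xe > 12 & xe < 34
  expect_equal(mean(st$tensor[span, "SXX"]), E0 * 0.01, tolerance = 0.01)
  # reaction force F = E0 * eps * A within 1%
  F <- reactionForce(mesh, mat, sol)
  expect_equal(as.numeric(F), E0 * 0.01 * 16, tolerance = 0.01)
  # equilibrium: end reactions equal and opposite
  expect_lt(abs(as.numeric(F) + attr(F, "balance")),
            1e-6 * abs(as.numeric(F)))
  # energy consistency: external work equals stored energy
  expect_equal(strainEnergy(mesh, mat, sol), 0.5 * as.numeric(F) * U,
               tolerance = 1e-4)
  # linearity: doubling U doubles F
  sol2 <- solveTension(mesh, mat, 2 * U)
  expect_equal(as.numeric(reactionForce(mesh, mat, sol2)),
               2 * as.numeric(F), tolerance = 1e-6)
})

test_that("iterative and dense direct solutions agree on a small mesh", {
  g <- array(255L, c(6, 3, 3)); g[3, 2, 2] <- 0L; g[4, 1, 1] <- 0L
  seg <- SegmentedVolume(g, 1)
  mesh <- buildMesh(seg)
  mat <- assignMaterials(mesh, seg, E0 = 5000, nu0 = 0.3)
  res <- dense_tension_solve(mesh, mat, U = 0.06)
  relerr <- sqrt(sum((res$uref - res$pcg$uvec)^2) / sum(res$uref^2))
  expect_lt(relerr, 1e-8)
})

test_that("principal stresses and stress intensity follow Mohr's circle", {
  ps <- fibrekin:::principal_stresses(rbind(
    c(5, 0, 0, 0, 0, 0),    # uniaxial
    c(0, 0, 0, 3, 0, 0),    # pure shear tau = 3
    c(2, 2, 2, 0, 0, 0)))   # hydrostatic
  expect_equal(ps[1, ], c(S1 = 5, S2 = 0, S3 = 0))
  expect_equal(ps[2, ], c(S1 = 3, S2 = 0, S3 = -3))
  expect_equal(unname(ps[3, 1] - ps[3, 3]), 0)
  # S_I = S1 - S3 = max pairwise difference, always >= 0
  set.seed(1)
  sig <- matrix(rnorm(600), ncol = 6)
  pr <- fibrekin:::principal_stresses(sig)
  expect_true(all(pr[, 1] >= pr[, 2] & pr[, 2] >= pr[, 3]))
  for (i in 1:100) {
    S <- matrix(0, 3, 3)
    S[1, 1] <- sig[i, 1]; S[2, 2] <- sig[i, 2]; S[3, 3] <- sig[i, 3]
    S[1, 2] <- S[2, 1] <- sig[i, 4]
    S[1, 3] <- S[3, 1] <- sig[i, 5]
    S[2, 3] <- S[3, 2] <- sig[i, 6]
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(unname(pr[i, ]), ev, tolerance = 1e-9)
  }
})

test_that("a notch concentrates stress, more so for sharper angles", {
  base <- bar_volume(40, 12, 6)
  E0 <- 20000
  # same depth h, decreasing opening w: theta shrinks, notch sharpens
  s1max <- sapply(c(20, 6), function(w) {
    nb <- carveNotch(base, suppressWarnings(
      notchGeometry("V", width = w, depth = 5)))
    mesh <- buildMesh(nb)
    mat <- assignMaterials(mesh, nb, E0 = E0, nu0 = 0.3)
    sol <- solveTension(mesh, mat, U = 0.4)
    st <- elementStresses(mesh, mat, sol)
    max(st$principal[, 1])
  })
  nominal <- E0 * 0.01
  expect_gt(s1max[1] / nominal, 1)      # concentration factor > 1
  expect_gt(s1max[2], s1max[1])         # smaller opening angle: sharper
})

test_that("a disconnected structure is rejected", {
  g <- array(255L, c(8, 3, 3))
  g[4, , ] <- 0L                        # severed mid-span
  seg <- SegmentedVolume(g, 1)
  mesh <- buildMesh(seg)
  mat <- assignMaterials(mesh, seg)
  expect_error(solveTension(mesh, mat, 0.1), "disconnected")
})

test_that("removing half the cross-section reduces the reaction force", {
  seg <- bar_volume(24, 4, 4)
  mesh <- buildMesh(seg)
  mat <- assignMaterials(mesh, seg)
  F0 <- as.numeric(reactionForce(mesh, mat, solveTension(mesh, mat, 0.24)))
  g <- voxelData(seg); g[12, , 1:2] <- 0L
  segc <- SegmentedVolume(g, 1)
  meshc <- buildMesh(segc)
  matc <- assignMaterials(meshc, segc)
  Fc <- as.numeric(reactionForce(meshc, matc,
                                 solveTension(meshc, matc, 0.24)))
  expect_lt(Fc, F0)
})
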