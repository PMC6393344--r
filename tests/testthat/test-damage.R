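fake_stresses <- function(tensor) {
  colnames(tensor) <- c("SXX", "SYY", "SZZ", "SXY", "SXZ", "SYZ")
  pr <- fibrekin:::principal_stresses(tensor)
  list(tensor = tensor, principal = pr, SI = pr[, 1] - pr[, 3])
}

test_that("criterion extraction follows the signed/absolute convention", {
  st <- fake_stresses(rbind(c(5, 0, 0, 0, 0, 0),
                            c(0, 0, 0, 0, 0, -2),
                            c(0, 0, 0, 3, 0, 0)))
  expect_equal(criterionValue(st, "SXX"), c(5, 0, 0))
  expect_equal(criterionValue(st, "SYZ"), c(0, 2, 0))  # |shear|
  expect_equal(criterionValue(st, "SI")[3], 6)          # pure shear: 2 tau
  expect_equal(criterionValue(st, "S1"), c(5, 2, 3))
  expect_error(criterionValue(st, "SVM"))
})

test_that("damage-set selection is a capped, tie-stable top-k", {
  vals <- 1:10
  intact <- rep(TRUE, 10)
  ids <- selectDamageSet(vals, f = 0.2, intact)   # ceiling(2) elements
  expect_equal(sort(ids), c(9L, 10L))
  # ties break toward the lower element index
  expect_equal(selectDamageSet(rep(1, 10), 0.3, intact), 1:3)
  # f = 1 selects all intact elements
  expect_equal(selectDamageSet(vals, 1, intact), order(-vals, 1:10))
  # already-damaged elements are excluded
  intact[10] <- FALSE
  expect_equal(sort(selectDamageSet(vals, 0.2, intact)), c(8L, 9L))
  # no intact elements left: saturation condition
  expect_error(selectDamageSet(vals, 0.5, rep(FALSE, 10)),
               class = "fibrekin_saturation")
  expect_error(selectDamageSet(vals, 0, intact), "0, 1")
})

test_that("ground-level conversion is irreversible and tracked", {
  seg <- bar_volume(6, 2, 2)
  mesh <- buildMesh(seg)
  mat <- assignMaterials(mesh, seg, E0 = 1000, nu0 = 0.3,
                         groundFactor = 1e-6)
  expect_identical(applyDamage(mat, integer(0)), mat)
  m2 <- applyDamage(mat, 5L)
  expect_equal(sum(m2@damaged), 1L)
  expect_equal(m2@E[5], 1e-6 * 1000)
  expect_equal(m2@nu0, mat@nu0)
  expect_error(applyDamage(m2, 5L), "re-damage")
  # reaction force strictly decreases after damage at the same U
  sol0 <- solveTension(mesh, mat, 0.06)
  F0 <- as.numeric(reactionForce(mesh, mat, sol0))
  m3 <- applyDamage(mat, c(5L, 6L))
  sol1 <- solveTension(mesh, m3, 0.06)
  F1 <- as.numeric(reactionForce(mesh, m3, sol1))
  expect_lt(F1, F0)
})

test_that("first damage localizes at the notch root", {
  seg <- notched_bar(40, 12, 6, w = 10, h = 4)
  mesh <- buildMesh(seg)
  mat <- assignMaterials(mesh, seg)
  L <- max(mesh@nodes[, 1])
  h <- runDamageSimulation(mesh, mat, "S1",
    schedule = list(U0 = 0.004 * L, Ubreak = 0.008 * L, nIncrements = 2,
                    f = 0.002))
  first <- h@newlyDamaged[[1]]
  # oracle: exhaustive stress ranking on the undamaged solve
  sol <- solveTension(mesh, mat, 0.004 * L)
  st <- elementStresses(mesh, mat, sol)
  k <- length(first)
  expect_equal(sort(first),
               sort(order(-st$principal[, 1],
                          seq_len(nElements(mesh)))[seq_len(k)]))
  # all first-damaged elements lie within 3 voxels of the notch root
  cen <- mesh@nodes[mesh@elems[, 1], ] + mesh@voxelSize / 2
  ys <- apply(voxelData(seg) == 255, 2, any)
  root <- c(L / 2, (max(which(ys)) - 4) * mesh@voxelSize)
  dist <- sqrt((cen[first, 1] - root[1])^2 + (cen[first, 2] - root[2])^2)
  expect_true(all(dist <= 3 * mesh@voxelSize + 1e-9))
})

test_that("damage histories are monotone, bounded and deterministic", {
  fx <- list(seg = notched_bar(24, 8, 6, w = 8, h = 3),
             mesh = buildMesh(notched_bar(24, 8, 6, w = 8, h = 3)))
  for (cr in damageCriteria()) {
    h <- sweep_run(fx, cr, n = 12)
    r <- damageRatio(h)
    if (length(r)) {
      expect_true(all(diff(r) >= 0))
      expect_true(all(r >= 0 & r <= 1))
    }
  }
  h1 <- sweep_run(fx, "SI", n = 10)
  h2 <- sweep_run(fx, "SI", n = 10)
  expect_identical(historyTable(h1), historyTable(h2))
  expect_identical(h1@newlyDamaged, h2@newlyDamaged)
})

test_that("empty schedules and force-displacement bookkeeping behave", {
  seg <- bar_volume(12, 3, 3)
  mesh <- buildMesh(seg)
  mat <- assignMaterials(mesh, seg)
  h0 <- runDamageSimulation(mesh, mat, "S1",
                            schedule = list(nIncrements = 0))
  expect_equal(nrow(historyTable(h0)), 0L)
  expect_error(forceDisplacement(h0), "empty")
  # undamaged linear ramp: F proportional to U within 1%
  L <- max(mesh@nodes[, 1])
  h <- runDamageSimulation(mesh, mat, "S1",
    schedule = list(U0 = 0.01 * L, Ubreak = 0.05 * L, nIncrements = 5,
                    strength = 1e9))   # strength never reached: no damage
  fd <- forceDisplacement(h)
  expect_equal(nrow(fd), 5L)
  slopes <- fd$F / fd$U
  expect_lt(diff(range(slopes)) / mean(slopes), 0.01)
  expect_true(all(diff(fd$U) > 0))
  # after heavy damage the force falls below the undamaged projection
  hd <- runDamageSimulation(mesh, mat, "S1",
    schedule = list(U0 = 0.01 * L, Ubreak = 0.05 * L, nIncrements = 5,
                    f = 0.05))
  fdd <- forceDisplacement(hd)
  expect_gte(nrow(fdd), 2L)
  expect_lt(fdd$F[nrow(fdd)], slopes[1] * fdd$U[nrow(fdd)])
})

test_that("late-stage peak stress decays as damage localizes", {
  fx <- preset_fixture("FU19", dvox = 10, ld = 2, seed = 4)
  h <- sweep_run(fx, "S1", n = 24)
  tab <- historyTable(h)
  expect_gt(nrow(tab), 6)
  # trend over the final third: peak criterion below its running maximum
  n3 <- floor(nrow(tab) / 3)
  late <- tab$maxCriterion[(nrow(tab) - n3 + 1):nrow(tab)]
  expect_lt(mean(late), max(tab$maxCriterion))
})
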