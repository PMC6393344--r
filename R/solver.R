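# Natural coordinates of the 8 hex corners, matching hex_corner_offsets.
hex_xi <- 2 * hex_corner_offsets - 1

# Isotropic elasticity matrix (engineering shear strains), 6x6.
iso_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Strain-displacement matrix (6 x 24) of the trilinear hexahedron with edge
# lengths `edges`, evaluated at natural coordinates (xi, eta, zeta).
# Dof order is node-major: (u1x, u1y, u1z, u2x, ...).
hex_B <- function(xi, eta, zeta, edges) {
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    s <- hex_xi[a, ]
    dN[a, 1] <- s[1] * (1 + eta * s[2]) * (1 + zeta * s[3]) / 8 * 2 / edges[1]
    dN[a, 2] <- s[2] * (1 + xi * s[1]) * (1 + zeta * s[3]) / 8 * 2 / edges[2]
    dN[a, 3] <- s[3] * (1 + xi * s[1]) * (1 + eta * s[2]) / 8 * 2 / edges[3]
  }
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[a, 1]
    B[2, c0 + 2] <- dN[a, 2]
    B[3, c0 + 3] <- dN[a, 3]
    B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]  # gamma_xy
    B[5, c0 + 1] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 1]  # gamma_xz
    B[6, c0 + 2] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 2]  # gamma_yz
  }
  B
}

#' Stiffness matrix of a trilinear hexahedral element
#'
#' 24 x 24 symmetric positive semi-definite stiffness of an 8-node cuboid
#' element with 2 x 2 x 2 Gauss integration; the null space consists of the
#' six rigid-body modes. Dofs are node-major (u1x, u1y, u1z, u2x, ...)
#' with corners in VTK hexahedron order.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio, in (0, 0.5).
#' @param edges element edge lengths (a, b, c), micrometers.
#' @return 24 x 24 numeric matrix (units: MPa x um = uN/um).
#' @export
hexStiffness <- function(E, nu, edges) {
  if (!is.finite(E) || E <= 0) stop("E must be positive", call. = FALSE)
  if (nu >= 0.5) stop("nu >= 0.5: incompressible limit not supported",
                      call. = FALSE)
  if (nu <= 0) stop("nu must be positive", call. = FALSE)
  edges <- rep_len(as.numeric(edges), 3L)
  D <- iso_D(E, nu)
  gp <- 1 / sqrt(3)
  detJ <- prod(edges) / 8
  K <- matrix(0, 24, 24)
  for (xi in c(-gp, gp)) for (eta in c(-gp, gp)) for (zeta in c(-gp, gp)) {
    B <- hex_B(xi, eta, zeta, edges)
    K <- K + t(B) %*% D %*% B * detJ
  }
  (K + t(K)) / 2
}

# Dof index matrix (m x 24, 1-based) for gathering element displacements.
elem_dofs <- function(elems) {
  m <- nrow(elems)
  dof <- matrix(0L, m, 24L)
  for (a in 1:8) {
    base <- 3L * (elems[, a] - 1L)
    dof[, 3 * a - 2] <- base + 1L
    dof[, 3 * a - 1] <- base + 2L
    dof[, 3 * a] <- base + 3L
  }
  dof
}

# Node index sets of the two loading faces (x = 0 and x = L).
end_nodes <- function(mesh) {
  x <- mesh@nodes[, 1]
  tolx <- mesh@voxelSize / 2
  list(x0 = which(x <= min(x) + tolx), xL = which(x >= max(x) - tolx),
       L = max(x) - min(x))
}

#' Solve the tensile boundary-value problem
#'
#' Linear elastic equilibrium on the voxel mesh under grip-type tensile
#' boundary conditions: the x = 0 face is fully fixed and the x = L face is
#' displaced by `U` along X with its transverse displacements suppressed
#' (glued ends). The reduced system is solved by Jacobi-preconditioned
#' conjugate gradients, matrix-free over the elements.
#'
#' @param mesh a [HexMesh-class] spanning from x = 0 to x = L.
#' @param materials a [MaterialField-class].
#' @param U applied end displacement, micrometers.
#' @param tol relative residual tolerance (default 1e-8).
#' @param maxit iteration cap; default `10 * sqrt(ndof)`, rounded up.
#' @param warmStart optional displacement vector (3 x nodes) to start from.
#' @param mustConverge error (TRUE) or warn (FALSE) on non-convergence.
#' @return list of class `TensionSolution`: `u` (n x 3 displacement
#'   matrix, um), `uvec` (flat dof vector), `iterations`, `relres`, `U`,
#'   `L`, `fixed` (logical dof mask), `ufix` (prescribed values).
#' @export
solveTension <- function(mesh, materials, U, tol = 1e-8, maxit = NULL,
                         warmStart = NULL, mustConverge = TRUE) {
  stopifnot(is(mesh, "HexMesh"), is(materials, "MaterialField"))
  comp <- meshComponents(mesh)
  if (!any(comp$report$spansEnds))
    stop("structure-disconnected: no element component spans both loading ",
         "ends", call. = FALSE)
  nn <- nrow(mesh@nodes)
  ndof <- 3L * nn
  ends <- end_nodes(mesh)
  fixed <- logical(ndof)
  ufix <- numeric(ndof)
  fixed[as.vector(outer(1:3, 3L * (ends$x0 - 1L), `+`))] <- TRUE
  fixed[as.vector(outer(1:3, 3L * (ends$xL - 1L), `+`))] <- TRUE
  ufix[3 * (ends$xL - 1L) + 1L] <- U
  if (is.null(maxit)) maxit <- as.integer(ceiling(10 * sqrt(ndof)))
  u0 <- if (is.null(warmStart)) numeric(ndof) else as.numeric(warmStart)
  if (length(u0) != ndof) stop("warmStart has wrong length", call. = FALSE)
  Ke <- hexStiffness(1, materials@nu0, rep(mesh@voxelSize, 3L))
  res <- cpp_pcg_hex(mesh@elems - 1L, as.vector(t(Ke)), materials@E, nn,
                     fixed, ufix, u0, tol, maxit)
  if (!res$converged) {
    msg <- sprintf(
      "solver did not converge: relative residual %.3g after %d iterations",
      res$relres, res$iterations)
    if (mustConverge) stop(msg, call. = FALSE) else warning(msg,
                                                            call. = FALSE)
  }
  structure(list(u = matrix(res$u, ncol = 3, byrow = TRUE),
                 uvec = res$u, iterations = res$iterations,
                 relres = res$relres, U = U, L = ends$L, fixed = fixed,
                 ufix = ufix),
            class = "TensionSolution")
}

#' Per-element stress states
#'
#' Strains from the trilinear shape-function gradients at the element
#' centroid, stresses by isotropic Hooke's law with the element's (possibly
#' damaged) modulus, principal stresses by closed-form symmetric
#' eigen-decomposition sorted descending, and the stress intensity
#' S_I = S_1 - S_3.
#'
#' @param mesh a [HexMesh-class].
#' @param materials a [MaterialField-class].
#' @param solution a `TensionSolution` from [solveTension()].
#' @return list with `tensor` (m x 6 matrix, columns SXX, SYY, SZZ, SXY,
#'   SXZ, SYZ, MPa), `principal` (m x 3, S1 >= S2 >= S3) and `SI`
#'   (numeric m).
#' @export
elementStresses <- function(mesh, materials, solution) {
  dof <- elem_dofs(mesh@elems)
  ue <- matrix(solution$uvec[dof], nrow = nrow(dof))
  B0 <- hex_B(0, 0, 0, rep(mesh@voxelSize, 3L))
  D1 <- iso_D(1, materials@nu0)
  sig <- (ue %*% t(B0)) %*% t(D1) * materials@E
  colnames(sig) <- c("SXX", "SYY", "SZZ", "SXY", "SXZ", "SYZ")
  pr <- principal_stresses(sig)
  list(tensor = sig, principal = pr,
       SI = pr[, 1] - pr[, 3])
}

# Vectorized eigenvalues of symmetric 3x3 stress tensors (trigonometric
# closed form), returned sorted descending per row.
principal_stresses <- function(sig) {
  sxx <- sig[, 1]; syy <- sig[, 2]; szz <- sig[, 3]
  sxy <- sig[, 4]; sxz <- sig[, 5]; syz <- sig[, 6]
  p1 <- sxy^2 + sxz^2 + syz^2
  q <- (sxx + syy + szz) / 3
  p2 <- (sxx - q)^2 + (syy - q)^2 + (szz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p <= .Machine$double.eps * (abs(q) + 1)
  ps <- pmax(p, .Machine$double.xmin)
  bxx <- (sxx - q) / ps; byy <- (syy - q) / ps; bzz <- (szz - q) / ps
  bxy <- sxy / ps; bxz <- sxz / ps; byz <- syz / ps
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[iso] <- q[iso]; e2[iso] <- q[iso]; e3[iso] <- q[iso]
  out <- cbind(S1 = e1, S2 = e2, S3 = e3)
  out
}

#' Reaction force at the loaded end
#'
#' Sums the nodal reaction forces along X over the x = L face; global
#' equilibrium requires this to equal minus the x = 0 face sum.
#'
#' @inheritParams elementStresses
#' @return reaction force in micronewtons, with attribute `balance` holding
#'   the x = 0 face sum (equal and opposite within solver tolerance).
#' @export
reactionForce <- function(mesh, materials, solution) {
  Ke <- hexStiffness(1, materials@nu0, rep(mesh@voxelSize, 3L))
  f <- cpp_hex_matvec(mesh@elems - 1L, as.vector(t(Ke)), materials@E,
                      nrow(mesh@nodes), solution$uvec)
  ends <- end_nodes(mesh)
  FL <- sum(f[3 * (ends$xL - 1L) + 1L])
  F0 <- sum(f[3 * (ends$x0 - 1L) + 1L])
  structure(FL, balance = F0)
}

#' Elastic strain energy of a solution
#'
#' `0.5 * t(u) %*% K %*% u`; on a converged solution this equals the
#' external work `0.5 * F * U` of the grip loading.
#'
#' @inheritParams elementStresses
#' @return strain energy in MPa um^3 (= uN um = pJ).
#' @export
strainEnergy <- function(mesh, materials, solution) {
  Ke <- hexStiffness(1, materials@nu0, rep(mesh@voxelSize, 3L))
  f <- cpp_hex_matvec(mesh@elems - 1L, as.vector(t(Ke)), materials@E,
                      nrow(mesh@nodes), solution$uvec)
  0.5 * sum(f * solution$uvec)
}

#' Mean lateral contraction of the mid-span
#'
#' Average inward radial displacement of the nodes in the central portion
#' of the fiber (away from the laterally constrained grips), the quantity
#' compared against deformed images to identify the Poisson ratio.
#'
#' @inheritParams elementStresses
#' @param regionFraction axial fraction of the fiber, centered at
#'   mid-length, over which to average (default 0.5).
#' @return mean inward radial displacement, micrometers (positive =
#'   contraction).
#' @export
lateralContraction <- function(mesh, solution, regionFraction = 0.5) {
  x <- mesh@nodes[, 1]
  L <- max(x) - min(x)
  mid <- abs(x - (min(x) + L / 2)) <= regionFraction * L / 2
  y <- mesh@nodes[mid, 2]; z <- mesh@nodes[mid, 3]
  cy <- mean(y); cz <- mean(z)
  ry <- y - cy; rz <- z - cz
  r <- sqrt(ry^2 + rz^2)
  keep <- r > .Machine$double.eps
  ur <- (solution$u[mid, 2][keep] * ry[keep] +
         solution$u[mid, 3][keep] * rz[keep]) / r[keep]
  -mean(ur)
}
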