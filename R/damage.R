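#' The eight damage criteria
#'
#' Scalar stress measures used to rank elements for degradation: the stress
#' intensity `SI` (= S1 - S3), the largest principal stress `S1`, the three
#' normal components `SXX`, `SYY`, `SZZ` (signed: damage is
#' tension-driven), and the three shear components `SXY`, `SXZ`, `SYZ`
#' (absolute value: shear damage is sign-indifferent).
#'
#' @return character vector of the eight criterion names.
#' @export
damageCriteria <- function() {
  c("SI", "S1", "SXX", "SYY", "SZZ", "SXY", "SXZ", "SYZ")
}

#' Extract the criterion scalar per element
#'
#' @param stresses result of [elementStresses()].
#' @param criterion one of [damageCriteria()].
#' @return numeric vector, MPa.
#' @export
criterionValue <- function(stresses, criterion) {
  criterion <- match.arg(criterion, damageCriteria())
  switch(criterion,
         SI = stresses$SI,
         S1 = stresses$principal[, 1],
         SXX = stresses$tensor[, "SXX"],
         SYY = stresses$tensor[, "SYY"],
         SZZ = stresses$tensor[, "SZZ"],
         SXY = abs(stresses$tensor[, "SXY"]),
         SXZ = abs(stresses$tensor[, "SXZ"]),
         SYZ = abs(stresses$tensor[, "SYZ"]))
}

#' Select the highest-stressed intact elements
#'
#' Returns the `ceiling(f * nIntact)` intact elements with the largest
#' criterion values; ties are broken toward the lower element index.
#'
#' @param values criterion value per element (all elements).
#' @param f fraction of the intact elements to damage, in (0, 1\].
#' @param intact logical per-element mask of not-yet-damaged elements.
#' @return integer element ids. Signals an error of class
#'   `fibrekin_saturation` when no intact element remains.
#' @export
selectDamageSet <- function(values, f, intact) {
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]", call. = FALSE)
  ids <- which(intact)
  if (!length(ids))
    stop(errorCondition("no intact element remains (damage saturated)",
                        class = c("fibrekin_saturation", "error",
                                  "condition")))
  k <- ceiling(f * length(ids))
  ids[order(-values[ids], ids)][seq_len(k)]
}

#' Convert elements to the ground material level
#'
#' Irreversibly sets the Young's modulus of the listed elements to
#' `groundFactor * E0`; the Poisson ratio is unchanged and the elements
#' stay in the mesh, so the system matrix remains well posed.
#'
#' @param materials a [MaterialField-class].
#' @param ids integer element ids; must all be intact.
#' @return the updated [MaterialField-class].
#' @export
applyDamage <- function(materials, ids) {
  if (!length(ids)) return(materials)
  if (any(materials@damaged[ids]))
    stop("attempt to re-damage an already damaged element", call. = FALSE)
  materials@E[ids] <- materials@groundFactor * materials@E0
  materials@damaged[ids] <- TRUE
  materials
}

#' Run an iterative stress-criterion damage simulation
#'
#' Quasi-static loop: at each load increment the end displacement follows a
#' ramp from `U0` to `Ubreak`, the elastic problem is solved once, the
#' criterion is evaluated over the intact elements, and the
#' highest-stressed elements are converted to the ground stiffness level.
#' Two conversion rules are available through the schedule:
#'
#' * **strength rule** (`strength` given, the default study conditions):
#'   every intact element whose criterion value exceeds the critical
#'   stress `strength` (MPa) is converted, optionally capped at
#'   `capFraction` of the intact elements per increment. Damage onset then
#'   happens when the local stress concentrations first reach the critical
#'   stress, which differs between criteria of different magnitudes --
#'   this is what separates aggressive from inefficient criteria.
#' * **fraction rule** (`strength = NULL`): the fixed fraction `f` of the
#'   intact elements with the highest criterion values is converted at
#'   every increment, regardless of stress level (useful for pure
#'   criterion comparisons at constant load).
#'
#' Damage accumulation is recorded as the damage ratio: cumulative damaged
#' elements over all damageable (solid) elements. The run stops early when
#' the maximum criterion value over intact elements falls below
#' `saturationFraction` of its first-increment value, or when the intact
#' elements no longer form a face-connected path between the loading ends
#' (the specimen has severed).
#'
#' @param mesh a [HexMesh-class].
#' @param materials a [MaterialField-class] (not mutated; a damaged copy
#'   evolves inside the run).
#' @param criterion one of [damageCriteria()].
#' @param schedule list with `U0`, `Ubreak` (micrometers), `nIncrements`,
#'   `f` (per-increment damage fraction for the fraction rule, default
#'   0.005), `strength` (critical stress, MPa; NULL selects the fraction
#'   rule), `capFraction` (optional per-increment cap under the strength
#'   rule) and `ramp` (`"linear"` or `"log"`; log spacing resolves the
#'   onset windows of criteria whose magnitudes differ by an order of
#'   magnitude within one run).
#' @param tol,maxit solver controls (see [solveTension()]).
#' @param saturationFraction early-stop threshold on the intact maximum
#'   criterion value, as a fraction of its initial value (default 0.01).
#' @param innerResolve when TRUE, re-solve and damage again at the same
#'   load level while the redistributed peak criterion value still exceeds
#'   its pre-damage value (at most `innerCap` extra solves per increment).
#'   Default FALSE: one solve per increment.
#' @param innerCap cap on inner re-solves per increment.
#' @param verbose print per-increment progress.
#' @return a [DamageHistory-class].
#' @export
runDamageSimulation <- function(mesh, materials, criterion = "S1",
                                schedule = list(), tol = 1e-8,
                                maxit = NULL, saturationFraction = 0.01,
                                innerResolve = FALSE, innerCap = 5L,
                                verbose = FALSE) {
  criterion <- match.arg(criterion, damageCriteria())
  sch <- utils::modifyList(list(U0 = NULL, Ubreak = NULL, nIncrements = 0L,
                                f = 0.005, strength = NULL,
                                capFraction = NULL, ramp = "linear"),
                           schedule)
  sch$ramp <- match.arg(sch$ramp, c("linear", "log"))
  n <- as.integer(sch$nIncrements)
  m <- nrow(mesh@elems)
  empty <- function(reason) {
    new("DamageHistory",
        table = data.frame(increment = integer(), U = numeric(),
                           F = numeric(), ratio = numeric(),
                           maxCriterion = numeric(), nNew = integer(),
                           nDamaged = integer(), iterations = integer()),
        newlyDamaged = list(), criterion = criterion,
        nDamageable = m, schedule = c(sch, list(stopReason = reason)))
  }
  if (n <= 0L) return(empty("empty schedule"))
  if (is.null(sch$U0) || is.null(sch$Ubreak))
    stop("schedule must provide U0 and Ubreak", call. = FALSE)
  Useq <- if (n == 1L) sch$Ubreak
          else if (sch$ramp == "log")
            exp(seq(log(sch$U0), log(sch$Ubreak), length.out = n))
          else seq(sch$U0, sch$Ubreak, length.out = n)
  mat <- materials
  rows <- vector("list", n)
  newly <- vector("list", n)
  maxc0 <- NA_real_
  uprev <- NULL
  Uprev <- NA_real_
  stopReason <- "completed"
  done <- 0L
  for (it in seq_len(n)) {
    intact <- !mat@damaged
    comp <- meshComponents(mesh, subset = intact)
    if (!any(comp$report$spansEnds)) { stopReason <- "load path lost"; break }
    U <- Useq[it]
    warm <- if (!is.null(uprev)) uprev * (U / Uprev) else NULL
    sol <- solveTension(mesh, mat, U, tol = tol, maxit = maxit,
                        warmStart = warm, mustConverge = FALSE)
    uprev <- sol$uvec; Uprev <- U
    st <- elementStresses(mesh, mat, sol)
    vals <- criterionValue(st, criterion)
    maxc <- max(vals[intact])
    if (it == 1L) maxc0 <- maxc
    if (maxc < saturationFraction * maxc0) {
      stopReason <- "criterion saturated"; break
    }
    FL <- as.numeric(reactionForce(mesh, mat, sol))
    if (is.null(sch$strength)) {
      ids <- tryCatch(selectDamageSet(vals, sch$f, intact),
                      fibrekin_saturation = function(e) integer(0))
      if (!length(ids)) { stopReason <- "all elements damaged"; break }
    } else {
      over <- which(intact & vals > sch$strength)
      if (length(over) && !is.null(sch$capFraction)) {
        k <- min(length(over), ceiling(sch$capFraction * sum(intact)))
        over <- over[order(-vals[over], over)][seq_len(k)]
      }
      ids <- over
    }
    mat <- applyDamage(mat, ids)
    if (innerResolve) {
      for (ii in seq_len(innerCap)) {
        intact2 <- !mat@damaged
        if (!sum(intact2)) break
        sol2 <- solveTension(mesh, mat, U, tol = tol, maxit = maxit,
                             warmStart = uprev, mustConverge = FALSE)
        uprev <- sol2$uvec
        st2 <- elementStresses(mesh, mat, sol2)
        vals2 <- criterionValue(st2, criterion)
        if (max(vals2[intact2]) <= maxc) break
        ids2 <- tryCatch(selectDamageSet(vals2, sch$f, intact2),
                         fibrekin_saturation = function(e) integer(0))
        if (!length(ids2)) break
        mat <- applyDamage(mat, ids2)
        ids <- c(ids, ids2)
      }
    }
    done <- done + 1L
    newly[[done]] <- ids
    rows[[done]] <- data.frame(increment = it, U = U, F = FL,
                               ratio = sum(mat@damaged) / m,
                               maxCriterion = maxc,
                               nNew = length(ids),
                               nDamaged = sum(mat@damaged),
                               iterations = sol$iterations)
    if (verbose)
      message(sprintf(
        "increment %d: U = %.3g um, F = %.4g uN, ratio = %.4f (%d cg its)",
        it, U, FL, sum(mat@damaged) / m, sol$iterations))
  }
  if (done == 0L) return(empty(stopReason))
  new("DamageHistory", table = do.call(rbind, rows[seq_len(done)]),
      newlyDamaged = newly[seq_len(done)], criterion = criterion,
      nDamageable = m, schedule = c(sch, list(stopReason = stopReason)))
}

#' Force-displacement curve of a damage run
#'
#' @param history a [DamageHistory-class].
#' @return data.frame with columns `U` (micrometers) and `F`
#'   (micronewtons), one row per increment.
#' @export
forceDisplacement <- function(history) {
  if (!nrow(history@table)) stop("empty damage history", call. = FALSE)
  history@table[, c("U", "F")]
}
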