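as_ratio_curve <- function(x) {
  if (is(x, "DamageHistory")) x@table$ratio else as.numeric(x)
}

#' Detect the three damage stages
#'
#' Decomposes a non-decreasing damage-ratio curve into onset, growth and
#' saturation: onset is the first increment where the ratio exceeds
#' `onsetThreshold` times the final ratio, saturation the first increment
#' where it reaches `saturationThreshold` times the final ratio, growth the
#' interval between. An identically zero curve yields NA boundaries (no
#' onset) rather than an error.
#'
#' @param x a [DamageHistory-class] or a numeric damage-ratio curve.
#' @param onsetThreshold fraction of the final ratio defining onset
#'   (default 0.01).
#' @param saturationThreshold fraction defining saturation (default 0.99).
#' @param monotoneTolerance largest admissible decrease between successive
#'   increments, as a fraction of the final ratio (measurement noise on an
#'   intrinsically non-decreasing quantity); larger violations are errors.
#' @return a [StageBoundaries-class].
#' @export
detectStages <- function(x, onsetThreshold = 0.01,
                         saturationThreshold = 0.99,
                         monotoneTolerance = 0.02) {
  r <- as_ratio_curve(x)
  final0 <- if (length(r)) max(r) else 0
  if (length(r) && (any(r < 0) ||
                    any(diff(r) < -monotoneTolerance * max(final0, 1e-12))))
    stop("damage-ratio curve must be non-negative and non-decreasing",
         call. = FALSE)
  r <- cummax(r)
  final <- if (length(r)) r[length(r)] else 0
  if (final <= 0)
    return(new("StageBoundaries", onset = NA_integer_,
               saturation = NA_integer_,
               growth = c(NA_integer_, NA_integer_),
               onsetThreshold = onsetThreshold,
               saturationThreshold = saturationThreshold))
  onset <- which(r > onsetThreshold * final)[1]
  saturation <- which(r >= saturationThreshold * final)[1]
  new("StageBoundaries", onset = as.integer(onset),
      saturation = as.integer(saturation),
      growth = as.integer(c(onset, saturation)),
      onsetThreshold = onsetThreshold,
      saturationThreshold = saturationThreshold)
}

# Local maxima (plateau-tolerant) of a numeric vector.
local_maxima <- function(s) {
  n <- length(s)
  if (n < 3) return(integer(0))
  which(vapply(2:(n - 1), function(i)
    s[i] >= s[i - 1] && s[i] >= s[i + 1], logical(1))) + 1L
}

#' Classify the damage growth as monomodal or bimodal
#'
#' Smooths the discrete damage rate within the growth stage with a moving
#' average and counts separated rate maxima: the growth is bimodal when at
#' least two local maxima are separated by a valley whose depth (peak minus
#' valley) exceeds `prominence` times the global maximum rate. A bimodal
#' growth reflects the transition from localized to diffuse damage; a
#' single rate peak or a flat rate is monomodal.
#'
#' @param x a [DamageHistory-class] or numeric damage-ratio curve.
#' @param window moving-average window (increments, default 5).
#' @param prominence required valley depth as a fraction of the maximum
#'   rate (default 0.25).
#' @param stages optional precomputed [StageBoundaries-class].
#' @return `"monomodal"`, `"bimodal"`, or `"inconclusive"` (growth stage
#'   shorter than the smoothing window).
#' @export
detectModality <- function(x, window = 5, prominence = 0.25,
                           stages = NULL) {
  r <- as_ratio_curve(x)
  if (is.null(stages)) stages <- detectStages(r)
  if (is.na(stages@onset)) return("inconclusive")
  g1 <- stages@growth[1]; g2 <- stages@growth[2]
  if (g2 - g1 + 1 < window + 2) return("inconclusive")
  rate <- diff(r[g1:g2])
  s <- as.numeric(stats::filter(rate, rep(1 / window, window),
                                sides = 2))
  s <- s[!is.na(s)]
  if (length(s) < 3) return("inconclusive")
  peaks <- local_maxima(s)
  if (length(peaks) < 2) return("monomodal")
  smax <- max(s)
  pk <- peaks[order(s[peaks], decreasing = TRUE)]
  main <- pk[1]
  for (p in pk[-1]) {
    lo <- min(main, p); hi <- max(main, p)
    valley <- min(s[lo:hi])
    if (min(s[main], s[p]) - valley >= prominence * smax)
      return("bimodal")
  }
  "monomodal"
}

#' Categorize damage criteria by aggressiveness
#'
#' Given one damage history per criterion on the same fixture and load
#' schedule, clusters the criteria into three groups on the standardized
#' (onset increment, final damage ratio) plane with fixed-seed k-means:
#' `aggressive` is the earliest-onset cluster, `inefficient` the cluster
#' with the latest onset and lowest saturation among the rest, and
#' `intermediate` the remainder. With fewer than three distinct behaviors
#' a degenerate report (all `intermediate`) is returned with a message.
#'
#' @param histories named list of [DamageHistory-class], one per criterion.
#' @param seed k-means seed (default 1).
#' @return data.frame with columns `criterion`, `onset`, `finalRatio`,
#'   `category`; attribute `degenerate` flags the fallback.
#' @export
categorizeCriteria <- function(histories, seed = 1) {
  stopifnot(length(histories) >= 2)
  feats <- t(vapply(histories, function(h) {
    r <- as_ratio_curve(h)
    st <- detectStages(r)
    onset <- if (is.na(st@onset)) length(r) + 1L else st@onset
    c(onset = onset, finalRatio = if (length(r)) r[length(r)] else 0)
  }, numeric(2)))
  out <- data.frame(criterion = names(histories),
                    onset = feats[, "onset"],
                    finalRatio = feats[, "finalRatio"],
                    row.names = NULL)
  std <- scale(feats)
  std[, apply(feats, 2, stats::sd) == 0] <- 0
  if (nrow(unique(feats)) < 3) {
    message("fewer than three distinct criterion behaviors: ",
            "degenerate clustering")
    out$category <- "intermediate"
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  km <- with_seed(seed, stats::kmeans(std, centers = 3, nstart = 25,
                                      iter.max = 100))
  cl <- km$cluster
  meanOnset <- tapply(out$onset, cl, mean)
  meanRatio <- tapply(out$finalRatio, cl, mean)
  aggressive <- as.integer(names(which.min(meanOnset)))
  rest <- setdiff(sort(unique(cl)), aggressive)
  sOn <- tapply(std[, "onset"], cl, mean)
  sRa <- tapply(std[, "finalRatio"], cl, mean)
  score <- sOn[as.character(rest)] - sRa[as.character(rest)]
  inefficient <- rest[which.max(score)]
  out$category <- "intermediate"
  out$category[cl == aggressive] <- "aggressive"
  out$category[cl == inefficient] <- "inefficient"
  attr(out, "degenerate") <- FALSE
  attr(out, "clusterMeans") <- data.frame(cluster = sort(unique(cl)),
                                          onset = as.numeric(meanOnset),
                                          finalRatio = as.numeric(meanRatio))
  out
}

#' Identify the solid-phase Young's modulus
#'
#' In the linear model the force-displacement slope is strictly
#' proportional to E0, so a single trial simulation suffices:
#' `E0 = trialE * experimentalSlope / modelSlope`.
#'
#' @param experimentalSlope measured stiffness, uN/um.
#' @param modelSlope simulated stiffness at `trialE`, uN/um.
#' @param trialE trial modulus of the simulation, MPa.
#' @return identified E0, MPa.
#' @export
identifyE0 <- function(experimentalSlope, modelSlope, trialE) {
  if (!all(is.finite(c(experimentalSlope, modelSlope, trialE))) ||
      experimentalSlope <= 0 || modelSlope <= 0 || trialE <= 0)
    stop("slopes and trial modulus must be positive", call. = FALSE)
  trialE * experimentalSlope / modelSlope
}

#' Identify the solid-phase Poisson ratio
#'
#' Scales the trial Poisson ratio by the ratio of observed to simulated
#' mean lateral contraction (measured away from the constrained ends),
#' assuming the same linearity as the modulus identification. The
#' contraction is only approximately linear in nu, so this is a one-step
#' correction, not an exact inversion. Results outside (0, 0.5) are
#' clamped with a warning.
#'
#' @param observedContraction measured mean lateral contraction, um.
#' @param modelContraction simulated contraction at `trialNu`, um.
#' @param trialNu trial Poisson ratio.
#' @return identified nu0, dimensionless, in (0, 0.5).
#' @export
identifyNu0 <- function(observedContraction, modelContraction, trialNu) {
  if (!is.finite(modelContraction) || modelContraction == 0)
    stop("model contraction must be nonzero", call. = FALSE)
  nu <- trialNu * observedContraction / modelContraction
  if (nu <= 0 || nu >= 0.5) {
    warning("identified Poisson ratio ", signif(nu, 4),
            " clamped into (0, 0.5)")
    nu <- min(max(nu, 1e-4), 0.5 - 1e-4)
  }
  nu
}
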