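`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Offsets (di, dj, dk) of a Euclidean ball of the given voxel radius,
# used as the structuring element of the 3D morphological operators.
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
  keep <- g$di^2 + g$dj^2 + g$dk^2 <= radius^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Gaussian smoothing of the columns of a matrix along rows, with either
# reflecting or circular boundary handling; kernel sd in row units.
smooth_gauss <- function(x, sd, circular = FALSE) {
  if (sd <= 0) return(x)
  half <- max(1L, as.integer(ceiling(3 * sd)))
  kern <- stats::dnorm(-half:half, sd = sd)
  kern <- kern / sum(kern)
  n <- nrow(x)
  if (circular) {
    idx <- function(i) ((i - 1) %% n) + 1
  } else {
    idx <- function(i) pmin(pmax(i, 1L), n)
  }
  out <- matrix(0, n, ncol(x))
  for (t in seq_along(kern)) {
    off <- t - half - 1L
    out <- out + kern[t] * x[idx(seq_len(n) + off), , drop = FALSE]
  }
  out
}

# Solid/air convention helpers: a two-phase volume uses gray 255 for solid.
solid_mask <- function(vol) voxelData(vol) == 255

assert_two_phase <- function(vol, what = "volume") {
  vals <- unique(as.vector(voxelData(vol)))
  if (!all(vals %in% c(0, 255)))
    stop(what, " must be two-valued (gray levels 0 and 255); ",
         "run segmentVolume() first", call. = FALSE)
  invisible(TRUE)
}
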