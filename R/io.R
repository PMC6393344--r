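#' Write a voxel volume as a multi-page TIFF with a metadata sidecar
#'
#' One 8-bit grayscale page per X slice, plus a YAML sidecar
#' (`<path>.yaml`) recording the voxel size, axis order and gray-level
#' convention, so the volume round-trips losslessly.
#'
#' @param volume a [VoxelVolume-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeVoxelVolume <- function(volume, path) {
  g <- voxelData(volume)
  d <- dim(g)
  pages <- lapply(seq_len(d[1]), function(i) g[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  yaml::write_yaml(list(
    voxel_size_um = voxelSize(volume),
    dims = as.integer(d),
    axis_order = "page = X slice (loading axis); page rows = Y, cols = Z",
    gray_levels = list(air = 0L, solid = 255L),
    segmented = is(volume, "SegmentedVolume")),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read a voxel volume from a multi-page TIFF
#'
#' @param path TIFF path written by [writeVoxelVolume()] (or any gray
#'   multi-page TIFF, one page per X slice).
#' @param voxelSize voxel edge length in micrometers; taken from the
#'   `<path>.yaml` sidecar when omitted.
#' @return a [VoxelVolume-class] (or [SegmentedVolume-class] if the
#'   sidecar marks the volume as segmented).
#' @export
readVoxelVolume <- function(path, voxelSize = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e)
                      stop("malformed TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  segmented <- FALSE
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (is.null(voxelSize)) voxelSize <- meta$voxel_size_um
    segmented <- isTRUE(meta$segmented)
  }
  if (is.null(voxelSize))
    stop("voxelSize not given and no metadata sidecar found (field ",
         "voxel_size_um missing)", call. = FALSE)
  d2 <- dim(pages[[1]])
  g <- array(0L, dim = c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages))
    g[i, , ] <- as.integer(round(pages[[i]] * 255))
  if (segmented) SegmentedVolume(g, voxelSize) else VoxelVolume(g, voxelSize)
}

#' Write a damage history to CSV
#'
#' One row per increment with the full per-increment record; the newly
#' damaged element ids are not serialized (write the label volume or VTK
#' snapshots for spatial analysis).
#'
#' @param history a [DamageHistory-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDamageHistory <- function(history, path) {
  tab <- history@table
  tab$criterion <- history@criterion
  tab$nDamageable <- history@nDamageable
  utils::write.csv(format(tab, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a damage history written by [writeDamageHistory()]
#'
#' @param path CSV path.
#' @return a [DamageHistory-class] (per-increment element ids are not
#'   recoverable from CSV and come back empty).
#' @export
readDamageHistory <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("increment", "U", "F", "ratio", "maxCriterion", "nNew",
            "nDamaged", "iterations", "criterion", "nDamageable")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("malformed damage-history CSV: missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  new("DamageHistory",
      table = tab[, c("increment", "U", "F", "ratio", "maxCriterion",
                      "nNew", "nDamaged", "iterations")],
      newlyDamaged = rep(list(integer(0)), nrow(tab)),
      criterion = as.character(tab$criterion[1]),
      nDamageable = as.integer(tab$nDamageable[1]),
      schedule = list(stopReason = "read from CSV"))
}

#' Write lumen statistics to CSV
#'
#' Per-slice rows followed by a summary block (mean/median area and
#' aspect, porosity) marked in the `slice` column.
#'
#' @param stats a [LumenStats-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLumenStats <- function(stats, path) {
  per <- stats@perSlice
  per$slice <- as.character(per$slice)
  s <- stats@summary
  block <- data.frame(
    slice = c("mean", "median", "porosity", "skipped_slices"),
    area = c(s$meanArea, s$medianArea, stats@porosity,
             stats@skippedSlices),
    aspect = c(s$meanAspect, s$medianAspect, NA, NA))
  utils::write.csv(rbind(per, block), path, row.names = FALSE)
  invisible(path)
}

#' Export a mesh with fields as a legacy-ASCII VTK unstructured grid
#'
#' Hexahedral cells with optional per-element (`cellData`) and per-node
#' (`pointData`) scalar fields, viewable in ParaView.
#'
#' @param mesh a [HexMesh-class].
#' @param path output `.vtk` path.
#' @param cellData named list of numeric per-element vectors.
#' @param pointData named list of numeric per-node vectors (or n x 3
#'   matrices, written as vectors).
#' @return `path`, invisibly.
#' @export
writeVTK <- function(mesh, path, cellData = list(), pointData = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh@nodes); m <- nrow(mesh@elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "fibrekin voxel mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  utils::write.table(format(mesh@nodes, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  utils::write.table(cbind(8L, mesh@elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  write_fields <- function(fields, count, label) {
    writeLines(sprintf("%s %d", label, count), con)
    for (nm in names(fields)) {
      v <- fields[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s float", nm), con)
        utils::write.table(format(v, digits = 9, trim = TRUE), con,
                           row.names = FALSE, col.names = FALSE,
                           quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s float 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(v, digits = 9, trim = TRUE), con)
      }
    }
  }
  if (length(cellData)) write_fields(cellData, m, "CELL_DATA")
  if (length(pointData)) write_fields(pointData, n, "POINT_DATA")
  invisible(path)
}
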