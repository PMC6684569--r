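#' @include AllClasses.R
NULL

#' Write a spatial map set as NIfTI volumes
#'
#' One `.nii.gz` file per map, named `<prefix><label>.nii.gz`, plus a
#' `<prefix>labels.tsv` sidecar fixing component order.
#'
#' @param maps a [SpatialMapSet-class].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return invisibly, the written map file paths.
#' @export
writeSpatialMaps <- function(maps, dir, prefix = "map_") {
  stopIfNot(is(maps, "SpatialMapSet"), "'maps' must be a SpatialMapSet")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- networkLabels(maps)
  paths <- file.path(dir, paste0(prefix, labels, ".nii.gz"))
  m <- spatialMaps(maps)
  for (k in seq_along(labels))
    RNifti::writeNifti(RNifti::asNifti(m[[k]]), paths[k])
  utils::write.table(
    data.frame(order = seq_along(labels), label = labels,
               file = basename(paths)),
    file.path(dir, paste0(prefix, "labels.tsv")),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a spatial map set written by [writeSpatialMaps()]
#'
#' @param dir directory holding the NIfTI volumes and labels sidecar.
#' @param prefix filename prefix used at write time.
#' @return a [SpatialMapSet-class].
#' @export
readSpatialMaps <- function(dir, prefix = "map_") {
  sidecar <- file.path(dir, paste0(prefix, "labels.tsv"))
  stopIfNot(file.exists(sidecar), sprintf("no labels sidecar at %s", sidecar))
  tab <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab <- tab[order(tab$order), ]
  maps <- lapply(file.path(dir, tab$file), function(p) {
    a <- RNifti::readNifti(p)
    array(as.numeric(a), dim = dim(a))
  })
  new("SpatialMapSet", maps = maps, labels = tab$label, mask = logical(0))
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion trace from a 6-column text file
#'
#' Accepts a whitespace- or tab-delimited file with one row per volume and
#' columns x, y, z (mm), roll, pitch, yaw (radians) — the layout of
#' realignment-parameter text files.
#'
#' @param path file path.
#' @return a [MotionTrace-class].
#' @export
readMotionTrace <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  stopIfNot(ncol(m) == 6L, "motion file must have 6 columns")
  colnames(m) <- c("x", "y", "z", "roll", "pitch", "yaw")
  new("MotionTrace", params = m)
}
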