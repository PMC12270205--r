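# File interfaces: NIfTI volumes for scans, saliency and atlas label maps;
# CSV for cohort, QC, and outcome tables.

#' Write volumes as NIfTI-1 files
#'
#' @param x Matrix of flattened volumes (one scan per row) or a single 3D
#'   array.
#' @param dims Spatial dimensions.
#' @param dir Output directory (created if needed).
#' @param ids Scan identifiers used as file names.
#' @param spacing Voxel spacing in mm per axis.
#' @return Invisibly, the written file paths.
#' @export
write_volumes_nifti <- function(x, dims, dir, ids = NULL,
                                spacing = c(1, 1, 1)) {
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- matrix(as.vector(x), nrow = 1L)
    dims <- dim(x)
  }
  if (is.null(ids)) ids <- sprintf("scan%04d", seq_len(nrow(x)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(ids, ".nii.gz"))
  for (i in seq_len(nrow(x))) {
    vol <- array(x[i, ], dims)
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = spacing), paths[i])
  }
  invisible(paths)
}

#' Read NIfTI volumes into a flattened matrix
#'
#' @param paths NIfTI file paths; all volumes must share a grid.
#' @return List: `x` (matrix, one flattened volume per row), `dims`.
#' @export
read_volumes_nifti <- function(paths) {
  vols <- lapply(paths, function(p) as.array(RNifti::readNifti(p)))
  dims <- dim(vols[[1]])
  for (v in vols) {
    if (!identical(dim(v), dims)) stop("volumes do not share a grid")
  }
  list(x = do.call(rbind, lapply(vols, as.vector)), dims = dims)
}

#' Write a cohort or outcome table as CSV
#'
#' @param table Data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort or outcome table from CSV
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
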