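#' 4D BOLD time series container
#'
#' Wraps a 4D numeric array (x, y, z, time) together with the acquisition
#' geometry needed downstream: voxel size in mm, repetition time in seconds,
#' and a 4x4 voxel-to-world affine (RAS, mm). If no affine is supplied, a
#' diagonal affine centred on the grid is constructed so that world
#' coordinates behave like MNI-style mm coordinates on synthetic data.
#'
#' @param data 4D numeric array, dimensions x, y, z, t.
#' @param voxel_mm voxel edge lengths in mm (length 1 or 3).
#' @param tr_s repetition time in seconds.
#' @param affine optional 4x4 voxel-to-world matrix (0-based voxel indices).
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, voxel_mm = c(3, 3, 3), tr_s = 2, affine = NULL) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array (x, y, z, t)")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(voxel_mm <= 0) || tr_s <= 0) stop("voxel size and TR must be positive")
  if (is.null(affine)) affine <- default_affine(dim(data)[1:3], voxel_mm)
  structure(list(data = data, voxel_mm = voxel_mm, tr_s = tr_s,
                 affine = affine),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_series> %d x %d x %d voxels, %d volumes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size %s mm, TR %.3g s\n",
              paste(format(x$voxel_mm), collapse = " x "), x$tr_s))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

n_volumes <- function(bold) dim(bold$data)[4]

#' 3D per-voxel statistic map
#'
#' Container for a voxelwise scalar statistic (Kendall's W, Fisher-z, CV,
#' t, ...) on the same grid as the BOLD data it came from. Values outside
#' the analysis mask are `NA`; in-mask voxels where the statistic is
#' undefined (e.g. a degenerate neighborhood) are also `NA` but remain
#' inside the mask, so "undefined" is never silently coded as zero.
#'
#' @param data 3D numeric array.
#' @param mask 3D logical array (defaults to all `TRUE`).
#' @param voxel_mm voxel size in mm.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(data, mask = NULL, voxel_mm = c(3, 3, 3), affine = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  if (!identical(dim(mask), dim(data))) stop("mask and data dimensions differ")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  data[!mask] <- NA_real_
  if (is.null(affine)) affine <- default_affine(dim(data), voxel_mm)
  structure(list(data = data, mask = mask, voxel_mm = voxel_mm,
                 affine = affine),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  d <- dim(x$data)
  v <- x$data[x$mask]
  cat(sprintf("<scalar_map> %d x %d x %d, %d in-mask voxels (%d undefined)\n",
              d[1], d[2], d[3], sum(x$mask), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  range %.4g .. %.4g\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(x)
}

default_affine <- function(grid, voxel_mm) {
  aff <- diag(c(voxel_mm, 1))
  aff[1:3, 4] <- -(grid - 1) / 2 * voxel_mm
  aff
}

# time x voxel matrix view of a 4D array
as_timeseries_matrix <- function(bold) {
  d <- dim(bold$data)
  t(matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4]))
}

matrix_to_bold <- function(mat, template) {
  d <- dim(template$data)
  arr <- array(t(mat), dim = c(d[1:3], nrow(mat)))
  bold_series(arr, voxel_mm = template$voxel_mm, tr_s = template$tr_s,
              affine = template$affine)
}

#' Convert voxel indices to world (MNI-style) coordinates
#'
#' @param index integer vector of length 3 (1-based voxel index) or an
#'   n x 3 matrix of indices.
#' @param affine 4x4 voxel-to-world matrix using 0-based voxel indices.
#' @return mm coordinates, same shape as the input.
#' @export
voxel_to_world <- function(index, affine) {
  ix <- if (is.matrix(index)) index else matrix(index, nrow = 1)
  xyz <- cbind(ix - 1, 1) %*% t(affine)
  out <- xyz[, 1:3, drop = FALSE]
  if (is.matrix(index)) out else drop(out)
}

#' Read a 4D BOLD NIfTI file
#'
#' @param path path to a .nii or .nii.gz file.
#' @param tr_s repetition time; if `NULL`, taken from the NIfTI header.
#' @return A [bold_series].
#' @export
read_bold <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (is.null(tr_s)) tr_s <- if (length(pd) >= 4) pd[4] else 2
  bold_series(unclass(img)[, , , , drop = FALSE], voxel_mm = pd[1:3],
              tr_s = tr_s, affine = unclass(RNifti::xform(img)))
}

#' Write a BOLD series as NIfTI-1
#' @param bold a [bold_series].
#' @param path output path (.nii or .nii.gz).
#' @export
write_bold <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_mm, bold$tr_s)
  RNifti::qform(img) <- structure(bold$affine, code = 2L)
  RNifti::sform(img) <- structure(bold$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D statistic/mask NIfTI file
#' @param path path to a .nii/.nii.gz file.
#' @param mask optional 3D logical mask.
#' @export
read_map <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- unclass(img)[, , , drop = TRUE]
  dim(arr) <- dim(arr)[1:3]
  scalar_map(arr, mask = mask, voxel_mm = RNifti::pixdim(img)[1:3],
             affine = unclass(RNifti::xform(img)))
}

#' Write a scalar map as NIfTI-1 (out-of-mask voxels become 0)
#' @param map a [scalar_map].
#' @param path output path.
#' @param na_value value substituted for `NA` voxels on disk.
#' @export
write_map <- function(map, path, na_value = 0) {
  arr <- map$data
  arr[is.na(arr)] <- na_value
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- map$voxel_mm
  RNifti::qform(img) <- structure(map$affine, code = 2L)
  RNifti::sform(img) <- structure(map$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Stack a list of scalar maps into a subjects x voxels matrix over a mask.
stack_maps <- function(maps, mask = NULL) {
  if (length(maps) == 0) stop("no maps supplied")
  if (is.null(mask)) mask <- maps[[1]]$mask
  do.call(rbind, lapply(maps, function(m) m$data[mask]))
}
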