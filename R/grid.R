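#' Partition a voxel grid into cubes
#'
#' Tiles a 3D voxel grid into axis-aligned cubes of side `cube_side`.
#' Cubes at the far end of a dimension keep only the remaining voxels,
#' so the tiling is always disjoint and complete. For the full
#' normalized infant template grid of 157 x 189 x 136 voxels and the
#' default side of 20 this yields 8 x 10 x 7 = 560 cubes.
#'
#' Axis convention used throughout the package: volume array axes
#' (i, j, k) with 1-based voxel indices; axial slices fix k, coronal
#' slices fix j, sagittal slices fix i.
#'
#' @param grid_shape integer 3-vector of voxel counts per axis.
#' @param cube_side cube side length in voxels (default 20).
#' @return data frame with one row per cube: block indices
#'   (`ix`, `iy`, `iz`, 1-based), origins (`ox`, `oy`, `oz`, 1-based
#'   voxel index of the cube's first voxel) and extents
#'   (`ex`, `ey`, `ez`).
#' @examples
#' nrow(partition_cubes(c(157, 189, 136), 20))  # 560
#' @export
partition_cubes <- function(grid_shape, cube_side = 20L) {
  grid_shape <- check_grid_shape(grid_shape)
  if (length(cube_side) != 1L || !is.finite(cube_side) || cube_side < 1)
    stop_config("cube_side must be a positive integer")
  cube_side <- as.integer(cube_side)
  nb <- ceiling(grid_shape / cube_side)
  idx <- expand.grid(ix = seq_len(nb[1]), iy = seq_len(nb[2]), iz = seq_len(nb[3]))
  origin <- (as.matrix(idx) - 1L) * cube_side + 1L
  extent <- pmin(matrix(grid_shape, nrow(idx), 3L, byrow = TRUE) - origin + 1L,
                 cube_side)
  out <- data.frame(idx,
                    ox = origin[, 1], oy = origin[, 2], oz = origin[, 3],
                    ex = extent[, 1], ey = extent[, 2], ez = extent[, 3])
  out$cube_id <- sprintf("c%d.%d.%d", out$ix, out$iy, out$iz)
  out
}

check_cube_in_volume <- function(volume, cube) {
  d <- dim(volume)
  if (length(d) != 3L)
    stop("volume must be a 3D array", call. = FALSE)
  if (cube$ox + cube$ex - 1L > d[1] || cube$oy + cube$ey - 1L > d[2] ||
      cube$oz + cube$ez - 1L > d[3] || any(c(cube$ox, cube$oy, cube$oz) < 1L))
    stop("cube lies outside the volume", call. = FALSE)
}

#' Slice a cube along the three orientations
#'
#' Extracts the cube's voxels from a volume and returns three ordered
#' stacks of 2D slices, one per orientation. Values are copied, never
#' resampled. An interior cube of extent 20^3 yields three stacks of
#' 20 slices of 20 x 20 pixels each.
#'
#' @param volume 3D numeric array.
#' @param cube one row of [partition_cubes()] (data frame or list).
#' @return named list of three slice stacks (`axial`, `coronal`,
#'   `sagittal`); each stack is a list with `cube`, `orientation` and
#'   `slices` (list of 2D matrices).
#' @export
slice_cube <- function(volume, cube) {
  check_cube_in_volume(volume, cube)
  xi <- cube$ox:(cube$ox + cube$ex - 1L)
  yi <- cube$oy:(cube$oy + cube$ey - 1L)
  zi <- cube$oz:(cube$oz + cube$ez - 1L)
  block <- volume[xi, yi, zi, drop = FALSE]
  stacks <- list(
    axial    = lapply(seq_len(cube$ez), function(s) matrix(block[, , s], cube$ex, cube$ey)),
    coronal  = lapply(seq_len(cube$ey), function(s) matrix(block[, s, ], cube$ex, cube$ez)),
    sagittal = lapply(seq_len(cube$ex), function(s) matrix(block[s, , ], cube$ey, cube$ez))
  )
  out <- lapply(ORIENTATIONS, function(o) {
    structure(list(cube = cube, orientation = o, slices = stacks[[o]]),
              class = "slice_stack")
  })
  names(out) <- ORIENTATIONS
  out
}

#' Map a slice-local pixel to its global voxel coordinate
#'
#' Inverse of the slicing indexing of [slice_cube()]. Pixel coordinates
#' follow the slice matrix layout: for axial slices (fixed k) rows run
#' along i and columns along j; coronal (fixed j) rows i, columns k;
#' sagittal (fixed i) rows j, columns k. All indices are 1-based; pixel
#' coordinates may be fractional (sub-pixel keypoint centers).
#'
#' @param cube one row of [partition_cubes()].
#' @param orientation `"axial"`, `"coronal"` or `"sagittal"`.
#' @param slice_index 1-based slice index within the cube.
#' @param pixel length-2 numeric (row, column) within the slice.
#' @return numeric 3-vector (i, j, k) of global voxel coordinates.
#' @export
local_to_global <- function(cube, orientation, slice_index, pixel) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  ext <- switch(orientation,
    axial    = c(cube$ex, cube$ey, cube$ez),
    coronal  = c(cube$ex, cube$ez, cube$ey),
    sagittal = c(cube$ey, cube$ez, cube$ex))
  if (slice_index < 1 || slice_index > ext[3] ||
      pixel[1] < 1 || pixel[1] > ext[1] || pixel[2] < 1 || pixel[2] > ext[2])
    stop("pixel/slice index outside cube extents", call. = FALSE)
  o <- c(cube$ox, cube$oy, cube$oz) - 1
  switch(orientation,
    axial    = o + c(pixel[1], pixel[2], slice_index),
    coronal  = o + c(pixel[1], slice_index, pixel[2]),
    sagittal = o + c(slice_index, pixel[1], pixel[2]))
}

#' Map a global voxel coordinate to its cube, slice and pixel
#'
#' Inverse of [local_to_global()] under a given cube partition.
#'
#' @param voxel integer 3-vector (i, j, k), 1-based.
#' @param grid_shape grid the partition was built on.
#' @param cube_side cube side length.
#' @param orientation slicing orientation.
#' @return list with `cube_index` (block indices), `slice_index`, `pixel`.
#' @export
global_to_local <- function(voxel, grid_shape, cube_side = 20L,
                            orientation = "axial") {
  orientation <- match.arg(orientation, ORIENTATIONS)
  grid_shape <- check_grid_shape(grid_shape)
  if (any(voxel < 1) || any(voxel > grid_shape))
    stop("voxel outside grid", call. = FALSE)
  block <- (voxel - 1) %/% cube_side + 1
  local <- (voxel - 1) %% cube_side + 1
  switch(orientation,
    axial    = list(cube_index = block, slice_index = local[3], pixel = local[1:2]),
    coronal  = list(cube_index = block, slice_index = local[2], pixel = local[c(1, 3)]),
    sagittal = list(cube_index = block, slice_index = local[1], pixel = local[2:3]))
}

#' Read a NIfTI volume as a plain array
#'
#' @param path path to a NIfTI-1 file.
#' @return 3D numeric array; the NIfTI affine is kept in the
#'   `"affine"` attribute but all geometry in this package operates in
#'   voxel space.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "affine") <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  arr
}

#' Write a plain array as a NIfTI volume
#'
#' @param volume 3D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}
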