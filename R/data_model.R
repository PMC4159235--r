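# Core domain types: atlas volumes, subject time series, motion traces,
# region specifications. All are plain lists with S3 classes and validators,
# the container style used across this package.

#' Construct an atlas volume
#'
#' An atlas volume pairs a 3D integer label grid (0 = background) with a
#' 4x4 voxel-to-mm affine and a label table mapping integer ids to region
#' names. Voxel indices are 0-based when passed through the affine; mm
#' coordinates refer to voxel centers.
#'
#' @param labels 3D integer array of region labels, 0 for background.
#' @param affine 4x4 numeric voxel-to-mm transform (applied to 0-based
#'   voxel indices).
#' @param label_table named integer vector or data.frame with columns
#'   \code{id}, \code{name}; ids present in the table but absent from the
#'   grid are kept and flagged.
#' @return An object of class \code{atlas_volume} with elements
#'   \code{labels}, \code{affine}, \code{label_table} (data.frame with
#'   \code{id}, \code{name}, \code{present}).
#' @export
atlas_volume <- function(labels, affine, label_table = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  if (any(labels < 0))
    stop("atlas labels must be >= 0")
  if (any(labels != round(labels)))
    stop("atlas labels must be integers")
  affine <- check_affine(affine)
  ids_in_grid <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(label_table)) {
    label_table <- data.frame(id = ids_in_grid,
                              name = paste0("region_", ids_in_grid),
                              stringsAsFactors = FALSE)
  } else if (!is.data.frame(label_table)) {
    label_table <- data.frame(id = as.integer(label_table),
                              name = names(label_table),
                              stringsAsFactors = FALSE)
  }
  label_table$id <- as.integer(label_table$id)
  label_table$present <- label_table$id %in% ids_in_grid
  structure(list(labels = labels, affine = affine,
                 label_table = label_table),
            class = "atlas_volume")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("affine must be invertible")
  affine
}

#' Construct a subject time-series container
#'
#' Holds the seed-ROI voxel series and the target (rest-of-brain) voxel
#' series of one subject on a shared, study-wide voxel ordering.
#'
#' @param roi_series numeric matrix, seed voxels x frames.
#' @param target_series numeric matrix, target voxels x frames.
#' @param roi_coords,target_coords integer matrices (voxels x 3) of 0-based
#'   grid coordinates; optional for purely matrix-based workflows.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id identifier string.
#' @return Object of class \code{subject_timeseries}.
#' @export
subject_timeseries <- function(roi_series, target_series,
                               roi_coords = NULL, target_coords = NULL,
                               tr_seconds, subject_id = "sub-01") {
  roi_series <- as.matrix(roi_series)
  target_series <- as.matrix(target_series)
  if (ncol(roi_series) != ncol(target_series))
    stop("roi and target series must share the number of frames")
  if (ncol(roi_series) < 2L)
    stop("need at least 2 frames")
  if (!all(is.finite(roi_series)) || !all(is.finite(target_series)))
    stop("time series contain non-finite values")
  if (!is.null(roi_coords)) {
    roi_coords <- as.matrix(roi_coords)
    stopifnot(nrow(roi_coords) == nrow(roi_series), ncol(roi_coords) == 3L)
  }
  if (!is.null(target_coords)) {
    target_coords <- as.matrix(target_coords)
    stopifnot(nrow(target_coords) == nrow(target_series),
              ncol(target_coords) == 3L)
  }
  structure(list(roi_series = roi_series, target_series = target_series,
                 roi_coords = roi_coords, target_coords = target_coords,
                 tr_seconds = tr_seconds, subject_id = subject_id),
            class = "subject_timeseries")
}

#' Construct a motion trace
#'
#' A frames x 6 matrix of rigid-body realignment parameters: three
#' translations in mm followed by three rotations in radians.
#'
#' @param params numeric matrix with 6 columns.
#' @return Object of class \code{motion_trace} (a matrix with column names
#'   \code{trans_x..rot_z}).
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L)
    stop("motion trace must have 6 columns (3 translations, 3 rotations)")
  if (!all(is.finite(params)))
    stop("motion trace contains non-finite values")
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(params, class = c("motion_trace", "matrix", "array"))
}

#' Specify a region by atlas labels and/or an mm bounding box
#'
#' A region specification selects voxels by atlas label id and, optionally,
#' by a strict mm bounding box on voxel centers (all six inequalities are
#' strict, e.g. lo < x < hi). Used to assemble seed and target masks,
#' including the midbrain box of the rest-of-brain mask.
#'
#' @param ids integer vector of atlas label ids (may be empty).
#' @param box optional numeric vector of mm bounds
#'   \code{c(x_lo, x_hi, y_lo, y_hi, z_lo, z_hi)}.
#' @param exclude_ids labels whose voxels are removed from the result even
#'   when captured by the box (typically the seed-ROI labels).
#' @param allow_absent if FALSE (default), ids missing from the atlas's
#'   label table raise an error.
#' @return Object of class \code{region_spec}.
#' @export
region_spec <- function(ids = integer(0), box = NULL,
                        exclude_ids = integer(0), allow_absent = FALSE) {
  ids <- as.integer(ids)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 6L)
      stop("box must be c(x_lo, x_hi, y_lo, y_hi, z_lo, z_hi)")
    if (any(box[c(1, 3, 5)] >= box[c(2, 4, 6)]))
      stop("box bounds must satisfy lo < hi")
  }
  structure(list(ids = ids, box = box,
                 exclude_ids = as.integer(exclude_ids),
                 allow_absent = isTRUE(allow_absent)),
            class = "region_spec")
}

#' Read a region specification from JSON or YAML
#'
#' @param path file with fields \code{ids}, optional \code{box},
#'   \code{exclude_ids}, \code{allow_absent}.
#' @return A \code{\link{region_spec}}.
#' @export
read_region_spec <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  region_spec(ids = x$ids %||% integer(0), box = x$box,
              exclude_ids = x$exclude_ids %||% integer(0),
              allow_absent = x$allow_absent %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return list with \code{data} (3D or 4D array) and \code{affine}
#'   (4x4 voxel-to-mm matrix, 0-based voxel indices).
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("cannot read NIfTI volume '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = matrix(as.numeric(RNifti::xform(img)), 4L, 4L))
}

#' Write a NIfTI volume
#'
#' Integer-valued arrays are stored with an integer datatype so label
#' volumes round-trip bit-exactly.
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(data, affine, path) {
  affine <- check_affine(affine)
  is_int <- all(data == round(data)) && max(abs(data)) < 2^31
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (is_int) "int32" else "double")
  invisible(path)
}

#' Read / write a motion trace as 6-column TSV
#'
#' @param path TSV file with header columns
#'   \code{trans_x trans_y trans_z rot_x rot_y rot_z} (mm / radians).
#' @return \code{read_motion_tsv}: a \code{\link{motion_trace}}.
#' @export
read_motion_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  motion_trace(as.matrix(tab))
}

#' @rdname read_motion_tsv
#' @param motion a \code{\link{motion_trace}}.
#' @export
write_motion_tsv <- function(motion, path) {
  utils::write.table(as.data.frame(unclass(motion)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a boolean region mask from an atlas and a region spec
#'
#' The mask is the union of (i) voxels whose atlas label is in
#' \code{spec$ids} and (ii) voxels whose mm center lies strictly inside
#' \code{spec$box}; voxels labeled with any of \code{spec$exclude_ids} are
#' then removed. Adding ids to a spec never removes voxels.
#'
#' @param atlas an \code{\link{atlas_volume}}.
#' @param spec a \code{\link{region_spec}}.
#' @return logical 3D array with the atlas's dimensions.
#' @export
build_region_mask <- function(atlas, spec) {
  stopifnot(inherits(atlas, "atlas_volume"), inherits(spec, "region_spec"))
  known <- atlas$label_table$id
  missing_ids <- setdiff(spec$ids, known)
  if (length(missing_ids) && !spec$allow_absent)
    stop(sprintf("region ids not in atlas label table: %s",
                 paste(missing_ids, collapse = ", ")))
  mask <- array(FALSE, dim(atlas$labels))
  if (length(spec$ids))
    mask <- mask | array(atlas$labels %in% spec$ids, dim(atlas$labels))
  if (!is.null(spec$box)) {
    mm <- voxel_centers_mm(dim(atlas$labels), atlas$affine)
    b <- spec$box
    inside <- mm[, 1] > b[1] & mm[, 1] < b[2] &
      mm[, 2] > b[3] & mm[, 2] < b[4] &
      mm[, 3] > b[5] & mm[, 3] < b[6]
    mask <- mask | array(inside, dim(atlas$labels))
  }
  if (length(spec$exclude_ids))
    mask[atlas$labels %in% spec$exclude_ids] <- FALSE
  if (!any(mask))
    stop("region specification produced an empty mask")
  mask
}

# mm centers of every voxel of a grid, rows in column-major voxel order,
# voxel indices 0-based.
voxel_centers_mm <- function(dims, affine) {
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1L,
                               y = seq_len(dims[2]) - 1L,
                               z = seq_len(dims[3]) - 1L))
  mm <- cbind(idx, 1) %*% t(affine)
  mm[, 1:3, drop = FALSE]
}

#' 0-based voxel coordinates of the TRUE voxels of a mask
#'
#' @param mask logical 3D array.
#' @return integer matrix (n x 3), rows in column-major order.
#' @export
mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  storage.mode(w) <- "integer"
  w - 1L
}

#' Resample a boolean mask onto another grid by nearest neighbor
#'
#' Each destination voxel center is mapped through the destination affine
#' into mm and back through the inverse source affine; the nearest source
#' voxel (rounded index) decides the destination value.
#'
#' @param mask logical 3D array on the source grid.
#' @param affine_src,affine_dst 4x4 voxel-to-mm affines.
#' @param dims_dst integer vector of 3 destination dimensions.
#' @return logical 3D array of dimensions \code{dims_dst}.
#' @export
resample_mask <- function(mask, affine_src, affine_dst, dims_dst) {
  affine_src <- check_affine(affine_src)
  affine_dst <- check_affine(affine_dst)
  mm <- voxel_centers_mm(dims_dst, affine_dst)
  src_idx <- round(cbind(mm, 1) %*% t(solve(affine_src)))[, 1:3, drop = FALSE]
  inside <- src_idx[, 1] >= 0 & src_idx[, 1] < dim(mask)[1] &
    src_idx[, 2] >= 0 & src_idx[, 2] < dim(mask)[2] &
    src_idx[, 3] >= 0 & src_idx[, 3] < dim(mask)[3]
  out <- rep(FALSE, prod(dims_dst))
  lin <- 1L + src_idx[inside, 1] + dim(mask)[1] *
    (src_idx[inside, 2] + dim(mask)[2] * src_idx[inside, 3])
  out[inside] <- mask[lin]
  array(out, dims_dst)
}
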