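#' @keywords internal
"_PACKAGE"

# ---- grid geometry and voxel indexing --------------------------------------
#
# Convention used throughout the package: voxel coordinates (i, j, k) are
# 0-based; the scalar "linear index" of a voxel is 0-based with i varying
# fastest (column-major, R's native array order):
#   index = i + dim[1] * (j + dim[2] * k).
# This order is fixed so that serialized ROI voxel lists are reproducible.
# TRs are 1-based in every user-facing report and in all R vectors.

#' Grid geometry
#'
#' Bundle of array dimensions and a 4x4 voxel-to-world affine. Voxel (i,j,k)
#' (0-based) maps to world mm coordinates `affine %*% c(i,j,k,1)`.
#'
#' @param dim integer length-3 array dimensions
#' @param affine 4x4 numeric voxel-to-world matrix
#' @return an object of class `grid_geometry`
#' @export
grid_geometry <- function(dim, affine) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1),
            is.matrix(affine), all(dim(affine) == c(4, 4)))
  structure(list(dim = dim, affine = affine), class = "grid_geometry")
}

#' Default grid geometry for an isotropic voxel size
#'
#' Affine places the grid centre at the world origin, axes aligned.
#'
#' @param dim length-3 dimensions
#' @param voxel_mm isotropic voxel size in mm
#' @return `grid_geometry`
#' @export
default_grid <- function(dim = c(24L, 24L, 18L), voxel_mm = 2) {
  dim <- as.integer(dim)
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (dim - 1) / 2
  grid_geometry(dim, aff)
}

#' Convert 0-based voxel coordinates to 0-based linear indices
#' @param ijk n x 3 matrix of 0-based voxel coordinates
#' @param dim grid dimensions
#' @return integer vector of 0-based linear indices (i fastest)
#' @export
vox_to_index <- function(ijk, dim) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  as.integer(ijk[, 1] + dim[1] * (ijk[, 2] + dim[2] * ijk[, 3]))
}

#' Convert 0-based linear indices back to voxel coordinates
#' @param idx 0-based linear indices
#' @param dim grid dimensions
#' @return n x 3 integer matrix of 0-based (i,j,k)
#' @export
index_to_vox <- function(idx, dim) {
  idx <- as.integer(idx)
  i <- idx %% dim[1]
  j <- (idx %/% dim[1]) %% dim[2]
  k <- idx %/% (dim[1] * dim[2])
  cbind(i = i, j = j, k = k)
}

#' World-mm coordinates of voxel centres
#' @param ijk n x 3 matrix of 0-based voxel coordinates
#' @param grid `grid_geometry`
#' @return n x 3 matrix of world coordinates (mm)
#' @export
vox_to_world <- function(ijk, grid) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

# ---- BoldRun ---------------------------------------------------------------

#' A single subject's 4D BOLD run
#'
#' @param data 4D numeric array (x, y, z, t)
#' @param tr_s repetition time in seconds
#' @param affine 4x4 voxel-to-world matrix
#' @param subject_id subject identifier
#' @param run_label run label (e.g. "movie", "localizer")
#' @return object of class `bold_run`
#' @export
bold_run <- function(data, tr_s, affine = diag(4), subject_id = "unknown",
                     run_label = "run") {
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[4] < 2) stop("a bold_run needs at least 2 volumes")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("tr_s must be positive")
  if (!all(is.finite(data))) stop("input BOLD data must be finite")
  structure(list(data = data, tr_s = tr_s, affine = affine,
                 subject_id = subject_id, run_label = run_label),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %s/%s: %dx%dx%d grid, %d TRs, TR=%gs\n",
              x$subject_id, x$run_label, d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

#' Read a 4D NIfTI BOLD run
#'
#' TR is taken from the NIfTI header; a `tr_s` argument overrides it (headers
#' of converted pediatric datasets are often wrong), with a warning when the
#' two disagree or the header value is unusable.
#'
#' @param path path to a 4D `.nii`/`.nii.gz` file
#' @param tr_s optional TR override in seconds
#' @param subject_id,run_label labels stored on the result
#' @return `bold_run`
#' @export
read_bold <- function(path, tr_s = NULL, subject_id = "unknown",
                      run_label = "run") {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(dim(img)) != 4)
    stop("expected 4D volume, got ", length(dim(img)), "D: ", path)
  hdr_tr <- RNifti::pixdim(img)[4]
  if (is.null(tr_s)) {
    if (!is.finite(hdr_tr) || hdr_tr <= 0)
      stop("header TR unusable (", hdr_tr, ") and no tr_s given: ", path)
    tr_s <- hdr_tr
  } else if (!isTRUE(all.equal(hdr_tr, tr_s))) {
    warning(sprintf("TR override: header says %g s, using %g s (%s)",
                    hdr_tr, tr_s, path))
  }
  bold_run(array(as.numeric(img), dim = dim(img)), tr_s = tr_s,
           affine = nifti_affine(img), subject_id = subject_id,
           run_label = run_label)
}

nifti_affine <- function(img) {
  x <- structure(RNifti::xform(img), dimnames = NULL)
  matrix(as.numeric(x), 4, 4)
}

#' Write a BOLD run (or plain 3D/4D array) as NIfTI
#' @param x `bold_run`, or numeric/logical array
#' @param path output path
#' @param grid `grid_geometry` used for the affine when `x` is a bare array
#' @export
write_bold <- function(x, path, grid = NULL) {
  if (inherits(x, "bold_run")) {
    img <- RNifti::asNifti(x$data)
    img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
    pd <- RNifti::pixdim(img); pd[4] <- x$tr_s
    RNifti::pixdim(img) <- pd
  } else {
    img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)))
    if (!is.null(grid))
      img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- Parcel ----------------------------------------------------------------

#' A parcel (search-space mask) on the cohort grid
#'
#' @param mask 3D logical array
#' @param label region label, e.g. "FFA"
#' @return object of class `parcel`
#' @export
parcel <- function(mask, label = "parcel") {
  stopifnot(length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim = dim(mask))
  n <- sum(mask)
  if (n < 1) stop("parcel '", label, "' is empty")
  structure(list(mask = mask, label = label, n_voxels = n), class = "parcel")
}

#' @export
print.parcel <- function(x, ...) {
  cat(sprintf("<parcel> %s: %d voxels on %s grid\n", x$label, x$n_voxels,
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' 0-based linear indices of a parcel's voxels (ascending)
#' @param p `parcel`
#' @return integer vector
#' @export
parcel_indices <- function(p) {
  sort(which(p$mask) - 1L)
}

#' Read a binary mask as a parcel
#' @param path NIfTI path
#' @param label region label
#' @export
read_parcel <- function(path, label = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("expected 3D mask: ", path)
  parcel(array(img != 0, dim = dim(img)), label = label)
}

#' Spherical parcel around a world-space peak
#'
#' A voxel belongs to the sphere iff its centre lies within `radius_mm` of
#' `center_world`. Used e.g. to build an early-visual-cortex search space
#' from published peak coordinates.
#'
#' @param center_world length-3 world coordinates (mm)
#' @param radius_mm sphere radius (mm), > 0
#' @param grid `grid_geometry`
#' @param label region label
#' @return `parcel`
#' @export
make_sphere_parcel <- function(center_world, radius_mm, grid, label = "sphere") {
  stopifnot(radius_mm > 0, length(center_world) == 3)
  d <- grid$dim
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  w <- vox_to_world(ijk, grid)
  keep <- sqrt(rowSums(sweep(w, 2, as.numeric(center_world))^2)) <= radius_mm
  if (!any(keep)) stop("sphere of radius ", radius_mm,
                       " mm contains no voxel centres")
  mask <- array(FALSE, dim = d)
  mask[ijk[keep, , drop = FALSE] + 1L] <- TRUE
  parcel(mask, label = label)
}

#' Union of two parcels
#' @param a,b parcels on the same grid
#' @param label label for the result
#' @export
parcel_union <- function(a, b, label = paste(a$label, b$label, sep = "+")) {
  stopifnot(all(dim(a$mask) == dim(b$mask)))
  parcel(a$mask | b$mask, label = label)
}

# ---- tabular IO ------------------------------------------------------------

#' Write named timecourses as a TSV (one TR per row)
#'
#' Missing entries are rendered as the literal `NA`; round-trips losslessly
#' with [read_timecourse_table()].
#'
#' @param tcs named list (or matrix with column names) of equal-length
#'   numeric timecourses
#' @param path output path
#' @export
write_timecourse_table <- function(tcs, path) {
  if (is.matrix(tcs)) tcs <- as.data.frame(tcs)
  if (length(tcs) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  lens <- vapply(tcs, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("all timecourses must have the same length")
  df <- as.data.frame(lapply(tcs, as.numeric), check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, nsmall = 0),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a timecourse TSV written by [write_timecourse_table()]
#' @param path TSV path
#' @return named list of numeric vectors (possibly empty)
#' @export
read_timecourse_table <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0 || !nzchar(first)) return(list())
  df <- utils::read.delim(path, check.names = FALSE)
  lapply(df, as.numeric)
}

#' Read a 6-column motion parameter TSV
#'
#' Columns: trans_x, trans_y, trans_z (mm), rot_x, rot_y, rot_z (radians),
#' one row per TR.
#' @param path TSV path
#' @return T x 6 numeric matrix with those column names
#' @export
read_motion <- function(path) {
  df <- utils::read.delim(path)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(need %in% names(df)))
    stop("motion file must have columns ", paste(need, collapse = ", "))
  as.matrix(df[, need])
}

#' Write motion parameters
#' @param motion T x 6 matrix (see [read_motion()])
#' @param path output path
#' @export
write_motion <- function(motion, path) {
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  utils::write.table(as.data.frame(motion), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a block-design timing table
#'
#' TSV with columns condition, onset_s, duration_s. Onsets must be
#' non-negative and non-decreasing within condition; durations positive.
#' @param path TSV path
#' @return data.frame of class `block_timing`
#' @export
read_block_timing <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  block_timing(df)
}

#' Construct / validate a block timing table
#' @param df data.frame with condition, onset_s, duration_s
#' @export
block_timing <- function(df) {
  need <- c("condition", "onset_s", "duration_s")
  if (!all(need %in% names(df))) stop("timing needs columns ",
                                      paste(need, collapse = ", "))
  if (any(df$onset_s < 0)) stop("onsets must be non-negative")
  if (any(df$duration_s <= 0)) stop("durations must be positive")
  for (cond in unique(df$condition)) {
    o <- df$onset_s[df$condition == cond]
    if (is.unsorted(o)) stop("onsets must be non-decreasing within condition")
  }
  class(df) <- c("block_timing", "data.frame")
  df
}

#' Write a block timing table
#' @param timing `block_timing` data.frame
#' @param path output path
#' @export
write_block_timing <- function(timing, path) {
  utils::write.table(as.data.frame(timing)[, c("condition", "onset_s",
                                               "duration_s")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- ssROI serialization ---------------------------------------------------

#' Subject-specific ROI
#'
#' An ordered set of at most `k` voxels inside a named parcel, tagged by the
#' definition method.
#'
#' @param label region label
#' @param method one of traditional, counter, movie, movie_half_A,
#'   movie_half_B
#' @param voxels ordered 0-based linear voxel indices
#' @param k requested size
#' @param parcel_label label of the parcel the voxels come from
#' @export
ssroi <- function(label, method, voxels, k, parcel_label = label) {
  method <- match.arg(method, c("traditional", "counter", "movie",
                                "movie_half_A", "movie_half_B"))
  voxels <- as.integer(voxels)
  if (anyDuplicated(voxels)) stop("duplicate voxels in ssROI")
  if (length(voxels) > k) stop("ssROI larger than requested k")
  structure(list(label = label, method = method, voxels = voxels,
                 k = as.integer(k), parcel_label = parcel_label),
            class = "ssroi")
}

#' @export
print.ssroi <- function(x, ...) {
  cat(sprintf("<ssroi> %s (%s): %d/%d voxels in parcel %s\n",
              x$label, x$method, length(x$voxels), x$k, x$parcel_label))
  invisible(x)
}

#' Write one or more ssROIs to JSON
#' @param rois an `ssroi` or list of them
#' @param path output path
#' @export
write_ssroi_json <- function(rois, path) {
  if (inherits(rois, "ssroi")) rois <- list(rois)
  payload <- lapply(rois, function(r)
    list(label = r$label, method = r$method, k = r$k,
         parcel_label = r$parcel_label, voxels = r$voxels))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ssROIs from JSON
#' @param path JSON path
#' @return list of `ssroi`
#' @export
read_ssroi_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i)
    ssroi(payload$label[i], payload$method[i],
          unlist(payload$voxels[i]), payload$k[i], payload$parcel_label[i]))
}
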