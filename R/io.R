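#' Read a NIfTI-1 volume
#'
#' Thin wrapper over RNifti that returns the data array together with the
#' voxel-to-world affine (sform preferred over qform, RNifti's `xform`
#' precedence).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (array) and `affine` (4 x 4 matrix).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    abort(paste("file not found:", path), class = "cortexdti_format_error")
  }
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)), error = function(e) {
    abort(paste("not a readable NIfTI file:", conditionMessage(e)),
          class = "cortexdti_format_error")
  })
  hdr <- RNifti::niftiHeader(img)
  aff <- if (hdr$sform_code > 0) {
    rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  } else {
    unclass(structure(RNifti::xform(img), code = NULL))
  }
  dimnames(aff) <- NULL
  list(data = array(as.numeric(img), dim(img)), affine = aff[1:4, 1:4])
}

#' Write a NIfTI-1 volume
#'
#' @param data Numeric array (3-D or 4-D).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 voxel-to-world affine stored as both sform and qform.
#' @param description Free-text header description (e.g. the tensor
#'   component order).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), description = "") {
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  if (nzchar(description)) {
    img <- RNifti::asNifti(img, list(descrip = substr(description, 1, 79)))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a tensor field to NIfTI
#'
#' Stores the six tensor components as a 4-D volume in lower-triangular
#' order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz) — declared in the header
#' description — plus sidecar S0 and degenerate-mask volumes.
#'
#' @param tensors A [tensor_field()].
#' @param prefix Output path prefix; writes `<prefix>_tensor.nii.gz`,
#'   `<prefix>_S0.nii.gz`, `<prefix>_degenerate.nii.gz`.
#' @return Named character vector of the paths written.
#' @export
write_tensor_nifti <- function(tensors, prefix) {
  stopifnot(inherits(tensors, "tensor_field"))
  paths <- c(
    tensor = paste0(prefix, "_tensor.nii.gz"),
    S0 = paste0(prefix, "_S0.nii.gz"),
    degenerate = paste0(prefix, "_degenerate.nii.gz")
  )
  write_nifti(tensors$D, paths["tensor"], tensors$affine,
              "lower-triangular Dxx Dxy Dyy Dxz Dyz Dzz (mm^2/s)")
  S0 <- tensors$S0; S0[is.na(S0)] <- 0
  write_nifti(S0, paths["S0"], tensors$affine)
  write_nifti(array(as.numeric(tensors$degenerate), dim(tensors$degenerate)),
              paths["degenerate"], tensors$affine)
  paths
}

#' Read an FSL-dialect gradient table
#'
#' bvals: one whitespace-separated row of b-values. bvecs: three rows (x, y,
#' z components in image coordinates), one column per volume. Directions
#' with b > 0 are renormalised to unit length with a warning if needed;
#' zero vectors with b > 0 are an error.
#'
#' @param bval_path,bvec_path File paths.
#' @param b0_threshold b-values below this are treated as baselines.
#' @return List with `bvals` and `bvecs` (3 x n).
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path, b0_threshold = 50) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L) {
    abort("bvec file must have 3 rows (FSL dialect)", class = "cortexdti_format_error")
  }
  if (ncol(bvecs) != length(bvals)) {
    abort(sprintf("gradient table mismatch: %d bvals vs %d bvecs",
                  length(bvals), ncol(bvecs)),
          class = "cortexdti_format_error")
  }
  dw <- which(bvals >= b0_threshold)
  if (length(dw)) {
    norms <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
    if (any(norms < 1e-8)) {
      abort("zero gradient vector on a diffusion-weighted volume",
            class = "cortexdti_format_error")
    }
    if (any(abs(norms - 1) > 1e-3)) {
      warn("non-unit gradient vectors renormalised")
    }
    bvecs[, dw] <- sweep(bvecs[, dw, drop = FALSE], 2L, norms, "/")
  }
  dimnames(bvecs) <- NULL
  list(bvals = bvals, bvecs = bvecs)
}

#' Write an FSL-dialect gradient table
#'
#' @param bvals,bvecs Gradient table as from [gradient_scheme()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bval_path)
  write.table(format(bvecs, trim = TRUE), bvec_path, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(c(bval_path, bvec_path))
}

#' Write / read a region-code sidecar
#'
#' JSON mapping of integer parcel codes to region names accompanying a
#' parcellation volume.
#'
#' @param lookup Tibble with `region_code` and `region` columns.
#' @param path JSON path.
#' @return `read_region_sidecar` returns the lookup tibble.
#' @export
write_region_sidecar <- function(lookup, path) {
  jsonlite::write_json(setNames(as.list(lookup$region),
                                as.character(lookup$region_code)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_region_sidecar
#' @export
read_region_sidecar <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble(region_code = as.integer(names(m)), region = unname(unlist(m)))
}
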