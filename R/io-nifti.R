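#' Read a NIfTI volume
#'
#' World coordinates follow the NIfTI RAS convention with 0-based voxel
#' indices. Label volumes are validated as integer-valued and are never
#' interpolated downstream.
#'
#' @param path Path to a .nii / .nii.gz file.
#' @param type "metric" or "label".
#' @return An `fw_volume`.
#' @export
read_volume <- function(path, type = c("metric", "label")) {
  type <- match.arg(type)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) abort(sprintf(
                    "Failed to read NIfTI file '%s': %s", path,
                    conditionMessage(e))))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  data <- as.array(img)
  attributes(data) <- list(dim = dim(img))
  if (type == "label") {
    if (any(data[is.finite(data)] %% 1 != 0)) {
      abort("Non-integer data cannot be read as a label volume.")
    }
    storage.mode(data) <- "integer"
  }
  fw_volume(data, aff, type = type)
}

#' Write an `fw_volume` to NIfTI
#'
#' Integer label data are stored as integers so labels round-trip
#' bit-exactly; the affine is written to both sform and qform.
#'
#' @param vol An `fw_volume`.
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "fw_volume"))
  data <- vol$data
  if (vol$type == "label") storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an FSL-style gradient table
#'
#' @param scheme A diffusion scheme.
#' @param prefix Output prefix; writes `<prefix>.bval` and `<prefix>.bvec`.
#' @return The two paths, invisibly.
#' @export
write_scheme <- function(scheme, prefix) {
  validate_scheme(scheme)
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval)
  writeLines(apply(t(scheme$bvecs), 1, function(rw)
    paste(sprintf("%.9g", rw), collapse = " ")), bvec)
  invisible(c(bval, bvec))
}

#' Read an FSL-style gradient table
#'
#' @param prefix Prefix of `<prefix>.bval` / `<prefix>.bvec` files.
#' @return A `diffusion_scheme`.
#' @export
read_scheme <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bv <- scan(paste0(prefix, ".bvec"), quiet = TRUE)
  bvecs <- t(matrix(bv, nrow = 3, byrow = TRUE))
  structure(list(bvals = bvals, bvecs = bvecs), class = "diffusion_scheme")
}
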