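#' Read a streamline bundle (TRK or TCK)
#'
#' Points are converted to world RAS mm whatever the on-disk convention:
#' TRK stores points in "voxmm" space under the header affine and voxel
#' order (version-2 headers required), TCK stores world mm directly.
#'
#' @param path Path ending in .trk or .tck.
#' @param tract Tract name (default: file stem).
#' @param hemisphere Hemisphere label for the returned bundle.
#' @return A `tract_bundle`.
#' @export
read_bundle <- function(path, tract = NULL, hemisphere = "left") {
  ext <- tolower(tools::file_ext(path))
  tract <- tract %||% tools::file_path_sans_ext(basename(path))
  sls <- switch(ext,
    trk = read_trk(path),
    tck = read_tck(path),
    abort(sprintf("Unknown streamline format '.%s'; supported: .trk, .tck",
                  ext)))
  if (length(sls$streamlines) == 0) {
    abort(sprintf("'%s' contains no streamlines.", path))
  }
  tract_bundle(sls$streamlines, tract = tract, hemisphere = hemisphere,
               affine = sls$affine, ref_dim = sls$ref_dim)
}

#' Write a streamline bundle (TRK or TCK)
#'
#' @param bundle A `tract_bundle` (points in world RAS mm).
#' @param path Output path ending in .trk or .tck.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    trk = write_trk(bundle, path),
    tck = write_tck(bundle, path),
    abort(sprintf("Unknown streamline format '.%s'; supported: .trk, .tck",
                  ext)))
  invisible(path)
}

# ---- TRK (TrackVis) ---------------------------------------------------

# orientation letters of an affine's voxel axes
affine_voxel_order <- function(affine) {
  pos <- c("R", "A", "S"); neg <- c("L", "P", "I")
  rot <- affine[1:3, 1:3]
  paste(vapply(1:3, function(j) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] >= 0) pos[i] else neg[i]
  }, character(1)), collapse = "")
}

write_trk <- function(bundle, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  aff <- bundle$affine
  vs <- voxel_size(aff)
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(raw(1), con)
  writeBin(as.integer(bundle$ref_dim), con, size = 2)
  writeBin(as.numeric(vs), con, size = 4)
  writeBin(numeric(3), con, size = 4)                 # origin (unused)
  writeBin(0L, con, size = 2)                         # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2)                         # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(aff)), con, size = 4)         # vox_to_ras row-major
  writeBin(raw(444), con)
  vo <- affine_voxel_order(aff)
  writeChar(vo, con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                               # pad2
  writeBin(numeric(6), con, size = 4)                 # image_orientation
  writeBin(raw(2), con)                               # pad1
  writeBin(raw(6), con)                               # invert/swap flags
  writeBin(length(bundle$streamlines), con, size = 4)
  writeBin(2L, con, size = 4)                         # version
  writeBin(1000L, con, size = 4)                      # hdr_size
  inv <- solve(aff)
  for (sl in bundle$streamlines) {
    vox <- cbind(sl, 1) %*% t(inv)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, vs, `*`)
    writeBin(nrow(sl), con, size = 4)
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, raw(), 6)
  if (!identical(rawToChar(id[1:5]), "TRACK")) {
    abort("Not a TRK file (bad id string).")
  }
  dim3 <- readBin(con, integer(), 3, size = 2)
  vs <- readBin(con, numeric(), 3, size = 4)
  invisible(readBin(con, numeric(), 3, size = 4))     # origin
  n_scalars <- readBin(con, integer(), 1, size = 2)
  invisible(readBin(con, raw(), 200))
  n_props <- readBin(con, integer(), 1, size = 2)
  invisible(readBin(con, raw(), 200))
  aff <- matrix(readBin(con, numeric(), 16, size = 4), 4, 4, byrow = TRUE)
  invisible(readBin(con, raw(), 444))
  invisible(readBin(con, raw(), 4))                   # voxel_order
  invisible(readBin(con, raw(), 4))
  invisible(readBin(con, numeric(), 6, size = 4))
  invisible(readBin(con, raw(), 2))
  invisible(readBin(con, raw(), 6))
  n_count <- readBin(con, integer(), 1, size = 4)
  version <- readBin(con, integer(), 1, size = 4)
  hdr_size <- readBin(con, integer(), 1, size = 4)
  if (!identical(hdr_size, 1000L)) {
    abort("Corrupt TRK header: hdr_size != 1000 (big-endian files unsupported).")
  }
  if (version < 2 || all(aff == 0)) {
    abort("TRK header lacks a version-2 vox_to_ras affine.")
  }
  sls <- list()
  repeat {
    np <- readBin(con, integer(), 1, size = 4)
    if (length(np) == 0) break
    pts <- matrix(readBin(con, numeric(), np * (3 + n_scalars), size = 4),
                  ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0) invisible(readBin(con, numeric(), n_props, size = 4))
    vox <- sweep(pts, 2, vs, `/`) - 0.5
    sls[[length(sls) + 1]] <- voxel_to_world(aff, vox)
    if (n_count > 0 && length(sls) == n_count) break
  }
  list(streamlines = sls, affine = aff, ref_dim = as.integer(dim3))
}

# ---- TCK (MRtrix) -----------------------------------------------------

write_tck <- function(bundle, path) {
  n <- length(bundle$streamlines)
  hdr_of <- function(offset) {
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
           "\nfile: . ", offset, "\nEND\n")
  }
  offset <- nchar(hdr_of(0))
  # fixed point: offset digits can grow once
  offset <- nchar(hdr_of(offset))
  hdr <- hdr_of(offset)
  stopifnot(nchar(hdr) == offset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (sl in bundle$streamlines) {
    writeBin(as.numeric(t(sl)), con, size = 4)
    writeBin(rep(NaN, 3), con, size = 4)
  }
  writeBin(rep(Inf, 3), con, size = 4)
  invisible(path)
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (!identical(first, "mrtrix tracks")) abort("Not a TCK file.")
  offset <- NULL
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) abort("Corrupt TCK header: missing END.")
    if (identical(ln, "END")) break
    kv <- strsplit(ln, ":\\s*")[[1]]
    if (kv[1] == "file") {
      offset <- as.integer(strsplit(trimws(kv[2]), "\\s+")[[1]][2])
    }
    if (kv[1] == "datatype" && trimws(kv[2]) != "Float32LE") {
      abort(sprintf("Unsupported TCK datatype '%s'.", trimws(kv[2])))
    }
  }
  if (is.null(offset)) abort("Corrupt TCK header: missing file offset.")
  close(con)
  con <- file(path, "rb")
  invisible(readBin(con, raw(), offset))
  vals <- readBin(con, numeric(), file.size(path), size = 4)
  vals <- vals[seq_len(3 * (length(vals) %/% 3))]
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  stop_i <- which(rowSums(matrix(is.infinite(pts), ncol = 3)) == 3)[1]
  if (!is.na(stop_i)) pts <- pts[seq_len(stop_i - 1), , drop = FALSE]
  sep <- rowSums(matrix(is.nan(pts), ncol = 3)) == 3
  grp <- cumsum(c(0, head(sep, -1)))
  keep <- which(!sep)
  sls <- lapply(split(keep, grp[keep]),
                function(ix) pts[ix, , drop = FALSE])
  names(sls) <- NULL
  list(streamlines = sls, affine = diag(4), ref_dim = c(0L, 0L, 0L))
}
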