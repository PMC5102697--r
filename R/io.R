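# Standard-format I/O: NIfTI-1 volumes via RNifti, whitespace-delimited
# motion parameter text, regional parcellation of 4D data, and mask
# import/export with a plain-text sidecar header.

#' Read a 4D BOLD volume
#'
#' @param path NIfTI-1 file path.
#' @return List with `data` (4D array), `TR` (from the header's 4th pixdim
#'   when present, else `NA`; headers are often wrong — override by flag
#'   in pipelines), and `image` (the `niftiImage` carrying the affine and
#'   header for lossless round trips).
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim(img)),
       TR = if (length(pd) >= 4) pd[4] else NA_real_,
       image = img)
}

#' Write a volume as NIfTI-1
#'
#' @param volume 3D or 4D numeric array.
#' @param path Output path.
#' @param reference Optional `niftiImage` whose affine/header to reuse.
#' @param TR Optional sampling interval stored in the 4th pixdim.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, reference = NULL, TR = NULL) {
  img <- if (is.null(reference)) RNifti::asNifti(volume)
         else RNifti::asNifti(volume, reference = reference)
  if (!is.null(TR) && length(dim(volume)) == 4) {
    pd <- RNifti::pixdim(img)
    pd[4] <- TR
    RNifti::pixdim(img) <- pd
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 6-column rigid-body motion parameter file
#'
#' Whitespace-delimited text with one row per time point. Realignment
#' tools differ in column order; named presets reorder to the package
#' convention (x, y, z translations then three rotations).
#'
#' @param path File path.
#' @param dialect `"translations_first"` (default; e.g. SPM `rp_*.txt`) or
#'   `"rotations_first"` (e.g. FSL `.par`).
#' @return N x 6 numeric matrix, translations in columns 1-3.
#' @export
read_motion <- function(path, dialect = c("translations_first", "rotations_first")) {
  dialect <- match.arg(dialect)
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6)
    stop("expected 6 whitespace-delimited columns (3 translations, 3 rotations)")
  if (dialect == "rotations_first") m <- m[, c(4:6, 1:3)]
  colnames(m) <- c("x", "y", "z", "rot1", "rot2", "rot3")
  m
}

#' Parcellate a 4D volume into regional time series
#'
#' Per-region (weighted) mean of member voxel series, with centroids as
#' the (weighted) mean 0-based voxel coordinates.
#'
#' @param v 4D numeric array.
#' @param labels 3D integer label array (0 = background).
#' @param weights Optional 3D per-voxel weight array.
#' @return List with `series` (time x regions matrix, columns named by
#'   region id) and `centroids` (data frame: `region`, `n_voxels`, `x`,
#'   `y`, `z`).
#' @export
apply_parcellation <- function(v, labels, weights = NULL) {
  dims <- dim(v)
  if (length(dims) != 4) stop("v must be 4D")
  if (!all(dim(labels) == dims[1:3])) stop("label grid does not match volume grid")
  if (any(labels != round(labels)) || any(labels < 0))
    stop("labels must be non-negative integers")
  if (is.null(weights)) weights <- array(1, dims[1:3])
  if (!all(dim(weights) == dims[1:3])) stop("weights grid does not match volume grid")
  vox <- matrix(v, ncol = dims[4])
  regions <- sort(unique(labels[labels > 0]))
  coords <- arrayInd(seq_len(prod(dims[1:3])), dims[1:3]) - 1L
  series <- matrix(NA_real_, dims[4], length(regions))
  cent <- matrix(NA_real_, length(regions), 3)
  nv <- integer(length(regions))
  for (k in seq_along(regions)) {
    sel <- which(labels == regions[k])
    w <- weights[sel]
    if (sum(w) <= 0) w <- rep(1, length(sel))
    w <- w / sum(w)
    series[, k] <- as.vector(t(vox[sel, , drop = FALSE]) %*% w)
    cent[k, ] <- colSums(coords[sel, , drop = FALSE] * w)
    nv[k] <- length(sel)
  }
  colnames(series) <- regions
  list(series = series,
       centroids = data.frame(region = regions, n_voxels = nv,
                              x = cent[, 1], y = cent[, 2], z = cent[, 3]))
}

#' Export a coefficient mask with a plain-text sidecar header
#'
#' Writes the binary mask as 0/1 integers (one row per time index,
#' whitespace-delimited scales) and a `.hdr` sidecar recording the scale
#' count, original length, boundary rule and filter name.
#'
#' @param m A `coef_mask`.
#' @param path Output path for the mask table.
#' @return `path`, invisibly.
#' @export
write_coefficient_mask <- function(m, path) {
  stopifnot(inherits(m, "coef_mask"))
  utils::write.table(matrix(as.integer(m), nrow(m), ncol(m)), path,
                     row.names = FALSE, col.names = FALSE)
  hdr <- c(paste("scales", attr(m, "J")), paste("N", attr(m, "N")),
           paste("boundary", attr(m, "boundary")),
           paste("filter", attr(m, "filter_name")),
           paste("L", attr(m, "L")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Import a coefficient mask written by [write_coefficient_mask()]
#'
#' @param path Path to the mask table (sidecar `.hdr` expected alongside).
#' @return A `coef_mask`.
#' @export
read_coefficient_mask <- function(path) {
  hdr <- strsplit(readLines(paste0(path, ".hdr")), " ")
  meta <- stats::setNames(vapply(hdr, `[`, character(1), 2),
                          vapply(hdr, `[`, character(1), 1))
  mask <- as.matrix(utils::read.table(path))
  structure(matrix(as.logical(as.integer(mask)), nrow(mask), ncol(mask)),
            N = as.integer(meta[["N"]]), J = as.integer(meta[["scales"]]),
            boundary = meta[["boundary"]], filter_name = meta[["filter"]],
            L = as.integer(meta[["L"]]),
            class = c("coef_mask", "matrix"))
}
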