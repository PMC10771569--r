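#' Voxelized tumor models
#'
#' A tumor is a binary 3D voxel mask standing in for a CT segmentation,
#' with needles inserted parallel to the z axis (normal to the axial
#' plane). Voxels are indexed (x, y, z); \code{voxel_size} is the edge
#' length per axis in mm.
#'
#' @param mask 3D array of 0/1 (or logical) voxels; must be non-empty.
#' @param voxel_size Voxel edge length(s) in mm, length 1 or 3.
#' @param needle_trajectories Optional n x 2 matrix of (x, y) needle entry
#'   coordinates in cm, relative to the mask centroid.
#' @return A \code{tumor_model}.
#' @export
tumor_model <- function(mask, voxel_size, needle_trajectories = NULL) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("format error: mask is not binary")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("empty-input error: tumor mask has no voxels set")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be strictly positive (mm)")
  structure(list(mask = mask, voxel_size = voxel_size,
                 needle_trajectories = needle_trajectories),
            class = "tumor_model")
}

#' @export
print.tumor_model <- function(x, ...) {
  cat(sprintf("<tumor_model> %s voxels at %s mm, volume %.3f cm3\n",
              paste(dim(x$mask), collapse = " x "),
              paste(signif(x$voxel_size, 3), collapse = " x "),
              tumor_volume(x) / 1000))
  invisible(x)
}

#' Tumor volume in mm3 (voxel counting)
#' @param tumor A \code{tumor_model}.
#' @export
tumor_volume <- function(tumor) {
  stopifnot(inherits(tumor, "tumor_model"))
  sum(tumor$mask) * prod(tumor$voxel_size)
}

#' Load a binary tumor mask from NIfTI or multi-page TIFF
#'
#' Reads a voxelized segmentation, checks that it is binary and
#' non-empty, and trims it to its bounding box plus a margin of
#' background voxels.
#'
#' @param path Path to a \code{.nii}/\code{.nii.gz} volume or a
#'   multi-page TIFF stack.
#' @param voxel_size Voxel size in mm (length 1 or 3). For NIfTI, taken
#'   from the header when omitted; required for TIFF.
#' @param margin Background margin retained around the bounding box, in
#'   voxels. Default 2.
#' @return A \code{\link{tumor_model}}.
#' @export
load_tumor_mask <- function(path, voxel_size = NULL, margin = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (is.null(voxel_size)) voxel_size <- RNifti::pixdim(img)[1:3]
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (is.null(voxel_size))
      stop("voxel_size (mm) is required for TIFF stacks")
    arr <- array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
  } else stop("unsupported mask format (expected .nii, .nii.gz or .tif)")
  if (length(dim(arr)) > 3) arr <- array(arr, dim(arr)[1:3])
  # binary = at most two distinct levels, background 0; accepts 0/1 and
  # 8-bit-scaled (0, 1/255) encodings alike
  vals <- sort(unique(round(as.vector(arr), 6)))
  if (length(vals) > 2 || (length(vals) == 2 && vals[1] != 0))
    stop("format error: mask volume is not binary (found grayscale values)")
  arr <- array(arr > 0, dim(arr))
  if (!any(arr)) stop("empty-input error: mask volume is all zero")
  tumor_model(trim_mask(arr, margin), voxel_size)
}

# bounding box of TRUE voxels plus `margin` background voxels per side,
# clipped to the array
trim_mask <- function(mask, margin = 2L) {
  rng <- lapply(1:3, function(k) {
    any_k <- apply(mask, k, any)
    range(which(any_k))
  })
  from <- pmax(vapply(rng, `[`, 0, 1) - margin, 1)
  to <- pmin(vapply(rng, `[`, 0, 2) + margin, dim(mask))
  mask[from[1]:to[1], from[2]:to[2], from[3]:to[3], drop = FALSE]
}

#' Embed a tumor in a conductive background box for field solving
#'
#' Builds a 3D voxel computational domain: the tumor voxels form region 1
#' and the surrounding background (hydrogel or liver parenchyma) region 2,
#' inside a box extending \code{margin_mm} beyond the tumor bounding box.
#' The box walls are insulating. Coordinates are cm, centered on the
#' tumor centroid in (x, y) and on the box in z, so needle trajectories
#' can be given relative to the tumor.
#'
#' @param tumor A \code{\link{tumor_model}}.
#' @param tumor_sigma Conductivity model for the tumor (default constant
#'   1.26 S/m, hepatocellular carcinoma).
#' @param background_sigma Conductivity model for the background (default
#'   constant 1.46 S/m).
#' @param margin_mm Background margin beyond the tumor bounding box, mm.
#' @return A \code{hydrogel_geometry} of shape \code{voxel_mask} with 3D
#'   \code{inside}/\code{region} arrays and \code{z} coordinates.
#' @export
tumor_domain <- function(tumor, tumor_sigma = conductivity_model(1.26),
                         background_sigma = conductivity_model(1.46),
                         margin_mm = 4) {
  stopifnot(inherits(tumor, "tumor_model"))
  vx <- tumor$voxel_size
  pad <- pmax(1L, ceiling(margin_mm / vx))
  d0 <- dim(tumor$mask)
  d <- d0 + 2L * pad
  mask <- array(FALSE, d)
  mask[pad[1] + seq_len(d0[1]), pad[2] + seq_len(d0[2]),
       pad[3] + seq_len(d0[3])] <- tumor$mask
  region <- array(2L, d)
  region[mask] <- 1L
  # cm coordinates, (x, y) origin at the tumor centroid
  ctr <- vapply(1:3, function(k)
    mean(slice.index(mask, k)[mask]), numeric(1))
  coord <- lapply(1:3, function(k)
    (seq_len(d[k]) - if (k < 3) ctr[k] else (d[k] + 1) / 2) * vx[k] / 10)
  structure(
    list(shape = "voxel_mask", plate_format = NA_integer_,
         nominal_area_mm2 = NA_real_,
         outer_diameter = NA_real_, inner_diameter = NA_real_,
         height = d[3] * vx[3] / 10, grid_spacing = vx[1] / 10,
         x = coord[[1]], y = coord[[2]], z = coord[[3]],
         inside = array(TRUE, d), region = region,
         region_names = c("tumor", "background"),
         region_sigma = list(tumor_sigma, background_sigma),
         voxel_size_mm = vx,
         cell_area_mm2 = vx[1] * vx[2],
         cell_volume_mm3 = prod(vx)),
    class = "hydrogel_geometry")
}
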