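# Exchange formats: CSV field maps and sweeps, legacy-VTK structured
# grids, multi-page TIFF stacks, NIfTI tumor masks. Units are declared
# in column names / headers (cm, V, V/cm, mm2, mm3).

#' Export a field map as CSV
#'
#' One row per in-domain grid cell with coordinates (cm), potential (V,
#' for single activations) and field magnitude (V/cm).
#'
#' @param x A \code{field_solution} or \code{cumulative_field}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_field_csv <- function(x, path) {
  g <- x$geometry
  nd <- dim(g$inside)
  idx <- which(g$inside, arr.ind = TRUE)
  df <- data.frame(x_cm = g$x[idx[, 1]], y_cm = g$y[idx[, 2]])
  if (length(nd) == 3) df$z_cm <- g$z[idx[, 3]]
  if (inherits(x, "field_solution")) df$phi_V <- x$phi[g$inside]
  df$E_V_per_cm <- x$Emag[g$inside]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a field or label map as a legacy VTK structured grid
#'
#' ASCII STRUCTURED_POINTS dataset with one scalar array per field
#' (potential in V where present, field magnitude in V/cm, labels);
#' cells outside the domain carry -1.
#'
#' @param x A \code{field_solution}, \code{cumulative_field}, or a plain
#'   array with a \code{geometry} attribute.
#' @param path Output \code{.vtk} file.
#' @param geometry Geometry for plain arrays.
#' @return \code{path}, invisibly.
#' @export
write_field_vtk <- function(x, path, geometry = NULL) {
  if (is.null(geometry)) geometry <- x$geometry
  g <- geometry
  nd <- dim(g$inside)
  if (length(nd) == 2) nd <- c(nd, 1L)
  h <- g$grid_spacing
  arrays <- list()
  if (inherits(x, "field_solution")) {
    arrays$phi_V <- x$phi
    arrays$E_V_per_cm <- x$Emag
  } else if (inherits(x, "cumulative_field")) {
    arrays$E_V_per_cm <- x$Emag
  } else {
    arrays$labels <- x
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ireplan field map (units: cm, V, V/cm)", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nd[1], nd[2], nd[3]),
               sprintf("ORIGIN %g %g %g", min(g$x), min(g$y),
                       if (!is.null(g$z)) min(g$z) else 0),
               sprintf("SPACING %g %g %g", h, h,
                       if (!is.null(g$z)) g$z[2] - g$z[1] else h),
               sprintf("POINT_DATA %d", prod(nd))), con)
  for (nm in names(arrays)) {
    v <- as.vector(arrays[[nm]])
    v[is.na(v)] <- -1
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(formatC(v, format = "g"), collapse = " "), con)
  }
  invisible(path)
}

#' Export an ablation sweep as CSV
#'
#' Columns \code{threshold_V_per_cm} and \code{ablated_mm2} (or
#' \code{ablated_mm3} for volumes).
#'
#' @param sweep An \code{\link{ablation_sweep}}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "ablation_sweep"))
  df <- data.frame(threshold_V_per_cm = sweep$threshold,
                   ablated = sweep$ablated)
  names(df)[2] <- paste0("ablated_", attr(sweep, "unit"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a binary stack as multi-page 8-bit TIFF
#'
#' @param stack 3D 0/1 array (slices along the third axis), or for label
#'   maps small integer values; stored as 8-bit grey.
#' @param path Output \code{.tif} file.
#' @return \code{path} invisibly (write); an integer array (read), with
#'   byte values restored.
#' @export
write_stack_tiff <- function(stack, path) {
  if (length(dim(stack)) == 2) stack <- array(stack, c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- stack[, , k]
    m[is.na(m)] <- 0
    m / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
  array(as.integer(round(arr * 255)), dim(arr))
}

#' Write a tumor mask as NIfTI
#'
#' @param tumor A \code{\link{tumor_model}}.
#' @param path Output \code{.nii} or \code{.nii.gz} file.
#' @return \code{path}, invisibly.
#' @export
write_tumor_nifti <- function(tumor, path) {
  stopifnot(inherits(tumor, "tumor_model"))
  img <- RNifti::asNifti(array(as.integer(tumor$mask), dim(tumor$mask)))
  RNifti::pixdim(img) <- tumor$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
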