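#' Write a time-resolved stack as a multi-page TIFF
#'
#' One page per time bin, 16-bit, counts stored scaled by 1/65535 (the TIFF
#' writer stores values in [0, 1]); the scale is fixed and recorded in the
#' JSON sidecar written next to the stack by [writeSceneBundle()].
#'
#' @param stack numeric array rows x cols x bins of counts (< 65536).
#' @param path output path.
#' @export
writeTiffStack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  if (max(stack) > 65535) stop("counts exceed the 16-bit range")
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [writeTiffStack()]
#'
#' @param path path of the stack.
#' @return numeric array rows x cols x bins of counts.
#' @export
readTiffStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * 65535)
  arr
}

#' Write / read a 16-bit label mask TIFF
#'
#' @param mask integer label matrix (values < 65536).
#' @param path file path.
#' @export
writeLabelTiff <- function(mask, path) {
  if (max(mask) > 65535) stop("labels exceed the 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelTiff
#' @export
readLabelTiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}

#' Write / read a 32-bit marker intensity TIFF
#'
#' Intensities are affinely mapped into [0, 1] for storage; the offset and
#' scale needed to invert the mapping are returned and must be kept (the
#' scene bundle records them in its sidecar).
#'
#' @param image numeric intensity matrix.
#' @param path file path.
#' @return (write) invisible list(offset, scale); (read) the intensity
#'   matrix.
#' @export
writeMarkerTiff <- function(image, path) {
  off <- min(image)
  sc <- max(image) - off
  if (sc <= 0) sc <- 1
  tiff::writeTIFF((image - off) / sc, path, bits.per.sample = 32L)
  invisible(list(offset = off, scale = sc))
}

#' @rdname writeMarkerTiff
#' @param offset,scale the affine mapping returned by the writer.
#' @export
readMarkerTiff <- function(path, offset = 0, scale = 1) {
  tiff::readTIFF(path) * scale + offset
}

#' Write a scene bundle: stack, masks, class labels and JSON sidecar
#'
#' The on-disk contract between the simulator and the analysis stages:
#' \code{stack.tif} (multi-page, page index = time bin), \code{cell_masks.tif}
#' and \code{class_labels.tif} (16-bit labels), and \code{sidecar.json}
#' holding the acquisition config, exact generating photophysics, seeds and
#' storage scales.
#'
#' @param sim result of [simulateTcspcStack()].
#' @param scene the \linkS4class{SyntheticScene}.
#' @param dir output directory (created if needed).
#' @return invisible named vector of the written paths.
#' @export
writeSceneBundle <- function(sim, scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(stack = file.path(dir, "stack.tif"),
             cells = file.path(dir, "cell_masks.tif"),
             classes = file.path(dir, "class_labels.tif"),
             sidecar = file.path(dir, "sidecar.json"))
  writeTiffStack(sim$stack, paths[["stack"]])
  writeLabelTiff(cellMasks(scene), paths[["cells"]])
  writeLabelTiff(classImage(scene), paths[["classes"]])
  sidecar <- sim$sidecar
  sidecar$storage <- list(countScale = 65535)
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a scene bundle's sidecar
#'
#' @param dir directory written by [writeSceneBundle()].
#' @return the sidecar list.
#' @export
readSceneSidecar <- function(dir) {
  jsonlite::read_json(file.path(dir, "sidecar.json"), simplifyVector = TRUE)
}

#' Reconstruct an AcquisitionConfig from a sidecar
#'
#' @param sidecar list read by [readSceneSidecar()].
#' @return an \linkS4class{AcquisitionConfig}.
#' @export
acquisitionFromSidecar <- function(sidecar) {
  a <- sidecar$acquisition
  AcquisitionConfig(repRate = a$repRate, nBins = a$nBins,
                    pixelSize = a$pixelSize, irfCenter = a$irfCenter,
                    irfFwhm = a$irfFwhm)
}
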