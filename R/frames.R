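#' Frame-stack utilities
#'
#' A frame stack is an `H x W x N` numeric array of 8-bit-range grayscale
#' frames (float values are allowed for intermediates). These helpers read
#' and write stacks as zero-padded numbered PNG files or multi-page TIFF, and
#' compute the pixel-wise temporal average.
#'
#' @name frame_stack
NULL

#' Pixel-wise average of a frame stack
#'
#' The temporal mean image of a static-scene stack is the "clean" reference
#' from which per-frame noise is measured.
#'
#' @param stack `H x W x N` array with `N >= 2`.
#' @return `H x W` numeric matrix (float precision).
#' @export
average_frames <- function(stack) {
  stack <- as_stack(stack)
  if (dim(stack)[3] < 2L) stop("at least 2 frames are required")
  rowMeans(stack, dims = 2)
}

#' Coerce to a frame stack array
#' @param x an `H x W x N` array, a matrix (single frame) or list of matrices.
#' @return `H x W x N` array.
#' @export
as_stack <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    if (!all(vapply(x, function(f) identical(dim(f), d), logical(1))))
      stop("all frames must share the same shape")
    return(array(unlist(x, use.names = FALSE), dim = c(d, length(x))))
  }
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (length(dim(x)) != 3L) stop("not a frame stack")
  x
}

#' Write a frame stack as numbered 8-bit PNG files
#'
#' @param stack `H x W x N` array, values in `[0, 255]`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return character vector of file paths, invisibly.
#' @export
write_stack_png <- function(stack, dir, prefix = "frame") {
  stack <- as_stack(stack)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- dim(stack)[3]
  width <- max(4L, nchar(as.character(n)))
  paths <- file.path(dir, sprintf("%s_%0*d.png", prefix, width, seq_len(n)))
  for (k in seq_len(n))
    png::writePNG(pmin(pmax(stack[, , k], 0), 255) / 255, paths[k])
  invisible(paths)
}

#' Read a directory of numbered PNG/TIFF frames into a stack
#'
#' Files are sorted by name; 16-bit and color inputs are reduced to 8-bit
#' grayscale (luminance).
#'
#' @param dir directory containing the frames.
#' @param pattern file-name regexp (default PNG and TIFF extensions).
#' @return `H x W x N` array with values in `[0, 255]`.
#' @export
read_stack <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no frames found in ", dir)
  frames <- lapply(files, read_frame)
  as_stack(frames)
}

#' Read one grayscale frame from PNG or TIFF
#' @param path image path.
#' @return numeric matrix in `[0, 255]`.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- luminance(img * 255) / 255
  img * 255
}

#' Write a frame stack as a multi-page TIFF
#' @param stack `H x W x N` array in `[0, 255]`.
#' @param path output `.tif` path.
#' @export
write_stack_tiff <- function(stack, path) {
  stack <- as_stack(stack)
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) pmin(pmax(stack[, , k], 0), 255) / 255)
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Finalize a float frame to 8-bit range
#' @param frame numeric matrix.
#' @return integer-valued matrix clipped to `[0, 255]` and rounded.
#' @export
as_gray8 <- function(frame) {
  out <- round(pmin(pmax(frame, 0), 255))
  storage.mode(out) <- "integer"
  out
}
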