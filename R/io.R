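#' Read an image file
#'
#' Reads a PNG (8- or 16-bit) into a float matrix or rows x cols x channels
#' array with values in \[0, 1\]. Alpha channels are dropped; single-channel
#' images come back as matrices.
#'
#' @param path image file path.
#' @return numeric matrix or 3-channel array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) img <- img[, , 1]                # gray + alpha
    else if (dim(img)[3] == 4L) img <- img[, , 1:3]         # drop alpha
    else if (dim(img)[3] == 1L) img <- img[, , 1]
  }
  img
}

#' Write a binary mask as 8-bit PNG
#'
#' @param mask logical matrix or [pixel_mask()].
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(as.matrix(mask) > 0.5), nrow(mask)), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; known keys override the defaults of
#' [geovote_control()].
#'
#' @param path YAML file path.
#' @return a `geovote_control` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(geovote_control, vals)
}
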