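#' Write an intensity image as 8-bit grayscale PNG
#'
#' @param x a [vessel_map()], [fundus_image()], or matrix in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  m <- map_pixels(x)
  png::writePNG(m, target = path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG as an intensity matrix
#'
#' Color images are collapsed to grayscale by channel averaging.
#'
#' @param path PNG file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                      c(1, 2), mean)
  a
}

#' Write / read a subject table as CSV
#'
#' The header is `subject_id,age,sex,eye,diagnosis,image_id`.
#'
#' @param table data.frame with those columns.
#' @param path CSV path.
#' @return `path` invisibly (write), or the data.frame (read).
#' @export
write_subject_table <- function(table, path) {
  cols <- c("subject_id", "age", "sex", "eye", "diagnosis", "image_id")
  stopifnot(all(cols %in% names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write run configuration as YAML
#' @param config named list.
#' @param path YAML path.
#' @return `path` invisibly (write), or a named list (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
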