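# Modal height of an image: histogram with fixed-width bins, background =
# median of the heights falling in the fullest bin. Robust to sparse
# particles sitting on a flat support.
.modal_height <- function(values, bin_width = 0.05) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) abort("empty image: no finite heights.")
  if (diff(range(v)) < bin_width) return(median(v))
  breaks <- seq(min(v), max(v) + bin_width, by = bin_width)
  bins <- findInterval(v, breaks, rightmost.closed = TRUE)
  modal <- as.integer(names(which.max(table(bins))))
  median(v[bins == modal])
}

#' Construct an AFM height image
#'
#' A rectangular grid of surface heights (nm) with physical pixel size. The
#' background level (the flat support the particles sit on) defaults to the
#' modal height of the image, estimated from a 0.05-nm-bin histogram.
#'
#' @param grid Numeric matrix of heights in nm (rows = y, columns = x).
#' @param pixel_size nm per pixel (> 0).
#' @param background Background level in nm; estimated from the histogram
#'   mode when `NULL`.
#'
#' @return An object of class `height_image`.
#' @seealso [read_height_image()], [detect_particles()], [gen_afm_image()]
#' @export
height_image <- function(grid, pixel_size, background = NULL) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  if (length(grid) == 0L) abort("empty image.")
  if (!is.finite(pixel_size) || pixel_size <= 0) abort("pixel_size must be > 0 nm.")
  if (any(!is.finite(grid))) abort("image heights must be finite.")
  if (is.null(background)) background <- .modal_height(grid)
  structure(
    list(grid = grid, pixel_size = pixel_size, background = background),
    class = "height_image"
  )
}

#' @export
print.height_image <- function(x, ...) {
  cat(sprintf(
    "<height_image> %d x %d px @ %.3g nm/px, background %.3g nm\n",
    nrow(x$grid), ncol(x$grid), x$pixel_size, x$background
  ))
  invisible(x)
}

#' Read an AFM height image from an ASCII grid
#'
#' The format is a header line `pixel_size_nm=<value>` followed by rows of
#' whitespace-separated heights in nm. All rows must have the same length.
#'
#' @param path File path.
#' @return A [height_image()] with the background estimated as the modal
#'   height (0.05-nm histogram bins).
#' @export
read_height_image <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort("image file must have a header and at least one row.")
  m <- regmatches(lines[1], regexec("^\\s*pixel_size_nm\\s*=\\s*([0-9.eE+-]+)\\s*$", lines[1]))[[1]]
  if (length(m) != 2L) abort("missing pixel size: header must be 'pixel_size_nm=<value>'.")
  px <- as.numeric(m[2])
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(unique(lengths(rows))) != 1L) abort("ragged rows in image grid.")
  vals <- suppressWarnings(as.numeric(unlist(rows, use.names = FALSE)))
  if (anyNA(vals)) abort("non-numeric values in image grid.")
  grid <- matrix(vals, nrow = length(rows), byrow = TRUE)
  height_image(grid, pixel_size = px)
}

#' Write a height image as an ASCII grid
#'
#' @param image A [height_image()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_height_image <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("pixel_size_nm=%.9g", image$pixel_size), con)
  writeLines(apply(image$grid, 1, function(r) paste(sprintf("%.6g", r), collapse = " ")), con)
  invisible(path)
}
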