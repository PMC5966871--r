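## ImageJ-style fluorescence quantification: per-ROI area, mean gray
## value and integrated density (area x mean = pixel sum), and the
## between-sample fold change of mean integrated density.

#' Read a plain (P2) PGM grayscale image
#'
#' @param path PGM file in the ASCII "P2" dialect.
#' @return numeric matrix (rows = image rows).
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop(path, ": only plain (P2) PGM is supported")
  dims <- as.integer(toks[2:3])   # width, height
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != prod(dims))
    stop(path, ": pixel count does not match header dimensions")
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

#' Write a matrix as a plain (P2) PGM image
#'
#' Values are clamped to `[0, maxval]` and rounded — quantization
#' happens only here; in-memory images stay real-valued.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param maxval maximum gray value declared in the header.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 65535L) {
  q <- round(pmin(pmax(image, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)),
               as.character(maxval)), con)
  apply(q, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Measure a rectangular region of interest
#'
#' Area (pixel count), mean gray value and integrated density
#' (area x mean gray = pixel sum) for one axis-aligned rectangle.
#'
#' @param image numeric matrix (non-negative intensities).
#' @param x,y 1-based column / row of the ROI's top-left pixel.
#' @param width,height ROI extent in pixels (> 0).
#' @return one-row data.frame: `x`, `y`, `width`, `height`, `area`,
#'   `mean_gray`, `integrated_density`.
#' @export
measure_roi <- function(image, x, y, width, height) {
  if (width <= 0 || height <= 0) stop("empty ROI")
  if (x < 1 || y < 1 || x + width - 1L > ncol(image) ||
      y + height - 1L > nrow(image))
    stop("ROI outside image bounds")
  px <- image[y:(y + height - 1L), x:(x + width - 1L), drop = FALSE]
  area <- length(px)
  mg <- mean(px)
  data.frame(x = x, y = y, width = width, height = height,
             area = area, mean_gray = mg,
             integrated_density = area * mg)
}

#' Measure a table of ROIs
#'
#' @param image numeric matrix.
#' @param rois data.frame with columns `x`, `y`, `width`, `height` (as
#'   produced by [simulate_images()] or read from a TSV).
#' @return data.frame of measurements, one row per ROI.
#' @export
measure_rois <- function(image, rois) {
  do.call(rbind, lapply(seq_len(nrow(rois)), function(i)
    measure_roi(image, rois$x[i], rois$y[i], rois$width[i],
                rois$height[i])))
}

#' Fold change of mean integrated density between two samples
#'
#' The ratio of the mean per-ROI integrated density of sample A to that
#' of sample B.  ROIs must be equally sized across the comparison — the
#' measurement convention for fixed-square selections.
#'
#' @param measurements_a,measurements_b data.frames from
#'   [measure_rois()] (non-empty).
#' @return the fold change (numeric scalar, a / b).
#' @export
fold_change <- function(measurements_a, measurements_b) {
  if (!nrow(measurements_a) || !nrow(measurements_b))
    stop("both measurement sets must be non-empty")
  if (length(unique(c(measurements_a$area, measurements_b$area))) != 1)
    stop("ROIs must be equally sized across the comparison")
  denom <- mean(measurements_b$integrated_density)
  if (denom == 0) stop("zero mean integrated density in denominator")
  mean(measurements_a$integrated_density) / denom
}
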