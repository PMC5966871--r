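## Synthetic fluorescence micrographs: each cell is a normalized 2-D
## Gaussian blob whose total (integrated) signal is
## copy_number * intensity_per_copy, on a constant background with
## additive Gaussian noise clamped at zero.  Pixel values are
## non-negative reals in memory and quantized only when written to PGM.

## discrete Gaussian stamp normalized to unit mass so the rendered blob
## conserves total signal exactly
gaussian_stamp <- function(sigma, radius) {
  d <- (-radius):radius
  k <- exp(-d^2 / (2 * sigma^2))
  st <- outer(k, k)
  st / sum(st)
}

#' Simulate a fluorescence cell image with known truth
#'
#' @param copy_numbers integer vector, one transgene copy number per
#'   cell (length = number of cells; empty for a pure-background image).
#' @param intensity_per_copy integrated signal contributed by one
#'   transgene copy (arbitrary units, > 0).
#' @param shape image `c(height, width)` in pixels.
#' @param psf_sigma Gaussian blob standard deviation (pixels).
#' @param background_level constant background added to every pixel.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (clamped so pixels stay non-negative).
#' @param seed RNG seed.
#' @param max_tries placement retries before giving up on a
#'   non-overlapping layout.
#' @return list with `image` (numeric matrix), `rois` (data.frame
#'   `cell`, `x`, `y`, `width`, `height`; 1-based pixel boxes bounding
#'   each blob) and `truth` (`cell`, `copy_number`, `true_signal`).
#' @export
simulate_images <- function(copy_numbers, intensity_per_copy = 100,
                            shape = c(128L, 128L), psf_sigma = 1.5,
                            background_level = 0, noise_sd = 0,
                            seed = 1L, max_tries = 1000L) {
  stopifnot(intensity_per_copy > 0, noise_sd >= 0, background_level >= 0)
  n_cells <- length(copy_numbers)
  h <- shape[1]; w <- shape[2]
  radius <- as.integer(ceiling(3 * psf_sigma))
  box <- 2L * radius + 1L
  if (n_cells > 0 && (h < box || w < box))
    stop("image too small for the blob size")
  withr::with_seed(seed, {
    ## non-overlapping centers by rejection sampling
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centers) < n_cells) {
      cand <- c(sample.int(h - box + 1L, 1L) + radius,
                sample.int(w - box + 1L, 1L) + radius)
      if (nrow(centers) == 0 ||
          all(abs(centers[, 1] - cand[1]) > box |
              abs(centers[, 2] - cand[2]) > box)) {
        centers <- rbind(centers, cand)
      }
      tries <- tries + 1L
      if (tries > max_tries && nrow(centers) < n_cells)
        stop("could not place ", n_cells,
             " non-overlapping cells after ", max_tries, " tries")
    }
    img <- matrix(background_level, nrow = h, ncol = w)
    stamp <- gaussian_stamp(psf_sigma, radius)
    true_signal <- copy_numbers * intensity_per_copy
    rois <- data.frame(cell = integer(0), x = integer(0), y = integer(0),
                       width = integer(0), height = integer(0))
    for (i in seq_len(n_cells)) {
      cy <- centers[i, 1]; cx <- centers[i, 2]
      ys <- (cy - radius):(cy + radius)
      xs <- (cx - radius):(cx + radius)
      img[ys, xs] <- img[ys, xs] + stamp * true_signal[i]
      rois <- rbind(rois, data.frame(cell = i, x = cx - radius,
                                     y = cy - radius, width = box,
                                     height = box))
    }
    if (noise_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, noise_sd), nrow = h)
    img[img < 0] <- 0
    list(image = img,
         rois = rois,
         truth = data.frame(cell = seq_len(n_cells),
                            copy_number = copy_numbers,
                            true_signal = true_signal))
  })
}
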