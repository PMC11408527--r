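#' Generate a synthetic autoradiograph-like banded image
#'
#' Emulates the geometry of an in situ hybridization film image around a
#' labelled structure: a uniform background with a Gaussian-profile band
#' of elevated intensity running across one axis (the expression signal)
#' plus independent pixel noise. Intensities follow the convention
#' higher value = stronger signal.
#'
#' @param width,height Image size in pixels (columns x rows).
#' @param band_center Band centre along the profile axis (column index).
#' @param band_sigma Gaussian half-width of the band (pixels).
#' @param band_amplitude Peak intensity of the band above background
#'   (>= 0, arbitrary units).
#' @param background_level Uniform background intensity.
#' @param noise_sd Per-pixel Gaussian noise SD.
#' @param seed Integer seed.
#' @return List with `image` (numeric `height x width` matrix) and
#'   `truth` (band centre, sigma, amplitude, background).
#' @export
gen_od_image <- function(width = 300, height = 150,
                         band_center = 150, band_sigma = 15,
                         band_amplitude = 100, background_level = 50,
                         noise_sd = 5, seed = 1L) {
  stopifnot(width >= 3, height >= 1, band_amplitude >= 0,
            band_sigma > 0, noise_sd >= 0)
  if (band_center < 1 || band_center > width)
    stop("band outside image")
  with_local_seed(seed, {
    profile <- band_amplitude * exp(-((seq_len(width) - band_center)^2) /
                                      (2 * band_sigma^2))
    img <- matrix(background_level, height, width) +
      matrix(profile, height, width, byrow = TRUE)
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(height * width, sd = noise_sd),
                          height, width)
    list(image = img,
         truth = list(band_center = band_center, band_sigma = band_sigma,
                      band_amplitude = band_amplitude,
                      background_level = background_level,
                      noise_sd = noise_sd))
  })
}
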