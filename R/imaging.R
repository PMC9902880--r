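#' Imaging and camera configuration for the movie simulator
#'
#' Parameters of the synthetic wide-field EMCCD acquisition. Defaults follow
#' the counting protocol (30 consecutive frames at 100 ms exposure per imaged
#' region); photobleaching-validation scenarios typically use longer movies
#' via [scenario_imaging()]. Coordinates are 0-based pixel indices with x =
#' column and y = row, and an emitter position refers to the centre of its
#' pixel; sub-pixel positions are allowed.
#'
#' The EMCCD model is: per pixel and frame, photons ~ Poisson(signal +
#' background); when `em_gain > 1` the electron-multiplying register is
#' approximated by Gamma(shape = photons, scale = em_gain) amplification
#' (excess noise factor 2); Gaussian read noise of SD `read_noise_sd` counts
#' and a fixed `offset` are added, and the result is rounded and clipped to
#' the 16-bit range.
#'
#' @param width,height Field size in pixels.
#' @param pixel_size Pixel size in um (object space).
#' @param n_frames Number of frames per region (default 30).
#' @param exposure Exposure per frame, seconds (default 0.1).
#' @param psf_sigma Gaussian PSF standard deviation in pixels.
#' @param photons_per_frame Mean detected photons per fluorophore per frame.
#' @param bleach_rate Photobleaching rate per frame (exponential lifetime
#'   1/bleach_rate frames).
#' @param background_photons Background photons per pixel per frame.
#' @param em_gain EM gain (counts per photo-electron); 1 disables the
#'   multiplication register.
#' @param read_noise_sd Read noise SD in counts.
#' @param offset Camera offset in counts.
#' @param multi_emitter_fraction Fraction of emitters carrying two
#'   fluorophores (co-located molecules), in [0, 1].
#' @param seed Optional RNG seed stored with the configuration; explicit
#'   `seed` arguments of the simulator functions take precedence.
#' @return An object of class `smi_imaging`.
#' @export
imaging_config <- function(width = 256, height = 256, pixel_size = 0.16,
                           n_frames = 30, exposure = 0.1, psf_sigma = 1.3,
                           photons_per_frame = 600, bleach_rate = 0.01,
                           background_photons = 20, em_gain = 30,
                           read_noise_sd = 10, offset = 100,
                           multi_emitter_fraction = 0, seed = NULL) {
  check_num(width, "width", min = 8, integer = TRUE)
  check_num(height, "height", min = 8, integer = TRUE)
  check_num(pixel_size, "pixel_size", min = 1e-6)
  check_num(n_frames, "n_frames", min = 1, integer = TRUE)
  check_num(exposure, "exposure", min = 0)
  check_num(psf_sigma, "psf_sigma", min = 0)
  check_num(photons_per_frame, "photons_per_frame", min = 0)
  check_num(bleach_rate, "bleach_rate", min = 0)
  check_num(background_photons, "background_photons", min = 0)
  check_num(em_gain, "em_gain", min = 1)
  check_num(read_noise_sd, "read_noise_sd", min = 0)
  check_num(offset, "offset", min = 0)
  check_num(multi_emitter_fraction, "multi_emitter_fraction", min = 0, max = 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, n_frames = as.integer(n_frames),
                 exposure = exposure, psf_sigma = psf_sigma,
                 photons_per_frame = photons_per_frame,
                 bleach_rate = bleach_rate,
                 background_photons = background_photons,
                 em_gain = em_gain, read_noise_sd = read_noise_sd,
                 offset = offset,
                 multi_emitter_fraction = multi_emitter_fraction,
                 seed = seed),
            class = "smi_imaging")
}

#' @export
print.smi_imaging <- function(x, ...) {
  cat(sprintf("Imaging config: %dx%d px (%.3g um/px), %d frames @ %.3g s\n",
              x$width, x$height, x$pixel_size, x$n_frames, x$exposure))
  cat(sprintf("  PSF sigma %.3g px, %.4g photons/frame, bleach rate %.3g/frame\n",
              x$psf_sigma, x$photons_per_frame, x$bleach_rate))
  cat(sprintf("  background %.3g photons/px, EM gain %.3g, read noise %.3g, offset %.3g\n",
              x$background_photons, x$em_gain, x$read_noise_sd, x$offset))
  invisible(x)
}

#' Peak signal-to-noise ratio of a single emitter
#'
#' SNR as used to characterize spot detectability: the expected peak-pixel
#' photon signal of a pixel-centred emitter divided by the photon-equivalent
#' noise SD of a background pixel (shot noise with EMCCD excess-noise factor 2
#' when `em_gain > 1`, plus read noise referred to the input). Detection on an
#' m-frame average improves on this figure by roughly sqrt(m).
#'
#' @param img An [imaging_config()] object.
#' @return A single number (unitless).
#' @export
expected_snr <- function(img) {
  if (!inherits(img, "smi_imaging")) abort_config("'img' must be smi_imaging")
  frac1 <- (pnorm(0.5 / img$psf_sigma) - pnorm(-0.5 / img$psf_sigma))^2
  peak <- img$photons_per_frame * frac1
  excess <- if (img$em_gain > 1) 2 else 1
  noise <- sqrt(excess * img$background_photons +
                  (img$read_noise_sd / img$em_gain)^2)
  peak / noise
}
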