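#' Sample ground-truth emitters for one imaged region
#'
#' Draws the emitter field for a synthetic region: the number of fluorescent
#' molecules is Poisson with mean `fluorescent_density x field area`,
#' positions are uniform over the field minus a border margin, a configurable
#' fraction of emitters carries two fluorophores, and each fluorophore gets a
#' photobleaching frame drawn from the exponential bleaching model (capped at
#' `n_frames`, meaning it survives the whole movie).
#'
#' @param assay An [assay_config()], [solve_competitive_occupancy()] result,
#'   or a plain non-negative number giving the emitter density per um^2.
#' @param img An [imaging_config()] object.
#' @param multi_emitter_fraction Fraction of emitters with two fluorophores;
#'   defaults to the value in `img`.
#' @param border_margin Margin in pixels kept free of emitters.
#' @param expected_count Optional expected emitter count; overrides the
#'   density x area product (used by the count-configured experiments).
#' @param seed Optional RNG seed.
#' @return An object of class `smi_truth`: a data frame with columns `x`, `y`
#'   (0-based pixel coordinates), `species`, `n_fluorophores`, and a list
#'   column `bleach_frames` (one bleach frame per fluorophore; a fluorophore
#'   with bleach frame b emits in frames 0..b-1).
#' @export
sample_emitters <- function(assay, img, multi_emitter_fraction = NULL,
                            border_margin = 8, expected_count = NULL,
                            seed = NULL) {
  if (!inherits(img, "smi_imaging")) abort_config("'img' must be smi_imaging")
  species <- "emitter"
  if (inherits(assay, "smi_assay")) {
    species <- assay$species
    assay <- solve_competitive_occupancy(assay)
  }
  if (inherits(assay, "smi_occupancy")) {
    species <- assay$species
    density <- assay$fluorescent_density
  } else {
    density <- check_num(assay, "density", min = 0)
  }
  frac <- multi_emitter_fraction %||% img$multi_emitter_fraction
  check_num(frac, "multi_emitter_fraction", min = 0, max = 1)
  check_num(border_margin, "border_margin", min = 0)
  area_um2 <- img$width * img$height * img$pixel_size^2
  lambda <- expected_count %||% (density * area_um2)
  check_num(lambda, "expected_count", min = 0)
  dens_px <- lambda / (img$width * img$height)
  if (dens_px > 0 && 0.5 / sqrt(dens_px) < 1)
    warning("emitter density so high that the expected nearest-neighbour ",
            "distance is below 1 px; spots will not be discriminable")
  with_seed(seed, {
    n <- rpois(1, lambda)
    if (n == 0) {
      truth <- data.frame(x = numeric(0), y = numeric(0),
                          species = character(0),
                          n_fluorophores = integer(0))
      truth$bleach_frames <- list()
    } else {
      x <- runif(n, border_margin, img$width - 1 - border_margin)
      y <- runif(n, border_margin, img$height - 1 - border_margin)
      nf <- 1L + rbinom(n, 1L, frac)
      bl <- lapply(nf, function(k) draw_bleach_frames(k, img))
      truth <- data.frame(x = x, y = y, species = species,
                          n_fluorophores = nf)
      truth$bleach_frames <- bl
    }
    structure(truth, class = c("smi_truth", "data.frame"),
              width = img$width, height = img$height, n_frames = img$n_frames)
  })
}

# One exponential bleach time per fluorophore, in frame units; ceiling() makes
# the discrete survival through frame t equal exp(-rate * t) at integer t.
draw_bleach_frames <- function(k, img) {
  if (img$bleach_rate <= 0) return(rep(img$n_frames, k))
  pmin.int(as.integer(ceiling(rexp(k, rate = img$bleach_rate))), img$n_frames)
}

#' Render a synthetic EMCCD movie from ground truth
#'
#' Renders each fluorophore as a pixel-integrated 2-D Gaussian of width
#' `psf_sigma` at its emitter position for every frame before its bleach
#' frame, adds uniform background, and applies the EMCCD noise chain: Poisson
#' photon statistics, Gamma electron-multiplication (when `em_gain > 1`),
#' Gaussian read noise and a fixed offset, rounded and clipped to [0, 65535].
#' Fluorophores missing a bleach frame (NA) get one drawn from the
#' exponential bleaching model.
#'
#' @param truth An [sample_emitters()] ground truth.
#' @param img An [imaging_config()] object.
#' @param region_id Identifier stored in the movie metadata.
#' @param noise If `FALSE`, return the noise-free expectation
#'   `em_gain * (signal + background) + offset` without rounding (used for
#'   photon-conservation checks).
#' @param seed Optional RNG seed.
#' @return An object of class `smi_movie`: `data` is an
#'   `n_frames x height x width` array of camera counts; `metadata` echoes the
#'   configuration.
#' @export
render_movie <- function(truth, img, region_id = 1L, noise = TRUE,
                         seed = NULL) {
  if (!inherits(truth, "smi_truth")) abort_config("'truth' must be smi_truth")
  if (!inherits(img, "smi_imaging")) abort_config("'img' must be smi_imaging")
  if (nrow(truth) > 0 &&
      (any(truth$x < 0) || any(truth$x > img$width - 1) ||
       any(truth$y < 0) || any(truth$y > img$height - 1)))
    abort_config("ground-truth positions outside the image bounds")
  nf <- img$n_frames
  with_seed(seed, {
    mu <- array(0, dim = c(img$height, img$width, nf))
    if (nrow(truth) > 0) {
      R <- ceiling(4 * max(img$psf_sigma, 0.5))
      for (i in seq_len(nrow(truth))) {
        bl <- truth$bleach_frames[[i]]
        if (anyNA(bl)) {
          miss <- is.na(bl)
          bl[miss] <- draw_bleach_frames(sum(miss), img)
        }
        patch <- psf_patch(truth$x[i], truth$y[i], img, R)
        for (b in bl) {
          nlive <- min(b, nf)
          if (nlive >= 1)
            mu[patch$rows, patch$cols, seq_len(nlive)] <-
              mu[patch$rows, patch$cols, seq_len(nlive)] +
              rep(patch$mass, nlive)
        }
      }
    }
    mu <- mu + img$background_photons
    if (!noise) {
      counts <- img$em_gain * mu + img$offset
    } else {
      photons <- rpois(length(mu), mu)
      amp <- if (img$em_gain > 1)
        rgamma(length(photons), shape = photons, scale = img$em_gain)
      else photons
      counts <- round(amp + rnorm(length(photons), 0, img$read_noise_sd) +
                        img$offset)
      counts <- pmin.int(pmax.int(counts, 0), 65535)
    }
    dim(counts) <- dim(mu)
    structure(list(data = aperm(counts, c(3, 1, 2)),
                   metadata = c(unclass(img), list(region_id = region_id))),
              class = "smi_movie")
  })
}

# Pixel-integrated Gaussian PSF mass over the patch around (x, y); 0-based
# coordinates, pixel i spans [i - 0.5, i + 0.5]. Mass falling outside the
# sensor is lost.
psf_patch <- function(x, y, img, R) {
  s <- max(img$psf_sigma, 1e-9)
  cols <- max(0, floor(x - R)):min(img$width - 1, ceiling(x + R))
  rows <- max(0, floor(y - R)):min(img$height - 1, ceiling(y + R))
  xm <- pnorm((cols + 0.5 - x) / s) - pnorm((cols - 0.5 - x) / s)
  ym <- pnorm((rows + 0.5 - y) / s) - pnorm((rows - 0.5 - y) / s)
  list(rows = rows + 1L, cols = cols + 1L,
       mass = img$photons_per_frame * outer(ym, xm))
}

#' @export
print.smi_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Synthetic movie: %d frames of %dx%d px (region %s)\n",
              d[1], d[2], d[3], x$metadata$region_id))
  cat(sprintf("  counts in [%g, %g], mean %.1f\n", min(x$data), max(x$data),
              mean(x$data)))
  invisible(x)
}

#' Simulate a set of imaged regions
#'
#' Generates `n_regions` independent regions (ground truth + movie) for one
#' sample, mirroring the protocol of imaging ten regions per sample. Regions
#' use per-region seeds derived deterministically from the master seed, so the
#' whole set is reproducible.
#'
#' @inheritParams sample_emitters
#' @param n_regions Number of regions (default 10).
#' @param seed Master seed for the set.
#' @return A list of `n_regions` elements, each `list(movie, truth)`.
#' @export
simulate_region_set <- function(assay, img, n_regions = 10, seed = NULL,
                                multi_emitter_fraction = NULL,
                                border_margin = 8, expected_count = NULL) {
  check_num(n_regions, "n_regions", min = 1, integer = TRUE)
  lapply(seq_len(n_regions), function(i) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, i)
    with_seed(s, {
      truth <- sample_emitters(assay, img,
                               multi_emitter_fraction = multi_emitter_fraction,
                               border_margin = border_margin,
                               expected_count = expected_count, seed = NULL)
      movie <- render_movie(truth, img, region_id = i, seed = NULL)
      list(movie = movie, truth = truth)
    })
  })
}
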