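# Shared small-scale configurations for fast unit tests.

tiny_imaging <- function(...) {
  imaging_config(width = 64, height = 64, ...)
}

# Noise-free rendering helper: expectation image scaled to camera counts.
noise_free_movie <- function(truth, img) {
  mv <- render_movie(truth, img, noise = FALSE)
  mv
}

# Build an smi_truth directly from coordinates (bleach at given frames, one
# fluorophore each unless bleach_frames is a list).
manual_truth <- function(x, y, img, bleach = img$n_frames, species = "e") {
  truth <- data.frame(x = x, y = y, species = species,
                      n_fluorophores = if (is.list(bleach))
                        lengths(bleach) else 1L)
  truth$bleach_frames <- if (is.list(bleach)) bleach
    else as.list(rep(as.integer(bleach), length.out = length(x)))
  structure(truth, class = c("smi_truth", "data.frame"),
            width = img$width, height = img$height, n_frames = img$n_frames)
}
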