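#' Analyze one movie: detect, extract traces, filter single molecules
#'
#' The per-region analysis chain: spot detection on the early-frame average,
#' aperture photometry traces, photobleaching step counting, and the
#' single-molecule acceptance filter.
#'
#' @param movie An `smi_movie`.
#' @param det [detection_params()].
#' @param trace_params List with `aperture_radius`, `annulus_inner`,
#'   `annulus_outer`, `penalty_beta`.
#' @param mode Trace-filter policy, `"counting"` (default) or `"validation"`.
#' @return An `smi_spots` table with the `accepted` column filled.
#' @export
analyze_movie <- function(movie, det = detection_params(),
                          trace_params = list(), mode = "counting") {
  tp <- utils::modifyList(list(aperture_radius = 3, annulus_inner = 5,
                               annulus_outer = 8, penalty_beta = 4),
                          trace_params)
  spots <- detect_spots(movie, det)
  if (nrow(spots) == 0) return(spots)
  traces <- extract_traces(movie, spots, tp$aperture_radius,
                           tp$annulus_inner, tp$annulus_outer)
  fits <- lapply(traces, function(tr) {
    if (isTRUE(tr$excluded)) tr
    else count_steps(tr, penalty_beta = tp$penalty_beta)
  })
  filter_single_molecules(spots, fits, mode = mode)
}

#' Simulate and analyze a full sample (one region set)
#'
#' Runs simulate -> detect -> trace-filter -> count for one sample and
#' returns the region-count summary.
#'
#' @inheritParams simulate_region_set
#' @inheritParams analyze_movie
#' @param label Sample label.
#' @return An `smi_counts`.
#' @export
run_counting_pipeline <- function(assay, img, n_regions = 10, seed = NULL,
                                  det = detection_params(),
                                  trace_params = list(), mode = "counting",
                                  label = "sample", expected_count = NULL,
                                  border_margin = NULL) {
  bm <- border_margin %||% det$border_margin
  regions <- simulate_region_set(assay, img, n_regions = n_regions,
                                 seed = seed, border_margin = bm,
                                 expected_count = expected_count)
  analyzed <- lapply(regions, function(r)
    analyze_movie(r$movie, det, trace_params, mode))
  count_regions(analyzed, label = label)
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' One page per frame, counts stored as 16-bit unsigned integers. The
#' write/read round trip is exact for integer counts in [0, 65535].
#'
#' @param movie An `smi_movie`.
#' @param path Output file path.
#' @export
write_movie_tiff <- function(movie, path) {
  if (!inherits(movie, "smi_movie")) abort_config("'movie' must be smi_movie")
  d <- dim(movie$data)
  pages <- lapply(seq_len(d[1]), function(f)
    pmin(pmax(movie$data[f, , ], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a movie
#'
#' @param path TIFF file path.
#' @param region_id Region identifier for the metadata.
#' @return An `smi_movie` (metadata limited to dimensions and region id).
#' @export
read_movie_tiff <- function(path, region_id = 1L) {
  if (!file.exists(path)) abort_data(sprintf("no such TIFF: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[f, , ] <- round(pg * 65535)
  }
  structure(list(data = arr,
                 metadata = list(region_id = region_id,
                                 n_frames = length(pages),
                                 height = dim(arr)[2], width = dim(arr)[3],
                                 source = path)),
            class = "smi_movie")
}

#' Analyze user-supplied movie stacks
#'
#' Detection-to-quantification on existing multi-page TIFF stacks (one stack
#' per imaged region), without simulation.
#'
#' @param paths Character vector of TIFF paths, one per region.
#' @param det [detection_params()].
#' @param trace_params See [analyze_movie()].
#' @param mode Trace-filter policy.
#' @param label Sample label.
#' @return A list with `counts` (an `smi_counts`) and `spots` (per-region
#'   spot tables).
#' @export
analyze_existing <- function(paths, det = detection_params(),
                             trace_params = list(), mode = "counting",
                             label = "sample") {
  if (length(paths) < 1) abort_data("no input TIFFs given")
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    abort_data(paste("missing input TIFFs:", paste(missing, collapse = ", ")))
  movies <- lapply(seq_along(paths), function(i)
    read_movie_tiff(paths[i], region_id = i))
  dims <- vapply(movies, function(m) dim(m$data), numeric(3))
  if (any(dims[1, ] != dims[1, 1]))
    abort_data("inconsistent frame counts across region stacks")
  if (any(dims[2, ] != dims[2, 1]) || any(dims[3, ] != dims[3, 1]))
    abort_data("inconsistent image dimensions across region stacks")
  spots <- lapply(movies, function(m) analyze_movie(m, det, trace_params, mode))
  list(counts = count_regions(spots, label = label), spots = spots)
}
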