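# Synthetic phosphorimager arrays.
#
# A hybridized array exposed on a storage phosphor screen yields an
# intensity image that is linear in spot radioactivity. The simulator
# renders each spot as a symmetric 2-D Gaussian whose total mass equals
# exposure_scale * probe signal, adds a uniform expected background, and
# draws realized pixel counts from a Poisson (radioactive counting
# statistics). With `noise = FALSE` the expected (noiseless) image is
# returned instead.

#' Simulation parameters
#'
#' @param pixel_size_um scanner resolution (micrometers per pixel); 50 um
#'   is a typical phosphorimager setting.
#' @param psf_sigma_um Gaussian spot standard deviation in micrometers
#'   (effective point-spread of printed spot plus screen blur).
#' @param background_rate expected background counts per pixel.
#' @param exposure_scale dimensionless gain: total expected counts deposited
#'   by a spot of unit signal (longer exposures = larger gain).
#' @param seed integer seed for the Poisson draw; a fixed seed gives a
#'   bit-identical image.
#' @return a `sim_params` list.
#' @export
sim_params <- function(pixel_size_um = 50, psf_sigma_um = 75,
                       background_rate = 2, exposure_scale = 5e5,
                       seed = 1L) {
  stopifnot(pixel_size_um > 0, psf_sigma_um > 0, background_rate >= 0,
            exposure_scale > 0)
  structure(list(pixel_size_um = pixel_size_um,
                 psf_sigma_um = psf_sigma_um,
                 background_rate = background_rate,
                 exposure_scale = exposure_scale,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Sample a ground-truth tRNA abundance profile
#'
#' Relative abundances are drawn i.i.d. log-normal (meanlog 0) and
#' normalized to sum to one; `lognormal_sigma = 0` gives the uniform
#' profile. Seeded for reproducibility.
#'
#' @param catalog a `trna_catalog` (one abundance per species).
#' @param lognormal_sigma sdlog of the log-normal (>= 0).
#' @param seed integer seed.
#' @return named numeric vector, species_id -> abundance, summing to 1.
#' @export
sample_profile <- function(catalog, lognormal_sigma = 1, seed = 1L) {
  stopifnot(inherits(catalog, "trna_catalog"), lognormal_sigma >= 0)
  ids <- catalog$species$species_id
  set.seed(as.integer(seed))
  x <- if (lognormal_sigma == 0) rep(1, length(ids)) else
    stats::rlnorm(length(ids), meanlog = 0, sdlog = lognormal_sigma)
  stats::setNames(x / sum(x), ids)
}

#' Expected probe signals under a ground truth
#'
#' Each probe captures the summed abundance of its target species (all
#' labeled molecules of equal size carry, on average, the same activity,
#' so spot activity is proportional to summed target abundance).
#'
#' @param probe_set a `probe_set`.
#' @param truth named abundance vector from [sample_profile()].
#' @return named numeric vector, probe_id -> expected signal.
#' @export
expected_probe_signal <- function(probe_set, truth) {
  p <- probe_set$probes
  unknown <- setdiff(unique(unlist(p$targets)), names(truth))
  if (length(unknown)) {
    stop("species missing from truth: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(
    vapply(p$targets, function(t) sum(truth[t]), 0),
    p$probe_id)
}

# image dimensions (pixels) that enclose a layout with a symmetric margin
.image_dims <- function(layout, pixel_size_um) {
  margin <- min(layout$x_um, layout$y_um)
  c(rows = ceiling((max(layout$y_um) + margin) / pixel_size_um),
    cols = ceiling((max(layout$x_um) + margin) / pixel_size_um))
}

#' Render a simulated phosphorimager image
#'
#' Expected pixel counts are `background_rate` plus, for every spot, the
#' spot's Gaussian mass integrated exactly over the pixel (separable
#' normal-CDF differences). Realized counts are Poisson with the seed in
#' `params`; `noise = FALSE` returns the expected image.
#'
#' @param layout an `array_layout`.
#' @param probe_signals named vector probe_id -> signal (e.g. from
#'   [expected_probe_signal()]).
#' @param params a [sim_params()] list.
#' @param noise draw Poisson counts (TRUE) or return the expectation.
#' @param dims optional c(rows, cols) pixel dimensions; spots outside the
#'   image are an error.
#' @return numeric matrix of counts with attribute `pixel_size_um`.
#' @export
render_array <- function(layout, probe_signals, params = sim_params(),
                         noise = TRUE, dims = NULL) {
  missing_p <- setdiff(unique(layout$probe_id), names(probe_signals))
  if (length(missing_p)) {
    stop("no signal for probe(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  px <- params$pixel_size_um
  if (is.null(dims)) dims <- .image_dims(layout, px)
  nr <- dims[[1]]; nc <- dims[[2]]
  if (any(layout$x_um > nc * px) || any(layout$y_um > nr * px) ||
      any(layout$x_um < 0) || any(layout$y_um < 0)) {
    stop("spot center outside image bounds", call. = FALSE)
  }
  xedge <- (0:nc) * px
  yedge <- (0:nr) * px
  expected <- matrix(params$background_rate, nr, nc)
  sig <- probe_signals[layout$probe_id]
  for (i in seq_len(nrow(layout))) {
    mass <- params$exposure_scale * sig[[i]]
    if (mass == 0) next
    cx <- stats::pnorm(xedge, layout$x_um[i], params$psf_sigma_um)
    cy <- stats::pnorm(yedge, layout$y_um[i], params$psf_sigma_um)
    expected <- expected + mass * (diff(cy) %o% diff(cx))
  }
  img <- if (noise) {
    set.seed(params$seed)
    matrix(stats::rpois(length(expected), expected), nr, nc)
  } else {
    expected
  }
  attr(img, "pixel_size_um") <- px
  img
}

#' Write / read an image as a plain TSV matrix
#'
#' One image row per line, tab-separated pixel values; a lossless text
#' round trip for integer count images.
#'
#' @param image numeric matrix.
#' @param path file path.
#' @param pixel_size_um recorded on read as the `pixel_size_um` attribute.
#' @export
write_image_tsv <- function(image, path) {
  utils::write.table(image, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path, pixel_size_um = 50) {
  img <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(img) <- NULL
  attr(img, "pixel_size_um") <- pixel_size_um
  img
}

#' Write / read a 16-bit grayscale TIFF image
#'
#' Counts are stored as 16-bit gray levels; values above 65535 are clamped
#' (a real scanner would saturate, and exposures are chosen to avoid it).
#'
#' @param image numeric matrix of counts.
#' @param path TIFF path.
#' @param pixel_size_um recorded on read as the `pixel_size_um` attribute.
#' @export
write_image_tiff <- function(image, path) {
  clamped <- pmin(pmax(image, 0), 65535)
  tiff::writeTIFF(clamped / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, pixel_size_um = 50) {
  img <- round(tiff::readTIFF(path) * 65535)
  dimnames(img) <- NULL
  attr(img, "pixel_size_um") <- pixel_size_um
  img
}

#' Write a simulation sidecar (parameters + ground truth) as YAML
#'
#' @param params a [sim_params()] list.
#' @param truth named abundance vector.
#' @param path YAML path.
#' @export
write_sim_sidecar <- function(params, truth, path) {
  yaml::write_yaml(list(params = unclass(params),
                        truth = as.list(truth)), path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_sidecar
#' @export
read_sim_sidecar <- function(path) {
  x <- yaml::read_yaml(path)
  list(params = do.call(sim_params, x$params),
       truth = unlist(x$truth))
}
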