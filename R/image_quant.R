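# Spot quantification.
#
# Given an image and a layout: register the grid (integer-pixel
# translation), integrate each spot over a disk, subtract the local
# background estimated as the median of an annulus around the spot,
# aggregate replicate spots per probe (median with MAD outlier flagging),
# and normalize to percent of total signal.

# spot centers in continuous pixel coordinates: pixel (r,c) spans
# [(c-1), c] x [(r-1), r] with its center at (c-0.5, r-0.5), so a physical
# position x_um maps to x_um / pixel_size
.centers_px <- function(layout, pixel_size_um) {
  data.frame(spot_id = layout$spot_id,
             probe_id = layout$probe_id,
             cx = layout$x_um / pixel_size_um,
             cy = layout$y_um / pixel_size_um,
             stringsAsFactors = FALSE)
}

# linear indices of pixels whose centers lie within `radius` of (cx, cy),
# optionally excluding those within `inner`
.disk_idx <- function(dim_img, cx, cy, radius, inner = -1) {
  rr <- max(1L, floor(cy - radius)):min(dim_img[1], ceiling(cy + radius))
  cc <- max(1L, floor(cx - radius)):min(dim_img[2], ceiling(cx + radius))
  if (!length(rr) || !length(cc)) return(integer(0))
  d2 <- outer((rr - 0.5 - cy)^2, (cc - 0.5 - cx)^2, `+`)
  keep <- d2 <= radius^2
  if (inner >= 0) keep <- keep & d2 > inner^2
  as.vector(outer(rr, (cc - 1L) * dim_img[1], `+`))[as.vector(keep)]
}

#' Register the spot grid against an image
#'
#' Searches integer-pixel translations (dx, dy) in a square window and keeps
#' the one maximizing the total intensity inside all spot disks. Ties are
#' broken by smallest |dx| + |dy|, then lexicographically by (dx, dy), so a
#' featureless image registers at (0, 0).
#'
#' @param image numeric matrix.
#' @param layout an `array_layout`.
#' @param pixel_size_um micrometers per pixel (defaults to the image
#'   attribute, else 50).
#' @param radius_px disk radius in pixels.
#' @param search_px half-width of the search window (>= 0).
#' @return list with `dx`, `dy` (pixels) and `score`.
#' @export
register_grid <- function(image, layout, pixel_size_um = NULL,
                          radius_px = 3, search_px = 3L) {
  stopifnot(search_px >= 0L)
  px <- pixel_size_um %||% attr(image, "pixel_size_um") %||% 50
  ctr <- .centers_px(layout, px)
  if (all(ctr$cx < 0 | ctr$cx > ncol(image)) ||
      all(ctr$cy < 0 | ctr$cy > nrow(image))) {
    stop("layout lies entirely outside the image", call. = FALSE)
  }
  offs <- expand.grid(dx = -search_px:search_px, dy = -search_px:search_px)
  offs <- offs[order(abs(offs$dx) + abs(offs$dy), offs$dx, offs$dy), ]
  best <- NULL
  for (k in seq_len(nrow(offs))) {
    dx <- offs$dx[k]; dy <- offs$dy[k]
    s <- 0
    for (i in seq_len(nrow(ctr))) {
      idx <- .disk_idx(dim(image), ctr$cx[i] + dx, ctr$cy[i] + dy, radius_px)
      s <- s + sum(image[idx])
    }
    if (is.null(best) || s > best$score) best <- list(dx = dx, dy = dy,
                                                      score = s)
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify one spot with local background subtraction
#'
#' Raw signal is the pixel sum over the disk of radius `radius_px` around
#' the spot center; the background level is the median pixel value in the
#' annulus between `radius_px` and `annulus_factor * radius_px`. The net
#' signal is the raw sum minus background times disk area, clamped at zero
#' (negative radioactivity is unphysical).
#'
#' @param image numeric matrix.
#' @param center_px c(cx, cy) in pixel coordinates.
#' @param radius_px disk radius, pixels.
#' @param annulus_factor outer annulus radius as a multiple of `radius_px`.
#' @return list: raw_sum, background_level, net_signal, n_pixels.
#' @export
quantify_spot <- function(image, center_px, radius_px = 3,
                          annulus_factor = 2) {
  cx <- center_px[[1]]; cy <- center_px[[2]]
  disk <- .disk_idx(dim(image), cx, cy, radius_px)
  ann <- .disk_idx(dim(image), cx, cy, annulus_factor * radius_px,
                   inner = radius_px)
  if (!length(ann)) stop("empty background annulus", call. = FALSE)
  if (!length(disk)) stop("spot disk outside image", call. = FALSE)
  raw <- sum(image[disk])
  bg <- stats::median(image[ann])
  list(raw_sum = raw,
       background_level = bg,
       net_signal = max(0, raw - bg * length(disk)),
       n_pixels = length(disk))
}

#' Aggregate replicate spot measurements for one probe
#'
#' Replicates farther than 3 MAD (scaled median absolute deviation,
#' [stats::mad()]) from the replicate median are flagged as outliers; the
#' aggregated signal is the median of the unflagged replicates. All
#' replicates flagged is an error.
#'
#' @param net_signals numeric vector of replicate net signals.
#' @return list: signal (median of kept replicates), flagged (logical
#'   vector), n_used.
#' @export
aggregate_replicates <- function(net_signals) {
  stopifnot(length(net_signals) >= 1L)
  med <- stats::median(net_signals)
  dev <- abs(net_signals - med)
  madv <- stats::mad(net_signals)
  flagged <- dev > 3 * madv
  if (all(flagged)) stop("all replicates flagged as outliers", call. = FALSE)
  list(signal = stats::median(net_signals[!flagged]),
       flagged = flagged,
       n_used = sum(!flagged))
}

#' Percent-of-total normalization
#'
#' Each probe's aggregated signal divided by the summed signal of all
#' probes, times 100, so profiles from different exposures are directly
#' comparable.
#'
#' @param signals named numeric vector, probe_id -> aggregated net signal.
#' @param metadata optional list attached to the profile (sample label,
#'   exposure, ...).
#' @return a `trna_profile` data frame: probe_id, net_signal,
#'   level_percent (summing to 100).
#' @export
normalize_profile <- function(signals, metadata = list()) {
  stopifnot(length(signals) >= 1L, !is.null(names(signals)))
  total <- sum(signals)
  if (total <= 0) stop("all signals are zero; nothing to normalize",
                       call. = FALSE)
  prof <- data.frame(probe_id = names(signals),
                     net_signal = as.numeric(signals),
                     level_percent = 100 * as.numeric(signals) / total,
                     stringsAsFactors = FALSE)
  structure(prof, class = c("trna_profile", "data.frame"),
            metadata = metadata)
}

#' Quantify a whole array image into a tRNA profile
#'
#' Pipeline: [register_grid()] -> [quantify_spot()] per spot ->
#' [aggregate_replicates()] per probe -> [normalize_profile()].
#' Deterministic for fixed inputs.
#'
#' @param image numeric matrix (counts).
#' @param layout an `array_layout`.
#' @param pixel_size_um micrometers per pixel (defaults to the image
#'   attribute, else 50).
#' @param radius_px spot integration radius, pixels.
#' @param search_px grid-registration search half-width (0 disables).
#' @param annulus_factor outer background-annulus radius multiplier.
#' @param metadata optional list stored on the profile.
#' @return a `trna_profile`; per-spot measurements are attached as the
#'   `spots` attribute (spot_id, probe_id, raw, background, net, flagged).
#' @export
quantify_array <- function(image, layout, pixel_size_um = NULL,
                           radius_px = 3, search_px = 2L,
                           annulus_factor = 2, metadata = list()) {
  px <- pixel_size_um %||% attr(image, "pixel_size_um") %||% 50
  fit <- if (search_px > 0L) {
    register_grid(image, layout, px, radius_px, search_px)
  } else {
    list(dx = 0L, dy = 0L, score = NA_real_)
  }
  ctr <- .centers_px(layout, px)
  meas <- lapply(seq_len(nrow(ctr)), function(i) {
    quantify_spot(image, c(ctr$cx[i] + fit$dx, ctr$cy[i] + fit$dy),
                  radius_px, annulus_factor)
  })
  spots <- data.frame(spot_id = ctr$spot_id,
                      probe_id = ctr$probe_id,
                      raw = vapply(meas, `[[`, 0, "raw_sum"),
                      background = vapply(meas, `[[`, 0, "background_level"),
                      net = vapply(meas, `[[`, 0, "net_signal"),
                      stringsAsFactors = FALSE)
  agg <- vapply(split(spots$net, spots$probe_id), function(v) {
    aggregate_replicates(v)$signal
  }, 0)
  flagged <- unsplit(lapply(split(spots$net, spots$probe_id), function(v) {
    aggregate_replicates(v)$flagged
  }), spots$probe_id)
  spots$flagged <- flagged
  # keep the layout's probe order
  agg <- agg[unique(layout$probe_id)]
  prof <- normalize_profile(agg, metadata = c(metadata,
                                              list(grid_fit = fit)))
  attr(prof, "spots") <- spots
  prof
}

#' Write a tRNA profile as TSV
#'
#' @param profile a `trna_profile`.
#' @param path output TSV (probe_id, net_signal, level_percent).
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "level_percent")
  if (!all(need %in% names(tab))) {
    stop("profile table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tab$net_signal)) tab$net_signal <- tab$level_percent
  structure(tab[, c("probe_id", "net_signal", "level_percent")],
            class = c("trna_profile", "data.frame"), metadata = list())
}
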