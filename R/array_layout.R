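# Spotted-array geometry: replicated probe spots on a regular grid with
# physical (micrometer) coordinates, serialized as a GAL-like TSV
# (Block / Row / Column / ID / Name plus coordinates).

#' Build a replicated spot layout
#'
#' Spots are assigned row-major on a regular grid with contiguous replicate
#' blocks per probe (replicate 1..r of probe 1, then probe 2, ...), which
#' mirrors manual pin-printing. An optional seeded shuffle scatters the
#' probe-to-position assignment for robustness testing.
#'
#' @param probe_set a `probe_set`, or a character vector of probe ids.
#' @param replicates spots per probe (>= 1).
#' @param grid_cols number of grid columns.
#' @param pitch_um center-to-center spot spacing, micrometers.
#' @param diameter_um printed spot diameter, micrometers.
#' @param grid_rows optional row count; defaults to the minimum that fits.
#' @param shuffle_seed optional integer; when given, spot positions are
#'   permuted reproducibly.
#' @return an `array_layout` data frame: spot_id, probe_id, block, row,
#'   col, x_um, y_um, diameter_um; attributes `replicates_per_probe`,
#'   `pitch_um`.
#' @export
build_layout <- function(probe_set, replicates = 8L, grid_cols = 24L,
                         pitch_um = 600, diameter_um = 300,
                         grid_rows = NULL, shuffle_seed = NULL) {
  probe_ids <- if (inherits(probe_set, "probe_set")) {
    probe_set$probes$probe_id
  } else {
    as.character(probe_set)
  }
  stopifnot(length(probe_ids) >= 1L, replicates >= 1L, grid_cols >= 1L,
            pitch_um > 0, diameter_um > 0)
  n <- length(probe_ids) * replicates
  need_rows <- ceiling(n / grid_cols)
  if (is.null(grid_rows)) grid_rows <- need_rows
  if (grid_rows * grid_cols < n) {
    stop("grid too small: ", grid_rows, "x", grid_cols, " < ", n, " spots",
         call. = FALSE)
  }
  idx <- seq_len(n)
  probe <- rep(probe_ids, each = replicates)
  if (!is.null(shuffle_seed)) {
    set.seed(as.integer(shuffle_seed))
    probe <- probe[sample.int(n)]
  }
  row <- ((idx - 1L) %/% grid_cols) + 1L
  col <- ((idx - 1L) %% grid_cols) + 1L
  layout <- data.frame(
    spot_id = sprintf("S%04d", idx),
    probe_id = probe,
    block = 1L,
    row = row,
    col = col,
    x_um = col * pitch_um,
    y_um = row * pitch_um,
    diameter_um = diameter_um,
    stringsAsFactors = FALSE
  )
  structure(layout, class = c("array_layout", "data.frame"),
            replicates_per_probe = as.integer(replicates),
            pitch_um = pitch_um)
}

#' Write a layout as a GAL-like TSV
#'
#' Tab-separated with columns Block, Row, Column, ID, Name, X_um, Y_um,
#' Dia_um (ID = spot id, Name = probe id). Coordinates are written with one
#' decimal (0.1 um), so write -> read round-trips and repeated writes are
#' byte-identical.
#'
#' @param layout an `array_layout`.
#' @param path output path.
#' @export
write_layout <- function(layout, path) {
  con <- file(path, "wb")  # binary mode: LF-only, byte-identical runs
  on.exit(close(con))
  writeLines("Block\tRow\tColumn\tID\tName\tX_um\tY_um\tDia_um", con)
  writeLines(sprintf("%d\t%d\t%d\t%s\t%s\t%.1f\t%.1f\t%.1f",
                     layout$block, layout$row, layout$col, layout$spot_id,
                     layout$probe_id, layout$x_um, layout$y_um,
                     layout$diameter_um), con)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("layout file has no spot rows: ", path,
                               call. = FALSE)
  header <- strsplit(lines[[1]], "\t")[[1]]
  need <- c("Block", "Row", "Column", "ID", "Name", "X_um", "Y_um", "Dia_um")
  if (!identical(header, need)) {
    stop("line 1: bad layout header, expected columns ",
         paste(need, collapse = "/"), call. = FALSE)
  }
  fields <- strsplit(lines[-1], "\t")
  nf <- vapply(fields, length, 1L)
  if (any(nf != 8L)) {
    stop("line ", which(nf != 8L)[[1]] + 1L, ": expected 8 fields, got ",
         nf[nf != 8L][[1]], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("line ", which(is.na(v))[[1]] + 1L,
                       ": non-numeric ", col, call. = FALSE)
    v
  }
  layout <- data.frame(
    spot_id = m[, 4], probe_id = m[, 5],
    block = as.integer(num(m[, 1], "Block")),
    row = as.integer(num(m[, 2], "Row")),
    col = as.integer(num(m[, 3], "Column")),
    x_um = num(m[, 6], "X_um"), y_um = num(m[, 7], "Y_um"),
    diameter_um = num(m[, 8], "Dia_um"),
    stringsAsFactors = FALSE
  )
  reps <- table(layout$probe_id)
  structure(layout, class = c("array_layout", "data.frame"),
            replicates_per_probe = if (length(unique(reps)) == 1L)
              as.integer(reps[[1]]) else NA_integer_,
            pitch_um = if (nrow(layout) > 1L)
              min(diff(sort(unique(layout$x_um)))) else NA_real_)
}
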