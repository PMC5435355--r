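# Degenerate probe-panel design.
#
# Probes are DNA 70-mers complementary to the 3' end of the mature tRNA
# body (terminal CCA excluded). Species whose 3' windows differ by fewer
# residues than the discrimination threshold cannot be told apart by
# hybridization and share a single probe, degenerated (IUPAC ambiguity
# codes) at the columns where their windows differ.

# IUPAC code <-> base-set lookup, built from Biostrings' canonical map.
.iupac_sets <- function() {
  m <- Biostrings::IUPAC_CODE_MAP
  stats::setNames(strsplit(m, ""), names(m))
}

.iupac_code_for <- function(bases) {
  m <- Biostrings::IUPAC_CODE_MAP
  key <- paste(sort(unique(bases)), collapse = "")
  hit <- names(m)[vapply(m, function(s) {
    paste(sort(strsplit(s, "")[[1]]), collapse = "") == key
  }, logical(1))]
  if (length(hit) != 1L) stop("no IUPAC code for base set {", key, "}",
                              call. = FALSE)
  hit
}

#' Probe-design parameters
#'
#' @param window_length probe/window length in nt; 70-mers discriminate
#'   species differing by roughly eight or more residues.
#' @param mismatch_threshold residues; species pairs whose windows differ by
#'   fewer than this many positions are merged onto one degenerate probe
#'   (strictly-less-than merge rule).
#' @param exclude_terminal_cca drop a terminal CCA before taking the window
#'   (the CCA end is universal and carries no discriminating information).
#' @param sodium_molarity monovalent-cation concentration (mol/L) used in
#'   the salt-adjusted melting-temperature formula; 0.3 M matches 2X SSC.
#' @return a `design_params` list.
#' @export
design_params <- function(window_length = 70L, mismatch_threshold = 8L,
                          exclude_terminal_cca = TRUE,
                          sodium_molarity = 0.3) {
  stopifnot(window_length >= 1L, mismatch_threshold >= 1L,
            sodium_molarity > 0)
  structure(list(window_length = as.integer(window_length),
                 mismatch_threshold = as.integer(mismatch_threshold),
                 exclude_terminal_cca = isTRUE(exclude_terminal_cca),
                 sodium_molarity = sodium_molarity),
            class = "design_params")
}

#' Extract the 3'-anchored probe window of a tRNA body
#'
#' Returns the last `window_length` residues of the CCA-less body (the
#' whole body when it is shorter than the window).
#'
#' @param sequence character vector of tRNA bodies (sense strand, 5'->3').
#' @param params a [design_params()] list.
#' @return character vector of windows.
#' @export
probe_window <- function(sequence, params = design_params()) {
  if (any(!nzchar(sequence))) stop("empty sequence", call. = FALSE)
  body <- sequence
  if (params$exclude_terminal_cca) {
    has_cca <- endsWith(body, "CCA")
    body[has_cca] <- substr(body[has_cca], 1L, nchar(body[has_cca]) - 3L)
  }
  n <- nchar(body)
  substr(body, pmax(1L, n - params$window_length + 1L), n)
}

#' Count mismatches between two 3'-anchored windows
#'
#' Windows are aligned at their 3' ends; each differing overlapped position
#' counts one mismatch, and each unpaired 5' residue of the longer window
#' also counts one. Symmetric, zero iff identical.
#'
#' @param a,b DNA windows (plain ACGT).
#' @return integer mismatch count.
#' @export
window_mismatch <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) stop("empty window", call. = FALSE)
  n <- min(na, nb)
  av <- substring(a, na - n + 1L, na)
  bv <- substring(b, nb - n + 1L, nb)
  diff <- sum(utf8ToInt(av) != utf8ToInt(bv))
  diff + abs(na - nb)
}

# windows of catalog species: their sequences are already CCA-less bodies,
# so the CCA exclusion must not be re-applied (a body can end in CCA by
# coincidence)
.catalog_windows <- function(species, params) {
  p <- params
  p$exclude_terminal_cca <- FALSE
  stats::setNames(probe_window(species$sequence, p), species$species_id)
}

# all-pairs mismatch matrix on a character vector of windows
.mismatch_matrix <- function(w) {
  n <- length(w)
  d <- matrix(0L, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d[i, j] <- d[j, i] <- window_mismatch(w[[i]], w[[j]])
      }
    }
  }
  d
}

#' Single-linkage clustering of species windows
#'
#' Two species fall in the same cluster when they are connected by a chain
#' of pairs each differing at fewer than `threshold` window positions
#' (strict `<`): any chain of near-identical isodecoders ends up on one
#' probe. Cluster order follows the position of each cluster's first member
#' in the input; members keep input order.
#'
#' @param windows named character vector, species_id -> window.
#' @param threshold mismatch threshold (merge when distance < threshold).
#' @return list of character vectors of species ids.
#' @export
cluster_species <- function(windows, threshold) {
  stopifnot(length(windows) >= 1L, !is.null(names(windows)))
  n <- length(windows)
  d <- .mismatch_matrix(windows)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && d[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  cl <- split(names(windows), root)
  cl <- cl[order(as.integer(names(cl)))]
  unname(cl)
}

#' IUPAC consensus of a cluster of windows
#'
#' Shorter windows are padded at their 5' end with a gap symbol treated as
#' fully degenerate (N). Each column becomes the IUPAC code of the union of
#' observed bases; the probe is the reverse complement of this consensus.
#'
#' @param windows character vector of ACGT windows.
#' @return list with `consensus` (target-strand IUPAC string), `probe`
#'   (reverse complement, 5'->3'), `degenerate_positions` (count of
#'   ambiguous columns).
#' @export
degenerate_consensus <- function(windows) {
  stopifnot(length(windows) >= 1L)
  if (any(grepl("[^ACGT]", windows))) {
    stop("non-DNA symbol in window", call. = FALSE)
  }
  L <- max(nchar(windows))
  padded <- vapply(windows, function(w) {
    paste0(strrep("-", L - nchar(w)), w)
  }, "")
  mat <- do.call(rbind, strsplit(padded, ""))
  cons <- vapply(seq_len(L), function(j) {
    col <- mat[, j]
    if (any(col == "-")) return("N")
    .iupac_code_for(col)
  }, "")
  consensus <- paste(cons, collapse = "")
  probe <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus)))
  list(consensus = consensus,
       probe = probe,
       degenerate_positions = sum(!cons %in% c("A", "C", "G", "T")))
}

#' Expected GC content of an IUPAC DNA string
#'
#' Ambiguity codes contribute their expected G+C fraction under a uniform
#' choice among their bases (W = 0, S = 1, N = 0.5, ...).
#'
#' @param sequence IUPAC DNA string(s).
#' @return percent GC, numeric vector.
#' @export
compute_gc <- function(sequence) {
  sets <- .iupac_sets()
  gc_frac <- vapply(sets, function(b) mean(b %in% c("G", "C")), 0)
  vapply(sequence, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    if (!all(ch %in% names(gc_frac))) {
      stop("invalid IUPAC symbol in sequence: '",
           ch[!ch %in% names(gc_frac)][[1]], "'", call. = FALSE)
    }
    100 * mean(gc_frac[ch])
  }, 0, USE.NAMES = FALSE)
}

#' Oligonucleotide melting temperature (salt-adjusted Marmur formula)
#'
#' `Tm = 81.5 + 16.6 log10([Na+]) + 0.41 GC% - 675 / length`, the classic
#' salt-corrected long-oligo relation. It depends on composition only, is
#' only trusted for oligos of at least 14 nt, and is the documented default;
#' callers can substitute any other model downstream since the probe table
#' carries plain sequences.
#'
#' @param sequence IUPAC DNA string(s), length >= 14.
#' @param sodium_molarity monovalent-cation molarity (> 0).
#' @return Tm in degrees Celsius.
#' @export
compute_tm <- function(sequence, sodium_molarity = 0.3) {
  if (sodium_molarity <= 0) stop("sodium molarity must be > 0", call. = FALSE)
  n <- nchar(sequence)
  if (any(n < 14L)) {
    stop("Tm formula requires length >= 14 nt", call. = FALSE)
  }
  81.5 + 16.6 * log10(sodium_molarity) + 0.41 * compute_gc(sequence) - 675 / n
}

# mismatches of a plain window against an IUPAC consensus, 3'-anchored;
# a base matches a column when it belongs to the column's base set
.consensus_mismatch <- function(window, consensus) {
  sets <- .iupac_sets()
  nw <- nchar(window); nc <- nchar(consensus)
  n <- min(nw, nc)
  wv <- strsplit(substring(window, nw - n + 1L, nw), "")[[1]]
  cv <- strsplit(substring(consensus, nc - n + 1L, nc), "")[[1]]
  ok <- mapply(function(b, code) b %in% sets[[code]], wv, cv)
  sum(!ok) + abs(nw - nc)
}

#' Audit a probe panel for cross-hybridization risk
#'
#' For every probe x non-target species, counts mismatches between the
#' species' 3' window and the probe's consensus window (IUPAC-aware).
#' Pairs below the discrimination threshold are flagged as
#' cross-hybridization risks.
#'
#' @param probe_set a `probe_set` from [design_probes()].
#' @param catalog the `trna_catalog` the panel was designed from.
#' @param params a [design_params()] list.
#' @return data frame probe_id, species_id, mismatches, flagged.
#' @export
cross_check <- function(probe_set, catalog,
                        params = probe_set$params) {
  sp <- catalog$species
  win <- .catalog_windows(sp, params)
  names(win) <- sp$species_id
  pr <- probe_set$probes
  rows <- vector("list", nrow(pr))
  for (i in seq_len(nrow(pr))) {
    others <- setdiff(sp$species_id, pr$targets[[i]])
    if (!length(others)) next
    mm <- vapply(others, function(s) {
      .consensus_mismatch(win[[s]], pr$consensus[[i]])
    }, 1)
    rows[[i]] <- data.frame(probe_id = pr$probe_id[[i]],
                            species_id = others,
                            mismatches = as.integer(mm),
                            stringsAsFactors = FALSE)
  }
  audit <- do.call(rbind, rows)
  if (is.null(audit)) {
    audit <- data.frame(probe_id = character(0), species_id = character(0),
                        mismatches = integer(0), stringsAsFactors = FALSE)
  }
  audit$flagged <- audit$mismatches < params$mismatch_threshold
  rownames(audit) <- NULL
  audit
}

# probe names from target species: "<aa>-<anticodon>" of the targets,
# "/"-joined across families, with -p<k> suffixes when several probes
# share a name (isodecoders split across probes)
.probe_names <- function(target_list, species) {
  fam <- stats::setNames(paste(species$amino_acid, species$anticodon,
                               sep = "-"), species$species_id)
  base <- vapply(target_list, function(t) {
    paste(sort(unique(fam[t])), collapse = "/")
  }, "")
  out <- base
  for (nm in unique(base[duplicated(base)])) {
    k <- which(base == nm)
    out[k] <- paste0(nm, "-p", seq_along(k))
  }
  out
}

#' Design the minimal degenerate probe panel for a catalog
#'
#' Runs the full pipeline: 3'-anchored windows, single-linkage clustering at
#' the mismatch threshold, IUPAC consensus and reverse complement per
#' cluster, GC / melting-temperature annotation, and a cross-hybridization
#' audit. Deterministic for a fixed catalog.
#'
#' @param catalog a `trna_catalog`.
#' @param params a [design_params()] list.
#' @return an object of class `probe_set`: list with `probes` (data frame:
#'   probe_id, sequence, consensus, targets (list column), n_targets,
#'   degenerate_positions, gc_percent, tm_celsius), `params`, `audit`.
#' @export
design_probes <- function(catalog, params = design_params()) {
  stopifnot(inherits(catalog, "trna_catalog"))
  sp <- catalog$species
  win <- .catalog_windows(sp, params)
  clusters <- cluster_species(win, params$mismatch_threshold)
  cons <- lapply(clusters, function(cl) degenerate_consensus(win[cl]))
  probes <- data.frame(
    probe_id = .probe_names(clusters, sp),
    sequence = vapply(cons, `[[`, "", "probe"),
    consensus = vapply(cons, `[[`, "", "consensus"),
    n_targets = vapply(clusters, length, 1L),
    degenerate_positions = vapply(cons, `[[`, 1L, "degenerate_positions"),
    stringsAsFactors = FALSE
  )
  probes$targets <- clusters
  probes$gc_percent <- compute_gc(probes$sequence)
  probes$tm_celsius <- compute_tm(probes$sequence, params$sodium_molarity)
  probes <- probes[, c("probe_id", "sequence", "consensus", "targets",
                       "n_targets", "degenerate_positions", "gc_percent",
                       "tm_celsius")]
  ps <- structure(list(probes = probes, params = params, audit = NULL),
                  class = "probe_set")
  ps$audit <- cross_check(ps, catalog, params)
  ps
}

#' @export
print.probe_set <- function(x, ...) {
  p <- x$probes
  cat("probe set: ", nrow(p), " probes covering ",
      sum(p$n_targets), " species (",
      sum(p$degenerate_positions > 0L), " degenerate probes)\n", sep = "")
  cat(sprintf("  mean GC %.1f%%, mean Tm %.1f C; %d cross-hyb flags\n",
              mean(p$gc_percent), mean(p$tm_celsius),
              sum(x$audit$flagged)))
  invisible(x)
}

#' Write / read a probe table as TSV
#'
#' Columns: probe_id, sequence, targets (comma-joined species ids),
#' degenerate_positions, gc_percent, tm_celsius. The consensus window is
#' included so the audit can be recomputed after a round trip.
#'
#' @param probe_set a `probe_set`.
#' @param path TSV path.
#' @export
write_probe_table <- function(probe_set, path) {
  p <- probe_set$probes
  out <- data.frame(probe_id = p$probe_id,
                    sequence = p$sequence,
                    targets = vapply(p$targets, paste, "", collapse = ","),
                    degenerate_positions = p$degenerate_positions,
                    gc_percent = sprintf("%.4f", p$gc_percent),
                    tm_celsius = sprintf("%.4f", p$tm_celsius),
                    consensus = p$consensus,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "sequence", "targets", "degenerate_positions")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("probe table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  probes <- data.frame(probe_id = tab$probe_id,
                       sequence = tab$sequence,
                       consensus = if ("consensus" %in% names(tab))
                         tab$consensus else NA_character_,
                       n_targets = lengths(strsplit(tab$targets, ",")),
                       degenerate_positions = tab$degenerate_positions,
                       gc_percent = if ("gc_percent" %in% names(tab))
                         as.numeric(tab$gc_percent) else
                           compute_gc(tab$sequence),
                       tm_celsius = if ("tm_celsius" %in% names(tab))
                         as.numeric(tab$tm_celsius) else
                           compute_tm(tab$sequence),
                       stringsAsFactors = FALSE)
  probes$targets <- strsplit(tab$targets, ",")
  structure(list(probes = probes, params = design_params(), audit = NULL),
            class = "probe_set")
}
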