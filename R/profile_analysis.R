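# Downstream analytics on tRNA profiles: replicate statistics, size-class
# fractions, fold change, gene-copy views, operon grouping, and
# wobble-aware codon-usage correlation.

.check_same_panel <- function(profiles) {
  ids <- lapply(profiles, function(p) p$probe_id)
  if (!all(vapply(ids[-1], identical, TRUE, ids[[1]]))) {
    stop("profiles do not share the same probe panel", call. = FALSE)
  }
  ids[[1]]
}

#' Replicate statistics across arrays
#'
#' Per-probe median, standard deviation and coefficient of variation
#' (100 * SD / mean) of the percent levels across two or more replicate
#' arrays, plus panel-level medians of those statistics. The CV is the
#' "false change" attributable to technical error: the apparent relative
#' change one would see between replicate arrays of the same sample.
#'
#' @param profiles list of >= 2 `trna_profile`s sharing one probe panel.
#' @return list with `per_probe` (data frame: probe_id, median_level,
#'   sd_level, cv_percent) and `panel` (median_level, median_sd, median_cv).
#' @export
replicate_stats <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2L)
  ids <- .check_same_panel(profiles)
  lev <- vapply(profiles, function(p) p$level_percent,
                numeric(length(ids)))
  per_probe <- data.frame(
    probe_id = ids,
    median_level = apply(lev, 1, stats::median),
    sd_level = apply(lev, 1, stats::sd),
    stringsAsFactors = FALSE
  )
  per_probe$cv_percent <- 100 * per_probe$sd_level / rowMeans(lev)
  list(per_probe = per_probe,
       panel = list(median_level = stats::median(per_probe$median_level),
                    median_sd = stats::median(per_probe$sd_level),
                    median_cv = stats::median(per_probe$cv_percent)))
}

# probe -> single size class of its targets (mixed classes are an error)
.probe_class <- function(probe_set, catalog) {
  cls <- stats::setNames(catalog$species$size_class,
                         catalog$species$species_id)
  vapply(seq_len(nrow(probe_set$probes)), function(i) {
    k <- unique(cls[probe_set$probes$targets[[i]]])
    if (length(k) != 1L || anyNA(k)) {
      stop("probe '", probe_set$probes$probe_id[[i]],
           "' targets species of mixed or unknown size class",
           call. = FALSE)
    }
    k
  }, "")
}

#' Size-class fractions of a profile
#'
#' Sums percent levels by tRNA size class; the two fractions are exactly
#' complementary (class I + class II = 100).
#'
#' @param profile a `trna_profile`.
#' @param probe_set the `probe_set` used on the array.
#' @param catalog the `trna_catalog`.
#' @return named numeric vector c(class_I, class_II) in percent.
#' @export
class_fractions <- function(profile, probe_set, catalog) {
  cls <- .probe_class(probe_set, catalog)
  names(cls) <- probe_set$probes$probe_id
  lev <- stats::setNames(profile$level_percent, profile$probe_id)
  ci <- sum(lev[names(cls)[cls == "I"]])
  c(class_I = ci, class_II = 100 - ci)
}

#' Fold change of a profile against a control
#'
#' Ratio of percent levels, probe by probe. Probes with zero control level
#' are reported as undefined (NA ratio, flagged), not infinite.
#'
#' @param profile,control_profile `trna_profile`s on the same panel.
#' @return data frame: probe_id, level, control_level, fold, undefined.
#' @export
fold_change <- function(profile, control_profile) {
  .check_same_panel(list(profile, control_profile))
  undef <- control_profile$level_percent <= 0
  data.frame(probe_id = profile$probe_id,
             level = profile$level_percent,
             control_level = control_profile$level_percent,
             fold = ifelse(undef, NA_real_,
                           profile$level_percent /
                             control_profile$level_percent),
             undefined = undef,
             stringsAsFactors = FALSE)
}

# total gene copies behind each probe (sum over its target species)
.probe_copies <- function(probe_set, catalog) {
  cp <- stats::setNames(catalog$species$gene_copies,
                        catalog$species$species_id)
  stats::setNames(
    vapply(probe_set$probes$targets, function(t) sum(cp[t]), 0),
    probe_set$probes$probe_id)
}

#' Median level per gene-copy-number group
#'
#' Probes are grouped by the total number of gene copies encoding their
#' targets; each group's median percent level is reported.
#'
#' @param profile a `trna_profile`.
#' @param probe_set,catalog panel and catalog.
#' @return named numeric vector, copy number -> median level.
#' @export
copy_group_medians <- function(profile, probe_set, catalog) {
  copies <- .probe_copies(probe_set, catalog)
  lev <- stats::setNames(profile$level_percent, profile$probe_id)
  g <- split(lev[names(copies)], copies)
  vapply(g, stats::median, 0)
}

#' Per-gene-copy expression levels
#'
#' Divides each probe's percent level by the number of gene copies encoding
#' its targets. With loci in the catalog, the result is expanded to one row
#' per gene, ordered by locus midpoint along the replicon (a per-copy
#' chromosomal view); otherwise one row per probe.
#'
#' @param profile a `trna_profile`.
#' @param probe_set,catalog panel and catalog.
#' @param by_locus expand to gene loci when available.
#' @return data frame with probe_id, per_copy_level and, per gene, gene_id,
#'   chrom and midpoint when `by_locus` and loci are present.
#' @export
per_copy_levels <- function(profile, probe_set, catalog, by_locus = TRUE) {
  copies <- .probe_copies(probe_set, catalog)
  stopifnot(all(copies >= 1))
  lev <- stats::setNames(profile$level_percent, profile$probe_id)
  per_probe <- data.frame(probe_id = names(copies),
                          copies = as.integer(copies),
                          level_percent = as.numeric(lev[names(copies)]),
                          per_copy_level = as.numeric(lev[names(copies)]) /
                            copies,
                          stringsAsFactors = FALSE)
  has_loci <- all(c("chrom", "start", "end") %in% names(catalog$genes))
  if (!by_locus || !has_loci) return(per_probe)
  sp2probe <- stats::setNames(
    rep(probe_set$probes$probe_id, lengths(probe_set$probes$targets)),
    unlist(probe_set$probes$targets))
  g <- catalog$genes
  g$probe_id <- sp2probe[g$species_id]
  g$midpoint <- (g$start + g$end) / 2
  out <- merge(g[, c("gene_id", "species_id", "probe_id", "chrom",
                     "midpoint")],
               per_probe, by = "probe_id")
  out <- out[order(out$chrom, out$midpoint), ]
  rownames(out) <- NULL
  out
}

#' Mean per-copy level by operon group
#'
#' Genes are grouped by their operon label (catalog `operons`; unlabeled
#' genes fall into `"other"`), e.g. to compare tRNA genes co-transcribed
#' with rRNA against the rest. Within each group the mean and SD of the
#' per-gene-copy levels are reported.
#'
#' @param profile a `trna_profile`.
#' @param probe_set,catalog panel and catalog (catalog should carry operon
#'   labels; all-"other" output results otherwise).
#' @return data frame: group, n_genes, mean_per_copy, sd_per_copy.
#' @export
group_mean_per_copy <- function(profile, probe_set, catalog) {
  copies <- .probe_copies(probe_set, catalog)
  lev <- stats::setNames(profile$level_percent, profile$probe_id)
  sp2probe <- stats::setNames(
    rep(probe_set$probes$probe_id, lengths(probe_set$probes$targets)),
    unlist(probe_set$probes$targets))
  g <- catalog$genes
  g$probe_id <- sp2probe[g$species_id]
  g$per_copy <- as.numeric(lev[g$probe_id]) / copies[g$probe_id]
  lab <- rep("other", nrow(g))
  if (!is.null(catalog$operons)) {
    j <- match(g$gene_id, names(catalog$operons))
    lab[!is.na(j)] <- unname(catalog$operons[j[!is.na(j)]])
  }
  res <- do.call(rbind, lapply(split(g$per_copy, lab), function(v) {
    data.frame(n_genes = length(v), mean_per_copy = mean(v),
               sd_per_copy = if (length(v) > 1L) stats::sd(v) else 0)
  }))
  res <- data.frame(group = rownames(res), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  res[order(res$group), ]
}

#' Default anticodon-wobble decoding rules
#'
#' Maps the anticodon wobble base (position 34, the first base of the
#' anticodon written 5'->3', in DNA alphabet) to the codon third bases it
#' can read: the standard Crick wobble set, with A treated as inosine
#' (reads U, C and A). Overridable per wobble base.
#'
#' @param overrides optional named list, wobble base -> character vector of
#'   readable codon third bases (DNA alphabet).
#' @return named list G/C/T/A -> readable third bases.
#' @export
default_decoding_rules <- function(overrides = NULL) {
  rules <- list(G = c("C", "T"),  # G34 reads C and U(T)
                C = "G",          # C34 reads G only
                T = c("A", "G"),  # U34 reads A and G
                A = c("T", "C", "A"))  # A34 as inosine: U, C, A
  if (!is.null(overrides)) {
    stopifnot(all(names(overrides) %in% names(rules)))
    rules[names(overrides)] <- overrides
  }
  if (any(lengths(rules) < 1L)) stop("every wobble base must read >= 1 codon",
                                     call. = FALSE)
  rules
}

.SENSE_CODONS <- {
  b <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# sense codons a species' anticodon can decode under the rules
.decoded_codons <- function(anticodon, rules) {
  ac <- strsplit(anticodon, "")[[1]]
  c1 <- .COMP[[ac[3]]]
  c2 <- .COMP[[ac[2]]]
  third <- rules[[ac[1]]]
  if (is.null(third)) stop("no decoding rule for wobble base ", ac[1],
                           call. = FALSE)
  intersect(paste0(c1, c2, third), .SENSE_CODONS)
}

#' Effective codon frequency decoded by each tRNA species
#'
#' A species decodes the sense codons whose first two bases Watson-Crick
#' pair anticodon positions 36 and 35 and whose third base is readable by
#' the wobble base (position 34) under `rules`. Each codon's usage is
#' shared equally among all catalog species decoding it
#' (`mode = "equal_split"`), which conserves total usage mass; the
#' `"winner_takes_all"` mode instead credits the full usage of a codon to
#' every decoder (for sensitivity analysis; not mass-conserving).
#'
#' @param codon_usage data frame with columns `codon` (DNA alphabet) and
#'   `frequency`, covering all sense codons.
#' @param catalog a `trna_catalog`.
#' @param rules decoding rules from [default_decoding_rules()].
#' @param mode `"equal_split"` (default) or `"winner_takes_all"`.
#' @return named numeric vector, species_id -> effective decoded frequency.
#'   Codons decoded by no species are reported in a warning.
#' @export
effective_codon_frequency <- function(codon_usage, catalog,
                                      rules = default_decoding_rules(),
                                      mode = c("equal_split",
                                               "winner_takes_all")) {
  mode <- match.arg(mode)
  stopifnot(all(c("codon", "frequency") %in% names(codon_usage)))
  codon_usage$codon <- toupper(codon_usage$codon)
  missing_c <- setdiff(.SENSE_CODONS, codon_usage$codon)
  if (length(missing_c)) {
    stop("codon usage table is missing sense codon(s): ",
         paste(utils::head(missing_c, 5L), collapse = ", "), call. = FALSE)
  }
  usage <- stats::setNames(codon_usage$frequency, codon_usage$codon)
  sp <- catalog$species
  dec <- lapply(sp$anticodon, .decoded_codons, rules = rules)
  names(dec) <- sp$species_id
  n_dec <- table(unlist(dec))
  orphan <- setdiff(.SENSE_CODONS, names(n_dec))
  if (length(orphan)) {
    warning("codon(s) decoded by no catalog species: ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }
  vapply(dec, function(cs) {
    if (!length(cs)) return(0)
    w <- if (mode == "equal_split") as.numeric(n_dec[cs]) else 1
    sum(usage[cs] / w)
  }, 0)
}

#' Correlate a profile with effective codon frequencies
#'
#' Squared Pearson correlation between per-probe percent levels and the
#' effective decoded codon frequency summed over each probe's targets.
#' Probes targeting selenocysteine tRNA are excluded by default (UGA
#' readthrough is context-dependent, not routine decoding).
#'
#' @param profile a `trna_profile`.
#' @param eff_freq species-level frequencies from
#'   [effective_codon_frequency()].
#' @param probe_set the probe panel.
#' @param catalog the catalog (used for the default SeC exclusion).
#' @param exclude character vector of probe ids to drop first; `NULL` means
#'   the default SeC exclusion, `character(0)` disables exclusion.
#' @return list: r_squared, n (points used), excluded (probe ids).
#' @export
correlate_codon_usage <- function(profile, eff_freq, probe_set,
                                  catalog = NULL, exclude = NULL) {
  p <- probe_set$probes
  if (is.null(exclude)) {
    exclude <- character(0)
    if (!is.null(catalog)) {
      sec <- catalog$species$species_id[catalog$species$amino_acid == "SeC"]
      exclude <- p$probe_id[vapply(p$targets, function(t) {
        any(t %in% sec)
      }, TRUE)]
    }
  }
  keep <- setdiff(profile$probe_id, exclude)
  x <- stats::setNames(profile$level_percent, profile$probe_id)[keep]
  f <- vapply(p$targets, function(t) sum(eff_freq[t]), 0)
  names(f) <- p$probe_id
  y <- f[keep]
  if (length(x) < 3L) stop("fewer than 3 points to correlate", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in levels or frequencies", call. = FALSE)
  }
  list(r_squared = stats::cor(x, y)^2,
       n = length(x),
       excluded = exclude)
}
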