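# Catalog of tRNA genes and deduplicated species.
#
# A catalog holds two tables: one row per gene (as found in the input FASTA,
# optionally with a chromosomal locus) and one row per unique mature sequence
# ("species"), with the number of gene copies encoding it. Species are the
# unit the probe-design module works on; genes are the unit the per-copy and
# operon analyses work on.

# Amino-acid vocabulary. Initiator methionine keeps its own label (fMet/iMet)
# so that initiator and elongator species get distinct probe names, but both
# behave as Met for size-class purposes.
.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val", "SeC", "fMet", "iMet")

.AA1 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", U = "SeC")

# Class II acceptors (long variable arm); everything else is class I.
.CLASS_II_AA <- c("Leu", "Ser", "SeC", "Tyr")

#' Normalize an amino-acid code
#'
#' Accepts three-letter codes (case-insensitive; `SeC`, `fMet` and `iMet`
#' allowed) or one-letter codes (`U` = selenocysteine). Unknown codes are an
#' error.
#'
#' @param x character vector of amino-acid codes.
#' @return character vector of canonical three-letter codes.
#' @export
normalize_aa <- function(x) {
  x <- as.character(x)
  out <- character(length(x))
  lut3 <- stats::setNames(.AA3, tolower(.AA3))
  for (i in seq_along(x)) {
    xi <- x[[i]]
    if (nchar(xi) == 1L && toupper(xi) %in% names(.AA1)) {
      out[[i]] <- .AA1[[toupper(xi)]]
    } else if (tolower(xi) %in% names(lut3)) {
      out[[i]] <- lut3[[tolower(xi)]]
    } else {
      stop("unknown amino-acid code: '", xi, "'", call. = FALSE)
    }
  }
  out
}

#' Assign the tRNA size class
#'
#' Class II comprises the leucine, serine, selenocysteine and tyrosine
#' acceptors (long variable arm, 85--93 nt mature length); all other
#' acceptors are class I (74--77 nt). The amino-acid rule is authoritative.
#' When mature lengths are supplied, the length-based rule (74--77 nt
#' implies I, 85--93 nt implies II) is evaluated as a consistency check and
#' a warning names any species where the two rules disagree; lengths in the
#' 78--84 nt gap are not checked.
#'
#' @param amino_acid character vector of amino-acid codes (see
#'   [normalize_aa()]); initiator methionine counts as Met.
#' @param length_nt optional integer vector of mature lengths (CCA included).
#' @return character vector of `"I"` / `"II"`.
#' @export
assign_size_class <- function(amino_acid, length_nt = NULL) {
  aa <- normalize_aa(amino_acid)
  aa[aa %in% c("fMet", "iMet")] <- "Met"
  cls <- ifelse(aa %in% .CLASS_II_AA, "II", "I")
  if (!is.null(length_nt)) {
    stopifnot(length(length_nt) == length(aa))
    by_len <- rep(NA_character_, length(aa))
    by_len[length_nt >= 74 & length_nt <= 77] <- "I"
    by_len[length_nt >= 85 & length_nt <= 93] <- "II"
    bad <- !is.na(by_len) & by_len != cls
    if (any(bad)) {
      warning("size-class rules disagree (amino-acid rule kept) for: ",
              paste0(amino_acid[bad], " (", length_nt[bad], " nt)",
                     collapse = ", "),
              call. = FALSE)
    }
  }
  cls
}

# Header conventions: a regex with two capture groups (amino acid, anticodon).
.HEADER_CONVENTIONS <- list(
  # e.g. ">Ecoli_tRNA-Ala-TGC-1-1" or ">tRNA-fMet-CAT-2"
  gtrnadb = "tRNA-([A-Za-z]{1,4})-([ACGTacgt]{3})"
)

.parse_header <- function(headers, convention) {
  rx <- if (convention %in% names(.HEADER_CONVENTIONS)) {
    .HEADER_CONVENTIONS[[convention]]
  } else {
    convention  # treated as a user-supplied regex with two groups
  }
  m <- regexec(rx, headers)
  parts <- regmatches(headers, m)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) {
    stop("FASTA header does not match the '", convention, "' convention: '",
         headers[bad][[1]], "'", call. = FALSE)
  }
  data.frame(
    amino_acid = normalize_aa(vapply(parts, `[[`, "", 2L)),
    anticodon  = toupper(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Parse a tRNA gene FASTA into a catalog
#'
#' Reads mature tRNA gene sequences, validates them, strips a terminal CCA
#' when present (a flag records which form was supplied; probe windows are
#' taken on the CCA-less body), and collapses identical mature sequences
#' into species with a gene-copy count. Species are ordered deterministically
#' by amino acid, anticodon, then sequence, and named
#' `<aa>-<anticodon>-<k>` with `k` numbering isodecoders within a family.
#'
#' @param fasta path to a FASTA file of mature sense-strand tRNA gene
#'   sequences (each at least 70 nt).
#' @param header_convention `"gtrnadb"` (default; headers contain
#'   `tRNA-<aa>-<anticodon>-...`) or a custom regex whose first two capture
#'   groups are the amino acid and the anticodon.
#' @param loci_bed optional path to a 6-column BED file of gene loci
#'   (0-based half-open); the BED `name` column must match gene ids.
#' @param operons optional named character vector mapping gene ids to operon
#'   labels (e.g. rRNA-operon membership).
#' @return an object of class `trna_catalog`: a list with data frames
#'   `genes` (gene_id, amino_acid, anticodon, sequence, length_mature,
#'   had_cca, species_id, and locus columns when a BED was given) and
#'   `species` (species_id, amino_acid, anticodon, sequence, length_mature,
#'   gene_copies, size_class), plus `operons`.
#' @export
parse_gene_fasta <- function(fasta, header_convention = "gtrnadb",
                             loci_bed = NULL, operons = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta, call. = FALSE)
  headers <- names(seqs)
  gene_id <- vapply(strsplit(headers, "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(gene_id)) stop("duplicated gene ids in FASTA", call. = FALSE)
  meta <- .parse_header(headers, header_convention)
  seq_chr <- toupper(as.character(seqs))
  if (any(grepl("[^ACGT]", seq_chr))) {
    stop("non-ACGT symbol in gene sequence: ",
         gene_id[grepl("[^ACGT]", seq_chr)][[1]], call. = FALSE)
  }
  len <- nchar(seq_chr)
  if (any(len < 70L)) {
    stop("tRNA gene shorter than 70 nt: ", gene_id[len < 70L][[1]],
         call. = FALSE)
  }
  had_cca <- endsWith(seq_chr, "CCA")
  body <- ifelse(had_cca, substr(seq_chr, 1L, len - 3L), seq_chr)
  length_mature <- ifelse(had_cca, len, len + 3L)  # canonical CCA-full length

  genes <- data.frame(gene_id = gene_id,
                      amino_acid = meta$amino_acid,
                      anticodon = meta$anticodon,
                      sequence = body,
                      length_mature = length_mature,
                      had_cca = had_cca,
                      stringsAsFactors = FALSE)

  # collapse identical mature bodies into species
  key <- genes$sequence
  grp <- split(seq_len(nrow(genes)), key)
  first <- vapply(grp, `[[`, 1L, 1L)
  sp <- data.frame(amino_acid = genes$amino_acid[first],
                   anticodon = genes$anticodon[first],
                   sequence = names(grp),
                   length_mature = genes$length_mature[first],
                   gene_copies = vapply(grp, length, 1L),
                   stringsAsFactors = FALSE)
  # genes collapsed into one species must agree on the header annotation
  for (g in grp) {
    if (length(unique(genes$amino_acid[g])) > 1L ||
        length(unique(genes$anticodon[g])) > 1L) {
      stop("genes with identical sequences carry conflicting annotations: ",
           paste(genes$gene_id[g], collapse = ", "), call. = FALSE)
    }
  }
  ord <- order(sp$amino_acid, sp$anticodon, sp$sequence)
  sp <- sp[ord, , drop = FALSE]
  fam <- paste(sp$amino_acid, sp$anticodon, sep = "-")
  idx <- stats::ave(seq_len(nrow(sp)), fam, FUN = seq_along)
  sp$species_id <- paste0(fam, "-", idx)
  sp$size_class <- assign_size_class(sp$amino_acid, sp$length_mature)
  sp <- sp[, c("species_id", "amino_acid", "anticodon", "sequence",
               "length_mature", "gene_copies", "size_class")]
  rownames(sp) <- NULL

  genes$species_id <- sp$species_id[match(genes$sequence, sp$sequence)]

  if (!is.null(loci_bed)) {
    loci <- read_loci_bed(loci_bed)
    j <- match(genes$gene_id, loci$name)
    if (anyNA(j)) {
      stop("BED loci missing for gene(s): ",
           paste(utils::head(genes$gene_id[is.na(j)], 3L), collapse = ", "),
           call. = FALSE)
    }
    genes$chrom <- loci$chrom[j]
    genes$start <- loci$start[j]
    genes$end <- loci$end[j]
    genes$strand <- loci$strand[j]
  }

  op <- NULL
  if (!is.null(operons)) {
    stopifnot(!is.null(names(operons)))
    unknown <- setdiff(names(operons), genes$gene_id)
    if (length(unknown)) {
      stop("operon labels for unknown gene(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    op <- operons
  }

  structure(list(genes = genes, species = sp, operons = op),
            class = "trna_catalog")
}

#' @export
print.trna_catalog <- function(x, ...) {
  cat("tRNA catalog: ", nrow(x$genes), " genes, ", nrow(x$species),
      " species, ", length(unique(x$species$anticodon)),
      " isoacceptor families\n", sep = "")
  cat("  size classes: ",
      sum(x$species$size_class == "I"), " class I / ",
      sum(x$species$size_class == "II"), " class II species\n", sep = "")
  invisible(x)
}

#' Group catalog species into isoacceptor families
#'
#' Families are keyed by the anticodon; every species belongs to exactly one
#' family.
#'
#' @param catalog a `trna_catalog`.
#' @return named list, anticodon -> character vector of species ids.
#' @export
group_isoacceptors <- function(catalog) {
  stopifnot(inherits(catalog, "trna_catalog"), nrow(catalog$species) > 0L)
  sp <- catalog$species
  fam <- split(sp$species_id, sp$anticodon)
  fam[order(names(fam))]
}

#' Read a 6-column BED file of gene loci
#'
#' Coordinates are 0-based half-open, as in the BED standard.
#'
#' @param path BED file path.
#' @return data frame with chrom, start, end, name, score, strand.
#' @export
read_loci_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  if (any(bed$start >= bed$end)) {
    stop("BED interval with start >= end: ",
         bed$name[bed$start >= bed$end][[1]], call. = FALSE)
  }
  bed
}

#' Write the species table of a catalog to TSV
#'
#' Columns: species_id, amino_acid, anticodon, copies, class, sequence
#' (CCA-less body).
#'
#' @param catalog a `trna_catalog`.
#' @param path output TSV path.
#' @export
write_catalog <- function(catalog, path) {
  sp <- catalog$species
  out <- data.frame(species_id = sp$species_id,
                    amino_acid = sp$amino_acid,
                    anticodon = sp$anticodon,
                    copies = sp$gene_copies,
                    class = sp$size_class,
                    sequence = sp$sequence,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write catalog genes back to FASTA
#'
#' Emits one record per gene copy with a gtRNAdb-style header
#' (`<gene_id> tRNA-<aa>-<anticodon>`). The terminal CCA is re-appended for
#' genes whose input carried it, so write followed by [parse_gene_fasta()]
#' round-trips the catalog.
#'
#' @param catalog a `trna_catalog`.
#' @param path output FASTA path.
#' @export
write_gene_fasta <- function(catalog, path) {
  g <- catalog$genes
  seqs <- ifelse(g$had_cca, paste0(g$sequence, "CCA"), g$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(g))) {
    writeLines(c(paste0(">", g$gene_id[i], " tRNA-", g$amino_acid[i], "-",
                        g$anticodon[i]),
                 seqs[i]), con)
  }
  invisible(path)
}
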