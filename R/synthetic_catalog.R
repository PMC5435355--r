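# Synthetic E. coli-like tRNA gene set.
#
# The real K-12 census that the array targets has 86 intron-less tRNA genes
# collapsing to 48 unique mature sequences in 40 anticodon families, with
# six probe-level isodecoder groups (Leu-CAG, initiator Met, elongator Met,
# Tyr-GTA, Val-GAC, Thr-GGT) differing at one to five window positions.
# This generator emits a SYNTHETIC gene set with exactly that census
# structure -- counts, family layout, copy numbers, size classes, isodecoder
# distances -- but with randomly drawn sequence bodies (57% GC), so it is a
# stand-in for the real gene set, not a copy of it. Everything downstream
# (probe design, layout, simulation, quantification, analytics) can be
# exercised end to end on it.

# family table: amino acid, anticodon, copies per species ("/"-separated =
# several isodecoder species), window mismatches between isodecoder pairs
# (0 = unrelated random sequences, i.e. a far pair kept on separate probes)
.SYN_FAMILIES <- local({
  txt <- c(
    "Ala TGC 3    0", "Ala GGC 2    0",
    "Arg ACG 4    0", "Arg CCG 1    0", "Arg TCT 1    0", "Arg CCT 1    0",
    "Asn GTT 4    0",
    "Asp GTC 3    0",
    "Cys GCA 1    0",
    "Gln TTG 2    0", "Gln CTG 2    0",
    "Glu TTC 5    0",
    "Gly GCC 4    0", "Gly TCC 1    0", "Gly CCC 1    0",
    "His GTG 1    0",
    "Ile GAT 3    0",
    "Leu GAG 1    0", "Leu TAG 1    0", "Leu CAA 1    0", "Leu TAA 1    0",
    "Leu CAG 3/1  2",   # isodecoder pair, 2 window mismatches -> merged
    "Lys TTT 6    0",
    "fMet CAT 2/1 1",   # initiator pair, 1 mismatch -> merged
    "Met CAT 2/1  3",   # elongator pair, 3 mismatches -> merged
    "Phe GAA 1    0",
    "Pro TGG 1    0", "Pro CGG 1    0", "Pro GGG 2    0",
    "Ser CGA 1    0", "Ser GCT 1    0", "Ser GGA 2    0",
    "Ser TGA 2/1  0",   # far isodecoder pair -> two separate probes
    "SeC TCA 1    0",
    "Thr TGT 1    0", "Thr CGT 2    0",
    "Thr GGT 2/1  5",   # isodecoder pair, 5 mismatches -> merged
    "Trp CCA 1    0",
    "Tyr GTA 2/1  2",   # isodecoder pair, 2 mismatches -> merged
    "Val TAC 1    0", "Val GAC 2/1 1"  # Val pair, 1 mismatch -> merged
  )
  f <- read.table(text = txt, col.names = c("aa", "anticodon", "copies",
                                            "pair_mismatch"),
                  stringsAsFactors = FALSE)
  f
})

# draw a random DNA body with the anticodon planted at positions 34-36
.syn_body <- function(len, anticodon, gc = 0.57) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  b <- sample(names(p), len, replace = TRUE, prob = p)
  b[34:36] <- strsplit(anticodon, "")[[1]]
  paste(b, collapse = "")
}

# mutate k positions of a body, restricted to its last-70 window and away
# from the planted anticodon, each to a different base
.syn_mutate <- function(body, k) {
  ch <- strsplit(body, "")[[1]]
  n <- length(ch)
  pool <- setdiff(seq.int(max(1L, n - 69L), n), 34:36)
  pos <- sample(pool, k)
  for (j in pos) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic E. coli-like tRNA gene set
#'
#' Produces a seeded, fully synthetic gene catalog with the census structure
#' of the E. coli K-12 tRNA complement: 86 genes, 48 unique species, 40
#' anticodon families, gene copies between 1 and 6, class II sizes for the
#' Leu/Ser/SeC/Tyr acceptors, six isodecoder pairs one to five window
#' mismatches apart (so the designed panel has 42 probes, six of them
#' degenerate) plus one distant isodecoder pair that stays on separate
#' probes. Sequence bodies are random at 57% GC -- they are NOT the real
#' gene sequences. Loci are scattered over a 4.64-Mb circular chromosome
#' and 14 genes of 6 species carry an `"rrn"` operon label, mimicking the
#' mixed tRNA/rRNA operons.
#'
#' @param seed integer seed; the catalog is a deterministic function of it.
#' @param fasta,bed optional paths; when given, the gene FASTA / 6-column
#'   BED of loci are also written there.
#' @return a `trna_catalog` (see [parse_gene_fasta()]) with operon labels.
#' @export
synthetic_ecoli_catalog <- function(seed = 101L, fasta = NULL, bed = NULL) {
  set.seed(as.integer(seed))
  fam <- .SYN_FAMILIES
  fam$aa_canon <- ifelse(fam$aa %in% c("fMet", "iMet"), "Met", fam$aa)
  fam$class2 <- fam$aa_canon %in% c("Leu", "Ser", "SeC", "Tyr")

  species <- list()
  for (i in seq_len(nrow(fam))) {
    copies <- as.integer(strsplit(fam$copies[i], "/")[[1]])
    n_sp <- length(copies)
    mature_len <- if (fam$class2[i]) sample(85:93, 1L) else sample(74:77, 1L)
    body_len <- mature_len - 3L  # CCA appended in the FASTA
    base <- .syn_body(body_len, fam$anticodon[i])
    for (s in seq_len(n_sp)) {
      body <- if (s == 1L) {
        base
      } else if (fam$pair_mismatch[i] > 0L) {
        .syn_mutate(base, fam$pair_mismatch[i])
      } else {
        .syn_body(body_len, fam$anticodon[i])  # far pair: unrelated body
      }
      species[[length(species) + 1L]] <- data.frame(
        aa = fam$aa[i], anticodon = fam$anticodon[i], body = body,
        copies = copies[s], stringsAsFactors = FALSE)
    }
  }
  species <- do.call(rbind, species)

  # expand species to gene copies with loci on a circular chromosome
  genome_len <- 4641652L
  n_genes <- sum(species$copies)
  starts <- sort(sample.int(genome_len - 200L, n_genes))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gi <- 0L
  fasta_lines <- character(0)
  bed_rows <- vector("list", n_genes)
  gene_ids <- character(n_genes)
  sp_of_gene <- integer(n_genes)
  for (i in seq_len(nrow(species))) {
    for (k in seq_len(species$copies[i])) {
      gi <- gi + 1L
      gene_ids[gi] <- sprintf("synEc_tRNA-%s-%s-%d-%d", species$aa[i],
                              species$anticodon[i], i, k)
      sp_of_gene[gi] <- i
      seq_full <- paste0(species$body[i], "CCA")
      fasta_lines <- c(fasta_lines, paste0(">", gene_ids[gi]), seq_full)
      bed_rows[[gi]] <- data.frame(
        chrom = "chr", start = starts[gi],
        end = starts[gi] + nchar(seq_full), name = gene_ids[gi],
        score = 0L, strand = strand[gi], stringsAsFactors = FALSE)
    }
  }
  bed_tab <- do.call(rbind, bed_rows)

  fasta_path <- fasta %||% tempfile(fileext = ".fa")
  bed_path <- bed %||% tempfile(fileext = ".bed")
  writeLines(fasta_lines, fasta_path)
  utils::write.table(bed_tab, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # 14 genes of 6 species sit in mixed tRNA/rRNA operons
  rrn_species <- list(c("Glu", "TTC", 4L), c("Ile", "GAT", 3L),
                      c("Ala", "TGC", 3L), c("Asp", "GTC", 2L),
                      c("Trp", "CCA", 1L), c("His", "GTG", 1L))
  operons <- character(0)
  for (r in rrn_species) {
    hit <- grep(sprintf("^synEc_tRNA-%s-%s-", r[[1]], r[[2]]), gene_ids,
                value = TRUE)
    operons <- c(operons, stats::setNames(rep("rrn", as.integer(r[[3]])),
                                          utils::head(hit, as.integer(r[[3]]))))
  }

  parse_gene_fasta(fasta_path, header_convention = "gtrnadb",
                   loci_bed = bed_path, operons = operons)
}
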