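# Shared fixture builders: everything is generated in code at test time.

# random ACGT body of length n (optionally at a target GC), seeded
rand_body <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# write a toy gene FASTA; records = list(list(id, aa, anticodon, seq), ...)
write_toy_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(records, function(r) {
    c(sprintf(">%s_tRNA-%s-%s-1-1", r$id, r$aa, r$anticodon), r$seq)
  }))
  writeLines(lines, path)
  path
}

# mutate a sequence at the given 1-based positions, each to a fixed
# different base (deterministic)
mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  ch[positions] <- nxt[ch[positions]]
  paste(ch, collapse = "")
}

# independent brute-force oracle for 3'-anchored mismatch counting:
# reverse both strings, walk position by position, count differences and
# unpaired residues
naive_mismatch <- function(a, b) {
  ra <- rev(strsplit(a, "")[[1]])
  rb <- rev(strsplit(b, "")[[1]])
  n <- max(length(ra), length(rb))
  length(ra) <- n
  length(rb) <- n
  sum(is.na(ra) | is.na(rb) | ra != rb)
}

# a small catalog with well-separated species (one probe each expected):
# k species, random 73-nt bodies + CCA, distinct anticodons
toy_catalog <- function(k = 4, seed = 11, aa = NULL, anticodons = NULL) {
  set.seed(seed)
  if (is.null(aa)) aa <- c("Ala", "Gly", "His", "Phe", "Asp", "Asn")[seq_len(k)]
  if (is.null(anticodons)) {
    anticodons <- c("TGC", "GCC", "GTG", "GAA", "GTC", "GTT")[seq_len(k)]
  }
  recs <- lapply(seq_len(k), function(i) {
    body_len <- if (aa[i] %in% c("Leu", "Ser", "SeC", "Tyr")) 85L else 73L
    list(id = paste0("g", i), aa = aa[i], anticodon = anticodons[i],
         seq = paste0(rand_body(body_len), "CCA"))
  })
  parse_gene_fasta(write_toy_fasta(recs))
}

# a probe set + catalog + flat profile for analytics tests, with chosen
# percent levels assigned to the probes (in probe order)
toy_profile <- function(probe_set, levels_percent) {
  stopifnot(length(levels_percent) == nrow(probe_set$probes))
  normalize_profile(stats::setNames(levels_percent,
                                    probe_set$probes$probe_id))
}

# uniform codon-usage table over the 61 sense codons
uniform_codon_usage <- function() {
  b <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sense <- setdiff(all64, c("TAA", "TAG", "TGA"))
  data.frame(codon = sense, frequency = 1 / length(sense),
             stringsAsFactors = FALSE)
}
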