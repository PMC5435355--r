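# Downstream analytics: replicate stats, class fractions, fold change,
# copy-number views, operon grouping, codon-usage correlation.

# fixed toy panel: 4 well-separated species, one probe each
analysis_fixture <- function(seed = 91) {
  catg <- toy_catalog(k = 4, seed = seed,
                      aa = c("Ala", "Leu", "Gly", "Ser"),
                      anticodons = c("TGC", "GAG", "GCC", "GCT"))
  ps <- design_probes(catg)
  list(catalog = catg, probes = ps)
}

test_that("replicate statistics reproduce hand-computed values", {
  fx <- analysis_fixture()
  p1 <- toy_profile(fx$probes, c(2, 4, 54, 40))
  p2 <- toy_profile(fx$probes, c(4, 4, 52, 40))
  st <- replicate_stats(list(p1, p2))
  i <- which(st$per_probe$probe_id == fx$probes$probes$probe_id[1])
  # levels {2, 4}: mean 3, SD sqrt(2), CV 100*sqrt(2)/3
  expect_equal(st$per_probe$median_level[i], 3)
  expect_equal(st$per_probe$sd_level[i], sqrt(2), tolerance = 1e-12)
  expect_equal(st$per_probe$cv_percent[i], 100 * sqrt(2) / 3,
               tolerance = 1e-9)
  # identical arrays: zero spread everywhere
  st0 <- replicate_stats(list(p1, p1, p1))
  expect_true(all(st0$per_probe$sd_level == 0))
  expect_true(all(st0$per_probe$cv_percent == 0))
  expect_equal(st0$panel$median_sd, 0)
  # uniform arrays: panel median level = 100 / n
  u <- toy_profile(fx$probes, rep(25, 4))
  expect_equal(replicate_stats(list(u, u, u))$panel$median_level, 25)
  expect_error(replicate_stats(list(p1)), "length")
  p_other <- normalize_profile(c(x = 1, y = 1, z = 1, w = 1))
  expect_error(replicate_stats(list(p1, p_other)), "panel")
})

test_that("class fractions sum levels by size class and are complementary", {
  fx <- analysis_fixture()
  # Ala + Gly are class I, Leu + Ser class II: constructed 60/40 split
  aa_of_probe <- vapply(fx$probes$probes$targets, function(t) {
    fx$catalog$species$amino_acid[match(t[1], fx$catalog$species$species_id)]
  }, "")
  lev <- ifelse(aa_of_probe %in% c("Ala", "Gly"), 30, 20)
  prof <- toy_profile(fx$probes, lev)
  fr <- class_fractions(prof, fx$probes, fx$catalog)
  expect_equal(unname(fr["class_I"]), 60)
  expect_equal(unname(fr["class_II"]), 40)
  expect_equal(sum(fr), 100)
  # all-class-I profile
  ci <- toy_catalog(k = 3, seed = 92)
  psi <- design_probes(ci)
  fri <- class_fractions(toy_profile(psi, c(50, 30, 20)), psi, ci)
  expect_equal(unname(fri), c(100, 0))
  # random profiles stay complementary
  set.seed(93)
  for (r in 1:5) {
    x <- runif(4)
    frr <- class_fractions(toy_profile(fx$probes, 100 * x / sum(x)),
                           fx$probes, fx$catalog)
    expect_equal(sum(frr), 100, tolerance = 1e-9)
  }
})

test_that("fold change is a level ratio with undefined zero-control entries", {
  fx <- analysis_fixture()
  prof <- toy_profile(fx$probes, c(9, 3, 48, 40))
  ctrl <- toy_profile(fx$probes, c(3, 3, 54, 40))
  fc <- fold_change(prof, ctrl)
  expect_equal(fc$fold[1], 3)
  expect_equal(fold_change(prof, prof)$fold, rep(1, 4))
  # inverting a reported overexpression: level 11.6 at fold 8.4 implies a
  # control level of 11.6 / 8.4
  prof2 <- toy_profile(fx$probes, c(11.6, 30, 30, 28.4))
  ctrl2 <- toy_profile(fx$probes, c(11.6 / 8.4, 40, 30,
                                    100 - 70 - 11.6 / 8.4))
  expect_equal(fold_change(prof2, ctrl2)$fold[1], 8.4, tolerance = 1e-9)
  # zero control: undefined, not infinite
  ctrl0 <- normalize_profile(stats::setNames(c(0, 3, 57, 40),
                                             fx$probes$probes$probe_id))
  fc0 <- fold_change(prof, ctrl0)
  expect_true(fc0$undefined[1])
  expect_true(is.na(fc0$fold[1]))
  expect_false(any(fc0$undefined[-1]))
})

test_that("copy-number groups take medians of probe levels", {
  catg <- synthetic_ecoli_catalog(seed = 9)
  ps <- design_probes(catg)
  prof <- toy_profile(ps, rep(100 / 42, 42))
  med <- copy_group_medians(prof, ps, catg)
  expect_true(all(med == 100 / 42))
  expect_setequal(names(med),
                  as.character(sort(unique(vapply(ps$probes$targets,
                    function(t) sum(catg$species$gene_copies[
                      match(t, catg$species$species_id)]), 0)))))
  # hand case: probes with copies {1, 1, 2} and levels {1, 3, 5}
  fx <- analysis_fixture()
  copies <- vapply(fx$probes$probes$targets, function(t) {
    sum(fx$catalog$species$gene_copies[
      match(t, fx$catalog$species$species_id)])
  }, 0)
  expect_true(all(copies == 1))  # toy catalog: all single copy
  prof1 <- toy_profile(fx$probes, c(1, 3, 5, 91))
  expect_equal(unname(copy_group_medians(prof1, fx$probes, fx$catalog)),
               stats::median(c(1, 3, 5, 91)))
})

test_that("per-copy levels divide by gene copies and order by locus", {
  catg <- synthetic_ecoli_catalog(seed = 9)
  ps <- design_probes(catg)
  set.seed(94)
  x <- runif(42)
  prof <- toy_profile(ps, 100 * x / sum(x))
  pc <- per_copy_levels(prof, ps, catg, by_locus = FALSE)
  expect_equal(pc$per_copy_level, pc$level_percent / pc$copies)
  i <- which(pc$copies == 2)[1]
  expect_equal(pc$per_copy_level[i], pc$level_percent[i] / 2)
  j <- which(pc$copies == 1)[1]
  expect_equal(pc$per_copy_level[j], pc$level_percent[j])
  # locus expansion: one row per gene, ordered by midpoint
  pl <- per_copy_levels(prof, ps, catg, by_locus = TRUE)
  expect_equal(nrow(pl), 86L)
  expect_true(!is.unsorted(pl$midpoint))
})

test_that("operon groups average per-copy levels with SD", {
  catg <- synthetic_ecoli_catalog(seed = 9)
  ps <- design_probes(catg)
  set.seed(95)
  x <- runif(42)
  prof <- toy_profile(ps, 100 * x / sum(x))
  gm <- group_mean_per_copy(prof, ps, catg)
  expect_setequal(gm$group, c("other", "rrn"))
  expect_equal(gm$n_genes[gm$group == "rrn"], 14L)
  expect_equal(sum(gm$n_genes), 86L)
  # independent recomputation of the rrn mean
  sp2probe <- stats::setNames(
    rep(ps$probes$probe_id, lengths(ps$probes$targets)),
    unlist(ps$probes$targets))
  copies <- stats::setNames(
    vapply(ps$probes$targets, function(t) sum(catg$species$gene_copies[
      match(t, catg$species$species_id)]), 0), ps$probes$probe_id)
  lev <- stats::setNames(prof$level_percent, prof$probe_id)
  g <- catg$genes
  rrn_genes <- g[g$gene_id %in% names(catg$operons), ]
  vals <- lev[sp2probe[rrn_genes$species_id]] /
    copies[sp2probe[rrn_genes$species_id]]
  expect_equal(gm$mean_per_copy[gm$group == "rrn"], mean(vals))
  expect_equal(gm$sd_per_copy[gm$group == "rrn"], stats::sd(vals))
  # a constant group has zero SD
  prof_c <- toy_profile(ps, rep(100 / 42, 42))
  gm_c <- group_mean_per_copy(prof_c, ps, catg)
  rrn_copies <- copies[sp2probe[rrn_genes$species_id]]
  if (length(unique(rrn_copies)) == 1L) {
    expect_equal(gm_c$sd_per_copy[gm_c$group == "rrn"], 0)
  }
})

test_that("wobble decoding assigns codons and conserves usage mass", {
  rules <- default_decoding_rules()
  # sole decoder: a Phe GAA anticodon reads TTC (Watson-Crick) and TTT
  # (G:U wobble); give those two codons usage 0.6 + 0.4 -> f = 1
  catg <- toy_catalog(k = 1, seed = 96, aa = "Phe", anticodons = "GAA")
  usage <- uniform_codon_usage()
  usage$frequency <- 0
  usage$frequency[usage$codon == "TTC"] <- 0.6
  usage$frequency[usage$codon == "TTT"] <- 0.4
  f <- suppressWarnings(effective_codon_frequency(usage, catg, rules))
  expect_equal(unname(f), 1.0)
  # a species decoding only a stop codon gets zero (anticodon CTA -> TAG)
  catg0 <- toy_catalog(k = 1, seed = 97, aa = "Leu", anticodons = "CTA")
  f0 <- suppressWarnings(effective_codon_frequency(usage, catg0, rules))
  expect_equal(unname(f0), 0)
  # equal split: two decoders sharing a codon halve its usage
  catg2 <- toy_catalog(k = 2, seed = 98, aa = c("Ile", "Ile"),
                       anticodons = c("GAT", "AAT"))
  usage2 <- uniform_codon_usage()
  usage2$frequency <- 0
  usage2$frequency[usage2$codon == "ATC"] <- 0.5
  f2 <- suppressWarnings(effective_codon_frequency(usage2, catg2, rules))
  expect_equal(unname(f2), c(0.25, 0.25))
  # winner-takes-all credits the full usage to each decoder
  f2w <- suppressWarnings(effective_codon_frequency(
    usage2, catg2, rules, mode = "winner_takes_all"))
  expect_equal(unname(f2w), c(0.5, 0.5))
  # mass conservation on the synthetic catalog with random usage
  big <- synthetic_ecoli_catalog(seed = 11)
  set.seed(99)
  u <- uniform_codon_usage()
  u$frequency <- runif(nrow(u))
  u$frequency <- u$frequency / sum(u$frequency)
  fb <- suppressWarnings(effective_codon_frequency(u, big))
  # independent decoded-codon oracle: brute force over all sense codons
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wob <- list(G = c("C", "T"), C = "G", T = c("A", "G"),
              A = c("T", "C", "A"))
  decoded_any <- vapply(u$codon, function(cod) {
    any(vapply(big$species$anticodon, function(ac) {
      a <- strsplit(ac, "")[[1]]
      substr(cod, 1, 1) == comp[[a[3]]] &&
        substr(cod, 2, 2) == comp[[a[2]]] &&
        substr(cod, 3, 3) %in% wob[[a[1]]]
    }, TRUE))
  }, TRUE)
  expect_equal(sum(fb), sum(u$frequency[decoded_any]), tolerance = 1e-9)
  # codon usage table must cover all sense codons
  expect_error(effective_codon_frequency(u[-1, ], big), "missing sense")
})

test_that("codon-usage correlation is squared Pearson with exclusions", {
  fx <- analysis_fixture()
  ids <- fx$catalog$species$species_id
  probe_ids <- fx$probes$probes$probe_id
  # map probe order to species order (toy: one target each)
  tgt <- vapply(fx$probes$probes$targets, `[[`, "", 1L)
  # y = 2x -> R^2 = 1
  prof <- toy_profile(fx$probes, c(10, 20, 30, 40))
  f1 <- stats::setNames(2 * c(10, 20, 30, 40)[match(ids, tgt)], ids)
  r1 <- correlate_codon_usage(prof, f1, fx$probes, exclude = character(0))
  expect_equal(r1$r_squared, 1, tolerance = 1e-12)
  expect_equal(r1$n, 4L)
  # hand case x = (1,2,3), y = (1,3,2): r = 0.5, R^2 = 0.25
  fx3 <- list(catalog = toy_catalog(k = 3, seed = 90),
              probes = design_probes(toy_catalog(k = 3, seed = 90)))
  prof3 <- toy_profile(fx3$probes, 100 * c(1, 2, 3) / 6)
  tgt3 <- vapply(fx3$probes$probes$targets, `[[`, "", 1L)
  f3 <- stats::setNames(c(1, 3, 2), tgt3)
  r3 <- correlate_codon_usage(prof3, f3, fx3$probes, exclude = character(0))
  expect_equal(r3$r_squared, 0.25, tolerance = 1e-12)
  # affine invariance in either vector
  r3b <- correlate_codon_usage(prof3, 10 + 7 * f3, fx3$probes,
                               exclude = character(0))
  expect_equal(r3b$r_squared, r3$r_squared, tolerance = 1e-12)
  # constant frequencies: error
  fconst <- stats::setNames(rep(2, 3), tgt3)
  expect_error(correlate_codon_usage(prof3, fconst, fx3$probes,
                                     exclude = character(0)),
               "zero variance")
  # SeC probes are excluded by default when a catalog is supplied
  catg <- synthetic_ecoli_catalog(seed = 11)
  ps <- design_probes(catg)
  set.seed(100)
  x <- runif(42)
  prof42 <- toy_profile(ps, 100 * x / sum(x))
  fr <- stats::setNames(runif(48), catg$species$species_id)
  res <- correlate_codon_usage(prof42, fr, ps, catg)
  expect_equal(res$n, 41L)
  expect_match(res$excluded, "SeC")
})

test_that("profiles built proportional to decoded frequency correlate at R^2 = 1", {
  catg <- synthetic_ecoli_catalog(seed = 17)
  ps <- design_probes(catg)
  set.seed(101)
  u <- uniform_codon_usage()
  u$frequency <- runif(nrow(u))
  u$frequency <- u$frequency / sum(u$frequency)
  f <- suppressWarnings(effective_codon_frequency(u, catg))
  # construct truth proportional to f (plus epsilon so no species is empty)
  truth <- (f + 1e-6) / sum(f + 1e-6)
  sig <- expected_probe_signal(ps, truth)
  lay <- build_layout(ps)
  img <- render_array(lay, sig, sim_params(seed = 17), noise = FALSE)
  prof <- quantify_array(img, lay, search_px = 0)
  res <- correlate_codon_usage(prof, f, ps, catg)
  expect_gt(res$r_squared, 0.999)
})
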