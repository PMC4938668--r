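# shared genome for the composition / planting checks
cfg200 <- sim_config(genome_length = 200000L, rng_seed = 1L)
g200 <- generate_genome(cfg200)

test_that("generated genome matches target composition and annotation invariants", {
  expect_lt(abs(g200$gc_content - 0.656), 0.01)
  b <- strsplit(g200$sequence, "", fixed = TRUE)[[1]]
  expect_equal(g200$gc_content, mean(b %in% c("G", "C")))

  cr <- g200$coding_regions
  expect_true(all((cr$end - cr$start + 1) %% 3 == 0))
  expect_true(all(cr$start >= 1 & cr$end <= nchar(g200$sequence)))
  expect_true(all(cr$start[-1] > cr$end[-nrow(cr)]))  # non-overlapping
  covered <- sum(cr$end - cr$start + 1) / nchar(g200$sequence)
  expect_lt(abs(covered - 0.9), 0.05)
  # no internal stops in synthesized genes
  expect_silent(usage <- codon_usage(g200))
  expect_equal(sum(usage), 1)

  # at least one SSR tract per 10 kb
  tr <- find_ssr_tracts(g200)
  win <- findInterval(tr$start, seq(1, 200000, by = 10000))
  expect_true(all(1:20 %in% win))
})

test_that("genome generation is deterministic and handles degenerate GC", {
  g2 <- generate_genome(cfg200)
  expect_identical(g200$sequence, g2$sequence)
  expect_identical(g200$coding_regions, g2$coding_regions)

  # gc = 1 with no coding regions: pure G/C
  gpure <- generate_genome(sim_config(genome_length = 2000, target_gc = 1,
                                      coding_fraction = 0, rng_seed = 3))
  expect_false(grepl("[AT]", gpure$sequence))
  # gc = 1 with coding: still valid codons (ATG/TGA termini only non-GC)
  gcod <- generate_genome(sim_config(genome_length = 5000, target_gc = 1,
                                     rng_seed = 3))
  expect_gt(gcod$gc_content, 0.99)
  expect_silent(codon_usage(gcod))

  expect_error(sim_config(genome_length = 500), "genome_length")
  expect_error(sim_config(target_gc = 0), "target_gc")
  expect_error(sim_config(spectrum_weights = rep(0, 6)), "spectrum_weights")
})

test_that("planted substitution counts follow the Poisson closed form", {
  # lambda = mu * L * T * n_lines = 1e-6 * 2e5 * 100 * 49 = 980 when all
  # hotspot multipliers are 1
  cfg <- sim_config(genome_length = 200000L, n_lines = 49L,
                    generations = 100L, mu_bs = 1e-6, mu_indel = 0,
                    motif_hotspots = NULL, cpg_multiplier = 1, rng_seed = 11L)
  pl <- plant_mutations(g200, cfg)
  n <- sum(pl$type == "sub")
  expect_lt(abs(n - 980), 3 * sqrt(980))
  # ref matches the genome at every planted site
  b <- strsplit(g200$sequence, "", fixed = TRUE)[[1]]
  expect_identical(pl$ref, b[pl$site])
  # at most one event per (line, site)
  expect_false(any(duplicated(pl[c("line", "site")])))

  # null rate
  pl0 <- plant_mutations(g200, sim_config(genome_length = 200000L,
                                          mu_bs = 0, mu_indel = 0))
  expect_equal(nrow(pl0), 0)
})

test_that("spectrum conditioning forces classes onto the right bases", {
  w <- c(AT_GC = 0, GC_AT = 1, AT_TA = 0, GC_TA = 0, AT_CG = 0, GC_CG = 0)
  cfg <- tiny_cfg(spectrum_weights = w, mu_bs = 5e-5, mu_indel = 0,
                  motif_hotspots = NULL, cpg_multiplier = 1)
  g <- generate_genome(cfg)
  pl <- plant_mutations(g, cfg)
  expect_gt(nrow(pl), 25)
  expect_true(all(pl$ref %in% c("G", "C")))
  expect_true(all(ifelse(pl$ref == "G", pl$alt == "A", pl$alt == "T")))
})

test_that("planted class frequencies converge to availability-weighted weights", {
  cfg <- sim_config(genome_length = 100000L, n_lines = 20L,
                    generations = 100L, mu_bs = 6e-5, mu_indel = 0,
                    motif_hotspots = NULL, cpg_multiplier = 1, rng_seed = 5L)
  g <- generate_genome(cfg)
  pl <- plant_mutations(g, cfg)
  expect_gt(nrow(pl), 1e4)
  cls <- classify_substitution(pl$ref, pl$alt)
  cnt <- table(factor(cls, levels = mutation_classes()))
  b <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  f_at <- mean(b %in% c("A", "T"))
  w <- cfg$spectrum_weights[mutation_classes()]
  avail <- ifelse(grepl("^AT", names(w)), f_at, 1 - f_at)
  p <- w * avail / sum(w * avail)
  expect_gt(stats::chisq.test(cnt, p = p)$p.value, 0.01)
})

test_that("pileups reflect the true alleles and the error model", {
  cfg0 <- tiny_cfg(genome_length = 5000L, n_lines = 3L, mu_bs = 0,
                   mu_indel = 0, seq_error_rate = 0, mask_rate = 0,
                   mean_depth = 50)
  g <- generate_genome(cfg0)
  pl <- plant_mutations(g, cfg0)
  pu <- emit_pileups(g, pl, cfg0)
  ref <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  for (l in 1:3) {
    m <- pu$counts[[l]]
    nonref <- rowSums(m) - m[cbind(seq_len(nrow(m)), match(ref, c("A","C","G","T")))]
    expect_true(all(nonref == 0))
  }

  # error rate recovered at unmutated sites
  cfg1 <- tiny_cfg(genome_length = 5000L, n_lines = 2L, mu_bs = 0,
                   mu_indel = 0, seq_error_rate = 0.01, mask_rate = 0,
                   mean_depth = 100)
  pu1 <- emit_pileups(g, plant_mutations(g, cfg1), cfg1)
  m <- pu1$counts[[1]]
  nonref_frac <- 1 - m[cbind(seq_len(nrow(m)),
                             match(ref, c("A","C","G","T")))] / rowSums(m)
  expect_lt(abs(mean(nonref_frac) - 0.01), 0.001)

  # a planted substitution is private to its line
  plx <- data.frame(line = 2L, site = 1234L, type = "sub",
                    ref = ref[1234], alt = setdiff(c("A","C","G","T"),
                                                   ref[1234])[1],
                    seq = NA_character_, len = 0L, stringsAsFactors = FALSE)
  pux <- emit_pileups(g, plx, cfg0)
  a_idx <- match(plx$alt, c("A", "C", "G", "T"))
  expect_equal(unname(pux$counts[[2]][1234, a_idx]),
               sum(pux$counts[[2]][1234, ]))
  expect_equal(unname(pux$counts[[1]][1234, a_idx]), 0L)
})

test_that("indel bookkeeping conserves base pairs and lines are independent", {
  cfg <- tiny_cfg(mu_bs = 5e-6, mu_indel = 5e-6)
  g <- generate_genome(cfg)
  pl <- plant_mutations(g, cfg)
  expect_gt(sum(pl$type != "sub"), 0)
  for (l in unique(pl$line)) {
    ev <- pl[pl$line == l, ]
    net <- sum(ev$len[ev$type == "ins"]) - sum(ev$len[ev$type == "del"])
    rec <- reconstruct_line_sequence(g, pl, l)
    expect_equal(nchar(rec) - nchar(g$sequence), net)
  }
  # deletions record the true deleted bases
  dels <- pl[pl$type == "del", ]
  if (nrow(dels) > 0) {
    for (k in seq_len(nrow(dels)))
      expect_identical(dels$seq[k],
                       substr(g$sequence, dels$site[k] + 1,
                              dels$site[k] + dels$len[k]))
  }

  # planting is deterministic, and adding lines keeps earlier lines intact
  pl2 <- plant_mutations(g, cfg)
  expect_identical(pl, pl2)
  cfg8 <- tiny_cfg(mu_bs = 5e-6, mu_indel = 5e-6, n_lines = 8L)
  pl8 <- plant_mutations(g, cfg8)
  pl8sub <- pl8[pl8$line <= 5, ]
  rownames(pl8sub) <- NULL
  expect_equal(pl, pl8sub)
})

test_that("config and genome round-trip through YAML / FASTA / GFF3", {
  cfg <- tiny_cfg()
  yml <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, yml)
  cfg2 <- read_sim_config(yml)
  expect_equal(cfg2$spectrum_weights, cfg$spectrum_weights)
  expect_equal(cfg2$rng_seed, cfg$rng_seed)
  expect_equal(cfg2$motif_hotspots, cfg$motif_hotspots)

  g <- generate_genome(cfg)
  fa <- tempfile(fileext = ".fasta")
  write_genome_fasta(g, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back[[1]]), g$sequence)

  gff <- tempfile(fileext = ".gff3")
  write_genome_gff3(g, gff)
  imp <- rtracklayer::import(gff)
  expect_equal(length(imp), nrow(g$coding_regions))
  expect_equal(GenomicRanges::start(imp), g$coding_regions$start)
  expect_equal(GenomicRanges::end(imp), g$coding_regions$end)
})
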