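test_that("substitutions collapse onto the six strand-symmetric classes", {
  expect_equal(classify_substitution("G", "A"), "GC_AT")
  expect_equal(classify_substitution("C", "T"), "GC_AT")
  expect_equal(classify_substitution("A", "G"), "AT_GC")
  expect_equal(classify_substitution("T", "C"), "AT_GC")
  expect_equal(classify_substitution("A", "C"), "AT_CG")
  expect_equal(classify_substitution("G", "C"), "GC_CG")
  expect_true(is_transition("G", "A"))
  expect_false(is_transition("G", "T"))
  # every class maps to itself under complementation of both alleles
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in names(comp)) for (a in setdiff(names(comp), r))
    expect_equal(classify_substitution(r, a),
                 classify_substitution(comp[[r]], comp[[a]]))
  expect_error(classify_substitution("N", "A"), "A,C,G,T")
  expect_error(classify_substitution("A", "A"), "differ")
})

test_that("spectrum table reproduces ts/tv bookkeeping", {
  fx <- fixture_from_counts()
  st <- spectrum_table(fx$calls)
  expect_equal(st$ts, 511)
  expect_equal(st$tv, 345)
  expect_equal(st$ts + st$tv, st$total)
  expect_equal(round(st$ts_tv_ratio, 2), 1.48)
})

test_that("coding annotation translates through strand and frame", {
  # forward gene ATG GGG TGA at 4..12; minus gene at 16..24
  minus_cds <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGCCTTGA")))
  g <- list(name = "toy",
            sequence = paste0("TTT", "ATGGGGTGA", "TTT", minus_cds, "TT"),
            coding_regions = data.frame(
              start = c(4L, 16L), end = c(12L, 24L),
              strand = c("+", "-"), frame = c(0L, 0L),
              stringsAsFactors = FALSE),
            gc_content = 0.4)
  calls <- data.frame(line = "line1",
                      site = c(9L, 6L, 2L),
                      ref = c("G", "G", "T"),
                      alt = c("A", "A", "C"), stringsAsFactors = FALSE)
  ann <- annotate_coding(calls, g)
  expect_equal(ann$effect, c("synonymous",    # GGG->GGA (Gly)
                             "nonsynonymous", # ATG->ATA (Met->Ile)
                             "noncoding"))
  expect_error(annotate_coding(transform(calls, site = 99L), g), "bounds")

  # property: random calls agree with a brute-force re-extraction oracle
  cfg <- tiny_cfg(genome_length = 6000L)
  gen <- generate_genome(cfg)
  code <- Biostrings::getGeneticCode("11")
  chars <- strsplit(gen$sequence, "", fixed = TRUE)[[1]]
  set.seed(99)
  sites <- sample(nchar(gen$sequence), 60)
  alts <- vapply(sites, function(s)
    sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1), character(1))
  calls <- data.frame(line = "line1", site = sites, ref = chars[sites],
                      alt = alts, stringsAsFactors = FALSE)
  ann <- annotate_coding(calls, gen)
  translate_region <- function(seq, cr) {
    s <- substr(seq, cr$start, cr$end)
    if (cr$strand == "-") s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       genetic.code = code))
  }
  for (i in seq_len(nrow(calls))) {
    cr_hit <- gen$coding_regions[gen$coding_regions$start <= calls$site[i] &
                                 gen$coding_regions$end >= calls$site[i], ]
    if (nrow(cr_hit) == 0) {
      expect_equal(ann$effect[i], "noncoding")
    } else {
      mut <- chars
      mut[calls$site[i]] <- calls$alt[i]
      aa0 <- translate_region(gen$sequence, cr_hit[1, ])
      aa1 <- translate_region(paste(mut, collapse = ""), cr_hit[1, ])
      # which codon the site falls in (stop->stop still counts nonsynonymous)
      idx <- if (cr_hit$strand[1] == "+")
        (calls$site[i] - cr_hit$start[1]) %/% 3 + 1
      else (cr_hit$end[1] - calls$site[i]) %/% 3 + 1
      syn <- aa0 == aa1 && substr(aa0, idx, idx) != "*"
      expect_equal(ann$effect[i],
                   if (syn) "synonymous" else "nonsynonymous",
                   label = paste("site", calls$site[i]))
    }
  }
})

test_that("expected N/S ratio matches exhaustive enumeration", {
  code <- Biostrings::getGeneticCode("11")
  u_ggg <- setNames(numeric(64), names(code))
  u_ggg["GGG"] <- 1
  # third position fully synonymous, first two fully nonsynonymous
  expect_equal(expected_ns_ratio(u_ggg, kappa = 1), 2.0)
  expect_equal(expected_ns_ratio(u_ggg, kappa = 7), 2.0)

  u_atg <- setNames(numeric(64), names(code))
  u_atg["ATG"] <- 1
  expect_error(expected_ns_ratio(u_atg, 2), "no synonymous")

  sense <- names(code)[code != "*"]
  u_unif <- setNames(numeric(64), names(code))
  u_unif[sense] <- 1 / length(sense)
  kappa <- 2 * 1.48
  expect_equal(expected_ns_ratio(u_unif, kappa),
               oracle_ns_ratio(u_unif, kappa), tolerance = 1e-12)

  # invariant under uniform rescaling of the usage weights
  expect_equal(expected_ns_ratio(u_unif * 7, kappa),
               expected_ns_ratio(u_unif, kappa))
  expect_error(expected_ns_ratio(u_unif, kappa = 0), "kappa")

  # genome codon usage feeds the expectation
  gen <- generate_genome(tiny_cfg())
  usage <- codon_usage(gen)
  r <- expected_ns_ratio(usage, kappa)
  expect_equal(r, oracle_ns_ratio(usage, kappa), tolerance = 1e-12)
  expect_gt(r, 1)
})

test_that("selection test compares observed N/S to the neutral expectation", {
  st <- selection_test(486, 230, 2.60)
  expect_equal(round(st$observed_ratio, 2), 2.11)
  expect_equal(st$df, 1L)
  # the two independent statistic constructions agree asymptotically
  g <- selection_test(486, 230, 2.60, method = "lrt")
  expect_lt(abs(st$statistic - g$statistic) / st$statistic, 0.05)
  expect_equal(st$p.value, pchisq(st$statistic, 1, lower.tail = FALSE))

  # observed exactly at expectation
  st0 <- selection_test(260, 100, 2.6)
  expect_equal(st0$statistic, 0)
  expect_equal(st0$p.value, 1)
  expect_error(selection_test(0, 0, 2.6), "at least one")
})

test_that("equilibrium GC is v/(u+v) with the expected symmetries", {
  eq <- equilibrium_gc(6.04e-10, 4.34e-10)
  expect_equal(round(100 * eq$gc, 1), 58.2)
  expect_equal(equilibrium_gc(1e-10, 1e-10)$gc, 0.5)
  expect_equal(equilibrium_gc(3e-10, 0)$gc, 1.0)
  expect_error(equilibrium_gc(0, 0), "both rates")
  expect_error(equilibrium_gc(-1e-10, 1e-10), "nonnegative")
  # complementarity
  for (v in c(1e-10, 5e-10)) for (u in c(2e-10, 7e-10))
    expect_equal(equilibrium_gc(v, u)$gc + equilibrium_gc(u, v)$gc, 1)

  # line bootstrap SE is seeded and plausible
  fx <- fixture_from_counts()
  b1 <- equilibrium_gc_boot(fx$calls, fx$exposures, reps = 200, seed = 4)
  b2 <- equilibrium_gc_boot(fx$calls, fx$exposures, reps = 200, seed = 4)
  expect_equal(b1$se, b2$se)
  expect_gt(b1$se, 0)
  expect_equal(b1$gc, equilibrium_gc(6.04e-10, 4.34e-10)$gc, tolerance = 0.01)
})

test_that("full-pipeline spectrum is invariant under reverse-complementation", {
  cfg <- flat_cfg(mu_bs = 2e-5, mu_indel = 0, genome_length = 8000L)
  g <- generate_genome(cfg)
  pu <- emit_pileups(g, plant_mutations(g, cfg), cfg)
  calls <- suppressMessages(call_mutations(call_line_consensus(pu)))
  calls_rc <- suppressMessages(
    call_mutations(call_line_consensus(revcomp_pileups(pu))))
  s1 <- spectrum_table(calls)
  s2 <- spectrum_table(calls_rc)
  expect_equal(s1$counts, s2$counts)
  expect_equal(s1$ts_tv_ratio, s2$ts_tv_ratio)
})
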