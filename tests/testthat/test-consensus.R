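test_that("line consensus applies depth and fraction thresholds", {
  pu <- make_pileups(list(
    lineA = count_matrix(c(0, 0, 100, 0),   # clean G
                         c(0, 0, 8, 0),     # depth below min_depth
                         c(40, 0, 60, 0),   # ambiguous 60/40
                         c(0, 0, 0, 0))))   # masked
  cons <- call_line_consensus(pu, min_depth = 10, min_fraction = 0.8)
  expect_equal(cons$alleles[, 1], c(3L, NA, NA, NA))
  expect_equal(cons$depth[, 1], c(100L, 8L, 100L, 0L))
  expect_error(call_line_consensus(pu, min_fraction = 0.5), "min_fraction")
})

test_that("mutations are line-vs-consensus differences; shared variants suppressed", {
  clean <- function(allele) count_matrix(c(0, 0, 0, 0) + 50 * (1:4 == allele))
  mats <- lapply(1:5, function(i) clean(3))          # all G
  mats[[2]] <- clean(1)                              # line 2 is A
  names(mats) <- paste0("line", 1:5)
  cons <- call_line_consensus(make_pileups(mats))
  calls <- call_mutations(cons)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$line, "line2")
  expect_equal(calls$ref, "G")
  expect_equal(calls$alt, "A")
  expect_equal(calls$fraction, 1)

  # same alt in 2 of 5 lines -> suppressed
  mats[[4]] <- clean(1)
  cons2 <- call_line_consensus(make_pileups(mats))
  expect_message(calls2 <- call_mutations(cons2), "suppressed")
  expect_equal(nrow(calls2), 0)
  expect_equal(attr(calls2, "suppressed_shared"), 2L)

  # fewer than 3 lines refused
  expect_error(call_mutations(call_line_consensus(make_pileups(mats[1:2]))),
               "at least 3 lines")
})

test_that("no false positives with error-free private mutations", {
  cfg <- flat_cfg(seq_error_rate = 0, mask_rate = 0, mu_indel = 0,
                  mu_bs = 2e-5)
  g <- generate_genome(cfg)
  pl <- plant_mutations(g, cfg)
  pu <- emit_pileups(g, pl, cfg)
  calls <- suppressMessages(call_mutations(call_line_consensus(pu)))
  truth <- paste(pl$line[pl$type == "sub"], pl$site[pl$type == "sub"],
                 pl$alt[pl$type == "sub"])
  got <- paste(match(calls$line, paste0("line", 1:cfg$n_lines)),
               calls$site, calls$alt)
  expect_true(all(got %in% truth))   # precision 1 at zero error
})

test_that("calls are invariant under line relabeling", {
  cfg <- flat_cfg(mu_bs = 2e-5, mu_indel = 0)
  g <- generate_genome(cfg)
  pu <- emit_pileups(g, plant_mutations(g, cfg), cfg)
  calls <- suppressMessages(call_mutations(call_line_consensus(pu)))
  perm <- c(3, 5, 1, 2, 4)
  pu2 <- make_pileups(setNames(pu$counts[perm], pu$lines))
  calls2 <- suppressMessages(call_mutations(call_line_consensus(pu2)))
  # site/ref/alt sets identical; lines mapped through the permutation
  expect_equal(calls[order(calls$site), c("site", "ref", "alt")],
               calls2[order(calls2$site), c("site", "ref", "alt")],
               ignore_attr = TRUE)
})

test_that("reverse-complementing genome and pileups mirrors every call", {
  cfg <- flat_cfg(mu_bs = 2e-5, mu_indel = 0, genome_length = 8000L)
  g <- generate_genome(cfg)
  pu <- emit_pileups(g, plant_mutations(g, cfg), cfg)
  calls <- suppressMessages(call_mutations(call_line_consensus(pu)))
  L <- nchar(g$sequence)
  calls_rc <- suppressMessages(
    call_mutations(call_line_consensus(revcomp_pileups(pu))))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(sort(calls_rc$site), sort(L + 1 - calls$site))
  o1 <- order(calls$site)
  o2 <- order(L + 1 - calls_rc$site)
  expect_equal(unname(comp[calls$ref[o1]]), calls_rc$ref[o2])
  expect_equal(unname(comp[calls$alt[o1]]), calls_rc$alt[o2])
})

test_that("indel calls are left-aligned and capped; shared ones suppressed", {
  g <- list(name = "toy", sequence = "TTCAAAAGTTACACACACGGT",
            coding_regions = data.frame(), gc_content = 0.3)
  # +A planted mid-homopolymer (anchor 6, after 3 As): left-aligns to anchor 3
  deltas <- data.frame(line = 1L, site = 6L, type = "ins", seq = "A", len = 1L,
                       stringsAsFactors = FALSE)
  out <- call_indels(deltas, g)
  expect_equal(out$site, 3L)
  expect_equal(out$seq, "A")
  # -AC inside the AC tract left-aligns to the tract start
  deltas2 <- data.frame(line = 1L, site = 12L, type = "del", seq = "AC",
                        len = 2L, stringsAsFactors = FALSE)
  out2 <- call_indels(deltas2, g)
  expect_equal(out2$site, 10L)
  expect_equal(out2$seq, "AC")
  # shared events suppressed; long events capped out
  deltas3 <- data.frame(line = 1:2, site = 6L, type = "ins", seq = "A",
                        len = 1L, stringsAsFactors = FALSE)
  expect_message(out3 <- call_indels(deltas3, g), "shared")
  expect_equal(nrow(out3), 0)
  long <- data.frame(line = 1L, site = 2L, type = "ins",
                     seq = strrep("A", 30), len = 30L, stringsAsFactors = FALSE)
  expect_equal(nrow(call_indels(long, g)), 0)
  # no deltas, no calls
  expect_equal(nrow(call_indels(deltas[0, ], g)), 0)
})

test_that("exposures count analyzable sites split by consensus base", {
  cfg <- flat_cfg(seq_error_rate = 0, mask_rate = 0, mu_bs = 0, mu_indel = 0,
                  genome_length = 10000L)
  g <- generate_genome(cfg)
  pu <- emit_pileups(g, plant_mutations(g, cfg), cfg)
  cons <- call_line_consensus(pu)
  ex <- compute_exposure(cons, cfg$generations)
  b <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
  expect_equal(ex$n_total, rep(10000L, cfg$n_lines))
  expect_equal(ex$n_GC, rep(sum(b %in% c("G", "C")), cfg$n_lines))
  expect_equal(ex$n_GC + ex$n_AT, ex$n_total)
  expect_equal(ex$exposure, ex$n_total * cfg$generations)

  # a fully masked line has zero exposure and contributes no calls
  pu$counts[[2]][] <- 0L
  cons2 <- call_line_consensus(pu)
  ex2 <- compute_exposure(cons2, cfg$generations)
  expect_equal(ex2$exposure[2], 0)
  expect_false("line2" %in% suppressMessages(call_mutations(cons2))$line)

  # the genome-scale exposure product: 49 lines x 6.77 Mb x 4900 generations
  ex_genome_scale <- data.frame(line = 1:49, n_total = 6.77e6, n_GC = 0, n_AT = 0,
                         generations = 4900)
  expect_equal(sum(ex_genome_scale$n_total * ex_genome_scale$generations), 1.625e12,
               tolerance = 1e-3)
})
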