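# Independent oracles and small fixtures shared across the test files.

# Exact Poisson CI by direct root-finding on the Poisson CDF: low solves
# P(X >= m | low) = alpha/2, high solves P(X <= m | high) = alpha/2.
# Deliberately independent of the chi-square quantile identity.
oracle_poisson_ci <- function(m, conf = 0.95) {
  a <- (1 - conf) / 2
  low <- if (m == 0) 0 else
    uniroot(function(lam) 1 - ppois(m - 1, lam) - a,
            c(1e-12, 3 * m + 20), tol = 1e-12)$root
  high <- uniroot(function(lam) ppois(m, lam) - a,
                  c(max(m, 1e-6), 6 * m + 40), tol = 1e-12)$root
  c(low, high)
}

# Brute-force sliding-window motif scan over both strands.
oracle_scan <- function(seq, motif, offset) {
  k <- nchar(motif)
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  hits <- integer(0)
  for (s in seq_len(L - k + 1)) {
    win <- substr(seq, s, s + k - 1)
    if (win == motif) hits <- c(hits, s + offset - 1L)
    if (win == rc) hits <- c(hits, s + k - offset)
  }
  sort(unique(hits))
}

oracle_cpg <- function(seq) {
  L <- nchar(seq)
  hits <- integer(0)
  for (s in seq_len(L - 1))
    if (substr(seq, s, s + 1) == "CG") hits <- c(hits, s, s + 1L)
  sort(unique(hits))
}

# Exhaustive repeat scan of a window: any homopolymer >= hp or tandem repeat
# (unit <= mu, copies >= mc) overlapping positions [a, b] of the window?
oracle_window_repeat <- function(win, a, b, hp = 4, mu = 6, mc = 3) {
  n <- nchar(win)
  ch <- strsplit(win, "", fixed = TRUE)[[1]]
  for (u in 1:mu) {
    need <- if (u == 1) hp else u * mc
    if (n < need) next
    for (s in 1:(n - u)) {
      e <- s + u - 1
      while (e + 1 <= n && ch[e + 1] == ch[e + 1 - u]) e <- e + 1
      if (e - s + 1 >= need && e >= a && s <= b) return(TRUE)
    }
  }
  FALSE
}

# Independent N/S expectation: enumerate all 9 single-base neighbors of each
# codon with the standard genetic code table (identical amino-acid table to
# table 11), weighting transitions kappa : transversions 1.
oracle_ns_ratio <- function(usage, kappa) {
  code <- Biostrings::GENETIC_CODE
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  nw <- sw <- 0
  for (cd in names(code)) {
    u <- usage[[cd]]
    if (is.null(u) || u == 0) next
    for (pos in 1:3) {
      b0 <- substr(cd, pos, pos)
      for (b1 in setdiff(c("A", "C", "G", "T"), b0)) {
        mut <- cd
        substr(mut, pos, pos) <- b1
        w <- u * if (purine[b0] == purine[b1]) kappa else 1
        if (code[cd] == code[mut] && code[cd] != "*") sw <- sw + w
        else nw <- nw + w
      }
    }
  }
  nw / sw
}

# Small simulation config used throughout the module tests.
tiny_cfg <- function(...) {
  args <- list(genome_length = 10000L, n_lines = 5L, generations = 20L,
               mu_bs = 1e-5, mu_indel = 2e-6, mean_depth = 60,
               seq_error_rate = 0.001, mask_rate = 0.02, rng_seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# a multiplier-free variant (hotspots off) for closed-form rate checks
flat_cfg <- function(...) {
  tiny_cfg(motif_hotspots = data.frame(motif = character(0),
                                       offset = integer(0),
                                       multiplier = numeric(0)),
           cpg_multiplier = 1, ...)
}

# hand-built pileup_set from a list of per-line count matrices
make_pileups <- function(mats) {
  structure(list(counts = mats, n_sites = nrow(mats[[1]]),
                 lines = names(mats)), class = "pileup_set")
}

# single-line count matrix helper: each row c(nA, nC, nG, nT)
count_matrix <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("A", "C", "G", "T")
  storage.mode(m) <- "integer"
  m
}

# reverse-complement a pileup_set (reverse site order, swap A<->T, C<->G)
revcomp_pileups <- function(p) {
  p$counts <- lapply(p$counts, function(m) {
    m2 <- m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
    colnames(m2) <- c("A", "C", "G", "T")
    m2
  })
  p
}

revcomp_genome <- function(g) {
  g$sequence <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g$sequence)))
  g$gc_content <- g$gc_content
  g
}

# exposure table for a fully analyzable genome (no sequencing step)
full_exposure <- function(genome, n_lines, generations) {
  b <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  n_gc <- sum(b %in% c("G", "C"))
  data.frame(line = paste0("line", seq_len(n_lines)),
             n_total = length(b), n_GC = n_gc, n_AT = length(b) - n_gc,
             generations = generations,
             exposure = length(b) * generations,
             stringsAsFactors = FALSE)
}

# planted substitutions formatted as a calls table
planted_as_calls <- function(planted) {
  s <- planted[planted$type == "sub", , drop = FALSE]
  data.frame(line = paste0("line", s$line), site = s$site, ref = s$ref,
             alt = s$alt, stringsAsFactors = FALSE)
}
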