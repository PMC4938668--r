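#' Scan a genome for motif target sites on both strands
#'
#' A genomic position is a target site if any of the motifs matches on
#' either strand with its target base (the base at \code{target_offset}
#' within the motif, 1-based) at that position. Reverse-strand matches are
#' reported at their forward-strand (mirrored) coordinate; overlapping
#' matches are deduplicated.
#'
#' @param genome a \code{genome_assembly} (or character sequence).
#' @param motifs character vector of motifs over A,C,G,T (IUPAC degeneracy
#'   unsupported).
#' @param target_offset integer vector (recycled) of 1-based target
#'   positions within each motif.
#' @return sorted integer vector of unique target positions (1-based).
#' @examples
#' g <- list(sequence = "TTGACCTT")
#' scan_motifs(g, "GACC", 2)  # the A at position 4
#' @export
scan_motifs <- function(genome, motifs, target_offset) {
  s <- if (is.list(genome)) genome$sequence else genome
  if (any(grepl("[^ACGT]", motifs)))
    stop("motifs must be over A,C,G,T (degenerate IUPAC codes unsupported)")
  target_offset <- rep_len(as.integer(target_offset), length(motifs))
  if (any(target_offset < 1L | target_offset > nchar(motifs)))
    stop("target_offset outside motif length")
  dna <- Biostrings::DNAString(s)
  hits <- integer(0)
  for (i in seq_along(motifs)) {
    k <- nchar(motifs[i])
    fwd <- Biostrings::start(Biostrings::matchPattern(motifs[i], dna))
    hits <- c(hits, fwd + target_offset[i] - 1L)
    rcm <- revcomp(motifs[i])
    rev <- Biostrings::start(Biostrings::matchPattern(rcm, dna))
    # the motif's offset j on the reverse strand sits at forward coordinate
    # (match start) + (k - j)
    hits <- c(hits, rev + k - target_offset[i])
  }
  sort(unique(hits))
}

#' CpG cytosine positions on both strands
#'
#' Returns the C of every 5'CG3' on the forward strand plus the G position
#' (whose complement C lies in a CpG on the reverse strand).
#'
#' @param genome a \code{genome_assembly} (or character sequence).
#' @return sorted integer vector of positions (1-based).
#' @examples
#' cpg_sites(list(sequence = "ACGT"))  # positions 2 and 3
#' @export
cpg_sites <- function(genome) {
  s <- if (is.list(genome)) genome$sequence else genome
  st <- Biostrings::start(Biostrings::matchPattern("CG", Biostrings::DNAString(s)))
  sort(unique(c(st, st + 1L)))
}

#' Hotspot enrichment of a mutation class at motif target sites
#'
#' Partitions the calls of one substitution class by membership in the motif
#' target-site set and compares the in-motif and out-of-motif rates. Site
#' counts for the denominators are restricted to the base pair the class
#' operates on (A:T or G:C); when a \code{line_consensus} is supplied they
#' are analyzable line-site exposures, otherwise raw genomic site counts
#' (the two coincide under uniform analyzability). An exact binomial test
#' compares k_in against the site-count expectation.
#'
#' @param calls a \code{mutation_calls} data.frame.
#' @param genome a \code{genome_assembly}.
#' @param motifs,target_offset as in \code{\link{scan_motifs}}; or pass
#'   \code{sites} directly.
#' @param class one of \code{\link{mutation_classes}()}.
#' @param consensus optional \code{line_consensus} for exposure-weighted
#'   denominators.
#' @param sites optional precomputed target-site positions (overrides
#'   \code{motifs}).
#' @return list of class \code{motif_enrichment}: \code{k_in}, \code{k_out},
#'   \code{n_in}, \code{n_out}, \code{fraction_in}, \code{fold},
#'   \code{p.value}, \code{per_motif} (k_in per motif), \code{class}.
#' @export
motif_enrichment <- function(calls, genome, motifs = NULL, target_offset = NULL,
                             class, consensus = NULL, sites = NULL) {
  stopifnot(class %in% mutation_classes())
  if (is.null(sites)) {
    if (is.null(motifs)) stop("supply either motifs or sites")
    sites <- scan_motifs(genome, motifs, target_offset)
  }
  if (length(sites) == 0L) stop("no motif target sites in the genome")
  seq_int <- seq_to_int(genome$sequence)
  at_class <- class %in% c("AT_GC", "AT_TA", "AT_CG")
  base_sites <- if (at_class) which(seq_int == 1L | seq_int == 4L)
                else which(seq_int == 2L | seq_int == 3L)
  sites <- intersect(sites, base_sites)
  if (length(sites) == 0L) stop("no motif target sites on the class base pair")

  cls <- classify_substitution(calls$ref, calls$alt)
  cc <- calls[cls == class, , drop = FALSE]
  in_set <- cc$site %in% sites
  k_in <- sum(in_set)
  k_out <- nrow(cc) - k_in

  if (!is.null(consensus)) {
    analyzable <- !is.na(consensus$alleles)
    n_in <- sum(analyzable[sites, , drop = FALSE])
    n_out <- sum(analyzable[setdiff(base_sites, sites), , drop = FALSE])
  } else {
    n_in <- length(sites)
    n_out <- length(base_sites) - length(sites)
  }
  fold <- if (n_in > 0 && n_out > 0 && k_out > 0)
    (k_in / n_in) / (k_out / n_out) else NA_real_
  pv <- if (k_in + k_out > 0)
    stats::binom.test(k_in, k_in + k_out, n_in / (n_in + n_out))$p.value
  else NA_real_

  per_motif <- NULL
  if (!is.null(motifs)) {
    target_offset <- rep_len(as.integer(target_offset), length(motifs))
    per_motif <- vapply(seq_along(motifs), function(i) {
      si <- intersect(scan_motifs(genome, motifs[i], target_offset[i]),
                      base_sites)
      sum(cc$site %in% si)
    }, integer(1))
    names(per_motif) <- motifs
  }
  structure(list(class = class, k_in = k_in, k_out = k_out,
                 n_in = n_in, n_out = n_out,
                 fraction_in = if (k_in + k_out > 0) k_in / (k_in + k_out)
                               else NA_real_,
                 fold = fold, p.value = pv, per_motif = per_motif),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("%s motif enrichment: %d of %d calls in motif targets (%.0f%%)\n",
              mutation_class_labels()[x$class], x$k_in, x$k_in + x$k_out,
              100 * x$fraction_in))
  cat(sprintf("  fold = %.2f (n_in %d, n_out %d), binomial p = %.3g\n",
              x$fold, x$n_in, x$n_out, x$p.value))
  if (!is.null(x$per_motif))
    cat("  per motif:", paste(sprintf("%s (%d)", names(x$per_motif),
                                      x$per_motif), collapse = ", "), "\n")
  invisible(x)
}

#' Flag indels lying in simple-sequence-repeat context
#'
#' An indel is in SSR context iff it lies within or immediately adjoins a
#' homopolymer run of at least \code{min_homopolymer} bp or a tandem repeat
#' with unit length at most \code{max_unit} and at least \code{min_copies}
#' copies, or its own sequence is an integer number of repeat units
#' continuing an adjacent tract.
#'
#' @param genome a \code{genome_assembly}.
#' @param indels an \code{indel_calls} data.frame.
#' @param min_homopolymer,max_unit,min_copies SSR thresholds.
#' @return \code{indels} with the \code{ssr} column filled.
#' @export
detect_ssr_context <- function(genome, indels, min_homopolymer = 4L,
                               max_unit = 6L, min_copies = 3L) {
  if (nrow(indels) == 0L) return(indels)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  pad <- max_unit * min_copies
  flag <- logical(nrow(indels))
  for (i in seq_len(nrow(indels))) {
    p <- indels$site[i]
    len <- indels$len[i]
    span0 <- max(1L, p - 1L)               # indel-adjacent interval
    span1 <- min(L, p + len + 1L)
    w0 <- max(1L, p - pad)
    w1 <- min(L, p + len + pad)
    win <- chars[w0:w1]
    flag[i] <- window_has_ssr(win, w0, span0, span1, min_homopolymer,
                              max_unit, min_copies)
    if (!flag[i] && indels$type[i] == "ins")
      flag[i] <- insertion_completes_tract(chars, p, indels$seq[i],
                                           min_homopolymer, max_unit,
                                           min_copies)
  }
  indels$ssr <- flag
  indels
}

# brute scan of a window for qualifying repeat runs overlapping [span0, span1]
window_has_ssr <- function(win, w_start, span0, span1, min_homopolymer,
                           max_unit, min_copies) {
  n <- length(win)
  for (u in seq_len(max_unit)) {
    need_len <- if (u == 1L) min_homopolymer else u * min_copies
    if (n < need_len) next
    # run[i] = TRUE if win[i] == win[i+u]
    same <- win[seq_len(n - u)] == win[(u + 1L):n]
    r <- rle(same)
    ends <- cumsum(r$lengths)
    for (j in which(r$values & r$lengths >= need_len - u)) {
      run_start <- ends[j] - r$lengths[j] + 1L
      run_len <- r$lengths[j] + u          # total tract length in bp
      g0 <- w_start + run_start - 1L
      g1 <- g0 + run_len - 1L
      if (g1 >= span0 && g0 <= span1) return(TRUE)
    }
  }
  FALSE
}

# inserted sequence is an integer number of repeat units, and together with
# the adjacent reference copies it forms a qualifying tract (covers slips
# that lengthen tracts just below the reference thresholds)
insertion_completes_tract <- function(chars, p, sq, min_homopolymer,
                                      max_unit, min_copies) {
  len <- nchar(sq)
  n <- length(chars)
  for (u in seq_len(min(max_unit, len))) {
    if (len %% u != 0L) next
    unit <- strsplit(substr(sq, 1L, u), "", fixed = TRUE)[[1]]
    if (!identical(strsplit(sq, "", fixed = TRUE)[[1]],
                   rep(unit, len %/% u))) next
    right <- 0L
    while (p + (right + 1L) * u <= n &&
           identical(chars[(p + right * u + 1L):(p + (right + 1L) * u)], unit))
      right <- right + 1L
    left <- 0L
    while (p - (left + 1L) * u + 1L >= 1L &&
           identical(chars[(p - (left + 1L) * u + 1L):(p - left * u)], unit))
      left <- left + 1L
    copies <- len %/% u + right + left
    if (u == 1L && copies >= min_homopolymer) return(TRUE)
    if (u > 1L && copies >= min_copies) return(TRUE)
  }
  FALSE
}

#' Summarize an indel call set
#'
#' @param indels an \code{indel_calls} data.frame (with \code{ssr} filled
#'   for the SSR fraction; NA flags are treated as FALSE).
#' @param max_len histogram upper bound.
#' @return list of class \code{indel_summary}: \code{n_insertions},
#'   \code{n_deletions}, \code{bp_inserted}, \code{bp_deleted},
#'   \code{net_bp}, \code{ins_del_ratio}, \code{ssr_count},
#'   \code{ssr_fraction}, \code{length_hist}.
#' @export
summarize_indels <- function(indels, max_len = 27L) {
  ins <- indels[indels$type == "ins", , drop = FALSE]
  del <- indels[indels$type == "del", , drop = FALSE]
  n_tot <- nrow(ins) + nrow(del)
  ssr_n <- if (n_tot > 0) sum(indels$ssr %in% TRUE) else 0L
  hist <- tabulate(pmin(indels$len, max_len), nbins = max_len)
  names(hist) <- seq_len(max_len)
  structure(list(n_insertions = nrow(ins), n_deletions = nrow(del),
                 bp_inserted = sum(ins$len), bp_deleted = sum(del$len),
                 net_bp = sum(ins$len) - sum(del$len),
                 ins_del_ratio = if (nrow(del) > 0) nrow(ins) / nrow(del)
                                 else NA_real_,
                 ssr_count = ssr_n,
                 ssr_fraction = if (n_tot > 0) ssr_n / n_tot else NA_real_,
                 length_hist = hist),
            class = "indel_summary")
}

#' @export
print.indel_summary <- function(x, ...) {
  cat(sprintf("indels: %d insertions (%d bp), %d deletions (%d bp), net %+d bp\n",
              x$n_insertions, x$bp_inserted, x$n_deletions, x$bp_deleted,
              x$net_bp))
  cat(sprintf("  ins:del ratio %.1f, SSR fraction %.2f%%\n",
              x$ins_del_ratio, 100 * x$ssr_fraction))
  invisible(x)
}
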