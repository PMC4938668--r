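#' Call the per-line consensus from pileup evidence
#'
#' A site is analyzable for a line iff its depth is at least \code{min_depth}
#' and the modal allele fraction is at least \code{min_fraction}; the line
#' consensus is then the modal allele, otherwise unresolved (N). The default
#' thresholds (10 reads, 80%) are deliberately conservative for ~126x data:
#' a fixed mutation in a clonal line should be supported by nearly every
#' read, and ambiguous sites are suppressed rather than guessed.
#'
#' @param pileups a \code{pileup_set}.
#' @param min_depth minimum depth (>= 1).
#' @param min_fraction minimum modal allele fraction, in (0.5, 1].
#' @return An object of class \code{line_consensus}: list with
#'   \code{alleles} (integer matrix n_sites x n_lines; codes 1..4 = A,C,G,T,
#'   NA = unresolved), \code{fraction} and \code{depth} matrices, and
#'   \code{lines}.
#' @export
call_line_consensus <- function(pileups, min_depth = 10L, min_fraction = 0.8) {
  stopifnot(min_depth >= 1L)
  if (!(min_fraction > 0.5 && min_fraction <= 1))
    stop("min_fraction must be in (0.5, 1]")
  nl <- length(pileups$counts)
  L <- pileups$n_sites
  al <- matrix(NA_integer_, L, nl)
  fr <- matrix(NA_real_, L, nl)
  dp <- matrix(0L, L, nl)
  for (l in seq_len(nl)) {
    m <- pileups$counts[[l]]
    depth <- as.integer(rowSums(m))
    modal <- max.col(m, ties.method = "first")
    modal_n <- m[cbind(seq_len(L), modal)]
    frac <- ifelse(depth > 0, modal_n / depth, 0)
    ok <- depth >= min_depth & frac >= min_fraction
    al[ok, l] <- modal[ok]
    fr[, l] <- frac
    dp[, l] <- depth
  }
  colnames(al) <- colnames(fr) <- colnames(dp) <- pileups$lines
  structure(list(alleles = al, fraction = fr, depth = dp,
                 lines = pileups$lines),
            class = "line_consensus")
}

#' @export
print.line_consensus <- function(x, ...) {
  cat(sprintf("line_consensus: %d lines x %d sites (%.1f%% analyzable)\n",
              length(x$lines), nrow(x$alleles),
              100 * mean(!is.na(x$alleles))))
  invisible(x)
}

# Cross-line consensus allele per site: majority over analyzable line calls.
# Ties (two alleles with the same top count) and all-missing sites are NA;
# the tie flag is returned so callers can log / exclude them from exposure.
cross_line_consensus <- function(consensus) {
  al <- consensus$alleles
  L <- nrow(al)
  cnt <- matrix(0L, L, 4L)
  for (a in 1:4) cnt[, a] <- rowSums(al == a, na.rm = TRUE)
  top <- do.call(pmax, as.data.frame(cnt))
  tie <- rowSums(cnt == top & cnt > 0L) >= 2L
  major <- max.col(cnt, ties.method = "first")
  major[top == 0L | tie] <- NA_integer_
  list(allele = major, tie = tie & top > 0L)
}

#' Call fixed mutations as line-vs-consensus differences
#'
#' The cross-line consensus at each site is the majority allele over the
#' lines with an analyzable call (ties exclude the site). A mutation is
#' emitted for every (line, site) whose line consensus differs from the
#' cross-line consensus. Because MA lines are independent, the same variant
#' recurring in \code{k_share} or more lines at one site is overwhelmingly
#' ancestral polymorphism or cross-contamination and is suppressed (counted
#' in the \code{suppressed_shared} attribute).
#'
#' @param consensus a \code{line_consensus}.
#' @param k_share suppress variants shared by >= this many lines (default 2).
#' @return data.frame of class \code{mutation_calls} with columns
#'   \code{line}, \code{site}, \code{ref} (cross-line consensus allele),
#'   \code{alt}, \code{fraction}, \code{depth}. Attributes:
#'   \code{suppressed_shared} (number of suppressed shared variant records)
#'   and \code{tie_sites} (sites excluded for cross-line ties).
#' @export
call_mutations <- function(consensus, k_share = 2L) {
  nl <- length(consensus$lines)
  if (nl < 3L)
    stop("line-vs-consensus calling needs at least 3 lines; got ", nl,
         " (a 2-line comparison cannot resolve which line mutated)")
  cc <- cross_line_consensus(consensus)
  al <- consensus$alleles
  diff <- which(!is.na(al) & !is.na(cc$allele) & al != cc$allele,
                arr.ind = TRUE)
  calls <- data.frame(line = consensus$lines[diff[, 2]],
                      site = as.integer(diff[, 1]),
                      ref = BASES[cc$allele[diff[, 1]]],
                      alt = BASES[al[diff]],
                      fraction = consensus$fraction[diff],
                      depth = consensus$depth[diff],
                      stringsAsFactors = FALSE)
  suppressed <- 0L
  if (nrow(calls) > 0) {
    key <- paste(calls$site, calls$alt)
    shared <- table(key)
    bad <- names(shared)[shared >= k_share]
    drop <- key %in% bad
    suppressed <- sum(drop)
    if (suppressed > 0)
      message(suppressed, " shared variant record(s) at ",
              length(bad), " site(s) suppressed as ancestral/contamination")
    calls <- calls[!drop, , drop = FALSE]
  }
  calls <- calls[order(calls$site, calls$line), , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "suppressed_shared") <- suppressed
  attr(calls, "tie_sites") <- sum(cc$tie)
  class(calls) <- c("mutation_calls", "data.frame")
  calls
}

#' Call indels from per-line sequence deltas
#'
#' Operates on the simulator's per-line sequence deltas (reconstructed-line
#' differences from the cross-line consensus sequence) rather than
#' re-implementing split-read realignment. The caller normalizes each event
#' by left-alignment (the leftmost equivalent placement in a repeat tract),
#' caps lengths at \code{indel_max_len}, and suppresses events shared by
#' \code{k_share} or more lines.
#'
#' @param deltas data.frame with columns \code{line}, \code{site} (anchor,
#'   1-based), \code{type} ("ins"/"del"), \code{seq}, \code{len} — e.g. the
#'   indel rows of a \code{planted_set}, or events parsed from an external
#'   comparison.
#' @param genome a \code{genome_assembly} (reference for left-alignment).
#' @param k_share shared-variant suppression threshold.
#' @param indel_max_len maximum reportable length (bp).
#' @return data.frame of class \code{indel_calls}: \code{line}, \code{site}
#'   (left-aligned anchor), \code{type}, \code{seq}, \code{len},
#'   \code{ssr} (NA until filled by \code{\link{detect_ssr_context}}).
#' @export
call_indels <- function(deltas, genome, k_share = 2L, indel_max_len = 27L) {
  ind <- deltas[deltas$type %in% c("ins", "del"), , drop = FALSE]
  empty <- data.frame(line = integer(0), site = integer(0),
                      type = character(0), seq = character(0),
                      len = integer(0), ssr = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("indel_calls", "data.frame")
  if (nrow(ind) == 0L) return(empty)
  ind <- ind[ind$len <= indel_max_len, , drop = FALSE]
  if (nrow(ind) == 0L) return(empty)

  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  site <- integer(nrow(ind))
  sq <- character(nrow(ind))
  for (k in seq_len(nrow(ind))) {
    la <- left_align_indel(chars, ind$site[k], ind$seq[k], ind$type[k])
    site[k] <- la$site
    sq[k] <- la$seq
  }
  out <- data.frame(line = ind$line, site = site, type = ind$type,
                    seq = sq, len = nchar(sq), ssr = NA,
                    stringsAsFactors = FALSE)
  key <- paste(out$site, out$type, out$seq)
  shared <- table(key)
  bad <- names(shared)[shared >= k_share]
  drop <- key %in% bad
  if (any(drop))
    message(sum(drop), " shared indel record(s) suppressed")
  out <- out[!drop, , drop = FALSE]
  out <- out[order(out$site, out$line), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "suppressed_shared") <- sum(drop)
  class(out) <- c("indel_calls", "data.frame")
  out
}

# Shift an indel to its leftmost equivalent placement: while the base before
# the anchor equals the last base of the (rotated) event sequence, rotate and
# step left. Standard VCF-style normalization.
left_align_indel <- function(chars, anchor, sq, type) {
  s <- strsplit(sq, "", fixed = TRUE)[[1]]
  len <- length(s)
  while (anchor >= 1L && chars[anchor] == s[len]) {
    s <- c(s[len], s[-len])
    anchor <- anchor - 1L
  }
  list(site = anchor, seq = paste(s, collapse = ""))
}

#' Per-line analyzable-site exposures
#'
#' Counts, for each line, the analyzable sites (line consensus resolved and
#' cross-line consensus defined), split by the cross-line consensus base
#' into G:C and A:T sites, and multiplies by the line's generation count.
#' These exposures are the denominator of every rate estimate.
#'
#' @param consensus a \code{line_consensus}.
#' @param generations scalar or per-line vector of generation counts.
#' @return data.frame of class \code{line_exposure}: \code{line},
#'   \code{n_total}, \code{n_GC}, \code{n_AT}, \code{generations},
#'   \code{exposure} (= n_total x generations).
#' @export
compute_exposure <- function(consensus, generations) {
  cc <- cross_line_consensus(consensus)
  nl <- length(consensus$lines)
  gens <- rep_len(generations, nl)
  ok_site <- !is.na(cc$allele)
  is_gc <- ok_site & (cc$allele == 2L | cc$allele == 3L)
  is_at <- ok_site & (cc$allele == 1L | cc$allele == 4L)
  n_total <- n_gc <- n_at <- integer(nl)
  for (l in seq_len(nl)) {
    have <- !is.na(consensus$alleles[, l])
    n_total[l] <- sum(have & ok_site)
    n_gc[l] <- sum(have & is_gc)
    n_at[l] <- sum(have & is_at)
  }
  out <- data.frame(line = consensus$lines, n_total = n_total,
                    n_GC = n_gc, n_AT = n_at, generations = gens,
                    exposure = n_total * gens, stringsAsFactors = FALSE)
  class(out) <- c("line_exposure", "data.frame")
  out
}

#' Write calls as a flat TSV and as minimal VCF 4.2
#'
#' The TSV mirrors a per-mutation supplementary-table layout (line,
#' position, ref, alt); the VCF carries one sample column per line with GT
#' 1 where the line holds the alternate allele.
#'
#' @param calls a \code{mutation_calls} data.frame.
#' @param path output path.
#' @param lines all line ids (VCF sample columns); defaults to those present.
#' @param chrom chromosome name for the VCF.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_calls_vcf <- function(calls, path, lines = unique(calls$line),
                            chrom = "chr") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "FORMAT", lines), collapse = "\t")), con)
  if (nrow(calls) > 0) {
    for (i in order(calls$site)) {
      gt <- ifelse(lines == calls$line[i], "1", "0")
      writeLines(paste(c(chrom, calls$site[i], ".", calls$ref[i],
                         calls$alt[i], ".", "PASS", "GT", gt),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
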