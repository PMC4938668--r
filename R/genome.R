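# Sequence <-> integer code helpers (1=A, 2=C, 3=G, 4=T). utf8ToInt keeps
# this O(n) without per-character dispatch.
seq_to_int <- function(s) {
  map <- integer(128L)
  map[utf8ToInt("ACGT")] <- 1:4
  ic <- map[utf8ToInt(s)]
  if (any(ic == 0L)) stop("sequence contains non-ACGT characters")
  ic
}

int_to_seq <- function(i) intToUtf8(utf8ToInt("ACGT")[i])

base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

#' Generate a synthetic annotated bacterial genome
#'
#' Produces a random genome with a target GC content, a target coding
#' density, simple-sequence-repeat (SSR) tracts, and extra copies of the
#' configured hotspot motifs, for use as the reference of a simulated MA
#' experiment.
#'
#' Coding regions are synthesized as random codon strings at the target base
#' composition with an ATG start, a TGA stop, and no internal stop codons
#' (bacterial code, translation table 11); there is no attempt to mimic real
#' gene content. SSR tracts (a homopolymer of 6 bp and a dinucleotide repeat
#' of 4 units) are planted in every 10 kb window, and hotspot motifs at
#' \code{motif_plant_per_kb}, both restricted to intergenic gaps so that no
#' internal stops are created; natural background occurrences arise freely in
#' coding sequence as well.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{genome_assembly}: list with \code{name},
#'   \code{sequence} (character scalar over ACGT), \code{coding_regions}
#'   (data.frame \code{start}, \code{end} 1-based closed, \code{strand},
#'   \code{frame}), and \code{gc_content} recomputed from the emitted
#'   sequence.
#' @examples
#' g <- generate_genome(sim_config(genome_length = 20000, rng_seed = 1))
#' abs(g$gc_content - 0.656) < 0.01
#' @export
generate_genome <- function(config) {
  config <- validate_sim_config(config)
  L <- config$genome_length
  gc <- config$target_gc
  probs <- base_probs(gc)

  with_local_seed(config$rng_seed, {
    seq_int <- sample.int(4L, L, replace = TRUE, prob = probs)

    # --- coding regions: fixed-length genes tiled with even gaps ---
    gene_len <- 999L
    n_genes <- as.integer(floor(config$coding_fraction * L / gene_len))
    if (n_genes == 0L && config$coding_fraction > 0) {
      gene_len <- as.integer(3L * floor(config$coding_fraction * L / 3L))
      n_genes <- as.integer(gene_len >= 9L)
    }
    coding <- data.frame(start = integer(0), end = integer(0),
                         strand = character(0), frame = integer(0),
                         stringsAsFactors = FALSE)
    if (n_genes > 0L) {
      total_gap <- L - n_genes * gene_len
      gap <- total_gap %/% (n_genes + 1L)
      starts <- gap + 1L + (0:(n_genes - 1L)) * (gene_len + gap)
      strands <- sample(c("+", "-"), n_genes, replace = TRUE)
      n_int <- (gene_len %/% 3L) - 2L  # internal codons per gene
      codons <- sample_sense_codons(n_int * n_genes, probs)
      for (g in seq_len(n_genes)) {
        body <- c(seq_to_int("ATG"),
                  codons[((g - 1L) * n_int * 3L + 1L):(g * n_int * 3L)],
                  seq_to_int("TGA"))
        if (strands[g] == "-") body <- rev(5L - body)  # reverse complement
        seq_int[starts[g]:(starts[g] + gene_len - 1L)] <- body
      }
      coding <- data.frame(start = starts, end = starts + gene_len - 1L,
                           strand = strands, frame = 0L,
                           stringsAsFactors = FALSE)
    }

    # --- intergenic gap catalogue for SSR / motif planting ---
    occupied <- logical(L)
    if (nrow(coding) > 0)
      for (g in seq_len(nrow(coding)))
        occupied[coding$start[g]:coding$end[g]] <- TRUE

    plant_in_gap <- function(piece, w0, w1) {
      k <- length(piece)
      cand <- which(!occupied[w0:w1]) + w0 - 1L
      cand <- cand[cand + k - 1L <= w1]
      cand <- cand[!occupied[pmin(cand + k - 1L, L)]]
      if (length(cand) == 0L) return(FALSE)
      p <- cand[sample.int(length(cand), 1L)]
      if (any(occupied[p:(p + k - 1L)])) return(FALSE)
      seq_int[p:(p + k - 1L)] <<- piece
      TRUE
    }

    # one homopolymer + one dinucleotide repeat per 10 kb window
    for (w0 in seq(1L, L, by = 10000L)) {
      w1 <- min(w0 + 9999L, L)
      if (w1 - w0 < 100L) next
      hb <- sample.int(4L, 1L, prob = probs)
      plant_in_gap(rep(hb, 6L), w0, w1)
      repeat {
        unit <- sample.int(4L, 2L, replace = TRUE, prob = probs)
        if (unit[1] != unit[2]) break
      }
      plant_in_gap(rep(unit, 4L), w0, w1)
    }

    # extra hotspot-motif copies at configurable density
    mh <- config$motif_hotspots
    n_plant <- round(config$motif_plant_per_kb * L / 1000)
    if (!is.null(mh) && nrow(mh) > 0 && n_plant > 0) {
      for (i in seq_len(n_plant)) {
        m <- mh$motif[sample.int(nrow(mh), 1L)]
        if (runif(1) < 0.5) m <- revcomp(m)
        plant_in_gap(seq_to_int(m), 1L, L)
      }
    }

    seq_chr <- int_to_seq(seq_int)
    genome <- structure(
      list(name = sprintf("synthetic_%dkb_seed%d", round(L / 1000),
                          config$rng_seed),
           sequence = seq_chr,
           coding_regions = coding,
           gc_content = mean(seq_int == 2L | seq_int == 3L)),
      class = "genome_assembly")
    genome
  })
}

# Sample n sense codons (no TAA/TAG/TGA) as a flat integer vector of 3n bases.
sample_sense_codons <- function(n, probs) {
  if (n == 0L) return(integer(0))
  b <- matrix(sample.int(4L, 3L * n, replace = TRUE, prob = probs),
              ncol = 3L, byrow = TRUE)
  repeat {
    stop_row <- (b[, 1] == 4L & b[, 2] == 1L & (b[, 3] == 1L | b[, 3] == 3L)) |
                (b[, 1] == 4L & b[, 2] == 3L & b[, 3] == 1L)
    if (!any(stop_row)) break
    k <- sum(stop_row)
    b[stop_row, ] <- matrix(sample.int(4L, 3L * k, replace = TRUE, prob = probs),
                            ncol = 3L)
  }
  as.integer(t(b))
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly '%s': %d bp, GC %.4f, %d coding regions (%.1f%% coding)\n",
              x$name, nchar(x$sequence), x$gc_content,
              nrow(x$coding_regions),
              100 * sum(x$coding_regions$end - x$coding_regions$start + 1) /
                nchar(x$sequence)))
  invisible(x)
}

#' Locate simple-sequence-repeat tracts
#'
#' Scans a genome for homopolymer runs and short tandem repeats, the tracts
#' where replication slippage concentrates small indels.
#'
#' @param genome a \code{genome_assembly} (or character sequence).
#' @param min_homopolymer minimum homopolymer run length (bp).
#' @param units repeat unit sizes to scan for tandem repeats.
#' @param min_copies minimum number of tandem unit copies.
#' @return data.frame with \code{start}, \code{end} (1-based closed),
#'   \code{unit_len}, \code{unit}.
#' @export
find_ssr_tracts <- function(genome, min_homopolymer = 5L, units = 2:3,
                            min_copies = 3L) {
  s <- if (inherits(genome, "genome_assembly")) genome$sequence else genome
  out <- list()
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_homopolymer
  if (any(keep))
    out[[length(out) + 1L]] <- data.frame(
      start = ends[keep] - r$lengths[keep] + 1L, end = ends[keep],
      unit_len = 1L, unit = r$values[keep], stringsAsFactors = FALSE)
  for (u in units) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, min_copies - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      len <- attr(m, "match.length")
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(m), end = as.integer(m) + len - 1L,
        unit_len = u, unit = substr(s, m, m + u - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      unit_len = integer(0), unit = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_len), , drop = FALSE]
}

#' Write a genome as FASTA and its annotation as GFF3
#'
#' @param genome a \code{genome_assembly}.
#' @param fasta,gff3 output paths.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, fasta) {
  dna <- Biostrings::DNAStringSet(stats::setNames(genome$sequence, genome$name))
  Biostrings::writeXStringSet(dna, fasta)
  invisible(fasta)
}

#' @rdname write_genome_fasta
#' @export
write_genome_gff3 <- function(genome, gff3) {
  cr <- genome$coding_regions
  con <- file(gff3, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$name,
                     nchar(genome$sequence)), con)
  if (nrow(cr) > 0) {
    writeLines(sprintf("%s\tmamutspec\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds%04d",
                       genome$name, cr$start, cr$end, cr$strand, cr$frame,
                       seq_len(nrow(cr))), con)
  }
  invisible(gff3)
}
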