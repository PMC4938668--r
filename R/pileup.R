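#' Emit per-line pileup allele counts
#'
#' Stands in for mapped-read evidence: at every site of every line, depth is
#' drawn as Poisson(\code{mean_depth}), each read supports the line's true
#' allele except that a read base is flipped to one of the three other bases
#' (uniformly) with probability \code{seq_error_rate}. A fraction
#' \code{mask_rate} of line-sites is masked to depth 0, emulating
#' unanalyzable positions. Indels do not alter the per-site base identity
#' (gapped columns are out of scope); their evidence travels as sequence
#' deltas to \code{\link{call_indels}}.
#'
#' @param genome a \code{genome_assembly}.
#' @param planted a \code{planted_set} from \code{\link{plant_mutations}}.
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{pileup_set}: list with \code{counts}
#'   (per line, an integer matrix of n_sites x 4 allele counts, columns
#'   A,C,G,T), \code{n_sites}, and \code{lines}.
#' @export
emit_pileups <- function(genome, planted, config) {
  config <- validate_sim_config(config)
  L <- nchar(genome$sequence)
  ref_int <- seq_to_int(genome$sequence)
  counts <- vector("list", config$n_lines)
  names(counts) <- paste0("line", seq_len(config$n_lines))

  for (l in seq_len(config$n_lines)) {
    true <- ref_int
    subs <- planted[planted$line == l & planted$type == "sub", , drop = FALSE]
    if (nrow(subs)) true[subs$site] <- base_to_int(subs$alt)
    counts[[l]] <- with_local_seed(line_seed(config$rng_seed, l, 2L), {
      pileup_one_line(true, config)
    })
  }
  structure(list(counts = counts, n_sites = L, lines = names(counts)),
            class = "pileup_set")
}

pileup_one_line <- function(true, config) {
  L <- length(true)
  depth <- stats::rpois(L, config$mean_depth)
  if (config$mask_rate > 0)
    depth[stats::runif(L) < config$mask_rate] <- 0L
  nerr <- stats::rbinom(L, depth, config$seq_error_rate)
  # split errors uniformly over the three non-true bases (multinomial by
  # successive binomials, fully vectorized)
  e1 <- stats::rbinom(L, nerr, 1 / 3)
  e2 <- stats::rbinom(L, nerr - e1, 1 / 2)
  e3 <- nerr - e1 - e2
  m <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  errs <- cbind(e1, e2, e3)
  for (a in 1:4) {
    idx <- which(true == a)
    if (!length(idx)) next
    m[idx, a] <- depth[idx] - nerr[idx]
    others <- setdiff(1:4, a)
    for (j in 1:3) m[idx, others[j]] <- errs[idx, j]
  }
  m
}

#' @export
print.pileup_set <- function(x, ...) {
  cat(sprintf("pileup_set: %d lines x %d sites\n", length(x$lines), x$n_sites))
  invisible(x)
}

#' Write pileups as a gzipped TSV
#'
#' Columns: line, pos (1-based), nA, nC, nG, nT.
#' @param pileups a \code{pileup_set}.
#' @param path output path (".gz" recommended).
#' @export
write_pileups_tsv <- function(pileups, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines("line\tpos\tnA\tnC\tnG\tnT", con)
  for (l in seq_along(pileups$counts)) {
    m <- pileups$counts[[l]]
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%d", pileups$lines[l],
                       seq_len(nrow(m)), m[, 1], m[, 2], m[, 3], m[, 4]), con)
  }
  invisible(path)
}
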