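#' Simulation configuration for a mutation-accumulation experiment
#'
#' Builds and validates the full parameter set of the forward simulator. The
#' defaults describe a desk-scale version of a bacterial MA design: a 200 kb
#' genome at 65.6% GC with 90% coding density, 49 surviving lines bottlenecked
#' for 100 generations, and a base-substitution rate inflated so that several
#' hundred substitutions accumulate in total (all downstream estimators are
#' scale-free in exposure, so conclusions transfer to genome-scale runs).
#'
#' The six spectrum weights are relative \emph{conditional} class rates:
#' within an A:T or G:C site, class probabilities are proportional to the
#' applicable three weights. Defaults follow the strongly GC-biased spectrum
#' of an MMR-lacking actinobacterium, in units of 1e-10 per site per
#' generation: A:T→G:C 3.95, G:C→A:T 2.76, A:T→T:A 0.27, G:C→T:A 1.58,
#' A:T→C:G 2.10, G:C→C:G 0.43.
#'
#' @param genome_length genome size in bp (>= 1000).
#' @param target_gc target GC fraction in (0, 1]; 1 is allowed as a
#'   degenerate composition (see \code{\link{generate_genome}}).
#' @param coding_fraction fraction of the genome covered by coding regions.
#' @param n_lines number of MA lines.
#' @param generations generations (single-cell bottleneck transfers) per line.
#' @param mu_bs base-substitution rate per site per generation.
#' @param mu_indel indel rate per site per generation.
#' @param spectrum_weights nonnegative weights for the six strand-collapsed
#'   substitution classes, named as \code{\link{mutation_classes}()}.
#' @param motif_hotspots data.frame with columns \code{motif} (ACGT string),
#'   \code{offset} (1-based target position within the motif) and
#'   \code{multiplier} (fold elevation of the A:T→C:G rate at target sites).
#' @param cpg_multiplier fold elevation (>= 1) of the G:C→A:T rate at CpG
#'   cytosines (both strands).
#' @param ssr_indel_fraction fraction of indels placed in SSR tracts as
#'   unit-length slippage events.
#' @param indel_max_len maximum indel length in bp.
#' @param insertion_bias insertion:deletion frequency ratio.
#' @param mean_depth mean sequencing depth per site (Poisson).
#' @param seq_error_rate per read-base error probability.
#' @param mask_rate per line-site probability of an unanalyzable (depth 0)
#'   site, emulating unmappable or filtered positions.
#' @param motif_plant_per_kb density of extra hotspot-motif copies planted in
#'   intergenic sequence, per kb (background occurrences arise naturally).
#' @param rng_seed master seed; one substream per line is derived from it.
#'
#' @return An object of class \code{sim_config} (a validated named list).
#' @examples
#' cfg <- sim_config(genome_length = 20000, n_lines = 6)
#' cfg$target_gc
#' @export
sim_config <- function(genome_length = 200000L,
                       target_gc = 0.656,
                       coding_fraction = 0.9,
                       n_lines = 49L,
                       generations = 100L,
                       mu_bs = 7e-7,
                       mu_indel = 1.7e-7,
                       spectrum_weights = c(AT_GC = 3.95, GC_AT = 2.76,
                                            AT_TA = 0.27, GC_TA = 1.58,
                                            AT_CG = 2.10, GC_CG = 0.43),
                       motif_hotspots = data.frame(
                         motif = c("GACC", "CACC"),
                         offset = c(2L, 2L),
                         multiplier = c(6.8, 6.8),
                         stringsAsFactors = FALSE),
                       cpg_multiplier = 3.5,
                       ssr_indel_fraction = 0.787,
                       indel_max_len = 27L,
                       insertion_bias = 2.1,
                       mean_depth = 126,
                       seq_error_rate = 0.002,
                       mask_rate = 0.03,
                       motif_plant_per_kb = 0.2,
                       rng_seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              target_gc = target_gc,
              coding_fraction = coding_fraction,
              n_lines = as.integer(n_lines),
              generations = generations,
              mu_bs = mu_bs,
              mu_indel = mu_indel,
              spectrum_weights = spectrum_weights,
              motif_hotspots = motif_hotspots,
              cpg_multiplier = cpg_multiplier,
              ssr_indel_fraction = ssr_indel_fraction,
              indel_max_len = as.integer(indel_max_len),
              insertion_bias = insertion_bias,
              mean_depth = mean_depth,
              seq_error_rate = seq_error_rate,
              mask_rate = mask_rate,
              motif_plant_per_kb = motif_plant_per_kb,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  chk_frac <- function(field, x, lo = 0, hi = 1, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        x < lo || x > hi || (lo_open && x == lo))
      fail(field, sprintf("must be a number in %s%s, %s]",
                          if (lo_open) "(" else "[", lo, hi))
  }
  if (cfg$genome_length < 1000L)
    fail("genome_length", "must be >= 1000 bp")
  chk_frac("target_gc", cfg$target_gc, lo_open = TRUE)
  chk_frac("coding_fraction", cfg$coding_fraction)
  if (cfg$n_lines < 1L) fail("n_lines", "must be >= 1")
  if (any(cfg$generations <= 0)) fail("generations", "must be positive")
  if (cfg$mu_bs < 0) fail("mu_bs", "must be >= 0")
  if (cfg$mu_indel < 0) fail("mu_indel", "must be >= 0")
  w <- cfg$spectrum_weights
  if (length(w) != 6L || any(w < 0) || all(w == 0) ||
      !all(mutation_classes() %in% names(w)))
    fail("spectrum_weights",
         "must be 6 nonnegative weights (not all zero) named as mutation_classes()")
  cfg$spectrum_weights <- w[mutation_classes()]
  mh <- cfg$motif_hotspots
  if (!is.null(mh) && nrow(mh) > 0) {
    if (!all(c("motif", "offset", "multiplier") %in% names(mh)))
      fail("motif_hotspots", "needs columns motif, offset, multiplier")
    if (any(grepl("[^ACGT]", mh$motif)))
      fail("motif_hotspots", "motifs must be over A,C,G,T")
    if (any(mh$offset < 1L | mh$offset > nchar(mh$motif)))
      fail("motif_hotspots", "offset outside motif length")
    if (any(mh$multiplier < 0)) fail("motif_hotspots", "multiplier must be >= 0")
  }
  if (cfg$cpg_multiplier < 0) fail("cpg_multiplier", "must be >= 0")
  chk_frac("ssr_indel_fraction", cfg$ssr_indel_fraction)
  if (cfg$indel_max_len < 1L) fail("indel_max_len", "must be >= 1")
  if (cfg$insertion_bias < 0) fail("insertion_bias", "must be >= 0")
  if (cfg$mean_depth <= 0) fail("mean_depth", "must be positive")
  chk_frac("seq_error_rate", cfg$seq_error_rate, hi = 0.75)
  chk_frac("mask_rate", cfg$mask_rate)
  if (cfg$motif_plant_per_kb < 0) fail("motif_plant_per_kb", "must be >= 0")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MA simulation config\n")
  cat(sprintf("  genome: %d bp, GC %.3f, coding %.2f\n",
              x$genome_length, x$target_gc, x$coding_fraction))
  cat(sprintf("  lines: %d x %s generations\n", x$n_lines,
              paste(unique(x$generations), collapse = "/")))
  cat(sprintf("  mu_bs %.3g, mu_indel %.3g per site per generation\n",
              x$mu_bs, x$mu_indel))
  cat(sprintf("  depth %g, error %.3g, mask %.3g, seed %d\n",
              x$mean_depth, x$seq_error_rate, x$mask_rate, x$rng_seed))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a \code{sim_config}.
#' @param path file path.
#' @return \code{read_sim_config} returns a validated \code{sim_config}.
#' @export
write_sim_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$spectrum_weights <- as.list(lst$spectrum_weights)
  lst$motif_hotspots <- if (is.null(lst$motif_hotspots)) NULL else
    as.list(lst$motif_hotspots)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$spectrum_weights <- unlist(lst$spectrum_weights)
  if (!is.null(lst$motif_hotspots))
    lst$motif_hotspots <- as.data.frame(lst$motif_hotspots,
                                        stringsAsFactors = FALSE)
  do.call(sim_config, lst)
}
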