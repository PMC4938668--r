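# C-motif set examined for G:C->A:T hotspots (cytosine at motif position 1)
C_MOTIFS <- c("CCGC", "CGCC", "CGCG", "CGGC")

#' Run the full MA analysis pipeline on a simulated experiment
#'
#' Executes simulate → consensus call → rates → spectrum → context as one
#' reproducible run: generates the genome, plants mutations, emits pileups,
#' calls line consensuses and mutations, computes exposures and rates, the
#' six-class spectrum with conditional rates and equilibrium GC, the N/S
#' selection test against the genome's own codon usage, hotspot-motif and
#' CpG enrichment, and the indel SSR summary. All randomness derives from
#' \code{config$rng_seed}; identical configs give identical results.
#'
#' @param config a \code{\link{sim_config}}.
#' @param output_dir optional directory; when given, every stage's output is
#'   persisted (FASTA, GFF3, YAML config, truth/calls/exposures/rates TSVs,
#'   VCF, gzipped pileup TSV, JSON report).
#' @param min_depth,min_fraction consensus thresholds
#'   (\code{\link{call_line_consensus}}).
#' @param k_share shared-variant suppression threshold.
#' @param boot_reps line-bootstrap replicates for the equilibrium-GC SE.
#' @return an object of class \code{summary_report} (nested list; see
#'   \code{\link{write_report_json}}).
#' @export
run_pipeline <- function(config, output_dir = NULL, min_depth = 10L,
                         min_fraction = 0.8, k_share = 2L,
                         boot_reps = 1000L) {
  config <- validate_sim_config(config)
  persist <- !is.null(output_dir)
  if (persist && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  pth <- function(f) file.path(output_dir, f)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genome <- stage("simulate:genome", generate_genome(config))
  planted <- stage("simulate:plant", plant_mutations(genome, config))
  pileups <- stage("simulate:pileups", emit_pileups(genome, planted, config))
  if (persist) {
    write_genome_fasta(genome, pth("genome.fasta"))
    write_genome_gff3(genome, pth("annotation.gff3"))
    write_sim_config(config, pth("config.yaml"))
    write_planted_tsv(planted, pth("truth.tsv"))
    write_pileups_tsv(pileups, pth("pileups.tsv.gz"))
  }

  consensus <- stage("call:consensus",
                     call_line_consensus(pileups, min_depth, min_fraction))
  calls <- stage("call:mutations", call_mutations(consensus, k_share))
  deltas <- planted[planted$type != "sub", , drop = FALSE]
  indels <- stage("call:indels",
                  call_indels(deltas, genome, k_share, config$indel_max_len))
  exposures <- stage("call:exposure",
                     compute_exposure(consensus, config$generations))
  indels <- stage("context:ssr", detect_ssr_context(genome, indels))
  if (persist) {
    write_calls_tsv(annotate_coding(calls, genome), pth("calls.tsv"))
    write_calls_vcf(calls, pth("calls.vcf"), lines = consensus$lines,
                    chrom = genome$name)
    write_calls_tsv(indels, pth("indels.tsv"))
    write_calls_tsv(exposures, pth("exposures.tsv"))
  }

  report <- stage("report", build_report(
    calls = calls, indels = indels, exposures = exposures,
    genome = genome, consensus = consensus,
    genome_sites = nchar(genome$sequence),
    motif_hotspots = config$motif_hotspots,
    boot_reps = boot_reps, seed = config$rng_seed))
  report$provenance$config_hash <- config_hash(config)
  report$provenance$suppressed_shared <- attr(calls, "suppressed_shared")
  report$provenance$tie_sites <- attr(calls, "tie_sites")

  if (persist) {
    if (!is.null(report$rates))
      write_rates_tsv(Filter(function(x) inherits(x, "rate_estimate"),
                             list(report$rates$overall, report$rates$indel,
                                  report$spectrum$conditional$gc_to_at,
                                  report$spectrum$conditional$at_to_gc)),
                      pth("rates.tsv"))
    write_report_json(report, pth("report.json"))
  }
  report
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_sim_config(config, tmp)
  unname(tools::md5sum(tmp))
}

# Shared report assembly for simulated runs (genome available) and
# count-level fixtures (annotations precomputed on the tables).
build_report <- function(calls, indels, exposures, genome = NULL,
                         consensus = NULL, genome_sites,
                         motif_hotspots = NULL, expected_ratio = NULL,
                         boot_reps = 1000L, seed = 1L, source = "pipeline") {
  no_events <- nrow(calls) == 0L
  per_line <- if (!no_events) table(calls$line) else NULL
  overall <- estimate_rate(nrow(calls), exposures,
                           per_line_counts = per_line, scope = "overall")
  indel_rate <- estimate_rate(nrow(indels), exposures, scope = "indel")
  rates <- list(overall = overall, indel = indel_rate,
                per_genome = genome_rate(overall, genome_sites),
                per_genome_indel = genome_rate(indel_rate, genome_sites))

  spectrum <- selection <- hotspots <- NULL
  coding_fraction <- NA_real_
  if (!no_events) {
    spec_tab <- spectrum_table(calls)
    cond <- conditional_rates(calls, exposures)
    eq <- if (cond$gc_to_at$m + cond$at_to_gc$m > 0) {
      e <- equilibrium_gc_boot(calls, exposures, reps = boot_reps, seed = seed)
      e
    } else NULL
    spectrum <- list(table = spec_tab, conditional = cond, equilibrium = eq)

    if (is.null(calls$effect) && !is.null(genome))
      calls <- annotate_coding(calls, genome)
    if (!is.null(calls$effect)) {
      n_ns <- sum(calls$effect == "nonsynonymous")
      n_s <- sum(calls$effect == "synonymous")
      coding_fraction <- (n_ns + n_s) / nrow(calls)
      if (is.null(expected_ratio) && !is.null(genome) &&
          nrow(genome$coding_regions) > 0 && spec_tab$tv > 0) {
        usage <- codon_usage(genome)
        expected_ratio <- expected_ns_ratio(usage,
                                            kappa = 2 * spec_tab$ts_tv_ratio)
      }
      selection <- list(n_obs = n_ns, s_obs = n_s,
                        observed_ratio = if (n_s > 0) n_ns / n_s else NA_real_,
                        expected_ratio = expected_ratio,
                        test = if (!is.null(expected_ratio) && n_ns + n_s > 0)
                          selection_test(n_ns, n_s, expected_ratio) else NULL)
    }

    hotspots <- build_hotspots(calls, genome, consensus, motif_hotspots)
  }

  structure(list(
    rates = rates,
    spectrum = spectrum,
    coding_fraction = coding_fraction,
    selection = selection,
    hotspots = hotspots,
    indels = summarize_indels(indels),
    flags = list(no_events = no_events),
    provenance = list(source = source, seed = seed,
                      n_lines = nrow(exposures),
                      version = as.character(utils::packageVersion("mamutspec")))),
    class = "summary_report")
}

build_hotspots <- function(calls, genome, consensus, motif_hotspots) {
  if (!is.null(genome)) {
    at_cg <- if (!is.null(motif_hotspots) && nrow(motif_hotspots) > 0)
      try_enrich(calls, genome, motif_hotspots$motif, motif_hotspots$offset,
                 "AT_CG", consensus) else NULL
    cpg <- try_enrich(calls, genome, NULL, NULL, "GC_AT", consensus,
                      sites = cpg_sites(genome))
    cmot <- try_enrich(calls, genome, C_MOTIFS, rep(1L, length(C_MOTIFS)),
                       "GC_AT", consensus)
    return(list(at_cg_motif = at_cg, gc_at_cpg = cpg, gc_at_cmotif = cmot))
  }
  # fixture path: membership flags precomputed on the calls table
  cls <- classify_substitution(calls$ref, calls$alt)
  frac <- function(flag_col, class) {
    if (is.null(calls[[flag_col]])) return(NULL)
    k <- sum(calls[[flag_col]] & cls == class)
    tot <- sum(cls == class)
    list(k_in = k, k_out = tot - k,
         fraction_in = if (tot > 0) k / tot else NA_real_)
  }
  list(at_cg_motif = frac("in_hotspot_motif", "AT_CG"),
       gc_at_cpg = frac("in_cpg", "GC_AT"),
       gc_at_cmotif = frac("in_c_motif", "GC_AT"))
}

try_enrich <- function(calls, genome, motifs, offsets, class, consensus,
                       sites = NULL) {
  tryCatch(motif_enrichment(calls, genome, motifs, offsets, class,
                            consensus = consensus, sites = sites),
           error = function(e) NULL)
}

#' @export
print.summary_report <- function(x, ...) {
  cat("=== MA summary report ===\n")
  if (isTRUE(x$flags$no_events)) cat("NOTE: no mutation events called\n")
  print(x$rates$overall)
  cat(sprintf("per-genome rate: %.4f per generation\n", x$rates$per_genome))
  print(x$rates$indel)
  if (!is.null(x$spectrum)) {
    print(x$spectrum$table)
    print(x$spectrum$conditional$gc_to_at)
    print(x$spectrum$conditional$at_to_gc)
    if (!is.null(x$spectrum$equilibrium)) print(x$spectrum$equilibrium)
  }
  if (!is.na(x$coding_fraction))
    cat(sprintf("coding fraction: %.2f%%\n", 100 * x$coding_fraction))
  if (!is.null(x$selection) && !is.null(x$selection$test))
    print(x$selection$test)
  if (!is.null(x$indels)) print(x$indels)
  invisible(x)
}

#' Build count-level call and exposure tables from printed marginals
#'
#' Reconstructs calls, indels and exposures whose marginal counts exactly
#' match a stated experiment summary (class counts, coding/selection splits,
#' indel counts and sizes, SSR and motif membership counts), so that every
#' downstream summary statistic can be recomputed from tables alone. The
#' defaults encode a 49-line GC-rich actinobacterial MA experiment: 856
#' substitutions in the six-class split 209/302/14/173/111/47, 716 coding
#' (486 N / 230 S), 141 insertions (206 bp) and 66 deletions (225 bp) with
#' 163 in SSRs, exposures of 6.77 Mb analyzable sites x 4900 generations
#' per line with 67.4% of analyzable sites G:C, and motif membership 50/111
#' A:T→C:G in hotspot motifs, 145/302 G:C→A:T at CpG, 65/302 at C-motifs.
#'
#' The analyzable G:C fraction (0.674) is the value implied by inverting the
#' experiment's two conditional rates against their class counts; it is
#' deliberately distinct from the genomic GC content, since conditional
#' rates divide by analyzable-site exposures.
#'
#' @param class_counts named 6-vector of substitution class counts.
#' @param n_nonsyn,n_syn nonsynonymous / synonymous counts (their sum is
#'   the coding count).
#' @param n_insertions,n_deletions,bp_inserted,bp_deleted indel marginals.
#' @param ssr_count indels in SSR context.
#' @param motif_counts named vector: \code{at_cg_in_motif},
#'   \code{gc_at_in_cpg}, \code{gc_at_in_c_motif}.
#' @param n_lines,sites_per_line,generations exposure structure.
#' @param gc_fraction fraction of analyzable sites that are G:C.
#' @param indel_max_len length cap used when spreading bp over events.
#' @return list of class \code{ma_fixture}: \code{calls}, \code{indels},
#'   \code{exposures}, \code{genome_sites}.
#' @examples
#' fx <- fixture_from_counts()
#' report <- fixture_report(fx)
#' signif(report$rates$overall$rate, 3)  # 5.27e-10
#' @export
fixture_from_counts <- function(class_counts = c(AT_GC = 209, GC_AT = 302,
                                                 AT_TA = 14, GC_TA = 173,
                                                 AT_CG = 111, GC_CG = 47),
                                n_nonsyn = 486, n_syn = 230,
                                n_insertions = 141, n_deletions = 66,
                                bp_inserted = 206, bp_deleted = 225,
                                ssr_count = 163,
                                motif_counts = c(at_cg_in_motif = 50,
                                                 gc_at_in_cpg = 145,
                                                 gc_at_in_c_motif = 65),
                                n_lines = 49, sites_per_line = 6.77e6,
                                generations = 4900, gc_fraction = 0.674,
                                indel_max_len = 27L) {
  if (!all(mutation_classes() %in% names(class_counts)))
    stop("class_counts must be named by mutation_classes()")
  class_counts <- class_counts[mutation_classes()]
  total <- sum(class_counts)
  n_coding <- n_nonsyn + n_syn
  if (n_coding > total)
    stop("inconsistent counts: N + S (", n_coding,
         ") exceeds total substitutions (", total, ")")
  if (ssr_count > n_insertions + n_deletions)
    stop("inconsistent counts: ssr_count exceeds total indels")
  if (bp_inserted < n_insertions || bp_deleted < n_deletions)
    stop("inconsistent counts: total bp smaller than event count")
  if (motif_counts["at_cg_in_motif"] > class_counts["AT_CG"] ||
      motif_counts["gc_at_in_cpg"] > class_counts["GC_AT"] ||
      motif_counts["gc_at_in_c_motif"] > class_counts["GC_AT"])
    stop("inconsistent counts: motif membership exceeds its class count")

  rep_alleles <- list(AT_GC = c("A", "G"), GC_AT = c("G", "A"),
                      AT_TA = c("A", "T"), GC_TA = c("G", "T"),
                      AT_CG = c("A", "C"), GC_CG = c("G", "C"))
  cls <- rep(mutation_classes(), class_counts)
  calls <- data.frame(
    line = rep_len(paste0("line", seq_len(n_lines)), total),
    site = seq_len(total) * 10L,
    ref = vapply(cls, function(k) rep_alleles[[k]][1], character(1)),
    alt = vapply(cls, function(k) rep_alleles[[k]][2], character(1)),
    stringsAsFactors = FALSE)
  # coding/effect labels: first n_coding rows coding (N then S)
  effect <- rep("noncoding", total)
  effect[seq_len(n_nonsyn)] <- "nonsynonymous"
  effect[n_nonsyn + seq_len(n_syn)] <- "synonymous"
  calls$effect <- effect
  calls$coding <- effect != "noncoding"
  flag_first <- function(class, k) {
    idx <- which(cls == class)
    out <- rep(FALSE, total)
    out[idx[seq_len(k)]] <- TRUE
    out
  }
  calls$in_hotspot_motif <- flag_first("AT_CG", motif_counts["at_cg_in_motif"])
  calls$in_cpg <- flag_first("GC_AT", motif_counts["gc_at_in_cpg"])
  calls$in_c_motif <- flag_first("GC_AT", motif_counts["gc_at_in_c_motif"])
  rownames(calls) <- NULL

  spread_lengths <- function(n, bp, cap) {
    lens <- rep(1L, n)
    extra <- bp - n
    i <- 1L
    while (extra > 0L && i <= n) {
      add <- min(extra, cap - 1L)
      lens[i] <- lens[i] + add
      extra <- extra - add
      i <- i + 1L
    }
    if (extra > 0L) stop("cannot spread ", bp, " bp over ", n,
                         " events with length cap ", cap)
    lens
  }
  ins_len <- spread_lengths(n_insertions, bp_inserted, indel_max_len)
  del_len <- spread_lengths(n_deletions, bp_deleted, indel_max_len)
  n_ind <- n_insertions + n_deletions
  indels <- data.frame(
    line = rep_len(paste0("line", seq_len(n_lines)), n_ind),
    site = seq_len(n_ind) * 100L,
    type = rep(c("ins", "del"), c(n_insertions, n_deletions)),
    seq = strrep("A", c(ins_len, del_len)),
    len = c(ins_len, del_len),
    ssr = seq_len(n_ind) <= ssr_count,
    stringsAsFactors = FALSE)

  n_gc <- gc_fraction * sites_per_line
  exposures <- data.frame(line = paste0("line", seq_len(n_lines)),
                          n_total = sites_per_line, n_GC = n_gc,
                          n_AT = sites_per_line - n_gc,
                          generations = generations,
                          exposure = sites_per_line * generations,
                          stringsAsFactors = FALSE)
  structure(list(calls = calls, indels = indels, exposures = exposures,
                 genome_sites = sites_per_line),
            class = "ma_fixture")
}

#' Summary report from a count-level fixture
#'
#' Recomputes every headline statistic (rates with CIs, spectrum,
#' conditional rates, equilibrium GC, coding fraction, observed N/S, motif
#' fractions, indel summary) from the fixture's tables through the same
#' estimator functions the pipeline uses.
#'
#' @param fx an \code{ma_fixture}.
#' @param expected_ratio optional expected N/S ratio to test against.
#' @param boot_reps,seed equilibrium-GC bootstrap settings.
#' @return a \code{summary_report}.
#' @export
fixture_report <- function(fx, expected_ratio = NULL, boot_reps = 1000L,
                           seed = 1L) {
  build_report(calls = fx$calls, indels = fx$indels,
               exposures = fx$exposures, genome_sites = fx$genome_sites,
               expected_ratio = expected_ratio, boot_reps = boot_reps,
               seed = seed, source = "fixture")
}

#' Write / read a summary report as JSON
#'
#' Serialization is lossless for every numeric field; S3 classes are
#' stripped to plain lists on write.
#'
#' @param report a \code{summary_report}.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else if (is.table(x)) {
    as.list(x)
  } else x
}
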