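#' Classify base substitutions into the six strand-collapsed classes
#'
#' Substitutions are collapsed onto the base pair, so C→T is the same class
#' as G→A (G:C→A:T). A change is a transition iff it swaps purine for purine
#' or pyrimidine for pyrimidine.
#'
#' @param ref,alt character vectors over A,C,G,T with \code{ref != alt}.
#' @return character vector of class codes (see
#'   \code{\link{mutation_classes}}).
#' @examples
#' classify_substitution("G", "A")  # "GC_AT"
#' classify_substitution("C", "T")  # "GC_AT" (complement collapse)
#' @export
classify_substitution <- function(ref, alt) {
  if (length(ref) != length(alt)) stop("ref and alt lengths differ")
  if (length(ref) == 0L) return(character(0))
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("ref/alt must be single bases in {A,C,G,T}")
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("C", "T")
  r <- ifelse(flip, unname(COMPLEMENT[ref]), ref)
  a <- ifelse(flip, unname(COMPLEMENT[alt]), alt)
  key <- paste0(r, a)
  map <- c(AG = "AT_GC", AT = "AT_TA", AC = "AT_CG",
           GA = "GC_AT", GT = "GC_TA", GC = "GC_CG")
  unname(map[key])
}

#' @rdname classify_substitution
#' @return \code{is_transition}: logical vector.
#' @export
is_transition <- function(ref, alt) {
  classify_substitution(ref, alt) %in% c("AT_GC", "GC_AT")
}

#' Tabulate a set of calls into a spectrum table
#'
#' @param calls a \code{mutation_calls} data.frame.
#' @return list of class \code{spectrum_table}: \code{counts} (named
#'   6-vector), \code{ts}, \code{tv}, \code{ts_tv_ratio}, \code{total}.
#' @export
spectrum_table <- function(calls) {
  cls <- classify_substitution(calls$ref, calls$alt)
  cnt <- stats::setNames(integer(6), mutation_classes())
  tab <- table(cls)
  cnt[names(tab)] <- as.integer(tab)
  ts <- unname(cnt["AT_GC"] + cnt["GC_AT"])
  tv <- unname(sum(cnt) - ts)
  structure(list(counts = cnt, ts = ts, tv = tv,
                 ts_tv_ratio = if (tv > 0) ts / tv else NA_real_,
                 total = sum(cnt)),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  lab <- mutation_class_labels()
  cat("substitution spectrum:\n")
  for (k in mutation_classes())
    cat(sprintf("  %-9s %d\n", lab[k], x$counts[k]))
  cat(sprintf("  transitions %d, transversions %d, ts/tv %.2f\n",
              x$ts, x$tv, x$ts_tv_ratio))
  invisible(x)
}

#' Annotate calls with their coding effect
#'
#' Maps each call onto the annotation; calls inside a coding region are
#' translated (bacterial code, translation table 11) honoring strand and
#' frame, and classified as synonymous or nonsynonymous. Any change to or
#' from a stop codon counts as nonsynonymous.
#'
#' @param calls a \code{mutation_calls} data.frame.
#' @param genome a \code{genome_assembly}.
#' @return \code{calls} with added columns \code{coding} (logical) and
#'   \code{effect} ("noncoding", "synonymous", "nonsynonymous").
#' @export
annotate_coding <- function(calls, genome) {
  L <- nchar(genome$sequence)
  if (nrow(calls) > 0 && (any(calls$site < 1L) || any(calls$site > L)))
    stop("call position outside genome bounds")
  cr <- genome$coding_regions
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  code <- Biostrings::getGeneticCode("11")
  effect <- rep("noncoding", nrow(calls))
  if (nrow(cr) > 0 && nrow(calls) > 0) {
    cr <- cr[order(cr$start), , drop = FALSE]
    gi <- findInterval(calls$site, cr$start)
    inside <- gi >= 1L & calls$site <= cr$end[pmax(gi, 1L)]
    for (i in which(inside)) {
      g <- gi[i]
      if (cr$strand[g] == "+") {
        off <- calls$site[i] - cr$start[g] - cr$frame[g]
        if (off < 0) next
        c0 <- cr$start[g] + cr$frame[g] + (off %/% 3L) * 3L
        cod <- chars[c0:(c0 + 2L)]
        pos <- off %% 3L + 1L
        mut <- cod
        mut[pos] <- calls$alt[i]
      } else {
        off <- cr$end[g] - cr$frame[g] - calls$site[i]
        if (off < 0) next
        c1 <- cr$end[g] - cr$frame[g] - (off %/% 3L) * 3L
        cod <- unname(COMPLEMENT[chars[c1:(c1 - 2L)]])
        pos <- off %% 3L + 1L
        mut <- cod
        mut[pos] <- unname(COMPLEMENT[calls$alt[i]])
      }
      aa0 <- code[paste(cod, collapse = "")]
      aa1 <- code[paste(mut, collapse = "")]
      effect[i] <- if (identical(unname(aa0), unname(aa1)) &&
                       aa0 != "*") "synonymous" else "nonsynonymous"
    }
  }
  calls$coding <- effect != "noncoding"
  calls$effect <- effect
  calls
}

#' Codon usage of the annotated coding sequence
#'
#' @param genome a \code{genome_assembly}.
#' @param drop_terminal_stop drop each gene's final codon if it is a stop.
#' @return named numeric vector of 64 codon frequencies summing to 1
#'   (class \code{codon_usage}).
#' @export
codon_usage <- function(genome, drop_terminal_stop = TRUE) {
  cr <- genome$coding_regions
  if (nrow(cr) == 0L) stop("genome has no coding regions")
  code <- Biostrings::getGeneticCode("11")
  all_codons <- names(code)
  cnt <- stats::setNames(numeric(64), all_codons)
  for (g in seq_len(nrow(cr))) {
    s <- substr(genome$sequence, cr$start[g], cr$end[g])
    if (cr$strand[g] == "-") s <- revcomp(s)
    if (cr$frame[g] > 0) s <- substr(s, cr$frame[g] + 1L, nchar(s))
    n3 <- (nchar(s) %/% 3L) * 3L
    cod <- substring(s, seq(1L, n3, 3L), seq(3L, n3, 3L))
    if (drop_terminal_stop && length(cod) > 0 &&
        code[cod[length(cod)]] == "*") cod <- cod[-length(cod)]
    if (any(code[cod[-length(cod)]] == "*"))
      warning("internal stop codon in coding region ", g)
    tab <- table(cod)
    cnt[names(tab)] <- cnt[names(tab)] + as.numeric(tab)
  }
  structure(cnt / sum(cnt), class = "codon_usage")
}

#' Expected nonsynonymous/synonymous ratio under neutrality
#'
#' Enumerates, for every codon weighted by usage, all nine single-base
#' changes, weighting transitions by \code{kappa} and transversions by 1,
#' and returns the ratio of total nonsynonymous to total synonymous weight.
#' Changes to or from a stop codon count as nonsynonymous. \code{kappa} is
#' the per-site transition:transversion \emph{rate} ratio; given an observed
#' count ratio R = ts/tv it is \code{2R}, because each site has one
#' transition target and two transversion targets.
#'
#' @param usage a \code{codon_usage} (or any named 64-vector of weights).
#' @param kappa per-site transition:transversion rate ratio (> 0).
#' @return expected N/S ratio (numeric).
#' @examples
#' u <- setNames(numeric(64), names(Biostrings::getGeneticCode("11")))
#' u["GGG"] <- 1
#' expected_ns_ratio(u, kappa = 2)  # 2.0
#' @export
expected_ns_ratio <- function(usage, kappa) {
  if (!(is.numeric(kappa) && kappa > 0)) stop("kappa must be > 0")
  code <- Biostrings::getGeneticCode("11")
  if (is.null(names(usage)) || !all(names(code) %in% names(usage)))
    stop("usage must be named by the 64 codons")
  n_w <- s_w <- 0
  for (codon in names(code)) {
    u <- usage[[codon]]
    if (u == 0) next
    b <- strsplit(codon, "", fixed = TRUE)[[1]]
    for (pos in 1:3) for (alt in setdiff(BASES, b[pos])) {
      mut <- b
      mut[pos] <- alt
      wgt <- u * if (is_transition(b[pos], alt)) kappa else 1
      syn <- code[codon] == code[paste(mut, collapse = "")] &&
             code[codon] != "*"
      if (syn) s_w <- s_w + wgt else n_w <- n_w + wgt
    }
  }
  if (s_w == 0)
    stop("no synonymous sites under this codon usage; N/S ratio undefined")
  n_w / s_w
}

#' Goodness-of-fit test of the N/S ratio against a neutral expectation
#'
#' Tests observed (N, S) counts against expected proportions
#' (r/(1+r), 1/(1+r)) where r is the expected N/S ratio. The primary
#' statistic is the Pearson chi-square on 1 df; \code{method = "lrt"} gives
#' the multinomial log-likelihood-ratio (G) statistic, an asymptotically
#' equivalent alternative used as a cross-check.
#'
#' @param n_obs,s_obs observed nonsynonymous and synonymous counts.
#' @param expected_ratio expected N/S ratio r.
#' @param method test statistic.
#' @return list of class \code{selection_test}: \code{n_obs}, \code{s_obs},
#'   \code{observed_ratio}, \code{expected_ratio}, \code{statistic},
#'   \code{df}, \code{p.value}, \code{method}.
#' @export
selection_test <- function(n_obs, s_obs, expected_ratio,
                           method = c("chisq", "lrt")) {
  method <- match.arg(method)
  if (n_obs + s_obs <= 0) stop("need at least one coding mutation")
  tot <- n_obs + s_obs
  p <- c(expected_ratio, 1) / (1 + expected_ratio)
  e <- tot * p
  obs <- c(n_obs, s_obs)
  stat <- if (method == "chisq") {
    sum((obs - e)^2 / e)
  } else {
    keep <- obs > 0
    2 * sum(obs[keep] * log(obs[keep] / e[keep]))
  }
  structure(list(n_obs = n_obs, s_obs = s_obs,
                 observed_ratio = if (s_obs > 0) n_obs / s_obs else Inf,
                 expected_ratio = expected_ratio, statistic = stat, df = 1L,
                 p.value = stats::pchisq(stat, 1L, lower.tail = FALSE),
                 method = method),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf("N/S selection test (%s): observed %d/%d = %.2f vs expected %.2f\n",
              x$method, x$n_obs, x$s_obs, x$observed_ratio, x$expected_ratio))
  cat(sprintf("  statistic = %.3f (df %d), p = %.4g\n", x$statistic, x$df,
              x$p.value))
  invisible(x)
}

#' Mutational-equilibrium GC content
#'
#' The GC fraction expected under mutation pressure alone: v/(u+v), where v
#' is the A/T→G/C conditional rate and u the G/C→A/T conditional rate.
#'
#' @param mu_at_gc conditional rate v in the GC direction.
#' @param mu_gc_at conditional rate u in the AT direction.
#' @return list of class \code{equilibrium_gc}: \code{gc} (fraction) and
#'   \code{se} (NA here; see \code{\link{equilibrium_gc_boot}}).
#' @examples
#' equilibrium_gc(6.04e-10, 4.34e-10)$gc  # 0.582
#' @export
equilibrium_gc <- function(mu_at_gc, mu_gc_at) {
  if (mu_at_gc < 0 || mu_gc_at < 0) stop("rates must be nonnegative")
  if (mu_at_gc + mu_gc_at == 0) stop("both rates are zero; equilibrium undefined")
  structure(list(gc = mu_at_gc / (mu_at_gc + mu_gc_at), se = NA_real_),
            class = "equilibrium_gc")
}

#' Line-bootstrap standard error of the equilibrium GC content
#'
#' Resamples lines with replacement, recomputes the two conditional rates
#' and the equilibrium GC on each replicate, and reports the bootstrap SD.
#'
#' @param calls a \code{mutation_calls} data.frame.
#' @param exposures a \code{line_exposure}.
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @return \code{equilibrium_gc} object with \code{se} filled and
#'   \code{reps} recorded.
#' @export
equilibrium_gc_boot <- function(calls, exposures, reps = 1000L, seed = 1L) {
  cr <- conditional_rates(calls, exposures)
  est <- equilibrium_gc(cr$at_to_gc$rate, cr$gc_to_at$rate)
  lines <- exposures$line
  cls <- classify_substitution(calls$ref, calls$alt)
  up_l <- tapply(cls %in% c("GC_AT", "GC_TA"), calls$line, sum)
  vn_l <- tapply(cls %in% c("AT_GC", "AT_CG"), calls$line, sum)
  u_cnt <- v_cnt <- stats::setNames(rep(0, length(lines)), lines)
  u_cnt[names(up_l)] <- up_l
  v_cnt[names(vn_l)] <- vn_l
  e_gc <- stats::setNames(exposures$n_GC * exposures$generations, lines)
  e_at <- stats::setNames(exposures$n_AT * exposures$generations, lines)
  bb <- with_local_seed(seed, {
    vapply(seq_len(reps), function(i) {
      pick <- sample(lines, length(lines), replace = TRUE)
      u <- sum(u_cnt[pick]) / sum(e_gc[pick])
      v <- sum(v_cnt[pick]) / sum(e_at[pick])
      if (u + v == 0) NA_real_ else v / (u + v)
    }, numeric(1))
  })
  est$se <- stats::sd(bb, na.rm = TRUE)
  est$reps <- reps
  est
}

#' @export
print.equilibrium_gc <- function(x, ...) {
  cat(sprintf("equilibrium GC content: %.1f%%%s\n", 100 * x$gc,
              if (!is.na(x$se)) sprintf(" (SE %.2f%%)", 100 * x$se) else ""))
  invisible(x)
}
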