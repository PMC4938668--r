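#' Exact Poisson confidence interval on the count scale
#'
#' Exact (Garwood-style) interval from chi-square quantiles:
#' \code{low = qchisq(alpha/2, 2m)/2}, \code{high = qchisq(1-alpha/2, 2m+2)/2},
#' with \code{low = 0} when \code{m = 0}. Callers scale by exposure to get a
#' rate-scale interval.
#'
#' @param m observed count (nonnegative integer).
#' @param conf confidence level in (0, 1).
#' @return numeric c(low, high) on the count scale.
#' @examples
#' poisson_ci(10)  # (4.795, 18.390)
#' @export
poisson_ci <- function(m, conf = 0.95) {
  if (!(is.numeric(conf) && length(conf) == 1L && conf > 0 && conf < 1))
    stop("conf must be in (0, 1)")
  if (m < 0 || m != round(m)) stop("m must be a nonnegative integer")
  a <- 1 - conf
  low <- if (m == 0) 0 else stats::qchisq(a / 2, 2 * m) / 2
  high <- stats::qchisq(1 - a / 2, 2 * m + 2) / 2
  c(low = low, high = high)
}

#' Estimate a per-site per-generation mutation rate
#'
#' Rate = m / total exposure, where exposure is the sum over lines of
#' analyzable sites x generations (optionally restricted to G:C or A:T
#' sites). The primary standard error is the among-line SEM (standard
#' deviation of per-line rates / sqrt(L)) when per-line counts are supplied;
#' the pure Poisson SE (sqrt(m)/exposure) is always reported alongside. The
#' 95% CI is the exact Poisson interval scaled by exposure.
#'
#' @param m total event count.
#' @param exposures a \code{line_exposure} data.frame (or any data.frame
#'   with \code{n_total}/\code{n_GC}/\code{n_AT} and \code{generations}).
#' @param per_line_counts optional named vector of per-line counts (names =
#'   line ids) enabling the among-line SEM.
#' @param sites which site class forms the denominator.
#' @param conf confidence level.
#' @param scope label for printing ("overall", "GC->AT", "indel", ...).
#' @return object of class \code{rate_estimate}: list with \code{m},
#'   \code{exposure}, \code{rate}, \code{se} (primary), \code{se_poisson},
#'   \code{se_among_line}, \code{ci95}, \code{conf}, \code{scope}.
#' @examples
#' ex <- data.frame(line = 1:49, n_total = 6.77e6, n_GC = 0, n_AT = 0,
#'                  generations = 4900)
#' estimate_rate(856, ex)$rate  # ~5.27e-10
#' @export
estimate_rate <- function(m, exposures, per_line_counts = NULL,
                          sites = c("total", "GC", "AT"), conf = 0.95,
                          scope = "overall") {
  sites <- match.arg(sites)
  ncol_ <- switch(sites, total = "n_total", GC = "n_GC", AT = "n_AT")
  n_l <- exposures[[ncol_]]
  e_l <- n_l * exposures$generations
  E <- sum(e_l)
  if (E <= 0) stop("total exposure is zero; cannot estimate a rate")
  rate <- m / E
  se_pois <- sqrt(m) / E
  se_line <- NA_real_
  if (!is.null(per_line_counts)) {
    ml <- rep(0, nrow(exposures))
    names(ml) <- exposures$line
    common <- intersect(names(per_line_counts), names(ml))
    ml[common] <- per_line_counts[common]
    use <- e_l > 0
    r_l <- ml[use] / e_l[use]
    if (sum(use) > 1) se_line <- stats::sd(r_l) / sqrt(sum(use))
  }
  ci <- poisson_ci(m, conf) / E
  structure(list(scope = scope, m = m, exposure = E, rate = rate,
                 se = if (!is.na(se_line)) se_line else se_pois,
                 se_poisson = se_pois, se_among_line = se_line,
                 ci95 = unname(ci), conf = conf),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s rate: %.3g per site per generation (m = %d, exposure = %.4g)\n",
              x$scope, x$rate, x$m, x$exposure))
  cat(sprintf("  SE = %.3g (Poisson %.3g%s), %g%% CI %.3g-%.3g\n",
              x$se, x$se_poisson,
              if (!is.na(x$se_among_line))
                sprintf(", among-line %.3g", x$se_among_line) else "",
              100 * x$conf, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Conditional mutation rates in the AT and GC directions
#'
#' The AT-direction rate divides the G:C→A:T and G:C→T:A counts by the G:C
#' site exposure; the GC-direction rate divides the A:T→G:C and A:T→C:G
#' counts by the A:T site exposure. Also returns all six per-class
#' conditional rates (each class over the exposure of the bases that can
#' undergo it).
#'
#' @param calls a \code{mutation_calls} data.frame (needs ref/alt, line).
#' @param exposures a \code{line_exposure} with the GC/AT split.
#' @param conf confidence level.
#' @return list of class \code{conditional_rates}: \code{gc_to_at} and
#'   \code{at_to_gc} (\code{rate_estimate}s), \code{per_class} (data.frame
#'   class, m, exposure, rate, ci_low, ci_high), \code{class_counts}.
#' @export
conditional_rates <- function(calls, exposures, conf = 0.95) {
  E_gc <- sum(exposures$n_GC * exposures$generations)
  E_at <- sum(exposures$n_AT * exposures$generations)
  if (E_gc <= 0 || E_at <= 0)
    stop("zero G:C or A:T exposure; cannot compute conditional rates")
  cls <- classify_substitution(calls$ref, calls$alt)
  cnt <- stats::setNames(integer(6), mutation_classes())
  tab <- table(cls)
  cnt[names(tab)] <- as.integer(tab)

  per_line <- function(classes) {
    keep <- cls %in% classes
    if (!any(keep)) return(NULL)
    tapply(rep(1L, sum(keep)), calls$line[keep], sum)
  }
  gc_to_at <- estimate_rate(unname(cnt["GC_AT"] + cnt["GC_TA"]), exposures,
                            per_line_counts = per_line(c("GC_AT", "GC_TA")),
                            sites = "GC", conf = conf, scope = "GC->AT")
  at_to_gc <- estimate_rate(unname(cnt["AT_GC"] + cnt["AT_CG"]), exposures,
                            per_line_counts = per_line(c("AT_GC", "AT_CG")),
                            sites = "AT", conf = conf, scope = "AT->GC")

  at_classes <- c("AT_GC", "AT_TA", "AT_CG")
  expo <- ifelse(mutation_classes() %in% at_classes, E_at, E_gc)
  ci <- t(vapply(seq_along(cnt), function(i) poisson_ci(cnt[i], conf) / expo[i],
                 numeric(2)))
  per_class <- data.frame(class = mutation_classes(),
                          label = unname(mutation_class_labels()),
                          m = unname(cnt), exposure = expo,
                          rate = unname(cnt) / expo,
                          ci_low = ci[, 1], ci_high = ci[, 2],
                          stringsAsFactors = FALSE)
  structure(list(gc_to_at = gc_to_at, at_to_gc = at_to_gc,
                 per_class = per_class, class_counts = cnt),
            class = "conditional_rates")
}

#' @export
print.conditional_rates <- function(x, ...) {
  print(x$gc_to_at)
  print(x$at_to_gc)
  df <- x$per_class
  cat("per-class conditional rates (x 1e-10):\n")
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-9s m=%4d  rate %6.2f  CI %6.2f-%6.2f\n", df$label[i],
                df$m[i], df$rate[i] * 1e10, df$ci_low[i] * 1e10,
                df$ci_high[i] * 1e10))
  invisible(x)
}

#' Per-genome mutation rate
#'
#' @param rate a \code{rate_estimate} or a numeric per-site rate.
#' @param genome_sites number of sites per genome.
#' @return numeric per-genome per-generation rate.
#' @examples
#' genome_rate(5.27e-10, 6.77e6)  # ~0.0036
#' @export
genome_rate <- function(rate, genome_sites) {
  if (genome_sites <= 0) stop("genome_sites must be positive")
  r <- if (inherits(rate, "rate_estimate")) rate$rate else rate
  r * genome_sites
}

#' Write rate estimates as TSV
#'
#' Columns: scope, m, exposure, rate, se, ci_low, ci_high.
#' @param rates list of \code{rate_estimate}s.
#' @param path output path.
#' @export
write_rates_tsv <- function(rates, path) {
  df <- do.call(rbind, lapply(rates, function(r)
    data.frame(scope = r$scope, m = r$m, exposure = r$exposure,
               rate = r$rate, se = r$se, ci_low = r$ci95[1],
               ci_high = r$ci95[2], stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
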