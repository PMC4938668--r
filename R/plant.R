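#' The six strand-collapsed substitution classes
#'
#' Class codes used throughout the package, in the conventional order:
#' transitions first. \code{AT_GC} denotes A:T→G:C, etc.
#'
#' @return character vector of the six class codes.
#' @export
mutation_classes <- function() {
  c("AT_GC", "GC_AT", "AT_TA", "GC_TA", "AT_CG", "GC_CG")
}

#' @rdname mutation_classes
#' @export
mutation_class_labels <- function() {
  c(AT_GC = "A:T->G:C", GC_AT = "G:C->A:T", AT_TA = "A:T->T:A",
    GC_TA = "G:C->T:A", AT_CG = "A:T->C:G", GC_CG = "G:C->C:G")
}

# alt allele (int code) for a given ref base (int) and class; 0 = class not
# applicable at that base. Rows = ref A,C,G,T; columns = mutation_classes().
alt_lookup <- function() {
  m <- matrix(0L, nrow = 4, ncol = 6,
              dimnames = list(BASES, mutation_classes()))
  m["A", c("AT_GC", "AT_TA", "AT_CG")] <- base_to_int(c("G", "T", "C"))
  m["T", c("AT_GC", "AT_TA", "AT_CG")] <- base_to_int(c("C", "A", "G"))
  m["G", c("GC_AT", "GC_TA", "GC_CG")] <- base_to_int(c("A", "T", "C"))
  m["C", c("GC_AT", "GC_TA", "GC_CG")] <- base_to_int(c("T", "A", "G"))
  m
}

#' Plant mutations into MA lines
#'
#' Draws, for each line, a Poisson number of base substitutions and short
#' indels and places them on the genome according to the configured spectrum
#' and hotspot structure. Per-site class rates are proportional to the three
#' spectrum weights applicable at the site's base pair; the A:T→C:G weight is
#' multiplied by the hotspot multiplier at motif target sites and the
#' G:C→A:T weight by \code{cpg_multiplier} at CpG cytosines. Rates are
#' calibrated so the genome-average substitution rate equals \code{mu_bs}
#' when all multipliers are 1 (hotspots add events above that baseline).
#'
#' Indels are insertions with probability
#' \code{insertion_bias/(1+insertion_bias)}; a fraction
#' \code{ssr_indel_fraction} are unit-length slippage events inside SSR
#' tracts, the rest occur at uniform positions with geometric lengths capped
#' at \code{indel_max_len}. At most one event is planted per (line, site).
#'
#' Each line has its own RNG substream derived from \code{rng_seed}, so
#' adding lines does not perturb earlier lines.
#'
#' @param genome a \code{genome_assembly}.
#' @param config a \code{\link{sim_config}}.
#' @return data.frame of class \code{planted_set} with columns \code{line},
#'   \code{site} (1-based; for indels the anchor base \emph{before} the
#'   event), \code{type} ("sub", "ins", "del"), \code{ref}, \code{alt}
#'   (substitutions), \code{seq} (indel sequence), \code{len}.
#' @export
plant_mutations <- function(genome, config) {
  config <- validate_sim_config(config)
  L <- nchar(genome$sequence)
  seq_int <- seq_to_int(genome$sequence)
  is_at <- seq_int == 1L | seq_int == 4L
  w <- config$spectrum_weights[mutation_classes()]

  # per-site A:T->C:G multiplier (hotspot motifs) and G:C->A:T multiplier (CpG)
  mult_atcg <- rep(1, L)
  mh <- config$motif_hotspots
  if (!is.null(mh) && nrow(mh) > 0) {
    for (i in seq_len(nrow(mh))) {
      tg <- scan_motifs(genome, mh$motif[i], mh$offset[i])
      mult_atcg[tg] <- pmax(mult_atcg[tg], mh$multiplier[i])
    }
  }
  mult_gcat <- rep(1, L)
  if (config$cpg_multiplier != 1) {
    cg <- cpg_sites(genome)
    mult_gcat[cg] <- config$cpg_multiplier
  }

  s_at0 <- w["AT_GC"] + w["AT_TA"] + w["AT_CG"]
  s_gc0 <- w["GC_AT"] + w["GC_TA"] + w["GC_CG"]
  s_base <- ifelse(is_at, s_at0, s_gc0)                     # multiplier-free
  s_site <- ifelse(is_at,
                   w["AT_GC"] + w["AT_TA"] + w["AT_CG"] * mult_atcg,
                   w["GC_AT"] * mult_gcat + w["GC_TA"] + w["GC_CG"])
  sbar <- mean(s_base)
  r_site <- if (sbar > 0) config$mu_bs * s_site / sbar else rep(0, L)

  altmap <- alt_lookup()
  tracts <- find_ssr_tracts(genome)
  gens <- rep_len(config$generations, config$n_lines)
  probs <- base_probs(genome$gc_content)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]

  out <- vector("list", config$n_lines)
  for (l in seq_len(config$n_lines)) {
    out[[l]] <- with_local_seed(line_seed(config$rng_seed, l, 1L), {
      plant_one_line(l, L, gens[l], r_site, seq_int, is_at, w,
                     mult_atcg, mult_gcat, altmap, config, tracts, probs,
                     chars)
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("planted_set", "data.frame")
  res
}

plant_one_line <- function(l, L, gens, r_site, seq_int, is_at, w,
                           mult_atcg, mult_gcat, altmap, config, tracts,
                           probs, chars) {
  events <- list()
  occupied <- integer(0)   # sites already hit in this line

  # --- substitutions ---
  lambda <- gens * sum(r_site)
  n_sub <- if (lambda > 0) stats::rpois(1L, lambda) else 0L
  if (n_sub > 0L) {
    sites <- sample.int(L, min(n_sub, L), prob = r_site)
    ref <- seq_int[sites]
    cls <- character(length(sites))
    alt <- integer(length(sites))
    for (k in seq_along(sites)) {
      i <- sites[k]
      if (is_at[i]) {
        cw <- c(AT_GC = unname(w["AT_GC"]), AT_TA = unname(w["AT_TA"]),
                AT_CG = unname(w["AT_CG"]) * mult_atcg[i])
      } else {
        cw <- c(GC_AT = unname(w["GC_AT"]) * mult_gcat[i],
                GC_TA = unname(w["GC_TA"]), GC_CG = unname(w["GC_CG"]))
      }
      cls[k] <- sample(names(cw), 1L, prob = cw)
      alt[k] <- altmap[ref[k], cls[k]]
    }
    events$sub <- data.frame(line = l, site = sites, type = "sub",
                             ref = BASES[ref], alt = BASES[alt],
                             seq = NA_character_, len = 0L,
                             stringsAsFactors = FALSE)
    occupied <- sites
  }

  # --- indels ---
  n_ind <- if (config$mu_indel > 0) stats::rpois(1L, config$mu_indel * L * gens) else 0L
  if (n_ind > 0L) {
    rows <- vector("list", n_ind)
    have_tracts <- nrow(tracts) > 0L
    for (k in seq_len(n_ind)) {
      is_ins <- stats::runif(1) < config$insertion_bias / (1 + config$insertion_bias)
      in_ssr <- have_tracts && stats::runif(1) < config$ssr_indel_fraction
      if (in_ssr) {
        tr <- tracts[sample.int(nrow(tracts), 1L), ]
        u <- tr$unit_len
        n_copies <- (tr$end - tr$start + 1L) %/% u
        anchor <- tr$start + u * sample.int(n_copies, 1L) - u - 1L
        if (anchor < 1L) anchor <- tr$start - 1L
        if (anchor < 1L) next
        sq <- tr$unit
        len <- u
        if (!is_ins && anchor + len > L) next
      } else {
        len <- min(1L + stats::rgeom(1L, 0.6), config$indel_max_len)
        anchor <- sample.int(L - config$indel_max_len - 1L, 1L)
        sq <- if (is_ins)
          int_to_seq(sample.int(4L, len, replace = TRUE, prob = probs))
        else substr(genome_chars_sub(chars, anchor + 1L, anchor + len), 1L, len)
      }
      span <- if (is_ins) anchor else anchor:(anchor + len)
      if (any(span %in% occupied)) next
      if (!is_ins) sq <- paste(chars[(anchor + 1L):(anchor + len)], collapse = "")
      occupied <- c(occupied, span)
      rows[[k]] <- data.frame(line = l, site = anchor,
                              type = if (is_ins) "ins" else "del",
                              ref = chars[anchor], alt = NA_character_,
                              seq = sq, len = len, stringsAsFactors = FALSE)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) events$ind <- do.call(rbind, rows)
  }

  if (length(events) == 0L)
    return(data.frame(line = integer(0), site = integer(0),
                      type = character(0), ref = character(0),
                      alt = character(0), seq = character(0), len = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}

genome_chars_sub <- function(chars, from, to) paste(chars[from:to], collapse = "")

#' Reconstruct the mutated sequence of one line
#'
#' Applies a line's planted substitutions and indels to the reference
#' sequence. Insertions are placed after their anchor position; deletions
#' remove \code{len} bases following the anchor.
#'
#' @param genome a \code{genome_assembly}.
#' @param planted a \code{planted_set}.
#' @param line line id.
#' @return character scalar: the line's genome sequence.
#' @export
reconstruct_line_sequence <- function(genome, planted, line) {
  ev <- planted[planted$line == line, , drop = FALSE]
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  subs <- ev[ev$type == "sub", , drop = FALSE]
  if (nrow(subs)) chars[subs$site] <- subs$alt
  ind <- ev[ev$type != "sub", , drop = FALSE]
  if (nrow(ind)) {
    ind <- ind[order(-ind$site), , drop = FALSE]
    for (k in seq_len(nrow(ind))) {
      p <- ind$site[k]
      if (ind$type[k] == "ins") {
        chars <- append(chars, strsplit(ind$seq[k], "", fixed = TRUE)[[1]],
                        after = p)
      } else {
        chars <- chars[-((p + 1L):(p + ind$len[k]))]
      }
    }
  }
  paste(chars, collapse = "")
}

#' Write the planted truth set as TSV
#'
#' Columns: line, pos (1-based), type, ref, alt, seq, len.
#' @param planted a \code{planted_set}.
#' @param path output path.
#' @export
write_planted_tsv <- function(planted, path) {
  utils::write.table(planted, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
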