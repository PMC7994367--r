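# CpG suppression metrics and sliding-window chromosome profiles.
#
# Obs/Exp follows the standard CpG odds-ratio convention: the observed CG
# dinucleotide frequency divided by the product of the single-strand C and
# G frequencies. CG and GC are each self-complementary, so both indexes
# are invariant under reverse complement of the input.

.seq_counts <- function(x) {
  dna <- if (is(x, "DNAString")) x else Biostrings::DNAString(toupper(x))
  di <- Biostrings::dinucleotideFrequency(dna)
  mono <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T"))
  list(cg = unname(di[["CG"]]), gc = unname(di[["GC"]]),
       dinuc_total = sum(di), c = unname(mono[["C"]]),
       g = unname(mono[["G"]]), base_total = sum(mono))
}

#' CG observed/expected odds ratio
#'
#' `f(CG) / (f(C) * f(G))` where `f(CG)` is the CG dinucleotide frequency
#' over valid (N-free) dinucleotides and `f(C)`, `f(G)` are single-strand
#' mononucleotide frequencies over valid bases. Values near 1 mean CG
#' occurs as expected from base composition; vertebrate genomes show
#' suppression (values well below 1).
#'
#' @param x DNA sequence (character or `DNAString`).
#' @return A single number; `NaN` with a warning when `f(C) * f(G) = 0`.
#' @examples
#' cg_obs_exp("CGCGCG") # 2.4
#' @export
cg_obs_exp <- function(x) {
  ct <- .seq_counts(x)
  cg_obs_exp_counts(ct$cg, ct$dinuc_total, ct$c, ct$g, ct$base_total)
}

#' CG odds ratio from pooled counts
#'
#' Count-level interface used for genome-wide (pooled over windows or
#' records) computation: pooling happens before the division, not by
#' averaging per-window ratios.
#'
#' @param cg CG dinucleotide count.
#' @param dinuc_total Total valid dinucleotides.
#' @param c_count,g_count Valid C and G base counts.
#' @param base_total Total valid bases.
#' @return The odds ratio `(cg/dinuc_total) / ((c/base) * (g/base))`.
#' @export
cg_obs_exp_counts <- function(cg, dinuc_total, c_count, g_count, base_total) {
  fc <- c_count / base_total
  fg <- g_count / base_total
  if (!is.finite(fc * fg) || fc * fg == 0) {
    warn("f(C) * f(G) is zero; CG Obs/Exp undefined")
    return(NaN)
  }
  (cg / dinuc_total) / (fc * fg)
}

#' CG/GC dinucleotide ratio
#'
#' Count of CG divided by count of GC on the given strand. If dinucleotide
#' occurrence reflected base composition alone the ratio would fluctuate
#' around 1; CpG suppression pushes it below 1.
#'
#' @param x DNA sequence (character or `DNAString`).
#' @return A single number; `NaN` with a warning when no GC occurs.
#' @examples
#' cg_gc_ratio("CGCG") # 2
#' @export
cg_gc_ratio <- function(x) {
  ct <- .seq_counts(x)
  if (ct$gc == 0) {
    warn("GC count is zero; CG/GC ratio undefined")
    return(NaN)
  }
  ct$cg / ct$gc
}

#' Genome or per-record CpG suppression summary
#'
#' Pools counts over all records (dinucleotides never span record
#' boundaries) and reports the CG Obs/Exp odds ratio, the CG/GC ratio and
#' G+C%.
#'
#' @param records Genome record tibble.
#' @param scope `"genome"` (one pooled row per species) or `"record"`
#'   (one row per record).
#' @return A tibble with `species` (and `record_id` for record scope),
#'   `obs_exp`, `cg_gc`, `gc_percent`, `n_bases`.
#' @export
cg_suppression <- function(records, scope = c("genome", "record")) {
  scope <- match.arg(scope)
  per_rec <- purrr::pmap_dfr(
    list(records$record_id, records$species, records$sequence),
    function(rid, sp, seq) {
      ct <- .seq_counts(seq)
      tibble(record_id = rid, species = sp, cg = ct$cg, gc = ct$gc,
             dinuc_total = ct$dinuc_total, c_count = ct$c, g_count = ct$g,
             base_total = ct$base_total)
    }
  )
  grp <- if (scope == "genome") "species" else c("species", "record_id")
  per_rec |>
    group_by(across(dplyr::all_of(grp))) |>
    summarise(across(c("cg", "gc", "dinuc_total", "c_count", "g_count",
                       "base_total"), sum), .groups = "drop") |>
    mutate(
      obs_exp = purrr::pmap_dbl(
        list(.data$cg, .data$dinuc_total, .data$c_count, .data$g_count,
             .data$base_total), cg_obs_exp_counts),
      cg_gc = .data$cg / .data$gc,
      gc_percent = 100 * (.data$c_count + .data$g_count) / .data$base_total,
      n_bases = .data$base_total
    ) |>
    select(dplyr::all_of(grp), "obs_exp", "cg_gc", "gc_percent", "n_bases")
}

#' Sliding-window oligonucleotide-group profile along chromosomes
#'
#' For each record and each requested degenerate group, computes the
#' group's composition (in percent) in fixed-length windows sliding with
#' a given step — the "1-Mb window, 100-kb step" chromosome landscape.
#' Arbitrary group labels of any (single or mixed) k are accepted, e.g.
#' `"CG"`, `"CCG+CGG"`, `"CTTCC+GGAAG"`.
#'
#' @param records Genome record tibble (use records assembled into
#'   chromosomes for interpretable landscapes).
#' @param group_labels Character vector of degenerate group labels.
#' @param window,step Window and step in bases (defaults 1 Mb / 100 kb).
#' @param max_n_fraction Windows with a higher N fraction are dropped.
#' @return A profile tibble: `record_id`, `chromosome_label`, `species`,
#'   `group`, `start`, `end`, `midpoint`, `value` (percent), with
#'   attributes `window` and `step`. Records shorter than `window` yield
#'   no rows.
#' @export
chromosome_profile <- function(records, group_labels, window = 1e6,
                               step = 1e5, max_n_fraction = 0.1) {
  stopifnot(length(group_labels) >= 1)
  ks <- nchar(sub("\\+.*$", "", group_labels))
  wins <- window_records(records, window = window, step = step,
                         max_n_fraction = max_n_fraction)
  if (nrow(wins) == 0) {
    out <- tibble(record_id = character(), chromosome_label = character(),
                  species = character(), group = character(),
                  start = integer(), end = integer(), midpoint = double(),
                  value = double())
    attr(out, "window") <- window; attr(out, "step") <- step
    return(out)
  }
  out <- purrr::map_dfr(unique(ks), function(k) {
    labs_k <- group_labels[ks == k]
    bad <- setdiff(labs_k, oligo_groups(k)$label)
    if (length(bad) > 0) {
      abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
    }
    comp <- window_composition(wins, records, k)
    comp |>
      select("record_id", "chromosome_label", "species", "start", "end",
             dplyr::all_of(labs_k)) |>
      tidyr::pivot_longer(dplyr::all_of(labs_k), names_to = "group",
                          values_to = "value") |>
      mutate(value = 100 * .data$value,
             midpoint = (.data$start + .data$end) / 2)
  }) |>
    select("record_id", "chromosome_label", "species", "group", "start",
           "end", "midpoint", "value") |>
    arrange(.data$record_id, .data$group, .data$start)
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Sliding-window CpG suppression profile
#'
#' Obs/Exp and CG/GC tracks along each record, the window-level
#' counterpart of [cg_suppression()].
#'
#' @inheritParams chromosome_profile
#' @return A tibble `record_id`, `chromosome_label`, `species`, `start`,
#'   `end`, `midpoint`, `obs_exp`, `cg_gc`, `gc_percent`.
#' @export
cg_suppression_profile <- function(records, window = 1e6, step = 1e5,
                                   max_n_fraction = 0.1) {
  wins <- window_records(records, window = window, step = step,
                         max_n_fraction = max_n_fraction)
  rec_ids <- unique(wins$record_id)
  wlist <- split(wins, factor(wins$record_id, levels = rec_ids))
  seqs <- records$sequence[match(rec_ids, records$record_id)]
  purrr::map2_dfr(wlist, seqs, function(w, seq) {
    dna <- Biostrings::DNAString(seq)
    v <- Biostrings::Views(dna, start = w$start + 1L, width = w$length)
    di <- Biostrings::dinucleotideFrequency(v)
    mono <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    base_total <- rowSums(mono)
    fc <- mono[, "C"] / base_total
    fg <- mono[, "G"] / base_total
    w |>
      mutate(midpoint = (.data$start + .data$end) / 2,
             obs_exp = (di[, "CG"] / rowSums(di)) / (fc * fg),
             cg_gc = di[, "CG"] / di[, "GC"],
             gc_percent = 100 * (mono[, "C"] + mono[, "G"]) / base_total)
  }) |>
    select("record_id", "chromosome_label", "species", "start", "end",
           "midpoint", "obs_exp", "cg_gc", "gc_percent")
}

#' Quadratic trend of a chromosome profile
#'
#' Ordinary least-squares fit of `value = a x^2 + b x + c` on the window
#' midpoints, one fit per record x group. The curvature sign summarises
#' the chromosome-scale trend (`a > 0`: values rise toward both ends).
#' Degenerate inputs (fewer than 3 distinct midpoints) fall back to an
#' exact line fit with `a = 0`.
#'
#' @param profile Profile tibble from [chromosome_profile()].
#' @return A tibble `record_id`, `group`, `a`, `b`, `c`, `resid_sd`,
#'   `r_squared`, `n`, `downward` (`a < 0`).
#' @export
fit_quadratic <- function(profile) {
  profile |>
    group_by(.data$record_id, .data$group) |>
    summarise(.fit = list({
      x <- .data$midpoint; y <- .data$value
      if (length(unique(x)) >= 3) {
        m <- lm(y ~ x + I(x^2))
        cf <- coef(m)
        a <- unname(cf[3]); b <- unname(cf[2]); cc <- unname(cf[1])
      } else {
        m <- lm(y ~ x)
        cf <- coef(m)
        a <- 0; b <- unname(cf[2]); cc <- unname(cf[1])
      }
      a <- ifelse(is.na(a), 0, a)
      res <- y - (a * x^2 + b * x + cc)
      tibble(a = a, b = b, c = cc,
             resid_sd = sd(res),
             r_squared = if (sd(y) > 0) 1 - sum(res^2) / sum((y - mean(y))^2)
                         else NA_real_,
             n = length(y), downward = a < 0)
    }), .groups = "drop") |>
    tidyr::unnest(".fit")
}

#' Call peaks on a chromosome profile
#'
#' Peaks are local maxima of the residuals about the quadratic baseline:
#' a window is a peak when its residual is at least `min_prominence`
#' (default twice the residual SD of its record x group fit) and is the
#' maximum within one window length on either side (first window wins on
#' plateaus). Peaks whose midpoint lies within `terminal_fraction` of
#' either chromosome end are classed `terminal`, the rest `internal`.
#'
#' @param profile Profile tibble from [chromosome_profile()].
#' @param min_prominence Absolute residual threshold; default
#'   `2 * resid_sd` per fit.
#' @param terminal_fraction Fraction of the record length defining the
#'   terminal zones (default 0.05).
#' @param record_lengths Optional named vector (`record_id` -> length in
#'   bases); defaults to the span covered by the profile.
#' @return A tibble `record_id`, `group`, `start`, `end`, `midpoint`,
#'   `value`, `residual`, `class` (`terminal`/`internal`).
#' @export
call_peaks <- function(profile, min_prominence = NULL,
                       terminal_fraction = 0.05, record_lengths = NULL) {
  window <- attr(profile, "window") %||%
    (profile$end[1] - profile$start[1])
  step <- attr(profile, "step") %||% window
  h <- max(1L, as.integer(ceiling(window / step)))
  fits <- fit_quadratic(profile)
  profile |>
    group_by(.data$record_id, .data$group) |>
    dplyr::group_modify(function(.x, .y) {
      .x <- .x |> arrange(.data$start)
      f <- fits[fits$record_id == .y$record_id & fits$group == .y$group, ]
      x <- .x$midpoint
      res <- .x$value - (f$a * x^2 + f$b * x + f$c)
      # default threshold: 2 residual SDs, floored well above float noise
      # so an exactly-fitting (flat or polynomial) profile yields no peaks
      thr <- min_prominence %||%
        max(2 * f$resid_sd, 1e-8 * mean(abs(.x$value)))
      n <- length(res)
      is_peak <- vapply(seq_len(n), function(m) {
        lo <- max(1L, m - h); hi <- min(n, m + h)
        res[m] >= thr && res[m] >= max(res[lo:hi]) &&
          !any(res[lo:hi][seq_len(m - lo)] == res[m])
      }, logical(1))
      L <- if (!is.null(record_lengths)) {
        unname(record_lengths[.y$record_id])
      } else max(.x$end)
      tibble(start = .x$start[is_peak], end = .x$end[is_peak],
             midpoint = x[is_peak], value = .x$value[is_peak],
             residual = res[is_peak],
             class = ifelse(x[is_peak] <= terminal_fraction * L |
                              x[is_peak] >= (1 - terminal_fraction) * L,
                            "terminal", "internal"))
    }) |>
    ungroup()
}
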