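# Synthetic multi-species genome generator.
#
# Species are first-order Markov chains over {A,C,G,T}: the transition
# matrix fixes a dinucleotide-level genome signature, and a CG-suppression
# parameter scales the C->G transition to hit a target CG odds ratio.
# Chromosome plans add a parabolic edge/center composition gradient and
# embedded CG-rich repeat blocks, with truth segments for every feature.

#' Define a species as a first-order Markov sequence model
#'
#' The transition matrix starts from the independence baseline
#' `P(b | a) = pi_b`, then the C row is adjusted so that
#' `P(G | C) = s * pi_G` (with the remaining C-row entries rescaled to sum
#' to 1). `s` is therefore a target CG odds ratio: `s = 1` leaves the
#' chain at independence (Obs/Exp = 1) and `s = 0` forbids CG entirely.
#' The exact predicted Obs/Exp, computed from the numerically solved
#' stationary distribution, is stored in the model and serves as the
#' oracle for recovery tests.
#'
#' @param name Species name.
#' @param pi Stationary-target base composition, length 4 (`A`, `C`, `G`,
#'   `T`), summing to 1.
#' @param cg_suppression Target CG odds ratio `s >= 0`; must satisfy
#'   `s * pi_G < 1`.
#' @param bias Optional named numeric vector of dinucleotide
#'   multipliers, e.g. `c(AG = 1.3, CT = 1.3)`: each named transition
#'   `P(a, b)` is scaled by the multiplier before rows are renormalised
#'   (the `C -> G` entry is pinned back to `s * pi_G` afterwards, so the
#'   CG target survives). Supplying both members of a complementary pair
#'   keeps the emitted genome strand-symmetric. This is how signatures
#'   richer than base composition — species differing in, say, `GA+TC`
#'   versus `AG+CT` at equal G+C% — are modelled.
#' @return An object of class `species_model`: list with `name`, `pi`,
#'   `P` (4x4 row-stochastic), `stationary`, `obs_exp` (predicted),
#'   `dinucleotide_groups` (predicted degenerate dinucleotide group
#'   frequencies).
#' @examples
#' species_model("toad", pi = c(.31, .19, .19, .31), cg_suppression = 0.3)
#' @export
species_model <- function(name, pi = c(0.25, 0.25, 0.25, 0.25),
                          cg_suppression = 1, bias = NULL) {
  stopifnot(length(pi) == 4, all(pi > 0), abs(sum(pi) - 1) < 1e-8,
            cg_suppression >= 0)
  bases <- c("A", "C", "G", "T")
  pi <- setNames(as.numeric(pi) / sum(pi), bases)
  s <- cg_suppression
  if (s * pi[["G"]] >= 1) {
    abort("cg_suppression too large: s * pi_G must be < 1")
  }
  P <- matrix(pi, nrow = 4, ncol = 4, byrow = TRUE,
              dimnames = list(bases, bases))
  if (!is.null(bias)) {
    stopifnot(!is.null(names(bias)), all(nchar(names(bias)) == 2),
              all(bias > 0))
    for (nm in names(bias)) {
      a <- substr(nm, 1, 1); b <- substr(nm, 2, 2)
      P[a, b] <- P[a, b] * bias[[nm]]
    }
    P <- P / rowSums(P)
  }
  P["C", "G"] <- s * pi[["G"]]
  other <- setdiff(bases, "G")
  P["C", other] <- P["C", other] * (1 - s * pi[["G"]]) / sum(P["C", other])

  # stationary distribution: left eigenvector of P for eigenvalue 1
  ev <- eigen(t(P))
  k <- which.min(abs(ev$values - 1))
  mu <- Re(ev$vectors[, k])
  mu <- setNames(mu / sum(mu), bases)

  # f(ab) = mu_a * P(a, b), pooled into degenerate groups
  dinuc <- as.vector(outer(mu, rep(1, 4)) * P)
  names(dinuc) <- as.vector(outer(bases, bases, paste0))
  map <- .kmer_group_map(2)
  groups <- tapply(dinuc[names(map)], map, sum)

  obs_exp <- unname(P["C", "G"] / mu[["G"]])
  structure(
    list(name = name, pi = pi, P = P, cg_suppression = s, bias = bias,
         stationary = mu, obs_exp = obs_exp,
         dinucleotide_groups = groups[sort(names(groups))]),
    class = "species_model"
  )
}

#' @export
print.species_model <- function(x, ...) {
  cat("Species model:", x$name, "\n")
  cat("  G+C%:", round(100 * sum(x$stationary[c("C", "G")]), 1),
      " target CG suppression s:", x$cg_suppression,
      " predicted CG Obs/Exp:", round(x$obs_exp, 4), "\n")
  invisible(x)
}

#' Emit a sequence from a species model
#'
#' The first base is drawn from the stationary distribution, the rest from
#' the transition matrix. Uses R's RNG (one uniform per base), so results
#' are reproducible under `set.seed()`.
#'
#' @param model A [species_model()].
#' @param length Number of bases.
#' @return A character string of length `length`.
#' @export
markov_sequence <- function(model, length) {
  stopifnot(inherits(model, "species_model"), length >= 1)
  u <- stats::runif(length)
  markov_emit_cpp(model$stationary, model$P, model$P, u, FALSE)
}

#' Plan a synthetic chromosome
#'
#' A plan combines a length, an optional edge/center composition gradient
#' and an optional set of embedded repeat blocks. Under a gradient the
#' per-position transition matrix is the mixture
#' `(1 - w) P_center + w P_edge` with the parabolic weight
#' `w(x) = (2 x / L - 1)^2`, so the edge model dominates at both
#' chromosome ends. A repeat block places `n_copies` of a repeat unit in
#' tandem, separated by `spacer`-length stretches emitted from the
#' background model — kb-scale repeats forming an Mb-scale block.
#'
#' @param length Chromosome length in bases.
#' @param gradient Optional `list(center = <species_model>, edge =
#'   <species_model>)`.
#' @param repeat_blocks Optional tibble/data frame with columns `start`
#'   (0-based), `n_copies`, `unit` (repeat unit sequence) and optionally
#'   `spacer` (bases between copies, default 80).
#' @return A `chromosome_plan` object (validated list).
#' @export
chromosome_plan <- function(length, gradient = NULL, repeat_blocks = NULL) {
  stopifnot(length >= 1)
  if (!is.null(gradient)) {
    stopifnot(inherits(gradient$center, "species_model"),
              inherits(gradient$edge, "species_model"))
  }
  if (!is.null(repeat_blocks)) {
    repeat_blocks <- as_tibble(repeat_blocks)
    if (!"spacer" %in% names(repeat_blocks)) repeat_blocks$spacer <- 80L
    repeat_blocks <- repeat_blocks |>
      mutate(block_length = .data$n_copies * nchar(.data$unit) +
               pmax(.data$n_copies - 1, 0) * .data$spacer,
             end = .data$start + .data$block_length) |>
      arrange(.data$start)
    if (any(repeat_blocks$end > length)) {
      abort("repeat block extends past the chromosome end")
    }
    if (nrow(repeat_blocks) > 1 &&
        any(repeat_blocks$start[-1] <
            repeat_blocks$end[-nrow(repeat_blocks)])) {
      abort("repeat blocks overlap")
    }
  }
  structure(list(length = as.integer(length), gradient = gradient,
                 repeat_blocks = repeat_blocks),
            class = "chromosome_plan")
}

#' Generate a CG-rich repeat unit
#'
#' Emits a repeat unit from a GC-rich, CG-enriched Markov model — the
#' kind of kb-scale repeated element whose tandem arrays form Mb-level
#' CG-rich blocks. Defaults give a 520-bp unit at ~60% G+C with CG
#' enriched about twofold over independence.
#'
#' @param length Unit length in bases (default 520).
#' @param gc Target G+C fraction.
#' @param cg_enrichment Target CG odds ratio of the unit's model.
#' @return A character string.
#' @export
synthetic_repeat_unit <- function(length = 520, gc = 0.6,
                                  cg_enrichment = 2) {
  at <- (1 - gc) / 2
  m <- species_model("repeat_unit", pi = c(at, gc / 2, gc / 2, at),
                     cg_suppression = cg_enrichment)
  markov_sequence(m, length)
}

#' Generate one synthetic chromosome from a plan
#'
#' Emits the background (plain chain or gradient mixture), splices in the
#' planned repeat blocks, and returns the record together with truth
#' segments locating every block.
#'
#' @param model Background [species_model()] (the center model under a
#'   gradient).
#' @param plan A [chromosome_plan()]; a bare number is taken as a plain
#'   chromosome of that length.
#' @param record_id Record identifier.
#' @param chromosome_label Optional chromosome label.
#' @return A list with `record` (one-row genome record tibble) and
#'   `truth` (tibble `record_id`, `start`, `end`, `zone`, `detail`).
#' @export
generate_chromosome <- function(model, plan, record_id,
                                chromosome_label = NA_character_) {
  stopifnot(inherits(model, "species_model"))
  if (!inherits(plan, "chromosome_plan")) plan <- chromosome_plan(plan)
  n <- plan$length
  u <- stats::runif(n)
  if (is.null(plan$gradient)) {
    seq <- markov_emit_cpp(model$stationary, model$P, model$P, u, FALSE)
    zone <- "background"
  } else {
    ctr <- plan$gradient$center; edg <- plan$gradient$edge
    seq <- markov_emit_cpp(ctr$stationary, ctr$P, edg$P, u, TRUE)
    zone <- "gradient"
  }
  truth <- tibble(record_id = record_id, start = 0L, end = n,
                  zone = zone, detail = model$name)
  blocks <- plan$repeat_blocks
  if (!is.null(blocks) && nrow(blocks) > 0) {
    for (r in seq_len(nrow(blocks))) {
      unit <- toupper(blocks$unit[r])
      pieces <- character(2 * blocks$n_copies[r] - 1)
      pieces[seq(1, length(pieces), by = 2)] <- unit
      if (blocks$n_copies[r] > 1 && blocks$spacer[r] > 0) {
        for (sidx in seq_len(blocks$n_copies[r] - 1)) {
          pieces[2 * sidx] <- markov_sequence(model, blocks$spacer[r])
        }
      }
      block_seq <- paste(pieces, collapse = "")
      substr(seq, blocks$start[r] + 1, blocks$start[r] +
               nchar(block_seq)) <- block_seq
    }
    truth <- bind_rows(
      truth,
      tibble(record_id = record_id, start = blocks$start,
             end = blocks$end, zone = "repeat_block",
             detail = sprintf("%d copies x %d bp", blocks$n_copies,
                              nchar(blocks$unit)))
    )
  }
  rec <- genome_records(seq, species = model$name, record_ids = record_id,
                        chromosome_labels = chromosome_label)
  list(record = rec, truth = truth)
}

#' Generate a multi-species synthetic genome collection
#'
#' Deterministic per seed: records are generated in table order with one
#' seeded RNG stream. Optionally writes one FASTA per species and a truth
#' TSV so the collection can feed the pipeline from files.
#'
#' @param models List of [species_model()] objects with distinct names.
#' @param plans Tibble with one row per chromosome: columns `species`,
#'   `record_id`, optional `chromosome_label`, and `plan` (list column of
#'   [chromosome_plan()] objects or plain lengths).
#' @param seed Integer seed.
#' @param dir Optional output directory for `<species>.fa` files and
#'   `truth.tsv`.
#' @return A list with `records` (genome record tibble for all species),
#'   `truth` (segment tibble), and `files` (named paths, when `dir`
#'   given).
#' @export
generate_collection <- function(models, plans, seed = 1, dir = NULL) {
  names(models) <- purrr::map_chr(models, "name")
  if (anyDuplicated(names(models))) {
    abort("duplicate species names in models")
  }
  plans <- as_tibble(plans)
  if (!"chromosome_label" %in% names(plans)) {
    plans$chromosome_label <- NA_character_
  }
  missing_sp <- setdiff(unique(plans$species), names(models))
  if (length(missing_sp) > 0) {
    abort(paste0("no model for species: ", paste(missing_sp, collapse = ", ")))
  }
  set.seed(seed)
  out <- purrr::pmap(
    list(plans$species, plans$record_id, plans$chromosome_label,
         plans$plan),
    function(sp, rid, chrom, plan) {
      generate_chromosome(models[[sp]], plan, record_id = rid,
                          chromosome_label = chrom)
    }
  )
  records <- bind_rows(purrr::map(out, "record"))
  truth <- bind_rows(purrr::map(out, "truth"))
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- purrr::map_chr(unique(records$species), function(sp) {
      recs <- records |> filter(.data$species == sp)
      set <- Biostrings::DNAStringSet(setNames(recs$sequence,
                                               recs$record_id))
      path <- file.path(dir, paste0(sp, ".fa"))
      Biostrings::writeXStringSet(set, path)
      path
    })
    names(files) <- unique(records$species)
    truth_path <- file.path(dir, "truth.tsv")
    readr::write_tsv(truth, truth_path, progress = FALSE)
    files <- c(files, truth = truth_path)
  }
  list(records = records, truth = truth, files = files)
}

#' Label windows with generator truth zones
#'
#' A window overlapping any repeat-block segment is labelled
#' `repeat_block`; otherwise it inherits its record's zone (`background`
#' or `gradient`).
#'
#' @param windows Window tibble from [window_records()].
#' @param truth Truth segment tibble from the generator.
#' @return `windows` with an added `zone` column.
#' @export
label_windows <- function(windows, truth) {
  blocks <- truth |> filter(.data$zone == "repeat_block")
  base_zone <- truth |>
    filter(.data$zone != "repeat_block") |>
    distinct(.data$record_id, .data$zone)
  windows |>
    left_join(base_zone, by = "record_id") |>
    mutate(zone = dplyr::coalesce(.data$zone, "background")) |>
    mutate(zone = purrr::pmap_chr(
      list(.data$record_id, .data$start, .data$end, .data$zone),
      function(rid, s, e, z) {
        hit <- blocks$record_id == rid & blocks$start < e & blocks$end > s
        if (any(hit)) "repeat_block" else z
      }
    ))
}

#' Chromosome-end variant of a species model
#'
#' Builds the "edge" model for a gradient chromosome: same signature,
#' shifted toward higher G+C and weaker CG suppression — the compositional
#' drift frog chromosomes show toward their ends. Pairing a base model
#' (center) with its variant (edge) in [chromosome_plan()] produces the
#' characteristic rise of CG toward both chromosome ends and gives each
#' genome realistic within-species heterogeneity.
#'
#' @param model A [species_model()].
#' @param gc_shift Additive shift of the G+C fraction (default +0.03).
#' @param s_shift Additive shift of the CG suppression target
#'   (default +0.15).
#' @return A new [species_model()].
#' @export
gradient_variant <- function(model, gc_shift = 0.03, s_shift = 0.15) {
  stopifnot(inherits(model, "species_model"))
  pi <- model$pi
  gc <- pi[["C"]] + pi[["G"]] + gc_shift
  at <- 1 - gc
  pi2 <- c(at * pi[["A"]] / (pi[["A"]] + pi[["T"]]),
           gc * pi[["C"]] / (pi[["C"]] + pi[["G"]]),
           gc * pi[["G"]] / (pi[["C"]] + pi[["G"]]),
           at * pi[["T"]] / (pi[["A"]] + pi[["T"]]))
  species_model(paste0(model$name, "_edge"), pi = pi2,
                cg_suppression = model$cg_suppression + s_shift,
                bias = model$bias)
}

#' Three ready-made species models spanning realistic CpG suppression
#'
#' Frog genomes span roughly 38-45% G+C and CG odds ratios from ~0.30 to
#' ~0.57; species at similar G+C% still differ in which complementary
#' dinucleotide pairs they favour. These models cover that spread: each
#' carries a distinct strand-symmetric dinucleotide bias (`AG+CT`,
#' `CA+TG`, `GA+TC` respectively) on top of its G+C% and CG-suppression
#' level, so every pair differs in at least two degenerate dinucleotide
#' groups by well over 15% relative. They are the default study condition
#' for the species-separation experiments.
#'
#' @return Named list of three [species_model()] objects (`spA` low-GC
#'   strongly suppressed, `spB` high-GC moderately suppressed, `spC`
#'   high-GC weakly suppressed).
#' @export
example_species_models <- function() {
  list(
    spA = species_model("spA", pi = c(0.3105, 0.1895, 0.1895, 0.3105),
                        cg_suppression = 0.30,
                        bias = c(AG = 1.3, CT = 1.3)),
    spB = species_model("spB", pi = c(0.2775, 0.2225, 0.2225, 0.2775),
                        cg_suppression = 0.45,
                        bias = c(CA = 1.3, TG = 1.3)),
    spC = species_model("spC", pi = c(0.2830, 0.2170, 0.2170, 0.2830),
                        cg_suppression = 0.57,
                        bias = c(GA = 1.3, TC = 1.3))
  )
}
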