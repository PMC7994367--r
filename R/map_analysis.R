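# Map products: species territories, rank-based contribution heat maps,
# satellite territories, shared and adjacent nodes.

#' Classify lattice nodes into species territories
#'
#' In `pure_only` mode a node is coloured for a species only when every
#' member window comes from that species; any mixture is black. In
#' `majority50` mode a node is coloured when one species holds strictly
#' more than 50% of its members. Empty nodes stay white.
#'
#' @param fit A [blsom()] fit (its stored assignment is used), or an
#'   assignment tibble if `nodes` is supplied.
#' @param mode `"majority50"` (default) or `"pure_only"`.
#' @param nodes Node tibble (`node`, `i`, `j`) when `fit` is a raw
#'   assignment tibble.
#' @return A territory tibble: `node`, `i`, `j`, `n`, `class`
#'   (`empty`/`pure`/`majority`/`mixed`), `species` (NA unless
#'   pure/majority) and `fraction` (top-species share, NA for empty),
#'   with attribute `mode`.
#' @export
classify_nodes <- function(fit, mode = c("majority50", "pure_only"),
                           nodes = NULL) {
  mode <- match.arg(mode)
  if (inherits(fit, "blsom")) {
    assignment <- fit$assignment
    nodes <- fit$nodes
  } else {
    assignment <- fit
    if (is.null(nodes)) abort("supply `nodes` when passing a raw assignment")
  }
  tallies <- assignment |>
    count(.data$node, .data$species, name = "n_sp") |>
    group_by(.data$node) |>
    arrange(desc(.data$n_sp), .data$species, .by_group = TRUE) |>
    summarise(n = sum(.data$n_sp),
              n_species = dplyr::n(),
              top_species = dplyr::first(.data$species),
              fraction = dplyr::first(.data$n_sp) / sum(.data$n_sp),
              .groups = "drop")
  out <- nodes |>
    left_join(tallies, by = "node") |>
    mutate(
      n = dplyr::coalesce(.data$n, 0L),
      class = dplyr::case_when(
        .data$n == 0L ~ "empty",
        .data$n_species == 1L ~ "pure",
        mode == "majority50" & .data$fraction > 0.5 ~ "majority",
        TRUE ~ "mixed"
      ),
      species = dplyr::if_else(.data$class %in% c("pure", "majority"),
                               .data$top_species, NA_character_)
    ) |>
    select("node", "i", "j", "n", "class", "species", "fraction")
  attr(out, "mode") <- mode
  out
}

#' Summarise how cleanly a map separates species
#'
#' Node purity is the mean, over non-empty nodes, of the share of the
#' node's most frequent species. A perfectly species-separated map scores
#' 1; under label exchangeability it approaches `1/n_species` from above
#' (small-count inflation shrinks as nodes hold more windows).
#'
#' @param fit A [blsom()] fit or an assignment tibble.
#' @return A one-row tibble: `purity`, `n_nodes_occupied`, `n_species`,
#'   `baseline` (`1/n_species`), `frac_pure`, `frac_majority`,
#'   `frac_mixed` (fractions of occupied nodes under majority50 rules).
#' @export
territory_purity <- function(fit) {
  assignment <- if (inherits(fit, "blsom")) fit$assignment else fit
  per_node <- assignment |>
    count(.data$node, .data$species, name = "n_sp") |>
    group_by(.data$node) |>
    summarise(n = sum(.data$n_sp), top = max(.data$n_sp),
              n_species_node = dplyr::n(), .groups = "drop")
  frac <- per_node$top / per_node$n
  n_species <- dplyr::n_distinct(assignment$species)
  tibble(
    purity = mean(frac),
    n_nodes_occupied = nrow(per_node),
    n_species = n_species,
    baseline = 1 / n_species,
    frac_pure = mean(per_node$n_species_node == 1),
    frac_majority = mean(frac > 0.5 & per_node$n_species_node > 1),
    frac_mixed = mean(frac <= 0.5)
  )
}

#' Rank-based contribution heat map of one oligonucleotide group
#'
#' Non-empty nodes are sorted in descending order of the group's weight
#' value; the top third is classed `high` (drawn pink), the middle third
#' `moderate` (white) and the bottom third `low` (green). Ties share the
#' class of their first occurrence in a stable sort by value (desc), then
#' `i`, then `j`.
#'
#' @param fit A [blsom()] fit.
#' @param group_label Degenerate group label, e.g. `"CG"` or `"AG+CT"`.
#' @return A tibble `node`, `i`, `j`, `value`, `rank`, `rank_class`
#'   (`high`/`moderate`/`low`, NA for empty nodes).
#' @export
contribution_heatmap <- function(fit, group_label) {
  stopifnot(inherits(fit, "blsom"))
  col <- match(group_label, fit$labels)
  if (is.na(col)) abort(paste0("unknown group label: ", group_label))
  occupied <- sort(unique(fit$assignment$node))
  out <- fit$nodes
  out$value <- fit$weights[, col]
  occ <- out[out$node %in% occupied, , drop = FALSE]
  ord <- order(-occ$value, occ$i, occ$j)
  n <- nrow(occ)
  b1 <- ceiling(n / 3); b2 <- ceiling(2 * n / 3)
  cls_by_rank <- c(rep("high", b1), rep("moderate", b2 - b1),
                   rep("low", n - b2))
  cls <- character(n)
  cls[ord] <- cls_by_rank
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  # tie blocks inherit the class of the first tied node in sort order
  vals_sorted <- occ$value[ord]
  first_pos <- !duplicated(vals_sorted)
  cls <- cls_by_rank[first_pos][match(occ$value, vals_sorted[first_pos])]
  out$rank <- NA_integer_; out$rank_class <- NA_character_
  out$rank[out$node %in% occupied] <- rank
  out$rank_class[out$node %in% occupied] <- cls
  out
}

# connected components (Moore/8-neighbour adjacency) of a node subset
.lattice_components <- function(nodes_ij) {
  n <- nrow(nodes_ij)
  if (n == 0) return(integer(0))
  key <- paste(nodes_ij$i, nodes_ij$j)
  idx <- setNames(seq_len(n), key)
  comp <- integer(n)
  cur <- 0L
  nb <- expand.grid(di = -1:1, dj = -1:1)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      keys <- paste(nodes_ij$i[v] + nb$di, nodes_ij$j[v] + nb$dj)
      hits <- idx[keys]
      hits <- hits[!is.na(hits)]
      new <- hits[comp[hits] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Extract satellite territories of a species
#'
#' The species' territory nodes (pure or majority) are split into
#' connected components under 8-neighbour lattice adjacency. The largest
#' component is the main territory; every other component with
#' `min_size <= size <= max_fraction_of_main * main_size` is reported as
#' a satellite together with its member windows.
#'
#' @param fit A [blsom()] fit.
#' @param species Species whose satellites to extract.
#' @param min_size Minimum satellite size in nodes.
#' @param max_fraction_of_main Maximum satellite size as a fraction of the
#'   main territory.
#' @param territory Optional precomputed [classify_nodes()] result in
#'   majority50 mode.
#' @return A tibble with one row per satellite: `satellite_id`, `size`
#'   (nodes), `n_windows`, `nodes` (list of node ids), `window_ids`
#'   (list). Zero rows when the species has a single connected territory.
#' @export
extract_satellites <- function(fit, species, min_size = 3,
                               max_fraction_of_main = 0.25,
                               territory = NULL) {
  stopifnot(inherits(fit, "blsom"))
  tmap <- territory %||% classify_nodes(fit, "majority50")
  sp_nodes <- tmap |>
    filter(.data$class %in% c("pure", "majority"),
           .data$species == !!species)
  if (nrow(sp_nodes) == 0) {
    abort(paste0("species not present on the map: ", species))
  }
  comp <- .lattice_components(sp_nodes)
  sizes <- tabulate(comp)
  main <- which.max(sizes)
  keep <- which(sizes >= min_size &
                  sizes <= max_fraction_of_main * sizes[main])
  keep <- setdiff(keep, main)
  if (length(keep) == 0) {
    return(tibble(satellite_id = character(), species = character(),
                  size = integer(), n_windows = integer(),
                  nodes = list(), window_ids = list()))
  }
  # order satellites by size desc for stable ids
  keep <- keep[order(-sizes[keep])]
  members <- fit$assignment |> filter(.data$species == !!species)
  purrr::imap_dfr(keep, function(cid, pos) {
    nd <- sp_nodes$node[comp == cid]
    win <- members$window_id[members$node %in% nd]
    tibble(satellite_id = sprintf("%s_sat%d", species, pos),
           species = species, size = length(nd), n_windows = length(win),
           nodes = list(nd), window_ids = list(win))
  })
}

#' Oligonucleotide enrichment of a window set against a genome
#'
#' Pools the composition of the selected windows (count-weighted, i.e.
#' the composition of their concatenation) and divides it element-wise by
#' a reference composition, typically the species' whole genome. Groups
#' absent from the reference get an infinite ratio and an `undefined`
#' flag.
#'
#' @param comp Composition tibble covering the windows.
#' @param window_ids Windows to pool (e.g. a satellite's `window_ids`).
#' @param reference Reference composition: a named frequency vector (as
#'   from [pool_composition()]) or a composition tibble to pool whole.
#' @param top_n Number of top-ratio groups to return (default 10).
#' @return A tibble `label`, `set_freq`, `reference_freq`, `ratio`,
#'   `undefined`, sorted by descending ratio, truncated to `top_n`.
#' @export
enrichment_ratios <- function(comp, window_ids, reference, top_n = 10) {
  pooled <- pool_composition(comp, window_ids)
  ref <- if (is.data.frame(reference)) pool_composition(reference) else reference
  labs <- names(pooled)
  stopifnot(all(labs %in% names(ref)))
  ref <- ref[labs]
  out <- tibble(label = labs, set_freq = as.numeric(pooled),
                reference_freq = as.numeric(ref)) |>
    mutate(ratio = .data$set_freq / .data$reference_freq,
           undefined = .data$reference_freq == 0) |>
    arrange(desc(.data$ratio), .data$label)
  if (any(out$undefined)) {
    warn("reference frequency 0 for some group(s); ratio reported as Inf")
  }
  head(out, top_n)
}

#' Nodes shared by two window sets
#'
#' Finds lattice nodes holding at least one window from each of two
#' filtered subsets (the "black node" criterion: a single foreign
#' sequence suffices to mark a node shared). Typical use: all windows of
#' species A against the windows of one chromosome of species B.
#'
#' @param fit A [blsom()] fit or assignment tibble.
#' @param a,b Filter expressions on the assignment columns, e.g.
#'   `species == "grug"` or
#'   `species == "pads" & chromosome_label == "chrW"`.
#' @return A tibble of shared nodes: `node`, `i`, `j`, `n_a`, `n_b`, with
#'   list columns `windows_a`, `windows_b` and attribute `records_a`
#'   (union of set-A source record ids, the scaffolds to extract).
#' @export
shared_nodes <- function(fit, a, b) {
  assignment <- if (inherits(fit, "blsom")) fit$assignment else fit
  sel_a <- eval_tidy(enquo(a), data = assignment)
  sel_b <- eval_tidy(enquo(b), data = assignment)
  if (!any(sel_a) || !any(sel_b)) {
    warn("a filter selected no windows; shared-node set is empty")
    out <- tibble(node = integer(), i = integer(), j = integer(),
                  n_a = integer(), n_b = integer(),
                  windows_a = list(), windows_b = list())
    attr(out, "records_a") <- character()
    return(out)
  }
  A <- assignment[sel_a, , drop = FALSE]
  B <- assignment[sel_b, , drop = FALSE]
  shared <- intersect(unique(A$node), unique(B$node))
  A <- A |> filter(.data$node %in% shared)
  B <- B |> filter(.data$node %in% shared)
  out <- tibble(node = sort(shared)) |>
    left_join(distinct(assignment, .data$node, .data$i, .data$j),
              by = "node") |>
    mutate(
      windows_a = purrr::map(.data$node, ~ A$window_id[A$node == .x]),
      windows_b = purrr::map(.data$node, ~ B$window_id[B$node == .x]),
      n_a = lengths(.data$windows_a),
      n_b = lengths(.data$windows_b)
    ) |>
    select("node", "i", "j", "n_a", "n_b", "windows_a", "windows_b")
  attr(out, "records_a") <- sort(unique(A$record_id))
  out
}

#' Nodes of a window set adjacent to a species territory
#'
#' Returns the nodes occupied by the filtered window set that lie within
#' a Chebyshev lattice distance of any node classified to the territory
#' species — the "dotted line along the territory border" pattern. With
#' `max_lattice_distance = 0` this reduces to co-occupancy of territory
#' nodes.
#'
#' @param fit A [blsom()] fit.
#' @param b Filter expression selecting the query window set.
#' @param species Territory species.
#' @param max_lattice_distance Chebyshev distance threshold (default 1).
#' @param territory Optional precomputed [classify_nodes()] result.
#' @return A tibble `node`, `i`, `j`, `n_b`, `min_distance`, with list
#'   column `windows_b` and attribute `records_b`.
#' @export
adjacent_nodes <- function(fit, b, species, max_lattice_distance = 1,
                           territory = NULL) {
  stopifnot(inherits(fit, "blsom"))
  assignment <- fit$assignment
  tmap <- territory %||% classify_nodes(fit, "majority50")
  terr <- tmap |> filter(.data$class %in% c("pure", "majority"),
                         .data$species == !!species)
  sel_b <- eval_tidy(enquo(b), data = assignment)
  B <- assignment[sel_b, , drop = FALSE]
  if (nrow(B) == 0 || nrow(terr) == 0) {
    out <- tibble(node = integer(), i = integer(), j = integer(),
                  n_b = integer(), min_distance = integer(),
                  windows_b = list())
    attr(out, "records_b") <- character()
    return(out)
  }
  b_nodes <- B |> distinct(.data$node, .data$i, .data$j)
  dmat <- pmax(abs(outer(b_nodes$i, terr$i, "-")),
               abs(outer(b_nodes$j, terr$j, "-")))
  mind <- apply(dmat, 1, min)
  keep <- mind <= max_lattice_distance
  out <- b_nodes[keep, , drop = FALSE] |>
    mutate(min_distance = mind[keep],
           windows_b = purrr::map(.data$node,
                                  ~ B$window_id[B$node == .x]),
           n_b = lengths(.data$windows_b)) |>
    select("node", "i", "j", "n_b", "min_distance", "windows_b") |>
    arrange(.data$node)
  attr(out, "records_b") <-
    sort(unique(B$record_id[B$node %in% out$node]))
  out
}
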