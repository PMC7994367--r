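# Degenerate oligonucleotide groups: a k-mer is pooled with its reverse
# complement so compositions do not depend on which strand was registered.
# Self-complementary k-mers (even k only) form singleton groups.

.oligo_env <- new.env(parent = emptyenv())

.all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  g <- do.call(expand.grid,
               c(rep(list(b), k), list(stringsAsFactors = FALSE)))
  # reverse columns so the last position varies fastest -> lexicographic
  do.call(paste0, rev(g))
}

.revcomp_chr <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Enumerate degenerate oligonucleotide groups
#'
#' Every k-mer over `{A,C,G,T}` is pooled with its reverse complement into
#' one group labelled `"X+Y"` with the lexicographically smaller member
#' first (e.g. `"AG+CT"`); self-complementary k-mers such as `CG` form
#' singleton groups labelled by the k-mer itself. There are `4^k / 2`
#' groups for odd k and `(4^k + 4^(k/2)) / 2` for even k: 2, 10, 32, 136
#' for k = 1..4.
#'
#' @param k Oligonucleotide length, `1 <= k <= 8`.
#' @return A tibble with columns `label`, `k`, `members` (list of 1-2
#'   k-mers) and `self_complementary`, sorted by `label`.
#' @examples
#' oligo_groups(2)
#' @export
oligo_groups <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > 8 || k != round(k)) {
    abort("k must be a single integer in 1..8")
  }
  k <- as.integer(k)
  key <- paste0("groups_", k)
  if (!is.null(.oligo_env[[key]])) return(.oligo_env[[key]])
  kmers <- .all_kmers(k)
  rc <- .revcomp_chr(kmers)
  label <- ifelse(kmers == rc, kmers,
                  paste(pmin(kmers, rc), pmax(kmers, rc), sep = "+"))
  tbl <- tibble(kmer = kmers, rc = rc, label = label) |>
    group_by(.data$label) |>
    summarise(members = list(sort(unique(c(.data$kmer, .data$rc)))),
              .groups = "drop") |>
    mutate(k = k,
           self_complementary = purrr::map_int(.data$members, length) == 1L) |>
    arrange(.data$label) |>
    select("label", "k", "members", "self_complementary")
  .oligo_env[[key]] <- tbl
  tbl
}

# named vector: kmer -> group label, in .all_kmers(k) order
.kmer_group_map <- function(k) {
  key <- paste0("map_", k)
  if (!is.null(.oligo_env[[key]])) return(.oligo_env[[key]])
  kmers <- .all_kmers(k)
  rc <- .revcomp_chr(kmers)
  map <- ifelse(kmers == rc, kmers,
                paste(pmin(kmers, rc), pmax(kmers, rc), sep = "+"))
  names(map) <- kmers
  .oligo_env[[key]] <- map
  map
}

#' Canonical group label of a k-mer
#'
#' `canonical_group(x)` equals `canonical_group(revcomp(x))` by
#' construction. K-mers containing `N` (or any non-ACGT character) return
#' `NA` and are skipped by the counting routines.
#'
#' @param kmer Character vector of k-mers (all the same length).
#' @return Character vector of group labels (`NA` where the k-mer is not
#'   over `{A,C,G,T}`).
#' @examples
#' canonical_group(c("AG", "TT", "CG", "AN"))
#' @export
canonical_group <- function(kmer) {
  k <- unique(nchar(kmer))
  if (length(k) != 1) abort("all k-mers must have the same length")
  map <- .kmer_group_map(k)
  unname(map[kmer])
}

# counts over groups for a DNAString/Views object; rows x groups matrix
.group_counts <- function(x, k) {
  counts <- Biostrings::oligonucleotideFrequency(x, width = k)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  map <- .kmer_group_map(k)
  counts <- counts[, names(map), drop = FALSE]
  labels <- sort(unique(unname(map)))
  ind <- matrix(0, nrow = length(map), ncol = length(labels),
                dimnames = list(names(map), labels))
  ind[cbind(seq_along(map), match(map, labels))] <- 1
  counts %*% ind
}

#' Degenerate composition of a single sequence
#'
#' Counts all overlapping k-mers on the given strand, pools complementary
#' k-mers into degenerate groups, and normalises by the number of valid
#' k-mers (k-mers containing `N` are skipped). Because of the grouping the
#' result is invariant under reverse complement of the input.
#'
#' @param sequence DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param k Oligonucleotide length.
#' @return Named numeric vector of group frequencies summing to 1, with
#'   attribute `total_count` (number of valid k-mers). If no valid k-mer
#'   exists the vector is all `NA` and `total_count` is 0.
#' @examples
#' composition_vector("ACGT", 2)
#' @export
composition_vector <- function(sequence, k) {
  stopifnot(length(sequence) == 1, nchar(sequence) >= k)
  cnt <- .group_counts(Biostrings::DNAString(toupper(sequence)), k)[1, ]
  tot <- sum(cnt)
  vals <- if (tot > 0) cnt / tot else cnt * NA_real_
  attr(vals, "total_count") <- tot
  vals
}

#' Composition matrix for a window table
#'
#' Computes the degenerate k-mer composition of every window by scanning
#' each record once (windows are views on the record, no copying). Windows
#' with zero valid k-mers (all-N) are flagged invalid, dropped with a
#' warning and tallied in the `"invalid"` attribute.
#'
#' @param windows Window tibble from [window_records()].
#' @param records Genome record tibble the windows were cut from.
#' @param k Oligonucleotide length (1-4 are the intended map inputs).
#' @return A tibble with the window metadata columns, `total_count`, and
#'   one frequency column per degenerate group (rows sum to 1). The group
#'   labels are stored in the `"group_labels"` attribute and `k` in `"k"`.
#' @export
window_composition <- function(windows, records, k) {
  stopifnot(is.data.frame(windows), is.data.frame(records))
  groups <- oligo_groups(k)$label
  rec_ids <- unique(windows$record_id)
  wlist <- split(windows, factor(windows$record_id, levels = rec_ids))
  seqs <- records$sequence[match(rec_ids, records$record_id)]
  if (anyNA(seqs)) {
    abort("windows reference record_id(s) missing from records")
  }
  blocks <- purrr::map2(wlist, seqs, function(w, seq) {
    dna <- Biostrings::DNAString(seq)
    v <- Biostrings::Views(dna, start = w$start + 1L, width = w$length)
    cnt <- .group_counts(v, k)
    tot <- rowSums(cnt)
    freq <- cnt / ifelse(tot > 0, tot, NA_real_)
    out <- w
    out$total_count <- as.integer(tot)
    dplyr::bind_cols(out, as_tibble(freq))
  })
  out <- bind_rows(blocks)
  # restore the original window order
  out <- out[match(windows$window_id, out$window_id), , drop = FALSE]
  invalid <- out |> filter(.data$total_count == 0)
  if (nrow(invalid) > 0) {
    warn(paste0(nrow(invalid),
                " window(s) had no valid k-mers (all N) and were dropped"))
    out <- out |> filter(.data$total_count > 0)
  }
  attr(out, "invalid") <- invalid$window_id
  attr(out, "k") <- as.integer(k)
  attr(out, "group_labels") <- groups
  out
}

# pull the group-frequency matrix out of a composition tibble
.composition_matrix <- function(comp, labels = NULL) {
  labels <- labels %||% attr(comp, "group_labels")
  if (is.null(labels)) {
    labels <- setdiff(names(comp)[vapply(comp, is.numeric, logical(1))],
                      c("start", "end", "length", "n_fraction", "total_count"))
    labels <- labels[grepl("^[ACGT]+(\\+[ACGT]+)?$", labels)]
  }
  missing <- setdiff(labels, names(comp))
  if (length(missing) > 0) {
    abort(paste0("composition table lacks group column(s): ",
                 paste(missing, collapse = ", ")))
  }
  m <- as.matrix(comp[, labels, drop = FALSE])
  rownames(m) <- comp$window_id
  m
}

#' Pool window compositions into one composition
#'
#' Count-weighted pooling: frequencies are recombined as
#' `sum(freq_i * total_i) / sum(total_i)`, i.e. exactly the composition of
#' the concatenated windows.
#'
#' @param comp Composition tibble from [window_composition()].
#' @param window_ids Optional subset of windows to pool (default all).
#' @return Named numeric vector of pooled group frequencies with attribute
#'   `total_count`.
#' @export
pool_composition <- function(comp, window_ids = NULL) {
  if (!is.null(window_ids)) {
    comp <- comp |> filter(.data$window_id %in% window_ids)
  }
  if (nrow(comp) == 0) abort("no windows to pool")
  m <- .composition_matrix(comp)
  w <- comp$total_count
  vals <- colSums(m * w) / sum(w)
  attr(vals, "total_count") <- sum(w)
  vals
}
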