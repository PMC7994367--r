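#' Read a genome assembly from FASTA
#'
#' Reads a (multi-record) FASTA assembly and returns one row per record with
#' the sequence held as an uppercase character string over `{A,C,G,T,N}`.
#' Lowercase (soft-masked) letters are uppercased; any other IUPAC or illegal
#' character is mapped to `N` with a warning.
#'
#' @param path Path to a FASTA file.
#' @param species Species label attached to every record in the file.
#' @param chromosome_labels Optional named character vector mapping
#'   `record_id` to a chromosome label (e.g. `c(scaf1 = "chr1")`). Records
#'   without an entry get `NA`.
#' @return A tibble with columns `record_id`, `species`, `chromosome_label`,
#'   `length`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGTacgt"), fa)
#' read_genome_fasta(fa, species = "toy")
#' @export
read_genome_fasta <- function(path, species, chromosome_labels = NULL) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  genome_records(seqs, species = species, record_ids = ids,
                 chromosome_labels = chromosome_labels)
}

#' Build a genome record table from in-memory sequences
#'
#' Constructor used by [read_genome_fasta()] and the synthetic generator.
#' Applies the same sanitation: uppercase, non-`ACGTN` characters to `N`.
#'
#' @param sequences Character vector of DNA sequences.
#' @param species Species label (length 1 or one per sequence).
#' @param record_ids Record identifiers; must be unique and non-empty.
#' @param chromosome_labels Optional named vector (`record_id` -> label) or
#'   unnamed vector parallel to `sequences`.
#' @return A genome record tibble (see [read_genome_fasta()]).
#' @export
genome_records <- function(sequences, species, record_ids,
                           chromosome_labels = NULL) {
  stopifnot(length(sequences) == length(record_ids))
  if (anyDuplicated(record_ids)) {
    abort("duplicate record_id in genome record collection")
  }
  empty <- !nzchar(sequences)
  if (any(empty)) {
    abort(paste0("record with empty sequence: ",
                 paste(record_ids[empty], collapse = ", ")))
  }
  seqs <- toupper(sequences)
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    warn(paste0("characters outside {A,C,G,T,N} mapped to N in record(s): ",
                paste(record_ids[bad], collapse = ", ")))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  chrom <- rep(NA_character_, length(seqs))
  if (!is.null(chromosome_labels)) {
    if (!is.null(names(chromosome_labels))) {
      hit <- match(record_ids, names(chromosome_labels))
      chrom <- unname(chromosome_labels[hit])
    } else {
      stopifnot(length(chromosome_labels) == length(seqs))
      chrom <- as.character(chromosome_labels)
    }
  }
  tibble(
    record_id = as.character(record_ids),
    species = rep_len(as.character(species), length(seqs)),
    chromosome_label = unname(chrom),
    length = unname(nchar(seqs)),
    sequence = unname(seqs)
  )
}

#' Cut genome records into fixed-length sliding windows
#'
#' Windows start at 0, `step`, `2*step`, ... while `start + window` fits in
#' the record; the trailing partial window is discarded so every composition
#' vector comes from the same sequence length. Windows never span records.
#' Windows whose fraction of `N` bases exceeds `max_n_fraction` are dropped
#' and tallied in the `"excluded"` attribute of the result.
#'
#' @param records Genome record tibble from [read_genome_fasta()].
#' @param window Window length in bases (e.g. `1e6`).
#' @param step Sliding step in bases (defaults to `window`, i.e.
#'   non-overlapping); must satisfy `window >= step >= 1`.
#' @param max_n_fraction Maximum tolerated fraction of `N` per window.
#' @return A tibble with columns `window_id`, `record_id`, `species`,
#'   `chromosome_label`, `start`, `end`, `length`, `n_fraction`
#'   (coordinates 0-based half-open), with an `"excluded"` attribute
#'   tibble counting N-filtered windows per record.
#' @export
window_records <- function(records, window, step = window,
                           max_n_fraction = 0.1) {
  stopifnot(is.data.frame(records), window >= 1, step >= 1)
  if (step > window) abort("step must not exceed window")
  window <- as.integer(round(window))
  step <- as.integer(round(step))

  per_record <- purrr::pmap(
    list(records$record_id, records$species, records$chromosome_label,
         records$length, records$sequence),
    function(rid, sp, chrom, len, seq) {
      if (len < window) return(NULL)
      starts <- seq.int(0L, len - window, by = step)
      dna <- Biostrings::DNAString(seq)
      v <- Biostrings::Views(dna, start = starts + 1L, width = window)
      nfrac <- as.vector(Biostrings::letterFrequency(v, "N")) / window
      tibble(
        window_id = sprintf("%s:%d-%d", rid, starts, starts + window),
        record_id = rid, species = sp, chromosome_label = chrom,
        start = starts, end = starts + window, length = window,
        n_fraction = nfrac
      )
    }
  )
  out <- bind_rows(per_record)
  if (nrow(out) == 0) {
    out <- tibble(window_id = character(), record_id = character(),
                  species = character(), chromosome_label = character(),
                  start = integer(), end = integer(), length = integer(),
                  n_fraction = double())
  }
  keep <- out$n_fraction <= max_n_fraction
  excluded <- out |>
    filter(!keep) |>
    count(.data$record_id, name = "n_excluded")
  if (nrow(excluded) > 0) {
    inform(paste0(sum(!keep), " window(s) exceeded max_n_fraction = ",
                  max_n_fraction, " and were excluded"))
  }
  out <- out[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Write windows as BED (0-based half-open)
#'
#' @param windows Window tibble from [window_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- windows |>
    select("record_id", "start", "end", "window_id", "species")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read windows back from BED written by [write_windows_bed()]
#'
#' @param path BED path.
#' @return A tibble with `record_id`, `start`, `end`, `window_id`, `species`.
#' @export
read_windows_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("record_id", "start", "end", "window_id",
                                "species"),
                  col_types = "ciicc", progress = FALSE)
}

#' Write any result table as TSV with a header row
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Write a JSON run manifest next to a result
#'
#' Records inputs, parameters, package version and seed so a run can be
#' reproduced exactly.
#'
#' @param path Output path for the manifest (JSON).
#' @param parameters Named list of parameters to record.
#' @param inputs Character vector of input file paths (optional).
#' @param seed Integer seed used for the run (optional).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, parameters = list(), inputs = character(),
                               seed = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required to write run manifests")
  }
  manifest <- list(
    package = "oligosom",
    version = as.character(utils::packageVersion("oligosom")),
    inputs = inputs,
    parameters = parameters,
    seed = seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
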