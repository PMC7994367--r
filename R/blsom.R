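# PCA-initialised batch-learning self-organizing map (BLSOM).
#
# Batch learning makes the trained map independent of the order of the
# input rows; PCA initialisation makes it deterministic (no random weight
# seeding). Both properties are exact here: eigenvector signs are fixed by
# convention and input rows are summed in a canonical order, so permuting
# the rows reproduces the trained grid bit for bit.

#' Lattice dimensions for a node budget
#'
#' The node budget is `B = round(n_sequences / avg_per_node)` ("one node
#' per ten sequences" at the default). The first lattice dimension spans
#' the first principal axis and the second is scaled by the ratio of the
#' principal standard deviations: `I = round(sqrt(B * sigma1 / sigma2))`,
#' `J = ceiling((sigma2 / sigma1) * I)`, both clipped to at least 2, so
#' `I * J` approximates `B` with the lattice aspect matching the data
#' cloud.
#'
#' @param n_sequences Number of input vectors.
#' @param avg_per_node Target mean number of sequences per node.
#' @param sigma1,sigma2 Standard deviations of the first and second
#'   principal components (`sigma1 >= sigma2`).
#' @return Integer vector `c(I, J)`.
#' @examples
#' blsom_grid_size(1000, 10, sigma1 = 4, sigma2 = 1)
#' @export
blsom_grid_size <- function(n_sequences, avg_per_node = 10, sigma1, sigma2) {
  stopifnot(n_sequences >= avg_per_node, avg_per_node >= 1, sigma1 > 0)
  B <- round(n_sequences / avg_per_node)
  if (sigma2 <= 0 || !is.finite(sigma2)) {
    warn("sigma2 is zero; degenerate second axis, using J = 2")
    I <- max(2L, as.integer(round(sqrt(B))))
    return(c(I = I, J = 2L))
  }
  I <- max(2L, as.integer(round(sqrt(B * sigma1 / sigma2))))
  J <- max(2L, as.integer(ceiling((sigma2 / sigma1) * I)))
  c(I = I, J = J)
}

# PCA pieces with deterministic eigenvector signs (largest-|.| entry > 0)
.blsom_pca <- function(X) {
  if (nrow(unique(X)) < 3) abort("need at least 3 distinct input vectors")
  x_av <- colMeans(X)
  ev <- eigen(cov(X), symmetric = TRUE)
  fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  b1 <- fix_sign(ev$vectors[, 1])
  b2 <- fix_sign(ev$vectors[, 2])
  s1 <- sqrt(max(ev$values[1], 0))
  s2 <- sqrt(max(ev$values[2], 0))
  if (s1 <= 0) abort("input vectors are all identical; PCA is degenerate")
  list(x_av = x_av, b1 = b1, b2 = b2, sigma1 = s1, sigma2 = s2)
}

# initial weights on the PCA plane:
# w_ij = x_av + (5*sigma1/I) * (b1*(i - I/2) + b2*(j - J/2)), i,j 0-based
.blsom_init <- function(pca, I, J) {
  grid <- expand.grid(j = 0:(J - 1), i = 0:(I - 1))  # i-major node order
  grid <- grid[, c("i", "j")]
  scale <- 5 * pca$sigma1 / I
  alpha <- scale * (grid$i - I / 2)
  beta <- scale * (grid$j - J / 2)
  W <- matrix(pca$x_av, nrow = nrow(grid), ncol = length(pca$x_av),
              byrow = TRUE) +
    outer(alpha, pca$b1) + outer(beta, pca$b2)
  list(W = W, nodes = tibble(node = seq_len(nrow(grid)),
                             i = grid$i, j = grid$j))
}

# best-matching node per row (min Euclidean distance; ties -> smallest
# node index, i.e. smallest i then j)
.blsom_bmu <- function(X, W) {
  D2 <- -2 * tcrossprod(X, W)
  D2 <- sweep(D2, 2, rowSums(W^2), "+")
  max.col(-D2, ties.method = "first")
}

#' Train a batch-learning self-organizing map on composition vectors
#'
#' Initial weights are laid on the plane of the first two principal axes
#' of the composition cloud, spanning five standard deviations of PC1
#' (`w_ij = x_av + (5 sigma1 / I)(b1 (i - I/2) + b2 (j - J/2))`). Each
#' batch epoch assigns every vector to its best-matching node (minimal
#' Euclidean distance) and replaces every node weight by the mean of all
#' vectors assigned within its square (Chebyshev) lattice neighbourhood;
#' the neighbourhood radius shrinks linearly from `max(I, J)/2` to 1, one
#' epoch per radius by default. Nodes with an empty neighbourhood keep
#' their weights.
#'
#' @param comp Composition tibble from [window_composition()], or any
#'   tibble with a `window_id` column plus numeric group columns (pass
#'   `labels` if the group columns cannot be inferred).
#' @param avg_per_node Target mean sequences per node (node budget
#'   `n/avg_per_node`); the default 10 matches common practice for
#'   species-territory maps.
#' @param grid_dim Optional explicit `c(I, J)` overriding the budget rule.
#' @param epochs Number of batch epochs; default is the number of radius
#'   values in the shrinking schedule. `epochs = 0` returns the
#'   PCA-initialised grid untouched.
#' @param labels Optional character vector naming the composition columns.
#' @return An object of class `blsom`: list with `weights` (nodes x
#'   groups), `nodes` (node/i/j tibble), `I`, `J`, `pca` (x_av, b1, b2,
#'   sigma1, sigma2), `radii`, `epochs`, `qe` (quantization error per
#'   epoch), `labels`, and `assignment` (tibble window_id, node, i, j,
#'   dist plus metadata carried from `comp`).
#' @export
blsom <- function(comp, avg_per_node = 10, grid_dim = NULL, epochs = NULL,
                  labels = NULL) {
  X <- .composition_matrix(comp, labels)
  if (anyNA(X) || any(!is.finite(X))) {
    abort("composition matrix contains NA or non-finite values")
  }
  pca <- .blsom_pca(X)
  if (is.null(grid_dim)) {
    grid_dim <- blsom_grid_size(nrow(X), avg_per_node,
                                pca$sigma1, pca$sigma2)
  }
  I <- as.integer(grid_dim[1]); J <- as.integer(grid_dim[2])
  stopifnot(I >= 2, J >= 2)
  init <- .blsom_init(pca, I, J)
  W <- init$W

  r0 <- max(I, J) / 2
  if (is.null(epochs)) epochs <- max(1L, as.integer(ceiling(r0)))
  radii <- if (epochs > 0) {
    pmax(1, round(seq(r0, 1, length.out = epochs)))
  } else numeric(0)

  # canonical row order: summation order, and hence the trained grid,
  # no longer depends on how the input rows were ordered
  ord <- do.call(order, as.data.frame(X))
  Xs <- X[ord, , drop = FALSE]
  M <- I * J
  ci <- init$nodes$i; cj <- init$nodes$j
  qe <- numeric(length(radii))

  for (e in seq_along(radii)) {
    bmu <- .blsom_bmu(Xs, W)
    qe[e] <- mean(sqrt(rowSums((Xs - W[bmu, , drop = FALSE])^2)))
    S <- matrix(0, M, ncol(Xs))
    sums <- rowsum(Xs, bmu)
    S[as.integer(rownames(sums)), ] <- sums
    counts <- tabulate(bmu, M)
    r <- radii[e]
    Nb <- (abs(outer(ci, ci, "-")) <= r) & (abs(outer(cj, cj, "-")) <= r)
    storage.mode(Nb) <- "double"
    numer <- Nb %*% S
    denom <- as.vector(Nb %*% counts)
    upd <- denom > 0
    W[upd, ] <- numer[upd, , drop = FALSE] / denom[upd]
  }

  fit <- structure(
    list(weights = W, nodes = init$nodes, I = I, J = J, pca = pca,
         radii = radii, epochs = length(radii), qe = qe,
         labels = colnames(X), k = attr(comp, "k")),
    class = "blsom"
  )
  fit$assignment <- blsom_assign(fit, comp)
  fit
}

#' Assign composition vectors to their best-matching nodes
#'
#' @param fit A trained [blsom()] object.
#' @param comp Composition tibble with the same group columns the map was
#'   trained on.
#' @return A tibble with `window_id`, any of `species`, `record_id`,
#'   `chromosome_label`, `start` present in `comp`, plus `node`, `i`, `j`
#'   and `dist` (Euclidean distance to the winning weight vector).
#' @export
blsom_assign <- function(fit, comp) {
  stopifnot(inherits(fit, "blsom"))
  X <- .composition_matrix(comp, fit$labels)
  bmu <- .blsom_bmu(X, fit$weights)
  meta_cols <- intersect(c("window_id", "species", "record_id",
                           "chromosome_label", "start"), names(comp))
  out <- comp |> select(dplyr::all_of(meta_cols))
  out$node <- bmu
  out$i <- fit$nodes$i[bmu]
  out$j <- fit$nodes$j[bmu]
  out$dist <- sqrt(rowSums((X - fit$weights[bmu, , drop = FALSE])^2))
  out
}

#' @export
print.blsom <- function(x, ...) {
  cat("Batch-learning SOM:", x$I, "x", x$J, "lattice,",
      length(x$labels), "oligonucleotide groups\n")
  cat("  epochs:", x$epochs,
      " radius:", if (length(x$radii)) paste0(x$radii[1], " -> ",
                                              x$radii[length(x$radii)]) else "-",
      "\n")
  if (length(x$qe)) cat("  final quantization error:",
                        signif(x$qe[length(x$qe)], 4), "\n")
  if (!is.null(x$assignment))
    cat("  assigned vectors:", nrow(x$assignment), "\n")
  invisible(x)
}

#' Tidy a trained map into a per-node tibble
#'
#' @param x A [blsom()] fit.
#' @param ... Unused.
#' @return One row per node: `node`, `i`, `j`, `n` (members), `species`
#'   (majority species or `NA` for empty nodes) and `fraction` (majority
#'   fraction).
#' @export
tidy.blsom <- function(x, ...) {
  tallies <- x$assignment |>
    count(.data$node, .data$species, name = "n_sp") |>
    group_by(.data$node) |>
    arrange(desc(.data$n_sp), .data$species, .by_group = TRUE) |>
    summarise(n = sum(.data$n_sp),
              species = dplyr::first(.data$species),
              fraction = dplyr::first(.data$n_sp) / sum(.data$n_sp),
              .groups = "drop")
  x$nodes |>
    left_join(tallies, by = "node") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' One-row summary of a trained map
#'
#' @param x A [blsom()] fit.
#' @param ... Unused.
#' @return A tibble with `I`, `J`, `nodes`, `n_vectors`, `epochs`,
#'   `final_radius`, `quantization_error`, `sigma1`, `sigma2`.
#' @export
glance.blsom <- function(x, ...) {
  tibble(I = x$I, J = x$J, nodes = x$I * x$J,
         n_vectors = nrow(x$assignment), epochs = x$epochs,
         final_radius = if (length(x$radii)) x$radii[length(x$radii)] else NA,
         quantization_error = if (length(x$qe)) x$qe[length(x$qe)] else NA,
         sigma1 = x$pca$sigma1, sigma2 = x$pca$sigma2)
}

#' Serialize a trained map to a plain-text bundle
#'
#' Writes `<stem>_nodes.tsv` (node, i, j and one column per group weight)
#' and `<stem>_meta.json` (dims, schedule, PCA vectors). The pair can be
#' reloaded with [read_blsom()].
#'
#' @param fit A [blsom()] fit.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_blsom <- function(fit, stem) {
  w <- fit$weights
  colnames(w) <- fit$labels
  w <- as_tibble(w)
  readr::write_tsv(dplyr::bind_cols(fit$nodes, w),
                   paste0(stem, "_nodes.tsv"), progress = FALSE)
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required to write the map metadata")
  }
  meta <- list(I = fit$I, J = fit$J, radii = fit$radii, epochs = fit$epochs,
               qe = fit$qe, labels = fit$labels, k = fit$k,
               x_av = fit$pca$x_av, b1 = fit$pca$b1, b2 = fit$pca$b2,
               sigma1 = fit$pca$sigma1, sigma2 = fit$pca$sigma2)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), digits = NA)
  invisible(stem)
}

#' Reload a map written by [write_blsom()]
#'
#' @param stem Path stem used when writing.
#' @return A `blsom` object (without an `assignment`; call
#'   [blsom_assign()] to re-assign data).
#' @export
read_blsom <- function(stem) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required to read the map metadata")
  }
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  tab <- readr::read_tsv(paste0(stem, "_nodes.tsv"), show_col_types = FALSE,
                         progress = FALSE)
  W <- as.matrix(tab[, meta$labels, drop = FALSE])
  structure(
    list(weights = unname(W),
         nodes = tab |> select("node", "i", "j"),
         I = meta$I, J = meta$J,
         pca = list(x_av = meta$x_av, b1 = meta$b1, b2 = meta$b2,
                    sigma1 = meta$sigma1, sigma2 = meta$sigma2),
         radii = meta$radii, epochs = meta$epochs, qe = meta$qe,
         labels = meta$labels, k = meta$k, assignment = NULL),
    class = "blsom"
  )
}
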