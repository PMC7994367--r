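# Independent oracles and small generators used across the suite.
# These deliberately avoid the package's counting/grouping code paths.

# reverse complement of a single string (N-safe)
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# naive position-scan degenerate composition: walk every k-mer, skip any
# containing N, label it min(kmer, revcomp)+"+"+max (or itself if
# palindromic), tally, normalise
oracle_composition <- function(s, k) {
  L <- nchar(s)
  kmers <- substring(s, 1:(L - k + 1), k:(L))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0) return(setNames(numeric(0), character(0)))
  rc <- vapply(kmers, oracle_revcomp, character(1), USE.NAMES = FALSE)
  lab <- ifelse(kmers == rc, kmers,
                paste(pmin(kmers, rc), pmax(kmers, rc), sep = "+"))
  tab <- table(lab)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

# brute-force count of degenerate groups of size k
oracle_group_count <- function(k) {
  b <- c("A", "C", "G", "T")
  g <- do.call(expand.grid, c(rep(list(b), k), list(stringsAsFactors = FALSE)))
  kmers <- do.call(paste0, g)
  rc <- vapply(kmers, oracle_revcomp, character(1), USE.NAMES = FALSE)
  length(unique(ifelse(kmers < rc, paste(kmers, rc), paste(rc, kmers))))
}

random_dna <- function(n, p = rep(0.25, 4), n_frac = 0) {
  letters <- c("A", "C", "G", "T")
  s <- sample(letters, n, replace = TRUE, prob = p)
  if (n_frac > 0) {
    idx <- sample(n, round(n * n_frac))
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

# stationary distribution by power iteration (independent of the
# eigen-based computation inside species_model)
oracle_stationary <- function(P, iters = 200) {
  mu <- rep(0.25, 4)
  for (i in seq_len(iters)) mu <- as.vector(mu %*% P)
  mu / sum(mu)
}

# predicted CG Obs/Exp of a first-order chain: f(CG)/(f(C) f(G)) with
# f(CG) = mu_C P(C,G), f(C) = mu_C, f(G) = mu_G
oracle_obs_exp <- function(P) {
  mu <- oracle_stationary(P)
  (mu[2] * P[2, 3]) / (mu[2] * mu[3])
}

# random frequency vectors around cluster centres, rows sum to 1
make_cluster_vectors <- function(n_per, centers, noise = 0.01) {
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c) {
    m <- matrix(rep(centers[c, ], n_per), nrow = n_per, byrow = TRUE)
    m + matrix(rnorm(length(m), 0, noise), nrow = n_per)
  }))
  X <- abs(X)
  X / rowSums(X)
}

# wrap a plain matrix as a composition tibble blsom() accepts
as_comp_tibble <- function(X, species = NULL) {
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  out <- tibble::as_tibble(X)
  out$window_id <- sprintf("w%04d", seq_len(nrow(X)))
  if (!is.null(species)) out$species <- species
  attr(out, "group_labels") <- paste0("V", seq_len(ncol(X)))
  out
}
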