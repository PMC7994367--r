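test_that("species models hit the CG-suppression construction exactly", {
  pi <- c(0.3, 0.2, 0.2, 0.3)
  m1 <- species_model("one", pi, cg_suppression = 1)
  # s = 1: independence, all rows equal pi, predicted Obs/Exp 1
  expect_equal(unname(m1$P), matrix(pi, 4, 4, byrow = TRUE))
  expect_equal(m1$obs_exp, 1)
  m0 <- species_model("zero", pi, cg_suppression = 0)
  expect_equal(m0$P["C", "G"], 0)
  expect_equal(m0$obs_exp, 0)
  set.seed(61)
  expect_equal(Biostrings::countPattern(
    "CG", Biostrings::DNAString(markov_sequence(m0, 2e5))), 0)
  # rows always sum to 1 and P(G|C) = s * pi_G before any renormalisation
  for (s in c(0.3, 0.45, 0.57, 1, 2)) {
    m <- species_model("m", pi, cg_suppression = s)
    expect_equal(unname(rowSums(m$P)), rep(1, 4))
    expect_equal(m$P["C", "G"], s * pi[3])
  }
  expect_error(species_model("bad", pi, cg_suppression = 6), "too large")
})

test_that("predicted Obs/Exp agrees with a power-iteration oracle", {
  set.seed(62)
  for (trial in 1:8) {
    pi <- runif(4, 0.1, 1); pi <- pi / sum(pi)
    s <- runif(1, 0, min(2, 0.9 / pi[3]))
    m <- species_model("m", pi, cg_suppression = s)
    expect_equal(m$obs_exp, oracle_obs_exp(m$P), tolerance = 1e-10)
    expect_equal(unname(m$stationary),
                 oracle_stationary(m$P), tolerance = 1e-10)
  }
})

test_that("emitted sequences match the analytic dinucleotide signature", {
  set.seed(63)
  m <- species_model("m", pi = c(0.28, 0.22, 0.22, 0.28),
                     cg_suppression = 0.45)
  s <- markov_sequence(m, 1e6)
  emp <- composition_vector(s, 2)
  pred <- m$dinucleotide_groups[names(emp)]
  # 3 binomial SDs per group on ~1e6 dinucleotides
  n <- attr(emp, "total_count")
  for (g in names(emp)) {
    sd3 <- 3 * sqrt(pred[[g]] * (1 - pred[[g]]) / n) *
      (1 + (grepl("\\+", g)))  # paired groups pool two draws
    expect_lt(abs(emp[[g]] - pred[[g]]), sd3 + 3e-4)
  }
  # measured CG odds ratio near the stored prediction
  expect_equal(cg_obs_exp(s), m$obs_exp, tolerance = 0.05)
})

test_that("gradient chromosomes rise toward both ends", {
  set.seed(64)
  center <- species_model("ctr", pi = c(0.31, 0.19, 0.19, 0.31),
                          cg_suppression = 0.3)
  edge <- species_model("edg", pi = c(0.24, 0.26, 0.26, 0.24),
                        cg_suppression = 1.2)
  plan <- chromosome_plan(4e6, gradient = list(center = center,
                                               edge = edge))
  gen <- generate_chromosome(center, plan, "chrG")
  prof <- chromosome_profile(gen$record, "CG", window = 4e5, step = 1e5)
  v <- prof$value
  n <- length(v)
  # both end windows dominate the interior
  expect_true(all(v[1] > v[4:(n - 3)]))
  expect_true(all(v[n] > v[4:(n - 3)]))
  # fitted curvature consistent with an edge-rich construction
  f <- fit_quadratic(prof)
  expect_gt(f$a, 0)
  expect_false(f$downward)
  expect_equal(gen$truth$zone, "gradient")
})

test_that("repeat blocks elevate CG in overlapping windows and are mapped", {
  set.seed(65)
  m <- species_model("bg", pi = c(0.31, 0.19, 0.19, 0.31),
                     cg_suppression = 0.3)
  unit <- synthetic_repeat_unit(520, gc = 0.6, cg_enrichment = 2)
  expect_equal(nchar(unit), 520)
  blocks <- tibble::tibble(start = 1e6, n_copies = 100, unit = unit)
  plan <- chromosome_plan(3e6, repeat_blocks = blocks)
  gen <- generate_chromosome(m, plan, "chrR")
  wins <- window_records(gen$record, 2e5, 1e5)
  lab <- label_windows(wins, gen$truth)
  expect_true(all(c("repeat_block", "background") %in% lab$zone))
  comp <- window_composition(wins, gen$record, 2)
  cg <- comp$CG * 100
  block_cg <- cg[lab$zone == "repeat_block"]
  flank_cg <- cg[lab$zone != "repeat_block"]
  expect_gt(min(block_cg), max(flank_cg))
  # truth covers the block coordinates exactly
  tr <- gen$truth[gen$truth$zone == "repeat_block", ]
  expect_equal(tr$start, 1e6)
  expect_equal(tr$end, 1e6 + 100 * 520 + 99 * 80)
  # invalid plans are rejected
  expect_error(chromosome_plan(1e5, repeat_blocks = blocks), "past the")
  expect_error(chromosome_plan(
    5e6, repeat_blocks = tibble::tibble(start = c(0, 1e4), n_copies = 100,
                                        unit = unit)), "overlap")
})

test_that("collections are deterministic per seed and write valid FASTA", {
  models <- example_species_models()[1:2]
  plans <- tibble::tibble(species = c("spA", "spB"),
                          record_id = c("A1", "B1"),
                          plan = list(3e5, 3e5))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  col1 <- generate_collection(models, plans, seed = 7, dir = dir1)
  col2 <- generate_collection(models, plans, seed = 7, dir = dir2)
  expect_identical(col1$records$sequence, col2$records$sequence)
  expect_identical(readLines(file.path(dir1, "spA.fa")),
                   readLines(file.path(dir2, "spA.fa")))
  col3 <- generate_collection(models, plans, seed = 8)
  expect_false(identical(col1$records$sequence, col3$records$sequence))
  # FASTA round-trip through the reader
  back <- read_genome_fasta(file.path(dir1, "spA.fa"), "spA")
  expect_equal(back$sequence,
               col1$records$sequence[col1$records$species == "spA"])
  # duplicate species names rejected
  expect_error(
    generate_collection(list(species_model("x"), species_model("x")),
                        plans), "duplicate")
})
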