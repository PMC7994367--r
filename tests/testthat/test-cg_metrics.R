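test_that("CG odds ratio and CG/GC match hand counts", {
  # CGCGCG: f(C)=f(G)=0.5, f(CG)=3/5 -> 2.4
  expect_equal(cg_obs_exp("CGCGCG"), 2.4)
  # CGCG: CG=2, GC=1
  expect_equal(cg_gc_ratio("CGCG"), 2)
  # zero CG occurrences (C and G both present)
  expect_equal(cg_obs_exp("GGAACC"), 0)
  # undefined cases are flagged
  expect_warning(expect_true(is.nan(cg_obs_exp("AATTAA"))), "undefined")
  expect_warning(expect_true(is.nan(cg_gc_ratio("ATATAT"))), "undefined")
})

test_that("both suppression indexes are reverse-complement invariant", {
  set.seed(51)
  for (trial in 1:10) {
    s <- random_dna(2000, p = runif(4, 0.1, 1) |> (\(p) p / sum(p))())
    expect_equal(cg_obs_exp(s), cg_obs_exp(oracle_revcomp(s)),
                 tolerance = 1e-12)
    expect_equal(cg_gc_ratio(s), cg_gc_ratio(oracle_revcomp(s)),
                 tolerance = 1e-12)
  }
})

test_that("iid sequence has odds ratio 1 and symmetric chains CG/GC 1", {
  set.seed(52)
  s <- random_dna(1e6, p = c(0.3, 0.2, 0.2, 0.3))
  expect_equal(cg_obs_exp(s), 1, tolerance = 0.01)
  # a first-order chain with symmetric construction: stationary oracle
  # predicts f(CG) = f(GC), so the ratio fluctuates around 1
  m <- species_model("sym", pi = c(0.25, 0.25, 0.25, 0.25),
                     cg_suppression = 1)
  expect_equal(cg_gc_ratio(markov_sequence(m, 5e5)), 1, tolerance = 0.02)
})

test_that("genome-wide Obs/Exp pools counts, not per-window ratios", {
  set.seed(53)
  recs <- genome_records(c(random_dna(4000, p = c(.4, .1, .1, .4)),
                           random_dna(4000, p = c(.1, .4, .4, .1))),
                         "sp", c("r1", "r2"))
  g <- cg_suppression(recs, scope = "genome")
  # construction oracle: pooled counts over records
  di <- colSums(Biostrings::dinucleotideFrequency(
    Biostrings::DNAStringSet(recs$sequence)))
  mono <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(recs$sequence), c("A", "C", "G", "T")))
  expected <- (di[["CG"]] / sum(di)) /
    ((mono[["C"]] / sum(mono)) * (mono[["G"]] / sum(mono)))
  expect_equal(g$obs_exp, expected)
  # and differs from the mean of per-record ratios for heterogeneous input
  per <- cg_suppression(recs, scope = "record")
  expect_false(isTRUE(all.equal(g$obs_exp, mean(per$obs_exp))))
  expect_equal(g$gc_percent,
               100 * (mono[["C"]] + mono[["G"]]) / sum(mono))
})

test_that("chromosome profiles have the right geometry and values", {
  set.seed(54)
  m <- species_model("flat", pi = c(0.3, 0.2, 0.2, 0.3),
                     cg_suppression = 0.5)
  rec <- genome_records(markov_sequence(m, 2e6), "flat", "chr1")
  prof <- chromosome_profile(rec, c("CG", "CA+TG"), window = 4e5,
                             step = 1e5)
  expect_equal(nrow(prof), 2 * (floor((2e6 - 4e5) / 1e5) + 1))
  expect_true(all(prof$value >= 0 & prof$value <= 100))
  expect_true(all(diff(prof$start[prof$group == "CG"]) == 1e5))
  # constant-composition chromosome -> flat profile
  cgv <- prof$value[prof$group == "CG"]
  expect_lt(sd(cgv) / mean(cgv), 0.02)
  # window count arithmetic on a longer record
  rec10 <- genome_records(strrep("ACGT", 2.5e6), "sp", "c10")
  prof10 <- chromosome_profile(rec10, "CG")
  expect_equal(nrow(prof10), floor((10e6 - 1e6) / 1e5) + 1)
  # record shorter than the window -> empty profile
  expect_equal(nrow(chromosome_profile(rec, "CG", window = 4e6)), 0)
  expect_error(chromosome_profile(rec, "CG+GC"), "unknown group")
})

test_that("quadratic fits recover exact polynomials and flag flats", {
  x <- seq(5e5, 9.5e6, by = 1e5)
  a <- -1e-15; b <- 9e-9; cc <- 3
  prof <- tibble::tibble(record_id = "c", group = "CG", start = x - 5e5,
                         end = x + 5e5, midpoint = x,
                         value = a * x^2 + b * x + cc)
  f <- fit_quadratic(prof)
  expect_equal(f$a, a, tolerance = 1e-8)
  expect_equal(f$b, b, tolerance = 1e-8)
  expect_equal(f$c, cc, tolerance = 1e-8)
  expect_true(f$downward)
  flat <- prof |> dplyr::mutate(value = 4)
  f2 <- fit_quadratic(flat)
  expect_equal(f2$a, 0, tolerance = 1e-20)
  # two-point degenerate input falls back to a line
  f3 <- fit_quadratic(prof[1:2, ])
  expect_equal(f3$a, 0)
})

test_that("peak calling finds implanted elevations and classifies ends", {
  # synthetic residual landscape: flat baseline with two bumps and a
  # terminal rise
  set.seed(55)
  n <- 120
  x <- seq(5e5, by = 1e5, length.out = n)
  v <- rnorm(n, 10, 0.02)
  v[40:42] <- v[40:42] + c(1, 2, 1)          # internal bump
  v[80] <- v[80] + 1.5                       # second internal bump
  v[1] <- v[1] + 2                           # terminal peak
  prof <- tibble::tibble(record_id = "c", group = "CG",
                         start = x - 5e5, end = x + 5e5, midpoint = x,
                         value = v)
  attr(prof, "window") <- 1e6; attr(prof, "step") <- 1e5
  pk <- call_peaks(prof, terminal_fraction = 0.05)
  expect_equal(sort(pk$midpoint[pk$class == "internal"]),
               c(x[41], x[80]))
  expect_true(x[1] %in% pk$midpoint[pk$class == "terminal"])
  # monotone profile: no internal peaks
  mono <- prof |> dplyr::mutate(value = seq(1, 5, length.out = n))
  pk2 <- call_peaks(mono)
  expect_equal(sum(pk2$class == "internal"), 0)
})
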