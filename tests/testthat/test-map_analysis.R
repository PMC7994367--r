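# small hand-built assignments make the classification rules fully checkable

fake_fit <- function(assignment, I, J) {
  nodes <- tibble::tibble(
    node = seq_len(I * J),
    i = rep(0:(I - 1), each = J),
    j = rep(0:(J - 1), times = I)
  )
  assignment$i <- nodes$i[assignment$node]
  assignment$j <- nodes$j[assignment$node]
  structure(list(nodes = nodes, I = I, J = J, assignment = assignment,
                 weights = matrix(0, I * J, 2), labels = c("x", "y")),
            class = "blsom")
}

make_assignment <- function(node_species) {
  # node_species: list node -> character vector of member species
  purrr::imap_dfr(node_species, function(sp, nd) {
    if (length(sp) == 0) return(NULL)
    tibble::tibble(window_id = sprintf("n%s_w%d", nd, seq_along(sp)),
                   species = sp, record_id = paste0("rec_", sp),
                   node = as.integer(nd))
  })
}

test_that("node classification honours the >50% majority rule", {
  asg <- make_assignment(list(
    `1` = c(rep("A", 6), rep("B", 4)),   # majority A at 0.6
    `2` = c(rep("A", 5), rep("B", 5)),   # tie -> mixed in both modes
    `3` = rep("B", 3),                   # pure
    `4` = character(0)                   # empty
  ))
  fit <- fake_fit(asg, 2, 2)
  maj <- classify_nodes(fit, "majority50")
  expect_equal(maj$class, c("majority", "mixed", "pure", "empty"))
  expect_equal(maj$species[1], "A")
  expect_equal(maj$fraction[1], 0.6)
  pure <- classify_nodes(fit, "pure_only")
  expect_equal(pure$class, c("mixed", "mixed", "pure", "empty"))
  # partition: every node classified once
  expect_equal(nrow(maj), 4)
  expect_equal(sum(table(maj$class)), fit$I * fit$J)
})

test_that("contribution heat map splits occupied nodes into tertiles", {
  asg <- make_assignment(as.list(setNames(rep("A", 9), 1:9)) |>
                           purrr::map(~ rep(.x, 2)))
  fit <- fake_fit(asg, 3, 3)
  fit$weights <- cbind(9:1 / 10, rep(0.5, 9))
  hm <- contribution_heatmap(fit, "x")
  expect_equal(hm$rank_class[order(-hm$value)],
               rep(c("high", "moderate", "low"), each = 3))
  # all-equal values collapse into one tie block classed high
  fit$weights[, 1] <- 0.3
  hm2 <- contribution_heatmap(fit, "x")
  expect_true(all(hm2$rank_class == "high"))
  expect_error(contribution_heatmap(fit, "CGG"), "unknown group")
  # relabeling species does not change the heat map (weights only)
  fit3 <- fit
  fit3$assignment$species <- "Z"
  fit3$weights[, 1] <- 9:1 / 10
  fit$weights[, 1] <- 9:1 / 10
  expect_equal(contribution_heatmap(fit, "x")$rank_class,
               contribution_heatmap(fit3, "x")$rank_class)
})

test_that("satellites are small disconnected components of a territory", {
  # lattice 10 x 8: main block of A nodes, a 3-node and a 2-node island
  I <- 10; J <- 8
  nodes <- expand.grid(i = 0:(I - 1), j = 0:(J - 1))
  node_id <- function(i, j) i * J + j + 1
  main <- node_id(rep(0:4, each = 5), rep(0:4, times = 5))      # 25 nodes
  sat3 <- node_id(c(8, 8, 9), c(6, 7, 7))
  sat2 <- node_id(c(8, 9), c(0, 0))
  b_nodes <- node_id(rep(6, 4), 2:5)
  asg <- dplyr::bind_rows(
    tibble::tibble(node = rep(main, 2), species = "A"),
    tibble::tibble(node = rep(sat3, 2), species = "A"),
    tibble::tibble(node = rep(sat2, 2), species = "A"),
    tibble::tibble(node = rep(b_nodes, 2), species = "B")
  )
  asg$window_id <- sprintf("w%03d", seq_len(nrow(asg)))
  asg$record_id <- paste0("rec", asg$species)
  fit <- fake_fit(asg, I, J)
  sats <- extract_satellites(fit, "A", min_size = 2,
                             max_fraction_of_main = 0.5)
  expect_equal(nrow(sats), 2)
  expect_equal(sats$size, c(3, 2))
  expect_setequal(unlist(sats$nodes[[1]]), sat3)
  # windows travel with their satellite
  expect_equal(sats$n_windows, c(6, 4))
  # min_size filters the 2-node island out
  sats2 <- extract_satellites(fit, "A", min_size = 3,
                              max_fraction_of_main = 0.5)
  expect_equal(nrow(sats2), 1)
  # a species with one connected territory has no satellites
  expect_equal(nrow(extract_satellites(fit, "B", min_size = 1,
                                       max_fraction_of_main = 1)), 0)
  expect_error(extract_satellites(fit, "C"), "not present")
})

test_that("diagonally touching nodes form one component", {
  asg <- make_assignment(list(`1` = "A", `4` = "A"))  # (0,0) and (1,1)
  fit <- fake_fit(asg, 2, 2)
  sats <- extract_satellites(fit, "A", min_size = 1,
                             max_fraction_of_main = 1)
  expect_equal(nrow(sats), 0)  # single Moore-connected component
})

test_that("enrichment ratios divide pooled set by reference composition", {
  set.seed(41)
  rec <- genome_records(random_dna(6000, p = c(.2, .3, .3, .2)), "sp", "r")
  wins <- window_records(rec, 500, 500)
  comp <- window_composition(wins, rec, 3)
  # satellite = whole genome -> all ratios 1
  er <- enrichment_ratios(comp, comp$window_id, comp, top_n = 32)
  expect_equal(er$ratio, rep(1, 32))
  # hand-built two-group check: freq 0.02 vs 0.01 -> ratio 2
  ref <- pool_composition(comp)
  ref2 <- ref; ref2[] <- ref2[] / 2
  er2 <- enrichment_ratios(comp, comp$window_id, ref2, top_n = 5)
  expect_equal(er2$ratio, rep(2, 5))
  # zero reference frequency flags an infinite ratio
  ref3 <- ref; ref3[1] <- 0
  expect_warning(er3 <- enrichment_ratios(comp, comp$window_id, ref3,
                                          top_n = 32), "Inf")
  expect_true(any(er3$undefined))
})

test_that("shared nodes require co-occupancy from both filters", {
  asg <- make_assignment(list(
    `1` = c("A", "A"), `2` = c("A", "B"), `3` = "B", `6` = c("B", "A")
  ))
  fit <- fake_fit(asg, 2, 3)
  sh <- shared_nodes(fit, species == "A", species == "B")
  expect_equal(sh$node, c(2L, 6L))
  expect_equal(attr(sh, "records_a"), "rec_A")
  # disjoint territories -> empty set
  asg2 <- make_assignment(list(`1` = "A", `4` = "B"))
  sh2 <- shared_nodes(fake_fit(asg2, 2, 2), species == "A", species == "B")
  expect_equal(nrow(sh2), 0)
  # empty filter warns
  expect_warning(shared_nodes(fit, species == "Z", species == "B"),
                 "no windows")
})

test_that("adjacency uses Chebyshev distance to the territory", {
  # A territory at (0..1, 0..1); B nodes at (2,2) (diagonal dist 1) and
  # (4,4) (far)
  I <- 5; J <- 5
  node_id <- function(i, j) i * J + j + 1
  asg <- dplyr::bind_rows(
    tibble::tibble(node = rep(node_id(c(0, 0, 1, 1), c(0, 1, 0, 1)), 3),
                   species = "A"),
    tibble::tibble(node = node_id(2, 2), species = "B"),
    tibble::tibble(node = node_id(4, 4), species = "B")
  )
  asg$window_id <- sprintf("w%03d", seq_len(nrow(asg)))
  asg$record_id <- paste0("rec", asg$species)
  fit <- fake_fit(asg, I, J)
  adj <- adjacent_nodes(fit, species == "B", "A", max_lattice_distance = 1)
  expect_equal(adj$node, node_id(2, 2))
  expect_equal(adj$min_distance, 1)
  # distance 0 reduces to co-occupancy of territory nodes
  adj0 <- adjacent_nodes(fit, species == "B", "A", max_lattice_distance = 0)
  expect_equal(nrow(adj0), 0)
  # far-inside nodes stay excluded at distance 1 but appear at 3
  adj3 <- adjacent_nodes(fit, species == "B", "A", max_lattice_distance = 3)
  expect_setequal(adj3$node, c(node_id(2, 2), node_id(4, 4)))
})
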