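test_that("population scaling from surface density", {
  expect_equal(population_from_density(1000, 399, 1.0), 3.99e5)
  expect_equal(population_from_density(5000, 399, 0), 0)
  # one third of the spiny layer-2/3 population
  d <- 8.25e6 / 399
  expect_equal(population_from_density(d, 399, 1/3), 2.75e6)
  expect_error(population_from_density(10, 399, 1.2), "<= 1")
})

test_that("population synapse totals are N x s, absent layers give zero", {
  ct <- data.frame(name = c("p2/3", "p5"), soma_layer = c("L2/3", "L5"),
                   population = c(8.25e6, 0), syn_L6 = c(78, 3109))
  S <- population_synapses(ct, "L6")
  expect_equal(S[["p2/3"]], 6.435e8)
  expect_equal(S[["p5"]], 0)
  expect_equal(unname(population_synapses(ct, "L1")), c(0, 0))
  expect_equal(unname(population_synapses(
    data.frame(name = "x", soma_layer = "L3", population = 2.75e6,
               syn_L6 = 2329), "L6")), 6.404750e9)
})

test_that("total reconstruction from a share inverts the share", {
  expect_equal(infer_total_from_share(6.41e8, 0.03), 2.136667e10,
               tolerance = 1e-6)
  expect_equal(infer_total_from_share(123, 1.0), 123)
  # the two printed routes to the total agree
  expect_equal(infer_total_from_share(6.41e8, 0.10 * 0.30),
               infer_total_from_share(6.41e9, 0.30))
  expect_error(infer_total_from_share(1, 0), "share")
})

test_that("unassigned fraction complements the assigned fraction", {
  ct <- data.frame(name = "all", soma_layer = "L6", population = 1,
                   syn_L6 = 0.30)
  b <- layer_budget(ct, "L6", total = 1)
  expect_equal(unassigned_fraction(b), 0.70)
  b2 <- layer_budget(transform(ct, syn_L6 = 1), "L6", total = 1)
  expect_equal(unassigned_fraction(b2), 0)
  # over-assignment is flagged, not clamped
  expect_warning(b3 <- layer_budget(transform(ct, syn_L6 = 1.05), "L6",
                                    total = 1), "exceed")
  expect_equal(unassigned_fraction(b3), -0.05)
  expect_error(layer_budget(ct, "L6", total = 0), "positive")
})

test_that("inverse solver returns contribution * total / population", {
  Tl <- budget_constants()$total_L6
  expect_equal(solve_per_cell_synapses(0.300, Tl, 2.75e6), 2329,
               tolerance = 1e-3)
  expect_equal(solve_per_cell_synapses(0.217, Tl, 2.185e6), 2115,
               tolerance = 4e-3)
  # limit: contribution -> 0 gives s -> 0
  expect_lt(solve_per_cell_synapses(1e-12, Tl, 2.75e6), 1e-2)
  expect_error(solve_per_cell_synapses(0.3, Tl, 0), "population")
})

test_that("solver and scenario report are exact inverses", {
  set.seed(123)
  base <- baseline_budget()
  for (r in 1:25) {
    c0 <- runif(1, 0.01, 0.6)
    Tl <- 10^runif(1, 8, 11)
    pop <- 10^runif(1, 5, 7)
    s <- solve_per_cell_synapses(c0, Tl, pop)
    expect_equal(c0, pop * s / Tl, tolerance = 1e-12)
  }
  # round trip through scenario_report against the package baseline
  for (c0 in c(0.05, 0.217, 0.300)) {
    sc <- scenario_report(base, list(
      new_cell_type("t", "L3", 8.25e6, 1/3, contribution = c0)))
    got <- sc$table$share[sc$table$kind == "new"]
    expect_equal(got, c0, tolerance = 1e-12)
  }
})

test_that("scenario shares and residual always sum to one", {
  base <- baseline_budget()
  sc0 <- scenario_report(base, list())
  expect_equal(sum(sc0$table$share) + sc0$unassigned, 1, tolerance = 1e-12)
  expect_equal(sc0$unassigned, base$unassigned)
  sc1 <- scenario_report(base, list(
    new_cell_type("half", "L3", 8.25e6, 0.5, contribution = 0.5)))
  expect_equal(sum(sc1$table$share) + sc1$unassigned, 1, tolerance = 1e-12)
  expect_equal(sc1$unassigned, base$unassigned - 0.5, tolerance = 1e-12)
  # specifying both c and s is rejected
  expect_error(new_cell_type("bad", "L3", 1e6, 0.5, contribution = 0.1,
                             per_cell = 100), "exactly one")
})

test_that("per-cell route and contribution route agree", {
  base <- baseline_budget()
  Tl <- base$total
  s <- solve_per_cell_synapses(0.25, Tl, 2e6)
  sc <- scenario_report(base, list(
    new_cell_type("t", "L4", 8e6, 0.25, per_cell = s)))
  expect_equal(sc$table$share[sc$table$kind == "new"], 0.25,
               tolerance = 1e-12)
})

test_that("increasing a per-cell count weakly decreases the unassigned fraction", {
  fx <- generate_budget_fixture()
  u0 <- unassigned_fraction(fx$budget)
  ct <- fx$cell_types
  for (i in seq_len(nrow(ct))) {
    ct2 <- ct
    ct2$syn_L6[i] <- ct2$syn_L6[i] * 1.5
    expect_lte(unassigned_fraction(layer_budget(ct2, "L6", fx$total)), u0)
  }
  # doubling populations while halving per-cell counts changes nothing
  ct3 <- transform(ct, population = population * 2, syn_L6 = syn_L6 / 2)
  expect_equal(unassigned_fraction(layer_budget(ct3, "L6", fx$total)), u0)
})

test_that("additional synapses scale with the unassigned gap", {
  b <- baseline_budget()
  expect_equal(additional_synapses_needed(b$unassigned - 0.1, b),
               0.1 * b$total)
  eps <- 1e-6
  expect_equal(additional_synapses_needed(b$unassigned - eps, b),
               eps * b$total)
  expect_error(additional_synapses_needed(0.9, b), "below")
})

test_that("fold changes land in the reported 25-30x range", {
  k <- budget_constants()
  s3 <- solve_per_cell_synapses(0.300, k$total_L6, k$n_spiny_L23 / 3)
  s4 <- solve_per_cell_synapses(0.217, k$total_L6, k$n_spiny_L4 / 4)
  f3 <- fold_change(s3, k$syn_per_cell[["p2/3"]])
  f4 <- fold_change(s4, k$syn_per_cell[["spiny L4 (mean)"]])
  expect_true(f3 >= 24 && f3 <= 31)
  expect_true(f4 >= 24 && f4 <= 31)
  expect_equal(fold_change(85, 85), 1)
  expect_error(fold_change(10, 0), "positive")
})

test_that("cell-type tables round-trip through TSV", {
  fx <- generate_budget_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_type_table(fx$cell_types, path)
  back <- read_cell_type_table(path)
  expect_equal(back$population, fx$cell_types$population)
  expect_equal(back$syn_L6, fx$cell_types$syn_L6)
  expect_error(read_cell_type_table(
    { p <- withr::local_tempfile(fileext = ".tsv")
      writeLines("name\tsoma_layer\npop\tL1", p); p }), "population")
})
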