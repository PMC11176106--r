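test_that("sampling-factor correction multiplies counts", {
  expect_equal(apply_sampling_factor(100, 2), 200)
  expect_equal(apply_sampling_factor(25, 4), 100)
  expect_equal(apply_sampling_factor(0, 4), 0)
  expect_error(apply_sampling_factor(10, 0), "factor")
  expect_error(apply_sampling_factor(-1, 2), ">= 0")
})

test_that("FLN divides group counts by the total outside injection sites", {
  counts <- rbind(make_counts("c1", "A17", 8000),
                  make_counts("c1", "A18", 1500),
                  make_counts("c1", "LGN", 500, layer = "-", factor = 4L))
  f <- fln(counts)
  expect_equal(f$fraction[f$area == "A17"], 0.80)
  expect_equal(f$fraction[f$area == "A18"], 0.15)
  expect_equal(f$fraction[f$area == "LGN"], 0.05)
  # degenerate single-area partition
  f1 <- fln(make_counts("c1", "A17", 100))
  expect_equal(f1$fraction, 1.0)
  # injection-site somata are excluded from numerator and denominator
  counts2 <- rbind(counts, make_counts("c1", "A17", 2000, in_inj = TRUE))
  expect_equal(fln(counts2)$fraction, f$fraction)
  # zero denominator errors rather than returning NaN
  expect_error(fln(make_counts("c1", "A17", 0)), "denominator")
})

test_that("FLN fractions always partition to one and are scale invariant", {
  set.seed(42)
  for (rep in 1:20) {
    n_areas <- sample(2:5, 1)
    areas <- paste0("A", seq_len(n_areas))
    counts <- make_counts("c1", areas,
                          corrected = 2 * sample.int(500, n_areas))
    f <- fln(counts)
    expect_equal(sum(f$fraction), 1, tolerance = 1e-9)
    scaled <- counts
    k <- sample(2:7, 1)
    scaled$corrected_n <- scaled$corrected_n * k
    scaled$counted_n <- scaled$counted_n * k
    expect_equal(fln(scaled)$fraction, f$fraction)
  }
})

test_that("FLN on corrected counts equals FLN on raw counts under a uniform factor", {
  counts <- make_counts("c1", c("A17", "A18", "A19"), c(600, 300, 100))
  raw <- counts
  raw$corrected_n <- raw$counted_n   # pretend no correction
  expect_equal(fln(counts)$fraction, fln(raw)$fraction)
})

test_that("animals without label in a group contribute a zero fraction", {
  counts <- rbind(make_counts("c1", c("A17", "A18"), c(90, 10)),
                  make_counts("c2", "A17", 50))
  f <- fln(counts)
  expect_equal(f$fraction[f$animal == "c2" & f$area == "A18"], 0)
  expect_equal(f$fraction[f$animal == "c2" & f$area == "A17"], 1)
})

test_that("laminar proportions cover L1..L6 and sum to one per animal", {
  counts <- make_counts("c1", "A17", c(40, 40, 20),
                        layer = c("L3", "L4", "L6"))
  lam <- laminar_proportions(counts, "A17")
  expect_equal(sum(lam$fraction), 1)
  expect_equal(lam$fraction[lam$layer == "L3"], 0.4)
  expect_equal(lam$fraction[lam$layer == "L4"], 0.4)
  expect_equal(lam$fraction[lam$layer == "L6"], 0.2)
  expect_equal(lam$fraction[lam$layer == "L1"], 0)
  expect_equal(nrow(lam), 6)
  # all-in-one-layer degenerate case
  lam3 <- laminar_proportions(make_counts("c1", "A17", 50), "A17")
  expect_equal(lam3$fraction[lam3$layer == "L3"], 1)
  expect_error(laminar_proportions(counts, "A99"), "A99")
})

test_that("cohort summaries use the sample SD and honour subsets", {
  s <- summarize_across_animals(c(a = 0.9, b = 0.9, c = 0.9))
  expect_equal(s$mean, 0.9)
  expect_equal(s$sd, 0)
  s2 <- summarize_across_animals(c(a = 0.6, b = 0.8, c = 1.0))
  expect_equal(s2$mean, 0.8)
  expect_equal(s2$sd, 0.2)
  # single-animal summaries have no SD
  s3 <- summarize_across_animals(c(a = 5.2))
  expect_equal(s3$n, 1)
  expect_true(is.na(s3$sd))
  # metadata predicate subsetting
  md <- data.frame(animal = c("a", "b", "c"),
                   border_injection = c(FALSE, TRUE, FALSE))
  s4 <- summarize_across_animals(c(a = 0.6, b = 0.8, c = 1.0),
                                 subset = function(m) !m$border_injection,
                                 metadata = md)
  expect_equal(s4$mean, 0.8)
  expect_equal(s4$n, 2)
  expect_error(summarize_across_animals(c(a = 1), subset = character(0)),
               "empty")
})

test_that("supragranular/granular/infragranular split sums to the input", {
  tri <- supra_infra_split(c(L3 = 0.5, L4 = 0.3, L5 = 0.2))
  expect_equal(unname(tri), c(0.5, 0.3, 0.2))
  expect_equal(unname(supra_infra_split(c(L4 = 1))), c(0, 1, 0))
  full <- c(L1 = 0.01, L2 = 0.2, L3 = 0.61, L4 = 0.1, L5 = 0.03, L6 = 0.05)
  expect_equal(sum(supra_infra_split(full)), 1)
  expect_equal(supra_infra_split(full)[["supragranular"]], 0.82)
  expect_error(supra_infra_split(c(L7 = 1)), "L7")
})

test_that("count_table aggregates somata with the right sampling factors", {
  m <- tiny_model()
  nn <- rbind(make_neurons(6, y = 500, layer = "L3"),
              make_neurons(2, y = 1500, layer = "L6",
                           id = c("x1", "x2"), in_inj = TRUE),
              make_neurons(4, area = "LGN", layer = NA, y = 200,
                           id = sprintf("g%d", 1:4)))
  ds <- animal_dataset("c1", m, nn, make_injections(1))
  ct <- count_table(ds)
  a17 <- ct[ct$area == "A17" & !ct$in_injection_site, ]
  expect_equal(a17$corrected_n, 12)
  expect_equal(a17$sampling_factor, 2L)
  lgn <- ct[ct$area == "LGN", ]
  expect_equal(lgn$sampling_factor, 4L)
  expect_equal(lgn$corrected_n, 16)
  expect_equal(sum(ct$counted_n), nrow(nn))
})
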