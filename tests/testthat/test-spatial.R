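test_that("nearest-injection distance is Euclidean in (x, y, z)", {
  m <- tiny_model()
  inj <- make_injections(1, x = 0, y = 0, section = 0)
  nn <- make_neurons(1, x = 3, y = 4, section = 0)
  rec <- min_distance_to_injection(nn, inj, m)
  expect_equal(rec$distance_um, 5)
  # ten sections apart at the same (x, y): 10 * 80 um
  nn2 <- make_neurons(1, x = 0, y = 0, section = 10)
  expect_equal(min_distance_to_injection(nn2, inj, m)$distance_um, 800)
  expect_error(min_distance_to_injection(nn, inj[0, ], m), "injection")
})

test_that("the nearer of several sites wins, ties to the lowest id", {
  m <- tiny_model()
  inj <- make_injections(2, x = c(12, 5), y = 0, section = 0)
  nn <- make_neurons(1, x = 0, y = 0, section = 0)
  rec <- min_distance_to_injection(nn, inj, m)
  expect_equal(rec$distance_um, 5)
  expect_equal(rec$nearest_injection, "inj2")
  # exact tie: equidistant sites resolve to the lower id
  inj_tie <- make_injections(2, x = c(5, -5), y = 0, section = 0)
  rec_tie <- min_distance_to_injection(nn, inj_tie, m)
  expect_equal(rec_tie$nearest_injection, "inj1")
})

test_that("minimum distances agree with an exhaustive pairwise scan", {
  m <- tiny_model()
  set.seed(99)
  nn <- make_neurons(500, x = runif(500, 0, 12000), y = runif(500, 0, 1890),
                     section = sample(0:19, 500, TRUE))
  inj <- make_injections(4, x = runif(4, 0, 12000), y = runif(4, 1400, 1890),
                         section = sample(0:19, 4, TRUE))
  rec <- min_distance_to_injection(nn, inj, m)
  brute <- vapply(seq_len(nrow(nn)), function(i) {
    min(vapply(seq_len(nrow(inj)), function(j) {
      sqrt((nn$x_um[i] - inj$x_um[j])^2 + (nn$y_um[i] - inj$y_um[j])^2 +
           (80 * (nn$section_index[i] - inj$section_index[j]))^2)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(rec$distance_um, brute)
})

test_that("distances are invariant under rigid translation", {
  m <- tiny_model()
  set.seed(3)
  nn <- make_neurons(100, x = runif(100, 0, 5000), y = runif(100, 0, 1890))
  inj <- make_injections(2, x = c(1000, 4000), y = c(1500, 1600))
  d0 <- min_distance_to_injection(nn, inj, m)$distance_um
  nn$x_um <- nn$x_um + 777; nn$y_um <- nn$y_um + 33
  inj$x_um <- inj$x_um + 777; inj$y_um <- inj$y_um + 33
  expect_equal(min_distance_to_injection(nn, inj, m)$distance_um, d0)
})

test_that("top-k ranking returns the most distant records", {
  m <- tiny_model()
  set.seed(5)
  nn <- make_neurons(50, x = runif(50, 0, 3000), y = runif(50, 0, 1890))
  # plant one far outlier in L5
  nn$x_um[17] <- 11000; nn$layer[17] <- "L5"
  rec <- min_distance_to_injection(nn, make_injections(1, x = 0, y = 0), m)
  top <- top_k_distant(rec, area = "A17", k = 30)
  expect_equal(top$id[1], nn$id[17])
  expect_equal(top$layer[1], "L5")
  expect_equal(nrow(top), 30)
  expect_true(all(diff(top$distance_um) <= 0))
  # undersized input returns everything; k = 1 returns the maximum
  expect_equal(nrow(top_k_distant(rec[1:5, ], k = 30)), 5)
  expect_equal(top_k_distant(rec, k = 1)$distance_um, max(rec$distance_um))
})

test_that("per-animal maximum distances summarize across the cohort", {
  rec <- data.frame(animal = rep(c("a", "b", "c"), each = 2),
                    id = 1:6, area = "A17",
                    distance_um = c(1, 6000, 8000, 2, 3, 10000))
  s <- max_distance_summary(rec, area = "A17")
  expect_equal(s$mean, 8000)
  expect_equal(s$sd, 2000)
  # all somata at the centre: maximum 0
  rec0 <- data.frame(animal = "a", id = 1:3, area = "A17", distance_um = 0)
  expect_equal(max_distance_summary(rec0)$mean, 0)
})

test_that("planted periodic clusters are recovered; uniform scatter is not", {
  m <- tiny_model()
  set.seed(7)
  n_exact <- 0; n_close <- 0
  centers <- c(0, 600, 1200)   # 4 bandwidths apart
  for (r in 1:100) {
    x <- unlist(lapply(centers, function(c0) rnorm(120, c0, 120)))
    nn <- data.frame(x_um = x, y_um = runif(length(x), 600, 880))
    cs <- detect_border_clusters(nn, m)
    if (nrow(cs$clusters) == 3) {
      n_exact <- n_exact + 1
      if (max(abs(sort(cs$clusters$center_um) - centers)) <= 60)
        n_close <- n_close + 1
    }
  }
  expect_gte(n_exact, 95)
  expect_gte(n_close, 95)
  # dense uniform scatter yields no clusters
  set.seed(11)
  fp <- 0
  for (r in 1:20) {
    nn <- data.frame(x_um = runif(2000, 0, 3000),
                     y_um = runif(2000, 600, 880))
    if (nrow(detect_border_clusters(nn, m)$clusters) > 0) fp <- fp + 1
  }
  expect_equal(fp, 0)
  # empty depth band: empty cluster set, not an error
  empty <- detect_border_clusters(make_neurons(5, y = 100), m)
  expect_equal(nrow(empty$clusters), 0)
  expect_equal(empty$n_somata, 0)
})

test_that("cluster spacing at the anatomical scale is recovered", {
  m <- tiny_model()
  set.seed(21)
  spac <- c()
  # spacings in the upper anatomical range, above the ~3-bandwidth
  # resolution limit of the kernel density estimate
  for (r in 1:20) {
    spacing <- runif(1, 600, 800)
    centers <- spacing * (0:4)
    x <- unlist(lapply(centers, function(c0) rnorm(150, c0, spacing / 5)))
    nn <- data.frame(x_um = x, y_um = runif(length(x), 600, 880))
    cs <- detect_border_clusters(nn, m)
    if (length(cs$spacing_um)) spac <- c(spac, mean(cs$spacing_um))
  }
  expect_true(length(spac) >= 18)
  expect_true(mean(spac) >= 400 && mean(spac) <= 800)
})
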