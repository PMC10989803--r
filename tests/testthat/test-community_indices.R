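test_that("cumulative selection takes the smallest qualifying prefix", {
  a <- c(o1 = 0.5, o2 = 0.3, o3 = 0.15, o4 = 0.05)
  expect_equal(select_cumulative(a, 0.80), c("o1", "o2"))
  expect_equal(select_cumulative(a, 0.85), c("o1", "o2", "o3"))
  expect_equal(select_cumulative(a, 1.0), c("o1", "o2", "o3", "o4"))

  # ties broken by table order; absent OTUs never selected
  b <- c(x = 0.4, y = 0.4, z = 0.2, w = 0)
  expect_equal(select_cumulative(b, 0.8), c("x", "y"))
  expect_equal(select_cumulative(b, 1.0), c("x", "y", "z"))

  expect_error(select_cumulative(a, 0), "level")
  expect_error(select_cumulative(c(o1 = 0, o2 = 0), 0.5), "no OTUs")
})

test_that("random selection is uniform, seeded, and bounded by richness", {
  a <- c(o1 = 0.2, o2 = 0.3, o3 = 0.5, o4 = 0)
  # n equal to richness: every replicate is the full present set
  sets <- select_random(a, 3, replicates = 5, seed = 1)
  for (s in sets) expect_setequal(s, c("o1", "o2", "o3"))

  # same seed, same subsets
  expect_identical(select_random(a, 2, 10, seed = 42),
                   select_random(a, 2, 10, seed = 42))

  # n = 1: selection frequencies uniform within binomial 3-sigma
  n_rep <- 3000
  draws <- unlist(select_random(a, 1, n_rep, seed = 7))
  p <- 1 / 3
  tol <- 3 * sqrt(p * (1 - p) / n_rep)
  for (id in c("o1", "o2", "o3"))
    expect_lt(abs(mean(draws == id) - p), tol)
  expect_false("o4" %in% draws)

  expect_warning(out <- select_random(a, 10, 5, seed = 1), "richness")
  expect_null(out)
})

test_that("CMTB is the abundance-weighted mean TB of the selection", {
  tb <- c(o1 = 2, o2 = 1, o3 = 5)
  expect_equal(cmtb(c(o1 = 0.9, o2 = 0, o3 = 0), tb, "o1"), 2)
  expect_equal(cmtb(c(o1 = 0.2, o2 = 0.2, o3 = 0.2), tb), mean(tb))
  expect_equal(cmtb(c(o1 = 0.6, o2 = 0.4, o3 = 0), tb, c("o1", "o2")), 1.6)
  # renormalizing the selected weights is a no-op (ratio weighting)
  expect_equal(cmtb(c(o1 = 0.3, o2 = 0.2, o3 = 0), tb, c("o1", "o2")), 1.6)
  expect_error(cmtb(c(o1 = 0.5), tb, character(0)), "empty")
})

test_that("resistance potential is the norm of the standardized pair", {
  expect_equal(resistance_potential(0, 0), 0)
  expect_equal(resistance_potential(1, 1), sqrt(2))
  expect_equal(resistance_potential(0.6, 0.8), 1)
  expect_error(resistance_potential(1.2, 0.5), "\\[0, 1\\]")
  expect_error(resistance_potential(0.5, -0.1), "\\[0, 1\\]")
})

test_that("compute_indices composes the per-sample calls", {
  # two OTUs per sample, one replicate: output must match hand chaining
  counts <- matrix(c(6, 4, 0,
                     2, 2, 6,
                     1, 0, 9), nrow = 3, byrow = TRUE,
                   dimnames = list(c("o1", "o2", "o3"),
                                   c("S1", "S2", "S3")))
  env <- matrix(c(-1.2, 0.3, 1.1, 0.5, -0.8, 0.2), ncol = 2,
                dimnames = list(c("S1", "S2", "S3"), c("v1", "v2")))
  tb <- tolerance_breadth_all(counts, env)
  rel <- to_relative_abundance(counts)
  ra <- response_asynchrony(rel)
  ind <- compute_indices(counts, scheme = selection_scheme("cumulative",
                                                           levels = 1.0),
                         tb = tb, ra = ra)
  tbv <- setNames(tb$tb, tb$otu_id)
  for (s in colnames(counts)) {
    row <- ind[ind$sample_id == s, ]
    expect_equal(row$cmtb, cmtb(rel[, s], tbv))
    expect_equal(row$cmra, cmra(rel[, s], ra))
  }
  expect_equal(ind$resistance,
               sqrt(ind$cmtb_stand^2 + ind$cmra_stand^2))
})

test_that("standardized indexes attain 0 and 1 and resistance stays bounded", {
  sim <- simulate_community(scenario(n_samples = 40, n_otus = 80,
                                     depth = 500, seed = 3))
  ind <- compute_indices(sim$counts, sim$env,
                         selection_scheme("cumulative"))
  for (lv in unique(ind$level)) {
    d <- ind[ind$level == lv, ]
    expect_equal(min(d$cmtb_stand), 0)
    expect_equal(max(d$cmtb_stand), 1)
    expect_equal(min(d$cmra_stand), 0)
    expect_equal(max(d$cmra_stand), 1)
    # CMTB bounded by the TB range of the pool
    tb <- tolerance_breadth_all(sim$counts, standardize_env(sim$env))
    expect_true(all(d$cmtb >= min(tb$tb, na.rm = TRUE) - 1e-12))
    expect_true(all(d$cmtb <= max(tb$tb, na.rm = TRUE) + 1e-12))
  }
  expect_true(all(ind$resistance >= 0 & ind$resistance <= sqrt(2) + 1e-12))
})

test_that("identical samples make min-max standardization fail loudly", {
  counts <- matrix(rep(c(5, 3, 2), 4), nrow = 3,
                   dimnames = list(c("o1", "o2", "o3"), paste0("S", 1:4)))
  tb <- data.frame(otu_id = c("o1", "o2", "o3"), tb = c(1, 2, 3),
                   n_occupied = c(4L, 4L, 4L))
  ids <- c("o1", "o2", "o3")
  ra <- matrix(0.2, 3, 3, dimnames = list(ids, ids)); diag(ra) <- -1
  expect_error(
    compute_indices(counts, scheme = selection_scheme("cumulative",
                                                      levels = 1.0),
                    tb = tb, ra = ra),
    "cmtb")
})

test_that("random-mode replicate means are Monte-Carlo consistent", {
  sim <- simulate_community(scenario(n_samples = 12, n_otus = 60,
                                     depth = 800, seed = 5))
  tb <- tolerance_breadth_all(sim$counts, standardize_env(sim$env))
  tbv <- setNames(tb$tb, tb$otu_id)
  rel <- to_relative_abundance(sim$counts)
  s <- colnames(rel)[1]
  n_sel <- 20
  # many-replicate reference mean and spread of the single-draw CMTB
  ref_sets <- select_random(rel[, s], n_sel, replicates = 10000, seed = 123)
  ref_vals <- vapply(ref_sets, function(x) cmtb(rel[, s], tbv, x), numeric(1))
  reps <- 100
  sets <- select_random(rel[, s], n_sel, replicates = reps, seed = 456)
  est <- mean(vapply(sets, function(x) cmtb(rel[, s], tbv, x), numeric(1)))
  se <- sd(ref_vals) / sqrt(reps)
  expect_lt(abs(est - mean(ref_vals)), 2 * se + 3 * sd(ref_vals) / sqrt(10000))
})

test_that("cumulative selection at level 1 equals the no-selection result", {
  counts <- random_count_table(25, 8, lambda = 3, seed = 77)
  env <- random_env_table(8, 3, seed = 77)
  tb <- tolerance_breadth_all(counts, env)
  tbv <- setNames(tb$tb, tb$otu_id)
  rel <- to_relative_abundance(counts)
  suppressMessages(ra <- response_asynchrony(rel))
  for (s in colnames(counts)) {
    sel <- select_cumulative(rel[, s], 1.0)
    expect_equal(cmtb(rel[, s], tbv, sel), cmtb(rel[, s], tbv))
    expect_equal(cmra(rel[, s], ra, sel), cmra(rel[, s], ra))
  }
})

test_that("method independence reports r = 1 against self and respects permutations", {
  sim <- simulate_community(scenario(n_samples = 30, n_otus = 60,
                                     depth = 500, seed = 11))
  ind <- compute_indices(sim$counts, sim$env,
                         selection_scheme("cumulative", levels = c(0.8, 0.9)))
  mi <- method_independence(ind)
  expect_equal(unname(diag(mi$cmtb)), rep(1, 2))
  expect_equal(unname(diag(mi$cmra)), rep(1, 2))
  expect_true(all(abs(mi$cmtb - t(mi$cmtb)) < 1e-12))

  # relabelling rows by a common sample permutation changes nothing
  perm <- sample(nrow(ind))
  expect_equal(method_independence(ind[perm, ])$min, mi$min)
})
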