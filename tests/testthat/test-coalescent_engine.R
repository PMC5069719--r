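test_that("demographic model validation catches inconsistent event lists", {
  expect_error(demographic_model(c(100, 200)), "named")
  expect_error(demographic_model(c(a = -5)), "> 0")
  expect_error(demographic_model(
    c(a = 10, b = 10),
    list(list(time = 5, kind = "merge", source = "a", sink = "b"),
         list(time = 2, kind = "size_change", pop = "b", new_size = 5))),
    "ordered")
  expect_error(demographic_model(c(a = 10, b = 10)), "one ancestral")
  expect_error(demographic_model(
    c(a = 10, b = 10),
    list(list(time = 1, kind = "merge", source = "a", sink = "b"),
         list(time = 2, kind = "size_change", pop = "a", new_size = 4))),
    "merged")
})

test_that("scenario templates expand to the documented event structure", {
  p <- c(N = 8000, Nb = 480, t1 = 9790, t2 = 15100, t3 = 132000)
  ns <- expand_scenario("northern_shift", p)
  expect_equal(ns$events[[2]]$kind, "merge")
  expect_equal(ns$events[[2]]$time, 15100)
  expect_equal(ns$events[[1]]$new_size, 480)

  isr <- expand_scenario("in_situ_refugia", p)
  expect_equal(isr$events[[2]]$time, 132000)

  expect_error(expand_scenario("northern_shift",
                               c(N = 100, Nb = 5, t1 = 20, t2 = 10,
                                 t3 = 30)), "t1 < t2 < t3")
  expect_error(expand_scenario("northern_shift",
                               c(N = 100, Nb = 100, t1 = 1, t2 = 2,
                                 t3 = 3)), "Nb")
  # near-null bottleneck is a valid boundary case
  ok <- expand_scenario("in_situ_refugia",
                        c(N = 100, Nb = 99, t1 = 1, t2 = 2, t3 = 3))
  expect_s3_class(ok, "demographic_model")
})

test_that("pairwise TMRCA matches E[T2] = Ne under constant size", {
  set.seed(101)
  Ne <- 600
  m <- demographic_model(c(a = Ne))
  reps <- 5000
  t2 <- vapply(seq_len(reps), function(i)
    max(simulate_genealogy(m, c(a = 2))$node_time), 0)
  se <- sd(t2) / sqrt(reps)
  expect_lt(abs(mean(t2) - Ne), 3 * se)
})

test_that("total branch length matches E[L_n] = 2 Ne sum(1/i)", {
  set.seed(102)
  Ne <- 500
  m <- demographic_model(c(a = Ne))
  reps <- 4000
  L3 <- vapply(seq_len(reps), function(i)
    total_branch_length(simulate_genealogy(m, c(a = 3))), 0)
  expect_lt(abs(mean(L3) - 3 * Ne), 3 * sd(L3) / sqrt(reps))
})

test_that("cross-population coalescence only happens after the merge", {
  set.seed(103)
  m <- demographic_model(
    c(north = 200, south = 200),
    list(list(time = 400, kind = "merge", source = "south",
              sink = "north")))
  for (i in 1:20) {
    g <- simulate_genealogy(m, c(north = 4, south = 4))
    # time of the MRCA of any north-south pair must be >= 400
    anc <- function(v) {
      path <- v
      while (g$parent[v] != 0) { v <- g$parent[v]; path <- c(path, v) }
      path
    }
    for (a in 1:4) for (b in 5:8) {
      common <- intersect(anc(a), anc(b))
      expect_gte(min(g$node_time[common]), 400)
    }
  }
})

test_that("HKY mutation: rate zero and Watterson's expectation", {
  set.seed(104)
  m <- demographic_model(c(a = 400))
  g <- simulate_genealogy(m, c(a = 6))
  d0 <- mutate_sequences(g, mutation_model_hky(rate = 0))
  expect_equal(length(unique(apply(d0$seq, 1, paste, collapse = ""))), 1)

  # E[S] = mu L * 2 Ne * sum_{i<n} 1/i in the low per-site-theta regime
  hky <- mutation_model_hky(rate = 2e-6, L = 663)
  reps <- 1500
  S <- vapply(seq_len(reps), function(i) {
    gg <- simulate_genealogy(m, c(a = 10))
    dd <- mutate_sequences(gg, hky)
    sum(apply(dd$seq, 2, function(x) length(unique(x)) > 1))
  }, 0)
  expS <- 2e-6 * 663 * 2 * 400 * sum(1 / (1:9))
  expect_lt(abs(mean(S) - expS), 3 * sd(S) / sqrt(reps))
})

test_that("HKY kernel: kappa -> Inf with equal frequencies gives only
           transitions", {
  transitions <- c("A" = "G", "G" = "A", "C" = "T", "T" = "C")
  set.seed(105)
  m <- demographic_model(c(a = 1000))
  g <- simulate_genealogy(m, c(a = 8))
  hky <- mutation_model_hky(rate = 5e-6, kappa = 1e9,
                            base_freq = rep(0.25, 4), L = 200)
  d <- mutate_sequences(g, hky)
  # every polymorphic site must hold a transition pair
  for (j in which(apply(d$seq, 2, function(x) length(unique(x)) > 1))) {
    alle <- unique(d$seq[, j])
    expect_length(alle, 2)
    expect_equal(unname(transitions[alle[1]]), alle[2])
  }
})

test_that("GSM microsatellites: rate zero, Ohta-Kimura He, and step mix", {
  set.seed(106)
  m <- demographic_model(c(a = 300))
  gens <- lapply(1:3, function(l) simulate_genealogy(m, c(a = 20),
                                                     ploidy_factor = 2))
  d0 <- mutate_microsats(gens, mutation_model_gsm(mu = rep(0, 3)))
  expect_true(all(d0$a1 == 20 & d0$a2 == 20))

  # SMM with theta = 4 N mu: E[He] = 1 - 1/sqrt(1 + 2 theta)
  Ne <- 300; mu <- 1e-3
  theta <- 2 * (2 * Ne) * mu
  reps <- 400
  he <- vapply(seq_len(reps), function(i) {
    gg <- lapply(1:2, function(l) simulate_genealogy(m, c(a = 40),
                                                     ploidy_factor = 2))
    dd <- mutate_microsats(gg, mutation_model_gsm(mu = rep(mu, 2),
                                                  p_step = 1))
    mean(observed_het(dd)$He)
  }, 0)
  expHe <- 1 - 1 / sqrt(1 + 2 * theta)
  expect_lt(abs(mean(he) - expHe), 3 * sd(he) / sqrt(reps))

  # fraction of single-step mutations tracks p_step
  steps <- abs(glacialdemog:::gsm_steps(10000, 0.9, 2.8))
  expect_lt(abs(mean(steps == 1) - 0.9), 0.02)
  multi <- steps[steps > 1]
  expect_gt(mean(multi), 2.5)
  expect_lt(mean(multi), 3.1)
})

test_that("with Nb = N and equal merge times the scenarios coincide", {
  set.seed(107)
  p1 <- c(N = 500, Nb = 499.99, t1 = 100, t2 = 800, t3 = 800.01)
  # northern_shift merges at t2, in_situ at t3; with t2 ~= t3 and Nb ~= N
  # the models are the same two-population split
  stat_of <- function(tmpl) {
    mdl <- expand_scenario(tmpl, p1)
    vapply(1:800, function(i) {
      g <- simulate_genealogy(mdl, c(north = 4, south = 4))
      max(g$node_time)
    }, 0)
  }
  a <- stat_of("northern_shift")
  b <- stat_of("in_situ_refugia")
  expect_gt(suppressWarnings(ks.test(a, b))$p.value, 0.01)
})

test_that("seeded simulations are reproducible and seed-sensitive", {
  m <- expand_scenario("northern_shift",
                       c(N = 300, Nb = 30, t1 = 50, t2 = 200, t3 = 1000))
  g1 <- simulate_genealogy(m, c(north = 5, south = 5), seed = 42)
  g2 <- simulate_genealogy(m, c(north = 5, south = 5), seed = 42)
  g3 <- simulate_genealogy(m, c(north = 5, south = 5), seed = 43)
  expect_identical(g1, g2)
  expect_false(identical(g1$node_time, g3$node_time))
})
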