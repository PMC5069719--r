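# Shared desk-scale reference tables (built once; ~15 s total)
mt_priors <- prior_set("mtDNA")
mt_config <- abc_sample_config("mtDNA")
mt_ref <- build_reference_table(priors = mt_priors, n_sim = 3000,
                                sample_config = mt_config, seed = 301)

test_that("prior draws respect bounds and ordering constraints", {
  set.seed(1)
  d <- draw_priors(mt_priors, 2000)
  expect_true(all(d$t1 < d$t2 & d$t2 < d$t3))
  expect_true(all(d$Nb < d$N))
  b <- mt_priors$bounds
  for (p in names(b)) {
    expect_true(all(d[[p]] >= b[[p]][1] & d[[p]] <= b[[p]][2]))
  }
  # rejection barely distorts the N marginal
  expect_gt(ks.test(d$N, "punif", 100, 100000)$p.value, 0.01)

  ms <- draw_priors(prior_set("microsat"), 500)
  expect_true(all(ms$mean_mu >= 1e-5 & ms$mean_mu <= 1e-3))
})

test_that("prior overrides change bounds and unknown names are rejected", {
  pr <- prior_set("mtDNA", mt_rate = c(5e-8, 5e-8), N = c(1000, 2000))
  expect_equal(pr$bounds$N, c(1000, 2000))
  expect_equal(pr$mt_rate, c(5e-8, 5e-8))
  expect_error(prior_set("mtDNA", bogus = 1), "unknown prior")
})

test_that("summary statistics: degenerate and closed-form cases", {
  # monomorphic alignment
  mat <- matrix("A", 6, 30)
  d <- seq_dataset(mat, population = rep(c("north", "south"), c(2, 4)))
  s <- summarize_dataset(d, c("north", "south"))
  expect_equal(unname(s[c("K_north", "S_north", "h_north", "fst")]),
               c(1, 0, 0, 0))

  # table-shaped dataset reproduces the frequency FST
  seqs <- sequences_from_table(table1_fixture(), seed = 5)
  s2 <- summarize_dataset(seqs, c("north", "south"))
  expect_equal(round(unname(s2["fst"]), 2), 0.19)
  expect_equal(unname(s2[c("K_north", "K_south", "S_north")]), c(7, 8, 15))

  # two microsat populations fixed for alleles 10 and 20
  ms <- msat_dataset(a1 = matrix(rep(c(10L, 20L), c(3, 3))),
                     a2 = matrix(rep(c(10L, 20L), c(3, 3))),
                     population = rep(c("north", "south"), c(3, 3)))
  s3 <- summarize_dataset(ms, c("north", "south"))
  expect_equal(unname(s3["mean_He_north"]), 0)
  expect_equal(unname(s3["dmu2"]), 100)
  expect_gt(unname(s3["fst"]), 0.9)

  expect_error(summarize_dataset(d, c("north", "south", "x")), "two popul")
})

test_that("summarize_dataset agrees with the internal fast path", {
  set.seed(6)
  par <- draw_priors(mt_priors, 1)[1, ]
  model <- expand_scenario("northern_shift",
                           c(N = par$N, Nb = par$Nb, t1 = par$t1,
                             t2 = par$t2, t3 = par$t3))
  gen <- simulate_genealogy(model, c(north = 24, south = 40), seed = 9)
  hky <- mutation_model_hky(rate = par$mt_rate, L = 663)
  ds <- mutate_sequences(gen, hky, seed = 10)
  slow <- summarize_dataset(ds, c("north", "south"))
  set.seed(10)
  invisible(sample.int(4L, 663, replace = TRUE,
                       prob = hky$base_freq))  # replay the root-sequence draw
  vs <- glacialdemog:::mutate_variable_sites(gen, hky)
  fast <- glacialdemog:::seq_summary_kernel(
    vs$V, match(gen$leaf_pop, c("north", "south")), c("north", "south"))
  expect_equal(slow, fast)
})

test_that("reference table bookkeeping: balance, constraints, normalization", {
  expect_equal(length(mt_ref$scenario), 3000)
  expect_equal(unname(table(mt_ref$scenario)["northern_shift"]), 1500L)
  expect_true(all(mt_ref$params$t1 < mt_ref$params$t2 &
                    mt_ref$params$t2 < mt_ref$params$t3))
  expect_gt(ks.test(mt_ref$params$N, "punif", 100, 100000)$p.value, 0.01)
  expect_true(all(mt_ref$scale[mt_ref$kept] > 0))
})

test_that("direct model choice: self-match, tie handling and symmetry", {
  row <- which(mt_ref$stats[, "S_north"] > 4)[1]
  ch <- model_choice_direct(mt_ref, mt_ref$stats[row, ], k = 1)
  expect_equal(unname(ch$prob[mt_ref$scenario[row]]), 1)
  expect_equal(sum(ch$prob), 1, tolerance = 1e-12)

  # identical simulators -> probabilities near 0.5: relabel a
  # single-template table into two pseudo-scenarios
  ref1 <- build_reference_table(templates = "northern_shift",
                                priors = mt_priors, n_sim = 2000,
                                sample_config = mt_config, seed = 302)
  ref1$scenario <- rep(c("A", "B"), length.out = 2000)
  ref1$templates <- c("A", "B")
  obs <- ref1$stats[11, ]
  chd <- model_choice_direct(ref1, obs, k = 500)
  expect_lt(abs(chd$prob["A"] - 0.5), 3 * sqrt(0.25 / 500))
  chl <- suppressWarnings(model_choice_logistic(ref1, obs, fraction = 0.25))
  expect_lt(abs(chl$prob["A"] - 0.5), 0.15)
  expect_true(all(chl$ci[, "lower"] <= chl$prob &
                    chl$prob <= chl$ci[, "upper"]))
})

test_that("probabilities sum to one and CIs bracket the point estimates", {
  set.seed(42)
  for (i in 1:5) {
    par <- draw_priors(mt_priors, 1)[1, ]
    s <- glacialdemog:::simulate_stats_once("in_situ_refugia", par,
                                            mt_config, mt_priors)
    for (ch in list(model_choice_direct(mt_ref, s, k = 200),
                    suppressWarnings(
                      model_choice_logistic(mt_ref, s, fraction = 0.05)))) {
      expect_equal(sum(ch$prob), 1, tolerance = 1e-9)
      expect_true(all(ch$ci[, "lower"] - 1e-9 <= ch$prob &
                        ch$prob <= ch$ci[, "upper"] + 1e-9))
    }
  }
})

test_that("rejection-only posteriors equal accepted-sample quantiles and
           wide acceptance reproduces the prior", {
  set.seed(7)
  par <- draw_priors(mt_priors, 1)[1, ]
  s <- glacialdemog:::simulate_stats_once("northern_shift", par,
                                          mt_config, mt_priors)
  post <- estimate_parameters(mt_ref, s, "northern_shift", fraction = 0.2,
                              adjust = "none")
  expect_equal(post$summary$median[post$summary$parameter == "N"],
               unname(median(post$accepted$N)))
  expect_equal(post$summary$q025[post$summary$parameter == "t1"],
               unname(quantile(post$accepted$t1, 0.025)))

  # acceptance fraction -> 1: posterior ~ prior
  post_all <- estimate_parameters(mt_ref, s, "northern_shift", fraction = 1,
                                  adjust = "none")
  expect_gt(ks.test(post_all$samples$N, "punif", 100, 100000)$p.value, 0.01)

  # loclinear draws stay inside the prior box
  post_ll <- estimate_parameters(mt_ref, s, "northern_shift",
                                 fraction = 0.05, adjust = "loclinear")
  b <- mt_priors$bounds
  for (p in names(b)) {
    expect_true(all(post_ll$samples[[p] ] >= b[[p]][1] &
                      post_ll$samples[[p]] <= b[[p]][2]))
  }
})

test_that("confidence_in_choice is deterministic under a fixed seed", {
  small <- build_reference_table(priors = mt_priors, n_sim = 1200,
                                 sample_config = mt_config, seed = 303)
  e1 <- confidence_in_choice(small, n_pods = 6, seed = 9, fraction = 0.05)
  e2 <- confidence_in_choice(small, n_pods = 6, seed = 9, fraction = 0.05)
  expect_identical(e1, e2)
  expect_true(e1$type_I >= 0 && e1$type_I <= 1)
  expect_true(e1$type_II >= 0 && e1$type_II <= 1)
})

test_that("error rates are low for well-separated scenario configurations", {
  # non-overlapping merge-time priors and a strong bottleneck, with an
  # informative fixed clock
  pr <- prior_set("mtDNA", mt_rate = c(5e-8, 5e-8), Nb = c(5, 50),
                  t2 = c(10000, 25000), t3 = c(150000, 200000))
  ref <- build_reference_table(priors = pr, n_sim = 4000,
                               sample_config = mt_config, seed = 304)
  er <- confidence_in_choice(ref, n_pods = 25, seed = 10, fraction = 0.02)
  expect_lt(er$type_I, 0.2)
  expect_lt(er$type_II, 0.2)
})

test_that("posterior-predictive checks flag gross misfit and pass self-fits", {
  set.seed(8)
  par <- draw_priors(mt_priors, 1)[1, ]
  s <- glacialdemog:::simulate_stats_once("northern_shift", par,
                                          mt_config, mt_priors)
  post <- estimate_parameters(mt_ref, s, "northern_shift", fraction = 0.05)
  pp <- model_check(post, mt_ref, s, n_rep = 60, seed = 11)
  expect_equal(nrow(pp), ncol(mt_ref$stats))
  expect_true(all(pp$p_two_sided >= 0 & pp$p_two_sided <= 1))
  # a self-generated observation should rarely sit in the extreme tails
  expect_gte(mean(pp$p_two_sided > 0.05), 0.8)

  s_far <- s; s_far["fst"] <- 99
  pp2 <- model_check(post, mt_ref, s_far, n_rep = 60, seed = 12)
  expect_lte(pp2$p_ge[pp2$stat == "fst"], 1 / 61)

  expect_error(model_check(post, mt_ref, s, n_rep = 0, seed = 1), "n_rep")
})
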