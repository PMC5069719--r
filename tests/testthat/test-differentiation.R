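test_that("haplotype distances: identity, p-distance and Jukes-Cantor", {
  m <- rbind(rep("A", 100), c("C", rep("A", 99)))
  d <- seq_dataset(m, sample_id = c("H1", "H2"))
  id <- haplotype_distances(d, "identity")
  expect_equal(unname(id$delta[1, 2]), 1)
  expect_equal(diag(id$delta), c(H1 = 0, H2 = 0))

  pd <- haplotype_distances(d, "p-distance")
  expect_equal(unname(pd$delta[1, 2]), 0.01)

  jc <- haplotype_distances(d, "jukes-cantor")
  expect_equal(unname(jc$delta[1, 2]), -0.75 * log(1 - 0.04 / 3),
               tolerance = 1e-12)
  expect_equal(round(unname(jc$delta[1, 2]), 6), 0.010067)

  same <- seq_dataset(rbind(rep("A", 10), rep("A", 10)),
                      sample_id = c("a", "b"))
  expect_equal(unname(haplotype_distances(same, "p-distance")$delta[1, 2]), 0)

  # p >= 3/4 leaves the JC correction undefined
  far <- seq_dataset(rbind(rep("A", 4), c("C", "C", "C", "G")),
                     sample_id = c("a", "b"))
  expect_error(haplotype_distances(far, "jukes-cantor"), "3/4")
})

test_that("identity-distance AMOVA reproduces the study FST and its
           exact intermediates", {
  tb <- table1_fixture()
  col <- collapse_to_haplotypes(sequences_from_table(tb, seed = 1))
  id <- haplotype_distances(col$haplotypes, "identity")
  a <- amova_two_level(tb, id, n_perm = 10000, seed = 123)
  expect_equal(a$ssd_within, 236 / 24 + 437 / 40, tolerance = 1e-12)
  expect_equal(a$sigma_b, (236 / 24 + 437 / 40) / 62, tolerance = 1e-12)
  expect_equal(a$n_c, 30)
  expect_equal(round(a$phi, 4), 0.1923)
  expect_equal(round(a$phi, 2), 0.19)
  expect_lt(a$p_value, 0.001)
})

test_that("AMOVA agrees with the brute-force pair-enumeration oracle", {
  for (seed in 1:4) {
    tb <- random_hap_table(6, c(9, 12), seed)
    seqs <- sequences_from_table(tb, n_segregating = 10, L = 80, seed = seed)
    col <- collapse_to_haplotypes(seqs)
    for (model in c("identity", "jukes-cantor")) {
      d <- haplotype_distances(col$haplotypes, model)
      a <- amova_two_level(col$table, d)
      o <- amova_oracle(unclass(col$table), d$delta)
      expect_equal(a$phi, o$phi, tolerance = 1e-10)
      expect_equal(a$sigma_a, o$sigma_a, tolerance = 1e-10)
      expect_equal(a$sigma_b, o$sigma_b, tolerance = 1e-10)
    }
  }
})

test_that("AMOVA degenerate cases: no structure and full fixation", {
  # identical frequency vectors: no among-population variance
  tb <- hap_table(matrix(c(3, 1, 3, 1), 2,
                         dimnames = list(c("H1", "H2"), c("a", "b"))))
  id <- structure(list(haplotype_ids = c("H1", "H2"),
                       delta = matrix(c(0, 1, 1, 0), 2,
                                      dimnames = list(c("H1", "H2"),
                                                      c("H1", "H2"))),
                       model = "identity"), class = "hap_dist")
  a <- amova_two_level(tb, id)
  expect_lte(a$phi, 0)
  expect_equal(a$phi_trunc, 0)

  # populations fixed for different haplotypes
  tb2 <- hap_table(matrix(c(5, 0, 0, 6), 2,
                          dimnames = list(c("H1", "H2"), c("a", "b"))))
  a2 <- amova_two_level(tb2, id)
  expect_equal(a2$phi, 1)
})

test_that("Phi is invariant to rescaling the distance matrix", {
  tb <- random_hap_table(5, c(8, 10), seed = 9)
  seqs <- sequences_from_table(tb, n_segregating = 8, L = 60, seed = 9)
  col <- collapse_to_haplotypes(seqs)
  d <- haplotype_distances(col$haplotypes, "p-distance")
  a1 <- amova_two_level(col$table, d)
  d$delta <- d$delta * 37.5
  a2 <- amova_two_level(col$table, d)
  expect_equal(a1$phi, a2$phi, tolerance = 1e-12)
})

test_that("phylogeography test: degenerate and structured cases", {
  tb <- table1_fixture()
  col <- collapse_to_haplotypes(sequences_from_table(tb, seed = 3))
  id <- haplotype_distances(col$haplotypes, "identity")
  expect_error(phylogeography_permutation_test(tb, id, seed = 1), "vacuous")

  # constant off-diagonal distances: delta_obs = 0 and every permutation
  # ties, so p = 1
  dconst <- haplotype_distances(col$haplotypes, "p-distance")
  dconst$delta[] <- 0.02
  diag(dconst$delta) <- 0
  r <- phylogeography_permutation_test(tb, dconst, n_perm = 200, seed = 4)
  expect_equal(r$delta_obs, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  # two divergent 6-haplotype clades perfectly partitioned by population:
  # strong phylogeographic signal
  k <- 12
  clade <- rep(c("A", "T"), each = 6)
  haps <- do.call(rbind, lapply(1:k, function(i) {
    s <- rep(c("A", "C"), c(30, 30))
    s[1:10] <- clade[i]          # deep split between clades
    s[10 + i] <- "G"             # private mutation per haplotype
    s
  }))
  hs <- seq_dataset(haps, sample_id = paste0("H", 1:k))
  tb2 <- hap_table(matrix(c(rep(5L, 6), rep(0L, 6),
                            rep(0L, 6), rep(5L, 6)), k,
                          dimnames = list(paste0("H", 1:k),
                                          c("north", "south"))))
  djc <- haplotype_distances(hs, "jukes-cantor")
  r2 <- phylogeography_permutation_test(tb2, djc, n_perm = 1999, seed = 5)
  expect_gt(r2$phi_st_obs, r2$f_st_obs)
  expect_lt(r2$p_value, 0.01)
})

test_that("permuting haplotype labels leaves frequency-based FST unchanged", {
  tb <- random_hap_table(6, c(10, 12), seed = 2)
  counts <- unclass(tb)
  id <- matrix(1, 6, 6); diag(id) <- 0
  f0 <- glacialdemog:::phi_from_counts(counts, id)$phi
  set.seed(1)
  for (i in 1:20) {
    pp <- sample.int(6)
    expect_equal(glacialdemog:::phi_from_counts(counts, id[pp, pp])$phi, f0,
                 tolerance = 1e-12)
  }
})

test_that("permutation p-values are uniform under random labels", {
  # continuous distances avoid ties; labels assigned uniformly at random
  set.seed(77)
  base <- random_seq_dataset(6, 400, seed = 77)
  base$sample_id <- paste0("H", 1:6)
  d <- haplotype_distances(base, "p-distance")
  B <- 99
  pvals <- vapply(1:400, function(i) {
    repeat {
      hap_of <- sample.int(6, 24, replace = TRUE)
      pop_of <- sample(rep(1:2, c(10, 14)))
      counts <- vapply(1:2, function(j) tabulate(hap_of[pop_of == j], 6),
                       integer(6))
      if (all(rowSums(counts) >= 1)) break
    }
    rownames(counts) <- paste0("H", 1:6)
    colnames(counts) <- c("a", "b")
    amova_two_level(hap_table(counts), d, n_perm = B,
                    seed = 1000 + i)$p_value
  }, 0)
  # p takes values j/(B+1); bin counts against discrete-uniform expectation
  bins <- table(cut(pvals, breaks = seq(0, 1, 0.2)))
  expect_gt(chisq.test(bins)$p.value, 0.001)
  expect_lt(abs(mean(pvals) - 0.5), 0.05)
})
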