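# Brute-force oracles used across tests. These deliberately re-derive
# quantities by direct enumeration, independent of the package's formulas.

# AMOVA variance components by explicit pair enumeration over individuals
amova_oracle <- function(table, delta) {
  hap_of <- rep(seq_len(nrow(table)), rowSums(table))
  pop_of <- rep(seq_len(ncol(table)),
                colSums(matrix(table, nrow(table))) * 0 +
                  colSums(table))
  # rebuild individual order: column-major within haplotype rows
  hap_of <- unlist(lapply(seq_len(ncol(table)), function(j)
    rep(seq_len(nrow(table)), table[, j])))
  pop_of <- rep(seq_len(ncol(table)), colSums(table))
  N <- length(hap_of)
  P <- ncol(table)
  ssd_tot <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ssd_tot <- ssd_tot + delta[hap_of[i], hap_of[j]]
  }
  ssd_tot <- ssd_tot / N
  ssd_w <- 0
  for (p in seq_len(P)) {
    idx <- which(pop_of == p)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        s <- s + delta[hap_of[idx[a]], hap_of[idx[b]]]
      }
    }
    ssd_w <- ssd_w + s / length(idx)
  }
  sigma_b <- ssd_w / (N - P)
  n_c <- (N - sum(colSums(table)^2) / N) / (P - 1)
  sigma_a <- ((ssd_tot - ssd_w) / (P - 1) - sigma_b) / n_c
  list(phi = sigma_a / (sigma_a + sigma_b), sigma_a = sigma_a,
       sigma_b = sigma_b, ssd_within = ssd_w)
}

# frequency FST by exhaustive pair counting: probability two random genes
# differ overall vs within populations
fst_pair_counting_oracle <- function(table) {
  id <- matrix(1, nrow(table), nrow(table))
  diag(id) <- 0
  amova_oracle(table, id)$phi
}

# nucleotide diversity by looping over all sequence pairs
pi_oracle <- function(mat) {
  n <- nrow(mat)
  keep <- which(colSums(mat == "-" | mat == "N") == 0)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(mat[i, keep] != mat[j, keep])
  }
  tot / choose(n, 2) / length(keep)
}

# a small random haplotype count table for property-style loops
random_hap_table <- function(k, sizes, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(k * length(sizes), 2), k, length(sizes))
    for (j in seq_along(sizes)) {
      while (sum(m[, j]) != sizes[j]) {
        i <- sample.int(k, 1)
        if (sum(m[, j]) > sizes[j] && m[i, j] > 0) m[i, j] <- m[i, j] - 1
        else if (sum(m[, j]) < sizes[j]) m[i, j] <- m[i, j] + 1
      }
    }
    if (all(rowSums(m) >= 1)) break
  }
  hap_table(m)
}

# random aligned sequences over ACGT with optional gap column
random_seq_dataset <- function(n, L, seed, pops = NULL) {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (is.null(pops)) pops <- rep("all", n)
  seq_dataset(mat, population = pops)
}
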