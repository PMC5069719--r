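#' Pairwise distances between haplotype representatives
#'
#' Distances over complete-deletion sites: `identity` scores 1 for any two
#' distinct haplotypes (the frequency-only model underlying FST),
#' `p-distance` the proportion of differing retained sites, and
#' `jukes-cantor` the correction \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3}p)}.
#'
#' @param hap_seqs a [seq_dataset()] holding one representative sequence per
#'   haplotype (as returned by [collapse_to_haplotypes()]).
#' @param model one of `"identity"`, `"p-distance"`, `"jukes-cantor"`.
#' @return A list of class `hap_dist` with `haplotype_ids`, `delta`
#'   (symmetric matrix, zero diagonal) and `model`.
#' @export
haplotype_distances <- function(hap_seqs,
                                model = c("identity", "p-distance",
                                          "jukes-cantor")) {
  model <- match.arg(model)
  stopifnot(inherits(hap_seqs, "seq_dataset"))
  k <- length(hap_seqs$sample_id)
  ids <- hap_seqs$sample_id
  if (model == "identity") {
    d <- matrix(1, k, k, dimnames = list(ids, ids))
    diag(d) <- 0
    if (anyDuplicated(apply(hap_seqs$seq, 1, paste, collapse = "")))
      warning("duplicate representative sequences under identity model")
    return(structure(list(haplotype_ids = ids, delta = d, model = model),
                     class = "hap_dist"))
  }
  keep <- retained_sites(hap_seqs$seq)
  if (length(keep) == 0) stop("no sites retained after complete deletion")
  sub <- hap_seqs$seq[, keep, drop = FALSE]
  p <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p[i, j] <- p[j, i] <- mean(sub[i, ] != sub[j, ])
  }
  d <- p
  if (model == "jukes-cantor") {
    if (any(p >= 0.75)) stop("p-distance >= 3/4: Jukes-Cantor undefined")
    d <- -0.75 * log(1 - 4 * p / 3)
  }
  structure(list(haplotype_ids = ids, delta = d, model = model),
            class = "hap_dist")
}

# Phi from a haplotype x population count matrix and a distance matrix.
# Returns the raw (possibly negative) Phi plus the variance components.
phi_from_counts <- function(counts, delta) {
  n_k <- colSums(counts)
  N <- sum(n_k)
  P <- ncol(counts)
  ssd_group <- function(cv, n) (crossprod(cv, delta %*% cv) / 2) / n
  ssd_w <- sum(vapply(seq_len(P),
                      function(j) ssd_group(counts[, j], n_k[j]), 0))
  ssd_t <- ssd_group(rowSums(counts), N)
  ssd_a <- ssd_t - ssd_w
  sigma_b <- ssd_w / (N - P)
  n_c <- (N - sum(n_k^2) / N) / (P - 1)
  sigma_a <- (ssd_a / (P - 1) - sigma_b) / n_c
  denom <- sigma_a + sigma_b
  phi <- if (denom == 0) NA_real_ else sigma_a / denom
  list(phi = as.numeric(phi), sigma_a = as.numeric(sigma_a),
       sigma_b = as.numeric(sigma_b), n_c = as.numeric(n_c),
       ssd_within = as.numeric(ssd_w), ssd_among = as.numeric(ssd_a))
}

#' Two-level haploid AMOVA (PhiST / FST)
#'
#' Partitions the pairwise-distance sum of squares into among- and
#' within-population components. With identity distances the resulting
#' statistic is the haplotype-frequency FST; with molecular distances it is
#' PhiST. The permutation null reassigns individuals among populations,
#' holding sample sizes fixed.
#'
#' @param table a [hap_table()].
#' @param dist a [haplotype_distances()] result (row order must match the
#'   table's haplotypes).
#' @param n_perm number of permutations for the p-value (0 = none).
#' @param seed RNG seed (required when `n_perm > 0`).
#' @return A list of class `amova_result` with variance components
#'   (`sigma_a`, `sigma_b`), `phi` (raw, possibly negative), `phi_trunc`
#'   (negative values truncated to 0 for reporting), `p_value` and
#'   `n_permutations`.
#' @export
amova_two_level <- function(table, dist, n_perm = 0, seed = NULL) {
  stopifnot(inherits(table, "hap_table"), inherits(dist, "hap_dist"))
  counts <- unclass(table)
  if (nrow(counts) != nrow(dist$delta))
    stop("distance matrix and table disagree on haplotype count")
  if (!is.null(rownames(counts)) &&
      !identical(rownames(counts), dist$haplotype_ids))
    counts <- counts[dist$haplotype_ids, , drop = FALSE]
  if (ncol(counts) < 2) stop("need >= 2 populations")
  if (sum(counts) < 3) stop("need >= 3 individuals")
  obs <- phi_from_counts(counts, dist$delta)
  if (is.na(obs$phi))
    warning("sigma_a + sigma_b = 0: Phi undefined")
  p_value <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed required for permutations")
    set.seed(seed)
    hap_of <- rep(seq_len(nrow(counts)), rowSums(counts))
    pop_sizes <- colSums(counts)
    pop_of <- rep(seq_len(ncol(counts)), pop_sizes)
    k <- nrow(counts)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(hap_of)
      cperm <- vapply(seq_len(ncol(counts)),
                      function(j) tabulate(perm[pop_of == j], k),
                      integer(k))
      if (phi_from_counts(cperm, dist$delta)$phi >= obs$phi - 1e-12)
        ge <- ge + 1L
    }
    p_value <- (ge + 1) / (n_perm + 1)
  }
  structure(c(obs, list(phi_trunc = max(0, obs$phi, na.rm = TRUE),
                        model = dist$model, p_value = p_value,
                        n_permutations = n_perm)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("two-level AMOVA (%s distances): Phi = %.4f", x$model, x$phi))
  if (x$phi < 0) cat(sprintf(" (reported as %.4f)", x$phi_trunc))
  cat(sprintf("\n  sigma_a = %.5f, sigma_b = %.5f, n_c = %.3f\n",
              x$sigma_a, x$sigma_b, x$n_c))
  if (!is.na(x$p_value))
    cat(sprintf("  permutation p = %.5g (%d permutations)\n",
                x$p_value, x$n_permutations))
  invisible(x)
}

#' Phylogeographic-structure permutation test (PhiST vs FST)
#'
#' Tests whether PhiST (distance-weighted) exceeds FST (frequency-only), the
#' signature of phylogeographic structure: related haplotypes co-occurring
#' geographically. The null permutes haplotype identities on the distance
#' matrix, which leaves haplotype frequencies — and hence FST — unchanged,
#' and recomputes PhiST for each draw (the Pons & Petit permutation logic).
#'
#' @param table a [hap_table()].
#' @param dist a [haplotype_distances()] result with a molecular model
#'   (`p-distance` or `jukes-cantor`); identity distances make the test
#'   vacuous and are rejected.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return A list of class `phylogeo_test` with `phi_st_obs`, `f_st_obs`,
#'   `delta_obs`, `p_value`, `n_permutations`.
#' @export
phylogeography_permutation_test <- function(table, dist, n_perm = 10000,
                                            seed = NULL) {
  stopifnot(inherits(table, "hap_table"), inherits(dist, "hap_dist"))
  if (dist$model == "identity")
    stop("identity distances make PhiST identical to FST; test vacuous")
  if (nrow(table) < 3) stop("need >= 3 haplotypes for a non-degenerate test")
  if (is.null(seed)) stop("seed required for permutations")
  counts <- unclass(table)
  if (!identical(rownames(counts), dist$haplotype_ids))
    counts <- counts[dist$haplotype_ids, , drop = FALSE]
  id <- matrix(1, nrow(counts), nrow(counts)); diag(id) <- 0
  phi_obs <- phi_from_counts(counts, dist$delta)$phi
  f_obs <- phi_from_counts(counts, id)$phi
  delta_obs <- phi_obs - f_obs
  set.seed(seed)
  k <- nrow(counts)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    pp <- sample.int(k)
    d_perm <- dist$delta[pp, pp]
    if (phi_from_counts(counts, d_perm)$phi - f_obs >= delta_obs - 1e-12)
      ge <- ge + 1L
  }
  structure(list(phi_st_obs = phi_obs, f_st_obs = f_obs,
                 delta_obs = delta_obs, p_value = (ge + 1) / (n_perm + 1),
                 n_permutations = n_perm),
            class = "phylogeo_test")
}

#' @export
print.phylogeo_test <- function(x, ...) {
  cat(sprintf(paste0("PhiST = %.4f, FST = %.4f, delta = %.4f; ",
                     "p = %.5g (%d permutations)\n"),
              x$phi_st_obs, x$f_st_obs, x$delta_obs, x$p_value,
              x$n_permutations))
  invisible(x)
}
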