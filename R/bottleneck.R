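#' Per-locus observed heterozygosity for one population
#'
#' Unbiased expected heterozygosity per locus from allele frequencies,
#' `He = n (1 - sum p_a^2) / (n - 1)` with `n` the number of typed gene
#' copies. Monomorphic loci (and loci with fewer than two typed genes) are
#' flagged non-informative; the heterozygosity-change tests exclude them.
#'
#' @param dataset a [msat_dataset()].
#' @param population population label to subset to (`NULL` = all samples).
#' @return A data.frame with `locus_id`, `n_genes`, `k`, `He`, `informative`.
#' @export
observed_het <- function(dataset, population = NULL) {
  stopifnot(inherits(dataset, "msat_dataset"))
  idx <- if (is.null(population)) seq_along(dataset$sample_id) else
    which(dataset$population == population)
  if (length(idx) == 0) stop("no samples in population ", population)
  rows <- lapply(seq_along(dataset$loci), function(l) {
    genes <- c(dataset$a1[idx, l], dataset$a2[idx, l])
    genes <- genes[!is.na(genes)]
    n <- length(genes)
    k <- length(unique(genes))
    he <- if (n >= 2 && k >= 2) {
      p <- as.vector(table(genes)) / n
      n * (1 - sum(p^2)) / (n - 1)
    } else 0
    data.frame(locus_id = dataset$loci[l], n_genes = n, k = k, He = he,
               informative = n >= 2 && k >= 2)
  })
  out <- do.call(rbind, rows)
  if (!any(out$informative))
    stop("all loci monomorphic (or undertyped): no informative loci")
  out
}

#' Tune the coalescent mutation parameter to a target allele count
#'
#' Bisection on `log(theta)` so that the mean simulated allele count of an
#' `n_genes`-gene constant-size coalescent matches `k`; used to keep the
#' exact-`k` rejection step of [simulate_heq()] efficient.
#'
#' @inheritParams simulate_heq
#' @param n_batch simulations per bisection evaluation.
#' @return Tuned `theta` (scalar).
#' @export
tune_heq_theta <- function(k, n_genes, model = c("TPM", "SMM"), p_step = 0.9,
                           multi_step_mean = 2.8, n_batch = 300) {
  model <- match.arg(model)
  ps <- if (model == "SMM") 1 else p_step
  lo <- log(1e-4); hi <- log(1e4)
  for (it in seq_len(25)) {
    mid <- (lo + hi) / 2
    mk <- mean(heq_replicates_cpp(n_genes, exp(mid), ps, multi_step_mean,
                                  n_batch)[, 1])
    if (mk < k) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

# exact distribution of a sum of independent Bernoulli(p_l) (Poisson-binomial)
poisson_binomial_pmf <- function(p) {
  f <- 1
  for (pl in p) f <- c(f * (1 - pl), 0) + c(0, f * pl)
  f
}

#' Equilibrium heterozygosity distribution conditioned on the allele count
#'
#' Simulates the coalescent of `n_genes` gene copies under a constant-size
#' mutation-drift equilibrium with stepwise (`SMM`) or two-phase (`TPM`)
#' mutation, retaining only replicates whose simulated allele count equals
#' the observed `k`. The mutation parameter `theta` is first tuned by
#' bisection so that the mean simulated allele count matches `k`, which keeps
#' the rejection step efficient.
#'
#' @param k observed allele count (`2 <= k <= n_genes`).
#' @param n_genes number of typed gene copies.
#' @param model `"SMM"` (all single-step) or `"TPM"`.
#' @param p_step single-step proportion under TPM (default 0.9).
#' @param multi_step_mean mean multi-step jump under TPM (default 2.8).
#' @param n_iter number of retained replicates (default 1000).
#' @param seed RNG seed (mandatory).
#' @param locus_id optional label carried through to the tests.
#' @param theta optional pre-tuned mutation parameter (see
#'   [tune_heq_theta()]); `NULL` tunes by bisection.
#' @return A list of class `heq_dist` with `replicates` (He values), `mean`,
#'   `sd`, `theta`, `acceptance`, `model`, `locus_id`.
#' @export
simulate_heq <- function(k, n_genes, model = c("TPM", "SMM"), p_step = 0.9,
                         multi_step_mean = 2.8, n_iter = 1000, seed,
                         locus_id = NA_character_, theta = NULL) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is mandatory")
  if (k < 2 || k > n_genes) stop("need 2 <= k <= n_genes")
  ps <- if (model == "SMM") 1 else p_step
  set.seed(seed)
  if (is.null(theta))
    theta <- tune_heq_theta(k, n_genes, model, p_step, multi_step_mean)
  kept <- numeric(0)
  tried <- 0L
  batch <- max(2000L, 2L * n_iter)
  while (length(kept) < n_iter) {
    rep <- heq_replicates_cpp(n_genes, theta, ps, multi_step_mean, batch)
    kept <- c(kept, rep[rep[, 1] == k, 2])
    tried <- tried + batch
    if (tried >= 2e6 && length(kept) / tried < 1e-4)
      stop("acceptance rate below 1e-4; check k, n_genes and model settings")
  }
  kept <- kept[seq_len(n_iter)]
  structure(list(locus_id = locus_id, model = model, replicates = kept,
                 mean = mean(kept), sd = sd(kept), theta = theta,
                 acceptance = length(kept) / tried, n_genes = n_genes,
                 k = k),
            class = "heq_dist")
}

#' Heterozygosity deficit/excess tests against mutation-drift equilibrium
#'
#' Compares per-locus observed heterozygosity with its simulated equilibrium
#' distribution given the observed allele count. Per locus the standardized
#' difference is `DH_l = (He_l - mean(Heq_l)) / sd(Heq_l)`; the tests are
#' (i) a sign test on the number of excess loci, with per-locus excess
#' probabilities estimated from each Heq distribution (an exact
#' Poisson-binomial tail, not a 0.5-binomial), (ii) the standardized
#' differences test `T2 = sum(DH_l) / sqrt(L)` against a standard normal, and
#' (iii) a Wilcoxon signed-rank test on the `DH_l`.
#'
#' @param observations data.frame from [observed_het()].
#' @param heq_dists list of [simulate_heq()] results, matched to
#'   `observations` by `locus_id`.
#' @return A list of class `bottleneck_result`: `model`, `direction`
#'   (`"deficit"` or `"excess"`, by the sign of mean DH), one-sided
#'   (`p_sign`, `p_std_one`, `p_wilcoxon_one`, in the labelled direction) and
#'   two-sided (`p_sign_two`, `p_std_diff`, `p_wilcoxon`) p-values, `T2`, and
#'   the per-locus table.
#' @export
heterozygosity_change_tests <- function(observations, heq_dists) {
  ids <- vapply(heq_dists, function(d) d$locus_id, "")
  obs <- observations[observations$informative, , drop = FALSE]
  mi <- match(obs$locus_id, ids)
  if (anyNA(mi)) stop("missing Heq distribution for loci: ",
                      paste(obs$locus_id[is.na(mi)], collapse = ", "))
  dists <- heq_dists[mi]
  sds <- vapply(dists, function(d) d$sd, 0)
  drop <- sds == 0
  if (any(drop)) {
    warning("dropping loci with degenerate Heq distribution: ",
            paste(obs$locus_id[drop], collapse = ", "))
    obs <- obs[!drop, , drop = FALSE]
    dists <- dists[!drop]
  }
  L <- nrow(obs)
  if (L < 4) stop("need >= 4 informative loci")
  heq_mean <- vapply(dists, function(d) d$mean, 0)
  heq_sd <- vapply(dists, function(d) d$sd, 0)
  dh <- (obs$He - heq_mean) / heq_sd
  # per-locus probability that an equilibrium draw counts as "excess"
  p_excess <- vapply(dists, function(d) mean(d$replicates > d$mean), 0)
  x_excess <- sum(dh > 0)
  pmf <- poisson_binomial_pmf(p_excess)
  p_lower <- sum(pmf[seq_len(x_excess + 1)])        # P(X <= x): deficit tail
  p_upper <- sum(pmf[(x_excess + 1):(L + 1)])       # P(X >= x): excess tail
  t2 <- sum(dh) / sqrt(L)
  direction <- if (mean(dh) < 0) "deficit" else "excess"
  # tied |DH| values fall back to the normal approximation quietly
  wil_two <- suppressWarnings(wilcox.test(dh, mu = 0)$p.value)
  wil_one <- suppressWarnings(
    wilcox.test(dh, mu = 0,
                alternative = if (direction == "deficit") "less"
                else "greater")$p.value)
  structure(list(
    model = dists[[1]]$model,
    direction = direction,
    n_loci = L,
    T2 = t2,
    p_std_diff = 2 * pnorm(-abs(t2)),
    p_std_one = if (direction == "deficit") pnorm(t2) else pnorm(-t2),
    p_sign = if (direction == "deficit") p_lower else p_upper,
    p_sign_two = min(1, 2 * min(p_lower, p_upper)),
    expected_excess = sum(p_excess),
    observed_excess = x_excess,
    p_wilcoxon = wil_two,
    p_wilcoxon_one = wil_one,
    per_locus = data.frame(locus_id = obs$locus_id, n_genes = obs$n_genes,
                           k = obs$k, He = obs$He, Heq_mean = heq_mean,
                           Heq_sd = heq_sd, DH = dh, p_excess = p_excess)),
    class = "bottleneck_result")
}

#' @export
print.bottleneck_result <- function(x, ...) {
  cat(sprintf("heterozygosity %s (%s, %d loci): %d/%d loci in excess (exp %.2f)\n",
              x$direction, x$model, x$n_loci, x$observed_excess, x$n_loci,
              x$expected_excess))
  cat(sprintf("  sign test p = %.4g | T2 = %.3f, p = %.4g | Wilcoxon p = %.4g (one-sided, %s)\n",
              x$p_sign, x$T2, x$p_std_one, x$p_wilcoxon_one, x$direction))
  invisible(x)
}

#' Run the full bottleneck analysis for one population
#'
#' Convenience wrapper: observed heterozygosities, one Heq distribution per
#' informative locus, then the three tests.
#'
#' @param dataset a [msat_dataset()].
#' @param population population label.
#' @param model `"SMM"` or `"TPM"`.
#' @param p_step,multi_step_mean TPM settings (see [simulate_heq()]).
#' @param n_iter retained Heq replicates per locus.
#' @param seed RNG seed; per-locus seeds are derived from it.
#' @return A `bottleneck_result`.
#' @export
bottleneck_test <- function(dataset, population, model = c("TPM", "SMM"),
                            p_step = 0.9, multi_step_mean = 2.8,
                            n_iter = 1000, seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("seed is mandatory")
  obs <- observed_het(dataset, population)
  inf <- which(obs$informative)
  dists <- lapply(seq_along(inf), function(i) {
    o <- obs[inf[i], ]
    simulate_heq(o$k, o$n_genes, model = model, p_step = p_step,
                 multi_step_mean = multi_step_mean, n_iter = n_iter,
                 seed = (seed + 7919L * i) %% .Machine$integer.max,
                 locus_id = o$locus_id)
  })
  heterozygosity_change_tests(obs, dists)
}
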