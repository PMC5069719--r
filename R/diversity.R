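#' Unbiased haplotype (gene) diversity with Nei's variance
#'
#' Computes Nei's (1987) small-sample-corrected gene diversity
#' \deqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' and its sampling variance
#' \deqn{V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   \left(\sum p_i^2\right)^2\right] + \sum p_i^2 -
#'   \left(\sum p_i^2\right)^2\right\}.}
#'
#' @param counts positive integer vector of haplotype counts.
#' @return A list of class `diversity_estimate` with `n`, `k`, `h`, `sd_h`.
#' @examples
#' haplotype_diversity(c(26, 3, 6, 1, 1, 1, 1, 1))
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  if (any(counts != round(counts))) stop("counts must be integers")
  n <- sum(counts)
  if (n < 2) stop("need n >= 2 gene copies")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  h <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  structure(list(n = n, k = length(counts), h = h, sd_h = sqrt(max(v, 0)),
                 pi = NULL, sd_pi = NULL),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("n = %d, k = %d, h = %.2f +/- %.3f", x$n, x$k, x$h, x$sd_h))
  if (!is.null(x$pi)) cat(sprintf(", pi = %.5f (%.2f%%)", x$pi, 100 * x$pi))
  cat("\n")
  invisible(x)
}

#' Nucleotide diversity (per site) of an alignment
#'
#' Mean proportion of differing sites over all sequence pairs, using complete
#' deletion of alignment columns containing `-` or `N`. No multiple-hit
#' correction is applied: this is the observed-proportion statistic usually
#' reported alongside haplotype diversity.
#'
#' @param seqs a [seq_dataset()].
#' @param group a population label, or `NULL` for all samples pooled.
#' @return A `diversity_estimate` with `pi` set (per-site proportion); `h` and
#'   `sd_h` refer to the haplotype composition of the same group.
#' @export
nucleotide_diversity <- function(seqs, group = NULL) {
  stopifnot(inherits(seqs, "seq_dataset"))
  idx <- if (is.null(group)) seq_along(seqs$sample_id) else
    which(seqs$population == group)
  if (length(idx) < 2) stop("need >= 2 sequences in group")
  keep <- retained_sites(seqs$seq)
  if (length(keep) == 0) stop("no sites retained after complete deletion")
  sub <- seqs$seq[idx, keep, drop = FALSE]
  n <- nrow(sub)
  # total pairwise differences via per-column allele counts:
  # sum_col [C(n,2) - sum_a C(n_a,2)]
  tot <- 0
  for (j in seq_len(ncol(sub))) {
    tab <- tabulate(match(sub[, j], VALID_RESIDUES), length(VALID_RESIDUES))
    tot <- tot + choose(n, 2) - sum(choose(tab, 2))
  }
  pi <- tot / choose(n, 2) / length(keep)
  key <- apply(sub, 1, paste, collapse = "")
  est <- haplotype_diversity(as.vector(table(key)))
  est$pi <- pi
  est
}

#' Rarefied haplotype richness (exact hypergeometric)
#'
#' Expected number of distinct haplotypes in a random subsample of `g`
#' individuals,
#' \deqn{E[S_g] = \sum_h \left[1 - \binom{n - n_h}{g} / \binom{n}{g}\right],}
#' with the standard (Heck et al.) variance; computed exactly via
#' [vegan::rarefy()], not by resampling. A seeded resampling mode
#' ([rarefy_richness_resample()]) exists for cross-checking.
#'
#' @param counts positive integer vector of haplotype counts.
#' @param g rarefaction depth in individuals, `1 <= g <= sum(counts)`.
#' @return A list of class `rarefaction_result` with `g`, `expected_richness`,
#'   `sd_richness`.
#' @export
rarefy_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (length(g) != 1 || g < 1 || g > n) stop("g must lie in [1, n]")
  r <- vegan::rarefy(matrix(counts, nrow = 1), sample = g, se = TRUE)
  structure(list(g = g, expected_richness = as.numeric(r[1, 1]),
                 sd_richness = as.numeric(r[2, 1])),
            class = "rarefaction_result")
}

#' Rarefied richness by explicit subsampling (Monte Carlo cross-check)
#'
#' @param counts positive integer haplotype counts.
#' @param g subsample size.
#' @param n_draws number of random subsamples.
#' @param seed RNG seed.
#' @return mean richness over draws.
#' @export
rarefy_richness_resample <- function(counts, g, n_draws = 1000, seed = 1) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (g < 1 || g > n) stop("g must lie in [1, n]")
  pool <- rep(seq_along(counts), counts)
  set.seed(seed)
  mean(vapply(seq_len(n_draws),
              function(i) length(unique(sample(pool, g))), 0))
}

#' Per-population diversity summary table
#'
#' Mirrors the usual report layout: sample size, haplotype count, rarefied
#' richness at the smallest population size, and h and pi with standard
#' deviations, for each population and for the pooled sample.
#'
#' @param seqs a [seq_dataset()].
#' @param rarefy_to rarefaction depth; default the smallest population size.
#' @return A data.frame with one row per population plus a `total` row.
#' @export
diversity_table <- function(seqs, rarefy_to = NULL) {
  stopifnot(inherits(seqs, "seq_dataset"))
  pops <- unique(seqs$population)
  sizes <- table(seqs$population)[pops]
  if (is.null(rarefy_to)) rarefy_to <- min(sizes)
  groups <- c(list(total = NULL), setNames(as.list(pops), pops))
  rows <- lapply(names(groups), function(nm) {
    est <- nucleotide_diversity(seqs, groups[[nm]])
    idx <- if (is.null(groups[[nm]])) seq_along(seqs$sample_id) else
      which(seqs$population == groups[[nm]])
    keep <- retained_sites(seqs$seq)
    key <- apply(seqs$seq[idx, keep, drop = FALSE], 1, paste, collapse = "")
    cnt <- as.vector(table(key))
    rr <- rarefy_richness(cnt, min(rarefy_to, sum(cnt)))
    data.frame(group = nm, n = est$n, hap_n = est$k,
               hap_r = rr$expected_richness, hap_r_sd = rr$sd_richness,
               h = round(est$h, 2), sd_h = round(est$sd_h, 3),
               pi_pct = round(100 * est$pi, 2))
  })
  do.call(rbind, rows)
}
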