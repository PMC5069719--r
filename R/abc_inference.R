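#' Prior set for the glacial-history scenarios
#'
#' Uniform priors on the demographic parameters, per marker set. Times are in
#' years (converted with the model's generation time, default 1 year per
#' generation), sizes in individuals. Mutation-rate priors: mtDNA per-site
#' per-year rate uniform on `mt_rate`; microsatellite mean per-generation
#' rate uniform on `mean_mu`, per-locus rates Gamma-distributed (shape
#' `gamma_shape`, mean tied to the drawn mean rate) truncated to
#' `locus_mu_bounds`.
#'
#' @param marker `"mtDNA"` or `"microsat"`.
#' @param ... named overrides: any of `N`, `Nb`, `t1`, `t2`, `t3` (length-2
#'   bounds), or `mt_rate` / `mean_mu`. A zero-width interval fixes a
#'   parameter (useful in recovery experiments with a known mutation rate).
#' @return A list of class `prior_set`.
#' @export
prior_set <- function(marker = c("mtDNA", "microsat"), ...) {
  marker <- match.arg(marker)
  ps <- if (marker == "mtDNA") {
    list(marker = marker,
         bounds = list(N = c(100, 100000), Nb = c(5, 1000),
                       t1 = c(5000, 24000), t2 = c(10000, 25000),
                       t3 = c(50000, 200000)),
         mt_rate = c(5e-9, 5e-8))
  } else {
    list(marker = marker,
         bounds = list(N = c(500, 15000), Nb = c(50, 1000),
                       t1 = c(5000, 22000), t2 = c(8000, 25000),
                       t3 = c(50000, 200000)),
         mean_mu = c(1e-5, 1e-3),
         locus_mu_bounds = c(1e-5, 1e-2),
         gamma_shape = 2)
  }
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% names(ps$bounds)) ps$bounds[[nm]] <- ov[[nm]]
    else if (nm %in% names(ps)) ps[[nm]] <- ov[[nm]]
    else stop("unknown prior parameter: ", nm)
  }
  structure(ps, class = "prior_set")
}

#' Draw parameter vectors from a prior set
#'
#' Uniform draws with the ordering constraint `t1 < t2 < t3` and `Nb < N`
#' enforced by rejection.
#'
#' @param priors a [prior_set()].
#' @param n number of draws.
#' @return A data.frame with columns `N`, `Nb`, `t1`, `t2`, `t3` and the
#'   marker's rate parameter (`mt_rate` or `mean_mu`).
#' @export
draw_priors <- function(priors, n) {
  stopifnot(inherits(priors, "prior_set"))
  b <- priors$bounds
  draw1 <- function(m) {
    d <- data.frame(N = runif(m, b$N[1], b$N[2]),
                    Nb = runif(m, b$Nb[1], b$Nb[2]),
                    t1 = runif(m, b$t1[1], b$t1[2]),
                    t2 = runif(m, b$t2[1], b$t2[2]),
                    t3 = runif(m, b$t3[1], b$t3[2]))
    if (priors$marker == "mtDNA") {
      d$mt_rate <- runif(m, priors$mt_rate[1], priors$mt_rate[2])
    } else {
      d$mean_mu <- runif(m, priors$mean_mu[1], priors$mean_mu[2])
    }
    d
  }
  out <- draw1(n)
  repeat {
    bad <- which(!(out$t1 < out$t2 & out$t2 < out$t3 & out$Nb < out$N))
    if (length(bad) == 0) break
    out[bad, ] <- draw1(length(bad))
  }
  out
}

# ---- summary-statistic kernels -------------------------------------------

# stats from an integer matrix of (variable) site states, rows = samples.
# pop: integer vector with values 1, 2 (two populations, fixed order).
seq_summary_kernel <- function(V, pop, pop_names = c("pop1", "pop2")) {
  n <- length(pop)
  per_pop <- function(g) {
    rows <- which(pop == g)
    m <- length(rows)
    if (ncol(V) == 0) {
      return(c(K = 1, S = 0, mpd = 0,
               h = 0))
    }
    sub <- V[rows, , drop = FALSE]
    diffs <- 0; s_count <- 0L
    for (j in seq_len(ncol(sub))) {
      tab <- tabulate(sub[, j], 4L)
      same <- sum(choose(tab, 2))
      pairs_diff <- choose(m, 2) - same
      diffs <- diffs + pairs_diff
      if (pairs_diff > 0) s_count <- s_count + 1L
    }
    key <- apply(sub, 1, paste, collapse = ",")
    cnt <- as.vector(table(key))
    h <- if (length(cnt) > 1) m * (1 - sum((cnt / m)^2)) / (m - 1) else 0
    c(K = length(cnt), S = s_count, mpd = diffs / choose(m, 2), h = h)
  }
  s1 <- per_pop(1L); s2 <- per_pop(2L)
  n1 <- sum(pop == 1L); n2 <- sum(pop == 2L)
  if (ncol(V) == 0) {
    mpd_b <- 0; fst <- 0
  } else {
    cross <- 0
    for (j in seq_len(ncol(V))) {
      t1 <- tabulate(V[pop == 1L, j], 4L)
      t2 <- tabulate(V[pop == 2L, j], 4L)
      cross <- cross + n1 * n2 - sum(t1 * t2)
    }
    mpd_b <- cross / (n1 * n2)
    key <- apply(V, 1, paste, collapse = ",")
    uk <- unique(key)
    counts <- vapply(1:2, function(g)
      tabulate(match(key[pop == g], uk), length(uk)), integer(length(uk)))
    if (length(uk) > 1) {
      id <- matrix(1, length(uk), length(uk)); diag(id) <- 0
      fst <- phi_from_counts(counts, id)$phi
      if (!is.finite(fst)) fst <- 0
    } else fst <- 0
  }
  out <- c(s1, s2, fst, mpd_b)
  names(out) <- c(paste0(c("K_", "S_", "mpd_", "h_"), pop_names[1]),
                  paste0(c("K_", "S_", "mpd_", "h_"), pop_names[2]),
                  "fst", "mpd_between")
  out
}

# stats from allele-size matrices (genes x loci), pop over genes (1/2)
msat_summary_kernel <- function(alleles, pop, pop_names = c("pop1", "pop2")) {
  per_pop <- function(g) {
    sub <- alleles[pop == g, , drop = FALSE]
    n <- nrow(sub)
    k <- apply(sub, 2, function(a) length(unique(a[!is.na(a)])))
    he <- apply(sub, 2, function(a) {
      a <- a[!is.na(a)]
      if (length(a) < 2 || length(unique(a)) < 2) return(0)
      p <- as.vector(table(a)) / length(a)
      length(a) * (1 - sum(p^2)) / (length(a) - 1)
    })
    v <- apply(sub, 2, function(a) {
      a <- a[!is.na(a)]
      if (length(a) < 2) return(0)
      var(a)
    })
    c(mean_k = mean(k), mean_He = mean(he), mean_var = mean(v))
  }
  s1 <- per_pop(1L); s2 <- per_pop(2L)
  # Nei-style FST from heterozygosities, ratio of averages over loci
  hs <- ht <- numeric(ncol(alleles))
  dmu2 <- numeric(ncol(alleles))
  for (l in seq_len(ncol(alleles))) {
    a1 <- alleles[pop == 1L, l]; a1 <- a1[!is.na(a1)]
    a2 <- alleles[pop == 2L, l]; a2 <- a2[!is.na(a2)]
    gd <- function(a) if (length(unique(a)) < 2) 0 else
      1 - sum((as.vector(table(a)) / length(a))^2)
    hs[l] <- mean(c(gd(a1), gd(a2)))
    ht[l] <- gd(c(a1, a2))
    dmu2[l] <- (mean(a1) - mean(a2))^2
  }
  fst <- if (sum(ht) > 0) 1 - sum(hs) / sum(ht) else 0
  out <- c(s1, s2, fst, mean(dmu2))
  names(out) <- c(paste0(c("mean_k_", "mean_He_", "mean_var_"), pop_names[1]),
                  paste0(c("mean_k_", "mean_He_", "mean_var_"), pop_names[2]),
                  "fst", "dmu2")
  out
}

#' Summary-statistic vector of a two-population dataset
#'
#' mtDNA set: per population the haplotype count, segregating sites, mean
#' pairwise differences and unbiased haplotype diversity, plus the
#' identity-AMOVA FST and the mean between-population pairwise differences.
#' Microsatellite set: per population the mean allele number, mean unbiased
#' He and mean allele-size variance, plus FST (heterozygosity-based, ratio
#' of averages over loci) and the mean squared difference in mean allele
#' size `(delta mu)^2`. Statistics undefined on monomorphic data are 0.
#'
#' @param dataset a [seq_dataset()] or [msat_dataset()].
#' @param pops optional character vector of the two population labels in
#'   order; default the first two in appearance order.
#' @return Named numeric vector.
#' @export
summarize_dataset <- function(dataset, pops = NULL) {
  if (is.null(pops)) pops <- unique(dataset$population)
  if (length(pops) != 2) stop("exactly two populations required")
  pop <- match(dataset$population, pops)
  if (anyNA(pop)) stop("samples outside the two named populations")
  if (inherits(dataset, "seq_dataset")) {
    keep <- retained_sites(dataset$seq)
    sub <- dataset$seq[, keep, drop = FALSE]
    poly <- which(apply(sub, 2, function(cl) length(unique(cl)) > 1))
    V <- matrix(match(sub[, poly, drop = FALSE], c("A", "C", "G", "T")),
                nrow = nrow(sub))
    seq_summary_kernel(V, pop, pops)
  } else if (inherits(dataset, "msat_dataset")) {
    genes <- rbind(dataset$a1, dataset$a2)
    msat_summary_kernel(genes, rep(pop, 2), pops)
  } else stop("unsupported dataset class")
}

# ---- reference table ------------------------------------------------------

# simulate one dataset's summary statistics under a scenario
simulate_stats_once <- function(scenario, par, sample_config, priors) {
  sc <- sample_config
  model <- expand_scenario(scenario,
                           c(N = par$N, Nb = par$Nb,
                             t1 = par$t1 / sc$generation_time,
                             t2 = par$t2 / sc$generation_time,
                             t3 = par$t3 / sc$generation_time),
                           generation_time = sc$generation_time)
  if (sc$marker == "mtDNA") {
    gen <- simulate_genealogy(model, c(north = sc$n_north,
                                       south = sc$n_south),
                              ploidy_factor = 1)
    hky <- mutation_model_hky(rate = par$mt_rate * sc$generation_time,
                              kappa = sc$kappa, base_freq = sc$base_freq,
                              L = sc$L)
    vs <- mutate_variable_sites(gen, hky)
    pop <- match(gen$leaf_pop, c("north", "south"))
    seq_summary_kernel(vs$V, pop, c("north", "south"))
  } else {
    lb <- priors$locus_mu_bounds
    mus <- pmin(pmax(rgamma(sc$n_loci, shape = priors$gamma_shape,
                            scale = par$mean_mu / priors$gamma_shape),
                     lb[1]), lb[2])
    gsm <- mutation_model_gsm(mu = mus, p_step = sc$p_step,
                              multi_step_mean = sc$multi_step_mean)
    gens <- lapply(seq_len(sc$n_loci), function(l)
      simulate_genealogy(model, c(north = 2 * sc$n_north,
                                  south = 2 * sc$n_south),
                         ploidy_factor = 2))
    ds <- mutate_microsats(gens, gsm)
    genes <- rbind(ds$a1, ds$a2)
    pop <- match(rep(ds$population, 2), c("north", "south"))
    msat_summary_kernel(genes, pop, c("north", "south"))
  }
}

#' Default simulation configuration for a marker
#'
#' @param marker `"mtDNA"` or `"microsat"`.
#' @param n_north,n_south samples per population (gene copies for mtDNA,
#'   individuals for microsatellites); defaults follow the emulated study
#'   design (24/40 sequences; 24/29 genotyped individuals).
#' @param generation_time years per generation.
#' @return A list usable as `sample_config`.
#' @export
abc_sample_config <- function(marker = c("mtDNA", "microsat"),
                              n_north = NULL, n_south = NULL,
                              generation_time = 1) {
  marker <- match.arg(marker)
  if (marker == "mtDNA") {
    list(marker = marker,
         n_north = if (is.null(n_north)) 24 else n_north,
         n_south = if (is.null(n_south)) 40 else n_south,
         L = 663, kappa = 10, base_freq = c(0.30, 0.25, 0.15, 0.30),
         generation_time = generation_time)
  } else {
    list(marker = marker,
         n_north = if (is.null(n_north)) 24 else n_north,
         n_south = if (is.null(n_south)) 29 else n_south,
         n_loci = 21, p_step = 0.9, multi_step_mean = 2.8,
         generation_time = generation_time)
  }
}

#' Build an ABC reference table
#'
#' Draws parameters from the priors, simulates one dataset per row via the
#' coalescent engine, and records the scenario id, the parameter draw and
#' the summary-statistic vector. Statistic columns are normalized by their
#' median and MAD over all rows; constant columns are dropped with a
#' warning.
#'
#' @param templates character vector of scenario names (balanced design).
#' @param priors a [prior_set()].
#' @param n_sim total number of simulations (split equally over templates).
#' @param sample_config an [abc_sample_config()].
#' @param seed RNG seed (mandatory).
#' @return A list of class `ref_table`: `scenario`, `params`, `stats`
#'   (raw matrix), `center`, `scale`, `kept` (stat columns with positive
#'   MAD), plus the configuration.
#' @export
build_reference_table <- function(templates = c("in_situ_refugia",
                                                "northern_shift"),
                                  priors, n_sim, sample_config, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(priors, "prior_set"), n_sim >= 2)
  set.seed(seed)
  per <- floor(n_sim / length(templates))
  scen <- rep(templates, times = per)  # interleaved, balanced
  params <- draw_priors(priors, length(scen))
  stats <- NULL
  for (i in seq_along(scen)) {
    s <- simulate_stats_once(scen[i], params[i, ], sample_config, priors)
    if (is.null(stats)) stats <- matrix(0, length(scen), length(s),
                                        dimnames = list(NULL, names(s)))
    stats[i, ] <- s
  }
  center <- apply(stats, 2, median)
  scale <- apply(stats, 2, mad)
  kept <- which(scale > 0)
  if (length(kept) < ncol(stats))
    warning("dropping constant summary statistics: ",
            paste(colnames(stats)[-kept], collapse = ", "))
  structure(list(scenario = scen, params = params, stats = stats,
                 center = center, scale = scale, kept = kept,
                 templates = templates, priors = priors,
                 sample_config = sample_config, seed = seed),
            class = "ref_table")
}

#' @export
print.ref_table <- function(x, ...) {
  cat("ABC reference table:", length(x$scenario), "rows (",
      paste(sprintf("%s: %d", x$templates,
                    tabulate(match(x$scenario, x$templates))),
            collapse = ", "), "),", length(x$kept), "statistics\n")
  invisible(x)
}

# normalized stats (kept columns) for reference rows and an observed vector
normalize_ref <- function(ref) {
  sweep(sweep(ref$stats[, ref$kept, drop = FALSE], 2, ref$center[ref$kept]),
        2, ref$scale[ref$kept], "/")
}
normalize_obs <- function(ref, observed) {
  observed <- observed[colnames(ref$stats)]
  (observed[ref$kept] - ref$center[ref$kept]) / ref$scale[ref$kept]
}

ref_distances <- function(ref, observed) {
  Z <- normalize_ref(ref)
  z0 <- normalize_obs(ref, observed)
  sqrt(colSums((t(Z) - z0)^2))
}

#' Direct (k-nearest-neighbour) ABC scenario choice
#'
#' Posterior probability of each scenario = its share among the `k`
#' reference rows closest to the observed statistics (Euclidean distance on
#' median/MAD-normalized statistics). All rows tying the k-th distance are
#' included — frequent when low-diversity data make many simulations
#' identical — so the estimate is invariant to row order. The CI is a
#' binomial normal approximation.
#'
#' @param ref a [build_reference_table()] result.
#' @param observed named statistic vector (as from [summarize_dataset()]).
#' @param k number of neighbours (default 500).
#' @return A list of class `abc_choice` with `prob` (named), `ci` (matrix),
#'   `method`, `acceptance`, `n_reference`.
#' @export
model_choice_direct <- function(ref, observed, k = 500) {
  n <- length(ref$scenario)
  if (k > n) stop("k exceeds the reference-table size")
  d <- ref_distances(ref, observed)
  # include all rows tying the k-th distance so the estimate does not
  # depend on reference-table row order
  d_k <- sort(d, partial = k)[k]
  sel <- which(d <= d_k)
  k <- length(sel)
  prob <- vapply(ref$templates,
                 function(s) mean(ref$scenario[sel] == s), 0)
  se <- sqrt(pmax(prob * (1 - prob), 0) / k)
  ci <- cbind(lower = pmax(0, prob - 1.96 * se),
              upper = pmin(1, prob + 1.96 * se))
  rownames(ci) <- names(prob)
  structure(list(prob = prob, ci = ci, method = "direct",
                 acceptance = k / n, n_reference = n, n_used = k),
            class = "abc_choice")
}

# weighted ridge logistic regression via IRLS; returns coefficients and
# penalized-information covariance. X excludes the intercept column.
ridge_logistic <- function(X, y, w, lambda = 1e-4, max_iter = 50) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- rep(0, p)
  pen <- diag(lambda, p)
  pen[1, 1] <- lambda / 100  # keep the intercept near-unpenalized
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    W <- w * mu * (1 - mu)
    H <- crossprod(Xd, W * Xd) + pen
    g <- crossprod(Xd, w * (y - mu)) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e)
      tryCatch(qr.solve(H, g, tol = 1e-12), error = function(e2) NULL))
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # dampen Newton steps to keep separated fits from diverging
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  if (any(!is.finite(beta))) return(NULL)
  eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
  mu <- 1 / (1 + exp(-eta))
  H <- crossprod(Xd, (w * mu * (1 - mu)) * Xd) + pen
  V <- tryCatch(solve(H), error = function(e) NULL)
  list(beta = beta, vcov = V, converged = TRUE)
}

#' Logistic-regression ABC scenario choice
#'
#' Fits a logistic regression of the scenario indicator on the normalized
#' summary statistics over the fraction of reference rows closest to the
#' observed data (Epanechnikov distance weights), and evaluates the fit at
#' the observed point (covariates centred there, so the intercept is the
#' logit of the posterior probability). A small ridge penalty keeps the fit
#' defined under separation; strong separation is flagged. If the closest
#' fraction contains a single scenario the method falls back to the direct
#' estimate with a warning.
#'
#' @param ref a [build_reference_table()] result.
#' @param observed named statistic vector.
#' @param fraction fraction of closest simulations used (default 0.01).
#' @return An `abc_choice` (CI by the delta method on the logit scale).
#' @export
model_choice_logistic <- function(ref, observed, fraction = 0.01) {
  n <- length(ref$scenario)
  m <- max(2, ceiling(fraction * n))
  d <- ref_distances(ref, observed)
  d_m <- sort(d, partial = m)[m]
  if (d_m == 0) {
    # the observed point coincides with >= m simulations (typical for
    # monomorphic data): the local fit degenerates to the scenario share
    # of the tie set
    out <- model_choice_direct(ref, observed, k = m)
    out$method <- "logistic(point-mass)"
    return(out)
  }
  sel <- order(d)[seq_len(m)]
  scen <- ref$scenario[sel]
  if (length(unique(scen)) < 2) {
    warning("closest fraction contains one scenario; falling back to direct")
    out <- model_choice_direct(ref, observed, k = m)
    out$method <- "logistic(fallback:direct)"
    return(out)
  }
  Z <- normalize_ref(ref)[sel, , drop = FALSE]
  z0 <- normalize_obs(ref, observed)
  X <- sweep(Z, 2, z0)
  dmax <- max(d[sel])
  w <- 1 - (d[sel] / dmax)^2
  w[w <= 0] <- min(w[w > 0]) / 2
  y <- as.numeric(scen == ref$templates[2])
  fit <- ridge_logistic(X, y, w, lambda = 1e-4)
  separated <- FALSE
  if (is.null(fit) || max(abs(fit$beta)) > 50) {
    fit <- ridge_logistic(X, y, w, lambda = 1e-1)
    separated <- TRUE
  }
  if (is.null(fit)) {
    warning("logistic fit failed; falling back to direct")
    out <- model_choice_direct(ref, observed, k = m)
    out$method <- "logistic(fallback:direct)"
    return(out)
  }
  b0 <- fit$beta[1]
  p2 <- 1 / (1 + exp(-b0))
  se0 <- if (!is.null(fit$vcov)) sqrt(fit$vcov[1, 1]) else NA_real_
  lo2 <- 1 / (1 + exp(-(b0 - 1.96 * se0)))
  hi2 <- 1 / (1 + exp(-(b0 + 1.96 * se0)))
  prob <- setNames(c(1 - p2, p2), ref$templates)
  ci <- rbind(c(1 - hi2, 1 - lo2), c(lo2, hi2))
  dimnames(ci) <- list(ref$templates, c("lower", "upper"))
  structure(list(prob = prob, ci = ci, method = "logistic",
                 separated = separated, acceptance = m / n,
                 n_reference = n),
            class = "abc_choice")
}

#' @export
print.abc_choice <- function(x, ...) {
  cat("ABC scenario choice (", x$method, "):\n", sep = "")
  for (s in names(x$prob)) {
    cat(sprintf("  %-18s p = %.3f (95%% CI %.3f-%.3f)\n", s, x$prob[s],
                x$ci[s, 1], x$ci[s, 2]))
  }
  invisible(x)
}

# logit transform of x to (a, b), clamped away from the bounds
bounded_logit <- function(x, a, b) {
  u <- pmin(pmax((x - a) / (b - a), 1e-8), 1 - 1e-8)
  log(u / (1 - u))
}
bounded_expit <- function(z, a, b) a + (b - a) / (1 + exp(-z))

#' ABC parameter estimation (rejection / local-linear adjustment)
#'
#' Restricts the reference table to one scenario, accepts the rows closest
#' to the observed statistics, and (optionally) applies the local-linear
#' regression adjustment: parameters are logit-transformed to their prior
#' bounds, regressed on the (normalized) statistic deviations with
#' Epanechnikov weights, shifted to the observed point, and back-transformed
#' — which also clamps the adjusted draws inside the prior support.
#'
#' @param ref a [build_reference_table()] result.
#' @param observed named statistic vector.
#' @param scenario scenario whose parameters are estimated.
#' @param fraction fraction of the scenario's rows accepted (default 0.05).
#' @param adjust `"loclinear"` or `"none"` (plain rejection).
#' @return A list of class `parameter_posterior`: `samples` (adjusted
#'   draws), `accepted` (raw accepted draws), `summary` data.frame with
#'   mean, median and 95% quantile CI per parameter.
#' @export
estimate_parameters <- function(ref, observed, scenario,
                                fraction = 0.05,
                                adjust = c("loclinear", "none")) {
  adjust <- match.arg(adjust)
  rows <- which(ref$scenario == scenario)
  if (length(rows) == 0) stop("scenario not in reference table: ", scenario)
  d <- ref_distances(ref, observed)[rows]
  m <- max(100, ceiling(fraction * length(rows)))
  if (m > length(rows)) stop("accepted set needs >= 100 rows of ", scenario)
  sel <- rows[order(d)[seq_len(m)]]
  pars <- ref$params[sel, , drop = FALSE]
  bounds <- ref$priors$bounds
  rate_name <- setdiff(names(pars), names(bounds))
  rate_bounds <- if (identical(rate_name, "mt_rate")) ref$priors$mt_rate
    else ref$priors$mean_mu
  all_bounds <- c(bounds, setNames(list(rate_bounds), rate_name))
  adjusted <- pars
  if (adjust == "loclinear") {
    Z <- normalize_ref(ref)[sel, , drop = FALSE]
    z0 <- normalize_obs(ref, observed)
    X <- sweep(Z, 2, z0)
    dsel <- d[order(d)[seq_len(m)]]
    dm <- max(dsel)
    w <- if (dm > 0) 1 - (dsel / dm)^2 else rep(1, m)
    if (!any(w > 0)) w <- rep(1, m)
    w[w <= 0] <- min(w[w > 0]) / 2
    for (p in names(pars)) {
      ab <- all_bounds[[p]]
      if (ab[2] <= ab[1]) next  # parameter fixed by a degenerate prior
      z <- bounded_logit(pars[[p]], ab[1], ab[2])
      fit <- lm.wfit(cbind(1, X), z, w)
      z_adj <- fit$coefficients[1] + fit$residuals
      adjusted[[p]] <- bounded_expit(z_adj, ab[1], ab[2])
    }
  }
  # the per-parameter adjustment can break the joint ordering constraints;
  # such draws cannot be simulated from and are discarded
  valid <- adjusted$t1 < adjusted$t2 & adjusted$t2 < adjusted$t3 &
    adjusted$Nb < adjusted$N
  n_dropped <- sum(!valid)
  if (n_dropped > 0) adjusted <- adjusted[valid, , drop = FALSE]
  if (nrow(adjusted) == 0) stop("no adjusted draws satisfy the constraints")
  summ <- do.call(rbind, lapply(names(adjusted), function(p) {
    v <- adjusted[[p]]
    data.frame(parameter = p, mean = mean(v), median = median(v),
               q025 = quantile(v, 0.025), q975 = quantile(v, 0.975),
               prior_lower = all_bounds[[p]][1],
               prior_upper = all_bounds[[p]][2], row.names = NULL)
  }))
  structure(list(scenario = scenario, samples = adjusted, accepted = pars,
                 summary = summ, adjust = adjust, n_accepted = m,
                 n_dropped = if (adjust == "loclinear") n_dropped else 0L),
            class = "parameter_posterior")
}

#' @export
print.parameter_posterior <- function(x, ...) {
  cat("ABC posterior for scenario", x$scenario, "(", x$adjust, ",",
      x$n_accepted, "accepted draws):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Confidence in scenario choice: type I / type II error rates
#'
#' Simulates pseudo-observed datasets (pods) from each scenario's prior,
#' classifies each with the logistic method against the supplied reference
#' table, and reports, for the focal scenario, the type I error (focal true
#' but not chosen) and type II error (focal false but chosen). "Chosen"
#' means posterior probability > 0.5.
#'
#' @param ref a [build_reference_table()] result.
#' @param n_pods pods per scenario.
#' @param seed RNG seed (mandatory).
#' @param focal focal scenario (default `"northern_shift"`).
#' @param fraction logistic acceptance fraction (default 0.01).
#' @return A list of class `error_rates` with `type_I`, `type_II`,
#'   `n_pods`, `focal`.
#' @export
confidence_in_choice <- function(ref, n_pods = 50, seed,
                                 focal = "northern_shift", fraction = 0.01) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(focal %in% ref$templates)
  set.seed(seed)
  classify <- function(scen) {
    pars <- draw_priors(ref$priors, n_pods)
    vapply(seq_len(n_pods), function(i) {
      s <- simulate_stats_once(scen, pars[i, ], ref$sample_config,
                               ref$priors)
      p <- suppressWarnings(model_choice_logistic(ref, s, fraction))
      unname(p$prob[focal])
    }, 0)
  }
  p_true <- classify(focal)
  others <- setdiff(ref$templates, focal)
  p_false <- unlist(lapply(others, classify))
  structure(list(focal = focal,
                 type_I = mean(p_true <= 0.5),
                 type_II = mean(p_false > 0.5),
                 n_pods = n_pods), class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("confidence in choosing '%s' (%d pods/scenario): type I = %.3f, type II = %.3f\n",
              x$focal, x$n_pods, x$type_I, x$type_II))
  invisible(x)
}

#' Posterior-predictive model checking
#'
#' Simulates datasets at parameter values drawn from the (adjusted)
#' posterior and reports, for every summary statistic, the tail probability
#' of the observed value among the replicates (two-sided).
#'
#' @param posterior a [estimate_parameters()] result.
#' @param ref the reference table the posterior came from (provides the
#'   scenario configuration and priors).
#' @param observed named statistic vector.
#' @param n_rep number of posterior-predictive replicates.
#' @param seed RNG seed (mandatory).
#' @return A data.frame with `stat`, `p_ge` (fraction of replicates at or
#'   above the observed value) and `p_two_sided`.
#' @export
model_check <- function(posterior, ref, observed, n_rep = 100, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_rep < 1) stop("n_rep must be >= 1")
  set.seed(seed)
  draws <- posterior$samples[sample.int(nrow(posterior$samples), n_rep,
                                        replace = TRUE), , drop = FALSE]
  sims <- t(vapply(seq_len(n_rep), function(i)
    simulate_stats_once(posterior$scenario, draws[i, ], ref$sample_config,
                        ref$priors),
    numeric(ncol(ref$stats))))
  observed <- observed[colnames(ref$stats)]
  p_ge <- vapply(seq_len(ncol(sims)), function(j)
    mean(sims[, j] >= observed[j]), 0)
  data.frame(stat = colnames(ref$stats), p_ge = p_ge,
             p_two_sided = pmin(1, 2 * pmin(p_ge, 1 - p_ge)))
}
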