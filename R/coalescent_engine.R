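#' Backward-time demographic model
#'
#' A set of populations with time-0 sizes and an ordered list of backward-time
#' events: `size_change(pop, new_size)` and `merge(source, sink)` (all
#' lineages of `source` move into `sink`, looking back in time). Times are in
#' generations; `generation_time` (years per generation) is carried as
#' metadata so year-denominated rates and priors can be converted.
#'
#' @param pop_sizes named numeric vector of time-0 population sizes (census
#'   gene-copy scaling is applied later via `ploidy_factor`).
#' @param events list of events, each a list with `time` plus either
#'   `kind = "size_change"`, `pop`, `new_size`, or `kind = "merge"`,
#'   `source`, `sink`.
#' @param generation_time years per generation (default 1).
#' @return A list of class `demographic_model`.
#' @export
demographic_model <- function(pop_sizes, events = list(),
                              generation_time = 1) {
  if (is.null(names(pop_sizes)) || any(!nzchar(names(pop_sizes))))
    stop("pop_sizes must be named")
  if (any(pop_sizes <= 0)) stop("population sizes must be > 0")
  times <- vapply(events, function(e) e$time, 0)
  if (any(times < 0)) stop("event times must be non-negative")
  if (is.unsorted(times)) stop("events must be ordered by time")
  pops <- names(pop_sizes)
  alive <- pops
  for (e in events) {
    if (!e$kind %in% c("size_change", "merge")) stop("unknown event kind")
    if (e$kind == "size_change") {
      if (!e$pop %in% alive) stop("size_change on unknown/merged pop ", e$pop)
      if (e$new_size <= 0) stop("sizes must be > 0")
    } else {
      if (!e$source %in% alive || !e$sink %in% alive)
        stop("merge names unknown/merged population")
      alive <- setdiff(alive, e$source)
    }
  }
  if (length(alive) != 1)
    stop("after all merges exactly one ancestral population must remain")
  structure(list(pop_sizes = pop_sizes, events = events,
                 generation_time = generation_time),
            class = "demographic_model")
}

#' Expand a glacial-history scenario template into a demographic model
#'
#' Both templates describe two populations (`north`, `south`) of present size
#' `N` whose southern member was reduced to `Nb` during the glacial period.
#' Looking backward in time:
#' \describe{
#'   \item{northern_shift}{the south shrinks to `Nb` at `t1` (the forward-time
#'     expansion after colonization) and merges into the north at the
#'     deglaciation time `t2` — the south was founded from the north when the
#'     ice retreated; `t3` plays no structural role.}
#'   \item{in_situ_refugia}{the south shrinks to its refugial size `Nb` at
#'     `t1` and merges into the north at the glaciation onset `t3` — a
#'     population persisted in southern refugia through the glaciation;
#'     `t2` plays no structural role.}
#' }
#' Alternative readings can be expressed by passing an explicit event list to
#' [demographic_model()].
#'
#' @param template `"northern_shift"` or `"in_situ_refugia"`.
#' @param params named vector/list with `N`, `Nb`, `t1`, `t2`, `t3`
#'   (sizes in individuals, times in generations); requires `Nb < N` and
#'   `t1 < t2 < t3`.
#' @param generation_time years per generation (default 1).
#' @return A [demographic_model()].
#' @export
expand_scenario <- function(template = c("northern_shift", "in_situ_refugia"),
                            params, generation_time = 1) {
  template <- match.arg(template)
  p <- as.list(params)
  need <- c("N", "Nb", "t1", "t2", "t3")
  if (!all(need %in% names(p))) stop("params must name ",
                                     paste(need, collapse = ", "))
  if (p$Nb >= p$N) stop("Nb must be smaller than N")
  if (!(p$t1 < p$t2 && p$t2 < p$t3)) stop("need t1 < t2 < t3")
  if (any(unlist(p[c("N", "Nb", "t1", "t2", "t3")]) <= 0))
    stop("parameters must be positive")
  merge_time <- if (template == "northern_shift") p$t2 else p$t3
  demographic_model(
    pop_sizes = c(north = p$N, south = p$N),
    events = list(
      list(time = p$t1, kind = "size_change", pop = "south",
           new_size = p$Nb),
      list(time = merge_time, kind = "merge", source = "south",
           sink = "north")),
    generation_time = generation_time)
}

#' Simulate a coalescent genealogy under a demographic model
#'
#' Standard structured coalescent: within a population holding `k` lineages
#' and `Ne = ploidy_factor * size` gene copies, each pair coalesces at rate
#' `1/Ne` per generation; lineages in different populations coalesce only
#' after their populations merge.
#'
#' @param model a [demographic_model()].
#' @param sample_sizes named integer vector of gene copies sampled per
#'   population (names must match the model's populations).
#' @param ploidy_factor 1 for mtDNA, 2 for autosomal loci.
#' @param seed optional RNG seed (`set.seed` is honoured if `NULL`).
#' @return A list of class `genealogy`: `n` leaves, `parent` (index vector,
#'   0 at the root), `node_time` (generations), `leaf_pop`.
#' @export
simulate_genealogy <- function(model, sample_sizes, ploidy_factor = 1,
                               seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (!is.null(seed)) set.seed(seed)
  pops <- names(model$pop_sizes)
  if (is.null(names(sample_sizes)) || !all(names(sample_sizes) %in% pops))
    stop("sample_sizes must be named after the model's populations")
  n <- sum(sample_sizes)
  if (n < 2) stop("need at least 2 sampled gene copies")
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  leaf_pop <- rep(names(sample_sizes), sample_sizes)
  lineage_node <- seq_len(n)           # active lineage -> node id
  lineage_pop <- match(leaf_pop, pops) # active lineage -> pop index
  sizes <- as.numeric(model$pop_sizes) * ploidy_factor
  events <- model$events
  ev_i <- 1L
  t <- 0
  next_node <- n + 1L
  while (length(lineage_node) > 1) {
    k_p <- tabulate(lineage_pop, length(pops))
    rates <- k_p * (k_p - 1) / 2 / sizes
    tot <- sum(rates)
    ev_time <- if (ev_i <= length(events)) events[[ev_i]]$time else Inf
    dt <- if (tot > 0) rexp(1, tot) else Inf
    if (t + dt >= ev_time) {
      if (!is.finite(ev_time))
        stop("lineages in unmergeable populations cannot coalesce")
      t <- ev_time
      e <- events[[ev_i]]
      if (e$kind == "size_change") {
        sizes[match(e$pop, pops)] <- e$new_size * ploidy_factor
      } else {
        lineage_pop[lineage_pop == match(e$source, pops)] <-
          match(e$sink, pops)
      }
      ev_i <- ev_i + 1L
      next
    }
    t <- t + dt
    p_sel <- sample.int(length(pops), 1, prob = rates / tot)
    in_p <- which(lineage_pop == p_sel)
    pair <- in_p[sample.int(length(in_p), 2)]
    parent[lineage_node[pair]] <- next_node
    node_time[next_node] <- t
    lineage_node[pair[1]] <- next_node
    lineage_pop[pair[1]] <- p_sel
    lineage_node <- lineage_node[-pair[2]]
    lineage_pop <- lineage_pop[-pair[2]]
    next_node <- next_node + 1L
  }
  structure(list(n = n, parent = parent, node_time = node_time,
                 leaf_pop = leaf_pop), class = "genealogy")
}

#' Total branch length of a genealogy (generations)
#' @param gen a `genealogy`.
#' @return numeric scalar.
#' @export
total_branch_length <- function(gen) {
  v <- seq_len(2L * gen$n - 2L)
  sum(gen$node_time[gen$parent[v]] - gen$node_time[v])
}

#' HKY sequence mutation model
#'
#' @param rate per-site per-generation substitution rate.
#' @param kappa transition/transversion rate ratio.
#' @param base_freq equilibrium frequencies for A, C, G, T (sum to 1).
#' @param L sequence length in sites.
#' @return A list of class `mutation_model_hky`.
#' @export
mutation_model_hky <- function(rate, kappa = 10,
                               base_freq = c(0.30, 0.25, 0.15, 0.30),
                               L = 663) {
  stopifnot(rate >= 0, kappa > 0, L > 0, length(base_freq) == 4)
  if (abs(sum(base_freq) - 1) > 1e-8) stop("base frequencies must sum to 1")
  structure(list(rate = rate, kappa = kappa, base_freq = base_freq, L = L),
            class = "mutation_model_hky")
}

#' Generalized stepwise microsatellite mutation model
#'
#' Each mutation moves the repeat count by +/-1 with probability `p_step`,
#' otherwise by a geometric multi-step of size >= 2 with mean
#' `multi_step_mean`; repeat counts reflect at a floor of 1.
#'
#' @param mu per-locus per-generation mutation rates (vector, one per locus).
#' @param p_step probability of a single-repeat step (default 0.9).
#' @param multi_step_mean mean multi-step jump size (default 2.8, must be > 2).
#' @param root_allele repeat count of the ancestral allele.
#' @return A list of class `mutation_model_gsm`.
#' @export
mutation_model_gsm <- function(mu, p_step = 0.9, multi_step_mean = 2.8,
                               root_allele = 20) {
  stopifnot(all(mu >= 0), p_step >= 0, p_step <= 1, multi_step_mean > 2,
            root_allele >= 1)
  structure(list(mu = mu, p_step = p_step,
                 multi_step_mean = multi_step_mean,
                 root_allele = root_allele),
            class = "mutation_model_gsm")
}

# internal: HKY single-mutation kernel. bases coded 1..4 = A,C,G,T;
# transitions are A<->G (1,3) and C<->T (2,4).
hky_mutate_base <- function(cur, kappa, freq) {
  w <- freq
  ti <- c(3L, 4L, 1L, 2L)[cur]
  w[ti] <- w[ti] * kappa
  w[cur] <- 0
  sample.int(4L, 1L, prob = w)
}

# internal: drop mutations on a genealogy and return per-sample states at
# mutated sites only. Returns list(sites, V) where V is an n x m integer
# matrix of base codes (1..4) and sites the site index of each column.
mutate_variable_sites <- function(gen, hky) {
  n <- gen$n
  v <- seq_len(2L * n - 2L)
  blen <- gen$node_time[gen$parent[v]] - gen$node_time[v]
  m_per_branch <- rpois(length(v), hky$rate * hky$L * blen)
  total_m <- sum(m_per_branch)
  if (total_m == 0)
    return(list(sites = integer(0),
                V = matrix(integer(0), n, 0),
                root_at_sites = integer(0)))
  sites <- sample.int(hky$L, total_m, replace = TRUE)
  usites <- sort(unique(sites))
  root_at_sites <- sample.int(4L, length(usites), replace = TRUE,
                              prob = hky$base_freq)
  # states at mutated sites, per node; root (node 2n-1) first
  n_nodes <- 2L * n - 1L
  states <- matrix(rep(root_at_sites, each = n_nodes), n_nodes,
                   length(usites))
  branch_of_mut <- rep.int(v, m_per_branch)
  col_of_mut <- match(sites, usites)
  ord <- order(branch_of_mut)  # group mutations by branch
  branch_of_mut <- branch_of_mut[ord]
  col_of_mut <- col_of_mut[ord]
  # nodes are created in time order, so parent index > child index;
  # walking nodes from the root down keeps states consistent
  muts_by_node <- split(col_of_mut, branch_of_mut)
  for (node in (n_nodes - 1L):1L) {
    states[node, ] <- states[gen$parent[node], ]
    cols <- muts_by_node[[as.character(node)]]
    if (!is.null(cols)) {
      for (cc in cols) {
        states[node, cc] <- hky_mutate_base(states[node, cc], hky$kappa,
                                            hky$base_freq)
      }
    }
  }
  keep <- which(apply(states[seq_len(n), , drop = FALSE], 2,
                      function(col) length(unique(col)) > 1))
  list(sites = usites[keep],
       V = states[seq_len(n), keep, drop = FALSE],
       root_at_sites = root_at_sites[keep])
}

#' Drop HKY mutations on a genealogy and return the sample alignment
#'
#' Mutations arise as a Poisson process on each branch at rate `L * rate`
#' per generation; each hits a uniformly chosen site and substitutes the
#' current base via the HKY kernel (rate proportional to `kappa * pi_j` for
#' transitions, `pi_j` for transversions). The root sequence is drawn from
#' the equilibrium base frequencies.
#'
#' @param gen a `genealogy` from [simulate_genealogy()].
#' @param hky a [mutation_model_hky()].
#' @param seed optional RNG seed.
#' @return A [seq_dataset()] with one sequence per sampled gene copy,
#'   populations from the genealogy's leaf labels.
#' @export
mutate_sequences <- function(gen, hky, seed = NULL) {
  stopifnot(inherits(gen, "genealogy"), inherits(hky, "mutation_model_hky"))
  if (!is.null(seed)) set.seed(seed)
  root <- sample.int(4L, hky$L, replace = TRUE, prob = hky$base_freq)
  vs <- mutate_variable_sites(gen, hky)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(rep(bases[root], each = gen$n), gen$n, hky$L)
  if (length(vs$sites) > 0) {
    mat[, vs$sites] <- bases[vs$V]
  }
  tab <- table(factor(gen$leaf_pop, levels = unique(gen$leaf_pop)))
  ids <- unlist(lapply(names(tab), function(p)
    sprintf("%s_%02d", p, seq_len(tab[[p]]))))
  seq_dataset(mat, sample_id = ids, population = gen$leaf_pop)
}

# internal: signed step sizes for m GSM mutation events
gsm_steps <- function(m, p_step, multi_step_mean) {
  if (m == 0) return(integer(0))
  single <- runif(m) < p_step
  size <- integer(m)
  size[single] <- 1L
  if (any(!single)) {
    # geometric conditioned >= 2 with mean multi_step_mean:
    # 2 + Geom(p), mean 2 + (1-p)/p  =>  p = 1/(multi_step_mean - 1)
    p <- 1 / (multi_step_mean - 1)
    size[!single] <- 2L + rgeom(sum(!single), p)
  }
  size * sample(c(-1L, 1L), m, replace = TRUE)
}

#' Drop generalized-stepwise mutations on per-locus genealogies
#'
#' Each locus has its own genealogy over `2 * n_individuals` gene copies and
#' its own rate `mu[l]`; mutations are Poisson on branches, each step +/-1
#' with probability `p_step`, otherwise +/- a geometric jump of mean
#' `multi_step_mean`, with a reflecting floor at 1 repeat. Consecutive gene
#' copies within a population pair into diploid individuals.
#'
#' @param genealogies list of `genealogy` objects, one per locus, all with
#'   the same leaf population structure (even counts per population).
#' @param gsm a [mutation_model_gsm()] with `length(mu) == length(genealogies)`.
#' @param seed optional RNG seed.
#' @return A [msat_dataset()].
#' @export
mutate_microsats <- function(genealogies, gsm, seed = NULL) {
  stopifnot(inherits(gsm, "mutation_model_gsm"),
            length(gsm$mu) == length(genealogies))
  if (!is.null(seed)) set.seed(seed)
  n_genes <- genealogies[[1]]$n
  if (n_genes %% 2 != 0) stop("need an even number of gene copies")
  n_ind <- n_genes / 2L
  alle <- vapply(seq_along(genealogies), function(l) {
    gen <- genealogies[[l]]
    n <- gen$n
    v <- seq_len(2L * n - 2L)
    blen <- gen$node_time[gen$parent[v]] - gen$node_time[v]
    m_per_branch <- rpois(length(v), gsm$mu[l] * blen)
    state <- numeric(2L * n - 1L)
    state[2L * n - 1L] <- gsm$root_allele
    for (node in (2L * n - 2L):1L) {
      s <- state[gen$parent[node]]
      for (st in gsm_steps(m_per_branch[node], gsm$p_step,
                           gsm$multi_step_mean)) {
        s <- s + st
        if (s < 1) s <- 2 - s  # reflect at the 1-repeat floor
      }
      state[node] <- s
    }
    state[seq_len(n)]
  }, numeric(n_genes))
  odd <- seq(1, n_genes, by = 2)
  msat_dataset(a1 = alle[odd, , drop = FALSE],
               a2 = alle[odd + 1, , drop = FALSE],
               population = genealogies[[1]]$leaf_pop[odd],
               loci = sprintf("loc%02d", seq_along(genealogies)))
}
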