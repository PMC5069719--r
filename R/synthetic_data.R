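#' The packaged haplotype-frequency fixture
#'
#' The mtDNA control-region haplotype counts of the two-population study
#' design this package emulates: 14 haplotypes over a northern (n = 24) and a
#' southern (n = 40) population, the single shared haplotype H1 dominating
#' the south. Identical to the TSV shipped at
#' `system.file("extdata/table1_haplotypes.tsv", package = "glacialdemog")`.
#'
#' @return A [hap_table()] (14 x 2, columns `north`, `south`).
#' @examples
#' colSums(table1_fixture())  # 24 40
#' @export
table1_fixture <- function() {
  north <- c(5, 0, 5, 6, 1, 3, 0, 0, 0, 2, 0, 0, 2, 0)
  south <- c(26, 3, 0, 0, 0, 0, 6, 1, 1, 0, 1, 1, 0, 1)
  hap_table(matrix(c(north, south), ncol = 2,
                   dimnames = list(paste0("H", 1:14),
                                   c("north", "south"))))
}

#' Expand a haplotype count table into an aligned sequence dataset
#'
#' Constructs one template sequence per haplotype, differing at exactly
#' `n_segregating` biallelic sites (placement and alleles seeded), and
#' expands them to individuals according to the table, row-major, so that
#' [collapse_to_haplotypes()] inverts the construction exactly.
#'
#' @param table a [hap_table()].
#' @param n_segregating number of polymorphic sites among the templates.
#' @param L alignment length.
#' @param seed RNG seed (mandatory).
#' @return A [seq_dataset()] with `sum(table)` samples.
#' @export
sequences_from_table <- function(table, n_segregating = 15, L = 663, seed) {
  stopifnot(inherits(table, "hap_table"))
  if (missing(seed)) stop("seed is mandatory")
  k <- nrow(table)
  if (k > 2^n_segregating)
    stop("cannot distinguish ", k, " haplotypes with ", n_segregating,
         " biallelic sites")
  if (n_segregating > L) stop("n_segregating exceeds L")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, L, replace = TRUE)
  sites <- sort(sample.int(L, n_segregating))
  repeat {
    alle <- t(replicate(n_segregating, sample(bases, 2)))
    patt <- matrix(rbinom(k * n_segregating, 1, 0.5), k, n_segregating)
    distinct <- !anyDuplicated(apply(patt, 1, paste, collapse = ""))
    polymorphic <- all(colSums(patt) > 0 & colSums(patt) < k)
    if (distinct && polymorphic) break
  }
  haps <- matrix(rep(backbone, each = k), k, L)
  for (s in seq_len(n_segregating)) {
    haps[, sites[s]] <- alle[s, patt[, s] + 1]
  }
  pops <- colnames(table)
  rows <- list(); ids <- character(0); popv <- character(0)
  tally <- setNames(integer(length(pops)), pops)
  for (i in seq_len(k)) {
    for (j in seq_along(pops)) {
      cnt <- table[i, j]
      if (cnt > 0) {
        for (r in seq_len(cnt)) {
          tally[j] <- tally[j] + 1L
          rows[[length(rows) + 1]] <- haps[i, ]
          ids <- c(ids, sprintf("%s_%02d", pops[j], tally[j]))
          popv <- c(popv, pops[j])
        }
      }
    }
  }
  seq_dataset(do.call(rbind, rows), sample_id = ids, population = popv)
}

#' Study design of the emulated survey
#'
#' @param n_north_mt,n_south_mt mtDNA sample sizes (default 24 / 40).
#' @param L control-region alignment length (default 663).
#' @param n_north_ms,n_south_ms genotyped individuals per population
#'   (default 24 / 29, totalling 53).
#' @param n_loci number of dinucleotide microsatellite loci (default 21).
#' @param seed mandatory RNG seed.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_north_mt = 24, n_south_mt = 40, L = 663,
                         n_north_ms = 24, n_south_ms = 29, n_loci = 21,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_north_mt > 0, n_south_mt > 0, n_north_ms > 0, n_south_ms > 0,
            n_loci > 0, L > 0)
  structure(list(n_north_mt = n_north_mt, n_south_mt = n_south_mt, L = L,
                 n_north_ms = n_north_ms, n_south_ms = n_south_ms,
                 n_loci = n_loci, seed = seed),
            class = "study_design")
}

#' Generate a pseudo-observed dataset under a demographic scenario
#'
#' Simulates one dataset (mtDNA alignment or microsatellite genotypes) under
#' a scenario template at fixed parameters, writes it in its standard format
#' (FASTA / GenePop) alongside a truth JSON recording the scenario,
#' parameters and seed, and returns the in-memory objects.
#'
#' @param template scenario name, `"northern_shift"` or `"in_situ_refugia"`.
#' @param params named vector with `N`, `Nb`, `t1`, `t2`, `t3`.
#' @param design a [study_design()].
#' @param marker `"mtDNA"` or `"microsat"`.
#' @param seed RNG seed.
#' @param dir output directory, or `NULL` to skip writing files.
#' @param mt_rate mtDNA per-site per-generation mutation rate.
#' @param mean_mu mean microsatellite per-generation mutation rate.
#' @return A list with `dataset`, `truth` and (if written) `files`.
#' @export
generate_pseudo_observed <- function(template, params, design,
                                     marker = c("mtDNA", "microsat"),
                                     seed, dir = NULL,
                                     mt_rate = 1.5e-8, mean_mu = 5e-4) {
  marker <- match.arg(marker)
  if (missing(seed)) stop("seed is mandatory")
  model <- expand_scenario(template, params)
  set.seed(seed)
  if (marker == "mtDNA") {
    gen <- simulate_genealogy(model, c(north = design$n_north_mt,
                                       south = design$n_south_mt),
                              ploidy_factor = 1)
    dataset <- mutate_sequences(gen, mutation_model_hky(rate = mt_rate,
                                                        L = design$L))
  } else {
    mus <- pmin(pmax(rgamma(design$n_loci, shape = 2,
                            scale = mean_mu / 2), 1e-5), 1e-2)
    gens <- lapply(seq_len(design$n_loci), function(l)
      simulate_genealogy(model, c(north = 2 * design$n_north_ms,
                                  south = 2 * design$n_south_ms),
                         ploidy_factor = 2))
    dataset <- mutate_microsats(gens, mutation_model_gsm(mu = mus))
  }
  truth <- list(scenario = template, params = as.list(params), seed = seed,
                marker = marker)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    data_path <- file.path(dir, if (marker == "mtDNA") "pod.fasta" else
      "pod.genepop.txt")
    if (marker == "mtDNA") write_fasta(dataset, data_path) else
      write_genepop(dataset, data_path)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
    files <- c(data = data_path, truth = truth_path)
  }
  list(dataset = dataset, truth = truth, files = files)
}
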