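default_config <- function() {
  list(
    input = list(fasta = NULL, pop_map = NULL, genepop = NULL,
                 haplotype_table = NULL, boundary_latitude = NULL,
                 label_column = NULL),
    seeds = list(permutations = NULL, bottleneck = NULL, abc = NULL),
    permutations = list(n_perm = 10000),
    bottleneck = list(model = "TPM", p_step = 0.9, n_iter = 1000),
    abc = list(marker = "mtDNA", n_sim = 20000, fraction = 0.01,
               k_direct = 500, estimate_fraction = 0.05),
    output_dir = "results"
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), checks it against the
#' schema, fills defaults — including the per-marker prior bounds of
#' [prior_set()] — and returns the effective configuration. Unknown keys are
#' rejected; every stochastic stage must carry an explicit seed; setting
#' both a label column and a boundary latitude is ambiguous and rejected.
#'
#' @param config path to a YAML file, or a list.
#' @return The effective configuration list (invisibly validated).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  def <- default_config()
  errs <- character(0)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    errs <- c(errs, paste("unknown keys:", paste(unknown, collapse = ", ")))
  for (sec in intersect(names(config), names(def))) {
    if (is.list(def[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad) > 0)
        errs <- c(errs, paste0("unknown keys in '", sec, "': ",
                               paste(bad, collapse = ", ")))
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  if (!is.null(def$input$boundary_latitude) &&
      !is.null(def$input$label_column))
    errs <- c(errs, "both label_column and boundary_latitude set (ambiguous)")
  if (def$abc$fraction > 1 || def$abc$fraction <= 0)
    errs <- c(errs, "abc$fraction must lie in (0, 1]")
  for (s in c("permutations", "bottleneck", "abc")) {
    if (is.null(def$seeds[[s]]))
      errs <- c(errs, paste0("missing seed: seeds$", s))
  }
  if (!def$abc$marker %in% c("mtDNA", "microsat"))
    errs <- c(errs, "abc$marker must be mtDNA or microsat")
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  def$abc$priors <- prior_set(def$abc$marker)
  def
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study-shaped analysis over one mtDNA alignment and one
#' microsatellite genotype file: per-population diversity, AMOVA
#' differentiation (FST with identity distances, PhiST with Jukes-Cantor
#' distances) with permutation p-values, the phylogeographic-structure
#' permutation test, heterozygosity-change bottleneck tests per population,
#' and ABC scenario choice plus parameter estimation. Writes a JSON report,
#' TSV tables and the effective configuration under `output_dir`.
#'
#' @param config a validated configuration ([validate_config()] is applied).
#' @return The report list, invisibly; side effect: files under
#'   `config$output_dir`.
#' @export
run_full_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] starting")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(config = cfg[setdiff(names(cfg), c("abc", "output_dir"))],
                 abc_settings = cfg$abc[setdiff(names(cfg$abc), "priors")])

  seqs <- stage("load-mtDNA", {
    if (is.null(cfg$input$fasta)) stop("input$fasta is required")
    read_fasta(cfg$input$fasta, pop_map = cfg$input$pop_map)
  })
  msat <- if (!is.null(cfg$input$genepop))
    stage("load-microsat", read_genepop(cfg$input$genepop,
                                        pop_names = unique(seqs$population)))
  else NULL

  report$diversity <- stage("diversity", diversity_table(seqs))
  write.table(report$diversity, file.path(cfg$output_dir, "diversity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  diffs <- stage("differentiation", {
    col <- collapse_to_haplotypes(seqs)
    d_id <- haplotype_distances(col$haplotypes, "identity")
    d_jc <- haplotype_distances(col$haplotypes, "jukes-cantor")
    fst <- amova_two_level(col$table, d_id,
                           n_perm = cfg$permutations$n_perm,
                           seed = cfg$seeds$permutations)
    phist <- amova_two_level(col$table, d_jc,
                             n_perm = cfg$permutations$n_perm,
                             seed = cfg$seeds$permutations + 1L)
    pg <- phylogeography_permutation_test(col$table, d_jc,
                                          n_perm = cfg$permutations$n_perm,
                                          seed = cfg$seeds$permutations + 2L)
    list(fst = fst, phi_st = phist, phylogeography = pg)
  })
  report$differentiation <- list(
    fst = diffs$fst$phi_trunc, fst_p = diffs$fst$p_value,
    phi_st = diffs$phi_st$phi_trunc, phi_st_p = diffs$phi_st$p_value,
    phylogeography_delta = diffs$phylogeography$delta_obs,
    phylogeography_p = diffs$phylogeography$p_value)

  if (!is.null(msat)) {
    report$bottleneck <- stage("bottleneck", {
      lapply(setNames(nm = unique(msat$population)), function(p) {
        r <- bottleneck_test(msat, p, model = cfg$bottleneck$model,
                             p_step = cfg$bottleneck$p_step,
                             n_iter = cfg$bottleneck$n_iter,
                             seed = cfg$seeds$bottleneck)
        list(direction = r$direction, p_sign = r$p_sign, T2 = r$T2,
             p_std_diff = r$p_std_diff, p_wilcoxon = r$p_wilcoxon)
      })
    })
  }

  report$abc <- stage("abc", {
    if (cfg$abc$n_sim < 10000)
      warning("ABC reference table below 10,000 rows; desk-scale only")
    sc <- abc_sample_config(cfg$abc$marker,
                            n_north = sum(seqs$population ==
                                            unique(seqs$population)[1]),
                            n_south = sum(seqs$population ==
                                            unique(seqs$population)[2]))
    ref <- build_reference_table(priors = cfg$abc$priors,
                                 n_sim = cfg$abc$n_sim, sample_config = sc,
                                 seed = cfg$seeds$abc)
    obs <- summarize_dataset(seqs)
    names(obs) <- colnames(ref$stats)  # north/south naming
    direct <- model_choice_direct(ref, obs, k = min(cfg$abc$k_direct,
                                                    cfg$abc$n_sim %/% 4))
    logistic <- model_choice_logistic(ref, obs, fraction = cfg$abc$fraction)
    best <- names(which.max(logistic$prob))
    post <- estimate_parameters(ref, obs, best,
                                fraction = cfg$abc$estimate_fraction)
    write.table(post$summary, file.path(cfg$output_dir,
                                        "abc_posterior.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(observed_stats = as.list(obs),
         direct = list(prob = as.list(direct$prob)),
         logistic = list(prob = as.list(logistic$prob),
                         ci = apply(logistic$ci, 1, as.list)),
         chosen_scenario = best,
         posterior = post$summary)
  })

  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  yaml::write_yaml(cfg[setdiff(names(cfg), "abc")],
                   file.path(cfg$output_dir, "config_effective.yaml"))
  invisible(report)
}
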