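#' Configure an end-to-end rhythm-analysis run
#'
#' Bundles every tunable of the pipeline — input table or path, reference
#' gene, calibrator rule, cosinor fitting method and search effort,
#' permutation count, classification rule and the single seed from which all
#' randomness flows — into one validated object.
#'
#' @param ct Either a Ct tibble or a path to a TSV/CSV Ct table.
#' @param reference Reference (housekeeping) gene id.
#' @param calibrator Calibrator rule for [relative_quantity()].
#' @param method Cosinor fitting method, `"mc"` or `"ls"`.
#' @param n_sims,top_k Monte-Carlo search effort (see [cosinor_mc()]).
#' @param n_perm Permutations for the cosinor p-value.
#' @param rule Oscillation classification rule.
#' @param seed Master seed.
#' @param out_dir Optional directory; when given, every stage writes a TSV.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ct, reference = "EF1a",
                            calibrator = c("mean_over_time", "first_timepoint"),
                            method = c("mc", "ls"), n_sims = 1e5, top_k = 400,
                            n_perm = 999, rule = c("p_only", "strict"),
                            seed = 1, out_dir = NULL) {
  structure(
    list(
      ct = ct, reference = reference, calibrator = match.arg(calibrator),
      method = match.arg(method), n_sims = n_sims, top_k = top_k,
      n_perm = n_perm, rule = match.arg(rule), seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full rhythm-detection pipeline
#'
#' Executes quantify (delta-delta-Ct and z-scores) -> aggregate across
#' colonies -> cosinor fits (aggregate and per colony) -> per-gene two-way
#' ANOVA -> oscillation classification -> summary table. All stages are
#' deterministic given the config seed. When `out_dir` is set, each stage's
#' table is written as TSV together with a `run_info.tsv` recording the
#' seed and a hash of the configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of tibbles: `expression`, `aggregate`, `fits`,
#'   `colony_fits`, `anova`, `summary`, plus `seed` and `config_hash`.
#' @examples
#' ct <- simulate_qpcr(sim_config(seed = 7))
#' res <- run_pipeline(pipeline_config(ct, method = "ls", n_perm = 199))
#' res$summary
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("config must be created with pipeline_config()")
  }
  ct <- if (is.character(config$ct)) read_ct_table(config$ct) else config$ct
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  expression <- stage("quantify",
    quantify_expression(ct, config$reference, config$calibrator))
  aggregate <- stage("aggregate", aggregate_colonies(expression))
  fits <- stage("fit",
    fit_rhythms(aggregate, method = config$method, n_sims = config$n_sims,
                top_k = config$top_k, n_perm = config$n_perm,
                seed = config$seed))
  colony_fits <- stage("fit_colonies",
    fit_rhythms(expression, method = "ls", n_perm = 0, seed = config$seed))
  anova <- stage("anova", rhythm_anova(expression))
  summary <- stage("classify",
    summarize_rhythms(fits, anova, colony_fits = colony_fits,
                      rule = config$rule))
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  out <- list(
    expression = expression, aggregate = aggregate, fits = fits,
    colony_fits = colony_fits, anova = anova, summary = summary,
    seed = config$seed, config_hash = hash
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (name in c("expression", "aggregate", "fits", "colony_fits",
                   "anova", "summary")) {
      write_tsv_table(out[[name]], file.path(config$out_dir,
                                             paste0(name, ".tsv")))
    }
    write_tsv_table(
      tibble(seed = config$seed, config_hash = hash),
      file.path(config$out_dir, "run_info.tsv")
    )
  }
  out
}
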