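#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable of the study pipeline in one validated object.
#' Two input modes are supported: `"synthetic"` (the package generates a
#' resting-like modular matrix plus a task-like matrix with boosted
#' between-module coupling and a planted hub, then runs the full builders on
#' simulated raw inputs) and `"matrices"` (user-supplied coactivation and
#' resting connectivity matrices, given as objects or TSV paths).
#'
#' @param mode `"synthetic"` or `"matrices"`.
#' @param coactivation,resting For `mode = "matrices"`: matrices or TSV
#'   paths.
#' @param grid Sparsity grid for the metric comparison.
#' @param metrics Metrics to compare.
#' @param hub_sparsities Sparsity levels for the hub analysis.
#' @param n_perm Permutations per test.
#' @param alpha Significance level.
#' @param seed Root seed for everything stochastic.
#' @param out_dir Output directory for result TSVs, or NULL to skip writing.
#' @param synth Named list overriding synthetic-generation defaults:
#'   `n_nodes`, `n_modules`, `mu_in`, `mu_out`, `sigma`, `between_boost`,
#'   `hub_node`, `hub_boost`, `n_subjects`, `t_len`, `tr_seconds`,
#'   `noise_sd`, `use_builders` (if FALSE, compare the weighted templates
#'   directly instead of simulating raw counts and time series).
#' @param random_reps Draws for the random-network reference curves (0 to
#'   skip).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "matrices"),
                       coactivation = NULL, resting = NULL,
                       grid = seq(0.06, 0.40, by = 0.01),
                       metrics = c("efficiency", "clustering", "modularity"),
                       hub_sparsities = c(0.10, 0.20, 0.30),
                       n_perm = 1000L, alpha = 0.001, seed = 1L,
                       out_dir = NULL, synth = list(), random_reps = 0L) {
  mode <- match.arg(mode)
  if (any(grid <= 0 | grid >= 1)) abort("Sparsity grid must lie in (0, 1).")
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  defaults <- list(
    n_nodes = 60L, n_modules = 4L, mu_in = 0.6, mu_out = 0.2, sigma = 0.05,
    between_boost = 0.25, hub_node = 1L, hub_boost = 0.5,
    n_subjects = 20L, t_len = 240L, tr_seconds = 1.8, noise_sd = 0.5,
    use_builders = TRUE
  )
  unknown <- setdiff(names(synth), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown synth setting(s): ", paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      mode = mode, coactivation = coactivation, resting = resting,
      grid = grid, metrics = check_metrics(metrics),
      hub_sparsities = hub_sparsities, n_perm = as.integer(n_perm),
      alpha = alpha, seed = as.integer(seed), out_dir = out_dir,
      synth = utils::modifyList(defaults, synth),
      random_reps = as.integer(random_reps)
    ),
    class = "run_config"
  )
}

#' Run the full task-versus-rest network comparison pipeline
#'
#' Builds (or loads) the coactivation and resting connectivity matrices,
#' correlates their edge weights, sweeps the permutation tests over the
#' sparsity grid, and runs the hub-shift analysis. All results are returned
#' and, when `out_dir` is set, written as tidy TSVs together with a run
#' report; a rerun with the same config and seed is byte-identical.
#'
#' @param config A [run_config()].
#' @return List with `coactivation`, `resting` (connectivity matrices),
#'   `weight_correlation` (Pearson r over node pairs), `tests`
#'   (a `perm_sweep` tibble), `hubs` (see [hub_analysis()]), `report`
#'   (tibble of per-stage log entries), and for synthetic runs `truth`
#'   (planted modules and hub).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list()
  log_stage <- function(stage, message, count = NA_integer_) {
    report[[length(report) + 1]] <<- tibble::tibble(
      stage = stage, message = message, count = as.integer(count)
    )
  }
  truth <- NULL
  if (config$mode == "synthetic") {
    sy <- config$synth
    sizes <- rep(sy$n_nodes %/% sy$n_modules, sy$n_modules)
    sizes[1] <- sizes[1] + sy$n_nodes - sum(sizes)
    rest_w <- gen_modular_matrix(modular_spec(
      sy$n_nodes, sizes, sy$mu_in, sy$mu_out, sy$sigma,
      seed = child_seed(config$seed, 1L)
    ))
    task_w <- boost_between_modules(rest_w, sy$between_boost)
    task_w <- plant_hub(task_w, sy$hub_node, sy$hub_boost)
    truth <- list(modules = attr(rest_w, "modules"),
                  hub_node = sy$hub_node,
                  hub_label = rownames(task_w)[sy$hub_node])
    log_stage("simulate", sprintf("generated %d-node modular templates", sy$n_nodes),
              sy$n_nodes)
    if (isTRUE(sy$use_builders)) {
      scales <- with_seed_maybe(child_seed(config$seed, 2L),
                                runif(sy$n_nodes, 0.5, 2))
      raw <- gen_seed_count_matrix(task_w, scales, noise_sd = 0.01,
                                   seed = child_seed(config$seed, 3L))
      coact <- build_coactivation_matrix(raw)
      log_stage("build-coact", "built coactivation matrix from simulated counts",
                nrow(coact))
      panel <- gen_subject_panel(
        rest_w, n_subjects = sy$n_subjects, t_len = sy$t_len,
        tr_seconds = sy$tr_seconds, noise_sd = sy$noise_sd,
        motion_spec = list(step_sd = 0.02, violator_subject = sy$n_subjects,
                           violator_peak_mm = 3.5),
        seed = child_seed(config$seed, 4L)
      )
      rb <- build_resting_matrix(panel)
      rest <- rb$matrix
      n_excl <- sum(rb$motion_log$excluded)
      log_stage("motion-screen",
                sprintf("%d subject(s) excluded (>3 mm), %d retained",
                        n_excl, rb$n_subjects_used), n_excl)
      log_stage("build-rest", "built group resting matrix", rb$n_subjects_used)
    } else {
      coact <- task_w
      rest <- rest_w
      log_stage("build", "comparing weighted templates directly", nrow(coact))
    }
  } else {
    load_m <- function(x) if (is.character(x)) read_matrix(x) else connectivity_matrix(x)
    coact <- load_m(config$coactivation)
    rest <- load_m(config$resting)
    log_stage("load", "loaded coactivation and resting matrices", nrow(coact))
  }
  check_same_labels(coact, rest)

  ut <- upper.tri(coact)
  weight_correlation <- cor(coact[ut], rest[ut])
  log_stage("weights", sprintf("weight correlation r = %.3f", weight_correlation),
            sum(ut))

  tests <- sweep_tests(
    coact, rest, grid = config$grid, metrics = config$metrics,
    n_perm = config$n_perm, alpha = config$alpha,
    seed = child_seed(config$seed, 5L)
  )
  log_stage("compare", sprintf("%d permutation tests, %d significant at alpha = %g",
                               nrow(tests), sum(tests$significant), config$alpha),
            nrow(tests))

  hubs <- hub_analysis(
    coact, rest, sparsities = config$hub_sparsities,
    n_perm = config$n_perm, seed = child_seed(config$seed, 6L)
  )
  log_stage("hubs", sprintf("hub analysis at %d sparsity level(s)",
                            length(config$hub_sparsities)),
            length(config$hub_sparsities))

  out <- list(
    coactivation = coact, resting = rest,
    weight_correlation = weight_correlation,
    tests = tests, hubs = hubs, truth = truth,
    config = config, report = dplyr::bind_rows(report)
  )
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(run$coactivation, file.path(dir, "coactivation_matrix.tsv"))
  write_matrix(run$resting, file.path(dir, "resting_matrix.tsv"))
  write.table(as.data.frame(run$tests), file.path(dir, "permutation_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (h in run$hubs) {
    tag <- sprintf("s%02d", round(h$sparsity * 100))
    write.table(as.data.frame(h$table),
                file.path(dir, paste0("degree_differences_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(h$envelope),
                file.path(dir, paste0("degree_envelope_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(as.data.frame(run$report), file.path(dir, "run_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- run$config
  cfg_lines <- c(
    paste0("mode: ", cfg$mode),
    paste0("seed: ", cfg$seed),
    paste0("n_perm: ", cfg$n_perm),
    paste0("alpha: ", cfg$alpha),
    paste0("grid: ", paste(cfg$grid, collapse = ",")),
    paste0("metrics: ", paste(cfg$metrics, collapse = ",")),
    paste0("hub_sparsities: ", paste(cfg$hub_sparsities, collapse = ","))
  )
  writeLines(cfg_lines, file.path(dir, "config.txt"))
  invisible(dir)
}
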