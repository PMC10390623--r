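#' Read and write cohort tables
#'
#' The cohort CSV dialect: one row per participant, columns
#' `participant_id`, `age`, `gender`, `education`, `income` (empty cell =
#' missing), `numeracy`, `working_memory`, then the 24 canonical outcome
#' columns.
#'
#' @param data A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(data, path) {
  write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$income[out$income == ""] <- NA
  out$income <- as.numeric(out$income)
  tibble::as_tibble(out)
}

#' Full run configuration
#'
#' Assembles the configuration of an end-to-end study replica.  Any field
#' can be overridden; the master `seed` determines every stage seed.  A
#' configuration can also be loaded from YAML or JSON with
#' [read_run_config()].
#'
#' @param generation Named list of [cohort_config()] overrides.
#' @param tasks List: `simulate` (default `FALSE`; when `TRUE` the four
#'   behavioral outcome columns are replaced by indices scored from
#'   simulated BART sessions and delay discounting choices), plus agent
#'   trait settings `target_mean`, `target_sd`, `rate_meanlog`,
#'   `rate_sdlog`, `temperature`.
#' @param sca List: `outcomes`, `covariate_pool`, `alpha`.
#' @param permutation List: `enabled`, `n_resamples`.
#' @param network List: `min_abs`.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generation = list(), tasks = list(), sca = list(),
                       permutation = list(), network = list(), seed = 1L) {
  defaults <- list(
    generation = list(),
    tasks = list(simulate = FALSE, target_mean = 8, target_sd = 2,
                 rate_meanlog = log(0.05), rate_sdlog = 0.7,
                 temperature = 0.5),
    sca = list(outcomes = outcome_labels(),
               covariate_pool = covariate_labels(), alpha = 0.05),
    permutation = list(enabled = TRUE, n_resamples = 500L),
    network = list(min_abs = 0.15),
    seed = seed
  )
  cfg <- defaults
  cfg$generation <- utils::modifyList(cfg$generation, generation)
  cfg$tasks <- utils::modifyList(cfg$tasks, tasks)
  cfg$sca <- utils::modifyList(cfg$sca, sca)
  cfg$permutation <- utils::modifyList(cfg$permutation, permutation)
  cfg$network <- utils::modifyList(cfg$network, network)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path A YAML (or JSON) file with the `run_config` fields.  Note
#'   that YAML 1.1 treats a bare `n` key as a boolean, so the cohort-size
#'   key must be written quoted (`"n": 175`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw),
                                    c("generation", "tasks", "sca",
                                      "permutation", "network", "seed"))])
}

#' Replace behavioral outcomes by simulated task indices
#'
#' Gives every participant agent traits (a BART pump target; a hyperbolic
#' discount rate), simulates a BART session and the shared 80-trial delay
#' discounting task for each, scores them, and overwrites the four
#' behavioral outcome columns (`bart_adjpumps_all`, `bart_adjpumps_linear`,
#' `bart_adjpumps_exponential`, `dd_prop_immediate`) with the scored
#' indices.  Neural outcomes are untouched.
#'
#' @param data A cohort tibble.
#' @param bart_seed,dd_seed Stage seeds (per-participant seeds are derived
#'   from them).
#' @param target_mean,target_sd Normal draw for the per-participant intended
#'   pump count, rounded and clipped to 1..15.
#' @param rate_meanlog,rate_sdlog Log-normal draw for the per-participant
#'   discount rate (per week).
#' @param temperature Softmax temperature of the choice rule.
#' @return A list: `cohort` (with replaced behavioral columns), `sessions`
#'   (all BART trials, with `participant_id`), `design` (the shared
#'   [dd_design()]), `choices` (all DD choices, with `participant_id`).
#' @export
simulate_task_outcomes <- function(data, bart_seed, dd_seed,
                                   target_mean = 8, target_sd = 2,
                                   rate_meanlog = log(0.05),
                                   rate_sdlog = 0.7, temperature = 0.5) {
  n <- nrow(data)
  traits <- withr::with_seed(bart_seed, tibble::tibble(
    target = pmin(15L, pmax(1L, as.integer(round(rnorm(n, target_mean,
                                                       target_sd))))),
    session_seed = sample.int(.Machine$integer.max - 1L, n)
  ))
  dd <- withr::with_seed(dd_seed, tibble::tibble(
    rate = rlnorm(n, rate_meanlog, rate_sdlog),
    choice_seed = sample.int(.Machine$integer.max - 1L, n)
  ))
  design <- dd_design(seed = dd_seed)

  sessions <- purrr::map(seq_len(n), function(i) {
    s <- simulate_bart(traits$target[i], seed = traits$session_seed[i])
    s$participant_id <- data$participant_id[i]
    s
  })
  choices <- purrr::map(seq_len(n), function(i) {
    ch <- simulate_dd_choices(design, discount_rate = dd$rate[i],
                              temperature = temperature,
                              seed = dd$choice_seed[i])
    ch$participant_id <- data$participant_id[i]
    ch
  })

  data$bart_adjpumps_all <- purrr::map_dbl(
    sessions, function(s) score_bart(s, "reward")$adj_avg_pumps)
  data$bart_adjpumps_linear <- purrr::map_dbl(
    sessions, function(s) score_bart(s, "linear")$adj_avg_pumps)
  data$bart_adjpumps_exponential <- purrr::map_dbl(
    sessions, function(s) score_bart(s, "exponential")$adj_avg_pumps)
  data$dd_prop_immediate <- purrr::map_dbl(
    choices, function(ch) score_dd(ch, design)$prop_immediate)

  list(cohort = data, sessions = dplyr::bind_rows(sessions),
       design = design, choices = dplyr::bind_rows(choices))
}

#' Run the end-to-end study replica
#'
#' Executes the full pipeline from one configuration: cohort generation,
#' optional task simulation and scoring, specification-curve analysis,
#' the global permutation test (unless disabled), and the correlation
#' network.  Every artifact is written under `output_dir` as CSV/JSON,
#' plus a `manifest.json` with seeds, counts and summary numbers.  The
#' manifest and summary files are byte-identical across runs with the same
#' configuration.
#'
#' @param config A [run_config()].
#' @param output_dir Writable output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  seeds <- as.list(derive_seeds(config$seed, 5L))
  names(seeds) <- c("cohort", "bart", "dd", "permutation", "network")
  write_json <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }

  message("stage cohort: generating ", config$generation$n %||% 175,
          " participants")
  gen <- config$generation
  gen$seed <- seeds$cohort
  cohort <- generate_cohort(do.call(cohort_config, gen))

  files <- list(cohort = "cohort.csv")
  if (isTRUE(config$tasks$simulate)) {
    message("stage tasks: simulating BART sessions and DD choices")
    sim <- simulate_task_outcomes(
      cohort, bart_seed = seeds$bart, dd_seed = seeds$dd,
      target_mean = config$tasks$target_mean,
      target_sd = config$tasks$target_sd,
      rate_meanlog = config$tasks$rate_meanlog,
      rate_sdlog = config$tasks$rate_sdlog,
      temperature = config$tasks$temperature
    )
    cohort <- sim$cohort
    write.csv(sim$sessions, p("bart_sessions.csv"), row.names = FALSE)
    write.csv(sim$design, p("dd_design.csv"), row.names = FALSE)
    write.csv(sim$choices, p("dd_choices.csv"), row.names = FALSE)
    files <- c(files, list(bart_sessions = "bart_sessions.csv",
                           dd_design = "dd_design.csv",
                           dd_choices = "dd_choices.csv"))
  }
  write_cohort(cohort, p("cohort.csv"))

  message("stage sca: fitting ",
          length(config$sca$outcomes) * 2^length(config$sca$covariate_pool),
          " specifications")
  curve <- run_sca(cohort, outcomes = config$sca$outcomes,
                   covariate_pool = config$sca$covariate_pool,
                   alpha = config$sca$alpha)
  specs_out <- dplyr::select(curve$fits, -"covariates")
  write.csv(specs_out, p("specs.csv"), row.names = FALSE)
  write_json(as.list(glance(curve)), p("sca_summary.json"))
  files <- c(files, list(specs = "specs.csv", sca_summary = "sca_summary.json"))

  perm <- NULL
  if (isTRUE(config$permutation$enabled)) {
    message("stage permutation: ", config$permutation$n_resamples,
            " resampled datasets")
    perm <- global_test(cohort, outcomes = config$sca$outcomes,
                        covariate_pool = config$sca$covariate_pool,
                        alpha = config$sca$alpha,
                        n_resamples = config$permutation$n_resamples,
                        seed = seeds$permutation)
    write.csv(tidy(perm), p("perm_null.csv"), row.names = FALSE)
    write_json(as.list(glance(perm)), p("perm_result.json"))
    files <- c(files, list(perm_null = "perm_null.csv",
                           perm_result = "perm_result.json"))
  }

  message("stage network: pairwise correlations and edges")
  cm <- cor_matrix(cohort)
  edges <- network_edges(cm, min_abs = config$network$min_abs)
  write.csv(as.data.frame(cm$r), p("corr_matrix.csv"))
  write.csv(edges, p("edges.csv"), row.names = FALSE)
  files <- c(files, list(corr_matrix = "corr_matrix.csv", edges = "edges.csv"))

  manifest <- list(
    package = "agespec",
    version = as.character(utils::packageVersion("agespec")),
    master_seed = config$seed,
    stage_seeds = seeds,
    n_participants = nrow(cohort),
    n_specifications = curve$n_specifications,
    n_positive = curve$n_positive,
    n_negative = curve$n_negative,
    n_null = curve$n_null,
    median_beta = curve$median_beta,
    p_global = if (!is.null(perm)) perm$p_global else NULL,
    n_edges = nrow(edges),
    files = files
  )
  write_json(manifest, p("manifest.json"))
  invisible(manifest)
}
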