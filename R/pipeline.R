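# End-to-end workflow: simulate/load -> rank features -> learn structure ->
# learn parameters -> anomaly screen -> scenario and pathway queries. Every
# stage writes a delimited-text report into the run directory and the run
# manifest records config, seed and output checksums so a run can be
# reproduced exactly from the manifest alone.

#' Pipeline configuration
#'
#' @param out_dir Output directory for the run.
#' @param input Path to a panel CSV, or `NULL` to simulate.
#' @param network Path to a network JSON declaring the roster when `input`
#'   is given (its arcs are ignored for learning).
#' @param synthetic A [cohort_config()] used when `input` is `NULL`.
#' @param target Target variable; `normal_state` its healthy state.
#' @param alpha,max_cond PC test level and conditioning-set cap.
#' @param pseudocount Dirichlet pseudocount for parameter learning.
#' @param em_max_iter,em_tol,em_restarts EM controls.
#' @param constraints A [dbn_constraints()], a constraint file path, or `NULL`.
#' @param scenarios Subset of `c("best", "worst")`.
#' @param pathway Variable chain for the pathway-strength report (rows are
#'   `NA` for arcs the learned structure lacks).
#' @param flag_quantile Anomaly flagging quantile.
#' @param seed Root seed; stage substreams derive from it.
#' @param normal_state Healthy target state label.
#' @param verbose Log stage progress?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL, network = NULL,
                            synthetic = cohort_config(), target = "CNS",
                            normal_state = "N", alpha = 0.01, max_cond = 2L,
                            pseudocount = 1, em_max_iter = 10L, em_tol = 1e-3,
                            em_restarts = 0L, constraints = NULL,
                            scenarios = c("best", "worst"),
                            pathway = c("PS", "WQ", "CNS"),
                            flag_quantile = 0.05, seed = 1L, verbose = TRUE) {
  structure(list(out_dir = out_dir, input = input, network = network,
                 synthetic = synthetic, target = target,
                 normal_state = normal_state, alpha = alpha,
                 max_cond = as.integer(max_cond), pseudocount = pseudocount,
                 em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 em_restarts = as.integer(em_restarts),
                 constraints = constraints, scenarios = scenarios,
                 pathway = pathway, flag_quantile = flag_quantile,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

pipeline_stop <- function(stage, code, message) {
  stop(structure(class = c("dbn_pipeline_error", "error", "condition"),
                 list(message = sprintf("[stage %s] [%s] %s", stage, code, message),
                      stage = stage, code = code, call = NULL)))
}

# default causal tiers of the cohort roster: interventions upstream of
# household conditions, upstream of parental covariates, upstream of
# child-level outcomes
cohort_tiers <- function() {
  c(CNS = 1L, CA = 1L, CS = 1L,
    MSW = 2L, DA = 2L, DE = 2L, MA = 2L, ME = 2L,
    HS = 3L, WQ = 3L, FS = 3L, HHA = 3L, HHS = 3L,
    PS = 4L)
}

#' Run the full analysis pipeline
#'
#' Stages: data (simulate or load), feature ranking, PC structure learning,
#' EM parameter learning, anomaly screening, best-/worst-case scenarios and
#' pathway strengths. Produces `manifest.json` plus seven delimited-text /
#' JSON outputs in `config$out_dir`; any stage failure aborts with the
#' stage name and a machine-readable code, leaving a `FAILED` marker.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (config$verbose) message("[dbnpanel] ", ...)
  stage_info <- list()
  run_stage <- function(stage, code, expr) {
    log_msg("stage ", stage, ": start")
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", stage, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      if (inherits(e, "dbn_pipeline_error")) stop(e)
      pipeline_stop(stage, code, conditionMessage(e))
    })
    stage_info[[stage]] <<- list(seconds = as.numeric(Sys.time() - st, units = "secs"))
    log_msg("stage ", stage, ": done")
    out
  }
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    outputs <<- c(outputs, name)
    path
  }

  # ---- data ----
  dat <- run_stage("data", "E_DATA", {
    if (is.null(config$input)) {
      cfg <- config$synthetic
      cfg$seed <- derive_seed(config$seed, "simulate")
      bundle <- sample_cohort(cfg)
      list(data = bundle$data, roster = bundle$network$structure, bundle = bundle)
    } else {
      if (is.null(config$network))
        pipeline_stop("data", "E_DATA", "input panels need a roster network file")
      net <- read_dbn(config$network)
      list(data = read_panel(config$input, net$structure), roster = net$structure,
           bundle = NULL)
    }
  })
  roster <- dat$roster
  stage_info$data$n_subjects <- length(panel_subjects(dat$data))

  # ---- feature ranking ----
  ranking <- run_stage("rank", "E_RANK", {
    cands <- setdiff(names(roster$variables), config$target)
    rank_features(dat$data, cands, config$target)
  })
  emit("feature_ranking.csv", function(p) write_ranking(ranking, p))

  # ---- structure learning ----
  constraints <- run_stage("structure", "E_CONSTRAINTS", {
    cn <- config$constraints
    if (is.character(cn)) cn <- read_constraints(cn)
    if (is.null(cn)) cn <- dbn_constraints()
    if (!inherits(cn, "dbn_constraints"))
      cn <- dbn_constraints(forbidden = cn$forbidden, required = cn$required)
    cn
  })
  pdag <- run_stage("structure", "E_STRUCTURE", {
    tiers <- cohort_tiers()
    tiers <- tiers[names(tiers) %in% names(roster$variables)]
    pc_learn(dat$data, roster, max_lag = 2L, constraints = constraints,
             alpha = config$alpha, max_cond = config$max_cond, tiers = tiers)
  })
  emit("ci_tests.csv", function(p) write_ci_log(pdag, p))
  learned <- pdag_to_structure(pdag, roster)
  stage_info$structure$n_arcs <- nrow(learned$arcs)
  stage_info$structure$n_tests <- nrow(pdag$tests)

  # ---- parameter learning ----
  fit <- run_stage("parameters", "E_PARAMS", {
    with_seed_(derive_seed(config$seed, "em"), {
      fit_em(learned, dat$data, pseudocount = config$pseudocount,
             max_iter = config$em_max_iter, tol = config$em_tol,
             restarts = config$em_restarts, verbose = FALSE)
    })
  })
  emit("network.json", function(p) write_dbn(fit$network, p))
  emit("network.dot", function(p) dbn_to_dot(fit$network, p))
  emit("learning_report.csv", function(p) {
    utils::write.csv(data.frame(iteration = seq_along(fit$objective_trace),
                                objective = fit$objective_trace,
                                loglik = fit$loglik_trace), p, row.names = FALSE)
  })
  stage_info$parameters$loglik <- fit$loglik
  stage_info$parameters$iterations <- fit$iterations

  # ---- anomaly screening ----
  ground <- unroll(fit$network)
  anomalies <- run_stage("anomaly", "E_ANOMALY", {
    anomaly_scores(ground, dat$data, config$flag_quantile)
  })
  emit("anomaly_scores.csv", function(p) utils::write.csv(anomalies, p, row.names = FALSE))

  # ---- scenarios ----
  report_nodes <- setdiff(names(roster$variables), config$target)
  for (sc in config$scenarios) {
    res <- run_stage(paste0("scenario_", sc), "E_SCENARIO", {
      scenario_analysis(fit$network, config$target, sc, report_nodes,
                        normal_state = config$normal_state)
    })
    emit(paste0("scenario_", sc, ".csv"),
         function(p) utils::write.csv(res$table, p, row.names = FALSE))
  }

  # ---- pathway strengths ----
  pw <- run_stage("pathway", "E_PATHWAY", {
    pairs_ok <- vapply(seq_len(length(config$pathway) - 1L), function(i) {
      any(learned$arcs$parent == config$pathway[i] &
            learned$arcs$child == config$pathway[i + 1L])
    }, logical(1))
    if (all(pairs_ok)) {
      pathway_strength(fit$network, config$pathway)
    } else {
      data.frame(parent = config$pathway[-length(config$pathway)],
                 child = config$pathway[-1L], lag = NA_integer_,
                 wave = NA_integer_, parent_map_state = NA_character_,
                 strength = NA_real_,
                 note = ifelse(pairs_ok, "arc present; skipped (broken chain)",
                               "arc not in learned structure"))
    }
  })
  emit("pathway_strength.csv", function(p) utils::write.csv(pw, p, row.names = FALSE))

  # ---- manifest ----
  manifest <- list(
    package = "dbnpanel",
    version = as.character(utils::packageVersion("dbnpanel")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = serialize_config(config),
    stages = stage_info,
    outputs = lapply(stats::setNames(outputs, outputs), function(f)
      list(md5 = unname(tools::md5sum(file.path(config$out_dir, f))))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("pipeline complete: ", length(outputs), " outputs in ", config$out_dir)
  invisible(manifest)
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$synthetic <- unclass(cfg$synthetic)
  if (inherits(cfg$constraints, "dbn_constraints"))
    cfg$constraints <- unclass(cfg$constraints)
  cfg$verbose <- NULL
  cfg$out_dir <- NULL
  cfg[!vapply(cfg, is.null, logical(1))]
}

null_if_empty <- function(x) if (is.null(x) || length(x) == 0L) NULL else x

#' Re-run a pipeline from its manifest
#'
#' Rebuilds the configuration recorded in `manifest.json` and executes the
#' pipeline into `out_dir`; with the recorded seed the outputs reproduce the
#' original run exactly.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Output directory for the re-run.
#' @return Invisibly, the new manifest.
#' @export
run_pipeline_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- m$config
  syn <- do.call(cohort_config, cfg$synthetic[c("n_subjects", "effect_strength",
                                                "missing_mechanism", "missing_rate",
                                                "seed")])
  cons <- NULL
  if (!is.null(cfg$constraints) && length(cfg$constraints) > 0L)
    cons <- dbn_constraints(forbidden = as.data.frame(cfg$constraints$forbidden),
                            required = as.data.frame(cfg$constraints$required))
  config <- pipeline_config(
    out_dir = out_dir, input = null_if_empty(cfg$input),
    network = null_if_empty(cfg$network), synthetic = syn,
    target = cfg$target, normal_state = cfg$normal_state, alpha = cfg$alpha,
    max_cond = cfg$max_cond, pseudocount = cfg$pseudocount,
    em_max_iter = cfg$em_max_iter, em_tol = cfg$em_tol,
    em_restarts = cfg$em_restarts, constraints = cons,
    scenarios = unlist(cfg$scenarios), pathway = unlist(cfg$pathway),
    flag_quantile = cfg$flag_quantile, seed = m$seed, verbose = FALSE)
  run_pipeline(config)
}
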