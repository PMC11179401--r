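#' End-to-end emulation pipeline
#'
#' simulate (optional) -> attrition -> match + weight -> outcomes ->
#' compare, deterministic under a fixed seed, with every stage's product
#' written as CSV and a JSON run manifest.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param sim Either a [sim_config()] (synthesize the registry) or NULL
#'   when `registry_dir` points at data on disk.
#' @param registry_dir,trial_path Input locations when not simulating.
#' @param trial_arms Named arm sizes to synthesize when `trial_path` is
#'   NULL (defaults: 301 ranibizumab monthly, 286 bevacizumab monthly).
#' @param criteria A [criterion_config()].
#' @param rules A [match_rules()].
#' @param schedule A [cost_schedule()].
#' @param method t-test variant, `"pooled"` or `"welch"`.
#' @param enrollment_window Length-2 Date vector bounding index dates;
#'   defaults to the simulation's date window, or (for registries loaded
#'   from disk) the observed study-drug injection range.
#' @param run_weights Set FALSE to skip the IPSW stage.
#' @param seed Master seed for the simulate stage.
#' @param out_dir Output directory (created if missing).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            registry_dir = NULL, trial_path = NULL,
                            trial_arms = c(ranibizumab_monthly = 301,
                                           bevacizumab_monthly = 286),
                            criteria = criterion_config(),
                            rules = match_rules(),
                            schedule = cost_schedule(),
                            method = "pooled",
                            enrollment_window = NULL,
                            run_weights = TRUE,
                            seed = 1L, out_dir = NULL) {
  if (is.null(enrollment_window) && !is.null(sim)) {
    enrollment_window <- c(sim$date_start, sim$date_end)
  }
  structure(list(sim = sim, registry_dir = registry_dir,
                 trial_path = trial_path, trial_arms = trial_arms,
                 criteria = criteria, rules = rules, schedule = schedule,
                 method = method, enrollment_window = enrollment_window,
                 run_weights = run_weights,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `out_dir`, `registry_dir`,
#' `trial_path`, `method`, `run_weights`, plus nested `sim`, `criteria`,
#' `rules`, and `costs` blocks whose entries override the corresponding
#' constructor defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$registry_dir)) NULL else {
    do.call(sim_config, c(y$sim %||% list(),
                          if (!is.null(y$seed) && is.null(y$sim$seed))
                            list(seed = y$seed)))
  }
  pipeline_config(
    sim = sim,
    registry_dir = y$registry_dir, trial_path = y$trial_path,
    trial_arms = unlist(y$trial_arms %||%
                          c(ranibizumab_monthly = 301,
                            bevacizumab_monthly = 286)),
    criteria = do.call(criterion_config, y$criteria %||% list()),
    rules = do.call(match_rules, y$rules %||% list()),
    schedule = cost_schedule(unlist(y$costs %||%
                                      c(ranibizumab = 2000,
                                        bevacizumab = 50))),
    method = y$method %||% "pooled",
    enrollment_window = if (!is.null(y$enrollment_window))
      as.Date(unlist(y$enrollment_window)),
    run_weights = y$run_weights %||% TRUE,
    seed = y$seed %||% 1L, out_dir = y$out_dir
  )
}

drug_of_arm <- function(arm) {
  if (grepl("ranibizumab", arm)) "ranibizumab" else "bevacizumab"
}

#' Run the full emulation pipeline
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return List of class `pipeline_result`: `registry`, `ground_truth`,
#'   `trial`, `attrition`, `cohorts`, per-drug `matches`, `weights`,
#'   `balance`, the `outcomes` table (one row per arm x method), the
#'   `comparisons` table, and the run `manifest`. When `config$out_dir` is
#'   set the tables are also written as CSV plus `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  warnings_log <- character()

  # --- simulate / load -------------------------------------------------
  gt <- NULL
  if (!is.null(config$registry_dir)) {
    registry <- stage("load", load_registry(config$registry_dir,
                                            config$criteria))
    say("load: registry from %s", config$registry_dir)
  } else {
    simr <- stage("simulate", generate_registry(config$sim))
    registry <- simr$registry
    gt <- simr$ground_truth
    say("simulate: %d patients, %d injection records",
        nrow(registry$patients), nrow(registry$injections))
  }
  trial <- if (!is.null(config$trial_path)) {
    stage("load", load_trial(config$trial_path))
  } else {
    do.call(rbind, lapply(names(config$trial_arms), function(arm) {
      generate_trial_arm(arm, config$trial_arms[[arm]],
                         seed = config$seed)
    }))
  }

  # --- attrition -------------------------------------------------------
  att <- stage("attrition", run_attrition(registry, config$criteria,
                                          window = config$enrollment_window))
  for (i in seq_len(nrow(att$attrition))) {
    say("attrition: %-55s %6d eyes", att$attrition$label[i],
        att$attrition$eyes[i])
  }

  drugs <- intersect(c("ranibizumab", "bevacizumab"),
                     unique(att$cohorts$drug))
  trial_by_drug <- split(trial, vapply(trial$arm, drug_of_arm, ""))

  matches <- list(); weights <- list(); balance <- list()
  summaries <- list(); outcome_rows <- list(); comp_inputs <- list()

  for (dr in drugs) {
    eyes <- att$cohorts[att$cohorts$drug == dr, , drop = FALSE]
    tr <- trial_by_drug[[dr]]
    if (is.null(tr) || nrow(eyes) == 0) next

    # --- matching ------------------------------------------------------
    ms <- stage("match", match_max_cardinality(tr, eyes, config$rules))
    matches[[dr]] <- ms
    say("match [%s]: %d/%d participants matched (%d%%)", dr,
        nrow(ms$pairs), nrow(tr), match_rate(ms, nrow(tr)))
    em_eyes <- eyes[match(eye_key(ms$pairs$patient_id,
                                  ms$pairs$laterality),
                          eye_key(eyes$patient_id, eyes$laterality)), ,
                    drop = FALSE]

    # --- weighting -----------------------------------------------------
    ws <- NULL
    if (isTRUE(config$run_weights)) {
      ws <- stage("weight", {
        fit <- fit_propensity(tr, eyes)
        withCallingHandlers(
          att_weights(fit, eyes),
          warning = function(w) {
            warnings_log <<- c(warnings_log, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      })
      weights[[dr]] <- ws
      balance[[dr]] <- balance_report(tr, eyes, ws)
      say("weight [%s]: sum(w) = %.1f, effective n = %.1f", dr,
          sum(ws$weights), effective_n(ws$weights))
    }

    # --- outcomes ------------------------------------------------------
    s_trial <- summarize_trial_arm(tr, schedule = config$schedule)
    s_em <- summarize_cohort(em_eyes, paste0(dr, "_prn_em"),
                             schedule = config$schedule)
    outcome_rows <- c(outcome_rows, list(cbind(method = "trial", s_trial),
                                         cbind(method = "em", s_em)))
    summaries[[paste0(dr, "_trial")]] <- change_stat(s_trial)
    summaries[[paste0(dr, "_em")]] <- change_stat(s_em)
    if (!is.null(ws)) {
      s_ipsw <- summarize_cohort(eyes, paste0(dr, "_prn_ipsw"),
                                 weights = ws,
                                 schedule = config$schedule)
      outcome_rows <- c(outcome_rows, list(cbind(method = "ipsw", s_ipsw)))
      summaries[[paste0(dr, "_ipsw")]] <- change_stat(s_ipsw)
      comp_inputs[[length(comp_inputs) + 1]] <-
        data.frame(a = paste0(dr, "_em"), b = paste0(dr, "_ipsw"))
      comp_inputs[[length(comp_inputs) + 1]] <-
        data.frame(a = paste0(dr, "_trial"), b = paste0(dr, "_ipsw"))
    }
    comp_inputs[[length(comp_inputs) + 1]] <-
      data.frame(a = paste0(dr, "_trial"), b = paste0(dr, "_em"))
  }

  outcomes <- do.call(rbind, outcome_rows)
  rownames(outcomes) <- NULL
  comparisons <- stage("compare", comparison_table(
    summaries, do.call(rbind, comp_inputs), method = config$method))

  manifest <- list(
    package_version = as.character(utils::packageVersion("trialemulate")),
    seed = config$seed,
    config_hash = sprintf("%08x", substream_seed(
      0L, jsonlite::toJSON(config[c("trial_arms", "method", "seed")],
                           auto_unbox = TRUE, force = TRUE))),
    row_counts = list(
      candidates = att$attrition$eyes[1],
      eligible = nrow(att$cohorts),
      matched = vapply(matches, function(m) nrow(m$pairs), integer(1)),
      outcomes = nrow(outcomes),
      comparisons = nrow(comparisons)
    ),
    warnings = warnings_log
  )

  result <- structure(list(
    registry = registry, ground_truth = gt, trial = trial,
    attrition = att$attrition, cohorts = att$cohorts,
    verdicts = att$verdicts,
    matches = matches, weights = weights, balance = balance,
    outcomes = outcomes, comparisons = comparisons, manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir)
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  }
  wr(result$attrition, "attrition.csv")
  wr(result$cohorts, "cohorts.csv")
  for (dr in names(result$matches)) {
    wr(result$matches[[dr]]$pairs, sprintf("pairs_%s.csv", dr))
  }
  for (dr in names(result$weights)) {
    w <- result$weights[[dr]]$weights
    wr(data.frame(eye_id = names(w), weight = unname(w)),
       sprintf("weights_%s.csv", dr))
    wr(result$balance[[dr]], sprintf("balance_%s.csv", dr))
  }
  wr(result$outcomes, "outcomes.csv")
  wr(result$comparisons, "comparisons.csv")
  # manifest last, written atomically via rename
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(result$manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Render the attrition table as aligned text
#'
#' @param attrition The attrition data.frame from [run_attrition()].
#' @return Character vector of lines, invisibly printed with `cat`-style
#'   alignment.
#' @export
render_attrition_text <- function(attrition) {
  lines <- c(sprintf("%-62s %9s %9s %7s", "Selection criteria", "Patients",
                     "Eyes", "% Eyes"),
             sprintf("%-62s %9d %9d %6.1f%%", attrition$label,
                     attrition$patients, attrition$eyes,
                     attrition$pct_eyes))
  structure(lines, class = "text_report")
}

#' Render the outcome table as aligned text
#'
#' Display rounding (letters to one decimal, adverse-event percentages to
#' two) happens here and only here; the underlying CSV keeps full
#' precision.
#'
#' @param outcomes The outcomes data.frame from [run_pipeline()].
#' @export
render_outcomes_text <- function(outcomes) {
  lines <- c(
    sprintf("%-28s %8s %8s %8s %8s %8s %10s %8s",
            "Arm", "N", "dVA", "%+15", "%-15", "Inj", "Cost", "AE%"),
    sprintf("%-28s %8.1f %8.1f %8.1f %8.1f %8.1f %10.2f %8.2f",
            paste(outcomes$arm, outcomes$method, sep = "/"), outcomes$n,
            outcomes$mean_change_letters, outcomes$pct_gain15,
            outcomes$pct_loss15, outcomes$mean_injections,
            outcomes$cost_per_patient, outcomes$endophthalmitis_pct))
  structure(lines, class = "text_report")
}

#' @export
print.text_report <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}
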