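# End-to-end orchestration: simulate -> (symmetry | couple | dimer |
# trajectory | power) -> machine-readable report. All randomness is routed
# through the config seed so a report is fully determined by config + seed.

pipeline_stages <- c("simulate", "symmetry", "couple", "dimer", "trajectory",
                     "power")

#' Read / write a flat key-value configuration file
#'
#' YAML-style flat mappings; round-trippable. Nested keys are allowed for
#' grouped generator and phantom parameters.
#'
#' @param path File path.
#' @return `read_config`: a named list. `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping", call. = FALSE)
  cfg
}

#' @rdname read_config
#' @param config Named list to serialise.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full rotational-state analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic ensemble:
#' `simulate` builds the particle table (and is required by `couple`,
#' `dimer` and `trajectory`); `symmetry` builds a c-ring phantom and infers
#' its symmetry order; `power` runs the detection-power analysis. A failing
#' stage is recorded in the report and its dependents are skipped.
#'
#' Recognised config keys: `stages` (subset of simulate, symmetry, couple,
#' dimer, trajectory, power), `seed`, `n_dimers`, `n_perm`, `generator` (arguments
#' of [generator_config()]), `phantom` (arguments of [make_cring_phantom()]),
#' `power_a` (amplitude grid), `power_reps`.
#'
#' @param config Named list or path to a YAML config file.
#' @param seed Seed used when the config supplies none.
#' @return A list of class `analysis_report` (JSON-serialisable).
#' @export
run_pipeline <- function(config = list(), seed = 1) {
  if (is.character(config)) config <- read_config(config)
  if (!is.list(config)) stop("`config` must be a list or a file path", call. = FALSE)
  known <- c("stages", "seed", "n_dimers", "n_perm", "generator", "phantom",
             "power_a", "power_reps")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stages <- config$stages %||% c("simulate", "symmetry", "couple", "dimer",
                                 "trajectory")
  bad_stage <- setdiff(stages, pipeline_stages)
  if (length(bad_stage)) {
    stop("unknown stage name(s): ", paste(bad_stage, collapse = ", "), call. = FALSE)
  }
  seed <- as.integer(config$seed %||% seed)
  cfg <- do.call(generator_config, c(config$generator %||% list(),
                                     list(seed = seed)))
  report <- list(
    config = config,
    seed = seed,
    version = as.character(utils::packageVersion("rotastat")),
    stages = list()
  )
  tab <- NULL
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) list(error = conditionMessage(e)))
  }

  if ("simulate" %in% stages) {
    report$stages$simulate <- run_stage("simulate", function() {
      n_dimers <- config$n_dimers %||% 11315L
      tab <<- make_particle_table(n_dimers, cfg, seed = seed)
      q <- stats::quantile(tab$theta_f1, c(0.025, 0.975), names = FALSE)
      list(n_particles = nrow(tab),
           n_dimers = n_dimers,
           f1_central95 = q,
           f1_half_width_deg = mean(abs(q)),
           stalk_modes_deg = find_angle_modes(tab$theta_stalk))
    })
  }

  if ("symmetry" %in% stages) {
    report$stages$symmetry <- run_stage("symmetry", function() {
      ph_args <- config$phantom %||% list(noise_sd = 0.05)
      ph <- do.call(make_cring_phantom, c(ph_args, list(seed = seed)))
      m <- ring_mask(radius = ph_args$radius %||% 30,
                     blob_sd = ph_args$blob_sd %||% 4)
      scan <- symmetry_order_scan(ph, mask = m)
      curve <- self_rotation_curve(ph, mask = m)
      inf <- infer_order(scan, curve)
      list(scan_scores = scan$scores, inferred_order = inf$order,
           scan_order = inf$scan_order, minima_count = inf$minima_count,
           spacing_cv = inf$spacing_cv, agreement = inf$agreement)
    })
  }

  needs_tab <- function(name, fun) {
    if (is.null(tab)) {
      list(skipped = "requires the simulate stage")
    } else {
      run_stage(name, fun)
    }
  }

  if ("couple" %in% stages) {
    report$stages$couple <- needs_tab("couple", function() {
      res <- coupling_test(tab, n_perm = config$n_perm %||% 999,
                           seed = seed + 1L)
      list(bin_n = res$bin_n, bin_p = res$bin_p,
           sinusoid_a = res$sinusoid$a, sinusoid_b = res$sinusoid$b,
           permutation_p = res$sinusoid$permutation_p,
           decision = res$decision)
    })
  }

  if ("dimer" %in% stages) {
    report$stages$dimer <- needs_tab("dimer", function() {
      res <- intradimer_tests(tab)
      list(f1_sign_p = res$f1_sign_p,
           stalk_mode_pairwise_p = as.list(res$stalk_mode_pairwise_p),
           n_dimers = res$n_dimers, n_excluded = res$n_excluded)
    })
  }

  if ("trajectory" %in% stages) {
    report$stages$trajectory <- needs_tab("trajectory", function() {
      res <- trajectory_bin_stats(tab)
      list(full_span_disp_A = unname(res$full_span["disp_A"]),
           full_span_f1_deg = unname(res$full_span["f1_deg"]),
           middle95_span_disp_A = unname(res$middle95_span["disp_A"]),
           middle95_span_f1_deg = unname(res$middle95_span["f1_deg"]))
    })
  }

  if ("power" %in% stages) {
    report$stages$power <- run_stage("power", function() {
      pw <- detection_power(config$power_a %||% c(0, 20, 30),
                            reps = config$power_reps %||% 200,
                            seed = seed + 2L)
      list(a = pw$a, power = pw$power)
    })
  }

  structure(report, class = "analysis_report")
}

#' Write an analysis report as JSON
#'
#' @param report A [run_pipeline()] result (or any JSON-serialisable list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
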