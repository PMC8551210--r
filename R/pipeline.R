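#' Configure a full pipeline run
#'
#' Exactly one of `scenario` (a [scenario_config()] for simulation) or
#' `input_dir` (a directory in the [write_scenario()] dialect) must be given.
#'
#' @param scenario a [scenario_config()] to simulate inputs, or `NULL`.
#' @param input_dir directory of input tables, or `NULL`.
#' @param t0 baseline window index.
#' @param t_L first lockdown window; `t_R` first post-lockdown window.
#' @param t_R see `t_L`.
#' @param K_list tail percentages for class extraction.
#' @param efficiency_variant `"norm"` or `"raw"` nodal efficiency for the
#'   disruption series.
#' @param do_segregation run clustering/classification/group tests.
#' @param do_regression run the quantile regression stage.
#' @param taus quantile levels for the regression stage.
#' @param bootstrap_reps wild-bootstrap replications (0 disables).
#' @param seed global seed for the stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, input_dir = NULL,
                       t0 = 0L, t_L = 1L, t_R = 5L,
                       K_list = c(10, 20, 30),
                       efficiency_variant = c("norm", "raw"),
                       do_segregation = TRUE, do_regression = TRUE,
                       taus = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
                       bootstrap_reps = 0L, seed = 1L) {
  if (is.null(scenario) == is.null(input_dir)) {
    stop_config("exactly one of `scenario` and `input_dir` must be set")
  }
  structure(list(scenario = scenario, input_dir = input_dir,
                 t0 = as.integer(t0), t_L = as.integer(t_L),
                 t_R = as.integer(t_R), K_list = K_list,
                 efficiency_variant = match.arg(efficiency_variant),
                 do_segregation = isTRUE(do_segregation),
                 do_regression = isTRUE(do_regression),
                 taus = taus, bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full disruption-and-segregation analysis
#'
#' Orchestrates all stages: simulate (or load) the inputs, build per-window
#' networks, compute efficiency, derive disruption indicators and class
#' labels, assemble the socioeconomic features, run the segregation analyses
#' and the quantile regressions. Every stage writes plain CSV outputs into
#' `out_dir` and the run ends with a `manifest.json` recording files, seeds
#' and per-stage timings.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, files = list(), timings = list())
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(dt, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    data.table::fwrite(dt, path)
    manifest$files[[name]] <<- basename(path)
    path
  }

  ## stage: inputs ----------------------------------------------------------
  scen <- tick("inputs", {
    if (!is.null(config$scenario)) {
      generate_scenario(config$scenario)
    } else {
      read_scenario(config$input_dir)
    }
  })
  grid <- window_grid(scen$config$start_date, scen$config$n_windows,
                      scen$config$window_length_days)

  ## stage: networks --------------------------------------------------------
  nets <- tick("networks", build_networks(scen$od_records, grid, scen$tile_map))
  edges_all <- data.table::rbindlist(lapply(nets, function(nw) {
    if (nrow(nw$edges) == 0) return(NULL)
    cbind(window = nw$window_index, nw$edges)
  }))
  emit(edges_all, "networks")
  emit(data.table::rbindlist(lapply(nets, function(nw) {
    cbind(window = nw$window_index, degree_strength(nw))
  })), "centralities")

  ## stage: efficiency ------------------------------------------------------
  eff <- tick("efficiency", efficiency_series(nets))
  emit(eff$nodal, "efficiency")
  emit(eff$global, "efficiency_global")

  ## stage: indicators ------------------------------------------------------
  ind <- tick("indicators", {
    series <- relative_variation(eff$nodal, t0 = config$t0,
                                 variant = config$efficiency_variant)
    indicators <- compute_indicators(series, t_L = config$t_L, t_R = config$t_R)
    classes <- data.table::rbindlist(lapply(config$K_list, function(K) {
      data.table::rbindlist(lapply(c("lockdown", "recovery"), function(ic) {
        cl <- extract_classes(indicators, K = K, indicator_col = ic)
        cbind(cl, K = K, indicator_used = ic)
      }))
    }))
    list(series = series, indicators = indicators, classes = classes)
  })
  delta_long <- data.table::as.data.table(as.table(ind$series$delta))
  data.table::setnames(delta_long, c("llm_id", "window", "delta_e"))
  emit(delta_long, "disruption")
  emit(ind$indicators, "indicators")
  emit(ind$classes, "classes")
  K_main <- max(config$K_list)
  labels_main <- ind$classes[K == K_main & indicator_used == "lockdown",
                             c("llm_id", "label"), with = FALSE]
  emit(class_recovery_curves(ind$series, labels_main), "class_curves")

  ## stage: features --------------------------------------------------------
  feats <- tick("features", {
    ft <- assemble_features(scen)
    list(raw = ft, std = standardize_features(ft))
  })
  emit(feats$raw, "features")
  emit(feats$std$std, "features_std")
  jsonlite::write_json(list(feature_cols = attr(feats$raw, "feature_cols"),
                            sectors = attr(feats$raw, "sectors")),
                       file.path(out_dir, "features_schema.json"),
                       auto_unbox = FALSE)
  manifest$files[["features_schema"]] <- "features_schema.json"

  ## stage: segregation -----------------------------------------------------
  seg <- NULL
  if (config$do_segregation) {
    seg <- tick("segregation", {
      pc <- hierarchical_purity(feats$std$std, labels_main)
      cv <- classify_classes(feats$std$std, labels_main, seed = config$seed)
      gt <- group_tests(feats$raw, labels_main)
      list(purity = pc, cv = cv, tests = gt)
    })
    emit(seg$purity$curve, "purity_curve")
    emit(seg$cv$folds, "cv_report")
    emit(seg$tests, "group_tests")
  }

  ## stage: regression ------------------------------------------------------
  reg <- NULL
  if (config$do_regression) {
    reg <- tick("regression", {
      lapply(stats::setNames(c("lockdown", "recovery"),
                             c("lockdown", "recovery")), function(ic) {
        des <- build_design(feats$std$std, ind$indicators, indicator_col = ic)
        qf <- fit_quantile(des, taus = config$taus)
        if (config$bootstrap_reps > 0) {
          qf <- wild_bootstrap_se(qf, n_reps = config$bootstrap_reps,
                                  seed = config$seed)
        }
        list(fit = qf, ols = fit_ols_reference(des))
      })
    })
    for (ic in names(reg)) {
      emit(tidy_quantile_fit(reg[[ic]]$fit), paste0("quantile_fit_", ic))
      emit(reg[[ic]]$ols, paste0("ols_", ic))
    }
  }

  path_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path_manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(scenario = scen, networks = nets, efficiency = eff,
                 indicators = ind, features = feats, segregation = seg,
                 regression = reg, manifest = manifest))
}
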