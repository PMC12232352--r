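#' Run the full simulation pipeline
#'
#' Orchestrates the stages end to end: generate the synthetic cohort,
#' simulate treatment pathways, assess calibration on a hold-out split,
#' run the three counterfactual second-line scenarios, and write contrast
#' tables, with every output plus a reproduction manifest written under
#' `out_dir`.  Per-stage progress is logged to `stderr`.
#'
#' @param config a named list (or path to a YAML file) with any of:
#'   `n` (cohort size, default 2000), `seed` (master seed, default 1),
#'   `out_dir` (output directory, required), `horizons` (reporting
#'   horizons in years, default 5), `subgroups` (`"overall"` and/or
#'   `"cvd"`, `"no_cvd"`), `holdout_fraction` (default 0.3),
#'   `cohort_spec`, `transition_spec`, `effects`, `risk_equations`,
#'   `event_models` (paths to config files; package defaults when absent),
#'   and `quiet`.
#' @return invisibly, a list with the stage objects and output paths.
#'   Outputs: `cohort.csv` (+ spec sidecar), `timelines.csv`,
#'   `calibration_report.csv` / `calibration_summary.json`,
#'   `arm_summaries.csv`, `contrasts.csv`, `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    n = 2000L, seed = 1L, horizons = 5, subgroups = "overall",
    holdout_fraction = 0.3, quiet = FALSE), config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required", call. = FALSE)
  if (any(cfg$horizons * 4 > max_quarters() - 1L)) {
    stop("horizons must lie within the 7.6-year horizon", call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!isTRUE(cfg$quiet)) {
    message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(name, " done in ",
        sprintf("%.1fs", as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  paths <- list()

  cspec <- if (!is.null(cfg$cohort_spec)) read_cohort_spec(cfg$cohort_spec)
           else default_cohort_spec(cfg$n)
  tspec <- if (!is.null(cfg$transition_spec))
             read_transition_spec(cfg$transition_spec)
           else default_transition_spec()
  registry <- if (!is.null(cfg$effects)) load_effects(cfg$effects)
              else default_effects_registry()
  equations <- if (!is.null(cfg$risk_equations))
                 read_risk_equations(cfg$risk_equations)
               else default_risk_equations()
  models <- if (!is.null(cfg$event_models))
              read_event_models(cfg$event_models)
            else default_event_models()

  cohort <- stage("generate", {
    co <- generate_cohort(cspec, seed = cfg$seed, n = cfg$n)
    paths$cohort <- file.path(cfg$out_dir, "cohort.csv")
    write_cohort(co, paths$cohort)
    co
  })

  timelines <- stage("pathways", {
    tl <- simulate_pathways(cohort, tspec, seed = derive_seed(cfg$seed, 2L))
    paths$timelines <- file.path(cfg$out_dir, "timelines.csv")
    write_timelines(tl, paths$timelines)
    tl
  })

  calib <- stage("calibrate", {
    parts <- split_holdout(cohort, cfg$holdout_fraction,
                           seed = derive_seed(cfg$seed, 3L))
    dev_idx <- match(parts$development$id, cohort$id)
    hold_idx <- match(parts$holdout$id, cohort$id)
    sub_tl <- function(idx) {
      tl <- timelines
      tl$states <- tl$states[idx, , drop = FALSE]
      tl$statin <- tl$statin[idx, , drop = FALSE]
      tl$bp_lowering <- tl$bp_lowering[idx, , drop = FALSE]
      tl$censor_quarter <- tl$censor_quarter[idx]
      tl$id <- tl$id[idx]
      tl
    }
    pred <- predicted_trajectories(
      run_cohort(parts$development, sub_tl(dev_idx), equations, models,
                 registry))
    obs_run <- run_cohort(parts$holdout, sub_tl(hold_idx), equations,
                          models, registry, mode = "stochastic",
                          seed = derive_seed(cfg$seed, 4L))
    obs <- predicted_trajectories(obs_run)
    obs <- tibble::tibble(outcome = obs$outcome, quarter = obs$quarter,
                          value = obs$mean)
    # small cohorts can lose late quarters in one split but not the other;
    # assess agreement on the common grid
    key <- function(d) paste(d$outcome, d$quarter)
    common <- intersect(key(pred), key(obs))
    report <- assess_agreement(pred[key(pred) %in% common, ],
                               obs[key(obs) %in% common, ])
    paths$calibration <- file.path(cfg$out_dir, "calibration_report.csv")
    paths$calibration_summary <- file.path(cfg$out_dir, "calibration_summary.json")
    write_calibration_report(report, paths$calibration,
                             paths$calibration_summary)
    report
  })

  cf <- stage("counterfactuals", {
    run_counterfactuals(cohort, timelines, equations, models, registry)
  })

  stage("contrast", {
    summaries <- do.call(rbind, lapply(names(cf), function(arm) {
      do.call(rbind, lapply(cfg$horizons, function(hz) {
        tab <- do.call(rbind, lapply(c(event_names(), risk_factor_names()),
          function(ep) aggregate_predictions(cf[[arm]], ep, hz)))
        tab$arm <- arm
        tab
      }))
    }))
    paths$arm_summaries <- file.path(cfg$out_dir, "arm_summaries.csv")
    utils::write.csv(as.data.frame(summaries), paths$arm_summaries,
                     row.names = FALSE)
    contrasts <- contrast_table(cf, endpoints = event_names(),
                                horizons = cfg$horizons,
                                subgroups = cfg$subgroups)
    paths$contrasts <- file.path(cfg$out_dir, "contrasts.csv")
    utils::write.csv(as.data.frame(contrasts), paths$contrasts,
                     row.names = FALSE)
    contrasts
  })

  manifest <- list(
    package = "diamicro",
    version = as.character(utils::packageVersion("diamicro")),
    seed = cfg$seed, n = cfg$n, horizons = cfg$horizons,
    subgroups = cfg$subgroups, holdout_fraction = cfg$holdout_fraction,
    outputs = lapply(paths, basename))
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  say("pipeline complete: ", cfg$out_dir)
  invisible(list(config = cfg, cohort = cohort, timelines = timelines,
                 calibration = calib, counterfactuals = cf, paths = paths))
}

#' Regimen flow table for pathway visualisation
#'
#' Yearly node/flow tables underlying a Sankey-style view of the pathway
#' mix: `nodes` gives, per year, the count and proportion of the full
#' cohort in each regimen category (censored individuals form their own
#' node, so node counts conserve the cohort size), and `flows` counts
#' year-to-year transitions between nodes.
#'
#' @param timelines a `diamicro_timelines`.
#' @param years follow-up years to tabulate (nodes at quarter `4 * year`).
#' @return list of tibbles `nodes` and `flows`.
#' @export
pathway_flow_table <- function(timelines, years = 0:7) {
  stopifnot(inherits(timelines, "diamicro_timelines"))
  n <- length(timelines$id)
  if (n == 0L) stop("empty timelines", call. = FALSE)
  lab <- function(year) {
    s <- timelines$states[, 4L * year + 1L]
    ifelse(is.na(s), "censored", timelines$codes[s])
  }
  labs <- vapply(years, lab, character(n))
  if (n == 1L) labs <- matrix(labs, nrow = 1L)
  nodes <- do.call(rbind, lapply(seq_along(years), function(j) {
    tab <- table(factor(labs[, j], levels = c(timelines$codes, "censored")))
    tibble::tibble(year = years[j], category = names(tab),
                   count = as.integer(tab),
                   proportion = as.integer(tab) / n)
  }))
  nodes <- nodes[nodes$count > 0L | nodes$category != "censored", ]
  flows <- NULL
  if (length(years) > 1L) {
    flows <- do.call(rbind, lapply(seq_len(length(years) - 1L), function(j) {
      tab <- table(from = labs[, j], to = labs[, j + 1L])
      df <- as.data.frame(tab, stringsAsFactors = FALSE)
      df <- df[df$Freq > 0L, ]
      tibble::tibble(year_from = years[j], year_to = years[j + 1L],
                     from = df$from, to = df$to, count = df$Freq)
    }))
  }
  list(nodes = tibble::as_tibble(nodes), flows = flows)
}

#' Stacked-area pathway plot (Sankey-style)
#'
#' Headless-safe rendering of the yearly regimen mix as a stacked area
#' chart; the tested surface is the underlying [pathway_flow_table()],
#' which is returned invisibly.
#'
#' @param timelines a `diamicro_timelines`.
#' @param path optional file to save the figure to (requires ggplot2).
#' @param years follow-up years.
#' @return invisibly, the flow table.
#' @export
plot_pathway_sankey <- function(timelines, path = NULL, years = 0:7) {
  ft <- pathway_flow_table(timelines, years)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    nodes <- ft$nodes
    p <- ggplot2::ggplot(nodes,
      ggplot2::aes(x = .data$year, y = .data$proportion,
                   fill = .data$category)) +
      ggplot2::geom_area(position = "stack") +
      ggplot2::labs(x = "Follow-up year", y = "Proportion of cohort",
                    fill = "Regimen") +
      ggplot2::theme_minimal()
    if (!is.null(path)) {
      ggplot2::ggsave(path, p, width = 8, height = 5)
    } else {
      print(p)
    }
  } else if (!is.null(path)) {
    warning("ggplot2 not available; figure not rendered", call. = FALSE)
  }
  invisible(ft)
}
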