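## End-to-end orchestration: prepare -> impute -> HMM -> decode -> iSSF ->
## RSS, driven by one configuration list (or YAML file), with every table
## written as CSV plus a JSON manifest so a run is reproducible from the
## manifest alone.

#' Default pipeline configuration
#'
#' @return nested list of defaults; see [run_pipeline()].
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    outdir = NULL,
    simulate = list(nrow = 100, ncol = 100, n_villages = 3,
                    track_length = 500, n_animals = 2, missing_rate = 0.1),
    input = NULL,
    boundary = "wrap",
    max_gap = 24 * 3600,
    diel = list(day_start = 6, day_end = 18, tz = "UTC"),
    ctcrw = list(estimate_obs_sd = FALSE, obs_sd = 0),
    hmm = list(covariates = c("dist_village", "dist_water", "ndvi"),
               n_starts = 2),
    issf = list(n_random = 15),
    rss_contrasts = list(
      list(covariate = "dist_village", x1 = 5000, x2 = 500),
      list(covariate = "ndvi", x1 = 0.3, x2 = 0))
  )
}

merge_config <- function(config) {
  base <- default_run_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  modifyList(base, config)
}

#' Validate pipeline inputs
#'
#' Checks track schema, timestamp order (unsorted is a warning; the
#' pipeline sorts), duplicate timestamps, and coverage of every fix by the
#' covariate stack's extent. Problems are reported, not thrown.
#'
#' @param tracks a `tm_track` data.frame (pooled, with `id`).
#' @param stack a `landscape_stack`.
#' @param wrap logical; with periodic lookup no fix is out of extent.
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(tracks, stack, wrap = FALSE) {
  errors <- character(); warnings <- character()
  need <- c("id", "time", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) {
    errors <- c(errors, paste("track missing column(s):",
                              paste(miss, collapse = ", ")))
    return(list(errors = errors, warnings = warnings))
  }
  for (a in unique(tracks$id)) {
    tt <- tracks$time[tracks$id == a]
    if (is.unsorted(tt)) {
      warnings <- c(warnings, paste0("animal ", a,
        ": timestamps unsorted; they will be auto-sorted"))
    }
    if (anyDuplicated(tt)) {
      warnings <- c(warnings, paste0("animal ", a,
        ": duplicate timestamps; earliest fix kept per slot"))
    }
  }
  if (!wrap) {
    ext <- raster_extent(stack$ndvi)
    oob <- sum(tracks$x < ext["xmin"] | tracks$x > ext["xmax"] |
                 tracks$y < ext["ymin"] | tracks$y > ext["ymax"])
    if (oob > 0) {
      errors <- c(errors, paste0(oob,
        " fix(es) fall outside the covariate stack extent"))
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Run the full analysis pipeline
#'
#' Sequences regularization, CTCRW gap imputation, step/diel preparation,
#' displacement summaries with the day/night rank-sum test, the pooled
#' 2-state HMM with Viterbi decoding, activity budgets and stationary
#' curves, and the iSSF candidate-model comparison with RSS contrasts.
#' With `config$simulate` set (the default) the inputs are generated by the
#' synthetic module under `config$seed`; with `config$input` they are read
#' from a track CSV and a landscape role map.
#'
#' All randomness is governed by `config$seed`. If `config$outdir` is set,
#' every table is written as CSV along with `manifest.json` (config, seeds,
#' package version, input checksums, record accounting); the outputs are
#' byte-identical across reruns of the same config.
#'
#' @param config list or YAML path; see [default_run_config()].
#' @return list of class `run_report` (tables + accounting), invisibly if
#'   written to disk.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config)
  accounting <- list()
  checksums <- NULL
  if (!is.null(cfg$input)) {
    tracks <- read_track_csv(cfg$input$tracks)
    stack <- read_landscape(cfg$input$landscape)
    wrap <- FALSE
    checksums <- as.list(tools::md5sum(c(cfg$input$tracks,
                                         cfg$input$landscape)))
  } else {
    sc <- sim_config(seed = cfg$seed, nrow = cfg$simulate$nrow,
                     ncol = cfg$simulate$ncol,
                     n_villages = cfg$simulate$n_villages,
                     track_length = cfg$simulate$track_length,
                     n_animals = cfg$simulate$n_animals,
                     missing_rate = cfg$simulate$missing_rate)
    stack <- make_landscape(sc)
    wrap <- identical(cfg$boundary, "wrap")
    trs <- lapply(seq_len(sc$n_animals), function(i) {
      sim <- simulate_hmm_track(sc, stack, id = paste0("animal", i),
                                seed = cfg$seed * 1000 + i,
                                boundary = cfg$boundary)
      inject_missingness(sim$track, sc$missing_rate,
                         seed = cfg$seed * 1000 + i + 500)
    })
    tracks <- do.call(rbind, trs)
    tracks <- new_track(tracks)
    attr(tracks, "interval") <- 3600
  }
  val <- validate_inputs(tracks, stack, wrap = wrap)
  if (length(val$errors)) {
    stop("stage 'validate': ", paste(val$errors, collapse = "; "))
  }
  # per-animal regularization + imputation
  step_list <- list()
  for (a in unique(tracks$id)) {
    tr <- tracks[tracks$id == a, , drop = FALSE]
    tr <- new_track(tr[order(tr$time), , drop = FALSE])
    reg <- regularize(tr, max_gap = cfg$max_gap)
    accounting[[paste0("dropped_offlattice_", a)]] <- attr(reg, "dropped")
    n_missing <- sum(reg$source == "missing")
    accounting[[paste0("missing_slots_", a)]] <- n_missing
    if (n_missing > 0) {
      cfit <- fit_ctcrw(reg, estimate_obs_sd = cfg$ctcrw$estimate_obs_sd,
                        obs_sd = cfg$ctcrw$obs_sd)
      reg <- impute(reg, cfit)
    }
    st <- compute_steps(reg)
    step_list[[a]] <- st
  }
  steps <- do.call(rbind, step_list)
  steps <- assign_diel(steps, cfg$diel$day_start, cfg$diel$day_end,
                       tz = cfg$diel$tz)
  steps <- attach_covariates(steps, stack, wrap = wrap)
  # displacement
  disp_overall <- displacement_summary(steps)
  disp_diel <- displacement_summary(steps, by = "diel")
  disp_diel_forest <- displacement_summary(steps, by = c("diel", "forest3"))
  mwu_rows <- list()
  dn <- mann_whitney_u(steps$step[steps$diel == "day"],
                       steps$step[steps$diel == "night"])
  mwu_rows[[1]] <- data.frame(comparison = "day_vs_night", group = "all",
                              U = dn$U_a, Z = dn$Z, p = dn$p)
  for (f in intersect(FOREST3_LEVELS, unique(steps$forest3))) {
    sf <- steps[steps$forest3 == f, , drop = FALSE]
    if (length(unique(sf$diel)) == 2) {
      m <- mann_whitney_u(sf$step[sf$diel == "day"],
                          sf$step[sf$diel == "night"])
      mwu_rows[[length(mwu_rows) + 1]] <-
        data.frame(comparison = "day_vs_night", group = f,
                   U = m$U_a, Z = m$Z, p = m$p)
    }
  }
  mwu_tab <- do.call(rbind, mwu_rows)
  # HMM
  hfit <- fit_hmm(steps, covariates = cfg$hmm$covariates,
                  n_starts = cfg$hmm$n_starts, seed = cfg$seed)
  states <- viterbi(steps, hfit)
  steps$state <- as.character(states)
  budget <- state_budget(states)
  curves <- lapply(hfit$covariates, function(cv) stationary_curve(hfit, cv))
  names(curves) <- hfit$covariates
  # iSSF
  kern <- fit_kernel(steps)
  strata <- build_strata(steps, stack, kern, n_random = cfg$issf$n_random,
                         seed = cfg$seed, wrap = wrap)
  accounting$issf_dropped_strata <- attr(strata, "n_dropped_strata")
  accounting$issf_dropped_candidates <- attr(strata, "n_dropped_candidates")
  accounting$issf_skipped_bearing <- attr(strata, "n_skipped_bearing")
  cmp <- compare_models(strata)
  best <- cmp$fits[[cmp$table$model[1]]]
  const <- attr(strata, "standardization")
  rss_rows <- list()
  for (ct in cfg$rss_contrasts) {
    if (!ct$covariate %in% names(best$coefficients)) next
    j <- match(ct$covariate, const$covariate)
    x1 <- setNames((ct$x1 - const$mean[j]) / const$sd[j], ct$covariate)
    x2 <- setNames((ct$x2 - const$mean[j]) / const$sd[j], ct$covariate)
    r <- rss(best, x1, x2)
    rss_rows[[length(rss_rows) + 1]] <- data.frame(
      covariate = ct$covariate, x1 = ct$x1, x2 = ct$x2,
      rss = r$rss, lower = r$lower, upper = r$upper)
  }
  rss_tab <- if (length(rss_rows)) do.call(rbind, rss_rows) else
    data.frame(covariate = character(), x1 = numeric(), x2 = numeric(),
               rss = numeric(), lower = numeric(), upper = numeric())
  report <- structure(list(
    validation = val,
    displacement = list(overall = disp_overall, by_diel = disp_diel,
                        by_diel_forest = disp_diel_forest),
    mann_whitney = mwu_tab,
    hmm = list(table = hfit$table, loglik = hfit$loglik,
               budget = budget, fit = hfit),
    stationary_curves = curves,
    issf = list(comparison = cmp$table, best = best$label,
                coefficients = best$table, fits = cmp$fits),
    rss = rss_tab,
    steps = steps,
    accounting = accounting), class = "run_report")
  if (!is.null(cfg$outdir)) {
    write_report(report, cfg, checksums)
    return(invisible(report))
  }
  report
}

write_report <- function(report, cfg, checksums = NULL) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(df, name) {
    write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              file.path(cfg$outdir, name), row.names = FALSE, quote = FALSE)
  }
  out(report$displacement$by_diel, "displacement_by_diel.csv")
  out(report$displacement$by_diel_forest, "displacement_by_diel_forest.csv")
  out(report$mann_whitney, "mann_whitney.csv")
  out(report$hmm$table, "hmm_parameters.csv")
  out(data.frame(state = names(report$hmm$budget),
                 proportion = as.numeric(report$hmm$budget)),
      "state_budget.csv")
  for (cv in names(report$stationary_curves)) {
    out(report$stationary_curves[[cv]],
        paste0("stationary_", cv, ".csv"))
  }
  out(report$issf$comparison, "issf_model_comparison.csv")
  out(report$issf$coefficients, "issf_coefficients.csv")
  out(report$rss, "rss.csv")
  dec <- report$steps[, c("id", "burst", "time", "x1", "y1", "step",
                          "angle", "diel", "forest3", "state")]
  dec$time <- format(dec$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out(dec, "decoded_steps.csv")
  manifest <- list(
    package = "tigermove",
    version = as.character(utils::packageVersion("tigermove")),
    rng = "Mersenne-Twister",
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "outdir")],
    input_checksums = checksums,
    accounting = report$accounting)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("tigermove run report\n")
  cat(sprintf(" steps analysed: %d\n", nrow(x$steps)))
  cat(sprintf(" HMM logLik %.2f; budget: encamping %.1f%%, travelling %.1f%%\n",
              x$hmm$loglik, 100 * x$hmm$budget[1], 100 * x$hmm$budget[2]))
  cat(sprintf(" best iSSF model: %s\n", x$issf$best))
  invisible(x)
}
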