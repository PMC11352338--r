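# End-to-end pipeline: run the configured stages (SIN, activity, geotaxis,
# redox) from a single YAML/JSON config, writing tidy CSVs, a methods echo
# (every threshold actually used) and a log. Deterministic given the seed.

.stageSeed <- function(seed, offset) (as.integer(seed) %% 2000000L) * 1000L + offset

#' Run the full analysis pipeline from a config
#'
#' The config (YAML or JSON file, or an equivalent list) names the inputs
#' for each stage; only configured stages run. Synthetic inputs are
#' generated from the stage parameters with seeds derived from the master
#' `seed`, so two runs of the same config are byte-identical. Stage
#' failures are reported with the stage name and, with `keepGoing = TRUE`
#' (default), do not stop the remaining stages.
#'
#' Config keys (all optional except `seed`):
#' \describe{
#'   \item{sin}{`genotypes` (list of `name`, `attraction`,
#'     `n_recordings`), `n_flies`, `duration_s`, `frame_rate_hz`,
#'     `n_random_networks`.}
#'   \item{activity}{`n_flies`, `n_days`, `period_h`,
#'     `mean_counts_per_min`, `constant_dark`.}
#'   \item{geotaxis}{`genotypes` (list of `name`, `p_climb`), `n_groups`,
#'     `flies_per_group`, `trials_per_group`.}
#'   \item{redox}{`samples` (list of `id`, `gsh_uM`, `gssg_uM`),
#'     `noise_sd`.}
#' }
#'
#' @param config path to a YAML/JSON config, or a list.
#' @param outputDir output directory; defaults to `config$output_dir`, or
#'   a per-run timestamped directory under the working directory.
#' @param keepGoing continue past stage failures.
#' @return invisibly, a list with `outputs` (written file paths),
#'   `results` (per-stage R objects) and `failures` (named error
#'   messages).
#' @export
runPipeline <- function(config, outputDir = NULL, keepGoing = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .stopIfNot(!is.null(config$seed), "config must set a seed")
  seed <- as.integer(config$seed)

  if (is.null(outputDir)) {
    outputDir <- config$output_dir %||%
      paste0("flysin_run_", format(Sys.time(), "%Y%m%d_%H%M%S"))
  }
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)

  outputs <- character(0)
  results <- list()
  failures <- character(0)
  logLines <- c("flysin pipeline run", sprintf("seed: %d", seed))
  emit <- function(df, name) {
    p <- file.path(outputDir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  runStage <- function(name, fun) {
    tryCatch({
      results[[name]] <<- fun()
      logLines <<- c(logLines, sprintf("stage %s: ok", name))
    }, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      logLines <<- c(logLines,
                     sprintf("stage %s: FAILED (%s)", name,
                             conditionMessage(e)))
      if (!keepGoing) stop(e)
    })
  }

  criteria <- InteractionCriteria()
  statsTargets <- list()

  if (!is.null(config$sin)) {
    runStage("sin", function() {
      sc <- config$sin
      nFl <- sc$n_flies %||% 12
      fps <- sc$frame_rate_hz %||% 30
      dur <- sc$duration_s %||% 1500
      nRand <- sc$n_random_networks %||% 10000
      genos <- sc$genotypes %||% list(list(name = "control", attraction = 0,
                                           n_recordings = 3))
      allZ <- list()
      allEv <- list()
      for (gi in seq_along(genos)) {
        gn <- genos[[gi]]
        arena <- ArenaSpec(frameRateHz = fps, durationS = dur)
        prof <- SocialProfile(attractionStrength = gn$attraction %||% 0)
        recs <- lapply(seq_len(gn$n_recordings %||% 3), function(ri) {
          simulateTrajectories(arena, nFl, prof,
                               seed = .stageSeed(seed, gi * 37L + ri),
                               genotype = gn$name,
                               recordingId = sprintf("%s_r%02d", gn$name, ri))
        })
        for (rec in recs) {
          ev <- detectEvents(rec, criteria)
          if (nrow(ev)) {
            ev <- cbind(data.frame(recording = rec@recordingId,
                                   genotype = rec@genotype), ev)
            allEv[[length(allEv) + 1L]] <- ev
          }
        }
        spec <- NullModelSpec(nRandomNetworks = nRand, groupSize = nFl,
                              seed = .stageSeed(seed, 500L + gi))
        allZ[[gi]] <- sinZScores(recs, spec, criteria)
      }
      z <- do.call(rbind, allZ)
      emit(z, "sin_zscores.csv")
      if (length(allEv)) emit(do.call(rbind, allEv), "sin_events.csv")
      if (length(genos) >= 2) {
        sel <- z$metric == "clustering_coefficient" &
          z$weight_mode == "count" & z$level == "local_mean"
        statsTargets[["sin_clustering_z_count"]] <<-
          data.frame(value = z$z[sel], group = z$genotype[sel])
      }
      z
    })
  }

  if (!is.null(config$activity)) {
    runStage("activity", function() {
      ac <- config$activity
      dd <- isTRUE(ac$constant_dark)
      prof <- ActivityProfile(
        periodH = ac$period_h %||% 24,
        meanCountsPerMin = ac$mean_counts_per_min %||% 1.5)
      nFl <- ac$n_flies %||% 16
      serlist <- lapply(seq_len(nFl), function(i) {
        simulateActivity(prof, nDays = ac$n_days %||% 5,
                         seed = .stageSeed(seed, 700L + i),
                         constantDark = dd, flyId = sprintf("fly_%02d", i))
      })
      sumRows <- list()
      boutRows <- list()
      perRows <- list()
      for (s in serlist) {
        sl <- detectSleep(s)
        if (nrow(sl$bouts)) {
          boutRows[[length(boutRows) + 1L]] <-
            cbind(data.frame(fly = s@flyId), sl$bouts)
        }
        if (!dd) {
          sumRows[[length(sumRows) + 1L]] <- data.frame(
            fly = s@flyId,
            light_mean = phaseSummary(s, "light"),
            dark_mean = phaseSummary(s, "dark"))
          perRows[[length(perRows) + 1L]] <-
            cbind(data.frame(fly = s@flyId), sl$perPhase)
        } else {
          pe <- estimatePeriod(s)
          sumRows[[length(sumRows) + 1L]] <- data.frame(
            fly = s@flyId, period_h = pe$period_h,
            significant = pe$significant)
        }
      }
      emit(do.call(rbind, sumRows),
           if (dd) "activity_period.csv" else "activity_summary.csv")
      if (length(boutRows)) emit(do.call(rbind, boutRows), "sleep_bouts.csv")
      if (length(perRows)) emit(do.call(rbind, perRows), "sleep_phase.csv")
      serlist
    })
  }

  if (!is.null(config$geotaxis)) {
    runStage("geotaxis", function() {
      gc <- config$geotaxis
      genos <- gc$genotypes %||% list(list(name = "control", p_climb = 0.7))
      trials <- do.call(rbind, lapply(seq_along(genos), function(gi) {
        gn <- genos[[gi]]
        simulateGeotaxis(gn$p_climb %||% 0.7,
                         nGroups = gc$n_groups %||% 5,
                         fliesPerGroup = gc$flies_per_group %||% 10,
                         trialsPerGroup = gc$trials_per_group %||% 5,
                         seed = .stageSeed(seed, 900L + gi),
                         genotype = gn$name)
      }))
      trials <- scoreTrials(trials)
      agg <- aggregateGeotaxis(trials)
      emit(trials, "geotaxis_trials.csv")
      emit(agg$groups, "geotaxis_groups.csv")
      emit(agg$genotypes, "geotaxis_genotypes.csv")
      if (length(genos) >= 2) {
        statsTargets[["geotaxis_group_score"]] <<-
          data.frame(value = agg$groups$score_pct,
                     group = agg$groups$genotype)
      }
      agg
    })
  }

  if (!is.null(config$redox)) {
    runStage("redox", function() {
      rc <- config$redox
      samples <- rc$samples %||% list(list(id = "s1", gsh_uM = 4, gssg_uM = 3))
      readings <- do.call(rbind, lapply(seq_along(samples), function(si) {
        sm <- samples[[si]]
        simulateAssayReadings(sm$gsh_uM, sm$gssg_uM,
                              noiseSd = rc$noise_sd %||% 0,
                              seed = .stageSeed(seed, 1100L + si),
                              sampleId = sm$id)
      }))
      res <- glutathioneAssay(readings)
      emit(readings, "redox_readings.csv")
      emit(res, "redox_glutathione.csv")
      res
    })
  }

  if (length(statsTargets)) {
    runStage("stats_report", function() {
      omni <- list()
      post <- list()
      for (ms in names(statsTargets)) {
        cmp <- chooseAndTest(statsTargets[[ms]], measure = ms)
        omni[[length(omni) + 1L]] <- data.frame(
          measure = ms, degenerate = cmp$degenerate,
          gate = if (is.null(cmp$gate)) NA_character_ else cmp$gate$test,
          gate_p = if (is.null(cmp$gate)) NA_real_ else cmp$gate$p,
          branch = cmp$branch,
          omnibus = if (is.null(cmp$omnibus)) NA_character_ else cmp$omnibus$test,
          p = if (is.null(cmp$omnibus)) NA_real_ else cmp$omnibus$p)
        if (!is.null(cmp$posthoc)) {
          post[[length(post) + 1L]] <-
            cbind(data.frame(measure = ms),
                  cmp$posthoc[c("pair", "p_adj")])
        }
      }
      emit(do.call(rbind, omni), "stats_omnibus.csv")
      if (length(post)) emit(do.call(rbind, post), "stats_posthoc.csv")
      omni
    })
  }

  echo <- list(
    seed = seed,
    interaction_criteria = list(
      max_distance_mm = maxDistanceMm(criteria),
      max_facing_angle_deg = criteria@maxFacingAngleDeg,
      angle_convention = criteria@angleConvention,
      min_duration_s = criteria@minDurationS),
    sleep_rule = "inactivity strictly longer than 5 min",
    alpha = 0.05
  )
  yaml::write_yaml(echo, file.path(outputDir, "methods_echo.yaml"))
  outputs <- c(outputs, file.path(outputDir, "methods_echo.yaml"))
  writeLines(logLines, file.path(outputDir, "log.txt"))

  invisible(list(outputs = outputs, results = results, failures = failures,
                 outputDir = outputDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
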