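# End-to-end pipeline driver: YAML config in, per-stage tables + JSON
# summary + parameter-echo log out. Deterministic given (config, seed).

pipelineDefaults <- function() list(
  seed = 1,
  synthetic = list(duration = 300, n_units = 4, ahv_gain = 0.15,
                   speed_gain = 0.3, baseline_rate = 5),
  stages = list(tuning = TRUE, rotation = TRUE, roc = TRUE,
                decoding = FALSE, connectivity = TRUE, behavior = TRUE),
  tuning = list(n_perm = 200),
  rotation = list(n_trials = 10),
  decoding = list(sizes = c(5, 10), n_boot = 3),
  connectivity = list(duration = 300, p_transmission = 0.25,
                      delay_ms = 2),
  behavior = list(n_blocks = 5, threshold = 15,
                  peaks = c(15, 20, 30, 45, 80))
)

# reject unknown keys anywhere in the config (no silent defaults for typos)
validateConfig <- function(cfg, template = pipelineDefaults(),
                           path = character(0)) {
  bad <- setdiff(names(cfg), names(template))
  if (length(bad))
    stopf("unknown config key: %s",
          paste(c(path, bad[1L]), collapse = "$"))
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      validateConfig(as.list(cfg[[k]]), template[[k]], c(path, k))
  }
  utils::modifyList(template, cfg)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Reads a YAML configuration (or an equivalent list), generates a
#' synthetic session, runs the enabled analysis stages, and writes
#' per-stage CSV tables, a JSON summary and a parameter-echo log into
#' the output directory. The run is a pure function of (config, seed):
#' repeating it yields a byte-identical summary. Unknown configuration
#' keys are fatal.
#'
#' @param config path to a YAML file or a named list.
#' @param outDir output directory.
#' @param seed overrides the config seed when not NULL.
#' @return The summary list, invisibly; files are written under
#'   \code{outDir}.
#' @export
runPipeline <- function(config = list(), outDir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validateConfig(cfg)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = cfg$seed)

  # synthetic session
  sy <- cfg$synthetic
  tr <- simulateTrajectory(sy$duration, seed = childSeed(cfg$seed, 1))
  writeTracking(tr, file.path(outDir, "tracking.csv"))
  kin <- computeKinematics(tr)
  specs <- lapply(seq_len(sy$n_units), function(u) {
    tuned <- u <= ceiling(sy$n_units / 2)
    neuronSpec(baselineRate = sy$baseline_rate,
               ahvGainRight = if (tuned) sy$ahv_gain else 0,
               ahvGainLeft = if (tuned) sy$ahv_gain / 2 else 0,
               speedGain = if (tuned) sy$speed_gain else 0)
  })
  spikes <- lapply(seq_along(specs), function(u)
    simulateTunedSpikes(kin, specs[[u]], seed = childSeed(cfg$seed, 10 + u),
                        unitId = sprintf("unit%02d", u)))
  names(spikes) <- vapply(spikes, unitId, "")
  writeSpikeData(spikes, file.path(outDir, "spikes"))
  summary$synthetic <- list(n_units = length(spikes),
                            duration_s = sy$duration)

  if (isTRUE(cfg$stages$tuning)) {
    rows <- lapply(names(spikes), function(id) {
      a <- classifyAHV(spikes[[id]], kin, nPerm = cfg$tuning$n_perm,
                       seed = childSeed(cfg$seed, 20))
      s <- classifySpeed(spikes[[id]], kin, nPerm = cfg$tuning$n_perm,
                         seed = childSeed(cfg$seed, 21))
      data.frame(unit_id = id, score_right = a$scoreRight,
                 score_left = a$scoreLeft, slope_right = a$slopeRight,
                 slope_left = a$slopeLeft, is_ahv = a$isAHV,
                 subtype = a$subtype, speed_score = s$score,
                 speed_sign = s$sign, is_speed = s$isSpeed)
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(outDir, "tuning.csv"),
                     row.names = FALSE)
    summary$tuning <- list(n_ahv = sum(tab$is_ahv),
                           n_speed = sum(tab$is_speed))
  }

  if (isTRUE(cfg$stages$rotation) || isTRUE(cfg$stages$roc) ||
      isTRUE(cfg$stages$decoding)) {
    rotSpecs <- lapply(seq_len(max(2L, min(sy$n_units, 6L))), function(u)
      list(baseline = sy$baseline_rate,
           speedGain = list(vestibular = if (u %% 2) 0.08 else 0,
                            vestibular_visual = if (u %% 2) 0.12 else 0,
                            visual = if (u %% 2) 0.04 else 0),
           dirGain = list(vestibular = 0.02, vestibular_visual = 0.02,
                          visual = 0.01)))
    sess <- simulateRotationSession(rotSpecs, cfg$rotation$n_trials,
                                    seed = childSeed(cfg$seed, 30))
    utils::write.csv(sess$trials, file.path(outDir, "trials.csv"),
                     row.names = FALSE)
    if (isTRUE(cfg$stages$rotation)) {
      rows <- lapply(names(sess$spikes), function(id) {
        rt <- rotationTuning(sess$spikes[[id]], sess$trials, sess$profiles,
                             nPerm = cfg$tuning$n_perm,
                             seed = childSeed(cfg$seed, 31))
        ev <- evokedResponse(sess$spikes[[id]], sess$trials, "CW")
        data.frame(unit_id = id, score_cw = rt$scoreCW,
                   score_ccw = rt$scoreCCW,
                   velocity_modulated = rt$isVelocityModulated,
                   modulation_index = ev$modulationIndex,
                   evoked_p = ev$pValue)
      })
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(outDir, "rotation.csv"),
                       row.names = FALSE)
      summary$rotation <- list(n_modulated = sum(tab$velocity_modulated),
                               median_modulation_index =
                                 stats::median(tab$modulation_index,
                                               na.rm = TRUE))
    }
    if (isTRUE(cfg$stages$roc)) {
      rows <- lapply(names(sess$spikes), function(id) {
        rr <- directionROC(sess$spikes[[id]], sess$trials, "full")
        data.frame(unit_id = id, auc = rr$auc,
                   auc_rectified = rr$aucRectified,
                   significant = rr$significant)
      })
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(outDir, "roc.csv"),
                       row.names = FALSE)
      summary$roc <- list(n_significant = sum(tab$significant))
    }
    if (isTRUE(cfg$stages$decoding)) {
      pool <- lapply(names(sess$spikes), function(id) {
        cw <- sess$trials$direction == "CW"
        list(rates = list(CW = trialRates(sess$spikes[[id]],
                                          sess$trials[cw, ]),
                          CCW = trialRates(sess$spikes[[id]],
                                           sess$trials[!cw, ])))
      })
      bd <- bootstrapDecoding(pool, cfg$decoding$sizes,
                              nBoot = cfg$decoding$n_boot,
                              seed = childSeed(cfg$seed, 40))
      utils::write.csv(bd, file.path(outDir, "decoding.csv"),
                       row.names = FALSE)
      summary$decoding <- list(max_accuracy = max(bd$accuracy))
    }
  }

  if (isTRUE(cfg$stages$connectivity)) {
    cp <- simulateCoupledPair(duration = cfg$connectivity$duration,
                              delayMs = cfg$connectivity$delay_ms,
                              pTransmission = cfg$connectivity$p_transmission,
                              seed = childSeed(cfg$seed, 50))
    det <- detectConnection(computeCCG(cp$a, cp$b))
    utils::write.csv(data.frame(lag_ms = det$lags, count = det$counts,
                                baseline = det$baseline),
                     file.path(outDir, "ccg.csv"), row.names = FALSE)
    summary$connectivity <- list(label = det$label)
  }

  if (isTRUE(cfg$stages$behavior)) {
    sess <- simulateGoNoGoSession(cfg$behavior$peaks,
                                  nBlocks = cfg$behavior$n_blocks,
                                  threshold = cfg$behavior$threshold,
                                  seed = childSeed(cfg$seed, 60))
    sc <- scoreSession(sess)
    utils::write.csv(sc, file.path(outDir, "behavior.csv"),
                     row.names = FALSE)
    agg <- stats::aggregate(accuracy ~ peak_splus + peak_sminus, sc, mean)
    fit <- fitPsychometric(abs(agg$peak_splus - agg$peak_sminus),
                           agg$accuracy)
    summary$behavior <- list(mean_accuracy = mean(sc$accuracy),
                             threshold_deg_s = fit$midpoint)
  }

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c("pipeline parameter echo:",
               utils::capture.output(utils::str(cfg))),
             file.path(outDir, "pipeline.log"))
  invisible(summary)
}
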