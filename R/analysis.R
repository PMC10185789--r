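# Central entry points: `nwr_analyze()` turns epochs into a classed
# analysis object (detections -> summaries -> conduction velocities ->
# optional statistical battery); `run_pipeline()` streams a simulated
# cohort through the same chain participant by participant, so arbitrarily
# large cohorts never hold all raw epochs in memory; `run_all()` is the
# file-based end-to-end run.

new_analysis <- function(events, trials, summaries, cv, clinical, battery,
                         grand_avg, config) {
  structure(list(events = events, trials = trials, summaries = summaries,
                 cv = cv, clinical = clinical, battery = battery,
                 grand_avg = grand_avg, config = config),
            class = "nwr_analysis")
}

#' Analyze a set of epochs
#'
#' Runs the conditioning chain and reflex detector over stimulus-locked
#' epochs, aggregates per-participant response summaries and, when a
#' clinical table is supplied, estimates conduction velocities and runs
#' the statistical battery.
#'
#' @param epochs List of `nwr_epoch` objects (raw; filtering is applied
#'   here).
#' @param clinical Optional clinical table.
#' @param preprocess A [preprocess_config()].
#' @param detection A [detection_config()].
#' @param battery Run the statistical battery (needs `clinical` with both
#'   groups for the group comparisons).
#' @return An object of class `nwr_analysis` with elements `events`,
#'   `trials`, `summaries`, `cv`, `clinical`, `battery`, `grand_avg`.
#' @export
nwr_analyze <- function(epochs, clinical = NULL,
                        preprocess = preprocess_config(),
                        detection = detection_config(),
                        battery = !is.null(clinical)) {
  pre <- preprocess_epochs(epochs, preprocess)
  det <- detect_epochs(pre, detection)
  summaries <- summarize_responses(det$events, det$trials)
  cv <- NULL
  bat <- NULL
  if (!is.null(clinical)) {
    cv <- estimate_cv_cohort(det$events, clinical)
    if (battery) bat <- run_battery(summaries, clinical)
  }
  ga <- grand_average_by_site(pre)
  new_analysis(det$events, det$trials, summaries, cv, clinical, bat, ga,
               list(preprocess = preprocess, detection = detection))
}

grand_average_by_site <- function(epochs) {
  out <- list()
  for (site in unique(vapply(epochs, `[[`, "", "site"))) {
    eps <- Filter(function(e) e$site == site && isTRUE(e$valid), epochs)
    if (length(eps)) out[[site]] <- grand_average(eps)
  }
  out
}

#' Run the simulate-analyze pipeline for one configuration
#'
#' Streams the synthetic cohort participant by participant through
#' filtering and detection, accumulating events, trial bookkeeping and
#' per-group grand averages without retaining raw epochs.  With `dir`
#' given, all artifacts (epoch TSVs, manifest, clinical table, event and
#' summary tables, conduction velocities, battery report, resolved
#' configuration, log) are written there; rerunning with the same
#' configuration reproduces them byte-identically.
#'
#' @param config A [run_config()].
#' @param dir Optional output directory.
#' @param battery Run the statistical battery at the end.
#' @param write_epoch_files Write per-participant epoch TSVs (only with
#'   `dir`; off by default because they dominate run time and size).
#' @param progress Emit one log line per participant.
#' @return An `nwr_analysis`; additionally carries `latents` and `truth`
#'   (planted ground-truth events) for simulator validation.
#' @export
run_pipeline <- function(config = run_config(), dir = NULL, battery = TRUE,
                         write_epoch_files = FALSE, progress = FALSE) {
  log_lines <- character()
  logmsg <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (progress) message(msg)
  }
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  clinical <- list()
  latents <- list()
  events <- list()
  trials <- list()
  manifest <- list()
  truth <- list()
  ga_acc <- list()  # running grand-average sums per group x site
  groups <- list(SCI = list(gp = config$sci, n = config$clinical$n_sci),
                 NDC = list(gp = config$ndc, n = config$clinical$n_ndc))
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (g$n < 1) next
    for (i in seq_len(g$n)) {
      p <- simulate_participant(g$gp, config$clinical, i, config$seed)
      pid <- p$record$participant_id
      pseed <- nwr_substream_seed(config$seed, i,
                                  if (gname == "SCI") 1L else 2L)
      clinical[[length(clinical) + 1L]] <- p$record
      latents[[pid]] <- p$latent
      n_ev <- 0L
      for (site in config$sites) {
        eps <- lapply(seq_len(config$n_trials), function(tr) {
          simulate_trial(p$latent, g$gp, site, tr, pid, seed = pseed)
        })
        for (ep in eps) {
          manifest[[length(manifest) + 1L]] <- data.frame(
            participant_id = pid, site = site, trial_index = ep$trial_index,
            energy_mJ = ep$energy_mJ, ISI_ms = attr(ep, "ISI_ms"),
            pain_rating = ep$pain_rating, valid = TRUE,
            stringsAsFactors = FALSE)
          pl <- attr(ep, "planted")
          if (nrow(pl)) {
            pl$participant_id <- pid; pl$site <- site
            pl$trial_index <- ep$trial_index
            truth[[length(truth) + 1L]] <- pl
          }
        }
        if (!is.null(dir) && write_epoch_files) {
          write_epochs(eps, file.path(dir, sprintf("epochs_%s_%s.tsv",
                                                   pid, site)))
        }
        pre <- preprocess_epochs(eps, config$preprocess)
        det <- detect_epochs(pre, config$detection)
        events[[length(events) + 1L]] <- det$events
        trials[[length(trials) + 1L]] <- det$trials
        n_ev <- n_ev + nrow(det$events)
        key <- paste(gname, site, sep = ".")
        acc <- ga_acc[[key]]
        for (ep in pre) {
          if (is.null(acc)) {
            acc <- list(TA = rectify(ep$samples_TA),
                        SO = rectify(ep$samples_SO),
                        time_ms = epoch_times(ep), n = 1L)
          } else {
            acc$TA <- acc$TA + rectify(ep$samples_TA)
            acc$SO <- acc$SO + rectify(ep$samples_SO)
            acc$n <- acc$n + 1L
          }
        }
        ga_acc[[key]] <- acc
      }
      logmsg(sprintf("%s: %d trials x %d sites, %d events", pid,
                     config$n_trials, length(config$sites), n_ev))
    }
  }
  clinical <- do.call(rbind, clinical)
  class(clinical) <- c("nwr_clinical", "data.frame")
  events <- do.call(rbind, events)
  trials <- do.call(rbind, trials)
  manifest <- do.call(rbind, manifest)
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  summaries <- summarize_responses(events, trials)
  cv <- estimate_cv_cohort(events, clinical)
  bat <- if (battery) run_battery(summaries, clinical) else NULL
  ga <- lapply(ga_acc, function(a) {
    list(time_ms = a$time_ms, TA = a$TA / a$n, SO = a$SO / a$n, n = a$n)
  })
  logmsg(sprintf("cohort: %d participants, %d trials (%d valid), %d events",
                 nrow(clinical), nrow(trials), sum(trials$valid),
                 nrow(events)))
  out <- new_analysis(events, trials, summaries, cv, clinical, bat, ga,
                      config)
  out$latents <- latents
  out$truth <- truth
  out$manifest <- manifest
  out$log <- log_lines
  if (!is.null(dir)) {
    write_clinical_table(clinical, file.path(dir, "clinical.tsv"))
    write_trial_manifest(manifest, file.path(dir, "manifest.tsv"))
    write_events(events, file.path(dir, "events.tsv"))
    utils::write.table(summaries, file.path(dir, "summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cv, file.path(dir, "cv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(bat)) {
      write_battery(bat, file.path(dir, "stats.tsv"),
                    file.path(dir, "stats.txt"))
    }
    yaml::write_yaml(strip_classes(config), file.path(dir, "config.yaml"))
    writeLines(log_lines, file.path(dir, "log.txt"))
  }
  out
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' End-to-end run into an output directory
#'
#' Simulate, preprocess, detect, summarize and analyze one configured
#' cohort, writing every artifact (including per-trial epoch files) under
#' `dir`.  Partial failures leave earlier artifacts in place.
#'
#' @param config A [run_config()].
#' @param dir Output directory.
#' @param figures Also render summary figures (see [report_figures()]).
#' @return The `nwr_analysis`, invisibly; artifacts in `dir`.
#' @export
run_all <- function(config = run_config(), dir, figures = TRUE) {
  res <- run_pipeline(config, dir = dir, battery = TRUE,
                      write_epoch_files = TRUE)
  if (figures) report_figures(res, dir)
  invisible(res)
}

#' Render report figures
#'
#' Grand-average rectified traces per group and site, and a bar chart of
#' mean reflex magnitude (AUC) per group, site and muscle, written as PNG
#' files.
#'
#' @param analysis An `nwr_analysis`.
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
report_figures <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  if (!length(analysis$grand_avg)) {
    warning("no epochs available; no figures written")
    return(invisible(written))
  }
  sites <- unique(sub("^[A-Z]+\\.", "", names(analysis$grand_avg)))
  for (site in sites) {
    f <- file.path(dir, paste0("grand_average_", site, ".png"))
    grDevices::png(f, width = 900, height = 600)
    keys <- grep(paste0("\\.", site, "$"), names(analysis$grand_avg),
                 value = TRUE)
    ymax <- max(vapply(keys, function(k) {
      max(analysis$grand_avg[[k]]$TA, analysis$grand_avg[[k]]$SO)
    }, 0))
    graphics::plot(NULL, xlim = c(-500, 3000), ylim = c(0, ymax * 1.05),
                   xlab = "time relative to stimulus (ms)",
                   ylab = "rectified EMG (uV)",
                   main = paste("Grand average, site", site))
    cols <- c(SCI.TA = "firebrick", SCI.SO = "salmon",
              NDC.TA = "navy", NDC.SO = "skyblue")
    for (k in keys) {
      ga <- analysis$grand_avg[[k]]
      gname <- sub("\\..*$", "", k)
      graphics::lines(ga$time_ms, ga$TA, col = cols[[paste0(gname, ".TA")]])
      graphics::lines(ga$time_ms, ga$SO, col = cols[[paste0(gname, ".SO")]])
    }
    graphics::abline(v = 0, lty = 2)
    graphics::legend("topright", legend = names(cols), col = cols, lty = 1)
    grDevices::dev.off()
    written <- c(written, f)
  }
  # AUC bars per site x group (TW2)
  s <- analysis$summaries
  if (!is.null(s) && !is.null(analysis$clinical)) {
    s <- merge(s, analysis$clinical[, c("participant_id", "group")],
               by = "participant_id")
    s <- s[s$window == "TW2" & !is.na(s$auc_mean_uVs), ]
    if (nrow(s)) {
      agg <- stats::aggregate(auc_mean_uVs ~ group + site, data = s,
                              FUN = mean)
      f <- file.path(dir, "auc_tw2.png")
      grDevices::png(f, width = 700, height = 500)
      m <- with(agg, tapply(auc_mean_uVs, list(group, site), mean))
      graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                        ylab = "mean AUC (uV s)", xlab = "site",
                        main = "Reflex magnitude, late window (TW2)")
      grDevices::dev.off()
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' @export
print.nwr_analysis <- function(x, ...) {
  n_part <- length(unique(x$trials$participant_id))
  cat("<nwr_analysis>\n")
  cat(sprintf("  %d participants, %d trials (%d valid), %d reflex events\n",
              n_part, nrow(x$trials), sum(x$trials$valid), nrow(x$events)))
  if (nrow(x$events)) {
    tw <- table(x$events$window)
    cat("  events by window:",
        paste(names(tw), as.integer(tw), sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$cv)) {
    ok <- x$cv$defined
    if (any(ok)) {
      cat(sprintf("  conduction velocity (TW2, FS-FH): %d defined, median %.2f m/s\n",
                  sum(ok), stats::median(x$cv$cv_mps[ok])))
    }
  }
  if (!is.null(x$battery)) {
    cat("  battery:", x$battery$n_tests, "tests\n")
  }
  invisible(x)
}

#' @export
summary.nwr_analysis <- function(object, ...) {
  s <- object$summaries
  out <- list()
  if (!is.null(object$clinical)) {
    s <- merge(s, object$clinical[, c("participant_id", "group")],
               by = "participant_id")
    rates <- stats::aggregate(response_rate_pct ~ group + site + window,
                              data = s[s$window %in% c("TW1", "TW2"), ],
                              FUN = mean)
    responders <- stats::aggregate(responder ~ group + site + window,
                                   data = s[s$window %in% c("TW1", "TW2"), ],
                                   FUN = function(z) 100 * mean(z))
    names(responders)[4] <- "responder_pct"
    out$mean_response_rate_pct <- rates
    out$responder_pct <- responders
  } else {
    out$mean_response_rate_pct <-
      stats::aggregate(response_rate_pct ~ site + window,
                       data = s[s$window %in% c("TW1", "TW2"), ], FUN = mean)
  }
  out$cv <- object$cv
  class(out) <- "summary.nwr_analysis"
  out
}

#' @export
print.summary.nwr_analysis <- function(x, ...) {
  cat("Mean response rate (%) by group, site, window:\n")
  print(x$mean_response_rate_pct, row.names = FALSE)
  if (!is.null(x$responder_pct)) {
    cat("\nResponders (%):\n")
    print(x$responder_pct, row.names = FALSE)
  }
  if (!is.null(x$cv) && any(x$cv$defined)) {
    cat("\nDefined conduction-velocity estimates (m/s):\n")
    print(summary(x$cv$cv_mps[x$cv$defined]))
  }
  invisible(x)
}

#' @export
plot.nwr_analysis <- function(x, site = NULL, ...) {
  if (!length(x$grand_avg)) {
    warning("no grand averages stored in this analysis")
    return(invisible(x))
  }
  keys <- names(x$grand_avg)
  if (!is.null(site)) keys <- grep(paste0("\\.", site, "$"), keys, value = TRUE)
  ymax <- max(vapply(keys, function(k) max(x$grand_avg[[k]]$TA,
                                           x$grand_avg[[k]]$SO), 0))
  graphics::plot(NULL, xlim = c(-500, 3000), ylim = c(0, ymax * 1.05),
                 xlab = "time relative to stimulus (ms)",
                 ylab = "rectified EMG (uV)",
                 main = "Grand-average motor responses", ...)
  cols <- grDevices::hcl.colors(max(length(keys), 2), "Dark 2")
  for (i in seq_along(keys)) {
    ga <- x$grand_avg[[keys[i]]]
    graphics::lines(ga$time_ms, ga$TA, col = cols[i], lty = 1)
    graphics::lines(ga$time_ms, ga$SO, col = cols[i], lty = 3)
  }
  graphics::abline(v = 0, lty = 2)
  graphics::legend("topright", legend = keys, col = cols[seq_along(keys)],
                   lty = 1)
  invisible(x)
}
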