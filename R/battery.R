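# The clinical statistical battery.  Tails policy: the a-priori
# hyperresponsiveness comparisons (responders, response rates, SCI > NDC)
# and the spasticity-vs-reflex correlations are one-tailed; everything else
# is two-tailed.  Alpha 0.05, no multiple-testing correction (the number of
# tests run is reported instead).  Missing data are handled by
# pairwise-complete deletion; n is reported per test.

battery_row <- function(analysis, res) {
  cbind(data.frame(analysis = analysis, stringsAsFactors = FALSE), res)
}

#' Run the clinical statistical battery
#'
#' Emits the full analysis set on a cohort: late-window (TW2) responder and
#' response-rate comparisons SCI versus NDC per site (one-tailed, effect
#' size r), latency and reflex-magnitude (AUC) comparisons (two-tailed),
#' per-stimulus pain-rating comparison (two-tailed), Kendall tau-b of
#' response rates versus spasticity scores (one-tailed) and versus
#' spontaneous pain (two-tailed), eta coefficients of neuropathic-pain
#' grading versus response rates and spasticity severity, and Fisher's
#' exact test with phi of neuropathic pain versus clinically relevant
#' spasticity.  With `summaries = NULL` only the clinical-table analyses
#' run.
#'
#' @param summaries Response summaries from [summarize_responses()], or
#'   `NULL` for a clinical-only battery.
#' @param clinical Clinical table (both groups, or SCI only).
#' @param alpha Significance level (reported, default 0.05).
#' @param rate_window Window whose response rates feed the group
#'   comparisons (default `"TW2"`, the only window with responses in both
#'   groups).
#' @param assoc_window Window whose response rates feed the clinical
#'   association analyses (default `"any"`).
#' @return An object of class `nwr_battery`: `results` (`StatResult` rows
#'   tagged by analysis), `n_tests`, `alpha`, `notes`.
#' @export
run_battery <- function(summaries, clinical, alpha = 0.05,
                        rate_window = "TW2", assoc_window = "any") {
  rows <- list()
  notes <- character()
  flags <- classify_clinical(clinical)
  cl <- merge(clinical, flags, by = "participant_id")
  sci <- cl[cl$group == "SCI", , drop = FALSE]

  if (!is.null(summaries)) {
    s <- merge(summaries, cl[, c("participant_id", "group")],
               by = "participant_id")
    sites <- intersect(NWR_SITES, unique(s$site))
    # responders SCI vs NDC (rate_window, any site)
    resp <- stats::aggregate(responder ~ participant_id + group,
                             data = s[s$window == rate_window, ], FUN = any)
    if (length(unique(resp$group)) == 2) {
      tab <- table(factor(resp$group, c("SCI", "NDC")),
                   factor(resp$responder, c(TRUE, FALSE)))
      res <- tryCatch(fisher_exact_2x2(tab, "greater"),
                      error = function(e) NULL)
      if (!is.null(res)) {
        rows[[length(rows) + 1L]] <-
          battery_row(paste0("responder_", rate_window, "_SCI_vs_NDC"), res)
      }
    }
    for (site in sites) {
      ss <- s[s$site == site & s$window == rate_window, ]
      xs <- ss$response_rate_pct[ss$group == "SCI"]
      ys <- ss$response_rate_pct[ss$group == "NDC"]
      if (length(xs) && length(ys)) {
        rows[[length(rows) + 1L]] <- battery_row(
          paste0("response_rate_", rate_window, "_", site, "_SCI_gt_NDC"),
          wilcoxon_rank_sum(xs, ys, "greater"))
        # latency and AUC: two-tailed, responders only
        for (var in c("latency_mean_ms", "auc_mean_uVs")) {
          xv <- ss[[var]][ss$group == "SCI" & ss$responder]
          yv <- ss[[var]][ss$group == "NDC" & ss$responder]
          if (length(xv) && length(yv)) {
            rows[[length(rows) + 1L]] <- battery_row(
              paste0(sub("_mean.*", "", var), "_", rate_window, "_", site,
                     "_SCI_vs_NDC"),
              wilcoxon_rank_sum(xv, yv, "two.sided"))
          }
        }
      }
      # pain ratings: two-tailed
      sp <- s[s$site == site & s$window == "any", ]
      xp <- sp$pain_rating_mean[sp$group == "SCI"]
      yp <- sp$pain_rating_mean[sp$group == "NDC"]
      if (sum(!is.na(xp)) && sum(!is.na(yp))) {
        rows[[length(rows) + 1L]] <- battery_row(
          paste0("pain_rating_", site, "_SCI_vs_NDC"),
          wilcoxon_rank_sum(xp, yp, "two.sided"))
      }
      # clinical associations: SCI response rates vs spasticity / pain
      sa <- s[s$site == site & s$window == assoc_window & s$group == "SCI", ]
      sa <- merge(sa, sci[, c("participant_id", "MAS_mean", "SCAT_mean",
                              "NRS_spontaneous", "CPG_neuropathic")],
                  by = "participant_id")
      if (nrow(sa) >= 3) {
        for (sc in c("MAS_mean", "SCAT_mean")) {
          if (sum(stats::complete.cases(sa$response_rate_pct, sa[[sc]])) >= 3) {
            rows[[length(rows) + 1L]] <- battery_row(
              paste0("rate_vs_", sub("_mean", "", sc), "_", site),
              kendall_tau_b(sa[[sc]], sa$response_rate_pct, "greater"))
          }
        }
        if (sum(stats::complete.cases(sa$response_rate_pct,
                                      sa$NRS_spontaneous)) >= 3) {
          rows[[length(rows) + 1L]] <- battery_row(
            paste0("rate_vs_NRS_", site),
            kendall_tau_b(sa$NRS_spontaneous, sa$response_rate_pct,
                          "two.sided"))
        }
        if (length(unique(sa$CPG_neuropathic[!is.na(sa$CPG_neuropathic)])) == 2) {
          rows[[length(rows) + 1L]] <- battery_row(
            paste0("eta_CPG_vs_rate_", site),
            eta_stat(sa$CPG_neuropathic, sa$response_rate_pct))
        }
      }
    }
  }

  # clinical-table-only analyses (SCI group)
  if (nrow(sci) >= 3) {
    cpg <- sci$CPG_neuropathic
    if (length(unique(cpg[!is.na(cpg)])) == 2) {
      for (sc in c("MAS_mean", "SCAT_mean")) {
        rows[[length(rows) + 1L]] <- battery_row(
          paste0("eta_CPG_vs_", sub("_mean", "", sc)),
          eta_stat(cpg, sci[[sc]]))
      }
      ok <- !is.na(cpg) & !is.na(sci$spasticity_relevant)
      if (length(unique(sci$spasticity_relevant[ok])) == 2) {
        tab <- table(factor(cpg[ok], c(TRUE, FALSE)),
                     factor(sci$spasticity_relevant[ok], c(TRUE, FALSE)))
        rows[[length(rows) + 1L]] <- battery_row(
          "fisher_CPG_vs_spasticity", fisher_exact_2x2(tab, "two.sided"))
      } else {
        notes <- c(notes, "spasticity constant; CPG x spasticity table skipped")
      }
    }
    for (sc in c("MAS_mean", "SCAT_mean")) {
      if (sum(stats::complete.cases(sci$NRS_spontaneous, sci[[sc]])) >= 3) {
        rows[[length(rows) + 1L]] <- battery_row(
          paste0("NRS_vs_", sub("_mean", "", sc)),
          kendall_tau_b(sci$NRS_spontaneous, sci[[sc]], "two.sided"))
      }
    }
  } else {
    notes <- c(notes, "fewer than 3 SCI records; clinical associations skipped")
  }

  results <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(results = results,
                 n_tests = if (is.null(results)) 0L else nrow(results),
                 alpha = alpha, notes = notes),
            class = "nwr_battery")
}

#' @export
print.nwr_battery <- function(x, ...) {
  cat("Clinical statistical battery:", x$n_tests, "tests, alpha =",
      x$alpha, "(no multiplicity correction)\n")
  if (!is.null(x$results)) {
    df <- x$results
    df$p_value <- signif(df$p_value, 3)
    df$statistic <- signif(df$statistic, 3)
    df$effect_size <- signif(df$effect_size, 3)
    print(df[, c("analysis", "method", "statistic", "p_value", "tails",
                 "effect_size", "effect_kind", "n")], row.names = FALSE)
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Write a battery report
#'
#' Machine-readable TSV of the result rows plus a human-readable text
#' report.
#'
#' @param battery An `nwr_battery`.
#' @param path_tsv,path_txt Output paths (either may be `NULL`).
#' @return `battery`, invisibly.
#' @export
write_battery <- function(battery, path_tsv = NULL, path_txt = NULL) {
  if (!is.null(path_tsv) && !is.null(battery$results)) {
    utils::write.table(battery$results, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_txt)) {
    con <- file(path_txt, "wt")
    on.exit(close(con))
    sink(con)
    print(battery)
    sink()
  }
  invisible(battery)
}
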