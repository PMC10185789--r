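# Domain containers and all on-disk artifacts.  Canonical format is TSV:
# language-neutral, diff-able, no binary dependency.  Epoch files carry
# '#'-prefixed metadata headers, one '# trial' line per trial block, then
# one row per sample (time_ms, TA_uV, SO_uV).  Missing-value tokens in
# clinical tables: "n.a.", "MD" and "" all map to NA.

#' Construct a stimulus-locked EMG epoch
#'
#' The unit of reflex detection: one two-channel (tibialis anterior,
#' soleus) trace locked to a single laser stimulus, canonically sampled at
#' 1000 Hz from 500 ms before to 3000 ms after stimulus onset (3501
#' samples).  Sample `i` sits at `t0_offset_ms + (i - 1) * 1000 / rate` ms.
#'
#' @param participant_id Participant identifier.
#' @param trial_index Trial number within the stimulation series.
#' @param site Stimulation site: `"FS"`, `"FD"` or `"FH"`.
#' @param energy_mJ Laser pulse energy (nominally 540/600/660 mJ).
#' @param sampling_rate_Hz Sampling rate; must exceed 900 Hz so the 450 Hz
#'   band edge stays below Nyquist.
#' @param t0_offset_ms Time of the first sample relative to stimulus onset.
#' @param samples_TA,samples_SO Channel sample vectors (microvolts), equal
#'   length.
#' @param pain_rating Per-stimulus pain rating, 0-100 or `NA`.
#' @param valid Logical; segmentation flags epochs with incomplete margins.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `nwr_epoch`.
#' @export
emg_epoch <- function(participant_id, trial_index, site, energy_mJ = NA_real_,
                      sampling_rate_Hz = 1000, t0_offset_ms = -500,
                      samples_TA = numeric(), samples_SO = numeric(),
                      pain_rating = NA_real_, valid = TRUE,
                      validate = TRUE) {
  ep <- structure(list(
    participant_id = as.character(participant_id),
    trial_index = as.integer(trial_index),
    site = as.character(site),
    energy_mJ = as.numeric(energy_mJ),
    sampling_rate_Hz = as.numeric(sampling_rate_Hz),
    t0_offset_ms = as.numeric(t0_offset_ms),
    samples_TA = as.numeric(samples_TA),
    samples_SO = as.numeric(samples_SO),
    pain_rating = as.numeric(pain_rating),
    valid = isTRUE(valid)
  ), class = "nwr_epoch")
  if (validate) validate_epoch(ep)
  ep
}

validate_epoch <- function(ep) {
  if (!ep$site %in% NWR_SITES) {
    stop("unknown site '", ep$site, "' (expected FS, FD or FH)")
  }
  if (length(ep$samples_TA) != length(ep$samples_SO)) {
    stop("channel length mismatch in trial ", ep$trial_index,
         " of participant ", ep$participant_id, ": TA has ",
         length(ep$samples_TA), " samples, SO has ", length(ep$samples_SO))
  }
  if (ep$sampling_rate_Hz <= 2 * 450) {
    stop("sampling rate must exceed 900 Hz (2 x 450 Hz band edge)")
  }
  invisible(ep)
}

#' Epoch time axis
#'
#' @param epoch An `nwr_epoch`.
#' @return Sample times in ms relative to stimulus onset.
#' @export
epoch_times <- function(epoch) {
  epoch$t0_offset_ms +
    (seq_along(epoch$samples_TA) - 1) * 1000 / epoch$sampling_rate_Hz
}

#' @export
print.nwr_epoch <- function(x, ...) {
  cat(sprintf(
    "<nwr_epoch> %s trial %d site %s: %d samples @ %g Hz, t0 = %g ms%s\n",
    x$participant_id, x$trial_index, x$site, length(x$samples_TA),
    x$sampling_rate_Hz, x$t0_offset_ms,
    if (x$valid) "" else " [invalid]"))
  invisible(x)
}

fmt_num <- function(x) {
  out <- as.character(signif(x, 7))
  out[is.na(x)] <- "NA"
  out
}

#' Write epochs to a TSV epoch file
#'
#' @param epochs List of `nwr_epoch` objects sharing participant, site,
#'   sampling rate and geometry.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(epochs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c("# nwreflex epoch file v1")
  if (length(epochs)) {
    ep1 <- epochs[[1]]
    for (ep in epochs) validate_epoch(ep)
    header <- c(header,
      paste0("# participant_id: ", ep1$participant_id),
      paste0("# site: ", ep1$site),
      paste0("# sampling_rate_Hz: ", fmt_num(ep1$sampling_rate_Hz)),
      paste0("# t0_offset_ms: ", fmt_num(ep1$t0_offset_ms)))
  }
  writeLines(c(header, "time_ms\tTA_uV\tSO_uV"), con)
  for (ep in epochs) {
    writeLines(sprintf("# trial %d energy_mJ=%s pain_rating=%s valid=%s",
                       ep$trial_index, fmt_num(ep$energy_mJ),
                       fmt_num(ep$pain_rating), ep$valid), con)
    tt <- epoch_times(ep)
    writeLines(paste(fmt_num(tt), fmt_num(ep$samples_TA),
                     fmt_num(ep$samples_SO), sep = "\t"), con)
  }
  invisible(path)
}

parse_kv <- function(s) {
  # "a=1 b=x" -> named character vector
  parts <- strsplit(trimws(s), "\\s+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) if (length(p) > 1) p[2] else NA_character_,
                         ""),
                  vapply(kv, `[`, "", 1))
}

#' Read epochs from a TSV epoch file
#'
#' @param path Path to a file written by [write_epochs()].
#' @return List of `nwr_epoch` objects in file order.
#' @export
read_epochs <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# nwreflex epoch file")) {
    stop("not an nwreflex epoch file (bad header at line 1): ", path)
  }
  meta <- list(participant_id = "P01", site = "FS",
               sampling_rate_Hz = 1000, t0_offset_ms = -500)
  i <- 2L
  while (i <= length(lines) && startsWith(lines[i], "# ") &&
         !startsWith(lines[i], "# trial")) {
    m <- regmatches(lines[i], regexec("^# ([A-Za-z0-9_]+): (.*)$", lines[i]))[[1]]
    if (length(m) != 3) stop("malformed header at line ", i, ": ", lines[i])
    key <- m[2]
    meta[[key]] <- if (key %in% c("sampling_rate_Hz", "t0_offset_ms")) {
      as.numeric(m[3])
    } else {
      m[3]
    }
    i <- i + 1L
  }
  if (i > length(lines) || !identical(lines[i], "time_ms\tTA_uV\tSO_uV")) {
    stop("malformed column header at line ", i, " of ", path)
  }
  i <- i + 1L
  epochs <- list()
  trial_meta <- NULL
  ta <- so <- NULL
  flush_trial <- function() {
    if (is.null(trial_meta)) return()
    ep <- emg_epoch(
      participant_id = meta$participant_id, trial_index = trial_meta$index,
      site = meta$site, energy_mJ = trial_meta$energy_mJ,
      sampling_rate_Hz = meta$sampling_rate_Hz,
      t0_offset_ms = meta$t0_offset_ms,
      samples_TA = ta, samples_SO = so,
      pain_rating = trial_meta$pain_rating, valid = trial_meta$valid)
    epochs[[length(epochs) + 1L]] <<- ep
  }
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "# trial")) {
      flush_trial()
      m <- regmatches(ln, regexec("^# trial ([0-9]+) ?(.*)$", ln))[[1]]
      if (length(m) != 3) stop("malformed trial line at line ", i, ": ", ln)
      kv <- parse_kv(m[3])
      num_or_na <- function(v) {
        if (is.null(v) || is.na(v) || identical(v, "NA")) NA_real_
        else as.numeric(v)
      }
      trial_meta <- list(index = as.integer(m[2]),
                         energy_mJ = num_or_na(kv[["energy_mJ"]]),
                         pain_rating = num_or_na(kv[["pain_rating"]]),
                         valid = !identical(kv[["valid"]], "FALSE"))
      ta <- numeric(); so <- numeric()
    } else if (nzchar(trimws(ln))) {
      if (is.null(trial_meta)) stop("sample row before any '# trial' line at line ", i)
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 3) {
        stop("channel length mismatch in trial ", trial_meta$index,
             ": expected 3 columns at line ", i, ", found ", length(f))
      }
      ta <- c(ta, as.numeric(f[2])); so <- c(so, as.numeric(f[3]))
    }
    i <- i + 1L
  }
  flush_trial()
  epochs
}

MISSING_TOKENS <- c("n.a.", "MD", "", "NA", "na", "n.a")

norm_missing <- function(x) {
  x <- trimws(x)
  x[x %in% MISSING_TOKENS] <- NA_character_
  x
}

parse_joints <- function(s) {
  # ";"-separated joint scores -> numeric vector (possibly length 0)
  if (is.na(s) || !nzchar(s)) return(numeric())
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

yn <- function(x, row, col) {
  x <- toupper(norm_missing(x))
  bad <- !is.na(x) & !x %in% c("Y", "N", "YES", "NO")
  if (any(bad)) {
    stop("unknown ", col, " value '", x[bad][1], "' in row ", row[bad][1])
  }
  ifelse(is.na(x), NA, substr(x, 1, 1) == "Y")
}

#' Read a clinical cohort table
#'
#' Reads a TSV with the cohort-table column layout (ID, Age, Gender, AIS,
#' NLI, TSI, SCIPI, CPG, NocP, NRS, MAS, SCAT, plus optional Group,
#' MAS_joints / SCAT_joints and the inter-site distance columns).  Missing
#' markers `"n.a."`, `"MD"` and empty cells map to `NA`.  MAS/SCAT columns
#' hold the per-participant joint-score means; joint-level scores, when
#' available, are `";"`-separated in the `*_joints` columns.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with one row per participant (class
#'   `nwr_clinical`): `participant_id`, `group`, `age_years`, `sex`, `AIS`,
#'   `NLI`, `TSI_years`, `SCIPI_score`, `CPG_neuropathic`, `NocP`,
#'   `NRS_spontaneous`, `MAS_mean`, `SCAT_mean`, `MAS_joints`,
#'   `SCAT_joints`, `distance_FS_FH_m`, `distance_FD_FH_m`.
#' @export
read_clinical_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           na.strings = NULL)
  if (nrow(raw) == 0) return(empty_clinical())
  get <- function(col, default = NA_character_) {
    if (col %in% names(raw)) norm_missing(raw[[col]]) else rep(default, nrow(raw))
  }
  rows <- seq_len(nrow(raw))
  ais <- get("AIS")
  bad <- !is.na(ais) & !ais %in% c("A", "B", "C", "D", "E")
  if (any(bad)) {
    stop("unknown AIS value '", ais[bad][1], "' in row ", rows[bad][1])
  }
  grp <- get("Group", "SCI")
  grp[is.na(grp)] <- "SCI"
  if (!all(grp %in% c("SCI", "NDC"))) {
    stop("unknown Group value '", setdiff(grp, c("SCI", "NDC"))[1], "'")
  }
  mas_joints <- get("MAS_joints", "")
  scat_joints <- get("SCAT_joints", "")
  out <- data.frame(
    participant_id = get("ID"),
    group = grp,
    age_years = as.numeric(get("Age")),
    sex = get("Gender"),
    AIS = ais,
    NLI = get("NLI"),
    TSI_years = as.numeric(get("TSI")),
    SCIPI_score = as.integer(get("SCIPI")),
    CPG_neuropathic = yn(get("CPG"), rows, "CPG"),
    NocP = yn(get("NocP"), rows, "NocP"),
    NRS_spontaneous = as.numeric(get("NRS")),
    MAS_mean = as.numeric(get("MAS")),
    SCAT_mean = as.numeric(get("SCAT")),
    MAS_joints = ifelse(is.na(mas_joints), "", mas_joints),
    SCAT_joints = ifelse(is.na(scat_joints), "", scat_joints),
    distance_FS_FH_m = as.numeric(get("distance_FS_FH_m")),
    distance_FD_FH_m = as.numeric(get("distance_FD_FH_m", "0.40")),
    stringsAsFactors = FALSE
  )
  # joint-mean consistency (tolerance 0.01) where both are present
  for (k in seq_len(nrow(out))) {
    mj <- parse_joints(out$MAS_joints[k])
    if (length(mj) && !is.na(out$MAS_mean[k]) &&
        abs(mean(mj) - out$MAS_mean[k]) > 0.01) {
      stop("MAS mean/joint-score mismatch in row ", k, " (",
           out$participant_id[k], ")")
    }
  }
  class(out) <- c("nwr_clinical", "data.frame")
  out
}

empty_clinical <- function() {
  out <- data.frame(
    participant_id = character(), group = character(), age_years = numeric(),
    sex = character(), AIS = character(), NLI = character(),
    TSI_years = numeric(), SCIPI_score = integer(),
    CPG_neuropathic = logical(), NocP = logical(),
    NRS_spontaneous = numeric(), MAS_mean = numeric(), SCAT_mean = numeric(),
    MAS_joints = character(), SCAT_joints = character(),
    distance_FS_FH_m = numeric(), distance_FD_FH_m = numeric(),
    stringsAsFactors = FALSE)
  class(out) <- c("nwr_clinical", "data.frame")
  out
}

#' Write a clinical cohort table
#'
#' Inverse of [read_clinical_table()]; `NA` values are written as `n.a.`.
#'
#' @param clinical A clinical `data.frame` as returned by
#'   [read_clinical_table()] or [simulate_clinical_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  tok <- function(x) {
    out <- as.character(x)
    out[is.na(x)] <- "n.a."
    out
  }
  raw <- data.frame(
    ID = tok(clinical$participant_id),
    Group = tok(clinical$group),
    Age = tok(clinical$age_years),
    Gender = tok(clinical$sex),
    AIS = tok(clinical$AIS),
    NLI = tok(clinical$NLI),
    TSI = tok(clinical$TSI_years),
    SCIPI = tok(clinical$SCIPI_score),
    CPG = tok(ifelse(clinical$CPG_neuropathic, "Y", "N")),
    NocP = tok(ifelse(clinical$NocP, "Y", "N")),
    NRS = tok(clinical$NRS_spontaneous),
    MAS = tok(clinical$MAS_mean),
    SCAT = tok(clinical$SCAT_mean),
    MAS_joints = clinical$MAS_joints,
    SCAT_joints = clinical$SCAT_joints,
    distance_FS_FH_m = tok(clinical$distance_FS_FH_m),
    distance_FD_FH_m = tok(clinical$distance_FD_FH_m),
    check.names = FALSE)
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference SCI cohort table
#'
#' The packaged clinical table of the 15-participant spinal-cord-injury
#' reference cohort (demographics, injury characteristics, pain and
#' spasticity scores) used throughout the examples and by the clinical
#' statistics battery.
#'
#' @return A clinical `data.frame`, see [read_clinical_table()].
#' @export
reference_cohort <- function() {
  read_clinical_table(system.file("extdata", "sci_cohort_clinical.tsv",
                                  package = "nwreflex", mustWork = TRUE))
}

#' Read / write a trial manifest
#'
#' One row per (participant, site, trial): laser energy, inter-stimulus
#' interval, per-stimulus pain rating and validity flag.
#'
#' @param path TSV path.
#' @return `read_trial_manifest()`: a `data.frame` with columns
#'   `participant_id`, `site`, `trial_index`, `energy_mJ`, `ISI_ms`,
#'   `pain_rating`, `valid`.
#' @export
read_trial_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$valid <- as.logical(df$valid)
  df
}

#' @rdname read_trial_manifest
#' @param manifest Manifest `data.frame`.
#' @export
write_trial_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a detection event table
#'
#' One row per detected reflex event (see [detect_trial()]).
#'
#' @param path TSV path.
#' @return `read_events()`: the event `data.frame`.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$coactivated <- as.logical(df$coactivated)
  df$valid <- as.logical(df$valid)
  df
}

#' @rdname read_events
#' @param events Event `data.frame`.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
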