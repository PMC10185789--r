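# Nonparametric primitives of the clinical battery, each specified so a
# brute-force oracle can verify it: Wilcoxon rank-sum (exact enumeration at
# small n, tie-corrected normal approximation otherwise, effect size
# r = |Z| / sqrt(N)), Fisher's exact 2x2 with phi, Kendall tau-b by pair
# counting with tie corrections, and the eta coefficient
# sqrt(SS_between / SS_total) for binary-vs-metric association.

stat_result <- function(method, statistic, p_value, tails, effect_size,
                        effect_kind, n, note = "") {
  data.frame(method = method, statistic = statistic, p_value = p_value,
             tails = tails, effect_size = effect_size,
             effect_kind = effect_kind, n = n, note = note,
             stringsAsFactors = FALSE)
}

tails_of <- function(alternative) {
  if (alternative == "two.sided") "two" else "one"
}

#' Wilcoxon rank-sum test with effect size r
#'
#' Rank-sum statistic `W` (sum of midranks of `x`).  For combined sample
#' sizes of at most `exact_max` the p-value comes from exhaustive
#' enumeration of all rank assignments; otherwise from the normal
#' approximation with tie correction and continuity correction.  The effect
#' size is `r = |Z| / sqrt(n1 + n2)` (small < 0.3, medium < 0.5,
#' large > 0.5).
#'
#' @param x,y Numeric samples (non-empty, `NA` removed).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_max Largest combined n for exact enumeration (default 12).
#' @return One-row `data.frame` (`StatResult`): method, statistic `W`,
#'   p-value, tails, effect size `r`, n.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less"),
                              exact_max = 12) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  all_v <- c(x, y)
  rk <- rank(all_v)  # midranks
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  degenerate <- v <= 0
  if (degenerate) {
    return(stat_result("wilcoxon_rank_sum", W, 1, tails_of(alternative),
                       0, "r", N, "all values identical"))
  }
  # z with continuity correction toward the null
  cc <- if (W > mu) 0.5 else if (W < mu) -0.5 else 0
  z <- (W - mu - cc) / sqrt(v)
  if (N <= exact_max) {
    # exhaustive enumeration over all C(N, n1) assignments of the midranks
    idx <- utils::combn(N, n1)
    Wd <- colSums(matrix(rk[idx], nrow = n1))
    eps <- 1e-9
    p_ge <- mean(Wd >= W - eps)
    p_le <- mean(Wd <= W + eps)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    p <- min(1, max(p, .Machine$double.xmin))
  }
  r <- abs(z) / sqrt(N)
  stat_result("wilcoxon_rank_sum", W, p, tails_of(alternative), r, "r", N)
}

as_2x2 <- function(t) {
  if (is.matrix(t)) {
    stopifnot(all(dim(t) == c(2, 2)))
    c(a = t[1, 1], b = t[1, 2], c = t[2, 1], d = t[2, 2])
  } else {
    stopifnot(length(t) == 4)
    stats::setNames(as.numeric(t), c("a", "b", "c", "d"))
  }
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, cell `a` is hypergeometric.  The two-sided
#' p-value sums the probabilities of all tables no more probable than the
#' observed one; one-sided p-values sum the corresponding tail.
#'
#' @param t 2x2 matrix or length-4 vector `(a, b, c, d)` in row order.
#' @param alternative `"two.sided"`, `"greater"` (positive `a`-cell
#'   association) or `"less"`.
#' @return One-row `StatResult` with the odds-ratio-free cell count `a` as
#'   statistic and phi as effect size.
#' @export
fisher_exact_2x2 <- function(t, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  v <- as_2x2(t)
  a <- v["a"]; b <- v["b"]; cc <- v["c"]; d <- v["d"]
  if (any(v < 0) || sum(v) == 0) stop("counts must be non-negative with positive total")
  m <- a + b; n <- cc + d; k <- a + cc
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    stop("every margin of the 2x2 table must be positive")
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- switch(alternative,
              two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
              greater = sum(probs[support >= a]),
              less = sum(probs[support <= a]))
  p <- min(1, p)
  phi <- tryCatch(phi_coefficient(v), error = function(e) NA_real_)
  stat_result("fisher_exact", unname(a), unname(p), tails_of(alternative),
              phi, "phi", unname(sum(v)))
}

#' Phi coefficient of a 2x2 table
#'
#' `|ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d))`, reported as an absolute value
#' (small < 0.3, medium 0.3-0.5, large > 0.5).
#'
#' @param t 2x2 matrix or length-4 vector `(a, b, c, d)`.
#' @return Phi in `[0, 1]`.
#' @export
phi_coefficient <- function(t) {
  v <- as_2x2(t)
  mrg <- c(v["a"] + v["b"], v["c"] + v["d"], v["a"] + v["c"], v["b"] + v["d"])
  if (any(mrg == 0)) stop("phi requires all margins > 0")
  unname(abs(v["a"] * v["d"] - v["b"] * v["c"]) / sqrt(prod(mrg)))
}

#' Kendall rank correlation tau-b
#'
#' Pair-counting implementation with tie corrections:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` where `C`/`D` are
#' concordant/discordant pair counts and `n1`, `n2` the tied-pair counts in
#' each variable.  The p-value uses the normal approximation for
#' `S = C - D` with the tie-corrected variance.
#'
#' @param x,y Numeric vectors (pairwise-complete, n >= 3 after removal).
#' @param alternative `"two.sided"`, `"greater"` (positive association) or
#'   `"less"`.
#' @return One-row `StatResult` with statistic `tau_b`.
#' @export
kendall_tau_b <- function(x, y,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("kendall_tau_b needs at least 3 complete pairs")
  C <- D <- 0
  for (i in 1:(n - 1)) {
    dx <- sign(x[(i + 1):n] - x[i])
    dy <- sign(y[(i + 1):n] - y[i])
    C <- C + sum(dx * dy > 0)
    D <- D + sum(dx * dy < 0)
  }
  S <- C - D
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    return(stat_result("kendall_tau_b", NA_real_, 1, tails_of(alternative),
                       NA_real_, "tau_b",
                       n, "zero variance in x or y; tau undefined"))
  }
  tau <- S / denom
  # tie-corrected variance of S
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v2 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (varS > 0) S / sqrt(varS) else 0
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  p <- min(1, max(p, .Machine$double.xmin))
  stat_result("kendall_tau_b", tau, p, tails_of(alternative), tau, "tau_b", n)
}

#' Eta coefficient for a binary grouping
#'
#' `eta = sqrt(SS_between / SS_total)` of the metric variable across the
#' two groups, pairwise-complete.  `eta^2` equals the R-squared of the
#' one-way two-level analysis-of-variance decomposition.
#'
#' @param groups Binary group labels (any two distinct values).
#' @param y Metric variable.
#' @return Eta in `[0, 1]`; `NA` (with a warning) when `SS_total` is zero.
#' @export
eta_coefficient <- function(groups, y) {
  ok <- stats::complete.cases(groups, y)
  g <- groups[ok]; y <- y[ok]
  lv <- unique(g)
  if (length(lv) != 2) stop("eta_coefficient needs exactly two non-empty groups")
  gm <- mean(y)
  sst <- sum((y - gm)^2)
  if (sst == 0) {
    warning("SS_total is zero; eta undefined")
    return(NA_real_)
  }
  ssb <- sum(vapply(lv, function(l) {
    yl <- y[g == l]
    length(yl) * (mean(yl) - gm)^2
  }, 0))
  sqrt(ssb / sst)
}

# Eta with a p-value from the equivalent one-way ANOVA F test (eta^2 is
# that model's R^2); used by the battery where an associated p is reported.
eta_stat <- function(groups, y, tails = "two") {
  ok <- stats::complete.cases(groups, y)
  g <- factor(groups[ok]); yy <- y[ok]
  n <- length(yy)
  eta <- eta_coefficient(as.character(g), yy)
  p <- NA_real_
  if (!is.na(eta) && n > 2) {
    r2 <- eta^2
    f <- (r2 / 1) / ((1 - r2) / (n - 2))
    p <- max(stats::pf(f, 1, n - 2, lower.tail = FALSE),
             .Machine$double.xmin)
  }
  stat_result("eta", eta, p, tails, eta, "eta", n)
}

#' Clinical relevance classification
#'
#' Applies the cohort's clinical thresholds to each record: spasticity is
#' clinically relevant when any examined joint exceeds grade 1 on either
#' the Modified Ashworth Scale or the spinal cord assessment tool (with
#' only joint means available, when either mean exceeds 1); the
#' neuropathic-pain screen is positive at SCIPI >= 4 of 7; spontaneous pain
#' is relevant at NRS >= 4 of 10.
#'
#' @param clinical Clinical `data.frame` (see [read_clinical_table()]).
#' @return `data.frame` with `participant_id`, `spasticity_relevant`,
#'   `scipi_positive`, `nrs_relevant`.
#' @export
classify_clinical <- function(clinical) {
  spast <- vapply(seq_len(nrow(clinical)), function(k) {
    mj <- parse_joints(clinical$MAS_joints[k])
    sj <- parse_joints(clinical$SCAT_joints[k])
    if (length(mj) || length(sj)) {
      return(any(c(mj, sj) > 1))
    }
    means <- c(clinical$MAS_mean[k], clinical$SCAT_mean[k])
    if (all(is.na(means))) return(NA)
    any(means > 1, na.rm = TRUE)
  }, NA)
  data.frame(
    participant_id = clinical$participant_id,
    spasticity_relevant = spast,
    scipi_positive = ifelse(is.na(clinical$SCIPI_score), NA,
                            clinical$SCIPI_score >= 4),
    nrs_relevant = ifelse(is.na(clinical$NRS_spontaneous), NA,
                          clinical$NRS_spontaneous >= 4),
    stringsAsFactors = FALSE)
}
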