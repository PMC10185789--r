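# Nonparametric primitives against closed forms and independent oracles.

test_that("Wilcoxon rank-sum: exact enumeration matches known small cases", {
  # complete separation of n1 = n2 = 3: two-tailed exact p = 2/20
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$tails, "two")
  # identical samples: p = 1, r = 0
  r0 <- wilcoxon_rank_sum(c(2, 2, 5), c(2, 5, 2))
  expect_equal(r0$p_value, 1)
  expect_equal(r0$effect_size, 0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon exact p agrees with the reference implementation without ties", {
  for (seed in 1:20) {
    d <- nwreflex:::with_seed(seed, {
      n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
      list(x = rnorm(n1), y = rnorm(n2),
           alt = sample(c("two.sided", "greater", "less"), 1))
    })
    mine <- wilcoxon_rank_sum(d$x, d$y, d$alt)
    ref <- stats::wilcox.test(d$x, d$y, alternative = d$alt, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10,
                 label = paste("seed", seed))
  }
})

test_that("Wilcoxon normal approximation tracks the reference at moderate n", {
  for (seed in 1:10) {
    d <- nwreflex:::with_seed(seed, {
      list(x = rnorm(20), y = rnorm(25, 0.5))
    })
    mine <- wilcoxon_rank_sum(d$x, d$y, "two.sided")
    ref <- stats::wilcox.test(d$x, d$y, exact = FALSE, correct = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
    # effect size r = |Z|/sqrt(N) stays in [0, 1]
    expect_gte(mine$effect_size, 0)
    expect_lte(mine$effect_size, 1)
  }
})

test_that("Fisher's exact test reproduces the printed pain-spasticity association", {
  # 2/8 spasticity among pain-positive vs 6/7 among pain-negative
  r <- fisher_exact_2x2(c(2, 6, 6, 1))
  expect_equal(round(r$p_value, 2), 0.04)
  expect_equal(round(r$effect_size, 2), 0.61)
  expect_equal(r$n, 15)
  # no association / perfect association edge cases
  expect_equal(fisher_exact_2x2(c(1, 1, 1, 1))$p_value, 1)
  expect_equal(fisher_exact_2x2(c(0, 5, 5, 0))$p_value, 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(c(0, 0, 3, 4)), "margin")
})

test_that("Fisher p equals hypergeometric enumeration for random tables (N <= 30)", {
  for (seed in 1:200) {
    tb <- nwreflex:::with_seed(seed, {
      repeat {
        v <- stats::rmultinom(1, sample(4:30, 1), prob = runif(4, 0.2, 1))[, 1]
        if (all(c(v[1] + v[2], v[3] + v[4], v[1] + v[3], v[2] + v[4]) > 0)) break
      }
      v
    })
    mine <- fisher_exact_2x2(tb)
    expect_equal(mine$p_value,
                 oracle_fisher_two_sided(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9,
                 label = paste("table", paste(tb, collapse = ",")))
  }
})

test_that("one-sided Fisher tails agree with the reference implementation", {
  for (seed in 1:30) {
    tb <- nwreflex:::with_seed(seed, {
      v <- stats::rmultinom(1, 20, prob = rep(0.25, 4))[, 1] + 1
      v
    })
    for (alt in c("greater", "less")) {
      mine <- fisher_exact_2x2(tb, alt)
      ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE), alternative = alt)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    }
  }
})

test_that("phi coefficient matches its closed form", {
  expect_equal(round(phi_coefficient(c(2, 6, 6, 1)), 2), 0.61)
  expect_equal(phi_coefficient(c(1, 1, 1, 1)), 0, ignore_attr = TRUE)
  expect_equal(phi_coefficient(c(5, 0, 0, 5)), 1, ignore_attr = TRUE)
  expect_error(phi_coefficient(c(5, 5, 0, 0)), "margins")
})

test_that("Kendall tau-b equals brute-force pair counting, with and without ties", {
  expect_equal(kendall_tau_b(1:3, 1:3)$statistic, 1)
  expect_equal(kendall_tau_b(1:3, 3:1)$statistic, -1)
  expect_equal(kendall_tau_b(c(1, 2, 2, 3), c(1, 3, 2, 4))$statistic,
               oracle_tau_b(c(1, 2, 2, 3), c(1, 3, 2, 4)))
  for (seed in 1:40) {
    d <- nwreflex:::with_seed(seed, {
      n <- sample(5:50, 1)
      list(x = sample(0:6, n, replace = TRUE),
           y = sample(0:10, n, replace = TRUE))
    })
    if (length(unique(d$x)) < 2 || length(unique(d$y)) < 2) next
    mine <- kendall_tau_b(d$x, d$y)
    expect_equal(mine$statistic, oracle_tau_b(d$x, d$y), tolerance = 1e-12)
    expect_equal(mine$statistic, cor(d$x, d$y, method = "kendall"),
                 tolerance = 1e-12)
  }
  # zero variance: flagged, never an invalid p
  r <- kendall_tau_b(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_true(is.na(r$statistic))
  expect_match(r$note, "zero variance")
  expect_error(kendall_tau_b(1:2, 1:2), "at least 3")
})

test_that("tau-b p-values agree with the reference normal approximation", {
  for (seed in 1:10) {
    d <- nwreflex:::with_seed(seed, {
      n <- 20
      list(x = rnorm(n), y = rnorm(n))
    })
    mine <- kendall_tau_b(d$x, d$y)
    ref <- suppressWarnings(
      stats::cor.test(d$x, d$y, method = "kendall", exact = FALSE,
                      continuity = FALSE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("eta is the square root of the between/total sum-of-squares ratio", {
  # equal group means -> 0; zero within-group variance -> 1
  expect_equal(eta_coefficient(rep(c("a", "b"), each = 3),
                               c(1, 2, 3, 3, 2, 1)), 0)
  expect_equal(eta_coefficient(c("a", "a", "b", "b"), c(2, 2, 7, 7)), 1)
  expect_warning(eta_coefficient(c("a", "a", "b"), c(4, 4, 4)), "undefined")
  expect_error(eta_coefficient(rep("a", 4), rnorm(4)), "two")

  # eta^2 equals the R^2 of the one-way ANOVA decomposition
  for (seed in 1:30) {
    d <- nwreflex:::with_seed(seed, {
      g <- sample(c("x", "y"), 12, replace = TRUE)
      if (length(unique(g)) < 2) g[1:2] <- c("x", "y")
      list(g = g, y = rnorm(12, ifelse(g == "x", 0, 0.8)))
    })
    eta <- eta_coefficient(d$g, d$y)
    fit <- stats::aov(y ~ g, data = data.frame(g = d$g, y = d$y))
    r2 <- summary(fit)[[1]][["Sum Sq"]][1] / sum(summary(fit)[[1]][["Sum Sq"]])
    expect_equal(eta^2, r2, tolerance = 1e-10)
  }
})

test_that("one-tailed p never exceeds the two-tailed p on the same data", {
  for (seed in 1:25) {
    d <- nwreflex:::with_seed(seed, {
      list(x = rnorm(8), y = rnorm(9, 0.6),
           u = sample(0:5, 12, replace = TRUE),
           v = sample(0:5, 12, replace = TRUE))
    })
    two <- wilcoxon_rank_sum(d$x, d$y, "two.sided")$p_value
    dir <- if (wilcoxon_rank_sum(d$x, d$y, "greater")$p_value <=
               wilcoxon_rank_sum(d$x, d$y, "less")$p_value) "greater" else "less"
    expect_lte(wilcoxon_rank_sum(d$x, d$y, dir)$p_value, two + 1e-12)
    if (length(unique(d$u)) > 1 && length(unique(d$v)) > 1) {
      t2 <- kendall_tau_b(d$u, d$v, "two.sided")$p_value
      t1 <- min(kendall_tau_b(d$u, d$v, "greater")$p_value,
                kendall_tau_b(d$u, d$v, "less")$p_value)
      expect_lte(t1, t2 + 1e-12)
    }
    f2 <- fisher_exact_2x2(c(3, 5, 6, 2), "two.sided")$p_value
    f1 <- min(fisher_exact_2x2(c(3, 5, 6, 2), "greater")$p_value,
              fisher_exact_2x2(c(3, 5, 6, 2), "less")$p_value)
    expect_lte(f1, f2 + 1e-12)
  }
})

test_that("clinical classification applies the relevance thresholds", {
  cl <- reference_cohort()
  flags <- classify_clinical(cl)
  # neuropathic-pain screen positive at >= 4 of 7: 8 of 15
  expect_equal(sum(flags$scipi_positive), 8)
  # NRS >= 4 boundary inclusive
  expect_true(flags$nrs_relevant[cl$NRS_spontaneous == 4][1])
  expect_equal(sum(flags$nrs_relevant), 10)
  # means-only spasticity rule reconstructs the printed 2x2 split
  tab <- table(cl$CPG_neuropathic, flags$spasticity_relevant)
  expect_equal(as.integer(tab[c("TRUE", "FALSE"), c("TRUE", "FALSE")]),
               c(2, 6, 6, 1))

  # joint-level any-joint rule dominates when joint scores exist
  rec <- cl[1, ]
  rec$MAS_joints <- "0.5;1.5"; rec$SCAT_joints <- "0;0"
  rec$MAS_mean <- 1.0; rec$SCAT_mean <- 0
  expect_true(classify_clinical(rec)$spasticity_relevant)
  rec$MAS_joints <- "0.5;1"; rec$SCAT_joints <- "1;1"
  expect_false(classify_clinical(rec)$spasticity_relevant)
})
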