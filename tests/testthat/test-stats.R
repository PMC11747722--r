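test_that("paired baseline-washout t-test matches the closed form", {
  cfg <- synth_config(n_animals = 3L, seed = 15L)
  tbl <- suppressWarnings(simulate_study_table(cfg))
  # force washout - baseline differences of exactly [1, 0, 2]
  b <- tbl$period_label == "baseline" & tbl$block == 1L
  w <- tbl$period_label == "washout"
  tbl$icp[b] <- c(10, 10, 10)[tbl$animal[b]]
  tbl$icp[w] <- c(11, 10, 12)[tbl$animal[w]]
  rep <- test_crossover_assumptions(tbl, "delta_icp")
  expect_equal(rep$statistics$t, sqrt(3), tolerance = 1e-9)
  expect_equal(rep$statistics$df, 2)
  expect_equal(rep$p$paired_baseline_washout, 2 * pt(-sqrt(3), 2),
               tolerance = 1e-9)

  # identical baseline and washout vectors degenerate and are flagged
  tbl$icp[w] <- c(10, 10, 10)[tbl$animal[w]]
  rep0 <- test_crossover_assumptions(tbl, "delta_icp")
  expect_true(is.na(rep0$p$paired_baseline_washout))
  expect_match(paste(rep0$notes, collapse = " "), "degenerate")
})

test_that("crossover assumption report carries all three design p-values", {
  cfg <- synth_config(n_animals = 8L, seed = 23L)
  tbl <- suppressWarnings(simulate_study_table(cfg))
  rep <- test_crossover_assumptions(tbl, "delta_icp")
  ps <- unlist(rep$p[c("carryover", "sequence", "period")])
  expect_true(all(is.finite(ps)))
  expect_true(all(ps >= 0 & ps <= 1))

  # single-sequence data cannot estimate sequence effects
  one <- tbl[tbl$sequence == tbl$sequence[1], ]
  rep1 <- test_crossover_assumptions(one, "delta_icp")
  expect_true(is.na(rep1$p$sequence))
  expect_match(paste(rep1$notes, collapse = " "), "single sequence")
})

test_that("baseline comparison picks the distribution-appropriate test", {
  base <- data.frame(
    animal = 1:6, block = 1L, period_label = "baseline",
    position = rep(c("prone", "supine"), each = 3)
  )
  base$same <- c(1, 2, 3, 1, 2, 3)
  base$far <- c(1, 2, 3, 101, 102, 103)
  out <- compare_baselines(base, c("same", "far"))
  expect_equal(out$p[out$variable == "same"], 1, tolerance = 1e-12)
  expect_lt(out$p[out$variable == "far"], 0.01)
  expect_equal(out$test, c("t", "t"))

  # a heavily skewed variable routes to Mann-Whitney
  set.seed(2)
  sk <- data.frame(animal = 1:24, block = 1L, period_label = "baseline",
                   position = rep(c("prone", "supine"), each = 12),
                   x = exp(rnorm(24, 0, 2)))
  outs <- compare_baselines(sk, "x")
  expect_equal(outs$test, "mann-whitney")
})

test_that("two-way RM ANOVA agrees with a brute-force stratum SS oracle", {
  set.seed(30)
  d <- expand.grid(animal = 1:4, peep = c(10, 15, 20),
                   position = c("prone", "supine"),
                   stringsAsFactors = FALSE)
  d$sequence <- "prone-first"; d$block <- 1L
  d$period_label <- "intervention"
  d$delta_icp <- rnorm(nrow(d)) + 0.8 * (d$position == "supine") +
    rep(rnorm(4), 6)                          # animal offsets
  rep <- anova_peep_position(d, "delta_icp")

  # brute-force sums of squares for the animal-blocked two-factor design
  y <- d$delta_icp; A <- factor(d$animal); P <- factor(d$peep)
  S <- factor(d$position)
  gm <- mean(y)
  ss <- function(f) {
    m <- tapply(y, f, mean)
    sum((m[f] - gm)^2)
  }
  ss_a <- ss(A); ss_p <- ss(P); ss_s <- ss(S)
  ss_ap <- ss(interaction(A, P)) - ss_a - ss_p
  ss_as <- ss(interaction(A, S)) - ss_a - ss_s
  ss_ps <- ss(interaction(P, S)) - ss_p - ss_s
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_a - ss_p - ss_s - ss_ap - ss_as - ss_ps
  f_peep <- (ss_p / 2) / (ss_ap / 6)
  f_pos <- (ss_s / 1) / (ss_as / 3)
  f_ixn <- (ss_ps / 2) / (ss_res / 6)
  expect_equal(unname(rep$statistics$F["peep"]), f_peep, tolerance = 1e-8)
  expect_equal(unname(rep$statistics$F["position"]), f_pos,
               tolerance = 1e-8)
  expect_equal(unname(rep$statistics$F["interaction"]), f_ixn,
               tolerance = 1e-8)
  expect_equal(rep$p$interaction, pf(f_ixn, 2, 6, lower.tail = FALSE),
               tolerance = 1e-8)

  # SS decomposition closes
  expect_equal(ss_a + ss_p + ss_s + ss_ap + ss_as + ss_ps + ss_res,
               ss_tot, tolerance = 1e-8)

  # constant outcome: no variance anywhere
  d0 <- d; d0$delta_icp <- 2
  rep0 <- anova_peep_position(d0, "delta_icp")
  expect_equal(unlist(rep0$p), c(peep = 1, position = 1, interaction = 1))

  # a missing cell is reported by name
  expect_error(anova_peep_position(d[-1, ], "delta_icp"),
               "missing PEEP x position")
})

test_that("repeated-measures one-way ANOVA matches aov and handles ties", {
  set.seed(33)
  d <- expand.grid(animal = 1:6, peep = c(10, 15, 20),
                   position = "prone", stringsAsFactors = FALSE)
  d$sequence <- "prone-first"; d$block <- 1L
  d$period_label <- "intervention"
  d$delta_icp <- 0.4 * (d$peep - 5) / 5 + rep(rnorm(6), 3) + rnorm(18, 0, .3)
  rep <- pooled_change_anova(d, "delta_icp")
  ref <- summary(aov(delta_icp ~ factor(peep) + Error(factor(animal)),
                     data = d))
  tab <- ref[["Error: Within"]][[1]]
  expect_equal(rep$statistics$F, tab["factor(peep)", "F value"],
               tolerance = 1e-9)
  expect_equal(rep$p$peep, tab["factor(peep)", "Pr(>F)"], tolerance = 1e-9)

  # identical deltas across levels for every animal
  d$delta_icp <- rep(rnorm(6), 3)
  rep0 <- pooled_change_anova(d, "delta_icp")
  expect_equal(rep0$statistics$F, 0)
  expect_equal(rep0$p$peep, 1)

  expect_error(pooled_change_anova(d[d$peep == 10, ], "delta_icp"),
               "2 intervention PEEP")
})

test_that("covariate screen: exact linearity, skipping, and reporting", {
  cfg <- synth_config(n_animals = 8L, seed = 41L)
  tbl <- suppressWarnings(simulate_study_table(cfg, resid_sd = 0))
  # overwrite: delta exactly linear in baseline cvp
  base <- tbl[tbl$period_label == "baseline", ]
  bk <- interaction(base$animal, base$block)
  iv <- tbl$period_label == "intervention"
  m <- match(interaction(tbl$animal, tbl$block)[iv], bk)
  tbl$delta_icp[iv] <- 2 * base$cvp[m] - 3
  out <- baseline_correlation_screen(tbl, c("cvp"))
  expect_equal(out$r, 1, tolerance = 1e-9)
  expect_equal(out$slope, 2, tolerance = 1e-6)

  tbl$flatcov <- 1
  expect_warning(baseline_correlation_screen(tbl, c("flatcov")),
                 "constant")
})
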