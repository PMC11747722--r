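#' @importFrom lme4 lmer
NULL

new_stat_report <- function(test, formula = NULL, estimates = NULL,
                            statistics = NULL, p = NULL, diagnostics = NULL,
                            notes = character()) {
  structure(list(test = test, formula = formula, estimates = estimates,
                 statistics = statistics, p = p, diagnostics = diagnostics,
                 notes = notes),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("Statistical report:", x$test, "\n")
  if (!is.null(x$formula)) cat("  model:", x$formula, "\n")
  if (!is.null(x$p)) {
    for (nm in names(x$p))
      cat(sprintf("  p[%s] = %s\n", nm, format.pval(x$p[[nm]], digits = 3)))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Crossover-design assumption tests
#'
#' Tests the assumptions of the two-period crossover design for a
#' change-from-baseline outcome: absence of carry-over, sequence
#' (prone-first vs supine-first) and period (first vs second block)
#' effects. A linear mixed model is fitted by maximum likelihood with PEEP
#' step, sequence and period as fixed effects plus the sequence-by-PEEP
#' interaction, and random intercepts for animal and for position within
#' animal. The carry-over p-value (the sequence x PEEP interaction, a
#' within-block contrast with ample residual information) is a
#' likelihood-ratio test between nested ML fits. The sequence and period
#' main effects are tested with Wald t statistics from the REML fit using
#' design-stratum degrees of freedom — sequence varies between animals
#' (df = n_animals - 2), period between blocks within animal
#' (df = n_animals - 1) — which keeps their type-I error near nominal at
#' study-sized n where the 1-df likelihood-ratio test is anticonservative.
#' The carry-over assumption is
#' additionally probed with a paired two-tailed t-test comparing each
#' animal's first-block baseline with its washout value of the underlying
#' variable.
#'
#' @param tbl study table (one row per animal x period) with columns
#'   \code{animal}, \code{sequence}, \code{block}, \code{position},
#'   \code{peep}, \code{period_label} and the outcome.
#' @param outcome change-from-baseline column, \code{"delta_icp"} (default)
#'   or \code{"delta_prx_z"}.
#' @return A \code{stat_report} with p-values \code{carryover},
#'   \code{sequence}, \code{period} and \code{paired_baseline_washout}.
#' @export
test_crossover_assumptions <- function(tbl,
                                       outcome = c("delta_icp",
                                                   "delta_prx_z",
                                                   "delta_prx")) {
  outcome <- match.arg(outcome)
  iv <- tbl[tbl$period_label == "intervention" & !is.na(tbl[[outcome]]), ]
  notes <- character()
  p <- list(carryover = NA_real_, sequence = NA_real_, period = NA_real_,
            paired_baseline_washout = NA_real_)

  if (length(unique(iv$sequence)) < 2L) {
    notes <- c(notes, "single sequence: sequence/carry-over not estimable")
  } else {
    d <- data.frame(y = iv[[outcome]], peep = factor(iv$peep),
                    seqn = factor(iv$sequence), period = factor(iv$block),
                    animal = factor(iv$animal),
                    position = factor(iv$position))
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                              calc.derivs = FALSE)
    fit <- function(fml, reml) suppressWarnings(suppressMessages(
      lme4::lmer(fml, data = d, REML = reml, control = ctrl)))
    full <- fit(y ~ peep * seqn + period + (1 | animal) +
                  (1 | animal:position), FALSE)
    addv <- fit(y ~ peep + seqn + period + (1 | animal) +
                  (1 | animal:position), FALSE)
    p$carryover <- lrt_p(addv, full)
    reml <- fit(y ~ peep + seqn + period + (1 | animal) +
                  (1 | animal:position), TRUE)
    co <- summary(reml)$coefficients
    n_anim <- nlevels(d$animal)
    p$sequence <- wald_p(co, "^seqn", n_anim - 2L)
    p$period <- wald_p(co, "^period", n_anim - 1L)
  }

  base_var <- switch(outcome, delta_icp = "icp", delta_prx = "prx",
                     delta_prx_z = "prx_z")
  pt <- paired_baseline_washout(tbl, base_var)
  p$paired_baseline_washout <- pt$p
  notes <- c(notes, pt$notes)

  new_stat_report(
    test = paste("crossover assumptions for", outcome),
    formula = paste(outcome, "~ peep * sequence + period",
                    "+ (1|animal) + (1|animal:position)  [ML, LRT]"),
    statistics = pt$stat, p = p, notes = notes)
}

wald_p <- function(coefs, pattern, df) {
  i <- grep(pattern, rownames(coefs))
  if (length(i) != 1L || df < 1L) return(NA_real_)
  2 * stats::pt(-abs(coefs[i, "t value"]), df)
}

lrt_p <- function(small, big) {
  ll0 <- as.numeric(stats::logLik(small))
  ll1 <- as.numeric(stats::logLik(big))
  df <- attr(stats::logLik(big), "df") - attr(stats::logLik(small), "df")
  if (df <= 0) return(NA_real_)
  stats::pchisq(max(0, 2 * (ll1 - ll0)), df = df, lower.tail = FALSE)
}

paired_baseline_washout <- function(tbl, var) {
  b <- tbl[tbl$period_label == "baseline" & tbl$block == 1L, ]
  w <- tbl[tbl$period_label == "washout", ]
  common <- intersect(b$animal, w$animal)
  if (length(common) < 2L || !var %in% names(tbl))
    return(list(p = NA_real_, stat = NULL,
                notes = "baseline/washout pairing unavailable"))
  x <- b[[var]][match(common, b$animal)]
  y <- w[[var]][match(common, w$animal)]
  d <- y - x
  if (stats::sd(d) == 0 || anyNA(d))
    return(list(p = NA_real_, stat = list(t = NA_real_, df = length(d) - 1),
                notes = "degenerate paired test (zero-variance differences)"))
  tt <- stats::t.test(y, x, paired = TRUE)
  list(p = tt$p.value,
       stat = list(t = unname(tt$statistic), df = unname(tt$parameter)),
       notes = character())
}

#' Compare baseline variables between positions
#'
#' For each variable, compares the pre-randomization first-block baseline
#' values between animals that started prone and animals that started
#' supine. Normality is assessed per group with the Shapiro-Wilk test; if
#' both groups are compatible with normality (p >= 0.05) a two-tailed
#' Welch t-test is used and mean (SD) reported, otherwise the Mann-Whitney
#' test with median (IQR). Groups smaller than 3 skip the normality test
#' and use Mann-Whitney.
#'
#' @param tbl study table.
#' @param variables character vector of numeric columns to compare;
#'   defaults to all numeric summary columns present.
#' @return A data frame with one row per variable: group summaries, the
#'   test used, its statistic and p-value.
#' @export
compare_baselines <- function(tbl, variables = NULL) {
  b <- tbl[tbl$period_label == "baseline" & tbl$block == 1L, ]
  if (length(unique(b$position)) < 2L)
    stop("baseline rows for both positions are required")
  if (is.null(variables)) {
    skip <- c("animal", "block", "period_index", "peep", "n_valid_icp")
    variables <- setdiff(names(b)[vapply(b, is.numeric, logical(1))], skip)
  }
  rows <- lapply(variables, function(v) {
    g1 <- b[[v]][b$position == "prone"]
    g2 <- b[[v]][b$position == "supine"]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    if (length(g1) < 2L || length(g2) < 2L)
      return(NULL)
    normal <- function(g) length(g) >= 3L && stats::sd(g) > 0 &&
      stats::shapiro.test(g)$p.value >= 0.05
    use_t <- normal(g1) && normal(g2)
    if (use_t && (stats::sd(g1) == 0 && stats::sd(g2) == 0)) use_t <- FALSE
    if (use_t) {
      ht <- stats::t.test(g1, g2)
      desc1 <- sprintf("%.3g ± %.3g", mean(g1), stats::sd(g1))
      desc2 <- sprintf("%.3g ± %.3g", mean(g2), stats::sd(g2))
    } else {
      ht <- suppressWarnings(stats::wilcox.test(g1, g2))
      q1 <- stats::quantile(g1, c(.25, .5, .75)); q2 <- stats::quantile(g2, c(.25, .5, .75))
      desc1 <- sprintf("%.3g (%.3g-%.3g)", q1[2], q1[1], q1[3])
      desc2 <- sprintf("%.3g (%.3g-%.3g)", q2[2], q2[1], q2[3])
    }
    data.frame(variable = v, n_prone = length(g1), n_supine = length(g2),
               prone = desc1, supine = desc2,
               test = if (use_t) "t" else "mann-whitney",
               statistic = unname(ht$statistic), p = ht$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way ANOVA of a change outcome over PEEP and position
#'
#' Two-way repeated-measures ANOVA of the outcome on PEEP level, position
#' and their interaction over the intervention periods, with animal as the
#' blocking factor (both factors vary within animal; one value per animal
#' per PEEP x position cell). Each effect is tested against its own
#' animal-interaction error stratum, so the change-score correlation
#' induced by the shared within-block baseline does not bias the tests.
#' The interaction term answers whether the PEEP effect differs between
#' prone and supine.
#'
#' @param tbl study table.
#' @param outcome outcome column, default \code{"delta_icp"}.
#' @return A \code{stat_report} with the stratum ANOVA tables in
#'   \code{statistics$anova} and p-values \code{peep}, \code{position},
#'   \code{interaction}.
#' @export
anova_peep_position <- function(tbl, outcome = "delta_icp") {
  iv <- tbl[tbl$period_label == "intervention", ]
  cells <- expand.grid(animal = unique(iv$animal),
                       peep = unique(iv$peep),
                       position = unique(iv$position))
  have <- interaction(iv$animal, iv$peep, iv$position, drop = FALSE)
  want <- interaction(cells$animal, cells$peep, cells$position)
  missing <- cells[!(want %in% have[!is.na(iv[[outcome]])]), , drop = FALSE]
  if (nrow(missing))
    stop("missing PEEP x position cells: ",
         paste(sprintf("animal %s peep %s %s", missing$animal,
                       missing$peep, missing$position), collapse = "; "))
  d <- data.frame(y = iv[[outcome]], peep = factor(iv$peep),
                  position = factor(iv$position),
                  animal = factor(iv$animal))
  if (stats::var(d$y) == 0) {
    p <- list(peep = 1, position = 1, interaction = 1)
    return(new_stat_report("two-way ANOVA (constant outcome)",
                           p = p, notes = "zero variance: all F = 0"))
  }
  fit <- stats::aov(y ~ peep * position +
                      Error(animal / (peep * position)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- grep(paste0("^", term, "\\s*$"), trimws(rownames(tab)))
    list(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  e_p <- pull("animal:peep", "peep")
  e_s <- pull("animal:position", "position")
  e_i <- pull("animal:peep:position", "peep:position")
  p <- list(peep = e_p$p, position = e_s$p, interaction = e_i$p)
  new_stat_report(
    test = paste("two-way repeated-measures ANOVA of", outcome,
                 "on PEEP x position"),
    formula = paste(outcome, "~ peep * position + Error(animal/(peep*position))"),
    statistics = list(anova = sm,
                      F = c(peep = e_p$F, position = e_s$F,
                            interaction = e_i$F)),
    p = p)
}

#' Repeated-measures one-way ANOVA of pooled changes over PEEP
#'
#' With prone and supine responses pooled (no interaction), tests whether
#' the change-from-baseline outcome differs across the intervention PEEP
#' levels with a classical within-subject one-way ANOVA (sphericity
#' assumed, no correction). The repeated unit is the position block
#' (animal x position); each unit must contribute one value per PEEP
#' level, incomplete units are dropped with a warning.
#'
#' @param tbl study table.
#' @param outcome outcome column, default \code{"delta_icp"}.
#' @return A \code{stat_report} with \code{statistics} (SS decomposition,
#'   F, df) and \code{p$peep}.
#' @export
pooled_change_anova <- function(tbl, outcome = "delta_icp") {
  iv <- tbl[tbl$period_label == "intervention" & !is.na(tbl[[outcome]]), ]
  levels_p <- sort(unique(iv$peep))
  if (length(levels_p) < 2L) stop("need at least 2 intervention PEEP levels")
  subj <- interaction(iv$animal, iv$position, drop = TRUE)
  counts <- table(subj)
  keep <- names(counts)[counts == length(levels_p)]
  if (length(keep) < length(counts))
    warning("dropping ", length(counts) - length(keep),
            " incomplete subject(s)")
  iv <- iv[subj %in% keep, ]
  subj <- droplevels(subj[subj %in% keep])
  y <- iv[[outcome]]
  trt <- factor(iv$peep)
  s <- nlevels(subj); k <- nlevels(trt)

  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  ss_subj <- k * sum((tapply(y, subj, mean) - gm)^2)
  ss_treat <- s * sum((tapply(y, trt, mean) - gm)^2)
  ss_err <- ss_total - ss_subj - ss_treat
  df_treat <- k - 1L
  df_err <- (s - 1L) * (k - 1L)
  if (ss_treat <= 1e-12 * max(1, ss_total)) {
    f <- 0; pv <- 1
  } else {
    f <- (ss_treat / df_treat) / (ss_err / df_err)
    pv <- stats::pf(f, df_treat, df_err, lower.tail = FALSE)
  }
  new_stat_report(
    test = paste("repeated-measures one-way ANOVA of", outcome,
                 "across PEEP (positions pooled)"),
    formula = paste(outcome, "~ peep + Error(animal:position)"),
    statistics = list(F = f, df = c(df_treat, df_err),
                      ss = c(treatment = ss_treat, subjects = ss_subj,
                             error = ss_err, total = ss_total)),
    p = list(peep = pv))
}

#' Exploratory baseline-covariate correlation screen
#'
#' For each baseline covariate, relates the PEEP-induced change in ICP
#' (intervention periods, prone and supine pooled) to the covariate's
#' value in the same position block's baseline period. Reports the Pearson
#' correlation between pooled per-period changes and the baseline
#' covariate, and the covariate slope and likelihood-ratio p-value from a
#' linear mixed model with a random animal intercept. No multiple-testing
#' correction is applied.
#'
#' @param tbl study table containing \code{delta_icp} and the covariate
#'   columns.
#' @param covariates character vector of covariate column names; defaults
#'   to the standard screen list intersected with available columns.
#' @param outcome change column, default \code{"delta_icp"}.
#' @return A data frame with one row per covariate: \code{slope}, \code{r},
#'   \code{p}, \code{n}. Constant covariates are skipped with a warning.
#' @export
baseline_correlation_screen <- function(tbl, covariates = NULL,
                                        outcome = "delta_icp") {
  if (is.null(covariates)) {
    std <- c("icp", "rap", "PaO2", "PaCO2", "VT_ml", "RR", "Paw_ei",
             "TPP_ei", "TPP_ee", "E_rs", "E_l", "MP_rs", "cvp", "PAP", "CO")
    covariates <- intersect(std, names(tbl))
  }
  iv <- tbl[tbl$period_label == "intervention" & !is.na(tbl[[outcome]]), ]
  base <- tbl[tbl$period_label == "baseline", ]
  bkey <- interaction(base$animal, base$block)
  ikey <- interaction(iv$animal, iv$block)
  m <- match(ikey, bkey)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  rows <- lapply(covariates, function(v) {
    x <- base[[v]][m]
    y <- iv[[outcome]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4L) return(NULL)
    if (stats::sd(x[ok]) == 0) {
      warning("covariate ", v, " is constant; skipped")
      return(NULL)
    }
    d <- data.frame(y = y[ok], x = x[ok], animal = factor(iv$animal[ok]))
    f1 <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ x + (1 | animal), data = d, REML = FALSE,
                 control = ctrl)))
    f0 <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ 1 + (1 | animal), data = d, REML = FALSE,
                 control = ctrl)))
    data.frame(covariate = v,
               slope = unname(lme4::fixef(f1)["x"]),
               r = stats::cor(d$x, d$y),
               p = lrt_p(f0, f1), n = nrow(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
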