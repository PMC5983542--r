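test_that("partial eta squared reproduces the printed effect sizes", {
  expect_equal(round(partial_eta_sq(12.46, 1, 49), 2), 0.20)
  expect_equal(round(partial_eta_sq(4.52, 1, 49), 2), 0.08)
  expect_equal(partial_eta_sq(0, 1, 49), 0)
  # algebraic identity over random inputs
  set.seed(103)
  F_ <- rexp(20, 1 / 5); d1 <- sample(1:4, 20, TRUE)
  d2 <- sample(10:80, 20, TRUE)
  expect_equal(partial_eta_sq(F_, d1, d2), F_ * d1 / (F_ * d1 + d2))
  expect_error(partial_eta_sq(1, 0, 10), "positive")
})

test_that("Cohen's ds conversion matches printed values", {
  expect_equal(cohens_ds_from_t(0, 26, 25), 0)
  expect_equal(round(cohens_ds_from_t(-0.84, 26, 25), 2), 0.24)
  expect_equal(round(cohens_ds_from_t(0.12, 26, 25), 2), 0.03)
  expect_error(cohens_ds_from_t(1, 1, 25), ">= 2")
})

test_that("Bonferroni thresholds divide the family alpha", {
  expect_equal(bonferroni_adjust(0.05, 5), 0.01)
  expect_equal(bonferroni_adjust(0.05, 10), 0.005)
  expect_equal(bonferroni_adjust(0.07, 1), 0.07)
  expect_error(bonferroni_adjust(0.05, 0), "m")
})

test_that("Fisher z comparison follows the closed form", {
  expect_equal(fisher_z_compare(0.4, 30, 0.4, 20)$z, 0)
  fz <- fisher_z_compare(0.57, 26, 0.29, 25)
  expect_equal(fz$z, 1.17, tolerance = 0.01)
  swap <- fisher_z_compare(0.29, 25, 0.57, 26)
  expect_equal(swap$z, -fz$z)
  expect_equal(fz$p, 2 * pnorm(-abs(fz$z)))
  expect_error(fisher_z_compare(1, 10, 0.5, 10), "strictly")
  expect_error(fisher_z_compare(0.2, 3, 0.5, 10), "exceed 3")
})

test_that("partial correlation reduces to Pearson without covariates", {
  set.seed(107)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)
})

test_that("controlling for the shared covariate removes the correlation", {
  set.seed(109)
  z <- rnorm(60)
  x <- z + 0.1 * rnorm(60)
  pc <- partial_correlation(x, z + 0.1 * rnorm(60),
                            covariates = data.frame(z = z))
  expect_lt(abs(pc$r), 0.35)
  expect_equal(pc$df, 60 - 1 - 2)
})

test_that("partial correlation matches an independent residualization", {
  x <- c(2.1, 3.4, 1.2, 5.6, 4.3)
  y <- c(1.0, 2.2, 0.4, 3.9, 3.1)
  z <- c(0.5, 1.1, 0.2, 2.0, 1.4)
  pc <- partial_correlation(x, y, z)
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-12)
  expect_equal(pc$n, 5)
  expect_error(partial_correlation(x, y, cbind(z, 2 * z)))
  expect_error(partial_correlation(x, y, rep(1, 5)), "constant")
  expect_error(partial_correlation(x[1:3], y[1:3], z[1:3]), "observations")
})

test_that("missing values are dropped casewise", {
  set.seed(113)
  x <- rnorm(25); y <- rnorm(25); z <- rnorm(25)
  x[c(2, 5)] <- NA
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$n, 23)
})

test_that("mixed ANOVA matches the hand-computed sums of squares", {
  d <- data.frame(subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
                  group = rep(c("control", "mdd"), each = 4),
                  valence = rep(c("rpe", "ppe"), 4),
                  value = c(1.2, 0.3, 0.9, 0.1, 0.4, 0.5, 0.2, 0.6))
  res <- mixed_anova(d, "value", "group", "valence")
  oracle <- oracle_split_plot(d$value, d$group, d$valence, d$subject)
  expect_equal(res$F[res$effect == "group"], oracle$F_group,
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "valence"], oracle$F_within,
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group x valence"],
               oracle$F_interaction, tolerance = 1e-10)
  expect_equal(res$pes, res$F * res$df1 / (res$F * res$df1 + res$df2))
})

test_that("mixed ANOVA handles two within factors and reports all effects", {
  set.seed(127)
  d <- expand.grid(subject = sprintf("s%02d", 1:12),
                   valence = c("rpe", "ppe"),
                   hemisphere = c("left", "right"))
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 6,
                    "control", "mdd")
  d$value <- rnorm(nrow(d))
  res <- mixed_anova(d, "value", "group", c("valence", "hemisphere"))
  expect_setequal(res$effect,
                  c("group", "valence", "group x valence", "hemisphere",
                    "group x hemisphere", "valence x hemisphere",
                    "group x valence x hemisphere"))
  expect_true(all(res$df2 == 10))
  expect_true(all(res$pes >= 0 & res$pes <= 1))
})

test_that("degenerate ANOVA inputs raise informative errors", {
  d <- data.frame(subject = rep(c("s1", "s2"), each = 2),
                  group = "control", valence = rep(c("a", "b"), 2),
                  value = rnorm(4))
  expect_error(mixed_anova(d, "value", "group", "valence"), "two levels")
  d2 <- data.frame(subject = c("s1", "s1", "s2"),
                   group = c("g1", "g1", "g2"),
                   valence = c("a", "b", "a"), value = rnorm(3))
  expect_error(mixed_anova(d2, "value", "group", "valence"), "cell")
})

test_that("learning-curve model recovers a planted reward deficit sign", {
  set.seed(131)
  make_cohort <- function(gain_deficit) {
    subs <- sprintf("s%02d", 1:16)
    grp <- rep(c("control", "mdd"), each = 8)
    do.call(rbind, lapply(seq_along(subs), function(i) {
      base <- 0.75 + rnorm(1, 0, 0.05)
      p_gain <- base - if (grp[i] == "mdd") gain_deficit else 0
      tr <- rep(1:30, 2)
      val <- rep(c("gain", "loss"), each = 30)
      p <- ifelse(val == "gain", p_gain, base)
      data.frame(subject = subs[i], group = grp[i], valence = val,
                 trial = tr, choice = rbinom(60, 1, pmin(pmax(p, 0), 1)))
    }))
  }
  # constant within-subject choice probabilities leave no slope variance,
  # so the random-slope fit may flag convergence; only signs matter here
  res <- suppressWarnings(learning_curve_interaction(make_cohort(0.25)))
  expect_lt(res$interaction_b, 0)
  expect_lt(res$interaction_p, 0.05)
  expect_equal(res$slopes$valence, c("gain", "loss"))
  expect_error(learning_curve_interaction(make_cohort(0)[0, ]), "empty")
  one_grp <- make_cohort(0)
  one_grp$group <- "control"
  expect_error(learning_curve_interaction(one_grp), "two groups")
})
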