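#' Partial eta squared from an F statistic
#'
#' eta_p^2 = F df1 / (F df1 + df2), the proportion of effect-plus-error
#' variance attributable to the effect in ANOVA designs.
#'
#' @param F_value F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared in \[0, 1\]. Vectorized.
#' @export
partial_eta_sq <- function(F_value, df1, df2) {
  if (any(df1 <= 0) || any(df2 <= 0))
    stop("degrees of freedom must be positive", call. = FALSE)
  if (any(F_value < 0)) stop("F must be >= 0", call. = FALSE)
  F_value * df1 / (F_value * df1 + df2)
}

#' Cohen's ds from a two-sample t statistic
#'
#' ds = |t| sqrt(1/n1 + 1/n2), the standardized mean difference implied by
#' an independent-groups t test.
#'
#' @param t_value t statistic.
#' @param n1,n2 Group sizes (>= 2).
#' @return Cohen's ds (>= 0). Vectorized in `t_value`.
#' @export
cohens_ds_from_t <- function(t_value, n1, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  abs(t_value) * sqrt(1 / n1 + 1 / n2)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha_family Family-wise error rate.
#' @param m Number of tests in the family (>= 1).
#' @return Per-test significance threshold `alpha_family / m`.
#' @export
bonferroni_adjust <- function(alpha_family, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha_family / m
}

#' Fisher z comparison of two independent correlations
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)) with a
#' two-sided normal p value.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (> 3).
#' @return List with `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Partial correlation controlling for covariates
#'
#' Correlates the residuals of `x` and `y` after linear regression on the
#' covariates (with intercept); with no covariates this is the Pearson
#' correlation. The p value uses a t reference with n - k - 2 degrees of
#' freedom, k the number of covariates. Rows with any missing value are
#' dropped.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric vector, matrix or data.frame of
#'   controlling variables.
#' @return An object of class `correlation_result`: `r`, `n`, `df`, `p`,
#'   `covariates` (names).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    Z <- matrix(numeric(0), nrow = length(x), ncol = 0)
    cov_names <- character(0)
  } else {
    Z <- as.matrix(as.data.frame(covariates))
    cov_names <- colnames(Z)
  }
  keep <- complete.cases(x, y, if (ncol(Z)) Z else rep(0, length(x)))
  x <- x[keep]; y <- y[keep]; Z <- Z[keep, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n <= k + 2)
    stop("need more than ", k + 2, " complete observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0 || (k > 0 && any(apply(Z, 2, sd) == 0)))
    stop("constant columns are not allowed", call. = FALSE)
  if (k > 0) {
    D <- cbind(1, Z)
    if (qr(D)$rank < ncol(D))
      stop("rank-deficient covariates", call. = FALSE)
    x <- lm.fit(D, x)$residuals
    y <- lm.fit(D, y)$residuals
  }
  r <- cor(x, y)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, n = n, df = df,
                 p = 2 * pt(-abs(tval), df),
                 covariates = cov_names),
            class = "correlation_result")
}

check_balanced <- function(data, subject, factors) {
  cells <- interaction(data[factors], drop = FALSE)
  tab <- table(data[[subject]], cells)
  if (any(tab != 1)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    if (nrow(miss) > 0)
      stop("missing cells: ",
           paste(apply(miss, 1, function(i)
             paste0(rownames(tab)[i[1]], ":", colnames(tab)[i[2]])),
             collapse = ", "), call. = FALSE)
    stop("design must have exactly one value per subject x cell",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Mixed-design (split-plot) ANOVA with partial eta squared
#'
#' Between-subjects Group crossed with one or more within-subject factors,
#' one observation per subject per within-cell, fitted by the classical
#' sums-of-squares decomposition (`aov` with subject Error strata, no
#' sphericity correction). Every effect is reported with F, degrees of
#' freedom, p, and partial eta squared.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the value column.
#' @param between Name of the between-subjects factor (default `"group"`).
#' @param within Character vector of within-subject factor names.
#' @param subject Name of the subject-id column (default `"subject"`).
#' @return An object of class `anova_result`: data.frame with `effect`,
#'   `F`, `df1`, `df2`, `p`, `pes`.
#' @export
mixed_anova <- function(data, dv, between = "group", within,
                        subject = "subject") {
  for (v in c(dv, between, within, subject))
    if (!v %in% names(data)) stop("column not found: ", v, call. = FALSE)
  data[[subject]] <- factor(data[[subject]])
  data[[between]] <- factor(data[[between]])
  for (w in within) data[[w]] <- factor(data[[w]])
  if (nlevels(data[[between]]) < 2)
    stop("between factor must have at least two levels", call. = FALSE)
  check_balanced(data, subject, within)
  fixed <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject, "/(",
                paste(within, collapse = " * "), "))")
  form <- as.formula(paste(dv, "~", fixed, "+", err))
  fit <- aov(form, data = data)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      if (terms[i] == "Residuals") next
      df2 <- tab["Residuals", "Df"]
      out[[length(out) + 1L]] <-
        data.frame(effect = gsub(":", " x ", terms[i]),
                   F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = df2,
                   p = tab[i, "Pr(>F)"],
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$pes <- partial_eta_sq(res$F, res$df1, res$df2)
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Mixed-effects learning-curve interaction model
#'
#' Linear probability model of trial-level choices on
#' Trials x Valence x Group with per-subject random intercepts, fitted by
#' REML (lmer, Satterthwaite p values). Valence is coded with loss as the
#' reference level and group with control as the reference, so the
#' Group x Valence coefficient is the MDD-minus-control accuracy deficit
#' specific to the gain condition (negative under a selective
#' reward-learning impairment); the per-valence Group x Trials slopes are
#' the group differences in learning speed, on the choice-probability-per-
#' trial scale.
#'
#' @param trials data.frame with columns `subject`, `group` (control/mdd),
#'   `valence` (gain/loss), `trial` (within-condition position) and
#'   `choice` (0/1 or proportion correct).
#' @return An object of class `learning_curve_result`: `interaction_b`,
#'   `interaction_se`, `interaction_p` (Group x Valence), plus a `slopes`
#'   data.frame with per-valence Group x Trials coefficients.
#' @export
learning_curve_interaction <- function(trials) {
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  trials$group <- factor(trials$group)
  trials$valence <- factor(trials$valence, levels = c("loss", "gain"))
  if (nlevels(droplevels(trials$group)) < 2)
    stop("need two groups", call. = FALSE)
  if (any(!c("gain", "loss") %in% trials$valence))
    stop("need both gain and loss trials", call. = FALSE)
  trials$trial_c <- trials$trial - mean(trials$trial)
  # random valence slopes absorb subject-specific valence effects (each
  # subject carries its own learning rates); without them the
  # Group x Valence test is anticonservative
  fit <- lmerTest::lmer(
    choice ~ trial_c * valence * group + (1 + valence | subject),
    data = trials,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  cf <- as.data.frame(summary(fit)$coefficients)
  iterm <- grep("^valencegain:group", rownames(cf), value = TRUE)
  slopes <- lapply(c("gain", "loss"), function(v) {
    sub <- trials[trials$valence == v, ]
    f <- lmerTest::lmer(choice ~ trial_c * group + (1 + trial_c | subject),
                        data = sub,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
    sc <- as.data.frame(summary(f)$coefficients)
    sterm <- grep("^trial_c:group", rownames(sc), value = TRUE)
    data.frame(valence = v, b = sc[sterm, "Estimate"],
               se = sc[sterm, "Std. Error"], p = sc[sterm, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  })
  structure(list(interaction_b = cf[iterm, "Estimate"],
                 interaction_se = cf[iterm, "Std. Error"],
                 interaction_p = cf[iterm, "Pr(>|t|)"],
                 slopes = do.call(rbind, slopes)),
            class = "learning_curve_result")
}
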