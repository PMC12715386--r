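#' Expected common-to-male allele ratio for a known sex composition
#'
#' Under an XY system the male-specific allele is carried only by males, at
#' a per-male common-to-male copy ratio `rho` (about 7 for the validated
#' locus). With every individual contributing equally to the DNA pool (mock
#' extract mixtures), a sample of M males and F females is expected to show
#' a common-to-male ratio of `rho * (M + F) / M`. In mass-proportional mode
#' (eDNA, shedding scaling with biomass) the head count is replaced by the
#' mass fraction: `rho * total_mass / male_mass`.
#'
#' @param n_males,n_females Individuals of each sex in the sample.
#' @param rho Per-male common-to-male copy ratio (default 7).
#' @param mode "equal" (per-capita contributions) or "mass".
#' @param male_mass,total_mass Masses in grams, for `mode = "mass"`.
#' @return Expected common-to-male ratio; `Inf` when no males.
#' @examples
#' expected_ratio(1, 1)      # 14
#' expected_ratio(3, 1)      # 28/3
#' @export
expected_ratio <- function(n_males, n_females = 0, rho = 7,
                           mode = c("equal", "mass"),
                           male_mass = NULL, total_mass = NULL) {
  mode <- match.arg(mode)
  stopifnot(rho > 0, n_males >= 0, n_females >= 0, n_males + n_females >= 1)
  if (n_males == 0) return(Inf)
  if (mode == "equal") {
    rho * (n_males + n_females) / n_males
  } else {
    stopifnot(!is.null(male_mass), !is.null(total_mass),
              male_mass > 0, total_mass >= male_mass)
    rho * total_mass / male_mass
  }
}

#' Expected ratio from known individuals
#'
#' When the individuals composing a sample are genotyped and their
#' per-individual common-to-male copy ratios are known, the hypothesised
#' common-to-male ratio of the pool follows from summing contributions:
#' with equal per-individual input the pool ratio is
#' `(M + F) / sum(1 / rho_i)` over the males; with mass-proportional
#' contributions each individual is weighted by `mass^b`. This is the
#' sharper alternative to the population-average model of
#' [expected_ratio()]: it absorbs known between-male copy-number variation
#' instead of averaging over it.
#'
#' @param inds data.frame with columns `sex` ("M"/"F") and `rho_i`
#'   (females `Inf` or `NA`), plus `mass_g` for mass mode (as produced by
#'   [simulate_individuals()]).
#' @param mode "equal" or "mass".
#' @param allometry_b Exponent for mass weighting.
#' @return Expected common-to-male ratio; `Inf` when no males.
#' @export
expected_ratio_individuals <- function(inds, mode = c("equal", "mass"),
                                       allometry_b = 1) {
  mode <- match.arg(mode)
  stopifnot(nrow(inds) >= 1, all(inds$sex %in% c("M", "F")))
  w <- if (mode == "equal") rep(1, nrow(inds)) else inds$mass_g^allometry_b
  inv_rho <- ifelse(inds$sex == "M" & is.finite(inds$rho_i), 1 / inds$rho_i, 0)
  male_part <- sum(w * inv_rho)
  if (male_part == 0) return(Inf)
  sum(w) / male_part
}

#' Male proportion implied by an observed allele ratio
#'
#' Inverts the equal-contribution expected-ratio model: if a sample of
#' male proportion p shows male-to-common ratio `r = p / rho`, then
#' `p = rho * r`. The raw estimate can exceed 1 (e.g., a sample dominated by
#' a high-copy male); both the raw and the [0, 1]-clamped value are
#' returned, and any confidence interval supplied on the male-to-common
#' scale is propagated through the same linear map.
#'
#' @param r_obs Observed male-to-common allele ratio (>= 0). May be a
#'   vector.
#' @param rho Per-male common-to-male copy ratio (default 7).
#' @param ci_low,ci_high Optional confidence bounds on `r_obs`.
#' @param mass_corrected Logical flag recorded in the result.
#' @return data.frame: `r_obs`, `p_male_raw`, `p_male` (clamped),
#'   `ci_low`, `ci_high` (clamped), `mass_corrected`.
#' @examples
#' estimate_male_proportion(1 / 14) # 0.5
#' @export
estimate_male_proportion <- function(r_obs, rho = 7,
                                     ci_low = NULL, ci_high = NULL,
                                     mass_corrected = FALSE) {
  stopifnot(all(r_obs >= 0), rho > 0)
  raw <- rho * r_obs
  clamp <- function(x) pmin(1, pmax(0, x))
  data.frame(
    r_obs = r_obs,
    p_male_raw = raw,
    p_male = clamp(raw),
    ci_low = if (is.null(ci_low)) NA_real_ else clamp(rho * ci_low),
    ci_high = if (is.null(ci_high)) NA_real_ else clamp(rho * ci_high),
    mass_corrected = mass_corrected
  )
}

#' Biomass correction of allele ratios
#'
#' Rescales observed allele ratios by the sample's body-mass composition:
#' male-to-common ratios are multiplied by the male-to-total mass
#' proportion, common-to-male ratios by its inverse. This converts a
#' biomass-weighted eDNA signal onto the per-capita scale the sex-ratio
#' model assumes, and is the identity when male mass equals total mass.
#'
#' @param ratio One-row data.frame with `common_to_male` and
#'   `male_to_common` (e.g., from [allele_ratio()]).
#' @param male_mass,total_mass Masses in grams; `0 < male_mass <= total_mass`
#'   except that `male_mass = 0` is allowed when no male signal is present.
#' @return The ratio data.frame with corrected values and a
#'   `mass_corrected` flag.
#' @export
mass_correct <- function(ratio, male_mass, total_mass) {
  stopifnot(total_mass > 0, male_mass >= 0, male_mass <= total_mass)
  if (male_mass == 0) {
    if (is.finite(ratio$male_to_common) && ratio$male_to_common > 0) {
      stop("male mass is zero but a male-allele signal is present; inconsistent metadata")
    }
    ratio$mass_corrected <- TRUE
    return(ratio)
  }
  f <- male_mass / total_mass
  ratio$male_to_common <- ratio$male_to_common * f
  ratio$common_to_male <- ratio$common_to_male / f
  for (col in c("ci_low", "ci_high")) {
    if (col %in% names(ratio)) ratio[[col]] <- ratio[[col]] / f
  }
  ratio$mass_corrected <- TRUE
  ratio
}

#' Parse "xM:yF" sex-composition labels
#'
#' @param label Character vector like "3M:1F", "1M" (= "1M:0F"), "4F".
#' @return data.frame with columns `n_males`, `n_females`.
#' @export
parse_group_label <- function(label) {
  one <- function(s) {
    s <- gsub(" ", "", s)
    m <- regmatches(s, regexec("^(?:([0-9]+)M)?:?(?:([0-9]+)F)?$", s))[[1]]
    if (length(m) == 0 || (m[2] == "" && m[3] == "")) {
      stop("cannot parse sex-composition label: '", s, "'")
    }
    c(n_males = if (m[2] == "") 0L else as.integer(m[2]),
      n_females = if (m[3] == "") 0L else as.integer(m[3]))
  }
  out <- as.data.frame(do.call(rbind, lapply(label, one)))
  out$label <- label
  out
}

#' Calibration regression of allele ratio against sex composition
#'
#' Two ordinary-least-squares calibrations of the assay:
#' \describe{
#'   \item{`"proportion"`}{`log10(male-to-common ratio + 1)` regressed on
#'     `log10(male proportion + 1)` — the dose-response of the male signal
#'     against the fraction of males.}
#'   \item{`"expected"`}{`log10(observed common-to-male ratio)` on
#'     `log10(expected common-to-male ratio)`; a slope not significantly
#'     different from 1 is evidence of accurate quantification, so the
#'     slope-equals-one test is reported.}
#' }
#'
#' @param x Predictor: male proportion (variant "proportion") or expected
#'   common-to-male ratio (variant "expected").
#' @param y Response: male-to-common ratio (variant "proportion") or
#'   observed common-to-male ratio (variant "expected").
#' @param variant Which calibration to fit.
#' @return Object of class `ednasex_calibration`: list with `slope`,
#'   `intercept`, `slope_ci_low`, `slope_ci_high`, `r_squared`,
#'   `f_statistic`, `df`, `p_value`, `slope_eq_one_p` (expected variant),
#'   and the underlying `lm` fit.
#' @export
calibrate <- function(x, y, variant = c("proportion", "expected")) {
  variant <- match.arg(variant)
  stopifnot(length(x) == length(y), length(x) >= 3)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2) stop("degenerate design: a single predictor value")
  if (variant == "proportion") {
    tx <- log10(x + 1); ty <- log10(y + 1)
  } else {
    stopifnot(all(x > 0), all(y > 0))
    tx <- log10(x); ty <- log10(y)
  }
  fit <- stats::lm(ty ~ tx)
  sm <- summary(fit)
  ci <- stats::confint(fit)["tx", ]
  slope <- unname(stats::coef(fit)["tx"])
  se <- sm$coefficients["tx", "Std. Error"]
  eq1 <- if (variant == "expected") {
    2 * stats::pt(abs((slope - 1) / se), df = fit$df.residual, lower.tail = FALSE)
  } else {
    NA_real_
  }
  out <- list(variant = variant, slope = slope,
              intercept = unname(stats::coef(fit)[1]),
              slope_ci_low = unname(ci[1]), slope_ci_high = unname(ci[2]),
              r_squared = sm$r.squared,
              f_statistic = unname(sm$fstatistic["value"]),
              df = unname(sm$fstatistic["dendf"]),
              p_value = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                                  sm$fstatistic["dendf"], lower.tail = FALSE),
              slope_eq_one_p = eq1, fit = fit)
  class(out) <- "ednasex_calibration"
  out
}

#' @export
print.ednasex_calibration <- function(x, ...) {
  cat(sprintf("Calibration (%s): slope = %.3f (95%% CI %.3f-%.3f), R2 = %.3f, F(%g) = %.2f, p = %.3g\n",
              x$variant, x$slope, x$slope_ci_low, x$slope_ci_high,
              x$r_squared, x$df, x$f_statistic, x$p_value))
  if (!is.na(x$slope_eq_one_p)) {
    cat(sprintf("  slope-equals-one test: p = %.3g\n", x$slope_eq_one_p))
  }
  invisible(x)
}

# Dunn's rank-based post hoc test after Kruskal-Wallis, with
# Benjamini-Hochberg adjustment; z statistics use the tie-corrected
# large-sample variance of mean rank differences.
dunn_bh <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  gl <- levels(groups)
  pairs <- utils::combn(gl, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    c(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ], p_unadj = res["p", ],
             p_adj = stats::p.adjust(res["p", ], method = "BH"),
             row.names = NULL)
}

#' Compare allele ratios across sex-ratio groups
#'
#' Omnibus and post hoc comparison of log10-transformed common-to-male
#' allele ratios between sex-composition groups. In `"auto"` mode a one-way
#' ANOVA is used when its assumptions hold — residual normality by
#' Shapiro-Wilk and homoscedasticity by Levene's test, both at p >= 0.05 —
#' with Tukey's HSD post hoc; otherwise a Kruskal-Wallis test followed by
#' Dunn's test with Benjamini-Hochberg adjustment.
#'
#' @param ratio Common-to-male allele ratios (positive).
#' @param group Group labels (coerced to factor).
#' @param mode "auto", "parametric" or "nonparametric".
#' @param log_transform Log10-transform ratios before testing (default TRUE).
#' @return Object of class `ednasex_grouptest`: list with `method`,
#'   `statistic`, `df`, `p_value`, `posthoc` (data.frame of pairwise
#'   comparisons) and assumption-check p-values.
#' @export
compare_groups <- function(ratio, group,
                           mode = c("auto", "parametric", "nonparametric"),
                           log_transform = TRUE) {
  mode <- match.arg(mode)
  if (is.factor(group) && any(table(group) == 0)) stop("empty group")
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  y <- if (log_transform) log10(ratio) else ratio
  keep <- is.finite(y)
  y <- y[keep]; group <- droplevels(group[keep])
  if (stats::var(y) == 0) {
    # no variation anywhere: omnibus statistic at its null value
    out <- list(method = if (mode == "parametric") "anova_tukey" else "kruskal_dunn_bh",
                statistic = 0, df = nlevels(group) - 1, df_resid = NA_real_,
                p_value = 1, posthoc = NULL,
                shapiro_p = NA_real_, levene_p = NA_real_)
    class(out) <- "ednasex_grouptest"
    return(out)
  }

  fit <- stats::aov(y ~ group)
  sw_p <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                   error = function(e) NA_real_)
  lev_p <- tryCatch(car::leveneTest(y ~ group)[1, "Pr(>F)"],
                    error = function(e) NA_real_)
  use_param <- switch(mode,
    parametric = TRUE,
    nonparametric = FALSE,
    auto = isTRUE(sw_p >= 0.05) && isTRUE(lev_p >= 0.05))

  if (use_param) {
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    posthoc <- data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL)
    out <- list(method = "anova_tukey",
                statistic = an["group", "F value"],
                df = an["group", "Df"],
                df_resid = an["Residuals", "Df"],
                p_value = an["group", "Pr(>F)"],
                posthoc = posthoc)
  } else {
    kw <- stats::kruskal.test(y ~ group)
    posthoc <- if (min(table(group)) >= 1 && nlevels(group) >= 2) {
      dunn_bh(y, group)
    } else NULL
    out <- list(method = "kruskal_dunn_bh",
                statistic = unname(kw$statistic),
                df = unname(kw$parameter),
                df_resid = NA_real_,
                p_value = kw$p.value,
                posthoc = posthoc)
  }
  out$shapiro_p <- sw_p
  out$levene_p <- lev_p
  class(out) <- "ednasex_grouptest"
  out
}

#' @export
print.ednasex_grouptest <- function(x, ...) {
  lab <- if (x$method == "anova_tukey") "ANOVA F" else "Kruskal-Wallis chi-squared"
  cat(sprintf("%s(%g) = %.2f, p = %.3g  [%s]\n",
              lab, x$df, x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Observed-versus-expected accuracy by group
#'
#' Per sex-composition group, a one-sample Wilcoxon signed-rank test of the
#' observed common-to-male ratios against the group's model-expected value.
#' The exact null distribution is used for n <= 25 (absent ties), the
#' normal approximation with continuity correction above. Groups with fewer
#' than 3 samples are skipped with a warning. p-values can optionally be
#' Benjamini-Hochberg adjusted across groups (off by default).
#'
#' @param ratio Observed common-to-male ratios.
#' @param group Group labels.
#' @param expected Named vector of expected ratios (names = group levels),
#'   or a single value recycled.
#' @param adjust Apply BH adjustment across groups.
#' @return data.frame: `group`, `n`, `expected`, `statistic` (V),
#'   `p_value`, and `p_adj` if requested.
#' @export
accuracy_vs_expected <- function(ratio, group, expected, adjust = FALSE) {
  group <- factor(group)
  gl <- levels(group)
  if (length(expected) == 1 && is.null(names(expected))) {
    expected <- stats::setNames(rep(expected, length(gl)), gl)
  }
  missing_exp <- setdiff(gl, names(expected))
  if (length(missing_exp)) stop("no expected value for group(s): ",
                                paste(missing_exp, collapse = ", "))
  rows <- lapply(gl, function(g) {
    x <- ratio[group == g]
    x <- x[is.finite(x)]
    if (length(x) < 3) {
      warning("group '", g, "' has fewer than 3 samples; skipped")
      return(NULL)
    }
    if (all(x == expected[[g]])) {
      # no departures at all: statistic at the null centre
      return(data.frame(group = g, n = length(x), expected = expected[[g]],
                        statistic = 0, p_value = 1))
    }
    exact <- length(x) <= 25 && !any(duplicated(abs(x - expected[[g]])))
    wt <- suppressWarnings(
      stats::wilcox.test(x, mu = expected[[g]], exact = exact, correct = TRUE))
    data.frame(group = g, n = length(x), expected = expected[[g]],
               statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(invisible(NULL))
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
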