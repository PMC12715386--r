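#' @keywords internal
# Per-row starting-material concentrations for a table of well counts.
per_well_conc <- function(wells, droplet_volume = 8.5e-4, mix_volume = 22) {
  vt <- if ("template_volume_ul" %in% names(wells)) wells$template_volume_ul else rep(4, nrow(wells))
  mapply(function(k, n, v) {
    if (k == n) return(Inf)
    poisson_lambda(k, n) / droplet_volume * mix_volume / v
  }, wells$positives, wells$accepted, vt)
}

# t-test of per-replicate concentrations against the negatives; one-sample
# vs 0 when the negatives are all zero, Welch two-sample otherwise.
lod_test <- function(pos_conc, neg_conc, alpha) {
  if (stats::sd(pos_conc) == 0) {
    # degenerate: identical replicates; call significant iff clearly above
    # every negative (no sampling variance to test against)
    sig <- mean(pos_conc) > 0 && all(pos_conc > max(neg_conc))
    return(list(statistic = NA_real_, df = NA_real_,
                p_value = if (sig) 0 else 1, significant = sig))
  }
  tt <- if (all(neg_conc == 0)) {
    stats::t.test(pos_conc, mu = 0, alternative = "two.sided")
  } else {
    stats::t.test(pos_conc, neg_conc, var.equal = FALSE)
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha)
}

#' Limit of detection from a dilution series
#'
#' Walks a dilution series of the male-specific allele from the most dilute
#' level upwards and reports as LoD the most dilute level whose
#' per-replicate starting-material concentrations differ significantly from
#' the negative (female) replicates: a one-sample t-test against zero when
#' all negatives are zero, otherwise a Welch two-sample t-test. Normality of
#' the positive replicates is checked by Shapiro-Wilk and reported as a
#' warning flag, not a gate. The reported LoD concentration is the
#' merged-well (pooled-count) estimate at that level, which is why the
#' attainable LoD drops as replicates are added.
#'
#' @param series data.frame of wells with columns `dilution_factor`,
#'   `target`, `positives`, `accepted` and optionally `template_volume_ul`.
#'   Only rows with `target == "male"` are used.
#' @param negatives data.frame of male-target wells from a female control.
#' @param alpha Significance level (default 0.05).
#' @param droplet_volume,mix_volume Volumes for the concentration formula.
#' @return Object of class `ednasex_lod`: a list with `lod_copies_per_ul`,
#'   `lod_level`, `test_statistic`, `degrees_freedom`, `p_value`,
#'   `min_replicates`, `defined`, `nonmonotone_flag` and a `per_level`
#'   data.frame of all levels tested.
#' @export
detect_lod <- function(series, negatives, alpha = 0.05,
                       droplet_volume = 8.5e-4, mix_volume = 22) {
  stopifnot(alpha > 0, alpha <= 0.5)
  male <- series[series$target == "male", , drop = FALSE]
  if (nrow(male) == 0) stop("series contains no male-target wells")
  neg <- negatives[negatives$target %in% c("male", NA) |
                     !"target" %in% names(negatives), , drop = FALSE]
  if (nrow(neg) == 0) neg <- negatives
  neg_conc <- per_well_conc(neg, droplet_volume, mix_volume)

  levels <- sort(unique(male$dilution_factor))
  per_level <- do.call(rbind, lapply(levels, function(f) {
    w <- male[male$dilution_factor == f, , drop = FALSE]
    if (nrow(w) < 2) stop("need >= 2 replicates per dilution level")
    conc <- per_well_conc(w, droplet_volume, mix_volume)
    res <- lod_test(conc, neg_conc, alpha)
    sw_p <- tryCatch(stats::shapiro.test(conc)$p.value, error = function(e) NA_real_)
    merged <- merge_wells(w, droplet_volume = droplet_volume, mix_volume = mix_volume)
    data.frame(dilution_factor = f, n_replicates = nrow(w),
               mean_conc = mean(conc), merged_conc = merged$conc_start,
               statistic = res$statistic, df = res$df, p_value = res$p_value,
               significant = res$significant, shapiro_p = sw_p)
  }))

  sig <- per_level$significant
  if (!any(sig)) {
    out <- list(defined = FALSE, lod_copies_per_ul = NA_real_,
                lod_level = NA_real_, test_statistic = NA_real_,
                degrees_freedom = NA_real_, p_value = NA_real_,
                min_replicates = min(per_level$n_replicates),
                nonmonotone_flag = FALSE, alpha = alpha, per_level = per_level)
    class(out) <- "ednasex_lod"
    return(out)
  }
  # significance should extend downward (less dilute) from the LoD level;
  # gaps mean a non-monotone pattern worth flagging
  lod_i <- max(which(sig))
  nonmono <- any(!sig[seq_len(lod_i)])
  if (nonmono) warning("non-monotone significance pattern across dilution levels")
  row <- per_level[lod_i, ]
  out <- list(defined = TRUE,
              lod_copies_per_ul = row$merged_conc,
              lod_level = row$dilution_factor,
              test_statistic = row$statistic,
              degrees_freedom = row$df,
              p_value = row$p_value,
              min_replicates = row$n_replicates,
              nonmonotone_flag = nonmono, alpha = alpha, per_level = per_level)
  class(out) <- "ednasex_lod"
  out
}

#' @export
print.ednasex_lod <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("LoD: %.3g copies/uL at dilution 1:%g (t = %.2f, df = %g, p = %.3g; %d replicates merged)\n",
                x$lod_copies_per_ul, x$lod_level, x$test_statistic,
                x$degrees_freedom, x$p_value, x$min_replicates))
  } else {
    cat("LoD: undefined (no dilution level significantly above negatives)\n")
  }
  invisible(x)
}

#' Limit of quantification from a dilution series
#'
#' Determines the lowest male-allele concentration at which the
#' common-to-male ratio is measured within an acceptable relative standard
#' deviation (default 30%). Two assessments are returned: per-well mode,
#' where each level's RSD is computed over single-well replicate ratios, and
#' merged mode, where the RSD is taken across the levels' merged
#' (pooled-count) ratios — replicate merging absorbs the subsampling noise
#' that dominates single wells at low copy number, so the merged-mode LoQ
#' typically sits at the most dilute level.
#'
#' @param series data.frame of wells (both targets) with columns
#'   `dilution_factor`, `target`, `positives`, `accepted`, optional
#'   `replicate` to pair wells across targets (row order within a level is
#'   used otherwise).
#' @param rsd_max Maximum acceptable RSD in percent (default 30).
#' @param droplet_volume,mix_volume Volumes for the concentration formula.
#' @return Object of class `ednasex_loq`: list with `loq_copies_per_ul`,
#'   `loq_level` (per-well mode), `merged_loq_copies_per_ul`,
#'   `merged_loq_level`, `merged_rsd_pct`, `rsd_threshold_pct`, `defined`,
#'   and a `per_level` data.frame (per-level per-well RSD and merged ratio).
#' @export
detect_loq <- function(series, rsd_max = 30,
                       droplet_volume = 8.5e-4, mix_volume = 22) {
  stopifnot(rsd_max > 0)
  levels <- sort(unique(series$dilution_factor))
  per_level <- do.call(rbind, lapply(levels, function(f) {
    lev <- series[series$dilution_factor == f, , drop = FALSE]
    com <- lev[lev$target == "common", , drop = FALSE]
    mal <- lev[lev$target == "male", , drop = FALSE]
    if (nrow(com) == 0 || nrow(mal) == 0) {
      stop("level 1:", f, " lacks wells for one of the targets")
    }
    if ("replicate" %in% names(lev)) {
      com <- com[order(com$replicate), , drop = FALSE]
      mal <- mal[order(mal$replicate), , drop = FALSE]
    }
    m <- min(nrow(com), nrow(mal))
    cc <- per_well_conc(com[seq_len(m), , drop = FALSE], droplet_volume, mix_volume)
    cm <- per_well_conc(mal[seq_len(m), , drop = FALSE], droplet_volume, mix_volume)
    ok <- cm > 0 & is.finite(cc)
    well_rsd <- if (sum(ok) >= 2) rsd(cc[ok] / cm[ok]) else NA_real_
    mc <- merge_wells(com, droplet_volume = droplet_volume, mix_volume = mix_volume)
    mm <- merge_wells(mal, droplet_volume = droplet_volume, mix_volume = mix_volume)
    merged_ratio <- if (mm$conc_start > 0) mc$conc_start / mm$conc_start else NA_real_
    data.frame(dilution_factor = f, n_ratio_wells = sum(ok),
               per_well_rsd_pct = well_rsd,
               merged_common = mc$conc_start, merged_male = mm$conc_start,
               merged_ratio = merged_ratio)
  }))

  qual <- which(!is.na(per_level$per_well_rsd_pct) &
                  per_level$per_well_rsd_pct < rsd_max)
  if (length(qual)) {
    i <- max(qual) # most dilute qualifying level
    loq_level <- per_level$dilution_factor[i]
    loq_conc <- per_level$merged_male[i]
  } else {
    loq_level <- NA_real_
    loq_conc <- NA_real_
  }

  mr <- per_level$merged_ratio[!is.na(per_level$merged_ratio)]
  merged_rsd <- if (length(mr) >= 2) rsd(mr) else NA_real_
  if (!is.na(merged_rsd) && merged_rsd < rsd_max) {
    j <- max(which(!is.na(per_level$merged_ratio)))
    m_level <- per_level$dilution_factor[j]
    m_conc <- per_level$merged_male[j]
  } else {
    m_level <- NA_real_
    m_conc <- NA_real_
  }

  out <- list(defined = length(qual) > 0 || !is.na(m_level),
              loq_copies_per_ul = loq_conc, loq_level = loq_level,
              merged_loq_copies_per_ul = m_conc, merged_loq_level = m_level,
              merged_rsd_pct = merged_rsd, rsd_threshold_pct = rsd_max,
              per_level = per_level)
  class(out) <- "ednasex_loq"
  out
}

#' @export
print.ednasex_loq <- function(x, ...) {
  cat(sprintf("LoQ (per-well replicates, RSD < %g%%): ", x$rsd_threshold_pct))
  if (is.na(x$loq_level)) cat("undefined\n") else
    cat(sprintf("%.3g copies/uL at dilution 1:%g\n", x$loq_copies_per_ul, x$loq_level))
  cat("LoQ (merged replicates): ")
  if (is.na(x$merged_loq_level)) cat("undefined\n") else
    cat(sprintf("%.3g copies/uL at dilution 1:%g (cross-level RSD %.1f%%)\n",
                x$merged_loq_copies_per_ul, x$merged_loq_level, x$merged_rsd_pct))
  invisible(x)
}

#' Exclude samples below the limit of detection
#'
#' Filters a table of sample-level male-allele concentrations against an
#' LoD and returns the retained samples together with an exclusion log, so
#' every dropped data point is accounted for.
#'
#' @param samples data.frame with columns `sample_id` and `male_conc`
#'   (merged starting-material male-allele concentration, copies/uL).
#' @param limits An `ednasex_lod` object, or a single numeric LoD in
#'   copies/uL.
#' @return List with `retained` (data.frame), `excluded` (data.frame with a
#'   `reason` column) and `n_excluded`.
#' @export
apply_limits <- function(samples, limits) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "male_conc") %in% names(samples)))
  lod <- if (inherits(limits, "ednasex_lod")) {
    if (!limits$defined) stop("LoD is undefined; cannot filter")
    limits$lod_copies_per_ul
  } else {
    as.numeric(limits)
  }
  if (nrow(samples) == 0) {
    return(list(retained = samples, excluded = cbind(samples, reason = character(0)),
                n_excluded = 0L))
  }
  below <- samples$male_conc < lod
  excluded <- samples[below, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- sprintf("male allele %.3g copies/uL below LoD %.3g",
                               excluded$male_conc, lod)
  } else {
    excluded$reason <- character(0)
  }
  list(retained = samples[!below, , drop = FALSE],
       excluded = excluded, n_excluded = sum(below))
}
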