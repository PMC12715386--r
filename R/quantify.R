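#' Poisson correction for droplet digital PCR
#'
#' Converts a positive-droplet count into the mean number of template copies
#' per droplet. Because a droplet can hold more than one copy, the raw
#' positive fraction underestimates the copy load; under random (Poisson)
#' partitioning the mean copies per droplet is `-log(1 - k/n)`.
#'
#' @param k Number of positive droplets (0 <= k < n).
#' @param n Number of accepted droplets (> 0).
#' @return Mean copies per droplet (lambda), a non-negative numeric.
#'   Vectorised over `k` and `n`.
#' @examples
#' poisson_lambda(5000, 10000) # log(2)
#' @export
poisson_lambda <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n))
  if (any(n <= 0)) stop("accepted droplet count must be positive")
  if (any(k < 0) || any(k > n)) stop("positives must satisfy 0 <= k <= n")
  if (any(k == n)) {
    stop("saturated well (k == n): lambda is unbounded; handle via concentration()")
  }
  -log(1 - k / n)
}

# Delta-method standard error of lambda-hat: Var(p-hat) = p(1-p)/n and
# d(lambda)/dp = 1/(1-p), so SE = sqrt(p / (n (1-p))).
lambda_se <- function(k, n) {
  p <- k / n
  sqrt(p / (n * (1 - p)))
}

#' Poisson-corrected concentration from one well (or pooled counts)
#'
#' Turns droplet counts into copies/uL, both at reaction scale and rescaled
#' to the starting material: `conc_start = conc_reaction * mix_volume /
#' template_volume`. A 95% confidence interval on the starting-material
#' scale is computed by the delta method on lambda-hat, clamped at zero.
#' For `k = 0` the point estimate is 0 and the upper bound is the
#' rule-of-three limit `-log(1 - 3/n) / droplet_volume * mix_volume /
#' template_volume`. A saturated well (`k == n`) is returned flagged with an
#' infinite point estimate rather than an error, so callers can exclude it.
#'
#' @param k Positive droplets.
#' @param n Accepted droplets.
#' @param droplet_volume Droplet volume in uL (default 8.5e-4, QX200).
#' @param template_volume Volume of DNA template in the reaction, uL.
#' @param mix_volume Total reaction mix volume, uL (default 22).
#' @param dilution_factor Dilution applied to the starting material before
#'   the reaction; recorded, not applied to the estimate.
#' @param wells_merged Number of wells the counts were pooled from.
#' @param conf_level Confidence level for the interval.
#' @return One-row data.frame: `lambda`, `conc_reaction`, `conc_start`,
#'   `ci_low`, `ci_high`, `wells_merged`, `k_total`, `n_total`,
#'   `dilution_factor`, `saturated`.
#' @examples
#' concentration(100, 17000, template_volume = 4)
#' @export
concentration <- function(k, n,
                          droplet_volume = 8.5e-4,
                          template_volume = 4,
                          mix_volume = 22,
                          dilution_factor = 1,
                          wells_merged = 1L,
                          conf_level = 0.95) {
  stopifnot(length(k) == 1, length(n) == 1, n > 0, k >= 0, k <= n,
            droplet_volume > 0, template_volume > 0, mix_volume > 0)
  scale <- mix_volume / template_volume / droplet_volume
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (k == n) {
    return(data.frame(
      lambda = Inf, conc_reaction = Inf, conc_start = Inf,
      ci_low = Inf, ci_high = Inf,
      wells_merged = as.integer(wells_merged),
      k_total = as.integer(k), n_total = as.integer(n),
      dilution_factor = dilution_factor, saturated = TRUE
    ))
  }

  lam <- poisson_lambda(k, n)
  conc_start <- lam * scale
  if (k == 0) {
    ci_low <- 0
    ci_high <- -log(1 - 3 / n) * scale
  } else {
    se <- lambda_se(k, n) * scale
    ci_low <- max(0, conc_start - z * se)
    ci_high <- conc_start + z * se
  }
  data.frame(
    lambda = lam, conc_reaction = lam / droplet_volume,
    conc_start = conc_start, ci_low = ci_low, ci_high = ci_high,
    wells_merged = as.integer(wells_merged),
    k_total = as.integer(k), n_total = as.integer(n),
    dilution_factor = dilution_factor, saturated = FALSE
  )
}

#' Merge replicate wells into one meta-well
#'
#' Pools positive and accepted droplet counts across replicate wells and
#' applies the Poisson correction to the pooled population. This is not the
#' mean of per-well concentrations: pooling treats the replicates as one
#' large partition set, which is what pushes detection and quantification
#' limits below what a single well can reach. Saturated wells (`k == n`) are
#' excluded from the pool with a warning.
#'
#' @param wells data.frame of well counts with columns `positives`,
#'   `accepted`, and optionally `sample_id`, `target`,
#'   `template_volume_ul`, `dilution_factor` (must be constant if present).
#' @param droplet_volume,mix_volume,conf_level Passed to [concentration()].
#' @return One-row data.frame as from [concentration()], with
#'   `wells_merged` set to the number of wells pooled.
#' @examples
#' w <- data.frame(positives = c(2, 1, 0, 1, 1, 1), accepted = 16500,
#'                 template_volume_ul = 4, dilution_factor = 256)
#' merge_wells(w)
#' @export
merge_wells <- function(wells, droplet_volume = 8.5e-4, mix_volume = 22,
                        conf_level = 0.95) {
  stopifnot(is.data.frame(wells), nrow(wells) >= 1,
            all(c("positives", "accepted") %in% names(wells)))
  for (col in c("sample_id", "target", "template_volume_ul", "dilution_factor")) {
    if (col %in% names(wells) && length(unique(wells[[col]])) > 1) {
      stop("wells to merge disagree on '", col, "'")
    }
  }
  vt <- if ("template_volume_ul" %in% names(wells)) wells$template_volume_ul[1] else 4
  dil <- if ("dilution_factor" %in% names(wells)) wells$dilution_factor[1] else 1

  sat <- wells$positives == wells$accepted
  if (any(sat)) {
    warning(sum(sat), " saturated well(s) excluded from merge")
    wells <- wells[!sat, , drop = FALSE]
    if (nrow(wells) == 0) stop("all wells saturated; nothing to merge")
  }
  concentration(sum(wells$positives), sum(wells$accepted),
                droplet_volume = droplet_volume, template_volume = vt,
                mix_volume = mix_volume, dilution_factor = dil,
                wells_merged = nrow(wells), conf_level = conf_level)
}

#' Common-to-male allele ratio with confidence interval
#'
#' Divides two concentration estimates (typically merged-well estimates of
#' the common and the male-specific allele from the same sample) and
#' propagates uncertainty by the delta method on the log ratio, assuming
#' independent numerator and denominator errors. A zero male concentration
#' yields an infinite common-to-male ratio with `male_to_common = 0`; both
#' zero is an error.
#'
#' @param common,male One-row data.frames from [concentration()] or
#'   [merge_wells()].
#' @param conf_level Confidence level.
#' @return One-row data.frame: `common_to_male`, `male_to_common`,
#'   `ci_low`, `ci_high` (common-to-male scale), `rsd_pct` (NA here; filled
#'   by per-well ratio summaries).
#' @export
allele_ratio <- function(common, male, conf_level = 0.95) {
  cc <- common$conc_start
  cm <- male$conc_start
  if (cc == 0 && cm == 0) stop("both allele concentrations are zero; ratio undefined")
  if (cm == 0) {
    return(data.frame(common_to_male = Inf, male_to_common = 0,
                      ci_low = NA_real_, ci_high = NA_real_,
                      rsd_pct = NA_real_))
  }
  ratio <- cc / cm
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  scale_c <- with(common, conc_start / lambda)
  scale_m <- with(male, conc_start / lambda)
  se_c <- lambda_se(common$k_total, common$n_total) * scale_c
  se_m <- lambda_se(male$k_total, male$n_total) * scale_m
  cv2 <- if (cc > 0) (se_c / cc)^2 else 0
  se_log <- sqrt(cv2 + (se_m / cm)^2)
  data.frame(common_to_male = ratio, male_to_common = 1 / ratio,
             ci_low = ratio * exp(-z * se_log),
             ci_high = ratio * exp(z * se_log),
             rsd_pct = NA_real_)
}

#' Relative standard deviation (percent)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation; the
#' usual measure of replicate precision for ddPCR ratio measurements.
#'
#' @param x Numeric vector, at least two values, non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(8.33, 8.40, 6.40, 7.30, 7.00)) # ~11.6, rounds to 12
#' @export
rsd <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("rsd needs at least two values")
  m <- mean(x)
  if (m == 0) stop("rsd undefined for zero mean")
  100 * stats::sd(x) / m
}

#' Classify raw droplets into positive/negative counts
#'
#' Applies per-channel 1-D fluorescence thresholds to droplet amplitudes and
#' returns per-well, per-channel counts. The comparison is inclusive: a
#' droplet at exactly the threshold is positive. By default the HEX channel
#' carries the male-specific probe and FAM the common-allele probe; the
#' mapping is configurable. Conservative thresholds (HEX >= 2400,
#' FAM >= 3000) keep cross-reactive droplets, whose amplitudes stay below
#' 2000 HEX, out of the positive count.
#'
#' @param reads data.frame with columns `well_id`, `channel` ("FAM"/"HEX")
#'   and `amplitude` (non-negative).
#' @param hex_min,fam_min Channel thresholds in fluorescence units.
#' @param channel_map Named character vector mapping channel to target.
#' @return data.frame with one row per (well, channel): `well_id`, `channel`,
#'   `target`, `positives`, `accepted`.
#' @export
classify_droplets <- function(reads, hex_min = 2400, fam_min = 3000,
                              channel_map = c(HEX = "male", FAM = "common")) {
  stopifnot(is.data.frame(reads),
            all(c("well_id", "channel", "amplitude") %in% names(reads)),
            hex_min > 0, fam_min > 0)
  if (nrow(reads) == 0) stop("no droplets")
  if (any(reads$amplitude < 0)) stop("negative amplitude")
  bad <- setdiff(unique(reads$channel), names(channel_map))
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  thr <- c(HEX = hex_min, FAM = fam_min)

  out <- do.call(rbind, lapply(
    split(reads, list(reads$well_id, reads$channel), drop = TRUE),
    function(d) {
      ch <- as.character(d$channel[1])
      data.frame(well_id = d$well_id[1], channel = ch,
                 target = unname(channel_map[[ch]]),
                 positives = sum(d$amplitude >= thr[[ch]]),
                 accepted = nrow(d))
    }))
  rownames(out) <- NULL
  out[order(out$well_id, out$channel), , drop = FALSE]
}
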