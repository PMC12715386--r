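droplet_csv_cols <- c("sample_id", "target", "positives", "accepted",
                      "template_volume_ul", "dilution_factor")
metadata_csv_cols <- c("sample_id", "group", "n_males", "n_females",
                       "male_mass_g", "total_mass_g", "series", "sample_type")

#' Read a droplet-count CSV
#'
#' One row per well x target. Required columns: `sample_id`, `target`,
#' `positives`, `accepted`, `template_volume_ul`, `dilution_factor`
#' (`plate` and `well` are carried through when present, as are any extra
#' columns). Rows violating `0 <= positives <= accepted` are rejected with
#' their row numbers.
#'
#' @param path CSV file path.
#' @return data.frame of well counts.
#' @export
read_droplet_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(droplet_csv_cols, names(x))
  if (length(missing)) {
    stop("droplet CSV missing required column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(x$positives < 0 | x$positives > x$accepted | x$accepted <= 0)
  if (length(bad)) {
    stop("invalid droplet counts (positives outside [0, accepted]) in row(s): ",
         paste(bad, collapse = ", "))
  }
  bad_t <- setdiff(unique(x$target), c("common", "male", "other"))
  if (length(bad_t)) stop("unknown target(s): ", paste(bad_t, collapse = ", "))
  x
}

#' Write a droplet-count CSV
#' @param x data.frame of well counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_droplet_csv <- function(x, path) {
  missing <- setdiff(droplet_csv_cols, names(x))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample-metadata CSV
#'
#' Columns: `sample_id`, `group` ("xM:yF" labels, or "NTC"), `n_males`,
#' `n_females`, `male_mass_g`, `total_mass_g`, `series`, `sample_type`
#' ("mock", "edna", "female_control", "ntc").
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(metadata_csv_cols, names(x))
  if (length(missing)) {
    stop("metadata CSV missing required column(s): ", paste(missing, collapse = ", "))
  }
  x
}

#' Write the merged-concentration table
#' @param x data.frame from [quantify_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the analysis constants: reaction geometry, fluorescence
#' thresholds, significance level, RSD acceptance threshold and the
#' per-male copy ratio. Round-trips losslessly through a flat YAML file.
#'
#' @param droplet_volume_ul,mix_volume_ul Reaction geometry.
#' @param hex_min,fam_min Fluorescence thresholds.
#' @param alpha LoD significance level.
#' @param rsd_max_pct LoQ acceptance threshold, percent.
#' @param rho Per-male common-to-male copy ratio.
#' @param seed Integer seed for any simulation steps.
#' @return List of class `ednasex_config`.
#' @export
run_config <- function(droplet_volume_ul = 8.5e-4, mix_volume_ul = 22,
                       hex_min = 2400, fam_min = 3000,
                       alpha = 0.05, rsd_max_pct = 30, rho = 7,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$droplet_volume_ul > 0, cfg$mix_volume_ul > 0,
            cfg$hex_min > 0, cfg$fam_min > 0,
            cfg$alpha > 0, cfg$alpha <= 0.5, cfg$rsd_max_pct > 0, cfg$rho > 0)
  class(cfg) <- "ednasex_config"
  cfg
}

#' @rdname run_config
#' @param cfg An `ednasex_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Merged-well quantification of every sample
#'
#' Pools replicate wells per (sample, target) and computes
#' Poisson-corrected concentrations; the canonical quantification table of
#' the pipeline.
#'
#' @param droplets data.frame of well counts (see [read_droplet_csv()]).
#' @param droplet_volume,mix_volume Reaction geometry (uL).
#' @return data.frame: `sample_id`, `target`, `wells_merged`, `k_total`,
#'   `n_total`, `lambda`, `conc_reaction`, `conc_start`, `ci_low`,
#'   `ci_high`, `saturated`.
#' @export
quantify_samples <- function(droplets, droplet_volume = 8.5e-4, mix_volume = 22) {
  pieces <- split(droplets, list(droplets$sample_id, droplets$target), drop = TRUE)
  out <- do.call(rbind, lapply(pieces, function(d) {
    est <- merge_wells(d, droplet_volume = droplet_volume, mix_volume = mix_volume)
    cbind(data.frame(sample_id = d$sample_id[1], target = d$target[1]),
          est[, c("wells_merged", "k_total", "n_total", "lambda",
                  "conc_reaction", "conc_start", "ci_low", "ci_high",
                  "saturated")])
  }))
  rownames(out) <- NULL
  out[order(out$sample_id, out$target), , drop = FALSE]
}

#' Run the full sex-ratio pipeline
#'
#' From well counts and sample metadata to male-proportion estimates and
#' the standard statistical report: merged-well quantification, control
#' checks (any positive NTC or blank raises a contamination warning and is
#' excluded), optional LoD filtering, per-sample allele ratios with
#' optional biomass correction, male-proportion estimates, the group
#' omnibus/post hoc comparison, observed-versus-expected accuracy tests and
#' both calibration regressions.
#'
#' @param droplets data.frame of well counts.
#' @param metadata data.frame of sample compositions.
#' @param config A [run_config()].
#' @param mass_correction Apply biomass correction to eDNA ratios.
#' @param lod Optional LoD (`ednasex_lod` or numeric copies/uL) for sample
#'   exclusion.
#' @param expected Optional named numeric vector of hypothesised
#'   common-to-male ratios per `sample_id` (e.g., built from genotyped
#'   individuals via [expected_ratio_individuals()]); used for the
#'   observed-versus-expected calibration and accuracy tests in place of
#'   the population-average model `rho * (M + F) / M`.
#' @return List of class `ednasex_result`: `concentrations`, `estimates`
#'   (per-sample ratios and male proportions), `group_test`, `accuracy`,
#'   `calibration_proportion`, `calibration_expected`, `exclusions`,
#'   `warnings`.
#' @export
run_pipeline <- function(droplets, metadata, config = run_config(),
                         mass_correction = FALSE, lod = NULL,
                         expected = NULL) {
  conc <- quantify_samples(droplets, droplet_volume = config$droplet_volume_ul,
                           mix_volume = config$mix_volume_ul)
  warnings_log <- character(0)
  exclusions <- data.frame(sample_id = character(0), reason = character(0))

  # control policy: positive NTC / blank => contamination warning, excluded
  ctrl_ids <- metadata$sample_id[metadata$sample_type %in% c("ntc", "blank")]
  for (sid in ctrl_ids) {
    kk <- conc$k_total[conc$sample_id == sid]
    if (length(kk) && any(kk > 0)) {
      msg <- sprintf("control %s has positive droplets: possible contamination", sid)
      warning(msg)
      warnings_log <- c(warnings_log, msg)
    }
    exclusions <- rbind(exclusions,
                       data.frame(sample_id = sid, reason = "control well"))
  }
  fem_ids <- metadata$sample_id[metadata$sample_type %in% "female_control"]
  if (length(fem_ids)) {
    exclusions <- rbind(exclusions,
                        data.frame(sample_id = fem_ids,
                                   reason = "all-female control"))
  }

  meta <- metadata[!metadata$sample_id %in% c(ctrl_ids, fem_ids), , drop = FALSE]

  # LoD-based exclusion of samples whose male signal is below detection
  if (!is.null(lod)) {
    male_tab <- conc[conc$target == "male" & conc$sample_id %in% meta$sample_id, ]
    filt <- apply_limits(data.frame(sample_id = male_tab$sample_id,
                                    male_conc = male_tab$conc_start), lod)
    if (filt$n_excluded > 0) {
      exclusions <- rbind(exclusions, filt$excluded[, c("sample_id", "reason")])
      meta <- meta[meta$sample_id %in% filt$retained$sample_id, , drop = FALSE]
    }
  }
  if (nrow(meta) == 0) stop("insufficient data: no samples remain after exclusions")

  estimates <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$sample_id[i]
    cc <- conc[conc$sample_id == sid & conc$target == "common", ]
    cm <- conc[conc$sample_id == sid & conc$target == "male", ]
    if (nrow(cc) == 0 || nrow(cm) == 0) return(NULL)
    rat <- allele_ratio(cc, cm)
    # replicate dispersion from per-well ratios
    dw <- droplets[droplets$sample_id == sid, ]
    co <- dw[dw$target == "common", ]; ma <- dw[dw$target == "male", ]
    m <- min(nrow(co), nrow(ma))
    pc <- per_well_conc(co[seq_len(m), , drop = FALSE],
                        config$droplet_volume_ul, config$mix_volume_ul)
    pm <- per_well_conc(ma[seq_len(m), , drop = FALSE],
                        config$droplet_volume_ul, config$mix_volume_ul)
    ok <- pm > 0 & is.finite(pc)
    rat$rsd_pct <- if (sum(ok) >= 2) rsd(pc[ok] / pm[ok]) else NA_real_
    if (mass_correction && meta$male_mass_g[i] > 0) {
      rat <- mass_correct(rat, meta$male_mass_g[i], meta$total_mass_g[i])
    } else {
      rat$mass_corrected <- FALSE
    }
    est <- estimate_male_proportion(rat$male_to_common, rho = config$rho,
                                    mass_corrected = rat$mass_corrected)
    data.frame(sample_id = sid, group = meta$group[i], series = meta$series[i],
               n_males = meta$n_males[i], n_females = meta$n_females[i],
               p_male_true = meta$n_males[i] / (meta$n_males[i] + meta$n_females[i]),
               common_conc = cc$conc_start, male_conc = cm$conc_start,
               common_to_male = rat$common_to_male,
               male_to_common = rat$male_to_common,
               ratio_rsd_pct = rat$rsd_pct,
               p_male_raw = est$p_male_raw, p_male = est$p_male,
               mass_corrected = rat$mass_corrected)
  }))
  rownames(estimates) <- NULL

  grp <- estimates[is.finite(estimates$common_to_male) & estimates$common_to_male > 0, ]
  group_test <- if (length(unique(grp$group)) >= 2 && nrow(grp) >= 4) {
    tryCatch(compare_groups(grp$common_to_male, grp$group),
             error = function(e) NULL)
  }
  if (is.null(expected)) {
    exp_per_sample <- mapply(expected_ratio, grp$n_males, grp$n_females,
                             MoreArgs = list(rho = config$rho))
    exp_per_group <- vapply(split(grp, grp$group), function(d) {
      expected_ratio(d$n_males[1], d$n_females[1], rho = config$rho)
    }, numeric(1))
  } else {
    exp_per_sample <- unname(expected[grp$sample_id])
    exp_per_group <- vapply(split(grp, grp$group), function(d) {
      mean(expected[d$sample_id])
    }, numeric(1))
  }
  accuracy <- if (nrow(grp) >= 3) {
    tryCatch(suppressWarnings(
      accuracy_vs_expected(grp$common_to_male, grp$group, exp_per_group)),
      error = function(e) NULL)
  }
  cal_prop <- tryCatch(
    calibrate(estimates$p_male_true, estimates$male_to_common,
              variant = "proportion"),
    error = function(e) NULL)
  cal_exp <- if (nrow(grp) >= 3) {
    tryCatch(calibrate(exp_per_sample, grp$common_to_male, variant = "expected"),
             error = function(e) NULL)
  }

  out <- list(concentrations = conc, estimates = estimates,
              group_test = group_test, accuracy = accuracy,
              calibration_proportion = cal_prop,
              calibration_expected = cal_exp,
              exclusions = exclusions, warnings = warnings_log,
              config = config)
  class(out) <- "ednasex_result"
  out
}

#' @export
print.ednasex_result <- function(x, ...) {
  cat("ednasex pipeline result:", nrow(x$estimates), "samples,",
      nrow(x$exclusions), "exclusion(s)\n")
  if (!is.null(x$group_test)) print(x$group_test)
  if (!is.null(x$calibration_proportion)) print(x$calibration_proportion)
  if (!is.null(x$calibration_expected)) print(x$calibration_expected)
  invisible(x)
}

#' Per-individual assay specificity check
#'
#' Validates the sex-linked assay on genotyped individuals: the male-specific
#' allele must be detected in every male and in no female, and the common
#' allele in every individual. Individuals failing either rule are listed.
#'
#' @param conc data.frame with columns `sample_id`, `target`, `conc_start`
#'   (one row per individual x target, e.g. from [quantify_samples()]).
#' @param sex Named character vector mapping `sample_id` to "M"/"F".
#' @return List: `valid` (logical), `failures` (data.frame), plus the
#'   male-ratio summary (`mean_ratio`, `rsd_pct`) over validated males.
#' @export
validate_assay <- function(conc, sex) {
  ids <- unique(conc$sample_id)
  rows <- lapply(ids, function(sid) {
    cc <- conc$conc_start[conc$sample_id == sid & conc$target == "common"]
    cm <- conc$conc_start[conc$sample_id == sid & conc$target == "male"]
    s <- sex[[sid]]
    fail <- if (length(cc) == 0 || cc == 0) "no common allele"
      else if (s == "M" && (length(cm) == 0 || cm == 0)) "male allele absent in male"
      else if (s == "F" && length(cm) && cm > 0) "male allele present in female"
      else NA_character_
    data.frame(sample_id = sid, sex = s, fail = fail,
               ratio = if (s == "M" && length(cm) && cm > 0) cc / cm else NA_real_)
  })
  tab <- do.call(rbind, rows)
  ratios <- tab$ratio[!is.na(tab$ratio)]
  list(valid = all(is.na(tab$fail)),
       failures = tab[!is.na(tab$fail), c("sample_id", "sex", "fail")],
       mean_ratio = if (length(ratios)) mean(ratios) else NA_real_,
       rsd_pct = if (length(ratios) >= 2) rsd(ratios) else NA_real_)
}
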