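#' Simulation configuration
#'
#' Defaults emulate the validated assay and study system: per-male
#' common-to-male copy ratios averaging 7 with ~38% relative standard
#' deviation between individuals (observed range 3-14), females carrying
#' only the common allele, a rare cross-reactive false-positive channel
#' whose rate scales with non-target DNA load, QX200-scale droplet yields,
#' and newt body masses with females slightly heavier than males.
#'
#' @param rho_mean Mean per-male common-to-male copy ratio.
#' @param rho_rsd_pct Between-male RSD of that ratio, percent.
#' @param rho_clip Range the ratio is clipped to (`NULL` to disable).
#' @param mass_mean_g Named mean body masses in grams, `c(M = , F = )`.
#' @param mass_cv Coefficient of variation of body mass within sex.
#' @param mock_c0 Common-allele copies/uL contributed per individual in a
#'   mock extract mixture.
#' @param shed_rate_per_g Common-allele copies/uL contributed per gram of
#'   body mass in an eDNA tank.
#' @param shed_cv Lognormal CV of the per-individual eDNA contribution.
#' @param allometry_b Exponent b in contribution ~ mass^b (1 = linear).
#' @param droplets_range Accepted droplets per well, uniform range.
#' @param false_pos_rate Cross-reactive positives per droplet per unit of
#'   common-allele mean copies per droplet.
#' @param contamination_rate Per-droplet contamination rate in controls.
#' @param n_wells_mock,n_wells_edna Technical replicate wells per sample.
#' @param template_volume_mock,template_volume_edna Template volume (uL).
#' @param droplet_volume,mix_volume Reaction geometry (uL).
#' @return A list of class `ednasex_simconfig`.
#' @export
sim_config <- function(rho_mean = 7, rho_rsd_pct = 38, rho_clip = c(3, 14),
                       mass_mean_g = c(M = 6, F = 7), mass_cv = 0.15,
                       mock_c0 = 50, shed_rate_per_g = 5, shed_cv = 0.5,
                       allometry_b = 1,
                       droplets_range = c(14000, 20000),
                       false_pos_rate = 3e-4, contamination_rate = 0,
                       n_wells_mock = 3, n_wells_edna = 6,
                       template_volume_mock = 2, template_volume_edna = 4,
                       droplet_volume = 8.5e-4, mix_volume = 22) {
  cfg <- as.list(environment())
  stopifnot(cfg$rho_mean > 0, cfg$rho_rsd_pct >= 0,
            is.null(rho_clip) || rho_clip[1] < rho_clip[2],
            all(cfg$mass_mean_g > 0), cfg$false_pos_rate >= 0,
            cfg$droplets_range[1] <= cfg$droplets_range[2])
  class(cfg) <- "ednasex_simconfig"
  cfg
}

# Run code under a local seed without disturbing the caller's RNG stream.
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rlnorm_meancv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate individuals
#'
#' Draws males and females with lognormal body masses around sex-specific
#' means and, for males, a lognormal per-individual common-to-male copy
#' ratio (clipped to the configured range). Females carry no male allele
#' (`rho_i = Inf`).
#'
#' @param n_m,n_f Numbers of males and females.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (local to this call).
#' @param id_prefix Prefix for individual ids.
#' @return data.frame: `id`, `sex` ("M"/"F"), `mass_g`, `rho_i`,
#'   `shed_mult` (lognormal per-individual shedding multiplier, mean 1).
#' @export
simulate_individuals <- function(n_m, n_f, cfg = sim_config(), seed = NULL,
                                 id_prefix = "ind") {
  stopifnot(n_m + n_f >= 1, n_m >= 0, n_f >= 0)
  with_sim_seed(seed, {
    sex <- c(rep("M", n_m), rep("F", n_f))
    mass <- rlnorm_meancv(length(sex), 1, cfg$mass_cv) *
      cfg$mass_mean_g[sex]
    rho <- rep(Inf, length(sex))
    if (n_m > 0) {
      r <- rlnorm_meancv(n_m, cfg$rho_mean, cfg$rho_rsd_pct / 100)
      if (!is.null(cfg$rho_clip)) {
        r <- pmin(cfg$rho_clip[2], pmax(cfg$rho_clip[1], r))
      }
      rho[sex == "M"] <- r
    }
    data.frame(id = sprintf("%s_%s%02d", id_prefix, sex, stats::ave(seq_along(sex), sex, FUN = seq_along)),
               sex = sex, mass_g = unname(mass), rho_i = rho,
               shed_mult = rlnorm_meancv(length(sex), 1, cfg$shed_cv))
  })
}

#' True allele concentrations contributed by a set of individuals
#'
#' Mock mode: every individual contributes the same common-allele
#' concentration `mock_c0` (equal-volume extract mixing after
#' normalisation). eDNA mode: each individual contributes in proportion to
#' `mass^b`, scaled by `shed_rate_per_g` and the individual's lognormal
#' shedding multiplier. In both modes a male's male-allele contribution is
#' its common-allele contribution divided by its copy ratio `rho_i`.
#'
#' @param inds data.frame from [simulate_individuals()].
#' @param mode "mock" or "edna".
#' @param cfg A [sim_config()].
#' @return Named numeric: `common`, `male` (copies/uL, starting material).
#' @export
simulate_sample <- function(inds, mode = c("mock", "edna"), cfg = sim_config()) {
  mode <- match.arg(mode)
  stopifnot(nrow(inds) >= 1)
  common_i <- if (mode == "mock") {
    rep(cfg$mock_c0, nrow(inds))
  } else {
    cfg$shed_rate_per_g * inds$mass_g^cfg$allometry_b * inds$shed_mult
  }
  male_i <- ifelse(is.finite(inds$rho_i), common_i / inds$rho_i, 0)
  c(common = sum(common_i), male = sum(male_i))
}

#' Simulate droplet partitioning for one sample
#'
#' Emulates the droplet reader: each well accepts a uniform random number
#' of droplets, each target's positive count is binomial with per-droplet
#' positive probability `1 - exp(-lambda)` where `lambda` is the mean
#' copies per droplet implied by the true concentration and the reaction
#' geometry. The male channel additionally receives rare cross-reactive
#' false positives at a rate proportional to the common-allele load. With
#' `amplitudes = TRUE`, per-droplet fluorescence amplitudes are also drawn:
#' true male-channel positives around 3500 HEX, cross-reactives below 2000
#' HEX, negatives around 1000 — so the conservative 2400 HEX threshold
#' separates them.
#'
#' @param true_conc Named numeric `c(common = , male = )`, copies/uL in the
#'   starting material.
#' @param n_wells Number of replicate wells.
#' @param template_volume Template volume per reaction (uL).
#' @param dilution_factor Recorded in the output (the concentrations given
#'   are taken as already diluted).
#' @param sample_id Sample identifier for the output rows.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @param amplitudes Also generate per-droplet amplitude reads.
#' @param is_control Draw contamination at `contamination_rate` instead of
#'   the true concentrations (used for NTCs and blanks).
#' @return data.frame of well counts (`well`, `sample_id`, `target`,
#'   `positives`, `accepted`, `template_volume_ul`, `dilution_factor`);
#'   with `amplitudes = TRUE`, a list also carrying `reads`.
#' @export
simulate_droplets <- function(true_conc, n_wells = 3, template_volume = 4,
                              dilution_factor = 1, sample_id = "S1",
                              cfg = sim_config(), seed = NULL,
                              amplitudes = FALSE, is_control = FALSE) {
  stopifnot(all(true_conc >= 0), n_wells >= 1)
  with_sim_seed(seed, {
    lam <- true_conc * (template_volume / cfg$mix_volume) * cfg$droplet_volume
    rows <- list()
    reads <- list()
    for (w in seq_len(n_wells)) {
      n <- sample(seq(cfg$droplets_range[1], cfg$droplets_range[2]), 1)
      well <- sprintf("%s_w%d", sample_id, w)
      if (is_control) {
        k_common <- stats::rbinom(1, n, cfg$contamination_rate)
        k_true_male <- stats::rbinom(1, n, cfg$contamination_rate)
        k_fp <- 0L
      } else {
        k_common <- stats::rbinom(1, n, 1 - exp(-lam[["common"]]))
        k_true_male <- stats::rbinom(1, n, 1 - exp(-lam[["male"]]))
        k_fp <- stats::rbinom(1, n - k_true_male,
                              min(1, cfg$false_pos_rate * lam[["common"]]))
      }
      rows[[w]] <- data.frame(
        well = well, sample_id = sample_id,
        target = c("common", "male"),
        positives = c(k_common, k_true_male + k_fp),
        accepted = n,
        template_volume_ul = template_volume,
        dilution_factor = dilution_factor)
      if (amplitudes) {
        amp_hex <- c(stats::rnorm(k_true_male, 3500, 200),
                     pmin(stats::rnorm(k_fp, 1800, 150), 1999),
                     stats::rnorm(n - k_true_male - k_fp, 1000, 150))
        amp_fam <- c(stats::rnorm(k_common, 4000, 250),
                     stats::rnorm(n - k_common, 1000, 150))
        reads[[w]] <- rbind(
          data.frame(well_id = well, channel = "HEX", amplitude = pmax(0, amp_hex)),
          data.frame(well_id = well, channel = "FAM", amplitude = pmax(0, amp_fam)))
      }
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- NULL
    if (amplitudes) list(counts = counts, reads = do.call(rbind, reads)) else counts
  })
}

#' Simulate a 4-fold dilution series
#'
#' Dilutes a pair of true extract concentrations across the given factors
#' and simulates replicate wells at every level, supporting LoD/LoQ
#' determination end to end.
#'
#' @param extract_conc Named numeric `c(common = , male = )` of the
#'   undiluted (level 1) starting material, copies/uL.
#' @param factors Dilution factors, increasing (default 1, 4, 16, 64, 256).
#' @param replicates Wells per level per target (default 6).
#' @param template_volume Template volume (uL), default 4.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @param sample_id Prefix for well ids.
#' @return data.frame of well counts with `dilution_factor` per level.
#' @export
simulate_dilution_series <- function(extract_conc,
                                     factors = c(1, 4, 16, 64, 256),
                                     replicates = 6, template_volume = 4,
                                     cfg = sim_config(), seed = NULL,
                                     sample_id = "series") {
  stopifnot(all(factors >= 1), !is.unsorted(factors), replicates >= 2)
  with_sim_seed(seed, {
    out <- lapply(factors, function(f) {
      simulate_droplets(extract_conc / f, n_wells = replicates,
                        template_volume = template_volume,
                        dilution_factor = f,
                        sample_id = sprintf("%s_d%g", sample_id, f),
                        cfg = cfg)
    })
    do.call(rbind, out)
  })
}

default_mock_groups <- c("1M", "3M:1F", "2M:1F", "1M:1F", "2M:2F", "1M:2F", "1M:3F")

#' Simulate a full mock or eDNA sex-ratio experiment
#'
#' Builds the standard design: a set of sex-composition groups, each
#' replicated in several series with freshly drawn individuals, each sample
#' measured in replicate wells, plus an all-female control and a
#' no-template control per series. One male and one female can be shared
#' across designated groups within every series, reproducing the design
#' feature that a single low-copy-ratio male drags down every one-male
#' sample it enters.
#'
#' @param groups Character vector of "xM:yF" labels.
#' @param n_series Biological replicate series per group.
#' @param n_wells Technical replicate wells per sample (defaults from the
#'   config by mode).
#' @param mode "mock" or "edna".
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @param shared_male_groups,shared_female_groups Groups in which the
#'   shared individual replaces one draw of its sex.
#' @param shared_male_rho Force the shared male's copy ratio (e.g., 3 for a
#'   distinctly low-ratio male); `NULL` draws it like any other male.
#' @return List: `droplets` (well counts), `metadata` (sample
#'   compositions), `truth` (true concentrations and male proportions).
#' @export
simulate_experiment <- function(groups = default_mock_groups,
                                n_series = 3, n_wells = NULL,
                                mode = c("mock", "edna"),
                                cfg = sim_config(), seed = NULL,
                                shared_male_groups = c("1M:1F", "2M:2F", "1M:2F", "1M:3F"),
                                shared_female_groups = c("1M:1F", "2M:2F", "2M:1F", "3M:1F"),
                                shared_male_rho = NULL) {
  mode <- match.arg(mode)
  if (is.null(n_wells)) {
    n_wells <- if (mode == "mock") cfg$n_wells_mock else cfg$n_wells_edna
  }
  vt <- if (mode == "mock") cfg$template_volume_mock else cfg$template_volume_edna
  comp <- parse_group_label(groups)

  with_sim_seed(seed, {
    shared_m <- simulate_individuals(1, 0, cfg, id_prefix = "shared")
    if (!is.null(shared_male_rho)) shared_m$rho_i <- shared_male_rho
    shared_f <- simulate_individuals(0, 1, cfg, id_prefix = "shared")

    droplets <- list()
    metadata <- list()
    truth <- list()
    i <- 0L
    for (s in seq_len(n_series)) {
      for (g in seq_along(groups)) {
        i <- i + 1L
        M <- comp$n_males[g]; F_ <- comp$n_females[g]
        use_sm <- groups[g] %in% shared_male_groups && M >= 1
        use_sf <- groups[g] %in% shared_female_groups && F_ >= 1
        fresh <- if (M - use_sm + F_ - use_sf > 0) {
          simulate_individuals(M - use_sm, F_ - use_sf, cfg,
                               id_prefix = sprintf("s%d_%s", s, groups[g]))
        }
        inds <- rbind(if (use_sm) shared_m, if (use_sf) shared_f, fresh)
        sid <- sprintf("%s_ser%s", gsub(":", "", groups[g]), LETTERS[s])
        conc <- simulate_sample(inds, mode, cfg)
        droplets[[i]] <- simulate_droplets(conc, n_wells = n_wells,
                                           template_volume = vt,
                                           sample_id = sid, cfg = cfg)
        male_mass <- sum(inds$mass_g[inds$sex == "M"])
        total_mass <- sum(inds$mass_g)
        metadata[[i]] <- data.frame(
          sample_id = sid, group = groups[g], n_males = M, n_females = F_,
          male_mass_g = male_mass, total_mass_g = total_mass,
          series = LETTERS[s], sample_type = mode)
        truth[[i]] <- data.frame(
          sample_id = sid, common = conc[["common"]], male = conc[["male"]],
          p_male = M / (M + F_),
          mass_fraction_male = male_mass / total_mass,
          expected_cm = expected_ratio_individuals(
            inds, mode = if (mode == "mock") "equal" else "mass",
            allometry_b = cfg$allometry_b))
      }
      # controls: all-female sample and NTC
      i <- i + 1L
      fc <- simulate_individuals(0, 2, cfg, id_prefix = sprintf("s%d_ctrl", s))
      sidf <- sprintf("0M2F_ser%s", LETTERS[s])
      concf <- simulate_sample(fc, mode, cfg)
      droplets[[i]] <- simulate_droplets(concf, n_wells = n_wells,
                                         template_volume = vt,
                                         sample_id = sidf, cfg = cfg)
      metadata[[i]] <- data.frame(
        sample_id = sidf, group = "0M:2F", n_males = 0L, n_females = 2L,
        male_mass_g = 0, total_mass_g = sum(fc$mass_g),
        series = LETTERS[s], sample_type = "female_control")
      truth[[i]] <- data.frame(sample_id = sidf, common = concf[["common"]],
                               male = concf[["male"]], p_male = 0,
                               mass_fraction_male = 0, expected_cm = Inf)
      i <- i + 1L
      sidn <- sprintf("NTC_ser%s", LETTERS[s])
      droplets[[i]] <- simulate_droplets(c(common = 0, male = 0),
                                         n_wells = 1, template_volume = vt,
                                         sample_id = sidn, cfg = cfg,
                                         is_control = TRUE)
      metadata[[i]] <- data.frame(
        sample_id = sidn, group = "NTC", n_males = 0L, n_females = 0L,
        male_mass_g = 0, total_mass_g = 0,
        series = LETTERS[s], sample_type = "ntc")
      truth[[i]] <- data.frame(sample_id = sidn, common = 0, male = 0,
                               p_male = NA_real_, mass_fraction_male = NA_real_,
                               expected_cm = NA_real_)
    }
    list(droplets = do.call(rbind, droplets),
         metadata = do.call(rbind, metadata),
         truth = do.call(rbind, truth))
  })
}
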