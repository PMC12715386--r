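# Small builders shared across test files.

# A block of replicate wells for one sample x target.
make_wells <- function(positives, accepted = 16500, target = "male",
                       sample_id = "S1", template_volume_ul = 4,
                       dilution_factor = 1) {
  data.frame(sample_id = sample_id, target = target,
             positives = positives,
             accepted = rep_len(accepted, length(positives)),
             template_volume_ul = template_volume_ul,
             dilution_factor = dilution_factor)
}

# Counts whose merged concentration is (approximately) a requested value.
counts_for_conc <- function(conc, n = 99000, template_volume = 4,
                            mix_volume = 22, droplet_volume = 8.5e-4) {
  lam <- conc * template_volume / mix_volume * droplet_volume
  round(n * (1 - exp(-lam)))
}

# A two-target dilution series data.frame from per-level per-well counts.
make_series <- function(common_k, male_k, factors, accepted = 16500,
                        template_volume_ul = 4) {
  do.call(rbind, lapply(seq_along(factors), function(i) {
    rbind(
      make_wells(common_k[[i]], accepted, "common",
                 sample_id = paste0("d", factors[i]),
                 template_volume_ul = template_volume_ul,
                 dilution_factor = factors[i]),
      make_wells(male_k[[i]], accepted, "male",
                 sample_id = paste0("d", factors[i]),
                 template_volume_ul = template_volume_ul,
                 dilution_factor = factors[i]))
  }))
}
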