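# Shared fixtures and desk-scale configurations.
#
# Desk scale: 300-point grid, 2x200 hidden layers, lr 3e-3 -> 3e-4 with the
# schedule drop at epoch 200, <= 400 epochs, patience 40. Same architecture
# family as the full-scale default, sized for minutes-not-hours runs; see
# the methods vignette for the rationale.

desk_grid <- function(n = 300) wn_grid(457, 1674, n)

desk_config <- function(latent_dim = 2, seed = 1L, input_dim = 300) {
  quantifier_config(
    input_dim = input_dim, hidden_layers = 2, hidden_width = 200,
    latent_dim = latent_dim, batch_size = 32, max_epochs = 400,
    lr_initial = 3e-3, lr_late = 3e-4, schedule_epoch = 200,
    early_stop_patience = 40, seed = seed)
}

# small config for fast mechanical tests (not for accuracy claims)
tiny_config <- function(input_dim = 120, latent_dim = 2, seed = 1L, ...) {
  quantifier_config(
    input_dim = input_dim, hidden_layers = 2, hidden_width = 32,
    latent_dim = latent_dim, batch_size = 8, max_epochs = 25,
    lr_initial = 3e-3, lr_late = 3e-4, schedule_epoch = 15,
    early_stop_patience = 25, seed = seed, ...)
}

# single-band library: each target metabolite keeps only its primary band,
# on a fixed background; used where band localization must be unambiguous
primary_only_library <- function() {
  lib <- default_library()
  for (m in c("uric_acid", "lactate", "tyrosine"))
    lib[[m]]$peaks <- lib[[m]]$peaks[1, ]
  lib
}

# design varying a single metabolite over its printed levels, others zero,
# constant mid-range background species
single_analyte_design <- function(metabolite, replicates = 6) {
  lv <- metabolite_levels()
  combos <- data.frame(uric_acid = 0, lactate = 0, tyrosine = 0,
                       urea = 6, glucose = 0.15, creatinine = 0.06,
                       ascorbic_acid = 0.03, glycine = 0.5, alanine = 0.5,
                       glutamate = 0.25)[rep(1, length(lv[[metabolite]])), ]
  combos[[metabolite]] <- lv[[metabolite]]
  combos <- cbind(combo_id = seq_len(nrow(combos)), combos)
  mixture_design(combos, replicates)
}
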