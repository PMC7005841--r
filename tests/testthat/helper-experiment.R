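# shared helpers for building experiments and extracting slopes

sim_annual <- function(seed, params = simulation_params(seed = seed),
                       min_biomass = 1) {
  params$seed <- as.integer(seed)
  e <- suppressWarnings(simulate_experiment(params))
  q <- add_quality(e$cuts)
  suppressWarnings(aggregate_annual(q, filter_swards(q, min_biomass)))
}

fitted_slopes <- function(fit) {
  s <- coef(fit)[grep(":d_term$", names(coef(fit)))]
  names(s) <- sub("^management", "", sub(":d_term$", "", names(s)))
  s[levels(management_regimes()$management)]
}

noise_free_params <- function(seed = 1) {
  simulation_params(sd_block = 0, sd_plot = 0, sd_cut = 0,
                    prob_missing = 0, seed = seed)
}

# minimal hand-built sward table accepted by simulate_cuts()
flat_swards <- function(n, management = "extensive", richness = 1) {
  reg <- management_regimes()
  reg <- reg[reg$management == management, ]
  data.frame(
    sward_id = sprintf("S%05d", seq_len(n)),
    plot_id = sprintf("Q%05d", seq_len(n)),
    block = rep_len(1:4, n),
    richness = richness,
    n_fg = 1, grass_present = TRUE, tall_herb_present = FALSE,
    legume_present = FALSE, legume_share = 0,
    management = factor(management,
                        levels = levels(reg$management)),
    cuts_per_year = reg$cuts_per_year,
    n_fertilization = reg$n_fertilization
  )
}
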