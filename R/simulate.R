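#' Parameters of the synthetic per-cut data generator
#'
#' The generator mirrors the statistical structure assumed by the
#' diversity-effect mixed model: per-management intercepts and square-root
#' diversity slopes for annual biomass, per-management legume effects,
#' functional-group and group-presence effects, Gaussian block and plot
#' random intercepts, and per-cut residual noise. Per-cut biomass is the
#' annual-structure mean divided by the regime's cut count plus per-cut
#' noise, so residual variance is heteroscedastic across cutting
#' frequencies. Raw forage chemistry is drawn on the measured-variable scale
#' (fermentation gas, crude protein, ether extract, NDF, ash, incubation
#' ammonia) around sward-level baselines with deterministic linear per-cut
#' trends, sign-constrained so that energy and protein decline while fiber
#' and ash rise over the season.
#'
#' Defaults are chosen to resemble a temperate floodplain meadow experiment:
#' monoculture annual yields of roughly 250-600 g DM m-2 depending on
#' management, diversity slopes of 60-120 g m-2 per unit square-root
#' richness (largest under intensive management), legume boosts of about
#' 80 g m-2, and first-cut chemistry around 48 mL gas day-1, 160 g CP kg-1,
#' 25 g EE kg-1, 440 g NDF kg-1 and 85 g ash kg-1.
#'
#' @param biomass_intercept Named numeric, annual-biomass intercept per
#'   management (g DM m-2 a-1).
#' @param diversity_slope Named numeric, slope on the square root of sown
#'   richness per management (g DM m-2 per unit sqrt(D)).
#' @param legume_effect Named numeric, additive annual-biomass effect of
#'   legume presence per management (g DM m-2).
#' @param fg_effect,grass_effect,tall_herb_effect Scalar effects of the
#'   number of functional groups and of grass / tall-herb presence.
#' @param sd_block,sd_plot,sd_cut Standard deviations of block intercepts,
#'   plot intercepts and per-cut residual noise (g DM m-2). All must be
#'   non-negative.
#' @param prob_missing Probability that a cut's biomass record is missing.
#' @param chem Named list of chemistry baselines (`*_base`, first-cut mean),
#'   per-cut linear trends (`*_trend`) and sward-level SDs (`*_sd`) for
#'   `gas` (mL day-1), `cp`, `ee`, `ndf`, `ash` (g kg-1 DM), plus the
#'   first-cut incubation quantities `nh3_blank`, `n_sample`, `nh3_sample`,
#'   `dm_mg` (mg) and `n_sample_sd`.
#' @param seed Master seed for all generator randomness.
#' @return An object of class `sim_params`.
#' @export
simulation_params <- function(
    biomass_intercept = c(extensive = 250, less_intensive = 350,
                          intensive = 450, highly_intensive = 500,
                          very_highly_intensive = 600),
    diversity_slope = c(extensive = 60, less_intensive = 80,
                        intensive = 120, highly_intensive = 90,
                        very_highly_intensive = 100),
    legume_effect = c(extensive = 60, less_intensive = 80,
                      intensive = 80, highly_intensive = 90,
                      very_highly_intensive = 90),
    fg_effect = 10, grass_effect = 30, tall_herb_effect = 20,
    sd_block = 40, sd_plot = 60, sd_cut = 80,
    prob_missing = 0.02,
    chem = list(
      gas_base = 48, gas_trend = -2.5, gas_sd = 3,
      cp_base = 160, cp_trend = -12, cp_sd = 10,
      ee_base = 25, ee_trend = 0, ee_sd = 3,
      ndf_base = 440, ndf_trend = 25, ndf_sd = 20,
      ash_base = 85, ash_trend = 5, ash_sd = 5,
      nh3_blank = 2, n_sample = 5, nh3_sample = 3, dm_mg = 200,
      n_sample_sd = 0.3
    ),
    seed = 1L) {
  lv <- management_levels()
  for (nm in c("biomass_intercept", "diversity_slope", "legume_effect")) {
    v <- get(nm)
    if (!all(lv %in% names(v)))
      stop("`", nm, "` must be named with all five management levels",
           call. = FALSE)
  }
  if (any(c(sd_block, sd_plot, sd_cut) < 0))
    stop("standard deviations must be non-negative", call. = FALSE)
  if (prob_missing < 0 || prob_missing > 1)
    stop("`prob_missing` must be in [0, 1]", call. = FALSE)
  # seasonal trend signs: energy/protein decline, fiber/ash rise
  if (chem$gas_trend > 0 || chem$cp_trend > 0)
    stop("gas and crude-protein trends must be <= 0 (declining quality)",
         call. = FALSE)
  if (chem$ndf_trend < 0 || chem$ash_trend < 0)
    stop("NDF and ash trends must be >= 0 (rising fiber/ash)", call. = FALSE)
  if (any(unlist(chem[grep("_sd$", names(chem))]) < 0))
    stop("chemistry SDs must be non-negative", call. = FALSE)
  structure(list(
    biomass_intercept = biomass_intercept[lv],
    diversity_slope = diversity_slope[lv],
    legume_effect = legume_effect[lv],
    fg_effect = fg_effect, grass_effect = grass_effect,
    tall_herb_effect = tall_herb_effect,
    sd_block = sd_block, sd_plot = sd_plot, sd_cut = sd_cut,
    prob_missing = prob_missing, chem = chem,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic experiment parameters\n")
  cat("  biomass intercepts:", paste(round(x$biomass_intercept), collapse = "/"), "\n")
  cat("  sqrt-diversity slopes:", paste(round(x$diversity_slope), collapse = "/"), "\n")
  cat("  SDs (block/plot/cut):", x$sd_block, x$sd_plot, x$sd_cut, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# annual-mean fixed-effect structure shared by the generator and the
# noise-free recovery tests
annual_mean_structure <- function(swards, params) {
  m <- as.character(swards$management)
  unname(params$biomass_intercept[m] +
    params$diversity_slope[m] * sqrt(swards$richness) +
    params$legume_effect[m] * as.numeric(swards$legume_present) +
    params$fg_effect * swards$n_fg +
    params$grass_effect * as.numeric(swards$grass_present) +
    params$tall_herb_effect * as.numeric(swards$tall_herb_present))
}

#' Simulate per-cut biomass and raw chemistry for a set of swards
#'
#' For each sward the regime's number of cuts is generated. Cut biomass is
#' `(annual mean + block + plot + per-cut noise) / cuts`; negative draws are
#' truncated at zero with a warning. Chemistry is drawn once per sward
#' (baseline level) and follows a deterministic linear trend over cuts, so
#' within-sward seasonal monotonicity holds exactly. Incubation ammonia
#' quantities for utilizable crude protein are generated for the first cut
#' only.
#'
#' @param swards Sward table from [build_swards()].
#' @param params A [simulation_params()] object; its `seed` drives all
#'   randomness, so identical inputs give identical tables.
#' @return A data.frame, one row per sward x cut, carrying the design
#'   columns plus `cut`, `biomass` (g DM m-2, possibly `NA` for missing
#'   records) and the raw chemistry columns `gas`, `cp`, `ee`, `ndf`,
#'   `ash`, `nh3_n_blank`, `n_sample_mg`, `nh3_n_sample`, `dm_mg`.
#' @examples
#' sw <- build_swards(build_design(seed = 1))
#' cuts <- simulate_cuts(sw, simulation_params(seed = 1))
#' @export
simulate_cuts <- function(swards, params = simulation_params()) {
  if (!inherits(params, "sim_params"))
    stop("`params` must come from simulation_params()", call. = FALSE)

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  blocks <- sort(unique(swards$block))
  plots <- unique(swards$plot_id)
  u_b <- stats::setNames(stats::rnorm(length(blocks), 0, params$sd_block),
                         blocks)
  u_p <- stats::setNames(stats::rnorm(length(plots), 0, params$sd_plot),
                         plots)

  mu <- annual_mean_structure(swards, params)
  h <- swards$cuts_per_year
  ch <- params$chem
  n <- nrow(swards)

  # sward-level chemistry baselines (one draw per sward, shared by cuts)
  base_gas <- ch$gas_base + stats::rnorm(n, 0, ch$gas_sd)
  base_cp  <- ch$cp_base  + stats::rnorm(n, 0, ch$cp_sd)
  base_ee  <- ch$ee_base  + stats::rnorm(n, 0, ch$ee_sd)
  base_ndf <- ch$ndf_base + stats::rnorm(n, 0, ch$ndf_sd)
  base_ash <- ch$ash_base + stats::rnorm(n, 0, ch$ash_sd)
  n_samp   <- ch$n_sample + stats::rnorm(n, 0, ch$n_sample_sd)

  sw <- rep(seq_len(n), h)       # row -> sward index
  cut <- sequence(h)             # 1..h within sward
  e <- stats::rnorm(length(sw), 0, params$sd_cut)
  biomass <- (mu[sw] + u_b[as.character(swards$block[sw])] +
                u_p[swards$plot_id[sw]] + e) / h[sw]
  if (any(biomass < 0)) {
    warning("negative simulated biomass truncated at 0", call. = FALSE)
    biomass <- pmax(biomass, 0)
  }
  if (params$prob_missing > 0)
    biomass[stats::runif(length(sw)) < params$prob_missing] <- NA_real_

  trend_ix <- cut - 1
  first <- cut == 1L
  out <- data.frame(
    sward_id = swards$sward_id[sw],
    cut = cut,
    biomass = as.numeric(biomass),
    gas = pmax(base_gas[sw] + ch$gas_trend * trend_ix, 0),
    cp  = pmax(base_cp[sw]  + ch$cp_trend  * trend_ix, 0),
    ee  = pmax(base_ee[sw]  + ch$ee_trend  * trend_ix, 0),
    ndf = pmax(base_ndf[sw] + ch$ndf_trend * trend_ix, 0),
    ash = pmin(pmax(base_ash[sw] + ch$ash_trend * trend_ix, 0), 1000),
    nh3_n_blank = ifelse(first, ch$nh3_blank, NA_real_),
    n_sample_mg = ifelse(first, n_samp[sw], NA_real_),
    nh3_n_sample = ifelse(first, ch$nh3_sample, NA_real_),
    dm_mg = ifelse(first, ch$dm_mg, NA_real_)
  )
  keep <- setdiff(names(swards), names(out))
  out <- cbind(out, swards[sw, keep, drop = FALSE])
  rownames(out) <- NULL
  out[, c("sward_id", keep, "cut", "biomass", "gas", "cp", "ee", "ndf",
          "ash", "nh3_n_blank", "n_sample_mg", "nh3_n_sample", "dm_mg")]
}

#' Simulate a full experiment (design, swards, cuts) from one seed
#'
#' @param params A [simulation_params()]; `params$seed` seeds the design
#'   draw and the cut simulation through deterministic substreams.
#' @param pool A [species_pool()].
#' @return A list with elements `design`, `swards` and `cuts`.
#' @export
simulate_experiment <- function(params = simulation_params(),
                                pool = species_pool()) {
  design <- build_design(pool, seed = params$seed)
  swards <- build_swards(design)
  # distinct substream for the measurement stage
  p2 <- params
  p2$seed <- (params$seed + 987653L) %% .Machine$integer.max
  cuts <- simulate_cuts(swards, p2)
  list(design = design, swards = swards, cuts = cuts)
}
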