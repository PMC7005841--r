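# polynomial rolling hash of the deparsed configuration (provenance header)
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles the generator parameters, chemistry and aggregation settings,
#' model options and economic rates under one master seed.
#'
#' @param seed Master seed; seeds every stage through deterministic
#'   substreams.
#' @param sim [simulation_params()] (its seed is overridden by `seed`).
#' @param nel_per_kg_milk Milk conversion coefficient, MJ NEL kg-1 milk.
#' @param min_biomass Sward filter threshold, g DM m-2.
#' @param responses Responses to model; `revenue` is derived from the milk
#'   production potential yield at the configured milk price.
#' @param n_tests Named Bonferroni family sizes per response (defaults: 1
#'   for biomass yield, 6 otherwise).
#' @param diversity_form Diversity transform for the fitted models.
#' @param rates [economic_rates()].
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, sim = simulation_params(seed = seed),
                       nel_per_kg_milk = 3.2, min_biomass = 1,
                       responses = c("biomass_yield", "qa_me", "revenue"),
                       n_tests = NULL, diversity_form = "sqrt",
                       rates = economic_rates()) {
  sim$seed <- as.integer(seed)
  if (is.null(n_tests)) {
    n_tests <- ifelse(responses == "biomass_yield", 1, 6)
    names(n_tests) <- responses
  }
  structure(list(seed = as.integer(seed), sim = sim,
                 nel_per_kg_milk = nel_per_kg_milk,
                 min_biomass = min_biomass, responses = responses,
                 n_tests = n_tests, diversity_form = diversity_form,
                 rates = rates),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys: `seed`, `nel_per_kg_milk`, `min_biomass`,
#' `responses`, `diversity_form`, `sim` (fields of [simulation_params()])
#' and `rates` (fields of [economic_rates()]). Missing keys keep defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1L
  sim_args <- y$sim
  if (!is.null(sim_args)) {
    for (nm in c("biomass_intercept", "diversity_slope", "legume_effect"))
      if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
    if (!is.null(sim_args$chem)) {
      ch <- formals(simulation_params)$chem
      ch <- eval(ch)
      ch[names(sim_args$chem)] <- sim_args$chem
      sim_args$chem <- ch
    }
  }
  sim <- do.call(simulation_params, c(sim_args, list(seed = seed)))
  rates <- if (!is.null(y$rates)) do.call(economic_rates, y$rates)
           else economic_rates()
  args <- list(seed = seed, sim = sim, rates = rates)
  for (nm in c("nel_per_kg_milk", "min_biomass", "responses",
               "diversity_form"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(run_config, args)
}

# CSV writers/readers with a provenance comment header
write_gq_csv <- function(x, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gqyield config=%s seed=%d", hash, seed), con)
  utils::write.csv(x, con, row.names = FALSE)
}

#' Read a pipeline CSV, skipping the provenance header
#'
#' @param path CSV path written by [run_all()].
#' @return A data.frame.
#' @export
read_gq_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

table_schemas <- function() {
  list(
    design = list(
      required = c("plot_id", "block", "richness", "n_fg", "grass_present",
                   "tall_herb_present", "legume_present", "legume_share"),
      checks = list(
        "block outside 1..4" = function(d) !(d$block %in% 1:4),
        "richness not a design level" =
          function(d) !(d$richness %in% c(1, 2, 4, 8, 16, 60)),
        "n_fg outside 1..4" = function(d) d$n_fg < 1 | d$n_fg > 4,
        "legume_share outside [0,1]" =
          function(d) d$legume_share < 0 | d$legume_share > 1,
        "legume presence/share mismatch" =
          function(d) (d$legume_share > 0) != (d$legume_present > 0)
      )),
    cut = list(
      required = c("sward_id", "cut", "cuts_per_year", "biomass", "gas",
                   "cp", "ee", "ndf", "ash"),
      checks = list(
        "negative biomass" = function(d) !is.na(d$biomass) & d$biomass < 0,
        "ash outside [0,1000]" =
          function(d) !is.na(d$ash) & (d$ash < 0 | d$ash > 1000),
        "negative chemistry" = function(d)
          apply(d[, c("gas", "cp", "ee", "ndf")] < 0, 1,
                function(z) any(z, na.rm = TRUE)),
        "cut index outside 1..cuts_per_year" =
          function(d) d$cut < 1 | d$cut > d$cuts_per_year
      )),
    quality = list(
      required = c("sward_id", "cut", "biomass", "me", "nel",
                   "milk_potential", "om"),
      checks = list(
        "energy ordering violated (me < nel)" =
          function(d) !is.na(d$me) & !is.na(d$nel) & d$me < d$nel,
        "negative energy" = function(d) !is.na(d$nel) & d$nel < 0
      )),
    annual = list(
      required = c("sward_id", "biomass_yield", "n_cuts_used"),
      checks = list(
        "negative biomass yield" = function(d) d$biomass_yield < 0
      ))
  )
}

#' Validate a pipeline table against its schema
#'
#' Checks required columns and row-level range/consistency rules for the
#' registered schemas (`"design"`, `"cut"`, `"quality"`, `"annual"`).
#' Violations abort with a message listing the rule and offending row
#' numbers.
#'
#' @param table A data.frame.
#' @param schema_name One of the registered schema names.
#' @return The table, invisibly, when valid.
#' @export
validate_table <- function(table, schema_name) {
  schemas <- table_schemas()
  if (!schema_name %in% names(schemas))
    stop("unknown schema: ", schema_name, call. = FALSE)
  sc <- schemas[[schema_name]]
  miss <- setdiff(sc$required, names(table))
  if (length(miss))
    stop("schema '", schema_name, "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  problems <- character(0)
  for (rule in names(sc$checks)) {
    bad <- which(sc$checks[[rule]](table))
    if (length(bad))
      problems <- c(problems, sprintf(
        "%s: rows %s", rule,
        paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (length(problems))
    stop("schema '", schema_name, "' violated:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(table)
}

#' Run the full pipeline: simulate, evaluate, aggregate, fit, value
#'
#' Executes all stages on one master seed and writes every table as CSV
#' with a provenance header (configuration hash and seed), plus a YAML
#' manifest. Outputs are byte-identical across runs with the same
#' configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_all <- function(config = run_config(), out_dir) {
  if (!inherits(config, "run_config"))
    stop("`config` must come from run_config()", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  emit <- function(x, name) write_gq_csv(x, file.path(out_dir, name), hash,
                                         seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  exp <- stage("simulate", {
    e <- simulate_experiment(config$sim)
    validate_table(e$design, "design")
    validate_table(e$cuts, "cut")
    e
  })
  emit(exp$design, "design.csv")
  emit(exp$cuts, "cuts.csv")

  quality <- stage("evaluate", {
    q <- add_quality(exp$cuts, config$nel_per_kg_milk)
    validate_table(q, "quality")
    q
  })
  emit(quality, "quality.csv")

  agg <- stage("aggregate", {
    flt <- filter_swards(quality, config$min_biomass)
    ann <- aggregate_annual(quality, flt)
    ann$revenue <- revenue(ann$qa_milk_potential, config$rates)$revenue
    validate_table(ann, "annual")
    list(annual = ann, filter = flt)
  })
  emit(agg$annual, "annual.csv")
  emit(agg$filter$dropped, "dropped_swards.csv")

  fits <- stage("fit", {
    lapply(stats::setNames(nm = config$responses), function(resp) {
      fit <- fit_diversity_model(agg$annual, resp,
                                 diversity_form = config$diversity_form)
      eff <- effect_inference(fit, n_tests = config$n_tests[[resp]])
      pred <- predict_diversity_grid(fit)
      list(fit = fit, effects = eff, predictions = pred)
    })
  })
  for (resp in config$responses) {
    f <- fits[[resp]]
    ctab <- data.frame(term = names(coef(f$fit)),
                       estimate = unname(coef(f$fit)),
                       se_model = sqrt(diag(f$fit$vcov_model)),
                       se_robust = sqrt(diag(f$fit$vcov_robust)))
    emit(ctab, sprintf("coefficients_%s.csv", resp))
    emit(f$effects$slopes, sprintf("effects_%s.csv", resp))
    emit(f$effects$pairwise, sprintf("wald_pairs_%s.csv", resp))
    emit(f$predictions, sprintf("predictions_%s.csv", resp))
  }

  econ <- stage("economics", {
    switches <- list(
      c("less_intensive", "intensive"),
      c("less_intensive", "very_highly_intensive")
    )
    costs <- do.call(rbind, lapply(switches, function(s) {
      led <- management_switch_cost(s[1], s[2], config$rates)
      data.frame(from = s[1], to = s[2],
                 total = led$total, total_printed = led$total_printed,
                 profit_change = led$profit_change)
    }))
    hay <- hay_transfer_cost(config$rates)
    restoration <- data.frame(
      option = c("hay_transfer", "reseeding_process"),
      euro_per_ha = c(hay$total, reseeding_process_cost(config$rates)))
    equi <- if ("revenue" %in% config$responses) {
      do.call(rbind, lapply(switches, function(s) {
        eq <- equivalent_diversity_change(fits$revenue$fit, s[1], s[2])
        data.frame(base = s[1], target = s[2],
                   revenue_gap = eq$revenue_gap,
                   D_equivalent = eq$D_equivalent,
                   D_species = eq$D_species)
      }))
    } else NULL
    list(switch_costs = costs, restoration = restoration,
         equivalence = equi)
  })
  emit(econ$switch_costs, "switch_costs.csv")
  emit(econ$restoration, "restoration_costs.csv")
  if (!is.null(econ$equivalence)) emit(econ$equivalence, "equivalence.csv")

  manifest <- list(
    package = "gqyield",
    version = as.character(utils::packageVersion("gqyield")),
    config_hash = hash,
    seed = seed,
    n_plots = nrow(exp$design),
    n_swards = length(unique(exp$cuts$sward_id)),
    n_swards_retained = nrow(agg$annual),
    n_swards_dropped = nrow(agg$filter$dropped),
    responses = config$responses
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(experiment = exp, quality = quality, annual = agg$annual,
                 filter = agg$filter, fits = fits, economics = econ,
                 manifest = manifest))
}
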