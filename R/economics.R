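#' Economic rates for grassland management costing
#'
#' Default rates reproduce typical German variable costs: a 0.31 Euro kg-1
#' milk price (2016/2017 average), 13 Euro h-1 labor, 0.75 Euro l-1 fuel,
#' calcium ammonium nitrate at 0.23 Euro kg-1 with 0.27 kg N kg-1, PK
#' fertilizer at 0.22 Euro kg-1 with 0.12 kg P and 0.24 kg K per kg, a
#' 250 Euro ha-1 opportunity cost for donor grassland in fresh hay
#' transfer, and per-task machine hours and fuel use per hectare.
#'
#' @param milk_price Euro kg-1 milk.
#' @param labor_rate Euro h-1.
#' @param fuel_price Euro l-1.
#' @param can_n_fraction kg N per kg calcium ammonium nitrate.
#' @param can_price Euro kg-1 calcium ammonium nitrate.
#' @param pk_p_fraction,pk_k_fraction kg P / kg K per kg PK fertilizer.
#' @param pk_price Euro kg-1 PK fertilizer.
#' @param hay_opportunity_cost Euro ha-1 compensation for the donor site.
#' @param tasks Data frame of per-task `hours` (h ha-1) and `fuel` (l ha-1)
#'   with row names naming the tasks.
#' @return An object of class `economic_rates`.
#' @export
economic_rates <- function(milk_price = 0.31, labor_rate = 13,
                           fuel_price = 0.75,
                           can_n_fraction = 0.27, can_price = 0.23,
                           pk_p_fraction = 0.12, pk_k_fraction = 0.24,
                           pk_price = 0.22,
                           hay_opportunity_cost = 250,
                           tasks = default_tasks()) {
  rates <- list(milk_price = milk_price, labor_rate = labor_rate,
                fuel_price = fuel_price, can_n_fraction = can_n_fraction,
                can_price = can_price, pk_p_fraction = pk_p_fraction,
                pk_k_fraction = pk_k_fraction, pk_price = pk_price,
                hay_opportunity_cost = hay_opportunity_cost, tasks = tasks)
  num <- unlist(rates[setdiff(names(rates), "tasks")])
  if (any(num < 0))
    stop("economic rates must be non-negative", call. = FALSE)
  fr <- c(can_n_fraction, pk_p_fraction, pk_k_fraction)
  if (any(fr <= 0 | fr > 1))
    stop("nutrient fractions must lie in (0, 1]", call. = FALSE)
  structure(rates, class = "economic_rates")
}

default_tasks <- function() {
  data.frame(
    hours = c(fertilizing = 0.55, cutting = 0.67, windrowing = 0.53,
              collecting = 3.56, reseeding = 0.27, rolling = 0.41,
              hay_transport = 5.27, hay_distribution = 0.89),
    fuel = c(fertilizing = 1.9, cutting = 4.85, windrowing = 3.18,
             collecting = 12.67, reseeding = 2.08, rolling = 2.46,
             hay_transport = 19.74, hay_distribution = 5.66)
  )
}

# whole-Euro reporting: round half away from zero
round_euro <- function(x) sign(x) * floor(abs(x) + 0.5)

new_cost_ledger <- function(items, description = NULL) {
  structure(list(items = items, total = sum(items),
                 description = description),
            class = "cost_ledger")
}

#' @export
print.cost_ledger <- function(x, ...) {
  if (!is.null(x$description)) cat(x$description, "\n")
  df <- data.frame(item = names(x$items),
                   euro_per_ha = round_euro(x$items))
  print(df, row.names = FALSE)
  cat("Total:", round_euro(x$total), "Euro ha-1 a-1 (",
      format(x$total, digits = 6), "at full precision )\n")
  invisible(x)
}

#' Milk revenue of a sward or prediction (Eq: revenue = yield x price)
#'
#' Converts a milk production potential yield from kg m-2 a-1 to
#' kg ha-1 a-1 and values it at the milk price.
#'
#' @param milk_yield_m2 Milk production potential yield, kg m-2 a-1.
#' @param rates An [economic_rates()] object.
#' @return Data frame with `milk_yield_ha` (kg ha-1 a-1) and `revenue`
#'   (Euro ha-1 a-1).
#' @examples
#' revenue(1.0) # 10,000 kg/ha at 0.31 -> 3100 Euro
#' @export
revenue <- function(milk_yield_m2, rates = economic_rates()) {
  if (any(milk_yield_m2 < 0, na.rm = TRUE))
    stop("milk yield must be non-negative", call. = FALSE)
  milk_ha <- milk_yield_m2 * 1e4
  data.frame(milk_yield_ha = milk_ha, revenue = milk_ha * rates$milk_price)
}

#' Cost of raising the fertilization level by given nutrient increments
#'
#' Calcium ammonium nitrate covers the nitrogen increment; a compound PK
#' fertilizer is bought to satisfy the binding one of the phosphorus and
#' potassium increments (max rule).
#'
#' @param dN,dP,dK Nutrient increments, kg ha-1 a-1. Defaults are the
#'   increments of one fertilization step (100 N, 43.6 P, 83 K).
#' @param rates An [economic_rates()] object.
#' @return Euro ha-1 a-1 (full precision).
#' @examples
#' fertilizer_increment_cost() # 165.12 -> printed as 165
#' @export
fertilizer_increment_cost <- function(dN = 100, dP = 43.6, dK = 83,
                                      rates = economic_rates()) {
  if (any(c(dN, dP, dK) < 0))
    stop("nutrient increments must be non-negative", call. = FALSE)
  dN / rates$can_n_fraction * rates$can_price +
    max(dP / rates$pk_p_fraction, dK / rates$pk_k_fraction) * rates$pk_price
}

#' Labor-plus-fuel cost of field tasks
#'
#' @param task_names Character vector of tasks from the rate table, e.g.
#'   `c("cutting", "windrowing", "collecting")` for one harvest pass.
#' @param rates An [economic_rates()] object.
#' @return Euro ha-1 a-1 (full precision).
#' @examples
#' task_cost("fertilizing") # 8.575 -> printed as 9
#' @export
task_cost <- function(task_names, rates = economic_rates()) {
  if (length(task_names) == 0) return(0)
  unknown <- setdiff(task_names, rownames(rates$tasks))
  if (length(unknown))
    stop("unknown task(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  t <- rates$tasks[task_names, ]
  sum(t$hours) * rates$labor_rate + sum(t$fuel) * rates$fuel_price
}

#' Process cost of reseeding with a seed mixture
#'
#' Reseeding and rolling (seed-mixture purchase priced separately; market
#' means for standard / price-adjusted standard / highly diverse mixtures
#' are inputs, not computed here).
#'
#' @param rates An [economic_rates()] object.
#' @return Euro ha-1 a-1 (full precision; 12.245 at default rates).
#' @export
reseeding_process_cost <- function(rates = economic_rates()) {
  task_cost(c("reseeding", "rolling"), rates)
}

#' Itemized variable costs of fresh hay transfer
#'
#' Cutting, windrowing, collecting, transporting and distributing fresh
#' seed-containing hay from a species-rich donor grassland, plus the
#' donor's opportunity cost.
#'
#' @param rates An [economic_rates()] object.
#' @return A `cost_ledger` (total 426.535 at default rates, printed 427).
#' @export
hay_transfer_cost <- function(rates = economic_rates()) {
  tn <- c("cutting", "windrowing", "hay_transport", "collecting",
          "hay_distribution")
  items <- vapply(tn, task_cost, numeric(1), rates = rates)
  items <- c(items, opportunity_cost = rates$hay_opportunity_cost)
  new_cost_ledger(items, "Fresh hay transfer, variable costs")
}

#' Variable cost of switching between management intensities
#'
#' Additional annual variable costs of moving from one regime to a more
#' intensive one: each 100 kg N ha-1 fertilization step costs one
#' fertilizer increment; a transition from zero to non-zero fertilization
#' adds the fertilizer-application task; each added cut costs one
#' cutting/windrowing/collecting pass. De-intensification yields the
#' negated ledger. The headline figure follows the printed convention of
#' rounding each component to whole Euro before summing; the full-precision
#' total is also returned.
#'
#' @param from,to Management regime names (see [management_regimes()]).
#' @param rates An [economic_rates()] object.
#' @return A `cost_ledger` with additional fields `total_printed` (item-
#'   rounded sum) and `profit_change` (cost as negative profit, the sign
#'   convention used when set against revenue gains).
#' @examples
#' management_switch_cost("less_intensive", "intensive") # 174
#' @export
management_switch_cost <- function(from, to, rates = economic_rates()) {
  reg <- management_regimes()
  rownames(reg) <- as.character(reg$management)
  if (!from %in% rownames(reg) || !to %in% rownames(reg))
    stop("unknown management regime", call. = FALSE)
  f <- reg[from, ]; t_ <- reg[to, ]

  n_steps <- (t_$n_fertilization - f$n_fertilization) / 100
  starts_fert <- as.numeric(f$n_fertilization == 0 & t_$n_fertilization > 0) -
    as.numeric(t_$n_fertilization == 0 & f$n_fertilization > 0)
  d_cuts <- t_$cuts_per_year - f$cuts_per_year

  items <- c(
    fertilizer = n_steps * fertilizer_increment_cost(rates = rates),
    fertilizer_application = starts_fert * task_cost("fertilizing", rates),
    cutting = d_cuts * task_cost(c("cutting", "windrowing", "collecting"),
                                 rates)
  )
  led <- new_cost_ledger(items,
                         sprintf("Management switch %s -> %s", from, to))
  # printed convention: whole-Euro unit costs (165 / 9 / 77) times counts
  led$total_printed <-
    n_steps * round_euro(fertilizer_increment_cost(rates = rates)) +
    starts_fert * round_euro(task_cost("fertilizing", rates)) +
    d_cuts * round_euro(task_cost(c("cutting", "windrowing", "collecting"),
                                  rates))
  led$profit_change <- -led$total_printed
  led
}

#' Diversity change equivalent to a management-intensity change
#'
#' Solves, on a fitted revenue model with a square-root diversity form, for
#' the species richness D* at which staying under the base management but
#' raising diversity from `D_start` to D* yields the same predicted revenue
#' gain as switching from the base to the target management at `D_start`:
#' beta_base (sqrt(D*) - sqrt(D_start)) = revenue gap.
#'
#' @param fit A [fit_diversity_model()] fit on a revenue response with
#'   `diversity_form = "sqrt"`.
#' @param M_base,M_target Base and target management levels.
#' @param D_start Starting richness (>= 1).
#' @param policy Covariate policy for the management gap prediction, see
#'   [predict_diversity_grid()].
#' @return List with `D_equivalent` (real-valued, clipped to \[1, 60\]),
#'   `D_species` (rounded), `revenue_gap`, `slope`, and `extrapolated`
#'   (TRUE when the unclipped solution lies outside the design range).
#' @export
equivalent_diversity_change <- function(fit, M_base, M_target, D_start = 1,
                                        policy = "mean") {
  if (fit$diversity_form != "sqrt")
    stop("equivalence solver requires the sqrt diversity form", call. = FALSE)
  if (D_start < 1) stop("`D_start` must be >= 1", call. = FALSE)
  g <- predict_diversity_grid(fit, D = D_start, policy = policy,
                              managements = unique(c(M_base, M_target)))
  gap <- g$predicted[match(M_target, g$management)] -
    g$predicted[match(M_base, g$management)]
  sl <- diversity_slopes(fit)
  beta <- sl$estimate[sl$management == M_base]
  if (length(beta) != 1 || is.na(beta))
    stop("no diversity slope for management ", M_base, call. = FALSE)
  if (beta <= 0 && gap != 0)
    return(list(D_equivalent = NA_real_, D_species = NA_integer_,
                revenue_gap = gap, slope = beta, extrapolated = NA,
                message = "non-positive diversity slope: no solution"))
  root <- (gap / beta + sqrt(D_start))^2
  clipped <- min(max(root, 1), 60)
  list(D_equivalent = clipped, D_species = as.integer(round(clipped)),
       revenue_gap = gap, slope = beta,
       extrapolated = root < 1 || root > 60)
}

#' Welch two-sample t-test
#'
#' Unequal-variance comparison of two samples (used to compare predicted
#' revenues between management intensities). Thin wrapper around
#' [stats::t.test()] with `var.equal = FALSE`; samples with zero pooled
#' variance are rejected as degenerate.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df` (Welch-Satterthwaite) and `p`.
#' @export
welch_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("both samples need at least 2 observations", call. = FALSE)
  if (stats::var(sample_a) + stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1))
    stop("both samples are constant: Welch statistic undefined", call. = FALSE)
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
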