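#' Forage nutritive-value estimation equations
#'
#' Printed regression equations linking Hohenheim gas test fermentation and
#' proximate composition to energy content, plus the standard protein and
#' organic-matter conversions. All contents are per kg dry matter.
#'
#' @name forage-equations
NULL

check_nonneg <- function(..., .names = NULL) {
  vals <- list(...)
  nms <- if (is.null(.names)) sapply(substitute(list(...))[-1], deparse)
         else .names
  for (i in seq_along(vals))
    if (any(vals[[i]] < 0, na.rm = TRUE))
      stop("`", nms[i], "` must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Crude protein from nitrogen content
#'
#' @param n_content Nitrogen content, g N kg-1 DM.
#' @return Crude protein, g kg-1 DM (6.25 x nitrogen).
#' @examples
#' crude_protein(24) # 150
#' @rdname forage-equations
#' @export
crude_protein <- function(n_content) {
  check_nonneg(n_content)
  6.25 * n_content
}

#' Metabolizable energy from gas production and composition
#'
#' @param gas Fermentation gas production over 24 h, mL day-1.
#' @param cp Crude protein, g kg-1 DM.
#' @param ee Ether extract, g kg-1 DM.
#' @return Metabolizable energy, MJ kg-1 DM.
#' @examples
#' metabolizable_energy(0, 0, 0) # 3.16, the equation intercept
#' @rdname forage-equations
#' @export
metabolizable_energy <- function(gas, cp, ee) {
  check_nonneg(gas, cp, ee)
  3.16 + 0.0695 * gas + 0.000730 * gas^2 + 0.00732 * cp + 0.02052 * ee
}

#' Net energy for lactation from gas production and composition
#'
#' @return Net energy for lactation, MJ kg-1 DM.
#' @rdname forage-equations
#' @export
net_energy_lactation <- function(gas, cp, ee) {
  check_nonneg(gas, cp, ee)
  1.64 + 0.0269 * gas + 0.00078 * gas^2 + 0.0051 * cp + 0.01325 * ee
}

#' Milk production potential of a feed
#'
#' Converts net energy for lactation into the mass of milk whose synthesis
#' it can support. The conversion coefficient (energy requirement per kg of
#' milk) is a calibration parameter; the default of 3.2 MJ NEL kg-1 milk is
#' consistent with energy-corrected milk requirements for dairy cows.
#'
#' @param nel Net energy for lactation, MJ kg-1 DM.
#' @param nel_per_kg_milk Energy requirement per kg milk, MJ NEL kg-1.
#' @return Milk production potential, kg milk kg-1 DM.
#' @examples
#' milk_production_potential(6.4, 3.2) # 2
#' @rdname forage-equations
#' @export
milk_production_potential <- function(nel, nel_per_kg_milk = 3.2) {
  check_nonneg(nel)
  if (any(nel_per_kg_milk <= 0))
    stop("`nel_per_kg_milk` must be positive", call. = FALSE)
  nel / nel_per_kg_milk
}

#' Utilizable crude protein from incubation ammonia balance
#'
#' uCP estimates the protein reaching the duodenum (microbial plus escape
#' protein) from the ammonia-N balance of a rumen-fluid incubation with and
#' without the feed sample. Negative results are physically impossible and
#' indicate measurement error; they are returned as computed but flagged
#' with a warning rather than clipped.
#'
#' @param nh3_n_blank Ammonia-N of the blank incubation, mg.
#' @param n_sample Nitrogen of the feed sample, mg.
#' @param nh3_n_sample Ammonia-N of the sample incubation, mg.
#' @param dm_mg Sample dry matter, mg.
#' @return Utilizable crude protein, g kg-1 DM.
#' @examples
#' utilizable_crude_protein(2, 5, 3, 200) # 125
#' @rdname forage-equations
#' @export
utilizable_crude_protein <- function(nh3_n_blank, n_sample, nh3_n_sample,
                                     dm_mg) {
  if (any(dm_mg <= 0, na.rm = TRUE))
    stop("`dm_mg` must be positive", call. = FALSE)
  ucp <- (nh3_n_blank + n_sample - nh3_n_sample) / dm_mg * 6.25 * 1000
  if (any(ucp < 0, na.rm = TRUE))
    warning("negative uCP value(s): ammonia balance exceeds blank + sample N, ",
            "check the incubation measurements", call. = FALSE)
  ucp
}

#' Organic matter from ash content
#'
#' @param ash Total ash, g kg-1 DM (0-1000).
#' @return Organic matter, g kg-1 DM (1000 - ash).
#' @rdname forage-equations
#' @export
organic_matter <- function(ash) {
  if (any(ash < 0 | ash > 1000, na.rm = TRUE))
    stop("`ash` must lie in [0, 1000] g kg-1", call. = FALSE)
  1000 - ash
}

#' Derive the full nutritive-value profile of one or more cuts
#'
#' Applies all estimation equations to a raw chemistry record. Inputs may be
#' vectors of equal length (e.g. columns of a cut table). uCP is only
#' computed where all four incubation fields are present.
#'
#' @param gas,cp,ee,ndf,ash Raw chemistry, see [metabolizable_energy()].
#' @param nh3_n_blank,n_sample,nh3_n_sample,dm_mg Optional incubation
#'   quantities for uCP (may be `NULL` or `NA`).
#' @param nel_per_kg_milk Milk conversion coefficient, MJ NEL kg-1 milk.
#' @return A data.frame with columns `me`, `nel`, `milk_potential`, `cp`,
#'   `ucp` (NA where incubation data are absent), `om`, `ndf`.
#' @examples
#' quality_profile(gas = 50, cp = 150, ee = 20, ndf = 450, ash = 90)
#' @export
quality_profile <- function(gas, cp, ee, ndf, ash,
                            nh3_n_blank = NULL, n_sample = NULL,
                            nh3_n_sample = NULL, dm_mg = NULL,
                            nel_per_kg_milk = 3.2) {
  me <- metabolizable_energy(gas, cp, ee)
  nel <- net_energy_lactation(gas, cp, ee)
  n <- length(me)
  ucp <- rep(NA_real_, n)
  if (!is.null(dm_mg)) {
    ok <- !is.na(nh3_n_blank) & !is.na(n_sample) &
      !is.na(nh3_n_sample) & !is.na(dm_mg)
    if (any(ok))
      ucp[ok] <- utilizable_crude_protein(nh3_n_blank[ok], n_sample[ok],
                                          nh3_n_sample[ok], dm_mg[ok])
  }
  data.frame(
    me = me,
    nel = nel,
    milk_potential = milk_production_potential(nel, nel_per_kg_milk),
    cp = cp,
    ucp = ucp,
    om = organic_matter(ash),
    ndf = ndf
  )
}

#' Append derived quality columns to a per-cut table
#'
#' @param cuts A cut table with raw chemistry columns `gas`, `cp`, `ee`,
#'   `ndf`, `ash` and optionally `nh3_n_blank`, `n_sample_mg`,
#'   `nh3_n_sample`, `dm_mg`.
#' @param nel_per_kg_milk Milk conversion coefficient.
#' @return `cuts` with columns `me`, `nel`, `milk_potential`, `ucp`, `om`
#'   added (`cp` and `ndf` are already native columns).
#' @export
add_quality <- function(cuts, nel_per_kg_milk = 3.2) {
  req <- c("gas", "cp", "ee", "ndf", "ash")
  miss <- setdiff(req, names(cuts))
  if (length(miss))
    stop("cut table lacks chemistry columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_ucp <- all(c("nh3_n_blank", "n_sample_mg", "nh3_n_sample",
                   "dm_mg") %in% names(cuts))
  qp <- quality_profile(
    cuts$gas, cuts$cp, cuts$ee, cuts$ndf, cuts$ash,
    nh3_n_blank = if (has_ucp) cuts$nh3_n_blank,
    n_sample = if (has_ucp) cuts$n_sample_mg,
    nh3_n_sample = if (has_ucp) cuts$nh3_n_sample,
    dm_mg = if (has_ucp) cuts$dm_mg,
    nel_per_kg_milk = nel_per_kg_milk
  )
  cbind(cuts, qp[, c("me", "nel", "milk_potential", "ucp", "om")])
}
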