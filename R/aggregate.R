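#' Linearly interpolate per-cut quality between first and last cut
#'
#' Chemistry is analysed for the first and last harvest of the year;
#' interior cuts are filled in by linear interpolation over cut number,
#' which is justified by the monotone seasonal change of the quality
#' variables (energy and protein decline, fiber and ash rise).
#'
#' @param q_first,q_last Quality at the first and last cut (numeric, may be
#'   a named vector of several variables).
#' @param h Number of cuts (>= 1). For `h = 1` only `q_first` is used.
#' @return For scalar input a numeric vector of length `h`; for vector
#'   input an `h` x `length(q_first)` matrix, rows = cuts.
#' @examples
#' interpolate_quality(12, 9, 4) # 12 11 10 9
#' @export
interpolate_quality <- function(q_first, q_last = q_first, h) {
  if (length(h) != 1 || is.na(h) || h < 1 || h != round(h))
    stop("`h` must be a positive integer", call. = FALSE)
  w <- if (h == 1) 0 else (seq_len(h) - 1) / (h - 1)
  out <- outer(1 - w, q_first) + outer(w, q_last)
  if (length(q_first) == 1) drop(out) else out
}

#' Drop swards with missing or very small cut biomass
#'
#' A sward is removed when any of its cuts has missing biomass, when a cut
#' record is absent entirely, or when any cut's biomass falls below
#' `min_biomass`. The dropped report makes the (configurable) smallness
#' threshold auditable, including a per-richness histogram of removals.
#'
#' @param cuts A per-cut table with columns `sward_id`, `cut`, `biomass`
#'   and `cuts_per_year` (and optionally `richness` for the histogram).
#' @param min_biomass Smallest admissible per-cut biomass, g DM m-2.
#' @return A list with `kept` (cut table restricted to retained swards),
#'   `dropped` (data.frame of sward_id, reason, richness) and
#'   `richness_histogram` (table of dropped swards by richness).
#' @export
filter_swards <- function(cuts, min_biomass = 1) {
  if (min_biomass < 0)
    stop("`min_biomass` must be non-negative", call. = FALSE)
  sid <- factor(cuts$sward_id, levels = unique(cuts$sward_id))
  n_rows <- as.vector(table(sid))
  h <- cuts$cuts_per_year[!duplicated(sid)]
  any_na <- as.vector(tapply(is.na(cuts$biomass), sid, any))
  any_small <- as.vector(tapply(!is.na(cuts$biomass) &
                                  cuts$biomass < min_biomass, sid, any))
  incomplete <- n_rows < h

  drop <- any_na | any_small | incomplete
  reason <- ifelse(any_na | incomplete, "missing", "small_biomass")
  ids <- levels(sid)
  richness <- if ("richness" %in% names(cuts))
    cuts$richness[!duplicated(sid)] else rep(NA_integer_, length(ids))

  dropped <- data.frame(sward_id = ids[drop], reason = reason[drop],
                        richness = richness[drop])
  list(
    kept = cuts[!(cuts$sward_id %in% dropped$sward_id), , drop = FALSE],
    dropped = dropped,
    richness_histogram = table(factor(dropped$richness,
                                      levels = sort(unique(richness))))
  )
}

quality_vars <- function() {
  c("me", "nel", "milk_potential", "cp", "om", "ndf")
}

#' Aggregate per-cut records to annual sward records
#'
#' Computes, per sward: annual biomass yield (sum over cuts), annual
#' average forage quality (biomass-weighted mean over cuts) and annual
#' quality-adjusted yield (sum of cut biomass x cut quality) for every
#' quality variable. Interior cuts use quality linearly interpolated
#' between the first and last cut, mirroring the measurement protocol.
#' Biomass is in g DM m-2 and quality per kg DM, so quality-adjusted yield
#' carries a 1/1000 mass conversion and is reported per m2 per year.
#' Utilizable crude protein is measured at the first cut only: its annual
#' value is the first-cut value and its yield uses first-cut biomass alone.
#'
#' @param cuts A quality-augmented cut table (see [add_quality()]).
#' @param filter Result of [filter_swards()]; computed with default
#'   threshold if not supplied.
#' @return A data.frame, one row per retained sward, with design columns,
#'   `biomass_yield`, `quality_<v>`, `qa_<v>` for each quality variable,
#'   `ucp`, `qa_ucp`, `ucp_first_cut_only = TRUE` and `n_cuts_used`.
#' @examples
#' cuts <- data.frame(sward_id = "a", cut = 1:2, cuts_per_year = 2,
#'                    biomass = c(200, 300), me = c(10, 8))
#' aggregate_annual(cuts)[, c("biomass_yield", "quality_me", "qa_me")]
#' @export
aggregate_annual <- function(cuts, filter = filter_swards(cuts)) {
  cuts <- filter$kept
  if (nrow(cuts) == 0)
    return(data.frame())
  cuts <- cuts[order(match(cuts$sward_id, unique(cuts$sward_id)), cuts$cut), ]
  sid <- factor(cuts$sward_id, levels = unique(cuts$sward_id))
  first_rows <- which(!duplicated(sid))
  h <- cuts$cuts_per_year[first_rows]
  last_rows <- first_rows + h - 1L
  g <- as.integer(sid)

  biomass_yield <- as.vector(rowsum(cuts$biomass, g))
  if (any(biomass_yield <= 0))
    stop("sward with zero annual biomass reached aggregation; ",
         "it should have been filtered", call. = FALSE)

  # interpolation weight of the last cut for each row
  w <- ifelse(h[g] == 1, 0, (cuts$cut - 1) / pmax(h[g] - 1, 1))

  vars <- intersect(quality_vars(), names(cuts))
  out <- cuts[first_rows, intersect(
    c("sward_id", "plot_id", "block", "management", "cuts_per_year",
      "n_fertilization", "richness", "n_fg", "grass_present",
      "tall_herb_present", "legume_present", "legume_share"),
    names(cuts)), drop = FALSE]
  rownames(out) <- NULL
  out$biomass_yield <- biomass_yield
  for (v in vars) {
    q1 <- cuts[[v]][first_rows]
    qh <- cuts[[v]][last_rows]
    qc <- q1[g] * (1 - w) + qh[g] * w
    qa <- as.vector(rowsum(cuts$biomass * qc, g)) / 1000
    out[[paste0("quality_", v)]] <- qa * 1000 / biomass_yield
    out[[paste0("qa_", v)]] <- qa
  }
  if ("ucp" %in% names(cuts)) {
    out$ucp <- cuts$ucp[first_rows]
    out$qa_ucp <- cuts$biomass[first_rows] * cuts$ucp[first_rows] / 1000
    out$ucp_first_cut_only <- TRUE
  }
  out$n_cuts_used <- h
  out
}
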