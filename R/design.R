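#' Species pool of a replacement-series grassland experiment
#'
#' The pool mirrors the 60-species Central European *Arrhenatherum* meadow
#' flora used in large biodiversity experiments, split into four functional
#' groups.
#'
#' @param n_grasses,n_small_herbs,n_tall_herbs,n_legumes Number of species
#'   per functional group. Defaults 16/12/20/12 (total 60).
#' @return An object of class `species_pool`.
#' @examples
#' species_pool()
#' @export
species_pool <- function(n_grasses = 16L, n_small_herbs = 12L,
                         n_tall_herbs = 20L, n_legumes = 12L) {
  counts <- c(grass = n_grasses, small_herb = n_small_herbs,
              tall_herb = n_tall_herbs, legume = n_legumes)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("functional-group counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("species pool is empty", call. = FALSE)
  structure(list(counts = counts, total = sum(counts)), class = "species_pool")
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Species pool:", x$total, "species\n")
  print(x$counts)
  invisible(x)
}

#' Management intensity regimes
#'
#' The five regimes combine cutting frequency and nitrogen fertilization:
#' extensive (1 cut, 0 N), less intensive (2 cuts, 0 N), intensive
#' (2 cuts, 100 kg N ha-1 a-1), highly intensive (4 cuts, 100 N) and
#' very highly intensive (4 cuts, 200 N).
#'
#' @return A data.frame with columns `management` (factor, ordered from
#'   extensive to very highly intensive), `cuts_per_year` and
#'   `n_fertilization` (kg N ha-1 a-1).
#' @examples
#' management_regimes()
#' @export
management_regimes <- function() {
  lv <- c("extensive", "less_intensive", "intensive",
          "highly_intensive", "very_highly_intensive")
  data.frame(
    management = factor(lv, levels = lv),
    cuts_per_year = c(1L, 2L, 2L, 4L, 4L),
    n_fertilization = c(0, 0, 100, 100, 200)
  )
}

management_levels <- function() levels(management_regimes()$management)

# richness levels and replicate counts of the blocked design
design_replicates <- function() {
  c("1" = 16L, "2" = 16L, "4" = 16L, "8" = 16L, "16" = 14L, "60" = 4L)
}

#' Build the blocked species-richness plot design
#'
#' Constructs 82 main plots across 4 blocks with sown richness levels
#' 1, 2, 4, 8, 16 and 60 replicated 16/16/16/16/14/4 times. Species
#' composition is drawn by random selection from the functional-group pool
#' (mixtures are assembled with replacement across plots, i.e. the same
#' species may recur in many mixtures; within a plot the D sown species are
#' distinct). Only the functional-group summary of each mixture is retained:
#' number of functional groups, presence of grasses, tall herbs and legumes,
#' and the legume share.
#'
#' @param pool A [species_pool()].
#' @param seed Integer seed controlling composition draws and block
#'   allocation.
#' @return A data.frame (one row per plot) with columns `plot_id`, `block`,
#'   `richness`, `n_fg`, `grass_present`, `tall_herb_present`,
#'   `legume_present`, `legume_share`.
#' @examples
#' d <- build_design(seed = 1)
#' table(d$richness)
#' @export
build_design <- function(pool = species_pool(), seed = 1L) {
  if (!inherits(pool, "species_pool"))
    stop("`pool` must be a species_pool object", call. = FALSE)
  if (pool$total < max(as.integer(names(design_replicates()))))
    stop("species pool smaller than the largest richness level", call. = FALSE)
  reps <- design_replicates()
  richness <- rep(as.integer(names(reps)), reps)
  n_plots <- length(richness)

  # species are labelled by functional group membership
  group_of <- rep(names(pool$counts), pool$counts)

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  comp <- lapply(richness, function(D) {
    idx <- sample.int(pool$total, D, replace = FALSE)
    group_of[idx]
  })

  # plots of each richness level spread as evenly as possible over 4 blocks
  block <- integer(n_plots)
  for (D in unique(richness)) {
    ix <- which(richness == D)
    block[ix] <- sample(rep_len(1:4, length(ix)))
  }

  n_leg <- vapply(comp, function(g) sum(g == "legume"), integer(1))
  design <- data.frame(
    plot_id = sprintf("P%02d", seq_len(n_plots)),
    block = block,
    richness = richness,
    n_fg = vapply(comp, function(g) length(unique(g)), integer(1)),
    grass_present = vapply(comp, function(g) any(g == "grass"), logical(1)),
    tall_herb_present = vapply(comp, function(g) any(g == "tall_herb"), logical(1)),
    legume_present = n_leg > 0,
    legume_share = n_leg / richness
  )
  design <- design[order(design$block, design$plot_id), ]
  rownames(design) <- NULL
  design
}

#' Cross plots with management regimes into swards
#'
#' Each main plot carries one sward per management regime (the core area
#' plus management subplots), giving plots x 5 swards.
#'
#' @param plots A design data.frame from [build_design()].
#' @return A data.frame, one row per sward, with `sward_id`, all plot
#'   columns, `management`, `cuts_per_year` and `n_fertilization`.
#' @examples
#' s <- build_swards(build_design(seed = 1))
#' nrow(s) # 410
#' @export
build_swards <- function(plots) {
  req <- c("plot_id", "block", "richness")
  if (!all(req %in% names(plots)))
    stop("`plots` must come from build_design()", call. = FALSE)
  regimes <- management_regimes()
  out <- merge(plots, regimes, by = NULL)
  out$management <- factor(out$management, levels = management_levels())
  out$sward_id <- paste(out$plot_id, out$management, sep = ".")
  out <- out[order(out$plot_id, out$management), ]
  rownames(out) <- NULL
  out[, c("sward_id", setdiff(names(out), "sward_id"))]
}

# save/restore the global RNG state so generator functions are
# self-contained in their seed usage
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
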