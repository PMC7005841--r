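#' Rank candidate diversity functional forms by information criteria
#'
#' Fits the diversity-effect model with each candidate transform of sown
#' richness (square root, linear, linear plus squared, logarithmic and
#' inverse) on the identical observation set, using maximum likelihood for
#' comparability, and reports AIC and BIC rankings. Individual fit failures
#' are recorded without aborting the race.
#'
#' @param data Annual sward table.
#' @param response Response column name.
#' @param forms Candidate forms, default all five.
#' @param legume_term Legume specification passed to
#'   [fit_diversity_model()].
#' @return Data frame with `form`, `n_obs`, `loglik`, `aic`, `bic`,
#'   `rank_aic`, `rank_bic` and `error` (NA when the fit succeeded).
#' @export
select_diversity_form <- function(data, response,
                                  forms = diversity_forms(),
                                  legume_term = "presence") {
  res <- lapply(forms, function(f) {
    fit <- tryCatch(
      fit_diversity_model(data, response, diversity_form = f,
                          legume_term = legume_term, criteria = TRUE),
      error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(form = f, n_obs = NA_integer_, loglik = NA_real_,
                 aic = NA_real_, bic = NA_real_,
                 error = conditionMessage(fit))
    else
      data.frame(form = f, n_obs = fit$n_obs, loglik = fit$loglik_ml,
                 aic = fit$aic, bic = fit$bic, error = NA_character_)
  })
  out <- do.call(rbind, res)
  ok <- stats::complete.cases(out[, c("aic", "bic")])
  if (length(unique(out$n_obs[ok])) > 1)
    stop("candidate forms were fitted on different observation sets",
         call. = FALSE)
  out$rank_aic <- rank(out$aic, na.last = "keep")
  out$rank_bic <- rank(out$bic, na.last = "keep")
  out
}

#' Per-management diversity-effect inference with Bonferroni and Wald tests
#'
#' Tests each management's diversity slope against zero with cluster-robust
#' standard errors, marking significance at the 5%, 1% and 0.1% levels
#' after Bonferroni division by `n_tests` (the number of response variables
#' in the family: six for forage-quality responses, one for biomass yield).
#' All ten pairwise equalities of slopes between managements are tested
#' with Wald statistics built from the robust covariance.
#'
#' @param fit A [fit_diversity_model()] fit.
#' @param n_tests Size of the Bonferroni family (>= 1).
#' @param levels Nominal significance levels.
#' @return An object of class `effect_table`: list with `slopes` (estimate,
#'   robust SE, t, p, significance symbol), `pairwise` (difference, SE,
#'   Wald statistic, p for each management pair), `n_tests` and
#'   `thresholds`.
#' @export
effect_inference <- function(fit, n_tests = 1,
                             levels = c(0.05, 0.01, 0.001)) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("`n_tests` must be >= 1", call. = FALSE)
  thresholds <- levels / n_tests
  p_coef <- length(fit$coefficients)
  contrast_df <- function(cvec) satterthwaite_df(fit, cvec)

  sl <- diversity_slopes(fit, "robust")
  nm_all <- names(fit$coefficients)
  slope_ix <- grep(":d_term$", nm_all)
  slope_lv <- sub("^management", "", sub(":d_term$", "", nm_all[slope_ix]))
  slope_ix <- slope_ix[match(management_levels(), slope_lv)]
  sl$t <- sl$estimate / sl$se
  sl$df <- vapply(slope_ix, function(i) {
    cvec <- numeric(p_coef); cvec[i] <- 1
    contrast_df(cvec)
  }, numeric(1))
  sl$p <- 2 * stats::pt(-abs(sl$t), df = sl$df)
  sl$signif <- vapply(sl$p, function(p) {
    if (p < thresholds[3]) "***"
    else if (p < thresholds[2]) "**"
    else if (p < thresholds[1]) "*"
    else ""
  }, character(1))

  nm <- names(fit$coefficients)
  ix <- grep(":d_term$", nm)
  lv <- sub("^management", "", sub(":d_term$", "", nm[ix]))
  ord <- match(management_levels(), lv)
  ix <- ix[ord]; lv <- lv[ord]
  V <- fit$vcov_robust
  pairs <- utils::combn(seq_along(ix), 2)
  pw <- data.frame(
    management_1 = lv[pairs[1, ]],
    management_2 = lv[pairs[2, ]]
  )
  pw$difference <- fit$coefficients[ix[pairs[1, ]]] -
    fit$coefficients[ix[pairs[2, ]]]
  pw$se <- sqrt(V[cbind(ix[pairs[1, ]], ix[pairs[1, ]])] +
                  V[cbind(ix[pairs[2, ]], ix[pairs[2, ]])] -
                  2 * V[cbind(ix[pairs[1, ]], ix[pairs[2, ]])])
  pw$wald <- (pw$difference / pw$se)^2
  pw$df <- vapply(seq_len(ncol(pairs)), function(j) {
    cvec <- numeric(p_coef)
    cvec[ix[pairs[1, j]]] <- 1
    cvec[ix[pairs[2, j]]] <- -1
    contrast_df(cvec)
  }, numeric(1))
  pw$p <- 2 * stats::pt(-abs(pw$difference / pw$se), df = pw$df)
  rownames(pw) <- NULL

  structure(list(slopes = sl, pairwise = pw, n_tests = n_tests,
                 thresholds = thresholds, df = fit$df_robust,
                 response = fit$response),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, digits = 4, ...) {
  cat("Diversity effects per management intensity (response:", x$response,
      ")\n")
  cat("Bonferroni family size:", x$n_tests, " adjusted levels:",
      paste(signif(x$thresholds, 3), collapse = "/"), "\n\n")
  print(cbind(x$slopes["management"],
              round(x$slopes[c("estimate", "se", "t", "df", "p")], digits),
              signif. = x$slopes$signif), row.names = FALSE)
  cat("\nPairwise Wald tests of slope equality:\n")
  print(cbind(x$pairwise[c("management_1", "management_2")],
              round(x$pairwise[c("difference", "se", "wald", "df", "p")],
                    digits)), row.names = FALSE)
  invisible(x)
}

#' Robustness of diversity slopes to the legume specification
#'
#' Refits the model with the square root of the sown legume share in place
#' of legume presence (both interacted with management) and reports the
#' per-management diversity slopes side by side. When no plot contains
#' legumes both specifications collapse to the same design matrix.
#'
#' @param data Annual sward table.
#' @param response Response column name.
#' @param diversity_form Diversity transform, default `"sqrt"`.
#' @return List with `comparison` (slopes and robust SEs of both variants)
#'   and the two fits (`fit_presence`, `fit_share`).
#' @export
legume_robustness <- function(data, response, diversity_form = "sqrt") {
  f1 <- fit_diversity_model(data, response, diversity_form,
                            legume_term = "presence")
  f2 <- fit_diversity_model(data, response, diversity_form,
                            legume_term = "sqrt_share")
  s1 <- diversity_slopes(f1)
  s2 <- diversity_slopes(f2)
  comparison <- data.frame(
    management = s1$management,
    slope_presence = s1$estimate, se_presence = s1$se,
    slope_sqrt_share = s2$estimate, se_sqrt_share = s2$se
  )
  list(comparison = comparison, fit_presence = f1, fit_share = f2)
}
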