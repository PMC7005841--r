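# build the transformed covariate columns predict needs from user-facing ones
prepare_newdata <- function(fit, newdata) {
  nd <- as.data.frame(newdata)
  if (!all(c("richness", "management") %in% names(nd)))
    stop("newdata needs `richness` and `management` columns", call. = FALSE)
  nd$management <- factor(as.character(nd$management),
                          levels = management_levels())
  if (anyNA(nd$management))
    stop("unknown management level in newdata", call. = FALSE)
  nd <- cbind(nd, diversity_terms(nd$richness, fit$diversity_form))
  if (!".legume" %in% names(nd)) {
    nd$.legume <- if (fit$legume_term == "presence")
      as.numeric(nd$legume_present) else sqrt(nd$legume_share)
  }
  if (!".grass" %in% names(nd)) nd$.grass <- as.numeric(nd$grass_present)
  if (!".tall_herb" %in% names(nd))
    nd$.tall_herb <- as.numeric(nd$tall_herb_present)
  nd
}

#' Predict annual responses from a fitted diversity model
#'
#' Fixed-effects predictions (random effects at zero). `newdata` must carry
#' `richness`, `management` and the covariates `legume_present` (or
#' `legume_share` for the share variant), `n_fg`, `grass_present` and
#' `tall_herb_present`.
#'
#' @param object A [fit_diversity_model()] fit.
#' @param newdata Data frame of prediction points; fitted values if `NULL`.
#' @param se.fit Also return robust standard errors of the predictions.
#' @param ... Unused.
#' @return Numeric vector of predictions, or a list with `fit` and `se.fit`.
#' @export
predict.diversity_fit <- function(object, newdata = NULL, se.fit = FALSE,
                                  ...) {
  nd <- if (is.null(newdata)) object$data else prepare_newdata(object, newdata)
  if (!is.null(newdata) && any(nd$richness < 1 | nd$richness > 60))
    warning("richness outside the experimental range [1, 60]: extrapolating",
            call. = FALSE)
  X <- stats::model.matrix(object$terms, nd,
                           xlev = list(management = management_levels()))
  X <- X[, names(object$coefficients), drop = FALSE]
  pred <- as.vector(X %*% object$coefficients)
  if (!se.fit) return(pred)
  se <- sqrt(rowSums((X %*% object$vcov_robust) * X))
  list(fit = pred, se.fit = se)
}

#' Predictions over a diversity gradient with a covariate policy
#'
#' The non-diversity covariates (legume term, functional groups, grass and
#' tall-herb presence) co-vary with sown richness by design, so predicted
#' diversity gradients depend on where those covariates are held. Policies:
#' `"mean"` fixes them at their grand means over the fitted data (smooth
#' curves, any D); `"design"` averages them within each observed richness
#' level (D restricted to design levels); `"fixed"` uses user-supplied
#' values.
#'
#' @param fit A [fit_diversity_model()] fit.
#' @param D Diversity grid (sown species richness values).
#' @param policy Covariate policy, see Details.
#' @param covariates For `policy = "fixed"`: named list with `legume`,
#'   `n_fg`, `grass`, `tall_herb` (on the transformed scale used by the
#'   model: legume presence 0/1 or sqrt share).
#' @param managements Management levels to predict for (default all five).
#' @return Data frame with `richness`, `management`, `predicted` and, when
#'   averaging is meaningful, the covariate values used.
#' @export
predict_diversity_grid <- function(fit, D = c(1, 2, 4, 8, 16, 60),
                                   policy = c("mean", "design", "fixed"),
                                   covariates = NULL,
                                   managements = management_levels()) {
  policy <- match.arg(policy)
  dat <- fit$data
  cov_at <- function(Di) {
    if (policy == "mean")
      colMeans(dat[, c(".legume", "n_fg", ".grass", ".tall_herb")])
    else if (policy == "design") {
      rows <- dat$richness == Di
      if (!any(rows))
        stop("richness ", Di, " not observed; use policy = \"mean\"",
             call. = FALSE)
      colMeans(dat[rows, c(".legume", "n_fg", ".grass", ".tall_herb")])
    } else {
      if (is.null(covariates))
        stop("policy = \"fixed\" needs `covariates`", call. = FALSE)
      c(.legume = covariates$legume, n_fg = covariates$n_fg,
        .grass = covariates$grass, .tall_herb = covariates$tall_herb)
    }
  }
  grid <- expand.grid(richness = D, management = managements,
                      stringsAsFactors = FALSE)
  cv <- t(vapply(grid$richness, cov_at, numeric(4)))
  nd <- data.frame(richness = grid$richness,
                   management = grid$management,
                   .legume = cv[, 1], n_fg = cv[, 2],
                   .grass = cv[, 3], .tall_herb = cv[, 4])
  nd$predicted <- predict(fit, nd)
  nd$management <- factor(nd$management, levels = management_levels())
  rownames(nd) <- NULL
  nd
}

#' @export
plot.diversity_fit <- function(x, D = sort(unique(x$data$richness)),
                               policy = "mean", ...) {
  g <- predict_diversity_grid(x, D = D, policy = policy)
  lv <- management_levels()
  cols <- grDevices::hcl.colors(length(lv), "Zissou 1")
  graphics::plot(range(g$richness), range(g$predicted), type = "n",
                 xlab = "sown species richness",
                 ylab = paste("predicted", x$response), ...)
  for (i in seq_along(lv)) {
    gi <- g[g$management == lv[i], ]
    gi <- gi[order(gi$richness), ]
    graphics::lines(gi$richness, gi$predicted, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = lv, col = cols, lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(g)
}
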