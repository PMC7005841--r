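diversity_forms <- function() {
  c("sqrt", "linear", "linear_squared", "log", "inverse")
}

# transformed diversity regressors for each candidate functional form
diversity_terms <- function(D, form) {
  switch(form,
    sqrt = data.frame(d_term = sqrt(D)),
    linear = data.frame(d_term = D),
    linear_squared = data.frame(d_term = D, d_term2 = D^2),
    log = data.frame(d_term = log(D)),
    inverse = data.frame(d_term = 1 / D),
    stop("unknown diversity form: ", form, call. = FALSE)
  )
}

#' Fit the per-management diversity-effect mixed model
#'
#' Fits a linear mixed model for an annual sward response with a separate
#' diversity slope per management intensity (cell-means interaction
#' coding), management dummies, a legume x management interaction, number
#' of functional groups, grass and tall-herb presence as fixed effects, and
#' random intercepts for block and plot (plots nested in blocks):
#'
#' \deqn{y = \alpha_M + \beta_{D\times M} f(D) + \beta_{L\times M} L +
#'   \beta_{FG} FG + \beta_G G + \beta_H H + u_B + u_P + e}
#'
#' `f(D)` is the chosen diversity transform; the default square root allows
#' a diminishing diversity effect. Estimation is by REML through
#' [lme4::lmer()]; a maximum-likelihood refit supplies the log-likelihood,
#' AIC and BIC used for functional-form comparison. Alongside the
#' model-based covariance, a cluster-robust sandwich covariance of the
#' fixed effects is computed with plots as clusters, guarding against
#' heteroscedasticity and within-plot correlation misspecification.
#'
#' Degenerate noise-free data (an exact linear fit) are detected and
#' handled by an ordinary least-squares path with all variance components
#' set to zero, so simulated fixed points are recovered exactly.
#'
#' @param data Annual sward table (see [aggregate_annual()]) with columns
#'   `management`, `richness`, `legume_present`, `legume_share`, `n_fg`,
#'   `grass_present`, `tall_herb_present`, `block`, `plot_id` and the
#'   response.
#' @param response Name of the response column (e.g. `"biomass_yield"`,
#'   `"qa_me"`, `"revenue"`).
#' @param diversity_form One of `"sqrt"`, `"linear"`, `"linear_squared"`,
#'   `"log"`, `"inverse"`.
#' @param legume_term `"presence"` (0/1 legume presence, the default) or
#'   `"sqrt_share"` (square root of the sown legume share) interacted with
#'   management.
#' @param criteria Compute the ML refit for AIC/BIC (default `TRUE`; skip
#'   in large simulation loops).
#' @return An object of class `diversity_fit` with methods [print()],
#'   [summary()], [coef()], [vcov()], [predict()], [residuals()],
#'   [simulate()], [logLik()] and [plot()].
#' @examples
#' \donttest{
#' exp <- simulate_experiment(simulation_params(seed = 42))
#' ann <- aggregate_annual(add_quality(exp$cuts))
#' fit <- fit_diversity_model(ann, "biomass_yield")
#' summary(fit)
#' }
#' @export
fit_diversity_model <- function(data, response,
                                diversity_form = "sqrt",
                                legume_term = c("presence", "sqrt_share"),
                                criteria = TRUE) {
  diversity_form <- match.arg(diversity_form, diversity_forms())
  legume_term <- match.arg(legume_term)
  req <- c("management", "richness", "legume_present", "n_fg",
           "grass_present", "tall_herb_present", "block", "plot_id", response)
  if (legume_term == "sqrt_share") req <- c(req, "legume_share")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("annual table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(data[, req]))
    stop("missing values in response or covariates; filter the data first",
         call. = FALSE)

  d <- data
  d$management <- factor(as.character(d$management),
                         levels = management_levels())
  absent <- setdiff(management_levels(), unique(as.character(d$management)))
  if (length(absent))
    stop("singular design: management level(s) absent: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (length(unique(d$block)) < 2 || any(table(d$block) < 2))
    stop("need at least 2 plots per block in at least 2 blocks",
         call. = FALSE)

  dt <- diversity_terms(d$richness, diversity_form)
  d <- cbind(d, dt)
  d$.legume <- if (legume_term == "presence") as.numeric(d$legume_present)
               else sqrt(d$legume_share)
  d$.y <- d[[response]]
  d$.grass <- as.numeric(d$grass_present)
  d$.tall_herb <- as.numeric(d$tall_herb_present)

  d_terms <- paste(sprintf("management:%s", names(dt)), collapse = " + ")
  fe_rhs <- paste("0 + management +", d_terms,
                  "+ management:.legume + n_fg + .grass + .tall_herb")
  fe_formula <- stats::as.formula(paste(".y ~", fe_rhs))
  me_formula <- stats::as.formula(
    paste(".y ~", fe_rhs, "+ (1 | block) + (1 | plot_id)"))

  # degenerate (noise-free) data: exact linear fit, OLS path
  ols <- stats::lm(fe_formula, data = d)
  X <- stats::model.matrix(ols)
  degenerate <- sum(stats::residuals(ols)^2) <=
    1e-16 * max(sum(d$.y^2), .Machine$double.eps)

  if (degenerate) {
    beta <- stats::coef(ols)
    vc <- c(block = 0, plot = 0, residual = 0)
    vcov_model <- matrix(0, length(beta), length(beta),
                         dimnames = list(names(beta), names(beta)))
    vcov_robust <- vcov_model
    engine <- ols
    df_info <- NULL
    ll <- aic <- bic <- NA_real_
  } else {
    engine <- tryCatch(
      lme4::lmer(me_formula, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE)),
      error = function(e)
        stop("mixed-model fit failed: ", conditionMessage(e), call. = FALSE))
    beta <- lme4::fixef(engine)
    vcmat <- lme4::VarCorr(engine)
    vc <- c(block = as.numeric(vcmat$block),
            plot = as.numeric(vcmat$plot_id),
            residual = stats::sigma(engine)^2)
    vcov_model <- as.matrix(stats::vcov(engine))
    dimnames(vcov_model) <- list(names(beta), names(beta))
    X <- lme4::getME(engine, "X")
    r <- d$.y - as.vector(X %*% beta)
    vcov_robust <- cluster_robust_vcov(X, r, d$plot_id,
                                       s2e = vc[["residual"]],
                                       s2u = vc[["block"]] + vc[["plot"]])
    df_info <- attr(vcov_robust, "df_info")
    attr(vcov_robust, "df_info") <- NULL
    dimnames(vcov_robust) <- dimnames(vcov_model)
    if (criteria) {
      ml <- lme4::refitML(engine)
      ll <- as.numeric(stats::logLik(ml))
      aic <- stats::AIC(ml)
      bic <- stats::BIC(ml)
    } else ll <- aic <- bic <- NA_real_
  }

  structure(list(
    coefficients = beta,
    varcomp = vc,
    vcov_model = vcov_model,
    vcov_robust = vcov_robust,
    n_clusters = length(unique(d$plot_id)),
    df_robust = length(unique(d$plot_id)) - 1L,
    robust_df_info = df_info,
    loglik_ml = ll, aic = aic, bic = bic,
    n_obs = nrow(d),
    response = response,
    diversity_form = diversity_form,
    legume_term = legume_term,
    degenerate = degenerate,
    engine = engine,
    terms = stats::delete.response(stats::terms(ols)),
    data = d,
    call = match.call()
  ), class = "diversity_fit")
}

# CR2 (bias-reduced linearization) cluster-robust sandwich for the LMM
# fixed effects. Working within-cluster covariance V_g = s2e I + s2u J
# (its inverse is (1/s2e) I - k J with k = s2u / (s2e (s2e + n s2u))).
# Each cluster's residual vector is premultiplied by the adjustment A_g
# solving A_g (V_g - X_g M X_g') A_g = V_g, which undoes the downward
# leverage bias of the plain sandwich in designs with few high-leverage
# clusters (here: the species-rich plots).
cluster_robust_vcov <- function(X, r, cluster, s2e, s2u) {
  cl <- split(seq_along(r), cluster)
  p <- ncol(X)
  bread <- matrix(0, p, p)
  Winv <- list()
  for (g in seq_along(cl)) {
    ix <- cl[[g]]
    Xg <- X[ix, , drop = FALSE]
    ng <- length(ix)
    k <- s2u / (s2e * (s2e + ng * s2u))
    sX <- colSums(Xg)
    bread <- bread + crossprod(Xg) / s2e - k * tcrossprod(sX)
    Winv[[g]] <- k  # store the Sherman-Morrison factor
  }
  M <- solve(bread)

  msqrt <- function(S, inv = FALSE) {
    es <- eigen(S, symmetric = TRUE)
    lam <- pmax(es$values, 1e-12 * max(es$values))
    pw <- if (inv) -0.5 else 0.5
    es$vectors %*% (lam^pw * t(es$vectors))
  }

  meat <- matrix(0, p, p)
  Q <- vector("list", length(cl))   # Q_g = (A_g W_g X_g), for Satterthwaite df
  Xl <- vector("list", length(cl))
  Vl <- vector("list", length(cl))
  for (g in seq_along(cl)) {
    ix <- cl[[g]]
    Xg <- X[ix, , drop = FALSE]
    rg <- r[ix]
    ng <- length(ix)
    Vg <- s2e * diag(ng) + s2u
    Vg_irt <- msqrt(Vg, inv = TRUE)            # V_g^{-1/2}
    Sg <- Vg - Xg %*% M %*% t(Xg)              # approx Var(r_g)
    B <- Vg_irt %*% Sg %*% Vg_irt
    Ag <- msqrt(Vg) %*% msqrt(B, inv = TRUE) %*% Vg_irt
    WgXg <- Xg / s2e - Winv[[g]] * matrix(colSums(Xg), ng, p, byrow = TRUE)
    u <- crossprod(WgXg, Ag %*% rg)
    meat <- meat + tcrossprod(u)
    Q[[g]] <- t(Ag) %*% WgXg
    Xl[[g]] <- Xg
    Vl[[g]] <- Vg
  }
  structure(M %*% meat %*% M,
            df_info = list(M = M, Q = Q, X = Xl, V = Vl))
}

# Bell-McCaffrey Satterthwaite degrees of freedom for the robust variance
# of the linear contrast c'beta: df = (tr Omega)^2 / tr(Omega^2) with
# Omega_{gh} = Cov(z_g' r_g, z_h' r_h) under the working model, where the
# CR2 variance estimator is sum_g (z_g' r_g)^2, z_g = Q_g M c.
satterthwaite_df <- function(fit, contrast) {
  info <- fit$robust_df_info
  if (is.null(info)) return(fit$df_robust)
  q <- info$M %*% contrast
  G <- length(info$Q)
  z <- lapply(info$Q, function(Qg) Qg %*% q)
  w <- mapply(function(Xg, zg) crossprod(Xg, zg), info$X, z)  # p x G
  dia <- mapply(function(Vg, zg) as.numeric(crossprod(zg, Vg %*% zg)),
                info$V, z)
  Omega <- diag(dia) - t(w) %*% info$M %*% w
  tr1 <- sum(diag(Omega))
  tr2 <- sum(Omega^2)
  if (tr2 <= 0) return(fit$df_robust)
  (tr1^2) / tr2
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat("Diversity-effect mixed model\n")
  cat("  response:", x$response, "  diversity form:", x$diversity_form,
      "  legume term:", x$legume_term, "\n")
  cat("  n =", x$n_obs, "swards,", x$n_clusters, "plots\n")
  cat("  variance components (block/plot/residual):",
      paste(signif(x$varcomp, 4), collapse = " / "), "\n")
  cat("Diversity slopes per management:\n")
  print(signif(diversity_slopes(x)$estimate, 5))
  invisible(x)
}

# per-management diversity slope estimates with robust and model SEs
diversity_slopes <- function(fit, vcov_type = "robust") {
  stopifnot(inherits(fit, "diversity_fit"))
  nm <- names(fit$coefficients)
  ix <- grep(":d_term$", nm)
  lv <- sub("^management", "", sub(":d_term$", "", nm[ix]))
  V <- if (vcov_type == "robust") fit$vcov_robust else fit$vcov_model
  data.frame(
    management = factor(lv, levels = management_levels()),
    estimate = unname(fit$coefficients[ix]),
    se = sqrt(diag(V)[ix]),
    row.names = NULL
  )[order(match(lv, management_levels())), ]
}

#' @export
coef.diversity_fit <- function(object, ...) object$coefficients

#' @export
vcov.diversity_fit <- function(object, type = c("robust", "model"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$vcov_robust else object$vcov_model
}

#' @export
logLik.diversity_fit <- function(object, ...) {
  structure(object$loglik_ml,
            df = length(object$coefficients) + 3,  # + 2 varcomps + residual
            nobs = object$n_obs, class = "logLik")
}

#' @export
residuals.diversity_fit <- function(object, type = c("marginal", "conditional"),
                                    ...) {
  type <- match.arg(type)
  X <- if (object$degenerate) stats::model.matrix(object$engine)
       else lme4::getME(object$engine, "X")
  marg <- object$data$.y - as.vector(X %*% object$coefficients)
  if (type == "marginal" || object$degenerate) marg
  else stats::residuals(object$engine)
}

#' @export
simulate.diversity_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$degenerate) {
    X <- stats::model.matrix(object$engine)
    mu <- as.vector(X %*% object$coefficients)
    return(as.data.frame(replicate(nsim, mu)))
  }
  stats::simulate(object$engine, nsim = nsim, seed = seed, ...)
}

#' @export
summary.diversity_fit <- function(object, ...) {
  se_m <- sqrt(diag(object$vcov_model))
  se_r <- sqrt(diag(object$vcov_robust))
  t_r <- object$coefficients / ifelse(se_r > 0, se_r, NA)
  tab <- data.frame(
    estimate = object$coefficients,
    se_model = se_m,
    se_robust = se_r,
    t_robust = t_r,
    p_robust = 2 * stats::pt(-abs(t_r), df = object$df_robust)
  )
  structure(list(fit = object, coefficients = tab), class = "summary.diversity_fit")
}

#' @export
print.summary.diversity_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nFixed effects (robust SEs clustered on plot, t with",
      x$fit$df_robust, "df):\n")
  print(round(x$coefficients, digits))
  if (!is.na(x$fit$aic))
    cat("\nML logLik:", round(x$fit$loglik_ml, 2),
        " AIC:", round(x$fit$aic, 2), " BIC:", round(x$fit$bic, 2), "\n")
  invisible(x)
}
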