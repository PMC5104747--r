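# Random-intercept mixed models for per-observation feature tables:
# model construction, likelihood-ratio tests, Tukey-family contrasts and
# marginal/conditional pseudo-R-squared. Fitting is delegated to lme4;
# this module owns model specification and reporting.

#' Fit a random-intercept mixed model to a feature table
#'
#' Builds and fits
#' `response ~ <fixed> + (1 | group_id) + (1 | participant_id)`
#' for a three-level design (observations within participants within
#' groups; participant labels must be unique within the dataset, i.e.
#' nested coding). `sound_model` enters with treatment contrasts (S1
#' reference), `session` as a two-level factor, `observation_number` as a
#' numeric covariate.
#'
#' @param table Feature table, e.g. from [gen_cohort()] or
#'   [features_from_segments()].
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect terms, a subset of
#'   `c("sound_model", "session", "observation_number")` (or empty for an
#'   intercept-only null model).
#' @param method `"REML"` (default, for reported coefficients) or `"ML"`
#'   (required for likelihood-ratio tests of fixed effects).
#' @return An object of class `mixed_fit`: list with `fit` (the lmerMod),
#'   `beta` (fixed-effect estimates and standard errors), `sd_group`,
#'   `sd_participant`, `sd_residual`, `loglik`, `df` (number of model
#'   parameters), `n_obs`, `method`, `converged`, `singular`,
#'   `messages`.
#' @export
fit_feature_lmm <- function(table, response = "value",
                            fixed = c("sound_model", "session",
                                      "observation_number"),
                            method = c("REML", "ML")) {
  method <- match.arg(method)
  if (!response %in% names(table))
    stop("response '", response, "' not found in table")
  if (!all(c("group_id", "participant_id") %in% names(table)))
    stop("table must carry group_id and participant_id columns")
  y <- table[[response]]
  if (!is.numeric(y) || sd(y) == 0)
    stop("response must be numeric and non-constant")
  if (length(unique(table$participant_id)) < 2)
    stop("need at least 2 participants")
  dat <- table
  dat$.response <- y
  if ("sound_model" %in% names(dat))
    dat$sound_model <- factor(dat$sound_model,
                              levels = intersect(c("S1", "S2", "S3"),
                                                 unique(as.character(dat$sound_model))))
  if ("session" %in% names(dat)) dat$session <- factor(dat$session)
  msgs0 <- character(0)
  rand <- character(0)
  for (g in c("group_id", "participant_id")) {
    if (length(unique(dat[[g]])) >= 2) {
      rand <- c(rand, sprintf("(1 | %s)", g))
    } else {
      msgs0 <- c(msgs0, paste0(g, " has a single level; its variance ",
                               "component is fixed at the boundary 0"))
    }
  }
  if (length(rand) == 0) stop("no random-intercept term is identifiable")
  rhs <- paste(c(if (length(fixed) > 0) fixed else "1", rand),
               collapse = " + ")
  form <- stats::as.formula(paste(".response ~", rhs))
  msgs <- msgs0
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = (method == "REML")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(grp) {
    i <- which(vc$grp == grp)
    if (length(i) == 0) 0 else vc$sdcor[i]
  }
  co <- summary(fit)$coefficients
  singular <- lme4::isSingular(fit)
  if (singular)
    msgs <- c(msgs, "singular fit: a variance component is estimated at 0")
  ll <- stats::logLik(fit)
  structure(list(
    fit = fit,
    beta = data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], row.names = NULL),
    sd_group = sd_of("group_id"),
    sd_participant = sd_of("participant_id"),
    sd_residual = stats::sigma(fit),
    loglik = as.numeric(ll),
    df = attr(ll, "df"),
    n_obs = nrow(dat),
    method = method,
    formula = form,
    converged = length(fit@optinfo$conv$lme4) == 0,
    singular = singular,
    messages = msgs
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s fit, %d observations, logLik %.3f\n",
              x$method, x$n_obs, x$loglik))
  cat(sprintf("  random-intercept SDs: group %.4f, participant %.4f, residual %.4f\n",
              x$sd_group, x$sd_participant, x$sd_residual))
  print(x$beta, digits = 4)
  if (x$singular) cat("  note: singular fit (variance component at 0)\n")
  invisible(x)
}

#' Likelihood-ratio test of nested mixed models
#'
#' `chi2 = 2 * (loglik_full - loglik_null)`, degrees of freedom equal to
#' the parameter-count difference, p-value from the chi-square upper
#' tail. Both fits must use maximum likelihood: REML likelihoods of
#' models with different fixed effects are not comparable.
#'
#' @param full,null `mixed_fit` objects, `null` nested in `full`.
#' @return A list with `chi2`, `df`, `p`.
#' @export
lr_test <- function(full, null) {
  stopifnot(inherits(full, "mixed_fit"), inherits(null, "mixed_fit"))
  if (full$method != "ML" || null$method != "ML")
    stop("likelihood-ratio tests require ML fits (method = 'ML')")
  df <- full$df - null$df
  if (df < 0) stop("models are not nested: null has more parameters")
  chi2 <- 2 * (full$loglik - null$loglik)
  if (chi2 < -1e-6)
    stop("models do not appear nested: full log-likelihood below null")
  chi2 <- max(chi2, 0)
  p <- if (df == 0) 1 else pchisq(chi2, df = df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Marginal and conditional pseudo-R-squared of a mixed fit
#'
#' Variance-partition formulation for Gaussian random-intercept models:
#' with `var_f = var(X %*% beta)` the variance of the fixed-effect
#' predictor and `var_g`, `var_p`, `var_e` the group, participant and
#' residual variance components,
#' `marginal = var_f / (var_f + var_g + var_p + var_e)` and
#' `conditional = (var_f + var_g + var_p) / (var_f + var_g + var_p +
#' var_e)`. Both lie in `[0, 1]` and conditional >= marginal.
#'
#' @param fit A `mixed_fit`.
#' @return A list with `marginal` and `conditional`.
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  X <- lme4::getME(fit$fit, "X")
  beta <- lme4::fixef(fit$fit)
  var_f <- var(as.vector(X %*% beta))
  var_g <- fit$sd_group^2
  var_p <- fit$sd_participant^2
  var_e <- fit$sd_residual^2
  total <- var_f + var_g + var_p + var_e
  if (total <= 0) stop("degenerate variance total")
  list(marginal = var_f / total,
       conditional = (var_f + var_g + var_p) / total)
}

#' Tukey-family pairwise contrasts of a fixed factor
#'
#' All pairwise differences of the factor-level estimates with
#' single-step (studentized-range family) multiplicity adjustment, via
#' `multcomp::glht`.
#'
#' @param fit A `mixed_fit` whose fixed effects include `factor`.
#' @param factor Name of the fixed factor (default `"sound_model"`).
#' @return A data frame with columns `pair`, `estimate`, `se`,
#'   `p_adjusted`.
#' @export
pairwise_contrasts <- function(fit, factor = "sound_model") {
  stopifnot(inherits(fit, "mixed_fit"))
  if (!any(grepl(paste0("^", factor), fit$beta$term)))
    stop("factor '", factor, "' is not among the fixed effects")
  linfct <- do.call(multcomp::mcp, setNames(list("Tukey"), factor))
  gl <- multcomp::glht(fit$fit, linfct = linfct)
  sm <- summary(gl)
  data.frame(pair = names(sm$test$coefficients),
             estimate = as.numeric(sm$test$coefficients),
             se = as.numeric(sm$test$sigma),
             p_adjusted = as.numeric(sm$test$pvalues),
             row.names = NULL)
}
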