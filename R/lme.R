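# Linear mixed-effects stage: REML random-intercept models of injury change
# on strain / strain rate (via lme4 behind this module surface), Nakagawa
# marginal R-squared, leave-one-animal-out predictive R-squared (PRESS),
# backward stepwise selection, and residual diagnostics.

.fixed_terms <- c("strain", "strain_rate", "severity", "interaction")

.build_formula <- function(fixed, random) {
  fixed <- unique(fixed)
  bad <- setdiff(fixed, .fixed_terms)
  if (length(bad) > 0) stop("unknown fixed term(s): ", paste(bad, collapse = ", "))
  slope <- intersect(c("strain", "strain_rate"), fixed)
  rhs <- setdiff(fixed, "interaction")
  if ("interaction" %in% fixed) {
    if (length(slope) == 0 || !"severity" %in% fixed) {
      stop("interaction requires a strain term and severity (hierarchy)")
    }
    rhs <- c(rhs, paste0(slope, ":severity"))
  }
  if (length(rhs) == 0) rhs <- "1"
  re <- paste0("(1 | ", random, ")", collapse = " + ")
  stats::as.formula(paste("change ~", paste(rhs, collapse = " + "), "+", re))
}

#' Fit a Gaussian random-intercept mixed model of injury change
#'
#' REML fit of `change` on a subset of the fixed effects strain, strain
#' rate, severity and the strain-by-severity interaction, with crossed
#' random intercepts for animals and/or segments.  Strain and strain rate
#' are not allowed together unless `collinearity_override` is set (their
#' collinearity makes joint models uninterpretable).  Non-convergence is
#' reported as a status, not an error, so model selection can skip the
#' candidate.
#'
#' @param changes Change table from [ipsi_minus_reference()] (one measure).
#' @param fixed Character subset of
#'   `c("strain", "strain_rate", "severity", "interaction")`.
#' @param random Character subset of `c("animal", "segment")`.
#' @param collinearity_override Allow strain and strain rate together.
#' @return Object of class `cci_lme`: coefficients, variance components
#'   (`sigma2`), fitted values, residuals, REML criterion, convergence and
#'   singularity status, and the underlying lme4 fit.
#' @export
fit_lme <- function(changes, fixed = "strain", random = c("animal", "segment"),
                    collinearity_override = FALSE) {
  if (length(unique(changes$animal)) < 2) stop("need at least 2 animals")
  if (length(unique(changes$measure)) > 1) {
    stop("change table mixes measures; filter to one first")
  }
  if (all(c("strain", "strain_rate") %in% fixed) && !collinearity_override) {
    stop("strain and strain_rate are collinear; not allowed together ",
         "(set collinearity_override to force)")
  }
  random <- match.arg(random, several.ok = TRUE)
  form <- .build_formula(fixed, random)
  dat <- changes
  dat$severity <- as.numeric(dat$severity == "moderate")
  fit <- NULL; converged <- FALSE; singular <- NA; msgs <- character()
  withCallingHandlers(
    fit <- try(lme4::lmer(form, data = dat, REML = TRUE,
                          control = lme4::lmerControl(
                            check.conv.singular = "ignore",
                            calc.derivs = FALSE)),
               silent = TRUE),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (!inherits(fit, "try-error") && !is.null(fit)) {
    conv_code <- fit@optinfo$conv$opt
    converged <- isTRUE(conv_code == 0) &&
      !any(grepl("failed to converge", msgs))
    singular <- lme4::isSingular(fit)
  }
  if (inherits(fit, "try-error")) fit <- NULL
  vc <- if (!is.null(fit)) {
    v <- as.data.frame(lme4::VarCorr(fit))
    sig <- stats::setNames(v$vcov, v$grp)
    list(animal = unname(sig["animal"] %|na|% 0),
         segment = unname(sig["segment"] %|na|% 0),
         resid = unname(sig["Residual"]))
  } else list(animal = NA, segment = NA, resid = NA)
  structure(list(formula = form, fixed = fixed, random = random,
                 coefficients = if (!is.null(fit)) lme4::fixef(fit),
                 sigma2 = vc,
                 fitted = if (!is.null(fit)) stats::fitted(fit),
                 fitted_fixed = if (!is.null(fit)) {
                   stats::predict(fit, re.form = NA)
                 },
                 residuals = if (!is.null(fit)) stats::residuals(fit),
                 reml = if (!is.null(fit)) lme4::REMLcrit(fit),
                 converged = converged, singular = singular,
                 data = dat, fit = fit),
            class = "cci_lme")
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' @export
print.cci_lme <- function(x, ...) {
  cat("cci_lme:", deparse(x$formula), "\n")
  if (is.null(x$fit)) {
    cat("  fit failed\n"); return(invisible(x))
  }
  cat("  converged:", x$converged,
      if (isTRUE(x$singular)) "(singular fit)", "\n")
  print(round(x$coefficients, 4))
  cat("  variance components: animal", signif(x$sigma2$animal, 4),
      "segment", signif(x$sigma2$segment, 4),
      "residual", signif(x$sigma2$resid, 4), "\n")
  cat("  marginal R2:", round(marginal_r2(x), 3), "\n")
  invisible(x)
}

#' @export
summary.cci_lme <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) print(summary(object$fit))
  invisible(object)
}

#' Nakagawa marginal R-squared
#'
#' Variance of the fixed-effect predictions divided by that variance plus
#' all random-effect and residual variance components.
#'
#' @param fit A converged [fit_lme()] object.
#' @return Marginal R-squared in [0, 1].
#' @export
marginal_r2 <- function(fit) {
  if (is.null(fit$fit)) stop("model did not fit")
  var_f <- mean((fit$fitted_fixed - mean(fit$fitted_fixed))^2)
  total <- var_f + fit$sigma2$animal + fit$sigma2$segment + fit$sigma2$resid
  if (total <= 0) stop("degenerate data: zero total variance")
  var_f / total
}

#' Leave-one-animal-out predictive R-squared
#'
#' Each animal is removed in turn, the model refitted, and the held-out
#' changes predicted from the fixed effects alone; `1 - PRESS / TSS` may be
#' negative (flagged).
#'
#' @param changes Change table (one measure).
#' @param fixed,random,collinearity_override As in [fit_lme()].
#' @return List: `value`, `negative` flag, `n_folds`, and `failed_folds`
#'   (animal ids whose refit did not converge; their rows are skipped).
#' @export
predictive_r2 <- function(changes, fixed = "strain",
                          random = c("animal", "segment"),
                          collinearity_override = FALSE) {
  animals <- unique(changes$animal)
  if (length(animals) < 3) stop("need at least 3 animals for LOO")
  press <- 0; used <- 0; failed <- c()
  y_all <- changes$change
  for (a in animals) {
    train <- changes[changes$animal != a, ]
    test <- changes[changes$animal == a, ]
    f <- fit_lme(train, fixed, random, collinearity_override)
    if (is.null(f$fit) || !f$converged) {
      failed <- c(failed, a)
      next
    }
    td <- test
    td$severity <- as.numeric(td$severity == "moderate")
    pred <- stats::predict(f$fit, newdata = td, re.form = NA,
                           allow.new.levels = TRUE)
    press <- press + sum((test$change - pred)^2)
    used <- used + nrow(test)
  }
  if (used == 0) stop("no LOO fold converged")
  tss <- sum((y_all - mean(y_all))^2) * used / length(y_all)
  val <- 1 - press / tss
  list(value = val, negative = val < 0, n_folds = length(animals),
       failed_folds = failed)
}

#' Backward stepwise model selection
#'
#' Starting from the full fixed-effect set, repeatedly drop the term whose
#' removal least degrades the predictive R-squared, while the degradation
#' stays within `tol`; the interaction is dropped before its main effects.
#' With `criterion = "aic"` the REML fits' AIC replaces predictive
#' R-squared (lower is better).
#'
#' @param changes Change table (one measure).
#' @param full_fixed Starting fixed-effect set.
#' @param random Random-intercept structure.
#' @param tol Maximum tolerated predictive-R-squared degradation per drop.
#' @param criterion `"predictive"` or `"aic"`.
#' @return Object of class `model_report`: data frame of candidate models
#'   (formula, marginal and predictive R2, converged, selected flag) plus
#'   the selected `cci_lme` fit and its diagnostics.
#' @export
backward_select <- function(changes, full_fixed = c("strain", "severity",
                                                    "interaction"),
                            random = c("animal", "segment"), tol = 0.01,
                            criterion = c("predictive", "aic")) {
  criterion <- match.arg(criterion)
  score <- function(fixed) {
    f <- fit_lme(changes, fixed, random)
    if (is.null(f$fit) || !f$converged) {
      return(list(fit = f, score = NA, pr2 = NA, mr2 = NA))
    }
    pr2 <- tryCatch(predictive_r2(changes, fixed, random)$value,
                    error = function(e) NA)
    sc <- if (criterion == "predictive") pr2 else -stats::AIC(f$fit)
    list(fit = f, score = sc, pr2 = pr2, mr2 = marginal_r2(f))
  }
  droppable <- function(fixed) {
    out <- fixed
    if ("interaction" %in% fixed) {
      out <- "interaction"              # hierarchy: interaction leaves first
    }
    out
  }
  current <- full_fixed
  cur <- score(current)
  if (is.na(cur$score)) stop("full model did not converge; no candidates")
  log <- list(list(fixed = current, mr2 = cur$mr2, pr2 = cur$pr2,
                   converged = cur$fit$converged, selected = FALSE))
  repeat {
    drops <- droppable(current)
    if (length(drops) == 0 || length(current) == 0) break
    cand <- lapply(drops, function(d) {
      fx <- setdiff(current, d)
      c(list(fixed = fx, dropped = d), score(fx))
    })
    ok <- !vapply(cand, function(cc) is.na(cc$score), TRUE)
    for (cc in cand) {
      log[[length(log) + 1]] <- list(fixed = cc$fixed, mr2 = cc$mr2,
                                     pr2 = cc$pr2,
                                     converged = !is.null(cc$fit$fit) &&
                                       cc$fit$converged,
                                     selected = FALSE)
    }
    if (!any(ok)) break
    cand <- cand[ok]
    best <- cand[[which.max(vapply(cand, `[[`, 0, "score"))]]
    if (best$score >= cur$score - tol) {
      current <- best$fixed
      cur <- best
      if (length(current) == 0) break
    } else break
  }
  # mark the selected model in the candidate log (first match)
  tab <- data.frame(
    model = vapply(log, function(l) paste(sort(l$fixed), collapse = "+"), ""),
    marginal_r2 = vapply(log, function(l) l$mr2 %||NA% NA_real_, 0),
    predictive_r2 = vapply(log, function(l) l$pr2 %||NA% NA_real_, 0),
    converged = vapply(log, `[[`, TRUE, "converged"))
  tab <- tab[!duplicated(tab$model), ]
  tab$selected <- tab$model == paste(sort(current), collapse = "+")
  fit <- cur$fit
  structure(list(candidates = tab, selected_fixed = current,
                 fit = fit, diagnostics = check_model(fit)),
            class = "model_report")
}

`%||NA%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' @export
print.model_report <- function(x, ...) {
  cat("model_report: selected fixed effects {",
      paste(x$selected_fixed, collapse = ", "), "}\n")
  print(x$candidates, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Residual diagnostics for a mixed-model fit
#'
#' Normality by Shapiro-Wilk on the residuals, homoscedasticity by a t-test
#' on the slope of |residual| against fitted values, collinearity by
#' pairwise Pearson correlation above 0.9 among the numeric fixed
#' covariates.
#'
#' @param fit A [fit_lme()] object.
#' @param alpha Significance level for the residual checks.
#' @return List of logical flags (`normality_ok`, `homoscedastic_ok`,
#'   `collinearity_ok`) with the supporting p-values / correlations.
#' @export
check_model <- function(fit, alpha = 0.05) {
  if (is.null(fit$fit)) stop("model did not fit; no residuals")
  r <- fit$residuals
  n <- length(r)
  sw <- stats::shapiro.test(if (n > 4999) sample(r, 4999) else r)
  sl <- stats::lm(abs(r) ~ fit$fitted)
  p_slope <- summary(sl)$coefficients[2, 4]
  covs <- intersect(c("strain", "strain_rate", "severity"), fit$fixed)
  max_r <- 0
  if (length(covs) >= 2) {
    cm <- stats::cor(fit$data[covs])
    max_r <- max(abs(cm[upper.tri(cm)]))
  }
  list(normality_ok = sw$p.value > alpha, normality_p = sw$p.value,
       homoscedastic_ok = p_slope > alpha, homoscedastic_p = p_slope,
       collinearity_ok = max_r <= 0.9, max_abs_cor = max_r)
}

#' Log-transform a change table
#'
#' Shifts the changes to strictly positive support (if needed) and takes the
#' natural log.  With an explicit `shift`, rows still non-positive after the
#' shift raise an error listing them.
#'
#' @param changes Change table.
#' @param shift NULL for an automatic shift, or a number added before log.
#' @return The transformed change table (attribute `shift` records the
#'   offset used).
#' @export
apply_log <- function(changes, shift = NULL) {
  y <- changes$change
  if (is.null(shift)) {
    shift <- if (min(y) <= 0) -min(y) + 1e-6 * max(1, diff(range(y))) else 0
  }
  bad <- which(y + shift <= 0)
  if (length(bad) > 0) {
    stop("non-positive values under log at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  changes$change <- log(y + shift)
  attr(changes, "shift") <- shift
  changes
}

#' Pearson product-moment correlation
#' @param x,y Numeric vectors, length >= 3, nonzero variance.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    stop("need vectors of equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance")
  }
  stats::cor(x, y)
}

#' Standardise strain covariates to unit variance
#' @param changes Change table with `strain` (and optionally `strain_rate`).
#' @return The table with covariates centred and scaled.
#' @export
standardize_covariates <- function(changes) {
  for (cv in intersect(c("strain", "strain_rate"), names(changes))) {
    if (all(is.na(changes[[cv]]))) next
    v <- changes[[cv]]
    changes[[cv]] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  changes
}
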