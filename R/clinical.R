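#' @noRd
glm_result <- function(coefficients, family, formula, n, converged,
                       dispersion = NULL, model = NULL, extra = list()) {
  structure(c(list(coefficients = coefficients, family = family,
                   formula = formula, n = n, converged = converged,
                   dispersion = dispersion, model = model), extra),
            class = "glm_result")
}

#' @noRd
coef_table <- function(est, se, conf = 0.95) {
  z <- est / se
  q <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             effect = unname(exp(est)),
             lower = unname(exp(est - q * se)),
             upper = unname(exp(est + q * se)),
             row.names = NULL)
}

#' @export
print.glm_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s model (n = %d)%s\n", x$family, x$n,
              if (isTRUE(x$converged)) "" else "  [did not converge]"))
  cat("  ", x$formula, "\n", sep = "")
  df <- x$coefficients
  df[, -1] <- lapply(df[, -1], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  if (!is.null(x$dispersion))
    cat(sprintf("  NB dispersion (size): %.3f\n", x$dispersion))
  if (isTRUE(x$non_proportional))
    cat("  note: proportional-odds assumption flagged by the score-test heuristic\n")
  invisible(x)
}

#' Median-dichotomize a clinical metric at a visit
#'
#' Computes each subject's percentage for the metric at the visit
#' (count / total sites) and flags subjects strictly below the within-visit
#' median. Values equal to the median fall in the "above" group (indicator
#' 0): "below median" is read literally.
#'
#' @param clinical Clinical records data frame (columns `subject_id`,
#'   `visit_month`, `sites_total` and the metric counts `sites_ppd5`,
#'   `sites_bleeding`, `sites_al13`).
#' @param metric `"ppd5"`, `"bleeding"` or `"al13"`.
#' @param visit Visit month to evaluate.
#' @return Named integer vector (1 = below median) over subjects at the
#'   visit; attribute `"median"` carries the median percentage.
#' @export
median_dichotomize <- function(clinical, metric = c("ppd5", "bleeding", "al13"),
                               visit) {
  metric <- match.arg(metric)
  col <- paste0("sites_", metric)
  rows <- clinical[clinical$visit_month == visit, ]
  if (nrow(rows) < 2) stop("need at least 2 subjects at visit ", visit)
  if (!col %in% names(clinical) || all(is.na(rows[[col]])))
    stop("metric '", metric, "' not available at visit ", visit)
  pct <- 100 * rows[[col]] / rows$sites_total
  med <- median(pct)
  structure(setNames(as.integer(pct < med), rows$subject_id), median = med)
}

#' Treat-to-target endpoint
#'
#' The clinical success definition of at most 4 sites with pocket probing
#' depth >= 5 mm.
#'
#' @param record Clinical record(s): data frame with column `sites_ppd5`, or
#'   a numeric vector of PPD >= 5 mm site counts.
#' @return Logical vector, `TRUE` when the endpoint is met.
#' @export
treat_to_target <- function(record) {
  x <- if (is.data.frame(record)) record$sites_ppd5 else record
  if (is.null(x)) stop("`sites_ppd5` is missing")
  x <= 4
}

#' @noRd
find_separating_variable <- function(y, df) {
  for (v in names(df)) {
    x <- df[[v]]
    if (is.numeric(x)) {
      if (max(x[y == 1]) < min(x[y == 0]) || max(x[y == 0]) < min(x[y == 1]))
        return(v)
    } else {
      tab <- table(x, y)
      if (any(rowSums(tab > 0) == 1) && length(unique(x)) > 1) return(v)
    }
  }
  NULL
}

#' Logistic association model between dysbiosis and a clinical indicator
#'
#' Maximum-likelihood logistic regression of a binary clinical indicator
#' (e.g. below-median outcome from [median_dichotomize()]) on the
#' normobiotic proportion, adjusted for covariates. The exposure effect is
#' reported per `per` increase in normobiotic proportion (default 0.1), so
#' an odds ratio of 1.26 means 26% higher odds of the favourable indicator
#' per 0.1 increase; rescale by powering if another unit is preferred.
#'
#' @param outcome Binary vector (both classes must occur).
#' @param exposure Numeric normobiotic proportion in `[0, 1]`.
#' @param covariates Optional data frame of adjustment covariates (age, sex,
#'   smoking, optionally arm).
#' @param per Exposure unit (default 0.1).
#' @return A `glm_result` with Wald 95% intervals; errors on perfect
#'   separation naming the separating variable.
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL, per = 0.1) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome has a single class; cannot fit")
  df <- data.frame(y = y, exposure_scaled = exposure / per)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep_warn && max(abs(coef(fit)[-1]), na.rm = TRUE) > 10) {
    v <- find_separating_variable(y, df[-1])
    stop("perfect separation detected",
         if (!is.null(v)) paste0(" (separating variable: '",
                                 sub("exposure_scaled", "exposure", v), "')"))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  glm_result(coef_table(est, se), "binomial (logit)",
             paste(deparse(stats::formula(fit)), collapse = ""),
             n = nrow(df), converged = fit$converged, model = fit)
}

#' Proportional-odds model of the microbial response category
#'
#' Ordinal logistic regression (logit link, three cutpoints for the four
#' ordered categories, higher = better response) of the response category on
#' treatment, the baseline normobiotic indicator, and the confounders age
#' band, sex and smoking. Odds ratios are per predictor with Wald 95%
#' intervals. A score-test-style heuristic compares per-threshold binary
#' logits and flags the fit when the proportional-odds assumption looks
#' violated.
#'
#' Maximum-likelihood ordinal regression carries a small upward
#' finite-sample bias on the odds-ratio scale at trial-sized n; with
#' `bias_correct = TRUE` a parametric-bootstrap correction (centered at the
#' fitted model) is subtracted from the coefficients.
#'
#' @param data Data frame with columns `category` (integer 0-3 or ordered
#'   factor), `treatment` (0/1 or factor), `baseline_normo` (0/1), and
#'   optionally `age_band`, `sex`, `smoking`.
#' @param covariates Character vector of adjustment columns present in
#'   `data`; default all of age band, sex, smoking that are present.
#' @param bias_correct Apply the parametric-bootstrap bias correction.
#' @param n_boot Bootstrap replicates for the correction (default 30).
#' @param boot_seed Seed for the bootstrap.
#' @return A `glm_result`; `cutpoints` holds the estimated cutpoints and
#'   `non_proportional` the heuristic flag.
#' @export
fit_ordinal_mediator <- function(data,
                                 covariates = intersect(c("age_band", "sex", "smoking"),
                                                        names(data)),
                                 bias_correct = FALSE, n_boot = 30,
                                 boot_seed = 1L) {
  need <- c("category", "treatment", "baseline_normo")
  if (!all(need %in% names(data)))
    stop("`data` needs columns: ", paste(need, collapse = ", "))
  y <- data$category
  if (is.numeric(y)) y <- factor(y, levels = sort(unique(y)), ordered = TRUE)
  if (!is.ordered(y)) y <- factor(y, ordered = TRUE)
  if (nlevels(droplevels(y)) < 3)
    stop("fewer than 3 response categories realized; ordinal model is degenerate")
  rhs <- c("treatment", "baseline_normo", covariates)
  df <- data.frame(.y = y, data[rhs], check.names = FALSE)
  fml <- as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- MASS::polr(fml, data = df, Hess = TRUE)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))[seq_along(est)]

  if (bias_correct) {
    X <- model.matrix(fml, df)[, -1, drop = FALSE]
    eta <- drop(X %*% est)
    zeta <- fit$zeta
    lv <- levels(y)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(boot_seed)
    boot <- replicate(n_boot, {
      u <- runif(nrow(df))
      yb <- rowSums(outer(u, zeta, function(uu, z) uu > plogis(z - eta)))
      db <- df
      db$.y <- factor(lv[yb + 1L], levels = lv, ordered = TRUE)
      fb <- try(suppressWarnings(MASS::polr(fml, data = db, Hess = FALSE)),
                silent = TRUE)
      if (inherits(fb, "try-error")) rep(NA_real_, length(est)) else coef(fb)
    })
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    bias <- rowMeans(boot, na.rm = TRUE) - est
    est <- est - bias
  }

  non_prop <- prop_odds_flag(df, rhs, y)
  glm_result(coef_table(est, se), "proportional odds (logit)",
             paste(deparse(fml), collapse = ""), n = nrow(df),
             converged = fit$convergence == 0, model = fit,
             extra = list(cutpoints = fit$zeta, non_proportional = non_prop,
                          bias_corrected = bias_correct))
}

# heuristic proportional-odds check: fit a binary logit at each threshold
# and test equality of each predictor's coefficients across thresholds,
# ignoring their covariance (conservative screening, not a formal test)
#' @noRd
prop_odds_flag <- function(df, rhs, y, alpha = 0.01) {
  lv <- levels(droplevels(y))
  J <- length(lv)
  fml_bin <- as.formula(paste(".yb ~", paste(rhs, collapse = " + ")))
  bs <- ses <- NULL
  for (j in seq_len(J - 1)) {
    db <- df
    db$.yb <- as.integer(as.integer(y) > j)
    fb <- try(suppressWarnings(glm(fml_bin, data = db, family = binomial())),
              silent = TRUE)
    if (inherits(fb, "try-error") || !fb$converged) return(NA)
    bs <- rbind(bs, coef(fb)[-1])
    ses <- rbind(ses, sqrt(diag(vcov(fb)))[-1])
  }
  flag <- FALSE
  for (p in seq_len(ncol(bs))) {
    w <- 1 / ses[, p]^2
    bbar <- sum(w * bs[, p]) / sum(w)
    x2 <- sum((bs[, p] - bbar)^2 * w)
    if (pchisq(x2, df = J - 2, lower.tail = FALSE) < alpha) flag <- TRUE
  }
  flag
}

#' Negative-binomial model of attachment-loss site counts
#'
#' NB2 maximum-likelihood regression with log link of the count of sites
#' with further attachment loss >= 1.3 mm on the chosen predictors, with the
#' log total number of sites as offset — i.e. modelling the per-site rate of
#' further attachment loss. Exponentiated coefficients are rate ratios.
#'
#' @param data Data frame with the response, `sites_total` and the
#'   predictors.
#' @param predictors Character vector among `"treatment"`, `"category"`,
#'   `"age_band"`, `"sex"`, `"smoking"` (at least one). `category` enters
#'   as ordinal numeric 0-3 by default, matching a constant per-category
#'   rate ratio.
#' @param response Response column (default `"sites_al13"`).
#' @param offset_var Column with the total number of sites (default
#'   `"sites_total"`).
#' @param category_as_factor Enter `category` as dummies instead of ordinal
#'   numeric (for prediction grids with unconstrained category steps).
#' @return A `glm_result` with the NB dispersion (size) reported.
#' @export
fit_nb_outcome <- function(data, predictors, response = "sites_al13",
                           offset_var = "sites_total",
                           category_as_factor = FALSE) {
  if (!length(predictors)) stop("need at least one predictor")
  miss <- setdiff(c(predictors, response, offset_var), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  y <- data[[response]]
  if (any(y < 0)) stop("negative counts in `", response, "`")
  if (any(y > data[[offset_var]]))
    stop("counts exceed total sites for some records")
  df <- data[c(response, predictors, offset_var)]
  if ("category" %in% predictors) {
    df$category <- if (category_as_factor) factor(df$category)
                   else as.numeric(df$category)
  }
  fml <- as.formula(paste(response, "~", paste(predictors, collapse = " + "),
                          "+ offset(log(", offset_var, "))"))
  fit <- suppressWarnings(MASS::glm.nb(fml, data = df))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  glm_result(coef_table(est, se), "negative binomial (log link, offset)",
             paste(deparse(fml), collapse = ""), n = nrow(df),
             converged = fit$converged, dispersion = fit$theta, model = fit)
}

#' Expected attachment-loss sites over a covariate grid
#'
#' Multiplicative model predictions: for each covariate combination the
#' expected number of sites with further attachment loss is
#' `sites_total * exp(linear predictor)`. Because the model is log-linear,
#' adjacent cells differ exactly by the corresponding rate ratio, and
#' doubling `sites_total` doubles every cell.
#'
#' @param nb_result A [fit_nb_outcome()] result.
#' @param grid Data frame of covariate combinations (columns must be model
#'   predictors); default: full crossing of treatment, smoking, age band and
#'   category as far as they are in the model.
#' @param sites_total Total sites per patient used for the prediction
#'   (default 146, about 24 teeth at 6 sites each).
#' @return The grid with an `expected_sites` column appended.
#' @export
prediction_grid <- function(nb_result, grid = NULL, sites_total = 146) {
  stopifnot(inherits(nb_result, "glm_result"))
  model <- nb_result$model
  if (is.null(model)) stop("result carries no underlying model object")
  vars <- all.vars(stats::formula(model))
  offset_var <- vars[length(vars)]
  preds <- setdiff(vars[-1], offset_var)
  if (is.null(grid)) {
    levs <- list(treatment = 0:1, smoking = c("no", "yes"),
                 age_band = c("<45", "45<55", ">55"), category = 0:3)
    mf <- model$model
    grid <- expand.grid(lapply(preds, function(p) {
      if (!is.null(levs[[p]]) && !is.factor(mf[[p]])) levs[[p]]
      else if (is.factor(mf[[p]])) levels(mf[[p]])
      else sort(unique(mf[[p]]))
    }), stringsAsFactors = FALSE)
    names(grid) <- preds
  } else {
    extra <- setdiff(names(grid), preds)
    if (length(extra)) stop("grid covariates not in the model: ",
                            paste(extra, collapse = ", "))
    absent <- setdiff(preds, names(grid))
    if (length(absent)) stop("grid must include every model predictor; missing: ",
                             paste(absent, collapse = ", "))
    for (p in intersect(names(grid), names(model$xlevels))) {
      bad <- setdiff(unique(as.character(grid[[p]])), model$xlevels[[p]])
      if (length(bad)) stop("unknown level(s) for '", p, "': ",
                            paste(bad, collapse = ", "))
    }
  }
  nd <- grid
  nd[[offset_var]] <- sites_total
  mu <- predict(model, newdata = nd, type = "response")
  out <- grid
  out$expected_sites <- as.numeric(mu)
  out
}

#' Project a treatment rate ratio onto an observed site count
#'
#' Multiplicative what-if arithmetic on model effects: given an observed (or
#' predicted) number of affected sites, applying a rate ratio yields the
#' expected count under the alternative condition and the corresponding
#' absolute change.
#'
#' @param sites Number of sites with further attachment loss.
#' @param rate_ratio Multiplicative effect to apply (e.g. 0.81 for a 19%
#'   reduction under antibiotics).
#' @return List with `expected` (`sites * rate_ratio`) and `reduction`
#'   (`sites * (1 - rate_ratio)`).
#' @export
treatment_effect_projection <- function(sites, rate_ratio) {
  list(expected = sites * rate_ratio, reduction = sites * (1 - rate_ratio))
}
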