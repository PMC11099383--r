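# Single-gene and combined two-gene survival screening of axis pairs.

#' Construct a survival dataset for one cohort
#'
#' @param clinical Tibble with columns `patient`, `time` (> 0, one unit per
#'   cohort), `event` (0/1, 1 = death observed), and optionally `cohort`.
#' @param expression Numeric matrix of (normalized) expression, genes in
#'   rows, patients in columns; column names must cover `clinical$patient`.
#' @param cohort Cohort label (recorded; single-cohort object).
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(clinical, expression, cohort = NA_character_) {
  clinical <- as_tibble(clinical)
  check_columns(clinical, c("patient", "time", "event"), "clinical")
  if (any(clinical$time <= 0)) stop_schema("survival times must be positive")
  if (!all(clinical$event %in% c(0, 1))) {
    stop_schema("event indicator must be 0/1")
  }
  expression <- as.matrix(expression)
  missing_pat <- setdiff(clinical$patient, colnames(expression))
  if (length(missing_pat) > 0) {
    stop_schema("patient(s) missing from expression matrix: %s",
                paste(utils::head(missing_pat, 3), collapse = ", "))
  }
  expression <- expression[, clinical$patient, drop = FALSE]
  structure(list(clinical = clinical, expression = expression,
                 cohort = cohort),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset> cohort %s: %d patients (%d events), %d genes\n",
              x$cohort, nrow(x$clinical), sum(x$clinical$event),
              nrow(x$expression)))
  invisible(x)
}

#' Median expression stratification
#'
#' Labels a patient `"high"` when the value is strictly above the cohort
#' median and `"low"` otherwise (ties go to low).
#'
#' @param values Finite numeric vector, length >= 4.
#' @return Factor with levels `low`, `high` (low first, so it is the Cox
#'   reference group).
#' @export
median_stratify <- function(values) {
  stopifnot(length(values) >= 4, all(is.finite(values)))
  if (max(values) == min(values)) {
    stop_schema("constant expression vector cannot be median-stratified")
  }
  factor(ifelse(values > median(values), "high", "low"),
         levels = c("low", "high"))
}

#' Combined two-gene stratification
#'
#' Patients strictly above both genes' medians form the both-high group;
#' patients at-or-below both medians form the both-low group (the same tie
#' rule as [median_stratify()]); mixed patients are labeled `excluded` and
#' dropped from the two-group comparison.
#'
#' @param values_r,values_p Finite numeric vectors, both non-constant,
#'   length >= 4.
#' @return Factor with levels `low`, `high`, `excluded` (`low` = both-low).
#'   If either the both-high or both-low group is empty the axis is
#'   untestable and `NULL` is returned.
#' @export
combined_stratify <- function(values_r, values_p) {
  stopifnot(length(values_r) == length(values_p), length(values_r) >= 4)
  gr <- median_stratify(values_r)
  gp <- median_stratify(values_p)
  lab <- ifelse(gr == "high" & gp == "high", "high",
         ifelse(gr == "low" & gp == "low", "low", "excluded"))
  if (!any(lab == "high") || !any(lab == "low")) return(NULL)
  factor(lab, levels = c("low", "high", "excluded"))
}

#' Two-group log-rank test with Kaplan-Meier curve tables
#'
#' @param time,event Survival time and 0/1 event indicator.
#' @param groups Factor with exactly two used levels; `excluded` entries
#'   (or `NA`) are dropped.
#' @return List with `statistic` (the log-rank chi-square), `p`, and `km`, a
#'   tibble of Kaplan-Meier curve points (`group`, `time`, `n_risk`,
#'   `n_event`, `survival`).
#' @export
km_logrank <- function(time, event, groups) {
  keep <- !is.na(groups) & as.character(groups) != "excluded"
  time <- time[keep]; event <- event[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) != 2 || any(table(groups) == 0)) {
    stop_schema("km_logrank requires exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  strata_group <- sub("^groups=", "", names(fit$strata))
  km <- tibble(group = rep(strata_group, fit$strata),
               time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv)
  list(statistic = unname(sd$chisq),
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       km = km)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling. For factor covariates
#' from [median_stratify()], `low` is the reference so the hazard ratio
#' compares high vs low expression.
#'
#' @param time,event Survival time and 0/1 event indicator.
#' @param covariate Binary factor or numeric vector, non-constant.
#' @return One-row tibble with `beta`, `hr`, `p` (Wald), `score_p` (score
#'   test, asymptotically the log-rank p for a two-group covariate). On
#'   non-convergence or infinite estimates, statistics are `NA`.
#' @export
cox_univariate <- function(time, event, covariate) {
  if (is.factor(covariate)) {
    keep <- !is.na(covariate) & as.character(covariate) != "excluded"
  } else {
    keep <- !is.na(covariate)
  }
  time <- time[keep]; event <- event[keep]
  covariate <- if (is.factor(covariate)) droplevels(covariate[keep]) else covariate[keep]
  if (length(unique(covariate)) < 2) {
    stop_schema("constant covariate cannot be fit")
  }
  if (sum(event) < 1) stop_schema("no observed events")
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ covariate, ties = "efron"),
    warning = function(w) structure(list(), class = "gpcraxes_cox_fail"),
    error = function(e) structure(list(), class = "gpcraxes_cox_fail"))
  if (inherits(fit, "gpcraxes_cox_fail")) {
    return(tibble(beta = NA_real_, hr = NA_real_, p = NA_real_,
                  score_p = NA_real_))
  }
  s <- summary(fit)
  beta <- unname(coef(fit)[1])
  tibble(beta = beta, hr = exp(beta),
         p = unname(s$coefficients[1, "Pr(>|z|)"]),
         score_p = unname(s$sctest[["pvalue"]]))
}

screen_one_gene <- function(time, event, values) {
  grp <- tryCatch(median_stratify(values), error = function(e) NULL)
  if (is.null(grp)) {
    return(list(cox = tibble(beta = NA_real_, hr = NA_real_, p = NA_real_,
                             score_p = NA_real_),
                logrank_p = NA_real_, groups = NULL))
  }
  cox <- cox_univariate(time, event, grp)
  lr <- tryCatch(km_logrank(time, event, grp)$p, error = function(e) NA_real_)
  list(cox = cox, logrank_p = lr, groups = grp)
}

#' Screen axes for combined survival association
#'
#' For every axis, stratifies patients by the receptor median, the partner
#' median, and the combined (both-high vs both-low) rule; fits Cox models
#' and log-rank tests for all three stratifications; and applies the axis
#' filter: the axis passes when its hazard ratio differs at least two-fold
#' from both individual hazard ratios (`hr_axis/hr_individual < 0.5` or
#' `> 2`), its log-rank p is below both individual log-rank p-values, and
#' `logrank_p_axis < 0.05`. Log-rank p-values of the combined
#' stratification are BH-adjusted across tested axes within the cohort.
#'
#' @param dataset A [survival_dataset()].
#' @param axes Tibble with `receptor`, `partner` (and optional
#'   `partner_kind`) resolvable in the dataset's expression matrix.
#' @param logrank_alpha Axis significance bound; default 0.05.
#' @param hr_fold Fold-change bound on the HR ratio; default 2.
#' @return Tibble of class `axis_screen`, one row per axis with the three
#'   HRs, betas, log-rank p-values, group sizes, `q` and `passes_filter`.
#' @export
axis_screen <- function(dataset, axes, logrank_alpha = 0.05, hr_fold = 2) {
  stopifnot(inherits(dataset, "survival_dataset"))
  axes <- distinct(as_tibble(axes))
  check_columns(axes, c("receptor", "partner"), "axes")
  if (!"partner_kind" %in% names(axes)) axes$partner_kind <- NA_character_
  cl <- dataset$clinical
  expr <- dataset$expression

  rows <- pmap(list(axes$receptor, axes$partner, axes$partner_kind),
               function(rec, par, kind) {
    na_row <- tibble(
      receptor = rec, partner = par, partner_kind = kind,
      hr_axis = NA_real_, hr_r = NA_real_, hr_p = NA_real_,
      beta_axis = NA_real_, beta_r = NA_real_, beta_p = NA_real_,
      logrank_p_axis = NA_real_, logrank_p_r = NA_real_,
      logrank_p_p = NA_real_, n_high = NA_integer_, n_low = NA_integer_)
    if (!rec %in% rownames(expr) || !par %in% rownames(expr)) return(na_row)
    vr <- expr[rec, ]; vp <- expr[par, ]
    sr <- screen_one_gene(cl$time, cl$event, vr)
    sp <- screen_one_gene(cl$time, cl$event, vp)
    comb <- tryCatch(combined_stratify(vr, vp), error = function(e) NULL)
    if (is.null(comb)) {
      na_row$hr_r <- sr$cox$hr; na_row$hr_p <- sp$cox$hr
      na_row$beta_r <- sr$cox$beta; na_row$beta_p <- sp$cox$beta
      na_row$logrank_p_r <- sr$logrank_p; na_row$logrank_p_p <- sp$logrank_p
      return(na_row)
    }
    ca <- cox_univariate(cl$time, cl$event, comb)
    la <- tryCatch(km_logrank(cl$time, cl$event, comb)$p,
                   error = function(e) NA_real_)
    tibble(
      receptor = rec, partner = par, partner_kind = kind,
      hr_axis = ca$hr, hr_r = sr$cox$hr, hr_p = sp$cox$hr,
      beta_axis = ca$beta, beta_r = sr$cox$beta, beta_p = sp$cox$beta,
      logrank_p_axis = la, logrank_p_r = sr$logrank_p,
      logrank_p_p = sp$logrank_p,
      n_high = sum(comb == "high"), n_low = sum(comb == "low"))
  })
  out <- list_rbind(rows)
  ratio_r <- out$hr_axis / out$hr_r
  ratio_p <- out$hr_axis / out$hr_p
  fold_ok <- function(x) !is.na(x) & (x < 1 / hr_fold | x > hr_fold)
  out$q <- adjust_pvalues(out$logrank_p_axis)
  out$passes_filter <- fold_ok(ratio_r) & fold_ok(ratio_p) &
    !is.na(out$logrank_p_axis) &
    out$logrank_p_axis < pmin(out$logrank_p_r, out$logrank_p_p) &
    out$logrank_p_axis < logrank_alpha
  out$passes_filter[is.na(out$passes_filter)] <- FALSE
  class(out) <- c("axis_screen", class(out))
  out
}

#' Combinatorial Cox model for one axis
#'
#' Builds the per-patient linear predictor
#' `beta_r * receptor_high(i) + beta_p * partner_high(i)` from the
#' univariate Cox coefficients of the median stratifications (indicators:
#' 1 = high; a continuous mode using the expression values themselves is
#' available via `indicator = FALSE`), stratifies patients at the
#' predictor's median, and evaluates the predictor-based stratification with
#' a second-round Cox fit and log-rank test. The model is selected when its
#' hazard ratio differs at least two-fold from both individual hazard ratios
#' and its log-rank p is significant and below both individual log-rank
#' p-values.
#'
#' @param dataset A [survival_dataset()].
#' @param receptor,partner Gene ids present in the expression matrix.
#' @param indicator Use high/low indicators (default) or continuous
#'   expression in the predictor.
#' @param logrank_alpha Significance bound; default 0.05.
#' @param hr_fold Fold bound for selection; default 2 (inclusive).
#' @return One-row tibble of class `combinatorial_cox`: `beta_r`, `beta_p`,
#'   `beta_c`, `hr_r`, `hr_p`, `hr_c`, `logrank_p_c`, `logrank_p_r`,
#'   `logrank_p_p`, `selected`. Degenerate predictors give missing
#'   statistics.
#' @export
combinatorial_cox <- function(dataset, receptor, partner, indicator = TRUE,
                              logrank_alpha = 0.05, hr_fold = 2) {
  stopifnot(inherits(dataset, "survival_dataset"))
  cl <- dataset$clinical
  expr <- dataset$expression
  stopifnot(receptor %in% rownames(expr), partner %in% rownames(expr))
  vr <- expr[receptor, ]; vp <- expr[partner, ]
  sr <- screen_one_gene(cl$time, cl$event, vr)
  sp <- screen_one_gene(cl$time, cl$event, vp)
  na_row <- tibble(receptor = receptor, partner = partner,
                   beta_r = sr$cox$beta, beta_p = sp$cox$beta,
                   beta_c = NA_real_, hr_r = sr$cox$hr, hr_p = sp$cox$hr,
                   hr_c = NA_real_, logrank_p_r = sr$logrank_p,
                   logrank_p_p = sp$logrank_p, logrank_p_c = NA_real_,
                   selected = FALSE)
  class(na_row) <- c("combinatorial_cox", class(na_row))
  if (is.na(sr$cox$beta) || is.na(sp$cox$beta)) return(na_row)

  xr <- if (indicator) as.numeric(sr$groups == "high") else vr
  xp <- if (indicator) as.numeric(sp$groups == "high") else vp
  predictor <- sr$cox$beta * xr + sp$cox$beta * xp
  if (max(predictor) == min(predictor)) return(na_row)

  grp <- tryCatch(median_stratify(predictor), error = function(e) NULL)
  if (is.null(grp)) return(na_row)
  cc <- cox_univariate(cl$time, cl$event, grp)
  lc <- tryCatch(km_logrank(cl$time, cl$event, grp)$p,
                 error = function(e) NA_real_)
  fold_ok <- function(hr_c, hr_i) {
    !is.na(hr_c) && !is.na(hr_i) &&
      (hr_c / hr_i >= hr_fold || hr_c / hr_i <= 1 / hr_fold)
  }
  selected <- fold_ok(cc$hr, sr$cox$hr) && fold_ok(cc$hr, sp$cox$hr) &&
    !is.na(lc) && lc < logrank_alpha &&
    lc < min(sr$logrank_p, sp$logrank_p, na.rm = TRUE)
  out <- na_row
  out$beta_c <- cc$beta; out$hr_c <- cc$hr; out$logrank_p_c <- lc
  out$selected <- isTRUE(selected)
  out
}

#' Regression of combinatorial on individual Cox coefficients
#'
#' Ordinary least squares of the combinatorial coefficient `beta_c` on the
#' individual receptor and partner coefficients (`beta_r`, `beta_p`) with an
#' intercept, fitted on selected combinatorial models only.
#'
#' @param results Tibble of [combinatorial_cox()] rows (stacked); only rows
#'   with `selected == TRUE` are used, and at least 3 are required.
#' @return Object of class `coef_regression` wrapping the `lm` fit, with
#'   [tidy()] and [glance()] methods.
#' @export
coefficient_regression <- function(results) {
  results <- as_tibble(results)
  check_columns(results, c("beta_r", "beta_p", "beta_c", "selected"),
                "combinatorial results")
  sel <- results[results$selected & complete.cases(
    results[, c("beta_r", "beta_p", "beta_c")]), , drop = FALSE]
  if (nrow(sel) < 3) {
    stop_schema("coefficient_regression needs >= 3 selected models, got %d",
                nrow(sel))
  }
  fit <- lm(beta_c ~ beta_r + beta_p, data = sel)
  if (fit$rank < 3) stop_schema("rank-deficient design in coefficient_regression")
  structure(list(fit = fit, n = nrow(sel)), class = "coef_regression")
}

#' @export
print.coef_regression <- function(x, ...) {
  cat(sprintf("<coef_regression> beta_c ~ beta_r + beta_p on %d selected models\n",
              x$n))
  print(coef(x$fit))
  invisible(x)
}

#' @rdname coefficient_regression
#' @param x A `coef_regression` object.
#' @param ... Unused.
#' @method tidy coef_regression
#' @export
tidy.coef_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = rownames(s), estimate = unname(s[, "Estimate"]),
         std_error = unname(s[, "Std. Error"]),
         statistic = unname(s[, "t value"]),
         p_value = unname(s[, "Pr(>|t|)"]))
}

#' @rdname coefficient_regression
#' @method glance coef_regression
#' @export
glance.coef_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         sigma = s$sigma, n = x$n)
}
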