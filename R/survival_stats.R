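# Survival statistics behind the pipeline: Kaplan-Meier curves, log-rank
# tests, Cox proportional-hazards fits, a per-gene univariate prognostic
# screen, and contingency tests for subtype-by-group tables. Estimation is
# delegated to the survival package; this module fixes the contracts
# (tie conventions, error handling, reported fields).

#' Kaplan-Meier product-limit estimate
#'
#' Censorings at an event time count as at risk for that time (the
#' standard censored-after-event tie convention).
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @return data.frame with one row per distinct event/censoring time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` (non-increasing,
#'   S(0) = 1), `std_err` (Greenwood standard error of S).
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1L) abort_icp("need >= 1 observation")
  if (any(times <= 0)) abort_icp("survival times must be positive")
  if (!all(events %in% c(0, 1))) abort_icp("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv,
             std_err = fit$std.err * fit$surv)
}

#' Survival probability at a horizon
#'
#' Reads S(t) off a [km_estimate()] table (step function, right
#' continuous).
#' @param km data.frame from [km_estimate()].
#' @param t horizon on the time scale of the fit.
#' @return S(t); 1 if `t` precedes the first observed time.
#' @export
km_survival_at <- function(km, t) {
  idx <- which(km$time <= t)
  if (!length(idx)) return(1)
  km$surv[max(idx)]
}

#' Log-rank test across groups
#'
#' @param times,events as in [km_estimate()].
#' @param groups per-sample group labels (>= 2 non-empty levels).
#' @return list: `statistic` (chi-squared), `df` (groups - 1), `p_value`,
#'   and per-group `observed`, `expected`, `var` (diagonal of the O - E
#'   covariance).
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) abort_icp("need >= 2 groups")
  if (any(table(groups) == 0L)) abort_icp("empty group level")
  if (sum(events) < 1L) abort_icp("need >= 1 event")
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = sd_fit$chisq, df = df,
       p_value = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE),
       observed = stats::setNames(sd_fit$obs, levels(groups)),
       expected = stats::setNames(sd_fit$exp, levels(groups)),
       var = stats::setNames(diag(as.matrix(sd_fit$var)), levels(groups)))
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson on the partial likelihood via `survival::coxph`
#' (Efron tie correction by default). Constant covariates and collinear
#' design matrices are rejected before fitting; monotone-likelihood
#' separation (|beta| > 20) is flagged as non-convergence.
#'
#' @param data data.frame with `os_time`, `os_event` and the covariate
#'   columns.
#' @param covariates names of covariate columns (numeric, or categorical
#'   columns which are expanded to treatment contrasts).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `cox_result`: `coef` data.frame (term, beta, HR,
#'   se, z, p, lower/upper 95% Wald CI), `loglik` (null, fitted),
#'   `converged`, `n`, `n_event`, and the underlying `fit`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!all(covariates %in% names(data)))
    abort_icp("missing covariate column(s): ",
              paste(setdiff(covariates, names(data)), collapse = ", "))
  if (sum(data$os_event) < 1L) abort_icp("need >= 1 event")
  for (cv in covariates) {
    v <- data[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      abort_icp("constant covariate: ", cv)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(os_time, os_event) ~",
    paste(covariates, collapse = " + ")))
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(covariates, collapse = " + "))),
    data)[, -1L, drop = FALSE]
  if (qr(mm)$rank < ncol(mm))
    abort_icp("collinear covariates: design matrix is rank deficient")
  fit <- survival::coxph(fml, data = data, ties = ties,
                         control = survival::coxph.control(
                           eps = 1e-9, iter.max = 50L))
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- all(abs(beta) <= 20)
  if (!converged)
    warning("possible monotone-likelihood separation (|beta| > 20)")
  coef_tab <- data.frame(
    term = names(beta), beta = unname(beta), hr = exp(unname(beta)),
    se = unname(se), z = unname(beta / se),
    p = 2 * stats::pnorm(-abs(unname(beta / se))),
    hr_lower = exp(unname(beta - 1.96 * se)),
    hr_upper = exp(unname(beta + 1.96 * se)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coef = coef_tab, loglik = fit$loglik,
                 score_test = sm$sctest, converged = converged,
                 n = fit$n, n_event = fit$nevent, ties = ties, fit = fit),
            class = "cox_result")
}

#' Univariate prognostic screen over genes
#'
#' Per gene: a univariate Cox fit on continuous expression (beta, HR, p)
#' and a log-rank test of the median expression split; the direction label
#' (favorable when higher expression lowers hazard) comes from the sign of
#' beta. Per-gene failures (constant genes, degenerate splits) are
#' recorded as NA rows, never fatal.
#'
#' @param expr genes x samples matrix.
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event`
#'   covering the matrix columns.
#' @return data.frame per gene: `gene`, `beta`, `hr`, `p_cox`,
#'   `p_logrank_median`, `direction` ("favorable"/"poor"/NA).
#' @export
univariate_screen <- function(expr, clinical) {
  idx <- match(colnames(expr), clinical$sample_id)
  if (anyNA(idx)) abort_icp("clinical table lacks some matrix samples")
  cl <- clinical[idx, ]
  out <- lapply(rownames(expr), function(g) {
    v <- expr[g, ]
    row <- data.frame(gene = g, beta = NA_real_, hr = NA_real_,
                      p_cox = NA_real_, p_logrank_median = NA_real_,
                      direction = NA_character_, stringsAsFactors = FALSE)
    if (stats::sd(v) == 0) {
      warning("constant gene skipped in screen: ", g)
      return(row)
    }
    d <- data.frame(os_time = cl$os_time, os_event = cl$os_event, expr = v)
    fit <- tryCatch(cox_fit(d, "expr"), error = function(e) NULL,
                    warning = function(w) suppressWarnings(cox_fit(d, "expr")))
    if (!is.null(fit)) {
      row$beta <- fit$coef$beta[1L]
      row$hr <- fit$coef$hr[1L]
      row$p_cox <- fit$coef$p[1L]
      row$direction <- if (row$beta < 0) "favorable" else "poor"
    }
    grp <- ifelse(v > stats::median(v), "high", "low")
    if (length(unique(grp)) == 2L) {
      lr <- tryCatch(logrank_test(cl$os_time, cl$os_event, grp),
                     error = function(e) NULL)
      if (!is.null(lr)) row$p_logrank_median <- lr$p_value
    }
    row
  })
  do.call(rbind, out)
}

# sample odds ratio with Haldane-Anscombe 0.5 correction on zero cells
sample_odds_ratio <- function(tab) {
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Association between two categorical variables
#'
#' 2x2 tables get a two-sided Fisher exact test (point-probability method,
#' i.e. summing tables whose probability does not exceed the observed
#' one) plus a Haldane-corrected sample odds ratio; larger tables get a
#' Pearson chi-squared test with df = (r-1)(c-1).
#'
#' @param a,b equal-length categorical vectors with >= 2 observed levels
#'   each (empty levels are dropped with a warning).
#' @return list: `table`, `statistic` (chi-squared; NA for Fisher),
#'   `df`, `p_value`, `odds_ratio` (2x2 only), `method`.
#' @export
contingency_test <- function(a, b) {
  if (length(a) != length(b)) abort_icp("inputs differ in length")
  a <- factor(as.character(a)); b <- factor(as.character(b))
  tab <- table(a, b)
  drop_r <- rowSums(tab) == 0; drop_c <- colSums(tab) == 0
  if (any(drop_r) || any(drop_c)) {
    warning("dropping empty level(s) after cross-tabulation")
    tab <- tab[!drop_r, !drop_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    abort_icp("need >= 2 observed levels in each variable")
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    ft <- stats::fisher.test(tab)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(table = tab, statistic = unname(chi$statistic), df = 1L,
         p_value = ft$p.value, odds_ratio = sample_odds_ratio(tab),
         method = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(table = tab, statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value,
         odds_ratio = NA_real_, method = "chisq")
  }
}
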