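# Kaplan-Meier, log-rank, Cox proportional hazards and score-based
# stratification. Estimation is delegated to the survival package
# (survfit/survdiff/coxph with Efron ties); this module defines the
# package's contracts around them.

check_surv <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time))) stop("non-finite survival times")
  if (any(time < 0)) stop("negative survival times")
  event <- as.logical(event)
  if (anyNA(event)) stop("missing event indicators")
  event
}

#' Kaplan-Meier product-limit curve
#'
#' @param time follow-up times (months, >= 0).
#' @param event logical/0-1 event indicators (FALSE = censored).
#' @return data.frame step function: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
km_curve <- function(time, event) {
  event <- check_surv(time, event)
  if (!length(time)) stop("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic with hypergeometric
#' variance; two-sided p from the chi-square distribution with
#' (groups - 1) degrees of freedom.
#'
#' @param time,event as in [km_curve()].
#' @param group grouping vector (>= 2 non-empty groups, >= 1 event).
#' @return list: `chisq`, `df`, `p_value`, `observed`, `expected` per
#'   group.
#' @export
log_rank <- function(time, event, group) {
  event <- check_surv(time, event)
  g <- factor(group)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need >=2 groups")
  if (any(table(g) == 0L)) stop("empty group")
  if (sum(event) < 1L) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = as.vector(sd$obs), expected = as.vector(sd$exp))
}

#' Cox proportional-hazards fit with Wald inference
#'
#' Maximises the Efron-tie partial likelihood (Breslow selectable) and
#' reports per-covariate hazard ratios with 95% Wald intervals. Refuses
#' constant covariates and models with more covariates than events;
#' coefficients whose estimate or standard error diverge (monotone
#' likelihood / perfect separation) are flagged non-estimable.
#'
#' @param time,event as in [km_curve()].
#' @param covariates data.frame of covariates (numeric, or factors which
#'   are dummy-expanded); rows aligned with `time`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_result`: data.frame with `term`, `coef`,
#'   `hr`, `ci_lower`, `ci_upper`, `z`, `p_value`, `non_estimable`;
#'   attributes `loglik` (model log partial likelihood), `ties`, `n`,
#'   `n_event`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  event <- check_surv(time, event)
  covariates <- as.data.frame(covariates)
  if (!nrow(covariates) || nrow(covariates) != length(time))
    stop("covariates must have one row per record")
  cc <- stats::complete.cases(covariates) & !is.na(time)
  covariates <- droplevels(covariates[cc, , drop = FALSE])
  time <- time[cc]; event <- event[cc]
  const <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const], collapse = ", "))
  X <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  if (sum(event) < ncol(X)) {
    warning("fewer events (", sum(event), ") than covariate terms (",
            ncol(X), "); refusing to fit")
    stop("under-determined Cox model")
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ X, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- colnames(X)   # summary rows follow design-matrix column order
  non_est <- !is.finite(co[, "se(coef)"]) | co[, "se(coef)"] > 100 |
    abs(co[, "coef"]) > 15
  res <- data.frame(term = terms, coef = co[, "coef"],
                    hr = exp(co[, "coef"]),
                    ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    z = co[, "z"], p_value = co[, "Pr(>|z|)"],
                    non_estimable = non_est,
                    stringsAsFactors = FALSE)
  if (any(non_est))
    warning("non-estimable coefficient(s) (diverging likelihood): ",
            paste(terms[non_est], collapse = ", "))
  rownames(res) <- NULL
  structure(res, class = c("cox_result", "data.frame"),
            loglik = fit$loglik[2L], ties = ties, n = length(time),
            n_event = sum(event))
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox PH (", attr(x, "ties"), " ties): n = ", attr(x, "n"),
      ", events = ", attr(x, "n_event"), "\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Stratify samples by a score
#'
#' Median rule: low = score <= cohort median, high = above (ties at the
#' cutoff go low). Tertile rule: three bins at the empirical tertiles
#' (again with <= at each cutoff); `combine_upper = TRUE` merges the
#' intermediate and high bins into a single "high" stratum, giving a
#' lowest-tertile-versus-rest contrast.
#'
#' @param scores named numeric vector (sample -> score); NAs allowed and
#'   returned as NA strata.
#' @param rule `"median"` or `"tertile"`.
#' @param combine_upper merge intermediate+high (tertile rule only).
#' @return list of class `strata_assignment`: `stratum` (named factor),
#'   `rule`, `cutoffs`.
#' @export
stratify <- function(scores, rule = c("median", "tertile"),
                     combine_upper = FALSE) {
  rule <- match.arg(rule)
  obs <- scores[!is.na(scores)]
  need <- if (rule == "median") 2L else 3L
  if (length(obs) < need)
    stop("need at least ", need, " non-missing scores for the ", rule, " rule")
  if (stats::sd(obs) == 0) stop("all scores equal; no informative split")
  if (rule == "median") {
    cut <- stats::median(obs)
    lab <- ifelse(scores <= cut, "low", "high")
    cutoffs <- c(median = cut)
    levels <- c("low", "high")
  } else {
    cutoffs <- stats::quantile(obs, c(1, 2) / 3, names = FALSE)
    lab <- ifelse(scores <= cutoffs[1L], "low",
                  ifelse(scores <= cutoffs[2L], "intermediate", "high"))
    names(cutoffs) <- c("tertile1", "tertile2")
    levels <- c("low", "intermediate", "high")
    if (combine_upper) {
      lab[lab %in% c("intermediate", "high")] <- "high"
      levels <- c("low", "high")
    }
  }
  stratum <- factor(lab, levels = levels)
  names(stratum) <- names(scores)
  structure(list(stratum = stratum, rule = rule, cutoffs = cutoffs,
                 combine_upper = combine_upper),
            class = "strata_assignment")
}

#' @export
print.strata_assignment <- function(x, ...) {
  cat("strata (", x$rule, " rule): ", sep = "")
  print(table(x$stratum))
  invisible(x)
}

# Univariable preselection of clinical covariates for multivariable
# models: keep covariates with Wald p < alpha in one-covariate fits.
uva_preselect <- function(time, event, covariates, alpha = 0.05) {
  keep <- character(0)
  for (v in names(covariates)) {
    x <- covariates[[v]]
    ok <- !is.na(x) & !is.na(time)
    if (length(unique(x[ok])) < 2L) next
    fit <- try(cox_fit(time[ok], event[ok],
                       stats::setNames(data.frame(x[ok]), v)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (any(fit$p_value < alpha & !fit$non_estimable, na.rm = TRUE))
      keep <- c(keep, v)
  }
  keep
}
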