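# Gene-set-level patient scores and the two-stage prognostic screen.

#' Per-sample median scores for a gene-set collection
#'
#' For each sample and each set, the median of the observed log2
#' abundances of the set's members present in the matrix. Sets with no
#' member in the matrix are excluded with a warning; a sample with no
#' observed member of a set scores NA.
#'
#' @param matrix abundance matrix.
#' @param collection named list of gene sets.
#' @return samples x sets numeric matrix; attribute `membership` holds
#'   the post-intersection member lists.
#' @export
geneset_median_score <- function(matrix, collection) {
  validate_abundance(matrix)
  members <- lapply(collection, intersect, x = rownames(matrix))
  empty <- !vapply(members, length, integer(1))
  if (any(empty)) {
    warning("excluded set(s) with no members in the matrix: ",
            paste(names(collection)[empty], collapse = ", "))
    members <- members[!empty]
  }
  if (!length(members)) stop("no gene set intersects the matrix")
  out <- vapply(members, function(g) {
    apply(matrix[g, , drop = FALSE], 2L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else stats::median(v)
    })
  }, numeric(ncol(matrix)))
  if (is.null(dim(out)))
    out <- matrix(out, ncol = length(members),
                  dimnames = list(colnames(matrix), names(members)))
  attr(out, "membership") <- members
  out
}

#' Per-sample ssGSEA scores for a gene-set collection
#'
#' Delegates to [ssgsea_matrix()]; returned in the same samples x sets
#' orientation as [geneset_median_score()].
#'
#' @inheritParams geneset_median_score
#' @param alpha ssGSEA exponent.
#' @param normalize per-sample range normalization (default off so that
#'   single-set scoring is well defined; see [ssgsea_matrix()]).
#' @return samples x sets numeric matrix of enrichment scores.
#' @export
geneset_ssgsea_score <- function(matrix, collection, alpha = 0.75,
                                 normalize = FALSE) {
  t(ssgsea_matrix(matrix, collection, alpha = alpha, normalize = normalize))
}

#' Two-stage prognostic screen of gene-set scores
#'
#' Stage 1: each set is scored per patient (median or ssGSEA rule), the
#' cohort is split at the median score, and a log-rank test is run per
#' endpoint; a set passes when any endpoint gives p < alpha. Stage 2:
#' passing sets enter a multivariable Cox model (high-vs-low stratum
#' indicator plus clinical covariates preselected by univariable
#' significance at p < 0.05); a set is retained when its stratum term
#' stays significant (p < alpha) for at least one passing endpoint.
#' Endpoints missing for more than `max_missing` of samples are skipped
#' with a warning.
#'
#' @param matrix abundance matrix.
#' @param collection named list of gene sets.
#' @param clinical clinical table (see [read_clinical()]) with endpoint
#'   columns.
#' @param endpoints endpoint labels to screen (default OS, LRFS, MFS).
#' @param alpha significance level for both stages (default 0.05).
#' @param score_rule `"median"` or `"ssgsea"`.
#' @param covariates clinical covariate columns for stage 2 (default:
#'   the intersection of `age`, `grade`, `subtype`, `site`, `tumor_size`,
#'   `depth`, `margins`, `sex`, `performance_status` with the table).
#' @param uva_preselect_covariates apply the univariable p < 0.05
#'   preselection before the multivariable fit (default TRUE).
#' @param p_adjust_stage1 optional multiplicity adjustment across sets at
#'   stage 1 (default `"none"`, matching raw log-rank filtering; `"BH"`
#'   available).
#' @param max_missing maximum tolerated fraction of samples missing an
#'   endpoint (default 0.2).
#' @return list of class `screen_report`: `table` (one row per set x
#'   endpoint with log-rank p, stage-1 flag, MVA HR/CI/p, retained flag),
#'   `retained` (set names), `scores`, `strata` (list per set),
#'   `covariates_used` (list per endpoint).
#' @export
prognostic_screen <- function(matrix, collection, clinical,
                              endpoints = c("OS", "LRFS", "MFS"),
                              alpha = 0.05,
                              score_rule = c("median", "ssgsea"),
                              covariates = NULL,
                              uva_preselect_covariates = TRUE,
                              p_adjust_stage1 = c("none", "BH"),
                              max_missing = 0.2) {
  score_rule <- match.arg(score_rule)
  p_adjust_stage1 <- match.arg(p_adjust_stage1)
  bad <- setdiff(endpoints, ENDPOINT_LABELS)
  if (length(bad)) stop("unknown endpoint(s): ", paste(bad, collapse = ", "))
  scores <- if (score_rule == "median")
    geneset_median_score(matrix, collection)
  else geneset_ssgsea_score(matrix, collection)
  cl <- clinical[match(rownames(scores), clinical$sample_id), , drop = FALSE]
  if (is.null(covariates))
    covariates <- intersect(c("age", "grade", "subtype", "site", "tumor_size",
                              "depth", "margins", "sex", "performance_status"),
                            names(cl))

  usable_ep <- character(0)
  for (ep in endpoints) {
    tc <- paste0(ep, "_time"); ec <- paste0(ep, "_event")
    if (!tc %in% names(cl) || !ec %in% names(cl)) {
      warning("endpoint ", ep, " not present in clinical table; skipped")
      next
    }
    if (mean(is.na(cl[[tc]]) | is.na(cl[[ec]])) > max_missing) {
      warning("endpoint ", ep, " missing for >", 100 * max_missing,
              "% of samples; skipped")
      next
    }
    usable_ep <- c(usable_ep, ep)
  }
  if (!length(usable_ep)) stop("no usable endpoint")

  strata <- lapply(colnames(scores), function(nm)
    stratify(stats::setNames(scores[, nm], rownames(scores)), rule = "median"))
  names(strata) <- colnames(scores)

  # stage 1: log-rank per set x endpoint
  s1 <- do.call(rbind, lapply(colnames(scores), function(nm) {
    st <- strata[[nm]]$stratum
    do.call(rbind, lapply(usable_ep, function(ep) {
      tv <- cl[[paste0(ep, "_time")]]; ev <- cl[[paste0(ep, "_event")]]
      ok <- !is.na(tv) & !is.na(ev) & !is.na(st)
      lr <- log_rank(tv[ok], ev[ok], st[ok])
      data.frame(set = nm, endpoint = ep, logrank_p = lr$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (p_adjust_stage1 == "BH")
    s1$logrank_p_adj <- stats::ave(s1$logrank_p, s1$endpoint,
                                   FUN = function(p) stats::p.adjust(p, "BH"))
  p_used <- if (p_adjust_stage1 == "BH") s1$logrank_p_adj else s1$logrank_p
  s1$pass_stage1 <- p_used < alpha

  # stage 2: MVA Cox for passing set x endpoint pairs
  cov_used <- list()
  s1$mva_hr <- NA_real_; s1$mva_ci_lower <- NA_real_
  s1$mva_ci_upper <- NA_real_; s1$mva_p <- NA_real_
  for (i in which(s1$pass_stage1)) {
    nm <- s1$set[i]; ep <- s1$endpoint[i]
    tv <- cl[[paste0(ep, "_time")]]; ev <- cl[[paste0(ep, "_event")]]
    st <- strata[[nm]]$stratum
    ok <- !is.na(tv) & !is.na(ev) & !is.na(st)
    covs <- cl[ok, covariates, drop = FALSE]
    # lump rare factor levels (< 5 cases) into "other": levels that thin
    # produce monotone partial likelihoods and spurious non-estimability
    for (v in names(covs)) {
      x <- covs[[v]]
      if (is.character(x) || is.factor(x)) {
        x <- as.character(x)
        tb <- table(x)
        x[x %in% names(tb)[tb < 5L]] <- "other"
        covs[[v]] <- x
      }
    }
    # drop covariates that are constant or mostly missing on this subset
    covs <- covs[, vapply(covs, function(v)
      length(unique(v[!is.na(v)])) > 1L && mean(is.na(v)) <= 0.5,
      logical(1)), drop = FALSE]
    if (uva_preselect_covariates && ncol(covs)) {
      keep <- uva_preselect(tv[ok], ev[ok], covs, alpha = 0.05)
      covs <- covs[, keep, drop = FALSE]
    }
    cov_used[[paste(nm, ep, sep = ".")]] <- names(covs)
    X <- cbind(data.frame(score_stratum = st[ok]), covs)
    fit <- try(cox_fit(tv[ok], ev[ok], X), silent = TRUE)
    if (inherits(fit, "try-error")) next
    row <- fit[fit$term == "score_stratumhigh", , drop = FALSE]
    if (!nrow(row)) next
    s1$mva_hr[i] <- row$hr
    s1$mva_ci_lower[i] <- row$ci_lower
    s1$mva_ci_upper[i] <- row$ci_upper
    s1$mva_p[i] <- row$p_value
  }
  retained_tab <- stats::aggregate(
    cbind(pass = pass_stage1 & !is.na(mva_p) & mva_p < alpha) ~ set,
    data = s1, FUN = any)
  s1$retained <- retained_tab$pass[match(s1$set, retained_tab$set)]
  structure(list(table = s1,
                 retained = retained_tab$set[retained_tab$pass],
                 scores = scores, strata = strata,
                 covariates_used = cov_used,
                 params = list(endpoints = usable_ep, alpha = alpha,
                               score_rule = score_rule,
                               p_adjust_stage1 = p_adjust_stage1)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("prognostic screen (", x$params$score_rule, " rule, alpha = ",
      x$params$alpha, ")\n", sep = "")
  print.data.frame(x$table, digits = 3)
  cat("retained:", if (length(x$retained))
    paste(x$retained, collapse = ", ") else "none", "\n")
  invisible(x)
}
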