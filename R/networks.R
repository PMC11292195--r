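# Coregulated-network discovery: correlation similarity, Monti consensus
# clustering with PAC model selection, SigClust, cluster scores, and
# clinical association tests.

#' Pairwise-complete Pearson similarity between proteins
#'
#' Computes the protein-protein Pearson correlation over jointly observed
#' samples. Pairs with fewer than `min_pairs` joint observations are
#' masked (`NA`). Proteins with zero variance on their observed support
#' have their whole row/column masked rather than propagating NaN. The
#' diagonal is set to 1.
#'
#' @param matrix abundance matrix (proteins x samples), >=3 samples.
#' @param min_pairs minimum joint observations per pair (default 10).
#' @return list of class `similarity_matrix`: `r` (symmetric correlation
#'   matrix), `pair_n` (joint-observation counts), `masked_items`
#'   (zero-variance proteins).
#' @export
correlation_similarity <- function(matrix, min_pairs = 10) {
  validate_abundance(matrix)
  if (ncol(matrix) < 3L) stop("need at least 3 samples")
  x <- t(matrix)                                  # samples x proteins
  obs <- !is.na(x)
  pair_n <- crossprod(obs)
  suppressWarnings(r <- stats::cor(x, use = "pairwise.complete.obs"))
  r[pair_n < min_pairs] <- NA
  zero_var <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[obs[, j], j]
    length(v) < 2L || stats::sd(v) == 0
  }, logical(1))
  if (any(zero_var)) {
    message(sum(zero_var), " zero-variance protein(s) masked in similarity matrix")
    r[zero_var, ] <- NA
    r[, zero_var] <- NA
  }
  diag(r) <- 1
  structure(list(r = r, pair_n = pair_n,
                 masked_items = colnames(x)[zero_var]),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix:", nrow(x$r), "items;",
      sum(is.na(x$r[upper.tri(x$r)])), "masked pairs\n")
  invisible(x)
}

# distance matrix for the inner clusterer: 1 - r for similarity input,
# Euclidean over features otherwise. NA distances (masked pairs) are
# imputed at the maximum observed distance so hclust stays defined.
consensus_dist <- function(data) {
  if (inherits(data, "similarity_matrix")) {
    d <- 1 - data$r
    d[is.na(d)] <- max(d, na.rm = TRUE)
    stats::as.dist(d)
  } else {
    stats::dist(data)
  }
}

consensus_items <- function(data) {
  if (inherits(data, "similarity_matrix")) rownames(data$r) else rownames(data)
}

#' Consensus clustering with PAC model selection
#'
#' Monti-style consensus clustering: for each of `n_resamples` resamples,
#' a random `subsample_fraction` of items is drawn without replacement
#' and clustered by hierarchical clustering (distance 1 - r when `data`
#' is a [correlation_similarity()] result, Euclidean over features
#' otherwise) cut at each k in `k_range`. The consensus matrix entry
#' (i, j) is the fraction of co-sampled resamples in which i and j fell
#' in the same cluster.
#'
#' k selection uses PAC (proportion of ambiguous clustering: off-diagonal
#' consensus values inside `(pac_lower, pac_upper)`) with the consensus-CDF
#' area as tie-breaker. A plain PAC minimum is degenerate when a coarser
#' k merges whole clusters consistently (PAC is then 0 for the coarse and
#' the true k alike), so the rule is: restrict to "stable" k with
#' PAC <= `pac_stable`; among those, keep k whose relative gain in the
#' area under the consensus-value CDF over k-1 is at least `delta_min`
#' (the first k in range always qualifies); choose the largest such k.
#' If no k is stable, fall back to the PAC minimum. The result is flagged
#' `no_stable_structure` when the minimum PAC exceeds `stable_pac_max`.
#' The final assignment is a hierarchical cut of 1 - consensus at the
#' chosen k.
#'
#' @param data items-by-features matrix, or a `similarity_matrix`.
#' @param k_range candidate cluster numbers (default 2:8).
#' @param n_resamples number of subsampling iterations (default 1000).
#' @param subsample_fraction fraction of items per resample (default 0.8).
#' @param linkage hclust linkage (default "average").
#' @param seed RNG seed.
#' @param pac_lower,pac_upper ambiguity band for PAC (defaults 0.1, 0.9).
#' @param pac_stable PAC level below which a k counts as stable for
#'   selection (default 0.1).
#' @param delta_min minimum relative consensus-CDF area gain for a k to
#'   supersede k-1 (default 0.1).
#' @param stable_pac_max if the minimum PAC exceeds this, the result is
#'   flagged `no_stable_structure` (default 0.2).
#' @param fixed_k optional: skip selection and report this k
#'   (reproduction mode).
#' @return list of class `consensus_result`: `consensus` (list of
#'   matrices per k), `pac` (named vector), `cdf_area` (named vector),
#'   `chosen_k`, `assignments` (named integer vector),
#'   `no_stable_structure`, `resample_log`.
#' @export
consensus_cluster <- function(data, k_range = 2:8, n_resamples = 1000,
                              subsample_fraction = 0.8, linkage = "average",
                              seed = 1, pac_lower = 0.1, pac_upper = 0.9,
                              pac_stable = 0.1, delta_min = 0.1,
                              stable_pac_max = 0.2, fixed_k = NULL) {
  items <- consensus_items(data)
  n <- length(items)
  if (is.null(items)) stop("data must carry item names")
  if (any(k_range < 1L)) stop("k_range must be >= 1")
  if (all(k_range == 1L))
    stop("k_range = {1} gives an all-ones consensus; cannot select k")
  k_range <- sort(unique(k_range[k_range >= 2L]))
  if (n < max(k_range) + 2L) stop("need at least max(k_range)+2 items")
  if (n_resamples < 2L) stop("n_resamples must be >= 2")

  d_full <- as.matrix(consensus_dist(data))
  m_sub <- max(2L, round(subsample_fraction * n))
  set.seed(seed)
  hit <- matrix(0, n, n)                       # co-sampled counts
  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  for (b in seq_len(n_resamples)) {
    ix <- sort(sample.int(n, m_sub))
    hit[ix, ix] <- hit[ix, ix] + 1
    hc <- stats::hclust(stats::as.dist(d_full[ix, ix]), method = linkage)
    for (k in k_range) {
      cl <- stats::cutree(hc, k = k)
      same <- outer(cl, cl, "==") * 1
      kk <- as.character(k)
      conn[[kk]][ix, ix] <- conn[[kk]][ix, ix] + same
    }
  }
  consensus <- lapply(conn, function(cm) {
    out <- ifelse(hit > 0, cm / hit, 0)
    diag(out) <- 1
    dimnames(out) <- list(items, items)
    out
  })
  off <- upper.tri(consensus[[1L]])
  pac <- vapply(consensus, function(cm) {
    v <- cm[off]
    mean(v > pac_lower & v < pac_upper)
  }, numeric(1))
  # area under the empirical CDF of off-diagonal consensus values
  cdf_area <- vapply(consensus, function(cm) {
    v <- sort(cm[off])
    sum(diff(c(0, v, 1)) * c(0, seq_along(v) / length(v)))
  }, numeric(1))
  delta <- c(Inf, diff(cdf_area) / utils::head(cdf_area, -1L))
  chosen_k <- if (!is.null(fixed_k)) {
    if (!fixed_k %in% k_range) stop("fixed_k must be in k_range")
    fixed_k
  } else {
    cand <- k_range[pac <= pac_stable & delta >= delta_min]
    if (length(cand)) max(cand) else k_range[which.min(pac)]
  }
  no_stable <- min(pac) > stable_pac_max
  if (no_stable) message("no stable structure: min PAC = ", signif(min(pac), 3))
  cm <- consensus[[as.character(chosen_k)]]
  hc_final <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
  assignments <- stats::cutree(hc_final, k = chosen_k)
  names(assignments) <- items
  structure(list(consensus = consensus, pac = pac, cdf_area = cdf_area,
                 chosen_k = chosen_k,
                 assignments = assignments, no_stable_structure = no_stable,
                 resample_log = list(n_resamples = n_resamples,
                                     subsample_fraction = subsample_fraction,
                                     linkage = linkage, seed = seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result: chosen k =", x$chosen_k, "| PAC:",
      paste(sprintf("k%s=%.3f", names(x$pac), x$pac), collapse = " "), "\n")
  if (x$no_stable_structure) cat("  flagged: no stable structure\n")
  invisible(x)
}

# 2-means cluster index: within-cluster SS / total SS about the grand mean.
cluster_index_2means <- function(x, nstart = 10) {
  km <- stats::kmeans(x, centers = 2L, nstart = nstart)
  tot <- sum(scale(x, scale = FALSE)^2)
  km$tot.withinss / tot
}

#' SigClust: significance of a 2-cluster split
#'
#' Tests the null hypothesis that the rows of `data` come from a single
#' multivariate Gaussian. The statistic is the 2-means cluster index
#' (within-cluster sum of squares over total). The null is simulated
#' from a zero-mean Gaussian with diagonal covariance equal to the
#' eigenvalues of the sample covariance, hard-thresholded from below at
#' a background-noise variance estimated as the squared MAD of all
#' (median-centred) data values. p is the fraction of null cluster
#' indices at or below the observed one.
#'
#' @param data items x features numeric matrix (>= 10 items).
#' @param n_sim null simulations (default 1000; < 100 draws a warning).
#' @param seed RNG seed.
#' @return list of class `sigclust_result`: `p_value`, `ci_observed`,
#'   `ci_null`, `eigenvalues` (thresholded), `sigma2_background`.
#' @export
sigclust <- function(data, n_sim = 1000, seed = 1) {
  data <- as.matrix(data)
  if (nrow(data) < 10L) stop("SigClust needs at least 10 items")
  if (anyNA(data)) stop("SigClust input must be complete")
  if (n_sim < 100L)
    warning("n_sim < 100: p-value resolution is only 1/", n_sim)
  sig2 <- stats::mad(as.vector(data))^2
  ev <- eigen(stats::cov(data), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, sig2)
  set.seed(seed)
  ci_obs <- cluster_index_2means(data)
  n <- nrow(data); p <- ncol(data)
  ci_null <- vapply(seq_len(n_sim), function(s) {
    sim <- matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(ev), p)
    cluster_index_2means(sim)
  }, numeric(1))
  pv <- mean(ci_null <= ci_obs)
  structure(list(p_value = pv, ci_observed = ci_obs, ci_null = ci_null,
                 eigenvalues = ev, sigma2_background = sig2),
            class = "sigclust_result")
}

#' @export
print.sigclust_result <- function(x, ...) {
  cat("SigClust: CI =", signif(x$ci_observed, 4), "p =",
      format.pval(x$p_value), "(", length(x$ci_null), "simulations )\n")
  invisible(x)
}

#' Restrict a similarity matrix to coregulated proteins
#'
#' Coregulated-network discovery is only meaningful for proteins that
#' correlate with something: items whose largest absolute off-diagonal
#' correlation falls below `min_abs_cor` behave as outliers under
#' hierarchical consensus clustering (each peeled cut is spent on a
#' noise singleton and genuine programs merge). This filter drops such
#' items before clustering.
#'
#' @param sim a [correlation_similarity()] result.
#' @param min_abs_cor minimum largest |r| with any partner (default 0.4).
#' @return the filtered `similarity_matrix`; dropped items recorded in
#'   the `dropped_items` element.
#' @export
filter_similarity <- function(sim, min_abs_cor = 0.4) {
  stopifnot(inherits(sim, "similarity_matrix"))
  r <- sim$r
  diag(r) <- NA
  top <- apply(abs(r), 1L, max, na.rm = TRUE)
  keep <- names(top)[!is.na(top) & top >= min_abs_cor &
                       !names(top) %in% sim$masked_items]
  dropped <- setdiff(rownames(sim$r), keep)
  if (length(dropped))
    message(length(dropped), " protein(s) without a correlate at |r| >= ",
            min_abs_cor, " excluded from network discovery")
  structure(list(r = sim$r[keep, keep, drop = FALSE],
                 pair_n = sim$pair_n[keep, keep, drop = FALSE],
                 masked_items = character(0), dropped_items = dropped),
            class = "similarity_matrix")
}

#' Per-sample median scores of protein clusters
#'
#' For each sample and each cluster, the median of the observed log2
#' abundances of the cluster's member proteins. A cluster with no
#' observed member in a sample yields `NA`.
#'
#' @param matrix abundance matrix.
#' @param assignments named vector (protein -> cluster id) as from
#'   [consensus_cluster()].
#' @return samples x clusters numeric matrix of median scores.
#' @export
cluster_median_scores <- function(matrix, assignments) {
  validate_abundance(matrix)
  members <- split(names(assignments), assignments)
  members <- lapply(members, intersect, x = rownames(matrix))
  members <- Filter(length, members)
  if (!length(members)) stop("no cluster has members present in the matrix")
  out <- vapply(members, function(g) {
    apply(matrix[g, , drop = FALSE], 2L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else stats::median(v)
    })
  }, numeric(ncol(matrix)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(members),
                                       dimnames = list(colnames(matrix),
                                                       names(members)))
  colnames(out) <- paste0("C", colnames(out))
  out
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie-corrected variance,
#' two-sided normal p-values, BH-adjusted across pairs.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @param p_adjust_method multiplicity adjustment (default "BH").
#' @return data.frame: `group1`, `group2`, `z`, `p_value`, `q_value`.
#' @export
dunn_test <- function(x, g, p_adjust_method = "BH") {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok], exclude = NULL)
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need >=2 groups")
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(g), 2L, simplify = FALSE)
  res <- do.call(rbind, lapply(pairs, function(pp) {
    i <- pp[1L]; j <- pp[2L]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    data.frame(group1 = i, group2 = j, z = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  res$q_value <- stats::p.adjust(res$p_value, method = p_adjust_method)
  rownames(res) <- NULL
  res
}

#' Associate cluster scores with grade and subtype
#'
#' Grade: two-sided Mann-Whitney per cluster between grade 2 and grade 3
#' cases (desmoid cases and ungraded cases excluded). Subtype:
#' Kruskal-Wallis across subtypes plus Dunn pairwise tests with BH
#' adjustment; subtype levels with fewer than `min_level_n` samples are
#' excluded from the pairwise stage.
#'
#' @param scores samples x clusters score matrix
#'   (from [cluster_median_scores()]); rownames are sample ids.
#' @param clinical clinical data.frame with `sample_id`, `grade`,
#'   `subtype` columns.
#' @param desmoid_label subtype label identifying desmoid cases
#'   (default "DES").
#' @param min_level_n minimum per-level size for pairwise tests (default 3).
#' @return list with data.frames `grade` (cluster, n2, n3, direction, p)
#'   and `subtype` (cluster, kw_p) plus `subtype_pairwise` (Dunn table
#'   per cluster).
#' @export
associate_scores <- function(scores, clinical, desmoid_label = "DES",
                             min_level_n = 3) {
  cl <- clinical[match(rownames(scores), clinical$sample_id), ]
  grade_tab <- do.call(rbind, lapply(colnames(scores), function(cc) {
    keep <- !is.na(cl$grade) & cl$grade %in% c(2, 3) &
      !is.na(cl$subtype) & cl$subtype != desmoid_label
    s <- scores[keep, cc]; gr <- cl$grade[keep]
    ok <- !is.na(s)
    s <- s[ok]; gr <- gr[ok]
    if (length(unique(gr)) < 2L)
      return(data.frame(cluster = cc, n2 = sum(gr == 2), n3 = sum(gr == 3),
                        direction = NA_character_, p_value = NA_real_))
    w <- suppressWarnings(stats::wilcox.test(s[gr == 3], s[gr == 2]))
    data.frame(cluster = cc, n2 = sum(gr == 2), n3 = sum(gr == 3),
               direction = if (stats::median(s[gr == 3]) >=
                               stats::median(s[gr == 2])) "up_in_3" else "down_in_3",
               p_value = w$p.value, stringsAsFactors = FALSE)
  }))
  subtype_tab <- list(); pairwise <- list()
  for (cc in colnames(scores)) {
    s <- scores[, cc]; st <- cl$subtype
    ok <- !is.na(s) & !is.na(st)
    kw <- stats::kruskal.test(s[ok], factor(st[ok]))$p.value
    subtype_tab[[cc]] <- data.frame(cluster = cc, kw_p = kw)
    lv <- table(st[ok])
    keep_lv <- names(lv)[lv >= min_level_n]
    if (length(lv) > length(keep_lv))
      message("excluded from pairwise tests (n < ", min_level_n, "): ",
              paste(setdiff(names(lv), keep_lv), collapse = ", "))
    sub <- ok & st %in% keep_lv
    pairwise[[cc]] <- if (length(keep_lv) >= 2L)
      dunn_test(s[sub], st[sub]) else NULL
  }
  list(grade = grade_tab, subtype = do.call(rbind, subtype_tab),
       subtype_pairwise = pairwise)
}

#' Associate sample subgroups with clinical variables
#'
#' Categorical variables are tested by the chi-square test of
#' independence against the subgroup labels; continuous variables by
#' Kruskal-Wallis. Variables named in `til_vars` (raw TIL densities) are
#' dichotomised at the cohort median (<= median is "low") before the
#' chi-square test. Expected-cell-count warnings are captured and
#' reported in the output, not raised.
#'
#' @param subgroups named vector sample -> subgroup label.
#' @param clinical clinical data.frame (`sample_id` plus variables).
#' @param variables columns of `clinical` to test (default: all except
#'   `sample_id` and endpoint columns).
#' @param til_vars variables to median-dichotomise first.
#' @return data.frame: `variable`, `test`, `statistic`, `p_value`, `note`.
#' @export
associate_clinical <- function(subgroups, clinical, variables = NULL,
                               til_vars = character(0)) {
  cl <- clinical[match(names(subgroups), clinical$sample_id), ]
  if (is.null(variables))
    variables <- setdiff(names(cl),
                         c("sample_id", grep("_(time|event)$", names(cl),
                                             value = TRUE)))
  g <- factor(subgroups)
  rows <- lapply(variables, function(v) {
    x <- cl[[v]]
    note <- ""
    if (v %in% til_vars) {
      med <- stats::median(x, na.rm = TRUE)
      x <- ifelse(x <= med, "low", "high")
      note <- sprintf("dichotomised at median %.3g", med)
    }
    ok <- !is.na(x)
    if (is.numeric(x) && !v %in% til_vars && length(unique(x[ok])) > 6L) {
      kw <- stats::kruskal.test(x[ok], g[ok])
      return(data.frame(variable = v, test = "kruskal-wallis",
                        statistic = unname(kw$statistic), p_value = kw$p.value,
                        note = note, stringsAsFactors = FALSE))
    }
    xf <- factor(x[ok])
    if (nlevels(xf) < 2L || length(unique(g[ok])) < 2L)
      return(data.frame(variable = v, test = "chi-square", statistic = NA_real_,
                        p_value = NA_real_, note = "single-level; skipped",
                        stringsAsFactors = FALSE))
    warned <- FALSE
    cs <- withCallingHandlers(
      stats::chisq.test(table(g[ok], xf), correct = FALSE),
      warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
    data.frame(variable = v, test = "chi-square",
               statistic = unname(cs$statistic), p_value = cs$p.value,
               note = paste0(note, if (warned) " low expected cell counts"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
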