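# Group-wise differential abundance on log2 intensities.

# Welch t-test of x vs y returning (delta, p); NULL when either arm has
# fewer than 2 observed values or both arms are constant.
welch_row <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NULL)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: identical constants give p = 1, shifted constants p = 0
    return(list(delta = mean(x) - mean(y),
                p = if (mean(x) == mean(y)) 1 else 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(delta = mean(x) - mean(y), p = tt$p.value)
}

de_core <- function(matrix, in_a, in_b, group_label, fdr, lfc,
                    min_frac_observed = 0.5) {
  validate_abundance(matrix)
  res <- data.frame(protein = rownames(matrix), group_label = group_label,
                    delta_log2 = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  excluded <- character(0)
  for (i in seq_len(nrow(matrix))) {
    xa <- matrix[i, in_a]; xb <- matrix[i, in_b]
    if (mean(!is.na(xa)) < min_frac_observed ||
        mean(!is.na(xb)) < min_frac_observed) {
      excluded <- c(excluded, rownames(matrix)[i]); next
    }
    w <- welch_row(xa, xb)
    if (is.null(w)) { excluded <- c(excluded, rownames(matrix)[i]); next }
    res$delta_log2[i] <- w$delta
    res$p_value[i] <- w$p
  }
  if (length(excluded))
    message(length(excluded), " protein(s) excluded (insufficient observed values)")
  tested <- !is.na(res$p_value)
  res$q_value <- NA_real_
  res$q_value[tested] <- stats::p.adjust(res$p_value[tested], method = "BH")
  res$direction <- ifelse(is.na(res$delta_log2), NA_character_,
                          ifelse(res$delta_log2 >= 0, "up", "down"))
  res$upregulated <- !is.na(res$q_value) & res$q_value < fdr &
    res$delta_log2 >= lfc
  attr(res, "excluded") <- excluded
  res
}

#' One-vs-rest differential abundance for one group
#'
#' Per-protein Welch t-test of one group against all other samples on the
#' observed log2 values. A protein is flagged `upregulated` when its BH
#' q-value is below `fdr` and its mean log2 difference is at least `lfc`
#' (defaults q < 0.01 and delta >= 1, i.e. fold change >= 2, both
#' thresholds inclusive on the effect side). Proteins with under half of
#' values observed in either arm, or fewer than two observations in an
#' arm, are excluded and reported via the `excluded` attribute.
#'
#' @param matrix abundance matrix.
#' @param labels character vector of group labels, one per sample
#'   (in column order).
#' @param group the group to contrast against the rest.
#' @param min_n minimum group size (default 20); smaller groups are refused.
#' @param fdr,lfc significance and effect thresholds.
#' @return data.frame with columns `protein`, `group_label`, `delta_log2`,
#'   `p_value`, `q_value`, `direction`, `upregulated`.
#' @export
one_vs_rest_de <- function(matrix, labels, group, min_n = 20,
                           fdr = 0.01, lfc = 1) {
  if (length(labels) != ncol(matrix))
    stop("labels must have one entry per sample column")
  in_a <- labels == group
  if (sum(in_a) < min_n)
    stop("group '", group, "' has ", sum(in_a),
         " samples; minimum required is ", min_n)
  de_core(matrix, in_a, !in_a, group, fdr, lfc)
}

#' Proteins uniquely upregulated in each group
#'
#' Runs [one_vs_rest_de()] for every eligible group; a protein is unique
#' to group g iff it is flagged upregulated in g's test and in no other
#' eligible group's test. The returned sets are pairwise disjoint.
#'
#' @inheritParams one_vs_rest_de
#' @param eligible_groups groups to test (default: all groups with at
#'   least `min_n` samples).
#' @return named list of character vectors (one per eligible group), with
#'   attribute `per_group` holding the full per-group DE tables.
#' @export
unique_upregulation <- function(matrix, labels, eligible_groups = NULL,
                                min_n = 20, fdr = 0.01, lfc = 1) {
  if (is.null(eligible_groups)) {
    tb <- table(labels)
    eligible_groups <- names(tb)[tb >= min_n]
  }
  if (length(eligible_groups) < 2L)
    stop("need at least 2 eligible groups")
  tabs <- lapply(eligible_groups, function(g)
    one_vs_rest_de(matrix, labels, g, min_n = min_n, fdr = fdr, lfc = lfc))
  names(tabs) <- eligible_groups
  up <- lapply(tabs, function(t) t$protein[t$upregulated])
  n_up <- table(unlist(up))
  uniq <- lapply(up, function(g) g[n_up[g] == 1L])
  attr(uniq, "per_group") <- tabs
  uniq
}

#' Two-group differential abundance
#'
#' Same statistic and thresholds as [one_vs_rest_de()] with two arbitrary
#' sample arms; `upregulated` means higher in `group_a`.
#'
#' @param matrix abundance matrix.
#' @param group_a,group_b character vectors of sample ids (or logical
#'   masks over columns) defining the two arms.
#' @inheritParams one_vs_rest_de
#' @return per-protein DE table as in [one_vs_rest_de()].
#' @export
two_group_de <- function(matrix, group_a, group_b, fdr = 0.01, lfc = 1) {
  as_mask <- function(g) {
    if (is.logical(g)) return(g)
    colnames(matrix) %in% g
  }
  in_a <- as_mask(group_a); in_b <- as_mask(group_b)
  if (any(in_a & in_b)) stop("arms overlap")
  if (sum(in_a) < 2L || sum(in_b) < 2L) stop("each arm needs >=2 samples")
  de_core(matrix, in_a, in_b, "A_vs_B", fdr, lfc)
}

#' Stratum robustness check (Kruskal-Wallis across strata)
#'
#' Tests whether protein abundance differs across sample strata (e.g.
#' tumour-content bins): a Kruskal-Wallis test per protein plus one test
#' of the per-sample global median across strata. Strata with fewer than
#' 2 samples are merged into the adjacent stratum (by factor-level order)
#' with a warning.
#'
#' @param matrix abundance matrix.
#' @param strata_labels factor/character of stratum per sample.
#' @return list: `per_protein` data.frame (`protein`, `p_value`,
#'   `q_value`), `global` (the KW p for per-sample medians), `strata`
#'   (the labels actually used after merging).
#' @export
stratum_robustness <- function(matrix, strata_labels) {
  if (length(strata_labels) != ncol(matrix))
    stop("strata_labels must have one entry per sample column")
  f <- factor(strata_labels)
  if (nlevels(f) < 2L) stop("need at least 2 strata")
  tb <- table(f)
  while (any(tb < 2L) && nlevels(f) > 1L) {
    small <- which(tb < 2L)[1L]
    nbr <- if (small == 1L) 2L else small - 1L
    warning("stratum '", levels(f)[small], "' has <2 samples; merged into '",
            levels(f)[nbr], "'")
    levels(f)[small] <- levels(f)[nbr]
    tb <- table(f)
  }
  if (nlevels(f) < 2L) stop("fewer than 2 usable strata after merging")
  pv <- apply(matrix, 1L, function(x) {
    ok <- !is.na(x)
    if (length(unique(f[ok])) < 2L) return(NA_real_)
    stats::kruskal.test(x[ok], f[ok])$p.value
  })
  per_protein <- data.frame(protein = rownames(matrix), p_value = pv,
                            q_value = stats::p.adjust(pv, method = "BH"),
                            stringsAsFactors = FALSE)
  med <- apply(matrix, 2L, stats::median, na.rm = TRUE)
  global <- stats::kruskal.test(med, f)$p.value
  list(per_protein = per_protein, global = global, strata = f)
}

# pooled-variance SAM denominator s_i per protein (Tusher et al. form)
sam_s <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  pooled <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / (na + nb - 2)
  sqrt((1 / na + 1 / nb) * pooled)
}

sam_d_stats <- function(matrix, in_a, in_b, s0) {
  apply(matrix, 1L, function(x) {
    xa <- x[in_a]; xb <- x[in_b]
    (mean(xa) - mean(xb)) / (sam_s(xa, xb) + s0)
  })
}

#' Two-class SAM with permutation-estimated FDR
#'
#' Significance-analysis-of-microarrays statistic
#' d_i = (mean_A - mean_B) / (s_i + s0), where s_i is the pooled-variance
#' standard error and s0 a variance-stabilising fudge factor. The null
#' distribution of d comes from group-label permutations: all distinct
#' label assignments are enumerated when there are at most
#' `n_permutations` of them, otherwise a seeded random subset is used.
#' For each threshold delta (a grid over the observed |d|), the estimated
#' FDR is the median over permutations of the null exceedance count
#' divided by the observed exceedance count, clipped to [0, 1].
#'
#' @param matrix abundance matrix (no missing values in the tested rows).
#' @param labels two-level grouping, one per sample.
#' @param n_permutations permutation budget (default 1000).
#' @param seed RNG seed for the random-subset mode.
#' @param s0_strategy `"median"` (median of s_i, default), `"zero"`, or
#'   `"percentile"` (s0 scanned over s_i percentiles, minimising the
#'   coefficient of variation of the d spread).
#' @param delta threshold(s); default a 25-point grid over observed |d|.
#' @param fdr_cut FDR used to call the significant set (default 0.05).
#' @return list of class `sam_result`: `d` (named vector), `s0`,
#'   `fdr_table` (delta, n_significant, median FDR), `significant`
#'   (protein names at the smallest delta with FDR <= `fdr_cut`),
#'   `n_permutations_used`, `exhaustive`.
#' @export
sam_two_class <- function(matrix, labels, n_permutations = 1000, seed = 1,
                          s0_strategy = c("median", "zero", "percentile"),
                          delta = NULL, fdr_cut = 0.05) {
  s0_strategy <- match.arg(s0_strategy)
  validate_abundance(matrix)
  if (anyNA(matrix)) stop("sam_two_class requires complete rows (filter first)")
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two levels")
  in_a <- f == levels(f)[1L]
  if (sum(in_a) < 2L || sum(!in_a) < 2L) stop("each group needs >=2 samples")
  n <- length(labels); na <- sum(in_a)

  s_i <- apply(matrix, 1L, function(x) sam_s(x[in_a], x[!in_a]))
  s0 <- switch(s0_strategy,
    zero = 0,
    median = stats::median(s_i),
    percentile = {
      cand <- stats::quantile(s_i, seq(0, 1, by = 0.05), names = FALSE)
      cv <- vapply(cand, function(s0c) {
        d <- sam_d_stats(matrix, in_a, !in_a, s0c)
        sp <- split(d, cut(rank(s_i, ties.method = "first"),
                           breaks = 5, labels = FALSE))
        mads <- vapply(sp, stats::mad, numeric(1))
        stats::sd(mads) / max(mean(mads), .Machine$double.eps)
      }, numeric(1))
      cand[which.min(cv)]
    })

  d_obs <- sam_d_stats(matrix, in_a, !in_a, s0)

  combs <- choose(n, na)
  exhaustive <- combs <= n_permutations
  if (exhaustive) {
    idx <- utils::combn(n, na, simplify = FALSE)
  } else {
    set.seed(seed)
    idx <- replicate(n_permutations, sample.int(n, na), simplify = FALSE)
  }
  null_d <- vapply(idx, function(ia) {
    m <- logical(n); m[ia] <- TRUE
    sam_d_stats(matrix, m, !m, s0)
  }, numeric(nrow(matrix)))
  if (is.null(dim(null_d))) null_d <- matrix(null_d, nrow = nrow(matrix))

  if (is.null(delta)) {
    dd <- sort(unique(abs(d_obs)))
    delta <- if (length(dd) > 25L)
      stats::quantile(dd, seq(0.02, 1, length.out = 25), names = FALSE) else dd
  }
  fdr_table <- do.call(rbind, lapply(delta, function(dl) {
    obs_n <- sum(abs(d_obs) >= dl)
    null_n <- apply(abs(null_d) >= dl, 2L, sum)
    fdr <- if (obs_n == 0L) 0 else min(1, stats::median(null_n) / obs_n)
    data.frame(delta = dl, n_significant = obs_n, fdr = fdr)
  }))
  ok <- fdr_table$fdr <= fdr_cut & fdr_table$n_significant > 0L
  significant <- if (any(ok)) {
    dl <- min(fdr_table$delta[ok])
    names(d_obs)[abs(d_obs) >= dl]
  } else character(0)
  structure(list(d = d_obs, s0 = s0, s = s_i, fdr_table = fdr_table,
                 significant = significant,
                 n_permutations_used = length(idx), exhaustive = exhaustive),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM two-class: ", length(x$d), " proteins, s0 = ",
      signif(x$s0, 4), ", ", x$n_permutations_used, " permutations (",
      if (x$exhaustive) "exhaustive" else "sampled", ")\n",
      length(x$significant), " significant protein(s)\n", sep = "")
  invisible(x)
}
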