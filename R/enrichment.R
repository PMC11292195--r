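# Single-sample gene-set enrichment and overrepresentation analysis.

#' Single-sample GSEA enrichment score for one profile
#'
#' Barbie-style running-sum score. Genes are ranked by profile value,
#' descending, with ties broken by gene symbol (stable lexicographic
#' order). Rank weights are |r|^alpha where r is the integer rank (the
#' top gene has rank N). Walking down the ranked list, the score is the
#' sum over positions of the difference between the weighted in-set ECDF
#' and the unweighted out-of-set ECDF.
#'
#' @param profile named numeric vector (gene -> value) for one sample;
#'   missing values are dropped before ranking.
#' @param gene_set character vector of gene symbols.
#' @param alpha rank-weighting exponent (default 0.75).
#' @return scalar enrichment score.
#' @export
ssgsea <- function(profile, gene_set, alpha = 0.75) {
  profile <- profile[!is.na(profile)]
  genes <- names(profile)
  if (is.null(genes) || anyDuplicated(genes))
    stop("profile must be named with unique gene symbols")
  n <- length(profile)
  in_set <- genes %in% gene_set
  m <- sum(in_set)
  if (m == 0L) stop("gene set does not intersect the profile")
  if (m == n) stop("gene set covers the whole profile; out-set ECDF undefined")
  ord <- order(-profile, genes)
  in_set <- in_set[ord]
  rank_val <- n:1                      # descending positions get ranks N..1
  w <- abs(rank_val)^alpha
  w[!in_set] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (n - m)
  sum(p_in - p_out)
}

#' ssGSEA scores for a matrix of samples and a gene-set collection
#'
#' Applies [ssgsea()] per sample and per set; per-sample missing values
#' are dropped before ranking. With `normalize = TRUE` all scores are
#' divided by the global score range (max - min over every sample and
#' set), the normalisation of the original single-sample GSEA
#' formulation; it rescales without reordering samples or sets.
#'
#' @param matrix abundance matrix (genes x samples).
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param alpha rank-weighting exponent.
#' @param normalize divide by the global score range (default TRUE).
#' @return sets x samples numeric matrix of enrichment scores.
#' @export
ssgsea_matrix <- function(matrix, collection, alpha = 0.75,
                          normalize = TRUE) {
  validate_abundance(matrix)
  usable <- Filter(function(s) length(intersect(s, rownames(matrix))) > 0L,
                   collection)
  if (length(usable) < length(collection))
    warning("dropped ", length(collection) - length(usable),
            " set(s) with no genes in the matrix")
  if (!length(usable)) stop("no gene set intersects the matrix")
  out <- vapply(colnames(matrix), function(s) {
    prof <- matrix[, s]
    names(prof) <- rownames(matrix)
    vapply(usable, function(gs) ssgsea(prof, gs, alpha = alpha), numeric(1))
  }, numeric(length(usable)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = length(usable),
                  dimnames = list(names(usable), colnames(matrix)))
  if (normalize) {
    rng <- diff(range(out))
    if (rng == 0) warning("zero global score range; normalization skipped")
    else out <- out / rng
  }
  out
}

#' Hallmark-style screen: per-set ANOVA of ssGSEA scores across subgroups
#'
#' Scores every set on the (full, unfiltered) matrix with
#' [ssgsea_matrix()], then tests each set's scores across subgroups by
#' one-way ANOVA (pooled variance) and adjusts with BH. Sets with zero
#' within-group variance everywhere take the exact-tie path (p = 1,
#' noted).
#'
#' @param matrix abundance matrix (full proteome).
#' @param collection gene-set collection.
#' @param subgroup_labels named vector sample -> subgroup (>=2 subgroups
#'   with >=3 samples each).
#' @param alpha ssGSEA exponent.
#' @param fdr significance threshold on BH q (default 0.05).
#' @return data.frame per set: `set`, group means, `f_statistic`,
#'   `p_value`, `q_value`, `significant`, `note`.
#' @export
hallmark_screen <- function(matrix, collection, subgroup_labels,
                            alpha = 0.75, fdr = 0.05) {
  g <- factor(subgroup_labels[colnames(matrix)])
  if (nlevels(g) < 2L) stop("need >=2 subgroups")
  if (any(table(g) < 3L)) stop("each subgroup needs >=3 samples")
  sc <- ssgsea_matrix(matrix, collection, alpha = alpha)
  rows <- lapply(rownames(sc), function(nm) {
    y <- sc[nm, ]
    means <- tapply(y, g, mean)
    wvar <- tapply(y, g, stats::var)
    if (all(wvar < .Machine$double.eps)) {
      pv <- if (max(means) - min(means) < .Machine$double.eps^0.5) 1 else 0
      return(data.frame(set = nm, t(means), f_statistic = NA_real_,
                        p_value = pv, note = "degenerate within-group variance",
                        check.names = FALSE, stringsAsFactors = FALSE))
    }
    fit <- stats::anova(stats::lm(y ~ g))
    data.frame(set = nm, t(means), f_statistic = fit$`F value`[1L],
               p_value = fit$`Pr(>F)`[1L], note = "",
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < fdr
  rownames(out) <- NULL
  out
}

#' Hypergeometric overrepresentation analysis
#'
#' Upper-tail hypergeometric p per collection term for the overlap of a
#' query set with each term, both intersected with the universe;
#' BH-adjusted and sorted by q. Terms with empty intersection are kept
#' with p = 1.
#'
#' @param query_set character vector (must be a subset of `universe`).
#' @param universe character vector of all considered genes (default
#'   choice in this package: all quantified proteins, not the genome).
#' @param collection named list of gene sets.
#' @return data.frame: `term`, `overlap`, `set_size`, `universe_size`,
#'   `query_size`, `p_value`, `q_value`, sorted by `q_value`.
#' @export
ora <- function(query_set, universe, collection) {
  query_set <- unique(query_set)
  universe <- unique(universe)
  if (!length(query_set)) stop("empty query set")
  if (!all(query_set %in% universe))
    stop("query set must be a subset of the universe")
  N <- length(universe); q <- length(query_set)
  rows <- lapply(names(collection), function(nm) {
    term <- intersect(collection[[nm]], universe)
    K <- length(term)
    k <- length(intersect(term, query_set))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, q, lower.tail = FALSE)
    data.frame(term = nm, overlap = k, set_size = K, universe_size = N,
               query_size = q, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$q_value, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
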