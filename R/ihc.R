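# Score-level immunohistochemistry computations.

#' H-score from per-cell DAB optical densities
#'
#' Cells are binned by cytoplasmic mean OD: negative below the first
#' threshold, then weak / moderate / strong with intervals closed on the
#' left (a cell exactly at a cutpoint takes the higher bin). H-score =
#' 100 * (weak + 2*moderate + 3*strong fractions), in [0, 300].
#'
#' @param od numeric vector of per-cell ODs (>= 0, at least one cell).
#' @param thresholds ascending cutpoints for weak/moderate/strong
#'   staining (defaults 0.14, 0.18, 0.23 OD).
#' @return list: `h_score`, `fractions` (negative/weak/moderate/strong,
#'   summing to 1), `n_cells`.
#' @export
h_score <- function(od, thresholds = c(0.14, 0.18, 0.23)) {
  if (!length(od)) stop("empty core: no cells")
  if (any(od < 0)) stop("negative OD")
  if (length(thresholds) != 3L || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be 3 strictly increasing cutpoints")
  bin <- cut(od, breaks = c(-Inf, thresholds, Inf), right = FALSE,
             labels = c("negative", "weak", "moderate", "strong"))
  f <- as.vector(table(bin)) / length(od)
  names(f) <- levels(bin)
  list(h_score = 100 * (f[["weak"]] + 2 * f[["moderate"]] + 3 * f[["strong"]]),
       fractions = f, n_cells = length(od))
}

#' Positive-pixel fraction
#'
#' Fraction of pixels with DAB OD at or above the threshold (inclusive).
#'
#' @param od numeric vector of per-pixel ODs (>= 1 pixel).
#' @param threshold positivity cutoff (default 0.15 OD).
#' @return fraction in [0, 1].
#' @export
positive_pixel_fraction <- function(od, threshold = 0.15) {
  if (!length(od)) stop("empty pixel vector")
  mean(od >= threshold)
}

#' Preservation-adjusted TIL density
#'
#' Replicate counts are scaled to 100% section area (count divided by
#' its preservation fraction), replicates with preservation below 0.5
#' are excluded, the remaining adjusted counts are averaged and
#' multiplied by the area-normalisation factor to give cells per square
#' millimetre.
#'
#' @param counts raw replicate counts.
#' @param preservation per-replicate section-preservation fraction in
#'   (0, 1].
#' @param area_factor area normalisation constant (default 1.274).
#' @return list: `density` (cells/mm^2, NA when every replicate is
#'   excluded), `n_used`, `excluded` (indices dropped).
#' @export
til_density <- function(counts, preservation, area_factor = 1.274) {
  if (length(counts) != length(preservation))
    stop("counts and preservation lengths differ")
  if (any(preservation <= 0 | preservation > 1))
    stop("preservation fractions must be in (0, 1]")
  use <- preservation >= 0.5
  if (!any(use))
    return(list(density = NA_real_, n_used = 0L, excluded = seq_along(counts)))
  adj <- counts[use] / preservation[use]
  list(density = mean(adj) * area_factor, n_used = sum(use),
       excluded = which(!use))
}

#' Three-component Gaussian mixture of per-case scores
#'
#' Fits a univariate three-component Gaussian mixture (unequal
#' variances) to per-case mean scores with `mclust` and labels the
#' components low / intermediate / high by ascending mean. The fit is
#' deterministic given the data (model-based hierarchical
#' initialisation); the `seed` argument is accepted for interface
#' stability and recorded.
#'
#' @param scores numeric vector of per-case scores (>= 9 cases, not all
#'   equal).
#' @param seed recorded RNG seed.
#' @return list of class `gmm_result`: `assignments` (factor
#'   low/intermediate/high), `means`, `sds`, `weights`, `loglik`,
#'   `converged`.
#' @importFrom mclust Mclust mclustBIC
#' @export
gmm_three_groups <- function(scores, seed = 1) {
  if (length(scores) < 9L) stop("need at least 9 cases")
  if (anyNA(scores)) stop("missing scores")
  if (stats::sd(scores) == 0) stop("all scores identical; degenerate fit refused")
  set.seed(seed)
  fit <- mclust::Mclust(scores, G = 3, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  ord <- order(fit$parameters$mean)
  lab <- c("low", "intermediate", "high")[match(fit$classification, ord)]
  structure(list(
    assignments = factor(lab, levels = c("low", "intermediate", "high")),
    means = unname(fit$parameters$mean[ord]),
    sds = sqrt(unname(fit$parameters$variance$sigmasq[ord])),
    weights = unname(fit$parameters$pro[ord]),
    loglik = fit$loglik,
    converged = TRUE, seed = seed), class = "gmm_result")
}

#' @export
print.gmm_result <- function(x, ...) {
  cat("3-component Gaussian mixture: means",
      paste(signif(x$means, 4), collapse = " / "), "\n")
  print(table(x$assignments))
  invisible(x)
}

#' Compare proteomic values across IHC-derived clusters
#'
#' Pairwise two-sided Mann-Whitney tests between clusters; clusters with
#' fewer than `min_n` cases are excluded with a message.
#'
#' @param values numeric proteomic measurements per case.
#' @param clusters cluster label per case.
#' @param min_n minimum cluster size (default 3).
#' @return data.frame: `cluster1`, `cluster2`, `n1`, `n2`, `p_value`.
#' @export
compare_proteomic_vs_ihc <- function(values, clusters, min_n = 3) {
  ok <- !is.na(values) & !is.na(clusters)
  values <- values[ok]; clusters <- factor(clusters[ok])
  tb <- table(clusters)
  drop <- names(tb)[tb < min_n]
  if (length(drop)) {
    message("excluded undersized cluster(s): ", paste(drop, collapse = ", "))
    keep <- !clusters %in% drop
    values <- values[keep]; clusters <- droplevels(clusters[keep])
  }
  if (nlevels(clusters) < 2L) stop("need >=2 usable clusters")
  pairs <- utils::combn(levels(clusters), 2L, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pp) {
    a <- values[clusters == pp[1L]]; b <- values[clusters == pp[2L]]
    w <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(cluster1 = pp[1L], cluster2 = pp[2L],
               n1 = length(a), n2 = length(b), p_value = w$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
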