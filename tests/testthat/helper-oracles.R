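# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles and stay separate from the package code
# paths they check.

# step-up BH by direct enumeration of the definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# double-loop ssGSEA running sum (rank weights |r|^alpha, ties by symbol)
ssgsea_brute <- function(profile, gene_set, alpha = 0.75) {
  profile <- profile[!is.na(profile)]
  genes <- names(profile)
  ord <- order(-profile, genes)
  genes <- genes[ord]
  n <- length(genes)
  in_set <- genes %in% gene_set
  m <- sum(in_set)
  rank_val <- n:1
  denom_in <- 0
  for (j in 1:n) if (in_set[j]) denom_in <- denom_in + abs(rank_val[j])^alpha
  es <- 0
  for (i in 1:n) {
    pin <- 0; pout <- 0
    for (j in 1:i) {
      if (in_set[j]) pin <- pin + abs(rank_val[j])^alpha else pout <- pout + 1
    }
    es <- es + pin / denom_in - pout / (n - m)
  }
  es
}

# exact upper-tail hypergeometric by summation of binomial coefficients
hyper_upper <- function(k, K, N, q) {
  if (K == 0) return(1)
  kk <- k:min(K, q)
  sum(choose(K, kk) * choose(N - K, q - kk)) / choose(N, q)
}

# Cox partial log-likelihood for one covariate, Breslow form (used on
# tie-free toys where Breslow = Efron), maximised by 1-D optimize()
cox_grid_coef <- function(time, event, x) {
  pl <- function(beta) {
    ll <- 0
    for (i in which(event)) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(pl, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# direct O/E/V log-rank tabulation over distinct event times (2 groups)
logrank_oev <- function(time, event, grp) {
  g1 <- grp == unique(grp)[1]
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(time[event]))) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == tt & event)
    d1 <- sum(time == tt & event & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Dunn pairwise z from the rank-sum formula, no package code
dunn_direct <- function(x, g) {
  r <- rank(x); N <- length(x)
  ties <- table(x)
  tc <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- sort(unique(g))
  out <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    a <- lv[i]; b <- lv[j]
    se <- sqrt((N * (N + 1) / 12 - tc) * (1 / sum(g == a) + 1 / sum(g == b)))
    z <- (mean(r[g == a]) - mean(r[g == b])) / se
    out[[paste(a, b)]] <- c(z = z, p = 2 * pnorm(-abs(z)))
  }
  out
}

# small labelled abundance matrix builder
toy_matrix <- function(values, proteins = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- proteins %||% paste0("P", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index between two labelings (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
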