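test_that("BH q-values match independent step-up enumeration", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.05)
  expect_equal(stats::p.adjust(p, "BH"), bh_stepup(p))
  set.seed(11)
  for (i in 1:20) {
    pv <- runif(sample(3:400, 1))
    expect_equal(stats::p.adjust(pv, "BH"), bh_stepup(pv))
  }
})

test_that("one-vs-rest flags at the inclusive fold-change boundary", {
  set.seed(21)
  n <- 30
  rest <- matrix(rnorm(3 * n, 20, 0.2), 3, n)
  grp <- rest + c(1, 0, 5)       # P1 exactly +1, P2 null, P3 strong
  m <- toy_matrix(cbind(grp, rest), samples = paste0("S", 1:(2 * n)))
  labels <- rep(c("A", "rest"), each = n)
  de <- one_vs_rest_de(m, labels, "A")
  expect_equal(de$delta_log2, c(1, 0, 5), tolerance = 1e-12)
  expect_true(de$upregulated[1])          # boundary delta = 1 is included
  expect_false(de$upregulated[2])         # identical distributions
  expect_true(de$upregulated[3])
  expect_error(one_vs_rest_de(m, labels, "A", min_n = 50), "minimum required")
})

test_that("uniquely upregulated sets are exclusive across groups", {
  set.seed(22)
  n <- 30
  base <- matrix(rnorm(4 * 3 * n, 20, 0.3), 4, 3 * n)
  m <- toy_matrix(base, proteins = c("X", "Y", "Z", "W"),
                  samples = paste0("S", 1:(3 * n)))
  labels <- rep(c("A", "B", "C"), each = n)
  m["X", labels == "A"] <- m["X", labels == "A"] + 2   # unique to A
  m["Y", labels == "A"] <- m["Y", labels == "A"] + 3   # shared A and B
  m["Y", labels == "B"] <- m["Y", labels == "B"] + 3
  uu <- unique_upregulation(m, labels, c("A", "B", "C"), min_n = 20)
  expect_equal(uu$A, "X")
  expect_false("Y" %in% unlist(uu))
  expect_length(uu$C, 0)
  expect_equal(anyDuplicated(unlist(uu)), 0L)
})

test_that("two-group DE is antisymmetric and null on copied arms", {
  set.seed(23)
  a <- matrix(rnorm(5 * 10, 20, 0.2), 5, 10)
  m_same <- toy_matrix(cbind(a, a), samples = paste0("S", 1:20))
  de0 <- two_group_de(m_same, paste0("S", 1:10), paste0("S", 11:20))
  expect_true(all(!de0$upregulated))
  expect_equal(de0$delta_log2, rep(0, 5))

  b <- matrix(rnorm(5 * 10, 20, 0.2), 5, 10)
  b[1, ] <- b[1, ] + 3
  m <- toy_matrix(cbind(a, b), samples = paste0("S", 1:20))
  de_ab <- two_group_de(m, paste0("S", 11:20), paste0("S", 1:10))
  expect_true(de_ab$upregulated[1])
  expect_false(any(de_ab$upregulated[-1]))
  de_ba <- two_group_de(m, paste0("S", 1:10), paste0("S", 11:20))
  expect_equal(de_ba$delta_log2, -de_ab$delta_log2)
})

test_that("DE flags are invariant to column order and global shifts", {
  set.seed(24)
  n <- 25
  m <- toy_matrix(matrix(rnorm(6 * 2 * n, 20, 0.5), 6, 2 * n),
                  samples = paste0("S", 1:(2 * n)))
  m[1, 1:n] <- m[1, 1:n] + 2
  labels <- rep(c("A", "B"), each = n)
  de <- one_vs_rest_de(m, labels, "A", min_n = 20)
  perm <- sample(ncol(m))
  de_perm <- one_vs_rest_de(m[, perm], labels[perm], "A", min_n = 20)
  expect_equal(de_perm$upregulated, de$upregulated)
  expect_equal(de_perm$delta_log2, de$delta_log2, tolerance = 1e-10)
  de_shift <- one_vs_rest_de(m + 7, labels, "A", min_n = 20)
  expect_equal(de_shift$upregulated, de$upregulated)
  expect_equal(de_shift$p_value, de$p_value, tolerance = 1e-10)
})

test_that("stratum robustness detects shifts and refuses single strata", {
  set.seed(25)
  m <- toy_matrix(matrix(rnorm(10 * 30, 20, 1), 10, 30),
                  samples = paste0("S", 1:30))
  strata <- rep(c("75-80", "80-90", ">90"), each = 10)
  m[1:3, strata == ">90"] <- m[1:3, strata == ">90"] + 5
  out <- stratum_robustness(m, strata)
  expect_true(all(out$per_protein$p_value[1:3] < 1e-3))
  expect_error(stratum_robustness(m, rep("only", 30)), "at least 2 strata")
  expect_warning(
    stratum_robustness(m, c(rep("a", 15), rep("b", 14), "tiny")), "merged")
})

test_that("SAM d statistics behave under separation, nulls and label swaps", {
  set.seed(26)
  vals <- matrix(rnorm(5 * 6, 20, 0.5), 5, 6)
  vals[1, 1:3] <- vals[1, 1:3] + 10 * 0.5       # one protein 10 sd apart
  m <- toy_matrix(vals, samples = paste0("S", 1:6))
  labels <- rep(c("hi", "lo"), each = 3)
  for (strat in c("median", "zero", "percentile")) {
    r <- sam_two_class(m, labels, s0_strategy = strat)
    expect_true(r$exhaustive)
    expect_equal(r$n_permutations_used, choose(6, 3))
    expect_equal(names(which.max(abs(r$d))), "P1")
    expect_true(all(r$fdr_table$fdr >= 0 & r$fdr_table$fdr <= 1))
  }
  r <- sam_two_class(m, labels)
  expect_true("P1" %in% r$significant)

  # identical groups per protein: all d exactly 0
  m_same <- toy_matrix(cbind(vals[, 1:3], vals[, 1:3]),
                       samples = paste0("S", 1:6))
  r0 <- sam_two_class(m_same, labels)
  expect_equal(unname(r0$d), rep(0, 5))
  expect_length(r0$significant, 0)

  # swapping labels negates d
  r_sw <- sam_two_class(m, ifelse(labels == "hi", "lo", "hi"))
  expect_equal(r_sw$d, -r$d)
})

test_that("SAM null for the 3v3 toy equals exhaustive 20-permutation enumeration", {
  set.seed(27)
  vals <- matrix(rnorm(4 * 6, 10, 1), 4, 6)
  m <- toy_matrix(vals, samples = paste0("S", 1:6))
  labels <- rep(c("A", "B"), each = 3)
  r <- sam_two_class(m, labels, s0_strategy = "zero")
  # oracle: direct enumeration of all 20 assignments with the plain
  # pooled-SE t-like statistic (s0 = 0)
  d_direct <- function(mask) {
    apply(vals, 1, function(x) {
      xa <- x[mask]; xb <- x[!mask]
      sp <- sqrt((1 / 3 + 1 / 3) *
                   (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / 4)
      (mean(xa) - mean(xb)) / sp
    })
  }
  combs <- utils::combn(6, 3, simplify = FALSE)
  null_counts <- vapply(r$fdr_table$delta, function(dl) {
    stats::median(vapply(combs, function(ix) {
      mask <- seq_len(6) %in% ix
      sum(abs(d_direct(mask)) >= dl)
    }, numeric(1)))
  }, numeric(1))
  obs_counts <- vapply(r$fdr_table$delta,
                       function(dl) sum(abs(r$d) >= dl), numeric(1))
  expect_equal(r$fdr_table$fdr,
               pmin(1, ifelse(obs_counts == 0, 0, null_counts / obs_counts)))
})
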