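test_that("pairwise-complete correlation matches the direct formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  m <- toy_matrix(rbind(x, y, x, -x), proteins = c("x", "y", "x2", "negx"))
  sim <- correlation_similarity(m, min_pairs = 3)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(sim$r["x", "y"], r_direct, tolerance = 1e-12)
  expect_equal(sim$r["x", "x2"], 1)            # duplicated rows
  expect_equal(sim$r["x", "negx"], -1)         # exact negation
  expect_true(isSymmetric(sim$r))
  expect_equal(unname(diag(sim$r)), rep(1, 4))
})

test_that("similarity is invariant to affine per-protein rescaling and masks", {
  set.seed(31)
  m <- toy_matrix(matrix(rnorm(5 * 20), 5, 20))
  s1 <- correlation_similarity(m, min_pairs = 5)
  m2 <- m * c(2, 3, 0.5, 10, 1) + c(100, -4, 0, 7, 2)
  s2 <- correlation_similarity(m2, min_pairs = 5)
  expect_equal(s2$r, s1$r, tolerance = 1e-12)

  # min_pairs masking and zero-variance handling
  m[1, 3:20] <- NA
  s3 <- suppressMessages(correlation_similarity(m, min_pairs = 10))
  expect_true(all(is.na(s3$r[1, -1])))
  m[2, ] <- 5
  s4 <- suppressMessages(correlation_similarity(m, min_pairs = 10))
  expect_true("P2" %in% s4$masked_items)
  expect_true(all(is.na(s4$r[2, -2])))
})

test_that("consensus is exact for duplicated profiles and recovers blocks", {
  # two exact profile copies: consensus 1 within, 0 between at k = 2
  set.seed(32)
  profA <- rnorm(8); profB <- rnorm(8) + 10
  data <- rbind(matrix(rep(profA, 6), 6, byrow = TRUE),
                matrix(rep(profB, 6), 6, byrow = TRUE))
  rownames(data) <- paste0("I", 1:12)
  cc <- consensus_cluster(data, k_range = 2:3, n_resamples = 50, seed = 5,
                          fixed_k = 2)
  cm2 <- cc$consensus[["2"]]
  expect_true(all(cm2[1:6, 1:6] == 1))
  expect_true(all(cm2[7:12, 7:12] == 1))
  expect_true(all(cm2[1:6, 7:12] == 0))
  expect_equal(unname(cc$assignments[1:6]), rep(1L, 6))
  expect_equal(unname(cc$assignments[7:12]), rep(2L, 6))

  # 3 correlated blocks in expression space -> k = 3, assignments = blocks
  set.seed(33)
  n_s <- 120; per <- 20; rho <- 0.8
  blocks <- do.call(rbind, lapply(1:3, function(b) {
    a <- rnorm(n_s)
    sqrt(rho) * matrix(a, per, n_s, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(per * n_s), per, n_s)
  }))
  rownames(blocks) <- paste0("P", 1:60); colnames(blocks) <- paste0("S", 1:n_s)
  sim <- correlation_similarity(blocks, min_pairs = 10)
  cc3 <- consensus_cluster(sim, k_range = 2:5, n_resamples = 100, seed = 6)
  expect_equal(cc3$chosen_k, 3L)
  truth <- rep(1:3, each = per)
  expect_gt(adjusted_rand(cc3$assignments, truth), 0.9)

  # structureless data is flagged
  set.seed(34)
  noise <- matrix(rnorm(30 * 12), 30, 12,
                  dimnames = list(paste0("I", 1:30), NULL))
  cc0 <- suppressMessages(consensus_cluster(noise, k_range = 2:4,
                                            n_resamples = 60, seed = 7,
                                            stable_pac_max = 0.15))
  expect_true(cc0$no_stable_structure)
  expect_true(all(cc0$pac > 0.15))     # no k markedly better than the rest
  expect_error(consensus_cluster(noise, k_range = 1), "all-ones")
})

test_that("consensus matrices are equivariant under item reordering", {
  set.seed(35)
  data <- rbind(matrix(rnorm(40, 0), 8, 5), matrix(rnorm(40, 8), 8, 5))
  rownames(data) <- paste0("I", 1:16)
  cc <- consensus_cluster(data, k_range = 2:3, n_resamples = 80, seed = 9)
  perm <- sample(16)
  ccp <- consensus_cluster(data[perm, ], k_range = 2:3, n_resamples = 80,
                           seed = 9)
  # well-separated groups: co-clustering structure identical after
  # mapping the permutation back, resampling noise notwithstanding
  expect_equal(ccp$consensus[["2"]][order(perm), order(perm)],
               cc$consensus[["2"]], tolerance = 0.05)
})

test_that("sigclust separates real clusters and is seed-deterministic", {
  set.seed(36)
  two <- rbind(matrix(rnorm(100), 20, 5), matrix(rnorm(100, 10), 20, 5))
  s <- sigclust(two, n_sim = 500, seed = 3)
  expect_lt(s$p_value, 0.01)
  s2 <- sigclust(two, n_sim = 500, seed = 3)
  expect_identical(s$p_value, s2$p_value)
  expect_warning(sigclust(two, n_sim = 50, seed = 1), "resolution")
  expect_error(sigclust(two[1:5, ]), "at least 10")
})

test_that("sigclust p is stable under rotation of the feature space", {
  set.seed(37)
  x <- matrix(rnorm(60 * 4), 60, 4)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))        # random orthogonal matrix
  p1 <- sigclust(x, n_sim = 400, seed = 8)$p_value
  p2 <- sigclust(x %*% q, n_sim = 400, seed = 8)$p_value
  expect_lt(abs(p1 - p2), 0.2)                  # loose: simulated nulls
  expect_gt(p1, 0.05)                           # single Gaussian: not split
})

test_that("cluster median scores use observed-value medians", {
  m <- toy_matrix(rbind(c(1, 1), c(2, 2), c(3, NA), c(10, 4)),
                  proteins = paste0("p", 1:4))
  asg <- c(p1 = 1, p2 = 1, p3 = 1, p4 = 2)
  sc <- cluster_median_scores(m, asg)
  expect_equal(sc["S1", "C1"], 2)        # {1,2,3}
  expect_equal(sc["S2", "C1"], 1.5)      # {1,2,NA} -> observed only
  asg2 <- c(p1 = 1, p2 = 1, p3 = 1, p4 = 1)
  expect_equal(cluster_median_scores(m, asg2)["S1", "C1"], 2.5)  # midpoint
  m2 <- m; m2[, 2] <- NA
  expect_true(is.na(cluster_median_scores(m2, asg)["S2", "C1"]))
})

test_that("Dunn pairwise tests match the direct rank formula", {
  x <- c(1.1, 2.3, 3.1, 4.2, 5.5, 2.0, 3.5, 4.4, 6.1, 7.2,
         8.0, 9.1, 10.2, 11.0, 12.5)
  g <- rep(c("A", "B", "C"), each = 5)
  d <- dunn_test(x, g)
  oracle <- dunn_direct(x, g)
  for (i in seq_len(nrow(d))) {
    key <- paste(d$group1[i], d$group2[i])
    expect_equal(d$z[i], unname(oracle[[key]]["z"]), tolerance = 1e-12)
    expect_equal(d$p_value[i], unname(oracle[[key]]["p"]), tolerance = 1e-12)
  }
  expect_equal(d$q_value, stats::p.adjust(d$p_value, "BH"))
})

test_that("score-clinical associations behave on constructed cohorts", {
  set.seed(38)
  n <- 40
  clin <- data.frame(sample_id = paste0("S", 1:n),
                     grade = rep(c(2, 3), each = n / 2),
                     subtype = rep(c("LMS", "UPS"), n / 2),
                     stringsAsFactors = FALSE)
  base <- runif(n / 2)                     # no ties across grades
  scores <- matrix(c(base, base + 1), ncol = 1,
                   dimnames = list(clin$sample_id, "C1"))
  a <- associate_scores(scores, clin)
  expect_lt(a$grade$p_value, 1e-3)
  expect_equal(a$grade$direction, "up_in_3")

  # identical scores across grades: MW p = 1
  scores_null <- matrix(rep(base, 2), ncol = 1,
                        dimnames = list(clin$sample_id, "C1"))
  a0 <- associate_scores(scores_null, clin)
  expect_gt(a0$grade$p_value, 0.99)

  # desmoid cases are excluded from the grade contrast
  clin2 <- clin; clin2$subtype[1:10] <- "DES"
  a2 <- associate_scores(scores, clin2)
  expect_equal(a2$grade$n2 + a2$grade$n3, 30)
})

test_that("clinical association tests: exact chi-square and skip rules", {
  sub <- setNames(rep(c("g1", "g2"), each = 10), paste0("S", 1:20))
  clin <- data.frame(sample_id = paste0("S", 1:20),
                     marker = rep(c("pos", "neg"), each = 10),
                     constant = "same",
                     til = c(1:10, 101:110),
                     stringsAsFactors = FALSE)
  rep_tab <- associate_clinical(sub, clin, c("marker", "constant"),
                                til_vars = character(0))
  # textbook chi-square for [[10,0],[0,10]] without correction
  expect_equal(rep_tab$statistic[rep_tab$variable == "marker"], 20)
  expect_lt(rep_tab$p_value[rep_tab$variable == "marker"], 1e-3)
  expect_match(rep_tab$note[rep_tab$variable == "constant"], "skipped")

  # TIL counts dichotomised at the median before the chi-square test
  til_tab <- associate_clinical(sub, clin, "til", til_vars = "til")
  expect_match(til_tab$note, "dichotomised")
  expect_lt(til_tab$p_value, 1e-3)
})
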