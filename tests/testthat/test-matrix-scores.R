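test_that("median gene-set scores use observed members only", {
  m <- toy_matrix(rbind(c(0, 1), c(2, NA), c(4, 5), c(9, 9)),
                  proteins = c("BGN", "DCN", "LUM", "OTHER"))
  coll <- list(PG = c("BGN", "DCN", "LUM"))
  sc <- geneset_median_score(m, coll)
  expect_equal(sc["S1", "PG"], 2)          # median of {0,2,4}
  expect_equal(sc["S2", "PG"], 3)          # median of {1,5}, DCN missing
  # adding an absent gene leaves scores unchanged
  sc2 <- geneset_median_score(m, list(PG = c(coll$PG, "ABSENT")))
  expect_equal(unname(sc2), unname(sc))
  expect_warning(geneset_median_score(m, c(coll, list(E = "NOPE"))),
                 "excluded")
})

test_that("ssGSEA set scores agree with the oracle and with sign logic", {
  set.seed(61)
  m <- toy_matrix(matrix(rnorm(30 * 4), 30, 4), proteins = paste0("g", 1:30))
  coll <- list(A = paste0("g", 1:5), B = paste0("g", 26:30))
  sc <- geneset_ssgsea_score(m, coll)
  for (s in colnames(m)) {
    prof <- setNames(m[, s], rownames(m))
    expect_equal(sc[s, "A"], ssgsea_brute(prof, coll$A), tolerance = 1e-9)
  }
  # sets of top-ranked vs bottom-ranked genes score positive vs negative
  mm <- toy_matrix(matrix(rep(30:1, 2), 30, 2), proteins = paste0("g", 1:30))
  sc2 <- geneset_ssgsea_score(mm, coll)
  expect_true(all(sc2[, "A"] > 0))
  expect_true(all(sc2[, "B"] < 0))
})

test_that("median and ssGSEA stratifications agree on a noiseless program", {
  # one latent program whose member values rise strictly with activity,
  # against a fixed dense background grid: both the median score and the
  # (rank-driven) ssGSEA score are monotone in the activity, so the
  # median splits coincide
  n <- 40
  a <- seq(-2, 2, length.out = n)
  bg_grid <- seq(10, 30, length.out = 400)
  m <- toy_matrix(rbind(outer(c(1, 1.5, 2), a) + 20,
                        matrix(bg_grid, 400, n)),
                  proteins = c(paste0("PGm", 1:3), paste0("bg", 1:400)),
                  samples = paste0("S", 1:n))
  coll <- list(PG = paste0("PGm", 1:3))
  med <- geneset_median_score(m, coll)[, 1]
  ssg <- geneset_ssgsea_score(m, coll)[, 1]
  expect_true(all(diff(ssg[order(med)]) >= 0))     # same patient ordering
  s_med <- stratify(med, "median")$stratum
  s_ssg <- stratify(ssg, "median")$stratum
  expect_equal(as.character(s_med), as.character(s_ssg))
})

test_that("prognostic screen retains a causal set and is deterministic", {
  spec <- cohort_spec(
    n_samples = 250,
    programs = list(list(name = "PG", n_proteins = 20, rho = 0.8)),
    n_background_proteins = 60,
    survival = list(lambda = 0.02, beta = -0.9, program = "PG",
                    censor_lambda = 0.005),
    seed = 63)
  co <- generate_cohort(spec)
  coll <- list(PG_set = co$truth$program_members$PG[1:11],
               decoy = co$truth$program_members$background[1:11])
  sr <- prognostic_screen(co$matrix, coll, co$clinical, endpoints = "OS")
  expect_true("PG_set" %in% sr$retained)
  expect_s3_class(sr$table, "data.frame")
  # protective direction: high program stratum has HR < 1
  pg_row <- sr$table[sr$table$set == "PG_set" & sr$table$endpoint == "OS", ]
  expect_lt(pg_row$mva_hr, 1)
  # deterministic given identical inputs
  sr2 <- prognostic_screen(co$matrix, coll, co$clinical, endpoints = "OS")
  expect_identical(sr$table, sr2$table)
})

test_that("a set tracking a clinical covariate fails MVA independence", {
  set.seed(64)
  n <- 200
  grade <- rep(c(2, 3), each = n / 2)
  # hazard driven by grade only; the gene set recodes grade with slight noise
  tt <- rexp(n, 0.02 * exp(1.2 * (grade - 2)))
  cc <- rexp(n, 0.004)
  clin <- data.frame(sample_id = paste0("S", 1:n), grade = grade,
                     age = round(runif(n, 30, 80)),
                     OS_time = pmin(tt, cc), OS_event = tt <= cc,
                     stringsAsFactors = FALSE)
  vals <- outer(rep(1, 3), -grade) + matrix(rnorm(3 * n, 0, 0.1), 3, n)
  m <- toy_matrix(vals + 20, proteins = paste0("gr", 1:3),
                  samples = clin$sample_id)
  sr <- prognostic_screen(m, list(G = paste0("gr", 1:3)), clin,
                          endpoints = "OS", covariates = c("grade", "age"))
  tab <- sr$table
  expect_true(tab$pass_stage1[1])            # prognostic in stage 1
  expect_false("G" %in% sr$retained)         # but not independent of grade
  expect_true("grade" %in% sr$covariates_used[["G.OS"]])
})

test_that("unknown endpoints and unusable endpoints are rejected or skipped", {
  m <- toy_matrix(matrix(rnorm(20), 2, 10), proteins = c("a", "b"))
  clin <- data.frame(sample_id = colnames(m),
                     OS_time = rexp(10), OS_event = rep(TRUE, 10))
  expect_error(
    prognostic_screen(m, list(S = "a"), clin, endpoints = "XX"),
    "unknown endpoint")
  clin$LRFS_time <- NA_real_; clin$LRFS_event <- NA
  expect_warning(
    sr <- prognostic_screen(m, list(S = c("a", "b")), clin,
                            endpoints = c("OS", "LRFS")),
    "missing for >")
  expect_equal(sr$params$endpoints, "OS")
})
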