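test_that("cohort generation is seed-deterministic and spec-validated", {
  spec <- cohort_spec(n_samples = 50, programs = list(
    list(name = "PG", n_proteins = 10, rho = 0.6)),
    n_background_proteins = 10, seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$activities, b$truth$activities)

  expect_error(cohort_spec(subtype_props = c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(cohort_spec(programs = list(
    list(name = "X", n_proteins = 5, rho = 1.2))), "rho")
  expect_error(cohort_spec(survival = list(lambda = -1, beta = 0,
                                           program = "PG",
                                           censor_lambda = 0.01)),
               "hazards")
  expect_error(cohort_spec(survival = list(lambda = 1, beta = 0,
                                           program = "NOPE",
                                           censor_lambda = 0.01)),
               "name a program")
})

test_that("within-block correlations converge to the specified rho", {
  spec <- cohort_spec(n_samples = 120, programs = list(
    list(name = "PG", n_proteins = 20, rho = 0.8)),
    n_background_proteins = 0, missing_rate = 0, seed = 91)
  co <- generate_cohort(spec)
  r <- cor(t(co$matrix))
  expect_gt(mean(r[upper.tri(r)]), 0.75)
  expect_lt(mean(r[upper.tri(r)]), 0.85)

  # single-factor closed form E[r] = rho, checked tighter at n = 1000
  spec2 <- cohort_spec(n_samples = 1000, programs = list(
    list(name = "PG", n_proteins = 12, rho = 0.5)),
    n_background_proteins = 0, missing_rate = 0, seed = 92)
  r2 <- cor(t(generate_cohort(spec2)$matrix))
  expect_equal(mean(r2[upper.tri(r2)]), 0.5, tolerance = 0.02)
})

test_that("generated clinical table is well-formed with linked survival", {
  co <- generate_cohort(cohort_spec(n_samples = 200, seed = 93))
  cl <- co$clinical
  expect_equal(anyDuplicated(cl$sample_id), 0L)
  expect_true(all(cl$OS_time >= 0))
  expect_type(cl$OS_event, "logical")
  expect_true(all(is.na(cl$grade) | cl$grade %in% c(2, 3)))
  # survival driver: higher PG activity protects (beta = -0.7)
  fit <- cox_fit(cl$OS_time, cl$OS_event, data.frame(z = co$truth$z))
  expect_lt(fit$coef, -0.3)
})

test_that("track generator limits: straight, diffusive, and scale laws", {
  # zero angular noise: every track has DI exactly 1
  straight <- generate_tracks(track_spec(n_tracks = 10, n_frames = 20,
                                         kappa = Inf, seed = 94))
  mets <- track_metrics_table(straight)
  expect_equal(mets$directionality_index, rep(1, 10), tolerance = 1e-12)

  # uniform random headings: mean DI low at 36 steps (random-walk regime)
  diffuse <- generate_tracks(track_spec(n_tracks = 60, n_frames = 37,
                                        kappa = 0, seed = 95))
  expect_lt(mean(track_metrics_table(diffuse)$directionality_index), 0.3)

  # doubling sigma doubles speed and leaves DI unchanged (same seed)
  t1 <- track_metrics_table(generate_tracks(track_spec(sigma = 5, seed = 96)))
  t2 <- track_metrics_table(generate_tracks(track_spec(sigma = 10, seed = 96)))
  expect_equal(t2$speed, 2 * t1$speed, tolerance = 1e-12)
  expect_equal(t2$directionality_index, t1$directionality_index,
               tolerance = 1e-12)

  # persistence: mean DI decreases with angular noise
  hi <- track_metrics_table(generate_tracks(track_spec(kappa = 20, seed = 97)))
  lo <- track_metrics_table(generate_tracks(track_spec(kappa = 0.5, seed = 97)))
  expect_gt(mean(hi$directionality_index), mean(lo$directionality_index))
})

test_that("IHC generator supports the H-score and mixture analyses", {
  # all mass far below the weak threshold: H-score 0 in every core
  low <- generate_ihc(ihc_spec(n_cores = 5, cells_per_core = 100,
                               weights = c(1, 0, 0),
                               meanlog = log(c(0.05, 0.16, 0.30)),
                               sdlog = c(0.1, 0.1, 0.1), seed = 98))
  hs <- vapply(split(low$od, low$core_id),
               function(v) h_score(v)$h_score, numeric(1))
  expect_equal(unname(hs), rep(0, 5))
  # determinism
  a <- generate_ihc(ihc_spec(seed = 5)); b <- generate_ihc(ihc_spec(seed = 5))
  expect_identical(a, b)
})

test_that("synthetic annotation and gene sets wire the cohort to the pipeline", {
  co <- generate_cohort(cohort_spec(n_samples = 40, seed = 90))
  db <- synthetic_annotation(co)
  expect_s3_class(db, "annotation_db")
  filt <- filter_matrix(co$matrix, db)
  # programs fully annotated, half of background annotated
  expect_equal(nrow(filt), 180 + 60)
  gs <- synthetic_gene_sets(co, seed = 90)
  expect_true(all(c("PG_set", "decoy01") %in% names(gs)))
  expect_true(all(gs$PG_set %in% co$truth$program_members$PG))
  expect_equal(anyDuplicated(unlist(gs[grep("decoy", names(gs))])), 0L)
})
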