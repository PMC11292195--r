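# Synthetic cohorts, cell tracks and IHC tables with the statistical
# structure the analysis pipeline assumes.

# Default histological-subtype proportions (11 subtypes, cohort-style).
DEFAULT_SUBTYPE_PROPS <- c(
  LMS = 0.25, UPS = 0.17, SS = 0.13, DDLPS = 0.12, DES = 0.12, AS = 0.09,
  ES = 0.05, RT = 0.04, ASPS = 0.01, CCS = 0.01, DSRCT = 0.01
)

default_programs <- function() {
  list(
    list(name = "PG", n_proteins = 60, rho = 0.8,
         subtype_shift = NULL, grade_shift = c("2" = 0.5, "3" = -0.5)),
    list(name = "BM", n_proteins = 60, rho = 0.8,
         subtype_shift = c(LMS = 1), grade_shift = NULL),
    list(name = "PROT", n_proteins = 60, rho = 0.8,
         subtype_shift = c(UPS = 1), grade_shift = NULL)
  )
}

#' Specification for a synthetic proteomic cohort
#'
#' Defines a cohort with block-correlated latent expression programs,
#' subtype/grade structure, and survival linked to one named program.
#' Each program is a single-factor block: per-sample activity
#' a ~ Normal(mu_subtype + mu_grade, 1); a member protein's value is
#' offset + sqrt(rho) * a + sqrt(1 - rho) * noise, so the expected
#' within-block protein-protein correlation is rho. Background proteins
#' are independent noise. Event and censoring times are exponential;
#' the event hazard is lambda * exp(beta * z) with z the standardised
#' activity of `survival$program`.
#'
#' @param n_samples cohort size (default 300).
#' @param subtype_props named proportions over subtypes (must sum to 1).
#' @param grade_probs probabilities of grade 2, grade 3 and unknown.
#' @param programs list of program blocks: `name`, `n_proteins`,
#'   `rho` in [0, 1), optional named `subtype_shift` / `grade_shift`.
#' @param n_background_proteins i.i.d. noise proteins (default 120).
#' @param missing_rate missing-at-random fraction (default 0.1).
#' @param survival list: `lambda` (baseline hazard per month), `beta`
#'   (log-HR per SD of the named program), `program`, `censor_lambda`.
#' @param seed RNG seed.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 300,
                        subtype_props = DEFAULT_SUBTYPE_PROPS,
                        grade_probs = c("2" = 0.358, "3" = 0.433,
                                        unknown = 0.209),
                        programs = default_programs(),
                        n_background_proteins = 120,
                        missing_rate = 0.1,
                        survival = list(lambda = 0.02, beta = -0.7,
                                        program = "PG",
                                        censor_lambda = 0.005),
                        seed = 1) {
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (abs(sum(subtype_props) - 1) > 1e-8) stop("subtype proportions must sum to 1")
  if (abs(sum(grade_probs) - 1) > 1e-8) stop("grade probabilities must sum to 1")
  for (p in programs) {
    if (is.null(p$name) || is.null(p$n_proteins) || is.null(p$rho))
      stop("each program needs name, n_proteins, rho")
    if (p$rho < 0 || p$rho >= 1) stop("program rho must be in [0, 1)")
  }
  if (anyDuplicated(vapply(programs, `[[`, "", "name")))
    stop("program names must be unique")
  if (survival$lambda <= 0 || survival$censor_lambda <= 0)
    stop("hazards must be > 0")
  if (!survival$program %in% vapply(programs, `[[`, "", "name"))
    stop("survival$program must name a program")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate in [0, 1)")
  structure(list(n_samples = n_samples, subtype_props = subtype_props,
                 grade_probs = grade_probs, programs = programs,
                 n_background_proteins = n_background_proteins,
                 missing_rate = missing_rate, survival = survival,
                 seed = seed), class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws a full abundance matrix, clinical table and ground-truth record
#' from a [cohort_spec()]. Deterministic given the spec's seed.
#'
#' @param spec a `cohort_spec`.
#' @return list: `matrix` (proteins x samples abundance matrix),
#'   `clinical` (data.frame with subtype, grade, covariates and
#'   OS/LRFS/MFS endpoints), `truth` (latent activities, standardized
#'   survival driver `z`, program membership, spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  subtype <- sample(names(spec$subtype_props), n, replace = TRUE,
                    prob = spec$subtype_props)
  grade_lab <- sample(names(spec$grade_probs), n, replace = TRUE,
                      prob = spec$grade_probs)
  grade <- suppressWarnings(as.integer(grade_lab))       # unknown -> NA

  activities <- matrix(NA_real_, n, length(spec$programs))
  colnames(activities) <- vapply(spec$programs, `[[`, "", "name")
  blocks <- list()
  rows <- list()
  for (p in spec$programs) {
    mu <- rep(0, n)
    if (!is.null(p$subtype_shift)) {
      hit <- subtype %in% names(p$subtype_shift)
      mu[hit] <- mu[hit] + p$subtype_shift[subtype[hit]]
    }
    if (!is.null(p$grade_shift)) {
      hit <- !is.na(grade) & as.character(grade) %in% names(p$grade_shift)
      mu[hit] <- mu[hit] + p$grade_shift[as.character(grade[hit])]
    }
    a <- stats::rnorm(n, mu, 1)
    activities[, p$name] <- a
    prot_ids <- sprintf("%s_%03d", p$name, seq_len(p$n_proteins))
    offsets <- stats::rnorm(p$n_proteins, 25, 2)
    vals <- offsets + sqrt(p$rho) * matrix(a, p$n_proteins, n, byrow = TRUE) +
      sqrt(1 - p$rho) * matrix(stats::rnorm(p$n_proteins * n), p$n_proteins, n)
    rownames(vals) <- prot_ids
    rows[[p$name]] <- vals
    blocks[[p$name]] <- prot_ids
  }
  if (spec$n_background_proteins > 0L) {
    bg_ids <- sprintf("BG_%03d", seq_len(spec$n_background_proteins))
    bg <- stats::rnorm(spec$n_background_proteins, 25, 2) +
      matrix(stats::rnorm(spec$n_background_proteins * n),
             spec$n_background_proteins, n)
    rownames(bg) <- bg_ids
    rows[["background"]] <- bg
    blocks[["background"]] <- bg_ids
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- sample_ids
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(length(mat)) < spec$missing_rate,
                   nrow(mat), ncol(mat))
    mat[mask] <- NA
  }

  z <- as.vector(scale(activities[, spec$survival$program]))
  haz <- spec$survival$lambda * exp(spec$survival$beta * z)
  clinical <- data.frame(
    sample_id = sample_ids, subtype = subtype, grade = grade,
    site = sample(c("extremity", "trunk", "retroperitoneal", "head_neck",
                    "intra_abdominal", "pelvic", "uterine"), n, replace = TRUE,
                  prob = c(0.39, 0.20, 0.18, 0.04, 0.09, 0.07, 0.03)),
    depth = sample(c("deep", "superficial"), n, replace = TRUE,
                   prob = c(0.82, 0.18)),
    margins = sample(c("R0", "R1", "R2"), n, replace = TRUE,
                     prob = c(0.46, 0.52, 0.02)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.63, 0.37)),
    performance_status = sample(0:3, n, replace = TRUE,
                                prob = c(0.6, 0.31, 0.07, 0.02)),
    preop_treatment = sample(c("none", "chemo", "radio", "chemo_radio"), n,
                             replace = TRUE, prob = c(0.87, 0.06, 0.03, 0.04)),
    tumor_size = round(stats::rlnorm(n, log(90), 0.6)),
    age = round(stats::runif(n, 18, 90)),
    stringsAsFactors = FALSE
  )
  for (ep in c("OS", "LRFS", "MFS")) {
    tt <- stats::rexp(n, haz)
    cc <- stats::rexp(n, spec$survival$censor_lambda)
    clinical[[paste0(ep, "_time")]] <- pmin(tt, cc)
    clinical[[paste0(ep, "_event")]] <- tt <= cc
  }
  validate_abundance(mat)
  list(matrix = mat, clinical = clinical,
       truth = list(activities = activities, z = z, subtype = subtype,
                    grade = grade, program_members = blocks, spec = spec))
}

#' Specification for synthetic cell tracks
#'
#' Persistent random walk: the heading evolves by wrapped-normal
#' increments with standard deviation 1/sqrt(kappa) (kappa = Inf gives
#' straight-line motion; kappa = 0 draws a fresh uniform heading each
#' step); step lengths are Rayleigh with scale sigma.
#'
#' @param n_tracks number of tracks (default 50).
#' @param n_frames frames per track (default 37: 18 h at 30-min
#'   intervals).
#' @param interval frame interval in minutes (default 30).
#' @param sigma Rayleigh step scale in micrometres (default 5).
#' @param kappa heading concentration (default 4).
#' @param condition condition label written on every row.
#' @param seed RNG seed.
#' @return validated list of class `track_spec`.
#' @export
track_spec <- function(n_tracks = 50, n_frames = 37, interval = 30,
                       sigma = 5, kappa = 4, condition = "control",
                       seed = 1) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (sigma <= 0) stop("sigma must be > 0")
  if (kappa < 0) stop("kappa must be >= 0")
  structure(list(n_tracks = n_tracks, n_frames = n_frames,
                 interval = interval, sigma = sigma, kappa = kappa,
                 condition = condition, seed = seed), class = "track_spec")
}

#' Generate persistent-random-walk tracks
#'
#' @param spec a [track_spec()].
#' @return track table (columns `track_id`, `frame`, `t`, `x`, `y`,
#'   `condition`) as produced by [read_tracks()].
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  set.seed(spec$seed)
  out <- lapply(seq_len(spec$n_tracks), function(i) {
    nsteps <- spec$n_frames - 1L
    steps <- spec$sigma * sqrt(-2 * log(stats::runif(nsteps)))  # Rayleigh
    theta0 <- stats::runif(1, 0, 2 * pi)
    if (spec$kappa == 0) {
      theta <- stats::runif(nsteps, 0, 2 * pi)
    } else if (is.infinite(spec$kappa)) {
      theta <- rep(theta0, nsteps)
    } else {
      incr <- stats::rnorm(nsteps, 0, 1 / sqrt(spec$kappa))
      theta <- (theta0 + cumsum(incr)) %% (2 * pi)
    }
    x <- c(0, cumsum(steps * cos(theta)))
    y <- c(0, cumsum(steps * sin(theta)))
    data.frame(track_id = sprintf("T%04d", i),
               frame = seq_len(spec$n_frames) - 1L,
               t = (seq_len(spec$n_frames) - 1L) * spec$interval,
               x = x, y = y, condition = spec$condition,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Specification for synthetic IHC cell tables
#'
#' Per-core cell ODs are drawn from a mixture of lognormal components.
#'
#' @param n_cores number of cores (default 30).
#' @param cells_per_core cells per core (default 200).
#' @param weights mixture weights (must sum to 1).
#' @param meanlog,sdlog lognormal parameters per component.
#' @param seed RNG seed.
#' @return validated list of class `ihc_spec`.
#' @export
ihc_spec <- function(n_cores = 30, cells_per_core = 200,
                     weights = c(1, 1, 1) / 3,
                     meanlog = log(c(0.08, 0.16, 0.30)),
                     sdlog = c(0.15, 0.1, 0.15), seed = 1) {
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (length(meanlog) != length(weights) || length(sdlog) != length(weights))
    stop("weights, meanlog, sdlog must have equal length")
  structure(list(n_cores = n_cores, cells_per_core = cells_per_core,
                 weights = weights, meanlog = meanlog, sdlog = sdlog,
                 seed = seed), class = "ihc_spec")
}

#' Generate a synthetic IHC cell-measurement table
#'
#' @param spec an [ihc_spec()].
#' @return data.frame: `core_id`, `cell_id`, `od`.
#' @export
generate_ihc <- function(spec) {
  stopifnot(inherits(spec, "ihc_spec"))
  set.seed(spec$seed)
  out <- lapply(seq_len(spec$n_cores), function(i) {
    comp <- sample(seq_along(spec$weights), spec$cells_per_core,
                   replace = TRUE, prob = spec$weights)
    od <- stats::rlnorm(spec$cells_per_core, spec$meanlog[comp],
                        spec$sdlog[comp])
    data.frame(core_id = sprintf("core%03d", i),
               cell_id = sprintf("c%04d", seq_len(spec$cells_per_core)),
               od = od, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annotation catalog matching a synthetic cohort
#'
#' Builds an `annotation_db` over the generated protein identifiers so a
#' synthetic cohort can be pushed through the annotation-filtering
#' stage: program proteins are annotated as core matrisome
#' (proteoglycans / glycoproteins) or matrisome-associated blocks in
#' rotation, the first half of the background proteins as adhesome
#' adaptors, and the remaining background is left unannotated so
#' filtering is non-trivial.
#'
#' @param cohort result of [generate_cohort()].
#' @return an `annotation_db` data.frame.
#' @export
synthetic_annotation <- function(cohort) {
  blocks <- cohort$truth$program_members
  prog_names <- setdiff(names(blocks), "background")
  divs <- rep(c("core_matrisome", "core_matrisome", "matrisome_associated"),
              length.out = length(prog_names))
  cats <- rep(c("proteoglycans", "glycoproteins", "ECM_regulators"),
              length.out = length(prog_names))
  rows <- mapply(function(pn, dv, ct) {
    data.frame(gene = blocks[[pn]], division = dv, category = ct,
               stringsAsFactors = FALSE)
  }, prog_names, divs, cats, SIMPLIFY = FALSE)
  bg <- blocks[["background"]]
  if (length(bg)) {
    half <- bg[seq_len(floor(length(bg) / 2))]
    rows <- c(rows, list(data.frame(gene = half, division = "adhesome",
                                    category = "adaptor",
                                    stringsAsFactors = FALSE)))
  }
  db <- do.call(rbind, rows)
  db$in_adhesome <- db$division == "adhesome"
  db <- db[order(db$gene), ]
  rownames(db) <- NULL
  structure(db, class = c("annotation_db", "data.frame"),
            source_version = "synthetic")
}

#' Gene-set collection matching a synthetic cohort
#'
#' One causal set per program (a `set_size` subset of each program's
#' member proteins, named `<program>_set`) plus `n_decoys` decoy sets of
#' background proteins sampled without replacement.
#'
#' @param cohort result of [generate_cohort()].
#' @param set_size members per set (default 11).
#' @param n_decoys number of background decoy sets (default 6).
#' @param seed RNG seed for decoy sampling.
#' @return named list of gene sets.
#' @export
synthetic_gene_sets <- function(cohort, set_size = 11, n_decoys = 6,
                                seed = 1) {
  blocks <- cohort$truth$program_members
  prog_names <- setdiff(names(blocks), "background")
  sets <- lapply(prog_names, function(pn) blocks[[pn]][seq_len(
    min(set_size, length(blocks[[pn]])))])
  names(sets) <- paste0(prog_names, "_set")
  bg <- blocks[["background"]]
  if (n_decoys > 0L) {
    if (length(bg) < n_decoys * set_size)
      stop("not enough background proteins for ", n_decoys, " decoy sets")
    set.seed(seed)
    pool <- sample(bg)
    for (i in seq_len(n_decoys)) {
      sets[[sprintf("decoy%02d", i)]] <-
        pool[((i - 1) * set_size + 1):(i * set_size)]
    }
  }
  sets
}
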