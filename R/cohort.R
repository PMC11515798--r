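#' Default taxon vocabulary for the cohort generator
#'
#' The first entries are the named signature species of the dysbiotic
#' (pathobiont) and normobiotic (commensal) communities used for topic
#' labeling; the remainder are anonymous filler taxa.
#'
#' @param vocab_size Total number of taxa (must exceed the 11 signature taxa).
#' @return Character vector of taxon names of length `vocab_size`.
#' @export
default_taxa <- function(vocab_size = 200) {
  sig <- c(pathobiont_taxa(), commensal_taxa())
  if (vocab_size <= length(sig))
    stop("`vocab_size` must exceed the ", length(sig), " signature taxa")
  c(sig, sprintf("Oral taxon %03d", seq_len(vocab_size - length(sig))))
}

#' Reference taxa lists for topic labeling
#'
#' Pathobionts driving the dysbiotic community and commensals driving the
#' normobiotic community of the subgingival microbiome. Both lists can be
#' overridden wherever they are used.
#'
#' @return Character vector of species names.
#' @export
pathobiont_taxa <- function() {
  c("Porphyromonas gingivalis", "Porphyromonas endodontalis",
    "Fusobacterium nucleatum subsp. vincentii", "Treponema denticola",
    "Fretibacterium sp.", "Prevotella sp.")
}

#' @rdname pathobiont_taxa
#' @export
commensal_taxa <- function() {
  c("Veillonella rogosae", "Veillonella parvula", "Veillonella dispar",
    "Rothia dentocariosa", "Fusobacterium nucleatum subsp. animalis")
}

#' Configuration of the synthetic two-arm periodontal cohort
#'
#' Builds the full parameter set of the generator. The defaults encode the
#' trial this package emulates: 163 patients randomized 1:1 to adjunctive
#' antibiotics or placebo, sampled at months 0, 2, 8, 14 and 26; a
#' two-community (dysbiotic/normobiotic) Dirichlet-multinomial taxa model;
#' an ordinal (proportional-odds) microbial response category per subject;
#' and a negative-binomial count of sites with further attachment loss
#' >= 1.3 mm, with log total sites as offset. Effect-size defaults are the
#' published estimates: treatment OR 6.42 and baseline-normobiotic OR 7.8 on
#' the mediator; per-category rate ratio 0.72 and direct treatment rate
#' ratio 0.82 on the outcome, with smoking and age rate ratios read off the
#' published prediction grid (reference rate 8.14 expected sites of 146).
#'
#' @param n_patients Number of trial subjects (default 163, minimum 8).
#' @param allocation Proportion assigned to the antibiotic arm, in (0,1).
#'   Assignment is a balanced permutation, as in a stratified trial.
#' @param visit_months Strictly increasing integer visit schedule starting
#'   at 0 (baseline).
#' @param vocab_size Number of taxa.
#' @param library_size_mean Expected reads per sample (lognormal).
#' @param library_size_sdlog Lognormal dispersion of library sizes.
#' @param dys_topic_params,norm_topic_params Named Dirichlet concentration
#'   vectors over the vocabulary for the two communities; `NULL` builds
#'   defaults with mass concentrated on the disjoint signature sets.
#' @param dys_signature,norm_signature Disjoint signature taxa sets.
#' @param baseline_theta_params Beta parameters of the baseline dysbiotic
#'   proportion in patients; default `c(1.8, 0.5)` (median approximately
#'   0.865, matching the dysbiosis-dominated baseline of untreated
#'   periodontitis, with roughly 14% of subjects below 0.5).
#' @param healthy_theta_params Beta parameters for healthy controls;
#'   default `c(1, 20)` (mass near zero dysbiosis).
#' @param mediator_model Proportional-odds coefficients on the log-odds
#'   scale: `treatment`, `baseline_normo`, `age45_55`, `age_gt55`, `sex`,
#'   `smoking`, and three `cutpoints`.
#' @param outcome_model Negative-binomial parameters on the log-rate scale:
#'   `intercept` (log rate per site of the reference cell), `treatment`
#'   (direct effect), `category` (per response category), `age45_55`,
#'   `age_gt55`, `sex`, `smoking`, and `dispersion` (NB size).
#' @param trajectory_archetypes List with `means` (4 x visits matrix of mean
#'   dysbiosis scores, rows in category order non-responder, indifferent,
#'   short-term responder, responder) and `noise_sd`.
#' @param covariate_dists List with `age_probs` (three bands <45, 45<55,
#'   >55), `sex_prob` (probability female) and `smoking_prob`.
#' @param normo_cut Dysbiosis score below which a baseline community is
#'   called normobiotic (default 0.5).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return An object of class `cohort_config` (validated list).
#' @export
cohort_config <- function(n_patients = 163,
                          allocation = 0.5,
                          visit_months = c(0, 2, 8, 14, 26),
                          vocab_size = 200,
                          library_size_mean = 20000,
                          library_size_sdlog = 0.3,
                          dys_topic_params = NULL,
                          norm_topic_params = NULL,
                          dys_signature = pathobiont_taxa(),
                          norm_signature = commensal_taxa(),
                          baseline_theta_params = c(1.8, 0.5),
                          healthy_theta_params = c(1, 20),
                          mediator_model = list(
                            treatment = log(6.42),
                            baseline_normo = log(7.8),
                            age45_55 = -0.2,
                            age_gt55 = -0.4,
                            sex = 0,
                            smoking = -0.5,
                            cutpoints = c(0.2, 1.4, 2.6)),
                          outcome_model = list(
                            intercept = log(8.14 / 146),
                            treatment = log(0.82),
                            category = log(0.72),
                            age45_55 = log(1.18),
                            age_gt55 = log(1.47),
                            sex = 0,
                            smoking = log(1.85),
                            dispersion = 2),
                          trajectory_archetypes = NULL,
                          covariate_dists = list(
                            age_probs = c(0.30, 0.40, 0.30),
                            sex_prob = 0.5,
                            smoking_prob = 0.35),
                          normo_cut = 0.5,
                          seed = 1L) {
  taxa <- default_taxa(vocab_size)
  if (is.null(dys_topic_params)) {
    dys_topic_params <- setNames(rep(0.15, vocab_size), taxa)
    dys_topic_params[dys_signature] <- 8
  }
  if (is.null(norm_topic_params)) {
    norm_topic_params <- setNames(rep(0.15, vocab_size), taxa)
    norm_topic_params[norm_signature] <- 8
  }
  if (is.null(trajectory_archetypes)) {
    v <- length(visit_months)
    means <- rbind(
      `non-responder`         = approx_traj(c(0.85, 0.75, 0.85), visit_months),
      `indifferent`           = approx_traj(c(0.85, 0.60, 0.45), visit_months),
      `short-term responder`  = approx_traj(c(0.85, 0.25, 0.62), visit_months),
      `responder`             = approx_traj(c(0.85, 0.15, 0.10), visit_months))
    trajectory_archetypes <- list(means = means, noise_sd = 0.1)
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients), allocation = allocation,
    visit_months = as.integer(visit_months), vocab_size = as.integer(vocab_size),
    library_size_mean = library_size_mean, library_size_sdlog = library_size_sdlog,
    taxa = taxa,
    dys_topic_params = dys_topic_params, norm_topic_params = norm_topic_params,
    dys_signature = dys_signature, norm_signature = norm_signature,
    baseline_theta_params = baseline_theta_params,
    healthy_theta_params = healthy_theta_params,
    mediator_model = mediator_model, outcome_model = outcome_model,
    trajectory_archetypes = trajectory_archetypes,
    covariate_dists = covariate_dists, normo_cut = normo_cut,
    seed = as.integer(seed)), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

# piecewise-linear archetype through (baseline, first post-baseline, final)
#' @noRd
approx_traj <- function(anchors, visits) {
  stopifnot(length(anchors) == 3, length(visits) >= 2)
  xs <- c(visits[1], visits[2], visits[length(visits)])
  stats::approx(xs, anchors, xout = visits, rule = 2, ties = max)$y
}

#' @noRd
validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) stop(sprintf("invalid `%s`: %s", field, msg),
                                    call. = FALSE)
  if (cfg$n_patients < 8)
    fail("n_patients", "need at least 8 subjects to realize 4 categories in both arms")
  if (!(cfg$allocation > 0 && cfg$allocation < 1))
    fail("allocation", "must lie strictly between 0 and 1")
  v <- cfg$visit_months
  if (v[1] != 0 || length(v) < 2 || any(diff(v) <= 0))
    fail("visit_months", "must be strictly increasing and start at 0")
  if (any(cfg$dys_topic_params <= 0)) fail("dys_topic_params", "must be strictly positive")
  if (any(cfg$norm_topic_params <= 0)) fail("norm_topic_params", "must be strictly positive")
  if (any(cfg$baseline_theta_params <= 0)) fail("baseline_theta_params", "must be strictly positive")
  if (any(cfg$healthy_theta_params <= 0)) fail("healthy_theta_params", "must be strictly positive")
  if (length(intersect(cfg$dys_signature, cfg$norm_signature)))
    fail("dys_signature", "signature sets of the two communities must be disjoint")
  if (!all(cfg$dys_signature %in% cfg$taxa) || !all(cfg$norm_signature %in% cfg$taxa))
    fail("dys_signature", "signature taxa must be part of the vocabulary")
  if (cfg$library_size_mean <= 0) fail("library_size_mean", "must be positive")
  med <- cfg$mediator_model
  if (length(med$cutpoints) != 3 || any(diff(med$cutpoints) <= 0))
    fail("mediator_model", "needs 3 strictly increasing cutpoints")
  if (!is.finite(cfg$outcome_model$dispersion) || cfg$outcome_model$dispersion <= 0)
    fail("outcome_model", "dispersion must be positive")
  A <- cfg$trajectory_archetypes$means
  if (!is.matrix(A) || nrow(A) != 4 || ncol(A) != length(v))
    fail("trajectory_archetypes", "means must be a 4 x length(visit_months) matrix")
  if (any(A < 0 | A > 1)) fail("trajectory_archetypes", "means must lie in [0,1]")
  if (cfg$trajectory_archetypes$noise_sd < 0)
    fail("trajectory_archetypes", "noise_sd must be non-negative")
  cut <- cfg$normo_cut; nv <- length(v)
  if (!all(A[1, ] >= cut))
    fail("trajectory_archetypes", "non-responder mean must stay dysbiotic (>= normo_cut) at all visits")
  if (!all(A[4, -1] < cut))
    fail("trajectory_archetypes", "responder mean must be normobiotic (< normo_cut) at all post-baseline visits")
  if (!(A[3, 2] < cut && A[3, nv] >= cut))
    fail("trajectory_archetypes", "short-term responder must be normobiotic at the first post-baseline visit and dysbiotic at the final visit")
  if (!(A[1, nv] == max(A[, nv]) && A[4, nv] == min(A[, nv])))
    fail("trajectory_archetypes", "at the final visit the non-responder mean must be highest and the responder mean lowest")
  p <- cfg$covariate_dists
  if (length(p$age_probs) != 3 || abs(sum(p$age_probs) - 1) > 1e-8)
    fail("covariate_dists", "age_probs must be 3 probabilities summing to 1")
  invisible(cfg)
}

#' Read a cohort configuration from a YAML file
#'
#' Scalar and vector fields of [cohort_config()] may be given in the file;
#' anything omitted keeps its default.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(cohort_config, lst)
}

#' @noRd
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' @noRd
with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

# draw ordinal categories 0..3 from the proportional-odds model
# logit P(Y <= k) = cutpoint_k - eta; shared uniforms enable paired draws
#' @noRd
draw_category <- function(eta, cutpoints, u) {
  blocked <- outer(u, cutpoints, function(uu, z) uu > plogis(z - eta))
  rowSums(blocked)
}

#' @noRd
mediator_eta <- function(cfg, treatment, normo0, age_band, sex, smoking) {
  m <- cfg$mediator_model
  m$treatment * treatment + m$baseline_normo * normo0 +
    m$age45_55 * (age_band == "45<55") + m$age_gt55 * (age_band == ">55") +
    m$sex * (sex == "F") + m$smoking * smoking
}

#' @noRd
outcome_log_rate <- function(cfg, treatment, category, age_band, sex, smoking) {
  o <- cfg$outcome_model
  o$intercept + o$treatment * treatment + o$category * category +
    o$age45_55 * (age_band == "45<55") + o$age_gt55 * (age_band == ">55") +
    o$sex * (sex == "F") + o$smoking * smoking
}

#' Generate a synthetic randomized two-arm cohort
#'
#' Draws covariates, randomizes treatment (balanced permutation, independent
#' of covariates), draws each subject's microbial response category from the
#' configured proportional-odds model given treatment, the baseline
#' normobiotic indicator and covariates, realizes per-visit true dysbiosis
#' scores from the category archetype plus truncated Gaussian noise, emits
#' per-sample taxa counts as a multinomial over the mixture of the two
#' community distributions weighted by the true score, and draws the count of
#' sites with further attachment loss >= 1.3 mm from the configured negative
#' binomial model with log total sites as offset.
#'
#' @param config A [cohort_config()].
#' @param include_taxa Generate the taxa count table (default `TRUE`). Large
#'   recovery simulations that only need the mediator and clinical layers can
#'   switch this off.
#' @return An object of class `synthetic_cohort`: list with `counts`
#'   (a [taxa_count_table] or `NULL`), `metadata` (per-sample subject, visit,
#'   arm), `clinical` (per subject-visit site counts plus covariates) and
#'   `truth` (realized latent variables: per-subject category, baseline
#'   dysbiotic proportion, per-sample true score).
#' @export
generate_cohort <- function(config, include_taxa = TRUE) {
  validate_cohort_config(config)
  cfg <- config
  with_preserved_rng({
    set.seed(cfg$seed)
    n <- cfg$n_patients
    visits <- cfg$visit_months
    nv <- length(visits)
    subj <- sprintf("S%04d", seq_len(n))

    n_trt <- round(cfg$allocation * n)
    arm <- sample(rep(c("antibiotic", "placebo"), c(n_trt, n - n_trt)))
    trt <- as.integer(arm == "antibiotic")
    age_band <- sample(c("<45", "45<55", ">55"), n, TRUE, cfg$covariate_dists$age_probs)
    sex <- ifelse(runif(n) < cfg$covariate_dists$sex_prob, "F", "M")
    smoking <- rbinom(n, 1, cfg$covariate_dists$smoking_prob)

    theta0 <- rbeta(n, cfg$baseline_theta_params[1], cfg$baseline_theta_params[2])
    normo0 <- as.integer(theta0 < cfg$normo_cut)
    eta <- mediator_eta(cfg, trt, normo0, age_band, sex, smoking)
    category <- draw_category(eta, cfg$mediator_model$cutpoints, runif(n))

    A <- cfg$trajectory_archetypes$means
    noise <- matrix(rnorm(n * nv, 0, cfg$trajectory_archetypes$noise_sd), n, nv)
    score <- matrix(pmin(1, pmax(0, A[category + 1L, , drop = FALSE] + noise)),
                    n, nv)

    sample_id <- as.vector(t(outer(subj, visits, function(s, v) sprintf("%s_M%02d", s, v))))
    metadata <- data.frame(
      sample_id = sample_id,
      subject_id = rep(subj, each = nv),
      visit_month = rep(visits, n),
      arm = rep(arm, each = nv),
      stringsAsFactors = FALSE)
    true_score <- as.vector(t(score))

    counts <- NULL
    if (include_taxa) {
      phi_dys <- rdirichlet1(cfg$dys_topic_params)
      phi_norm <- rdirichlet1(cfg$norm_topic_params)
      lib <- pmax(100, round(rlnorm(n * nv,
        meanlog = log(cfg$library_size_mean) - cfg$library_size_sdlog^2 / 2,
        sdlog = cfg$library_size_sdlog)))
      cm <- matrix(0L, n * nv, cfg$vocab_size,
                   dimnames = list(sample_id, cfg$taxa))
      for (i in seq_len(n * nv)) {
        p <- true_score[i] * phi_dys + (1 - true_score[i]) * phi_norm
        cm[i, ] <- rmultinom(1, lib[i], p)[, 1]
      }
      counts <- taxa_count_table(cm, study = "synthetic")
      attr(counts, "topic_truth") <- list(phi_dys = phi_dys, phi_norm = phi_norm)
    }

    teeth <- pmin(28, pmax(18, 16 + rbinom(n, 16, 0.5)))
    sites_total <- 6L * teeth
    clin <- vector("list", nv)
    o <- cfg$outcome_model
    for (j in seq_len(nv)) {
      m <- visits[j]
      lr <- outcome_log_rate(cfg, trt, category, age_band, sex, smoking)
      frac <- if (max(visits) > 0) m / max(visits) else 0
      al13 <- if (m == 0) rep(0L, n) else
        rnbinom(n, mu = sites_total * exp(lr) * frac, size = o$dispersion)
      al13 <- pmin(al13, sites_total)
      sc <- score[, j]
      ppd5 <- rbinom(n, sites_total, plogis(-2.2 + 1.5 * sc))
      bleed <- rbinom(n, sites_total, plogis(-1.3 + 1.2 * sc))
      clin[[j]] <- data.frame(
        subject_id = subj, visit_month = m, arm = arm,
        sites_total = sites_total, sites_ppd5 = ppd5,
        sites_bleeding = bleed, sites_al13 = al13,
        age_band = age_band, sex = sex,
        smoking = ifelse(smoking == 1, "yes", "no"),
        stringsAsFactors = FALSE)
    }
    clinical <- do.call(rbind, clin)
    clinical <- clinical[order(clinical$subject_id, clinical$visit_month), ]
    rownames(clinical) <- NULL

    truth <- list(
      subjects = data.frame(subject_id = subj, arm = arm, category = category,
                            baseline_theta = theta0, baseline_normo = normo0,
                            age_band = age_band, sex = sex,
                            smoking = smoking, stringsAsFactors = FALSE),
      samples = data.frame(sample_id = sample_id, true_score = true_score,
                           stringsAsFactors = FALSE))

    structure(list(counts = counts, metadata = metadata, clinical = clinical,
                   truth = truth, config = cfg),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects x %d visits (%s taxa table)\n",
              x$config$n_patients, length(x$config$visit_months),
              if (is.null(x$counts)) "no" else
                paste0(ncol(x$counts$counts), "-taxon")))
  tab <- table(factor(x$truth$subjects$category, levels = 0:3))
  cat("  response categories 0..3:", paste(tab, collapse = " / "), "\n")
  invisible(x)
}

#' Generate healthy-control samples
#'
#' Single-visit samples whose true dysbiotic proportion is drawn from the
#' healthy Beta distribution of the configuration (mass concentrated near
#' zero). No clinical outcome records are produced.
#'
#' @param config A [cohort_config()].
#' @param n Number of control samples (>= 1).
#' @param seed Seed; defaults to `config$seed + 1` so controls differ from
#'   the patient cohort generated at the same configuration.
#' @return A `synthetic_cohort` with `clinical = NULL`.
#' @export
generate_healthy_controls <- function(config, n, seed = config$seed + 1L) {
  validate_cohort_config(config)
  if (length(n) != 1L || is.na(n) || n < 1) stop("`n` must be a positive integer")
  n <- as.integer(n)
  cfg <- config
  with_preserved_rng({
    set.seed(seed)
    theta <- rbeta(n, cfg$healthy_theta_params[1], cfg$healthy_theta_params[2])
    phi_dys <- rdirichlet1(cfg$dys_topic_params)
    phi_norm <- rdirichlet1(cfg$norm_topic_params)
    lib <- pmax(100, round(rlnorm(n,
      meanlog = log(cfg$library_size_mean) - cfg$library_size_sdlog^2 / 2,
      sdlog = cfg$library_size_sdlog)))
    ids <- sprintf("H%04d_M00", seq_len(n))
    cm <- matrix(0L, n, cfg$vocab_size, dimnames = list(ids, cfg$taxa))
    for (i in seq_len(n)) {
      p <- theta[i] * phi_dys + (1 - theta[i]) * phi_norm
      cm[i, ] <- rmultinom(1, lib[i], p)[, 1]
    }
    metadata <- data.frame(sample_id = ids,
                           subject_id = sprintf("H%04d", seq_len(n)),
                           visit_month = 0L, arm = "healthy",
                           stringsAsFactors = FALSE)
    structure(list(counts = taxa_count_table(cm, study = "healthy"),
                   metadata = metadata, clinical = NULL,
                   truth = list(samples = data.frame(sample_id = ids,
                                                     true_score = theta)),
                   config = cfg),
              class = "synthetic_cohort")
  })
}

#' Marginal treatment rate ratio implied by a configuration
#'
#' The configured outcome model conditions on the mediator, so the marginal
#' (unadjusted) treatment effect on attachment-loss rates is not one of its
#' parameters. This helper computes it by Monte Carlo: covariates and the
#' latent proportional-odds uniforms are drawn once and each subject's
#' expected rate is evaluated under both arms, giving the ratio of marginal
#' expected rates with a paired-delta-method standard error.
#'
#' @param config A [cohort_config()].
#' @param n_mc Number of Monte-Carlo subjects (>= 1e4).
#' @param seed Seed for the Monte-Carlo draw (default `config$seed`).
#' @return List with `estimate` (marginal rate ratio), `se` (Monte-Carlo
#'   standard error on the ratio scale) and `n_mc`.
#' @export
implied_total_effect <- function(config, n_mc = 1e5, seed = config$seed) {
  validate_cohort_config(config)
  if (n_mc < 1e4) stop("`n_mc` must be at least 10^4")
  cfg <- config
  with_preserved_rng({
    set.seed(seed)
    age_band <- sample(c("<45", "45<55", ">55"), n_mc, TRUE,
                       cfg$covariate_dists$age_probs)
    sex <- ifelse(runif(n_mc) < cfg$covariate_dists$sex_prob, "F", "M")
    smoking <- rbinom(n_mc, 1, cfg$covariate_dists$smoking_prob)
    theta0 <- rbeta(n_mc, cfg$baseline_theta_params[1], cfg$baseline_theta_params[2])
    normo0 <- as.integer(theta0 < cfg$normo_cut)
    u <- runif(n_mc)
    rate_under <- function(trt) {
      eta <- mediator_eta(cfg, trt, normo0, age_band, sex, smoking)
      cat_ <- draw_category(eta, cfg$mediator_model$cutpoints, u)
      exp(outcome_log_rate(cfg, trt, cat_, age_band, sex, smoking))
    }
    r1 <- rate_under(1L); r0 <- rate_under(0L)
    m1 <- mean(r1); m0 <- mean(r0)
    est <- m1 / m0
    v <- (stats::var(r1) / m1^2 + stats::var(r0) / m0^2 -
            2 * stats::cov(r1, r0) / (m1 * m0)) / n_mc
    list(estimate = est, se = est * sqrt(pmax(v, 0)), n_mc = n_mc)
  })
}

#' Calibrate the generator to a target marginal treatment effect
#'
#' Solves for the mediator-model treatment log-odds such that the marginal
#' treatment rate ratio implied by the configuration (see
#' [implied_total_effect()]) equals `target_rr`, by root finding on a fixed
#' Monte-Carlo draw.
#'
#' @param config A [cohort_config()].
#' @param target_rr Target marginal rate ratio (e.g. 0.73).
#' @param n_mc Monte-Carlo size used during root finding.
#' @param interval Search interval for the treatment log-odds.
#' @param seed Seed of the fixed Monte-Carlo draw.
#' @return The calibrated `cohort_config`; attribute `"calibration"` records
#'   the solved log-odds and the achieved implied rate ratio.
#' @export
calibrate_total_effect <- function(config, target_rr, n_mc = 2e5,
                                   interval = c(-2, 4), seed = config$seed) {
  validate_cohort_config(config)
  f <- function(g) {
    cfg <- config
    cfg$mediator_model$treatment <- g
    implied_total_effect(cfg, n_mc = n_mc, seed = seed)$estimate - target_rr
  }
  root <- uniroot(f, interval, tol = 1e-5)
  out <- config
  out$mediator_model$treatment <- root$root
  achieved <- implied_total_effect(out, n_mc = n_mc, seed = seed)
  attr(out, "calibration") <- list(treatment_log_odds = root$root,
                                   achieved_rr = achieved$estimate,
                                   mc_se = achieved$se, target_rr = target_rr)
  out
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `counts.tsv` (taxa x samples), `samples.tsv`, `clinical.tsv` and
#' `truth_subjects.tsv` / `truth_samples.tsv` into a directory.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$counts))
    write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(cohort$metadata, "samples.tsv")
  if (!is.null(cohort$clinical)) wt(cohort$clinical, "clinical.tsv")
  if (!is.null(cohort$truth$subjects)) wt(cohort$truth$subjects, "truth_subjects.tsv")
  wt(cohort$truth$samples, "truth_samples.tsv")
  invisible(dir)
}
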