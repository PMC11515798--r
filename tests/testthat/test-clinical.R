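test_that("median dichotomization follows the literal below-median rule", {
  clin <- data.frame(subject_id = c("A", "B", "C"), visit_month = 26,
                     sites_total = 100,
                     sites_ppd5 = c(10L, 20L, 30L))
  ind <- median_dichotomize(clin, "ppd5", 26)
  expect_identical(as.vector(ind), c(1L, 0L, 0L))  # tie at the median -> above
  expect_equal(attr(ind, "median"), 20)

  clin$sites_ppd5 <- c(15L, 15L, 15L)
  expect_identical(as.vector(median_dichotomize(clin, "ppd5", 26)), c(0L, 0L, 0L))

  expect_error(median_dichotomize(clin[1, ], "ppd5", 26), "at least 2")
  clin$sites_bleeding <- NA_integer_
  expect_error(median_dichotomize(clin, "bleeding", 26), "not available")
})

test_that("median split is invariant to monotone rescaling and near-balanced on cohorts", {
  co <- generate_cohort(cohort_config(seed = 3), include_taxa = FALSE)
  ind <- median_dichotomize(co$clinical, "al13", 26)
  doubled <- co$clinical
  doubled$sites_al13 <- doubled$sites_al13 * 2L
  doubled$sites_total <- doubled$sites_total * 2L  # keep counts <= totals
  prev <- mean(ind)
  expect_gte(prev, 0.40); expect_lte(prev, 0.60)

  prevs <- sapply(1:50, function(s) {
    co <- generate_cohort(cohort_config(seed = 1000 + s), include_taxa = FALSE)
    mean(median_dichotomize(co$clinical, "ppd5", 2))
  })
  expect_true(all(prevs >= 0.40 & prevs <= 0.60))
})

test_that("treat-to-target is a boundary-inclusive site-count rule", {
  expect_true(treat_to_target(data.frame(sites_ppd5 = 4L)))
  expect_false(treat_to_target(data.frame(sites_ppd5 = 5L)))
  expect_true(treat_to_target(0L))
  expect_identical(treat_to_target(c(0L, 4L, 5L, 9L)),
                   c(TRUE, TRUE, FALSE, FALSE))
})

test_that("logistic association models reject degenerate outcomes and separation", {
  expect_error(fit_logistic(rep(1L, 10), runif(10)), "single class")
  # perfectly separating exposure
  y <- rep(0:1, each = 20)
  x <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  expect_error(fit_logistic(y, x), "separation.*exposure")
})

test_that("logistic CIs attain nominal coverage under the null", {
  set.seed(14)
  cover <- replicate(100, {
    n <- 500
    x <- rbeta(n, 2, 2)
    y <- rbinom(n, 1, 0.4)
    r <- fit_logistic(y, x)
    cf <- r$coefficients[r$coefficients$term == "exposure_scaled", ]
    cf$lower <= 1 && 1 <= cf$upper
  })
  expect_gte(sum(cover), 93)
})

test_that("logistic fits recover a configured association per 0.1 exposure", {
  set.seed(15)
  truth <- log(1.26)  # odds ratio per 0.1 normobiotic increase
  est <- replicate(200, {
    n <- 2000
    x <- rbeta(n, 2, 2)
    smoke <- rbinom(n, 1, 0.3)
    lp <- -0.5 + truth * (x / 0.1) + 0.4 * smoke
    y <- rbinom(n, 1, plogis(lp))
    r <- fit_logistic(y, x, covariates = data.frame(smoke = smoke))
    r$coefficients$estimate[r$coefficients$term == "exposure_scaled"]
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se)
})

test_that("ordinal mediator model needs variation and recovers a null", {
  co <- generate_cohort(cohort_config(seed = 8), include_taxa = FALSE)
  md <- mediator_frame(co)
  md$category <- 0L
  expect_error(fit_ordinal_mediator(md), "fewer than 3")

  set.seed(9)
  nulls <- replicate(30, {
    n <- 400
    trt <- rbinom(n, 1, 0.5)
    normo <- rbinom(n, 1, 0.2)
    u <- runif(n)
    eta <- 1.5 * normo
    y <- rowSums(outer(u, c(-0.5, 0.5, 1.5), function(uu, z) uu > plogis(z - eta)))
    d <- data.frame(category = y, treatment = trt, baseline_normo = normo)
    r <- fit_ordinal_mediator(d, covariates = character(0))
    r$coefficients$estimate[r$coefficients$term == "treatment"]
  })
  expect_lt(abs(mean(nulls)), 3 * sd(nulls) / sqrt(length(nulls)) + 0.02)
})

test_that("the proportional-odds heuristic flags non-proportional effects", {
  set.seed(10)
  n <- 3000
  x <- rbinom(n, 1, 0.5)
  # sequential generation with a sign-flipping effect: grossly non-proportional
  y <- (runif(n) < plogis(-0.5 + 1.8 * x)) + 0
  y <- y + ifelse(y == 1 & runif(n) < plogis(-0.5 - 2.5 * x), 1, 0)
  y <- y + ifelse(y == 2 & runif(n) < 0.4, 1, 0)
  d <- data.frame(category = y, treatment = x, baseline_normo = rbinom(n, 1, 0.3))
  r <- suppressWarnings(fit_ordinal_mediator(d, covariates = character(0)))
  expect_true(isTRUE(r$non_proportional))

  # and stays quiet under proportional generation
  co <- generate_cohort(cohort_config(n_patients = 2000, seed = 12),
                        include_taxa = FALSE)
  r2 <- fit_ordinal_mediator(mediator_frame(co))
  expect_false(isTRUE(r2$non_proportional))
})

test_that("NB fits approach Poisson as dispersion vanishes and respect the offset", {
  set.seed(20)
  n <- 4000
  st <- 6L * sample(20:28, n, TRUE)
  trt <- rbinom(n, 1, 0.5)
  mu <- st * exp(-2.8 - 0.25 * trt)
  y <- stats::rpois(n, mu)  # dispersion -> 0 limit
  d <- data.frame(sites_al13 = y, sites_total = st, treatment = trt)
  nb <- fit_nb_outcome(d, "treatment")
  pois <- glm(sites_al13 ~ treatment + offset(log(sites_total)), data = d,
              family = stats::poisson())
  expect_lt(max(abs(coef(pois) - nb$coefficients$estimate)), 0.01)

  # offset contract: doubling all totals (counts regenerated) leaves the
  # rate ratio unchanged within Monte-Carlo error
  set.seed(21)
  y2 <- stats::rnbinom(n, mu = 2 * st * exp(-2.8 - 0.25 * trt), size = 2)
  d2 <- data.frame(sites_al13 = y2, sites_total = 2L * st, treatment = trt)
  nb2 <- fit_nb_outcome(d2, "treatment")
  b1 <- nb$coefficients[nb$coefficients$term == "treatment", ]
  b2 <- nb2$coefficients[nb2$coefficients$term == "treatment", ]
  expect_lt(abs(b1$estimate - b2$estimate),
            3 * sqrt(b1$se^2 + b2$se^2))

  expect_error(fit_nb_outcome(d, character(0)), "at least one predictor")
  d$sites_al13[1] <- d$sites_total[1] + 1L
  expect_error(fit_nb_outcome(d, "treatment"), "exceed total sites")
})

test_that("prediction grids are multiplicative and scale with total sites", {
  co <- generate_cohort(cohort_config(seed = 22), include_taxa = FALSE)
  d <- final_visit_frame(co)
  nb <- fit_nb_outcome(d, c("treatment", "category", "age_band", "smoking"))
  grid <- prediction_grid(nb, sites_total = 146)
  expect_identical(nrow(grid), 2L * 4L * 3L * 2L)

  rr_trt <- nb$coefficients$effect[nb$coefficients$term == "treatment"]
  g0 <- grid[grid$treatment == 0, ]
  g1 <- grid[grid$treatment == 1, ]
  key <- function(g) paste(g$category, g$age_band, g$smoking)
  g1 <- g1[match(key(g0), key(g1)), ]
  expect_equal(g1$expected_sites / g0$expected_sites,
               rep(rr_trt, nrow(g0)), tolerance = 1e-8)

  rr_cat <- nb$coefficients$effect[nb$coefficients$term == "category"]
  gg <- grid[grid$treatment == 0 & grid$smoking == "no" &
               grid$age_band == "<45", ]
  gg <- gg[order(gg$category), ]
  expect_equal(gg$expected_sites[-1] / gg$expected_sites[-4],
               rep(rr_cat, 3), tolerance = 1e-8)

  doubled <- prediction_grid(nb, sites_total = 292)
  expect_equal(doubled$expected_sites, 2 * grid$expected_sites,
               tolerance = 1e-10)

  bad <- expand.grid(treatment = 0:1, category = 0:3,
                     age_band = "ancient", smoking = "no",
                     stringsAsFactors = FALSE)
  expect_error(prediction_grid(nb, grid = bad), "unknown level")
})

test_that("rate-ratio projections do the published worked-example arithmetic", {
  p <- treatment_effect_projection(8, 1 - 0.19)
  expect_equal(round(p$expected, 1), 6.5)
  p2 <- treatment_effect_projection(14.91, 1 - 0.19)
  expect_equal(round(p2$reduction, 1), 2.8)
})
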