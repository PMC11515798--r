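test_that("the study DAG is acyclic with randomized treatment", {
  dag <- build_study_dag()
  expect_s3_class(dag, "causal_dag")
  expect_identical(dag_parents(dag, "treatment"), character(0))
  expect_identical(dag_parents(dag, "response_pattern"),
                   sort(c("treatment", "baseline_characteristics",
                          "age", "sex", "smoking")))
  expect_error(causal_dag(c("a", "b"), rbind(c("a", "b"), c("b", "a"))),
               "cycle")
  expect_error(causal_dag("a", rbind(c("a", "z"))), "undeclared")
})

test_that("adjustment sets match textbook graphs", {
  # confounded triangle: Z -> A, Z -> B, A -> B
  tri <- causal_dag(c("A", "B", "Z"),
                    rbind(c("Z", "A"), c("Z", "B"), c("A", "B")))
  expect_identical(backdoor_adjustment_sets(tri, "A", "B"), list("Z"))

  # chain A -> M -> B: nothing to adjust
  chain <- causal_dag(c("A", "M", "B"), rbind(c("A", "M"), c("M", "B")))
  expect_identical(backdoor_adjustment_sets(chain, "A", "B"),
                   list(character(0)))

  # collider A -> C <- B with A -> B: still nothing to adjust
  coll <- causal_dag(c("A", "B", "C"),
                     rbind(c("A", "C"), c("B", "C"), c("A", "B")))
  expect_identical(backdoor_adjustment_sets(coll, "A", "B"),
                   list(character(0)))

  expect_error(backdoor_adjustment_sets(tri, "A", "A"), "differ")
})

test_that("study DAG: empty set for the total effect, confounders plus treatment for the mediator", {
  dag <- build_study_dag()
  total <- backdoor_adjustment_sets(dag, "treatment", "al13_outcome")
  expect_identical(total, list(character(0)))

  med <- backdoor_adjustment_sets(dag, "response_pattern", "al13_outcome")
  expect_true(all(c("age", "sex", "smoking") %in% med[[1]]))
  expect_identical(sort(med[[1]]), c("age", "sex", "smoking", "treatment"))

  # dropping the confounder edges leaves only the treatment fork
  dag2 <- dag
  dag2$edges <- dag2$edges[!(dag2$edges$from %in% c("age", "sex", "smoking")), ]
  med2 <- backdoor_adjustment_sets(dag2, "response_pattern", "al13_outcome")
  expect_identical(med2, list("treatment"))
})

test_that("d-separation and minimal sets agree with the moral-graph oracle", {
  dags <- list(
    build_study_dag(),
    causal_dag(c("A", "B", "Z"), rbind(c("Z", "A"), c("Z", "B"), c("A", "B"))),
    causal_dag(c("A", "M", "B"), rbind(c("A", "M"), c("M", "B"))),
    # butterfly/M-structure: U1 -> X, U1 -> C, U2 -> C, U2 -> Y, X -> Y
    causal_dag(c("X", "Y", "C", "U1", "U2"),
               rbind(c("U1", "X"), c("U1", "C"), c("U2", "C"), c("U2", "Y"),
                     c("X", "Y"))),
    # 6-node tangle
    causal_dag(c("X", "Y", "A", "B", "C", "D"),
               rbind(c("A", "X"), c("A", "B"), c("B", "Y"), c("X", "C"),
                     c("C", "Y"), c("D", "X"), c("D", "Y"))))
  for (dag in dags) {
    xy <- if ("X" %in% dag$nodes) c("X", "Y") else
      c(dag$nodes[1], if ("B" %in% dag$nodes) "B" else dag$nodes[2])
    if (identical(dag$nodes[1], "treatment")) xy <- c("treatment", "al13_outcome")
    others <- setdiff(dag$nodes, xy)
    # every conditioning subset agrees between implementation and oracle
    for (size in 0:length(others)) {
      combos <- if (size == 0) list(character(0)) else
        apply(combn(others, size), 2, identity, simplify = FALSE)
      for (z in combos)
        expect_identical(d_separated(dag, xy[1], xy[2], z),
                         dsep_moral(dag, xy[1], xy[2], z),
                         info = paste(xy[1], xy[2], paste(z, collapse = "+")))
    }
    # minimal backdoor sets agree with subset brute force
    expect_identical(canon_sets(backdoor_adjustment_sets(dag, xy[1], xy[2])),
                     canon_sets(backdoor_brute(dag, xy[1], xy[2])))
  }
})

test_that("M-structure adjustment avoids the collider", {
  mdag <- causal_dag(c("X", "Y", "C", "U1", "U2"),
                     rbind(c("U1", "X"), c("U1", "C"), c("U2", "C"),
                           c("U2", "Y"), c("X", "Y")))
  sets <- backdoor_adjustment_sets(mdag, "X", "Y")
  expect_true(any(vapply(sets, length, integer(1)) == 0L))
  # conditioning on C alone opens the path: not a valid singleton set
  expect_false(any(vapply(sets, function(s) identical(s, "C"), logical(1))))
})

test_that("difference-method identities hold for degenerate and normal posteriors", {
  # point masses at the published total and direct effects
  tot <- rep(log(0.73), 4000)
  dir <- rep(log(0.82), 4000)
  mr <- mediation_difference(tot, dir)
  expect_equal(round(mr$indirect$rr, 2), 0.89)
  expect_equal(mr$indirect$rr, 0.73 / 0.82, tolerance = 1e-12)

  # identical draw sets: identity pairing collapses the interval at 1
  set.seed(2)
  x <- rnorm(5000, -0.2, 0.1)
  id <- mediation_difference(x, x, pairing = "identity")
  expect_equal(id$indirect$rr, 1)
  expect_equal(diff(id$indirect$ci), 0)
  rnd <- mediation_difference(x, x, pairing = "random")
  expect_equal(rnd$indirect$rr, 1, tolerance = 0.01)

  # independent normals: the difference matches the convolution moments
  a <- rnorm(20000, -0.4, 0.15)
  b <- rnorm(20000, -0.1, 0.2)
  conv <- mediation_difference(a, b)
  expect_equal(mean(conv$draws_indirect), -0.3, tolerance = 0.01)
  expect_equal(sd(conv$draws_indirect), sqrt(0.15^2 + 0.2^2), tolerance = 0.01)

  expect_error(mediation_difference(rnorm(10), rnorm(9)), "subsample")
  sub <- mediation_difference(rnorm(1000), rnorm(900), subsample = TRUE)
  expect_identical(sub$n_draws, 900L)
})

test_that("Bayesian NB posteriors agree with maximum likelihood at large n", {
  co <- generate_cohort(cohort_config(n_patients = 1500, seed = 33),
                        include_taxa = FALSE)
  d <- final_visit_frame(co)
  ml <- fit_nb_outcome(d, c("treatment", "category"))
  bf <- fit_bayesian_nb(d, c("treatment", "category"), seed = 5,
                        adapt = 300, burn = 300, iter = 600)
  for (term in c("treatment", "category")) {
    post <- bf$draws[, paste0("b_", term)]
    mlest <- ml$coefficients$estimate[ml$coefficients$term == term]
    expect_lt(abs(median(post) - mlest), 3 * sd(post))
  }
  expect_true(all(bf$rhat < 1.05, na.rm = TRUE))
  expect_error(fit_bayesian_nb(d[0, ], "treatment"), "no rows")
})

test_that("near-flat priors reproduce the conjugate gamma posterior in the Poisson limit", {
  set.seed(6)
  n <- 40
  y <- stats::rpois(n, 5)
  # a common exposure of 100 sites; the near-flat coefficient prior and a
  # huge NB size prior put the model in its Poisson limit with an
  # effectively flat prior on the log rate, whose posterior is then
  # Gamma(sum y, total exposure)
  d <- data.frame(sites_al13 = as.integer(y), sites_total = 100L)
  bf <- fit_bayesian_nb(d, character(0),
                        priors = list(coef_sd = 10, size_sd = 2000),
                        seed = 8, adapt = 500, burn = 500, iter = 1500)
  rate_draws <- exp(bf$draws[, "b_(Intercept)"])
  expo <- 100 * n
  expect_equal(mean(rate_draws) / (sum(y) / expo), 1, tolerance = 0.03)
  expect_equal(sd(rate_draws) / (sqrt(sum(y)) / expo), 1, tolerance = 0.15)
})

test_that("the full mediation analysis derives its models from the DAG", {
  co <- generate_cohort(cohort_config(seed = 44), include_taxa = FALSE)
  d <- final_visit_frame(co)
  ma <- run_mediation_analysis(d, seed = 9, adapt = 250, burn = 250, iter = 500)
  expect_identical(sort(ma$total_fit$terms), sort(c("(Intercept)", "treatment")))
  expect_true(all(c("treatment", "category", "smokingyes") %in%
                    ma$direct_fit$terms))
  expect_identical(length(ma$mediation$draws_indirect), 2000L)
  expect_true(ma$mediation$total$ci[1] < ma$mediation$total$rr &&
                ma$mediation$total$rr < ma$mediation$total$ci[2])

  # removing the confounder edges changes the direct-model specification
  dag2 <- build_study_dag()
  dag2$edges <- dag2$edges[!(dag2$edges$from %in% c("age", "sex", "smoking")), ]
  ma2 <- run_mediation_analysis(d, dag = dag2, seed = 9, adapt = 250,
                                burn = 250, iter = 500)
  expect_false("smokingyes" %in% ma2$direct_fit$terms)
  expect_true("category" %in% ma2$direct_fit$terms)
})
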