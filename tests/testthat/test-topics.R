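test_that("disjoint-vocabulary corpora separate cleanly", {
  # documents large enough that the document-topic prior (alpha = 25 by
  # default) cannot blur the separation
  m <- rbind(s1 = c(a = 300L, b = 200L, c = 0L, d = 0L),
             s2 = c(a = 0L, b = 0L, c = 260L, d = 240L))
  fit <- fit_topics(taxa_count_table(m), n_iterations = 500, burn_in = 100,
                    seed = 2)
  # each sample loads >= 0.9 on its own topic, and those topics differ
  k1 <- which.max(fit$doc_topic["s1", ])
  k2 <- which.max(fit$doc_topic["s2", ])
  expect_false(k1 == k2)
  expect_gte(fit$doc_topic["s1", k1], 0.9)
  expect_gte(fit$doc_topic["s2", k2], 0.9)
  expect_gte(sum(fit$topic_word[k1, c("a", "b")]), 0.9)
  expect_gte(sum(fit$topic_word[k2, c("c", "d")]), 0.9)
})

test_that("a single-taxon corpus collapses both topics to the point mass", {
  m <- rbind(s1 = c(only = 5L), s2 = c(only = 3L))
  fit <- fit_topics(taxa_count_table(m), n_iterations = 100, burn_in = 20)
  expect_equal(unname(fit$topic_word[, 1]), c(1, 1))
})

test_that("simplex constraints hold on fits", {
  co <- generate_cohort(fast_config())
  fit <- fit_topics(co$counts, n_iterations = 120, burn_in = 40, seed = 5)
  expect_true(all(abs(rowSums(fit$doc_topic) - 1) < 1e-8))
  expect_true(all(abs(rowSums(fit$topic_word) - 1) < 1e-8))
  expect_true(all(fit$doc_topic >= 0) && all(fit$topic_word >= 0))
})

test_that("Gibbs posterior means match exhaustive enumeration on tiny corpora", {
  cases <- list(
    rbind(s1 = c(x = 2L, y = 1L, z = 0L), s2 = c(x = 0L, y = 1L, z = 2L)),
    rbind(s1 = c(x = 3L, y = 1L, z = 0L), s2 = c(x = 0L, y = 2L, z = 2L)),
    rbind(s1 = c(x = 2L, y = 0L), s2 = c(x = 0L, y = 2L), s3 = c(x = 2L, y = 2L)))
  for (m in cases) {
    oracle <- lda_enum_doc_topic(m, K = 2, alpha = 0.5, eta = 0.5)
    fit <- fit_topics(taxa_count_table(m), K = 2, alpha = 0.5, eta = 0.5,
                      n_iterations = 30000, burn_in = 3000, seed = 7)
    # topics are exchangeable: compare against both column orders
    d1 <- max(abs(fit$doc_topic - oracle))
    d2 <- max(abs(fit$doc_topic[, 2:1] - oracle))
    expect_lt(min(d1, d2), 0.02)
  }
})

test_that("fits are exactly equivariant to sample order", {
  co <- generate_cohort(fast_config())
  tab <- co$counts
  perm <- sample(nrow(tab$counts))
  tab_perm <- taxa_count_table(tab$counts[perm, ], study = tab$study[perm])
  f1 <- suppressWarnings(fit_topics(tab, n_iterations = 60, burn_in = 20, seed = 3))
  f2 <- suppressWarnings(fit_topics(tab_perm, n_iterations = 60, burn_in = 20, seed = 3))
  expect_identical(f1$doc_topic[tab_perm$sample_ids, ], f2$doc_topic)
  expect_identical(f1$topic_word, f2$topic_word[, colnames(f1$topic_word)])
})

test_that("labeling identifies the pathobiont-heavy topic and rejects ties", {
  co <- generate_cohort(fast_config())
  fit <- fit_topics(co$counts, n_iterations = 150, burn_in = 50, seed = 5)
  lab <- label_topics(fit)
  ev <- lab$evidence
  expect_gt(ev[lab$dysbiotic_topic_index, "pathobiont_mass"],
            ev[lab$normobiotic_topic_index, "pathobiont_mass"])
  expect_gt(lab$margin, 0)

  # constructed tie
  fake <- fit
  fake$topic_word[] <- 1 / ncol(fake$topic_word)
  expect_error(label_topics(fake), "ambiguous")

  expect_error(label_topics(fit, pathobiont_list = "No such taxon",
                            commensal_list = "Another missing taxon"),
               "none of the listed taxa")
  expect_error(label_topics(fit, pathobiont_list = c("A"), commensal_list = c("A")),
               "disjoint")
})

test_that("dysbiosis score is the dysbiotic loading and complements normobiosis", {
  co <- generate_cohort(fast_config())
  fit <- fit_topics(co$counts, n_iterations = 150, burn_in = 50, seed = 5)
  lab <- label_topics(fit)
  sc <- dysbiosis_score(fit, lab)
  expect_true(all(sc >= 0 & sc <= 1))
  normo <- fit$doc_topic[, lab$normobiotic_topic_index]
  expect_true(all(abs(sc + normo - 1) < 1e-8))
  # tracks the generator's true mixing weight
  truth <- setNames(co$truth$samples$true_score, co$truth$samples$sample_id)
  expect_gte(cor(sc, truth[names(sc)]), 0.9)
})

test_that("the score is a faithful surrogate of the pathobiont/commensal log-ratio", {
  co <- generate_cohort(cohort_config(n_patients = 60, vocab_size = 120,
                                      library_size_mean = 5000, seed = 17))
  fit <- fit_topics(co$counts, n_iterations = 150, burn_in = 50, seed = 3)
  lab <- label_topics(fit)
  sc <- dysbiosis_score(fit, lab)
  cm <- co$counts$counts
  patho <- rowSums(cm[, intersect(pathobiont_taxa(), colnames(cm)), drop = FALSE])
  comm <- rowSums(cm[, intersect(commensal_taxa(), colnames(cm)), drop = FALSE])
  lr <- log((patho + 0.5) / (comm + 0.5))
  expect_gte(cor(sc, lr[names(sc)], method = "spearman"), 0.8)
})

test_that("fold-in reproduces training scores and respects monotonicity", {
  co <- generate_cohort(fast_config())
  fit <- fit_topics(co$counts, n_iterations = 150, burn_in = 50, seed = 5)
  lab <- label_topics(fit)
  train <- dysbiosis_score(fit, lab)
  sub <- subset_samples(co$counts, co$counts$sample_ids[1:20])
  folded <- fold_in(fit, sub, lab, seed = 9, n_iterations = 300, burn_in = 60)
  expect_lt(max(abs(folded - train[names(folded)])), 0.05)

  # a sample built from the top dysbiotic-topic taxa scores high
  top <- names(sort(fit$topic_word[lab$dysbiotic_topic_index, ],
                    decreasing = TRUE))[1:5]
  m <- matrix(200L, 1, 5, dimnames = list("new1", top))
  expect_gt(fold_in(fit, taxa_count_table(m), lab, seed = 1), 0.9)

  # adding dysbiotic counts to a mixed sample never decreases the score
  base <- co$counts$counts[3, , drop = FALSE]
  prev <- -Inf
  for (extra in c(0L, 200L, 800L, 3000L)) {
    m2 <- base
    m2[, top] <- m2[, top] + extra
    rownames(m2) <- "probe"
    s <- fold_in(fit, taxa_count_table(m2), lab, seed = 4,
                 n_iterations = 300, burn_in = 60)
    expect_gte(s, prev - 0.01)
    prev <- s
  }

  # zero vocabulary overlap errors
  m3 <- matrix(5L, 1, 2, dimnames = list("n1", c("alien1", "alien2")))
  expect_error(predict(fit, taxa_count_table(m3)), "no overlap")
})

test_that("healthy/disease contrast behaves at the edges", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  same <- healthy_vs_disease_contrast(x, x)
  expect_equal(same$median_difference, 0)
  expect_gt(same$p_value, 0.9)
  expect_error(healthy_vs_disease_contrast(0.5, c(0.1, 0.2)), "at least 2")
})

test_that("degenerate fit arguments are rejected", {
  tab <- toy_counts()
  expect_error(fit_topics(tab, K = 1), "at least 2")
  expect_error(fit_topics(tab, n_iterations = 10, burn_in = 10), "exceed")
  m <- rbind(s1 = c(a = 1L, b = 1L), s2 = c(a = 1L, b = 1L))
  expect_error(fit_topics(taxa_count_table(m), K = 3), "vocabulary smaller")
})
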