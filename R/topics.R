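#' Fit the latent community (topic) model
#'
#' Fits latent Dirichlet allocation to a taxa count table by collapsed Gibbs
#' sampling. Each topic is a distribution over taxa (a microbial community of
#' co-occurring taxa); each sample is a mixture over topics. The number of
#' topics defaults to two so that the fitted communities can be labeled
#' dysbiotic and normobiotic (see [label_topics()]). Point estimates are
#' posterior means of the smoothed topic proportions over post-burn-in
#' sweeps.
#'
#' Samples and taxa are canonicalized to a sorted order internally before
#' sampling, so the fit is invariant to row and column permutations of the
#' input: permuting samples permutes the fitted loadings identically.
#'
#' @param table A [taxa_count_table].
#' @param K Number of topics (>= 2; default 2).
#' @param alpha Document-topic Dirichlet concentration (default `50 / K`).
#' @param eta Topic-word Dirichlet concentration (default 0.1).
#' @param seed Integer seed of the sampler (deterministic given the seed).
#' @param n_iterations Total Gibbs sweeps (default 200).
#' @param burn_in Sweeps discarded before averaging (default
#'   `n_iterations %/% 4`).
#' @return An object of class `topic_fit` with elements `topic_word`
#'   (K x taxa, rows on the simplex), `doc_topic` (samples x K, rows on the
#'   simplex), `alpha`, `eta`, `seed`, `n_iterations`, `burn_in`,
#'   `loglik_trace` and `converged` (heuristic flag; `FALSE` with a warning
#'   when the trace is still trending at the end).
#' @export
fit_topics <- function(table, K = 2, alpha = 50 / K, eta = 0.1, seed = 1L,
                       n_iterations = 200, burn_in = n_iterations %/% 4) {
  stopifnot(inherits(table, "taxa_count_table"))
  if (nrow(table$counts) < 1) stop("count table is empty")
  if (K < 2) stop("`K` must be at least 2")
  if (ncol(table$counts) < K && ncol(table$counts) > 1)
    stop("vocabulary smaller than K")
  if (n_iterations <= burn_in) stop("`n_iterations` must exceed `burn_in`")
  if (alpha <= 0 || eta <= 0) stop("`alpha` and `eta` must be positive")

  ord_s <- order(table$sample_ids)
  ord_t <- order(table$taxon_ids)
  m <- table$counts[ord_s, ord_t, drop = FALSE]

  res <- lda_gibbs_cpp(m, as.integer(K), alpha, eta,
                       as.integer(n_iterations), as.integer(burn_in),
                       as.integer(seed))
  theta <- res$doc_topic
  phi <- res$topic_word
  rownames(theta) <- rownames(m)
  colnames(theta) <- paste0("topic", seq_len(K))
  rownames(phi) <- paste0("topic", seq_len(K))
  colnames(phi) <- colnames(m)

  # undo the canonical ordering
  theta <- theta[match(table$sample_ids, rownames(theta)), , drop = FALSE]
  phi <- phi[, match(table$taxon_ids, colnames(phi)), drop = FALSE]

  ll <- res$loglik
  converged <- loglik_converged(ll)
  fit <- structure(list(K = as.integer(K), topic_word = phi,
                        doc_topic = theta, alpha = alpha, eta = eta,
                        seed = as.integer(seed),
                        n_iterations = as.integer(n_iterations),
                        burn_in = as.integer(burn_in),
                        loglik_trace = ll, converged = converged,
                        vocab = table$taxon_ids,
                        sample_ids = table$sample_ids,
                        n_tokens = res$n_tokens),
                   class = "topic_fit")
  if (!converged)
    warning("log-likelihood still trending at the last iterations; ",
            "consider more sweeps", call. = FALSE)
  fit
}

# trend heuristic: mean of the last tenth should not exceed the mean of the
# third quarter by more than a trace-noise margin
#' @noRd
loglik_converged <- function(ll) {
  n <- length(ll)
  if (n < 20) return(TRUE)
  last <- ll[seq(floor(0.9 * n) + 1, n)]
  mid <- ll[seq(floor(0.5 * n) + 1, floor(0.75 * n))]
  drift <- mean(last) - mean(mid)
  noise <- 3 * sd(last) / sqrt(length(last)) + 2 * sd(last)
  drift <= max(noise, 0.01 * diff(range(ll)))
}

#' @export
print.topic_fit <- function(x, ...) {
  cat(sprintf("topic_fit: K = %d topics over %d taxa, %d samples (%.0f tokens)\n",
              x$K, length(x$vocab), length(x$sample_ids), x$n_tokens))
  cat(sprintf("  collapsed Gibbs: %d sweeps (burn-in %d), seed %d, alpha %.3g, eta %.3g\n",
              x$n_iterations, x$burn_in, x$seed, x$alpha, x$eta))
  if (!x$converged) cat("  warning: likelihood trace still trending\n")
  invisible(x)
}

#' @export
summary.topic_fit <- function(object, n_top = 8, ...) {
  cat(sprintf("Topic model with K = %d topics\n\n", object$K))
  for (k in seq_len(object$K)) {
    top <- sort(object$topic_word[k, ], decreasing = TRUE)[seq_len(n_top)]
    cat(sprintf("topic%d top taxa:\n", k))
    for (i in seq_along(top))
      cat(sprintf("  %-45s %.3f\n", names(top)[i], top[i]))
  }
  invisible(object)
}

#' @export
plot.topic_fit <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$loglik_trace, type = "l", xlab = "Gibbs sweep",
       ylab = "collapsed log-likelihood", main = "trace")
  barplot(t(x$doc_topic), border = NA, space = 0, col = seq_len(x$K) + 1,
          main = "topic loadings", xlab = "samples", ylab = "proportion")
  invisible(x)
}

#' Score new samples against a fitted topic model (fold-in)
#'
#' Infers topic proportions for new samples with the fitted topic-word
#' distributions held fixed, by Gibbs sampling of the new samples' topic
#' assignments only. Taxa absent from the fitted vocabulary are dropped; the
#' dropped count fraction is reported via the `"dropped_fraction"` attribute.
#'
#' @param object A [fit_topics()] fit.
#' @param newdata A [taxa_count_table] of samples to score; must share at
#'   least one taxon with the fitted vocabulary.
#' @param seed Sampler seed.
#' @param n_iterations,burn_in Gibbs sweeps for the fold-in chains.
#' @param ... Unused.
#' @return Matrix (new samples x K) of topic proportions.
#' @export
predict.topic_fit <- function(object, newdata, seed = 1L,
                              n_iterations = 200,
                              burn_in = n_iterations %/% 4, ...) {
  stopifnot(inherits(newdata, "taxa_count_table"))
  shared <- intersect(object$vocab, newdata$taxon_ids)
  if (!length(shared))
    stop("no overlap between the fitted vocabulary and the new table's taxa")
  total <- sum(as.numeric(newdata$counts))
  kept <- sum(as.numeric(newdata$counts[, shared, drop = FALSE]))
  dropped <- 1 - kept / total
  if (dropped > 0)
    message(sprintf("fold-in: dropping %.1f%% of counts on %d taxa outside the fitted vocabulary",
                    100 * dropped, length(setdiff(newdata$taxon_ids, shared))))

  ord <- order(newdata$sample_ids)
  m <- newdata$counts[ord, shared, drop = FALSE]
  if (any(rowSums(m) == 0))
    stop("samples with no counts on the fitted vocabulary: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  phi <- object$topic_word[, shared, drop = FALSE]
  # renormalize the fixed topic-word rows to the shared vocabulary
  phi <- phi / rowSums(phi)
  theta <- lda_fold_in_cpp(m, phi, object$alpha,
                           as.integer(n_iterations), as.integer(burn_in),
                           as.integer(seed))
  rownames(theta) <- rownames(m)
  colnames(theta) <- paste0("topic", seq_len(object$K))
  theta <- theta[match(newdata$sample_ids, rownames(theta)), , drop = FALSE]
  attr(theta, "dropped_fraction") <- dropped
  theta
}

#' Label the fitted topics as dysbiotic and normobiotic
#'
#' With K = 2, the topic carrying strictly more topic-word mass on the
#' pathobiont reference list is labeled dysbiotic, the other normobiotic.
#' Labeling (never the topic index, which is arbitrary up to label
#' switching across seeds) determines the orientation of the dysbiosis
#' score.
#'
#' @param fit A [fit_topics()] fit with `K = 2`.
#' @param pathobiont_list,commensal_list Non-empty, disjoint taxa sets;
#'   defaults are the signature species of the dysbiotic and normobiotic
#'   subgingival communities ([pathobiont_taxa()], [commensal_taxa()]).
#' @return An object of class `topic_labeling`: `dysbiotic_topic_index`,
#'   `normobiotic_topic_index`, `evidence` (2 x 2 matrix of summed
#'   topic-word mass on the two lists) and `margin` (difference in
#'   pathobiont mass between the two topics, always > 0).
#' @export
label_topics <- function(fit, pathobiont_list = pathobiont_taxa(),
                         commensal_list = commensal_taxa()) {
  stopifnot(inherits(fit, "topic_fit"))
  if (fit$K != 2) stop("topic labeling requires K = 2")
  if (!length(pathobiont_list) || !length(commensal_list))
    stop("reference lists must be non-empty")
  if (length(intersect(pathobiont_list, commensal_list)))
    stop("reference lists must be disjoint")
  in_vocab <- union(intersect(pathobiont_list, fit$vocab),
                    intersect(commensal_list, fit$vocab))
  if (!length(in_vocab))
    stop("none of the listed taxa occur in the fitted vocabulary")
  mass <- function(lst) rowSums(fit$topic_word[, intersect(lst, fit$vocab),
                                               drop = FALSE])
  pmass <- mass(pathobiont_list)
  cmass <- mass(commensal_list)
  margin <- abs(pmass[1] - pmass[2])
  if (margin <= 1e-6)
    stop("ambiguous labeling: pathobiont mass nearly equal between topics (margin ",
         format(margin), "); label manually")
  dys <- which.max(pmass)
  evidence <- cbind(pathobiont_mass = pmass, commensal_mass = cmass)
  rownames(evidence) <- paste0("topic", 1:2)
  structure(list(dysbiotic_topic_index = as.integer(dys),
                 normobiotic_topic_index = as.integer(3 - dys),
                 evidence = evidence, margin = unname(margin)),
            class = "topic_labeling")
}

#' @export
print.topic_labeling <- function(x, ...) {
  cat(sprintf("topic_labeling: dysbiotic = topic%d, normobiotic = topic%d (margin %.3f)\n",
              x$dysbiotic_topic_index, x$normobiotic_topic_index, x$margin))
  print(round(x$evidence, 4))
  invisible(x)
}

#' Per-sample dysbiosis score
#'
#' The degree of dysbiosis of a sample is the relative proportion of the
#' dysbiotic to the normobiotic community; with K = 2 topics this equals the
#' sample's loading on the dysbiotic topic.
#'
#' @param fit A [fit_topics()] fit.
#' @param labeling A [label_topics()] labeling of that fit.
#' @param doc_topic Optional topic-proportion matrix to score instead of the
#'   fit's own loadings (e.g. fold-in output from [predict.topic_fit()]).
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
dysbiosis_score <- function(fit, labeling, doc_topic = NULL) {
  stopifnot(inherits(fit, "topic_fit"), inherits(labeling, "topic_labeling"))
  m <- if (is.null(doc_topic)) fit$doc_topic else doc_topic
  setNames(m[, labeling$dysbiotic_topic_index], rownames(m))
}

#' Fold in new samples and return their dysbiosis scores
#'
#' Convenience wrapper around [predict.topic_fit()] and [dysbiosis_score()].
#'
#' @inheritParams predict.topic_fit
#' @param labeling A [label_topics()] labeling (defaults to labeling the fit
#'   with the standard reference lists).
#' @param fit A [fit_topics()] fit.
#' @param new_table New samples as a [taxa_count_table].
#' @return Named numeric vector of dysbiosis scores for the new samples.
#' @export
fold_in <- function(fit, new_table, labeling = label_topics(fit), seed = 1L,
                    n_iterations = 200, burn_in = n_iterations %/% 4) {
  theta <- predict(fit, new_table, seed = seed,
                   n_iterations = n_iterations, burn_in = burn_in)
  out <- dysbiosis_score(fit, labeling, doc_topic = theta)
  attr(out, "dropped_fraction") <- attr(theta, "dropped_fraction")
  out
}

#' Contrast dysbiosis between healthy and untreated-disease samples
#'
#' Compares two groups of dysbiosis scores with a two-sided Wilcoxon
#' rank-sum test. In a coherent fit, healthy periodontium samples carry
#' higher normobiotic loadings (lower dysbiosis scores) than untreated
#' periodontitis samples.
#'
#' @param scores_healthy,scores_untreated Numeric vectors of dysbiosis
#'   scores, each of length >= 2.
#' @return List with `median_healthy`, `median_untreated`,
#'   `median_difference` (untreated minus healthy) and `p_value`.
#' @export
healthy_vs_disease_contrast <- function(scores_healthy, scores_untreated) {
  if (length(scores_healthy) < 2 || length(scores_untreated) < 2)
    stop("each group needs at least 2 samples")
  p <- wilcox.test(scores_healthy, scores_untreated, exact = FALSE)$p.value
  list(median_healthy = median(scores_healthy),
       median_untreated = median(scores_untreated),
       median_difference = median(scores_untreated) - median(scores_healthy),
       p_value = p)
}
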