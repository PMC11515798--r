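#' Build per-subject dysbiosis trajectories
#'
#' Aligns per-sample dysbiosis scores into one trajectory per subject over
#' the visit schedule. Subjects without a baseline (month 0) sample are
#' excluded and listed in the `"excluded"` attribute; missing later visits
#' are recorded in the mask.
#'
#' @param scores Named numeric vector of dysbiosis scores (names are sample
#'   ids), e.g. from [dysbiosis_score()].
#' @param metadata Data frame with columns `sample_id`, `subject_id` and
#'   `visit_month` covering the scored samples.
#' @return An object of class `trajectory_set`: list with `visit_months`
#'   (sorted union), `scores` (subjects x visits matrix, `NA` where
#'   missing) and `mask` (logical matrix, `TRUE` where observed).
#' @export
build_trajectories <- function(scores, metadata) {
  if (!length(scores)) stop("no scores supplied")
  need <- c("sample_id", "subject_id", "visit_month")
  if (!all(need %in% names(metadata)))
    stop("`metadata` needs columns: ", paste(need, collapse = ", "))
  md <- metadata[metadata$sample_id %in% names(scores), need]
  if (!nrow(md)) stop("no metadata rows match the scored samples")
  visits <- sort(unique(md$visit_month))
  subjects <- unique(md$subject_id)
  m <- matrix(NA_real_, length(subjects), length(visits),
              dimnames = list(subjects, paste0("M", visits)))
  idx <- cbind(match(md$subject_id, subjects), match(md$visit_month, visits))
  m[idx] <- scores[md$sample_id]
  has_baseline <- !is.na(m[, 1])
  excluded <- rownames(m)[!has_baseline]
  if (length(excluded))
    message("excluding ", length(excluded), " subject(s) without baseline: ",
            paste(excluded, collapse = ", "))
  m <- m[has_baseline, , drop = FALSE]
  if (!nrow(m)) stop("no subjects with a baseline sample")
  structure(list(visit_months = visits, scores = m, mask = !is.na(m)),
            class = "trajectory_set", excluded = excluded)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d subjects x %d visits (months %s); %d missing values\n",
              nrow(x$scores), length(x$visit_months),
              paste(x$visit_months, collapse = ", "), sum(!x$mask)))
  invisible(x)
}

#' @noRd
impute_locf <- function(m) {
  for (j in seq_len(ncol(m))[-1]) {
    miss <- is.na(m[, j])
    m[miss, j] <- m[miss, j - 1]
  }
  m
}

#' Cluster dysbiosis trajectories
#'
#' Agglomerative hierarchical clustering of the per-subject score vectors,
#' cut at `k` clusters. Missing visits are imputed by last observation
#' carried forward (the baseline is always present), or incomplete subjects
#' dropped. Assignment is deterministic.
#'
#' @param trajectories A [build_trajectories()] object.
#' @param k Number of clusters (default 4, one per named response pattern).
#' @param linkage `"ward"` (Ward's minimum variance, the default),
#'   `"average"` or `"complete"`.
#' @param distance Only `"euclidean"` is supported.
#' @param impute `"locf"` (default) or `"drop"` (drop incomplete subjects).
#' @return List of class `trajectory_clusters`: `assignments` (named integer
#'   vector), `merge_heights` (dendrogram heights), `means` (k x visits
#'   cluster mean trajectories), `imputed` (the matrix used), `k`.
#' @export
cluster_trajectories <- function(trajectories, k = 4,
                                 linkage = c("ward", "average", "complete"),
                                 distance = "euclidean",
                                 impute = c("locf", "drop")) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  linkage <- match.arg(linkage)
  impute <- match.arg(impute)
  distance <- match.arg(distance, "euclidean")
  m <- trajectories$scores
  m <- if (impute == "locf") impute_locf(m) else m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < k)
    stop("fewer subjects (", nrow(m), ") than requested clusters (", k, ")")
  if (nrow(m) == k) {  # one subject per cluster; no tree needed
    cl <- setNames(seq_len(k), rownames(m))
    heights <- numeric(0)
  } else {
    hc <- hclust(dist(m, method = distance),
                 method = c(ward = "ward.D2", average = "average",
                            complete = "complete")[[linkage]])
    cl <- cutree(hc, k = k)
    heights <- hc$height
  }
  means <- t(sapply(seq_len(k), function(g)
    colMeans(m[cl == g, , drop = FALSE])))
  rownames(means) <- paste0("cluster", seq_len(k))
  structure(list(assignments = cl, merge_heights = heights, means = means,
                 imputed = m, k = as.integer(k), linkage = linkage),
            class = "trajectory_clusters")
}

#' @noRd
category_names <- function() {
  c(`0` = "non-responder", `1` = "indifferent",
    `2` = "short-term responder", `3` = "responder")
}

#' Assign ordinal microbial response categories to trajectory clusters
#'
#' Each cluster is labeled from its mean trajectory relative to the
#' normobiosis cut, using the baseline, the first post-treatment and the
#' final visit: a cluster that stays dysbiotic at all three is a
#' non-responder (0); one that is normobiotic at both post-treatment
#' anchors is a responder (3); normobiotic early but dysbiotic again at the
#' end is a short-term responder (2); anything else is indifferent (1). The
#' categories are ordinal: 0 < 1 < 2 < 3 with higher values indicating a
#' better microbial response. All subjects inherit their cluster's label;
#' several clusters may legitimately map to the same named category (a
#' warning is emitted).
#'
#' @param clusters A [cluster_trajectories()] result.
#' @param trajectories The matching [build_trajectories()] object (used for
#'   the visit schedule).
#' @param normo_cut Score below which the mean community is called
#'   normobiotic (default 0.5).
#' @return Data frame of class `response_pattern` with columns `subject_id`,
#'   `cluster_id`, `category` (integer 0-3) and `name`.
#' @export
assign_categories <- function(clusters, trajectories, normo_cut = 0.5) {
  stopifnot(inherits(clusters, "trajectory_clusters"),
            inherits(trajectories, "trajectory_set"))
  mm <- clusters$means
  nv <- ncol(mm)
  if (nv < 3) stop("need at least baseline, one post-treatment and a final visit")
  cat_of <- function(mu) {
    base <- mu[1] >= normo_cut
    post <- mu[2] >= normo_cut
    fin <- mu[nv] >= normo_cut
    if (base && post && fin) 0L            # stayed dysbiotic
    else if (!post && !fin) 3L             # transitioned and maintained
    else if (!post && fin) 2L              # transitioned then reverted
    else 1L                                # no discernible pattern
  }
  cluster_cat <- apply(mm, 1, cat_of)
  if (anyDuplicated(cluster_cat))
    warning("multiple clusters map to the same response category: ",
            paste(names(table(cluster_cat))[table(cluster_cat) > 1], collapse = ", "),
            call. = FALSE)
  cat_subj <- cluster_cat[clusters$assignments]
  out <- data.frame(subject_id = names(clusters$assignments),
                    cluster_id = unname(clusters$assignments),
                    category = unname(cat_subj),
                    name = unname(category_names()[as.character(cat_subj)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("response_pattern", "data.frame")
  out
}
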