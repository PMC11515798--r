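#' Construct a directed acyclic graph
#'
#' Small explicit DAG container for causal reasoning about the study
#' variables. Edges must connect declared nodes and the graph must be
#' acyclic.
#'
#' @param nodes Character vector of node names.
#' @param edges Two-column matrix or data frame (`from`, `to`).
#' @return An object of class `causal_dag`.
#' @export
causal_dag <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  undeclared <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(undeclared))
    stop("edges reference undeclared nodes: ", paste(undeclared, collapse = ", "))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  dag <- structure(list(nodes = nodes, edges = edges), class = "causal_dag")
  if (is.null(topological_order(dag))) stop("graph contains a cycle")
  dag
}

#' @export
print.causal_dag <- function(x, ...) {
  cat(sprintf("causal_dag: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges)))
    cat("  ", x$edges$from[i], "->", x$edges$to[i], "\n")
  invisible(x)
}

#' @noRd
topological_order <- function(dag) {
  nodes <- dag$nodes
  indeg <- setNames(integer(length(nodes)), nodes)
  for (v in dag$edges$to) indeg[v] <- indeg[v] + 1L
  queue <- nodes[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    ch <- dag$edges$to[dag$edges$from == v]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

#' Parents, children, ancestors and descendants of DAG nodes
#'
#' @param dag A [causal_dag()].
#' @param node Node name (for `dag_parents`/`dag_children`) or character
#'   vector of nodes (for the closure functions, which include the nodes
#'   themselves).
#' @return Character vector of node names.
#' @export
dag_parents <- function(dag, node) sort(dag$edges$from[dag$edges$to == node])

#' @rdname dag_parents
#' @export
dag_children <- function(dag, node) sort(dag$edges$to[dag$edges$from == node])

#' @rdname dag_parents
#' @export
dag_descendants <- function(dag, node) {
  seen <- character(0); frontier <- node
  while (length(frontier)) {
    nxt <- unique(dag$edges$to[dag$edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, nxt)
  }
  sort(union(node, seen))
}

#' @rdname dag_parents
#' @export
dag_ancestors <- function(dag, node) {
  seen <- character(0); frontier <- node
  while (length(frontier)) {
    nxt <- unique(dag$edges$from[dag$edges$to %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, nxt)
  }
  sort(union(node, seen))
}

#' The study DAG
#'
#' The fixed causal diagram of the trial: randomized antibiotic treatment
#' (no incoming edges) affects the attachment-loss outcome directly and via
#' the microbial response pattern; baseline characteristics (the baseline
#' microbiome state) shape the response pattern; age, sex and smoking
#' confound the mediator-outcome relation by affecting both.
#'
#' @return A [causal_dag()] over nodes `treatment`, `response_pattern`,
#'   `al13_outcome`, `age`, `sex`, `smoking`, `baseline_characteristics`.
#' @export
build_study_dag <- function() {
  causal_dag(
    nodes = c("treatment", "response_pattern", "al13_outcome",
              "age", "sex", "smoking", "baseline_characteristics"),
    edges = rbind(
      c("treatment", "response_pattern"),
      c("treatment", "al13_outcome"),
      c("response_pattern", "al13_outcome"),
      c("baseline_characteristics", "response_pattern"),
      c("age", "response_pattern"), c("age", "al13_outcome"),
      c("sex", "response_pattern"), c("sex", "al13_outcome"),
      c("smoking", "response_pattern"), c("smoking", "al13_outcome")))
}

# enumerate all simple paths between x and y on the skeleton, keeping the
# edge directions for collider checks
#' @noRd
all_paths <- function(dag, x, y) {
  adj <- lapply(setNames(nm = dag$nodes), function(v)
    union(dag$edges$to[dag$edges$from == v], dag$edges$from[dag$edges$to == v]))
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) { paths[[length(paths) + 1L]] <<- path; return(invisible()) }
    for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
  }
  walk(x)
  paths
}

#' @noRd
has_edge <- function(dag, from, to) any(dag$edges$from == from & dag$edges$to == to)

# a path is blocked by z iff some non-endpoint vertex is a non-collider in z,
# or a collider with neither itself nor any descendant in z
#' @noRd
path_blocked <- function(dag, path, z) {
  n <- length(path)
  if (n < 3) return(FALSE)
  for (i in 2:(n - 1)) {
    v <- path[i]
    collider <- has_edge(dag, path[i - 1], v) && has_edge(dag, path[i + 1], v)
    if (collider) {
      if (!length(intersect(dag_descendants(dag, v), z))) return(TRUE)
    } else {
      if (v %in% z) return(TRUE)
    }
  }
  FALSE
}

#' Test d-separation by path enumeration
#'
#' `x` and `y` are d-separated given `z` when every path between them on the
#' graph skeleton is blocked: a non-collider on the path is in `z`, or a
#' collider has neither itself nor any descendant in `z`.
#'
#' @param dag A [causal_dag()].
#' @param x,y Node names.
#' @param z Character vector of conditioning nodes (may be empty).
#' @return Logical.
#' @export
d_separated <- function(dag, x, y, z = character(0)) {
  stopifnot(x %in% dag$nodes, y %in% dag$nodes, all(z %in% dag$nodes))
  if (x == y) stop("x and y must differ")
  paths <- all_paths(dag, x, y)
  all(vapply(paths, function(p) path_blocked(dag, p, z), logical(1)))
}

#' Minimal backdoor adjustment sets
#'
#' Enumerates the minimal covariate sets Z satisfying the backdoor
#' criterion for the effect of `exposure` on `outcome`: Z contains no
#' descendant of the exposure (nor any forbidden node) and blocks every
#' backdoor path — every path that starts with an edge into the exposure.
#' The graphs in this setting are small, so candidate subsets are checked
#' explicitly against the path-enumeration blocking test.
#'
#' @param dag A [causal_dag()].
#' @param exposure,outcome Node names (distinct).
#' @param forbidden Nodes excluded from adjustment (e.g. unmeasured).
#' @return List of character vectors (possibly containing only
#'   `character(0)`, meaning no adjustment is required), minimal under set
#'   inclusion, ordered by size.
#' @export
backdoor_adjustment_sets <- function(dag, exposure, outcome,
                                     forbidden = character(0)) {
  stopifnot(exposure %in% dag$nodes, outcome %in% dag$nodes)
  if (exposure == outcome) stop("exposure and outcome must differ")
  paths <- all_paths(dag, exposure, outcome)
  backdoor <- Filter(function(p) has_edge(dag, p[2], p[1]), paths)
  candidates <- setdiff(dag$nodes,
                        c(dag_descendants(dag, exposure), outcome, forbidden))
  valid <- list()
  for (size in 0:length(candidates)) {
    combos <- if (size == 0) list(character(0)) else
      apply(utils::combn(candidates, size), 2, identity, simplify = FALSE)
    for (z in combos) {
      if (any(vapply(valid, function(v) all(v %in% z), logical(1)))) next
      if (all(vapply(backdoor, function(p) path_blocked(dag, p, z), logical(1))))
        valid[[length(valid) + 1L]] <- z
    }
  }
  valid
}
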