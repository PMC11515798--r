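# Independent oracles used by the test suite. These deliberately use
# different algorithms from the package implementations they check.

# Exact LDA posterior mean of the document-topic proportions by exhaustive
# enumeration of all K^N token-topic assignment vectors, weighted by the
# collapsed joint p(w, z) under Dirichlet-multinomial integration.
lda_enum_doc_topic <- function(counts, K, alpha, eta) {
  counts <- as.matrix(counts)
  D <- nrow(counts); V <- ncol(counts)
  tok_d <- tok_w <- integer(0)
  for (d in seq_len(D)) for (w in seq_len(V)) {
    c_ <- counts[d, w]
    if (c_ > 0) { tok_d <- c(tok_d, rep(d, c_)); tok_w <- c(tok_w, rep(w, c_)) }
  }
  N <- length(tok_d)
  stopifnot(N <= 10)  # K^N enumeration
  nd <- tabulate(tok_d, D)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logw <- numeric(nrow(grid))
  theta_num <- matrix(0, D, K)
  for (g in seq_len(nrow(grid))) {
    z <- grid[g, ]
    ndk <- matrix(0, D, K); nkw <- matrix(0, K, V)
    for (i in seq_len(N)) {
      ndk[tok_d[i], z[i]] <- ndk[tok_d[i], z[i]] + 1
      nkw[z[i], tok_w[i]] <- nkw[z[i], tok_w[i]] + 1
    }
    nk <- rowSums(nkw)
    lw <- sum(lgamma(nkw + eta)) - sum(lgamma(nk + V * eta)) +
      sum(lgamma(ndk + alpha))
    logw[g] <- lw
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  for (g in seq_len(nrow(grid))) {
    z <- grid[g, ]
    ndk <- matrix(0, D, K)
    for (i in seq_len(N)) ndk[tok_d[i], z[i]] <- ndk[tok_d[i], z[i]] + 1
    theta_num <- theta_num + w[g] * (ndk + alpha) / (nd + K * alpha)
  }
  theta_num
}

# d-separation via the moral ancestral graph (independent of the package's
# path-enumeration implementation): x indep y | z iff x and y are
# disconnected in the moralized subgraph on ancestors of {x, y} union z
# after deleting z.
dsep_moral <- function(dag, x, y, z) {
  anc <- dag_ancestors(dag, c(x, y, z))
  ed <- dag$edges[dag$edges$from %in% anc & dag$edges$to %in% anc, ]
  undirected <- rbind(as.matrix(ed), as.matrix(ed)[, 2:1, drop = FALSE])
  # moralize: marry parents of each common child
  for (v in anc) {
    pa <- ed$from[ed$to == v]
    if (length(pa) > 1) {
      prs <- t(combn(pa, 2))
      undirected <- rbind(undirected, prs, prs[, 2:1, drop = FALSE])
    }
  }
  keep <- setdiff(anc, z)
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  undirected <- undirected[undirected[, 1] %in% keep & undirected[, 2] %in% keep, ,
                           drop = FALSE]
  reached <- x
  repeat {
    nxt <- unique(undirected[undirected[, 1] %in% reached, 2])
    nxt <- setdiff(nxt, reached)
    if (!length(nxt)) break
    reached <- c(reached, nxt)
  }
  !(y %in% reached)
}

# brute-force minimal backdoor sets: test every candidate subset with the
# moral-graph d-separation oracle applied to the graph with the exposure's
# outgoing edges removed, then filter to minimal sets.
backdoor_brute <- function(dag, exposure, outcome, forbidden = character(0)) {
  bd <- dag
  bd$edges <- bd$edges[bd$edges$from != exposure, ]
  candidates <- setdiff(dag$nodes,
                        c(dag_descendants(dag, exposure), outcome, forbidden))
  valid <- list()
  for (size in 0:length(candidates)) {
    combos <- if (size == 0) list(character(0)) else
      apply(combn(candidates, size), 2, identity, simplify = FALSE)
    for (zz in combos)
      if (dsep_moral(bd, exposure, outcome, zz))
        valid[[length(valid) + 1L]] <- sort(zz)
  }
  minimal <- Filter(function(v)
    !any(vapply(valid, function(u)
      length(u) < length(v) && all(u %in% v), logical(1))), valid)
  minimal
}

canon_sets <- function(sets) {
  s <- lapply(sets, function(x) sort(as.character(x)))
  s[order(vapply(s, function(x) paste(length(x), paste(x, collapse = ",")),
                 character(1)))]
}
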