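# Independent reference implementations used as oracles.  These stay
# deliberately naive (loops, enumeration, textbook formulas) and share no
# code with the package.

# Topological overlap by explicit triple loop.
naive_tom <- function(adj) {
  n <- nrow(adj)
  w <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    ki <- sum(adj[i, -i]); kj <- sum(adj[j, -j])
    w[i, j] <- (l + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
  }
  dimnames(w) <- dimnames(adj)
  w
}

# Average-linkage agglomeration by exhaustive O(n^3) search.  Returns the
# merge sequence as leaf-index sets plus merge heights.
naive_upgma <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best_h <- Inf
    best <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, best_h)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Leaf-index sets of every merge of an hclust tree, in merge order.
hclust_merge_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    grab <- function(x) if (x < 0) -x else sets[[x]]
    sets[[k]] <- sort(c(grab(tree$merge[k, 1]), grab(tree$merge[k, 2])))
  }
  sets
}

# Upper-tail hypergeometric P(X >= x) by direct enumeration with choose().
hyper_tail_enum <- function(x, n_term, n_bg, n_mod) {
  xs <- x:min(n_term, n_mod)
  xs <- xs[n_mod - xs <= n_bg - n_term]
  sum(choose(n_term, xs) * choose(n_bg - n_term, n_mod - xs)) /
    choose(n_bg, n_mod)
}

# Textbook pooled-variance two-sample t.
pooled_t_formula <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}

# A small two-module dataset that survives the default screen; used by the
# pipeline tests.
small_pipeline_config <- function(seed = 42L, out_dir = tempfile()) {
  eff <- data.frame(gene = 1:95,
                    log10_fc = rep(0.2, 95),
                    bias = rep(c("F", "M"), length.out = 95))
  pipeline_config(
    out_dir = out_dir,
    simulate = simulation_config(
      n_genes = 200, n_male = 60, n_female = 60,
      module_sizes = c(40, 35), module_loading = 0.7,
      loading_spread = 0.1, sex_effects = eff,
      noise_sd = 0.15, seed = seed),
    gene_sets = character(0),
    beta = 6, seed = seed)
}
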