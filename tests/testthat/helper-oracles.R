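# Independent oracles and small fixture builders shared across tests.

# Exhaustive hypergeometric upper-tail sum from binomial coefficients:
# P(X >= k) for X ~ Hypergeometric(N, K, n). Deliberately uses choose()
# only, independent of phyper().
oracle_fisher <- function(k, K, n, N) {
  xs <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Hand-coded Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j) m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj_sorted, 1)
  out
}

# Transitive closure by boolean matrix powering: reach[i, j] is TRUE when
# j is a strict ancestor of i.
oracle_reachability <- function(dag) {
  ids <- dag$terms$term_id
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) adj[id, dag$parents[[id]]] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# OBO fixtures ---------------------------------------------------------------

chain_obo <- function() c(
  "format-version: 1.2", "",
  "[Term]", "id: T:c", "name: leaf", "is_a: T:b ! mid", "",
  "[Term]", "id: T:b", "name: mid", "is_a: T:a ! top", "",
  "[Term]", "id: T:a", "name: top")

diamond_obo <- function() c(
  "[Term]", "id: T:d", "name: bottom", "is_a: T:b", "is_a: T:c", "",
  "[Term]", "id: T:b", "name: left", "is_a: T:a", "",
  "[Term]", "id: T:c", "name: right", "is_a: T:a", "",
  "[Term]", "id: T:a", "name: top")

# Random DAG on n nodes: node i > 1 draws 1-2 parents among nodes 1..i-1,
# so the result is acyclic by construction. Returned as an ontology_dag.
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("R:%03d", seq_len(n))
  parents <- list()
  parents[[ids[1L]]] <- character(0)
  for (i in 2:n) {
    np <- sample(1:min(2L, i - 1L), 1L)
    parents[[ids[i]]] <- ids[sample.int(i - 1L, np)]
  }
  dcanno:::new_ontology_dag(ids, ids, rep("R", n), parents)
}

# Direct-only annotation table over a random DAG, for propagation tests.
random_annotation_table <- function(dag, n_domains, seed) {
  set.seed(seed)
  ids <- dag$terms$term_id
  recs <- do.call(rbind, lapply(seq_len(n_domains), function(i) {
    terms <- sample(ids, sample(1:3, 1L))
    data.frame(domain_id = sprintf("D%02d", i), domain_type = "other",
               term_id = terms, term_name = "", p = runif(length(terms), 0, 1e-4),
               fdr = NA_real_, s = rnorm(length(terms), 5),
               score = runif(length(terms), 1, 100), origin = "direct",
               stringsAsFactors = FALSE)
  }))
  recs$fdr <- pmin(recs$p * 10, 1)
  recs <- recs[!duplicated(recs[c("domain_id", "term_id")]), , drop = FALSE]
  class(recs) <- c("annotation_table", "data.frame")
  recs
}

# Reference annotation table built from explicit term -> member-domain sets.
reference_from_members <- function(membership, domain_type = "Pfam") {
  rows <- do.call(rbind, lapply(names(membership), function(t) {
    data.frame(domain_id = membership[[t]], domain_type = domain_type,
               term_id = t, term_name = t, p = NA_real_, fdr = NA_real_,
               s = NA_real_, score = NA_real_, origin = "direct",
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("annotation_table", "data.frame")
  rows
}

# Worked-example inputs packaged with dcanno.
example_input_path <- function() {
  system.file("extdata", "immune_pfam_domains.txt", package = "dcanno")
}
example_reference_path <- function() {
  system.file("extdata", "gobp_immune_reference.tsv", package = "dcanno")
}
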