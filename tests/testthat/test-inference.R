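test_that("fisher_one_sided reproduces exact tail probabilities", {
  expect_equal(fisher_one_sided(0, 5, 5, 10), 1.0)
  expect_equal(fisher_one_sided(5, 5, 5, 10), 1 / 252)
  # tail over X in {4, 5, 6}: (C(8,4)C(12,2) + C(8,5)C(12,1) + C(8,6)) / C(20,6)
  expect_equal(fisher_one_sided(4, 8, 6, 20), 5320 / 38760)
  expect_error(fisher_one_sided(6, 5, 5, 10), "k must satisfy")
  expect_error(fisher_one_sided(1, 11, 5, 10), "exceed N")
})

test_that("fisher_one_sided matches the exhaustive choose() oracle on a small-N sweep", {
  for (N in c(2, 5, 9, 14)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in max(0, K + n - N):min(K, n)) {
          expect_equal(fisher_one_sided(k, K, n, N),
                       oracle_fisher(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("bh_adjust reproduces hand-derived step-up values and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(bh_adjust(1.0), 1.0)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("bh_adjust is permutation-invariant, never below raw p, and matches its oracle", {
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1L))^sample(1:3, 1L)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("hypergeom_strength follows the z formula with degenerate conventions", {
  expect_equal(hypergeom_strength(2, 10, 20, 100), 0.0)  # k equals mu
  expect_equal(hypergeom_strength(8, 10, 20, 100),
               6 / sqrt(20 * 0.1 * 0.9 * 80 / 99))
  expect_equal(hypergeom_strength(7, 7, 7, 7), 0.0)      # sigma = 0
  expect_equal(hypergeom_strength(1, 1, 1, 1), 0.0)      # N < 2
})

test_that("rescale_scores maps strengths linearly onto [1, 100]", {
  expect_equal(rescale_scores(c(2, 5, 11)), c(1, 34, 100))
  expect_equal(rescale_scores(7), 100)
  expect_equal(rescale_scores(c(0, 10)), c(1, 100))
  expect_error(rescale_scores(numeric(0)), "empty")
})

test_that("infer_annotations keeps a strongly planted pair and drops null matrices", {
  # 40 proteins; domain D on 10; term t on 9 of the 10 carriers and 2 others;
  # a background term keeps every protein inside the joint universe
  flat <- parse_obo(c("[Term]", "id: t", "name: planted", "",
                      "[Term]", "id: bg", "name: background"))
  prots <- sprintf("P%02d", 1:40)
  pdm <- lapply(prots, function(p) if (p <= "P10") "D" else "D0")
  names(pdm) <- prots
  ptm <- lapply(prots, function(p) {
    if (p <= "P09" || p %in% c("P11", "P12")) c("t", "bg") else "bg"
  })
  names(ptm) <- prots
  cm <- build_correspondence_matrix(ptm, pdm, flat)
  expect_equal(oracle_fisher(9, 11, 10, 40), 2.0511e-06, tolerance = 1e-4)
  tab <- infer_annotations(cm, flat, fdr_threshold = 0.01)
  expect_true(any(tab$domain_id == "D" & tab$term_id == "t" &
                    tab$origin == "direct"))
  expect_false(any(tab$domain_id == "D0" & tab$fdr < 2e-6))

  # a single weak pair: BH of one value is itself, above the threshold
  weak <- build_correspondence_matrix(list(P1 = "t", P2 = "t"),
                                      list(P1 = "D", P2 = "D0"), flat)
  expect_warning(
    tab2 <- infer_annotations(weak, flat, fdr_threshold = 0.05),
    "no significant")
  expect_equal(nrow(tab2), 0L)
})

test_that("every direct record in an inferred table satisfies the FDR filter and invariants", {
  spec <- synthetic_spec(n_proteins = 300L, seed = 11L)
  corpus <- generate_corpus(spec)
  cm <- build_correspondence_matrix(corpus$ptm, corpus$pdm, corpus$dag)
  tab <- infer_annotations(cm, corpus$dag, fdr_threshold = 1e-3)
  direct <- tab[tab$origin == "direct", ]
  expect_gt(nrow(direct), 0L)
  expect_true(all(direct$fdr < 1e-3))
  expect_true(all(tab$p <= tab$fdr + 1e-15))
  expect_true(all(tab$score >= 1 & tab$score <= 100))
  expect_false(any(duplicated(tab[c("domain_id", "term_id")])))
})

test_that("propagation fills ancestors with max scores and inherited statistics", {
  chain <- parse_obo(chain_obo())
  tab <- data.frame(domain_id = "D", domain_type = "other", term_id = "T:c",
                    term_name = "leaf", p = 1e-6, fdr = 1e-5, s = 4,
                    score = 50, origin = "direct", stringsAsFactors = FALSE)
  class(tab) <- c("annotation_table", "data.frame")
  out <- propagate_annotations(tab, chain)
  expect_equal(nrow(out), 3L)
  expect_equal(out$score, rep(50, 3))
  expect_setequal(out$origin[out$term_id != "T:c"], "propagated")
  expect_equal(out$p, rep(1e-6, 3))

  # max rule under a common parent
  two <- data.frame(domain_id = "D", domain_type = "other",
                    term_id = c("T:b", "T:c"), term_name = "",
                    p = c(1e-4, 1e-8), fdr = c(1e-3, 1e-7), s = c(2, 6),
                    score = c(40, 70), origin = "direct",
                    stringsAsFactors = FALSE)
  class(two) <- c("annotation_table", "data.frame")
  vee <- parse_obo(c("[Term]", "id: T:b", "is_a: T:a", "",
                     "[Term]", "id: T:c", "is_a: T:a", "",
                     "[Term]", "id: T:a"))
  out2 <- propagate_annotations(two, vee)
  expect_equal(out2$score[out2$term_id == "T:a"], 70)
  expect_equal(out2$p[out2$term_id == "T:a"], 1e-8)  # from the 70-score record
  expect_equal(out2$score[out2$term_id == "T:b"], 40)

  # diamond: one bottom annotation spreads to all four terms
  dia <- parse_obo(diamond_obo())
  one <- tab
  one$term_id <- "T:d"
  out3 <- propagate_annotations(one, dia)
  expect_equal(nrow(out3), 4L)
  expect_equal(sort(unique(out3$score)), 50)

  expect_error(propagate_annotations(tab, parse_obo(c("[Term]", "id: T:z"))),
               "T:c")
})

test_that("propagation closure and score monotonicity hold on random tables; it is idempotent", {
  for (seed in 1:12) {
    dag <- random_dag(sample(6:25, 1L), seed)
    tab <- random_annotation_table(dag, n_domains = sample(1:4, 1L),
                                   seed = seed + 100L)
    out <- propagate_annotations(tab, dag)
    # ancestor closure
    for (i in seq_len(nrow(out))) {
      anc <- ancestors(dag, out$term_id[i])
      covered <- out$term_id[out$domain_id == out$domain_id[i]]
      expect_true(all(anc %in% covered))
      # score non-decreasing towards the root
      for (p in dag$parents[[out$term_id[i]]]) {
        expect_gte(out$score[out$domain_id == out$domain_id[i] &
                               out$term_id == p],
                   out$score[i])
      }
    }
    again <- propagate_annotations(out, dag)
    expect_equal(as.data.frame(again), as.data.frame(out))
  }
})

test_that("annotation tables round-trip through the TSV writer", {
  spec <- synthetic_spec(n_proteins = 200L, seed = 5L)
  corpus <- generate_corpus(spec)
  cm <- build_correspondence_matrix(corpus$ptm, corpus$pdm, corpus$dag)
  tab <- infer_annotations(cm, corpus$dag)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(tab, path)
  back <- read_annotation_table(path)
  expect_equal(back$domain_id, tab$domain_id)
  expect_equal(back$term_id, tab$term_id)
  expect_equal(back$p, tab$p, tolerance = 1e-12)
  expect_equal(back$score, tab$score, tolerance = 1e-12)
  meta <- attr(back, "metadata")
  expect_equal(meta$corpus_N, attr(tab, "metadata")$corpus_N)
  expect_equal(as.numeric(meta$fdr_threshold), 1e-3)
})
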