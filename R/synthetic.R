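#' Specification of a synthetic annotation corpus
#'
#' Describes a corpus of proteins with domain content and ontology term
#' sets in which chosen (domain, term) associations are planted at a known
#' within-carrier rate against a background rate, so the whole
#' build-and-enrich path can be validated against ground truth.
#'
#' Defaults emulate a moderately sized curated corpus: 500 proteins, a
#' catalogue of 20 domains each carried by 15% of proteins, a
#' depth-3/branching-2 ontology tree (15 terms), three planted pairs at
#' within-rate 0.9 versus background 0.05, and unplanted leaf terms
#' attached at a base rate of 0.05.
#'
#' @param n_proteins Number of proteins (default 500).
#' @param domain_prevalence Named numeric vector: per-domain carrier
#'   probability in (0,1). Default: 20 domains `SD01..SD20` at 0.15.
#' @param dag_depth,dag_branching Shape of the generated ontology tree
#'   (defaults 3 and 2).
#' @param planted data.frame with columns `domain_id`, `term_id`,
#'   `within_rate`, `background_rate`. Default: the first three domains
#'   paired with three distinct leaves at 0.9 / 0.05. Planted terms must be
#'   leaves so that ancestor propagation is itself observable.
#' @param base_term_rate Attachment probability of unplanted leaf terms
#'   (default 0.05).
#' @param seed Integer seed driving all draws (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 500L,
                           domain_prevalence = NULL,
                           dag_depth = 3L, dag_branching = 2L,
                           planted = NULL, base_term_rate = 0.05,
                           seed = 1L) {
  if (is.null(domain_prevalence)) {
    domain_prevalence <- stats::setNames(rep(0.15, 20L),
                                         sprintf("SD%02d", 1:20))
  }
  stopifnot(n_proteins >= 1L, all(domain_prevalence > 0),
            all(domain_prevalence < 1), dag_depth >= 1L, dag_branching >= 1L,
            base_term_rate >= 0, base_term_rate < 1)
  dag <- generate_dag(dag_depth, dag_branching)
  leaves <- dag$terms$term_id[lengths(dag$children[dag$terms$term_id]) == 0L]
  if (is.null(planted)) {
    nd <- min(3L, length(domain_prevalence), length(leaves))
    planted <- data.frame(
      domain_id = names(domain_prevalence)[seq_len(nd)],
      term_id = leaves[seq_len(nd)],
      within_rate = 0.9,
      background_rate = 0.05,
      stringsAsFactors = FALSE)
  }
  stopifnot(all(planted$within_rate > planted$background_rate),
            all(planted$domain_id %in% names(domain_prevalence)),
            all(planted$term_id %in% dag$terms$term_id))
  if (!all(planted$term_id %in% leaves)) {
    stop("planted terms must be leaves of the generated ontology")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 domain_prevalence = domain_prevalence,
                 dag = dag, dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 planted = planted, base_term_rate = base_term_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a rooted ontology tree
#'
#' A complete tree of the given depth and branching factor — a valid DAG
#' with `sum(branching^(0:depth))` terms, ids `SYN:0000001` onward assigned
#' breadth-first, namespace `"SYN"`. Construction is deterministic; `seed`
#' is accepted for interface symmetry with the corpus generator.
#'
#' @param depth Number of levels below the root (>= 1).
#' @param branching Children per internal node (>= 1).
#' @param seed Ignored; the tree is fully determined by its shape.
#' @return An `ontology_dag`.
#' @export
generate_dag <- function(depth, branching, seed = NULL) {
  stopifnot(depth >= 1L, branching >= 1L)
  n_terms <- sum(branching^(0:depth))
  ids <- sprintf("SYN:%07d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- ids
  parents[[1L]] <- character(0)
  # breadth-first: node i > 1 hangs off node ceil((i - 1) / branching)
  for (i in seq_len(n_terms)[-1L]) {
    parents[[i]] <- ids[[ceiling((i - 1L) / branching)]]
  }
  new_ontology_dag(ids, paste("synthetic term", seq_len(n_terms)),
                   rep("SYN", n_terms), parents)
}

#' Generate a synthetic corpus with planted domain-term associations
#'
#' Each protein carries each domain independently with its prevalence
#' (proteins drawing zero domains are redrawn, up to a bounded number of
#' attempts). For every planted (domain, term) pair, carriers of the
#' domain receive the term with `within_rate` and non-carriers with
#' `background_rate`; unplanted leaf terms attach at `base_term_rate`.
#' Term sets hold direct (leaf-level) annotations only — ancestor closure
#' is the matrix builder's job. All randomness comes from one generator
#' seeded by `spec$seed`, so equal seeds give identical corpora.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `ptm` (protein-term map; proteins with empty term sets
#'   omitted), `pdm` (protein-domain map, `domain_type = "other"`), `truth`
#'   (the planted-pair data.frame) and `dag`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)

  np <- spec$n_proteins
  prots <- sprintf("P%05d", seq_len(np))
  doms <- names(spec$domain_prevalence)
  prev <- spec$domain_prevalence

  dmat <- matrix(stats::runif(np * length(doms)) < rep(prev, each = np),
                 nrow = np, dimnames = list(prots, doms))
  tries <- 0L
  while (any(rowSums(dmat) == 0L)) {
    tries <- tries + 1L
    if (tries > 100L) stop("cannot draw a non-empty domain set for every protein")
    empty <- rowSums(dmat) == 0L
    dmat[empty, ] <- stats::runif(sum(empty) * length(doms)) <
      rep(prev, each = sum(empty))
  }

  dag <- spec$dag
  leaves <- dag$terms$term_id[lengths(dag$children[dag$terms$term_id]) == 0L]
  tmat <- matrix(FALSE, nrow = np, ncol = length(leaves),
                 dimnames = list(prots, leaves))
  planted_terms <- unique(spec$planted$term_id)
  for (t in setdiff(leaves, planted_terms)) {
    tmat[, t] <- stats::runif(np) < spec$base_term_rate
  }
  for (i in seq_len(nrow(spec$planted))) {
    d <- spec$planted$domain_id[i]
    t <- spec$planted$term_id[i]
    carrier <- dmat[, d]
    rate <- ifelse(carrier, spec$planted$within_rate[i],
                   spec$planted$background_rate[i])
    tmat[, t] <- tmat[, t] | (stats::runif(np) < rate)
  }

  pdm <- lapply(prots, function(p) doms[dmat[p, ]])
  names(pdm) <- prots
  attr(pdm, "domain_type") <- "other"
  ptm <- lapply(prots, function(p) leaves[tmat[p, ]])
  names(ptm) <- prots
  ptm <- ptm[lengths(ptm) > 0L]

  list(ptm = ptm, pdm = pdm, truth = spec$planted, dag = dag)
}

#' Write an ontology DAG as an OBO flat file
#'
#' Emits one `[Term]` stanza per term with `id`, `name`, `namespace` and
#' `is_a` lines, parseable by [parse_obo()].
#'
#' @param dag An `ontology_dag`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines("format-version: 1.2", con)
    for (i in seq_len(nrow(dag$terms))) {
      id <- dag$terms$term_id[i]
      ps <- dag$parents[[id]]
      writeLines(c("", "[Term]",
                   paste0("id: ", id),
                   paste0("name: ", dag$terms$name[i]),
                   paste0("namespace: ", dag$terms$namespace[i]),
                   if (length(ps)) paste0("is_a: ", ps)), con)
    }
  })
}

#' Write a protein-term map as a GAF 2.2 file
#'
#' Minimal 17-column rows (database `SYN`, evidence code `EXP`), readable
#' by [read_gaf()] and by standard GAF tooling.
#'
#' @param ptm Named list: protein id to term ids.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gaf <- function(ptm, path) {
  prots <- rep(names(ptm), lengths(ptm))
  terms <- unlist(ptm, use.names = FALSE)
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines("!gaf-version: 2.2", con)
    if (length(prots)) {
      writeLines(paste("SYN", prots, prots, "involved_in", terms, "SYN:0000000",
                       "EXP", "", "P", "", "", "protein", "taxon:0000", "20200101",
                       "SYN", "", "", sep = "\t"), con)
    }
  })
}

#' Write a protein-domain map as assignment TSV
#'
#' Header `protein_id<TAB>domain_id`, one row per (protein, domain), as
#' produced by domain-scan pipelines and read by
#' [read_domain_assignments()].
#'
#' @param pdm Named list: protein id to domain ids.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_assignments <- function(pdm, path) {
  prots <- rep(names(pdm), lengths(pdm))
  doms <- unlist(pdm, use.names = FALSE)
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines("protein_id\tdomain_id", con)
    if (length(prots)) writeLines(paste(prots, doms, sep = "\t"), con)
  })
}
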