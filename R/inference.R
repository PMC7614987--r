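#' One-sided Fisher's exact test for over-representation
#'
#' Exact upper-tail probability P(X >= k) for X hypergeometric with
#' universe N, K "successes" (proteins carrying the term) and n draws
#' (proteins carrying the domain). This is the one-sided Fisher's exact
#' test of the 2x2 protein table; the exact tail sum is used, never a
#' normal approximation.
#'
#' @param k Observed overlap count(s).
#' @param K Term marginal(s).
#' @param n Domain marginal(s).
#' @param N Universe size(s).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_one_sided(5, 5, 5, 10)   # 1/choose(10,5)
#' @export
fisher_one_sided <- function(k, K, n, N) {
  check_counts(k, K, n, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_counts <- function(k, K, n, N) {
  if (any(N < 1L)) stop("universe N must be at least 1")
  if (any(K > N) || any(n > N)) stop("marginals K and n cannot exceed N")
  if (any(k < 0L) || any(k > pmin(K, n))) {
    stop("overlap k must satisfy 0 <= k <= min(K, n)")
  }
  invisible(TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are attached to their input p-values, so the output is
#' in the same order as the input and invariant to permutation.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted values, capped at 1, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric z-score (annotation strength)
#'
#' Standardised deviation of the observed overlap from its hypergeometric
#' expectation: s = (k - mu) / sigma with mu = nK/N and
#' sigma^2 = n (K/N)(1 - K/N)(N - n)/(N - 1). Degenerate cases (sigma = 0,
#' or N < 2) return 0 by convention so downstream rescaling is total.
#'
#' @inheritParams fisher_one_sided
#' @return Numeric vector of z-scores.
#' @export
hypergeom_strength <- function(k, K, n, N) {
  check_counts(k, K, n, N)
  out <- numeric(length(k + K + n + N))
  k <- rep_len(k, length(out)); K <- rep_len(K, length(out))
  n <- rep_len(n, length(out)); N <- rep_len(N, length(out))
  ok <- N >= 2
  mu <- n * K / N
  v <- ifelse(ok, n * (K / N) * (1 - K / N) * (N - n) / pmax(N - 1, 1), 0)
  pos <- ok & v > 0
  out[pos] <- (k[pos] - mu[pos]) / sqrt(v[pos])
  out
}

#' Rescale annotation strengths into the 1-100 range
#'
#' Linear min-max rescaling of raw hypergeometric strengths over the
#' significant set: score = 1 + 99 (s - min) / (max - min). When all
#' strengths are equal, every score is 100 (a single significant record is
#' maximal support by convention).
#'
#' @param strengths Non-empty numeric vector of raw strengths.
#' @return Numeric vector of scores in \[1, 100\].
#' @export
rescale_scores <- function(strengths) {
  if (!length(strengths)) stop("cannot rescale an empty strength set")
  rng <- range(strengths)
  if (rng[1L] == rng[2L]) return(rep(100, length(strengths)))
  1 + 99 * (strengths - rng[1L]) / (rng[2L] - rng[1L])
}

#' Infer domain-to-term annotations from a correspondence matrix
#'
#' Every (term, domain) pair with overlap k >= `min_k` is tested with the
#' one-sided Fisher's exact test; Benjamini-Hochberg adjustment is applied
#' jointly across all tested pairs of the build; pairs with FDR below
#' `fdr_threshold` become direct annotation records carrying the raw
#' hypergeometric strength and its min-max rescaled 1-100 annotation score
#' (rescaled over the significant direct set, before propagation). The
#' resulting table is then closed under ancestors with
#' [propagate_annotations()].
#'
#' @param cm A `correspondence_matrix`.
#' @param dag The `ontology_dag` the terms live in.
#' @param fdr_threshold Keep pairs with FDR strictly below this (default 1e-3).
#' @param min_k Minimum overlap for a pair to be tested (default 1; pairs
#'   with k = 0 have p = 1 and are never informative).
#' @param min_K,min_n Optional minimum marginals for a pair to enter testing
#'   (default 0 = off).
#' @return An `annotation_table`: data.frame with columns `domain_id`,
#'   `domain_type`, `term_id`, `term_name`, `p`, `fdr`, `s`, `score`,
#'   `origin`, plus `metadata` attribute (ontology, domain_type,
#'   fdr_threshold, corpus N).
#' @export
infer_annotations <- function(cm, dag, fdr_threshold = 1e-3, min_k = 1L,
                              min_K = 0L, min_n = 0L) {
  stopifnot(inherits(cm, "correspondence_matrix"),
            inherits(dag, "ontology_dag"),
            fdr_threshold > 0, fdr_threshold <= 1)
  pr <- cm$pairs
  K <- cm$K[pr$term_id]
  n <- cm$n[pr$domain_id]
  keep <- pr$k >= min_k & K >= min_K & n >= min_n
  pr <- pr[keep, , drop = FALSE]; K <- K[keep]; n <- n[keep]
  ontology <- ontology_label(dag)
  meta <- list(ontology = ontology, domain_type = cm$domain_type,
               fdr_threshold = fdr_threshold, corpus_N = cm$N)
  if (!nrow(pr)) {
    warning("no (term, domain) pair passes the testing filter; empty table")
    return(empty_annotation_table(meta))
  }
  p <- fisher_one_sided(pr$k, K, n, cm$N)
  fdr <- bh_adjust(p)
  sig <- fdr < fdr_threshold
  if (!any(sig)) {
    warning("no significant (domain, term) association at FDR < ",
            fdr_threshold)
    return(empty_annotation_table(meta))
  }
  pr <- pr[sig, , drop = FALSE]
  s <- hypergeom_strength(pr$k, K[sig], n[sig], cm$N)
  tab <- data.frame(
    domain_id = pr$domain_id,
    domain_type = cm$domain_type,
    term_id = pr$term_id,
    term_name = term_name_of(dag, pr$term_id),
    p = p[sig],
    fdr = fdr[sig],
    s = s,
    score = rescale_scores(s),
    origin = "direct",
    stringsAsFactors = FALSE)
  tab <- sort_annotation_table(tab)
  attr(tab, "metadata") <- meta
  class(tab) <- c("annotation_table", "data.frame")
  propagate_annotations(tab, dag)
}

ontology_label <- function(dag) {
  ns <- unique(dag$terms$namespace)
  ns <- ns[nzchar(ns)]
  if (length(ns)) paste(sort(ns), collapse = "+") else "unnamed"
}

term_name_of <- function(dag, term_ids) {
  nm <- stats::setNames(dag$terms$name, dag$terms$term_id)
  out <- unname(nm[term_ids])
  out[is.na(out)] <- ""
  out
}

empty_annotation_table <- function(meta) {
  tab <- data.frame(domain_id = character(0), domain_type = character(0),
                    term_id = character(0), term_name = character(0),
                    p = numeric(0), fdr = numeric(0), s = numeric(0),
                    score = numeric(0), origin = character(0),
                    stringsAsFactors = FALSE)
  attr(tab, "metadata") <- meta
  class(tab) <- c("annotation_table", "data.frame")
  tab
}

sort_annotation_table <- function(tab) {
  tab <- tab[order(tab$domain_id, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Propagate annotations to all ancestor terms (True Path Rule)
#'
#' For each domain, every ancestor of an annotated term receives a record:
#' origin `"propagated"` unless the ancestor already carries a direct
#' record. A propagated record carries the strongest support among the
#' domain's directly annotated descendants of that term: the maximum score
#' and raw strength, and the minimum p and FDR. Direct records keep their
#' own statistics but their score is raised to the maximum over their
#' annotated descendants, so scores are non-decreasing towards the root
#' along every path.
#'
#' Idempotent: propagating an already-propagated table changes nothing.
#'
#' @param tab An `annotation_table` (direct records at minimum).
#' @param dag The `ontology_dag`.
#' @return The closed `annotation_table`, deterministically sorted by
#'   (domain_id, term_id).
#' @export
propagate_annotations <- function(tab, dag) {
  stopifnot(inherits(tab, "annotation_table") || is.data.frame(tab),
            inherits(dag, "ontology_dag"))
  meta <- attr(tab, "metadata") %||%
    list(ontology = ontology_label(dag), domain_type = "other",
         fdr_threshold = NA_real_, corpus_N = NA_integer_)
  bad <- setdiff(unique(tab$term_id), dag$terms$term_id)
  if (length(bad)) {
    stop("annotation references term(s) not in the ontology: ",
         paste(bad, collapse = ", "))
  }
  if (!nrow(tab)) return(empty_annotation_table(meta))

  rev_topo <- rev(dag$topo)     # children before parents
  domains <- unique(tab$domain_id)
  out <- vector("list", length(domains))
  names(out) <- domains
  for (dom in domains) {
    rec <- tab[tab$domain_id == dom, , drop = FALSE]
    direct <- rec[rec$origin == "direct", , drop = FALSE]
    base <- if (nrow(direct)) direct else rec   # re-propagation keeps stats
    covered <- unique(unlist(lapply(base$term_id, function(t)
      c(t, ancestors(dag, t))), use.names = FALSE))
    own_row <- stats::setNames(match(covered, base$term_id), covered)
    # reverse-topological aggregation over the covered sub-DAG: each node
    # accumulates the strongest support among its annotated descendants
    score <- stats::setNames(rep(-Inf, length(covered)), covered)
    s_agg <- stats::setNames(rep(-Inf, length(covered)), covered)
    p_agg <- stats::setNames(rep(Inf, length(covered)), covered)
    fdr_agg <- stats::setNames(rep(Inf, length(covered)), covered)
    for (t in intersect(rev_topo, covered)) {
      b <- own_row[[t]]
      if (!is.na(b)) {
        score[[t]] <- base$score[b]
        s_agg[[t]] <- base$s[b]
        p_agg[[t]] <- base$p[b]
        fdr_agg[[t]] <- base$fdr[b]
      }
      for (ch in intersect(dag$children[[t]], covered)) {
        score[[t]] <- max(score[[t]], score[[ch]])
        s_agg[[t]] <- max(s_agg[[t]], s_agg[[ch]])
        p_agg[[t]] <- min(p_agg[[t]], p_agg[[ch]])
        fdr_agg[[t]] <- min(fdr_agg[[t]], fdr_agg[[ch]])
      }
    }
    res <- data.frame(
      domain_id = dom,
      domain_type = base$domain_type[1L],
      term_id = covered,
      term_name = term_name_of(dag, covered),
      p = unname(p_agg[covered]),
      fdr = unname(fdr_agg[covered]),
      s = unname(s_agg[covered]),
      score = unname(score[covered]),
      origin = "propagated",
      stringsAsFactors = FALSE)
    has_own <- !is.na(own_row[covered])
    ow <- own_row[covered][has_own]
    res$p[has_own] <- base$p[ow]
    res$fdr[has_own] <- base$fdr[ow]
    res$s[has_own] <- base$s[ow]
    res$origin[has_own] <- base$origin[ow]
    out[[dom]] <- res
  }
  res <- sort_annotation_table(do.call(rbind, out))
  attr(res, "metadata") <- meta
  class(res) <- c("annotation_table", "data.frame")
  res
}

#' Write an annotation table as TSV
#'
#' Tab-separated columns `domain_id`, `domain_type`, `term_id`, `term_name`,
#' `p`, `fdr`, `score`, `origin`, preceded by `#`-prefixed provenance
#' metadata lines (ontology, domain type, FDR threshold, corpus size). Rows
#' are ordered by (domain_id, term_id) so repeated runs are byte-identical.
#'
#' @param tab An `annotation_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(tab, path) {
  meta <- attr(tab, "metadata") %||% list()
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# ontology=", meta$ontology %||% ""),
      paste0("# domain_type=", meta$domain_type %||% ""),
      paste0("# fdr_threshold=", format_num(meta$fdr_threshold %||% NA_real_)),
      paste0("# corpus_N=", meta$corpus_N %||% ""),
      paste("domain_id", "domain_type", "term_id", "term_name",
            "p", "fdr", "score", "origin", sep = "\t")), con)
    if (nrow(tab)) {
      writeLines(paste(tab$domain_id, tab$domain_type, tab$term_id,
                       tab$term_name, format_num(tab$p), format_num(tab$fdr),
                       format_num(tab$score), tab$origin, sep = "\t"), con)
    }
  })
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1))
  out
}

#' Read an annotation table written by [write_annotation_table()]
#'
#' @param path Path to the TSV file.
#' @return An `annotation_table` (the raw strength column `s` is not stored
#'   in the TSV and is restored as `NA`).
#' @export
read_annotation_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  metal <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  meta <- list()
  for (ml in metal) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  meta$fdr_threshold <- suppressWarnings(as.numeric(meta$fdr_threshold))
  meta$corpus_N <- suppressWarnings(as.integer(meta$corpus_N))
  if (!length(body)) stop("annotation table has no header line")
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(domain_id = "character",
                                         domain_type = "character",
                                         term_id = "character",
                                         term_name = "character",
                                         p = "numeric", fdr = "numeric",
                                         score = "numeric",
                                         origin = "character"))
  df$s <- rep(NA_real_, nrow(df))
  df <- df[, c("domain_id", "domain_type", "term_id", "term_name",
               "p", "fdr", "s", "score", "origin")]
  df <- sort_annotation_table(df)
  attr(df, "metadata") <- meta
  class(df) <- c("annotation_table", "data.frame")
  df
}
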