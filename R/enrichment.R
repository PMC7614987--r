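#' Read a plain-text domain list
#'
#' One identifier per line; `#` starts a comment (whole line or trailing);
#' blank lines ignored. Duplicates are kept here and removed by
#' [resolve_input()] so the caller can report them.
#'
#' @param path File path or character vector of lines.
#' @return Character vector of domain identifiers.
#' @export
read_domain_list <- function(path) {
  lines <- read_input_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Split an input domain list into usable and unknown identifiers
#'
#' Deduplicates the input (first occurrence kept) and partitions it into
#' domains present in the reference table's domain universe and domains the
#' reference knows nothing about. Unknown domains are reported, never
#' silently dropped.
#'
#' @param input_domains Character vector of domain identifiers.
#' @param reference An `annotation_table` used as the reference.
#' @return List with elements `usable` and `dropped` (character vectors).
#' @export
resolve_input <- function(input_domains, reference) {
  if (!nrow(reference)) stop("reference annotation table is empty")
  input <- unique(as.character(input_domains))
  input <- input[nzchar(input)]
  if (!length(input)) stop("input domain list is empty")
  universe <- unique(reference$domain_id)
  usable <- input[input %in% universe]
  dropped <- setdiff(input, usable)
  if (!length(usable)) {
    stop("none of the input domains is present in the reference annotation")
  }
  if (length(dropped)) {
    message(length(dropped), " input domain(s) absent from the reference: ",
            paste(dropped, collapse = ", "))
  }
  list(usable = usable, dropped = dropped)
}

#' Domain-based ontology enrichment analysis
#'
#' Tests a user domain list against a reference annotation table. The
#' domain universe is, by default, all reference-annotated domains (a
#' user-supplied `background` overrides it). For every term annotating at
#' least one usable input domain, with K annotated domains in the universe
#' and overlap k with the n usable input domains, the one-sided Fisher's
#' exact p-value and the hypergeometric z-score are computed;
#' Benjamini-Hochberg adjustment runs across all tested terms. Terms with
#' FDR below `fdr_threshold` and overlap at least `min_overlap` are
#' returned, sorted by FDR ascending, ties by z descending, then term id.
#'
#' @param input_domains Character vector of domain identifiers (the user
#'   list; duplicates are removed).
#' @param reference An `annotation_table` (e.g. from
#'   [read_annotation_table()]).
#' @param fdr_threshold Significance cut-off on the adjusted value
#'   (default 0.05).
#' @param min_overlap Minimum overlap count for a term to be reported
#'   (default 1).
#' @param namespace Optional: restrict the reference to terms of this
#'   ontology namespace, looked up in `dag`.
#' @param dag Optional `ontology_dag`, needed only for `namespace`.
#' @param background Optional character vector of domain ids overriding the
#'   universe; must cover the usable input.
#' @param test_all_terms If `TRUE`, every reference term enters the
#'   multiple-testing family, not only terms overlapping the input.
#' @return A data.frame of class `enrichment_result` with columns
#'   `term_id`, `term_name`, `z`, `p`, `fdr`, `num`, `n_anno` (annotated
#'   domains of the term in the universe) and `members` (list column of
#'   overlapping domain ids, sorted); attributes `n_input` (usable input
#'   size), `universe_N`, `usable`, `dropped`, `fdr_threshold`,
#'   `min_overlap`.
#' @export
enrich_domains <- function(input_domains, reference, fdr_threshold = 0.05,
                           min_overlap = 1L, namespace = NULL, dag = NULL,
                           background = NULL, test_all_terms = FALSE) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1, min_overlap >= 1L)
  ref <- as.data.frame(reference)
  if (!is.null(namespace)) {
    if (is.null(dag)) stop("namespace filtering requires the ontology DAG")
    keep_terms <- dag$terms$term_id[dag$terms$namespace == namespace]
    ref <- ref[ref$term_id %in% keep_terms, , drop = FALSE]
    if (!nrow(ref)) stop("reference has no terms in namespace ", namespace)
  }
  res_in <- resolve_input(input_domains, ref)
  usable <- res_in$usable
  universe <- if (is.null(background)) {
    unique(ref$domain_id)
  } else {
    unique(as.character(background))
  }
  missing_bg <- setdiff(usable, universe)
  if (length(missing_bg)) {
    stop("background does not contain usable input domain(s): ",
         paste(missing_bg, collapse = ", "))
  }
  ref <- ref[ref$domain_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(usable)
  if (N < n) stop("input exceeds the domain universe (wrong domain type?)")

  term_sets <- lapply(split(ref$domain_id, ref$term_id), unique)
  term_names <- vapply(split(ref$term_name, ref$term_id), `[[`, "", 1L)
  k <- vapply(term_sets, function(d) length(intersect(d, usable)), integer(1))
  tested <- if (test_all_terms) rep(TRUE, length(k)) else k >= 1L
  if (!any(tested)) return(empty_enrichment(n, N, res_in,
                                            fdr_threshold, min_overlap))
  tid <- names(term_sets)[tested]
  K <- lengths(term_sets)[tested]
  kk <- k[tested]
  p <- fisher_one_sided(kk, K, n, N)
  z <- hypergeom_strength(kk, K, n, N)
  fdr <- bh_adjust(p)
  # a threshold of 1 disables FDR filtering (reports every tested term,
  # including degenerate input-equals-universe runs where every fdr is 1)
  keep <- (fdr < fdr_threshold | fdr_threshold >= 1) & kk >= min_overlap
  members <- lapply(term_sets[tested], function(d) sort(intersect(d, usable)))
  out <- data.frame(term_id = tid,
                    term_name = unname(term_names[tid]),
                    z = z, p = p, fdr = fdr,
                    num = as.integer(kk), n_anno = as.integer(K),
                    stringsAsFactors = FALSE)
  out$members <- unname(members)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$fdr, -out$z, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  finish_enrichment(out, n, N, res_in, fdr_threshold, min_overlap)
}

empty_enrichment <- function(n, N, res_in, fdr_threshold, min_overlap) {
  out <- data.frame(term_id = character(0), term_name = character(0),
                    z = numeric(0), p = numeric(0), fdr = numeric(0),
                    num = integer(0), n_anno = integer(0),
                    stringsAsFactors = FALSE)
  out$members <- list()
  finish_enrichment(out, n, N, res_in, fdr_threshold, min_overlap)
}

finish_enrichment <- function(out, n, N, res_in, fdr_threshold, min_overlap) {
  attr(out, "n_input") <- n
  attr(out, "universe_N") <- N
  attr(out, "usable") <- res_in$usable
  attr(out, "dropped") <- res_in$dropped
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "min_overlap") <- min_overlap
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Top enriched terms
#'
#' First `top_n` rows of an already-sorted enrichment result (FDR
#' ascending, ties by z descending, then term id) — the set shown in the
#' dot plot.
#'
#' @param results An `enrichment_result`.
#' @param top_n Number of terms to keep (default 5).
#' @return The truncated `enrichment_result`.
#' @export
top_terms <- function(results, top_n = 5L) {
  stopifnot(top_n >= 0)
  utils::head(results, top_n)
}

#' Write an enrichment report (TSV + dot-plot data)
#'
#' The main report has `#` metadata lines carrying the usable input size n
#' and universe N, then tab-separated columns `term_id`, `term_name`, `z`,
#' `p`, `fdr`, `num`, `n_anno`, `members` (comma-joined). A companion
#' dot-plot data file (`term_id`, `z`, `fdr`) holds the top `top_n` terms.
#' Empty results produce header-only files.
#'
#' @param results An `enrichment_result`.
#' @param path Output path for the report TSV.
#' @param dotplot_path Output path for the dot-plot data (default:
#'   `<path>` with a `.dotplot.tsv` suffix).
#' @param top_n Terms carried into the dot-plot data (default 5).
#' @return Invisibly, `path`.
#' @export
write_enrichment_report <- function(results, path,
                                    dotplot_path = NULL, top_n = 5L) {
  if (is.null(dotplot_path)) {
    dotplot_path <- paste0(sub("\\.tsv$", "", path), ".dotplot.tsv")
  }
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# n_input=", attr(results, "n_input")),
      paste0("# universe_N=", attr(results, "universe_N")),
      paste0("# fdr_threshold=", format_num(attr(results, "fdr_threshold"))),
      paste0("# min_overlap=", attr(results, "min_overlap")),
      paste("term_id", "term_name", "z", "p", "fdr", "num", "n_anno",
            "members", sep = "\t")), con)
    if (nrow(results)) {
      writeLines(paste(results$term_id, results$term_name,
                       format_num(results$z), format_num(results$p),
                       format_num(results$fdr), results$num, results$n_anno,
                       vapply(results$members, paste, "", collapse = ","),
                       sep = "\t"), con)
    }
  })
  top <- top_terms(results, top_n)
  atomic_write(dotplot_path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(paste("term_id", "z", "fdr", sep = "\t"), con)
    if (nrow(top)) {
      writeLines(paste(top$term_id, format_num(top$z), format_num(top$fdr),
                       sep = "\t"), con)
    }
  })
  invisible(path)
}

#' Read back an enrichment report
#'
#' Parses a TSV written by [write_enrichment_report()], restoring the
#' result data.frame (members as a list column) and the n/N metadata.
#'
#' @param path Report TSV path.
#' @return An `enrichment_result`.
#' @export
read_enrichment_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  metal <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  meta <- list()
  for (ml in metal) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  if (!length(body)) stop("enrichment report has no header line")
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, quote = "", comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(term_id = "character"))
  members <- if (nrow(df)) {
    strsplit(as.character(df$members), ",", fixed = TRUE)
  } else {
    list()
  }
  df$members <- members
  df$num <- as.integer(df$num)
  df$n_anno <- as.integer(df$n_anno)
  attr(df, "n_input") <- as.integer(meta$n_input)
  attr(df, "universe_N") <- as.integer(meta$universe_N)
  attr(df, "fdr_threshold") <- suppressWarnings(as.numeric(meta$fdr_threshold))
  attr(df, "min_overlap") <- as.integer(meta$min_overlap)
  class(df) <- c("enrichment_result", "data.frame")
  df
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result:", nrow(x), "term(s); input n =",
      attr(x, "n_input"), "of universe N =", attr(x, "universe_N"), "\n")
  if (nrow(x)) {
    show <- as.data.frame(x)[, c("term_id", "term_name", "z", "fdr", "num")]
    print(utils::head(show, 10))
  }
  invisible(x)
}
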