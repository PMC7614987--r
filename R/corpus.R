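#' Read protein-to-term annotations from a GAF file
#'
#' Parses a Gene Association File (GAF 2.x). Comment lines starting with `!`
#' are skipped, the protein accession is taken from column 2 and the term id
#' from column 5. Rows whose qualifier (column 4) contains the `NOT` token
#' are dropped, as are rows whose evidence code (column 7) is listed in
#' `evidence_exclude`. All evidence codes are kept by default.
#'
#' @param path Path to a GAF file, or a character vector of GAF lines.
#' @param evidence_exclude Character vector of evidence codes to drop
#'   (e.g. `"IEA"`). Default: none.
#' @return A named list mapping protein id to a character vector of term ids
#'   (a protein-term map). Proteins with no retained annotation are absent.
#' @export
read_gaf <- function(path, evidence_exclude = character(0)) {
  lines <- read_input_lines(path)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7L)) {
    stop("GAF format error: fewer than 7 columns at data line ",
         which(nf < 7L)[1L])
  }
  prot <- vapply(fields, `[[`, "", 2L)
  qual <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  evid <- vapply(fields, `[[`, "", 7L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual) & !(evid %in% evidence_exclude)
  prot <- prot[keep]; term <- term[keep]
  if (!length(prot)) return(stats::setNames(list(), character(0)))
  lapply(split(term, prot), function(x) sort(unique(x)))
}

#' Read protein-to-domain assignments from TSV
#'
#' Expects at least two tab-separated columns, `protein_id` and `domain_id`
#' (extra columns, e.g. coordinates or e-values from a domain scan, are
#' ignored). A header row is auto-detected. Repeated (protein, domain) rows
#' collapse to presence/absence: a protein carries a domain or it does not,
#' regardless of copy number.
#'
#' @param path Path to a TSV file, or a character vector of lines.
#' @param domain_type Label for the domain definition used, one of
#'   `"SCOP-SF"`, `"SCOP-FA"`, `"Pfam"`, `"InterPro"`, `"other"`.
#' @return A named list mapping protein id to a character vector of domain
#'   ids, with attribute `domain_type`. Rows with a blank domain id are
#'   rejected with a warning reporting their count.
#' @export
read_domain_assignments <- function(path, domain_type = c("other", "SCOP-SF",
                                    "SCOP-FA", "Pfam", "InterPro")) {
  domain_type <- match.arg(domain_type)
  lines <- read_input_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty domain-assignment input")
  # pad with a trailing field so strsplit keeps empty last columns
  fields <- strsplit(paste0(lines, "\t"), "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("domain-assignment format error: fewer than 2 columns at line ",
         which(lengths(fields) < 2L)[1L])
  }
  first <- fields[[1L]]
  if (grepl("protein|domain", paste(first[1:2], collapse = " "),
            ignore.case = TRUE)) {
    fields <- fields[-1L]
    if (!length(fields)) stop("empty domain-assignment input (header only)")
  }
  prot <- vapply(fields, `[[`, "", 1L)
  dom <- vapply(fields, `[[`, "", 2L)
  blank <- !nzchar(trimws(dom)) | !nzchar(trimws(prot))
  if (any(blank)) {
    warning(sum(blank), " row(s) with blank protein or domain id rejected")
    prot <- prot[!blank]; dom <- dom[!blank]
  }
  if (!length(prot)) stop("no usable domain-assignment rows")
  out <- lapply(split(dom, prot), function(x) sort(unique(x)))
  attr(out, "domain_type") <- domain_type
  out
}

read_input_lines <- function(path) {
  if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    out <- unlist(strsplit(as.character(path), "\n", fixed = TRUE),
                  use.names = FALSE)
    if (is.null(out)) character(0) else out
  }
}

#' Build the term-by-domain correspondence matrix
#'
#' The sufficient statistic of the annotation inference: for every ontology
#' term t and domain d it records k(t,d), the number of proteins carrying
#' both, together with the marginals K(t) (proteins with the term), n(d)
#' (proteins with the domain) and N (proteins present in both inputs, the
#' joint universe). Each protein's term set is closed under ancestors
#' before counting, so a parent term's count is never smaller than a
#' child's (True Path Rule at protein level).
#'
#' @param ptm Protein-term map from [read_gaf()] or a named list.
#' @param pdm Protein-domain map from [read_domain_assignments()].
#' @param dag `ontology_dag` used for closure; annotations to terms absent
#'   from the DAG are dropped with a warning.
#' @param close_terms Close each protein's term set under ancestors first
#'   (default `TRUE`).
#' @return Object of class `correspondence_matrix`: list with `pairs`
#'   (data.frame `term_id`, `domain_id`, `k` for all pairs with k > 0),
#'   `K`, `n` (named integer vectors), `N`, and `domain_type`.
#' @export
build_correspondence_matrix <- function(ptm, pdm, dag, close_terms = TRUE) {
  stopifnot(inherits(dag, "ontology_dag"))
  joint <- intersect(names(ptm), names(pdm))
  if (!length(joint)) {
    stop("annotation and domain inputs share no protein identifiers")
  }
  clo <- if (close_terms) term_closures(dag) else NULL

  dropped_terms <- 0L
  term_sets <- lapply(ptm[joint], function(ts) {
    ids <- resolve_term_ids(dag, ts)
    dropped_terms <<- dropped_terms + sum(is.na(ids))
    ids <- ids[!is.na(ids)]
    if (!length(ids)) return(character(0))
    if (close_terms) {
      unique(unlist(clo[ids], use.names = FALSE))
    } else {
      unique(ids)
    }
  })
  if (dropped_terms > 0L) {
    warning(dropped_terms, " annotation(s) to terms absent from the ontology dropped")
  }
  keep <- lengths(term_sets) > 0L
  joint <- joint[keep]
  term_sets <- term_sets[keep]
  if (!length(joint)) stop("no protein retains a term known to the ontology")
  dom_sets <- lapply(pdm[joint], unique)

  N <- length(joint)
  t_long <- data.frame(
    protein = rep(joint, lengths(term_sets)),
    term_id = unlist(term_sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  d_long <- data.frame(
    protein = rep(joint, lengths(dom_sets)),
    domain_id = unlist(dom_sets, use.names = FALSE),
    stringsAsFactors = FALSE)

  K <- vapply(split(t_long$protein, t_long$term_id),
              function(x) length(unique(x)), integer(1))
  n <- vapply(split(d_long$protein, d_long$domain_id),
              function(x) length(unique(x)), integer(1))

  m <- merge(t_long, d_long, by = "protein")
  key <- paste(m$term_id, m$domain_id, sep = "\r")
  tab <- table(key)                       # sets are unique per protein
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  pairs <- data.frame(
    term_id = vapply(parts, `[[`, "", 1L),
    domain_id = vapply(parts, `[[`, "", 2L),
    k = as.integer(tab),
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$term_id, pairs$domain_id), , drop = FALSE]
  rownames(pairs) <- NULL

  structure(
    list(pairs = pairs,
         K = K[sort(names(K))],
         n = n[sort(names(n))],
         N = N,
         domain_type = attr(pdm, "domain_type") %||% "other"),
    class = "correspondence_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correspondence_matrix <- function(x, ...) {
  cat("correspondence_matrix:", length(x$K), "terms x", length(x$n),
      "domains over", x$N, "proteins;", nrow(x$pairs),
      "non-zero co-occurrence pairs\n")
  invisible(x)
}

#' Write a correspondence matrix as sparse triplet TSV
#'
#' Emits two files: `<path>` with the non-zero triplets
#' (`term_id`, `domain_id`, `k`) and `<path>.marginals` with per-term `K`,
#' per-domain `n` rows and the universe size `N`.
#'
#' @param cm A `correspondence_matrix`.
#' @param path Output path for the triplet file.
#' @return Invisibly, `path`.
#' @export
write_correspondence_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "correspondence_matrix"))
  atomic_write(path, function(p) {
    utils::write.table(cm$pairs, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  marg <- rbind(
    data.frame(kind = "term", id = names(cm$K), count = as.integer(cm$K)),
    data.frame(kind = "domain", id = names(cm$n), count = as.integer(cm$n)),
    data.frame(kind = "universe", id = "N", count = cm$N))
  atomic_write(paste0(path, ".marginals"), function(p) {
    utils::write.table(marg, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  invisible(path)
}
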