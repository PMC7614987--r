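#' Parse an OBO flat file into an ontology DAG
#'
#' Reads an OBO 1.2/1.4 flat file and returns the directed acyclic graph of
#' its non-obsolete terms. Only `is_a` edges are used by default; `part_of`
#' relationships can be opted in. Obsolete stanzas are dropped entirely and
#' `alt_id` lines are recorded as aliases that resolve to the primary id, so
#' corpus annotations using superseded identifiers are not lost.
#'
#' Files carrying several namespaces (e.g. the three Gene Ontology branches)
#' keep their multiple roots as separate sub-DAGs distinguished by the
#' `namespace` field; no artificial super-root is added.
#'
#' @param path Path to an OBO file, or a character vector of OBO lines.
#' @param use_part_of Logical; also treat `relationship: part_of` lines as
#'   parent edges (default `FALSE`).
#' @return An object of class `ontology_dag`: a list with elements
#'   `terms` (data.frame of `term_id`, `name`, `namespace`), `parents` and
#'   `children` (named lists of character vectors), `roots`, `alt`
#'   (named character vector mapping alternate to primary ids) and `topo`
#'   (a topological order with parents before children).
#' @examples
#' obo <- c("[Term]", "id: T:2", "name: child", "is_a: T:1 ! parent",
#'          "", "[Term]", "id: T:1", "name: parent")
#' dag <- parse_obo(obo)
#' dag$roots
#' @export
parse_obo <- function(path, use_part_of = FALSE) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(as.character(path), "\n", fixed = TRUE), use.names = FALSE)
  }

  stanzas <- list()
  cur <- NULL
  cur_start <- NA_integer_
  in_term <- FALSE
  flush <- function() {
    if (in_term) stanzas[[length(stanzas) + 1L]] <<- list(fields = cur, line = cur_start)
  }
  for (i in seq_along(lines)) {
    ln <- sub("\\s+$", "", lines[[i]])
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      cur <- list()
      cur_start <- i
      next
    }
    if (!in_term) next
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 1L) stop("malformed OBO stanza: no 'tag: value' at line ", i)
    tag <- substr(ln, 1L, m - 1L)
    val <- sub("^\\s+", "", substr(ln, m + 1L, nchar(ln)))
    val <- sub("\\s*!.*$", "", val)          # trailing ' ! comment'
    cur[[length(cur) + 1L]] <- c(tag = tag, value = val, line = i)
  }
  flush()

  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list(); alt_from <- character(0); alt_to <- character(0)
  for (st in stanzas) {
    f <- st$fields
    tags <- vapply(f, `[[`, "", "tag")
    vals <- vapply(f, `[[`, "", "value")
    id <- vals[tags == "id"]
    if (length(id) != 1L || !nzchar(id)) {
      stop("malformed OBO stanza: missing id in [Term] at line ", st$line)
    }
    if (any(tags == "is_obsolete" & tolower(vals) == "true")) next
    par <- vals[tags == "is_a"]
    if (use_part_of) {
      rel <- vals[tags == "relationship"]
      rel <- rel[grepl("^part_of\\s+", rel)]
      par <- c(par, sub("^part_of\\s+", "", rel))
    }
    name <- vals[tags == "name"]
    ns <- vals[tags == "namespace"]
    a <- vals[tags == "alt_id"]
    ids <- c(ids, id)
    nms <- c(nms, if (length(name)) name[[1L]] else "")
    nss <- c(nss, if (length(ns)) ns[[1L]] else "")
    parents[[id]] <- unique(par)
    if (length(a)) { alt_from <- c(alt_from, a); alt_to <- c(alt_to, rep(id, length(a))) }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term id in OBO input: ", ids[duplicated(ids)][1L])
  }
  unresolved <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(unresolved)) {
    stop("is_a parent(s) not defined as non-obsolete terms: ",
         paste(unresolved, collapse = ", "))
  }
  alt <- stats::setNames(alt_to, alt_from)
  new_ontology_dag(ids, nms, nss, parents, alt)
}

# Internal constructor shared by parse_obo and generate_dag: validates
# acyclicity (Kahn), derives children lists, roots and a topological order.
new_ontology_dag <- function(ids, names, namespaces, parents, alt = character(0)) {
  parents <- parents[ids]
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  names(parents) <- ids
  children <- lapply(ids, function(x) character(0))
  names(children) <- ids
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  # Kahn's algorithm on parent -> child direction: roots first.
  indeg <- lengths(parents)
  topo <- character(0)
  queue <- ids[indeg == 0L]
  indeg_left <- indeg
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg_left[[ch]] <- indeg_left[[ch]] - 1L
      if (indeg_left[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(ids)) {
    rem <- setdiff(ids, topo)
    # walk parent pointers inside the remainder until a node repeats
    path <- rem[[1L]]
    repeat {
      nxt <- intersect(parents[[path[[length(path)]]]], rem)[1L]
      if (nxt %in% path) {
        cyc <- c(path[which(path == nxt):length(path)], nxt)
        stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
      }
      path <- c(path, nxt)
    }
  }
  if (!any(lengths(parents) == 0L)) stop("ontology has no root term")
  structure(
    list(
      terms = data.frame(term_id = ids, name = names, namespace = namespaces,
                         stringsAsFactors = FALSE),
      parents = parents,
      children = children,
      roots = ids[lengths(parents) == 0L],
      alt = alt,
      topo = topo
    ),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms,",
      sum(lengths(x$parents)), "is_a edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

# Resolve possibly-alternate ids to primary ids; NA for unknown ids.
resolve_term_ids <- function(dag, term_ids) {
  out <- term_ids
  is_alt <- out %in% names(dag$alt)
  out[is_alt] <- unname(dag$alt[out[is_alt]])
  out[!out %in% dag$terms$term_id] <- NA_character_
  out
}

#' Strict ancestors of a term
#'
#' All terms reachable from `term_id` by following `is_a` edges towards the
#' roots, excluding `term_id` itself.
#'
#' @param dag An `ontology_dag`.
#' @param term_id A single term identifier (alternate ids are resolved).
#' @return Character vector of ancestor term ids (unordered set).
#' @export
ancestors <- function(dag, term_id) {
  stopifnot(inherits(dag, "ontology_dag"), length(term_id) == 1L)
  id <- resolve_term_ids(dag, term_id)
  if (is.na(id)) stop("unknown term id: ", term_id)
  seen <- character(0)
  frontier <- dag$parents[[id]]
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
  }
  unique(seen)
}

#' Close a term set under ancestors (True Path Rule)
#'
#' Returns the union of `term_ids` with every ancestor of each member, i.e.
#' the smallest superset satisfying the True Path Rule: annotation to a term
#' implies annotation to all of its ancestors. Idempotent and monotone.
#'
#' @param dag An `ontology_dag`.
#' @param term_ids Character vector of term ids (alternate ids resolved).
#' @return Character vector, sorted, containing `term_ids` and all ancestors.
#' @export
close_term_set <- function(dag, term_ids) {
  stopifnot(inherits(dag, "ontology_dag"))
  ids <- resolve_term_ids(dag, term_ids)
  if (anyNA(ids)) stop("unknown term id(s): ",
                       paste(term_ids[is.na(ids)], collapse = ", "))
  out <- ids
  frontier <- unique(unlist(dag$parents[ids], use.names = FALSE))
  while (length(frontier)) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
  }
  sort(unique(out))
}

# Full closure (term itself + ancestors) for every term, computed once in
# topological order; used by the matrix builder and propagation.
term_closures <- function(dag) {
  clo <- vector("list", nrow(dag$terms))
  names(clo) <- dag$terms$term_id
  for (id in dag$topo) {            # parents appear before children
    ps <- dag$parents[[id]]
    clo[[id]] <- unique(c(id, unlist(clo[ps], use.names = FALSE)))
  }
  clo
}

#' Write the DAG edge list as TSV
#'
#' Dumps child -> parent `is_a` edges, one per row, for debugging and
#' interchange.
#'
#' @param dag An `ontology_dag`.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_edge_list <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  ch <- rep(names(dag$parents), lengths(dag$parents))
  pa <- unlist(dag$parents, use.names = FALSE)
  df <- data.frame(child_id = ch, parent_id = pa, stringsAsFactors = FALSE)
  df <- df[order(df$child_id, df$parent_id), , drop = FALSE]
  atomic_write(path, function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

# Write a file atomically: produce it under a temporary name in the target
# directory, then rename, so failed runs leave no partial output behind.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".part")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("cannot write output file: ", path)
  invisible(path)
}
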