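#' Read an ontology from OBO 1.2
#'
#' Minimal OBO parser covering what GO-style enrichment needs: `[Term]`
#' stanzas with `id`, `name`, `namespace` and `is_a` tags. Obsolete terms
#' (`is_obsolete: true`) are skipped, and other stanza types (`[Typedef]`,
#' ...) are ignored. The `is_a` relation must be acyclic and closed over the
#' declared terms.
#'
#' @param path OBO file path.
#' @return An object of class `ontology`: a list with
#'   \describe{
#'     \item{terms}{data.frame with columns `id`, `name`, `namespace`}
#'     \item{edges}{data.frame with columns `child`, `parent` (direct is_a)}
#'     \item{graph}{an igraph directed graph, edges child -> parent}
#'   }
#' @export
read_obo <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  in_term <- FALSE
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <- cur
    }
    terms
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(is_a = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      key <- sub(":.*$", "", ln)
      val <- trimws(sub("^[^:]+:\\s*", "", ln))
      val <- sub("\\s*!.*$", "", val)  # strip trailing comments
      if (key == "id") cur$id <- val
      else if (key == "name") cur$name <- val
      else if (key == "namespace") cur$namespace <- val
      else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
      else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    }
  }
  terms <- flush(cur, terms)
  ids <- vapply(terms, function(t) t$id, "")
  term_df <- data.frame(
    id = ids,
    name = vapply(terms, function(t) if (is.null(t$name)) "" else t$name, ""),
    namespace = vapply(terms, function(t) if (is.null(t$namespace)) "" else t$namespace, ""),
    stringsAsFactors = FALSE
  )
  edges <- do.call(rbind, lapply(terms, function(t) {
    if (length(t$is_a) == 0) return(NULL)
    data.frame(child = t$id, parent = t$is_a, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }
  make_ontology(term_df, edges)
}

#' Construct and validate an ontology object
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`.
#' @return An `ontology` object (see [read_obo()]).
#' @export
make_ontology <- function(terms, edges) {
  undeclared <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(undeclared) > 0) {
    stop("is_a references undeclared term(s): ",
         paste(undeclared, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = terms$id, stringsAsFactors = FALSE)
  )
  if (nrow(edges) > 0 && !igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc[1])
    stop(sprintf("cyclic is_a relation (e.g. involving %s -> %s)",
                 ends[1], ends[2]))
  }
  structure(list(terms = terms, edges = edges, graph = g),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms, %d is_a edges, namespaces: %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

#' Ancestor closure of ontology terms
#'
#' For each requested term, the set of terms reachable through `is_a` edges
#' (including the term itself) — the true-path closure used for enrichment.
#'
#' @param ontology An `ontology` object.
#' @param ids Term ids (default: all).
#' @return Named list mapping each id to its ancestor set (self included).
#' @export
term_ancestors <- function(ontology, ids = ontology$terms$id) {
  unknown <- setdiff(ids, ontology$terms$id)
  if (length(unknown) > 0) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  }
  res <- lapply(ids, function(id) {
    names(igraph::subcomponent(ontology$graph, id, mode = "out"))
  })
  names(res) <- ids
  res
}

#' Write an ontology to OBO 1.2
#'
#' @param ontology An `ontology` object.
#' @param path Output path.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  par_of <- split(ontology$edges$parent, ontology$edges$child)
  for (i in seq_len(nrow(ontology$terms))) {
    t <- ontology$terms[i, ]
    writeLines(c("", "[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace)), con)
    for (p in par_of[[t$id]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}
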