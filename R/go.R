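#' Propagate annotations up the ontology
#'
#' True-path closure: each gene's term set is extended with every `is_a`
#' ancestor of its direct terms. Idempotent.
#'
#' @param annotations Named list, gene -> direct term ids.
#' @param ontology An `ontology` object.
#' @return Named list, gene -> closed term set (sorted, unique).
#' @export
propagate_annotations <- function(annotations, ontology) {
  used <- unique(unlist(annotations, use.names = FALSE))
  unknown <- setdiff(used, ontology$terms$id)
  if (length(unknown) > 0) {
    stop("annotation to unknown term(s): ", paste(unknown, collapse = ", "))
  }
  anc <- term_ancestors(ontology, used)
  lapply(annotations, function(terms) {
    sort(unique(unlist(anc[terms], use.names = FALSE)))
  })
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a draw of
#' `n` genes from a population of `N`, of which `K` carry the category,
#' contains at least `k` carriers.
#'
#' @param k Observed category count in the study set.
#' @param n Study set size.
#' @param K Category count in the population.
#' @param N Population size.
#' @return Probability in \[0, 1\].
#' @export
hypergeometric_p <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || any(k > pmin(n, K)) ||
      any(n > N) || any(K > N)) {
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K), n <= N, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Yekutieli adjustment
#'
#' FDR control under arbitrary dependence: the Benjamini-Hochberg step-up
#' procedure scaled by the harmonic sum c(m) = sum(1/i, i = 1..m), enforced
#' monotone and capped at 1. Input order is preserved.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
adjust_yekutieli <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' GO term enrichment of a study set
#'
#' Upper-tail hypergeometric test per term, with Benjamini-Yekutieli
#' adjustment applied within each ontology namespace separately. Counts are
#' of distinct genes; annotations should be propagated
#' ([propagate_annotations()]) beforehand.
#'
#' @param study Character vector of study gene symbols (subset of population).
#' @param population Character vector of population gene symbols.
#' @param annotations Named list, gene -> term ids (propagated).
#' @param ontology An `ontology` object (for term names and namespaces).
#' @return Data.frame with one row per term annotated to >= 1 study gene:
#'   `term_id`, `name`, `namespace`, `k`, `n`, `K`, `N`, `p_raw`, `p_adjusted`,
#'   `test`, sorted by adjusted p then term id.
#' @export
enrich_terms <- function(study, population, annotations, ontology) {
  study <- unique(study)
  population <- unique(population)
  stray <- setdiff(study, population)
  if (length(stray) > 0) {
    stop("study gene(s) absent from population: ", paste(stray, collapse = ", "))
  }
  n <- length(study)
  N <- length(population)
  ann_study <- annotations[intersect(study, names(annotations))]
  ann_pop <- annotations[intersect(population, names(annotations))]
  k_tab <- table(unlist(ann_study, use.names = FALSE))
  K_tab <- table(unlist(ann_pop, use.names = FALSE))
  terms <- names(k_tab)
  if (length(terms) == 0) {
    return(data.frame(term_id = character(), name = character(),
                      namespace = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), test = character(),
                      stringsAsFactors = FALSE))
  }
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  meta <- ontology$terms[match(terms, ontology$terms$id), ]
  res <- data.frame(
    term_id = terms, name = meta$name, namespace = meta$namespace,
    k = k, n = n, K = K, N = N,
    p_raw = hypergeometric_p(k, n, K, N),
    p_adjusted = NA_real_, test = "hypergeometric",
    stringsAsFactors = FALSE
  )
  for (ns in unique(res$namespace)) {
    sel <- res$namespace == ns
    res$p_adjusted[sel] <- adjust_yekutieli(res$p_raw[sel])
  }
  res <- res[order(res$p_adjusted, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Shared GO terms within bidirectional gene pairs
#'
#' For each pair, the intersection of the two members' DIRECT term sets,
#' overall and split by namespace, plus the distribution of shared-term
#' counts over pairs and the fraction of pairs sharing at least one term.
#' Direct (unpropagated) annotations are the default: under propagation every
#' annotated pair would trivially share the namespace roots.
#'
#' @param pairs Pair data.frame (columns `pair_id`, `plus_symbol`,
#'   `minus_symbol`).
#' @param annotations Named list, gene -> direct term ids.
#' @param ontology An `ontology` object.
#' @return List with `records` (per-pair data.frame: `pair_id`, `shared_count`,
#'   per-namespace counts, `shared_terms`, `unannotated` flag), `histogram`
#'   (shared-count table over pairs), and `fraction_sharing` (pairs with
#'   >= 1 shared term / all pairs).
#' @export
pair_shared_terms <- function(pairs, annotations, ontology) {
  ns_of <- stats::setNames(ontology$terms$namespace, ontology$terms$id)
  namespaces <- c("biological_process", "molecular_function", "cellular_component")
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- annotations[[pairs$plus_symbol[i]]]
    b <- annotations[[pairs$minus_symbol[i]]]
    unann <- is.null(a) || is.null(b)
    shared <- intersect(a, b)
    per_ns <- vapply(namespaces, function(ns) sum(ns_of[shared] == ns), 0L)
    c(list(pair_id = pairs$pair_id[i], shared_count = length(shared)),
      as.list(stats::setNames(per_ns, paste0("shared_", c("bp", "mf", "cc")))),
      list(shared_terms = paste(sort(shared), collapse = ","),
           unannotated = unann))
  })
  records <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(records)) {
    records <- data.frame(pair_id = character(), shared_count = integer(),
                          shared_bp = integer(), shared_mf = integer(),
                          shared_cc = integer(), shared_terms = character(),
                          unannotated = logical(), stringsAsFactors = FALSE)
  }
  hist <- table(records$shared_count)
  frac <- if (nrow(records) == 0) NA_real_ else mean(records$shared_count >= 1)
  list(records = records, histogram = hist, fraction_sharing = frac)
}

#' Gene-set (pathway) enrichment from GMT collections
#'
#' One-sided Fisher's exact test per set — the upper hypergeometric tail on
#' the 2x2 margins — with Benjamini-Hochberg FDR across all sets in the
#' collection. Stands in for pathway-database enrichment on any GMT input.
#'
#' @param study,population Gene symbol vectors (study within population).
#' @param gmt Named list from [read_gmt()].
#' @return Data.frame: `set_id`, `name`, `collection`, `k`, `n`, `K`, `N`,
#'   `p_raw`, `p_adjusted`, `test`, sorted by adjusted p then set id.
#' @export
enrich_gene_sets <- function(study, population, gmt) {
  study <- unique(study)
  population <- unique(population)
  stray <- setdiff(study, population)
  if (length(stray) > 0) {
    stop("study gene(s) absent from population: ", paste(stray, collapse = ", "))
  }
  keep <- vapply(gmt, function(s) length(intersect(s$genes, population)) > 0, TRUE)
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " gene set(s) with no population members")
    gmt <- gmt[keep]
  }
  if (length(gmt) == 0) {
    return(data.frame(set_id = character(), name = character(),
                      collection = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), test = character(),
                      stringsAsFactors = FALSE))
  }
  n <- length(study)
  N <- length(population)
  k <- vapply(gmt, function(s) length(intersect(s$genes, study)), 0L)
  K <- vapply(gmt, function(s) length(intersect(s$genes, population)), 0L)
  res <- data.frame(
    set_id = names(gmt), name = names(gmt), collection = "gmt",
    k = k, n = n, K = K, N = N,
    p_raw = hypergeometric_p(k, n, K, N),
    p_adjusted = stats::p.adjust(hypergeometric_p(k, n, K, N), method = "BH"),
    test = "fisher-one-sided", stringsAsFactors = FALSE
  )
  res <- res[order(res$p_adjusted, res$set_id), ]
  rownames(res) <- NULL
  res
}
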