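chain_ontology <- function() {
  make_ontology(
    data.frame(id = c("T:A", "T:B", "T:C", "T:D"),
               name = c("a", "b", "c", "d"),
               namespace = "biological_process", stringsAsFactors = FALSE),
    data.frame(child = c("T:B", "T:C", "T:D", "T:D"),
               parent = c("T:A", "T:B", "T:B", "T:C"), stringsAsFactors = FALSE))
}

test_that("annotation propagation closes over is_a ancestors", {
  ont <- make_ontology(
    data.frame(id = c("T:A", "T:B", "T:C"), name = c("a", "b", "c"),
               namespace = "biological_process", stringsAsFactors = FALSE),
    data.frame(child = c("T:B", "T:C"), parent = c("T:A", "T:B"),
               stringsAsFactors = FALSE))
  prop <- propagate_annotations(list(g1 = "T:C"), ont)
  expect_setequal(prop$g1, c("T:A", "T:B", "T:C"))
  # idempotence
  expect_equal(propagate_annotations(prop, ont), prop)

  # diamond: D is_a B, D is_a C, B and C is_a A; A counted once
  dia <- chain_ontology()
  prop <- propagate_annotations(list(g1 = "T:D"), dia)
  expect_equal(prop$g1, sort(c("T:A", "T:B", "T:C", "T:D")))

  expect_error(propagate_annotations(list(g1 = "T:NOPE"), dia), "unknown term")
})

test_that("hypergeometric upper tail matches exhaustive draw enumeration", {
  # spot values derivable by direct enumeration
  expect_equal(hypergeometric_p(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeometric_p(0, 3, 4, 8), 1.0)
  expect_equal(hypergeometric_p(2, 3, 4, 8), hyper_enum_upper(2, 3, 4, 8))

  # all valid parameter combinations with N <= 12
  for (N in 1:12) for (n in 0:N) for (K in 0:N) {
    draws <- if (n == 0) matrix(integer(0), nrow = 0, ncol = 1)
             else utils::combn(N, n)
    overlaps <- if (n == 0) 0L else colSums(draws <= K)
    for (k in 0:min(n, K)) {
      expect_equal(hypergeometric_p(k, n, K, N), mean(overlaps >= k),
                   tolerance = 1e-12)
    }
  }
  expect_error(hypergeometric_p(6, 5, 5, 10), "invalid")
  expect_error(hypergeometric_p(1, 5, 5, 4), "invalid")
})

test_that("Benjamini-Yekutieli adjustment matches hand-evaluated cases", {
  expect_equal(adjust_yekutieli(0.03), 0.03)
  # m = 2, c(2) = 1.5: candidates 0.01*2*1.5/1 and 0.04*2*1.5/2
  expect_equal(adjust_yekutieli(c(0.01, 0.04)), c(0.03, 0.06))
  # m = 3, c(3) = 11/6; step-up minima then cap at 1
  expect_equal(adjust_yekutieli(c(0.01, 0.02, 0.9)), c(0.055, 0.055, 1))
  expect_equal(adjust_yekutieli(c(1, 1, 1)), c(1, 1, 1))
  # input order restored
  expect_equal(adjust_yekutieli(c(0.04, 0.01)), c(0.06, 0.03))
  expect_error(adjust_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BY adjustment is monotone and dominates raw p and BH", {
  set.seed(41)
  for (i in 1:10) {
    p <- runif(sample(5:40, 1))
    by <- adjust_yekutieli(p)
    expect_true(all(by >= p))
    expect_true(all(by <= 1))
    expect_true(all(by >= stats::p.adjust(p, "BH")))
    ord <- order(p)
    expect_true(all(diff(by[ord]) >= -1e-12))
  }
})

test_that("term enrichment counts distinct genes and adjusts per namespace", {
  ont <- make_ontology(
    data.frame(id = c("T:P", "T:Q", "T:R"), name = c("p", "q", "r"),
               namespace = c("biological_process", "biological_process",
                             "molecular_function"), stringsAsFactors = FALSE),
    data.frame(child = character(), parent = character()))
  pop <- sprintf("g%02d", 1:20)
  study <- pop[1:10]
  ann <- lapply(stats::setNames(pop, pop), function(g) {
    t <- character(0)
    i <- as.integer(sub("g", "", g))
    if (i <= 8 || i > 18) t <- c(t, "T:P")   # 8 study, 2 non-study
    if (i %% 2 == 0) t <- c(t, "T:Q")
    if (i <= 3) t <- c(t, "T:R")
    t
  })
  res <- enrich_terms(study, pop, ann, ont)
  rp <- res[res$term_id == "T:P", ]
  expect_equal(rp$k, 8L)
  expect_equal(rp$K, 10L)
  expect_equal(rp$p_raw, hyper_enum_upper(8, 10, 10, 20))
  # namespace-wise adjustment: the single MF term is adjusted alone (m = 1)
  rr <- res[res$term_id == "T:R", ]
  expect_equal(rr$p_adjusted, rr$p_raw)

  # saturation: study = population makes every p = 1 and k = K
  res2 <- enrich_terms(pop, pop, ann, ont)
  expect_true(all(res2$k == res2$K))
  expect_true(all(res2$p_raw == 1))

  # term with no study gene is absent
  ann2 <- ann; ann2$g20 <- c(ann2$g20, "T:X")
  ont2 <- make_ontology(
    rbind(ont$terms, data.frame(id = "T:X", name = "x",
                                namespace = "molecular_function")),
    ont$edges)
  expect_false("T:X" %in% enrich_terms(study, pop, ann2, ont2)$term_id)

  expect_error(enrich_terms(c(study, "stranger"), pop, ann, ont), "stranger")
})

test_that("pair shared-term analysis intersects direct annotations", {
  ont <- make_ontology(
    data.frame(id = c("T:1", "T:2", "T:3"), name = c("1", "2", "3"),
               namespace = c("biological_process", "molecular_function",
                             "cellular_component"), stringsAsFactors = FALSE),
    data.frame(child = character(), parent = character()))
  pairs <- data.frame(pair_id = c("p1", "p2"),
                      plus_symbol = c("a", "c"), minus_symbol = c("b", "d"),
                      stringsAsFactors = FALSE)
  ann <- list(a = c("T:1", "T:2"), b = c("T:2", "T:3"),
              c = "T:1", d = "T:3")
  res <- pair_shared_terms(pairs, ann, ont)
  expect_equal(res$records$shared_count, c(1L, 0L))
  expect_equal(res$records$shared_mf, c(1L, 0L))
  expect_equal(res$fraction_sharing, 0.5)

  # swapping plus/minus members leaves the fraction unchanged
  sw <- pairs
  names(sw)[2:3] <- c("minus_symbol", "plus_symbol")
  expect_equal(pair_shared_terms(sw, ann, ont)$fraction_sharing, 0.5)

  # unannotated gene: empty set, flagged
  ann$d <- NULL
  res <- pair_shared_terms(pairs, ann, ont)
  expect_true(res$records$unannotated[2])
  expect_equal(res$records$shared_count[2], 0L)
})

test_that("gene-set enrichment equals the one-sided Fisher test", {
  pop <- sprintf("g%02d", 1:10)
  study <- pop[1:5]
  gmt <- list(
    hit = list(description = "d", genes = c(pop[1:5], pop[1:2])),  # dups collapse
    miss = list(description = "d", genes = pop[6:10])
  )
  res <- enrich_gene_sets(study, pop, gmt)
  hit <- res[res$set_id == "hit", ]
  expect_equal(hit$k, 5L)
  expect_equal(hit$p_raw, 1 / choose(10, 5))
  expect_equal(res$p_raw[res$set_id == "miss"], 1.0)

  # cross-check against fisher.test on the 2x2 margins
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    tab <- matrix(c(r$k, r$n - r$k, r$K - r$k, r$N - r$n - r$K + r$k), 2)
    expect_equal(r$p_raw, stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }

  expect_warning(
    res2 <- enrich_gene_sets(study, pop, c(gmt, list(
      empty = list(description = "d", genes = character(0))))),
    "skipping")
  expect_equal(nrow(res2), 2)
})
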