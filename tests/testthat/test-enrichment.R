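# Exhaustive-enumeration oracle for the hypergeometric tail: fraction of
# all C(N, n) draws with at least k annotated genes.
enum_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

test_that("the hypergeometric tail equals exhaustive enumeration for small urns", {
  for (N in c(8, 10, 12)) {
    for (K in c(0, 3, N %/% 2, N)) {
      for (n in c(0, 2, 5)) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_tail(k, K, n, N), enum_tail(k, K, n, N),
                       tolerance = 1e-12,
                       info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
})

test_that("hypergeometric tail: closed-form spot value and degenerate cases", {
  exact <- 1 - (choose(40, 5) + 10 * choose(40, 4)) / choose(50, 5)
  expect_equal(hypergeom_tail(2, 10, 5, 50), exact, tolerance = 1e-12)
  expect_equal(round(hypergeom_tail(2, 10, 5, 50), 4), 0.2581)
  expect_equal(hypergeom_tail(0, 10, 5, 50), 1)
  expect_equal(hypergeom_tail(5, 5, 5, 5), 1)
  expect_error(hypergeom_tail(6, 10, 5, 50))
  expect_error(hypergeom_tail(2, 60, 5, 50))
})

test_that("BH adjustment matches a hand-written step-up oracle", {
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (r in m:1) {
      prev <- min(prev, m * p[o[r]] / r)
      adj[o[r]] <- prev
    }
    adj
  }
  set.seed(11)
  for (rep_ in 1:10) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_correct(p), step_up(p), tolerance = 1e-12)
  }
  expect_equal(bh_correct(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_correct(0.03), 0.03)
  # permutation invariance and monotonicity along the sorted order
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_correct(p)[perm], bh_correct(p[perm]))
  adj <- bh_correct(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("BH over the published pathway table reproduces the corrected column", {
  tab <- bhlh_pathway_fixture()
  expect_equal(nrow(tab), 16)
  adj <- bh_correct(tab$p_value)
  # printed raw P values carry 7-decimal rounding, which propagates into
  # the recomputed adjustment at up to ~3e-7 absolute
  expect_lt(max(abs(adj - tab$corrected_p_value)), 5e-7)
  # the step-up minimum: the Melanogenesis row inherits the Jak-STAT row's
  # adjusted value exactly
  expect_equal(adj[11], adj[12])
  expect_lt(abs(adj[11] - 0.2386888), 1e-7)
  expect_equal(sum(adj <= 0.05), 6)
  expect_equal(sum(tab$database == "KEGG"), 11)
  expect_equal(sum(tab$p_value <= 0.5), 16)
})

test_that("a planted enriched term ranks first", {
  g <- generate_annotations(
    planted = data.frame(term = "planted_1", K = 20, fold = 10),
    n_null = 20, sample_size = 20, background_size = 1000, seed = 4)
  ann <- annotations(split(g$annotations$gene, g$annotations$term),
                     background_size = g$background_size)
  res <- enrich(g$sample, ann)
  expect_equal(res$term[1], "planted_1")
  tr <- g$truth[g$truth$term == "planted_1", ]
  expect_equal(res$k[res$term == "planted_1"], tr$k)
  expect_equal(res$K[res$term == "planted_1"], tr$K)
  # oracle recomputation of the reported p
  expect_equal(res$raw_p[1],
               hypergeom_tail(tr$k, tr$K, length(g$sample), tr$N))
})

test_that("enrichment p-values are invariant to gene relabeling", {
  g <- generate_annotations(seed = 8, n_null = 10)
  terms <- split(g$annotations$gene, g$annotations$term)
  ann <- annotations(terms, g$background_size)
  res <- enrich(g$sample, ann)
  relabel <- stats::setNames(
    sprintf("x%05d", seq_len(g$background_size)),
    sprintf("g%05d", seq_len(g$background_size)))
  terms2 <- lapply(terms, function(v) unname(relabel[v]))
  res2 <- enrich(unname(relabel[g$sample]),
                 annotations(terms2, g$background_size))
  expect_equal(res2$raw_p, res$raw_p)
  expect_equal(res2$k, res$k)
})

test_that("sample genes outside the stated background warn and are excluded", {
  univ <- c("a", "b", "c", sprintf("g%02d", 1:97))
  ann <- annotations(list(t1 = c("a", "b", "c")), background = univ)
  expect_equal(ann$background_size, 100)
  expect_warning(res <- enrich(c("a", "zzz"), ann), "absent")
  expect_equal(res$n, 1)
  expect_equal(res$k, 1)
  # a sample with no background genes at all yields an empty result
  expect_warning(res0 <- enrich("zzz", ann), "absent")
  expect_equal(nrow(res0), 0)
  # without an explicit universe the sample is taken at face value
  ann2 <- annotations(list(t1 = c("a", "b", "c")), background_size = 100)
  res2 <- enrich(c("a", "g55"), ann2)
  expect_equal(res2$n, 2)
})

test_that("coherence is the group coverage percentage at one decimal", {
  expect_equal(coherence(2, 7), 28.6)
  expect_equal(coherence(7, 7), 100)
  expect_equal(coherence(0, 5), 0)
  expect_error(coherence(8, 7))
})

test_that("the published GO table carries 65 enriched annotations across groups", {
  tab <- bhlh_go_enrichment_fixture()
  fs <- frequency_summary(tab)
  expect_equal(sum(fs$term_counts$n_groups), 65)
  expect_equal(sum(fs$category_totals$n_rows), 65)
  # the groups with too few annotated members report no enrichment at all
  for (g in c("D", "F", "Orphan")) {
    rows <- tab[tab$group == g, ]
    expect_equal(nrow(rows[rows$term_id != "None", ]), 0)
  }
  # a term enriched in several supergroups counts once per group
  tra <- fs$term_counts[fs$term_counts$term == "GO:0030528", ]
  expect_equal(tra$n_groups, 4)  # A, B, C and E
  # empty input
  fs0 <- frequency_summary(list())
  expect_equal(nrow(fs0$term_counts), 0)
})

test_that("annotation sets validate their background and round-trip from TSV", {
  expect_error(annotations(list(t1 = letters), background_size = 10),
               "smaller than the union")
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tterm", "g1\tt1", "g2\tt1", "g3\tt2"), tmp)
  ann <- read_annotations(tmp, background_size = 50)
  expect_equal(sort(ann$terms$t1), c("g1", "g2"))
  expect_equal(ann$background_size, 50)
  # GMT shape
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("t1\tdesc\tg1\tg2", "t2\tdesc\tg3"), gmt)
  ann2 <- read_annotations(gmt, background_size = 50, format = "gmt")
  expect_equal(ann2$terms$t1, c("g1", "g2"))
})
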