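test_that("hypergeom_tail matches closed forms and handles degenerate cases", {
  expect_equal(hypergeom_tail(10, 4, 5, 3), 66 / 252)
  expect_equal(hypergeom_tail(100, 10, 50, 0), 1)       # tail from zero
  expect_equal(hypergeom_tail(8, 8, 5, 5), 1)           # N = K: X = n surely
  expect_equal(hypergeom_tail(8, 8, 5, 3), 1)
  expect_equal(hypergeom_tail(100, 10, 10, 10), 1 / choose(100, 10))
  expect_error(hypergeom_tail(10, 4, 11, 3), class = "plkscreen_domain_error")
  expect_error(hypergeom_tail(10, 11, 5, 3), class = "plkscreen_domain_error")
  expect_error(hypergeom_tail(10, 2, 5, 3), class = "plkscreen_domain_error")
  expect_error(hypergeom_tail(10, 4, 5, -1), class = "plkscreen_domain_error")
  expect_error(hypergeom_tail(10, 4, 5.5, 3), class = "plkscreen_domain_error")
})

test_that("hypergeom_tail agrees with stats::phyper over random parameters", {
  set.seed(300)
  for (rep in 1:300) {
    N <- sample(1:2000, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_tail(N, K, n, k),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("hypergeom_tail is monotone in k and in K", {
  N <- 60; n <- 20; K <- 15
  p_k <- vapply(0:min(n, K), function(k) hypergeom_tail(N, K, n, k),
                numeric(1))
  expect_true(all(diff(p_k) <= 1e-12))                  # non-increasing in k
  k <- 5
  p_K <- vapply(k:40, function(K) hypergeom_tail(N, K, n, k), numeric(1))
  expect_true(all(diff(p_K) >= -1e-12))                 # non-decreasing in K
})

test_that("cluster_proteins builds counts, members and the closed-form tail", {
  universe <- sprintf("U%03d", 1:100)
  special <- universe[1:10]
  ann <- tiny_annotations(universe, special)
  cl <- cluster_proteins(special, ann, namespaces = "biological_process",
                         min_members = 1)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$N, 100L)
  expect_equal(cl$K, 10L)
  expect_equal(cl$n, 10L)
  expect_equal(cl$k, 10L)
  expect_equal(cl$p_value, 1 / choose(100, 10))
  expect_equal(strsplit(cl$members, ";")[[1]], sort(special))

  # hit proteins without annotation in the chosen namespaces are excluded from n
  cl2 <- cluster_proteins(c(special, "UNANNOTATED"), ann,
                          namespaces = "biological_process", min_members = 1)
  expect_equal(cl2$n, 10L)

  expect_equal(nrow(cluster_proteins(character(), ann,
                                     namespaces = "biological_process")), 0L)
  expect_equal(nrow(cluster_proteins(special, ann,
                                     namespaces = "biological_process",
                                     min_members = 11)), 0L)
  expect_error(cluster_proteins(special, ann, namespaces = "phase"),
               class = "plkscreen_domain_error")
})

test_that("clusters are sorted by p, then descending k, then term", {
  universe <- sprintf("U%03d", 1:60)
  extra <- rbind(
    data.frame(protein_id = universe[1:6], namespace = "biological_process",
               term = "alpha", stringsAsFactors = FALSE),
    data.frame(protein_id = universe[1:6], namespace = "biological_process",
               term = "beta", stringsAsFactors = FALSE),
    data.frame(protein_id = universe[31:60], namespace = "biological_process",
               term = "common", stringsAsFactors = FALSE))
  ann <- tiny_annotations(universe, universe[1:6], extra = extra)
  cl <- cluster_proteins(universe[1:6], ann,
                         namespaces = "biological_process", min_members = 1)
  # "alpha" and "beta" tie exactly; lexicographic break
  ab <- cl$term[cl$term %in% c("alpha", "beta")]
  expect_equal(ab, c("alpha", "beta"))
  expect_true(all(diff(cl$p_value) >= -1e-12))
})

test_that("filter_clusters keeps p <= alpha inclusively, with optional BH", {
  cl <- data.frame(namespace = "biological_process",
                   term = c("a", "b", "c"),
                   N = 100L, K = 10L, n = 10L, k = c(5L, 4L, 1L),
                   p_value = c(0.05, 0.10, 0.2),
                   members = "x", stringsAsFactors = FALSE)
  kept <- filter_clusters(cl, alpha = 0.1)
  expect_equal(kept$term, c("a", "b"))                  # boundary inclusive
  expect_equal(filter_clusters(cl, alpha = 1)$term, cl$term)
  expect_error(filter_clusters(cl, alpha = 0), class = "plkscreen_config_error")

  cl$p_value <- c(0.01, 0.02, 0.9)
  bh <- filter_clusters(cl, alpha = 0.1, adjust = TRUE)
  expect_equal(bh$term, c("a", "b"))
  expect_equal(bh$p_adjusted, c(0.03, 0.03))            # hand-computed BH

  # filtering never adds members
  all_m <- unlist(strsplit(cl$members, ";"))
  kept_m <- unlist(strsplit(kept$members, ";"))
  expect_true(all(kept_m %in% all_m))
})

test_that("null-term p-values are stochastically no smaller than uniform", {
  set.seed(400)
  n_univ <- 300
  universe <- sprintf("U%03d", seq_len(n_univ))
  hits <- sample(universe, 100)
  n_terms <- 600
  p <- numeric(n_terms)
  # terms assigned uniformly at random, independent of the hit set
  member_mat <- matrix(runif(n_univ * n_terms) < 0.1, nrow = n_univ)
  n_ann <- length(hits)  # treat every protein as annotated (N = universe)
  for (t in seq_len(n_terms)) {
    members <- universe[member_mat[, t]]
    K <- length(members)
    k <- sum(hits %in% members)
    p[t] <- hypergeom_tail(n_univ, K, n_ann, k)
  }
  ks <- suppressWarnings(stats::ks.test(p, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})
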