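#' Upper-tail hypergeometric by-chance probability
#'
#' The screen's cluster enrichment statistic: the probability of observing at
#' least `k` annotated proteins in a cluster by chance. `N` is the total
#' number of annotated proteins in the reference set, `K` the number of those
#' annotated with the term of interest, `n` the number of annotated proteins
#' drawn into the cluster, and `k` the number of cluster members carrying the
#' term. The tail `P(X >= k)` is summed in log-space over
#' `x = k ... min(n, K)` of the hypergeometric pmf
#' `C(K,x) C(N-K,n-x) / C(N,n)`.
#'
#' @param N,K,n,k Non-negative integer counts with `k <= n <= N`,
#'   `K <= N`, `k <= K`.
#' @return Probability in `(0, 1]`.
#' @examples
#' hypergeom_tail(10, 4, 5, 3)  # 66/252
#' @export
hypergeom_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      plk_error("domain_error", "N, K, n, k must be non-negative integers")
  }
  if (k > n || n > N || K > N || k > K)
    plk_error("domain_error",
              sprintf("invalid counts: need k <= n <= N, K <= N, k <= K (got N=%d K=%d n=%d k=%d)",
                      N, K, n, k))
  if (k == 0) return(1)
  x <- seq.int(k, min(n, K))
  logp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  m <- max(logp)
  min(exp(m + log(sum(exp(logp - m)))), 1)
}

#' Construct an annotation set
#'
#' Flat (non-hierarchical) protein annotations over the namespaces
#' `biological_process`, `cellular_component`, `molecular_function`, `phase`
#' and `cancer`.
#'
#' @param assignments Data frame with columns `protein_id`, `namespace`,
#'   `term` (one row per assignment; duplicates are dropped).
#' @param universe_size Total number of annotated proteins `N` in the
#'   reference set; defaults to the number of distinct annotated proteins in
#'   `assignments` and may not be smaller than it.
#' @return An `annotation_set` object: list with `assignments`, `namespaces`
#'   (those present) and `universe_size`.
#' @export
annotation_set <- function(assignments, universe_size = NULL) {
  req <- c("protein_id", "namespace", "term")
  if (!is.data.frame(assignments) || !all(req %in% names(assignments)))
    plk_error("input_error",
              "assignments must be a data frame with columns protein_id, namespace, term")
  a <- unique(assignments[req])
  a[] <- lapply(a, as.character)
  if (nrow(a)) {
    if (any(is.na(a$protein_id) | !nzchar(a$protein_id)))
      plk_error("input_error", "empty protein identifier in annotations")
    if (any(is.na(a$term) | !nzchar(a$term)))
      plk_error("input_error", "empty annotation term")
    bad <- setdiff(unique(a$namespace), NAMESPACE_VOCABULARY)
    if (length(bad))
      plk_error("input_error",
                sprintf("unknown annotation namespace(s): %s (allowed: %s)",
                        paste(bad, collapse = ", "),
                        paste(NAMESPACE_VOCABULARY, collapse = ", ")))
  }
  a <- a[order(a$namespace, a$term, a$protein_id), , drop = FALSE]
  rownames(a) <- NULL
  n_annotated <- length(unique(a$protein_id))
  if (is.null(universe_size)) universe_size <- n_annotated
  if (!is.numeric(universe_size) || universe_size < n_annotated)
    plk_error("input_error",
              sprintf("universe_size (%s) smaller than the %d distinct annotated proteins",
                      universe_size, n_annotated))
  structure(list(assignments = a,
                 namespaces = sort(unique(a$namespace)),
                 universe_size = as.integer(universe_size)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", length(unique(x$assignments$protein_id)),
      " annotated proteins, ", length(unique(paste(x$assignments$namespace,
                                                   x$assignments$term))),
      " terms, universe N = ", x$universe_size,
      "\n  namespaces: ", paste(x$namespaces, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.empty_clusters <- function() {
  data.frame(namespace = character(), term = character(), N = integer(),
             K = integer(), n = integer(), k = integer(), p_value = numeric(),
             members = character(), stringsAsFactors = FALSE)
}

#' Group hit proteins into annotation-term clusters with enrichment P
#'
#' Forms one cluster per (namespace, term) pair that annotates at least
#' `min_members` proteins of the hit set, restricted to the chosen
#' namespaces, and scores each with the by-chance probability
#' [hypergeom_tail()]. `n` counts the hit proteins carrying at least one
#' annotation in the chosen namespaces (unannotated hits are excluded, as the
#' statistic is defined over annotated proteins); `K` counts the term's
#' carriers in the whole annotation universe; `N` is the universe size.
#'
#' @param hit_ids Character vector of hit protein identifiers.
#' @param annotations An [annotation_set()].
#' @param namespaces Namespaces over which to cluster; default the three GO
#'   namespaces.
#' @param min_members Minimum hit-set members for a term to form a cluster.
#' @return Data frame of clusters with columns `namespace`, `term`, `N`, `K`,
#'   `n`, `k`, `p_value`, `members` (semicolon-joined, sorted), ordered by
#'   ascending `p_value`, ties broken by descending `k` then term.
#' @export
cluster_proteins <- function(hit_ids, annotations, namespaces = GO_NAMESPACES,
                             min_members = 1L) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (!is.numeric(min_members) || min_members < 1)
    plk_error("config_error", "min_members must be >= 1")
  missing_ns <- setdiff(namespaces, annotations$namespaces)
  if (length(missing_ns))
    plk_error("domain_error",
              sprintf("namespace(s) absent from annotations: %s",
                      paste(missing_ns, collapse = ", ")))
  hit_ids <- unique(as.character(hit_ids))
  if (!length(hit_ids)) return(.empty_clusters())

  a <- annotations$assignments
  a <- a[a$namespace %in% namespaces, , drop = FALSE]
  hit_a <- a[a$protein_id %in% hit_ids, , drop = FALSE]
  n <- length(unique(hit_a$protein_id))
  if (!n) return(.empty_clusters())

  key_all <- paste(a$namespace, a$term, sep = "\r")
  key_hit <- paste(hit_a$namespace, hit_a$term, sep = "\r")
  members_by_term <- split(hit_a$protein_id, key_hit)
  members_by_term <- members_by_term[lengths(members_by_term) >= min_members]
  if (!length(members_by_term)) return(.empty_clusters())
  K_by_term <- vapply(split(a$protein_id, key_all),
                      function(p) length(unique(p)), integer(1))

  N <- annotations$universe_size
  keys <- names(members_by_term)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    namespace = vapply(parts, `[`, character(1), 1L),
    term = vapply(parts, `[`, character(1), 2L),
    N = N,
    K = unname(K_by_term[keys]),
    n = n,
    k = unname(lengths(members_by_term)),
    p_value = NA_real_,
    members = vapply(members_by_term,
                     function(m) paste(sort(m), collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$p_value <- mapply(hypergeom_tail, N = out$N, K = out$K, n = out$n,
                        k = out$k)
  out <- out[order(out$p_value, -out$k, out$term, out$namespace), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard clusters above the by-chance probability threshold
#'
#' Retains clusters with `p_value <= alpha` (the screen discards enrichments
#' with p > 0.1), preserving input order. Optionally applies
#' Benjamini-Hochberg adjustment before thresholding; the screen's flat rule
#' uses raw p-values, so adjustment is off by default.
#'
#' @param clusters Cluster data frame from [cluster_proteins()].
#' @param alpha Threshold in `(0, 1]`, applied inclusively; default 0.1.
#' @param adjust If `TRUE`, threshold Benjamini-Hochberg adjusted p-values
#'   (added as column `p_adjusted`).
#' @return Filtered cluster data frame.
#' @export
filter_clusters <- function(clusters, alpha = 0.1, adjust = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    plk_error("config_error", "alpha must be in (0, 1]")
  if (!nrow(clusters)) return(clusters)
  p <- clusters$p_value
  if (adjust) {
    clusters$p_adjusted <- stats::p.adjust(p, method = "BH")
    p <- clusters$p_adjusted
  }
  out <- clusters[p <= alpha + .SIM_EPS, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# protein ids covered by at least one cluster
.cluster_member_union <- function(clusters) {
  if (!nrow(clusters)) return(character())
  unique(unlist(strsplit(clusters$members, ";", fixed = TRUE)))
}
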