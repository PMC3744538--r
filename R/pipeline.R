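#' Configuration of the substrate screening cascade
#'
#' Bundles the motifs and thresholds of the five-stage filter cascade:
#' (i) presence of the kinase consensus phosphorylation motif, (ii) at least
#' `min_similarity` identity with it (screen default 0.80, inclusive),
#' (iii) membership in an annotation cluster whose by-chance probability
#' passes `enrichment_alpha` (default 0.1), (iv) presence of the PBD
#' recognition motif (matched exactly — an identity threshold on a 3-mer with
#' one constrained position is meaningless), and (v) annotation in every
#' required namespace (default cell-cycle phase and cancer).
#'
#' @param kinase_motif Kinase consensus motif notation.
#' @param pbd_motif PBD recognition motif notation.
#' @param min_similarity Stage-ii identity threshold in `[0, 1]`.
#' @param scan_mode `"identity"` or `"substitution"` (BLOSUM62-style).
#' @param enrichment_alpha Stage-iii by-chance probability threshold in
#'   `(0, 1]`.
#' @param enrichment_namespaces Namespaces used for stage-iii clustering.
#' @param required_namespaces Namespaces a candidate must carry to pass
#'   stage v.
#' @param pbd_strict If `TRUE`, the PBD motif's `[P/X]` position is
#'   restricted to proline (see [apply_strict()]); by default any residue is
#'   accepted there, since proline is preferred, not required.
#' @param min_cluster_members Minimum hit-set members for a term to form a
#'   cluster.
#' @param adjust_p If `TRUE`, Benjamini-Hochberg adjust cluster p-values
#'   before thresholding (off by default, matching the flat p > 0.1 discard).
#' @param spacing Optional numeric `c(min_gap, max_gap)`: if set, stage iv
#'   additionally requires some PBD hit whose phosphoacceptor lies between
#'   `min_gap` and `max_gap` residues from a qualifying kinase-motif
#'   phosphoacceptor. Off (`NULL`) by default — no spacing constraint is
#'   imposed between the two motifs.
#' @param seed Optional integer seed recorded in run manifests.
#' @return A `pipeline_config` object (validated list).
#' @export
pipeline_config <- function(kinase_motif = "[E/D]X[pS/pT][I/L/V/M]X[E]",
                            pbd_motif = "S-[pS/pT]-[P/X]",
                            min_similarity = 0.80,
                            scan_mode = "identity",
                            enrichment_alpha = 0.1,
                            enrichment_namespaces = GO_NAMESPACES,
                            required_namespaces = c("phase", "cancer"),
                            pbd_strict = FALSE,
                            min_cluster_members = 3L,
                            adjust_p = FALSE,
                            spacing = NULL,
                            seed = NULL) {
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.character(kinase_motif) && length(kinase_motif) == 1L &&
        nzchar(kinase_motif), "kinase_motif must be a non-empty string")
  chk(is.character(pbd_motif) && length(pbd_motif) == 1L && nzchar(pbd_motif),
      "pbd_motif must be a non-empty string")
  chk(is.numeric(min_similarity) && length(min_similarity) == 1L &&
        !is.na(min_similarity) && min_similarity >= 0 && min_similarity <= 1,
      "min_similarity must be in [0, 1]")
  chk(is.character(scan_mode) && length(scan_mode) == 1L &&
        scan_mode %in% c("identity", "substitution"),
      "scan_mode must be 'identity' or 'substitution'")
  chk(is.numeric(enrichment_alpha) && length(enrichment_alpha) == 1L &&
        !is.na(enrichment_alpha) && enrichment_alpha > 0 &&
        enrichment_alpha <= 1, "enrichment_alpha must be in (0, 1]")
  chk(is.character(enrichment_namespaces) && length(enrichment_namespaces) >= 1 &&
        all(enrichment_namespaces %in% NAMESPACE_VOCABULARY),
      sprintf("enrichment_namespaces must be drawn from {%s}",
              paste(NAMESPACE_VOCABULARY, collapse = ", ")))
  chk(is.character(required_namespaces) &&
        all(required_namespaces %in% NAMESPACE_VOCABULARY),
      sprintf("required_namespaces must be drawn from {%s}",
              paste(NAMESPACE_VOCABULARY, collapse = ", ")))
  chk(is.logical(pbd_strict) && length(pbd_strict) == 1L && !is.na(pbd_strict),
      "pbd_strict must be TRUE or FALSE")
  chk(is.numeric(min_cluster_members) && length(min_cluster_members) == 1L &&
        !is.na(min_cluster_members) && min_cluster_members >= 1,
      "min_cluster_members must be >= 1")
  chk(is.logical(adjust_p) && length(adjust_p) == 1L && !is.na(adjust_p),
      "adjust_p must be TRUE or FALSE")
  chk(is.null(spacing) ||
        (is.numeric(spacing) && length(spacing) == 2L && !anyNA(spacing) &&
           spacing[1] >= 0 && spacing[1] <= spacing[2]),
      "spacing must be NULL or c(min_gap, max_gap) with 0 <= min_gap <= max_gap")
  chk(is.null(seed) || (is.numeric(seed) && length(seed) == 1L && !is.na(seed)),
      "seed must be NULL or a single number")
  if (length(problems))
    plk_error("config_error",
              paste0("invalid configuration:\n  - ",
                     paste(problems, collapse = "\n  - ")))
  structure(list(kinase_motif = kinase_motif, pbd_motif = pbd_motif,
                 min_similarity = min_similarity, scan_mode = scan_mode,
                 enrichment_alpha = enrichment_alpha,
                 enrichment_namespaces = enrichment_namespaces,
                 required_namespaces = required_namespaces,
                 pbd_strict = pbd_strict,
                 min_cluster_members = as.integer(min_cluster_members),
                 adjust_p = adjust_p, spacing = spacing, seed = seed),
            class = "pipeline_config")
}

#' Run the staged substrate screen
#'
#' Executes the full filter cascade over a proteome and annotation set:
#' \describe{
#'   \item{stage i}{proteins with at least one kinase-motif window whose
#'     phosphoacceptor matches (similarity threshold 0);}
#'   \item{stage ii}{subset whose best window similarity is at least
#'     `min_similarity`;}
#'   \item{stage iii}{subset belonging to at least one annotation cluster
#'     retained at `enrichment_alpha` (cluster hit set = stage-ii survivors,
#'     scored against the full annotated universe);}
#'   \item{stage iv}{subset with at least one exact PBD recognition motif
#'     hit;}
#'   \item{stage v}{subset carrying at least one term in each required
#'     namespace.}
#' }
#' Final candidates are ranked by [rank_candidates()]. The run is
#' deterministic for fixed inputs and configuration.
#'
#' @param proteome An [Biostrings::AAStringSet] or named character vector.
#' @param annotations An [annotation_set()].
#' @param config A [pipeline_config()].
#' @return A `plk_screen` object: list with `candidates` (one row per
#'   stage-i protein, with stage flags, phases, cancer flag and final rank),
#'   `stage_counts`, `clusters` (all stage-iii clusters), `retained_clusters`,
#'   `kinase_hits` (at `min_similarity`), `pbd_hits`, `phase_groups` and the
#'   `config`.
#' @export
run_screen <- function(proteome, annotations, config = pipeline_config()) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)

  # configuration errors are reported before any scanning
  kin <- tryCatch(compile_motif(config$kinase_motif, name = "kinase"),
                  plkscreen_error = function(e)
                    plk_error("config_error", conditionMessage(e)))
  pbd <- tryCatch(compile_motif(config$pbd_motif, name = "pbd"),
                  plkscreen_error = function(e)
                    plk_error("config_error", conditionMessage(e)))
  if (config$pbd_strict) pbd <- apply_strict(pbd)
  missing_ns <- setdiff(c(config$enrichment_namespaces,
                          config$required_namespaces),
                        annotations$namespaces)
  if (length(missing_ns))
    plk_error("config_error",
              sprintf("namespace(s) required by the configuration are absent from the annotations: %s",
                      paste(missing_ns, collapse = ", ")))
  seqs <- .as_protein_vector(proteome)

  # stages i and ii come from a single scan at threshold 0
  kin_all <- scan_proteome(seqs, kin, min_similarity = 0,
                           mode = config$scan_mode)
  summ <- hit_summary(kin_all)
  stage1 <- summ$protein_id
  best_sim <- stats::setNames(summ$best_similarity, summ$protein_id)
  stage2 <- stage1[best_sim[stage1] >= config$min_similarity - .SIM_EPS]

  clusters <- cluster_proteins(stage2, annotations,
                               namespaces = config$enrichment_namespaces,
                               min_members = config$min_cluster_members)
  retained <- filter_clusters(clusters, alpha = config$enrichment_alpha,
                              adjust = config$adjust_p)
  stage3 <- intersect(stage2, .cluster_member_union(retained))

  pbd_hits <- scan_proteome(seqs, pbd, min_similarity = 1, mode = "identity")
  kin_pass <- kin_all[kin_all$similarity >= config$min_similarity - .SIM_EPS, ,
                      drop = FALSE]
  pbd_pos <- .pbd_positive(stage3, kin_pass, pbd_hits, config$spacing)
  stage4 <- intersect(stage3, pbd_pos)

  a <- annotations$assignments
  has_all_req <- function(ids) {
    keep <- rep(TRUE, length(ids))
    for (ns in config$required_namespaces) {
      carriers <- unique(a$protein_id[a$namespace == ns])
      keep <- keep & ids %in% carriers
    }
    ids[keep]
  }
  stage5 <- has_all_req(stage4)

  phase_list <- .phases_for(stage1, annotations)
  cancer_ids <- unique(a$protein_id[a$namespace == "cancer"])
  min_p <- .min_cluster_p(stage1, retained)
  pbd_n <- stats::setNames(rep(0L, length(stage1)), stage1)
  if (nrow(pbd_hits)) {
    tab <- table(pbd_hits$protein_id)
    pbd_n[names(tab)[names(tab) %in% stage1]] <-
      as.integer(tab[names(tab)[names(tab) %in% stage1]])
  }
  kin_n <- stats::setNames(rep(0L, length(stage1)), stage1)
  if (nrow(kin_pass)) {
    tab <- table(kin_pass$protein_id)
    kin_n[names(tab)[names(tab) %in% stage1]] <-
      as.integer(tab[names(tab)[names(tab) %in% stage1]])
  }

  candidates <- data.frame(
    protein_id = stage1,
    n_kinase_hits = unname(kin_n[stage1]),
    best_similarity = unname(best_sim[stage1]),
    n_pbd_hits = unname(pbd_n[stage1]),
    min_cluster_p = unname(min_p[stage1]),
    phases = vapply(phase_list[stage1], paste, character(1), collapse = ","),
    cancer_flag = stage1 %in% cancer_ids,
    has_kinase_motif = rep(TRUE, length(stage1)),
    passed_similarity = stage1 %in% stage2,
    passed_enrichment = stage1 %in% stage3,
    has_pbd_motif = stage1 %in% stage4,
    passed_annotation = stage1 %in% stage5,
    rank = rep(NA_integer_, length(stage1)),
    stringsAsFactors = FALSE
  )
  finals <- candidates[candidates$passed_annotation, , drop = FALSE]
  if (nrow(finals)) {
    ranked <- rank_candidates(finals)
    candidates$rank[match(ranked$protein_id, candidates$protein_id)] <-
      ranked$rank
    phaseless <- ranked$protein_id[!nzchar(ranked$phases)]
    if (length(phaseless))
      warning(sprintf("phase-less final candidate(s): %s",
                      paste(phaseless, collapse = ", ")), call. = FALSE)
  }
  candidates <- candidates[order(!candidates$passed_annotation,
                                 candidates$rank,
                                 -candidates$best_similarity,
                                 candidates$protein_id), , drop = FALSE]
  rownames(candidates) <- NULL

  stage_counts <- data.frame(
    stage = c("i_kinase_motif", "ii_similarity", "iii_enrichment",
              "iv_pbd_motif", "v_phase_cancer"),
    description = c("kinase consensus motif present (phosphoacceptor match)",
                    sprintf("similarity >= %g", config$min_similarity),
                    sprintf("member of enriched cluster (p <= %g)",
                            config$enrichment_alpha),
                    "PBD recognition motif present (exact)",
                    sprintf("annotated in: %s",
                            paste(config$required_namespaces, collapse = " & "))),
    n_proteins = c(length(stage1), length(stage2), length(stage3),
                   length(stage4), length(stage5)),
    stringsAsFactors = FALSE
  )

  final_ranked <- candidates[!is.na(candidates$rank), , drop = FALSE]
  structure(list(candidates = candidates,
                 stage_counts = stage_counts,
                 clusters = clusters,
                 retained_clusters = retained,
                 kinase_hits = kin_pass,
                 pbd_hits = pbd_hits,
                 phase_groups = build_phase_groups(final_ranked),
                 config = config),
            class = "plk_screen")
}

# proteins among `ids` with >= 1 exact PBD hit, optionally within the
# configured phosphoacceptor spacing of a qualifying kinase hit
.pbd_positive <- function(ids, kin_pass, pbd_hits, spacing) {
  pos <- intersect(ids, unique(pbd_hits$protein_id))
  if (is.null(spacing) || !length(pos)) return(pos)
  keep <- vapply(pos, function(id) {
    kp <- kin_pass$phospho_position[kin_pass$protein_id == id]
    pp <- pbd_hits$phospho_position[pbd_hits$protein_id == id]
    if (!length(kp) || !length(pp)) return(FALSE)
    gaps <- abs(outer(pp, kp, "-"))
    any(gaps >= spacing[1] & gaps <= spacing[2])
  }, logical(1))
  pos[keep]
}

.min_cluster_p <- function(ids, retained) {
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (!nrow(retained)) return(out)
  for (j in seq_len(nrow(retained))) {
    mem <- strsplit(retained$members[j], ";", fixed = TRUE)[[1]]
    mem <- intersect(mem, ids)
    out[mem] <- pmin(out[mem], retained$p_value[j], na.rm = TRUE)
  }
  out
}

#' Normalize a protein's cell-cycle phase annotations
#'
#' Collects the phase-namespace terms attached to a protein and normalizes
#' them to the closed vocabulary `{G1, S, G2, M, cytokinesis, checkpoint}`
#' (case-insensitive; compound labels `"G2/M"` and `"G1/S"` are split into
#' their components). A protein may carry multiple phases.
#'
#' @param protein_id Single protein identifier.
#' @param annotations An [annotation_set()].
#' @return Character vector of phases (possibly empty).
#' @export
assign_phases <- function(protein_id, annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  .phases_for(protein_id, annotations)[[1]]
}

.phases_for <- function(ids, annotations) {
  a <- annotations$assignments
  a <- a[a$namespace == "phase", , drop = FALSE]
  lut <- stats::setNames(PHASE_VOCABULARY, toupper(PHASE_VOCABULARY))
  norm1 <- function(term) {
    parts <- strsplit(toupper(term), "/", fixed = TRUE)[[1]]
    bad <- setdiff(parts, names(lut))
    if (length(bad))
      plk_error("input_error",
                sprintf("phase term '%s' outside the vocabulary {%s}", term,
                        paste(PHASE_VOCABULARY, collapse = ", ")))
    unname(lut[parts])
  }
  by_id <- split(a$term, a$protein_id)
  out <- lapply(stats::setNames(ids, ids), function(id) {
    terms <- by_id[[id]]
    if (is.null(terms)) return(character())
    phases <- unique(unlist(lapply(terms, norm1)))
    phases[order(match(phases, PHASE_VOCABULARY))]
  })
  out
}

#' Rank final candidates
#'
#' Stable sort of stage-v survivors by descending best similarity, then
#' ascending minimum retained-cluster p-value, then descending number of PBD
#' hits, then ascending protein identifier; ranks are assigned 1..m.
#'
#' @param candidates Candidate data frame with columns `protein_id`,
#'   `best_similarity`, `min_cluster_p`, `n_pbd_hits`.
#' @return The data frame sorted by rank, with a `rank` column.
#' @export
rank_candidates <- function(candidates) {
  p <- candidates$min_cluster_p
  p[is.na(p)] <- Inf
  ord <- order(-candidates$best_similarity, p, -candidates$n_pbd_hits,
               candidates$protein_id)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Group final candidates by cell-cycle phase
#'
#' A protein annotated with several phases appears in several groups; the
#' checkpoint group is kept separate from the true phases.
#'
#' @param candidates Ranked candidate data frame with columns `protein_id`
#'   and `phases` (comma-joined).
#' @return Named list mapping each observed phase label to its sorted protein
#'   identifier set.
#' @export
build_phase_groups <- function(candidates) {
  if (!nrow(candidates)) return(stats::setNames(list(), character()))
  phase_lists <- strsplit(candidates$phases, ",", fixed = TRUE)
  pairs <- data.frame(
    phase = unlist(phase_lists),
    protein_id = rep(candidates$protein_id, lengths(phase_lists)),
    stringsAsFactors = FALSE
  )
  pairs <- pairs[nzchar(pairs$phase), , drop = FALSE]
  if (!nrow(pairs)) return(stats::setNames(list(), character()))
  groups <- lapply(split(pairs$protein_id, pairs$phase),
                   function(x) sort(unique(x)))
  groups[order(match(names(groups), PHASE_VOCABULARY))]
}

#' @export
print.plk_screen <- function(x, ...) {
  cat("<plk_screen> staged substrate screen\n")
  sc <- x$stage_counts
  for (j in seq_len(nrow(sc)))
    cat(sprintf("  %-16s %5d  %s\n", sc$stage[j], sc$n_proteins[j],
                sc$description[j]))
  nf <- sum(!is.na(x$candidates$rank))
  cat("  final ranked candidates:", nf, "\n")
  cat("  retained clusters:", nrow(x$retained_clusters), "of",
      nrow(x$clusters), "\n")
  invisible(x)
}
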