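#' Specification of a synthetic proteome and annotation world
#'
#' Describes a simulated screening world: a background of i.i.d. random
#' protein sequences, a planted subset of "true substrate" proteins carrying
#' one exact instance of each default motif at recorded non-overlapping
#' positions, and annotation sets in which the planted proteins are enriched
#' for a cell-cycle term, carry a cell-cycle phase and a cancer flag.
#' Background proteins may receive a single-mismatch ("near-miss") kinase
#' motif window, which separates the 0.8 and 1.0 similarity thresholds.
#'
#' Planted proteins always receive the enriched term, one phase drawn from
#' `phase_mixture` and the cancer flag under the defaults
#' (`q_pos = cancer_rate_pos = 1`), so that every planted substrate survives
#' all five screen stages by construction; lower `q_pos`/`cancer_rate_pos`
#' to study incomplete annotation.
#'
#' @param n_proteins Number of proteins.
#' @param n_planted Number of planted true substrates (`<= n_proteins`).
#' @param length_mean,length_sd Protein length distribution (normal, rounded,
#'   clamped to at least max motif length + 10 residues).
#' @param background_frequencies Named 20-vector of residue probabilities
#'   summing to 1; default uniform 0.05.
#' @param near_miss_rate Probability a background protein receives one
#'   single-mismatch kinase-motif window.
#' @param phase_mixture Probability vector over
#'   `{G1, S, G2, M, cytokinesis, checkpoint}` for the planted proteins'
#'   phase; default weighted toward G2/M.
#' @param q_pos,q_neg Probability that a planted / background protein
#'   receives the enriched term `"cell cycle"`.
#' @param cancer_rate_pos,cancer_rate_neg Same for the cancer flag.
#' @param bg_phase_rate Probability a background protein carries a uniformly
#'   drawn phase term (the planted mixture concerns planted proteins only).
#' @param n_noise_terms Number of random annotation terms spread uniformly
#'   over all proteins.
#' @param noise_term_density Per-protein inclusion probability of each noise
#'   term.
#' @param seed Random seed; the world is reproducible for a fixed seed.
#' @return A `synthetic_spec` object (validated list).
#' @export
synthetic_spec <- function(n_proteins = 500L,
                           n_planted = 50L,
                           length_mean = 250,
                           length_sd = 50,
                           background_frequencies = NULL,
                           near_miss_rate = 0.05,
                           phase_mixture = c(G1 = 0.10, S = 0.15, G2 = 0.25,
                                             M = 0.25, cytokinesis = 0.15,
                                             checkpoint = 0.10),
                           q_pos = 1.0, q_neg = 0.05,
                           cancer_rate_pos = 1.0, cancer_rate_neg = 0.05,
                           bg_phase_rate = 0.10,
                           n_noise_terms = 20L,
                           noise_term_density = 0.05,
                           seed = 7L) {
  if (is.null(background_frequencies))
    background_frequencies <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(is.numeric(n_proteins) && n_proteins >= 1, "n_proteins must be >= 1")
  chk(is.numeric(n_planted) && n_planted >= 0 && n_planted <= n_proteins,
      "n_planted must be in [0, n_proteins]")
  chk(is.numeric(length_mean) && length_mean > 0, "length_mean must be > 0")
  chk(is.numeric(length_sd) && length_sd >= 0, "length_sd must be >= 0")
  chk(is.numeric(background_frequencies) &&
        length(background_frequencies) == 20 &&
        setequal(names(background_frequencies), AA_STANDARD) &&
        all(background_frequencies >= 0) &&
        abs(sum(background_frequencies) - 1) <= 1e-9,
      "background_frequencies must be a named 20-vector over the standard alphabet summing to 1")
  probs <- c(near_miss = near_miss_rate, q_pos = q_pos, q_neg = q_neg,
             cancer_pos = cancer_rate_pos, cancer_neg = cancer_rate_neg,
             bg_phase = bg_phase_rate, noise_density = noise_term_density)
  chk(is.numeric(probs) && all(probs >= 0 & probs <= 1),
      "all rates must be probabilities in [0, 1]")
  chk(is.numeric(phase_mixture) &&
        setequal(names(phase_mixture), PHASE_VOCABULARY) &&
        all(phase_mixture >= 0) && abs(sum(phase_mixture) - 1) <= 1e-9,
      "phase_mixture must be a probability vector over the phase vocabulary")
  chk(is.numeric(n_noise_terms) && n_noise_terms >= 0,
      "n_noise_terms must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1L && !is.na(seed),
      "seed must be a single number")
  if (length(problems))
    plk_error("config_error",
              paste0("invalid synthetic spec:\n  - ",
                     paste(problems, collapse = "\n  - ")))
  structure(list(n_proteins = as.integer(n_proteins),
                 n_planted = as.integer(n_planted),
                 length_mean = length_mean, length_sd = length_sd,
                 background_frequencies = background_frequencies[AA_STANDARD],
                 near_miss_rate = near_miss_rate,
                 phase_mixture = phase_mixture[PHASE_VOCABULARY],
                 q_pos = q_pos, q_neg = q_neg,
                 cancer_rate_pos = cancer_rate_pos,
                 cancer_rate_neg = cancer_rate_neg,
                 bg_phase_rate = bg_phase_rate,
                 n_noise_terms = as.integer(n_noise_terms),
                 noise_term_density = noise_term_density,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# draw one exact instance of a motif; wildcard residues come from the
# background distribution, constrained ones from it restricted to the set
.draw_instance <- function(motif, freqs) {
  vapply(seq_len(motif$length), function(i) {
    set <- motif$positions[[i]]
    sample(set, 1L, prob = freqs[set])
  }, character(1))
}

#' Generate a synthetic proteome, annotation set and ground truth
#'
#' Reproducible for a fixed seed (byte-identical outputs when written with
#' the package's writers). Planted proteins contain exactly one inserted
#' exact instance of the default kinase and PBD motifs at recorded,
#' non-overlapping positions; background proteins are i.i.d. draws from the
#' background frequencies, with a near-miss kinase window (one constrained
#' non-phosphoacceptor position mutated off-consensus) inserted at
#' `near_miss_rate`. Annotations are assigned per the spec's rates. If an
#' insertion is infeasible the protein's length is redrawn longer — planted
#' windows are never truncated.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `proteome` ([Biostrings::AAStringSet]), `annotations`
#'   ([annotation_set()]), `truth` (one row per planted protein: insertion
#'   coordinates, inserted windows, phases, terms) and `near_miss` (one row
#'   per inserted near-miss window).
#' @export
generate_world <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  kin <- compile_motif("[E/D]X[pS/pT][I/L/V/M]X[E]", name = "kinase")
  pbd <- compile_motif("S-[pS/pT]-[P/X]", name = "pbd")
  min_len <- max(kin$length, pbd$length) + 10L
  freqs <- spec$background_frequencies

  with_seed(spec$seed, {
    n <- spec$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    planted <- sort(sample(ids, spec$n_planted))
    lens <- pmax(as.integer(round(rnorm(n, spec$length_mean, spec$length_sd))),
                 min_len)
    seqs <- vapply(lens, function(L)
      paste(sample(AA_STANDARD, L, replace = TRUE, prob = freqs),
            collapse = ""), character(1))
    names(seqs) <- ids

    truth <- NULL
    if (length(planted)) {
      rows <- lapply(planted, function(id) {
        i <- match(id, ids)
        L <- lens[i]
        # redraw longer if both motifs cannot be placed without overlap
        while (L < kin$length + pbd$length) {
          L <- as.integer(round(spec$length_mean + abs(rnorm(1, 0, spec$length_sd))))
          L <- max(L, min_len)
          lens[i] <<- L
          seqs[i] <<- paste(sample(AA_STANDARD, L, TRUE, freqs), collapse = "")
        }
        kin_start <- sample.int(L - kin$length + 1L, 1L)
        allowed <- setdiff(seq_len(L - pbd$length + 1L),
                           (kin_start - pbd$length + 1L):(kin_start + kin$length - 1L))
        pbd_start <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
        kin_win <- paste(.draw_instance(kin, freqs), collapse = "")
        pbd_win <- paste(.draw_instance(pbd, freqs), collapse = "")
        s <- seqs[[i]]
        substr(s, kin_start, kin_start + kin$length - 1L) <- kin_win
        substr(s, pbd_start, pbd_start + pbd$length - 1L) <- pbd_win
        seqs[i] <<- s
        data.frame(protein_id = id, kinase_start = kin_start,
                   kinase_window = kin_win, pbd_start = pbd_start,
                   pbd_window = pbd_win, stringsAsFactors = FALSE)
      })
      truth <- do.call(rbind, rows)
    }

    # near-miss windows on a fraction of the background
    background <- setdiff(ids, planted)
    nm_rows <- list()
    for (id in background) {
      if (runif(1) > spec$near_miss_rate) next
      i <- match(id, ids)
      L <- lens[i]
      if (L < kin$length) next
      win <- .draw_instance(kin, freqs)
      constrained <- setdiff(which(!kin$wildcard), kin$phospho_index)
      pos <- if (length(constrained) == 1L) constrained else sample(constrained, 1L)
      off <- setdiff(AA_STANDARD, kin$positions[[pos]])
      win[pos] <- sample(off, 1L, prob = freqs[off] / sum(freqs[off]))
      start <- sample.int(L - kin$length + 1L, 1L)
      s <- seqs[[i]]
      substr(s, start, start + kin$length - 1L) <- paste(win, collapse = "")
      seqs[i] <- s
      nm_rows[[length(nm_rows) + 1L]] <-
        data.frame(protein_id = id, start = start,
                   window = paste(win, collapse = ""),
                   mutated_position = pos, stringsAsFactors = FALSE)
    }
    near_miss <- if (length(nm_rows)) do.call(rbind, nm_rows) else
      data.frame(protein_id = character(), start = integer(),
                 window = character(), mutated_position = integer(),
                 stringsAsFactors = FALSE)

    # annotations
    rows <- list()
    add <- function(pid, ns, term)
      rows[[length(rows) + 1L]] <<-
        data.frame(protein_id = pid, namespace = ns, term = term,
                   stringsAsFactors = FALSE)
    is_planted <- ids %in% planted
    cc <- runif(n) <= ifelse(is_planted, spec$q_pos, spec$q_neg)
    if (any(cc)) add(ids[cc], "biological_process", "cell cycle")
    ca <- runif(n) <= ifelse(is_planted, spec$cancer_rate_pos,
                             spec$cancer_rate_neg)
    if (any(ca)) add(ids[ca], "cancer", "cancer census")
    if (length(planted)) {
      phases <- sample(names(spec$phase_mixture), length(planted),
                       replace = TRUE, prob = spec$phase_mixture)
      add(planted, "phase", phases)
      truth$phase <- phases
      truth$has_cell_cycle_term <- cc[match(planted, ids)]
      truth$has_cancer_term <- ca[match(planted, ids)]
    }
    bgph <- background[runif(length(background)) <= spec$bg_phase_rate]
    if (length(bgph))
      add(bgph, "phase", sample(PHASE_VOCABULARY, length(bgph), replace = TRUE))
    if (spec$n_noise_terms > 0) {
      for (t in seq_len(spec$n_noise_terms)) {
        # cycle namespaces so that >= 3 noise terms cover all three GO
        # namespaces deterministically
        ns <- GO_NAMESPACES[((t - 1L) %% 3L) + 1L]
        mem <- ids[runif(n) <= spec$noise_term_density]
        if (length(mem)) add(mem, ns, sprintf("noise_term_%02d", t))
      }
    }
    assignments <- do.call(rbind, rows)
    annotations <- annotation_set(assignments)

    list(proteome = Biostrings::AAStringSet(seqs),
         annotations = annotations,
         truth = truth,
         near_miss = near_miss,
         spec = spec)
  })
}

#' Analytic expected motif-window rate under the background model
#'
#' For an i.i.d. background sequence model, returns the expected number of
#' qualifying windows per protein of length `length_mean`:
#' `(L - l + 1) * P(window qualifies)`, where a window qualifies iff its
#' phosphoacceptor position matches (forced) and at most
#' `l - ceiling(min_similarity * l)` constrained non-phosphoacceptor
#' positions mismatch. `P` is computed exactly by summing, over all subsets
#' of constrained positions allowed to mismatch, the product of per-position
#' match/mismatch probabilities.
#'
#' @param spec A [synthetic_spec()] (supplies the background frequencies and
#'   the length).
#' @param motif A `motif_pattern`.
#' @param min_similarity Similarity threshold in `[0, 1]`.
#' @return Expected windows per protein, with attribute `per_window`, the
#'   per-window qualification probability.
#' @examples
#' sp <- synthetic_spec()
#' kin <- compile_motif("[E/D]X[pS/pT][I/L/V/M]X[E]")
#' attr(expected_hit_rate(sp, kin, 1.0), "per_window")   # 1e-4
#' attr(expected_hit_rate(sp, kin, 0.8), "per_window")   # 1e-4 * 33
#' @export
expected_hit_rate <- function(spec, motif, min_similarity = 0.8) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(motif, "motif_pattern"))
  freqs <- spec$background_frequencies
  l <- motif$length
  p_pos <- vapply(seq_len(l), function(i)
    if (motif$wildcard[i]) 1 else sum(freqs[motif$positions[[i]]]), numeric(1))
  p_phos <- p_pos[motif$phospho_index]
  constrained <- setdiff(which(!motif$wildcard), motif$phospho_index)
  max_mm <- l - as.integer(ceiling(min_similarity * l - .SIM_EPS))

  p_match <- prod(p_pos[constrained])
  total <- 0
  for (m in 0:min(max_mm, length(constrained))) {
    if (m == 0) { total <- total + p_match; next }
    subsets <- utils::combn(constrained, m, simplify = FALSE)
    for (S in subsets) {
      contrib <- prod(vapply(constrained, function(j)
        if (j %in% S) 1 - p_pos[j] else p_pos[j], numeric(1)))
      total <- total + contrib
    }
  }
  per_window <- p_phos * total
  L <- spec$length_mean
  out <- max(L - l + 1, 0) * per_window
  attr(out, "per_window") <- per_window
  out
}
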