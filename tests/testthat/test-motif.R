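test_that("compile_motif parses the kinase and PBD consensus notations", {
  kin <- kinase_motif()
  expect_equal(kin$length, 6L)
  expect_equal(kin$phospho_index, 3L)
  expect_setequal(kin$positions[[1]], c("E", "D"))
  expect_true(kin$wildcard[2])
  expect_equal(length(kin$positions[[2]]), 20L)
  expect_setequal(kin$positions[[3]], c("S", "T"))
  expect_setequal(kin$positions[[4]], c("I", "L", "V", "M"))
  expect_true(kin$wildcard[5])
  expect_equal(kin$positions[[6]], "E")

  pbd <- pbd_motif()
  expect_equal(pbd$length, 3L)
  expect_equal(pbd$positions[[1]], "S")
  expect_equal(pbd$phospho_index, 2L)
  expect_setequal(pbd$positions[[2]], c("S", "T"))
  # the [P/X] alternative widens the third position to the full alphabet
  expect_true(pbd$wildcard[3])
  expect_equal(length(pbd$positions[[3]]), 20L)
  # the strict reading restricts it back to proline
  strict <- apply_strict(pbd)
  expect_equal(strict$positions[[3]], "P")
  expect_false(strict$wildcard[3])

  # separators and 'p' placement variants
  expect_equal(compile_motif("S-[pS/pT]-[P/X]")$phospho_index,
               compile_motif("S[pS/pT][P/X]")$phospho_index)
  expect_setequal(compile_motif("[pT/pS]E")$positions[[1]], c("S", "T"))
})

test_that("compile_motif rejects malformed notations", {
  expect_error(compile_motif("[E/D]X[S/T][I/L/V/M]X[E]"),
               class = "plkscreen_notation_error")  # no phosphoacceptor
  expect_error(compile_motif("[pS][pT]E"),
               class = "plkscreen_notation_error")  # two phosphoacceptors
  expect_error(compile_motif("[pE/pD]XX"),
               class = "plkscreen_notation_error")  # phospho not in {S,T}
  expect_error(compile_motif("pX-S"), class = "plkscreen_notation_error")
  expect_error(compile_motif("[]X[pS]"), class = "plkscreen_notation_error")
  expect_error(compile_motif("[E/1]X[pS]"), class = "plkscreen_notation_error")
  expect_error(compile_motif("E7[pS]"), class = "plkscreen_notation_error")
  expect_error(compile_motif("[E/D"), class = "plkscreen_notation_error")
  expect_error(compile_motif("[pS]"), class = "plkscreen_notation_error")  # length 1
})

test_that("similarity_index counts matched positions over all positions", {
  kin <- kinase_motif()
  expect_equal(similarity_index("EASIAE", kin), 1)
  expect_equal(similarity_index("QASIAE", kin), 5 / 6)
  expect_equal(similarity_index("QAAIAQ", kin), 0.5)
  # ambiguity letters match only wildcard positions
  expect_equal(similarity_index("BXSIA*", kin), 4 / 6)
  expect_error(similarity_index("EASIAEK", kin),
               class = "plkscreen_length_error")
})

test_that("substitution similarity rescues positive-scoring residues only", {
  kin <- kinase_motif()
  expect_equal(substitution_similarity("EASIAE", kin), 1)
  expect_equal(substitution_similarity("QASIAE", kin), 1)     # Q:E = +2
  expect_equal(substitution_similarity("GASIAE", kin), 5 / 6) # G:E, G:D <= 0
  # substitution score always >= identity score
  set.seed(41)
  for (i in 1:50) {
    w <- paste(sample(AA20, 6, replace = TRUE), collapse = "")
    expect_gte(substitution_similarity(w, kin), similarity_index(w, kin))
  }
})

test_that("scan_protein emits sorted 1-based hits with exact phosphoacceptor", {
  kin <- kinase_motif()
  hits <- scan_protein("MEASIAEK", kin, min_similarity = 0.8, id = "p1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 7L)
  expect_equal(hits$window, "EASIAE")
  expect_equal(hits$similarity, 1)
  expect_equal(hits$phospho_position, 4L)

  expect_equal(nrow(scan_protein("AAAAAAAA", kin, 0)), 0L)   # no S/T
  expect_equal(nrow(scan_protein("EASIA", kin, 0)), 0L)      # shorter than motif
  expect_equal(nrow(scan_protein("", kin, 0)), 0L)
  # lowercase input is uppercased
  expect_equal(nrow(scan_protein("measiaek", kin, 0.8)), 1L)
  # overlapping qualifying windows are all retained
  two <- scan_protein("EASIAEASLAE", kin, 0.8, id = "x")
  expect_equal(two$start, c(1L, 6L))
})

test_that("scanner agrees with the naive per-window oracle", {
  set.seed(101)
  b62 <- blosum62()
  for (rep in 1:60) {
    motif <- random_motif()
    seqn <- random_sequence(200, ambiguous_rate = if (rep %% 3) 0 else 0.05)
    thr <- sample(c(0, 0.5, 0.8, 1), 1)
    mode <- if (rep %% 4 == 0 && !grepl("[BZUX*]", seqn)) "substitution" else "identity"
    got <- scan_protein(seqn, motif, thr, mode = mode, id = "t")
    want <- naive_scan(seqn, motif, thr, mode = mode, matrix = b62)
    expect_equal(got$start, want$start)
    expect_equal(got$window, want$window)
    expect_equal(got$similarity, want$similarity)
    expect_equal(got$phospho_position, want$phospho_position)
  }
})

test_that("scan properties: threshold monotonicity, mode dominance, wildcards, phosphoacceptor", {
  set.seed(202)
  kin <- kinase_motif()
  for (rep in 1:25) {
    motif <- random_motif()
    seqn <- random_sequence(150, ambiguous_rate = 0)
    a <- sample(c(0, 0.3, 0.6), 1)
    b <- a + sample(c(0.2, 0.4), 1)
    lo <- scan_protein(seqn, motif, a)
    hi <- scan_protein(seqn, motif, b)
    expect_true(all(hi$start %in% lo$start))           # hits(a) >= hits(b), a <= b
    idm <- scan_protein(seqn, motif, b, mode = "identity")
    sbm <- scan_protein(seqn, motif, b, mode = "substitution")
    expect_true(all(idm$start %in% sbm$start))         # substitution superset
    # every reported phosphoacceptor residue is S or T
    all_hits <- rbind(lo, sbm)
    if (nrow(all_hits))
      expect_true(all(substr(seqn, all_hits$phospho_position,
                             all_hits$phospho_position) %in% c("S", "T")))
  }
  # changing a window only at wildcard positions never changes the score
  set.seed(203)
  for (rep in 1:25) {
    w <- paste(sample(AA20, 6, replace = TRUE), collapse = "")
    w2 <- w
    for (i in which(kin$wildcard))
      substr(w2, i, i) <- sample(AA20, 1)
    expect_equal(similarity_index(w, kin), similarity_index(w2, kin))
  }
})

test_that("scan_proteome concatenates per-protein scans and validates ids", {
  kin <- kinase_motif()
  prot <- c(p1 = "MEASIAEK", p2 = "AAAAAAAA")
  hits <- scan_proteome(prot, kin, 0.8)
  expect_equal(unique(hits$protein_id), "p1")
  summ <- hit_summary(hits)
  expect_equal(summ$protein_id, "p1")
  expect_equal(summ$best_similarity, 1)

  expect_equal(nrow(scan_proteome(character(0), kin, 0.8)), 0L)
  expect_error(scan_proteome(c(a = "MEASIAEK", a = "MEASIAEK"), kin, 0.8),
               class = "plkscreen_input_error")
  expect_error(scan_proteome(c("MEASIAEK"), kin, 0.8),
               class = "plkscreen_input_error")
  # AAStringSet input is accepted
  xs <- Biostrings::AAStringSet(c(p1 = "MEASIAEK"))
  expect_equal(nrow(scan_proteome(xs, kin, 0.8)), 1L)
})
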