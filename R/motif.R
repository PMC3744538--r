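#' Compile a degenerate motif from its bracket notation
#'
#' Parses the field's bracket notation for short linear motifs, e.g. the Plk1
#' kinase consensus phosphorylation motif `"[E/D]X[pS/pT][I/L/V/M]X[E]"` or
#' the polo-box-domain recognition motif `"S-[pS/pT]-[P/X]"`. Each token is a
#' single residue letter, the wildcard `X`, or a bracketed alternation of
#' residues separated by `/`. A `p` prefix marks the phosphoacceptor token
#' (exactly one is required, and its residue set must be a subset of S/T).
#' Optional `-` separators between tokens are ignored. Inside a bracket, a
#' bare `X` alternative (as in `[P/X]`) widens the position to the full
#' 20-letter alphabet; the non-wildcard alternatives are retained as the
#' "strict" reading of the position (see [apply_strict()]).
#'
#' @param notation Motif notation string.
#' @param name Optional short label stored on the pattern; defaults to the
#'   notation itself.
#' @return A `motif_pattern` object: a list with elements `name`, `positions`
#'   (list of allowed-residue character vectors, full alphabet at wildcards),
#'   `wildcard` (logical per position), `strict_positions` (allowed sets
#'   before `X`-widening, used by [apply_strict()]), `phospho_index` and
#'   `length`.
#' @examples
#' m <- compile_motif("[E/D]X[pS/pT][I/L/V/M]X[E]", name = "plk1_kinase")
#' m$phospho_index  # 3
#' @export
compile_motif <- function(notation, name = NULL) {
  if (!is.character(notation) || length(notation) != 1L || is.na(notation) ||
      !nzchar(notation))
    plk_error("notation_error", "motif notation must be a non-empty string")
  s <- gsub("[[:space:]]", "", notation)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "-") { i <- i + 1L; next }
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(close))
        plk_error("notation_error",
                  sprintf("unclosed '[' at character %d of %s", i, notation))
      content <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (!nzchar(content))
        plk_error("notation_error",
                  sprintf("empty bracketed token at character %d of %s", i, notation))
      tokens[[length(tokens) + 1L]] <- .parse_alternation(content, notation)
      i <- close + 1L
    } else if (ch == "]") {
      plk_error("notation_error",
                sprintf("unmatched ']' at character %d of %s", i, notation))
    } else {
      phospho <- FALSE
      if (ch == "p") {
        phospho <- TRUE
        i <- i + 1L
        if (i > length(chars))
          plk_error("notation_error",
                    sprintf("dangling 'p' prefix at end of %s", notation))
        ch <- chars[i]
      }
      tokens[[length(tokens) + 1L]] <- .parse_residue_token(ch, phospho, notation)
      i <- i + 1L
    }
  }
  if (length(tokens) < 2L)
    plk_error("notation_error",
              sprintf("motif must have at least 2 positions, got %d in %s",
                      length(tokens), notation))
  is_phos <- vapply(tokens, `[[`, logical(1), "phospho")
  if (sum(is_phos) == 0L)
    plk_error("notation_error",
              sprintf("no phosphoacceptor ('p'-prefixed) token in %s", notation))
  if (sum(is_phos) > 1L)
    plk_error("notation_error",
              sprintf("multiple phosphoacceptor tokens in %s", notation))
  phospho_index <- which(is_phos)
  phos_set <- tokens[[phospho_index]]$set
  if (tokens[[phospho_index]]$wildcard || !all(phos_set %in% c("S", "T")))
    plk_error("notation_error",
              sprintf("phosphoacceptor set {%s} is not a subset of {S,T} in %s",
                      paste(phos_set, collapse = ","), notation))
  structure(list(
    name = if (is.null(name)) notation else name,
    positions = lapply(tokens, function(t) if (t$wildcard) AA_STANDARD else t$set),
    wildcard = vapply(tokens, `[[`, logical(1), "wildcard"),
    strict_positions = lapply(tokens, `[[`, "strict"),
    phospho_index = phospho_index,
    length = length(tokens)
  ), class = "motif_pattern")
}

.parse_residue_token <- function(ch, phospho, notation) {
  if (ch == "X")
    return(list(set = AA_STANDARD, wildcard = TRUE, strict = AA_STANDARD,
                phospho = phospho))
  if (!ch %in% AA_STANDARD)
    plk_error("notation_error",
              sprintf("unknown residue letter '%s' in %s", ch, notation))
  list(set = ch, wildcard = FALSE, strict = ch, phospho = phospho)
}

.parse_alternation <- function(content, notation) {
  alts <- strsplit(content, "/", fixed = TRUE)[[1]]
  if (length(alts) == 0L || any(!nzchar(alts)))
    plk_error("notation_error",
              sprintf("empty alternative in token [%s] of %s", content, notation))
  phospho <- any(startsWith(alts, "p"))
  letters <- sub("^p", "", alts)
  if (any(nchar(letters) != 1L))
    plk_error("notation_error",
              sprintf("alternatives must be single letters in [%s] of %s",
                      content, notation))
  has_x <- "X" %in% letters
  residues <- unique(letters[letters != "X"])
  if (any(!residues %in% AA_STANDARD))
    plk_error("notation_error",
              sprintf("unknown residue letter in token [%s] of %s", content, notation))
  if (has_x) {
    # an explicit X alternative widens the position to the full alphabet;
    # the named residues are kept as the strict reading
    list(set = AA_STANDARD, wildcard = TRUE,
         strict = if (length(residues)) residues else AA_STANDARD,
         phospho = phospho)
  } else {
    if (!length(residues))
      plk_error("notation_error",
                sprintf("empty token [%s] of %s", content, notation))
    list(set = residues, wildcard = FALSE, strict = residues, phospho = phospho)
  }
}

#' Restrict X-widened motif positions to their named alternatives
#'
#' The PBD recognition motif is written `S-[pS/pT]-[P/X]`: proline is
#' preferred but not required at the third position, so by default that
#' position is a wildcard ("relaxed" reading). `apply_strict()` returns the
#' strict reading, in which every position that was widened by an explicit
#' `X` alternative is restricted to its named residues (here `{P}`).
#'
#' @param motif A `motif_pattern`.
#' @return A `motif_pattern` with widened positions restricted.
#' @export
apply_strict <- function(motif) {
  stopifnot(inherits(motif, "motif_pattern"))
  widened <- motif$wildcard &
    vapply(motif$strict_positions, function(s) length(s) < length(AA_STANDARD),
           logical(1))
  motif$positions[widened] <- motif$strict_positions[widened]
  motif$wildcard[widened] <- FALSE
  motif
}

#' @export
print.motif_pattern <- function(x, ...) {
  toks <- vapply(seq_len(x$length), function(i) {
    set <- if (x$wildcard[i]) "X" else paste(x$positions[[i]], collapse = "/")
    if (i == x$phospho_index) paste0("p(", set, ")") else paste0("[", set, "]")
  }, character(1))
  cat("<motif_pattern> ", x$name, ": ", paste(toks, collapse = " "),
      " (length ", x$length, ", phosphoacceptor at ", x$phospho_index, ")\n",
      sep = "")
  invisible(x)
}

# per-position logical match profile of a window against a motif
.match_profile <- function(chars, motif, mode = "identity", matrix = NULL) {
  vapply(seq_len(motif$length), function(i) {
    if (motif$wildcard[i]) return(TRUE)
    hit <- chars[i] %in% motif$positions[[i]]
    if (!hit && mode == "substitution") {
      if (!chars[i] %in% rownames(matrix))
        plk_error("matrix_error",
                  sprintf("residue '%s' absent from substitution matrix", chars[i]))
      hit <- max(matrix[chars[i], motif$positions[[i]]]) > 0
    }
    hit
  }, logical(1))
}

#' Fraction of motif positions matched by a window (identity mode)
#'
#' Scores a window of motif length as matched-positions / length, where
#' position i matches iff the window residue is in the motif's allowed set at
#' i. Wildcard positions always match; non-standard letters (B, Z, U, X, *)
#' match only wildcard positions. The phosphoacceptor position is scored like
#' any other — the hard phosphoacceptor constraint is applied by
#' [scan_protein()], not here. This is the "identity with the consensus
#' motif" index to which the screen's 80% threshold is applied.
#'
#' @param window Residue string of exactly motif length (uppercase).
#' @param motif A `motif_pattern`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' kin <- compile_motif("[E/D]X[pS/pT][I/L/V/M]X[E]")
#' similarity_index("EASIAE", kin)  # 1
#' similarity_index("QASIAE", kin)  # 5/6
#' @export
similarity_index <- function(window, motif) {
  stopifnot(inherits(motif, "motif_pattern"))
  chars <- .window_chars(window, motif)
  mean(.match_profile(chars, motif, "identity"))
}

#' Fraction of motif positions matched under a substitution matrix
#'
#' Substitution-mode analogue of [similarity_index()], approximating a
#' BLOSUM62-scored search: position i counts as matched iff the window
#' residue equals an allowed residue or scores positively against at least
#' one allowed residue in the matrix. Since the BLOSUM62 diagonal is
#' positive, every identity-mode match is also a substitution-mode match, so
#' this score is always `>=` [similarity_index()] on the same window.
#'
#' @inheritParams similarity_index
#' @param matrix A substitution matrix with residue dimnames; defaults to
#'   BLOSUM62 from \pkg{Biostrings}.
#' @return Fraction in `[0, 1]`.
#' @examples
#' kin <- compile_motif("[E/D]X[pS/pT][I/L/V/M]X[E]")
#' substitution_similarity("QASIAE", kin)  # 1: Q scores +2 against E
#' substitution_similarity("GASIAE", kin)  # 5/6: G scores <= 0 against E and D
#' @export
substitution_similarity <- function(window, motif, matrix = blosum62()) {
  stopifnot(inherits(motif, "motif_pattern"))
  chars <- .window_chars(window, motif)
  mean(.match_profile(chars, motif, "substitution", matrix))
}

.window_chars <- function(window, motif) {
  stopifnot(is.character(window), length(window) == 1L)
  if (nchar(window) != motif$length)
    plk_error("length_error",
              sprintf("window length %d does not match motif length %d",
                      nchar(window), motif$length))
  strsplit(window, "", fixed = TRUE)[[1]]
}

.empty_hits <- function() {
  data.frame(protein_id = character(), motif_name = character(),
             start = integer(), end = integer(), window = character(),
             phospho_position = integer(), similarity = numeric(),
             mode = character(), stringsAsFactors = FALSE)
}

#' Scan one protein for motif windows
#'
#' Evaluates every window of motif length (step 1). A hit is emitted iff
#' (a) the phosphoacceptor position matches exactly — the residue there is in
#' the motif's allowed S/T set — and (b) the window's similarity under the
#' chosen mode is at least `min_similarity`. All qualifying windows are
#' reported, including overlapping ones, sorted by start. Coordinates are
#' 1-based inclusive.
#'
#' @param sequence Protein sequence: a single string or an
#'   [Biostrings::AAString]; converted to uppercase.
#' @param motif A `motif_pattern`.
#' @param min_similarity Similarity threshold in `[0, 1]`; the screen default
#'   is 0.80, applied inclusively.
#' @param mode `"identity"` (exact set membership) or `"substitution"`
#'   (positive substitution score also counts, see
#'   [substitution_similarity()]).
#' @param id Protein identifier recorded in the hit table.
#' @param matrix Substitution matrix for `mode = "substitution"`.
#' @return A data frame of motif hits with columns `protein_id`,
#'   `motif_name`, `start`, `end`, `window`, `phospho_position`,
#'   `similarity`, `mode`. Sequences shorter than the motif yield zero rows.
#' @examples
#' kin <- compile_motif("[E/D]X[pS/pT][I/L/V/M]X[E]")
#' scan_protein("MEASIAEK", kin, min_similarity = 0.8, id = "demo")
#' @export
scan_protein <- function(sequence, motif, min_similarity = 0.8,
                         mode = c("identity", "substitution"), id = NA_character_,
                         matrix = NULL) {
  stopifnot(inherits(motif, "motif_pattern"))
  mode <- match.arg(mode)
  if (!is.numeric(min_similarity) || length(min_similarity) != 1L ||
      is.na(min_similarity) || min_similarity < 0 || min_similarity > 1)
    plk_error("config_error", "min_similarity must be a number in [0, 1]")
  seqc <- toupper(as.character(sequence))
  l <- motif$length
  L <- nchar(seqc)
  if (L < l) return(.empty_hits())
  chars <- strsplit(seqc, "", fixed = TRUE)[[1]]
  if (mode == "substitution" && is.null(matrix)) matrix <- blosum62()

  # per motif position, a logical over sequence positions: does the residue
  # match the allowed set at that motif position?
  ok <- base::matrix(FALSE, nrow = L, ncol = l)
  for (i in seq_len(l)) {
    if (motif$wildcard[i]) { ok[, i] <- TRUE; next }
    ok[, i] <- chars %in% motif$positions[[i]]
    if (mode == "substitution") {
      letters <- unique(chars[!ok[, i]])
      for (ch in letters) {
        if (!ch %in% rownames(matrix))
          plk_error("matrix_error",
                    sprintf("residue '%s' absent from substitution matrix", ch))
        if (max(matrix[ch, motif$positions[[i]]]) > 0)
          ok[chars == ch, i] <- TRUE
      }
    }
  }
  nwin <- L - l + 1L
  matches <- integer(nwin)
  for (i in seq_len(l)) matches <- matches + ok[i:(i + nwin - 1L), i]
  sims <- matches / l

  # hard constraint: exact phosphoacceptor match, independent of mode
  phos_set <- intersect(motif$positions[[motif$phospho_index]], c("S", "T"))
  phos_pos <- seq_len(nwin) + motif$phospho_index - 1L
  phos_ok <- chars[phos_pos] %in% phos_set

  keep <- phos_ok & sims >= min_similarity - .SIM_EPS
  starts <- which(keep)
  if (!length(starts)) return(.empty_hits())
  data.frame(
    protein_id = rep(as.character(id), length(starts)),
    motif_name = rep(motif$name, length(starts)),
    start = starts,
    end = starts + l - 1L,
    window = substring(seqc, starts, starts + l - 1L),
    phospho_position = starts + motif$phospho_index - 1L,
    similarity = sims[starts],
    mode = rep(mode, length(starts)),
    stringsAsFactors = FALSE
  )
}

#' Scan a whole proteome for motif windows
#'
#' Applies [scan_protein()] to every record and concatenates the hit tables,
#' preserving input record order. Identifiers must be unique.
#'
#' @param proteome An [Biostrings::AAStringSet] or named character vector of
#'   protein sequences; names are the protein identifiers.
#' @inheritParams scan_protein
#' @return A hit data frame as in [scan_protein()]. Use [hit_summary()] for
#'   the set of hit proteins and per-protein best similarity.
#' @export
scan_proteome <- function(proteome, motif, min_similarity = 0.8,
                          mode = c("identity", "substitution"), matrix = NULL) {
  mode <- match.arg(mode)
  seqs <- .as_protein_vector(proteome)
  if (mode == "substitution" && is.null(matrix)) matrix <- blosum62()
  if (!length(seqs)) return(.empty_hits())
  out <- vector("list", length(seqs))
  for (j in seq_along(seqs))
    out[[j]] <- scan_protein(seqs[[j]], motif, min_similarity, mode,
                             id = names(seqs)[j], matrix = matrix)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.as_protein_vector <- function(proteome) {
  seqs <- if (methods::is(proteome, "XStringSet")) {
    stats::setNames(as.character(proteome), names(proteome))
  } else if (is.character(proteome)) proteome
  else plk_error("input_error",
                 "proteome must be an AAStringSet or named character vector")
  if (!length(seqs)) return(stats::setNames(character(0), character(0)))
  if (is.null(names(seqs)) || any(is.na(names(seqs)) | !nzchar(names(seqs))))
    plk_error("input_error", "every protein needs a non-empty identifier")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    plk_error("input_error",
              sprintf("duplicate protein identifiers: %s",
                      paste(dup, collapse = ", ")))
  toupper(seqs)
}

#' Per-protein summary of a motif hit table
#'
#' @param hits A hit data frame from [scan_proteome()].
#' @return Data frame with one row per protein with at least one hit:
#'   `protein_id`, `n_hits`, `best_similarity`, sorted by `protein_id`.
#' @export
hit_summary <- function(hits) {
  if (!nrow(hits))
    return(data.frame(protein_id = character(), n_hits = integer(),
                      best_similarity = numeric(), stringsAsFactors = FALSE))
  agg <- split(hits$similarity, hits$protein_id)
  data.frame(
    protein_id = names(agg),
    n_hits = lengths(agg),
    best_similarity = vapply(agg, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
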