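# Independent oracles and small fixture builders shared across tests.

kinase_motif <- function() compile_motif("[E/D]X[pS/pT][I/L/V/M]X[E]",
                                         name = "kinase")
pbd_motif <- function() compile_motif("S-[pS/pT]-[P/X]", name = "pbd")

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Naive window-by-window, position-by-position scan oracle, written
# independently of the package's vectorized scanner.
naive_scan <- function(sequence, motif, min_similarity,
                       mode = "identity", matrix = NULL) {
  sequence <- toupper(sequence)
  l <- motif$length
  L <- nchar(sequence)
  rows <- list()
  if (L >= l) {
    for (s in seq_len(L - l + 1L)) {
      win <- substr(sequence, s, s + l - 1L)
      chars <- strsplit(win, "")[[1]]
      matched <- logical(l)
      for (i in seq_len(l)) {
        if (motif$wildcard[i]) { matched[i] <- TRUE; next }
        matched[i] <- chars[i] %in% motif$positions[[i]]
        if (!matched[i] && mode == "substitution")
          matched[i] <- max(matrix[chars[i], motif$positions[[i]]]) > 0
      }
      phos <- chars[motif$phospho_index] %in%
        intersect(motif$positions[[motif$phospho_index]], c("S", "T"))
      sim <- sum(matched) / l
      if (phos && sim >= min_similarity - 1e-9)
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, window = win, similarity = sim,
          phospho_position = s + motif$phospho_index - 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), window = character(),
                      similarity = numeric(), phospho_position = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail: all
# C(N, n) equally likely draws of n from N with the first K "annotated".
enum_hypergeom_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- combn(N, n)
  ann <- colSums(draws <= K)
  mean(ann >= k)
}

# Random degenerate motif with a valid S/T phosphoacceptor.
random_motif <- function() {
  l <- sample(2:8, 1)
  phospho <- sample(l, 1)
  toks <- character(l)
  for (i in seq_len(l)) {
    if (i == phospho) {
      toks[i] <- paste0("[", paste0("p", sample(list("S", "T", c("S", "T")),
                                                1)[[1]], collapse = "/"), "]")
    } else if (runif(1) < 0.3) {
      toks[i] <- "X"
    } else {
      set <- sample(AA20, sample(1:4, 1))
      toks[i] <- if (length(set) == 1) set else
        paste0("[", paste(set, collapse = "/"), "]")
    }
  }
  compile_motif(paste(toks, collapse = ""))
}

random_sequence <- function(max_len = 200, ambiguous_rate = 0.02) {
  L <- sample(0:max_len, 1)
  alphabet <- c(AA20, "B", "Z", "U", "X", "*")
  probs <- c(rep((1 - ambiguous_rate) / 20, 20), rep(ambiguous_rate / 5, 5))
  paste(sample(alphabet, L, replace = TRUE, prob = probs), collapse = "")
}

# Small hand-built annotation world: `universe` ids, one enriched term on
# `special`, plus any extra assignment rows supplied.
tiny_annotations <- function(universe, special,
                             term = "cell cycle",
                             namespace = "biological_process",
                             extra = NULL) {
  rows <- data.frame(protein_id = special, namespace = namespace, term = term,
                     stringsAsFactors = FALSE)
  filler <- setdiff(universe, special)
  if (length(filler))
    rows <- rbind(rows, data.frame(protein_id = filler,
                                   namespace = "molecular_function",
                                   term = "filler", stringsAsFactors = FALSE))
  if (!is.null(extra)) rows <- rbind(rows, extra)
  annotation_set(rows)
}
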