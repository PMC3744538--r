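#' Read a multi-record protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] with line-level validation so that
#' malformed input is reported with its line number. Records preserve input
#' order, sequences are uppercased, identifiers are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path FASTA file path.
#' @return An [Biostrings::AAStringSet] named by identifier.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    plk_error("input_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">"))
    plk_error("parse_error",
              sprintf("%s: line %d: sequence data before first '>' header",
                      path, nonblank[1]))
  hdr <- which(startsWith(trimws(lines), ">"))
  ids <- vapply(lines[hdr], function(h)
    strsplit(sub("^\\s*>", "", h), "\\s+")[[1]][1], character(1),
    USE.NAMES = FALSE)
  empty <- which(is.na(ids) | !nzchar(ids))
  if (length(empty))
    plk_error("parse_error",
              sprintf("%s: line %d: header with empty identifier", path,
                      hdr[empty[1]]))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    plk_error("parse_error",
              sprintf("%s: duplicate record identifier(s): %s", path,
                      paste(unique(dup), collapse = ", ")))
  x <- Biostrings::readAAStringSet(path)
  x <- Biostrings::AAStringSet(toupper(as.character(x)))
  names(x) <- ids
  x
}

#' Write protein records as FASTA
#'
#' Deterministic writer: input order, 60-column wrapping, LF line endings.
#'
#' @param proteome An [Biostrings::AAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  seqs <- .as_protein_vector(proteome)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read annotations in GMT format
#'
#' One tab-separated line per term: term, namespace (in the description
#' column), then member identifiers. Namespaces must belong to the closed
#' vocabulary (`biological_process`, `cellular_component`,
#' `molecular_function`, `phase`, `cancer`).
#'
#' @param path GMT file path.
#' @param universe_size Optional override of the annotated-universe size `N`;
#'   defaults to the number of distinct member identifiers in the file.
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path, universe_size = NULL) {
  if (!file.exists(path))
    plk_error("input_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  rows <- list()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      plk_error("parse_error",
                sprintf("%s: line %d: expected at least 3 tab-separated fields, got %d",
                        path, i, length(fields)))
    ns <- fields[2]
    if (!ns %in% NAMESPACE_VOCABULARY)
      plk_error("parse_error",
                sprintf("%s: line %d: unknown namespace '%s' (allowed: %s)",
                        path, i, ns,
                        paste(NAMESPACE_VOCABULARY, collapse = ", ")))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members))
      rows[[length(rows) + 1L]] <-
        data.frame(protein_id = members, namespace = ns, term = fields[1],
                   stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), namespace = character(),
               term = character(), stringsAsFactors = FALSE)
  annotation_set(assignments, universe_size = universe_size)
}

#' Write an annotation set in GMT format
#'
#' Deterministic writer: terms sorted by (namespace, term), members sorted,
#' LF line endings. `write_gmt()` then [read_gmt()] preserves term and
#' member sets.
#'
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  a <- annotations$assignments
  key <- paste(a$namespace, a$term, sep = "\r")
  keys <- sort(unique(key))
  lines <- vapply(keys, function(kk) {
    sel <- key == kk
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    paste(c(parts[2], parts[1], sort(unique(a$protein_id[sel]))),
          collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# deterministic TSV writer: headers mandatory, LF endings, numeric columns
# formatted with 6 significant digits
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

#' Load a pipeline configuration from a YAML key-value file
#'
#' Unspecified keys take the screen defaults (the kinase and PBD motifs,
#' similarity 0.80, enrichment alpha 0.1); every value is range-checked and
#' all violations are reported at once. An empty file yields the default
#' configuration.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    plk_error("input_error", sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals))
    plk_error("config_error",
              sprintf("%s: expected a key-value mapping", path))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    plk_error("config_error",
              sprintf("unknown configuration key(s): %s (known: %s)",
                      paste(unknown, collapse = ", "),
                      paste(known, collapse = ", ")))
  for (k in c("enrichment_namespaces", "required_namespaces"))
    if (!is.null(vals[[k]])) vals[[k]] <- as.character(unlist(vals[[k]]))
  if (!is.null(vals$spacing)) vals$spacing <- as.numeric(unlist(vals$spacing))
  do.call(pipeline_config, vals)
}

#' Write the tables of a completed screen run
#'
#' Emits `candidates.tsv`, `stage_counts.tsv`, `clusters.tsv`,
#' `phase_groups.tsv` and `manifest.json` into a directory.
#'
#' @param screen A `plk_screen` result from [run_screen()].
#' @param dir Output directory (created if needed).
#' @param inputs Named character vector of input file paths recorded (with
#'   MD5 digests) in the manifest.
#' @return `dir`, invisibly.
#' @export
write_screen_outputs <- function(screen, dir, inputs = character()) {
  stopifnot(inherits(screen, "plk_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(screen$candidates, file.path(dir, "candidates.tsv"))
  write_tsv(screen$stage_counts, file.path(dir, "stage_counts.tsv"))
  cl <- screen$clusters
  cl$retained <- paste(cl$namespace, cl$term) %in%
    paste(screen$retained_clusters$namespace, screen$retained_clusters$term)
  write_tsv(cl, file.path(dir, "clusters.tsv"))
  pg <- screen$phase_groups
  pg_df <- data.frame(
    phase = names(pg),
    n_proteins = vapply(pg, length, integer(1)),
    members = vapply(pg, paste, character(1), collapse = ";"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  write_tsv(pg_df, file.path(dir, "phase_groups.tsv"))
  manifest <- run_manifest(config = unclass(screen$config), inputs = inputs,
                           stage_counts = screen$stage_counts)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

# manifest of a successful run: config snapshot, input digests, seed,
# version, timestamp, per-stage counts
run_manifest <- function(config = list(), inputs = character(),
                         stage_counts = NULL, seed = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(unlist(inputs))) else list()
  list(tool = "plkscreen",
       version = as.character(utils::packageVersion("plkscreen")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = if (is.null(seed)) config$seed else seed,
       config = config,
       input_md5 = digests,
       stage_counts = stage_counts)
}
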