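#' Build a protein dataset tibble
#'
#' The central data container of the package is an ordinary tibble with one
#' row per protein and columns `id` (character, unique), `sequence`
#' (character, upper-case one-letter amino-acid codes) and, optionally,
#' `labels` (a list column holding one integer 0/1 vector per protein, aligned
#' 1:1 with the sequence; 1 marks an early-folding residue).
#'
#' @param id Character vector of unique protein identifiers.
#' @param sequence Character vector of amino-acid sequences (one-letter code).
#' @param labels Optional list of per-residue integer 0/1 vectors, one per
#'   protein, each with `nchar(sequence)` elements.
#' @return A tibble with columns `id`, `sequence` and (if given) `labels`.
#' @examples
#' efold_dataset(c("p1", "p2"), c("ACDEF", "GHIK"))
#' @export
efold_dataset <- function(id, sequence, labels = NULL) {
  d <- tibble(id = as.character(id), sequence = toupper(as.character(sequence)))
  if (!is.null(labels)) d$labels <- labels
  validate_dataset(d)
}

#' Validate a protein dataset tibble
#'
#' Checks identifier uniqueness, sequence alphabet, and label/sequence
#' alignment. Non-canonical residue codes (X, B, Z) are accepted with a
#' warning; any other letter is an error.
#'
#' @param proteins A tibble with columns `id`, `sequence` and optionally
#'   `labels`.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_dataset <- function(proteins) {
  stopifnot(is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$id) > 0) {
    abort(paste0("duplicate protein ids: ",
                 paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", ")))
  }
  if (any(nchar(proteins$sequence) < 1)) {
    abort("every sequence must have length >= 1")
  }
  letters_used <- unique(unlist(strsplit(proteins$sequence, "")))
  bad <- setdiff(letters_used, c(AA_ALPHABET, AA_NONCANONICAL))
  if (length(bad) > 0) {
    abort(paste0("invalid residue code(s): ", paste(bad, collapse = ", ")))
  }
  odd <- intersect(letters_used, AA_NONCANONICAL)
  if (length(odd) > 0) {
    warn(paste0("non-canonical residue code(s) present (encoded neutrally): ",
                paste(odd, collapse = ", ")))
  }
  if ("labels" %in% names(proteins)) {
    len_ok <- map_int(proteins$labels, length) == nchar(proteins$sequence)
    if (!all(len_ok)) {
      abort(paste0("label vector length mismatch for: ",
                   paste(proteins$id[!len_ok], collapse = ", ")))
    }
    vals <- unlist(proteins$labels)
    if (!all(vals %in% c(0L, 1L))) abort("labels must be 0/1")
  }
  as_tibble(proteins)
}

#' Read a multi-record FASTA file
#'
#' Wrapped sequence lines are concatenated, whitespace is stripped and
#' sequences are upper-cased. The record id is the header text up to the
#' first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !startsWith(lines[[1]], ">")) {
    abort(paste0("not FASTA-formatted: ", path))
  }
  hdr_idx <- which(startsWith(lines, ">"))
  ids <- sub("^>\\s*", "", lines[hdr_idx])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  seqs <- map2_chr_(hdr_idx, ends, function(a, b) {
    if (b <= a) return("")
    gsub("\\s", "", paste(lines[(a + 1L):b], collapse = ""))
  })
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("empty sequence under header(s): ", paste(ids[empty], collapse = ", ")))
  }
  efold_dataset(ids, seqs)
}

# map2 returning character; kept local to avoid depending on purrr type-variants
map2_chr_ <- function(x, y, f) vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), character(1))

#' Write a dataset to FASTA
#'
#' @param proteins A dataset tibble (see [efold_dataset()]).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  validate_dataset(proteins)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[[i]]), con)
    s <- proteins$sequence[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Attach early-folding annotations to a dataset
#'
#' The annotation file is a tab-separated table with a header row and columns
#' `protein_id`, `residue_number` (1-based) and `label` (the value `EARLY`).
#' Residues listed there are labelled 1; every other residue of every protein
#' in `proteins` is labelled 0.
#'
#' @param path Path to the annotation TSV.
#' @param proteins A dataset tibble.
#' @return The dataset with a `labels` list column attached.
#' @export
read_annotations <- function(path, proteins) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  validate_dataset(proteins)
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "character"))
  names(ann) <- c("protein_id", "residue_number", "label")
  unknown <- setdiff(ann$protein_id, proteins$id)
  if (length(unknown) > 0) {
    abort(paste0("annotation references unknown protein id(s): ",
                 paste(unique(unknown), collapse = ", ")))
  }
  lens <- setNames(nchar(proteins$sequence), proteins$id)
  bad <- ann$residue_number < 1 | ann$residue_number > lens[ann$protein_id]
  if (any(bad)) {
    b <- ann[bad, , drop = FALSE][1, ]
    abort(paste0("residue_number out of range: protein ", b$protein_id,
                 " position ", b$residue_number))
  }
  if (nrow(ann) > 0 && !all(ann$label == "EARLY")) {
    abort("annotation labels must all be 'EARLY'")
  }
  labels <- map(seq_len(nrow(proteins)), function(i) {
    v <- integer(lens[[i]])
    pos <- ann$residue_number[ann$protein_id == proteins$id[[i]]]
    v[pos] <- 1L
    v
  })
  proteins$labels <- labels
  validate_dataset(proteins)
}

#' Write early-folding annotations
#'
#' Inverse of [read_annotations()]: writes one row per positively labelled
#' residue.
#'
#' @param proteins A labelled dataset tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(proteins, path) {
  validate_dataset(proteins)
  if (!"labels" %in% names(proteins)) abort("dataset has no labels")
  rows <- residues(proteins) |> filter(.data$label == 1L)
  out <- data.frame(protein_id = rows$protein_id,
                    residue_number = rows$residue_number,
                    label = "EARLY")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand a dataset to one row per residue
#'
#' @param proteins A dataset tibble.
#' @return A tibble with columns `protein_id`, `residue_number` (1-based),
#'   `amino_acid` and, when labels are present, `label`.
#' @export
residues <- function(proteins) {
  validate_dataset(proteins)
  lens <- nchar(proteins$sequence)
  out <- tibble(
    protein_id = rep(proteins$id, lens),
    residue_number = unlist(lapply(lens, seq_len)),
    amino_acid = unlist(strsplit(proteins$sequence, ""))
  )
  if ("labels" %in% names(proteins)) out$label <- unlist(proteins$labels)
  out
}

#' Write per-residue early-folding scores
#'
#' Produces a TSV with columns `protein_id`, `residue_number` (1-based),
#' `amino_acid`, `probability` (written with 6 significant digits) and
#' `binary_call` (1 iff `probability >= tau`, threshold inclusive).
#'
#' @param proteins A dataset tibble.
#' @param scores Numeric vector of per-residue probabilities in \[0, 1\], one
#'   per residue in dataset order (protein order, then residue order).
#' @param path Output path.
#' @param tau Decision threshold (default 0.163).
#' @return `path`, invisibly.
#' @export
write_scores <- function(proteins, scores, path, tau = 0.163) {
  res <- residues(proteins)
  if (length(scores) != nrow(res)) {
    abort(paste0("score count (", length(scores), ") != residue count (", nrow(res), ")"))
  }
  if (any(scores < 0 | scores > 1)) abort("scores must lie in [0, 1]")
  out <- data.frame(
    protein_id = res$protein_id,
    residue_number = res$residue_number,
    amino_acid = res$amino_acid,
    probability = signif(scores, 6),
    binary_call = classify(scores, tau)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path Path to a score TSV.
#' @return A tibble with columns `protein_id`, `residue_number`,
#'   `amino_acid`, `probability`, `binary_call`.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              colClasses = c("character", "integer", "character",
                                             "numeric", "integer")))
}
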