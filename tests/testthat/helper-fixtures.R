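# Shared fixtures: small in-code datasets and file writers.

random_sequence <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

# a tiny labelled dataset with hand-set profiles (no generator involved)
tiny_labelled_dataset <- function() {
  proteins <- efold_dataset(
    c("p1", "p2"),
    c("ACDEFGH", "KLMNP"),
    labels = list(c(0L, 1L, 1L, 0L, 0L, 0L, 1L), c(0L, 0L, 1L, 1L, 0L))
  )
  res <- residues(proteins)
  profiles <- tibble::tibble(
    protein_id = res$protein_id,
    residue_number = res$residue_number,
    dyna = seq_len(nrow(res)) / nrow(res),
    side = rev(seq_len(nrow(res))) / nrow(res),
    helix = rep(0.3, nrow(res)),
    strand = sin(seq_len(nrow(res))),
    coil = cos(seq_len(nrow(res)))
  )
  list(proteins = proteins, profiles = profiles)
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal classic-format DSSP text. ACC occupies columns 35-38, the amino
# acid column 14, chain column 12, residue number columns 6-10.
dssp_fixture_lines <- function(rows) {
  hdr <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "REFERENCE  synthetic fixture",
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
           "    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA")
  )
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (r$aa == "!") {
      sprintf("%5d      %s %s", i, " ", "!")
    } else {
      sprintf("%5d%5d %s %s%20s%4d", i, r$resno, r$chain, r$aa, "", r$acc)
    }
  }, character(1))
  c(hdr, body)
}
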