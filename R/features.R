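# Names of the 25 feature columns: 5 channels x window offsets -2..+2,
# concatenated in the fixed channel order dyna, side, helix, strand, coil.
feature_names <- function() {
  offs <- c("m2", "m1", "0", "p1", "p2")
  as.vector(vapply(PROFILE_CHANNELS, function(ch) paste(ch, offs, sep = "_"),
                   character(5)))
}

#' Read / write per-residue profile tables
#'
#' Profile files are long-format TSVs with header `protein_id`,
#' `residue_number`, `channel`, `value`, where `channel` is one of `dyna`,
#' `side`, `helix`, `strand`, `coil`. In memory the package uses the wide
#' form: one row per residue, one column per channel.
#'
#' @param path Path to a profile TSV.
#' @return `read_profiles()`: a wide tibble with columns `protein_id`,
#'   `residue_number` and the five channels.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  long <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      colClasses = c("character", "integer",
                                                     "character", "numeric")))
  bad <- setdiff(unique(long$channel), PROFILE_CHANNELS)
  if (length(bad) > 0) abort(paste0("unknown profile channel(s): ", paste(bad, collapse = ", ")))
  wide <- tidyr::pivot_wider(long, names_from = "channel", values_from = "value")
  missing <- setdiff(PROFILE_CHANNELS, names(wide))
  if (length(missing) > 0) abort(paste0("missing channel(s): ", paste(missing, collapse = ", ")))
  arrange(wide, .data$protein_id, .data$residue_number)[,
    c("protein_id", "residue_number", PROFILE_CHANNELS)]
}

#' @rdname read_profiles
#' @param profiles A wide profile tibble.
#' @export
write_profiles <- function(profiles, path) {
  long <- tidyr::pivot_longer(profiles, all_of(PROFILE_CHANNELS),
                              names_to = "channel", values_to = "value")
  utils::write.table(as.data.frame(long), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# One-hot window encoding of position i (1-based) of a sequence: for each
# window offset -w..+w (clamped to the termini) a 20-column block over the
# canonical alphabet. Non-canonical letters (X, B, Z) get the neutral
# encoding 1/20 in every column of their block.
encode_window <- function(letters_vec, i, w) {
  L <- length(letters_vec)
  idx <- pmin(pmax(i + (-w:w), 1L), L)
  out <- numeric((2L * w + 1L) * 20L)
  for (k in seq_along(idx)) {
    aa <- letters_vec[[idx[[k]]]]
    block <- (k - 1L) * 20L
    j <- match(aa, AA_ALPHABET)
    if (is.na(j)) {
      out[block + seq_len(20L)] <- 1 / 20
    } else {
      out[block + j] <- 1
    }
  }
  out
}

# Windowed one-hot design matrix for whole sequences (rows: residues in
# dataset order). Used by both training and prediction of the profile model.
window_design <- function(proteins, w) {
  rows <- map(proteins$sequence, function(s) {
    lv <- strsplit(s, "")[[1]]
    t(vapply(seq_along(lv), function(i) encode_window(lv, i, w),
             numeric((2L * w + 1L) * 20L)))
  })
  do.call(rbind, rows)
}

#' Train a per-channel linear profile predictor
#'
#' Fits, independently for each of the five profile channels, an ordinary
#' least-squares linear regression from a windowed one-hot encoding of the
#' amino-acid sequence (window half-width `w_p`, clamp-padded at the termini)
#' to the observed per-residue channel values. When the design is rank
#' deficient the minimum-norm least-squares solution is returned and a
#' warning is emitted.
#'
#' @param proteins A dataset tibble (see [efold_dataset()]).
#' @param profiles A wide profile tibble aligned to `proteins` (one row per
#'   residue; see [read_profiles()]).
#' @param w_p Window half-width of the sequence context (default 5, i.e. an
#'   11-residue window).
#' @return An object of class `profile_predictor`: the per-channel weight
#'   vectors (intercept first) plus the window half-width.
#' @export
train_profile_predictor <- function(proteins, profiles, w_p = 5) {
  validate_dataset(proteins)
  profiles <- check_profiles_aligned(proteins, profiles)
  X <- cbind(1, window_design(proteins, w_p))
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[[1]]
  pos <- sv$d > tol
  # every one-hot block sums to the intercept column, so the design always
  # loses one rank per window position; only a deficit beyond that signals a
  # genuinely degenerate input (too few residues, single-letter sequences)
  structural_rank <- 1L + (2L * w_p + 1L) * 19L
  if (nrow(X) < ncol(X) || sum(pos) < min(nrow(X), structural_rank)) {
    warn("rank-deficient profile design; returning minimum-norm solution")
  }
  # pseudoinverse applied per channel: beta = V D^+ U' y
  coefs <- map(PROFILE_CHANNELS, function(ch) {
    y <- profiles[[ch]]
    sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  })
  structure(
    list(w = as.integer(w_p), coef = setNames(map(coefs, as.numeric), PROFILE_CHANNELS)),
    class = "profile_predictor"
  )
}

#' @export
print.profile_predictor <- function(x, ...) {
  cat("<profile_predictor> window half-width", x$w,
      "| channels:", paste(names(x$coef), collapse = ", "), "\n")
  invisible(x)
}

#' Predict the five profile channels from sequence
#'
#' @param proteins A dataset tibble.
#' @param predictor A fitted [train_profile_predictor()] object.
#' @return A wide profile tibble (raw, unnormalized values).
#' @export
predict_profiles <- function(proteins, predictor) {
  validate_dataset(proteins)
  stopifnot(inherits(predictor, "profile_predictor"))
  X <- cbind(1, window_design(proteins, predictor$w))
  res <- residues(proteins)
  out <- tibble(protein_id = res$protein_id, residue_number = res$residue_number)
  for (ch in PROFILE_CHANNELS) out[[ch]] <- as.numeric(X %*% predictor$coef[[ch]])
  out
}

#' Shift values linearly onto \[0, 1\]
#'
#' Applies `(v - min) / (max - min)` to one per-residue value vector. A
#' degenerate (constant) vector maps to the constant 0.5, keeping values
#' centred in the target range.
#'
#' @param values Numeric vector, length >= 1.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_shift <- function(values) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  rng <- range(values)
  if (rng[[1]] == rng[[2]]) return(rep(0.5, length(values)))
  (values - rng[[1]]) / (rng[[2]] - rng[[1]])
}

#' Normalize profile channels per protein
#'
#' By default only the backbone-dynamics channel (`dyna`) is min-max shifted
#' to \[0, 1\] within each sequence; the other channels pass through
#' unchanged. Set `channels = PROFILE_CHANNELS` internally via
#' `normalize_all = TRUE` to shift every channel.
#'
#' @param profiles A wide profile tibble.
#' @param normalize_all Shift all five channels instead of `dyna` only.
#' @return The profile tibble with shifted values.
#' @export
normalize_profiles <- function(profiles, normalize_all = FALSE) {
  chans <- if (normalize_all) PROFILE_CHANNELS else "dyna"
  profiles |>
    group_by(.data$protein_id) |>
    mutate(across(all_of(chans), minmax_shift)) |>
    ungroup()
}

#' Assemble the windowed feature vector of one residue
#'
#' Concatenates, in the fixed channel order `dyna`, `side`, `helix`,
#' `strand`, `coil`, each channel's values at window positions i-2 .. i+2.
#' Window positions outside the sequence clamp to the terminal residue's
#' value, so the result always has exactly 25 dimensions.
#'
#' @param profile_matrix Numeric matrix (residues x 5 channels, channel order
#'   fixed) for one protein.
#' @param i Residue index, 1-based.
#' @return Numeric vector of length 25.
#' @export
assemble_features <- function(profile_matrix, i) {
  L <- nrow(profile_matrix)
  if (i < 1 || i > L) abort(paste0("residue index out of range: ", i))
  idx <- pmin(pmax(i + (-2:2), 1L), L)
  as.vector(profile_matrix[idx, ])  # column-major: channel blocks of 5
}

check_profiles_aligned <- function(proteins, profiles) {
  res <- residues(proteins)
  profiles <- arrange(profiles,
                      match(.data$protein_id, proteins$id), .data$residue_number)
  if (nrow(profiles) != nrow(res) ||
      !identical(profiles$protein_id, res$protein_id) ||
      !identical(as.integer(profiles$residue_number), as.integer(res$residue_number))) {
    abort("profiles do not align 1:1 with dataset residues")
  }
  profiles
}

#' Build the feature matrix of a whole dataset
#'
#' One row per residue across all proteins, in dataset order (protein order,
#' then residue order). Columns are the 25 window features named
#' `<channel>_<offset>` with offsets `m2, m1, 0, p1, p2`, preceded by
#' `protein_id`, `residue_number` and (when the dataset is labelled)
#' `label`. The `dyna` channel is min-max shifted per sequence before
#' windowing (see [normalize_profiles()]).
#'
#' @param proteins A dataset tibble; must carry labels unless
#'   `require_labels = FALSE`.
#' @param profiles A wide profile tibble aligned to `proteins`.
#' @param normalize_all Min-max shift all channels, not only `dyna`.
#' @param require_labels Error when the dataset is unlabelled (default TRUE).
#' @return A tibble of features (and labels) as described.
#' @export
featurize_dataset <- function(proteins, profiles, normalize_all = FALSE,
                              require_labels = TRUE) {
  validate_dataset(proteins)
  if (require_labels && !"labels" %in% names(proteins)) {
    abort("dataset has no labels; pass require_labels = FALSE to featurize anyway")
  }
  profiles <- check_profiles_aligned(proteins, profiles)
  profiles <- normalize_profiles(profiles, normalize_all = normalize_all)
  feats <- map(proteins$id, function(pid) {
    pm <- as.matrix(profiles[profiles$protein_id == pid, PROFILE_CHANNELS])
    t(vapply(seq_len(nrow(pm)), function(i) assemble_features(pm, i), numeric(25)))
  })
  X <- do.call(rbind, feats)
  colnames(X) <- feature_names()
  res <- residues(proteins)
  out <- tibble(protein_id = res$protein_id, residue_number = res$residue_number)
  if ("labels" %in% names(proteins)) out$label <- res$label
  bind_cols_safe(out, as_tibble(X))
}

bind_cols_safe <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  for (nm in names(b)) a[[nm]] <- b[[nm]]
  a
}

# Extract the bare 25-column numeric matrix from a feature tibble.
feature_matrix <- function(features) {
  fn <- feature_names()
  missing <- setdiff(fn, names(features))
  if (length(missing) > 0) abort(paste0("missing feature column(s): ", paste(missing, collapse = ", ")))
  as.matrix(features[, fn])
}
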