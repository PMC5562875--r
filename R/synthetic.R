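## Synthetic fixture generator: labelled datasets with the statistical shape
## of curated pulsed-labelling HDX training data (30 proteins of 56-164
## residues, median length ~121, ~14% early-folding residues in contiguous
## runs, five per-residue profile channels carrying the label signal), plus
## idealized backbone structures and score/label sets of known AUC.

# Kyte-Doolittle hydropathy, rescaled to roughly [-0.5, 0.5]; used as the
# amino-acid-dependent offset of the latent foldability track (hydrophobic
# residues are more likely to fold early).
KD_OFFSET <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
) / 9

#' Configuration of the synthetic dataset generator
#'
#' Defaults emulate the composition of curated pulsed-labelling HDX training
#' data: 30 proteins with lengths in 56-164 (median about 121) and an
#' early-folding residue fraction of about 0.142 (482 of 3398 residues).
#'
#' @param n_proteins Number of proteins (default 30).
#' @param length_min,length_max Sequence length bounds (defaults 56, 164).
#' @param length_median Target median length (default 121).
#' @param early_fraction Target fraction of positive residues (default
#'   0.142).
#' @param signal Strength of the label signal carried by the profile
#'   channels; 0 makes the channels pure noise (default 1).
#' @param noise_sd Standard deviation of the additive channel noise
#'   (default 0.25).
#' @param smooth_window Moving-average window of the latent foldability
#'   track (default 7).
#' @param min_run Minimum length of a positive run; shorter runs are dropped
#'   (default 3).
#' @param seed Random seed (integer) or NULL.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 30, length_min = 56,
                             length_max = 164, length_median = 121,
                             early_fraction = 0.142, signal = 1,
                             noise_sd = 0.25, smooth_window = 7,
                             min_run = 3, seed = NULL) {
  if (early_fraction <= 0 || early_fraction >= 1) {
    abort("early_fraction must lie strictly between 0 and 1")
  }
  if (!(length_min <= length_median && length_median <= length_max)) {
    abort("need length_min <= length_median <= length_max")
  }
  if (n_proteins < 1) abort("n_proteins must be >= 1")
  structure(
    list(n_proteins = n_proteins, length_min = length_min,
         length_max = length_max, length_median = length_median,
         early_fraction = early_fraction, signal = signal,
         noise_sd = noise_sd, smooth_window = smooth_window,
         min_run = min_run, seed = seed),
    class = "synthetic_config"
  )
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - w %/% 2); hi <- min(n, i + w %/% 2)
    mean(x[lo:hi])
  }, numeric(1))
}

# Monotone channel transforms: distinct shapes so the five channels are not
# copies of one another, while all remaining increasing in the latent track.
CHANNEL_TRANSFORMS <- list(
  dyna = function(z) z,
  side = function(z) tanh(z),
  helix = function(z) 1 / (1 + exp(-z)),
  strand = function(z) z / (1 + abs(z)),
  coil = function(z) asinh(z)
)

#' Generate a labelled synthetic dataset with per-residue profiles
#'
#' Per protein: a random sequence with Swiss-Prot-like amino-acid
#' frequencies; a latent smooth "foldability" track (moving-average-smoothed
#' Gaussian noise plus hydropathy-dependent amino-acid offsets);
#' early-folding labels on the contiguous runs where the track exceeds the
#' dataset-wide quantile matched to `early_fraction` (runs shorter than
#' `min_run` dropped, mimicking secondary-structure-element positives); and
#' five profile channels, each a distinct noisy monotone transform of the
#' latent track scaled by `signal`, so the planted signal is learnable from
#' the channels and absent when `signal = 0`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `proteins` (labelled dataset tibble), `profiles`
#'   (wide profile tibble), `latent` (list of latent tracks) and `params`
#'   (the generating constants).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_proteins
  lens <- sample_lengths(n, config)
  ids <- sprintf("syn%03d", seq_len(n))
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = AA_FREQS), collapse = "")
  }, character(1))
  latent <- map(seq_len(n), function(i) {
    lv <- strsplit(seqs[[i]], "")[[1]]
    z <- moving_average(rnorm(lens[[i]]), config$smooth_window)
    # smoothed hydropathy: early folding reflects the local segment's
    # composition, not single residues, and keeps the track's runs contiguous
    z <- as.numeric(scale(z)) +
      moving_average(unname(KD_OFFSET[lv]), config$smooth_window)
    z
  })
  thr <- match_threshold(latent, config$early_fraction, config$min_run)
  labels <- map(latent, function(z) drop_short_runs(as.integer(z > thr), config$min_run))
  proteins <- efold_dataset(ids, seqs, labels)
  res <- residues(proteins)
  profiles <- tibble(protein_id = res$protein_id,
                     residue_number = res$residue_number)
  zall <- unlist(latent)
  for (ch in PROFILE_CHANNELS) {
    f <- CHANNEL_TRANSFORMS[[ch]]
    profiles[[ch]] <- 0.5 + 0.3 * config$signal * f(zall) +
      rnorm(length(zall), sd = config$noise_sd)
  }
  list(proteins = proteins, profiles = profiles, latent = latent,
       params = list(threshold = thr, aa_offset = KD_OFFSET,
                     transforms = names(CHANNEL_TRANSFORMS),
                     config = config))
}

# lengths from a scaled beta so the median sits near the configured target
# while respecting the bounds
sample_lengths <- function(n, config) {
  span <- config$length_max - config$length_min
  m <- (config$length_median - config$length_min) / span
  a <- 2.2
  b <- if (m >= 0.999) 0.01 else a * (1 - m) / m  # beta mean at target median
  config$length_min + round(span * stats::rbeta(n, a, b))
}

# Threshold on the latent track matched to the target positive fraction:
# because runs shorter than min_run are dropped, the naive quantile
# undershoots, so the cut level is chosen (over a quantile grid) to make the
# realized post-filter fraction closest to the target. Deterministic given
# the latent tracks.
match_threshold <- function(latent, target, min_run) {
  all_z <- unlist(latent)
  qs <- quantile(all_z, seq(max(0, 1 - 2.5 * target), 1 - 0.5 * target,
                            length.out = 201), names = FALSE)
  realized <- vapply(qs, function(thr) {
    mean(unlist(lapply(latent, function(z)
      drop_short_runs(as.integer(z > thr), min_run))))
  }, numeric(1))
  qs[[which.min(abs(realized - target))]]
}

drop_short_runs <- function(lab, min_run) {
  r <- rle(lab)
  r$values[r$values == 1L & r$lengths < min_run] <- 0L
  inverse.rle(r)
}

#' Write a synthetic dataset to disk in the pipeline's file formats
#'
#' Writes `sequences.fasta`, `annotations.tsv` and `profiles.tsv` under
#' `dir`.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    annotations = file.path(dir, "annotations.tsv"),
    profiles = file.path(dir, "profiles.tsv")
  )
  write_fasta(dataset$proteins, paths[["fasta"]])
  write_annotations(dataset$proteins, paths[["annotations"]])
  write_profiles(dataset$profiles, paths[["profiles"]])
  invisible(paths)
}

#' Generate an idealized backbone structure fixture
#'
#' Builds a poly-alanine backbone (atoms N, CA, C, O and amide H per
#' residue) along either an ideal alpha-helical trace (2.3 A radius, 1.5 A
#' rise, 100 degrees per residue) or an extended zigzag strand trace with
#' 3.8 A between consecutive CA atoms. The helix packs heavy atoms much closer
#' together, so its contact S2 values exceed the extended chain's.
#'
#' @param n_residues Number of residues (>= 2).
#' @param geometry `"ideal_helix"` or `"extended"`.
#' @return An atom tibble usable with [contact_s2()].
#' @export
generate_structure_fixture <- function(n_residues,
                                       geometry = c("ideal_helix", "extended")) {
  geometry <- match.arg(geometry)
  if (n_residues < 2) abort("need at least 2 residues")
  i <- seq_len(n_residues)
  ca <- if (geometry == "ideal_helix") {
    ang <- (i - 1) * 100 * pi / 180
    cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (i - 1))
  } else {
    # beta-strand-like zigzag (a perfectly straight trace would make the
    # amide-H bisector construction degenerate); CA-CA spacing exactly 3.8 A
    cbind(0.5 * (-1)^i, 0, sqrt(3.8^2 - 1) * (i - 1))
  }
  # local chain directions (last residue reuses the previous one)
  d <- rbind(ca[-1, , drop = FALSE] - ca[-n_residues, , drop = FALSE],
             ca[n_residues, ] - ca[n_residues - 1, ])
  d <- d / sqrt(rowSums(d^2))
  # carbonyl C sits ~40% along CA(i)->CA(i+1); N sits ~38% back from CA(i)
  cc <- ca + 1.5 * d
  nn <- ca - 1.45 * rbind(d[1, ], d[-n_residues, , drop = FALSE])
  perp <- t(apply(d, 1, function(v) {
    ref <- if (abs(v[[3]]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- c(v[[2]] * ref[[3]] - v[[3]] * ref[[2]],
           v[[3]] * ref[[1]] - v[[1]] * ref[[3]],
           v[[1]] * ref[[2]] - v[[2]] * ref[[1]])
    p / sqrt(sum(p^2))
  }))
  oo <- cc + 1.23 * perp
  hh <- t(vapply(i, function(k) {
    # the first residue has no real preceding carbonyl; extrapolate one
    # slightly off-axis so the N-H bisector direction stays well defined
    cprev <- if (k == 1) nn[1, ] - 1.3 * d[1, ] + 0.5 * perp[1, ] else cc[k - 1, ]
    amide_h_position(nn[k, ], ca[k, ], cprev)
  }, numeric(3)))
  per_res <- function(xyz, atom, element) {
    tibble(chain = "A", residue_number = i, residue_type = "ALA",
           atom_name = atom, element = element,
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  arrange(bind_rows(
    per_res(nn, "N", "N"), per_res(ca, "CA", "C"), per_res(cc, "C", "C"),
    per_res(oo, "O", "O"), per_res(hh, "H", "H")
  ), .data$residue_number, match(.data$atom_name, c("N", "CA", "C", "O", "H")))
}

#' Generate scores and labels with a known expected AUC
#'
#' Binormal model: negative scores are N(0, 1), positive scores are
#' N(mu, 1) with `mu = sqrt(2) * qnorm(auc_target)`, whose population AUC is
#' exactly `auc_target`. An `auc_target` of 1 uses fully separated uniform
#' blocks instead.
#'
#' @param n Number of scores.
#' @param auc_target Expected AUC in \[0.5, 1\].
#' @param seed Random seed or NULL.
#' @param prevalence Positive-class fraction (default 0.142).
#' @return A tibble with columns `score` and `label`.
#' @export
generate_labelled_scores <- function(n, auc_target, seed = NULL,
                                     prevalence = 0.142) {
  if (auc_target < 0.5 || auc_target > 1) abort("auc_target must lie in [0.5, 1]")
  if (!is.null(seed)) set.seed(seed)
  label <- rbinom(n, 1, prevalence)
  if (length(unique(label)) < 2) abort("degenerate draw: single class; enlarge n")
  score <- if (auc_target >= 1) {
    ifelse(label == 1L, runif(n, 0.6, 1), runif(n, 0, 0.4))
  } else {
    mu <- sqrt(2) * qnorm(auc_target)
    rnorm(n) + mu * label
  }
  tibble(score = score, label = as.integer(label))
}

#' Generate linear-profile training data with known coefficients
#'
#' Test harness for the profile predictor: draws random sequences, draws a
#' ground-truth weight vector per channel over the windowed one-hot encoding
#' (block-centered, zero intercept, so the weights are identifiable up to
#' the encoding's null space) and emits targets `X beta + noise`.
#'
#' @param n_sequences Number of sequences (default 50).
#' @param length Sequence length (default 60).
#' @param w_p Window half-width (default 2).
#' @param noise_sd Target noise standard deviation (default 0.05).
#' @param seed Random seed or NULL.
#' @return A list with `proteins`, `profiles` and `coef` (the true
#'   per-channel weight vectors, intercept first).
#' @export
generate_linear_profile_data <- function(n_sequences = 50, length = 60,
                                         w_p = 2, noise_sd = 0.05,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n_sequences), function(i) {
    paste(sample(AA_ALPHABET, length, replace = TRUE, prob = AA_FREQS),
          collapse = "")
  }, character(1))
  proteins <- efold_dataset(sprintf("lin%03d", seq_len(n_sequences)), seqs)
  X <- cbind(1, window_design(proteins, w_p))
  p <- (2 * w_p + 1) * 20
  true_coef <- map(PROFILE_CHANNELS, function(ch) {
    b <- rnorm(p, sd = 0.3)
    # center each 20-column block so the weights avoid the one-hot null space
    for (k in seq_len(2 * w_p + 1)) {
      idx <- (k - 1) * 20 + seq_len(20)
      b[idx] <- b[idx] - mean(b[idx])
    }
    c(0, b)
  })
  names(true_coef) <- PROFILE_CHANNELS
  res <- residues(proteins)
  profiles <- tibble(protein_id = res$protein_id,
                     residue_number = res$residue_number)
  for (ch in PROFILE_CHANNELS) {
    profiles[[ch]] <- as.numeric(X %*% true_coef[[ch]]) +
      rnorm(nrow(X), sd = noise_sd)
  }
  list(proteins = proteins, profiles = profiles, coef = true_coef, w_p = w_p)
}
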