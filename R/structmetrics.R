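## Structure-derived quantities (RSA, contact-S2) and the statistical
## machinery used to compare score distributions between residue groups.

# Maximum accessible surface areas (A^2) per residue type.
# "sander": Rost & Sander (1994); "tien": Tien et al. (2013), theoretical.
MAX_ASA <- list(
  sander = c(A = 106, R = 248, N = 157, D = 163, C = 135, Q = 198, E = 194,
             G = 84,  H = 184, I = 169, L = 164, K = 205, M = 188, F = 197,
             P = 136, S = 130, T = 142, W = 227, Y = 222, V = 142),
  tien   = c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
             G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
             P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
)

#' Parse a classic-format DSSP output file
#'
#' Reads the per-residue block of a DSSP file (the lines after the
#' `#  RESIDUE AA STRUCTURE ...` header) and extracts chain, residue number,
#' amino acid and the solvent-accessible surface area (`ACC`, in A^2).
#' Chain-break marker lines (amino acid `!`) are skipped.
#'
#' @param path Path to a DSSP file.
#' @return A tibble with columns `chain`, `residue_number`, `amino_acid`,
#'   `acc`.
#' @export
parse_dssp <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) != 1) abort(paste0("malformed DSSP header in ", path))
  body <- lines[seq(hdr + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  tibble(
    chain = trimws(substr(body, 12, 12)),
    residue_number = as.integer(trimws(substr(body, 6, 10))),
    amino_acid = substr(body, 14, 14),
    acc = as.numeric(trimws(substr(body, 35, 38)))
  )
}

#' Relative solvent accessibility
#'
#' Divides a DSSP accessible surface area by the residue type's maximum
#' accessible area. Values above 1 (possible for unusual conformations) are
#' not clipped; a warning flags them.
#'
#' @param acc Accessible surface area(s), A^2.
#' @param amino_acid One-letter code(s), same length as `acc`.
#' @param scale `"sander"` (Rost & Sander, default) or `"tien"`.
#' @return Numeric RSA values.
#' @export
rsa <- function(acc, amino_acid, scale = c("sander", "tien")) {
  scale <- match.arg(scale)
  stopifnot(all(acc >= 0))
  maxasa <- MAX_ASA[[scale]][amino_acid]
  if (anyNA(maxasa)) {
    abort(paste0("unknown residue type(s): ",
                 paste(unique(amino_acid[is.na(maxasa)]), collapse = ", ")))
  }
  out <- acc / unname(maxasa)
  if (any(out > 1)) warn("RSA values above 1 present (not clipped)")
  out
}

#' Contact-model order-parameter settings
#'
#' The contact S2 of residue i is
#' `tanh(b * (sum_k w * exp(-d_kH / r0) + sum_k exp(-d_kO / r0))) - c`,
#' where the sums run over heavy atoms of residues outside the exclusion set
#' (residues i and i-1), `d_kH` is the distance to the backbone amide proton
#' of residue i and `d_kO` the distance to the carbonyl oxygen of residue
#' i-1. The default constants follow the contact-model literature and are
#' fully configurable.
#'
#' @param b Overall scale (> 0).
#' @param w Weight of the amide-proton contact path.
#' @param r0 Exponential decay length, A (> 0).
#' @param c Offset subtracted from the tanh.
#' @return A list of parameters for [contact_s2()].
#' @export
contact_s2_params <- function(b = 0.8, w = 0.8, r0 = 1, c = 0.1) {
  stopifnot(b > 0, r0 > 0)
  list(b = b, w = w, r0 = r0, c = c)
}

#' Per-residue contact S2 from atomic coordinates
#'
#' Estimates backbone rigidity from exponentially weighted counts of heavy
#' atoms near two probes: the backbone amide proton of each residue and the
#' carbonyl oxygen of the preceding residue. When the structure lacks amide
#' hydrogens (typical for X-ray models) the proton is placed geometrically
#' from N, CA and the previous residue's carbonyl carbon. The first residue
#' of each chain, and residues with missing probe atoms, get `NA`.
#'
#' @param structure An atom tibble with columns `chain`, `residue_number`,
#'   `residue_type`, `atom_name`, `element`, `x`, `y`, `z` (see
#'   [read_structure()] or [generate_structure_fixture()]).
#' @param params Parameter list from [contact_s2_params()].
#' @return A tibble with columns `chain`, `residue_number`, `s2`.
#' @export
contact_s2 <- function(structure, params = contact_s2_params()) {
  stopifnot(all(c("chain", "residue_number", "atom_name", "element",
                  "x", "y", "z") %in% names(structure)))
  if (!all(is.finite(c(structure$x, structure$y, structure$z)))) {
    abort("non-finite coordinates")
  }
  heavy <- structure[structure$element != "H", , drop = FALSE]
  hxyz <- as.matrix(heavy[, c("x", "y", "z")])
  res_key <- paste(structure$chain, structure$residue_number)
  heavy_key <- paste(heavy$chain, heavy$residue_number)

  res_tab <- distinct(structure[, c("chain", "residue_number")])
  res_tab <- arrange(res_tab, .data$chain, .data$residue_number)
  out <- numeric(nrow(res_tab))
  atom_xyz <- function(chain, resno, name) {
    sel <- structure$chain == chain & structure$residue_number == resno &
      structure$atom_name == name
    if (!any(sel)) return(NULL)
    as.numeric(structure[which(sel)[[1]], c("x", "y", "z")])
  }
  for (r in seq_len(nrow(res_tab))) {
    ch <- res_tab$chain[[r]]
    i <- res_tab$residue_number[[r]]
    prev_exists <- any(structure$chain == ch & structure$residue_number == i - 1)
    if (!prev_exists) {
      out[[r]] <- NA_real_
      next
    }
    h <- atom_xyz(ch, i, "H")
    if (is.null(h)) {
      nn <- atom_xyz(ch, i, "N"); ca <- atom_xyz(ch, i, "CA")
      cp <- atom_xyz(ch, i - 1, "C")
      h <- if (!is.null(nn) && !is.null(ca) && !is.null(cp)) {
        amide_h_position(nn, ca, cp)
      } else NULL
    }
    o <- atom_xyz(ch, i - 1, "O")
    if (is.null(h) || is.null(o)) {
      out[[r]] <- NA_real_
      next
    }
    excl <- heavy_key %in% paste(ch, c(i, i - 1))
    ext <- hxyz[!excl, , drop = FALSE]
    if (nrow(ext) == 0) {
      out[[r]] <- tanh(0) - params$c
      next
    }
    dh <- sqrt(rowSums((ext - matrix(h, nrow(ext), 3, byrow = TRUE))^2))
    do <- sqrt(rowSums((ext - matrix(o, nrow(ext), 3, byrow = TRUE))^2))
    s <- params$w * sum(exp(-dh / params$r0)) + sum(exp(-do / params$r0))
    out[[r]] <- tanh(params$b * s) - params$c
  }
  tibble(chain = res_tab$chain, residue_number = res_tab$residue_number, s2 = out)
}

# Standard geometric placement of a backbone amide proton: 1.01 A from N,
# along the bisector pointing away from CA and the previous carbonyl carbon.
amide_h_position <- function(n, ca, c_prev) {
  u <- (n - ca) / sqrt(sum((n - ca)^2))
  v <- (n - c_prev) / sqrt(sum((n - c_prev)^2))
  b <- u + v
  n + 1.01 * b / sqrt(sum(b^2))
}

#' Read a PDB coordinate file into an atom tibble
#'
#' Thin wrapper over `bio3d::read.pdb()` producing the atom-table layout the
#' structure metrics consume.
#'
#' @param path Path to a PDB file.
#' @return An atom tibble (see [contact_s2()]).
#' @export
read_structure <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB files requires the bio3d package")
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(trimws(a$elety), 1, 1)
  }
  tibble(
    chain = as.character(a$chain),
    residue_number = as.integer(a$resno),
    residue_type = as.character(a$resid),
    atom_name = trimws(as.character(a$elety)),
    element = trimws(as.character(elem)),
    x = a$x, y = a$y, z = a$z
  )
}

#' Remove per-amino-acid composition bias from a value distribution
#'
#' Subtracts, for each amino-acid type, the median of that type's values
#' (over all groups pooled) from each value, then adds back the global
#' median so the corrected values stay on the original scale. After
#' correction every amino-acid type has the same median (the global
#' pre-correction median), so between-group comparisons are no longer driven
#' by amino-acid composition. The operation is idempotent.
#'
#' @param values Numeric vector.
#' @param amino_acids Character vector of types aligned with `values`.
#' @return Corrected numeric vector, same order as the input.
#' @export
bias_correct <- function(values, amino_acids) {
  if (length(values) == 0) abort("empty input")
  stopifnot(length(values) == length(amino_acids))
  med_type <- tapply(values, amino_acids, median)
  as.numeric(values - med_type[amino_acids] + median(values))
}

#' Two-sided Wilcoxon rank-sum test p-value
#'
#' Uses the exact null distribution when the combined sample size is at most
#' 20 and there are no ties, and the normal approximation with continuity
#' and tie correction otherwise (the default behaviour family of
#' `wilcox.test`).
#'
#' @param x,y Numeric samples (both non-empty).
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, clipped to 1, with the
#' output in the input order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1 | !is.finite(pvalues))) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p Numeric p-values.
#' @return Character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare value distributions between residue groups
#'
#' For every pair of groups, computes the two-sided Wilcoxon rank-sum
#' p-value, adjusts across all pairs with Benjamini-Hochberg and attaches
#' significance stars. Optionally removes amino-acid composition bias first
#' (see [bias_correct()], applied to the pooled values). Also returns
#' per-group distribution summaries, including the notch interval
#' `median +/- 1.57 * IQR / sqrt(n)`.
#'
#' @param data A data frame with one row per residue.
#' @param value Name of the numeric value column (default `"value"`).
#' @param group Name of the grouping column (default `"group"`).
#' @param amino_acid Name of the amino-acid column, required when
#'   `bias_correction = TRUE`.
#' @param bias_correction Apply the per-amino-acid bias correction before
#'   testing (default FALSE).
#' @return A list with tibbles `comparisons` (`group1, group2, n1, n2,
#'   p_value, p_adjusted, stars`) and `summaries` (`group, n, mean, median,
#'   q1, q3, notch_low, notch_high`).
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           amino_acid = NULL, bias_correction = FALSE) {
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  v <- data[[value]]
  g <- as.character(data[[group]])
  if (bias_correction) {
    if (is.null(amino_acid) || !amino_acid %in% names(data)) {
      abort("bias correction needs an amino-acid column")
    }
    v <- bias_correct(v, data[[amino_acid]])
  }
  groups <- unique(g)
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(table(g) < 1)) abort("every group needs at least one value")
  pairs <- utils::combn(groups, 2)
  comp <- map(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    tibble(group1 = g1, group2 = g2,
           n1 = sum(g == g1), n2 = sum(g == g2),
           p_value = wilcoxon_ranksum(v[g == g1], v[g == g2]))
  }) |> bind_rows()
  comp$p_adjusted <- adjust_bh(comp$p_value)
  comp$stars <- significance_stars(comp$p_adjusted)
  summaries <- tibble(group = groups) |>
    mutate(stats = map(.data$group, function(gg) {
      x <- v[g == gg]
      q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[[3]] - q[[1]]
      tibble(n = length(x), mean = mean(x), median = q[[2]],
             q1 = q[[1]], q3 = q[[3]],
             notch_low = q[[2]] - 1.57 * iqr / sqrt(length(x)),
             notch_high = q[[2]] + 1.57 * iqr / sqrt(length(x)))
    })) |>
    tidyr::unnest("stats")
  list(comparisons = comp, summaries = summaries)
}

#' Write a group-comparison report as TSV
#'
#' @param comparison A result of [compare_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(comparison, path) {
  utils::write.table(as.data.frame(comparison$comparisons), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
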