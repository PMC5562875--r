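test_that("parse_dssp reads residues and skips chain breaks", {
  rows <- data.frame(resno = c(1L, 2L, 0L, 10L), chain = c("A", "A", " ", "B"),
                     aa = c("M", "K", "!", "G"), acc = c(234L, 56L, 0L, 7L))
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(dssp_fixture_lines(rows), path)
  d <- parse_dssp(path)
  expect_equal(nrow(d), 3)
  expect_equal(d$acc, c(234, 56, 7))
  expect_equal(d$amino_acid, c("M", "K", "G"))
  expect_equal(d$chain, c("A", "A", "B"))
  expect_equal(d$residue_number, c(1L, 2L, 10L))
})

test_that("parse_dssp errors on missing files and malformed headers", {
  expect_error(parse_dssp(file.path(tempdir(), "none.dssp")), "not found")
  bad <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c("not", "a dssp file"), bad)
  expect_error(parse_dssp(bad), "malformed")
})

test_that("RSA divides by the max-ASA of the chosen scale", {
  expect_equal(rsa(0, "G"), 0)
  expect_equal(rsa(106, "A"), 1)
  expect_equal(rsa(53, "A"), 0.5)
  expect_equal(rsa(129, "A", scale = "tien"), 1)
  expect_error(rsa(10, "U"), "unknown residue.*U")
  expect_warning(over <- rsa(200, "A"), "above 1")
  expect_gt(over, 1)
})

# hand-built micro-structures for the contact model
micro_structure <- function(extra = NULL) {
  base <- tibble::tibble(
    chain = "A",
    residue_number = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    residue_type = "ALA",
    atom_name = c("N", "CA", "C", "O", "N", "CA", "C", "H"),
    element = c("N", "C", "C", "O", "N", "C", "C", "H"),
    x = c(0, 1.5, 2.4, 2.4, 3.3, 4.8, 5.7, 3.0),
    y = c(0, 0, 1.0, 2.23, 0.8, 0.8, 1.8, 1.75),
    z = 0
  )
  dplyr::bind_rows(base, extra)
}

test_that("contact S2 with no external heavy atoms equals -c", {
  s <- micro_structure()
  p <- contact_s2_params()
  out <- contact_s2(s, p)
  expect_true(is.na(out$s2[out$residue_number == 1]))  # no preceding residue
  expect_equal(out$s2[out$residue_number == 2], tanh(0) - p$c)
})

test_that("contact S2 matches the closed form for one atom at distance r0", {
  p <- contact_s2_params()
  s0 <- micro_structure()
  h <- as.numeric(s0[s0$atom_name == "H", c("x", "y", "z")])
  o <- as.numeric(s0[s0$residue_number == 1 & s0$atom_name == "O",
                     c("x", "y", "z")])
  # place a lone heavy atom equidistant (r0) from the amide H probe and the
  # carbonyl O probe: it sits on the perpendicular bisector plane
  mid <- (h + o) / 2
  d_ho <- sqrt(sum((h - o)^2))
  perp <- c(0, 0, 1)  # both probes lie in z = 0
  offset <- sqrt(p$r0^2 - (d_ho / 2)^2)
  atom <- tibble::tibble(chain = "A", residue_number = 99L,
                         residue_type = "ALA", atom_name = "CB", element = "C",
                         x = mid[1], y = mid[2], z = mid[3] + offset)
  out <- contact_s2(micro_structure(atom), p)
  expected <- tanh(p$b * (p$w + 1) * exp(-1)) - p$c
  expect_equal(out$s2[out$residue_number == 2], expected, tolerance = 1e-10)
})

test_that("moving an external atom farther never increases S2", {
  p <- contact_s2_params()
  dists <- c(1, 2, 4, 8)
  vals <- vapply(dists, function(dd) {
    atom <- tibble::tibble(chain = "A", residue_number = 99L,
                           residue_type = "ALA", atom_name = "CB",
                           element = "C", x = 3.0, y = 1.75, z = dd)
    out <- contact_s2(micro_structure(atom), p)
    out$s2[out$residue_number == 2]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # bounded above by 1 - c
  expect_true(all(vals < 1 - p$c))
})

test_that("hydrogens are excluded from the heavy-atom sums", {
  p <- contact_s2_params()
  hyd <- tibble::tibble(chain = "A", residue_number = 99L,
                        residue_type = "ALA", atom_name = "H1", element = "H",
                        x = 3.0, y = 1.75, z = 0.5)
  out <- contact_s2(micro_structure(hyd), p)
  expect_equal(out$s2[out$residue_number == 2], tanh(0) - p$c)
})

test_that("bias correction matches the stated formula and is idempotent", {
  values <- c(1, 3, 2, 4)
  aa <- c("A", "A", "C", "C")
  got <- bias_correct(values, aa)
  expect_equal(got, c(1.5, 3.5, 1.5, 3.5))
  # per-type medians all equal the global pre-correction median
  expect_equal(as.numeric(tapply(got, aa, median)), c(2.5, 2.5))
  expect_equal(bias_correct(got, aa), got)
  # single type: unchanged
  expect_equal(bias_correct(c(5, 7, 9), c("W", "W", "W")), c(5, 7, 9))
  expect_error(bias_correct(numeric(0), character(0)), "empty")

  set.seed(6)
  for (i in 1:20) {
    v <- rnorm(60)
    a <- sample(c("A", "L", "K", "S"), 60, replace = TRUE)
    corr <- bias_correct(v, a)
    meds <- tapply(corr, a, median)
    expect_equal(as.numeric(meds), rep(median(v), length(meds)))
    expect_equal(bias_correct(corr, a), corr)
  }
})

test_that("wilcoxon rank-sum gives exact small-sample p-values", {
  expect_equal(wilcoxon_ranksum(c(1, 2), c(3, 4)), 1 / 3)
  x <- c(0.3, 1.2, 2.5)
  expect_equal(wilcoxon_ranksum(x, x), 1)
  a <- c(1.1, 5.2, 2.2, 0.4); b <- c(3.3, 6.1, 0.9)
  expect_equal(wilcoxon_ranksum(a, b), wilcoxon_ranksum(b, a))
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("benjamini-hochberg matches the hand step-up computation", {
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.07, 5)), rep(0.07, 5))
  expect_true(all(adjust_bh(c(0.5, 0.01, 0.9)) >= c(0.5, 0.01, 0.9)))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance stars switch exactly at 0.05 / 0.01 / 0.001", {
  expect_equal(significance_stars(c(0.0009, 0.001, 0.009, 0.01, 0.049, 0.05)),
               c("***", "**", "**", "*", "*", ""))
})

test_that("group comparison flags separated groups and not identical ones", {
  x <- c(0.3, 0.5, 0.2, 0.8, 0.4)
  same <- data.frame(value = c(x, x), group = rep(c("g1", "g2"), each = 5))
  res <- compare_groups(same)
  expect_equal(res$comparisons$p_adjusted, 1)
  expect_equal(res$comparisons$stars, "")

  set.seed(8)
  sep <- data.frame(value = c(rnorm(50), rnorm(50, mean = 3)),
                    group = rep(c("lo", "hi"), each = 50))
  res2 <- compare_groups(sep)
  expect_equal(res2$comparisons$stars, "***")
  expect_equal(res2$summaries$n, c(50, 50))
  # notch interval is median +/- 1.57 IQR / sqrt(n)
  lo <- res2$summaries[res2$summaries$group == "lo", ]
  iqr <- lo$q3 - lo$q1
  expect_equal(lo$notch_high - lo$median, 1.57 * iqr / sqrt(50))
  expect_error(compare_groups(data.frame(value = 1:3, group = "only")),
               "2 groups")
})

test_that("bias-corrected comparison removes a pure composition effect", {
  # two groups whose difference comes entirely from amino-acid composition:
  # A-residues have high values, L-residues low, group 'a' is A-rich
  set.seed(9)
  aa <- c(rep("A", 60), rep("L", 60))
  value <- ifelse(aa == "A", 1, 0) + rnorm(120, sd = 0.05)
  group <- c(rep("a", 45), rep("b", 15), rep("a", 15), rep("b", 45))
  d <- data.frame(value = value, group = group, amino_acid = aa)
  raw <- compare_groups(d)
  corrected <- compare_groups(d, amino_acid = "amino_acid", bias_correction = TRUE)
  expect_lt(raw$comparisons$p_value, 0.001)
  expect_gt(corrected$comparisons$p_value, 0.05)
})
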