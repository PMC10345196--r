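long_df <- function(position, mut, score, wt = NULL) {
  d <- data.frame(position = position, mut = mut, score = score,
                  stringsAsFactors = FALSE)
  if (!is.null(wt)) d$wt <- wt
  d
}

test_that("ddG rescaling divides Rosetta units by 2.9 and clamps to 0-5", {
  raw <- score_matrix(long_df(c(1, 1, 1), c("G", "S", "W"),
                              c(5.8, -1.0, 20.3)),
                      kind = "ddG", provenance = "rosetta_raw")
  norm <- normalize_ddg(raw)
  expect_equal(norm$values["G", "1"], 2.0)          # 5.8 / 2.9
  expect_equal(norm$values["S", "1"], 0.0)          # clamped from below
  expect_equal(norm$values["W", "1"], 5.0)          # 20.3/2.9 = 7 -> 5
  expect_identical(norm$provenance, "kcal_mol")

  ## values already in kcal/mol are not divided again
  kcal <- score_matrix(long_df(1, "G", -1.0), kind = "ddG",
                       provenance = "kcal_mol")
  expect_equal(normalize_ddg(kcal)$values["G", "1"], 0.0)
})

test_that("normalization is idempotent and order-preserving", {
  set.seed(5)
  vals <- runif(2000, -10, 25)
  m <- score_matrix(long_df(rep(1:100, each = 20), rep(AA_ALPHABET, 100),
                            vals),
                    kind = "ddG", provenance = "rosetta_raw")
  f1 <- normalize_ddg(m)
  f2 <- normalize_ddg(f1)
  expect_identical(f1$values, f2$values)
  ## x <= y implies f(x) <= f(y)
  v1 <- f1$values[order(vals)]
  expect_true(all(diff(v1) >= 0))
})

test_that("non-finite ddG values are rejected naming the variant", {
  m <- score_matrix(long_df(c(3, 3), c("G", "S"), c(1, Inf)),
                    kind = "ddG", provenance = "rosetta_raw")
  expect_error(normalize_ddg(m), "3S")
})

test_that("residue averages are means over available substitutions", {
  m <- score_matrix(long_df(c(2, 2, 2, 5), c("A", "C", "D", "G"),
                            c(1, 2, 3, 4.2)),
                    kind = "ddG", provenance = "kcal_mol")
  expect_equal(residue_average(m, 2), 2.0)
  expect_equal(residue_average(m, 5), 4.2)
  expect_true(is.na(residue_average(m, 9)))

  set.seed(6)
  v <- runif(19, -6, 0)
  m2 <- score_matrix(long_df(rep(7, 19), setdiff(AA_ALPHABET, "A"), v),
                     kind = "ddE", provenance = "gemme")
  expect_equal(residue_average(m2, 7), mean(v))
})

test_that("neighbour averages pool the flanking positions", {
  m <- score_matrix(long_df(c(1, 1, 3, 3), c("A", "C", "A", "C"),
                            c(1, 3, 5, 7)),
                    kind = "ddG", provenance = "kcal_mol")
  expect_equal(neighbour_average(m, 2), 4.0)   # pooled mean of {1,3,5,7}

  ## chain terminus: only the single existing neighbour is used
  m2 <- score_matrix(long_df(c(2, 2), c("A", "C"), c(2, 4)),
                     kind = "ddG", provenance = "kcal_mol")
  expect_equal(neighbour_average(m2, 1), 3.0)
  expect_true(is.na(neighbour_average(m2, 5)))

  ## constant field: interior neighbour average is the constant
  mc <- score_matrix(long_df(rep(1:5, each = 3),
                             rep(c("A", "C", "D"), 5), rep(1.7, 15)),
                     kind = "ddG", provenance = "kcal_mol")
  expect_equal(neighbour_average(mc, 3), 1.7)
})

test_that("neighbour average never depends on the position's own values", {
  set.seed(7)
  base <- long_df(rep(1:5, each = 19),
                  rep(setdiff(AA_ALPHABET, "A"), 5), runif(95, -6, 0))
  m <- score_matrix(base, kind = "ddE", provenance = "gemme")
  before <- neighbour_average(m, 3)
  perturbed <- base
  perturbed$score[perturbed$position == 3] <- -6.9
  m2 <- score_matrix(perturbed, kind = "ddE", provenance = "gemme")
  expect_equal(neighbour_average(m2, 3), before)
})

test_that("score readers round-trip long, matrix and variant-label forms", {
  set.seed(8)
  tab <- data.frame(position = rep(1:4, each = 19),
                    wt = rep(c("A", "C", "D", "E"), each = 19),
                    mut = c(sapply(c("A", "C", "D", "E"),
                                   function(a) setdiff(AA_ALPHABET, a))),
                    score = round(runif(76, -6, 0), 4))
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE, quote = FALSE)
  m <- read_score_long(f, kind = "ddE", provenance = "gemme")
  expect_equal(sum(is.finite(m$values)), 76)
  expect_equal(m$values["C", "1"], tab$score[tab$position == 1 & tab$mut == "C"])
  expect_equal(unname(m$wt["3"]), "D")

  ## matrix TSV, both orientations
  mat <- m$values
  tf <- tempfile(fileext = ".tsv")
  write.table(mat, tf, sep = "\t", quote = FALSE)
  m2 <- read_score_matrix_tsv(tf, kind = "ddE")
  expect_equal(m2$values, mat)
  write.table(t(mat), tf, sep = "\t", quote = FALSE)
  m3 <- read_score_matrix_tsv(tf, kind = "ddE")
  expect_equal(m3$values, mat)

  ## Rosetta-style variant labels
  rf <- tempfile(fileext = ".csv")
  write.csv(data.frame(variant = c("A1G", "A1S", "C2W"),
                       score = c(2.9, 5.8, 8.7)), rf, row.names = FALSE)
  mr <- read_rosetta_ddg(rf)
  expect_identical(mr$provenance, "rosetta_raw")
  expect_equal(normalize_ddg(mr)$values["G", "1"], 1.0)
})

test_that("feature assembly yields 19 complete rows per covered position", {
  pl <- planted_variants(n_residues = 3, seed = 2)
  expect_equal(nrow(pl$features), 3 * 19)
  expect_true(all(pl$features$complete))
  expect_equal(attr(pl$features, "coverage"), 1)
  ## the eight features appear in the contracted order
  expect_true(all(FEATURE_NAMES %in% names(pl$features)))
})

test_that("positions absent from the structure yield incomplete rows", {
  pl <- planted_variants(n_residues = 6, seed = 3)
  wcn <- weighted_contact_number(pl$model)
  wcn <- wcn[wcn$position != 4, ]
  feats <- suppressMessages(
    assemble_features(pl$ddg, pl$dde, wcn,
                      attr(pl$model, "wt_sequence")))
  expect_equal(sum(!feats$complete), 19)
  expect_true(all(feats$position[!feats$complete] == 4))
  expect_equal(attr(feats, "coverage"), 5 / 6)

  ## complete-row count agrees with a brute-force enumerator
  brute <- sum(vapply(seq_len(6), function(p) {
    if (p == 4) 0L else 19L
  }, integer(1)))
  expect_equal(attr(feats, "n_complete"), brute)
})

test_that("wild-type disagreements are reported with positions", {
  pl <- planted_variants(n_residues = 4, seed = 4)
  wrong <- attr(pl$model, "wt_sequence")
  substr(wrong, 2, 2) <- if (substr(wrong, 2, 2) == "A") "C" else "A"
  expect_error(
    suppressMessages(assemble_features(pl$ddg, pl$dde,
                                       weighted_contact_number(pl$model),
                                       wrong)),
    "position\\(s\\): 2")
})

test_that("unnormalized ddG input is refused", {
  raw <- score_matrix(long_df(1, "G", 5.8), kind = "ddG",
                      provenance = "rosetta_raw")
  dde <- score_matrix(long_df(1, "G", -2), kind = "ddE",
                      provenance = "gemme")
  wcn <- data.frame(position = 1, wcn = 1)
  expect_error(assemble_features(raw, dde, wcn, "A"), "normalize_ddg")
})

test_that("feature tables round-trip through CSV with provenance headers", {
  pl <- planted_variants(n_residues = 3, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_variant_features(pl$features, f, params = list(r0 = 7.0))
  expect_match(readLines(f, n = 1), "^# r0=7")
  back <- read_variant_features(f)
  expect_equal(back$ddG_variant, pl$features$ddG_variant)
  expect_equal(nrow(back), nrow(pl$features))
})
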