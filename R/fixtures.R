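#' Specification for a synthetic test fixture
#'
#' Bundles every knob of the synthetic-data generators so that a fixture
#' is a pure, fully serializable function of its spec and seed: structure
#' size and packing, the per-class feature distributions that plant the
#' four variant classes, and the trimodal assay-score mixtures. The
#' defaults plant the class architecture the method is built around:
#' stable-but-inactive positions pair a small stability change (mean 0.5
#' kcal/mol) with strong conservation (mean -5), total-loss positions a
#' large stability change (mean 4) with strong conservation, wild-type-like
#' positions are unconserved and stable, and the low-abundance/
#' high-activity corner is destabilized but unconserved -- so neither
#' feature alone separates any class, while the combination does.
#'
#' @param n_residues Protein length (default 160).
#' @param fraction_buried Fraction of residues placed in the buried core
#'   helix of the synthetic bundle (default 0.25).
#' @param class_fractions Named fractions over [VARIANT_CLASSES] used to
#'   plant one true class per position (default 0.35/0.25/0.20/0.20).
#' @param feature_dist Named list per class with `ddG_mean`, `ddG_sd`,
#'   `ddE_mean`, `ddE_sd` (kcal/mol and dimensionless respectively).
#' @param mave List describing each assay's three score components:
#'   `means`, `sds` (low/intermediate/high) and `mid_fraction`, the
#'   probability that a variant reads out as intermediate-effect in an
#'   assay (default 4%).
#' @param seed Master integer seed; sub-generators derive fixed offsets
#'   from it.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 160,
                         fraction_buried = 0.25,
                         class_fractions = c(
                           WT_LIKE = 0.35, TOTAL_LOSS = 0.25, SBI = 0.20,
                           LOW_ABUNDANCE_HIGH_ACTIVITY = 0.20),
                         feature_dist = list(
                           WT_LIKE = list(ddG_mean = 0.5, ddG_sd = 0.6,
                                          ddE_mean = -1.0, ddE_sd = 0.6),
                           TOTAL_LOSS = list(ddG_mean = 4.0, ddG_sd = 0.6,
                                             ddE_mean = -5.0, ddE_sd = 0.6),
                           SBI = list(ddG_mean = 0.5, ddG_sd = 0.6,
                                      ddE_mean = -5.0, ddE_sd = 0.6),
                           LOW_ABUNDANCE_HIGH_ACTIVITY =
                             list(ddG_mean = 4.0, ddG_sd = 0.6,
                                  ddE_mean = -1.0, ddE_sd = 0.6)),
                         mave = list(means = c(0, 0.5, 1),
                                     sds = c(0.08, 0.08, 0.08),
                                     mid_fraction = 0.04),
                         seed = 1) {
  stopifnot(n_residues >= 2,
            fraction_buried >= 0, fraction_buried <= 1,
            abs(sum(class_fractions) - 1) < 1e-9,
            setequal(names(class_fractions), VARIANT_CLASSES),
            setequal(names(feature_dist), VARIANT_CLASSES),
            length(mave$means) == 3, length(mave$sds) == 3,
            all(mave$sds > 0))
  structure(list(n_residues = as.integer(n_residues),
                 fraction_buried = fraction_buried,
                 class_fractions = class_fractions[VARIANT_CLASSES],
                 feature_dist = feature_dist,
                 mave = mave, seed = as.integer(seed)),
            class = "fixture_spec")
}

## ideal alpha-helix C-alpha trace: radius 2.3 A, 100 deg/residue,
## 1.5 A rise, giving consecutive C-alpha distances of ~3.8 A
helix_trace <- function(n, origin = c(0, 0, 0), phase = 0) {
  i <- seq_len(n) - 1
  theta <- phase + i * 100 * pi / 180
  cbind(origin[1] + 2.3 * cos(theta),
        origin[2] + 2.3 * sin(theta),
        origin[3] + 1.5 * i)
}

#' Generate a synthetic protein structure
#'
#' Builds an idealized C-alpha trace, deterministic per seed. Geometry
#' `"helix"` is a single straight alpha-helix (consecutive C-alpha
#' distances ~3.8 Angstrom). Geometry `"bundle"` (default) packs one
#' central helix -- holding `fraction_buried` of the residues -- inside a
#' ring of outer helices ~8 Angstrom away, so the central positions have
#' high weighted contact numbers (buried) and the outer ones low
#' (exposed) by construction. A small seeded coordinate jitter breaks
#' exact symmetry. The wild-type sequence is drawn uniformly over the 20
#' amino acids.
#'
#' @param spec A [fixture_spec()].
#' @param geometry `"bundle"` or `"helix"`.
#' @return A `structure_model` with attributes `buried_positions`
#'   (integer vector; empty for `"helix"`) and `wt_sequence`.
#' @export
make_structure <- function(spec, geometry = c("bundle", "helix")) {
  geometry <- match.arg(geometry)
  n <- spec$n_residues
  set.seed(spec$seed + 11L)

  if (geometry == "helix") {
    xyz <- helix_trace(n)
    buried <- integer(0)
    order_pos <- seq_len(n)
  } else {
    n_core <- round(spec$fraction_buried * n)
    n_out <- n - n_core
    k <- max(3L, ceiling(n_out / max(n_core, 20L)))
    sizes <- rep(n_out %/% k, k)
    if (n_out %% k > 0) sizes[seq_len(n_out %% k)] <- sizes[seq_len(n_out %% k)] + 1L
    radius <- 8
    blocks <- list()
    for (j in seq_len(k)) {
      ang <- 2 * pi * (j - 1) / k
      blocks[[j]] <- helix_trace(sizes[j],
                                 origin = c(radius * cos(ang),
                                            radius * sin(ang), 0),
                                 phase = ang)
    }
    core <- helix_trace(n_core)
    ## core helix is the second sequence block so it is not terminal
    xyz <- rbind(blocks[[1]], core,
                 do.call(rbind, blocks[-1]))
    buried <- seq(sizes[1] + 1L, length.out = n_core)
    order_pos <- seq_len(n)
  }

  xyz <- xyz + matrix(stats::rnorm(3 * n, sd = 0.15), ncol = 3)
  wt <- sample(AA_ALPHABET, n, replace = TRUE)
  model <- new_structure_model(
    data.frame(chain = "A", position = order_pos, aa = wt,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE),
    source = paste0("synthetic-", geometry))
  attr(model, "buried_positions") <- as.integer(buried)
  attr(model, "wt_sequence") <- paste(wt, collapse = "")
  model
}

#' Generate planted substitution score matrices
#'
#' Draws one true class per position from the spec's class fractions,
#' then samples all 19 substitution scores per position from that class's
#' stability (ddG) and conservation (ddE) distributions, clipped into the
#' valid ranges (0--5 kcal/mol and -7--0). With the distribution standard
#' deviations at 0 the scores equal the class means exactly. The planted
#' labels are returned for recovery tests.
#'
#' @param spec A [fixture_spec()].
#' @param structure The matching `structure_model` (supplies the
#'   wild-type sequence).
#' @return List with `ddg` and `dde` ([score_matrix()]s, positions x 19)
#'   and `true_class` (named character vector, one class per position).
#' @export
make_score_matrices <- function(spec, structure) {
  wt <- strsplit(attr(structure, "wt_sequence"), "")[[1]]
  n <- length(wt)
  set.seed(spec$seed + 22L)
  true_class <- sample(VARIANT_CLASSES, n, replace = TRUE,
                       prob = spec$class_fractions)
  names(true_class) <- seq_len(n)

  rows <- lapply(seq_len(n), function(p) {
    muts <- setdiff(AA_ALPHABET, wt[p])
    fd <- spec$feature_dist[[true_class[p]]]
    data.frame(position = p, wt = wt[p], mut = muts,
               ddg = pmin(5, pmax(0, stats::rnorm(19, fd$ddG_mean, fd$ddG_sd))),
               dde = pmin(0, pmax(-7, stats::rnorm(19, fd$ddE_mean, fd$ddE_sd))),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  ddg <- score_matrix(data.frame(position = long$position, wt = long$wt,
                                 mut = long$mut, score = long$ddg),
                      kind = "ddG", provenance = "kcal_mol")
  dde <- score_matrix(data.frame(position = long$position, wt = long$wt,
                                 mut = long$mut, score = long$dde),
                      kind = "ddE", provenance = "gemme")
  list(ddg = ddg, dde = dde, true_class = true_class)
}

#' Generate paired trimodal assay scores
#'
#' For every variant, the true class dictates which outer component of
#' each assay's three-Gaussian mixture it is drawn from (e.g. a
#' stable-but-inactive variant draws its abundance score from the high
#' component and its activity score from the low component); a small
#' fraction of variants instead read out as intermediate-effect and draw
#' from the middle component, which sits between the modes. Planted
#' mixture parameters are recorded so threshold recovery can be checked
#' against the analytic intersection.
#'
#' @param spec A [fixture_spec()].
#' @param true_class Named character vector from [make_score_matrices()].
#' @param structure The matching `structure_model`.
#' @return data.frame with columns `position`, `wt`, `mut`,
#'   `abundance_score`, `activity_score` and attributes
#'   `true_variant_class` and `planted_mixture`.
#' @export
make_mave_scores <- function(spec, true_class, structure) {
  wt <- strsplit(attr(structure, "wt_sequence"), "")[[1]]
  n <- length(wt)
  set.seed(spec$seed + 33L)
  mu <- spec$mave$means
  sig <- spec$mave$sds
  midf <- spec$mave$mid_fraction

  pos <- rep(seq_len(n), each = 19L)
  mut <- unlist(lapply(wt, function(a) setdiff(AA_ALPHABET, a)),
                use.names = FALSE)
  cls <- true_class[pos]

  ## component index per assay: 1 = low, 2 = intermediate, 3 = high
  ab_comp <- ifelse(cls %in% c("WT_LIKE", "SBI"), 3L, 1L)
  ac_comp <- ifelse(cls %in% c("WT_LIKE", "LOW_ABUNDANCE_HIGH_ACTIVITY"),
                    3L, 1L)
  nv <- length(pos)
  ab_comp[stats::runif(nv) < midf] <- 2L
  ac_comp[stats::runif(nv) < midf] <- 2L

  out <- data.frame(
    position = pos, wt = wt[pos], mut = mut,
    abundance_score = stats::rnorm(nv, mu[ab_comp], sig[ab_comp]),
    activity_score = stats::rnorm(nv, mu[ac_comp], sig[ac_comp]),
    stringsAsFactors = FALSE
  )
  attr(out, "true_variant_class") <- unname(cls)
  attr(out, "planted_mixture") <- spec$mave
  out
}

#' Overwrite substitution scores at selected positions
#'
#' Utility for planting perturbations, e.g. emulating oligomer-context
#' stability input by raising the ddG of interface positions above the
#' total-loss range before re-running prediction.
#'
#' @param matrix A [score_matrix()].
#' @param positions Positions whose (non-missing) values to overwrite.
#' @param value Replacement score.
#' @return The modified `score_matrix`.
#' @export
set_position_scores <- function(matrix, positions, value) {
  stopifnot(inherits(matrix, "score_matrix"))
  cols <- match(as.character(as.integer(positions)), colnames(matrix$values))
  if (any(is.na(cols))) {
    stop("position(s) not in matrix: ",
         paste(positions[is.na(cols)], collapse = ", "))
  }
  for (j in cols) {
    keep <- !is.na(matrix$values[, j])
    matrix$values[keep, j] <- value
  }
  matrix
}

#' Write a complete synthetic fixture to disk
#'
#' Generates structure, score matrices and assay scores from one spec and
#' writes them in the formats the pipeline consumes: a C-alpha PDB, two
#' long-form score CSVs, a paired MAVE CSV, and `truth.json` holding the
#' planted per-position classes, buried positions, mixture parameters and
#' the spec itself (so the fixture can be regenerated).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
make_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- make_structure(spec)
  mats <- make_score_matrices(spec, model)
  mave <- make_mave_scores(spec, mats$true_class, model)

  paths <- list(
    pdb = file.path(dir, "structure.pdb"),
    ddg = file.path(dir, "ddg.csv"),
    dde = file.path(dir, "dde.csv"),
    mave = file.path(dir, "mave.csv"),
    truth = file.path(dir, "truth.json")
  )
  res <- model$residues
  bio3d::write.pdb(file = paths$pdb,
                   xyz = as.numeric(t(as.matrix(res[, c("x", "y", "z")]))),
                   resno = res$position,
                   resid = bio3d::aa123(res$aa),
                   chain = res$chain,
                   elety = rep("CA", nrow(res)))
  write_score_long <- function(m, path) {
    idx <- which(!is.na(m$values), arr.ind = TRUE)
    wt <- strsplit(attr(model, "wt_sequence"), "")[[1]]
    long <- data.frame(
      position = as.integer(colnames(m$values)[idx[, 2]]),
      wt = wt[as.integer(colnames(m$values)[idx[, 2]])],
      mut = rownames(m$values)[idx[, 1]],
      score = m$values[idx], stringsAsFactors = FALSE)
    long <- long[order(long$position, long$mut), ]
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  }
  write_score_long(mats$ddg, paths$ddg)
  write_score_long(mats$dde, paths$dde)
  utils::write.csv(mave, paths$mave, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(true_class = as.list(mats$true_class),
         buried_positions = attr(model, "buried_positions"),
         wt_sequence = attr(model, "wt_sequence"),
         planted_mixture = spec$mave,
         spec = unclass(spec)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(spec = spec, model = model, ddg = mats$ddg,
                 dde = mats$dde, true_class = mats$true_class,
                 mave = mave, paths = paths))
}
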