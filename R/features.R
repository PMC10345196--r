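#' The eight model features, in their contracted column order
#'
#' Variant and per-residue/neighbour-average stability (ddG) and
#' conservation (ddE) scores, target-residue hydrophobicity, and the
#' weighted contact number. Trained bundles record this ordering and
#' prediction matches columns by these names.
#' @export
FEATURE_NAMES <- c("ddG_variant", "ddE_variant",
                   "ddG_residue_avg", "ddE_residue_avg",
                   "ddG_neighbour_avg", "ddE_neighbour_avg",
                   "hydrophobicity_target", "wcn")

#' Assemble the per-variant feature table
#'
#' Joins normalized stability changes, conservation scores, structure-derived
#' contact numbers and target-residue hydrophobicity into one row per
#' possible substitution (position, target amino acid != wild type), each
#' carrying the eight model features: variant ddG and ddE, their per-residue
#' and flanking-neighbour averages, the hydrophobicity of the target amino
#' acid, and the weighted contact number. Rows missing any feature (position
#' absent from a score matrix or from the structure) are flagged incomplete;
#' they are reported but never enter training or prediction.
#'
#' @param ddg A [score_matrix()] of kind `"ddG"`, already normalized to
#'   kcal/mol (see [normalize_ddg()]).
#' @param dde A [score_matrix()] of kind `"ddE"`.
#' @param struct_features data.frame with columns `position` and `wcn`,
#'   typically from [weighted_contact_number()]. Positions occurring in
#'   several chains (oligomer input) are collapsed by averaging.
#' @param wt_sequence Reference amino-acid sequence (1-based positions).
#' @param scale Hydrophobicity scale (named vector over the 20 amino acids);
#'   defaults to Kyte-Doolittle.
#' @return A data.frame of class `variant_features` with identifier columns
#'   `position`, `wt`, `mut`, the eight feature columns in model order, and
#'   a logical `complete` column. Attributes `coverage` (fraction of
#'   positions with at least one complete row) and `n_complete` summarize
#'   coverage accounting.
#' @examples
#' \dontrun{
#' feats <- assemble_features(ddg, dde, weighted_contact_number(model),
#'                            wt_sequence = seq)
#' subset(feats, complete)
#' }
#' @export
assemble_features <- function(ddg, dde, struct_features, wt_sequence,
                              scale = default_hydrophobicity()) {
  stopifnot(inherits(ddg, "score_matrix"), inherits(dde, "score_matrix"))
  if (ddg$kind != "ddG" || dde$kind != "ddE") {
    stop("expected a ddG matrix and a ddE matrix, in that order")
  }
  if (ddg$provenance == "rosetta_raw") {
    stop("ddG matrix is still in Rosetta energy units; run normalize_ddg() first")
  }
  check_hydrophobicity_scale(scale)

  wt_vec <- strsplit(toupper(wt_sequence), "")[[1]]
  L <- length(wt_vec)
  if (L == 0) stop("empty wild-type sequence")

  ## wild-type annotations carried by the matrices must agree with the sequence
  for (m in list(ddg, dde)) {
    if (!is.null(m$wt)) {
      pos <- as.integer(names(m$wt))
      pos <- pos[pos >= 1 & pos <= L]
      bad <- pos[m$wt[as.character(pos)] != wt_vec[pos]]
      if (length(bad) > 0) {
        stop("wild-type mismatch between ", m$kind,
             " matrix and wt_sequence at position(s): ",
             paste(utils::head(bad, 10), collapse = ", "))
      }
    }
  }

  sf <- as.data.frame(struct_features)
  stopifnot(all(c("position", "wcn") %in% names(sf)))
  if (anyDuplicated(sf$position)) {
    message("collapsing duplicated structure positions (multi-chain model) ",
            "by averaging wcn")
    sf <- stats::aggregate(wcn ~ position, data = sf, FUN = mean)
  }
  wcn_by_pos <- stats::setNames(sf$wcn, sf$position)

  pos <- rep(seq_len(L), each = 19L)
  wt <- wt_vec[pos]
  mut <- unlist(lapply(wt_vec, function(a) setdiff(AA_ALPHABET, a)),
                use.names = FALSE)

  lookup <- function(m, p, a) {
    j <- match(as.character(p), colnames(m$values))
    v <- rep(NA_real_, length(p))
    ok <- !is.na(j)
    v[ok] <- m$values[cbind(match(a[ok], AA_ALPHABET), j[ok])]
    v
  }

  upos <- seq_len(L)
  ddg_res <- residue_average(ddg, upos)
  dde_res <- residue_average(dde, upos)
  ddg_nb <- neighbour_average(ddg, upos)
  dde_nb <- neighbour_average(dde, upos)

  tab <- data.frame(
    position = pos, wt = wt, mut = mut,
    ddG_variant = lookup(ddg, pos, mut),
    ddE_variant = lookup(dde, pos, mut),
    ddG_residue_avg = ddg_res[pos],
    ddE_residue_avg = dde_res[pos],
    ddG_neighbour_avg = ddg_nb[pos],
    ddE_neighbour_avg = dde_nb[pos],
    hydrophobicity_target = unname(scale[mut]),
    wcn = unname(wcn_by_pos[as.character(pos)]),
    stringsAsFactors = FALSE
  )
  tab$complete <- stats::complete.cases(tab[, FEATURE_NAMES])

  covered <- unique(tab$position[tab$complete])
  attr(tab, "coverage") <- length(covered) / L
  attr(tab, "n_complete") <- sum(tab$complete)
  class(tab) <- c("variant_features", "data.frame")
  message("feature table: ", sum(tab$complete), "/", nrow(tab),
          " complete variant rows; ", length(covered), "/", L,
          " positions covered")
  tab
}

#' Read and write variant feature tables
#'
#' CSV round-trip for the eight-feature table. `write_variant_features`
#' records run parameters as `#`-prefixed header comments for provenance;
#' `read_variant_features` skips them.
#'
#' @param table A `variant_features` data.frame.
#' @param path File path.
#' @param params Optional named list recorded in the header (e.g. divisor,
#'   clamp bounds, `r0`).
#' @return The path (writer, invisibly) or the table (reader).
#' @export
write_variant_features <- function(table, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(paste0("# ", names(params), "=",
                      vapply(params, function(x) paste(x, collapse = ","), "")),
               con)
  }
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_variant_features
#' @export
read_variant_features <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(c("position", "wt", "mut", FEATURE_NAMES), names(tab))
  if (length(missing) > 0) {
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"complete" %in% names(tab)) {
    tab$complete <- stats::complete.cases(tab[, FEATURE_NAMES])
  }
  class(tab) <- c("variant_features", "data.frame")
  tab
}
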