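#' Position-by-substitution score matrices
#'
#' A `score_matrix` holds one score per (sequence position, target amino
#' acid): either predicted stability changes (`kind = "ddG"`, in Rosetta
#' energy units or kcal/mol) or evolutionary conservation scores
#' (`kind = "ddE"`, dimensionless, 0 for conservative substitutions down
#' to about -7 for substitutions incompatible with the family). Values are
#' stored as a 20-row matrix (rows: canonical amino acids, alphabetical;
#' columns: 1-based sequence positions), `NA` marking unscored variants.
#' Wild-type self-substitutions are excluded: they carry no substitution
#' signal and every summary here assumes at most 19 variants per position.
#'
#' @param values Numeric 20 x L matrix, or a long data.frame with columns
#'   `position`, `mut`, `score` (and optionally `wt`).
#' @param kind `"ddG"` or `"ddE"`.
#' @param provenance One of `"rosetta_raw"` (Rosetta energy units, not yet
#'   rescaled), `"kcal_mol"`, `"rasp"`, `"gemme"`.
#' @param wt Optional named character vector giving the wild-type amino
#'   acid at each position (names are positions).
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(values, kind = c("ddG", "ddE"),
                         provenance = c("kcal_mol", "rosetta_raw",
                                        "rasp", "gemme"),
                         wt = NULL) {
  kind <- match.arg(kind)
  provenance <- match.arg(provenance)

  if (is.data.frame(values)) {
    stopifnot(all(c("position", "mut", "score") %in% names(values)))
    values$mut <- toupper(values$mut)
    bad <- !(values$mut %in% AA_ALPHABET)
    if (any(bad)) {
      stop("non-canonical target amino acid(s): ",
           paste(unique(values$mut[bad]), collapse = ", "))
    }
    if ("wt" %in% names(values) && is.null(wt)) {
      values$wt <- toupper(values$wt)
      wt_tab <- unique(values[, c("position", "wt")])
      if (anyDuplicated(wt_tab$position)) {
        stop("conflicting wild-type annotations at position(s): ",
             paste(wt_tab$position[duplicated(wt_tab$position)], collapse = ", "))
      }
      wt <- stats::setNames(wt_tab$wt, wt_tab$position)
      self <- values$mut == values$wt
      values <- values[!self, , drop = FALSE]
    }
    positions <- sort(unique(as.integer(values$position)))
    m <- matrix(NA_real_, nrow = 20, ncol = length(positions),
                dimnames = list(AA_ALPHABET, positions))
    idx <- cbind(match(values$mut, AA_ALPHABET),
                 match(as.integer(values$position), positions))
    if (anyDuplicated(idx)) stop("duplicated variant entries in score table")
    m[idx] <- values$score
    values <- m
  } else {
    values <- as.matrix(values)
    if (nrow(values) != 20) stop("score matrix must have 20 amino-acid rows")
    rownames(values) <- toupper(rownames(values))
    if (!setequal(rownames(values), AA_ALPHABET)) {
      stop("matrix rows must be the 20 canonical amino acids")
    }
    values <- values[AA_ALPHABET, , drop = FALSE]
    if (is.null(colnames(values))) {
      colnames(values) <- seq_len(ncol(values))
    }
  }

  if (!is.null(wt)) {
    ## blank wild-type self-substitution cells
    pos <- intersect(names(wt), colnames(values))
    values[cbind(match(wt[pos], AA_ALPHABET), match(pos, colnames(values)))] <- NA_real_
  }

  obj <- structure(list(values = values, kind = kind,
                        provenance = provenance, wt = wt),
                   class = "score_matrix")
  if (kind == "ddE") {
    v <- values[is.finite(values)]
    if (length(v) > 0 && (min(v) < -7.5 || max(v) > 0.5)) {
      warning("ddE values outside the expected [-7, 0] range ",
              "(min ", signif(min(v), 3), ", max ", signif(max(v), 3),
              "); used as read")
    }
  }
  obj
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix [", x$kind, ", ", x$provenance, "]: ",
      ncol(x$values), " positions, ",
      sum(is.finite(x$values)), " scored variants\n", sep = "")
  invisible(x)
}

#' @export
dim.score_matrix <- function(x) dim(x$values)

## internal: integer positions covered by a score matrix
positions_of <- function(matrix) as.integer(colnames(matrix$values))

#' Read substitution scores from standard file layouts
#'
#' Three dialects are supported: a long-form CSV with header
#' `position,wt,mut,score`; a matrix-form TSV in the layout emitted by
#' conservation-score tools (20 amino-acid rows by L position columns, or
#' transposed -- orientation is detected from the shape); and a summary
#' CSV of stability predictions keyed by variant labels such as `A123G`
#' (columns `variant,score`, replicate averaging done upstream).
#'
#' @param path Input file.
#' @param kind `"ddG"` or `"ddE"`.
#' @param provenance Score provenance; defaults to `"rosetta_raw"` for
#'   `read_rosetta_ddg`, `"gemme"` for matrix input, `"kcal_mol"` otherwise.
#' @return A [score_matrix()].
#' @export
read_score_long <- function(path, kind, provenance = "kcal_mol") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  score_matrix(tab, kind = kind, provenance = provenance)
}

#' @rdname read_score_long
#' @export
read_score_matrix_tsv <- function(path, kind, provenance = "gemme") {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != 20 && ncol(m) == 20) {
    m <- t(m)
  } else if (nrow(m) != 20) {
    stop("matrix input must have 20 amino acids on one axis (got ",
         nrow(m), " x ", ncol(m), ")")
  }
  colnames(m) <- sub("^[A-Za-z]", "", colnames(m))  # tolerate "V12"-style headers
  score_matrix(m, kind = kind, provenance = provenance)
}

#' @rdname read_score_long
#' @export
read_rosetta_ddg <- function(path, provenance = "rosetta_raw") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "score") %in% names(tab)))
  m <- regmatches(tab$variant,
                  regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tab$variant))
  bad <- lengths(m) != 4
  if (any(bad)) {
    stop("unparseable variant label(s): ",
         paste(utils::head(tab$variant[bad], 5), collapse = ", "))
  }
  long <- data.frame(
    position = as.integer(vapply(m, `[`, "", 3)),
    wt = toupper(vapply(m, `[`, "", 2)),
    mut = toupper(vapply(m, `[`, "", 4)),
    score = tab$score,
    stringsAsFactors = FALSE
  )
  score_matrix(long, kind = "ddG", provenance = provenance)
}

#' Rescale and clamp stability predictions
#'
#' Stability changes arriving in Rosetta energy units are divided by 2.9
#' to bring them onto a scale corresponding to kcal/mol; all values are
#' then clamped into `[clamp_low, clamp_high]` (default 0--5 kcal/mol),
#' the range in which stability differences are informative for the
#' classifier. Idempotent: already-normalized input passes through with
#' only the (order-preserving) clamp re-applied.
#'
#' @param matrix A `score_matrix` of kind `"ddG"`.
#' @param rosetta_divisor Conversion divisor applied when provenance is
#'   `"rosetta_raw"` (default 2.9).
#' @param clamp_low,clamp_high Clamp bounds in kcal/mol (defaults 0 and 5).
#' @return A `score_matrix` with provenance `"kcal_mol"`.
#' @examples
#' m <- score_matrix(data.frame(position = 1, mut = "G", score = 5.8),
#'                   kind = "ddG", provenance = "rosetta_raw")
#' normalize_ddg(m)$values["G", "1"]  # 2.0
#' @export
normalize_ddg <- function(matrix, rosetta_divisor = 2.9,
                          clamp_low = 0, clamp_high = 5) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (matrix$kind != "ddG") stop("normalize_ddg applies to ddG matrices only")
  v <- matrix$values
  bad <- which(!is.na(v) & !is.finite(v), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite ddG value for variant(s): ",
         paste(paste0(colnames(v)[bad[, 2]], rownames(v)[bad[, 1]]),
               collapse = ", "))
  }
  if (matrix$provenance == "rosetta_raw") v <- v / rosetta_divisor
  v <- pmin(pmax(v, clamp_low), clamp_high)
  matrix$values <- v
  matrix$provenance <- "kcal_mol"
  matrix
}

#' Per-position score summaries
#'
#' `residue_average` is the arithmetic mean over all scored substitutions
#' at one position (wild-type self-substitutions are never stored, so never
#' included). `neighbour_average` pools every scored substitution from the
#' flanking positions `i - 1` and `i + 1` and averages them; at a chain
#' terminus the single existing neighbour is used. Both return `NA` when no
#' values are available, which downstream feature assembly treats as an
#' incomplete row.
#'
#' @param matrix A `score_matrix`.
#' @param position 1-based sequence position (vectorized).
#' @return Numeric vector of means (`NA` where unavailable).
#' @export
residue_average <- function(matrix, position) {
  stopifnot(inherits(matrix, "score_matrix"))
  cols <- match(as.character(as.integer(position)), colnames(matrix$values))
  vapply(cols, function(j) {
    if (is.na(j)) return(NA_real_)
    v <- matrix$values[, j]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' @rdname residue_average
#' @export
neighbour_average <- function(matrix, position) {
  stopifnot(inherits(matrix, "score_matrix"))
  vapply(as.integer(position), function(p) {
    cols <- match(as.character(c(p - 1L, p + 1L)), colnames(matrix$values))
    v <- unlist(lapply(cols[!is.na(cols)],
                       function(j) matrix$values[, j]), use.names = FALSE)
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
}
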