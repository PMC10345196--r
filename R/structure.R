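#' Read a protein structure into a position-indexed model
#'
#' Parses a PDB file and extracts the C-alpha trace (and, optionally, all
#' heavy atoms) of the selected chain(s). Residue positions are taken from
#' the author numbering, which for the intended inputs is aligned to the
#' reference (UniProt isoform) sequence; `renumber = TRUE` remaps the
#' positions of each chain to 1..n in sequence order instead, reporting the
#' mapping, for structures whose author numbering is offset.
#'
#' Only `ATOM` records of the first model are considered; `HETATM` records
#' and alternate locations other than the first are ignored. Residues
#' lacking a C-alpha atom are dropped with a warning that names them.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier(s) to keep, or `NULL` for all chains.
#' @param renumber If `TRUE`, remap author residue numbers to 1..n per chain.
#' @param keep_atoms If `TRUE` (default), retain all heavy-atom records so
#'   that solvent exposure can be computed; C-alpha-only models suffice for
#'   contact numbers and distances.
#' @return An object of class `structure_model`: a list with
#'   `residues` (data.frame: `chain`, `position`, `aa`, `x`, `y`, `z`, one
#'   row per C-alpha), `atoms` (data.frame of heavy atoms or `NULL`), and
#'   `numbering` (data.frame mapping author numbering to model positions).
#' @examples
#' pdb <- system.file("extdata", "mini_helix.pdb", package = "funsites")
#' model <- read_structure(pdb)
#' head(model$residues)
#' @export
read_structure <- function(path, chain = NULL, renumber = FALSE,
                           keep_atoms = TRUE) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records found in ", path)
  atoms <- atoms[is.na(atoms$alt) | atoms$alt %in% c("", "A"), , drop = FALSE]

  available <- sort(unique(atoms$chain))
  if (!is.null(chain)) {
    missing <- setdiff(chain, available)
    if (length(missing) > 0) {
      stop("chain(s) ", paste(missing, collapse = ", "),
           " not present; available chains: ",
           paste(available, collapse = ", "))
    }
    atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  }

  ## drop hydrogens; exposure and contacts are heavy-atom/CA quantities
  atoms <- atoms[!(atoms$elesy %in% c("H", "D")), , drop = FALSE]

  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ca$insert)
  dup <- duplicated(ca_key)
  if (any(dup)) ca <- ca[!dup, , drop = FALSE]  # first altloc kept above
  no_ca <- setdiff(unique(key), paste(ca$chain, ca$resno, ca$insert))
  if (length(no_ca) > 0) {
    warning(length(no_ca), " residue(s) without a C-alpha excluded: ",
            paste(utils::head(no_ca, 10), collapse = "; "))
    atoms <- atoms[!(key %in% no_ca), , drop = FALSE]
  }

  ord <- order(ca$chain, ca$resno)
  ca <- ca[ord, , drop = FALSE]
  residues <- data.frame(
    chain = ca$chain,
    position = ca$resno,
    aa = bio3d::aa321(ca$resid),
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE
  )

  numbering <- data.frame(chain = residues$chain,
                          author = residues$position,
                          position = residues$position)
  if (renumber) {
    for (ch in unique(residues$chain)) {
      sel <- residues$chain == ch
      numbering$position[sel] <- seq_len(sum(sel))
    }
    residues$position <- numbering$position
    message("renumbered ", nrow(residues), " residues to 1..n per chain ",
            "(see $numbering for the author-number mapping)")
  }

  atom_df <- NULL
  if (keep_atoms) {
    pos_lookup <- stats::setNames(numbering$position,
                                  paste(numbering$chain, numbering$author))
    atom_df <- data.frame(
      chain = atoms$chain,
      position = unname(pos_lookup[paste(atoms$chain, atoms$resno)]),
      aa = bio3d::aa321(atoms$resid),
      elety = atoms$elety,
      elesy = atoms$elesy,
      x = atoms$x, y = atoms$y, z = atoms$z,
      stringsAsFactors = FALSE
    )
  }

  if (any(!is.finite(as.matrix(residues[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure")
  }

  structure(list(residues = residues, atoms = atom_df,
                 numbering = numbering, source = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$residues), "residues in",
      length(unique(x$residues$chain)), "chain(s)",
      paste0("(", paste(unique(x$residues$chain), collapse = ","), ")"),
      if (is.null(x$atoms)) "[C-alpha only]" else
        paste0("[", nrow(x$atoms), " heavy atoms]"), "\n")
  invisible(x)
}

## internal: construct a structure_model directly from a residue table
new_structure_model <- function(residues, atoms = NULL, source = "synthetic") {
  residues <- as.data.frame(residues)
  stopifnot(all(c("chain", "position", "aa", "x", "y", "z") %in% names(residues)))
  structure(list(residues = residues, atoms = atoms,
                 numbering = data.frame(chain = residues$chain,
                                        author = residues$position,
                                        position = residues$position),
                 source = source),
            class = "structure_model")
}

#' Smooth contact switching function
#'
#' The weight given to a residue pair at C-alpha distance `r` when counting
#' contacts: `s(r) = (1 - (r/r0)^6) / (1 - (r/r0)^12)`. The printed form is
#' 0/0 at `r = r0`; the implementation uses the algebraically identical,
#' singularity-free factorization `1 / (1 + (r/r0)^6)`, which equals the
#' printed form everywhere else and takes the removable-limit value 1/2 at
#' `r = r0`. Strictly decreasing in `r`, with `s(0) = 1` and `s -> 0` as
#' `r -> Inf`.
#'
#' @param r Distance(s) in Angstrom, `>= 0`.
#' @param r0 Switching midpoint in Angstrom (default 7.0).
#' @return Numeric vector of contact weights in `(0, 1]`.
#' @examples
#' switching_function(c(0, 7, 14), r0 = 7)  # 1, 0.5, 1/65
#' @export
switching_function <- function(r, r0 = 7.0) {
  if (!is.numeric(r0) || length(r0) != 1 || !is.finite(r0) || r0 <= 0) {
    stop("r0 must be a single positive number")
  }
  if (any(r < 0, na.rm = TRUE)) stop("distances must be non-negative")
  1 / (1 + (r / r0)^6)
}

#' Weighted contact number per residue
#'
#' For each residue `i`, sums the switching function of the C-alpha
#' distance to every other residue in the model: `WCN_i = sum_{j != i}
#' s(r_ij)`. All chains present in the model contribute, so a model built
#' from an oligomer yields oligomer-context contact numbers. A dense local
#' environment (buried residue) gives a high WCN, an exposed one a low WCN.
#'
#' @param model A `structure_model`.
#' @param r0 Switching midpoint in Angstrom (default 7.0).
#' @return A data.frame with columns `chain`, `position`, `aa`, `wcn`, one
#'   row per residue in model order.
#' @export
weighted_contact_number <- function(model, r0 = 7.0) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  if (nrow(res) < 2) {
    stop("weighted contact number needs at least 2 residues")
  }
  d <- as.matrix(stats::dist(res[, c("x", "y", "z")]))
  s <- switching_function(d, r0)
  diag(s) <- 0
  data.frame(chain = res$chain, position = res$position, aa = res$aa,
             wcn = rowSums(s), row.names = NULL,
             stringsAsFactors = FALSE)
}

## van der Waals radii (A) by element for solvent accessibility
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90)

## internal: near-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Relative solvent exposure per residue
#'
#' Shrake-Rupley accessible surface area over the model's heavy atoms,
#' normalized per residue by a published table of theoretical maximum
#' accessible areas (Tien et al. 2013) and capped at 1. Residues whose
#' relative exposure falls below `threshold` are flagged buried. This is an
#' analysis-level quantity (e.g. for stratifying predictions by burial); it
#' is not one of the eight classifier features.
#'
#' @param model A `structure_model` read with `keep_atoms = TRUE`.
#' @param threshold Relative-exposure cutoff below which a residue is
#'   flagged buried (default 0.20).
#' @param probe Probe (solvent) radius in Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 120).
#' @return data.frame with columns `chain`, `position`, `aa`, `sasa`
#'   (absolute, A^2), `rel_sasa` in `[0, 1]` (`NA` when the residue type
#'   has no reference area), and `buried`.
#' @export
relative_exposure <- function(model, threshold = 0.20, probe = 1.4,
                              n_points = 120) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(model$atoms) || nrow(model$atoms) == 0) {
    stop("model has no atom records; re-read the structure with keep_atoms = TRUE")
  }
  atoms <- model$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- VDW_RADII[toupper(atoms$elesy)]
  radii[is.na(radii)] <- 1.70
  ext <- radii + probe
  sphere <- fibonacci_sphere(n_points)

  n <- nrow(atoms)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    ## neighbours whose extended spheres can occlude atom i
    dd <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(dd < ext[i] + ext & seq_len(n) != i)
    pts <- sweep(sphere * ext[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- sqrt(colSums((t(pts) - xyz[j, ])^2))
        free <- free & dj >= ext[j]
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    asa[i] <- frac * 4 * pi * ext[i]^2
  }

  key <- paste(atoms$chain, atoms$position)
  res_key <- unique(key)
  out <- data.frame(
    chain = atoms$chain[match(res_key, key)],
    position = atoms$position[match(res_key, key)],
    aa = atoms$aa[match(res_key, key)],
    sasa = as.numeric(tapply(asa, factor(key, levels = res_key), sum)),
    stringsAsFactors = FALSE
  )
  ref <- MAX_ASA_TIEN2013[out$aa]
  out$rel_sasa <- pmin(1, out$sasa / ref)
  out$buried <- out$rel_sasa < threshold
  attr(out, "threshold") <- threshold
  out[order(out$chain, out$position), ]
}

#' Minimum C-alpha distance to a set of site positions
#'
#' For every residue in the model, the minimum C-alpha--C-alpha distance to
#' any residue at one of the given sequence positions (e.g. catalytic
#' residues). A site position's own distance is 0. When a position occurs
#' in several chains, the minimum over all copies is reported.
#'
#' @param model A `structure_model`.
#' @param site_positions Non-empty vector of sequence positions present in
#'   the model.
#' @return data.frame with columns `chain`, `position`, `aa`, `distance`.
#' @export
min_distance_to_sites <- function(model, site_positions) {
  stopifnot(inherits(model, "structure_model"))
  site_positions <- unique(as.integer(site_positions))
  if (length(site_positions) == 0) stop("site_positions must be non-empty")
  res <- model$residues
  missing <- setdiff(site_positions, res$position)
  if (length(missing) > 0) {
    stop("site position(s) not in model: ", paste(missing, collapse = ", "))
  }
  site_xyz <- as.matrix(res[res$position %in% site_positions,
                            c("x", "y", "z"), drop = FALSE])
  xyz <- as.matrix(res[, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(xyz^2), rep(1, nrow(site_xyz))) +
              outer(rep(1, nrow(xyz)), rowSums(site_xyz^2)) -
              2 * xyz %*% t(site_xyz))
  d[d < 0 | !is.finite(d)] <- 0  # guard tiny negatives from rounding
  data.frame(chain = res$chain, position = res$position, aa = res$aa,
             distance = apply(d, 1, min), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write per-residue structural features to TSV
#'
#' Writes position, amino acid, contact number and (when available)
#' relative exposure with the parameter values recorded in a `#`-prefixed
#' header line for provenance.
#'
#' @param wcn data.frame from [weighted_contact_number()].
#' @param path Output file path.
#' @param exposure Optional data.frame from [relative_exposure()].
#' @param r0 Switching midpoint used, recorded in the header.
#' @return `path`, invisibly.
#' @export
write_struct_features <- function(wcn, path, exposure = NULL, r0 = 7.0) {
  out <- wcn
  if (!is.null(exposure)) {
    m <- match(paste(out$chain, out$position),
               paste(exposure$chain, exposure$position))
    out$rel_sasa <- exposure$rel_sasa[m]
    out$buried <- exposure$buried[m]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# r0=", r0,
                    if (!is.null(exposure))
                      paste0(" exposure_threshold=",
                             attr(exposure, "threshold")) else ""), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
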