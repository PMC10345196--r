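## Shared test helpers: all fixtures are built in code at test time.

## Minimal hand-written PDB text (CA-only unless extra atoms given).
## residues: data.frame(chain, resno, resid3, x, y, z)
write_test_pdb <- function(residues, path = tempfile(fileext = ".pdb"),
                           extra_atoms = NULL) {
  fmt <- function(serial, elety, resid, chain, resno, x, y, z, elesy) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, elety, resid, chain, resno, x, y, z, elesy)
  }
  lines <- character(0)
  serial <- 0
  for (i in seq_len(nrow(residues))) {
    r <- residues[i, ]
    serial <- serial + 1
    lines <- c(lines, fmt(serial, " CA ", r$resid3, r$chain, r$resno,
                          r$x, r$y, r$z, "C"))
  }
  if (!is.null(extra_atoms)) {
    for (i in seq_len(nrow(extra_atoms))) {
      a <- extra_atoms[i, ]
      serial <- serial + 1
      lines <- c(lines, fmt(serial, paste0(" ", a$elety, strrep(" ", 3 - nchar(a$elety))),
                            a$resid3, a$chain, a$resno, a$x, a$y, a$z, a$elesy))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

## A structure_model built directly from coordinates (bypasses file I/O).
model_from_coords <- function(xyz, chain = "A", aa = NULL,
                              positions = NULL) {
  n <- nrow(xyz)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(positions)) positions <- seq_len(n)
  funsites:::new_structure_model(
    data.frame(chain = chain, position = positions, aa = aa,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE))
}

## Planted four-class variant set: features + true labels, sized by
## residue count (19 variants per position).
planted_variants <- function(n_residues = 100, seed = 1, ...) {
  spec <- fixture_spec(n_residues = n_residues, seed = seed, ...)
  model <- make_structure(spec)
  mats <- make_score_matrices(spec, model)
  feats <- suppressMessages(
    assemble_features(mats$ddg, mats$dde,
                      weighted_contact_number(model),
                      attr(model, "wt_sequence")))
  list(features = feats,
       labels = unname(mats$true_class[as.character(feats$position)]),
       true_class = mats$true_class, model = model,
       ddg = mats$ddg, dde = mats$dde, spec = spec)
}

## Analytic intersection of two weighted Gaussians (independent of the
## package's quadratic solver; used as the ground-truth oracle).
analytic_intersection <- function(w1, m1, s1, w3, m3, s3) {
  f <- function(x) w1 * dnorm(x, m1, s1) - w3 * dnorm(x, m3, s3)
  stats::uniroot(f, lower = m1 + 1e-9, upper = m3 - 1e-9,
                 tol = 1e-12)$root
}
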