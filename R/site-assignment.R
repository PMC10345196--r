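#' Aggregate variant predictions into residue-level class calls
#'
#' A residue is assigned the class that at least half of its classified
#' variants fall into; positions where no class reaches 50% remain
#' unclassified, as does an exact two-way 50/50 tie (noted in the `tie`
#' column -- a tie has no majority-like winner). Residues whose assigned
#' class is stable-but-inactive are flagged as predicted functional sites.
#' Fractions are taken over the variants actually classified at the
#' position, so partial mutational coverage is handled naturally.
#'
#' @param predictions data.frame with columns `position` and `class`
#'   (e.g. from [predict.classifier_bundle()]).
#' @param min_variants Minimum classified variants required to report a
#'   position (default 1).
#' @return data.frame of class `residue_assignment`: `position`,
#'   `n_variants`, one `frac_<CLASS>` column per class observed,
#'   `assigned_class` (`"UNCLASSIFIED"` when no class reaches 0.5),
#'   `functional_site` (logical), `tie` (logical).
#' @examples
#' p <- data.frame(position = rep(1, 19),
#'                 class = rep(c("SBI", "WT_LIKE"), c(10, 9)))
#' assign_residues(p)  # 10/19 >= 0.5: functional site
#' @export
assign_residues <- function(predictions, min_variants = 1) {
  stopifnot(all(c("position", "class") %in% names(predictions)))
  pred <- predictions[!is.na(predictions$class), , drop = FALSE]
  classes <- sort(unique(c(pred$class, VARIANT_CLASSES)))
  tab <- table(position = pred$position,
               class = factor(pred$class, levels = classes))
  n <- rowSums(tab)
  frac <- tab / n

  assigned <- rep("UNCLASSIFIED", nrow(tab))
  tie <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    f <- frac[i, ]
    top <- max(f)
    if (top >= 0.5) {
      winners <- names(f)[f == top]
      if (length(winners) == 1) {
        assigned[i] <- winners
      } else {
        tie[i] <- TRUE  # exact 50/50 split: no majority-like winner
      }
    }
  }

  out <- data.frame(position = as.integer(rownames(tab)),
                    n_variants = as.integer(n),
                    stringsAsFactors = FALSE)
  for (cl in classes) out[[paste0("frac_", cl)]] <- as.numeric(frac[, cl])
  out$assigned_class <- assigned
  out$functional_site <- assigned == "SBI"
  out$tie <- tie
  out <- out[out$n_variants >= min_variants, , drop = FALSE]
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  class(out) <- c("residue_assignment", "data.frame")
  out
}

#' Collapse four-class predictions to binary calls
#'
#' For validation against single-assay experiments the four classes are
#' projected onto two: in `"function"` mode, wild-type-like and
#' low-abundance/high-activity variants retain activity (`"functional"`)
#' while stable-but-inactive and total-loss variants do not
#' (`"inactive"`); in `"abundance"` mode, wild-type-like and
#' stable-but-inactive variants are `"high"` abundance, the other two
#' `"low"`.
#'
#' @param classes Character vector over [VARIANT_CLASSES].
#' @param mode `"function"` or `"abundance"`.
#' @return Character vector of binary calls.
#' @export
binary_projection <- function(classes, mode = c("function", "abundance")) {
  mode <- match.arg(mode)
  map <- if (mode == "function") {
    c(WT_LIKE = "functional", LOW_ABUNDANCE_HIGH_ACTIVITY = "functional",
      SBI = "inactive", TOTAL_LOSS = "inactive")
  } else {
    c(WT_LIKE = "high", SBI = "high",
      TOTAL_LOSS = "low", LOW_ABUNDANCE_HIGH_ACTIVITY = "low")
  }
  bad <- !is.na(classes) & !(classes %in% names(map))
  if (any(bad)) {
    stop("unknown class(es): ", paste(unique(classes[bad]), collapse = ", "))
  }
  unname(map[classes])
}

#' Compare residue assignments from two runs
#'
#' Pairs per-position class calls from two analyses of the same protein --
#' typically one using the monomer structure and one using the oligomer as
#' input to the stability predictions and contact numbers -- and tabulates
#' every class transition. Positions that are functional sites in run A
#' but total-loss in run B are highlighted: when run B is the
#' oligomer-context run, substitutions there destabilize the complex but
#' not the isolated chain, the signature of a protein-protein interface
#' residue. Positions are matched by reference-sequence numbering.
#'
#' @param run_a,run_b `residue_assignment` data.frames sharing positions.
#' @return List of class `interface_comparison`: `by_position` (position,
#'   `class_a`, `class_b`, `changed`, `interface_candidate`),
#'   `transitions` (contingency table A rows x B columns),
#'   `interface_candidates` (positions going functional -> total-loss).
#' @export
compare_runs <- function(run_a, run_b) {
  shared <- intersect(run_a$position, run_b$position)
  if (length(shared) == 0) stop("runs share no positions")
  a <- run_a[match(shared, run_a$position), ]
  b <- run_b[match(shared, run_b$position), ]
  by_pos <- data.frame(
    position = shared,
    class_a = a$assigned_class,
    class_b = b$assigned_class,
    changed = a$assigned_class != b$assigned_class,
    stringsAsFactors = FALSE
  )
  by_pos$interface_candidate <-
    a$assigned_class == "SBI" & b$assigned_class == "TOTAL_LOSS"
  levels_all <- sort(unique(c(by_pos$class_a, by_pos$class_b)))
  transitions <- table(A = factor(by_pos$class_a, levels = levels_all),
                       B = factor(by_pos$class_b, levels = levels_all))
  structure(list(by_position = by_pos, transitions = transitions,
                 interface_candidates =
                   by_pos$position[by_pos$interface_candidate]),
            class = "interface_comparison")
}

#' @export
print.interface_comparison <- function(x, ...) {
  cat("interface_comparison:", nrow(x$by_position), "shared positions,",
      sum(x$by_position$changed), "changed;",
      length(x$interface_candidates),
      "functional->total-loss interface candidate(s)\n")
  print(x$transitions)
  invisible(x)
}

#' Summarize predicted functional sites
#'
#' Counts and fractions of residues per assigned class, and -- when a
#' structure and a set of reference (e.g. catalytic) positions are given
#' -- the distribution of minimum C-alpha distances from each predicted
#' functional site to the nearest reference residue, with the fraction
#' closer than `cutoff` (default 10 Angstrom).
#'
#' @param assignments A `residue_assignment` data.frame.
#' @param model Optional [structure_model][read_structure()] for distances.
#' @param catalytic_positions Optional vector of reference positions (must
#'   all be present in `model`).
#' @param cutoff Distance cutoff in Angstrom for the proximity fraction.
#' @return List with `class_counts`, `class_fractions` (summing to 1 over
#'   assigned classes plus `UNCLASSIFIED`), `n_functional`, and when
#'   distances were computed, `functional_distances` (data.frame) and
#'   `fraction_within_cutoff`.
#' @export
functional_site_summary <- function(assignments, model = NULL,
                                    catalytic_positions = NULL,
                                    cutoff = 10) {
  counts <- table(assignments$assigned_class)
  fractions <- counts / sum(counts)
  out <- list(class_counts = counts, class_fractions = fractions,
              n_functional = sum(assignments$functional_site),
              cutoff = cutoff)
  if (!is.null(catalytic_positions)) {
    if (is.null(model)) stop("a structure model is required for distances")
    dmap <- min_distance_to_sites(model, catalytic_positions)
    fpos <- assignments$position[assignments$functional_site]
    dd <- dmap[dmap$position %in% fpos, c("position", "distance")]
    dd <- dd[!duplicated(dd$position), ]
    out$functional_distances <- dd
    out$fraction_within_cutoff <-
      if (nrow(dd) > 0) mean(dd$distance < cutoff) else NA_real_
  }
  out
}

#' Write residue assignments
#'
#' `write_residue_assignments` writes the per-residue table as CSV (with a
#' JSON class-count summary alongside when `summary_json = TRUE`).
#' `write_class_pdb` writes a C-alpha PDB trace with the assigned class
#' encoded as an integer in the B-factor column (0 unclassified, then the
#' index within [VARIANT_CLASSES]) for colouring in molecular viewers.
#'
#' @param assignments A `residue_assignment` data.frame.
#' @param path Output path.
#' @param summary_json Also write `<path>.json` with class counts.
#' @param model A `structure_model` providing coordinates.
#' @return `path`, invisibly.
#' @export
write_residue_assignments <- function(assignments, path,
                                      summary_json = TRUE) {
  utils::write.csv(as.data.frame(assignments), path, row.names = FALSE,
                   quote = FALSE)
  if (summary_json) {
    jsonlite::write_json(
      list(n_positions = nrow(assignments),
           n_functional = sum(assignments$functional_site),
           class_counts = as.list(table(assignments$assigned_class))),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_residue_assignments
#' @export
write_class_pdb <- function(model, assignments, path) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  code <- stats::setNames(seq_along(VARIANT_CLASSES), VARIANT_CLASSES)
  m <- match(res$position, assignments$position)
  b <- ifelse(is.na(m), 0,
              ifelse(assignments$assigned_class[m] == "UNCLASSIFIED", 0,
                     code[assignments$assigned_class[m]]))
  b[is.na(b)] <- 0
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(res[, c("x", "y", "z")]))),
                   resno = res$position,
                   resid = bio3d::aa123(res$aa),
                   chain = res$chain,
                   elety = rep("CA", nrow(res)),
                   b = as.numeric(b))
  invisible(path)
}
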