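## Pipeline configuration defaults: every method constant is a config key.
pipeline_defaults <- function() {
  list(
    chain = NULL,
    ddg_format = "long",        # long | matrix | rosetta
    ddg_provenance = "kcal_mol",
    dde_format = "long",        # long | matrix
    rosetta_divisor = 2.9,
    clamp_low = 0, clamp_high = 5,
    r0 = 7.0,
    exposure_threshold = 0.20,
    folds = 5,
    assign_fraction = 0.5,
    distance_cutoff = 10,
    abundance_larger_is_high = TRUE,
    activity_larger_is_high = TRUE,
    grid_search = FALSE,
    nrounds = 300,
    depth = 6, eta = 0.1, lambda = 3,
    seed = 1
  )
}

#' Read a pipeline configuration file
#'
#' Flat YAML of key-value pairs; unknown keys are kept, known keys
#' override the defaults (conversion divisor 2.9, clamp 0--5 kcal/mol,
#' contact switching midpoint 7 Angstrom, 20% exposure threshold, 5
#' cross-validation folds, 0.5 residue-assignment fraction, 10 Angstrom
#' distance cutoff).
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- pipeline_defaults()
  out[names(cfg)] <- cfg
  out
}

## internal: fail with the stage name and offending input
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full functional-site discovery pipeline
#'
#' featurize -> (label assay scores) -> train or load model -> predict ->
#' assign residues, with one seed fanned out to every random component
#' and a manifest recording the configuration, input digests, seeds and
#' package version. Reruns with the same configuration and inputs produce
#' byte-identical primary outputs.
#'
#' Required config keys: `pdb`, `ddg`, `dde`, `out_dir`, and either
#' `mave` (paired assay scores to derive training labels from) or
#' `model` (path to a previously saved bundle). Optional: `catalytic`
#' (text file of reference positions, one per line), `truth` (a fixture
#' `truth.json` to score recovery against), `wt_sequence`, plus the
#' defaults listed in [read_pipeline_config()].
#'
#' @param config Named list (or path to a YAML file) of configuration
#'   values.
#' @return Invisibly, a list with the fitted objects, output paths and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- pipeline_defaults()
  cfg[names(config)] <- config

  required <- c("pdb", "ddg", "dde", "out_dir")
  missing <- required[!vapply(required, function(k)
    !is.null(cfg[[k]]), TRUE)]
  if (length(missing) > 0) {
    stop("config missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(cfg$mave) && is.null(cfg$model)) {
    stop("config must provide either 'mave' (to train) or 'model' (to apply)")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)

  model <- stage("read-structure",
                 read_structure(cfg$pdb, chain = cfg$chain))

  ddg <- stage("read-ddg", switch(cfg$ddg_format,
    long = read_score_long(cfg$ddg, "ddG", provenance = cfg$ddg_provenance),
    matrix = read_score_matrix_tsv(cfg$ddg, "ddG",
                                   provenance = cfg$ddg_provenance),
    rosetta = read_rosetta_ddg(cfg$ddg),
    stop("unknown ddg_format: ", cfg$ddg_format)))
  dde <- stage("read-dde", switch(cfg$dde_format,
    long = read_score_long(cfg$dde, "ddE", provenance = "gemme"),
    matrix = read_score_matrix_tsv(cfg$dde, "ddE"),
    stop("unknown dde_format: ", cfg$dde_format)))
  ddg <- stage("normalize-ddg",
               normalize_ddg(ddg, rosetta_divisor = cfg$rosetta_divisor,
                             clamp_low = cfg$clamp_low,
                             clamp_high = cfg$clamp_high))

  wt_sequence <- cfg$wt_sequence
  if (is.null(wt_sequence)) {
    res <- model$residues[model$residues$chain == model$residues$chain[1], ]
    wt <- rep("X", max(res$position))
    wt[res$position] <- res$aa
    wt_sequence <- paste(wt, collapse = "")
  }

  wcn <- stage("contact-numbers",
               weighted_contact_number(model, r0 = cfg$r0))
  features <- stage("featurize",
                    assemble_features(ddg, dde, wcn, wt_sequence))
  paths <- list(features = file.path(cfg$out_dir, "features.csv"))
  write_variant_features(features, paths$features,
                         params = list(r0 = cfg$r0,
                                       rosetta_divisor = cfg$rosetta_divisor,
                                       clamp = c(cfg$clamp_low, cfg$clamp_high),
                                       seed = seed))
  message("featurize: ", sum(features$complete), "/", nrow(features),
          " complete variant rows")

  labels <- NULL
  if (!is.null(cfg$mave)) {
    mave <- stage("read-mave", read_mave(cfg$mave))
    labels <- stage("label-mave",
                    label_mave(mave, seed = seed,
                               abundance_larger_is_high =
                                 isTRUE(cfg$abundance_larger_is_high),
                               activity_larger_is_high =
                                 isTRUE(cfg$activity_larger_is_high)))
    paths$labels <- file.path(cfg$out_dir, "labels.csv")
    write_mave_labels(labels, paths$labels)
    message("label-mave: ", sum(!is.na(labels$data$class)), " labelled variants")
  }

  if (!is.null(cfg$model)) {
    bundle <- stage("load-model", load_bundle(cfg$model))
  } else {
    key_f <- paste(features$position, features$mut)
    key_l <- paste(labels$data$position, labels$data$mut)
    m <- match(key_f, key_l)
    train_ok <- features$complete & !is.na(m) &
      !is.na(labels$data$class[m])
    train_tab <- features[train_ok, , drop = FALSE]
    train_lab <- labels$data$class[m[train_ok]]
    bundle <- stage("train", {
      if (isTRUE(cfg$grid_search)) {
        grid_search(train_tab, train_lab, k = cfg$folds, seed = seed)
      } else {
        b <- train_classifier(train_tab, train_lab,
                              params = list(depth = cfg$depth, eta = cfg$eta,
                                            lambda = cfg$lambda),
                              nrounds = cfg$nrounds, seed = seed)
        b$cv <- cross_validate(train_tab, train_lab, k = cfg$folds,
                               seed = seed,
                               params = list(depth = cfg$depth, eta = cfg$eta,
                                             lambda = cfg$lambda),
                               nrounds = cfg$nrounds)
        b
      }
    })
    paths$model <- file.path(cfg$out_dir, "model.json")
    save_bundle(bundle, paths$model)
    message("train: ", bundle$n_train, " variants; mean CV accuracy ",
            signif(bundle$cv$mean_accuracy, 3))
  }

  predictions <- stage("predict", predict(bundle, features))
  paths$predictions <- file.path(cfg$out_dir, "predictions.csv")
  utils::write.csv(predictions, paths$predictions, row.names = FALSE,
                   quote = FALSE)
  message("predict: ", nrow(predictions), " variants classified, ",
          nrow(attr(predictions, "unpredicted")), " unpredicted")

  assignments <- stage("assign-sites", assign_residues(predictions))
  paths$residues <- file.path(cfg$out_dir, "residues.csv")
  write_residue_assignments(assignments, paths$residues)
  paths$class_pdb <- file.path(cfg$out_dir, "classes.pdb")
  write_class_pdb(model, assignments, paths$class_pdb)
  message("assign-sites: ", nrow(assignments), " positions, ",
          sum(assignments$functional_site), " functional sites")

  summary_args <- list(assignments = assignments)
  if (!is.null(cfg$catalytic)) {
    cat_pos <- as.integer(readLines(cfg$catalytic))
    summary_args <- list(assignments = assignments, model = model,
                         catalytic_positions = cat_pos,
                         cutoff = cfg$distance_cutoff)
  }
  site_summary <- stage("summarize", do.call(functional_site_summary,
                                             summary_args))

  report <- NULL
  if (!is.null(cfg$truth)) {
    truth <- jsonlite::read_json(cfg$truth, simplifyVector = TRUE)
    true_class <- unlist(truth$true_class)
    true_fun <- as.integer(names(true_class)[true_class == "SBI"])
    called_fun <- assignments$position[assignments$functional_site]
    all_pos <- assignments$position
    tp <- length(intersect(called_fun, true_fun))
    fn <- length(setdiff(intersect(true_fun, all_pos), called_fun))
    fp <- length(setdiff(called_fun, true_fun))
    tn <- length(all_pos) - tp - fn - fp
    report <- list(
      n_positions = length(all_pos),
      tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA
    )
    paths$report <- file.path(cfg$out_dir, "report.json")
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    message("truth comparison: sensitivity ", signif(report$sensitivity, 3),
            ", specificity ", signif(report$specificity, 3))
  }

  input_files <- unlist(cfg[intersect(c("pdb", "ddg", "dde", "mave",
                                        "model", "catalytic", "truth"),
                                      names(cfg))])
  manifest <- list(
    command = "run_pipeline",
    version = as.character(utils::packageVersion("funsites")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_digests = as.list(tools::md5sum(input_files))
  )
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(model = model, features = features, labels = labels,
                 bundle = bundle, predictions = predictions,
                 assignments = assignments, site_summary = site_summary,
                 report = report, paths = paths, manifest = manifest))
}
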