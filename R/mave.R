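#' The four phenotypic variant classes
#'
#' Wild-type-like (high abundance, high activity), total loss (low/low),
#' stable-but-inactive (high abundance, low activity -- the signature of a
#' directly functional residue) and low abundance with retained activity.
#' @export
VARIANT_CLASSES <- c("WT_LIKE", "TOTAL_LOSS", "SBI",
                     "LOW_ABUNDANCE_HIGH_ACTIVITY")

#' Fit a three-component Gaussian mixture to assay scores
#'
#' Deep mutational scanning score distributions are typically multimodal:
#' a wild-type-like mode, a loss-of-function mode, and intermediate-effect
#' variants between them. This fits a free three-component univariate
#' Gaussian mixture by expectation-maximization, with k-means
#' initialization and multiple restarts (best log-likelihood kept), so the
#' two outer components can anchor a classification threshold. Components
#' are returned sorted by mean, making the fit invariant to label
#' switching; the whole procedure is deterministic given `seed`.
#'
#' @param scores Numeric vector of assay scores (at least 30 finite values).
#' @param seed Integer seed controlling k-means restarts.
#' @param n_restarts Number of EM restarts (default 10).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `gmm3_fit`: list with `components`
#'   (data.frame `weight`, `mean`, `sd`, sorted by mean), `loglik`,
#'   `n_iter`, `seed`.
#' @export
fit_three_gaussians <- function(scores, seed = 1, n_restarts = 10,
                                max_iter = 1000, tol = 1e-8) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  if (n < 30) stop("need at least 30 scores to fit three components")
  if (diff(range(scores)) == 0) {
    stop("degenerate data: all scores identical")
  }

  sd_floor <- max(1e-6, 1e-4 * stats::sd(scores))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    km <- suppressWarnings(stats::kmeans(scores, centers = 3, nstart = 1,
                                         iter.max = 50))
    mu <- as.numeric(km$centers)
    sig <- vapply(1:3, function(k) {
      v <- stats::sd(scores[km$cluster == k])
      if (!is.finite(v) || v < sd_floor) sd_floor * 10 else v
    }, numeric(1))
    w <- as.numeric(table(factor(km$cluster, levels = 1:3))) / n
    w[w == 0] <- 1e-6
    w <- w / sum(w)

    ll_old <- -Inf
    converged <- FALSE
    iter <- 0
    repeat {
      iter <- iter + 1
      ## E-step in log space
      lp <- vapply(1:3, function(k) {
        log(w[k]) + stats::dnorm(scores, mu[k], sig[k], log = TRUE)
      }, numeric(n))
      m <- apply(lp, 1, max)
      lse <- m + log(rowSums(exp(lp - m)))
      ll <- sum(lse)
      resp <- exp(lp - lse)
      ## M-step
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * scores) / nk
      sig <- sqrt(colSums(resp * (scores - rep(mu, each = n))^2) / nk)
      sig <- pmax(sig, sd_floor)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_old <- ll
    }
    if (converged && (is.null(best) || ll > best$loglik)) {
      best <- list(w = w, mu = mu, sig = sig, loglik = ll, n_iter = iter)
    }
  }
  if (is.null(best)) {
    stop("EM failed to converge in any of ", n_restarts,
         " restarts (max_iter = ", max_iter, ", tol = ", tol, ")")
  }
  ord <- order(best$mu)
  structure(list(
    components = data.frame(weight = best$w[ord], mean = best$mu[ord],
                            sd = best$sig[ord]),
    loglik = best$loglik, n_iter = best$n_iter, seed = seed
  ), class = "gmm3_fit")
}

#' @export
print.gmm3_fit <- function(x, ...) {
  cat("3-component Gaussian mixture (logLik ", signif(x$loglik, 6), "):\n",
      sep = "")
  print(format(x$components, digits = 4))
  invisible(x)
}

#' Classification threshold from the outer mixture components
#'
#' Solves for the score at which the weighted densities of the first
#' (lowest-mean) and last (highest-mean) fitted Gaussians are equal --
#' the natural decision boundary between the low and high score modes.
#' The middle component only absorbs intermediate-effect variants and
#' plays no role here. The equality is a quadratic in the score (linear
#' when the two standard deviations coincide); the root lying strictly
#' between the two outer means is returned.
#'
#' @param fit A `gmm3_fit` (or any list with a `components` data.frame of
#'   `weight`, `mean`, `sd` sorted by mean; only rows 1 and the last row
#'   are used).
#' @return The threshold score (scalar).
#' @export
intersection_threshold <- function(fit) {
  comp <- fit$components
  k <- nrow(comp)
  w1 <- comp$weight[1]; m1 <- comp$mean[1]; s1 <- comp$sd[1]
  w3 <- comp$weight[k]; m3 <- comp$mean[k]; s3 <- comp$sd[k]
  if (m3 <= m1) stop("outer component means must be distinct and ordered")

  ## w1 N(x; m1, s1) = w3 N(x; m3, s3)  =>  a x^2 + b x + c = 0
  a <- 1 / (2 * s3^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m3 / s3^2
  c <- m3^2 / (2 * s3^2) - m1^2 / (2 * s1^2) + log((w1 * s3) / (w3 * s1))

  if (abs(a) < 1e-12 * (1 / s1^2)) {
    roots <- -c / b
  } else {
    disc <- b^2 - 4 * a * c
    if (disc < 0) {
      stop("outer-component densities do not intersect between the modes; ",
           "supply a manual threshold")
    }
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m3]
  if (length(inside) == 0) {
    stop("no density intersection between the outer means (",
         signif(m1, 4), ", ", signif(m3, 4), "); supply a manual threshold")
  }
  inside[1]
}

#' Binary high/low calls from a score threshold
#'
#' @param scores Numeric assay scores.
#' @param threshold Finite threshold score.
#' @param larger_is_functional Direction of the assay: if `TRUE` (default)
#'   larger scores mean more functional/abundant. Scores on the functional
#'   side of the threshold are called `"high"`; a score exactly at the
#'   threshold counts as `"high"` in either orientation (a fixed,
#'   documented convention -- with continuous scores ties are measure-zero).
#' @return Character vector of `"high"` / `"low"` (`NA` in, `NA` out).
#' @export
binarize <- function(scores, threshold, larger_is_functional = TRUE) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  functional_side <- if (larger_is_functional) scores >= threshold
                     else scores <= threshold
  ifelse(is.na(scores), NA_character_,
         ifelse(functional_side, "high", "low"))
}

#' Combine paired abundance/activity calls into the four variant classes
#'
#' high/high is wild-type-like, low/low a total loss, high abundance with
#' low activity a stable-but-inactive (SBI) variant, and low abundance
#' with high activity the remaining class. Variants missing either call
#' map to `NA` and are excluded from training by the callers.
#'
#' @param abundance_call,activity_call Character vectors of
#'   `"high"`/`"low"` calls.
#' @return Character vector over [VARIANT_CLASSES].
#' @export
combine_classes <- function(abundance_call, activity_call) {
  stopifnot(length(abundance_call) == length(activity_call))
  key <- paste(abundance_call, activity_call, sep = "/")
  map <- c("high/high" = "WT_LIKE",
           "low/low"   = "TOTAL_LOSS",
           "high/low"  = "SBI",
           "low/high"  = "LOW_ABUNDANCE_HIGH_ACTIVITY")
  out <- unname(map[key])
  out[is.na(abundance_call) | is.na(activity_call)] <- NA_character_
  out
}

#' Read a paired MAVE score table
#'
#' CSV with header `position,wt,mut,abundance_score,activity_score`;
#' either score column may be absent (single-assay validation mode).
#'
#' @param path CSV file path.
#' @return data.frame with one row per variant.
#' @export
read_mave <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "wt", "mut")
  if (!all(need %in% names(tab))) {
    stop("MAVE table must have columns position, wt, mut")
  }
  if (!any(c("abundance_score", "activity_score") %in% names(tab))) {
    stop("MAVE table has neither abundance_score nor activity_score")
  }
  id <- paste0(tab$wt, tab$position, tab$mut)
  if (anyDuplicated(id)) {
    stop("duplicated variant(s): ", paste(utils::head(id[duplicated(id)], 5),
                                          collapse = ", "))
  }
  tab
}

#' Derive four-class training labels from paired MAVE scores
#'
#' For each assay, fits the trimodal score distribution with
#' [fit_three_gaussians()], takes the [intersection_threshold()] of the
#' outer components as the cutoff, and binarizes. Paired calls are then
#' combined into the four variant classes. Assay orientation (whether a
#' large score means functional/abundant) is a required input, never
#' inferred from the data.
#'
#' @param mave data.frame from [read_mave()] with both score columns.
#' @param seed Integer seed for the mixture fits.
#' @param abundance_larger_is_high,activity_larger_is_high Orientation of
#'   each assay (default `TRUE`: larger score = more abundant / active).
#' @return An object of class `mave_labels`: list with `data` (the input
#'   plus `abundance_call`, `activity_call`, `class` columns), `fits`
#'   (per-assay `gmm3_fit`s), and `thresholds`.
#' @export
label_mave <- function(mave, seed = 1,
                       abundance_larger_is_high = TRUE,
                       activity_larger_is_high = TRUE) {
  stopifnot(all(c("abundance_score", "activity_score") %in% names(mave)))
  fits <- list(
    abundance = fit_three_gaussians(
      mave$abundance_score[is.finite(mave$abundance_score)], seed = seed),
    activity = fit_three_gaussians(
      mave$activity_score[is.finite(mave$activity_score)], seed = seed + 1L)
  )
  thresholds <- c(abundance = intersection_threshold(fits$abundance),
                  activity = intersection_threshold(fits$activity))
  out <- mave
  out$abundance_call <- binarize(mave$abundance_score, thresholds["abundance"],
                                 abundance_larger_is_high)
  out$activity_call <- binarize(mave$activity_score, thresholds["activity"],
                                activity_larger_is_high)
  out$class <- combine_classes(out$abundance_call, out$activity_call)
  n_na <- sum(is.na(out$class))
  if (n_na > 0) {
    message(n_na, " variant(s) missing an assay call excluded from labels")
  }
  structure(list(data = out, fits = fits, thresholds = thresholds,
                 seed = seed,
                 orientation = c(abundance = abundance_larger_is_high,
                                 activity = activity_larger_is_high)),
            class = "mave_labels")
}

#' @export
print.mave_labels <- function(x, ...) {
  cat("mave_labels:", nrow(x$data), "variants; thresholds",
      paste(names(x$thresholds), signif(x$thresholds, 4),
            sep = "=", collapse = ", "), "\n")
  print(table(x$data$class, useNA = "ifany"))
  invisible(x)
}

#' Write labelled MAVE data with a mixture-parameter sidecar
#'
#' Writes the labelled variant table as CSV and, alongside it, a JSON
#' sidecar (`<path>.json`) recording the fitted mixture parameters,
#' thresholds, orientations and seed for provenance.
#'
#' @param labels A `mave_labels` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mave_labels <- function(labels, path) {
  utils::write.csv(labels$data, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    thresholds = as.list(labels$thresholds),
    orientation = as.list(labels$orientation),
    seed = labels$seed,
    fits = lapply(labels$fits, function(f) {
      list(components = f$components, loglik = f$loglik, n_iter = f$n_iter)
    })
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
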