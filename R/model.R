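#' Fit the linear model linking divergence to optimal mismatch rate
#'
#' Ordinary least squares of the observed optimal mismatch rate (percent of
#' read length) on genetic distance or per-residue mutation rate (a fraction
#' in `[0, 1]`). This is the model at the core of the pseudo-reference
#' decision: given a distance to a candidate pseudo-reference it predicts the
#' mapping mismatch budget that maximizes the unique mapping rate.
#'
#' @param points Tibble of training points.
#' @param x,y Column names for predictor and response. Defaults match the
#'   output of [virtual_experiment()].
#' @return An object of class `pra_model` with elements `slope` (percent per
#'   unit distance), `intercept` (percent), `r2`, `rmse` (training, percent
#'   points), `points`, and the underlying `lm` fit.
#' @export
fit_mismatch_model <- function(points, x = "mutation_rate",
                               y = "optimal_mismatch_rate") {
  stopifnot(all(c(x, y) %in% names(points)))
  px <- points[[x]]
  py <- points[[y]]
  ok <- is.finite(px) & is.finite(py)
  if (sum(ok) < 2) abort("need at least two finite training points")
  if (length(unique(px[ok])) < 2) abort("all predictor values are equal")
  dat <- data.frame(x = px[ok], y = py[ok])
  fit <- lm(y ~ x, data = dat)
  res <- stats::residuals(fit)
  ss_tot <- sum((dat$y - mean(dat$y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r2 = r2,
      rmse = sqrt(mean(res^2)),
      points = tibble(x = dat$x, y = dat$y),
      x_name = x, y_name = y,
      fit = fit
    ),
    class = "pra_model"
  )
}

#' @export
print.pra_model <- function(x, ...) {
  cat(sprintf(
    "<pra_model> optimal mismatch rate (%%) = %.3f + %.3f * %s  (r2 = %.4f, rmse = %.3f, n = %d)\n",
    x$intercept, x$slope, x$x_name, x$r2, x$rmse, nrow(x$points)
  ))
  invisible(x)
}

#' @rdname fit_mismatch_model
#' @param x A `pra_model`.
#' @param ... Unused.
#' @export
tidy.pra_model <- function(x, ...) {
  tibble(
    term = c("(Intercept)", x$x_name),
    estimate = c(x$intercept, x$slope),
    std.error = unname(summary(x$fit)$coefficients[, "Std. Error"])
  )
}

#' @rdname fit_mismatch_model
#' @export
glance.pra_model <- function(x, ...) {
  tibble(r.squared = x$r2, rmse = x$rmse, nobs = nrow(x$points))
}

#' Predict the optimal mismatch rate for a new distance
#'
#' Applies the fitted line and clamps the prediction to `[0, 100]` percent.
#' Predictions outside the training range carry an extrapolation warning.
#'
#' @param model A `pra_model`.
#' @param x Genetic distance or mutation rate (same scale the model was
#'   trained on); non-negative.
#' @param read_length Optional read length L; when given, the nearest integer
#'   mismatch count `N = round(rate/100 * L)` is included.
#' @return A tibble with `x`, `predicted_mismatch_rate` (percent) and, when
#'   `read_length` is given, `predicted_N`.
#' @export
predict_mismatch <- function(model, x, read_length = NULL) {
  stopifnot(inherits(model, "pra_model"))
  if (any(x < 0)) abort("distance must be non-negative")
  rng <- range(model$points$x)
  if (any(x < rng[1] | x > rng[2])) {
    warn("prediction outside the training range (extrapolation)")
  }
  rate <- pmin(pmax(model$intercept + model$slope * x, 0), 100)
  out <- tibble(x = x, predicted_mismatch_rate = rate)
  if (!is.null(read_length)) {
    out$predicted_N <- as.integer(round(rate / 100 * read_length))
  }
  out
}

#' Root-mean-square error on held-out points
#'
#' Fits the linear model on `train_points` and measures the RMSE of its
#' predictions on `test_points`.
#'
#' @inheritParams fit_mismatch_model
#' @param train_points,test_points Tibbles of points (same columns).
#' @return A single number (percent points).
#' @export
holdout_rmse <- function(train_points, test_points, x = "mutation_rate",
                         y = "optimal_mismatch_rate") {
  if (nrow(test_points) == 0) abort("no test points")
  model <- fit_mismatch_model(train_points, x = x, y = y)
  pred <- model$intercept + model$slope * test_points[[x]]
  sqrt(mean((pred - test_points[[y]])^2))
}

#' Decision thresholds for choosing an assembly strategy
#'
#' Shipped defaults: a pseudo-reference is considered close enough when the
#' genetic distance is at most 0.101 for the orthologous transcriptome,
#' 0.189 for 16S rRNA or 0.363 for the mitochondrial D-loop (the largest
#' distances at which pseudo-reference-based assembly still outperformed de
#' novo assembly), and the predicted optimal mismatch rate must not exceed
#' 14.44%. When several markers are available the preference order is
#' orthologous transcriptome, then 16S, then D-loop. Boundaries are
#' inclusive. `max_ambiguous` is the N-base fraction above which the read QC
#' warning fires.
#'
#' @param p_ortholog,p_16s,p_dloop Per-marker distance thresholds.
#' @param max_mismatch_rate Upper bound on the predicted rate, percent.
#' @param max_ambiguous Ambiguous-base fraction triggering the QC warning.
#' @return A named list of class `decision_thresholds`.
#' @export
decision_thresholds <- function(p_ortholog = 0.101, p_16s = 0.189,
                                p_dloop = 0.363, max_mismatch_rate = 14.44,
                                max_ambiguous = 0.05) {
  stopifnot(p_ortholog > 0, p_16s > 0, p_dloop > 0, max_mismatch_rate > 0)
  structure(
    list(
      p = c(ortholog = p_ortholog, `16s` = p_16s, dloop = p_dloop),
      preference = c("ortholog", "16s", "dloop"),
      max_mismatch_rate = max_mismatch_rate,
      max_ambiguous = max_ambiguous
    ),
    class = "decision_thresholds"
  )
}

#' Decide among reference-based, pseudo-reference-based and de novo assembly
#'
#' The decision flow: (1) if the species' own reference genome is available,
#' use it; (2) otherwise take the first marker available in the preference
#' order (orthologous transcriptome, 16S, D-loop); if its distance is within
#' the marker's threshold AND the model-predicted optimal mismatch rate is
#' within `max_mismatch_rate`, recommend pseudo-reference-based assembly with
#' that predicted rate; (3) otherwise recommend de novo assembly. A read set
#' with a high fraction of ambiguous bases adds a warning that the observed
#' optimum may exceed the prediction (N bases never match, so they act as
#' extra mismatches).
#'
#' @param ref_available Is the query species' own genome available?
#' @param distances Named numeric vector of per-marker genetic distances;
#'   names among `ortholog`, `16s`, `dloop`.
#' @param model A `pra_model` (default [default_model()]).
#' @param thresholds A [decision_thresholds()] object.
#' @param read_ambiguous_fraction Optional [ambiguous_fraction()] of the read
#'   set, for the QC warning.
#' @param read_length Read length, to report the integer mismatch budget.
#' @return An object of class `pra_decision`: list with `strategy`
#'   (`"REFERENCE_BASED"`, `"PRA"` or `"DE_NOVO"`), `marker`, `distance`,
#'   `predicted_mismatch_rate` (present iff strategy is PRA), `predicted_N`,
#'   `rationale` and `warnings`.
#' @export
decide_strategy <- function(ref_available = FALSE, distances = NULL,
                            model = default_model(),
                            thresholds = decision_thresholds(),
                            read_ambiguous_fraction = NULL,
                            read_length = 100L) {
  warnings <- character()
  if (!is.null(read_ambiguous_fraction) &&
      read_ambiguous_fraction > thresholds$max_ambiguous) {
    warnings <- c(warnings, sprintf(
      "ambiguous-base fraction %.3f exceeds %.3f: observed optimal mismatch rates may exceed the model prediction",
      read_ambiguous_fraction, thresholds$max_ambiguous
    ))
  }
  mk_decision <- function(strategy, marker = NA_character_,
                          distance = NA_real_, rate = NULL, rationale) {
    structure(
      list(
        strategy = strategy, marker = marker, distance = distance,
        predicted_mismatch_rate = if (is.null(rate)) NA_real_ else rate,
        predicted_N = if (is.null(rate)) NA_integer_
                      else as.integer(round(rate / 100 * read_length)),
        rationale = rationale, warnings = warnings
      ),
      class = "pra_decision"
    )
  }
  if (isTRUE(ref_available)) {
    return(mk_decision(
      "REFERENCE_BASED",
      rationale = "the species' own reference genome is available"
    ))
  }
  if (is.null(distances) || length(distances) == 0 || all(is.na(distances))) {
    abort("cannot decide: no reference available and no genetic distance supplied")
  }
  marker <- thresholds$preference[
    thresholds$preference %in% names(distances)[!is.na(distances)]
  ][1]
  if (is.na(marker)) {
    abort(paste0(
      "cannot decide: distances must be named among ",
      paste(thresholds$preference, collapse = ", ")
    ))
  }
  d <- unname(distances[[marker]])
  p <- thresholds$p[[marker]]
  pred <- suppressWarnings(predict_mismatch(model, d, read_length))
  rate <- pred$predicted_mismatch_rate[1]
  if (d <= p && rate <= thresholds$max_mismatch_rate) {
    mk_decision(
      "PRA", marker, d, rate,
      rationale = sprintf(
        "%s distance %.4g is within %.4g and predicted mismatch rate %.2f%% is within %.2f%%",
        marker, d, p, rate, thresholds$max_mismatch_rate
      )
    )
  } else {
    mk_decision(
      "DE_NOVO", marker, d,
      rationale = sprintf(
        "%s distance %.4g vs threshold %.4g, predicted mismatch rate %.2f%% vs bound %.2f%%: pseudo-reference too distant",
        marker, d, p, rate, thresholds$max_mismatch_rate
      )
    )
  }
}

#' @export
print.pra_decision <- function(x, ...) {
  cat("<pra_decision>", x$strategy, "\n")
  cat("  rationale:", x$rationale, "\n")
  if (x$strategy == "PRA") {
    cat(sprintf(
      "  predicted optimal mismatch rate: %.2f%% (N = %d)\n",
      x$predicted_mismatch_rate, x$predicted_N
    ))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' The bundled default mismatch-rate model
#'
#' The package does not hard-code model coefficients: the canonical model is
#' a procedure (run [virtual_experiment()], then [fit_mismatch_model()]).
#' For convenience a training-point table from one seeded synthetic run is
#' bundled and refitted on load, so the default model is always derived from
#' its stored points.
#'
#' @return A `pra_model`.
#' @export
default_model <- function() {
  path <- system.file("extdata", "default_model_points.tsv", package = "pseudoref")
  pts <- readr::read_tsv(path, show_col_types = FALSE)
  fit_mismatch_model(pts)
}

#' Write / read a fitted model as JSON
#'
#' The JSON holds the coefficients, fit statistics and the training points;
#' [read_model()] refits from the stored points, so a round trip reproduces
#' the model exactly from its data rather than trusting stored coefficients.
#'
#' @param model A `pra_model`.
#' @param path JSON path.
#' @return `path` invisibly; for [read_model()], a `pra_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pra_model"))
  jsonlite::write_json(
    list(
      slope = model$slope, intercept = model$intercept,
      r2 = model$r2, rmse = model$rmse,
      x_name = model$x_name, y_name = model$y_name,
      points = model$points
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- tibble(x = obj$points$x, y = obj$points$y)
  names(pts) <- c(obj$x_name %||% "mutation_rate", obj$y_name %||% "optimal_mismatch_rate")
  fit_mismatch_model(pts, x = names(pts)[1], y = names(pts)[2])
}
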