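# ToxPi-style weighted-slice risk integration. A metric table (chemicals x
# named metrics) plus a config assigning each metric a transform, a class
# (slice) and optionally a control value is turned into per-class slice
# scores in [0,1], a weighted overall score and a rank per chemical.
#
# Pipeline per metric: transform (orient so larger = higher concern) ->
# min-max scale across chemicals -> average within class -> weighted sum of
# class scores. Degenerate (constant) metrics scale to 0 for every chemical
# so that a metric showing no variation contributes nothing; missing values
# also scale to 0 (the ToxPi missing-data convention).

#' Construct a ToxPi metric table
#'
#' @param values Numeric matrix or data frame, chemicals in rows (rownames),
#'   metrics in columns; at least 2 chemicals. `NA` marks missing slots.
#' @param config Data frame with one row per metric: `metric`, `class`,
#'   `transform` (`"identity"`, `"negate"` or `"absdiff_vs_control"`) and
#'   `control_value` (required for `absdiff_vs_control`, `NA` otherwise).
#' @return Object of class `metric_table`.
#' @export
metric_table <- function(values, config) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("min-max scaling needs at least 2 chemicals")
  if (is.null(rownames(values))) stop("values must have chemical rownames")
  stopifnot(all(c("metric", "class", "transform") %in% names(config)))
  if (!"control_value" %in% names(config)) config$control_value <- NA_real_
  miss <- setdiff(colnames(values), config$metric)
  if (length(miss)) {
    stop("metrics missing from config: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(config$metric)) stop("each metric must appear once in config")
  bad <- setdiff(config$transform,
                 c("identity", "negate", "absdiff_vs_control"))
  if (length(bad)) stop("unknown transform(s): ", paste(bad, collapse = ", "))
  needs_ctrl <- config$transform == "absdiff_vs_control"
  if (any(needs_ctrl & is.na(config$control_value))) {
    stop("absdiff_vs_control metrics need a control_value")
  }
  config <- config[match(colnames(values), config$metric), ]
  structure(list(values = values, config = config), class = "metric_table")
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("<metric_table> %d chemicals x %d metrics in %d classes\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$config$class))))
  invisible(x)
}

#' Orient a raw metric so larger means higher concern
#'
#' `identity` leaves values unchanged; `negate` flips sign (for docking
#' scores and binding free energies, where more negative = stronger binding =
#' higher concern); `absdiff_vs_control` replaces each value with its
#' absolute difference from a control value (for structural-perturbation
#' metrics where change in either direction is the signal).
#'
#' @param values Named numeric vector (chemical -> value).
#' @param transform One of `"identity"`, `"negate"`, `"absdiff_vs_control"`.
#' @param control_value Control value, required for `absdiff_vs_control`.
#' @return Named numeric vector, same names.
#' @export
transform_metric <- function(values, transform, control_value = NULL) {
  switch(transform,
    identity = values,
    negate = -values,
    absdiff_vs_control = {
      if (is.null(control_value) || is.na(control_value)) {
        stop("absdiff_vs_control requires a control_value")
      }
      abs(values - control_value)
    },
    stop("unknown transform: ", transform)
  )
}

#' Min-max scale a metric across chemicals
#'
#' Maps values to [0,1] by `(v - min)/(max - min)`. A constant metric
#' (max == min) scales to 0 for every chemical; `NA` values scale to 0.
#' With `method = "xmax"` values are instead divided by the maximum
#' (an alternative uniformization retained behind this flag).
#'
#' @param values Named numeric vector, at least 2 entries.
#' @param method `"minmax"` (default) or `"xmax"`.
#' @return Named numeric vector in [0,1].
#' @export
minmax_scale <- function(values, method = c("minmax", "xmax")) {
  method <- match.arg(method)
  if (length(values) < 2) stop("min-max scaling needs at least 2 values")
  out <- rep(0, length(values))
  names(out) <- names(values)
  ok <- !is.na(values)
  if (!any(ok)) return(out)
  v <- values[ok]
  if (method == "minmax") {
    rng <- range(v)
    if (rng[2] > rng[1]) out[ok] <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    m <- max(v)
    if (m != 0) out[ok] <- v / m
  }
  out
}

#' Compute ToxPi slice and overall scores
#'
#' Each metric is transformed and scaled, slice scores are the arithmetic
#' mean of the scaled metrics in each class, and the overall score is the
#' weight-weighted sum of slice scores. Weights must sum to 1 (default:
#' equal 20% weights over the table's five classes, or uniform weights for
#' any other class count).
#'
#' @param table A [metric_table()].
#' @param weights Named numeric vector class -> weight, summing to 1 within
#'   1e-9. `NULL` for uniform weights.
#' @param scale_method Passed to [minmax_scale()].
#' @return Object of class `toxpi_result`: data frame with one row per
#'   chemical (`chemical`, one `slice_*` column per class, `overall`,
#'   `rank`), ordered by rank; the scaled metric matrix is attached as
#'   attribute `"scaled"`.
#' @export
toxpi_scores <- function(table, weights = NULL,
                         scale_method = c("minmax", "xmax")) {
  stopifnot(inherits(table, "metric_table"))
  scale_method <- match.arg(scale_method)
  cfg <- table$config
  classes <- unique(cfg$class)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(classes), length(classes)),
                               classes)
  }
  miss <- setdiff(classes, names(weights))
  if (length(miss)) {
    stop("classes missing from weights: ", paste(miss, collapse = ", "))
  }
  if (abs(sum(weights[classes]) - 1) > 1e-9) stop("weights must sum to 1")
  scaled <- vapply(seq_len(ncol(table$values)), function(j) {
    tr <- transform_metric(table$values[, j], cfg$transform[[j]],
                           cfg$control_value[[j]])
    minmax_scale(tr, method = scale_method)
  }, numeric(nrow(table$values)))
  dimnames(scaled) <- dimnames(table$values)
  slice <- vapply(classes, function(cl) {
    rowMeans(scaled[, cfg$metric[cfg$class == cl], drop = FALSE])
  }, numeric(nrow(scaled)))
  overall <- as.numeric(slice %*% weights[classes])
  out <- data.frame(chemical = rownames(table$values),
                    stats::setNames(as.data.frame(slice),
                                    paste0("slice_", classes)),
                    overall = overall, check.names = FALSE)
  out <- rank_profiles(out)
  attr(out, "scaled") <- scaled
  attr(out, "weights") <- weights[classes]
  class(out) <- c("toxpi_result", class(out))
  out
}

#' Rank ToxPi profiles by overall score
#'
#' Descending overall score; ties broken lexicographically by chemical name;
#' ranks assigned 1..n.
#'
#' @param results Data frame with columns `chemical` and `overall`.
#' @return The data frame ordered by rank with a `rank` column.
#' @export
rank_profiles <- function(results) {
  stopifnot(all(c("chemical", "overall") %in% names(results)))
  ord <- order(-results$overall, results$chemical)
  out <- results[ord, setdiff(names(results), "rank"), drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.toxpi_result <- function(x, ...) {
  cat("<toxpi_result>\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Read a ToxPi metric table from CSV + JSON config
#'
#' The CSV holds chemicals in a `chemical` column and metrics in the
#' remaining columns; the JSON config maps each metric name to
#' `{class, transform, control_value?}`.
#'
#' @param values_path CSV path.
#' @param config_path JSON path.
#' @return A [metric_table()].
#' @export
read_metric_table <- function(values_path, config_path) {
  df <- utils::read.csv(values_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"chemical" %in% names(df)) stop(values_path, ": no 'chemical' column")
  extra <- setdiff(names(df), "chemical")
  # a 'verified' bookkeeping column may accompany fixtures; it is not a metric
  extra <- setdiff(extra, "verified")
  vals <- as.matrix(df[, extra, drop = FALSE])
  rownames(vals) <- df$chemical
  cfgl <- jsonlite::read_json(config_path)
  cfg <- do.call(rbind, lapply(names(cfgl), function(m) {
    e <- cfgl[[m]]
    data.frame(metric = m, class = e$class, transform = e$transform,
               control_value = if (is.null(e$control_value)) NA_real_
                               else as.numeric(e$control_value))
  }))
  metric_table(vals, cfg)
}
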