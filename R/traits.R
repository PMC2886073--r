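#' Construct / validate a trait table
#'
#' A trait table has one row per metric x species x population measurement.
#' The `population` column is optional; a missing or empty population id
#' means the species contributes a single measurement for that metric.
#'
#' @param x A data.frame with columns `metric`, `species`, `value` and
#'   optionally `population`.
#' @return A validated `trait_table` (a data.frame).
#' @export
as_trait_table <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("metric", "species", "value")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("trait table is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"population" %in% names(x)) x$population <- ""
  x <- x[, c("metric", "species", "population", "value")]
  for (col in c("metric", "species", "population"))
    x[[col]] <- trimws(as.character(x[[col]]))
  x$population[is.na(x$population)] <- ""
  if (!is.numeric(x$value)) {
    val <- suppressWarnings(as.numeric(x$value))
    bad <- which(is.na(val) & !is.na(x$value) & nzchar(trimws(x$value)))
    if (length(bad))
      stop("non-numeric trait value(s) in row(s): ", paste(bad, collapse = ", "))
    x$value <- val
  }
  bad <- which(!is.finite(x$value))
  if (length(bad))
    stop("missing or non-finite trait value(s) in row(s): ",
         paste(bad, collapse = ", "))
  key <- paste(x$metric, x$species, x$population, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (metric, species, population) row(s): ",
         paste(d, collapse = ", "))
  }
  class(x) <- c("trait_table", "data.frame")
  x
}

#' Read a trait table from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row containing
#' `metric`, `species`, `value` and optionally `population`.
#'
#' @param path Path to the CSV file.
#' @return A `trait_table`.
#' @export
read_trait_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = TRUE)
  as_trait_table(x)
}

#' Write a trait table to CSV
#'
#' @param table A `trait_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Box-Cox transform a vector of trait values
#'
#' Fits the Box-Cox exponent by maximizing the profile log-likelihood of
#' the power-transformed sample over lambda in \[-5, 5\], and returns the
#' transformed values. Non-positive inputs are first shifted by
#' `-min(values) + 1e-6 * range` so that the power transform is defined.
#' The transform is `(x^lambda - 1)/lambda` for `lambda != 0` and `log(x)`
#' for `lambda = 0`.
#'
#' @param values Numeric vector, length >= 3, not all equal.
#' @param lambda Optional: fix the exponent instead of estimating it.
#' @return List with `transformed`, `lambda` and `shift`.
#' @examples
#' boxcox_transform(rlnorm(50))$lambda
#' @export
boxcox_transform <- function(values, lambda = NULL) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop("need at least 3 values to fit a Box-Cox transform")
  if (any(!is.finite(values))) stop("values must be finite")
  rng <- diff(range(values))
  if (rng == 0) stop("degenerate input: all values equal")
  shift <- if (min(values) <= 0) -min(values) + 1e-6 * rng else 0
  x <- values + shift
  lx <- log(x)
  slx <- sum(lx)
  n <- length(x)
  profile_ll <- function(l) {
    y <- if (abs(l) < 1e-10) lx else (x^l - 1) / l
    v <- mean((y - mean(y))^2)
    -n / 2 * log(v) + (l - 1) * slx
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(profile_ll, interval = c(-5, 5),
                           maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
  }
  transformed <- if (abs(lambda) < 1e-10) lx else (x^lambda - 1) / lambda
  list(transformed = transformed, lambda = lambda, shift = shift)
}

#' Standardize values to zero mean and unit population variance
#'
#' Centers and divides by the standard deviation with divisor `n` (not
#' `n - 1`), so that the total quadratic entropy of the standardized values
#' is exactly 1 and node contributions read directly as proportions of
#' total trait diversity.
#'
#' @param values Numeric vector with positive variance.
#' @return List with `scaled`, `scale` (the divisor-n sd) and `center`.
#' @examples
#' standardize(c(0, 2, 4, 6))$scaled
#' @export
standardize <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  center <- mean(values)
  v <- mean((values - center)^2)
  if (v <= 0) stop("degenerate input: zero variance")
  scale <- sqrt(v)
  list(scaled = (values - center) / scale, scale = scale, center = center)
}

#' Per-species mean trait values
#'
#' @param table A `trait_table`.
#' @param metric Metric name to extract.
#' @return Named numeric vector: species -> mean over its populations.
#' @export
species_means <- function(table, metric) {
  table <- as_trait_table(as.data.frame(table))
  rows <- table[table$metric == metric, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("metric not found in trait table: ", metric)
  means <- tapply(rows$value, rows$species, mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Prepare one metric for decomposition
#'
#' Applies the package's preprocessing to the pooled species x population
#' values of one metric: optional Box-Cox transform (exponent fitted on the
#' pooled values) followed by standardization to unit population variance.
#'
#' @param table A `trait_table`.
#' @param metric Metric name.
#' @param boxcox Apply the Box-Cox step? Default `TRUE`.
#' @return Object of class `prepared_trait`: a list with `table` (the
#'   metric's rows plus a `z` column of transformed, standardized values),
#'   `lambda`, `shift` and `scale`.
#' @export
prepare_trait <- function(table, metric, boxcox = TRUE) {
  table <- as_trait_table(as.data.frame(table))
  rows <- table[table$metric == metric, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("metric not found in trait table: ", metric)
  if (length(unique(rows$species)) < 2L)
    stop("metric ", metric, " has fewer than 2 species")
  if (boxcox) {
    bc <- boxcox_transform(rows$value)
  } else {
    bc <- list(transformed = rows$value, lambda = NA_real_, shift = 0)
  }
  st <- standardize(bc$transformed)
  rows$z <- st$scaled
  rownames(rows) <- NULL
  structure(list(table = rows, lambda = bc$lambda, shift = bc$shift,
                 scale = st$scale),
            class = "prepared_trait")
}

#' @export
print.prepared_trait <- function(x, ...) {
  cat("Prepared trait '", x$table$metric[1], "': ", nrow(x$table),
      " measurements, ", length(unique(x$table$species)), " species\n",
      sep = "")
  if (!is.na(x$lambda)) cat("  Box-Cox lambda =", signif(x$lambda, 4),
                            " shift =", signif(x$shift, 4), "\n")
  cat("  standardizing scale =", signif(x$scale, 4), "\n")
  invisible(x)
}
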