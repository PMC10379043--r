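# Simple-OLS structure-property fitting and correlation tables.  The model
# is P = C1 * I + C2 with coefficient uncertainties reported as twice the
# standard error, plus R^2, residual SE, the regression F statistic and its
# significance — the full report conventional in QSPR work.

#' Fit a simple least-squares structure-property model
#'
#' Regresses a property `y` on a single descriptor `x` by ordinary least
#' squares (via [stats::lm()]) and collects the complete QSPR report.  For
#' simple regression the identities `F == (n - 2) R^2 / (1 - R^2)` and
#' `F == (slope / SE_slope)^2` hold; they are useful cross-checks on any
#' reported fit.
#'
#' @param x descriptor values (the predictor).
#' @param y property values (the response).
#' @return a [FitResult-class].
#' @examples
#' f <- fitSimpleOLS(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' rSquared(f)  # 0.36
#' @export
fitSimpleOLS <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3L) {
    stop("need at least 3 observations", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values are not allowed in a fit", call. = FALSE)
  }
  if (max(x) - min(x) == 0) {
    stop("constant predictor: x has no variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on noise-free data; a perfect fit is legitimate here
  sm <- withCallingHandlers(summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  fstat <- unname(sm$fstatistic[1L])
  methods::new("FitResult",
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    slopeSE = sm$coefficients[2L, 2L],
    interceptSE = sm$coefficients[1L, 2L],
    r2 = sm$r.squared,
    se = sm$sigma,
    fstat = fstat,
    sf = stats::pf(fstat, 1, n - 2L, lower.tail = FALSE),
    n = as.integer(n),
    residuals = unname(stats::residuals(fit))
  )
}

#' Accessors for FitResult
#'
#' @param x,object a [FitResult-class].
#' @param ... unused.
#' @return `coef` returns `c(intercept, slope)`; the others return the
#'   corresponding scalar slot.
#' @name FitResult-accessors
#' @aliases rSquared residualSE fStatistic fSignificance sampleSize
NULL

#' @rdname FitResult-accessors
#' @export
setMethod("rSquared", "FitResult", function(x) x@r2)

#' @rdname FitResult-accessors
#' @export
setMethod("residualSE", "FitResult", function(x) x@se)

#' @rdname FitResult-accessors
#' @export
setMethod("fStatistic", "FitResult", function(x) x@fstat)

#' @rdname FitResult-accessors
#' @export
setMethod("fSignificance", "FitResult", function(x) x@sf)

#' @rdname FitResult-accessors
#' @export
setMethod("sampleSize", "FitResult", function(x) x@n)

#' @rdname FitResult-accessors
#' @export
setMethod("coef", "FitResult", function(object, ...) {
  c(intercept = object@intercept, slope = object@slope)
})

#' @rdname FitResult-accessors
#' @export
setMethod("residuals", "FitResult", function(object, ...) object@residuals)

#' Predict from a FitResult
#'
#' @param object a [FitResult-class].
#' @param newx descriptor values to predict at.
#' @param ... unused.
#' @return `slope * newx + intercept`.
#' @export
setMethod("predict", "FitResult", function(object, newx, ...) {
  object@slope * newx + object@intercept
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("P = %.4g(+/-%.3g) I %s %.4g(+/-%.3g)\n",
              object@slope, 2 * object@slopeSE,
              if (object@intercept < 0) "-" else "+",
              abs(object@intercept), 2 * object@interceptSE))
  cat(sprintf("  R2 = %.4f, SE = %.4g, F = %.4f, SF = %.3g, n = %d\n",
              object@r2, object@se, object@fstat, object@sf, object@n))
  invisible(object)
})

#' Flatten a FitResult to a named list
#'
#' Keys follow the conventional report layout, with coefficient
#' uncertainties already doubled (`slope_pm = 2 * SE(slope)`, likewise
#' `intercept_pm`).  Suitable for JSON serialization.
#'
#' @param fit a [FitResult-class].
#' @return named list with elements `slope, intercept, slope_pm,
#'   intercept_pm, r2, se, f, sf, n`.
#' @export
fitReport <- function(fit) {
  stopifnot(methods::is(fit, "FitResult"))
  list(
    slope = fit@slope,
    intercept = fit@intercept,
    slope_pm = 2 * fit@slopeSE,
    intercept_pm = 2 * fit@interceptSE,
    r2 = fit@r2,
    se = fit@se,
    f = fit@fstat,
    sf = fit@sf,
    n = fit@n
  )
}

#' Pearson correlation coefficient
#'
#' Thin wrapper over [stats::cor()] with the preconditions this package
#' needs (equal lengths, no missing values, both vectors non-constant).
#' Its square equals the `r2` of the corresponding simple OLS fit.
#'
#' @param x,y numeric vectors.
#' @return correlation in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 observations", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (max(x) - min(x) == 0 || max(y) - min(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Absolute Pearson correlation table
#'
#' For each (index, property) column pair, the absolute Pearson
#' correlation.  Values are returned at full precision; report output is
#' conventionally rounded to 3 decimals.
#'
#' @param ds data.frame of records.
#' @param indexCols names of descriptor columns.
#' @param propertyCols names of property columns.
#' @return numeric matrix, rows = properties, columns = indices.
#' @export
correlationTable <- function(ds, indexCols, propertyCols) {
  missing <- setdiff(c(indexCols, propertyCols), names(ds))
  if (length(missing)) {
    stop(sprintf("unknown column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- matrix(NA_real_, length(propertyCols), length(indexCols),
                dimnames = list(propertyCols, indexCols))
  for (p in propertyCols) {
    for (i in indexCols) {
      out[p, i] <- abs(pearsonR(ds[[i]], ds[[p]]))
    }
  }
  out
}

# run expr with the RNG seeded, restoring the caller's RNG state after
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Split a dataset into train and test partitions
#'
#' Uniform sampling without replacement: the train set receives
#' `ceiling(n * trainFraction)` records, the test set the remainder.  The
#' partition is a deterministic function of `seed`.
#'
#' @param ds data.frame of records.
#' @param trainFraction fraction of records to train on, default 0.8.
#' @param seed integer seed.
#' @return `list(train = , test = )` of two disjoint data.frames covering
#'   `ds`.
#' @export
trainTestSplit <- function(ds, trainFraction = 0.8, seed) {
  n <- nrow(ds)
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie strictly between 0 and 1", call. = FALSE)
  }
  nTrain <- ceiling(n * trainFraction)
  if (nTrain < 3L) {
    stop("train set too small to fit (need >= 3 records)", call. = FALSE)
  }
  idx <- .withSeed(seed, sample.int(n, nTrain))
  list(train = ds[sort(idx), , drop = FALSE],
       test = ds[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' External validation of a fitted model
#'
#' Returns the squared Pearson correlation between the model's predictions
#' on a held-out set and the observed values — the "data variance on the
#' test set" conventionally quoted for QSPR external validation.  When the
#' test set equals the training set this reduces to the training R^2.
#'
#' @param fit a [FitResult-class].
#' @param testX,testY held-out descriptor and property values.
#' @return squared correlation in `[0, 1]`.
#' @export
validateOnTest <- function(fit, testX, testY) {
  pred <- predict(fit, testX)
  pearsonR(pred, testY)^2
}
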