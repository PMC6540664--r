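#' Group means and standard deviations
#'
#' Arithmetic mean and sample SD (n-1 denominator) of selected variables
#' within groups, dropping missing values per variable. Date variables are
#' summarised on day-of-year (Jan 1 = 1) and additionally rendered as a
#' `dd-Mon` date at the mean.
#'
#' @param records data.frame of per-individual records.
#' @param group_by name of the grouping column.
#' @param variables character vector of columns to summarise.
#' @return long data.frame with `group`, `variable`, `n`, `mean`, `sd`,
#'   and `mean_date` (NA for non-date variables). Single-observation
#'   groups have `sd = NA`.
#' @export
groupSummary <- function(records, group_by, variables) {
  out <- list()
  for (g in unique(records[[group_by]])) {
    sub <- records[records[[group_by]] == g, , drop = FALSE]
    if (!nrow(sub)) stop("empty group: ", g)
    for (v in variables) {
      x <- sub[[v]]
      is_date <- inherits(x, "Date")
      if (is_date) x <- dayOfYear(x)
      x <- x[!is.na(x)]
      if (!length(x)) stop("no non-missing values for ", v, " in group ", g)
      m <- mean(x)
      out[[length(out) + 1L]] <- data.frame(
        group = g, variable = v, n = length(x), mean = m,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        mean_date = if (is_date) doyToLabel(m) else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Day of year
#'
#' Day-of-year with January 1 = 1, in each date's own calendar year (the
#' "Julian date" convention of the field's tables).
#'
#' @param date Date vector.
#' @return integer vector.
#' @export
dayOfYear <- function(date) as.POSIXlt(as.Date(date))$yday + 1L

doyToLabel <- function(doy) {
  format(as.Date(round(doy) - 1, origin = "2014-01-01"), "%d-%b")
}

#' Fit a Gaussian linear model
#'
#' Ordinary least squares with treatment coding; for a `site` factor the
#' reference level is DF when present. Returns the coefficient table and
#' the Gaussian log-likelihood in a `LinearModelFit`.
#'
#' @param formula model formula.
#' @param data data.frame; rows with missing values in the model variables
#'   are dropped.
#' @return object of class `LinearModelFit`: list with `terms` (coefficient
#'   names), `estimate`, `se`, `t`, `p`, `df_residual`, `loglik`, `n`,
#'   `formula`, and the underlying `fit`.
#' @export
fitLM <- function(formula, data) {
  vars <- all.vars(formula)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  if ("site" %in% names(data) && is.character(data$site))
    data$site <- factor(data$site)
  if ("site" %in% names(data) && is.factor(data$site) &&
      "DF" %in% levels(data$site))
    data$site <- stats::relevel(data$site, ref = "DF")
  fit <- stats::lm(formula, data = data)
  if (fit$rank < ncol(stats::model.matrix(fit)))
    stop("rank-deficient design")
  cf <- summary(fit)$coefficients
  structure(list(terms = rownames(cf),
                 estimate = cf[, 1], se = cf[, 2], t = cf[, 3], p = cf[, 4],
                 df_residual = fit$df.residual,
                 loglik = as.numeric(stats::logLik(fit)),
                 n = nrow(data), formula = formula, fit = fit),
            class = "LinearModelFit")
}

#' @export
print.LinearModelFit <- function(x, ...) {
  cat("LinearModelFit:", deparse(x$formula), " (n =", x$n, ")\n")
  print(data.frame(term = x$terms, estimate = x$estimate, se = x$se,
                   t = x$t, p = x$p, row.names = NULL))
  cat(sprintf("residual df %d, logLik %.3f\n", x$df_residual, x$loglik))
  invisible(x)
}

#' Likelihood-ratio test between nested Gaussian fits
#'
#' @param full,reduced `LinearModelFit` objects on the same data.
#' @return list with `chisq`, `df`, `p`.
#' @export
lrTest <- function(full, reduced) {
  chisq <- 2 * (full$loglik - reduced$loglik)
  df <- length(full$terms) - length(reduced$terms)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Backward elimination by likelihood-ratio tests
#'
#' Starting from the full model, repeatedly drops the removable term
#' (respecting marginality: an interaction is dropped before its main
#' effects) whose likelihood-ratio test against the current model has the
#' largest p-value above `alpha`; stops when every remaining term is
#' significant or protected.
#'
#' @param formula full model formula.
#' @param data data.frame.
#' @param alpha retention threshold (default 0.05).
#' @return list with `fit` (final `LinearModelFit`) and `trace`
#'   (data.frame of dropped terms with their LRT statistic, df and p).
#' @export
backwardEliminate <- function(formula, data, alpha = 0.05) {
  vars <- all.vars(formula)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  current <- formula
  trace <- data.frame(dropped = character(), chisq = numeric(),
                      df = numeric(), p = numeric(), stringsAsFactors = FALSE)
  repeat {
    fit <- fitLM(current, data)
    droppable <- attr(stats::terms(current), "term.labels")
    droppable <- dropScope(droppable)
    if (!length(droppable)) break
    tests <- lapply(droppable, function(tm) {
      red <- stats::update(current, paste(". ~ . -", tm))
      lrTest(fit, fitLM(red, data))
    })
    p <- vapply(tests, `[[`, numeric(1), "p")
    if (all(p <= alpha)) break
    k <- which.max(p)
    trace <- rbind(trace, data.frame(dropped = droppable[k],
                                     chisq = tests[[k]]$chisq,
                                     df = tests[[k]]$df, p = p[k],
                                     stringsAsFactors = FALSE))
    current <- stats::update(current, paste(". ~ . -", droppable[k]))
    if (!length(attr(stats::terms(current), "term.labels"))) break
  }
  list(fit = fitLM(current, data), trace = trace)
}

# terms that no retained higher-order term is marginal to
dropScope <- function(labels) {
  keep <- vapply(labels, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    !any(vapply(labels, function(other) {
      if (other == tm) return(FALSE)
      oparts <- strsplit(other, ":", fixed = TRUE)[[1]]
      all(parts %in% oparts)
    }, logical(1)))
  }, logical(1))
  labels[keep]
}

#' Pearson correlation test
#'
#' Product-moment correlation with the t test on n - 2 degrees of freedom
#' (two-sided).
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return list with `r`, `t`, `df`, `p`, `n` (class `CorrelationResult`).
#' @export
pearsonTest <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), t = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, n = length(x)),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, t = %.3f, df = %d, p = %.4f (n = %d)\n",
              x$r, x$t, x$df, x$p, x$n))
  invisible(x)
}

#' Two-group comparison
#'
#' Welch two-sample t test (two-sided) on a numeric variable split by a
#' two-level label -- used e.g. to test males vs females within a group.
#'
#' @param values numeric vector.
#' @param labels vector with exactly two levels after dropping NAs.
#' @return list with `statistic`, `df`, `p`, `means` (named), `n`.
#' @export
compareGroups <- function(values, labels) {
  ok <- stats::complete.cases(values, labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must have exactly two levels")
  if (min(table(labels)) < 2) stop("both groups need at least 2 values")
  tt <- stats::t.test(values[labels == lv[1]], values[labels == lv[2]])
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       means = stats::setNames(tapply(values, labels, mean), sort(lv)),
       n = length(values))
}

#' Model summary table
#'
#' Flattens one or more `LinearModelFit`s into the tabular layout used for
#' reporting (variable, term, estimate, SE, t, df, p).
#'
#' @param fits named list of `LinearModelFit` objects.
#' @return data.frame.
#' @export
modelSummaryTable <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(variable = nm, term = f$terms, estimate = f$estimate,
               se = f$se, t = f$t, df = f$df_residual, p = f$p,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
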