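#' Per-cluster survey results
#'
#' The unit of analysis of a completed cluster survey: for each cluster
#' (school visit) the number of children examined and the number meeting
#' the condition definition.
#'
#' @param school_id Character vector of school identifiers.
#' @param n_examined Integer vector of children examined per cluster
#'   (each >= 1).
#' @param n_positive Integer vector of children meeting the condition
#'   definition (0 <= n_positive <= n_examined).
#' @return A data frame of class \code{"sehra_clusters"}.
#' @examples
#' cluster_results(c("A", "B"), n_examined = c(100, 100),
#'                 n_positive = c(10, 30))
#' @export
cluster_results <- function(school_id, n_examined, n_positive) {
  if (length(n_examined) != length(n_positive) ||
      length(school_id) != length(n_examined))
    stop("'school_id', 'n_examined' and 'n_positive' must have equal length",
         call. = FALSE)
  if (length(n_examined) == 0L)
    stop("no cluster results supplied", call. = FALSE)
  if (any(n_examined < 1) || any(n_examined != round(n_examined)))
    stop("'n_examined' must be whole numbers >= 1", call. = FALSE)
  if (any(n_positive < 0) || any(n_positive > n_examined) ||
      any(n_positive != round(n_positive)))
    stop("'n_positive' must be whole numbers in [0, n_examined]",
         call. = FALSE)
  structure(data.frame(school_id = as.character(school_id),
                       n_examined = as.integer(n_examined),
                       n_positive = as.integer(n_positive),
                       stringsAsFactors = FALSE),
            class = c("sehra_clusters", "data.frame"))
}

#' Read per-cluster results from CSV
#'
#' Expects columns \code{school_id}, \code{n_examined}, \code{n_positive};
#' \code{#} lines are comments.
#'
#' @param path Path to the CSV file.
#' @return A \code{"sehra_clusters"} data frame.
#' @export
read_cluster_results <- function(path) {
  if (!file.exists(path))
    stop(sprintf("results file not found: '%s'", path), call. = FALSE)
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("school_id", "n_examined", "n_positive"))
    if (!col %in% names(d))
      stop(sprintf("results file is missing required column '%s'", col),
           call. = FALSE)
  cluster_results(d$school_id, d$n_examined, d$n_positive)
}

#' Prevalence estimate from a cluster survey
#'
#' Analyses a completed (or simulated) two-stage survey at the cluster
#' level. Because the PPS-with-fixed-quota design is self-weighting, the
#' point estimate is the unweighted mean of the cluster proportions, and
#' its standard error is the between-cluster standard deviation divided by
#' \eqn{\sqrt{c}} — the standard cluster-level (ultimate cluster) variance
#' estimator, which absorbs any intracluster correlation without modelling
#' it. When clusters differ materially in size (shortfall schools,
#' absentee losses), \code{weights = "examined"} switches to the
#' examined-count-weighted ratio estimator with its linearised variance.
#'
#' The confidence interval uses a Student-t quantile with \eqn{c - 1}
#' degrees of freedom by default — few clusters is the realistic regime —
#' and is truncated to \eqn{[0, 1]} after construction. With a single
#' cluster the estimate is returned with the standard error flagged
#' undefined (NA).
#'
#' @param results A [cluster_results()] data frame (any data frame with
#'   \code{n_examined} and \code{n_positive} columns is accepted).
#' @param confidence Two-sided confidence level. Default 0.95.
#' @param quantile \code{"t"} (default) for \eqn{t_{c-1}} quantiles, or
#'   \code{"normal"} for standard-normal quantiles (matching the sizing
#'   formula's multiplier).
#' @param weights \code{"equal"} (default; self-weighting design) or
#'   \code{"examined"} (ratio estimator weighted by children examined).
#' @return An object of class \code{"sehra_estimate"} with fields
#'   \code{p_hat}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{deff_hat} (empirical design effect, see [estimate_deff()]),
#'   \code{achieved_rel_precision} (CI half-width / \code{p_hat}),
#'   \code{n_total}, \code{n_clusters}, \code{confidence},
#'   \code{quantile}, \code{weights}.
#' @examples
#' est <- cluster_prevalence_estimate(
#'   cluster_results(c("A", "B"), c(100, 100), c(10, 30)))
#' est$p_hat  # 0.2
#' est$se     # 0.1
#' @export
cluster_prevalence_estimate <- function(results, confidence = 0.95,
                                        quantile = c("t", "normal"),
                                        weights = c("equal", "examined")) {
  quantile <- match.arg(quantile)
  weights <- match.arg(weights)
  if (is.null(results) || nrow(results) == 0L)
    stop("no cluster results supplied", call. = FALSE)
  check_number(confidence, "confidence", 0, 1,
               closed_lower = FALSE, closed_upper = FALSE)
  x <- results$n_positive
  n <- results$n_examined
  c_ <- length(n)
  props <- x / n
  if (weights == "equal") {
    p_hat <- mean(props)
    se <- if (c_ >= 2L) sd(props) / sqrt(c_) else NA_real_
  } else {
    p_hat <- sum(x) / sum(n)
    se <- if (c_ >= 2L) {
      resid <- x - p_hat * n
      sqrt(c_ / (c_ - 1) * sum(resid^2)) / sum(n)
    } else NA_real_
  }
  q <- if (quantile == "t") {
    if (c_ >= 2L) qt(1 - (1 - confidence) / 2, df = c_ - 1L) else NA_real_
  } else qnorm(1 - (1 - confidence) / 2)
  half <- q * se
  n_total <- sum(n)
  srs_var <- p_hat * (1 - p_hat) / n_total
  structure(list(
    p_hat = p_hat, se = se,
    ci_low = max(0, p_hat - half), ci_high = min(1, p_hat + half),
    deff_hat = if (!is.na(se) && srs_var > 0) se^2 / srs_var else NA_real_,
    achieved_rel_precision = if (p_hat > 0) half / p_hat else NA_real_,
    n_total = n_total, n_clusters = c_,
    confidence = confidence, quantile = quantile, weights = weights),
    class = "sehra_estimate")
}

#' @export
print.sehra_estimate <- function(x, digits = 4, ...) {
  cat("Cluster-survey prevalence estimate\n\n")
  cat(sprintf("  prevalence = %.*g  (%d children in %d clusters)\n",
              digits, x$p_hat, x$n_total, x$n_clusters))
  if (is.na(x$se)) {
    cat("  standard error undefined (single cluster)\n")
  } else {
    cat(sprintf("  SE = %.*g;  %g%% CI [%.*g, %.*g]  (%s quantile)\n",
                digits, x$se, 100 * x$confidence,
                digits, x$ci_low, digits, x$ci_high, x$quantile))
    cat(sprintf("  empirical DEFF = %.*g;  achieved precision = %.*g of prevalence\n",
                digits, x$deff_hat, digits, x$achieved_rel_precision))
  }
  invisible(x)
}

#' @export
summary.sehra_estimate <- function(object, ...) {
  print(object, ...)
}

#' @export
coef.sehra_estimate <- function(object, ...) {
  c(p_hat = object$p_hat)
}

#' @export
confint.sehra_estimate <- function(object, parm, level, ...) {
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list("p_hat", c("lower", "upper")))
}

#' Empirical design effect of a completed survey
#'
#' The ratio of the cluster-design variance of the prevalence estimator to
#' the variance simple random sampling of the same total size would have
#' given: \eqn{\widehat{DEFF} = se^2 / (\hat p (1-\hat p) / n)}. Values
#' near 1 indicate no clustering of the outcome; under equal cluster sizes
#' \eqn{m} the expectation is \eqn{1 + (m-1)\rho} for intracluster
#' correlation \eqn{\rho}.
#'
#' @param results A [cluster_results()] data frame (>= 2 clusters).
#' @param ... Passed to [cluster_prevalence_estimate()].
#' @return The empirical design effect; NA (with a warning) when the
#'   estimated prevalence is 0 or 1, where the SRS variance vanishes.
#' @examples
#' estimate_deff(cluster_results(c("A", "B"), c(100, 100), c(10, 30)))  # 12.5
#' @export
estimate_deff <- function(results, ...) {
  est <- cluster_prevalence_estimate(results, ...)
  if (est$n_clusters < 2L)
    stop("at least 2 clusters are needed to estimate a design effect",
         call. = FALSE)
  if (est$p_hat <= 0 || est$p_hat >= 1) {
    warning("estimated prevalence is 0 or 1; design effect undefined")
    return(NA_real_)
  }
  est$deff_hat
}

#' Achieved relative precision of an estimate
#'
#' The realised CI half-width as a fraction of the estimated prevalence,
#' comparable directly with the \code{rel_precision} the survey was sized
#' for.
#'
#' @param estimate A \code{"sehra_estimate"} object.
#' @return Half-width / \code{p_hat}; NA (flagged by warning) when
#'   \code{p_hat} is zero.
#' @export
achieved_relative_precision <- function(estimate) {
  stopifnot(inherits(estimate, "sehra_estimate"))
  if (is.na(estimate$achieved_rel_precision))
    warning("achieved precision undefined (zero prevalence or single cluster)")
  estimate$achieved_rel_precision
}
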