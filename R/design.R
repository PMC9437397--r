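#' Survey design parameters
#'
#' Bundle of the statistical knobs of the cluster-survey sample-size
#' calculation: the confidence multiplier, the desired relative precision,
#' the design effect, the anticipated non-participation rate and the
#' number of children examined per cluster.
#'
#' The defaults are the recommended rapid-assessment settings: a 95%
#' two-sided confidence interval (\eqn{Z = 1.96}), a confidence-interval
#' half-width of 20% of the prevalence, a conservative design effect of
#' 2.0 for clusters of 100 children, and a 20% allowance for
#' non-participation and absenteeism.
#'
#' @param z Confidence multiplier (standard-normal quantile). Default 1.96,
#'   the two-sided multiplier for alpha = 0.05.
#' @param rel_precision Desired relative precision \eqn{r}: the target CI
#'   half-width as a fraction of the prevalence, in (0, 1). Default 0.20.
#' @param deff Design effect applied multiplicatively to the
#'   simple-random-sample size. Must be >= 1. Default 2.0.
#' @param nonresponse_rate Anticipated non-participation and absenteeism
#'   fraction in \[0, 1). The sample is inflated by
#'   \code{1 + nonresponse_rate}. Default 0.20.
#' @param cluster_size Children examined per cluster (positive integer).
#'   Default 100.
#'
#' @return An object of class \code{"sehra_parameters"}: a named list of
#'   the five validated parameters.
#' @examples
#' design_parameters()
#' design_parameters(deff = 1, nonresponse_rate = 0)
#' @export
design_parameters <- function(z = 1.96, rel_precision = 0.20, deff = 2.0,
                              nonresponse_rate = 0.20, cluster_size = 100L) {
  check_number(z, "z", lower = 0, closed_lower = FALSE)
  check_number(rel_precision, "rel_precision", 0, 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(deff, "deff", lower = 1)
  check_number(nonresponse_rate, "nonresponse_rate", 0, 1,
               closed_upper = FALSE)
  check_number(cluster_size, "cluster_size", lower = 1)
  if (cluster_size != round(cluster_size))
    stop("'cluster_size' must be a whole number", call. = FALSE)
  structure(list(z = z, rel_precision = rel_precision, deff = deff,
                 nonresponse_rate = nonresponse_rate,
                 cluster_size = as.integer(cluster_size)),
            class = "sehra_parameters")
}

#' @export
print.sehra_parameters <- function(x, ...) {
  cat("Cluster-survey design parameters\n")
  cat(sprintf("  confidence multiplier z : %.4g\n", x$z))
  cat(sprintf("  relative precision      : %.4g (CI half-width / prevalence)\n",
              x$rel_precision))
  cat(sprintf("  design effect           : %.4g\n", x$deff))
  cat(sprintf("  non-participation rate  : %.4g\n", x$nonresponse_rate))
  cat(sprintf("  cluster size            : %d children\n", x$cluster_size))
  invisible(x)
}

as_parameters <- function(params) {
  if (inherits(params, "sehra_parameters")) return(params)
  if (is.list(params)) return(do.call(design_parameters, params))
  stop("'params' must be a design_parameters() object", call. = FALSE)
}

#' A labelled prevalence scenario
#'
#' A prevalence scenario names a region/condition group and carries the
#' anticipated proportion of children needing services. Composite
#' scenarios (e.g. all vision impairment plus non-vision-impairing
#' conditions) may supply the component proportions; these must sum to
#' \code{p} to within 0.001, mirroring how regional totals are built by
#' summing condition-group prevalences on the proportion scale.
#'
#' @param p Prevalence as a proportion, strictly inside (0, 1).
#' @param label Free-text description (region and condition group).
#' @param components Optional named numeric vector of component
#'   proportions summing to \code{p}.
#' @return An object of class \code{"sehra_scenario"}.
#' @examples
#' prevalence_scenario(0.189, "SE Asia, all conditions",
#'                     components = c(vi = 0.17, nvic = 0.019))
#' @export
prevalence_scenario <- function(p, label = "", components = NULL) {
  check_number(p, "p", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  if (!is.null(components)) {
    if (!is.numeric(components) || any(components <= 0))
      stop("'components' must be positive proportions", call. = FALSE)
    if (abs(sum(components) - p) > 0.001)
      stop(sprintf(
        "component proportions sum to %.4f, not the stated total %.4f",
        sum(components), p), call. = FALSE)
  }
  structure(list(label = as.character(label), p = p, components = components),
            class = "sehra_scenario")
}

as_scenario <- function(x) {
  if (inherits(x, "sehra_scenario")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(prevalence_scenario(x))
  stop("expected a prevalence_scenario() or a single proportion", call. = FALSE)
}

#' Unadjusted sample size for estimating a prevalence
#'
#' The simple-random-sample size needed to estimate a prevalence \eqn{P}
#' with absolute CI half-width \eqn{d}:
#' \deqn{n = Z^2 P (1 - P) / d^2,}
#' with the half-width taken in relative terms, \eqn{d = r P}, so that
#' \eqn{n = Z^2 (1 - P) / (r^2 P)}. The value is returned unrounded; the
#' clustering and non-participation adjustments are applied by
#' [sample_size()].
#'
#' Under the relative-precision formulation the required size is strictly
#' decreasing in the prevalence: rarer conditions need larger samples for
#' the same proportional precision.
#'
#' @param p Anticipated prevalence, in (0, 1).
#' @param z Confidence multiplier. Default 1.96.
#' @param rel_precision Relative precision \eqn{r} in (0, 1). Default 0.20.
#' @return The exact (unrounded) sample size in children.
#' @examples
#' base_sample_size(0.17)            # 468.9
#' base_sample_size(0.5, z = 1, rel_precision = 0.2)  # 25
#' @export
base_sample_size <- function(p, z = 1.96, rel_precision = 0.20) {
  check_number(p, "p", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  check_number(z, "z", lower = 0, closed_lower = FALSE)
  check_number(rel_precision, "rel_precision", 0, 1,
               closed_lower = FALSE, closed_upper = FALSE)
  d <- rel_precision * p
  z^2 * p * (1 - p) / d^2
}

#' Cluster-survey sample size with all adjustments
#'
#' Runs the full sizing chain for a prevalence scenario: the unadjusted
#' size from [base_sample_size()], multiplied by the design effect,
#' inflated for anticipated non-participation, rounded up to a whole
#' number of children, and converted to a whole number of clusters.
#'
#' @param scenario A [prevalence_scenario()] or a bare proportion.
#' @param params A [design_parameters()] object (or list of its fields).
#' @return An object of class \code{"sehra_samplesize"} with fields
#'   \code{n_base} (unrounded SRS size), \code{n_deff}
#'   (\code{n_base * deff}), \code{n_inflated}
#'   (\code{n_deff * (1 + nonresponse_rate)}), \code{n_final}
#'   (ceiling of \code{n_inflated}), \code{n_clusters}
#'   (ceiling of \code{n_final / cluster_size}) and
#'   \code{achieved_precision}, the relative precision implied by
#'   \code{n_final} (always at or below the requested precision because of
#'   the ceiling).
#' @examples
#' sample_size(0.17)                       # n_final 1126, 12 clusters
#' sample_size(prevalence_scenario(0.039)) # the low-prevalence extreme
#' @seealso [achievable_precision()] for the inverse problem,
#'   [deff_sensitivity()] for the design-effect sensitivity table.
#' @export
sample_size <- function(scenario, params = design_parameters()) {
  scenario <- as_scenario(scenario)
  params <- as_parameters(params)
  n_base <- base_sample_size(scenario$p, params$z, params$rel_precision)
  n_deff <- n_base * params$deff
  n_inflated <- n_deff * (1 + params$nonresponse_rate)
  n_final <- as.integer(ceiling(n_inflated))
  n_clusters <- as.integer(ceiling(n_final / params$cluster_size))
  structure(list(
    label = scenario$label, p = scenario$p,
    n_base = n_base, n_deff = n_deff, n_inflated = n_inflated,
    n_final = n_final, n_clusters = n_clusters,
    achieved_precision = achievable_precision(n_final, scenario$p, params),
    params = params), class = "sehra_samplesize")
}

#' @export
print.sehra_samplesize <- function(x, digits = 4, ...) {
  cat("Cluster-survey sample size\n\n")
  line <- function(lab, fmt, ...)
    cat(sprintf("  %-20s= %s\n", lab, sprintf(fmt, ...)))
  if (nzchar(x$label)) line("scenario", "%s", x$label)
  line("prevalence", "%.*g", digits, x$p)
  line("n (unadjusted)", "%.2f", x$n_base)
  line(sprintf("n x DEFF %.3g", x$params$deff), "%.2f", x$n_deff)
  line(sprintf("n x (1 + %.3g)", x$params$nonresponse_rate), "%.2f",
       x$n_inflated)
  line("n (final, children)", "%d", x$n_final)
  line(sprintf("clusters of %d", x$params$cluster_size), "%d", x$n_clusters)
  line("achieved precision", "%.*g of prevalence", digits,
       x$achieved_precision)
  invisible(x)
}

#' @export
as.data.frame.sehra_samplesize <- function(x, ...) {
  data.frame(label = x$label, p = x$p, n_base = x$n_base,
             n_deff = x$n_deff, n_inflated = x$n_inflated,
             n_final = x$n_final, n_clusters = x$n_clusters,
             achieved_precision = x$achieved_precision,
             stringsAsFactors = FALSE)
}

#' Relative precision achievable with an available sample size
#'
#' The algebraic inverse of the sizing chain: given \code{n_available}
#' children (before losses), the relative CI half-width the design can
#' deliver is
#' \deqn{r = Z \sqrt{DEFF (1 + a) (1 - P) / (n P)},}
#' where \eqn{a} is the non-participation rate. When fewer schools (hence
#' fewer children) than calculated can be visited, precision degrades as
#' \eqn{1/\sqrt{n}}.
#'
#' @param n_available Number of children that can be sampled (>= 1).
#' @param p Anticipated prevalence, in (0, 1).
#' @param params A [design_parameters()] object.
#' @return The achievable relative precision (fraction of prevalence).
#' @examples
#' achievable_precision(1126, 0.17)  # just under the requested 0.20
#' achievable_precision(563, 0.17)   # half the children: sqrt(2) wider
#' @export
achievable_precision <- function(n_available, p, params = design_parameters()) {
  check_number(n_available, "n_available", lower = 1)
  check_number(p, "p", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  params <- as_parameters(params)
  params$z * sqrt(params$deff * (1 + params$nonresponse_rate) * (1 - p) /
                    (n_available * p))
}

#' Sensitivity of the sample size to the design effect
#'
#' Recomputes the full sizing chain over a vector of candidate design
#' effects, holding all other parameters fixed — the sensitivity analysis
#' used to settle on a conservative design effect before fieldwork.
#' \code{n_deff} is exactly proportional to the design effect, so
#' \code{n_final} is non-decreasing along the table; the \code{deff = 1}
#' row is the unclustered (simple random sample) design.
#'
#' @param scenario A [prevalence_scenario()] or bare proportion.
#' @param params A [design_parameters()] object; its \code{deff} is
#'   overridden row by row.
#' @param deff_values Numeric vector of design effects, each >= 1.
#' @return A data frame with one row per design effect and the full set of
#'   [sample_size()] fields.
#' @examples
#' deff_sensitivity(0.17, deff_values = c(1, 1.5, 2, 3))
#' @export
deff_sensitivity <- function(scenario, params = design_parameters(),
                             deff_values = c(1, 1.5, 2, 2.5, 3)) {
  scenario <- as_scenario(scenario)
  params <- as_parameters(params)
  if (!is.numeric(deff_values) || length(deff_values) == 0L)
    stop("'deff_values' must be a non-empty numeric vector", call. = FALSE)
  if (any(deff_values < 1))
    stop("all 'deff_values' must be >= 1", call. = FALSE)
  rows <- lapply(deff_values, function(d) {
    pars <- params
    pars$deff <- d
    cbind(deff = d, as.data.frame(sample_size(scenario, pars)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample-size table for a set of prevalence scenarios
#'
#' Applies [sample_size()] to each scenario in turn and returns one report
#' row per scenario, in input order. Composite scenarios carry their
#' component sum check via [prevalence_scenario()].
#'
#' @param scenarios A list of [prevalence_scenario()] objects (bare
#'   proportions are accepted).
#' @param params A [design_parameters()] object applied to every scenario.
#' @return A data frame with one row per scenario.
#' @examples
#' scenario_table(list(
#'   prevalence_scenario(0.17,  "SE Asia, all VI"),
#'   prevalence_scenario(0.189, "SE Asia, all conditions",
#'                       components = c(vi = 0.17, nvic = 0.019))))
#' @export
scenario_table <- function(scenarios, params = design_parameters()) {
  if (!is.list(scenarios) || length(scenarios) == 0L)
    stop("'scenarios' must be a non-empty list", call. = FALSE)
  rows <- lapply(scenarios, function(s) as.data.frame(sample_size(s, params)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
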