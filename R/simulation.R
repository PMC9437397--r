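#' Synthetic school population with controlled prevalence and ICC
#'
#' Generates a school population in which a binary outcome ("needs
#' eye-care services") has marginal prevalence \code{p_true} and
#' intracluster correlation \code{icc} by the beta-binomial construction:
#' each school's latent prevalence is drawn from
#' \eqn{Beta(\alpha, \beta)} with \eqn{\alpha = p(1-\rho)/\rho},
#' \eqn{\beta = (1-p)(1-\rho)/\rho} (so \eqn{E[\pi_s] = p} and
#' \eqn{Var[\pi_s] = p(1-p)\rho}), and children are independent
#' Bernoulli draws at their school's latent prevalence. Pairwise
#' within-school correlation then equals \eqn{\rho} exactly; with
#' \eqn{\rho = 0} every school sits at \code{p_true} and the population is
#' an unclustered Bernoulli population.
#'
#' Enrollments are drawn from \code{enrollment_law}:
#' \code{list(type = "fixed", size = n)} or
#' \code{list(type = "lognormal", meanlog, sdlog, min)}. The default,
#' a lognormal with mean about 500 pupils, broad dispersion
#' (\code{sdlog = 0.8}) and a floor of 20, produces both very large
#' schools (selected more than once under PPS) and schools too small to
#' fill a cluster — the two edge cases a planner must anticipate.
#'
#' @param n_schools Number of schools (>= 1).
#' @param p_true Marginal prevalence, in (0, 1).
#' @param icc Intracluster correlation \eqn{\rho} in \[0, 1). (\eqn{\rho =
#'   1} is rejected: the Beta parameters degenerate.)
#' @param enrollment_law Distribution descriptor for school enrollments
#'   (see Details).
#' @param seed Optional integer seed; the same seed regenerates the
#'   identical population.
#' @return An object of class \code{"sehra_population"}: a list with
#'   \code{frame} (a [school_frame()] with a \code{pi_s} column of latent
#'   school prevalences), \code{outcomes} (per-school integer 0/1
#'   vectors), \code{p_true}, \code{icc} and \code{prevalence} (the
#'   realised finite-population prevalence).
#' @examples
#' pop <- generate_population(20, p_true = 0.17, icc = 1/99, seed = 1)
#' pop$prevalence
#' @export
generate_population <- function(n_schools, p_true, icc = 0,
                                enrollment_law = list(type = "lognormal",
                                                      meanlog = log(500) - 0.32,
                                                      sdlog = 0.8, min = 20),
                                seed = NULL) {
  check_number(n_schools, "n_schools", lower = 1)
  n_schools <- as.integer(n_schools)
  check_number(p_true, "p_true", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  check_number(icc, "icc", 0, 1, closed_upper = FALSE)
  if (!is.list(enrollment_law) || is.null(enrollment_law$type))
    stop("'enrollment_law' must be a list with a 'type' field", call. = FALSE)
  with_seed(seed, {
    enr <- switch(enrollment_law$type,
      fixed = rep.int(as.integer(enrollment_law$size), n_schools),
      lognormal = {
        m <- enrollment_law$min %||% 20
        pmax(as.integer(round(rlnorm(n_schools,
                                     enrollment_law$meanlog %||% (log(500) - 0.32),
                                     enrollment_law$sdlog %||% 0.8))),
             as.integer(m))
      },
      stop(sprintf("unknown enrollment law '%s'", enrollment_law$type),
           call. = FALSE))
    pi_s <- if (icc > 0) {
      a <- p_true * (1 - icc) / icc
      b <- (1 - p_true) * (1 - icc) / icc
      rbeta(n_schools, a, b)
    } else rep.int(p_true, n_schools)
    outcomes <- lapply(seq_len(n_schools),
                       function(s) rbinom(enr[s], 1L, pi_s[s]))
    frame <- school_frame(data.frame(
      school_id = sprintf("S%03d", seq_len(n_schools)),
      enrollment = enr, stringsAsFactors = FALSE))
    frame$pi_s <- pi_s
    structure(list(frame = frame, outcomes = outcomes, p_true = p_true,
                   icc = icc,
                   prevalence = sum(vapply(outcomes, sum, 0)) / sum(enr),
                   enrollment_law = enrollment_law, seed = seed),
              class = "sehra_population")
  })
}

#' @export
print.sehra_population <- function(x, ...) {
  cat(sprintf(
    "Synthetic school population: %d schools, %d children\n",
    nrow(x$frame), attr(x$frame, "total_enrollment")))
  cat(sprintf("  target prevalence %.4g (realised %.4g), ICC %.4g\n",
              x$p_true, x$prevalence, x$icc))
  invisible(x)
}

#' Simulate one full two-stage survey on a synthetic population
#'
#' Runs the complete field procedure in silico: schools are drawn by
#' [pps_systematic_sample()], children within each selected school by
#' [second_stage_sample()], child-level non-participation is applied as
#' independent Bernoulli thinning at \code{nonresponse_rate}, and the
#' examined children are analysed with [cluster_prevalence_estimate()].
#' A school allocated several clusters contributes that many analysis
#' clusters (its sampled children are split evenly among them); a school
#' smaller than its quota is enumerated completely and contributes its
#' whole roster.
#'
#' @param population A [generate_population()] object.
#' @param n_clusters Number of clusters to field.
#' @param cluster_size Children per cluster. Default 100.
#' @param nonresponse_rate Probability a selected child is absent/refuses.
#'   Default 0.
#' @param confidence,quantile,weights Passed to
#'   [cluster_prevalence_estimate()].
#' @param seed Optional integer seed governing school selection, child
#'   selection and non-response jointly.
#' @return A \code{"sehra_estimate"} with an extra \code{clusters} field
#'   holding the per-cluster [cluster_results()].
#' @examples
#' pop <- generate_population(40, 0.17, icc = 1/99,
#'                            enrollment_law = list(type = "fixed", size = 250),
#'                            seed = 1)
#' simulate_survey(pop, n_clusters = 12, seed = 2)
#' @export
simulate_survey <- function(population, n_clusters, cluster_size = 100L,
                            nonresponse_rate = 0, confidence = 0.95,
                            quantile = c("t", "normal"),
                            weights = c("equal", "examined"), seed = NULL) {
  stopifnot(inherits(population, "sehra_population"))
  quantile <- match.arg(quantile)
  weights <- match.arg(weights)
  check_number(nonresponse_rate, "nonresponse_rate", 0, 1,
               closed_upper = FALSE)
  frame <- population$frame
  with_seed(seed, {
    alloc <- pps_systematic_sample(frame, n_clusters,
                                   cluster_size = cluster_size)
    ids <- character(0); exam <- integer(0); pos <- integer(0)
    for (i in seq_len(nrow(alloc))) {
      sid <- alloc$school_id[i]
      row <- match(sid, frame$school_id)
      sel <- second_stage_sample(frame[row, , drop = FALSE],
                                 cluster_size = cluster_size,
                                 clusters_assigned = alloc$clusters_assigned[i])
      if (nonresponse_rate > 0) {
        keep <- runif(length(sel)) >= nonresponse_rate
        if (!any(keep)) keep[sample.int(length(sel), 1L)] <- TRUE
        sel <- sel[keep]
      }
      h <- alloc$clusters_assigned[i]
      # split a multi-hit school's children evenly into its h clusters
      grp <- rep(seq_len(h), length.out = length(sel))
      y <- population$outcomes[[row]][sel]
      for (k in seq_len(h)) {
        ids <- c(ids, if (h == 1L) sid else sprintf("%s.%d", sid, k))
        exam <- c(exam, sum(grp == k))
        pos <- c(pos, sum(y[grp == k]))
      }
    }
    est <- cluster_prevalence_estimate(
      cluster_results(ids, exam, pos),
      confidence = confidence, quantile = quantile, weights = weights)
    est$clusters <- cluster_results(ids, exam, pos)
    est
  })
}

#' Monte-Carlo validation of the survey design's statistical contract
#'
#' Repeats the whole pipeline — generate a fresh population, field a
#' survey, estimate — \code{reps} times and summarises whether the design
#' delivers what the sample-size calculation promises: confidence
#' intervals with nominal coverage of the true prevalence, a design
#' effect matching \eqn{1 + (m - 1)\rho}, and CI half-widths within the
#' requested fraction of the prevalence.
#'
#' Coverage is assessed against the superpopulation prevalence
#' \code{p_true}, not each replicate's realised finite-population
#' prevalence (the two differ in small populations). The empirical design
#' effect is the across-replicate variance of \eqn{\hat p} divided by the
#' binomial variance \eqn{\bar p (1 - \bar p) / \bar n} a simple random
#' sample of the same average size would have.
#'
#' @param n_schools,p_true,icc,enrollment_law Population settings, as in
#'   [generate_population()].
#' @param n_clusters,cluster_size,nonresponse_rate,confidence,quantile,weights
#'   Survey settings, as in [simulate_survey()].
#' @param reps Number of replicates (>= 1; >= 100 recommended for stable
#'   coverage).
#' @param seed Optional master seed; per-replicate seeds are derived from
#'   it.
#' @return An object of class \code{"sehra_validation"}: a list with
#'   \code{reps}, \code{coverage}, \code{empirical_deff},
#'   \code{mean_deff_hat} (mean of the per-survey design effects),
#'   \code{mean_rel_precision}, \code{bias}, \code{mean_p_hat},
#'   \code{mc_se} (Monte-Carlo standard error of the bias),
#'   \code{mean_n_total} and the per-replicate \code{estimates} data
#'   frame.
#' @examples
#' v <- monte_carlo_validate(n_schools = 40, p_true = 0.17, icc = 1/99,
#'                           enrollment_law = list(type = "fixed", size = 250),
#'                           n_clusters = 30, reps = 100, seed = 1)
#' v$empirical_deff  # close to 1 + 99 * (1/99) = 2
#' @export
monte_carlo_validate <- function(n_schools, p_true, icc, n_clusters,
                                 cluster_size = 100L, nonresponse_rate = 0,
                                 enrollment_law = list(type = "fixed",
                                                       size = 500),
                                 reps = 1000L, confidence = 0.95,
                                 quantile = c("t", "normal"),
                                 weights = c("equal", "examined"),
                                 seed = NULL) {
  quantile <- match.arg(quantile)
  weights <- match.arg(weights)
  check_number(reps, "reps", lower = 1)
  reps <- as.integer(reps)
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), 2L * reps)
  p_hat <- se <- lo <- hi <- relp <- deff <- n_tot <- numeric(reps)
  for (r in seq_len(reps)) {
    pop <- generate_population(n_schools, p_true, icc,
                               enrollment_law = enrollment_law,
                               seed = seeds[2L * r - 1L])
    est <- simulate_survey(pop, n_clusters, cluster_size = cluster_size,
                           nonresponse_rate = nonresponse_rate,
                           confidence = confidence, quantile = quantile,
                           weights = weights, seed = seeds[2L * r])
    p_hat[r] <- est$p_hat; se[r] <- est$se
    lo[r] <- est$ci_low; hi[r] <- est$ci_high
    relp[r] <- est$achieved_rel_precision
    deff[r] <- est$deff_hat; n_tot[r] <- est$n_total
  }
  pbar <- mean(p_hat)
  structure(list(
    reps = reps,
    coverage = mean(lo <= p_true & p_true <= hi),
    empirical_deff = var(p_hat) / (pbar * (1 - pbar) / mean(n_tot)),
    mean_deff_hat = mean(deff),
    mean_rel_precision = mean(relp),
    bias = pbar - p_true,
    mean_p_hat = pbar,
    mc_se = sd(p_hat) / sqrt(reps),
    mean_n_total = mean(n_tot),
    p_true = p_true, icc = icc, confidence = confidence,
    n_clusters = n_clusters, cluster_size = cluster_size,
    nonresponse_rate = nonresponse_rate, quantile = quantile, seed = seed,
    estimates = data.frame(p_hat = p_hat, se = se, ci_low = lo,
                           ci_high = hi, rel_precision = relp,
                           deff_hat = deff, n_total = n_tot)),
    class = "sehra_validation")
}

#' @export
print.sehra_validation <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Monte-Carlo validation: %d replicate surveys (%d clusters of %d)\n\n",
    x$reps, x$n_clusters, x$cluster_size))
  cat(sprintf("  true prevalence %.4g, ICC %.4g, non-response %.4g\n",
              x$p_true, x$icc, x$nonresponse_rate))
  cat(sprintf("  bias                = %+.*g (MC SE %.2g)\n",
              digits, x$bias, x$mc_se))
  cat(sprintf("  %2.0f%% CI coverage     = %.*g\n", 100 * x$confidence,
              digits, x$coverage))
  cat(sprintf("  empirical DEFF      = %.*g (variance-ratio, across replicates)\n",
              digits, x$empirical_deff))
  cat(sprintf("  mean rel. precision = %.*g of prevalence\n",
              digits, x$mean_rel_precision))
  invisible(x)
}
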