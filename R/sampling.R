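#' Systematic PPS selection of schools
#'
#' Selects clusters with probability proportionate to school size by the
#' cumulative-total method: enrollments are cumulated in frame order, the
#' sampling interval is \eqn{I = N / k} for total enrollment \eqn{N} and
#' \eqn{k} clusters, a start \eqn{u} is drawn uniformly on \eqn{[0, I)},
#' and the schools containing the points \eqn{u + jI}, \eqn{j = 0, ...,
#' k-1} are selected. A school whose enrollment span covers several points
#' receives several clusters (the very-large-school case); the per-draw
#' selection probability of a school is its enrollment share.
#'
#' @param frame A [school_frame()].
#' @param n_clusters Number of clusters \eqn{k} to allocate (>= 1, at most
#'   the total enrollment so the interval is at least one pupil).
#' @param cluster_size Children to examine per cluster; used to fill the
#'   \code{children_to_sample} and \code{shortfall} columns. Default 100.
#' @param seed Optional integer seed for the random start (the global RNG
#'   stream is left untouched when a seed is supplied).
#' @param start Optional explicit start in \eqn{[0, I)}; overrides the
#'   random draw (useful for enumeration and audit).
#' @return An object of class \code{"sehra_allocation"}: a data frame with
#'   one row per selected school (\code{school_id}, \code{enrollment},
#'   \code{clusters_assigned}, \code{children_to_sample} — capped at
#'   enrollment — and \code{shortfall}), with attributes \code{interval},
#'   \code{start}, \code{seed} and \code{n_clusters}. The
#'   \code{clusters_assigned} column always sums to \code{n_clusters}.
#' @examples
#' frame <- school_frame(data.frame(school_id = c("A", "B", "C"),
#'                                  enrollment = c(300, 100, 100)))
#' pps_systematic_sample(frame, n_clusters = 5, seed = 1)
#' @export
pps_systematic_sample <- function(frame, n_clusters, cluster_size = 100L,
                                  seed = NULL, start = NULL) {
  stopifnot(inherits(frame, "sehra_frame"))
  total <- attr(frame, "total_enrollment")
  if (nrow(frame) == 0L || total == 0L)
    stop("cannot sample from an empty frame", call. = FALSE)
  check_number(n_clusters, "n_clusters", lower = 1)
  if (n_clusters != round(n_clusters))
    stop("'n_clusters' must be a whole number", call. = FALSE)
  n_clusters <- as.integer(n_clusters)
  if (n_clusters > total)
    stop(sprintf(
      "n_clusters (%d) exceeds total enrollment (%d); interval undefined",
      n_clusters, total), call. = FALSE)
  check_number(cluster_size, "cluster_size", lower = 1)
  interval <- total / n_clusters
  if (is.null(start)) {
    start <- with_seed(seed, runif(1, 0, interval))
  } else {
    check_number(start, "start", lower = 0, upper = interval,
                 closed_upper = FALSE)
  }
  points <- start + (seq_len(n_clusters) - 1) * interval
  # school i owns [cum[i-1], cum[i]); zero-enrollment spans are empty and
  # can never contain a point
  idx <- findInterval(points, c(0, cumsum(as.numeric(frame$enrollment))))
  hits <- table(idx)
  sel <- as.integer(names(hits))
  clusters <- as.integer(hits)
  enr <- frame$enrollment[sel]
  want <- clusters * as.integer(cluster_size)
  out <- data.frame(school_id = frame$school_id[sel],
                    enrollment = enr,
                    clusters_assigned = clusters,
                    children_to_sample = pmin(want, enr),
                    shortfall = pmax(0L, want - enr),
                    stringsAsFactors = FALSE)
  structure(out, interval = interval, start = start, seed = seed,
            n_clusters = n_clusters,
            cluster_size = as.integer(cluster_size),
            class = c("sehra_allocation", "data.frame"))
}

# Equal split of `quota` across groups of sizes `sizes` by largest-remainder
# apportionment, capping each group at its size and redistributing any
# excess equally over the groups with spare capacity. Ties on remainders
# break by group order.
allocate_quota <- function(quota, sizes) {
  g <- length(sizes)
  alloc <- integer(g)
  capacity <- as.integer(sizes)
  open <- capacity > 0L
  left <- as.integer(quota)
  while (left > 0L && any(open)) {
    k <- sum(open)
    share <- left / k
    base <- floor(share)
    add <- rep.int(as.integer(base), k)
    rem <- left - base * k
    if (rem > 0L) add[seq_len(rem)] <- add[seq_len(rem)] + 1L
    prop <- integer(g)
    prop[open] <- add
    take <- pmin(prop, capacity - alloc)
    alloc <- alloc + take
    left <- left - sum(take)
    open <- capacity - alloc > 0L
    # progress guaranteed: every round either allocates or closes groups
    if (all(take == 0L)) break
  }
  alloc
}

#' Select children within a selected school
#'
#' The second sampling stage: a fixed quota of children
#' (\code{cluster_size} per assigned cluster) is drawn from the school
#' roster by simple random sampling without replacement, so that combined
#' with PPS school selection every enrolled child has the same overall
#' inclusion probability. When year-group counts are available the quota
#' is spread equally across year groups (largest-remainder apportionment,
#' capped at the group size with the excess redistributed), then sampled
#' at random within each group. A school too small to fill its quota is
#' enumerated completely (a census) and the shortfall recorded.
#'
#' Pupils are indexed 1..enrollment in roster order; with year groups the
#' roster is taken as ordered by group (group 1 first).
#'
#' @param school A one-row data frame (or list) with \code{enrollment} and
#'   optional year-group counts, e.g. a row of a [school_frame()].
#' @param cluster_size Children per cluster. Default 100.
#' @param clusters_assigned Clusters allocated to this school (a large
#'   school hit more than once samples \code{clusters_assigned *
#'   cluster_size} children). Default 1.
#' @param seed Optional integer seed.
#' @return An integer vector of selected pupil indices, with attributes
#'   \code{shortfall} (children missing from the quota) and, when year
#'   groups are used, \code{yg_allocation}.
#' @examples
#' sch <- data.frame(school_id = "S1", enrollment = 450,
#'                   yg_1 = 75, yg_2 = 75, yg_3 = 75,
#'                   yg_4 = 75, yg_5 = 75, yg_6 = 75)
#' sel <- second_stage_sample(sch, cluster_size = 100, seed = 7)
#' attr(sel, "yg_allocation")  # 17 17 17 17 16 16
#' @export
second_stage_sample <- function(school, cluster_size = 100L,
                                clusters_assigned = 1L, seed = NULL) {
  enrollment <- as.integer(school$enrollment %||% school[["enrollment"]])
  if (is.na(enrollment) || enrollment < 1L)
    stop("school enrollment must be >= 1 to sample children", call. = FALSE)
  check_number(cluster_size, "cluster_size", lower = 1)
  check_number(clusters_assigned, "clusters_assigned", lower = 1)
  quota <- as.integer(cluster_size) * as.integer(clusters_assigned)
  if (enrollment <= quota) {
    out <- seq_len(enrollment)
    attr(out, "shortfall") <- quota - enrollment
    return(out)
  }
  nm <- names(school)
  yg_cols <- grep("^yg_", nm, value = TRUE)
  yg <- if (length(yg_cols)) as.integer(unlist(school[yg_cols])) else integer()
  yg <- yg[!is.na(yg)]
  out <- with_seed(seed, {
    if (length(yg) && sum(yg) == enrollment) {
      alloc <- allocate_quota(quota, yg)
      offsets <- cumsum(c(0L, yg[-length(yg)]))
      sel <- unlist(lapply(seq_along(yg), function(g) {
        if (alloc[g] == 0L) return(integer())
        offsets[g] + sample.int(yg[g], alloc[g])
      }))
      attr(sel, "yg_allocation") <- alloc
      sel
    } else {
      sample.int(enrollment, quota)
    }
  })
  attr(out, "shortfall") <- 0L
  out
}

#' Per-child inclusion probability of the two-stage design
#'
#' For a school with enrollment \eqn{e} inside the regular range
#' (\eqn{m \le e \le I}, where \eqn{m} is the cluster size and \eqn{I} the
#' sampling interval), the chance a given child is examined is the product
#' of the two stages, \eqn{(k e / N) \times (m / e) = k m / N} — identical
#' for every child regardless of school size. This self-weighting property
#' is what lets the analysis use unweighted cluster summaries.
#'
#' Schools outside the regular range are flagged: \code{undersized}
#' (enrollment below the cluster quota, so stage two is a census and the
#' child probability drops to \eqn{k e / N \cdot 1}) and \code{certainty}
#' (enrollment above the interval, where multiple hits make the single-draw
#' formula inapplicable).
#'
#' @param frame A [school_frame()].
#' @param n_clusters Number of clusters \eqn{k}.
#' @param cluster_size Cluster size \eqn{m}. Default 100.
#' @param school_id Optional school identifier; if supplied, the scalar
#'   probability for that school's children is returned (an error if the
#'   school is flagged).
#' @return With \code{school_id}: a single probability. Otherwise a data
#'   frame with one row per school: \code{school_id}, \code{enrollment},
#'   \code{p_child}, and logical flags \code{undersized} and
#'   \code{certainty}.
#' @examples
#' frame <- school_frame(data.frame(school_id = letters[1:5],
#'                                  enrollment = rep(2000, 5)))
#' inclusion_probability(frame, n_clusters = 10, cluster_size = 100)
#' @export
inclusion_probability <- function(frame, n_clusters, cluster_size = 100L,
                                  school_id = NULL) {
  stopifnot(inherits(frame, "sehra_frame"))
  check_number(n_clusters, "n_clusters", lower = 1)
  check_number(cluster_size, "cluster_size", lower = 1)
  total <- attr(frame, "total_enrollment")
  interval <- total / n_clusters
  e <- frame$enrollment
  undersized <- e < cluster_size
  certainty <- e > interval
  p_regular <- n_clusters * cluster_size / total
  p_child <- ifelse(undersized, n_clusters * e / total, p_regular)
  p_child[certainty] <- NA_real_
  out <- data.frame(school_id = frame$school_id, enrollment = e,
                    p_child = p_child, undersized = undersized,
                    certainty = certainty, stringsAsFactors = FALSE)
  if (is.null(school_id)) return(out)
  row <- out[out$school_id == school_id, ]
  if (nrow(row) != 1L)
    stop(sprintf("school '%s' not in frame", school_id), call. = FALSE)
  if (row$certainty)
    stop(sprintf(
      "school '%s' exceeds the sampling interval (%.1f); certainty selection, single-draw formula inapplicable",
      school_id, interval), call. = FALSE)
  row$p_child
}
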