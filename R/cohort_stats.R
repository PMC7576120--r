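# Matching, cluster-robust (GEE-style) group comparisons, contingency and
# multiplicity procedures. The mean model uses an identity link with an
# independence working structure, so group estimates are plain means and the
# standard errors come from the subject-level sandwich formula; Wald p-values
# use the normal reference, as is conventional for estimating-equation fits.

#' Greedy age/axial-length matching of controls to cases
#'
#' Nearest-neighbor matching without replacement on the standardized
#' (age, axial length) distance. For each case eye, the `k` nearest eligible
#' pool eyes (within both tolerances, not yet used) are selected. Cases are
#' processed in eye-id order and distance ties are broken by a seeded random
#' ordering, so the result is invariant to row order given the seed.
#'
#' @param cases data.frame of case eyes with columns `eye_id`, `subject_id`,
#'   `age`, `axial_length`.
#' @param pool data.frame of candidate control eyes (same columns); subjects
#'   must be disjoint from the cases.
#' @param age_tol,al_tol eligibility tolerances (years, mm).
#' @param k controls per case (default 2).
#' @param rng_seed seed for tie-breaking.
#' @return a data.frame with one row per selected control: `case_eye_id`,
#'   `control_eye_id`, `rank`, `distance`.
#' @export
match_controls <- function(cases, pool, age_tol = 10, al_tol = 0.5, k = 2,
                           rng_seed = NULL) {
  need <- c("eye_id", "subject_id", "age", "axial_length")
  stopifnot(all(need %in% names(cases)), all(need %in% names(pool)))
  if (k < 1) stop_config("k must be >= 1")
  if (age_tol <= 0 || al_tol <= 0) stop_config("tolerances must be positive")
  if (length(intersect(cases$subject_id, pool$subject_id))) {
    stop_config("control pool overlaps the case subjects")
  }
  sd_age <- stats::sd(c(cases$age, pool$age))
  sd_al <- stats::sd(c(cases$axial_length, pool$axial_length))
  sd_age <- if (is.na(sd_age) || sd_age == 0) 1 else sd_age
  sd_al <- if (is.na(sd_al) || sd_al == 0) 1 else sd_al
  tie <- with_seed(rng_seed, stats::runif(nrow(pool)))
  used <- rep(FALSE, nrow(pool))
  out <- list()
  for (cid in sort(cases$eye_id)) {
    cs <- cases[cases$eye_id == cid, , drop = FALSE][1, ]
    elig <- !used &
      abs(pool$age - cs$age) <= age_tol &
      abs(pool$axial_length - cs$axial_length) <= al_tol
    if (sum(elig) < k) {
      stop(sprintf("matching failure: only %d eligible controls for case %s (need %d)",
                   sum(elig), cid, k), call. = FALSE)
    }
    d <- sqrt(((pool$age - cs$age) / sd_age)^2 +
                ((pool$axial_length - cs$axial_length) / sd_al)^2)
    cand <- which(elig)[order(d[elig], tie[elig])][seq_len(k)]
    used[cand] <- TRUE
    out[[cid]] <- data.frame(case_eye_id = cid,
                             control_eye_id = pool$eye_id[cand],
                             rank = seq_len(k), distance = sort(d[cand]),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, df = 1, as used for the sex contingency
#' comparison.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return a list with `statistic` and `p_value`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(3, 12, 21, 23), 2))  # p = 0.059
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("table must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in the 2x2 table", call. = FALSE)
  }
  # small-expected-count caveat is the caller's concern; inputs are validated
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return alpha / m.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 12)  # 0.0041667, i.e. 0.0042 to 4 dp
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  alpha / m
}

# Cluster-robust cell-means fit: y ~ factor(f) with clusters `cl`.
# Returns the cell means and their sandwich covariance. With identity link
# and independence working correlation the coefficients are the cell means
# and the covariance is B M B with B = diag(1/n_j) and M the sum over
# clusters of outer products of per-cell residual sums.
cluster_robust_cellmeans <- function(y, f, cl, small_sample = FALSE) {
  f <- factor(f)
  lev <- levels(f)
  n_j <- as.numeric(table(f))
  means <- tapply(y, f, mean)
  e <- y - means[f]
  g <- unique(cl)
  meat <- matrix(0, length(lev), length(lev))
  for (ci in g) {
    sel <- cl == ci
    u <- vapply(lev, function(l) sum(e[sel & f == l]), numeric(1))
    meat <- meat + tcrossprod(u)
  }
  bread <- diag(1 / n_j, length(lev))
  vc <- bread %*% meat %*% bread
  if (small_sample) {
    G <- length(g)
    if (G > 1) vc <- vc * G / (G - 1)
  }
  dimnames(vc) <- list(lev, lev)
  list(levels = lev, means = as.numeric(means), vcov = vc,
       n = n_j, n_clusters = length(g))
}

wald_p <- function(est, se) {
  if (se == 0) return(if (est == 0) 1 else 0)
  2 * stats::pnorm(-abs(est) / se)
}

#' Cluster-robust two-group comparison
#'
#' Group-mean model with identity link and independence working structure;
#' standard errors are cluster-robust (sandwich) with clusters defined by
#' subject, so paired eyes of one subject are never treated as independent.
#' The difference is mean(first group) - mean(second group) with groups in
#' sorted order (control minus siod for the default labels), tested with a
#' normal-reference Wald statistic.
#'
#' @param data data.frame of per-eye values.
#' @param value,group,subject column names.
#' @param measure label carried into the output.
#' @param small_sample apply a G/(G-1) cluster-count correction to the
#'   variance (off by default; the raw sandwich is the reference estimator).
#' @return an object of class `cohort_comparison`: group means, cluster-robust
#'   SEs, eye/subject counts, difference, its SE and p-value.
#' @export
clustered_group_difference <- function(data, value = "value", group = "group",
                                       subject = "subject_id",
                                       measure = value,
                                       small_sample = FALSE) {
  y <- data[[value]]
  gr <- as.character(data[[group]])
  cl <- as.character(data[[subject]])
  if (is.null(y) || is.null(gr) || is.null(cl)) {
    stop("missing required columns", call. = FALSE)
  }
  levs <- sort(unique(gr))
  if (length(levs) != 2) stop("exactly two groups are required", call. = FALSE)
  for (l in levs) {
    if (length(unique(cl[gr == l])) < 2) {
      stop(sprintf("group '%s' has fewer than 2 subjects", l), call. = FALSE)
    }
  }
  stat <- lapply(levs, function(l) {
    yi <- y[gr == l]; ci <- cl[gr == l]
    m <- mean(yi)
    e <- yi - m
    v <- sum(tapply(e, ci, sum)^2) / length(yi)^2
    if (small_sample) {
      G <- length(unique(ci))
      v <- v * G / (G - 1)
    }
    list(mean = m, se = sqrt(v), n_eyes = length(yi),
         n_subjects = length(unique(ci)))
  })
  names(stat) <- levs
  diff <- stat[[1]]$mean - stat[[2]]$mean
  se_diff <- sqrt(stat[[1]]$se^2 + stat[[2]]$se^2)
  structure(list(measure = measure, groups = levs,
                 means = vapply(stat, `[[`, 0, "mean"),
                 ses = vapply(stat, `[[`, 0, "se"),
                 n_eyes = vapply(stat, function(s) as.numeric(s$n_eyes), 0),
                 n_subjects = vapply(stat, function(s) as.numeric(s$n_subjects), 0),
                 difference = diff, se_difference = se_diff,
                 p_value = wald_p(diff, se_diff)),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("%s: %s %.2f +/- %.2f vs %s %.2f +/- %.2f; diff %.2f (SE %.2f), p = %.4f\n",
              x$measure, x$groups[1], x$means[1], x$ses[1], x$groups[2],
              x$means[2], x$ses[2], x$difference, x$se_difference, x$p_value))
  invisible(x)
}

#' Clock-hour sector comparison across conditions
#'
#' Per clock hour, fits a cluster-robust condition-means model over the three
#' conditions (control, SIOD, repositioned SIOD) with clusters defined by
#' subject, which handles both paired eyes and the repeated conditions of the
#' same eye in one cluster. The three pairwise Wald contrasts are flagged at
#' the Bonferroni threshold 0.05/12.
#'
#' @param data long data.frame of sector means.
#' @param value,condition,subject,hour column names.
#' @param conditions the three condition labels, in (control, siod,
#'   repositioned) order.
#' @param alpha family-wise level used for the Bonferroni flags.
#' @param small_sample see [clustered_group_difference()].
#' @return a data.frame of class `sector_comparison` with 12 rows: per-hour
#'   least-squares means and SEs per condition, three pairwise p-values and
#'   significance flags; the threshold is stored in
#'   `attr(x, "bonferroni_threshold")`.
#' @export
sector_comparison_table <- function(data, value = "thickness",
                                    condition = "condition",
                                    subject = "subject_id", hour = "hour",
                                    conditions = c("control", "siod",
                                                   "siod_repositioned"),
                                    alpha = 0.05, small_sample = FALSE) {
  if (length(conditions) != 3) stop("three conditions are required", call. = FALSE)
  present <- unique(as.character(data[[condition]]))
  if (!all(conditions %in% present)) {
    stop(sprintf("missing condition(s): %s",
                 paste(setdiff(conditions, present), collapse = ", ")),
         call. = FALSE)
  }
  hours <- sort(unique(data[[hour]]))
  if (length(hours) != 12) stop("expected 12 clock hours", call. = FALSE)
  thr <- bonferroni_threshold(alpha, 12)
  contrasts <- list(control_vs_siod = c(1, -1, 0),
                    control_vs_repositioned = c(1, 0, -1),
                    siod_vs_repositioned = c(0, 1, -1))
  rows <- lapply(hours, function(h) {
    d <- data[data[[hour]] == h & data[[condition]] %in% conditions, ]
    f <- factor(as.character(d[[condition]]), levels = conditions)
    fit <- cluster_robust_cellmeans(d[[value]], f, as.character(d[[subject]]),
                                    small_sample = small_sample)
    ms <- fit$means
    ses <- sqrt(diag(fit$vcov))
    ps <- vapply(contrasts, function(cn) {
      est <- sum(cn * ms)
      se <- sqrt(drop(t(cn) %*% fit$vcov %*% cn))
      wald_p(est, se)
    }, numeric(1))
    data.frame(hour = h,
               mean_control = ms[1], se_control = ses[1],
               mean_siod = ms[2], se_siod = ses[2],
               mean_repositioned = ms[3], se_repositioned = ses[3],
               p_control_vs_siod = ps[1],
               p_control_vs_repositioned = ps[2],
               p_siod_vs_repositioned = ps[3],
               sig_control_vs_siod = ps[1] < thr,
               sig_control_vs_repositioned = ps[2] < thr,
               sig_siod_vs_repositioned = ps[3] < thr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- thr
  class(out) <- c("sector_comparison", class(out))
  out
}
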