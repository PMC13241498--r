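#' Cluster-based permutation test of a group-average time course against zero
#'
#' First level: a point-wise one-sample t-test across participants at each
#' time bin, thresholded at `first_alpha` (two-sided — both constriction
#' and dilation are hypothesised). Contiguous runs of at least
#' `min_cluster` suprathreshold bins form clusters; the cluster statistic
#' is the maximum |t| within the cluster (a summed-|t| mass variant is
#' available via `statistic = "mass"`). Second level: each permutation
#' flips the sign of every participant's whole trace independently, the
#' first level is recomputed, and the largest cluster statistic (0 when no
#' cluster forms) is recorded; a cluster's p-value is the fraction of
#' permutation maxima at least as large, computed as `(1 + #exceed) /
#' (n_permutations + 1)` so it is never exactly zero. Clusters with
#' p < `second_alpha` are flagged significant.
#'
#' @param participant_means Numeric matrix, participants x time bins (e.g.
#'   each participant's event-locked average pupil trace), or a data frame
#'   in long format with columns `participant`, `time_s`, `value`.
#' @param time_s Time axis (required for a matrix input; taken from the
#'   data frame otherwise).
#' @param n_permutations Number of sign-flip permutations (default 20000).
#' @param first_alpha First-level two-sided alpha (default 0.05).
#' @param second_alpha Cluster-level alpha (default 0.01).
#' @param min_cluster Minimum cluster extent in bins (default 2).
#' @param statistic `"max"` (maximum |t| in the cluster) or `"mass"`
#'   (summed |t|).
#' @return Object of class `cluster_result`: list with `clusters` (tibble
#'   `start_s, end_s, statistic, p_value, significant`), `pointwise`
#'   (tibble `time_s, t, p`), and the test settings.
#' @export
cluster_permutation_test <- function(participant_means, time_s = NULL,
                                     n_permutations = 20000,
                                     first_alpha = 0.05, second_alpha = 0.01,
                                     min_cluster = 2,
                                     statistic = c("max", "mass")) {
  statistic <- match.arg(statistic)
  if (is.data.frame(participant_means)) {
    stopifnot(all(c("participant", "time_s", "value") %in% names(participant_means)))
    wide <- tidyr::pivot_wider(participant_means, id_cols = "participant",
                               names_from = "time_s", values_from = "value")
    time_s <- as.numeric(names(wide)[-1])
    participant_means <- as.matrix(wide[, -1])
  }
  X <- participant_means
  n <- nrow(X)
  if (n < 5) abort("cluster test requires at least 5 participants")
  if (anyNA(X)) abort("participant means contain missing values; complete them upstream")
  if (is.null(time_s)) time_s <- seq_len(ncol(X))
  tcrit <- function(m, s2) m / sqrt(s2 / n)

  css <- colSums(X^2)
  one_level <- function(m) {
    s2 <- (css - n * m^2) / (n - 1)
    tt <- tcrit(m, s2)
    p <- 2 * pt(-abs(tt), df = n - 1)
    list(t = tt, p = p)
  }
  cluster_stats <- function(tt, p) {
    mask <- !is.na(p) & p < first_alpha
    r <- rle(as.vector(mask))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values & r$lengths >= min_cluster)
    if (length(keep) == 0) return(NULL)
    tibble(
      start_bin = starts[keep], end_bin = ends[keep],
      statistic = map_dbl(keep, function(j) {
        tt_c <- abs(tt[starts[j]:ends[j]])
        if (statistic == "max") max(tt_c) else sum(tt_c)
      })
    )
  }

  obs <- one_level(colMeans(X))
  obs_clusters <- cluster_stats(obs$t, obs$p)

  # permutation null: random sign flip per participant; since flips do not
  # change colSums(X^2), only the flipped mean must be recomputed
  flips <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  nrow = n_permutations)
  M <- flips %*% X / n
  S2 <- sweep(-n * M^2, 2, css, `+`) / (n - 1)
  Tm <- abs(M / sqrt(S2 / n))
  Tm[is.na(Tm)] <- 0
  tthr <- stats::qt(1 - first_alpha / 2, df = n - 1)
  if (statistic == "max") {
    # the max cluster statistic equals the largest |t| at any bin that,
    # together with a suprathreshold neighbour, lies inside a >=2-bin run
    # (min_cluster = 2); for larger min_cluster fall back to the run scan
    mask <- Tm > tthr
    m <- ncol(mask)
    if (min_cluster <= 2) {
      inside <- mask & (cbind(FALSE, mask[, -m, drop = FALSE]) |
                          cbind(mask[, -1, drop = FALSE], FALSE))
      if (min_cluster <= 1) inside <- mask
      null_max <- do.call(pmax, c(as.data.frame(Tm * inside), list(0)))
    } else {
      null_max <- map_dbl(seq_len(n_permutations), function(k) {
        cs <- cluster_stats(Tm[k, ], 2 * pt(-Tm[k, ], df = n - 1))
        if (is.null(cs)) 0 else max(cs$statistic)
      })
    }
  } else {
    null_max <- map_dbl(seq_len(n_permutations), function(k) {
      cs <- cluster_stats(Tm[k, ], 2 * pt(-Tm[k, ], df = n - 1))
      if (is.null(cs)) 0 else max(cs$statistic)
    })
  }

  clusters <- if (is.null(obs_clusters)) {
    tibble(start_s = numeric(), end_s = numeric(), statistic = numeric(),
           p_value = numeric(), significant = logical())
  } else {
    obs_clusters |>
      mutate(start_s = time_s[.data$start_bin],
             end_s = time_s[.data$end_bin],
             p_value = map_dbl(.data$statistic,
                               ~ (1 + sum(null_max >= .x)) / (n_permutations + 1)),
             significant = .data$p_value < second_alpha) |>
      select("start_s", "end_s", "statistic", "p_value", "significant")
  }

  structure(
    list(clusters = clusters,
         pointwise = tibble(time_s = time_s, t = obs$t, p = obs$p),
         n_permutations = n_permutations, first_alpha = first_alpha,
         second_alpha = second_alpha, min_cluster = min_cluster,
         statistic = statistic, n_participants = n),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d participant(s), %d permutation(s), %s statistic\n",
              x$n_participants, x$n_permutations, x$statistic))
  if (nrow(x$clusters) == 0) {
    cat("  no clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %.2f to %.2f s: stat = %.2f, p = %.4g%s\n",
                  x$clusters$start_s[i], x$clusters$end_s[i],
                  x$clusters$statistic[i], x$clusters$p_value[i],
                  if (x$clusters$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}

#' @rdname cluster_permutation_test
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @rdname cluster_permutation_test
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_participants = x$n_participants,
         n_permutations = x$n_permutations,
         n_clusters = nrow(x$clusters),
         n_significant = sum(x$clusters$significant),
         min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_)
}
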