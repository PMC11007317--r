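#' Subjects-by-electrodes SWA dataset
#'
#' Bundles the log-relative SWA matrix (one row per subject, one column per
#' electrode), the behavioral score vector and optional per-subject
#' covariates, together with the montage used for adjacency.
#'
#' @param maps numeric matrix, subjects x electrodes, with electrode labels
#'   as column names (no missing values).
#' @param scores numeric vector, one score per subject.
#' @param covariates optional data frame of per-subject covariate columns.
#' @param mont the [montage()] the electrodes live on.
#' @param subject_id optional subject identifiers.
#' @return a `swa_dataset` object.
#' @export
swa_dataset <- function(maps, scores, covariates = NULL,
                        mont = standard_montage_59(), subject_id = NULL) {
  maps <- as.matrix(maps)
  if (is.null(colnames(maps))) {
    stop_swatopo("maps must carry electrode labels as column names.",
                 "swatopo_format_error")
  }
  if (nrow(maps) != length(scores)) {
    stop_swatopo("one score per subject (matrix row) is required.",
                 "swatopo_format_error")
  }
  if (anyNA(maps) || anyNA(scores)) {
    stop_swatopo("missing values are not allowed.", "swatopo_format_error")
  }
  if (!all(colnames(maps) %in% mont$label)) {
    stop_swatopo("montage does not cover all electrodes.",
                 "swatopo_format_error")
  }
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    stopifnot(nrow(covariates) == nrow(maps))
  }
  structure(
    list(maps = maps, scores = as.numeric(scores), covariates = covariates,
         electrodes = colnames(maps), montage = mont,
         subject_id = subject_id %||% sprintf("s%02d", seq_len(nrow(maps)))),
    class = "swa_dataset"
  )
}

#' @export
print.swa_dataset <- function(x, ...) {
  cat(sprintf("<swa_dataset: %d subjects x %d electrodes, %d covariates>\n",
              nrow(x$maps), ncol(x$maps),
              if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}

#' Electrode-wise Pearson correlation map
#'
#' Pearson r between the behavioral score and each electrode's log-relative
#' SWA across subjects.
#'
#' @param data a [swa_dataset()] with n >= 4 subjects.
#' @return tibble `electrode`, `r`.
#' @export
pearson_map <- function(data) {
  stopifnot(inherits(data, "swa_dataset"))
  n <- nrow(data$maps)
  if (n < 4) {
    stop_swatopo("need at least 4 subjects.", "swatopo_parameter_error")
  }
  if (sd(data$scores) == 0) {
    stop_swatopo("scores have zero variance.", "swatopo_validation_error")
  }
  sds <- apply(data$maps, 2, sd)
  if (any(sds == 0)) {
    stop_swatopo(
      sprintf("zero variance at electrode %s.",
              data$electrodes[which(sds == 0)[1]]),
      "swatopo_validation_error"
    )
  }
  tibble(electrode = data$electrodes,
         r = as.numeric(cor(data$maps, data$scores)))
}

#' Critical Pearson r for a two-sided test
#'
#' `r_crit = t / sqrt(t^2 + n - 2)` with t the `1 - alpha/2` quantile of the
#' t distribution on `n - 2` degrees of freedom: the electrode-level
#' threshold that forms suprathreshold clusters.
#'
#' @param n number of subjects (>= 4).
#' @param alpha two-sided significance level in (0, 1).
#' @return critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  assert_scalar_number(n, "n", lower = 4)
  if (!(alpha > 0 && alpha < 1)) {
    stop_swatopo("alpha must lie in (0, 1).", "swatopo_parameter_error")
  }
  tq <- qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(tq^2 + n - 2)
}

#' Electrode adjacency graph
#'
#' Two electrodes are neighbours when their 3-D Euclidean distance is at most
#' `distance_threshold` millimetres. The default of 40 mm on an 85-mm head
#' gives roughly 4-8 neighbours per electrode on the built-in 59-channel
#' montage.
#'
#' @param mont a [montage()].
#' @param distance_threshold mm (> 0).
#' @return an `adjacency_graph`: named list of neighbour index vectors plus
#'   `labels` and the threshold.
#' @export
adjacency_graph <- function(mont, distance_threshold = 40) {
  if (distance_threshold <= 0) {
    stop_swatopo("distance_threshold must be positive.",
                 "swatopo_parameter_error")
  }
  d <- chord_distances(mont)
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) {
    which(d[i, ] <= distance_threshold & seq_len(n) != i)
  })
  structure(list(neighbors = nb, labels = mont$label,
                 distance_threshold = distance_threshold),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("<adjacency_graph: %d electrodes, threshold %g mm, degree %d-%d>\n",
              length(x$labels), x$distance_threshold, min(deg), max(deg)))
  invisible(x)
}

# max cluster size among same-sign suprathreshold electrodes;
# idx: integer electrode indices, sgn: +1/-1 per entry, nb: neighbour list
max_cluster_size <- function(idx, sgn, nb) {
  k <- length(idx)
  if (k < 2) return(k)
  best <- 1L
  seen <- logical(k)
  pos <- integer(length(nb))      # map electrode index -> position in idx
  pos[idx] <- seq_len(k)
  for (s in seq_len(k)) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      for (e in nb[[idx[cur]]]) {
        p <- pos[e]
        if (p > 0L && !seen[p] && sgn[p] == sgn[cur]) {
          seen[p] <- TRUE
          stack <- c(stack, p)
        }
      }
    }
    if (size > best) best <- size
  }
  best
}

#' Suprathreshold clusters of a correlation map
#'
#' Connected components, under the adjacency graph, of electrodes whose |r|
#' reaches the critical value, split by correlation sign (a positive and a
#' negative electrode never join the same cluster).
#'
#' @param rmap tibble `electrode`, `r` (from [pearson_map()]).
#' @param graph an [adjacency_graph()].
#' @param r_crit electrode-level critical |r|.
#' @return tibble `cluster`, `sign`, `size`, `electrodes` (list column),
#'   ordered by decreasing size; zero rows when nothing is suprathreshold.
#' @export
find_clusters <- function(rmap, graph, r_crit) {
  ei <- match(rmap$electrode, graph$labels)
  if (anyNA(ei)) {
    stop_swatopo("correlation map electrodes missing from graph.",
                 "swatopo_format_error")
  }
  supra <- which(abs(rmap$r) >= r_crit)
  if (!length(supra)) {
    return(tibble(cluster = integer(), sign = integer(), size = integer(),
                  electrodes = list()))
  }
  idx <- ei[supra]
  sgn <- sign(rmap$r[supra])
  k <- length(idx)
  seen <- logical(k)
  pos <- integer(length(graph$labels))
  pos[idx] <- seq_len(k)
  comps <- list()
  for (s in seq_len(k)) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    members <- integer()
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      for (e in graph$neighbors[[idx[cur]]]) {
        p <- pos[e]
        if (p > 0L && !seen[p] && sgn[p] == sgn[cur]) {
          seen[p] <- TRUE
          stack <- c(stack, p)
        }
      }
    }
    comps[[length(comps) + 1L]] <-
      list(sign = sgn[members[1]],
           electrodes = rmap$electrode[supra[members]])
  }
  out <- tibble(
    cluster = seq_along(comps),
    sign = map_int(comps, ~ as.integer(.x$sign)),
    size = map_int(comps, ~ length(.x$electrodes)),
    electrodes = map(comps, "electrodes")
  )
  out <- arrange(out, desc(.data$size))
  out$cluster <- seq_len(nrow(out))
  out
}

# all permutations of 1..n (lexicographic), n! rows
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Suprathreshold cluster permutation test
#'
#' Electrode-wise Pearson correlations between log-relative SWA and the
#' behavioral score are thresholded at the two-sided critical r for
#' `alpha_electrode`; suprathreshold neighbours of equal sign form observed
#' clusters. The null distribution of the maximal cluster size (over both
#' signs) is built by permuting the score vector against the fixed SWA
#' matrix. A cluster's p-value is the add-one permutation estimator
#' `(1 + #\{null >= size\}) / (1 + n_permutations)`; the critical cluster
#' size is the 95th-percentile threshold realized as the smallest size whose
#' p-value does not exceed `alpha_cluster`, so `size >= critical` and
#' `p <= alpha_cluster` coincide. When `n! <= 40320` the permutations are
#' enumerated exhaustively instead of sampled.
#'
#' @param data a [swa_dataset()].
#' @param graph an [adjacency_graph()]; defaults to the dataset montage at
#'   40 mm.
#' @param alpha_electrode electrode-forming two-sided alpha (default 0.05).
#' @param alpha_cluster cluster-level alpha; `1 - alpha_cluster` is the
#'   percentile of the null used as critical threshold (default 0.05).
#' @param n_permutations number of random permutations (>= 100; default
#'   5000); ignored when enumerating exhaustively.
#' @param seed integer seed for the permutation draw.
#' @return a `cluster_test` object; see [tidy.cluster_test()] and
#'   [glance.cluster_test()].
#' @export
cluster_permutation_test <- function(data, graph = NULL,
                                     alpha_electrode = 0.05,
                                     alpha_cluster = 0.05,
                                     n_permutations = 5000, seed = 1L) {
  stopifnot(inherits(data, "swa_dataset"))
  if (is.null(graph)) graph <- adjacency_graph(data$montage)
  n <- nrow(data$maps)
  exhaustive <- factorial(n) <= 40320
  if (!exhaustive && n_permutations < 100) {
    stop_swatopo("need at least 100 permutations.", "swatopo_parameter_error")
  }
  rmap <- pearson_map(data)
  rc <- critical_r(n, alpha_electrode)
  obs <- find_clusters(rmap, graph, rc)

  # standardized matrix/score so r = Z' s / (n - 1)
  Z <- scale(data$maps)
  s <- as.numeric(scale(data$scores))
  ei <- match(data$electrodes, graph$labels)
  nb <- graph$neighbors

  if (exhaustive) {
    perms <- all_permutations(n)
    P <- nrow(perms)
    S <- matrix(s[t(perms)], nrow = n)
  } else {
    set.seed(seed)
    P <- as.integer(n_permutations)
    S <- vapply(seq_len(P), function(i) s[sample.int(n)], numeric(n))
  }
  R <- crossprod(Z, S) / (n - 1)
  null_max <- integer(P)
  for (p in seq_len(P)) {
    supra <- which(abs(R[, p]) >= rc)
    if (length(supra)) {
      null_max[p] <- max_cluster_size(ei[supra], sign(R[supra, p]), nb)
    }
  }

  p_for_size <- function(sz) (1 + sum(null_max >= sz)) / (1 + P)
  obs$p_value <- vapply(obs$size, p_for_size, 0)
  cand <- seq_len(max(c(null_max, obs$size, 0L)) + 1L)
  pc <- vapply(cand, p_for_size, 0)
  critical_size <- cand[which(pc <= alpha_cluster)[1]]
  obs$significant <- obs$size >= critical_size

  structure(
    list(r_map = rmap, r_critical = rc, clusters = obs,
         null_max_sizes = null_max, critical_cluster_size = critical_size,
         n_permutations = P, exhaustive = exhaustive, seed = seed,
         alpha_electrode = alpha_electrode, alpha_cluster = alpha_cluster,
         n_subjects = n),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "<cluster_test: n=%d, r_crit=%.4f, %d permutations%s, critical size %d>\n",
    x$n_subjects, x$r_critical, x$n_permutations,
    if (x$exhaustive) " (exhaustive)" else "", x$critical_cluster_size
  ))
  if (nrow(x$clusters)) {
    df <- x$clusters
    df$electrodes <- map_chr(df$electrodes, paste, collapse = ",")
    print(df)
  } else {
    cat("no suprathreshold clusters\n")
  }
  invisible(x)
}

#' Tidy a cluster permutation test
#'
#' @param x a `cluster_test`.
#' @param ... unused.
#' @return one row per observed cluster: `cluster`, `sign`, `size`,
#'   `electrodes` (comma-joined), `p_value`, `significant`.
#' @method tidy cluster_test
#' @export
tidy.cluster_test <- function(x, ...) {
  df <- x$clusters
  df$electrodes <- map_chr(df$electrodes, paste, collapse = ",")
  df
}

#' @rdname tidy.cluster_test
#' @return `glance()`: one-row summary of the test.
#' @method glance cluster_test
#' @export
glance.cluster_test <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_electrodes = nrow(x$r_map),
    r_critical = x$r_critical,
    n_permutations = x$n_permutations,
    exhaustive = x$exhaustive,
    critical_cluster_size = x$critical_cluster_size,
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    max_cluster_size = if (nrow(x$clusters)) max(x$clusters$size) else 0L
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Correlation between cluster-mean SWA and the score
#'
#' Averages the log-relative SWA over the cluster electrodes per subject and
#' correlates the means with the behavioral score (two-sided t test on
#' `n - 2` degrees of freedom).
#'
#' @param data a [swa_dataset()].
#' @param cluster character vector of electrode labels (non-empty).
#' @return one-row tibble `r`, `r_squared`, `p_value`, `df`, `n`.
#' @export
cluster_mean_correlation <- function(data, cluster) {
  stopifnot(inherits(data, "swa_dataset"))
  if (!length(cluster)) {
    stop_swatopo("cluster must be non-empty.", "swatopo_parameter_error")
  }
  ci <- match(cluster, data$electrodes)
  if (anyNA(ci)) {
    stop_swatopo("cluster electrode missing from dataset.",
                 "swatopo_format_error")
  }
  cm <- rowMeans(data$maps[, ci, drop = FALSE])
  n <- length(cm)
  r <- cor(cm, data$scores)
  df <- n - 2
  tstat <- r * sqrt(df / (1 - r^2))
  tibble(r = r, r_squared = r^2,
         p_value = 2 * pt(-abs(tstat), df), df = df, n = n)
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection onto an intercept plus the covariate columns;
#' `df = n - 2 - k` for `k` covariates, two-sided p from the t distribution.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data frame of covariates.
#' @return one-row tibble `r`, `p_value`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates) {
  cv <- as.matrix(as.data.frame(covariates))
  n <- length(x)
  k <- ncol(cv)
  if (n <= k + 3) {
    stop_swatopo("too few observations for the covariate count.",
                 "swatopo_parameter_error")
  }
  if (qr(cbind(1, cv))$rank < k + 1) {
    stop_swatopo("collinear covariates.", "swatopo_validation_error")
  }
  rx <- residuals(lm(x ~ cv))
  ry <- residuals(lm(y ~ cv))
  if (sd(rx) <= 1e-10 * sd(x) || sd(ry) <= 1e-10 * sd(y)) {
    stop_swatopo("zero residual variance; partial correlation undefined.",
                 "swatopo_validation_error")
  }
  r <- cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  tibble(r = r, p_value = 2 * pt(-abs(tstat), df), df = df, n = n)
}

#' Per-cycle cluster correlations
#'
#' Correlates the cluster-mean log-relative SWA with the score separately per
#' sleep cycle, plus a pooled analysis in which the per-subject cluster means
#' of the pooled cycles (2-4 by default) are averaged before correlating.
#'
#' @param cycle_maps list (one element per subject) of per-cycle map lists as
#'   returned by [per_cycle_relative_swa()]; every subject must have every
#'   requested cycle.
#' @param scores numeric score per subject.
#' @param cluster electrode labels of the cluster.
#' @param mont montage (for dataset construction).
#' @param cycles cycle numbers to analyse (default 1:4).
#' @param pool cycle numbers to pool (default 2:4).
#' @return list with `per_cycle` (tibble, one row per cycle) and `pooled`
#'   (one-row tibble).
#' @export
per_cycle_analysis <- function(cycle_maps, scores, cluster,
                               mont = standard_montage_59(), cycles = 1:4,
                               pool = 2:4) {
  wanted <- sprintf("cycle_%d", cycles)
  missing_subj <- which(map_lgl(cycle_maps, ~ !all(wanted %in% names(.x))))
  if (length(missing_subj)) {
    stop_swatopo(
      sprintf("missing cycles for subject(s): %s.",
              paste(missing_subj, collapse = ", ")),
      "swatopo_validation_error"
    )
  }
  ds_for <- function(cyc) {
    m <- do.call(rbind, map(cycle_maps, function(cm) {
      mp <- cm[[sprintf("cycle_%d", cyc)]]
      stats::setNames(mp$value, mp$electrode)
    }))
    swa_dataset(m, scores, mont = mont)
  }
  per_cycle <- dplyr::bind_rows(map(cycles, function(cyc) {
    res <- cluster_mean_correlation(ds_for(cyc), cluster)
    mutate(res, cycle = cyc, .before = 1)
  }))
  pooled_means <- rowMeans(vapply(pool, function(cyc) {
    ds <- ds_for(cyc)
    rowMeans(ds$maps[, match(cluster, ds$electrodes), drop = FALSE])
  }, numeric(length(scores))))
  n <- length(scores)
  r <- cor(pooled_means, scores)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  pooled <- tibble(cycles = paste(pool, collapse = "+"), r = r,
                   r_squared = r^2, p_value = 2 * pt(-abs(tstat), n - 2),
                   df = n - 2, n = n)
  list(per_cycle = per_cycle, pooled = pooled)
}

#' Write / read a cluster-test report as JSON
#'
#' Serializes the observed clusters, the permutation-null summary (tabulated
#' max cluster sizes), p-values, seed and parameters with full numeric
#' precision; rewriting the report of a seeded run is byte-identical.
#'
#' @param result a `cluster_test`.
#' @param path output JSON path.
#' @return `write_cluster_report()` the path invisibly; `read_cluster_report()`
#'   the parsed list.
#' @export
write_cluster_report <- function(result, path) {
  stopifnot(inherits(result, "cluster_test"))
  tab <- table(result$null_max_sizes)
  payload <- list(
    parameters = list(
      n_subjects = result$n_subjects,
      alpha_electrode = result$alpha_electrode,
      alpha_cluster = result$alpha_cluster,
      r_critical = result$r_critical,
      n_permutations = result$n_permutations,
      exhaustive = result$exhaustive,
      seed = result$seed
    ),
    critical_cluster_size = result$critical_cluster_size,
    clusters = lapply(seq_len(nrow(result$clusters)), function(i) {
      row <- result$clusters[i, ]
      list(cluster = row$cluster, sign = row$sign, size = row$size,
           electrodes = row$electrodes[[1]], p_value = row$p_value,
           significant = row$significant)
    }),
    null_max_size_counts = list(size = as.integer(names(tab)),
                                count = as.integer(tab)),
    r_map = list(electrode = result$r_map$electrode, r = result$r_map$r)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cluster_report
#' @export
read_cluster_report <- function(path) {
  if (!file.exists(path)) {
    stop_swatopo(sprintf("report not found: %s", path), "swatopo_io_error")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
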