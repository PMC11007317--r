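#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_histogram
#'   geom_vline geom_smooth scale_color_gradient2 coord_fixed theme_minimal
#'   labs geom_step
#' @export
ggplot2::autoplot

# azimuthal-equidistant projection of montage positions to 2-D (nose up)
project_montage <- function(mont) {
  r <- head_radius(mont)
  th <- acos(pmin(1, pmax(-1, mont$z / r)))   # inclination from vertex
  az <- atan2(mont$x, mont$y)                 # 0 = front, + right
  tibble(electrode = mont$label, px = th * sin(az), py = th * cos(az))
}

#' Plot a topographic map
#'
#' Flat azimuthal projection of the electrode positions (nose up), coloured
#' by map value.
#'
#' @param object a [topomap()].
#' @param mont the [montage()] to project (default built-in 59-channel).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot topomap
#' @export
autoplot.topomap <- function(object, mont = standard_montage_59(), ...) {
  proj <- project_montage(mont)
  df <- dplyr::inner_join(as_tibble(object), proj, by = "electrode")
  mid <- switch(map_kind(object), log_relative = 0, relative = 1,
                mean(df$value))
  ggplot(df, aes(.data$px, .data$py, color = .data$value)) +
    geom_point(size = 5) +
    scale_color_gradient2(midpoint = mid) +
    coord_fixed() +
    theme_minimal() +
    labs(title = sprintf("%s SWA topography", map_kind(object)),
         x = NULL, y = NULL, color = "value")
}

#' Plot a cluster permutation test
#'
#' Histogram of the permutation null of maximal cluster sizes with the
#' critical cluster-size threshold and the observed cluster sizes.
#'
#' @param object a `cluster_test`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cluster_test
#' @export
autoplot.cluster_test <- function(object, ...) {
  df <- tibble(max_size = object$null_max_sizes)
  p <- ggplot(df, aes(.data$max_size)) +
    geom_histogram(binwidth = 1, fill = "grey70", color = "white") +
    geom_vline(xintercept = object$critical_cluster_size - 0.5,
               linetype = "dashed") +
    theme_minimal() +
    labs(x = "max cluster size under permutation",
         y = "permutations",
         title = sprintf("cluster-size null (critical size %d)",
                         object$critical_cluster_size))
  if (nrow(object$clusters)) {
    p <- p + geom_vline(xintercept = object$clusters$size, color = "red3")
  }
  p
}

#' Plot a hypnogram
#'
#' Classic staircase plot with deep sleep at the bottom and REM highlighted.
#'
#' @param object a [hypnogram()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  lev <- c("N3", "N2", "N1", "REM", "W")
  df <- tibble(
    hours = (seq_along(object$stages) - 1) * object$epoch_length / 3600,
    stage = factor(object$stages, levels = lev)
  )
  ggplot(df, aes(.data$hours, as.integer(.data$stage))) +
    geom_step() +
    ggplot2::scale_y_continuous(breaks = seq_along(lev), labels = lev) +
    theme_minimal() +
    labs(x = "hours since lights off", y = NULL, title = "hypnogram")
}
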