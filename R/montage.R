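#' Electrode montages
#'
#' A montage is a tibble with one row per electrode: `label`, and 3-D scalp
#' coordinates `x`, `y`, `z` in millimetres on a sphere of radius
#' `head_radius` (stored as an attribute). The coordinate convention is
#' x to the right, y anterior, z up, origin at the head centre.
#'
#' @param df data frame with columns `label`, `x`, `y`, `z` (mm).
#' @param head_radius sphere radius in mm; defaults to the median norm of the
#'   supplied positions.
#' @param tol relative tolerance for the on-sphere check.
#' @return a `swa_montage` tibble.
#' @export
montage <- function(df, head_radius = NULL, tol = 1e-6) {
  df <- as_tibble(df)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_swatopo("montage needs columns label, x, y, z.", "swatopo_format_error")
  }
  df$label <- as.character(df$label)
  if (anyDuplicated(df$label)) {
    stop_swatopo("montage labels must be unique.", "swatopo_format_error")
  }
  r <- sqrt(df$x^2 + df$y^2 + df$z^2)
  if (is.null(head_radius)) head_radius <- stats::median(r)
  if (any(abs(r - head_radius) > tol * head_radius + 1e-9)) {
    stop_swatopo(
      sprintf("electrode positions must lie on a sphere of radius %.3g mm.", head_radius),
      "swatopo_format_error"
    )
  }
  attr(df, "head_radius") <- head_radius
  class(df) <- c("swa_montage", class(df))
  df
}

#' @export
print.swa_montage <- function(x, ...) {
  cat(sprintf("<montage: %d electrodes, head radius %.1f mm>\n",
              nrow(x), attr(x, "head_radius")))
  NextMethod()
}

#' Head radius of a montage
#' @param m a montage.
#' @return radius in mm.
#' @export
head_radius <- function(m) attr(m, "head_radius")

# spherical linear interpolation between unit vectors a and b at fraction t
slerp <- function(a, b, t) {
  om <- acos(max(-1, min(1, sum(a * b))))
  if (om < 1e-12) return(a)
  (sin((1 - t) * om) * a + sin(t * om) * b) / sin(om)
}

# unit position for inclination theta from the vertex and azimuth phi from
# the front (positive to the right), both in degrees
incl_az <- function(theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
}

#' Built-in 59-channel scalp montage
#'
#' Idealized 10-10 positions on a sphere for the 59 scalp electrodes of a
#' 64-channel cap after removing the channels used only for sleep scoring
#' (EOG/EMG/mastoids) and the ground/reference sites AFz and FCz. The outer
#' ring lies at 72 degrees inclination from the vertex with labels every 18
#' degrees of azimuth; interior rows are equal great-circle subdivisions of
#' the arcs running from the left edge through the midline to the right edge.
#'
#' @param head_radius_mm sphere radius in millimetres (default 85).
#' @return a [montage()] tibble of 59 electrodes.
#' @export
standard_montage_59 <- function(head_radius_mm = 85) {
  pos <- list()
  ring <- c("Fpz", "Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8", "O2",
            "Oz", "O1", "PO7", "P7", "TP7", "T7", "FT7", "F7", "AF7", "Fp1")
  for (i in seq_along(ring)) {
    pos[[ring[i]]] <- incl_az(72, (i - 1) * 18)
  }
  mid <- c(AFz = -54, Fz = -36, FCz = -18, Cz = 0, CPz = 18, Pz = 36, POz = 54)
  for (lab in names(mid)) {
    th <- abs(mid[[lab]])
    pos[[lab]] <- incl_az(th, if (mid[[lab]] <= 0) 0 else 180)
  }
  row_fill <- function(left, centre, right, labs_l, labs_r) {
    nl <- length(labs_l)
    for (i in seq_len(nl)) {
      pos[[labs_l[i]]] <<- slerp(pos[[left]], pos[[centre]], i / (nl + 1))
    }
    nr <- length(labs_r)
    for (i in seq_len(nr)) {
      pos[[labs_r[i]]] <<- slerp(pos[[centre]], pos[[right]], i / (nr + 1))
    }
  }
  row_fill("F7", "Fz", "F8", c("F5", "F3", "F1"), c("F2", "F4", "F6"))
  row_fill("FT7", "FCz", "FT8", c("FC5", "FC3", "FC1"), c("FC2", "FC4", "FC6"))
  row_fill("T7", "Cz", "T8", c("C5", "C3", "C1"), c("C2", "C4", "C6"))
  row_fill("TP7", "CPz", "TP8", c("CP5", "CP3", "CP1"), c("CP2", "CP4", "CP6"))
  row_fill("P7", "Pz", "P8", c("P5", "P3", "P1"), c("P2", "P4", "P6"))
  row_fill("AF7", "AFz", "AF8", "AF3", "AF4")
  row_fill("PO7", "POz", "PO8", "PO3", "PO4")
  pos$AFz <- NULL
  pos$FCz <- NULL
  m <- unname(do.call(rbind, pos)) * head_radius_mm
  montage(
    tibble(label = names(pos), x = m[, 1], y = m[, 2], z = m[, 3]),
    head_radius = head_radius_mm
  )
}

#' Read / write a montage TSV
#'
#' Tab-separated file with header `label  x  y  z`, coordinates in mm.
#'
#' @param path file path.
#' @return `read_montage()` a [montage()]; `write_montage()` the path,
#'   invisibly.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) {
    stop_swatopo(sprintf("montage file not found: %s", path), "swatopo_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  montage(df)
}

#' @rdname read_montage
#' @param m a montage.
#' @export
write_montage <- function(m, path) {
  out <- data.frame(label = m$label, x = fmt17(m$x), y = fmt17(m$y), z = fmt17(m$z))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# pairwise great-circle (arc) distances in mm between montage electrodes
arc_distances <- function(m) {
  r <- head_radius(m)
  p <- as.matrix(m[, c("x", "y", "z")]) / r
  cosang <- tcrossprod(p)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  d <- r * acos(cosang)
  dimnames(d) <- list(m$label, m$label)
  d
}

# pairwise Euclidean (chord) distances in mm
chord_distances <- function(m) {
  p <- as.matrix(m[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(p))
  dimnames(d) <- list(m$label, m$label)
  d
}
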