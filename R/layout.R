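#' Construct or import a sensor layout
#'
#' A sensor layout is a table of sensor positions on (roughly) a hemispheric
#' helmet surface: `sensor_id`, Cartesian `x`, `y`, `z` in meters, `kind`
#' (`"mag"` or `"grad"`), and `pair_id` linking the two planar gradiometers of
#' a site (empty for magnetometers). The default layout mimics a 306-channel
#' whole-head system: 102 sites placed quasi-uniformly on a hemisphere, each
#' carrying one magnetometer and one pair of planar gradiometers.
#'
#' @param csv Optional path to a layout CSV with columns
#'   `sensor_id,x,y,z,kind,pair_id`; when supplied, parameters are ignored.
#' @param n_sites Number of helmet sites for the generated layout (default 102).
#' @param radius Helmet radius in meters (default 0.09).
#' @return A data frame of class `sensor_layout`.
#' @export
#' @examples
#' lay <- make_sensor_layout()
#' table(lay$kind)  # 102 mag, 204 grad
make_sensor_layout <- function(csv = NULL, n_sites = 102L, radius = 0.09) {
  if (!is.null(csv)) {
    return(read_sensor_layout(csv))
  }
  stopifnot_scalar_number(n_sites, "n_sites", positive = TRUE)
  stopifnot_scalar_number(radius, "radius", positive = TRUE)
  n_sites <- as.integer(n_sites)

  # Fibonacci lattice on the upper hemisphere: quasi-uniform site coverage.
  i <- seq_len(n_sites) - 0.5
  z <- i / n_sites                       # in (0, 1): upper hemisphere
  phi <- pi * (1 + sqrt(5)) * i
  r_xy <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(x = r_xy * cos(phi), y = r_xy * sin(phi), z = z)

  site <- sprintf("S%03d", seq_len(n_sites))
  df <- data.frame(
    sensor_id = c(paste0(site, "_mag"), paste0(site, "_g1"), paste0(site, "_g2")),
    x = rep(pos[, "x"], 3L),
    y = rep(pos[, "y"], 3L),
    z = rep(pos[, "z"], 3L),
    kind = rep(c("mag", "grad", "grad"), each = n_sites),
    pair_id = c(rep("", n_sites), rep(paste0(site, "_gpair"), 2L)),
    stringsAsFactors = FALSE
  )
  validate_sensor_layout(df)
}

validate_sensor_layout <- function(df) {
  need <- c("sensor_id", "x", "y", "z", "kind", "pair_id")
  if (!all(need %in% names(df))) {
    stop("layout must have columns: ", paste(need, collapse = ","), call. = FALSE)
  }
  df <- df[, need]
  df$sensor_id <- as.character(df$sensor_id)
  df$pair_id <- as.character(df$pair_id)
  df$pair_id[is.na(df$pair_id)] <- ""
  if (anyDuplicated(df$sensor_id)) stop("duplicate sensor_id in layout", call. = FALSE)
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("non-finite sensor coordinates", call. = FALSE)
  }
  if (!all(df$kind %in% c("mag", "grad"))) stop("kind must be 'mag' or 'grad'", call. = FALSE)
  pid <- df$pair_id[nzchar(df$pair_id)]
  if (length(pid)) {
    tab <- table(pid)
    if (any(tab != 2L)) {
      stop("pair_id must link exactly two sensors: ",
           paste(names(tab)[tab != 2L], collapse = ","), call. = FALSE)
    }
    bad_kind <- df$pair_id[nzchar(df$pair_id) & df$kind != "grad"]
    if (length(bad_kind)) {
      stop("pair_id set on non-gradiometer sensors: ",
           paste(unique(bad_kind), collapse = ","), call. = FALSE)
    }
  }
  class(df) <- c("sensor_layout", "data.frame")
  df
}

#' Read a sensor layout from CSV
#'
#' @param path CSV with columns `sensor_id,x,y,z,kind,pair_id`.
#' @return A `sensor_layout` data frame.
#' @export
read_sensor_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = list(
    sensor_id = "character", pair_id = "character"
  ))
  validate_sensor_layout(df)
}

#' Write a sensor layout to CSV
#'
#' @param layout A `sensor_layout`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_layout <- function(layout, path) {
  layout <- validate_sensor_layout(layout)
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf(
    "<sensor_layout> %d sensors (%d mag, %d grad, %d planar pairs)\n",
    nrow(x), sum(x$kind == "mag"), sum(x$kind == "grad"),
    length(unique(x$pair_id[nzchar(x$pair_id)]))
  ))
  invisible(x)
}

#' Positions of the sensors of one kind, or of combined planar pairs
#'
#' For `kind = "grad_pairs"` one row per complete planar pair is returned at
#' the shared site position, named by `pair_id`.
#'
#' @param layout A `sensor_layout`.
#' @param kind `"mag"`, `"grad"`, or `"grad_pairs"`.
#' @return Matrix with rownames (sensor or pair ids) and columns x, y, z.
#' @export
layout_positions <- function(layout, kind = c("mag", "grad", "grad_pairs")) {
  kind <- match.arg(kind)
  layout <- validate_sensor_layout(layout)
  if (kind == "grad_pairs") {
    g <- layout[layout$kind == "grad" & nzchar(layout$pair_id), , drop = FALSE]
    if (!nrow(g)) stop("layout has no complete gradiometer pairs", call. = FALSE)
    first <- g[!duplicated(g$pair_id), , drop = FALSE]
    m <- as.matrix(first[, c("x", "y", "z")])
    rownames(m) <- first$pair_id
    return(m)
  }
  s <- layout[layout$kind == kind, , drop = FALSE]
  if (!nrow(s)) stop("layout has no sensors of kind ", kind, call. = FALSE)
  m <- as.matrix(s[, c("x", "y", "z")])
  rownames(m) <- s$sensor_id
  m
}
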