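# Conversion Pa s/um^4 -> mmHg min/mL/m, from 1 mmHg = 133.322 Pa,
# 1 mL = 1e12 um^3, 1 min = 60 s, 1 m = 1e6 um.
RES_UM4_TO_MMHG <- 1e18 / (133.322 * 60)

#' Unit conversion for resistance per unit length
#'
#' Converts between the package's working unit, Pa s / um^4, and the
#' physiological reporting unit mmHg min / mL / m. The single conversion
#' constant is `1e18 / (133.322 * 60) ~ 1.25e14` (mmHg min/mL/m per
#' Pa s/um^4), derived from 1 mmHg = 133.322 Pa, 1 mL = 1e12 um^3,
#' 1 min = 60 s, 1 m = 1e6 um.
#'
#' @param R resistance values.
#' @param from,to `"SI-um"` (Pa s/um^4) or `"mmHg-min-mL-m"`.
#' @return converted values.
#' @export
convert_resistance <- function(R, from = "SI-um", to = "mmHg-min-mL-m") {
  units <- c("SI-um", "mmHg-min-mL-m")
  from <- match.arg(from, units); to <- match.arg(to, units)
  f <- c("SI-um" = 1, "mmHg-min-mL-m" = RES_UM4_TO_MMHG)
  R * f[[to]] / f[[from]]
}

#' Read a cross-section stack
#'
#' Reads the documented stack formats. JSON: an array of objects
#' `{z, centerline_point, axial_vector, vertices: [[x, y], ...]}` (the two
#' vector fields optional). CSV: long form with columns
#' `section_id, z, vertex_index, x, y`. Units um; vertices counter-clockwise.
#' Sections must come in strictly increasing z; the first offending section is
#' named otherwise.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @return list of `cross_section` objects.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  secs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(seq_along(raw), function(i) {
      s <- raw[[i]]
      if (is.null(s$z) || is.null(s$vertices))
        stop("parse error in section ", i, ": need fields 'z' and 'vertices'")
      v <- do.call(rbind, lapply(s$vertices, unlist))
      tryCatch(
        cross_section(v, z = s$z,
                      centerline_point = if (is.null(s$centerline_point))
                        c(0, 0, s$z) else unlist(s$centerline_point),
                      axial_vector = if (is.null(s$axial_vector))
                        c(0, 0, 1) else unlist(s$axial_vector)),
        error = function(e) stop("section ", i, ": ", conditionMessage(e)))
    })
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    need <- c("section_id", "z", "vertex_index", "x", "y")
    if (!all(need %in% names(df)))
      stop("parse error: CSV stack needs columns ",
           paste(need, collapse = ", "))
    ids <- unique(df$section_id)
    lapply(ids, function(id) {
      d <- df[df$section_id == id, ]
      d <- d[order(d$vertex_index), ]
      cross_section(cbind(d$x, d$y), z = d$z[1L])
    })
  } else stop("unknown stack format (expect .json or .csv): ", path)
  z <- vapply(secs, function(s) s$z, numeric(1))
  if (is.unsorted(z, strictly = TRUE)) {
    i <- which(diff(z) <= 0)[1L]
    stop(sprintf("sections out of order: section %d (z = %g) does not increase past z = %g",
                 i + 1L, z[i + 1L], z[i]))
  }
  secs
}

#' Write a cross-section stack
#'
#' @param sections list of `cross_section` objects, or a `duct_geometry`.
#' @param path output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(sections, path) {
  if (inherits(sections, "duct_geometry")) sections <- sections$sections
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- lapply(sections, function(s) {
      list(z = s$z, centerline_point = s$centerline_point,
           axial_vector = s$axial_vector,
           vertices = unname(apply(s$vertices, 1L, function(r) as.list(r),
                                   simplify = FALSE)))
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- do.call(rbind, lapply(seq_along(sections), function(i) {
      s <- sections[[i]]
      data.frame(section_id = i, z = s$z,
                 vertex_index = seq_len(nrow(s$vertices)),
                 x = s$vertices[, 1L], y = s$vertices[, 2L])
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  } else stop("unknown stack format (expect .json or .csv): ", path)
  invisible(path)
}

#' Write a resistance profile to CSV
#'
#' Columns `z_um, R_local, method, A_um2, d2A_dz2, included, units`; the
#' resistance column is converted to the requested unit.
#'
#' @param profile a `resistance_profile`.
#' @param path output path.
#' @param units `"SI-um"` (default, Pa s/um^4) or `"mmHg-min-mL-m"`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, units = "SI-um") {
  df <- as.data.frame(profile)
  df$R_local <- convert_resistance(df$R_local, from = "SI-um", to = units)
  df$units <- units
  utils::write.csv(format(df, digits = 15, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a resistance profile written by [write_profile()]
#'
#' @param path CSV path.
#' @return a `resistance_profile` in Pa s/um^4.
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path)
  R <- convert_resistance(df$R_local, from = df$units[1L], to = "SI-um")
  resistance_profile(z = df$z_um, R_local = R, method = df$method[1L],
                     A = df$A_um2, d2A = df$d2A_dz2,
                     included = as.logical(df$included))
}
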