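#' Head-movement displacement index
#'
#' Summarises a realignment time-series (3 translations in mm, 3 rotations
#' in radians per volume) as the mean absolute volume-to-volume change
#' pooled over all parameters, the scalar motion covariate entered into the
#' group GLMs. By default rotations are converted to arc displacement on a
#' 50 mm sphere before pooling so all six channels share units of mm;
#' `rotations = "raw"` pools the raw parameter values instead, and
#' `"exclude"` uses translations only.
#'
#' @param series Data frame or matrix with 6 columns (tx, ty, tz in mm;
#'   rx, ry, rz in radians), one row per volume in acquisition order.
#' @param rotations `"convert"` (default), `"raw"`, or `"exclude"`.
#' @param sphere_radius Radius in mm for the rotation-to-arc conversion.
#' @return Scalar displacement index (mm).
#' @export
#' @examples
#' s <- rbind(rep(0, 6), c(1, 1, 1, 0, 0, 0))
#' displacement_index(s)  # mean(1,1,1,0,0,0) = 0.5
displacement_index <- function(series, rotations = c("convert", "raw", "exclude"),
                               sphere_radius = 50) {
  rotations <- match.arg(rotations)
  m <- as.matrix(series)
  storage.mode(m) <- "double"
  if (ncol(m) != 6L) {
    abort("realignment series must have 6 columns (3 translations, 3 rotations)",
          class = "cortexdti_format_error")
  }
  if (nrow(m) < 2L) {
    abort("displacement index undefined for fewer than 2 volumes",
          class = "cortexdti_undefined_index_error")
  }
  if (!all(is.finite(m))) {
    abort("non-finite realignment estimates", class = "cortexdti_contract_error")
  }
  if (rotations == "convert") m[, 4:6] <- m[, 4:6] * sphere_radius
  if (rotations == "exclude") m <- m[, 1:3, drop = FALSE]
  mean(abs(diff(m)))
}

#' Structure volumes as fractions of total intracranial volume
#'
#' @param volumes Named numeric vector or two-column data frame
#'   (`structure`, `volume_mm3`) of structure volumes in mm^3.
#' @param tiv Total intracranial volume in mm^3 (> 0).
#' @return A tibble with columns `structure`, `volume_mm3`, `fraction`
#'   (volume / TIV), plus the TIV in the `tiv` attribute.
#' @export
#' @examples
#' volume_fractions(c(cortical_gm = 6e5), tiv = 1.5e6)  # fraction 0.4
volume_fractions <- function(volumes, tiv) {
  if (!is.numeric(tiv) || length(tiv) != 1L || tiv <= 0) {
    abort("tiv must be a single positive number", class = "cortexdti_parameter_error")
  }
  if (is.data.frame(volumes)) {
    out <- tibble(structure = as.character(volumes[[1L]]),
                  volume_mm3 = as.numeric(volumes[[2L]]))
  } else {
    out <- tibble(structure = names(volumes) %||% paste0("v", seq_along(volumes)),
                  volume_mm3 = as.numeric(volumes))
  }
  if (any(out$volume_mm3 < 0)) {
    abort("structure volumes must be >= 0", class = "cortexdti_contract_error")
  }
  if (any(out$volume_mm3 > tiv)) {
    warn("structure volume exceeds TIV: check units")
  }
  out$fraction <- out$volume_mm3 / tiv
  attr(out, "tiv") <- tiv
  out
}

#' Read an FSL-style realignment parameter file
#'
#' Whitespace-delimited text, one row per volume, six columns (translations
#' mm, rotations rad). Comment lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return Tibble with columns tx, ty, tz, rx, ry, rz.
#' @export
read_realignment <- function(path) {
  m <- as.matrix(read.table(path, comment.char = "#"))
  if (ncol(m) != 6L) {
    abort(sprintf("expected 6 realignment columns, found %d", ncol(m)),
          class = "cortexdti_format_error")
  }
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  as_tibble(m)
}

#' Read a structure-volume table
#'
#' Accepts a plain CSV with columns `structure, volume_mm3` or an
#' aseg.stats-style whitespace table whose comment headers start with `#`.
#'
#' @param path File path.
#' @return Tibble with columns `structure`, `volume_mm3`.
#' @export
read_volume_table <- function(path) {
  first <- readLines(path, n = 50L)
  body <- first[!startsWith(trimws(first), "#") & nzchar(trimws(first))]
  if (length(body) == 0L) {
    abort("no data rows in volume table", class = "cortexdti_format_error")
  }
  if (grepl(",", body[[1L]])) {
    df <- utils::read.csv(path, comment.char = "#")
    tibble(structure = as.character(df[[1L]]), volume_mm3 = as.numeric(df[[2L]]))
  } else {
    df <- read.table(path, comment.char = "#", stringsAsFactors = FALSE)
    # aseg.stats rows: index SegId NVoxels Volume_mm3 StructName ...
    if (ncol(df) >= 5L && is.character(df[[5L]])) {
      tibble(structure = df[[5L]], volume_mm3 = as.numeric(df[[4L]]))
    } else {
      tibble(structure = as.character(df[[1L]]), volume_mm3 = as.numeric(df[[2L]]))
    }
  }
}
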