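# Plain-text TSV dialects for curves, loops and height maps. Proprietary
# instrument formats are out of scope; these dialects carry exactly what the
# analysis needs.

meta_header <- function(metadata, extra = list()) {
  kv <- c(extra, metadata)
  if (!length(kv)) return(character())
  sprintf("# %s\t%s", names(kv), vapply(kv, as.character, character(1L)))
}

read_meta_header <- function(lines) {
  meta_lines <- grep("^# ", lines, value = TRUE)
  if (!length(meta_lines)) return(list())
  parts <- strsplit(sub("^# ", "", meta_lines), "\t", fixed = TRUE)
  vals <- lapply(parts, function(p) {
    v <- if (length(p) > 1L) p[[2L]] else ""
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, vapply(parts, `[[`, character(1L), 1L))
}

#' Write / read a force curve in the TSV curve dialect
#'
#' UTF-8 TSV with `# key<TAB>value` metadata comment lines, a header line,
#' and columns `segment` (approach|retract), `z_nm`, `signal`; one file per
#' curve. Calibration is not stored in the file -- it is supplied at read
#' time, as in a real workflow where one calibration covers a whole session.
#'
#' @param curve A [force_curve()].
#' @param path File path.
#' @param calibration Calibration attached to the curve on reading.
#'
#' @return `write_force_curve` returns `path` invisibly;
#'   `read_force_curve` returns a [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_header(curve$metadata), con)
  writeLines("segment\tz_nm\tsignal", con)
  seg <- rbind(
    data.frame(segment = "approach", curve$approach),
    data.frame(segment = "retract", curve$retract)
  )
  utils::write.table(seg, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path, calibration = afm_calibration()) {
  lines <- readLines(path, encoding = "UTF-8")
  metadata <- read_meta_header(lines)
  body <- lines[!startsWith(lines, "# ")]
  d <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  if (!all(c("segment", "z_nm", "signal") %in% names(d))) {
    stop("curve file ", path,
         " lacks required columns segment/z_nm/signal", call. = FALSE)
  }
  force_curve(
    approach = d[d$segment == "approach", c("z_nm", "signal")],
    retract = d[d$segment == "retract", c("z_nm", "signal")],
    calibration = calibration,
    metadata = metadata
  )
}

#' Write / read a friction loop in the TSV loop dialect
#'
#' TSV with columns `x_nm`, `v_trace`, `v_retrace`; the optional applied
#' load and other metadata are carried in `# key<TAB>value` header comments
#' (`load_nN` for the load).
#'
#' @param loop A [friction_loop()].
#' @param path File path.
#'
#' @return `write_friction_loop` returns `path` invisibly;
#'   `read_friction_loop` returns a [friction_loop()].
#' @export
write_friction_loop <- function(loop, path) {
  stopifnot(inherits(loop, "friction_loop"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  extra <- if (!is.null(loop$load)) list(load_nN = loop$load) else list()
  writeLines(meta_header(loop$metadata, extra), con)
  writeLines("x_nm\tv_trace\tv_retrace", con)
  utils::write.table(
    data.frame(loop$x_nm, loop$v_trace, loop$v_retrace),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_friction_loop
#' @export
read_friction_loop <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  metadata <- read_meta_header(lines)
  body <- lines[!startsWith(lines, "# ")]
  d <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  if (!all(c("x_nm", "v_trace", "v_retrace") %in% names(d))) {
    stop("loop file ", path,
         " lacks required columns x_nm/v_trace/v_retrace", call. = FALSE)
  }
  load <- metadata$load_nN
  metadata$load_nN <- NULL
  friction_loop(d$x_nm, d$v_trace, d$v_retrace, load = load,
                metadata = metadata)
}

#' Write / read a height map in the TSV matrix dialect
#'
#' Three header comment lines (`rows`, `cols`, `pixel_nm`) followed by the
#' height matrix, one tab-separated row per line, in nm.
#'
#' @param map A [height_map()].
#' @param path File path.
#'
#' @return `write_height_map` returns `path` invisibly; `read_height_map`
#'   returns a [height_map()].
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# %s\t%s",
                     c("rows", "cols", "pixel_nm"),
                     c(nrow(map$grid), ncol(map$grid), map$pixel_nm)), con)
  utils::write.table(map$grid, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- read_meta_header(lines[1:3])
  if (!all(c("rows", "cols", "pixel_nm") %in% names(hdr))) {
    stop("height-map file ", path,
         " lacks the rows/cols/pixel_nm header", call. = FALSE)
  }
  body <- lines[!startsWith(lines, "# ")]
  grid <- as.matrix(utils::read.delim(text = body, header = FALSE))
  dimnames(grid) <- NULL
  if (nrow(grid) != hdr$rows || ncol(grid) != hdr$cols) {
    stop("height-map dimensions do not match the header", call. = FALSE)
  }
  height_map(grid, pixel_nm = hdr$pixel_nm)
}
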