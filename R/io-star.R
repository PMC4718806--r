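# STAR metadata I/O for the single-data-block particle dialect: one
# `data_` block with a `loop_`, `_rln*` column labels, whitespace-separated
# rows, offsets stored in pixels.  Hand-written because no installed R
# package parses STAR tables.

.star_columns <- c(
  image_name         = "_rlnImageName",
  rot                = "_rlnAngleRot",
  tilt               = "_rlnAngleTilt",
  psi                = "_rlnAnglePsi",
  origin_x           = "_rlnOriginX",
  origin_y           = "_rlnOriginY",
  defocus_u          = "_rlnDefocusU",
  defocus_v          = "_rlnDefocusV",
  astig_angle        = "_rlnDefocusAngle",
  voltage            = "_rlnVoltage",
  cs                 = "_rlnSphericalAberration",
  amplitude_contrast = "_rlnAmplitudeContrast")

.star_optional <- c(
  phase_shift   = "_rlnPhaseShift",
  class_label   = "_rlnClassNumber",
  random_subset = "_rlnRandomSubset")

#' Read a particle STAR file
#'
#' Parses a single-block STAR table carrying the Euler angles, in-plane
#' offsets (pixels), CTF parameters and image references of a particle set,
#' preserving row order.  Image references are `index@stack` with a 1-based
#' slice index.  Mandatory columns are the `_rln` labels for image name,
#' the three Euler angles, the two origins, defocus U/V/angle, voltage,
#' spherical aberration and amplitude contrast; `_rlnPhaseShift`,
#' `_rlnClassNumber` and `_rlnRandomSubset` are optional.
#'
#' @param path file path.
#' @param pixel_size pixel size in Angstrom to record on the set (STAR
#'   tables in this dialect do not carry it).
#' @param box box size in pixels to record on the set.
#' @return a [particle_set()], one row per table row.
#' @export
read_star <- function(path, pixel_size = 1, box = 64L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  li <- which(lines == "loop_")
  if (!length(li)) stop("no loop_ block in STAR file")
  i <- li[1] + 1L
  labels <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    labels <- c(labels, sub("\\s+#\\d+$", "", lines[i]))
    i <- i + 1L
  }
  rows <- lines[i:length(lines)]
  rows <- rows[nzchar(rows) & !startsWith(rows, "#")]
  if (!length(rows)) stop("STAR table has no data rows")
  toks <- strsplit(rows, "\\s+")
  bad <- which(lengths(toks) != length(labels))
  if (length(bad))
    stop("row ", bad[1], ": expected ", length(labels), " fields, got ",
         length(toks[[bad[1]]]))
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- labels

  need <- .star_columns
  missing <- setdiff(need, labels)
  if (length(missing))
    stop("STAR file lacks mandatory column(s): ",
         paste(missing, collapse = ", "))

  parse_num <- function(label) {
    x <- suppressWarnings(as.numeric(tab[[label]]))
    bad <- which(is.na(x))
    if (length(bad))
      stop("row ", bad[1], ": cannot parse ", label, " value '",
           tab[[label]][bad[1]], "'")
    x
  }

  ref <- tab[[need[["image_name"]]]]
  parts <- regmatches(ref, regexec("^(\\d+)@(.+)$", ref))
  badref <- which(lengths(parts) != 3L)
  if (length(badref))
    stop("row ", badref[1], ": image reference '", ref[badref[1]],
         "' is not of the form index@stack")
  df <- data.frame(
    image_name = vapply(parts, `[`, "", 3L),
    image_index = as.integer(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE)
  for (col in setdiff(names(need), "image_name"))
    df[[col]] <- parse_num(need[[col]])
  df$phase_shift <- if (.star_optional[["phase_shift"]] %in% labels)
    parse_num(.star_optional[["phase_shift"]]) else 0
  if (.star_optional[["class_label"]] %in% labels)
    df$class_label <- as.integer(parse_num(.star_optional[["class_label"]]))
  if (.star_optional[["random_subset"]] %in% labels)
    df$random_subset <- as.integer(parse_num(.star_optional[["random_subset"]]))
  particle_set(df, pixel_size = pixel_size, box = box)
}

#' Write a particle STAR file
#'
#' Inverse of [read_star()]: numeric fields are written with eight
#' significant digits, so a round trip preserves them to 1e-6 relative.
#'
#' @param particles a [particle_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_star <- function(particles, path) {
  stopifnot(inherits(particles, "particle_set"))
  cols <- .star_columns
  opt <- .star_optional[c("phase_shift" ,
                          if (!is.null(particles$class_label)) "class_label",
                          if (!is.null(particles$random_subset)) "random_subset")]
  labels <- c(cols, opt)
  header <- c("", "data_particles", "", "loop_",
              sprintf("%s #%d", labels, seq_along(labels)))
  fmt <- function(x) formatC(x, digits = 8, format = "g", width = 15)
  body_cols <- list(sprintf("%06d@%s", particles$image_index,
                            particles$image_name))
  for (col in setdiff(names(labels), "image_name"))
    body_cols <- c(body_cols, list(fmt(particles[[col]])))
  writeLines(c(header, do.call(paste, body_cols)), path)
  invisible(path)
}
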