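#' Particle table
#'
#' A data frame of particle records with voxel coordinates (1-based,
#' continuous, R convention), ZYZ intrinsic Euler angles in degrees
#' (`rot`, `tilt`, `psi`; RELION convention) and a dimensionless
#' cross-correlation score in [-1, 1].
#'
#' @param x,y,z numeric voxel coordinates (1-based).
#' @param rot,tilt,psi Euler angles, degrees.
#' @param score correlation scores in [-1, 1].
#' @return A data frame of class `particle_table`.
#' @export
particle_table <- function(x = numeric(), y = numeric(), z = numeric(),
                           rot = numeric(), tilt = numeric(), psi = numeric(),
                           score = numeric()) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   rot = as.numeric(rot), tilt = as.numeric(tilt),
                   psi = as.numeric(psi), score = as.numeric(score))
  validate_particle_table(df)
  class(df) <- c("particle_table", "data.frame")
  df
}

particle_cols <- c("x", "y", "z", "rot", "tilt", "psi", "score")

validate_particle_table <- function(df, dim = NULL) {
  missing <- setdiff(particle_cols, names(df))
  if (length(missing))
    stop("particle table: missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) && any(!is.finite(as.matrix(df[particle_cols]))))
    stop("particle table: non-finite values")
  if (nrow(df) && any(df$score < -1 | df$score > 1))
    stop("particle table: score outside [-1, 1]")
  if (!is.null(dim) && nrow(df)) {
    ok <- df$x >= 1 & df$x <= dim[1] & df$y >= 1 & df$y <= dim[2] &
      df$z >= 1 & df$z <= dim[3]
    if (any(!ok)) stop("particle table: coordinates outside volume bounds")
  }
  invisible(df)
}

#' Read a particle table (TSV or STAR dialect)
#'
#' Plain files are read as tab-separated with a header line carrying the
#' seven canonical columns. Files whose first non-blank line starts with
#' `data_` are parsed as a STAR loop; RELION-style tags
#' (`_rlnCoordinateX/Y/Z`, `_rlnAngleRot/Tilt/Psi`,
#' `_rlnAutopickFigureOfMerit`) map onto the canonical columns.
#'
#' @param path input file.
#' @return A [particle_table].
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) stop("read_particles: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  df <- if (length(nonblank) && startsWith(trimws(nonblank[1]), "data_")) {
    read_star_particles(lines)
  } else {
    utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  validate_particle_table(df)
  df <- df[particle_cols]
  class(df) <- c("particle_table", "data.frame")
  df
}

star_tag_map <- c(
  `_rlnCoordinateX` = "x", `_rlnCoordinateY` = "y", `_rlnCoordinateZ` = "z",
  `_rlnAngleRot` = "rot", `_rlnAngleTilt` = "tilt", `_rlnAnglePsi` = "psi",
  `_rlnAutopickFigureOfMerit` = "score")

read_star_particles <- function(lines) {
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (!length(loop_at)) stop("read_particles: STAR file without loop_ block")
  i <- loop_at[1] + 1L
  tags <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("\\s+#.*$", "", lines[i]))
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  body <- body[nzchar(body) & !startsWith(body, "data_")]
  if (length(body)) {
    rows <- do.call(rbind, strsplit(body, "\\s+"))
    df <- as.data.frame(apply(rows, 2, as.numeric))
  } else {
    df <- as.data.frame(matrix(numeric(), 0, length(tags)))
  }
  names(df) <- ifelse(tags %in% names(star_tag_map), star_tag_map[tags], tags)
  df
}

#' Write a particle table as TSV or STAR
#'
#' @param table a [particle_table].
#' @param path destination file.
#' @param format `"tsv"` (default) or `"star"`.
#' @return `path`, invisibly.
#' @export
write_particles <- function(table, path, format = c("tsv", "star")) {
  format <- match.arg(format)
  validate_particle_table(table)
  table <- as.data.frame(table)[particle_cols]
  if (format == "tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    tags <- names(star_tag_map)[match(particle_cols, star_tag_map)]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("data_particles", "", "loop_",
                 sprintf("%s #%d", tags, seq_along(tags))), con)
    if (nrow(table)) {
      writeLines(apply(format(table, digits = 17, trim = TRUE,
                              scientific = FALSE), 1,
                       paste, collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Convert particle coordinates between R 1-based and 0-based conventions
#'
#' @param table a [particle_table].
#' @return The table with `x`, `y`, `z` shifted by one.
#' @export
particles_to_zero_based <- function(table) {
  table$x <- table$x - 1; table$y <- table$y - 1; table$z <- table$z - 1
  table
}

#' @rdname particles_to_zero_based
#' @export
particles_from_zero_based <- function(table) {
  table$x <- table$x + 1; table$y <- table$y + 1; table$z <- table$z + 1
  table
}
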