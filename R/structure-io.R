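#' Single configuration (frame)
#'
#' @param coords n x 3 numeric matrix of coordinates in nm.
#' @param time time stamp in ps.
#' @param box orthorhombic box edge lengths in nm (length-3), or NULL
#'   for a non-periodic configuration.
#' @param wrapped logical: are coordinates wrapped into the primary box?
#'   MSD analysis requires unwrapped coordinates (see [unwrap_trajectory()]).
#' @return an object of class \code{md_frame}.
#' @export
md_frame <- function(coords, time = 0, box = NULL, wrapped = !is.null(box)) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(box <= 0))
      stop("box must be three positive edge lengths (nm)")
  }
  structure(list(coords = coords, time = time, box = box,
                 wrapped = isTRUE(wrapped)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat("md_frame:", nrow(x$coords), "atoms, t =", x$time, "ps,",
      if (is.null(x$box)) "no box" else
        paste0("box ", paste(signif(x$box, 6), collapse = " x "), " nm"),
      "\n")
  invisible(x)
}

# --- format helpers ---------------------------------------------------

.format_of <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("gro", "pdb", "xyz")))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("gro", "pdb", "xyz"))
    stop("cannot infer format from extension '", ext,
         "'; pass format = gro|pdb|xyz")
  ext
}

.parse_gro_block <- function(lines, start, path) {
  natoms <- suppressWarnings(as.integer(trimws(lines[start + 1L])))
  if (is.na(natoms))
    stop(path, ": line ", start + 1L, ": expected atom count")
  if (start + 1L + natoms + 1L > length(lines))
    stop(path, ": truncated GRO block starting at line ", start)
  rows <- lines[(start + 2L):(start + 1L + natoms)]
  name <- trimws(substr(rows, 11L, 15L))
  xyz <- matrix(NA_real_, natoms, 3L)
  for (k in 1:3) {
    field <- substr(rows, 21L + 8L * (k - 1L), 28L + 8L * (k - 1L))
    xyz[, k] <- suppressWarnings(as.numeric(field))
  }
  if (anyNA(xyz)) {
    bad <- which(apply(is.na(xyz), 1L, any))[1L]
    stop(path, ": line ", start + 1L + bad, ": malformed GRO atom line")
  }
  boxline <- strsplit(trimws(lines[start + 2L + natoms]), "\\s+")[[1]]
  box <- suppressWarnings(as.numeric(boxline[1:3]))
  if (anyNA(box))
    stop(path, ": line ", start + 2L + natoms, ": malformed box line")
  if (all(box == 0)) box <- NULL
  # time from "t= <ps>" in the title line, if present
  time <- 0
  m <- regmatches(lines[start],
                  regexpr("t=\\s*[-0-9.eE+]+", lines[start]))
  if (length(m)) time <- as.numeric(sub("t=\\s*", "", m))
  list(name = name, coords = xyz, box = box, time = time,
       next_line = start + 3L + natoms)
}

.parse_xyz_block <- function(lines, start, path, scale = 0.1) {
  natoms <- suppressWarnings(as.integer(trimws(lines[start])))
  if (is.na(natoms))
    stop(path, ": line ", start, ": expected atom count")
  if (start + 1L + natoms > length(lines))
    stop(path, ": truncated XYZ block starting at line ", start)
  comment <- lines[start + 1L]
  rows <- lines[(start + 2L):(start + 1L + natoms)]
  parts <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(parts, length, 0L) < 4L)
  if (length(bad))
    stop(path, ": line ", start + 1L + bad[1L], ": malformed XYZ atom line")
  el <- vapply(parts, `[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))) * scale
  if (anyNA(xyz))
    stop(path, ": malformed coordinates in XYZ block at line ", start)
  box <- NULL
  m <- regmatches(comment,
                  regexpr("box\\s+[-0-9.eE+ ]+", comment))
  if (length(m)) {
    b <- as.numeric(strsplit(trimws(sub("box\\s+", "", m)), "\\s+")[[1]])
    if (length(b) >= 3L && !anyNA(b[1:3])) box <- b[1:3] * scale
  }
  time <- 0
  m <- regmatches(comment, regexpr("t=\\s*[-0-9.eE+]+", comment))
  if (length(m)) time <- as.numeric(sub("t=\\s*", "", m))
  list(name = el, element = el, coords = xyz, box = box, time = time,
       next_line = start + 2L + natoms)
}

# --- public readers/writers ------------------------------------------

#' Read a structure file (GRO, PDB or XYZ)
#'
#' GRO coordinates are interpreted in nm; PDB and XYZ in Angstrom and
#' converted to nm (1 nm = 10 Angstrom).  The box is taken from the GRO
#' box line, the PDB CRYST1 record, or a \code{box lx ly lz} token in
#' the XYZ comment line; if absent it is left unset (NULL).
#'
#' @param path file path.
#' @param format \code{"gro"}, \code{"pdb"} or \code{"xyz"}; inferred
#'   from the file extension when omitted.
#' @return list with \code{atoms} (a skeleton data.frame with atom
#'   \code{name} and, where available, \code{element}) and \code{frame}
#'   (an [md_frame()]).
#' @export
read_structure <- function(path, format = NULL) {
  format <- .format_of(path, format)
  if (!file.exists(path)) stop(path, ": no such file")
  lines <- readLines(path)
  if (!length(lines)) stop(path, ": empty file")
  if (format == "gro") {
    blk <- .parse_gro_block(lines, 1L, path)
    atoms <- data.frame(name = blk$name)
  } else if (format == "xyz") {
    blk <- .parse_xyz_block(lines, 1L, path)
    atoms <- data.frame(name = blk$name, element = blk$element)
  } else {
    rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
    if (!length(rec)) stop(path, ": no ATOM/HETATM records")
    name <- trimws(substr(rec, 13L, 16L))
    el <- trimws(substr(rec, 77L, 78L))
    xyz <- cbind(as.numeric(substr(rec, 31L, 38L)),
                 as.numeric(substr(rec, 39L, 46L)),
                 as.numeric(substr(rec, 47L, 54L)))
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 1L, any))[1L]
      stop(path, ": malformed ATOM record (record ", bad, ")")
    }
    xyz <- xyz * md_constants$nm_per_angstrom
    box <- NULL
    cr <- lines[startsWith(lines, "CRYST1")]
    if (length(cr)) {
      b <- c(as.numeric(substr(cr[1L], 7L, 15L)),
             as.numeric(substr(cr[1L], 16L, 24L)),
             as.numeric(substr(cr[1L], 25L, 33L)))
      if (!anyNA(b)) box <- b * md_constants$nm_per_angstrom
    }
    blk <- list(coords = xyz, box = box, time = 0)
    atoms <- data.frame(name = name,
                        element = ifelse(nzchar(el), el, NA_character_))
  }
  list(atoms = atoms,
       frame = md_frame(blk$coords, time = blk$time, box = blk$box))
}

#' Write a structure file (GRO, PDB or XYZ)
#'
#' @param frame an [md_frame()] (coordinates in nm).
#' @param path output path.
#' @param format see [read_structure()].
#' @param atoms optional data.frame with \code{name} and/or
#'   \code{element} columns; defaults to generic carbon labels.
#' @export
write_structure <- function(frame, path, format = NULL, atoms = NULL) {
  format <- .format_of(path, format)
  n <- nrow(frame$coords)
  name <- if (!is.null(atoms$name)) atoms$name else rep("C", n)
  el <- if (!is.null(atoms$element)) atoms$element else
    substr(name, 1L, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.structure_lines(frame, format, name, el), con)
  invisible(path)
}

.structure_lines <- function(frame, format, name, el) {
  x <- frame$coords
  n <- nrow(x)
  if (format == "gro") {
    hdr <- sprintf("generated t= %.6f", frame$time)
    rows <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    1L, "MOL", substr(name, 1L, 5L),
                    seq_len(n) %% 100000L, x[, 1], x[, 2], x[, 3])
    box <- frame$box %||% c(0, 0, 0)
    c(hdr, sprintf("%5d", n), rows,
      sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  } else if (format == "xyz") {
    a <- x / md_constants$nm_per_angstrom
    cm <- sprintf("t= %.6f", frame$time)
    if (!is.null(frame$box))
      cm <- paste(cm, "box",
                  paste(sprintf("%.6f",
                                frame$box / md_constants$nm_per_angstrom),
                        collapse = " "))
    c(sprintf("%d", n), cm,
      sprintf("%-4s %14.6f %14.6f %14.6f", el, a[, 1], a[, 2], a[, 3]))
  } else {
    a <- x / md_constants$nm_per_angstrom
    out <- character()
    if (!is.null(frame$box))
      out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     frame$box[1] * 10, frame$box[2] * 10,
                     frame$box[3] * 10, 90, 90, 90)
    c(out,
      sprintf("ATOM  %5d %-4s MOL A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
              seq_len(n) %% 100000L, substr(name, 1L, 4L),
              a[, 1], a[, 2], a[, 3], substr(el, 1L, 2L)),
      "END")
  }
}
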