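## Structure writers/readers: XYZ, extended-XYZ, minimal P1 CIF, PDB.

.modelBoxFor <- function(model) {
  if (is(model, "SlabModel")) return(model@box)
  at <- model@atoms
  if (!nrow(at)) return(c(10, 10, 10))
  apply(at[, c("x", "y", "z")], 2, function(v) diff(range(v))) + 10
}

.writeXYZLike <- function(at, path, comment) {
  lines <- c(sprintf("%d", nrow(at)), comment)
  if (nrow(at))
    lines <- c(lines, sprintf("%-2s %14.6f %14.6f %14.6f",
                              at$element, at$x, at$y, at$z))
  writeLines(lines, path)
}

.latticeString <- function(box)
  sprintf('Lattice="%.6f 0.0 0.0 0.0 %.6f 0.0 0.0 0.0 %.6f"',
          box[1], box[2], box[3])

#' Write a structural model to disk
#'
#' Supported formats: plain `xyz`, `extxyz` (extended XYZ with `Lattice` and
#' `Properties` headers including occupancy and site class), minimal P1 `cif`
#' and `pdb` (CRYST1 + HETATM records). Round-trips through
#' [readStructure()] (xyz, extxyz, cif) preserve atom count, elements and
#' coordinates.
#'
#' @param model a [NanocrystalModel-class] or [SlabModel-class]
#' @param path output file path
#' @param format one of "xyz", "extxyz", "cif", "pdb"
#' @return `path`, invisibly
#' @export
setGeneric("writeStructure", function(model, path, format = "xyz")
  standardGeneric("writeStructure"))

.writeStructureImpl <- function(model, path, format) {
  format <- match.arg(format, c("xyz", "extxyz", "cif", "pdb"))
  at <- model@atoms
  if (format %in% c("cif", "pdb") && !nrow(at))
    stop("model non-empty required for ", format)
  box <- .modelBoxFor(model)
  if (format == "xyz") {
    .writeXYZLike(at, path, "generated by nanotherm")
  } else if (format == "extxyz") {
    comment <- paste(.latticeString(box),
                     "Properties=species:S:1:pos:R:3:occupancy:R:1:site_class:S:1")
    lines <- c(sprintf("%d", nrow(at)), comment)
    if (nrow(at))
      lines <- c(lines, sprintf("%-2s %14.6f %14.6f %14.6f %8.4f %s",
                                at$element, at$x, at$y, at$z, at$occupancy,
                                at$siteClass))
    writeLines(lines, path)
  } else if (format == "cif") {
    lines <- c("data_nanotherm",
               "_symmetry_space_group_name_H-M   'P 1'",
               sprintf("_cell_length_a   %.6f", box[1]),
               sprintf("_cell_length_b   %.6f", box[2]),
               sprintf("_cell_length_c   %.6f", box[3]),
               "_cell_angle_alpha 90", "_cell_angle_beta 90",
               "_cell_angle_gamma 90",
               "loop_",
               "_atom_site_label",
               "_atom_site_type_symbol",
               "_atom_site_fract_x",
               "_atom_site_fract_y",
               "_atom_site_fract_z",
               "_atom_site_occupancy",
               sprintf("%s%d %s %.8f %.8f %.8f %.4f",
                       at$element, seq_len(nrow(at)), at$element,
                       at$x / box[1], at$y / box[2], at$z / box[3],
                       at$occupancy))
    writeLines(lines, path)
  } else {
    lines <- c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       box[1], box[2], box[3], 90, 90, 90),
               sprintf("HETATM%5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       seq_len(nrow(at)),
                       substr(at$element, 1, 4), "MOL",
                       1L, at$x, at$y, at$z, at$occupancy, 0,
                       at$element),
               "END")
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname writeStructure
#' @export
setMethod("writeStructure", "NanocrystalModel", .writeStructureImpl)

#' @rdname writeStructure
#' @export
setMethod("writeStructure", "SlabModel", .writeStructureImpl)

#' Read a structure file written by [writeStructure()]
#'
#' @param path input file
#' @param format "xyz", "extxyz" or "cif" (auto-detected from the extension
#'   when NULL)
#' @return a data.frame with columns element, x, y, z, occupancy, siteClass
#'   and, when available, a "box" attribute c(Lx, Ly, Lz)
#' @export
readStructure <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", extxyz = "extxyz", cif = "cif",
                     stop("unsupported output: cannot infer format from '",
                          ext, "'"))
  }
  format <- match.arg(format, c("xyz", "extxyz", "cif"))
  lines <- readLines(path)
  if (format %in% c("xyz", "extxyz")) {
    n <- as.integer(lines[1])
    comment <- if (length(lines) >= 2) lines[2] else ""
    body <- if (n > 0) lines[2 + seq_len(n)] else character(0)
    toks <- strsplit(trimws(body), "\\s+")
    el <- vapply(toks, `[[`, "", 1)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (n == 0) xyz <- matrix(0, 0, 3)
    occ <- rep(1, n); sc <- rep("organic", n)
    if (format == "extxyz" && n > 0 && length(toks[[1]]) >= 6) {
      occ <- vapply(toks, function(tk) as.numeric(tk[5]), numeric(1))
      sc <- vapply(toks, `[[`, "", 6)
    } else if (n > 0) {
      sc <- ifelse(el == "Fe", "oct_Fe", ifelse(el == "O", "lattice_O",
                                                "organic"))
    }
    out <- .atomsFromParts(el, xyz, occ, sc)
    m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(m) == 2) {
      v <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
      attr(out, "box") <- v[c(1, 5, 9)]
    }
    return(out)
  }
  ## minimal CIF reader for the dialect written above
  getNum <- function(key) as.numeric(sub(paste0(key, "\\s+"), "",
                                         grep(key, lines, value = TRUE)[1]))
  box <- c(getNum("_cell_length_a"), getNum("_cell_length_b"),
           getNum("_cell_length_c"))
  start <- max(grep("^_atom_site_", lines)) + 1
  body <- lines[start:length(lines)]
  body <- body[nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "\\s+")
  el <- vapply(toks, `[[`, "", 2)
  fr <- t(vapply(toks, function(tk) as.numeric(tk[3:5]), numeric(3)))
  occ <- vapply(toks, function(tk) as.numeric(tk[6]), numeric(1))
  out <- .atomsFromParts(el, sweep(fr, 2, box, "*"), occ,
                         rep("organic", length(el)))
  attr(out, "box") <- box
  out
}

## Pattern IO: two-column text (q, I) with '#' headers + JSON sidecar -------

#' Write / read a scattering pattern
#'
#' Two-column text (q, I) with `#` comment headers; metadata goes to a JSON
#' sidecar `<path>.json`.
#'
#' @param pattern a [ScatteringPattern-class]
#' @param path output text file
#' @return `path` invisibly (write) or a [ScatteringPattern-class] (read)
#' @export
writePattern <- function(pattern, path) {
  stopifnot(is(pattern, "ScatteringPattern"))
  writeLines(c("# nanotherm scattering pattern",
               "# q(1/angstrom)  I(arb)",
               sprintf("%.8g %.10g", pattern@q, pattern@I)), path)
  jsonlite::write_json(pattern@meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePattern
#' @export
readPattern <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  q <- vapply(toks, function(tk) as.numeric(tk[1]), numeric(1))
  I <- vapply(toks, function(tk) as.numeric(tk[2]), numeric(1))
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new("ScatteringPattern", q = q, I = I, meta = as.list(meta))
}
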