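#' Atom-table representation of a macromolecular complex
#'
#' A complex is held as a tibble with one row per heavy (or hydrogen) atom and
#' columns `chain`, `resno` (author residue number), `icode` (insertion code,
#' `""` if none), `resname` (three-letter code), `atom` (atom label such as
#' `CA` or `NZ`), `element`, `x`, `y`, `z` (Angstrom), `occupancy` and `b`
#' (temperature factor). The tibble carries attributes `source`
#' (`pdb`, `mmcif` or `synthetic`) and `title`, and class `gdtr_structure`.
#'
#' @param atoms Data frame with the columns above (missing `icode`,
#'   `element`, `occupancy`, `b` are filled with defaults).
#' @param source Format tag.
#' @param title Free-text title.
#' @return A `gdtr_structure` tibble.
#' @export
as_structure <- function(atoms, source = "synthetic", title = "") {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("chain", "resno", "resname", "atom", "x", "y", "z") %in%
                  names(atoms)))
  if (is.null(atoms[["icode"]])) atoms$icode <- ""
  if (is.null(atoms[["element"]])) {
    atoms$element <- substr(gsub("[0-9']", "", atoms$atom), 1, 1)
  }
  if (is.null(atoms[["occupancy"]])) atoms$occupancy <- 1
  if (is.null(atoms[["b"]])) atoms$b <- 0
  atoms$icode <- atoms$icode %|NA|% ""
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, c("chain", "resno", "icode", "resname", "atom",
                     "element", "x", "y", "z", "occupancy", "b")]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element)))
    abort("empty element symbols in atom table")
  structure(atoms,
            class = c("gdtr_structure", class(atoms)),
            source = source, title = title)
}

# restore class/attrs after dplyr verbs strip them
restore_structure <- function(atoms, template) {
  as_structure(as_tibble(atoms),
               source = attr(template, "source") %||% "synthetic",
               title = attr(template, "title") %||% "")
}

#' @export
print.gdtr_structure <- function(x, ...) {
  res <- dplyr::distinct(as_tibble(x), .data$chain, .data$resno, .data$icode)
  cat(sprintf("<gdtr_structure> %d chains, %d residues, %d atoms [%s]\n",
              length(unique(x$chain)), nrow(res), nrow(x),
              attr(x, "source") %||% "?"))
  if (nzchar(attr(x, "title") %||% "")) cat(" title:", attr(x, "title"), "\n")
  print(as_tibble(x), ...)
  invisible(x)
}

STANDARD_AA3 <- names(AA3)

#' Read a protein structure (PDB or mmCIF)
#'
#' Parses ATOM/HETATM protein records into an atom tibble. Waters and
#' non-protein heteroatoms are excluded; alternate locations are resolved to
#' the highest-occupancy copy (ties broken by altloc letter order); author
#' numbering and insertion codes are preserved verbatim; residues with
#' non-standard three-letter codes are retained with a warning.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @return A [as_structure()] tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse ", format, " file '",
                                     path, "': ", conditionMessage(e)))
  )
  at <- as_tibble(parsed$atom)
  # protein residues only: amino-acid HETATMs (e.g. MSE) kept, waters/ligands out
  at <- filter(at, .data$resid %in% c(STANDARD_AA3, "MSE", "UNK") |
                 (.data$type == "ATOM" & !.data$resid %in% c("HOH", "WAT")))
  at <- filter(at, !.data$resid %in% c("HOH", "WAT"))
  if (nrow(at) == 0) abort(paste0("no protein atoms in ", path))
  unknown <- setdiff(unique(at$resid), c(STANDARD_AA3, "MSE", "UNK"))
  if (length(unknown) > 0)
    warn(paste0("unknown residue codes retained: ",
                paste(unknown, collapse = ", ")))
  at$alt <- at$alt %|NA|% ""
  at$insert <- at$insert %|NA|% ""
  at$o <- at$o %|NA|% 1
  # altloc resolution: highest occupancy, ties by altloc letter order;
  # file order preserved otherwise
  at$.row <- seq_len(nrow(at))
  at <- at |>
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$.row)
  as_structure(
    tibble(chain = at$chain, resno = at$resno, icode = at$insert,
           resname = at$resid, atom = at$elety,
           element = ifelse(nzchar(at$elesy %|NA|% ""), at$elesy,
                            substr(gsub("[0-9']", "", at$elety), 1, 1)),
           x = at$x, y = at$y, z = at$z,
           occupancy = at$o, b = at$b %|NA|% 0),
    source = format, title = paste(parsed$header %||% "", collapse = " ")
  )
}

#' Write a structure as a PDB file
#'
#' Standard fixed-column v3.3 layout; round-trips through [read_structure()].
#'
#' @param s A `gdtr_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  s <- as_tibble(s)
  if (any(nchar(s$chain) > 1))
    abort("PDB format allows single-character chain ids only")
  if (nrow(s) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(s)),
    resno = s$resno, resid = s$resname, chain = s$chain,
    insert = ifelse(nzchar(s$icode), s$icode, NA),
    elety = s$atom, o = s$occupancy, b = s$b,
    elesy = s$element
  )
  invisible(path)
}

#' Per-residue view of a structure
#'
#' @param s A `gdtr_structure`.
#' @return Tibble with one row per residue: `chain`, `resno`, `icode`,
#'   `resname`, `aa` (one-letter) and `res_key` (unique id string).
#' @export
structure_residues <- function(s) {
  as_tibble(s) |>
    distinct(.data$chain, .data$resno, .data$icode, .data$resname) |>
    mutate(aa = aa_three_to_one(.data$resname),
           res_key = paste0(.data$chain, "/", .data$resno, .data$icode))
}

#' One-letter sequence of one chain
#'
#' @param s A `gdtr_structure`.
#' @param chain Chain id.
#' @return Amino-acid string in residue (file) order.
#' @export
structure_sequence <- function(s, chain) {
  res <- structure_residues(s)
  res <- res[res$chain == chain, ]
  if (nrow(res) == 0) abort(paste0("no chain '", chain, "' in structure"))
  paste(res$aa, collapse = "")
}

# atom tibble for one residue key "chain/resno+icode"
residue_atoms <- function(s, chain, resno, icode = "") {
  filter(as_tibble(s), .data$chain == !!chain, .data$resno == !!resno,
         .data$icode == !!icode)
}

heavy_atoms <- function(at) filter(at, toupper(.data$element) != "H")
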