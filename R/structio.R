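# ---- crystal cell -----------------------------------------------------------

#' Crystallographic unit cell
#'
#' Container for unit-cell dimensions, space group and the number of
#' asymmetric units per cell, as read from a PDB CRYST1 record or supplied
#' directly.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @param space_group Space-group symbol (e.g. `"I 2 2 2"`).
#' @param z Number of asymmetric units per cell (CRYST1 Z value).
#'
#' @return An object of class `"crystal_cell"`.
#' @seealso [cell_volume()], [solvent_content()]
#' @export
crystal_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                         space_group = "P 1", z = 1L) {
  lengths <- c(a = a, b = b, c = c)
  angles <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("cell edge lengths must be positive and finite")
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  z <- as.integer(z)
  if (is.na(z) || z < 1L) stop("z (asymmetric units per cell) must be >= 1")
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         space_group = space_group, z = z),
    class = "crystal_cell"
  )
}

#' Unit-cell volume
#'
#' General triclinic volume
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#'   +2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param cell A [crystal_cell()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "crystal_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  cell$a * cell$b * cell$c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' @export
print.crystal_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.3f b=%.3f c=%.3f A  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  cat(sprintf("Space group %s, Z = %d, V = %.0f A^3\n",
              x$space_group, x$z, cell_volume(x)))
  invisible(x)
}

# ---- structure container ----------------------------------------------------

# Internal constructor. `atoms` is a data.frame with columns:
# chain, resno, insert, resid, elety, elesy, x, y, z, o
new_structure3d <- function(atoms, cell = NULL, source_id = "") {
  needed <- c("chain", "resno", "insert", "resid", "elety", "elesy",
              "x", "y", "z", "o")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- as.character(atoms$insert)
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell, source_id = source_id),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d '%s': %d atoms, %d chain(s)\n",
              x$source_id, nrow(x$atoms), length(chain_ids(x))))
  for (ch in chain_ids(x)) {
    at <- x$atoms[x$atoms$chain == ch, ]
    cat(sprintf("  chain %s: residues %d..%d (%d resolved)\n",
                ch, min(at$resno), max(at$resno),
                length(unique(paste(at$resno, at$insert)))))
  }
  if (!is.null(x$cell)) print(x$cell)
  invisible(x)
}

#' Chain identifiers of a structure, in file order
#' @param structure A `structure3d` object.
#' @return Character vector of chain ids.
#' @export
chain_ids <- function(structure) {
  stopifnot(inherits(structure, "structure3d"))
  unique(structure$atoms$chain)
}

#' Atom table of one chain
#' @param structure A `structure3d` object.
#' @param chain Chain identifier.
#' @return The chain's atoms as a data.frame, in file order.
#' @export
chain_atoms <- function(structure, chain) {
  stopifnot(inherits(structure, "structure3d"))
  at <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("no such chain: ", chain)
  at
}

water_resids <- c("HOH", "WAT", "DOD", "H2O")

# ---- reading ----------------------------------------------------------------

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into a flat atom table plus (for PDB) the
#' crystallographic cell. Only the first model is kept; for alternate
#' locations only altloc `A` (or blank) is retained; waters are dropped
#' unless `keep_waters = TRUE`.
#'
#' @param path Path to the structure file.
#' @param dialect `"auto"` (default, by file extension), `"pdb"` or `"mmcif"`.
#' @param keep_waters Keep water residues? Default `FALSE`.
#' @return A `structure3d` object.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                           keep_waters = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("could not parse ", path, " as ", dialect,
                             ": ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || !nrow(at))
    stop("empty structure: no ATOM/HETATM records in ", path)
  # first model / altloc A policy
  alt <- at$alt
  keep_alt <- is.na(alt) | alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  if (!keep_waters) at <- at[!(at$resid %in% water_resids), , drop = FALSE]
  if (!nrow(at)) stop("empty structure: no non-water atoms in ", path)
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(
    chain = chain,
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    elesy = element_of(at$elesy, at$elety),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    o = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    stringsAsFactors = FALSE
  )
  cell <- if (dialect == "pdb") parse_cryst1(path) else parse_cif_cell(path)
  new_structure3d(atoms, cell = cell,
                  source_id = sub("\\.[^.]*$", "", basename(path)))
}

# element symbol: prefer the file's, else first letter of the atom name
element_of <- function(elesy, elety) {
  e <- as.character(elesy)
  bad <- is.na(e) | e == ""
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", elety), 1, 1))
  e[bad] <- guess[bad]
  e
}

parse_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  cl <- cl[1]
  num <- function(i, j) as.numeric(substr(cl, i, j))
  z <- suppressWarnings(as.integer(substr(cl, 67, 70)))
  crystal_cell(num(7, 15), num(16, 24), num(25, 33),
               num(34, 40), num(41, 47), num(48, 54),
               space_group = trimws(substr(cl, 56, 66)),
               z = if (is.na(z)) 1L else z)
}

parse_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pick <- function(tag) {
    ln <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(trimws(ln[1]), "[[:space:]]+")[[1]][2]))
  }
  a <- pick("_cell.length_a"); b <- pick("_cell.length_b"); c <- pick("_cell.length_c")
  if (any(is.na(c(a, b, c)))) return(NULL)
  al <- pick("_cell.angle_alpha"); be <- pick("_cell.angle_beta"); ga <- pick("_cell.angle_gamma")
  z <- pick("_cell.Z_PDB")
  sg <- grep("^_symmetry.space_group_name_H-M", lines, value = TRUE)
  sg <- if (length(sg)) gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sg[1]))) else "P 1"
  crystal_cell(a, b, c,
               ifelse(is.na(al), 90, al), ifelse(is.na(be), 90, be),
               ifelse(is.na(ga), 90, ga),
               space_group = sg, z = if (is.na(z)) 1L else as.integer(z))
}

# ---- terminal C-alpha -------------------------------------------------------

#' Terminal C-alpha coordinate of a chain
#'
#' Returns the coordinate of the C-alpha atom of the first (`n_term`) or last
#' (`c_term`) *resolved* residue of a chain that contains a C-alpha. Crystal
#' structures routinely lack density for terminal residues, so "terminus"
#' here means the first/last residue actually present in the coordinates;
#' a terminal residue without a C-alpha falls back to the nearest resolved
#' residue that has one.
#'
#' @param structure A `structure3d` object.
#' @param chain Chain identifier.
#' @param end `"n_term"` or `"c_term"`.
#' @return Numeric length-3 coordinate (Angstrom).
#' @export
chain_terminal_ca <- function(structure, chain, end = c("n_term", "c_term")) {
  end <- match.arg(end)
  at <- chain_atoms(structure, chain)
  res_key <- paste(at$resno, at$insert)
  res_order <- unique(res_key)              # file order of resolved residues
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (!nrow(ca))
    stop("chain ", chain, " has no C-alpha atom in any residue")
  ca_res <- unique(paste(ca$resno, ca$insert))
  scan <- if (end == "n_term") res_order else rev(res_order)
  hit <- scan[scan %in% ca_res][1]
  row <- ca[paste(ca$resno, ca$insert) == hit, , drop = FALSE][1, ]
  c(row$x, row$y, row$z)
}

# ---- writing ----------------------------------------------------------------

#' Write a structure as a PDB file
#'
#' Emits a CRYST1 record (when cell metadata is present) followed by
#' fixed-width ATOM records, one TER per chain and END. Coordinates are
#' written to 3 decimals, the PDB dialect's precision, so
#' `read_structure(write_structure(s))` reproduces chains, residues and
#' coordinates to 1e-3 Angstrom.
#'
#' @param structure A `structure3d` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "structure3d"))
  at <- structure$atoms
  if (!nrow(at)) stop("refusing to write an empty structure")
  lines <- character(0)
  if (!is.null(structure$cell)) {
    cc <- structure$cell
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                     cc$a, cc$b, cc$c, cc$alpha, cc$beta, cc$gamma,
                     cc$space_group, cc$z)
  }
  serial <- 0L
  for (ch in chain_ids(structure)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      name <- sub$elety[i]
      name <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, name, sub$resid[i], substr(ch, 1, 1),
        sub$resno[i], ifelse(sub$insert[i] == "", " ", sub$insert[i]),
        sub$x[i], sub$y[i], sub$z[i], sub$o[i], 0,
        sub$elesy[i]))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  con <- file(path, "wb")      # fixed newlines so equal seeds give equal bytes
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
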