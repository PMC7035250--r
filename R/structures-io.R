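## Structure / trajectory file IO and atom selection.
##
## PDB reading is delegated to bio3d (the field-standard R reader of the
## fixed-column format); writing, the XYZ dialect and multi-model
## trajectory output are implemented here so round-trips stay within the
## documented column conventions.

.new_atoms <- function(serial, name, element, resname, resid, chain,
                       xyz) {
  data.frame(serial = as.integer(serial), name = as.character(name),
             element = as.character(element),
             resname = as.character(resname), resid = as.integer(resid),
             chain = as.character(chain),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Create a structure from an atom table
#'
#' @param atoms data.frame with columns serial, name, element, resname,
#'   resid, chain, x, y, z.
#' @param box optional numeric(3) box lengths (Angstrom).
#' @return a [G4Structure-class].
#' @export
G4Structure <- function(atoms, box = rep(NA_real_, 3)) {
  new("G4Structure", atoms = atoms, box = box)
}

#' Create a trajectory
#'
#' @param topology a [G4Structure-class].
#' @param coords n_atoms x 3 x n_frames array (Angstrom).
#' @param times frame times in ps, strictly increasing.
#' @return a [G4Trajectory-class].
#' @export
G4Trajectory <- function(topology, coords, times) {
  new("G4Trajectory", topology = topology, coords = coords,
      times = as.numeric(times))
}

## light syntactic validation of ATOM/HETATM records so malformed lines
## are reported with their line number instead of silently dropped
.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("PDB parse error at line ", i, ": record shorter than ",
           "coordinate fields", call. = FALSE)
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop("PDB parse error at line ", i, ": non-numeric coordinates",
           call. = FALSE)
  }
  invisible(TRUE)
}

.structure_from_bio3d <- function(pdb) {
  a <- pdb$atom
  el <- trimws(a$elesy)
  el[is.na(el) | !nzchar(el)] <- substr(trimws(a$elety[is.na(el) | !nzchar(el)]), 1, 1)
  G4Structure(.new_atoms(a$eleno, trimws(a$elety), el, trimws(a$resid),
                         a$resno, ifelse(is.na(a$chain), "A", a$chain),
                         matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)))
}

.read_xyz_blocks <- function(lines, path) {
  blocks <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("XYZ parse error at line ", i, ": expected atom count",
           call. = FALSE)
    if (i + 1 + n > length(lines))
      stop("XYZ parse error: truncated block starting at line ", i,
           call. = FALSE)
    body <- lines[(i + 2):(i + 1 + n)]
    tok <- strsplit(trimws(body), "\\s+")
    if (any(lengths(tok) < 4))
      stop("XYZ parse error near line ", i + 2,
           ": need 'element x y z'", call. = FALSE)
    el <- vapply(tok, `[`, "", 1)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("XYZ parse error near line ", i + 2, ": bad coordinates",
           call. = FALSE)
    blocks[[length(blocks) + 1]] <- list(el = el, xyz = xyz)
    i <- i + 2 + n
  }
  if (!length(blocks)) stop("parse error: ", path, " contains no atoms",
                            call. = FALSE)
  blocks
}

#' Read an atomic structure
#'
#' Reads a single structure from a PDB file (first model of a
#' multi-model file) or an XYZ file.
#'
#' @param path file path.
#' @param format \code{"pdb"} or \code{"xyz"}; default guessed from the
#'   file extension.
#' @return a [G4Structure-class] with atoms in file order.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    if (!any(grepl("^(ATOM|HETATM)", lines)))
      stop("parse error: no ATOM/HETATM records in ", path, call. = FALSE)
    .validate_pdb_lines(lines)
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
                    error = function(e)
                      stop("PDB parse error in ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    .structure_from_bio3d(pdb)
  } else {
    b <- .read_xyz_blocks(readLines(path, warn = FALSE), path)[[1]]
    n <- length(b$el)
    G4Structure(.new_atoms(seq_len(n), b$el, b$el, b$el, 1L, "A", b$xyz))
  }
}

#' Read a trajectory
#'
#' Multi-model PDB (one MODEL per frame) or concatenated XYZ blocks.
#' Frame times are \code{(model_index - 1) * dt}.
#'
#' @param path file path.
#' @param format \code{"pdb"} or \code{"xyz"} (auto by extension).
#' @param dt frame spacing in ps used when the file carries no times.
#' @return a [G4Trajectory-class].
#' @export
readTrajectory <- function(path, format = c("auto", "pdb", "xyz"),
                           dt = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    if (!any(grepl("^(ATOM|HETATM)", lines)))
      stop("parse error: no ATOM/HETATM records in ", path, call. = FALSE)
    .validate_pdb_lines(lines)
    ## consistent atom counts across models, reported per model
    starts <- grep("^MODEL", lines)
    if (length(starts) > 1) {
      ends <- grep("^ENDMDL", lines)
      if (length(ends) != length(starts))
        stop("structural error: unbalanced MODEL/ENDMDL in ", path,
             call. = FALSE)
      counts <- mapply(function(s, e)
        sum(grepl("^(ATOM|HETATM)", lines[s:e])), starts, ends)
      if (length(unique(counts)) > 1) {
        bad <- which(counts != counts[1])[1]
        stop("structural error: model ", bad, " has ", counts[bad],
             " atoms, model 1 has ", counts[1], call. = FALSE)
      }
    }
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = TRUE),
                    error = function(e)
                      stop("PDB parse error in ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    topo <- .structure_from_bio3d(pdb)
    nf <- nrow(pdb$xyz)
    arr <- array(NA_real_, c(nAtoms(topo), 3, nf))
    for (k in seq_len(nf))
      arr[, , k] <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    G4Trajectory(topo, arr, (seq_len(nf) - 1) * dt)
  } else {
    blocks <- .read_xyz_blocks(lines, path)
    n <- length(blocks[[1]]$el)
    bad <- which(vapply(blocks, function(b) length(b$el), 0L) != n)
    if (length(bad))
      stop("structural error: model ", bad[1],
           " has a different atom count", call. = FALSE)
    topo <- G4Structure(.new_atoms(seq_len(n), blocks[[1]]$el,
                                   blocks[[1]]$el, blocks[[1]]$el, 1L,
                                   "A", blocks[[1]]$xyz))
    arr <- array(NA_real_, c(n, 3, length(blocks)))
    for (k in seq_along(blocks)) arr[, , k] <- blocks[[k]]$xyz
    G4Trajectory(topo, arr, (seq_along(blocks) - 1) * dt)
  }
}

.pdb_atom_line <- function(serial, name, resname, chain, resid, xyz,
                           element) {
  rec <- if (resname %in% c("K", "HOH", "NA", "MG")) "HETATM" else "ATOM"
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000, nm, substr(resname, 1, 3),
          substr(chain, 1, 1), resid %% 10000, xyz[1], xyz[2], xyz[3],
          1.0, 0.0, substr(element, 1, 2))
}

.structure_pdb_lines <- function(structure) {
  a <- structure@atoms
  vapply(seq_len(nrow(a)), function(i)
    .pdb_atom_line(a$serial[i], a$name[i], a$resname[i], a$chain[i],
                   a$resid[i], c(a$x[i], a$y[i], a$z[i]), a$element[i]),
    "")
}

#' Write a structure
#'
#' @param structure a [G4Structure-class].
#' @param path output file.
#' @param format \code{"pdb"} or \code{"xyz"} (auto by extension).
#' @return the path, invisibly.
#' @export
writeStructure <- function(structure, path,
                           format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  a <- structure@atoms
  if (format == "pdb") {
    writeLines(c(.structure_pdb_lines(structure), "END"), path)
  } else {
    body <- sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z)
    writeLines(c(as.character(nrow(a)), "generated by g4slip", body), path)
  }
  invisible(path)
}

#' Write a trajectory as a multi-model PDB (or XYZ blocks)
#'
#' @param traj a [G4Trajectory-class].
#' @param path output file.
#' @param format \code{"pdb"} or \code{"xyz"} (auto by extension).
#' @return the path, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  s <- traj@topology
  out <- character()
  for (k in seq_len(nFrames(traj))) {
    s@atoms[, c("x", "y", "z")] <- traj@coords[, , k]
    if (format == "pdb") {
      out <- c(out, sprintf("MODEL     %4d", k), .structure_pdb_lines(s),
               "ENDMDL")
    } else {
      a <- s@atoms
      out <- c(out, as.character(nrow(a)),
               sprintf("frame %d t=%g ps", k, traj@times[k]),
               sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y,
                       a$z))
    }
  }
  if (format == "pdb") out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

## ---- atom selection mini-language -------------------------------------

.sel_tokenize <- function(expression) {
  expression <- gsub("([()])", " \\1 ", expression)
  tok <- strsplit(trimws(expression), "\\s+")[[1]]
  tok[nzchar(tok)]
}

.sel_parse_items <- function(tokens, pos, numeric_items) {
  keywords <- c("and", "or", "resnum", "resid", "resname", "name", "elem",
                "(", ")")
  items <- character()
  while (pos <= length(tokens) && !(tolower(tokens[pos]) %in% keywords)) {
    items <- c(items, tokens[pos])
    pos <- pos + 1
  }
  if (!length(items))
    stop("selection syntax error at token ", pos,
         ": expected values after keyword", call. = FALSE)
  if (numeric_items) {
    vals <- integer()
    for (it in items) {
      parts <- strsplit(it, ",")[[1]]
      for (p in parts) {
        if (grepl("^[0-9]+-[0-9]+$", p)) {
          ab <- as.integer(strsplit(p, "-")[[1]])
          vals <- c(vals, seq(ab[1], ab[2]))
        } else if (grepl("^[0-9]+$", p)) {
          vals <- c(vals, as.integer(p))
        } else {
          stop("selection syntax error: bad residue number '", p, "'",
               call. = FALSE)
        }
      }
    }
    list(values = vals, pos = pos)
  } else {
    vals <- unlist(strsplit(items, ","))
    list(values = vals[nzchar(vals)], pos = pos)
  }
}

.sel_primary <- function(tokens, pos, a) {
  if (pos > length(tokens))
    stop("selection syntax error at token ", pos, ": unexpected end",
         call. = FALSE)
  t <- tolower(tokens[pos])
  if (t == "(") {
    r <- .sel_or(tokens, pos + 1, a)
    if (r$pos > length(tokens) || tokens[r$pos] != ")")
      stop("selection syntax error at token ", r$pos,
           ": expected ')'", call. = FALSE)
    return(list(mask = r$mask, pos = r$pos + 1))
  }
  if (t %in% c("resnum", "resid")) {
    r <- .sel_parse_items(tokens, pos + 1, TRUE)
    list(mask = a$resid %in% r$values, pos = r$pos)
  } else if (t == "resname") {
    r <- .sel_parse_items(tokens, pos + 1, FALSE)
    list(mask = a$resname %in% r$values, pos = r$pos)
  } else if (t == "name") {
    r <- .sel_parse_items(tokens, pos + 1, FALSE)
    list(mask = a$name %in% r$values, pos = r$pos)
  } else if (t == "elem") {
    r <- .sel_parse_items(tokens, pos + 1, FALSE)
    list(mask = a$element %in% r$values, pos = r$pos)
  } else {
    stop("selection syntax error at token ", pos, ": unknown keyword '",
         tokens[pos], "'", call. = FALSE)
  }
}

.sel_and <- function(tokens, pos, a) {
  r <- .sel_primary(tokens, pos, a)
  while (r$pos <= length(tokens) && tolower(tokens[r$pos]) == "and") {
    r2 <- .sel_primary(tokens, r$pos + 1, a)
    r <- list(mask = r$mask & r2$mask, pos = r2$pos)
  }
  r
}

.sel_or <- function(tokens, pos, a) {
  r <- .sel_and(tokens, pos, a)
  while (r$pos <= length(tokens) && tolower(tokens[r$pos]) == "or") {
    r2 <- .sel_and(tokens, r$pos + 1, a)
    r <- list(mask = r$mask | r2$mask, pos = r2$pos)
  }
  r
}

#' Select atoms with a small selection language
#'
#' Supported terms: \code{resnum} (numbers, commas and \code{a-b}
#' ranges), \code{resname}, \code{name}, \code{elem}, combined with
#' \code{and} / \code{or} and parentheses, e.g.
#' \code{"resnum 2-4,8-10 and name O6"}.
#'
#' @param structure a [G4Structure-class].
#' @param expression selection string.
#' @return sorted integer vector of atom indices (possibly empty).
#' @export
selectAtoms <- function(structure, expression) {
  a <- structure@atoms
  tokens <- .sel_tokenize(expression)
  if (!length(tokens))
    stop("selection syntax error: empty expression", call. = FALSE)
  r <- .sel_or(tokens, 1, a)
  if (r$pos <= length(tokens))
    stop("selection syntax error at token ", r$pos, ": trailing '",
         tokens[r$pos], "'", call. = FALSE)
  which(r$mask)
}

#' Neutralising counterions for a single-stranded DNA sequence
#'
#' A 5'-OH single strand of n nucleotides carries n - 1 backbone
#' phosphates, each with charge -1.  The number of cations to add for
#' neutrality is that phosphate count minus any cations already
#' retained with the solute (e.g. channel K+ between G-tetrads),
#' floored at zero.  The 22-nt human telomeric sequence with the two
#' inter-tetrad channel ions retained thus takes 19 added K+.
#'
#' @param sequence nucleotide string (e.g. \code{"AGGGTTAGGGTTAGGGTTAGGG"}).
#' @param retained_cations cations kept from the input structure.
#' @return integer count of cations to add.
#' @export
neutralizingCounterions <- function(sequence, retained_cations = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1,
            nchar(sequence) >= 1, retained_cations >= 0)
  max(nchar(sequence) - 1L - as.integer(retained_cations), 0L)
}
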