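#' @title Molecular graph input/output
#' @description Parse SMILES and SDF (V2000) structures into the
#'   hydrogen-complete chemical-graph representation that every descriptor
#'   in the package consumes: explicit hydrogens, element labels, formal
#'   charges, ring/aromaticity flags and a 0/1 connectivity matrix.
#'   Parsing, hydrogen addition and ring perception are delegated to
#'   OpenBabel via ChemmineOB/ChemmineR.
#' @name chemio
NULL

# ---- molecule class ---------------------------------------------------------

new_molecule <- function(id, element, charge, conn, in_ring, aromatic,
                         sdf_text = NULL) {
  n <- length(element)
  atoms <- data.frame(
    index = seq_len(n) - 1L,
    element = element,
    formal_charge = as.integer(charge),
    in_ring = as.logical(in_ring),
    is_aromatic = as.logical(aromatic),
    stringsAsFactors = FALSE
  )
  dimnames(conn) <- NULL
  mol <- structure(
    list(id = id, atoms = atoms, connectivity = conn, sdf_text = sdf_text),
    class = "ao_molecule"
  )
  validate_molecule(mol)
}

validate_molecule <- function(mol) {
  atoms <- mol$atoms
  conn <- mol$connectivity
  props <- element_properties()
  unknown <- setdiff(unique(atoms$element), rownames(props))
  if (length(unknown) > 0) {
    stop("unsupported element(s) in molecule '", mol$id, "': ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(atoms)
  if (!is.matrix(conn) || nrow(conn) != n || ncol(conn) != n) {
    stop("connectivity matrix dimensions do not match atom count")
  }
  if (!all(conn %in% c(0, 1))) stop("connectivity entries must be 0/1")
  if (any(diag(conn) != 0)) stop("connectivity diagonal must be zero")
  if (!isTRUE(all.equal(conn, t(conn)))) stop("connectivity must be symmetric")
  if (n > 1) {
    g <- igraph::graph_from_adjacency_matrix(conn, mode = "undirected")
    if (igraph::components(g)$no > 1) {
      stop("molecule '", mol$id,
           "' has multiple fragments; salts/mixtures are not supported")
    }
  }
  mol
}

#' @export
print.ao_molecule <- function(x, ...) {
  counts <- table(x$atoms$element)
  formula <- paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
  cat("<ao_molecule> ", x$id, ": ", formula, ", ",
      sum(x$connectivity) / 2, " bonds, ",
      sum(x$atoms$in_ring), " ring atoms\n", sep = "")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol An `ao_molecule`.
#' @return Integer atom count (hydrogens included).
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# ---- OpenBabel plumbing -----------------------------------------------------

ob_convert <- function(from, to, text, add_h = FALSE) {
  if (add_h) {
    ChemmineOB::convertFormat(from, to, text,
                              options = data.frame(names = "h", args = ""))
  } else {
    ChemmineOB::convertFormat(from, to, text)
  }
}

# split raw SDF text into per-record line lists (records end with "$$$$")
split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) return(list())
  starts <- c(1L, head(ends, -1) + 1L)
  Map(function(s, e) lines[s:(e - 1)], starts, ends)
}

# formal charges from the "M  CHG" property lines of one raw SDF record
sdf_record_charges <- function(record_lines, n_atoms) {
  charge <- integer(n_atoms)
  for (ln in grep("^M  CHG", record_lines, value = TRUE)) {
    fields <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)),
                                  "\\s+")[[1]])
    if (length(fields) >= 2) {
      idx <- fields[seq(1, length(fields), by = 2)]
      val <- fields[seq(2, length(fields), by = 2)]
      charge[idx] <- val
    }
  }
  charge
}

# one ChemmineR::SDF object + its raw record text -> ao_molecule
sdf_to_molecule <- function(sdf, record_lines, id) {
  ab <- ChemmineR::atomblock(sdf)
  labels <- rownames(ab)
  element <- sub("_\\d+$", "", labels)
  n <- length(element)
  conn <- matrix(0L, n, n)
  bb <- ChemmineR::bondblock(sdf)
  if (n > 1 && nrow(bb) > 0) {
    for (b in seq_len(nrow(bb))) {
      i <- bb[b, 1]; j <- bb[b, 2]
      conn[i, j] <- 1L; conn[j, i] <- 1L
    }
  }
  charge <- sdf_record_charges(record_lines, n)
  in_ring <- rep(FALSE, n)
  aromatic <- rep(FALSE, n)
  if (n >= 3 && sum(conn) / 2 >= n) { # a cycle needs at least as many bonds as atoms
    rng <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                    error = function(e) NULL)
    if (!is.null(rng) && length(rng$RINGS) > 0) {
      ring_atoms <- unique(unlist(rng$RINGS))
      in_ring[match(ring_atoms, labels)] <- TRUE
      arom_rings <- rng$RINGS[which(rng$AROMATIC)]
      if (length(arom_rings) > 0) {
        aromatic[match(unique(unlist(arom_rings)), labels)] <- TRUE
      }
    }
  }
  mol <- new_molecule(id, element, charge, conn, in_ring, aromatic,
                      sdf_text = record_lines)
  check_valence(mol, ChemmineR::bondblock(sdf))
  mol
}

# order-weighted valence consistency check (hydrogen-complete graph)
check_valence <- function(mol, bb) {
  n <- n_atoms(mol)
  val <- numeric(n)
  if (n > 1 && nrow(bb) > 0) {
    for (b in seq_len(nrow(bb))) {
      o <- bb[b, 3]
      if (o == 4) o <- 1.5 # aromatic bond convention in some writers
      val[bb[b, 1]] <- val[bb[b, 1]] + o
      val[bb[b, 2]] <- val[bb[b, 2]] + o
    }
  }
  allowed <- list(H = 1, C = 4, N = 3, O = 2, F = 1, S = c(2, 4, 6),
                  Cl = 1, Br = 1, I = 1)
  for (i in seq_len(n)) {
    el <- mol$atoms$element[i]
    ok <- allowed[[el]] + mol$atoms$formal_charge[i] * (el %in% c("N", "O"))
    # aromatic (order-1.5) rings yield fractional sums; round to nearest
    if (!any(abs(round(val[i]) - ok) < 0.6) && val[i] > 0) {
      stop("atom ", i, " (", el, ") in molecule '", mol$id,
           "' has bond order sum ", val[i],
           " inconsistent with standard valence")
    }
  }
  invisible(TRUE)
}

# ---- public readers/writers -------------------------------------------------

#' Parse a SMILES string into a hydrogen-complete molecule
#'
#' The SMILES is converted to an SDF record with explicit hydrogens using
#' OpenBabel, then the record is turned into an atom table plus 0/1
#' connectivity matrix. Ring membership and aromaticity are flagged per
#' atom; formal charges are taken from the structure.
#'
#' @param smiles A single SMILES string.
#' @param id Compound identifier stored on the molecule.
#' @return An `ao_molecule`: list with `id`, `atoms`
#'   (index/element/formal_charge/in_ring/is_aromatic) and `connectivity`.
#' @export
#' @examples
#' mol <- read_smiles("c1ccccc1O", "phenol")
#' n_atoms(mol) # 13: C6H5OH
read_smiles <- function(smiles, id = "mol_1") {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(trimws(smiles))) stop("malformed structure: empty SMILES")
  sdf_txt <- tryCatch(
    ob_convert("SMI", "SDF", paste0(smiles, "\t", id, "\n"), add_h = TRUE),
    error = function(e) "")
  mols <- parse_sdf_text(sdf_txt, default_id = id)
  if (length(mols) != 1 || n_atoms(mols[[1]]) == 0) {
    stop("malformed structure: could not parse SMILES '", smiles, "'")
  }
  mols[[1]]$id <- id
  attr(mols[[1]], "smiles") <- smiles
  mols[[1]]
}

# single-atom / bond-less record (ChemmineR's container requires bonds):
# element symbols sit in field 4 of the atom-block lines
atoms_only_molecule <- function(record_lines, id) {
  counts <- record_lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  if (is.na(natoms) || natoms < 1) stop("unreadable SDF counts line")
  element <- vapply(record_lines[4 + seq_len(natoms)], function(ln) {
    strsplit(trimws(ln), "\\s+")[[1]][4]
  }, character(1), USE.NAMES = FALSE)
  new_molecule(id, element, sdf_record_charges(record_lines, natoms),
               matrix(0L, natoms, natoms), rep(FALSE, natoms),
               rep(FALSE, natoms), sdf_text = record_lines)
}

# parse multi-record SDF text (hydrogens must already be explicit)
parse_sdf_text <- function(txt, default_id = NULL) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  records <- split_sdf_records(lines)
  if (length(records) == 0) return(list())
  nbonds <- vapply(records, function(r) {
    v <- suppressWarnings(as.integer(substr(r[4], 4, 6)))
    if (is.na(v)) -1L else v
  }, integer(1))
  bonded <- which(nbonds >= 1)
  sdfset <- NULL
  if (length(bonded) > 0) {
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp))
    writeLines(unlist(lapply(records[bonded], c, "$$$$")), tmp)
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp, skipErrors = TRUE))
    if (length(sdfset) != length(bonded)) {
      stop("unreadable SDF record (parsed ", length(sdfset), " of ",
           length(records), " records)")
    }
  }
  out <- vector("list", length(records))
  for (k in seq_along(records)) {
    nm <- trimws(records[[k]][1])
    if (!nzchar(nm)) nm <- if (!is.null(default_id)) default_id else paste0("mol_", k)
    out[[k]] <- tryCatch({
      if (nbonds[k] >= 1) {
        sdf_to_molecule(sdfset[[match(k, bonded)]], records[[k]], nm)
      } else {
        atoms_only_molecule(records[[k]], nm)
      }
    }, error = function(e) stop("error in SDF record ", k, ": ",
                                conditionMessage(e)))
  }
  out
}

#' Read molecules from an SDF (V2000) file
#'
#' Implicit hydrogens are made explicit before parsing. The record name is
#' used as compound id; unnamed records get `mol_<index>`.
#'
#' @param path Path to an SDF file.
#' @return List of `ao_molecule`, in file order (empty list for an empty
#'   file).
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) return(list())
  hydro <- ob_convert("SDF", "SDF", paste0(txt, "\n"), add_h = TRUE)
  parse_sdf_text(hydro)
}

#' Write molecules to an SDF file
#'
#' Molecules parsed from SMILES/SDF carry their normalized
#' hydrogen-explicit SDF record, which is written verbatim; molecules
#' without one get a minimal V2000 record (all bonds order 1, since the
#' graph representation does not retain bond orders).
#'
#' @param mols List of `ao_molecule` (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "ao_molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    if (!is.null(mol$sdf_text)) {
      rec <- mol$sdf_text
      rec[1] <- mol$id
      writeLines(rec, con)
    } else {
      writeLines(minimal_sdf_record(mol), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

minimal_sdf_record <- function(mol) {
  n <- n_atoms(mol)
  bonds <- which(upper.tri(mol$connectivity) & mol$connectivity == 1,
                 arr.ind = TRUE)
  hdr <- c(mol$id, " aoqsar", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, mol$atoms$element)
  bond_lines <- if (nrow(bonds) > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], 1L)
  } else character(0)
  chg <- which(mol$atoms$formal_charge != 0)
  chg_lines <- if (length(chg) > 0) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, mol$atoms$formal_charge[chg]),
                   collapse = ""))
  } else character(0)
  c(hdr, atom_lines, bond_lines, chg_lines, "M  END")
}

#' Read SMILES structures from a file
#'
#' One structure per line, optionally followed by a tab and an id.
#'
#' @param path Path to the SMILES file.
#' @return List of `ao_molecule`.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    id <- if (length(parts) >= 2 && nzchar(trimws(parts[2]))) trimws(parts[2])
          else paste0("mol_", k)
    out[[k]] <- read_smiles(trimws(parts[1]), id)
  }
  out
}

#' Canonicalize SMILES strings
#'
#' Batch conversion to OpenBabel canonical SMILES, used to detect duplicate
#' structures.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES (NA for unparseable input).
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  ids <- paste0("s", seq_along(smiles))
  txt <- paste0(paste(smiles, ids, sep = "\t"), "\n", collapse = "")
  out <- tryCatch(ob_convert("SMI", "CAN", txt), error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  res <- rep(NA_character_, length(smiles))
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      k <- match(parts[2], ids)
      if (!is.na(k)) res[k] <- parts[1]
    }
  }
  res
}

# ---- graph distances --------------------------------------------------------

#' All-pairs topological distances of a molecule
#'
#' Shortest-path lengths, in bond counts, over the hydrogen-complete bond
#' graph.
#'
#' @param mol An `ao_molecule` (must be a single connected fragment).
#' @return Symmetric integer matrix with zero diagonal.
#' @export
#' @examples
#' d <- graph_distances(read_smiles("CC", "ethane"))
#' max(d) # 3: H-C-C-H
graph_distances <- function(mol) {
  n <- n_atoms(mol)
  if (n == 1) return(matrix(0L, 1, 1))
  g <- igraph::graph_from_adjacency_matrix(mol$connectivity, mode = "undirected")
  d <- igraph::distances(g)
  if (any(is.infinite(d))) stop("disconnected molecular graph")
  dimnames(d) <- NULL
  storage.mode(d) <- "integer"
  d
}
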