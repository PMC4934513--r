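# Water residue names excluded on parse.
.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a macromolecular structure from a PDB file
#'
#' Parses ATOM/HETATM records of a PDB-format file into a `structure3d`
#' object. By default waters and hydrogens are dropped and alternate
#' locations are collapsed to a single conformer (highest occupancy, ties
#' broken by alt-loc letter order), so that downstream geometry sees one
#' position per atom. Residue numbering and atom order are kept exactly as
#' authored in the file; coordinates are in Angstrom.
#'
#' @param path Path to a PDB-format file.
#' @param chain Optional single chain identifier; only atoms of that chain
#'   are retained.
#' @param model Model number for multi-model files (default 1).
#' @param keep_water Keep water residues (HOH etc.)? Default `FALSE`.
#' @param keep_hydrogens Keep hydrogen/deuterium atoms? Default `FALSE`.
#' @param id Structure identifier; defaults to the file base name plus the
#'   chain letter when a chain filter is given (e.g. `"3W2TA"`).
#' @return A `structure3d` object: a list with `id` and `atoms`, where
#'   `atoms` is a data frame with one row per atom (columns `serial`,
#'   `name`, `alt`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`,
#'   `o`, `b`, `elem`, `het`).
#' @export
read_structure <- function(path, chain = NULL, model = 1,
                           keep_water = FALSE, keep_hydrogens = FALSE,
                           id = NULL) {
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = (model > 1), rm.alt = FALSE,
                    verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (model > 1) {
    if (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) < model) {
      stop("model ", model, " not present in '", path, "'")
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name   = as.character(at$elety),
    alt    = ifelse(is.na(at$alt), "", as.character(at$alt)),
    resid  = as.character(at$resid),
    chain  = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    elem = .atom_elements(at),
    het  = at$type == "HETATM",
    stringsAsFactors = FALSE
  )

  if (!is.null(chain)) {
    atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  }
  if (!keep_water) {
    atoms <- atoms[!(atoms$resid %in% .WATER_NAMES), , drop = FALSE]
  }
  if (!keep_hydrogens) {
    atoms <- atoms[!(atoms$elem %in% c("H", "D")), , drop = FALSE]
  }
  atoms <- .collapse_altlocs(atoms)
  if (nrow(atoms) == 0) {
    stop("empty selection: no atoms retained from '", path, "'",
         if (!is.null(chain)) paste0(" (chain ", chain, ")") else "")
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in '", path, "'")
  }
  if (is.null(id)) {
    id <- paste0(sub("\\.(pdb|ent)(\\.gz)?$", "",
                     basename(path), ignore.case = TRUE),
                 if (!is.null(chain)) chain else "")
  }
  new_structure3d(atoms, id = id)
}

#' Construct a structure3d object from an atom table
#'
#' @param atoms Atom data frame (see [read_structure()] for columns).
#' @param id Structure identifier string.
#' @return A `structure3d` object.
#' @export
new_structure3d <- function(atoms, id = "structure") {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "resid", "chain", "resno", "x", "y", "z", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$elem)) atoms$elem <- .elem_from_name(atoms$name)
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "structure3d")
}

# Element symbols: prefer the file's element column, fall back to the
# atom-name heuristic.
.atom_elements <- function(at) {
  e <- toupper(trimws(as.character(at$elesy)))
  bad <- is.na(e) | e == ""
  if (any(bad)) e[bad] <- .elem_from_name(as.character(at$elety)[bad])
  e
}

# Derive an element symbol from a PDB atom name: strip digits/primes, take
# the leading letter; two-letter metals are not needed for contact typing.
.elem_from_name <- function(name) {
  nm <- gsub("[0-9']", "", toupper(trimws(name)))
  ifelse(nchar(nm) == 0, "X", substr(nm, 1, 1))
}

# Alt-loc policy: within each (chain, resno, insert, resid, name) group keep
# the highest-occupancy record; ties broken by alt-loc letter order.
.collapse_altlocs <- function(atoms) {
  if (nrow(atoms) == 0) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$o, atoms$alt)
  keep_first <- !duplicated(key[ord])
  sel <- sort(ord[keep_first])  # restore original file order
  atoms[sel, , drop = FALSE]
}

#' @export
print.structure3d <- function(x, ...) {
  np <- sum(!x$atoms$het)
  nh <- sum(x$atoms$het)
  cat("<structure3d> ", x$id, ": ", np, " protein atoms, ",
      nh, " hetero atoms, chains: ",
      paste(sort(unique(x$atoms$chain)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Atom identity keys ("chain/resno[insert]/resid/name")
#'
#' A compact unique identifier per atom within one model, e.g. `"A/630//SER/OG"`.
#' @param atoms Atom data frame or `structure3d`.
#' @return Character vector of keys.
#' @export
atom_keys <- function(atoms) {
  if (inherits(atoms, "structure3d")) atoms <- atoms$atoms
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, atoms$name,
        sep = "/")
}

# Short human label like "S630/OG" used in reports.
.atom_label <- function(atoms) {
  if (inherits(atoms, "structure3d")) atoms <- atoms$atoms
  paste0(atoms$resid, atoms$resno, atoms$insert, "/", atoms$name)
}

#' Select a ligand instance from a structure
#'
#' Finds the hetero-residue group with the given het code. When several
#' copies exist (multiple chains or residue numbers), a chain and/or
#' residue number must be supplied to disambiguate; the function refuses to
#' guess and lists the candidates instead.
#'
#' @param s A `structure3d`.
#' @param het_code Three-letter hetero residue code (e.g. `"SVR"`).
#' @param chain Optional chain identifier.
#' @param resno Optional residue number.
#' @return A `ligand3d` object (fields `het_code`, `chain`, `resno`,
#'   `atoms`).
#' @export
select_ligand <- function(s, het_code, chain = NULL, resno = NULL) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  sel <- a$het & a$resid == het_code
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!is.null(resno)) sel <- sel & a$resno == resno
  hits <- a[sel, , drop = FALSE]
  if (nrow(hits) == 0) {
    stop("ligand '", het_code, "' not found in structure ", s$id)
  }
  inst <- unique(hits[, c("chain", "resno", "insert")])
  if (nrow(inst) > 1) {
    stop("ambiguous ligand '", het_code, "' in ", s$id, ": candidates ",
         paste(paste0(inst$chain, "/", inst$resno, inst$insert),
               collapse = ", "),
         "; supply chain= and/or resno= to disambiguate")
  }
  structure(list(het_code = het_code, chain = inst$chain[1],
                 resno = inst$resno[1], atoms = hits),
            class = "ligand3d")
}

#' @export
print.ligand3d <- function(x, ...) {
  cat("<ligand3d> ", x$het_code, " ", x$chain, "/", x$resno, ": ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records via bio3d. Coordinates are
#' written at the format's 3-decimal precision.
#'
#' @param s A `structure3d`.
#' @param path Output file path.
#' @param header Optional character vector of REMARK lines (written first,
#'   each prefixed with `REMARK   `).
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path, header = NULL) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  if (!is.null(header)) {
    writeLines(paste0("REMARK   ", header), con)
  }
  close(con)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = a$serial,
    elety = a$name, chain = ifelse(a$chain == "", " ", a$chain),
    insert = ifelse(a$insert == "", "", a$insert),
    alt = ifelse(a$alt == "", "", a$alt),
    o = a$o, b = a$b, elesy = a$elem,
    append = !is.null(header)
  )
  invisible(path)
}

#' Write a docked pose as PDB plus a PyMOL command script
#'
#' The output PDB contains the target atoms followed by the transplanted
#' ligand as HETATM records on a separate chain; the PyMOL script loads the
#' PDB, highlights the anchor (motif) residues and shows the ligand as
#' sticks.
#'
#' @param pose A `docked_pose` (see [dock_ligand()]).
#' @param target The target `structure3d` in the same frame as the pose.
#' @param out_pdb Output PDB path.
#' @param out_pml Output PyMOL script path.
#' @param ligand_chain Chain identifier given to the transplanted ligand
#'   (default `"Z"`).
#' @return Invisibly, a list with the two paths.
#' @export
write_docked <- function(pose, target, out_pdb, out_pml,
                         ligand_chain = "Z") {
  stopifnot(inherits(pose, "docked_pose"), inherits(target, "structure3d"))
  lig <- pose$ligand
  lig$chain <- ligand_chain
  lig$het <- TRUE
  lig$serial <- max(target$atoms$serial) + seq_len(nrow(lig))
  combined <- new_structure3d(rbind(target$atoms, lig),
                              id = paste0(target$id, "+", pose$het_code))
  hdr <- c(paste0("docked ligand ", pose$het_code, " into ", target$id),
           paste0("frame=", pose$frame,
                  " anchor_rmsd=", formatC(pose$anchor_rmsd, digits = 4,
                                           format = "f")))
  write_structure(combined, out_pdb, header = hdr)

  anch <- pose$anchors$target
  sel_res <- unique(paste0("(chain ", ifelse(anch$chain == "", '""', anch$chain),
                           " and resi ", anch$resno, ")"))
  pml <- c(
    paste0("# PyMOL script generated by motifdock"),
    paste0("load ", basename(out_pdb), ", docked"),
    "hide everything, docked",
    "show cartoon, docked and polymer",
    paste0("select motif_residues, docked and (",
           paste(sel_res, collapse = " or "), ")"),
    "show sticks, motif_residues",
    "color yellow, motif_residues",
    paste0("select docked_ligand, docked and chain ", ligand_chain),
    "show sticks, docked_ligand",
    "color magenta, docked_ligand",
    "zoom docked_ligand, 8"
  )
  con <- tryCatch(file(out_pml, "w"), error = function(e)
    stop("cannot open '", out_pml, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  writeLines(pml, con)
  close(con)
  invisible(list(pdb = out_pdb, pml = out_pml))
}

#' Download a PDB entry from the RCSB archive
#'
#' Convenience fetcher for regression analyses against published
#' structures; never used by the core pipeline or the fixture-based test
#' suite. Files are cached in `dir`.
#'
#' @param id Four-character PDB accession.
#' @param dir Cache directory (default `tempdir()`).
#' @return Path to the downloaded (or cached) PDB file.
#' @export
fetch_pdb <- function(id, dir = tempdir()) {
  id <- toupper(id)
  stopifnot(grepl("^[0-9][A-Z0-9]{3}$", id))
  dest <- file.path(dir, paste0(id, ".pdb"))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  url <- paste0("https://files.rcsb.org/download/", id, ".pdb")
  ok <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
    error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not download PDB entry ", id, " from ", url,
         " (no network access?)")
  }
  dest
}
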