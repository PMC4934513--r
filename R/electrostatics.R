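# Electrostatic potential assignment. Potentials are scalars in kT/e; the
# pipeline only ever consumes *pairwise differences* (PD), so any source
# that preserves relative values is usable: an OpenDX grid (APBS output), a
# per-atom table, or the built-in screened-Coulomb surrogate.

#' Read an OpenDX scalar grid (APBS dialect)
#'
#' Parses a regular-grid OpenDX scalar field of the kind written by
#' Poisson-Boltzmann solvers: `object 1 class gridpositions counts nx ny nz`,
#' `origin`, three axis-aligned `delta` rows, and a data section in which
#' the z index varies fastest.
#'
#' @param path Path to a `.dx` file.
#' @return A `dx_grid` object: list with `origin` (3-vector, Angstrom),
#'   `delta` (3-vector of grid spacings), `counts` (3 integers) and
#'   `values` (array of dim `counts`).
#' @export
read_opendx <- function(path) {
  if (!file.exists(path)) stop("OpenDX file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]

  gp <- grep("object\\s+1\\s+class\\s+gridpositions\\s+counts", lines,
             value = TRUE)
  if (length(gp) != 1) stop("malformed OpenDX header: missing gridpositions")
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", gp)),
                                "\\s+")[[1]])
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 2)) {
    stop("malformed OpenDX header: bad counts")
  }
  org_line <- grep("^\\s*origin\\s", lines, value = TRUE)
  if (length(org_line) < 1) stop("malformed OpenDX header: missing origin")
  origin <- as.numeric(strsplit(trimws(sub("origin", "", org_line[1])),
                                "\\s+")[[1]])
  del_lines <- grep("^\\s*delta\\s", lines, value = TRUE)
  if (length(del_lines) != 3) stop("malformed OpenDX header: need 3 deltas")
  dmat <- t(vapply(del_lines, function(l)
    as.numeric(strsplit(trimws(sub("delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  if (any(abs(dmat[upper.tri(dmat) | lower.tri(dmat)]) > 1e-12)) {
    stop("non-axis-aligned OpenDX grids are not supported")
  }
  delta <- diag(dmat)
  if (any(delta <= 0)) stop("malformed OpenDX header: non-positive delta")

  data_start <- grep("object\\s+3\\s+class\\s+array", lines)
  if (length(data_start) != 1) stop("malformed OpenDX header: missing array")
  body <- lines[(data_start + 1):length(lines)]
  stop_at <- grep("^(attribute|component|object|end)", body)
  if (length(stop_at)) body <- body[seq_len(min(stop_at) - 1)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(counts)) {
    stop("OpenDX data count mismatch: expected ", prod(counts),
         " values, found ", length(vals))
  }
  # DX convention: z varies fastest. Store as values[ix, iy, iz].
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  structure(list(origin = origin, delta = delta, counts = counts,
                 values = arr, path = path),
            class = "dx_grid")
}

#' @export
print.dx_grid <- function(x, ...) {
  cat("<dx_grid> counts ", paste(x$counts, collapse = "x"),
      ", origin (", paste(format(x$origin), collapse = ", "),
      "), spacing (", paste(format(x$delta), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Trilinear interpolation on an OpenDX grid
#'
#' @param grid A `dx_grid`.
#' @param xyz Numeric matrix (n x 3) or length-3 vector of query points.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_grid <- function(grid, xyz) {
  stopifnot(inherits(grid, "dx_grid"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  f <- sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$delta, "/")
  hi <- grid$counts - 1
  tol <- 1e-9
  if (any(f < -tol) || any(sweep(f, 2, hi, "-") > tol)) {
    stop("query point outside OpenDX grid bounds")
  }
  f <- pmin(pmax(f, 0), matrix(hi, nrow(f), 3, byrow = TRUE))
  i0 <- pmin(floor(f), matrix(hi - 1, nrow(f), 3, byrow = TRUE))
  t <- f - i0
  v <- grid$values
  out <- numeric(nrow(f))
  for (r in seq_len(nrow(f))) {
    i <- i0[r, 1] + 1; j <- i0[r, 2] + 1; k <- i0[r, 3] + 1
    tx <- t[r, 1]; ty <- t[r, 2]; tz <- t[r, 3]
    c00 <- v[i, j, k]     * (1 - tx) + v[i + 1, j, k]     * tx
    c10 <- v[i, j + 1, k] * (1 - tx) + v[i + 1, j + 1, k] * tx
    c01 <- v[i, j, k + 1] * (1 - tx) + v[i + 1, j, k + 1] * tx
    c11 <- v[i, j + 1, k + 1] * (1 - tx) + v[i + 1, j + 1, k + 1] * tx
    out[r] <- (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
              (c01 * (1 - ty) + c11 * ty) * tz
  }
  out
}

#' Read a per-atom potential table
#'
#' Whitespace- or tab-separated columns: chain, resno, resname, atomname,
#' potential (kT/e). A header line is allowed.
#'
#' @param path Path to the table.
#' @return Data frame with those five columns.
#' @export
read_potential_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chain", "resno", "resname",
                                        "atomname", "potential"),
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "character"))
  # tolerate a header row
  suppressWarnings({
    num <- as.numeric(df$potential)
  })
  if (is.na(num[1]) && nrow(df) > 1) {
    df <- df[-1, , drop = FALSE]
    num <- suppressWarnings(as.numeric(df$potential))
  }
  if (any(is.na(num))) stop("non-numeric potential values in ", path)
  data.frame(chain = df$chain, resno = as.integer(df$resno),
             resname = df$resname, atomname = df$atomname,
             potential = num, stringsAsFactors = FALSE)
}

#' Read a PQR file for partial charges
#'
#' PQR is a whitespace-separated PDB-like format whose last two numeric
#' columns are charge and radius.
#'
#' @param path Path to a PQR file.
#' @return Data frame: `name`, `resid`, `chain`, `resno`, `x`, `y`, `z`,
#'   `charge`, `radius`.
#' @export
read_pqr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(lines)) stop("no ATOM/HETATM records in PQR file ", path)
  recs <- lapply(strsplit(trimws(lines), "\\s+"), function(tok) {
    n <- length(tok)
    has_chain <- n >= 11 && is.na(suppressWarnings(as.numeric(tok[5])))
    off <- if (has_chain) 1L else 0L
    list(name = tok[3], resid = tok[4],
         chain = if (has_chain) tok[5] else "",
         resno = as.integer(tok[5 + off]),
         x = as.numeric(tok[6 + off]), y = as.numeric(tok[7 + off]),
         z = as.numeric(tok[8 + off]),
         charge = as.numeric(tok[9 + off]),
         radius = as.numeric(tok[10 + off]))
  })
  do.call(rbind, lapply(recs, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

#' Built-in formal charge table
#'
#' Minimal side-chain formal charges used by the surrogate potential:
#' carboxylates of Asp/Glu carry -1 split over the two oxygens, Lys +1 on
#' NZ, Arg +1 split over NH1/NH2; His neutral. Overridable by passing a
#' custom table to [assign_potentials()].
#'
#' @return Data frame with columns `resid`, `name`, `charge`.
#' @export
default_charges <- function() {
  data.frame(
    resid = c("ASP", "ASP", "GLU", "GLU", "LYS", "ARG", "ARG"),
    name = c("OD1", "OD2", "OE1", "OE2", "NZ", "NH1", "NH2"),
    charge = c(-0.5, -0.5, -0.5, -0.5, 1, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Assign an electrostatic potential to every atom of a structure
#'
#' Three sources are supported:
#' \describe{
#'   \item{`dx_grid`}{trilinear interpolation of an OpenDX scalar field at
#'     each atom position;}
#'   \item{data frame}{a per-atom table (see [read_potential_table()]);
#'     every structure atom must be matched by chain/resno/atom name;}
#'   \item{`"surrogate"`}{a screened-Coulomb model
#'     \eqn{\phi(i) = \sum_{j \ne i} q_j \exp(-\kappa r_{ij}) /
#'     (\epsilon_r r_{ij})} over partial charges `q` from a charge table
#'     (default [default_charges()]), with screening `kappa` (1/Angstrom),
#'     relative dielectric `eps_r`, and self-exclusion radius `eps`.}
#' }
#'
#' @param s A `structure3d`.
#' @param source A `dx_grid`, a data frame, or `"surrogate"`.
#' @param charges Charge table for surrogate mode (`resid`, `name`,
#'   `charge`); default [default_charges()]. May also be a PQR data frame
#'   from [read_pqr()] (matched by chain/resno/name).
#' @param kappa Screening constant, 1/Angstrom (default 0.1).
#' @param eps_r Relative dielectric (default 10).
#' @param eps Self-exclusion distance in Angstrom (default 0.1): pairs
#'   closer than this contribute nothing.
#' @return A `potentials` object: named numeric vector (names are
#'   [atom_keys()]) with attributes `source` and `params`.
#' @export
assign_potentials <- function(s, source = "surrogate",
                              charges = default_charges(),
                              kappa = 0.1, eps_r = 10, eps = 0.1) {
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  keys <- atom_keys(a)

  if (inherits(source, "dx_grid")) {
    phi <- interpolate_grid(source, as.matrix(a[, c("x", "y", "z")]))
    src <- "grid"
    params <- list(path = source$path)
  } else if (is.data.frame(source)) {
    tk <- paste(source$chain, source$resno, source$atomname, sep = "/")
    sk <- paste(a$chain, a$resno, a$name, sep = "/")
    idx <- match(sk, tk)
    if (anyNA(idx)) {
      missing_at <- .atom_label(a[is.na(idx), , drop = FALSE])[1]
      stop("no potential in table for atom ", missing_at,
           " (and possibly others)")
    }
    phi <- source$potential[idx]
    src <- "table"
    params <- list(n_table = nrow(source))
  } else if (identical(source, "surrogate")) {
    q <- .atom_charges(a, charges)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    w <- exp(-kappa * d) / (eps_r * d)
    w[d <= eps] <- 0          # self + coincident exclusion
    phi <- as.numeric(w %*% q)
    src <- "surrogate"
    params <- list(kappa = kappa, eps_r = eps_r, eps = eps)
  } else {
    stop("unknown potential source; give a dx_grid, a data frame, ",
         "or \"surrogate\"")
  }
  if (any(!is.finite(phi))) stop("non-finite potential computed")
  names(phi) <- keys
  structure(phi, class = "potentials", source = src, params = params)
}

# Per-atom partial charges from a charge table: either a PQR-style table
# matched per atom by chain/resno/name, or a (resid, name, charge) table
# typed by residue name.
.atom_charges <- function(a, charges) {
  if (all(c("chain", "resno", "name", "charge") %in% names(charges))) {
    idx <- match(paste(a$chain, a$resno, a$name, sep = "/"),
                 paste(charges$chain, charges$resno, charges$name,
                       sep = "/"))
  } else if (all(c("resid", "name", "charge") %in% names(charges))) {
    idx <- match(paste(a$resid, a$name, sep = "/"),
                 paste(charges$resid, charges$name, sep = "/"))
  } else {
    stop("charge table needs columns (resid, name, charge) or ",
         "(chain, resno, name, charge)")
  }
  q <- charges$charge[idx]
  q[is.na(q)] <- 0
  q
}

#' @export
print.potentials <- function(x, ...) {
  cat("<potentials> ", length(x), " atoms, source=", attr(x, "source"),
      ", range [", format(min(x), digits = 4), ", ",
      format(max(x), digits = 4), "] kT/e\n", sep = "")
  invisible(x)
}

#' Pairwise potential-difference matrix
#'
#' `PD[i, j] = phi(i) - phi(j)`: antisymmetric with zero diagonal, in kT/e.
#'
#' @param p A `potentials` object (or named numeric vector).
#' @param keys Atom keys selecting and ordering the atoms (default: all).
#' @return Numeric matrix with `dimnames = list(keys, keys)`.
#' @export
pairwise_pd <- function(p, keys = names(p)) {
  idx <- match(keys, names(p))
  if (anyNA(idx)) {
    stop("atoms not assigned a potential: ",
         paste(keys[is.na(idx)], collapse = ", "))
  }
  phi <- as.numeric(p)[idx]
  pd <- outer(phi, phi, "-")
  dimnames(pd) <- list(keys, keys)
  pd
}
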