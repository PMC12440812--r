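## Atomic-structure data model, extended XYZ I/O, neighbor lists.

#' Construct an atomic system
#'
#' An `atomic_system` bundles species, Cartesian positions, an optional
#' periodic cell, the total charge, and optional reference labels (energy,
#' forces, partial charges). All geometry is in Angstrom, energies in eV,
#' forces in eV/Angstrom, charges in units of the elementary charge.
#'
#' @param species Integer vector of atomic numbers (>= 1).
#' @param positions N x 3 numeric matrix of Cartesian coordinates [Angstrom].
#' @param cell Optional 3 x 3 matrix whose rows are the lattice vectors.
#' @param pbc Logical vector of length 3 (periodicity per lattice direction).
#' @param total_charge Total charge of the system [e].
#' @param energy Optional reference energy [eV].
#' @param forces Optional N x 3 matrix of reference forces [eV/Angstrom].
#' @param charges Optional vector of reference partial charges [e]; must sum
#'   to `total_charge` within 1e-6.
#' @param info Optional named list of free-form frame metadata.
#' @return An object of class `atomic_system`.
#' @export
atomic_system <- function(species, positions, cell = NULL,
                          pbc = c(FALSE, FALSE, FALSE), total_charge = 0,
                          energy = NULL, forces = NULL, charges = NULL,
                          info = list()) {
  species <- as.integer(species)
  positions <- matrix(as.numeric(positions), ncol = 3)
  sys <- structure(list(
    species = species, positions = positions, cell = cell,
    pbc = as.logical(pbc), total_charge = as.numeric(total_charge),
    energy = energy, forces = forces, charges = charges, info = info
  ), class = "atomic_system")
  validate_system(sys)
  sys
}

#' Validate an atomic system's invariants
#'
#' @param sys An `atomic_system`.
#' @return The system, invisibly, if valid; otherwise an error is raised.
#' @export
validate_system <- function(sys) {
  n <- length(sys$species)
  if (n < 1L || any(sys$species < 1L)) stop("species must be atomic numbers >= 1")
  if (nrow(sys$positions) != n) stop("positions must have one row per atom")
  if (!is.null(sys$forces) && (nrow(sys$forces) != n || ncol(sys$forces) != 3))
    stop("forces must be an N x 3 matrix")
  if (!is.null(sys$charges)) {
    if (length(sys$charges) != n) stop("charges must have one entry per atom")
    if (abs(sum(sys$charges) - sys$total_charge) > 1e-6)
      stop(sprintf("charges sum to %.8f but total_charge is %.8f",
                   sum(sys$charges), sys$total_charge))
  }
  if (length(sys$pbc) != 3) stop("pbc must have length 3")
  if (any(sys$pbc)) {
    if (is.null(sys$cell)) stop("periodic systems require a cell")
    if (abs(det(sys$cell)) <= 1e-12) stop("cell is singular")
  }
  invisible(sys)
}

#' @export
print.atomic_system <- function(x, ...) {
  cat(sprintf("atomic_system: %d atoms (%s), Q_tot = %+g e%s\n",
              length(x$species),
              paste(unique(.z_to_symbol(x$species)), collapse = ","),
              x$total_charge,
              if (any(x$pbc)) ", periodic" else ""))
  if (!is.null(x$energy)) cat(sprintf("  energy: %.6f eV\n", x$energy))
  invisible(x)
}

n_atoms <- function(sys) length(sys$species)

## ---- extended XYZ -------------------------------------------------------

# parse a key=value header line where values may be double-quoted
.parse_extxyz_info <- function(line, lineno) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|[^ ]+)'
  rest <- line
  while (grepl(pat, rest)) {
    m <- regmatches(rest, regexec(pat, rest))[[1]]
    key <- m[2]
    val <- if (m[3] != "" && startsWith(m[3], "\"")) m[4] else m[3]
    out[[key]] <- val
    rest <- sub(pat, "", rest)
  }
  if (!length(out)) stop("malformed extended XYZ header at line ", lineno)
  out
}

#' Read structures from an extended XYZ file
#'
#' Supports the common ase-style dialect: a `Lattice="..."` key with nine
#' numbers (rows are lattice vectors), a `Properties=` column description
#' with `species:S:1:pos:R:3` plus optional `forces:R:3` and `charge:R:1`
#' columns, and `energy`, `total_charge`, `pbc` info keys. Absent labels stay
#' absent (`NULL`), they are never zero-filled.
#'
#' @param path Path to an extended XYZ file.
#' @return A list of [atomic_system()] objects, one per frame.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  systems <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("\\S", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("expected atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated frame starting at line ", i)
    info <- .parse_extxyz_info(lines[i + 1L], i + 1L)

    props <- info[["Properties"]]
    if (is.null(props)) props <- "species:S:1:pos:R:3"
    fields <- strsplit(props, ":")[[1]]
    if (length(fields) %% 3 != 0) stop("malformed Properties string at line ", i + 1L)
    pnames <- fields[seq(1, length(fields), 3)]
    pcount <- as.integer(fields[seq(3, length(fields), 3)])
    ncol_expect <- sum(pcount)

    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[ \t]+")
    bad <- which(vapply(toks, length, 1L) != ncol_expect)
    if (length(bad))
      stop("wrong column count at line ", i + 1L + bad[1],
           " (expected ", ncol_expect, ")")
    tab <- do.call(rbind, toks)

    col <- 1L
    species <- NULL; positions <- NULL; forces <- NULL; charges <- NULL
    for (k in seq_along(pnames)) {
      cols <- col:(col + pcount[k] - 1L)
      block <- tab[, cols, drop = FALSE]
      if (pnames[k] == "species") {
        species <- .symbol_to_z(as.vector(block))
      } else {
        num <- matrix(as.numeric(block), ncol = pcount[k])
        if (pnames[k] == "pos") positions <- num
        else if (pnames[k] == "forces") forces <- num
        else if (pnames[k] %in% c("charge", "charges")) charges <- as.vector(num)
      }
      col <- col + pcount[k]
    }
    if (is.null(species) || is.null(positions))
      stop("frame at line ", i, " lacks species/pos columns")

    cell <- NULL
    if (!is.null(info[["Lattice"]])) {
      v <- as.numeric(strsplit(trimws(info[["Lattice"]]), "[ \t]+")[[1]])
      if (length(v) != 9 || anyNA(v)) stop("malformed Lattice at line ", i + 1L)
      cell <- matrix(v, nrow = 3, byrow = TRUE)
    }
    pbc <- c(FALSE, FALSE, FALSE)
    if (!is.null(info[["pbc"]]))
      pbc <- toupper(strsplit(trimws(info[["pbc"]]), "[ \t]+")[[1]]) == "T"
    energy <- if (!is.null(info[["energy"]])) as.numeric(info[["energy"]]) else NULL
    qtot <- if (!is.null(info[["total_charge"]])) as.numeric(info[["total_charge"]]) else 0
    extra <- info[setdiff(names(info), c("Lattice", "Properties", "pbc",
                                         "energy", "total_charge"))]

    sys <- tryCatch(
      atomic_system(species, positions, cell = cell, pbc = pbc,
                    total_charge = qtot, energy = energy, forces = forces,
                    charges = charges, info = extra),
      error = function(e) stop("invalid frame at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    systems[[length(systems) + 1L]] <- sys
    i <- i + 2L + n
  }
  systems
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write structures to an extended XYZ file
#'
#' Inverse of [read_extxyz()]: numeric fields are printed at full double
#' precision so that a read/write round trip is the identity.
#'
#' @param systems A list of [atomic_system()] objects (or a single one).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_extxyz <- function(systems, path) {
  if (inherits(systems, "atomic_system")) systems <- list(systems)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  for (sys in systems) {
    validate_system(sys)
    n <- n_atoms(sys)
    props <- "species:S:1:pos:R:3"
    if (!is.null(sys$forces)) props <- paste0(props, ":forces:R:3")
    if (!is.null(sys$charges)) props <- paste0(props, ":charge:R:1")
    hdr <- character()
    if (!is.null(sys$cell))
      hdr <- c(hdr, sprintf('Lattice="%s"',
                            paste(.fmt(as.vector(t(sys$cell))), collapse = " ")))
    hdr <- c(hdr, paste0("Properties=", props))
    if (!is.null(sys$energy)) hdr <- c(hdr, paste0("energy=", .fmt(sys$energy)))
    hdr <- c(hdr, paste0("total_charge=", .fmt(sys$total_charge)))
    hdr <- c(hdr, sprintf('pbc="%s"', paste(ifelse(sys$pbc, "T", "F"), collapse = " ")))
    for (k in names(sys$info)) hdr <- c(hdr, sprintf('%s="%s"', k, sys$info[[k]]))
    writeLines(as.character(n), con)
    writeLines(paste(hdr, collapse = " "), con)
    rows <- cbind(.z_to_symbol(sys$species),
                  matrix(.fmt(sys$positions), ncol = 3))
    if (!is.null(sys$forces)) rows <- cbind(rows, matrix(.fmt(sys$forces), ncol = 3))
    if (!is.null(sys$charges)) rows <- cbind(rows, .fmt(sys$charges))
    writeLines(apply(rows, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

## ---- neighbor lists -----------------------------------------------------

# perpendicular widths of a cell (rows = lattice vectors)
.cell_widths <- function(cell) {
  v <- abs(det(cell))
  a <- cell[1, ]; b <- cell[2, ]; c_ <- cell[3, ]
  cross <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                            x[3] * y[1] - x[1] * y[3],
                            x[1] * y[2] - x[2] * y[1])
  c(v / sqrt(sum(cross(b, c_)^2)),
    v / sqrt(sum(cross(c_, a)^2)),
    v / sqrt(sum(cross(a, b)^2)))
}

#' Build a directed neighbor list
#'
#' Lists every ordered pair `(i, j)` whose (minimum-image, for periodic
#' systems) distance is strictly below `cutoff`. Edges are ordered
#' lexicographically by `(i, j)`. For periodic systems the cutoff must not
#' exceed half the smallest perpendicular cell width so that the minimum
#' image convention is valid.
#'
#' @param system An [atomic_system()].
#' @param cutoff Cutoff radius in Angstrom (> 0); the test is `r < cutoff`.
#' @return An object of class `neighbor_list` with fields `edges` (E x 2
#'   integer matrix, 1-based), `displacements` (E x 3, `R_j - R_i`),
#'   `distances`, and `cutoff`.
#' @export
build_neighbor_list <- function(system, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- n_atoms(system)
  periodic <- any(system$pbc)
  if (periodic) {
    if (!all(system$pbc)) stop("partial periodicity is not supported")
    wmin <- min(.cell_widths(system$cell))
    if (cutoff > wmin / 2)
      stop(sprintf(paste0("cutoff %.3f exceeds half the minimum cell width %.3f; ",
                          "replicate the cell before building the neighbor list"),
                   cutoff, wmin / 2))
  }
  disp <- array(0, c(n, n, 3))
  for (k in 1:3) disp[, , k] <- outer(system$positions[, k], system$positions[, k],
                                      function(a, b) b - a)
  if (periodic) {
    # wrap the displacement matrix through fractional coordinates
    dmat <- matrix(disp, ncol = 3)
    frac <- dmat %*% solve(system$cell)
    frac <- frac - round(frac)
    dmat <- frac %*% system$cell
    disp <- array(dmat, c(n, n, 3))
  }
  r <- sqrt(disp[, , 1]^2 + disp[, , 2]^2 + disp[, , 3]^2)
  sel <- which(r < cutoff & row(r) != col(r), arr.ind = TRUE)
  if (nrow(sel)) {
    ord <- order(sel[, 1], sel[, 2])
    sel <- sel[ord, , drop = FALSE]
  }
  idx <- (sel[, 2] - 1) * n + sel[, 1]
  structure(list(
    edges = cbind(i = sel[, 1], j = sel[, 2]),
    displacements = cbind(disp[, , 1][idx], disp[, , 2][idx], disp[, , 3][idx]),
    distances = r[idx],
    cutoff = cutoff
  ), class = "neighbor_list")
}

#' @export
print.neighbor_list <- function(x, ...) {
  cat(sprintf("neighbor_list: %d directed edges, cutoff %.3f Angstrom\n",
              nrow(x$edges), x$cutoff))
  invisible(x)
}
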