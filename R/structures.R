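# Atomistic structure container, PDB ingestion, and synthetic builders.
#
# A `param_structure` is the minimal description the confinement-length
# algorithm needs: atom positions (nm) plus per-atom Lennard-Jones
# parameters (kJ/mol, nm) and partial charges (e). Crystallographic
# fidelity is deliberately not attempted for the synthetic builders --
# the delta algorithm consumes only positions and parameters, so
# simple-cubic lattices are used for spheres, pores and slabs.

#' Per-atom-type force-field parameter table
#'
#' Maps atom type names to Lennard-Jones epsilon (kJ/mol), sigma (nm)
#' and partial charge (e). Every atom type referenced by a structure
#' must have an entry.
#'
#' @param types character vector of type names
#' @param epsilon LJ well depths (kJ/mol), recycled
#' @param sigma LJ zero-crossing distances (nm), recycled
#' @param charge partial charges (e), recycled
#' @return data.frame of class `parameter_table`
#' @export
#' @examples
#' parameter_table(c("SI", "OS"), epsilon = c(2.5, 0.65),
#'                 sigma = c(0.39, 0.32), charge = c(0.9, -0.45))
parameter_table <- function(types, epsilon, sigma, charge = 0) {
  tab <- data.frame(type = as.character(types),
                    epsilon = as.numeric(epsilon),
                    sigma = as.numeric(sigma),
                    charge = as.numeric(charge),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$type)) stop("duplicate atom types in parameter table")
  if (any(tab$epsilon < 0)) stop("lj epsilon must be >= 0")
  if (any(tab$sigma <= 0)) stop("lj sigma must be > 0")
  class(tab) <- c("parameter_table", "data.frame")
  tab
}

#' Read a parameter table from a config file
#'
#' Accepts either a YAML mapping (`type: {epsilon: ..., sigma: ...,
#' charge: ...}`) or a whitespace-delimited table with a header line
#' `type epsilon sigma charge`.
#'
#' @param path file path
#' @return `parameter_table`
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    tab <- do.call(rbind, lapply(names(y), function(ty) {
      e <- y[[ty]]
      data.frame(type = ty, epsilon = e$epsilon, sigma = e$sigma,
                 charge = if (is.null(e$charge)) 0 else e$charge)
    }))
  } else {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  parameter_table(tab$type, tab$epsilon, tab$sigma, tab$charge)
}

lookup_params <- function(types, table) {
  idx <- match(types, table$type)
  if (anyNA(idx)) {
    missing <- unique(types[is.na(idx)])
    stop("atom type(s) not found in parameter table: ",
         paste(missing, collapse = ", "))
  }
  table[idx, c("epsilon", "sigma", "charge")]
}

new_param_structure <- function(atoms, box = NULL, label = "") {
  s <- structure(list(atoms = atoms, box = box, label = label),
                 class = "param_structure")
  validate_structure(s)
  s
}

#' Validate a `param_structure`
#'
#' Checks the container invariants: at least one atom, unique atom
#' ids, finite coordinates, nonnegative epsilon, positive sigma and,
#' when a periodic box is present, all positions inside it.
#'
#' @param s `param_structure`
#' @return the structure, invisibly; errors on violation
#' @export
validate_structure <- function(s) {
  a <- s$atoms
  if (nrow(a) < 1) stop("structure must contain at least one atom")
  if (anyDuplicated(a$id)) stop("atom ids must be unique")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  if (any(a$epsilon < 0)) stop("lj epsilon must be >= 0")
  if (any(a$sigma <= 0)) stop("lj sigma must be > 0")
  if (!is.null(s$box)) {
    if (length(s$box) != 3 || any(s$box <= 0)) stop("box must be 3 positive lengths")
    pos <- as.matrix(a[, c("x", "y", "z")])
    if (any(pos < -1e-9) || any(sweep(pos, 2, s$box) > 1e-9))
      stop("all positions must lie inside the box")
  }
  invisible(s)
}

#' @export
print.param_structure <- function(x, ...) {
  cat("param_structure:", x$label, "\n")
  cat("  atoms:", nrow(x$atoms), " types:",
      paste(unique(x$atoms$type), collapse = ","), "\n")
  if (!is.null(x$box)) cat("  box (nm):", paste(signif(x$box, 4), collapse = " x "), "\n")
  invisible(x)
}

atom_positions <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

make_atoms <- function(pos, type, table, is_surface = FALSE) {
  p <- lookup_params(rep_len(type, nrow(pos)), table)
  data.frame(id = seq_len(nrow(pos)),
             type = rep_len(type, nrow(pos)),
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             epsilon = p$epsilon, sigma = p$sigma, charge = p$charge,
             is_surface = rep_len(is_surface, nrow(pos)),
             stringsAsFactors = FALSE)
}

#' Read an atomistic structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), converts coordinates from
#' Angstrom to nm, and attaches Lennard-Jones parameters and partial
#' charges from the parameter table, keyed by the PDB atom name
#' (element symbol as fallback). When alternate locations are present
#' only the first is kept, with a warning.
#'
#' @param path PDB file
#' @param table `parameter_table` resolving every atom type in the file
#' @return `param_structure` with coordinates in nm
#' @export
read_structure <- function(path, table) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  if (any(a$alt != "" & !is.na(a$alt) & a$alt != "A")) {
    warning("alternate locations present; keeping first altloc only")
    a <- a[a$alt %in% c("", NA, "A"), ]
  }
  types <- trimws(a$elety)
  pos <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  p <- lookup_params(types, table)
  atoms <- data.frame(id = seq_len(nrow(a)), type = types,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      epsilon = p$epsilon, sigma = p$sigma, charge = p$charge,
                      is_surface = FALSE, stringsAsFactors = FALSE)
  new_param_structure(atoms, box = NULL, label = basename(path))
}

#' Write / read a structure as a plain text table
#'
#' Serialization used for reproducibility: a whitespace-delimited
#' table with columns id, type, x, y, z, epsilon, sigma, charge,
#' is_surface (lengths in nm, energies in kJ/mol, charges in e).
#'
#' @param s `param_structure`
#' @param path output file
#' @return `write_structure`: path invisibly; `read_structure_table`:
#'   the structure
#' @export
write_structure <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(s$box))
    writeLines(sprintf("# box %.9g %.9g %.9g", s$box[1], s$box[2], s$box[3]), con)
  utils::write.table(format(s$atoms, digits = 12), con, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure_table <- function(path) {
  lines <- readLines(path, n = 1)
  box <- NULL
  if (grepl("^# box", lines[1]))
    box <- as.numeric(strsplit(trimws(sub("^# box", "", lines[1])), "\\s+")[[1]])
  atoms <- utils::read.table(path, header = TRUE, comment.char = "#",
                             stringsAsFactors = FALSE)
  new_param_structure(atoms, box = box, label = basename(path))
}

cubic_lattice <- function(lo, hi, spacing) {
  g <- lapply(seq_len(3), function(k) seq(ceiling(lo[k] / spacing),
                                          floor(hi[k] / spacing)) * spacing)
  as.matrix(expand.grid(x = g[[1]], y = g[[2]], z = g[[3]]))
}

#' Build a spherical nanoparticle on a cubic lattice
#'
#' Atoms sit on a simple-cubic lattice clipped to a sphere centred at
#' the origin; a fixture emulating spherical hydroxylated
#' nanoparticles. Deterministic for fixed inputs.
#'
#' @param radius sphere radius (nm)
#' @param spacing lattice constant (nm), must be < radius
#' @param type atom type (single name)
#' @param table `parameter_table`
#' @return `param_structure`
#' @export
build_sphere <- function(radius, spacing, type, table) {
  if (!(radius > spacing && spacing > 0))
    stop("require radius > spacing > 0")
  pos <- cubic_lattice(rep(-radius, 3), rep(radius, 3), spacing)
  pos <- pos[sqrt(rowSums(pos^2)) <= radius + 1e-12, , drop = FALSE]
  atoms <- make_atoms(pos, type, table)
  # outer shell flagged as surface (within one lattice constant of the boundary)
  atoms$is_surface <- sqrt(rowSums(pos^2)) > radius - spacing
  new_param_structure(atoms, label = sprintf("sphere R=%.3g nm", radius))
}

#' Build a cylindrical pore wall on a cubic lattice
#'
#' Annular shell with inner radius `pore_radius` and thickness
#' `wall_thickness`, axis along z; the periodic box length along the
#' axis equals `length`.
#'
#' @param pore_radius inner (pore) radius (nm)
#' @param wall_thickness radial wall thickness (nm), >= spacing
#' @param length axial length (nm)
#' @param spacing lattice constant (nm)
#' @param type atom type
#' @param table `parameter_table`
#' @return `param_structure` with an axial periodic box
#' @export
build_cylindrical_pore <- function(pore_radius, wall_thickness, length,
                                   spacing, type, table) {
  if (any(c(pore_radius, wall_thickness, length, spacing) <= 0))
    stop("all pore dimensions must be positive")
  if (wall_thickness < spacing) stop("wall_thickness must be >= spacing")
  rmax <- pore_radius + wall_thickness
  pos <- cubic_lattice(c(-rmax, -rmax, 0), c(rmax, rmax, length - spacing / 2),
                       spacing)
  rad <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  keep <- rad >= pore_radius - 1e-12 & rad <= rmax + 1e-12
  pos <- pos[keep, , drop = FALSE]
  rad <- rad[keep]
  # shift into the box [0, L) x same x same
  half <- rmax + spacing
  pos[, 1] <- pos[, 1] + half
  pos[, 2] <- pos[, 2] + half
  atoms <- make_atoms(pos, type, table)
  atoms$is_surface <- rad < pore_radius + spacing
  new_param_structure(atoms, box = c(2 * half, 2 * half, length),
                      label = sprintf("pore R=%.3g nm", pore_radius))
}

#' Build an armchair carbon nanotube
#'
#' Rolls a honeycomb carbon lattice (C-C bond length 0.142 nm) into an
#' (n,n) armchair tube with axis along z. Tube radius follows the
#' standard rolling construction d = (a/pi) sqrt(n^2 + nm + m^2) with
#' a = sqrt(3) * 0.142 nm. Carbons are neutral with default LJ
#' parameters sigma_CC = 0.36 nm, epsilon_CC = 0.29 kJ/mol (already
#' combined with water oxygen).
#'
#' @param n,m chiral indices; only armchair (n == m) is supported
#' @param length tube length (nm)
#' @param table optional `parameter_table` with a "C" entry; defaults
#'   to the combined CNT-water parameters above
#' @return `param_structure`
#' @export
build_cnt <- function(n, m, length, table = NULL) {
  if (n != m) stop("unsupported chirality: only armchair (n = m) tubes are built")
  if (length <= 0) stop("length must be positive")
  if (is.null(table))
    table <- parameter_table("C", epsilon = 0.29, sigma = 0.36, charge = 0)
  acc <- 0.142                      # C-C bond length, nm
  circ <- 3 * acc * n               # |C_h| for armchair (n,n)
  R <- circ / (2 * pi)
  dz <- sqrt(3) / 2 * acc           # axial spacing of atomic rings
  # unrolled armchair sheet: ring j at height j*dz carries 2n atoms whose
  # circumferential coordinates are x = 1.5*acc*s + {0, acc} for the n
  # values of s in [0, 2n) with s = j (mod 2)
  J <- floor((length - 1e-9) / dz) + 1
  rings <- lapply(seq_len(J) - 1, function(j) {
    s <- seq(j %% 2, 2 * n - 1, by = 2)
    x <- c(1.5 * acc * s, 1.5 * acc * s + acc)
    cbind(x = x %% circ, y = j * dz)
  })
  xy <- do.call(rbind, rings)
  phi <- 2 * pi * xy[, 1] / circ
  pos <- cbind(R * cos(phi), R * sin(phi), xy[, 2])
  atoms <- make_atoms(pos, "C", table, is_surface = TRUE)
  new_param_structure(atoms, label = sprintf("CNT (%d,%d)", n, m))
}

#' Build a rectangular planar slab
#'
#' Square-footprint simple-cubic slab with its top layer at z = 0 and
#' deeper layers at negative z; the top layer is flagged `is_surface`
#' and its outward normal is +z by convention. Serves as the
#' analytic-limit fixture for flat walls.
#'
#' @param area slab footprint area (nm^2)
#' @param layers number of atomic layers (>= 1)
#' @param spacing lattice constant (nm)
#' @param type atom type
#' @param table `parameter_table`
#' @return `param_structure`
#' @export
build_planar_slab <- function(area, layers, spacing, type, table) {
  if (layers < 1) stop("layers must be >= 1")
  if (area <= 0 || spacing <= 0) stop("area and spacing must be positive")
  side <- sqrt(area)
  nxy <- max(2, round(side / spacing))
  xy <- (seq_len(nxy) - 1) * spacing
  zs <- -(seq_len(layers) - 1) * spacing
  pos <- as.matrix(expand.grid(x = xy, y = xy, z = zs))
  atoms <- make_atoms(pos, type, table)
  atoms$is_surface <- pos[, 3] == 0
  new_param_structure(atoms, label = sprintf("slab %dx%d x%d", nxy, nxy, layers))
}
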