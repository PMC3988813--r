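# Shared fixtures, built in code.

# generic silica-like atom types: X neutral, XQ charged surface type
fix_table <- function() {
  parameter_table(c("X", "XQ"), epsilon = c(0.65, 0.65),
                  sigma = c(0.32, 0.32), charge = c(0, 0.4))
}

# structure with a single atom at the origin
single_atom <- function(sigma = 0.32, epsilon = 0.65, charge = 0) {
  nanoconfine:::new_param_structure(
    data.frame(id = 1L, type = "X", x = 0, y = 0, z = 0,
               epsilon = epsilon, sigma = sigma, charge = charge,
               is_surface = TRUE))
}

# arbitrary small structure from explicit positions
structure_from <- function(pos, epsilon = 0.65, sigma = 0.32, charge = 0,
                           box = NULL) {
  n <- nrow(pos)
  nanoconfine:::new_param_structure(
    data.frame(id = seq_len(n), type = "X",
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               epsilon = rep_len(epsilon, n), sigma = rep_len(sigma, n),
               charge = rep_len(charge, n),
               is_surface = TRUE), box = box)
}

# laterally periodic slab: lattice commensurate with the box so only
# the top and bottom layers are exposed
periodic_slab <- function(nxy = 6, layers = 3, spacing = 0.3,
                          charge = 0) {
  xy <- (seq_len(nxy) - 1) * spacing
  zs <- 2 + (seq_len(layers) - 1) * spacing
  pos <- as.matrix(expand.grid(x = xy, y = xy, z = zs))
  structure_from(pos, charge = charge,
                 box = c(nxy * spacing, nxy * spacing, 10))
}

# small slab used for the delta property checks
delta_slab <- function(charge = 0) periodic_slab(5, 2, 0.3, charge = charge)
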