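# Small structural fixtures built in code.

atom_row <- function(atom, element, res_name, res_num, x, y, z,
                     chain = "A", occ = 1, altloc = "") {
  tibble::tibble(atom = atom, element = element, res_name = res_name,
                 chain = chain, res_num = as.integer(res_num), ins = "",
                 x = x, y = y, z = z, occ = occ, altloc = altloc)
}

# A linear mini-receptor: CA at x = 0, 4, 8, ... on the x axis, one
# side-chain atom per residue 1.5 A above in y.
mini_receptor <- function(res_names, sc_atoms = NULL, sc_elements = NULL) {
  n <- length(res_names)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <-
      atom_row("CA", "C", res_names[i], i, 4 * (i - 1), 0, 0)
    sc <- if (is.null(sc_atoms)) "SC" else sc_atoms[i]
    el <- if (is.null(sc_elements)) "C" else sc_elements[i]
    if (!is.na(sc)) {
      rows[[length(rows) + 1]] <-
        atom_row(sc, el, res_names[i], i, 4 * (i - 1), 1.5, 0)
    }
  }
  dplyr::bind_rows(rows)
}

simple_ligand <- function(x = 0, y = 3, z = 0, atom = "O1", element = "O") {
  atom_row(atom, element, "LIG", 1, x, y, z, chain = "L")
}

# Toy complex cached once per test session (generation is deterministic).
toy_cache <- new.env()
get_toy <- function() {
  if (is.null(toy_cache$toy)) toy_cache$toy <- make_toy_complex()
  toy_cache$toy
}

# A pocket whose CA coordinates are the given matrix.
pocket_with_coords <- function(m, polar = rep(FALSE, nrow(m)),
                               res_names = NULL) {
  n <- nrow(m)
  res_names <- res_names %||% ifelse(polar, "SER", "ALA")
  res <- tibble::tibble(
    res_id = paste0("A:", seq_len(n)), chain = "A", res_num = seq_len(n),
    ins = "", res_name = res_names, polar = polar)
  rownames(m) <- res$res_id
  structure(list(residues = res, ca_coords = m), class = "binding_pocket")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal V2000 molblocks for chemotype tests ------------------------------

molblock <- function(name, atoms, bonds, parity = NULL) {
  # atoms: data.frame(x, y, z, el, chg); bonds: data.frame(a1, a2, order,
  # stereo); chg uses V2000 legacy codes (3 = +1, 5 = -1)
  n_a <- nrow(atoms); n_b <- nrow(bonds)
  lines <- c(name, "  pocketforge-test", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_a, n_b))
  for (i in seq_len(n_a)) {
    p <- if (is.null(parity)) 0 else parity[i]
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0%3d%3d  0  0  0  0  0  0  0  0  0",
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$el[i], atoms$chg[i], p))
  }
  for (i in seq_len(n_b)) {
    lines <- c(lines, sprintf("%3d%3d%3d%3d  0  0  0", bonds$a1[i],
                              bonds$a2[i], bonds$order[i], bonds$stereo[i]))
  }
  c(lines, "M  END", "$$$$")
}

# chain molecule: atoms given as element string vector, single bonds along
# the chain; coordinates spread on x so nothing overlaps
chain_mol <- function(name, elements, charges = NULL, orders = NULL,
                      parity = NULL) {
  n <- length(elements)
  charges <- charges %||% rep(0, n)
  atoms <- data.frame(x = seq_len(n) * 1.5, y = 0, z = 0, el = elements,
                      chg = charges)
  bonds <- if (n < 2) {
    data.frame(a1 = integer(), a2 = integer(), order = integer(),
               stereo = integer())
  } else {
    data.frame(a1 = seq_len(n - 1), a2 = seq_len(n - 1) + 1,
               order = orders %||% rep(1, n - 1), stereo = 0)
  }
  molblock(name, atoms, bonds, parity)
}

write_sdf_fixture <- function(blocks) {
  path <- tempfile(fileext = ".sdf")
  writeLines(unlist(blocks), path)
  path
}

# 2-methylbutan-2-ol-like branched molecule without stereocentre and
# butan-2-ol with one (C2 bears OH, CH3, C2H5, H).
butan2ol_block <- function(name = "butan2ol") {
  atoms <- data.frame(
    x = c(0, 1.5, 3.0, 4.5, 1.5), y = c(0, 0, 0, 0, 1.4), z = 0,
    el = c("C", "C", "C", "C", "O"), chg = 0)
  bonds <- data.frame(a1 = c(1, 2, 3, 2), a2 = c(2, 3, 4, 5),
                      order = 1, stereo = 0)
  molblock(name, atoms, bonds)
}
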