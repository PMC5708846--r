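# Residue types whose side chains bear H-bond-capable or charged groups.
polar_residue_types <- c("SER", "THR", "TYR", "ASN", "GLN", "HIS", "LYS",
                         "ARG", "ASP", "GLU", "TRP", "CYS")

#' Define the binding pocket of a complex
#'
#' A residue belongs to the pocket when any of its heavy atoms lies within
#' `cutoff` of any seed atom; the boundary is inclusive (d <= cutoff).
#' By default the seed is the bound ligand's heavy atoms; a user-supplied
#' coordinate matrix (e.g. the corners/grid of a pocket box) can replace
#' it. Residues are ordered by (chain, residue number, insertion code) and
#' flagged polar from a fixed residue-type table.
#'
#' @param complex A [pf_complex()].
#' @param seed Optional n x 3 matrix of seed coordinates; defaults to the
#'   ligand's heavy atoms.
#' @param cutoff Distance cutoff in Angstrom (default 1.5).
#' @return An object of class `binding_pocket`: a residue tibble
#'   (`res_id`, `chain`, `res_num`, `ins`, `res_name`, `polar`) plus the
#'   matrix of pocket C-alpha coordinates.
#' @export
define_pocket <- function(complex, seed = NULL, cutoff = 1.5) {
  if (cutoff <= 0) abort_pf("pocket cutoff must be > 0", "empty_pocket_error")
  if (is.null(seed)) {
    lig <- complex$ligand[complex$ligand$element != "H", ]
    seed <- as.matrix(lig[, c("x", "y", "z")])
  }
  seed <- as.matrix(seed)
  if (nrow(seed) == 0) abort_pf("empty pocket seed", "empty_pocket_error")
  at <- complex$receptor[complex$receptor$element != "H", ]
  d <- cross_dist(as.matrix(at[, c("x", "y", "z")]), seed)
  hit <- apply(d, 1, min) <= cutoff
  res <- dplyr::distinct(at[hit, ], .data$chain, .data$res_num, .data$ins,
                         .data$res_name)
  if (nrow(res) == 0) {
    abort_pf("no residue within cutoff of the seed (empty pocket)",
             "empty_pocket_error")
  }
  pocket_from_residues(complex, res)
}

pocket_from_residues <- function(complex, res) {
  res <- dplyr::arrange(res, .data$chain, .data$res_num, .data$ins)
  res$res_id <- res_id(res$chain, res$res_num, res$ins)
  res$polar <- res$res_name %in% polar_residue_types
  ca <- dplyr::semi_join(
    complex$receptor[complex$receptor$atom == "CA", ], res,
    by = c("chain", "res_num", "ins"))
  ca <- dplyr::arrange(ca, .data$chain, .data$res_num, .data$ins)
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- res_id(ca$chain, ca$res_num, ca$ins)
  structure(list(
    residues = res[, c("res_id", "chain", "res_num", "ins", "res_name", "polar")],
    ca_coords = m),
    class = "binding_pocket")
}

#' Re-extract a previously defined pocket from another conformation
#'
#' Keeps the residue list (hence comparability) fixed while taking
#' coordinates from `complex`.
#'
#' @param complex A [pf_complex()] containing every pocket residue.
#' @param pocket A `binding_pocket` whose residue list to reuse.
#' @return A `binding_pocket` with `complex`'s coordinates.
#' @export
extract_pocket <- function(complex, pocket) {
  res <- pocket$residues
  have <- dplyr::semi_join(
    dplyr::distinct(complex$receptor, .data$chain, .data$res_num, .data$ins),
    res, by = c("chain", "res_num", "ins"))
  if (nrow(have) != nrow(res)) {
    abort_pf("pocket residue(s) absent from complex", "correspondence_error")
  }
  pocket_from_residues(complex, res[, c("chain", "res_num", "ins", "res_name")])
}

#' @export
print.binding_pocket <- function(x, ...) {
  cat("<binding_pocket> ", nrow(x$residues), " residues (",
      sum(x$residues$polar), " polar)\n", sep = "")
  invisible(x)
}

check_same_residues <- function(a, b) {
  ra <- a$residues$res_id; rb <- b$residues$res_id
  if (!identical(ra, rb)) {
    diff <- c(setdiff(ra, rb), setdiff(rb, ra))
    abort_pf(paste0("pocket residue lists differ: ",
                    paste(diff, collapse = ", ")), "correspondence_error")
  }
}

#' Superimpose pockets onto a reference
#'
#' Least-squares rigid-body superposition of each target pocket's C-alpha
#' atoms onto the reference pocket, with the post-fit RMSD. All pockets
#' must share an identical ordered residue list; the reference is left
#' untouched.
#'
#' @param reference A `binding_pocket`.
#' @param targets A list of `binding_pocket`s (a single pocket is
#'   accepted).
#' @return A list with `aligned` (list of fitted n x 3 coordinate
#'   matrices) and `rmsd` (numeric vector, Angstrom).
#' @export
superimpose_pockets <- function(reference, targets) {
  if (inherits(targets, "binding_pocket")) targets <- list(targets)
  ref <- reference$ca_coords
  out <- purrr::map(targets, function(tg) {
    check_same_residues(reference, tg)
    fit_coords(tg$ca_coords, ref)
  })
  list(aligned = purrr::map(out, "coords"),
       rmsd = purrr::map_dbl(out, "rmsd"))
}

# Kabsch-style least-squares fit of `mob` onto `ref` (both n x 3).
fit_coords <- function(mob, ref) {
  cm <- colMeans(mob); cr <- colMeans(ref)
  a <- sweep(mob, 2, cm); b <- sweep(ref, 2, cr)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(a %*% rot, 2, cr, "+")
  dimnames(fitted) <- dimnames(mob)
  list(coords = fitted, rmsd = sqrt(mean(rowSums((fitted - ref)^2))))
}
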