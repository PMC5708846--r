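# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-directory seed derived from the run hierarchy.
# Integer arithmetic kept below 2^53 so it is exact in doubles, and the
# result is kept inside R's 32-bit integer range.
derive_seed <- function(master_seed, replica = 0L, round = 0L, directory = 0L) {
  h <- (as.numeric(master_seed) %% 2147483647) + 1
  for (k in c(replica, round, directory)) {
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# Canonical residue identifier "chain:resnum[ins]".
res_id <- function(chain, res_num, ins = "") {
  ins <- ifelse(is.na(ins) | ins == " ", "", ins)
  paste0(chain, ":", res_num, ins)
}

# Euclidean distances between the rows of two coordinate matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

abort_pf <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pocketforge_error"))
}

is_backbone_atom <- function(atom) atom %in% c("N", "CA", "C", "O", "OXT")
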