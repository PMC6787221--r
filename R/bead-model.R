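#' Residue-bead model of a protein chain
#'
#' One bead per residue (Calpha-like), with per-residue domain labels and a
#' flexible-residue set that downstream samplers may pivot. Validity demands
#' chain-like geometry: consecutive beads 2.9-4.1 Angstrom apart and no
#' non-adjacent pair closer than `clash_cutoff`.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param residue Residue numbers (default `1:n`).
#' @param domain Per-residue domain labels (default `"all"`).
#' @param flexible Logical per-residue flexibility flags (default all FALSE).
#' @param clash_cutoff Minimum allowed non-adjacent bead distance (default
#'   3.0 A; compact lattice-packed domains sit near 3.8 A).
#' @param validate Check invariants (default TRUE).
#' @return Tibble of class `bead_model` with columns `residue`, `x`, `y`,
#'   `z`, `domain`, `flexible`.
#' @export
bead_model <- function(xyz, residue = NULL, domain = NULL, flexible = NULL,
                       clash_cutoff = 3.0, validate = TRUE) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  residue <- residue %||% seq_len(n)
  domain <- domain %||% rep("all", n)
  flexible <- flexible %||% rep(FALSE, n)
  stopifnot(length(residue) == n, length(domain) == n, length(flexible) == n)
  out <- tibble(residue = residue, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                domain = domain, flexible = flexible)
  class(out) <- c("bead_model", class(out))
  attr(out, "clash_cutoff") <- clash_cutoff
  if (validate) validate_bead_model(out)
  out
}

#' @rdname bead_model
#' @param model A `bead_model`.
#' @export
validate_bead_model <- function(model) {
  xyz <- bead_coords(model)
  n <- nrow(xyz)
  if (n < 2) abort("a bead model needs at least 2 beads.")
  steps <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  if (any(steps < 2.9 | steps > 4.1)) {
    abort(sprintf("consecutive bead distance outside [2.9, 4.1] A at position(s) %s.",
                  paste(head(which(steps < 2.9 | steps > 4.1), 5), collapse = ", ")))
  }
  cutoff <- attr(model, "clash_cutoff") %||% 3.0
  d <- as.matrix(stats::dist(xyz))
  d[abs(row(d) - col(d)) <= 1] <- Inf
  if (min(d) < cutoff) {
    abort(sprintf("non-adjacent beads closer than %.1f A (min %.2f A).",
                  cutoff, min(d)))
  }
  invisible(model)
}

#' Bead coordinates as a plain matrix
#'
#' @param model A `bead_model` (or an n x 3 matrix, returned unchanged).
#' @return n x 3 numeric matrix of coordinates (Angstrom).
#' @export
bead_coords <- function(model) {
  if (is.matrix(model)) return(model)
  as.matrix(model[, c("x", "y", "z")])
}

bead_flexible <- function(model) {
  if (is.matrix(model)) return(rep(FALSE, nrow(model)))
  model$flexible
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> %d beads (%s), %d flexible, Rg %.1f A\n",
              nrow(x), paste(unique(x$domain), collapse = "/"),
              sum(x$flexible), radius_of_gyration(bead_coords(x))))
  invisible(x)
}
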