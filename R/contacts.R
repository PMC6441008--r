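#' Residue identifiers
#'
#' @param chain chain identifier.
#' @param resseq residue sequence number (1-based PDB numbering).
#' @param icode insertion code (default empty).
#' @return object of class `residue_id`.
#' @export
residue_id <- function(chain, resseq, icode = "") {
  structure(list(chain = as.character(chain), resseq = as.integer(resseq),
                 icode = as.character(icode)), class = "residue_id")
}

#' @export
format.residue_id <- function(x, ...) {
  paste0(x$chain, ":", x$resseq, if (nzchar(x$icode)) x$icode else "")
}

#' @export
print.residue_id <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

residue_rows <- function(atoms, res) {
  which(atoms$chain == res$chain & atoms$resseq == res$resseq &
          atoms$icode == res$icode)
}

#' Geometric center of a residue's side chain
#'
#' Unweighted mean position of the residue's heavy side-chain atoms (all
#' non-hydrogen atoms except the backbone N, CA, C and the carbonyl O/OXT).
#' Glycine has no side chain; its CA position is returned by convention.
#'
#' @param frame a [structure_frame()].
#' @param residue a [residue_id()].
#' @return length-3 numeric vector (Angstrom).
#' @export
sidechain_center <- function(frame, residue) {
  rows <- residue_rows(frame$atoms, residue)
  if (!length(rows))
    stop_gpcrstab(sprintf("residue %s not found", format(residue)),
                  "unknown_residue_error")
  a <- frame$atoms[rows, , drop = FALSE]
  side <- rows[toupper(a$element) != "H" &
                 !a$atom_name %in% c("N", "CA", "C", "O", "OXT")]
  if (!length(side)) {
    if (any(a$resname == "GLY")) {
      ca <- rows[a$atom_name == "CA"]
      if (!length(ca))
        stop_gpcrstab(sprintf("glycine %s has no CA atom", format(residue)),
                      "degenerate_residue_error")
      return(as.numeric(frame$xyz[ca[1L], ]))
    }
    stop_gpcrstab(sprintf("residue %s has no side-chain heavy atoms",
                          format(residue)), "degenerate_residue_error")
  }
  colMeans(frame$xyz[side, , drop = FALSE])
}

#' Side-chain center distance across an ensemble
#'
#' Per-frame Euclidean distance between the side-chain centers of two
#' residues, with mean and sample standard deviation.  Small standard
#' deviations indicate a stable interaction between the residues.
#'
#' @param ensemble a [structure_ensemble()].
#' @param res_a,res_b [residue_id()]s present in every frame.
#' @return object of class `contact_series`: list with `pair` (formatted
#'   labels), `distances` (per-frame, Angstrom), `mean`, `sd`.
#' @export
distance_series <- function(ensemble, res_a, res_b) {
  distances <- vapply(seq_len(n_frames(ensemble)), function(i) {
    fr <- get_frame(ensemble, i)
    sqrt(sum((sidechain_center(fr, res_a) - sidechain_center(fr, res_b))^2))
  }, numeric(1))
  structure(list(pair = c(format(res_a), format(res_b)),
                 distances = distances,
                 mean = mean(distances),
                 sd = if (length(distances) > 1L) stats::sd(distances) else 0),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("<contact_series> %s - %s: %.2f +/- %.2f A over %d frames\n",
              x$pair[1L], x$pair[2L], x$mean, x$sd, length(x$distances)))
  invisible(x)
}
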