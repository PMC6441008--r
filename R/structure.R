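#' Structure frames and ensembles
#'
#' A *structure frame* is one conformation of a molecule: an atom table
#' (name, element, chain, residue number, insertion code, residue name)
#' together with an `N x 3` coordinate matrix in Angstrom.  A *structure
#' ensemble* is an ordered collection of frames that all share the same atom
#' table, e.g. snapshots sampled from a molecular dynamics trajectory or the
#' models of a multi-model PDB file.
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `chain`,
#'   `resseq`, `icode`, `resname` (one row per atom).
#' @param xyz numeric `N x 3` matrix of coordinates (Angstrom).
#' @param frame_time optional time stamp of the snapshot (ns).
#' @return `structure_frame()` returns an object of class `structure_frame`;
#'   `structure_ensemble()` one of class `structure_ensemble`.
#' @seealso [parse_structure()], [write_structure()], [select_atoms()]
#' @export
structure_frame <- function(atoms, xyz, frame_time = NULL) {
  atoms <- validate_atom_table(atoms)
  xyz <- as_xyz_matrix(xyz, nrow(atoms))
  structure(list(atoms = atoms, xyz = xyz, frame_time = frame_time),
            class = "structure_frame")
}

#' @rdname structure_frame
#' @param frames list of coordinate matrices (each `N x 3`) or of
#'   `structure_frame` objects sharing one atom table.
#' @param label construct name, e.g. `"L126W"`.
#' @export
structure_ensemble <- function(atoms, frames, label = "") {
  if (length(frames) < 1L)
    stop_gpcrstab("an ensemble needs at least one frame", "empty_input_error")
  if (inherits(frames[[1L]], "structure_frame"))
    frames <- lapply(frames, `[[`, "xyz")
  atoms <- validate_atom_table(atoms)
  frames <- lapply(frames, as_xyz_matrix, n = nrow(atoms))
  structure(list(atoms = atoms, frames = frames, label = label),
            class = "structure_ensemble")
}

validate_atom_table <- function(atoms) {
  need <- c("atom_name", "element", "chain", "resseq", "icode", "resname")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop_gpcrstab(paste0("atom table lacks column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "invalid_atoms_error")
  if (nrow(atoms) < 1L)
    stop_gpcrstab("atom table is empty", "invalid_atoms_error")
  if (any(!nzchar(atoms$atom_name)))
    stop_gpcrstab("atom_name must be non-empty", "invalid_atoms_error")
  atoms$resseq <- as.integer(atoms$resseq)
  rownames(atoms) <- NULL
  atoms[need]
}

as_xyz_matrix <- function(xyz, n) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L || nrow(xyz) != n)
    stop_gpcrstab(sprintf("coordinates must be a %d x 3 matrix", n),
                  "invalid_coordinates_error")
  if (any(!is.finite(xyz)))
    stop_gpcrstab("coordinates must be finite", "invalid_coordinates_error")
  dimnames(xyz) <- NULL
  xyz
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms, %d residues\n", nrow(x$atoms),
              nrow(unique(x$atoms[c("chain", "resseq", "icode")]))))
  invisible(x)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> '%s': %d frames x %d atoms\n",
              x$label, length(x$frames), nrow(x$atoms)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `structure_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Extract one frame of an ensemble
#' @param ensemble a `structure_ensemble`.
#' @param i frame index (1-based).
#' @return a `structure_frame`.
#' @export
get_frame <- function(ensemble, i) {
  structure_frame(ensemble$atoms, ensemble$frames[[i]])
}

# ---- PDB I/O ---------------------------------------------------------------
# Fixed-column PDB (ATOM/HETATM/MODEL/ENDMDL/END).  Columns follow the
# wwPDB v3.3 layout; coordinates are written with 3 decimals.

#' Parse a (multi-model) PDB text into a structure ensemble
#'
#' `MODEL`/`ENDMDL` records delimit frames; a file without them yields a
#' single-frame ensemble.  Hydrogens are retained (flagged by their element);
#' for alternate locations only the first altloc seen per atom is kept, with
#' a warning.  All models must carry the identical atom list in the same
#' order, as trajectory snapshots do.
#'
#' @param pdb_text character scalar (or vector of lines) of PDB text.
#' @param label optional ensemble label.
#' @return a [structure_ensemble()].
#' @export
parse_structure <- function(pdb_text, label = "") {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1L]] else as.character(pdb_text)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    sub("\\s+$", "", rec) %in% c("ATOM", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_atom))
    stop_gpcrstab("no ATOM/HETATM records found", "parse_error")

  # frame id per atom line: cumulative MODEL count (0 when no MODEL records)
  model_id <- cumsum(is_model)
  frame_of <- model_id[is_atom]
  if (all(frame_of == 0L)) frame_of <- rep(1L, sum(is_atom))
  if (any(frame_of == 0L))
    stop_gpcrstab("ATOM records found outside MODEL blocks in a multi-model file",
                  "parse_error")

  al <- lines[is_atom]
  lineno <- which(is_atom)
  al <- formatC(al, width = 80, flag = "-")
  xs <- suppressWarnings(as.numeric(substr(al, 31L, 38L)))
  ys <- suppressWarnings(as.numeric(substr(al, 39L, 46L)))
  zs <- suppressWarnings(as.numeric(substr(al, 47L, 54L)))
  resseq <- suppressWarnings(as.integer(substr(al, 23L, 26L)))
  bad <- !is.finite(xs) | !is.finite(ys) | !is.finite(zs) | is.na(resseq)
  if (any(bad))
    stop_gpcrstab(sprintf("malformed ATOM/HETATM record at line %d: '%s'",
                          lineno[which(bad)[1L]],
                          trimws(lines[lineno[which(bad)[1L]]], "right")),
                  "parse_error")

  atom_name <- trimws(substr(al, 13L, 16L))
  altloc <- substr(al, 17L, 17L)
  resname <- trimws(substr(al, 18L, 20L))
  chain <- trimws(substr(al, 22L, 22L))
  icode <- trimws(substr(al, 27L, 27L))
  element <- trimws(substr(al, 77L, 78L))
  element[!nzchar(element)] <- guess_element(atom_name[!nzchar(element)])

  df <- data.frame(frame = frame_of, atom_name = atom_name, element = element,
                   chain = chain, resseq = resseq, icode = icode,
                   resname = resname, altloc = altloc,
                   x = xs, y = ys, z = zs, stringsAsFactors = FALSE)

  # altloc policy: keep the first altloc per (frame, residue, atom name)
  if (any(!df$altloc %in% c(" ", ""))) {
    key <- paste(df$frame, df$chain, df$resseq, df$icode, df$atom_name,
                 sep = "\r")
    drop <- duplicated(key) & !df$altloc %in% c(" ", "")
    first_alt <- !duplicated(key) & !df$altloc %in% c(" ", "")
    if (any(drop)) {
      warn_gpcrstab(sprintf("%d alternate-location atom(s) dropped (first altloc kept)",
                            sum(drop)), "altloc_warning")
      df <- df[!drop, , drop = FALSE]
    } else if (any(first_alt)) {
      # lone altloc labels (e.g. all 'A'): nothing dropped, keep silently
    }
  }

  ids <- sort(unique(df$frame))
  per <- split(df, df$frame)
  ref <- per[[1L]]
  sig <- function(d) paste(d$atom_name, d$chain, d$resseq, d$icode, d$resname,
                           collapse = "\r")
  ref_sig <- sig(ref)
  for (k in seq_along(per)) {
    if (nrow(per[[k]]) != nrow(ref) || sig(per[[k]]) != ref_sig)
      stop_gpcrstab(sprintf("model %d does not share the atom list of model %d",
                            ids[k], ids[1L]), "ensemble_consistency_error")
  }
  atoms <- ref[c("atom_name", "element", "chain", "resseq", "icode", "resname")]
  frames <- lapply(per, function(d) cbind(d$x, d$y, d$z))
  structure_ensemble(atoms, frames, label = label)
}

guess_element <- function(atom_name) {
  # strip leading digits (e.g. "1HB1"), take leading letters;
  # hydrogens and two-letter elements of common hetero atoms resolved by name
  nm <- sub("^[0-9']+", "", atom_name)
  first <- substr(nm, 1L, 1L)
  two <- toupper(substr(nm, 1L, 2L))
  el <- first
  el[first == "H"] <- "H"
  el[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "SE")]
  el
}

#' Write a structure ensemble as multi-model PDB text
#'
#' Coordinates are emitted with 3 decimals in the fixed wwPDB columns.  A
#' single-frame ensemble is written without `MODEL`/`ENDMDL` wrappers; a
#' multi-frame one gets one `MODEL` block per frame.  The text ends with
#' `END`.
#'
#' @param ensemble a [structure_ensemble()] or [structure_frame()].
#' @return character scalar of PDB text.
#' @export
write_structure <- function(ensemble) {
  if (inherits(ensemble, "structure_frame"))
    ensemble <- structure_ensemble(ensemble$atoms, list(ensemble$xyz))
  a <- ensemble$atoms
  if (any(vapply(ensemble$frames, function(m) any(abs(m) >= 10000), TRUE)))
    stop_gpcrstab("coordinate magnitude >= 10000 A cannot be written in PDB fixed columns",
                  "format_overflow_error")
  name_fmt <- ifelse(nchar(a$atom_name) < 4L,
                     sprintf(" %-3s", a$atom_name),
                     sprintf("%-4s", a$atom_name))
  pre <- sprintf("ATOM  %5d %s %-3s %1s%4d%1s   ",
                 seq_len(nrow(a)) %% 100000L, name_fmt, a$resname,
                 a$chain, a$resseq, ifelse(nzchar(a$icode), a$icode, " "))
  post <- sprintf("  1.00  0.00          %2s", a$element)
  one_frame <- function(m) {
    paste0(pre, sprintf("%8.3f%8.3f%8.3f", m[, 1L], m[, 2L], m[, 3L]), post)
  }
  nf <- length(ensemble$frames)
  if (nf == 1L) {
    out <- c(one_frame(ensemble$frames[[1L]]), "END")
  } else {
    out <- unlist(lapply(seq_len(nf), function(i) {
      c(sprintf("MODEL%6d", i), one_frame(ensemble$frames[[i]]), "ENDMDL")
    }))
    out <- c(out, "END")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# ---- atom selection --------------------------------------------------------

#' Indices of atoms belonging to a named domain
#'
#' `domain` may be a segment name of the map, `"TM"` for the union of the
#' seven transmembrane segments, or `"ALL"` for the union of every segment.
#' `atom_class = "heavy"` keeps all non-hydrogen atoms; `"backbone"` keeps
#' atoms named N, CA, C (the carbonyl O counts as backbone chemically but is
#' excluded from superposition, the common trajectory-analysis convention).
#'
#' @param atoms atom table of a frame/ensemble.
#' @param segmap a [segment_map()].
#' @param domain segment name, `"TM"`, or `"ALL"`.
#' @param atom_class `"heavy"` or `"backbone"`.
#' @return integer vector of row indices into `atoms` (frame order).
#' @export
select_atom_indices <- function(atoms, segmap, domain = "ALL",
                                atom_class = c("heavy", "backbone")) {
  atom_class <- match.arg(atom_class)
  segs <- if (identical(domain, "ALL")) {
    names(segmap$segments)
  } else if (identical(domain, "TM")) {
    segmap$tm_names
  } else {
    if (!domain %in% names(segmap$segments))
      stop_gpcrstab(sprintf("unknown domain '%s' (have: %s)", domain,
                            paste(names(segmap$segments), collapse = ", ")),
                    "unknown_domain_error")
    domain
  }
  in_dom <- rep(FALSE, nrow(atoms))
  for (s in segs) {
    rng <- segmap$segments[[s]]
    for (r in seq_len(nrow(rng))) {
      in_dom <- in_dom | (atoms$chain == rng$chain[r] &
                            atoms$resseq >= rng$start[r] &
                            atoms$resseq <= rng$end[r])
    }
  }
  keep <- if (atom_class == "heavy") {
    in_dom & toupper(atoms$element) != "H"
  } else {
    in_dom & atoms$atom_name %in% c("N", "CA", "C")
  }
  idx <- which(keep)
  if (!length(idx))
    stop_gpcrstab(sprintf("selection '%s'/%s is empty", domain, atom_class),
                  "empty_selection_error")
  idx
}

#' Select atom coordinates of a domain
#'
#' @param frame a [structure_frame()].
#' @inheritParams select_atom_indices
#' @return `n x 3` coordinate matrix, in frame order, with the selected row
#'   indices attached as attribute `"indices"`.
#' @export
select_atoms <- function(frame, segmap, domain = "ALL",
                         atom_class = c("heavy", "backbone")) {
  idx <- select_atom_indices(frame$atoms, segmap, domain, atom_class)
  out <- frame$xyz[idx, , drop = FALSE]
  attr(out, "indices") <- idx
  out
}
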