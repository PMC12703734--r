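#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records; one \code{frame} per MODEL block
#' (a single frame when no MODEL records are present). Chain identifiers,
#' residue numbering and elements (inferred from columns 77-78, falling back
#' to the atom name) are preserved. No force-field fields are populated.
#'
#' @param path PDB file path.
#' @return list with \code{topology} (skeleton: no charges/LJ/GB fields) and
#'   \code{frames} (list of \code{frame} objects).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_id <- cumsum(substr(lines, 1, 5) == "MODEL")
  if (max(model_id) == 0L) model_id <- model_id + 1L
  model_of_atom <- model_id[is_atom]
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)

  parse_num <- function(txt, lo, hi, what, lineno) {
    s <- trimws(substr(txt, lo, hi))
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) | s == "")
    if (length(bad))
      stop("malformed ", what, " field at line ",
           lineno[bad[1]], " of ", path)
    v
  }
  first <- model_of_atom == model_of_atom[1]
  l1 <- atom_lines[first]
  ln1 <- atom_lineno[first]
  name <- trimws(substr(l1, 13, 16))
  resname <- trimws(substr(l1, 18, 20))
  chain <- substr(l1, 22, 22)
  resnum <- parse_num(l1, 23, 26, "residue number", ln1)
  elem <- trimws(substr(l1, 77, 78))
  elem[elem == ""] <- toupper(substr(gsub("[^A-Za-z].*", "",
                                          name[elem == ""]), 1, 1))
  natom <- length(l1)

  n_models <- max(model_of_atom)
  frames <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    lm <- atom_lines[model_of_atom == m]
    lnm <- atom_lineno[model_of_atom == m]
    if (length(lm) != natom)
      stop("MODEL ", m, " has ", length(lm), " atoms; MODEL 1 has ", natom)
    xyz <- cbind(parse_num(lm, 31, 38, "x", lnm),
                 parse_num(lm, 39, 46, "y", lnm),
                 parse_num(lm, 47, 54, "z", lnm))
    frames[[m]] <- frame(xyz, time_ps = m - 1)
  }
  # unique 1-based residue index in order of appearance
  res_key <- paste(chain, resnum)
  res_idx <- match(res_key, unique(res_key))
  at <- data.frame(serial = seq_len(natom), name = name, element = elem,
                   residue_index = res_idx, residue_name = resname,
                   chain_id = chain, stringsAsFactors = FALSE)
  list(topology = topology(at), frames = frames)
}

#' Write a PDB file
#'
#' Fixed-column records; multi-frame input becomes MODEL/ENDMDL blocks.
#' Round-trips through \code{\link{read_pdb}} with coordinates preserved at
#' the 0.001 Angstrom format precision.
#'
#' @param top a \code{topology}.
#' @param frames a \code{frame} or list of frames.
#' @param path output path.
#' @param water_resname residue name to emit for water ("WAT" or "HOH").
#' @param renumber if TRUE, renumber residues sequentially with chain B
#'   continuing after the last residue of chain A (the convention used when
#'   preparing two-chain complexes).
#' @return invisibly, the path.
#' @export
write_pdb <- function(top, frames, path, water_resname = NULL,
                      renumber = FALSE) {
  if (inherits(frames, "frame")) frames <- list(frames)
  at <- top$atoms
  resname <- at$residue_name
  if (!is.null(water_resname)) resname[is_water(top)] <- water_resname
  resnum <- at$residue_index
  if (renumber) resnum <- match(paste(at$chain_id, at$residue_index),
                                unique(paste(at$chain_id, at$residue_index)))
  multi <- length(frames) > 1L
  con <- file(path, "w"); on.exit(close(con))
  for (m in seq_along(frames)) {
    xyz <- frames[[m]]$xyz
    if (nrow(xyz) != nrow(at))
      stop("frame ", m, " atom count does not match topology")
    if (any(abs(xyz) > 9999.999))
      stop("coordinate overflows the fixed-width PDB field (|x| > 9999.999)")
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    nm <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial %% 100000L, nm, substr(resname, 1, 3), at$chain_id,
      resnum %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      toupper(substr(at$element, 1, 2))), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
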