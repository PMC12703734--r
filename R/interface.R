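#' Interfacial residues by solvent-accessibility change
#'
#' A residue is interfacial when its SASA in the isolated chain exceeds its
#' SASA in the complex by more than \code{threshold} (default 0.50 A^2, the
#' standard cutoff for this protocol). Waters and ions never qualify. The
#' computation is done once on the supplied complex frame.
#'
#' @param fr a \code{\link{frame}} of the two-chain complex.
#' @param top its \code{\link{topology}}; must contain two protein chains.
#' @param threshold Delta-SASA threshold, A^2.
#' @param ... further arguments to \code{\link{compute_sasa}}.
#' @return object of class \code{interface_spec}: data.frame(chain_id,
#'   residue_index, residue_name, dsasa) of interfacial residues, the full
#'   per-residue Delta-SASA table, and the threshold.
#' @export
find_interface_residues <- function(fr, top, threshold = 0.50, ...) {
  at <- top$atoms
  prot <- !is_water(top) & !is_ion(top)
  chains <- unique(at$chain_id[prot])
  if (length(chains) < 2L)
    stop("interface detection needs two protein chains; found ",
         length(chains))
  prot_idx <- which(prot)
  sasa_cx <- compute_sasa(fr, top, atoms = prot_idx, ...)
  rows <- list()
  for (ch in chains) {
    ch_idx <- which(prot & at$chain_id == ch)
    sasa_iso <- compute_sasa(fr, top, atoms = ch_idx, ...)
    res <- unique(at$residue_index[ch_idx])
    for (r in res) {
      aidx <- ch_idx[at$residue_index[ch_idx] == r]
      ds <- sum(sasa_iso$per_atom[aidx]) - sum(sasa_cx$per_atom[aidx])
      rows[[length(rows) + 1L]] <-
        data.frame(chain_id = ch, residue_index = r,
                   residue_name = at$residue_name[aidx[1L]], dsasa = ds)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(residues = tab[tab$dsasa > threshold, , drop = FALSE],
                 dsasa_table = tab, threshold = threshold),
            class = "interface_spec")
}

#' @export
print.interface_spec <- function(x, ...) {
  cat("Interface (Delta-SASA >", x$threshold, "A^2):", nrow(x$residues),
      "residue(s)\n")
  if (nrow(x$residues)) print(x$residues, row.names = FALSE)
  invisible(x)
}

#' Write an interface listing as delimited text
#' @param spec an \code{interface_spec}.
#' @param path output path.
#' @export
write_interface_report <- function(spec, path) {
  utils::write.table(spec$residues, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Center of mass of the interfacial residues
#'
#' Mass-weighted centroid over all atoms of the interfacial residues. When
#' the topology has no masses (PDB skeleton), a standard element-mass table
#' is used.
#'
#' @param fr a \code{\link{frame}}.
#' @param top its \code{\link{topology}}.
#' @param interface an \code{interface_spec} from
#'   \code{\link{find_interface_residues}}.
#' @return length-3 numeric vector, Angstrom.
#' @export
interface_com <- function(fr, top, interface) {
  res <- interface$residues
  if (!nrow(res)) stop("empty interface")
  at <- top$atoms
  sel <- which(paste(at$chain_id, at$residue_index) %in%
               paste(res$chain_id, res$residue_index))
  m <- atom_masses(top)[sel]
  colSums(fr$xyz[sel, , drop = FALSE] * m) / sum(m)
}

atom_masses <- function(top) {
  m <- top$atoms$mass
  if (all(!is.na(m))) return(m)
  ref <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, F = 18.998, CL = 35.45, NA. = 22.990, K = 39.098,
           MG = 24.305)
  el <- toupper(top$atoms$element)
  el[el == "NA"] <- "NA."
  fallback <- unname(ref[el])
  if (anyNA(fallback) && anyNA(m))
    stop("no mass for element '",
         top$atoms$element[which(is.na(m) & is.na(fallback))[1]], "'")
  ifelse(is.na(m), fallback, m)
}

#' Select the waters closest to the interface center of mass
#'
#' Water molecules are ranked by the distance from their oxygen (or the
#' water center of mass) to \code{com}; the \code{n} closest are retained.
#' Distance ties break on the lower water molecule index, so the selection
#' does not depend on input order.
#'
#' @param fr a \code{\link{frame}}.
#' @param top its \code{\link{topology}}.
#' @param com interface center of mass, length-3, Angstrom.
#' @param n number of waters to retain (30 in the reference protocol).
#' @param measure \code{"oxygen"} (default; for 3-site water the oxygen sits
#'   at the center of mass to good approximation) or \code{"com"}.
#' @return list: \code{water_residues} (retained water residue indices,
#'   sorted by distance), \code{atoms} (their atom indices),
#'   \code{distances}, \code{com}, \code{n_requested}.
#' @export
select_closest_waters <- function(fr, top, com, n = 30,
                                  measure = c("oxygen", "com")) {
  measure <- match.arg(measure)
  wat <- which(is_water(top))
  if (!length(wat)) stop("topology contains no water")
  at <- top$atoms
  wres <- unique(at$residue_index[wat])
  pos <- t(vapply(wres, function(r) {
    idx <- wat[at$residue_index[wat] == r]
    if (measure == "oxygen") {
      ox <- idx[toupper(substr(at$element[idx], 1, 1)) == "O"]
      if (length(ox)) return(fr$xyz[ox[1L], ])
    }
    m <- atom_masses(top)[idx]
    colSums(fr$xyz[idx, , drop = FALSE] * m) / sum(m)
  }, numeric(3)))
  d <- sqrt(colSums((t(pos) - com)^2))
  if (length(wres) < n) {
    warning("only ", length(wres), " waters present; retaining all")
    n <- length(wres)
  }
  ord <- order(d, wres)            # distance, then molecule index
  keep <- ord[seq_len(n)]
  list(water_residues = wres[keep],
       atoms = wat[at$residue_index[wat] %in% wres[keep]],
       distances = d[keep], com = com, n_requested = n)
}

#' Partition a complex into receptor and ligand atom sets
#'
#' The ligand is one protein chain (by default chain B, the chain
#' renumbered after chain A, i.e. the smaller partner under the standard
#' preparation convention); the receptor is the other chain plus any
#' retained interfacial waters. Ions must already be stripped. Retained
#' waters are always assigned to the receptor: assigning them to the
#' ligand is known to inflate frame-to-frame scatter without improving
#' ranking.
#'
#' @param top a \code{\link{topology}} with two protein chains.
#' @param ligand_chain chain label of the ligand.
#' @param retained_waters optional water selection from
#'   \code{\link{select_closest_waters}} (or a list of them, one per frame).
#' @return object of class \code{system_partition}: \code{receptor_core},
#'   \code{ligand} (atom index vectors), \code{water_atoms} (atom indices or
#'   per-frame list, possibly empty), and accessors via
#'   \code{\link{partition_atoms}}.
#' @export
partition_system <- function(top, ligand_chain = "B",
                             retained_waters = NULL) {
  at <- top$atoms
  prot <- !is_water(top) & !is_ion(top)
  chains <- unique(at$chain_id[prot])
  if (!(ligand_chain %in% chains))
    stop("ligand chain '", ligand_chain, "' not present (chains: ",
         paste(chains, collapse = ", "), ")")
  lig <- which(prot & at$chain_id == ligand_chain)
  rec <- which(prot & at$chain_id != ligand_chain)
  waters <- NULL
  per_frame <- FALSE
  if (!is.null(retained_waters)) {
    if (!is.null(retained_waters$atoms)) {
      waters <- retained_waters$atoms
    } else {
      per_frame <- TRUE
      waters <- lapply(retained_waters, `[[`, "atoms")
    }
  }
  structure(list(receptor_core = rec, ligand = lig, water_atoms = waters,
                 per_frame_waters = per_frame, ligand_chain = ligand_chain),
            class = "system_partition")
}

#' Atom index sets of complex/receptor/ligand for one frame
#' @param part a \code{system_partition}.
#' @param frame_i frame number (used when waters are selected per frame).
#' @return list(complex, receptor, ligand) of sorted atom index vectors;
#'   receptor and ligand are disjoint and their union is the complex.
#' @export
partition_atoms <- function(part, frame_i = 1L) {
  w <- part$water_atoms
  if (part$per_frame_waters) w <- w[[frame_i]]
  receptor <- sort(c(part$receptor_core, w))
  list(complex = sort(c(receptor, part$ligand)), receptor = receptor,
       ligand = sort(part$ligand))
}
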