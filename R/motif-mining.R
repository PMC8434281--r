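# Detection of zinc coordination sites and CXXHX motifs, plus the
# alpha-turn and unique-sequence filters applied to the mined set.

#' Find zinc coordination sites in a structure
#'
#' One site is reported per zinc ion having at least one protein or water
#' ligand within the coordination cutoff; ligands are sorted by distance
#' and classified by donor type (Cys S-gamma, His ring N, carboxylate O,
#' backbone O, water, other).
#'
#' @param s a \code{zt_structure}
#' @param cutoff heavy-atom coordination cutoff in Angstrom (default 3.0,
#'   which covers the survey's mean S-Zn 2.34 A and N-Zn 2.1 A bond
#'   lengths with margin)
#' @return list of zinc sites, each a list with \code{structure_id},
#'   \code{chain}, \code{zn_xyz} and a \code{ligands} data.frame
#'   (chain, resno, insert, resid, elety, type, dist)
#' @export
find_zinc_sites <- function(s, cutoff = 3.0) {
  stopifnot(cutoff > 1.5, cutoff < 3.5)
  at <- s$atoms
  zn_i <- which(at$resid == "ZN" | (at$elesy == "ZN" & at$het))
  sites <- list()
  for (zi in zn_i) {
    zn <- as.numeric(at[zi, c("x", "y", "z")])
    d <- sqrt((at$x - zn[1])^2 + (at$y - zn[2])^2 + (at$z - zn[3])^2)
    cand <- which(d <= cutoff & seq_len(nrow(at)) != zi &
                    !(at$resid == "ZN"))
    if (!length(cand)) next
    lig <- at[cand, c("chain", "resno", "insert", "resid", "elety"),
              drop = FALSE]
    lig$dist <- d[cand]
    lig$type <- mapply(function(resid, elety) {
      if (resid == "CYS" && elety == "SG") "cys_sg"
      else if (resid == "HIS" && elety %in% c("ND1", "NE2")) "his_n"
      else if (resid %in% c("ASP", "GLU") &&
               elety %in% c("OD1", "OD2", "OE1", "OE2")) "carboxylate_o"
      else if (elety == "O" && resid %in% c("HOH", "WAT")) "water"
      else if (elety == "O") "backbone_o"
      else "other"
    }, lig$resid, lig$elety)
    lig <- lig[order(lig$dist), , drop = FALSE]
    rownames(lig) <- NULL
    sites[[length(sites) + 1L]] <- list(structure_id = s$id,
                                        chain = at$chain[zi],
                                        zn_xyz = zn, ligands = lig)
  }
  sites
}

#' Find zinc-coordinated C-X1-X2-H-X3 motifs
#'
#' A motif is emitted when a Cys at position i and a His at position i+3
#' are consecutive in author numbering on one chain (all of i..i+4 present,
#' no insertion codes inside the window) and the Cys S-gamma plus one His
#' ring nitrogen coordinate the same zinc.  The His binding atom is the
#' ring nitrogen closer to the zinc; if the two ring nitrogens are within
#' 0.1 A of each other the motif is flagged ambiguous.
#'
#' @param s a \code{zt_structure}
#' @param sites zinc sites from \code{\link{find_zinc_sites}} (defaults to
#'   mining them from \code{s})
#' @param chains optional chain allowlist
#' @return list of motifs of class \code{zt_motif}
#' @export
find_cxxhx_motifs <- function(s, sites = find_zinc_sites(s), chains = NULL) {
  motifs <- list()
  for (site in sites) {
    lig <- site$ligands
    cys_lig <- lig[lig$type == "cys_sg", , drop = FALSE]
    for (ci in seq_len(nrow(cys_lig))) {
      chain <- cys_lig$chain[ci]
      if (!is.null(chains) && !(chain %in% chains)) next
      i0 <- cys_lig$resno[ci]
      if (cys_lig$insert[ci] != "") next
      window <- i0:(i0 + 4L)
      resn <- vapply(window, function(r) residue_name(s, chain, r),
                     character(1))
      if (any(is.na(resn))) {
        next
      }
      cres <- chain_residues(s, chain)
      if (any(cres$insert[cres$resno %in% window] != "")) {
        warning("motif window ", s$id, " ", chain, " ", i0,
                " skipped: insertion codes inside window")
        next
      }
      if (resn[4] != "HIS") next
      his_no <- i0 + 3L
      his_lig <- lig[lig$type == "his_n" & lig$chain == chain &
                       lig$resno == his_no, , drop = FALSE]
      if (!nrow(his_lig)) next
      nd1 <- atom_xyz(s, chain, his_no, "ND1")
      ne2 <- atom_xyz(s, chain, his_no, "NE2")
      dd <- c(ND1 = if (is.null(nd1)) Inf else
        sqrt(sum((nd1 - site$zn_xyz)^2)),
        NE2 = if (is.null(ne2)) Inf else sqrt(sum((ne2 - site$zn_xyz)^2)))
      his_atom <- names(dd)[which.min(dd)]
      ambiguous <- is.finite(dd[1]) && is.finite(dd[2]) &&
        abs(dd[1] - dd[2]) < 0.1
      ca_i <- atom_xyz(s, chain, i0, "CA")
      ca_i4 <- atom_xyz(s, chain, i0 + 4L, "CA")
      if (is.null(ca_i) || is.null(ca_i4)) next
      seq5 <- paste(vapply(resn, function(r)
        if (r %in% names(.aa1)) .aa1[[r]] else "X", character(1)),
        collapse = "")
      m <- structure(list(
        structure_id = s$id, chain = chain, start = i0,
        sequence = seq5, his_binding_atom = his_atom,
        ambiguous_tautomer = ambiguous,
        s_zn_distance = cys_lig$dist[ci],
        n_zn_distance = unname(min(dd)),
        ca_distance_i_i4 = sqrt(sum((ca_i4 - ca_i)^2)),
        zn_xyz = site$zn_xyz), class = "zt_motif")
      m$hbond_i_i4 <- hbond_i_i4(m, s)
      motifs[[length(motifs) + 1L]] <- m
    }
  }
  motifs
}

#' @export
print.zt_motif <- function(x, ...) {
  cat(sprintf("<zt_motif> %s_%s %d-%d %s (His %s, S-Zn %.2f A, Ca(i)-Ca(i+4) %.2f A)\n",
              x$structure_id, x$chain, x$start, x$start + 4L, x$sequence,
              x$his_binding_atom, x$s_zn_distance, x$ca_distance_i_i4))
  invisible(x)
}

#' Alpha-turn filter on the Ca(i)-Ca(i+4) distance
#'
#' @param m a \code{zt_motif}
#' @param max_ca maximum Ca(i)-Ca(i+4) distance in Angstrom (boundary
#'   inclusive; the survey's criterion is 7 A)
#' @return logical
#' @export
alpha_turn_filter <- function(m, max_ca = 7.0) {
  if (is.null(m$ca_distance_i_i4) || !is.finite(m$ca_distance_i_i4))
    stop("alpha_turn_filter: missing C-alpha distance for motif at ",
         m$structure_id, " ", m$chain, " ", m$start)
  m$ca_distance_i_i4 <= max_ca
}

#' Collapse motifs to unique five-residue sequences
#'
#' One representative per distinct sequence string; the representative is
#' the lexicographically smallest (structure_id, chain, start) triple.
#'
#' @param motifs list of \code{zt_motif}
#' @return list of representative motifs
#' @export
deduplicate_sequences <- function(motifs) {
  if (!length(motifs)) return(motifs)
  key <- vapply(motifs, function(m)
    sprintf("%s\r%s\r%09d", m$structure_id, m$chain, m$start), character(1))
  seqs <- vapply(motifs, function(m) m$sequence, character(1))
  ord <- order(seqs, key)
  motifs <- motifs[ord]
  motifs[!duplicated(seqs[ord])]
}

#' Tabulate mined motifs
#'
#' @param motifs list of \code{zt_motif}
#' @return data.frame, one row per motif
#' @export
motif_table <- function(motifs) {
  if (!length(motifs))
    return(data.frame(structure_id = character(), chain = character(),
                      start = integer(), sequence = character(),
                      his_atom = character(), s_zn = numeric(),
                      n_zn = numeric(), ca_i_i4 = numeric(),
                      hbond = logical()))
  do.call(rbind, lapply(motifs, function(m)
    data.frame(structure_id = m$structure_id, chain = m$chain,
               start = m$start, sequence = m$sequence,
               his_atom = m$his_binding_atom, s_zn = m$s_zn_distance,
               n_zn = m$n_zn_distance, ca_i_i4 = m$ca_distance_i_i4,
               hbond = m$hbond_i_i4, stringsAsFactors = FALSE)))
}
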