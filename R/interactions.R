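#' Non-covalent interaction detection
#'
#' Distance-only detectors for the contact classes used in structure
#' narratives and LigPlot-style schematics: polar contacts (hydrogen
#' bonds/electrostatics, not distinguished), hydrophobic carbon-carbon
#' contacts, metal coordination and water-mediated bridges.  Crystal
#' structures at typical resolutions carry no reliable hydrogens, so no
#' donor/acceptor angle term is applied; this over-calls somewhat relative
#' to geometry-aware definitions.  Default cutoffs: 3.4 A polar, 3.9 A
#' hydrophobic, 2.8 A metal inner sphere; all overridable.
#'
#' @name interactions
NULL

POLAR_ELEMENTS <- c("N", "O", "S")

# side-chain carbons not bonded to N/O in the standard amino-acid topology
APOLAR_CARBONS <- list(
  ALA = "CB", ARG = c("CB", "CG"), ASN = "CB", ASP = "CB", CYS = "CB",
  GLN = c("CB", "CG"), GLU = c("CB", "CG"), GLY = character(0),
  HIS = "CB", ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"), LYS = c("CB", "CG", "CD"),
  MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG"), SER = character(0), THR = "CG2",
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  VAL = c("CB", "CG1", "CG2"))

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

resolve_sel <- function(s, sel) {
  if (is.character(sel) && length(sel) == 1L) sel <- select_residues(s, sel)
  as.data.frame(sel)
}

atom_label <- function(a) paste0(a$chain, ":", a$resid, a$resno, "/", a$elety)

pair_records <- function(kind, A, B, d_max) {
  if (nrow(A) == 0L || nrow(B) == 0L) {
    warning("empty atom selection for ", kind, " detection")
    return(empty_records())
  }
  pa <- as.matrix(A[, c("x", "y", "z")])
  pb <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
    outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  hits <- which(d2 <= d_max^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty_records())
  i <- hits[, 1]; j <- hits[, 2]
  same_res <- A$chain[i] == B$chain[j] & A$resno[i] == B$resno[j] &
    A$insert[i] == B$insert[j]
  i <- i[!same_res]; j <- j[!same_res]
  if (length(i) == 0L) return(empty_records())
  out <- data.frame(kind = kind,
                    chain_a = A$chain[i], resno_a = A$resno[i],
                    resid_a = A$resid[i], atom_a = A$elety[i],
                    chain_b = B$chain[j], resno_b = B$resno[j],
                    resid_b = B$resid[j], atom_b = B$elety[j],
                    distance = sqrt(pmax(0, d2[cbind(i, j)])),
                    waters = "", stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}

empty_records <- function() {
  structure(data.frame(kind = character(0), chain_a = character(0),
                       resno_a = integer(0), resid_a = character(0),
                       atom_a = character(0), chain_b = character(0),
                       resno_b = integer(0), resid_b = character(0),
                       atom_b = character(0), distance = numeric(0),
                       waters = character(0), stringsAsFactors = FALSE),
            class = c("interaction_records", "data.frame"))
}

#' @export
print.interaction_records <- function(x, ...) {
  cat(sprintf("interaction_records: %d contact(s)\n", nrow(x)))
  if (nrow(x)) print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Polar contacts (hydrogen bonds / electrostatics)
#'
#' All N/O/S atom pairs across two disjoint residue selections within
#' `d_max`, excluding pairs within one residue, sorted by distance.
#'
#' @param s a [structure_model].
#' @param sel_a,sel_b residue selections: either selection strings (see
#'   [select_residues()]) or atom-table subsets.
#' @param d_max distance cutoff, Angstrom.
#' @return An `interaction_records` data frame.
#' @export
find_polar_contacts <- function(s, sel_a, sel_b, d_max = 3.4) {
  A <- resolve_sel(s, sel_a); B <- resolve_sel(s, sel_b)
  pair_records("hbond",
               A[A$elesy %in% POLAR_ELEMENTS, , drop = FALSE],
               B[B$elesy %in% POLAR_ELEMENTS, , drop = FALSE], d_max)
}

#' Hydrophobic carbon-carbon contacts
#'
#' Pairs of apolar carbons (side-chain carbons not bonded to N or O in the
#' residue's standard topology; all carbons except the backbone C for
#' non-standard residues) across two selections within `d_max`.
#'
#' @inheritParams find_polar_contacts
#' @export
find_hydrophobic_contacts <- function(s, sel_a, sel_b, d_max = 3.9) {
  apolar <- function(A) {
    known <- A$resid %in% names(APOLAR_CARBONS)
    ok <- logical(nrow(A))
    ok[known] <- mapply(function(r, e) e %in% APOLAR_CARBONS[[r]],
                        A$resid[known], A$elety[known])
    ok[!known] <- A$elesy[!known] == "C" & A$elety[!known] != "C"
    A[A$elesy == "C" & ok, , drop = FALSE]
  }
  A <- resolve_sel(s, sel_a); B <- resolve_sel(s, sel_b)
  out <- pair_records("hydrophobic", apolar(A), apolar(B), d_max)
  out
}

#' Metal coordination sphere
#'
#' N/O/S atoms — protein, water or ligand — within `d_max` of each metal
#' matching `metal`.  Each coordinating atom yields one record, so a
#' bidentate carboxylate appears as two records.
#'
#' @param s a [structure_model].
#' @param metal hetero selector (residue name or element), e.g. `"ZN"`.
#' @param d_max inner-sphere cutoff, Angstrom.
#' @param chain optional chain restriction for the metal.
#' @return An `interaction_records` data frame (kind `"metal"`), metal on
#'   the `a` side, ordered by coordinating residue then distance.
#' @export
find_metal_coordination <- function(s, metal = "ZN", d_max = 2.8,
                                    chain = NULL) {
  M <- hetero_atoms(s, metal, chain)
  if (nrow(M) == 0L) stop("no hetero atom matches selector '", metal, "'")
  a <- s$atom
  partners <- a[a$elesy %in% POLAR_ELEMENTS, , drop = FALSE]
  out <- pair_records("metal", M, partners, d_max)
  out <- out[order(out$chain_b, out$resno_b, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Water-mediated polar bridges
#'
#' Breadth-first search over the polar-contact graph from selection A
#' through up to `max_waters` ordered waters to selection B; every link
#' (atom-water and water-water) must be within `d_max`.  The shortest
#' bridge (fewest waters, then shortest total path length) is reported per
#' residue pair.
#'
#' @inheritParams find_polar_contacts
#' @param max_waters maximum number of bridging waters.
#' @return `interaction_records` with kind `"water_bridge"`; `distance` is
#'   the summed path length and `waters` the ordered water residue numbers
#'   (comma-separated).
#' @export
find_water_bridges <- function(s, sel_a, sel_b, d_max = 3.4, max_waters = 3) {
  A <- resolve_sel(s, sel_a); B <- resolve_sel(s, sel_b)
  A <- A[A$elesy %in% POLAR_ELEMENTS, , drop = FALSE]
  B <- B[B$elesy %in% POLAR_ELEMENTS, , drop = FALSE]
  w <- s$atom[s$atom$resid %in% WATER_NAMES & s$atom$elesy == "O", ,
              drop = FALSE]
  if (nrow(A) == 0L || nrow(B) == 0L || nrow(w) == 0L) return(empty_records())
  wxyz <- as.matrix(w[, c("x", "y", "z")])
  dmat <- function(P, Q) {
    d2 <- outer(unname(rowSums(P^2)), rep(1, nrow(Q))) +
      outer(rep(1, nrow(P)), unname(rowSums(Q^2))) - 2 * P %*% t(Q)
    d2[d2 < 0] <- 0
    sqrt(d2)
  }
  dAw <- dmat(as.matrix(A[, c("x", "y", "z")]), wxyz)
  dBw <- dmat(as.matrix(B[, c("x", "y", "z")]), wxyz)
  dww <- dmat(wxyz, wxyz)
  records <- list()
  res_a <- paste(A$chain, A$resno, A$insert)
  for (ra in unique(res_a)) {
    ai <- which(res_a == ra)
    # BFS frontier: water index, path, entry atom, accumulated length
    seen <- rep(FALSE, nrow(w))
    start <- which(apply(dAw[ai, , drop = FALSE] <= d_max, 2, any))
    frontier <- lapply(start, function(wi) {
      k <- ai[which.min(dAw[ai, wi])]
      list(wi = wi, path = wi, a_atom = k, len = min(dAw[ai, wi]))
    })
    seen[start] <- TRUE
    depth <- 1L
    while (length(frontier)) {
      for (node in frontier) {
        hits <- which(dBw[, node$wi] <= d_max)
        for (bi in hits) {
          records[[length(records) + 1L]] <- list(
            a = node$a_atom, b = bi, path = node$path,
            len = node$len + sum_path(dww, node$path) + dBw[bi, node$wi])
        }
      }
      if (depth >= max_waters) break
      nxt <- list()
      for (node in frontier) {
        nbr <- which(dww[node$wi, ] <= d_max & !seen)
        for (wi in nbr) {
          seen[wi] <- TRUE
          nxt[[length(nxt) + 1L]] <- list(wi = wi, path = c(node$path, wi),
                                          a_atom = node$a_atom, len = node$len)
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
  }
  if (length(records) == 0L) return(empty_records())
  out <- do.call(rbind, lapply(records, function(r) {
    data.frame(kind = "water_bridge",
               chain_a = A$chain[r$a], resno_a = A$resno[r$a],
               resid_a = A$resid[r$a], atom_a = A$elety[r$a],
               chain_b = B$chain[r$b], resno_b = B$resno[r$b],
               resid_b = B$resid[r$b], atom_b = B$elety[r$b],
               distance = r$len,
               waters = paste(w$resno[r$path], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out$n_waters <- lengths(strsplit(out$waters, ","))
  key <- paste(out$chain_a, out$resno_a, out$chain_b, out$resno_b)
  out <- out[order(key, out$n_waters, out$distance), , drop = FALSE]
  out <- out[!duplicated(paste(out$chain_a, out$resno_a, out$chain_b,
                               out$resno_b)), , drop = FALSE]
  out$n_waters <- NULL
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}

sum_path <- function(dww, path) {
  if (length(path) < 2L) return(0)
  sum(dww[cbind(path[-length(path)], path[-1])])
}

#' Per-residue interface fingerprint
#'
#' For each polymer residue of a peptide chain, all polar, hydrophobic,
#' metal-mediated and water-bridged contacts against a receptor chain
#' (LigPlot-style), with non-interacting residues listed explicitly.
#'
#' @param s a [structure_model] containing both chains.
#' @param peptide_chain,receptor_chain chain identifiers.
#' @param d_polar,d_hydrophobic,d_metal cutoffs, Angstrom.
#' @param max_waters bridging-water limit.
#' @return Class `interface_fingerprint`: list with `records` (all
#'   contacts, peptide side `a`), `by_residue` (per-peptide-residue record
#'   counts by kind) and `silent` (peptide residue numbers with no
#'   contacts).
#' @export
interface_fingerprint <- function(s, peptide_chain, receptor_chain,
                                  d_polar = 3.4, d_hydrophobic = 3.9,
                                  d_metal = 2.8, max_waters = 3) {
  chains <- structure_chains(s, polymer = TRUE)
  for (ch in c(peptide_chain, receptor_chain))
    if (!ch %in% chains) stop("no polymer chain '", ch, "' in ", s$id)
  a <- s$atom
  pep <- a[a$chain == peptide_chain & a$record == "ATOM", , drop = FALSE]
  rec <- a[a$chain == receptor_chain & a$record == "ATOM", , drop = FALSE]
  res <- list(suppressWarnings(find_polar_contacts(s, pep, rec, d_polar)),
              suppressWarnings(find_hydrophobic_contacts(s, pep, rec,
                                                         d_hydrophobic)),
              suppressWarnings(find_water_bridges(s, pep, rec, d_polar,
                                                  max_waters)))
  metals <- a[a$record == "HETATM" &
                a$elesy %in% c("ZN", "CA", "MG", "MN", "FE", "CU", "NI", "CO") &
                !a$resid %in% WATER_NAMES, , drop = FALSE]
  if (nrow(metals)) {
    m <- pair_records("metal", pep[pep$elesy %in% POLAR_ELEMENTS, ,
                                   drop = FALSE], metals, d_metal)
    res[[length(res) + 1L]] <- m
  }
  records <- do.call(rbind, lapply(res, as.data.frame))
  class(records) <- c("interaction_records", "data.frame")
  pres <- sort(unique(pep$resno))
  counts <- table(factor(records$resno_a, levels = pres), records$kind)
  silent <- pres[rowSums(counts) == 0]
  structure(list(records = records,
                 by_residue = as.data.frame.matrix(counts),
                 silent = silent,
                 peptide_chain = peptide_chain,
                 receptor_chain = receptor_chain),
            class = "interface_fingerprint")
}

#' @export
print.interface_fingerprint <- function(x, ...) {
  cat(sprintf("interface_fingerprint: chain %s vs chain %s, %d contact(s)\n",
              x$peptide_chain, x$receptor_chain, nrow(x$records)))
  print(x$by_residue)
  if (length(x$silent))
    cat("non-interacting peptide residues:",
        paste(x$silent, collapse = ", "), "\n")
  invisible(x)
}
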