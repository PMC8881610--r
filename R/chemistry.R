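## interaction chemistry rule table: donors/acceptors, charged groups,
## aromatic rings, apolar atoms for the 20 standard residues + Aib

# side-chain rules; backbone N (donor, antecedent CA; not PRO) and O/OXT
# (acceptors, antecedent C) are added for every amino residue
.SIDECHAIN_RULES <- list(
  ARG = list(don = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
             cation = list(atoms = c("NH1", "NH2", "NE", "CZ"),
                           charged = c("NE", "NH1", "NH2")),
             apolar = c("CB", "CG")),
  LYS = list(don = c(NZ = "CE"),
             cation = list(atoms = "NZ", charged = "NZ"),
             apolar = c("CB", "CG", "CD")),
  HIS = list(don = c(ND1 = "CG", NE2 = "CE1"), acc = c(ND1 = "CG", NE2 = "CE1"),
             cation = list(atoms = c("ND1", "NE2"), charged = c("ND1", "NE2")),
             rings = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
             apolar = "CB"),
  ASP = list(acc = c(OD1 = "CG", OD2 = "CG"),
             anion = list(atoms = c("CG", "OD1", "OD2"),
                          charged = c("OD1", "OD2")),
             apolar = "CB"),
  GLU = list(acc = c(OE1 = "CD", OE2 = "CD"),
             anion = list(atoms = c("CD", "OE1", "OE2"),
                          charged = c("OE1", "OE2")),
             apolar = c("CB", "CG")),
  ASN = list(don = c(ND2 = "CG"), acc = c(OD1 = "CG"), apolar = "CB"),
  GLN = list(don = c(NE2 = "CD"), acc = c(OE1 = "CD"), apolar = c("CB", "CG")),
  SER = list(don = c(OG = "CB"), acc = c(OG = "CB")),
  THR = list(don = c(OG1 = "CB"), acc = c(OG1 = "CB"), apolar = "CG2"),
  TYR = list(don = c(OH = "CZ"), acc = c(OH = "CZ"),
             rings = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
             apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2")),
  TRP = list(don = c(NE1 = "CD1"),
             rings = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                          c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
             apolar = c("CB", "CG", "CD1", "CD2", "CE2", "CE3",
                        "CZ2", "CZ3", "CH2")),
  PHE = list(rings = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
             apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  CYS = list(apolar = c("CB", "SG")),
  MET = list(apolar = c("CB", "CG", "SD", "CE")),
  ALA = list(apolar = "CB"),
  VAL = list(apolar = c("CB", "CG1", "CG2")),
  LEU = list(apolar = c("CB", "CG", "CD1", "CD2")),
  ILE = list(apolar = c("CB", "CG1", "CG2", "CD1")),
  PRO = list(apolar = c("CB", "CG", "CD")),
  GLY = list(),
  # alpha-aminoisobutyric acid: backbone donor/acceptor only, two
  # hydrophobic side-chain methyl carbons
  AIB = list(apolar = c("CB1", "CB2"))
)

.AMINO_RESID <- c(names(.SIDECHAIN_RULES))

#' Assign interaction chemistry to a model
#'
#' Builds the donor/acceptor, charged-group, aromatic-ring and
#' apolar-atom sets needed by [detectContacts()]. The 20 standard
#' residues plus Aib are covered by an explicit rule table; residues
#' not in the table (lipid tails, gamma-Glu/OEG linker components,
#' modified lysines) fall back to element rules: carbons and sulfurs
#' are classed hydrophobic, nitrogens and oxygens donor-and-acceptor
#' (with a geometric antecedent: the nearest heavy atom of the same
#' residue). Unknown residues are logged, never dropped.
#'
#' @param model a [StructureModel-class].
#' @return A [ChemistryAssignment-class].
#' @export
assignChemistry <- function(model) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  a <- a[a$element != "H", , drop = FALSE]
  donors <- list(); acceptors <- list(); apolar <- list()
  cations <- list(); anions <- list(); rings <- list()
  unknownSeen <- character()
  for (rk in unique(.residKey(a))) {
    res <- a[.residKey(a) == rk, , drop = FALSE]
    resid <- res$resid[1]
    xyzOf <- function(atom) {
      i <- match(atom, res$elety)
      if (is.na(i)) NULL else as.numeric(res[i, c("x", "y", "z")])
    }
    base <- res[1, c("chain", "resno", "insert", "resid", "label")]
    addAtom <- function(pool, atom, antecedent) {
      p <- xyzOf(atom); if (is.null(p)) return(pool)
      q <- if (!is.na(antecedent)) xyzOf(antecedent) else NULL
      row <- cbind(base, data.frame(atom = atom, x = p[1], y = p[2], z = p[3],
        ax = if (is.null(q)) NA_real_ else q[1],
        ay = if (is.null(q)) NA_real_ else q[2],
        az = if (is.null(q)) NA_real_ else q[3]))
      c(pool, list(row))
    }
    rules <- .SIDECHAIN_RULES[[resid]]
    if (!is.null(rules) || resid %in% .AMINO_RESID) {
      # backbone
      if (resid != "PRO") donors <- addAtom(donors, "N", "CA")
      acceptors <- addAtom(acceptors, "O", "C")
      acceptors <- addAtom(acceptors, "OXT", "C")
      for (d in names(rules$don)) donors <- addAtom(donors, d, rules$don[[d]])
      for (ac in names(rules$acc))
        acceptors <- addAtom(acceptors, ac, rules$acc[[ac]])
      for (ap in rules$apolar) apolar <- addAtom(apolar, ap, NA)
      if (!is.null(rules$cation)) {
        present <- intersect(rules$cation$charged, res$elety)
        if (length(present)) {
          xyz <- as.matrix(res[match(present, res$elety), c("x", "y", "z")])
          cations[[length(cations) + 1L]] <- list(
            key = base, atoms = intersect(rules$cation$atoms, res$elety),
            charged = present, center = colMeans(xyz))
        }
      }
      if (!is.null(rules$anion)) {
        present <- intersect(rules$anion$charged, res$elety)
        if (length(present))
          anions[[length(anions) + 1L]] <- list(
            key = base, atoms = intersect(rules$anion$atoms, res$elety),
            charged = present)
      }
      for (ringAtoms in rules$rings) {
        present <- intersect(ringAtoms, res$elety)
        if (length(present) == length(ringAtoms)) {
          xyz <- as.matrix(res[match(present, res$elety), c("x", "y", "z")])
          cen <- colMeans(xyz)
          sv <- svd(sweep(xyz, 2, cen))
          rings[[length(rings) + 1L]] <- list(
            key = base, atoms = present, centroid = cen,
            normal = sv$v[, 3] / sqrt(sum(sv$v[, 3]^2)))
        }
      }
      # C-terminal carboxylate behaves as an anionic group
      if (all(c("O", "OXT") %in% res$elety))
        anions[[length(anions) + 1L]] <- list(
          key = base, atoms = c("C", "O", "OXT"), charged = c("O", "OXT"))
    } else {
      unknownSeen <- c(unknownSeen, resid)
      for (i in seq_len(nrow(res))) {
        ele <- res$element[i]; atom <- res$elety[i]
        if (ele %in% c("C", "S")) {
          apolar <- addAtom(apolar, atom, NA)
        } else if (ele %in% c("N", "O")) {
          d <- sqrt((res$x - res$x[i])^2 + (res$y - res$y[i])^2 +
                      (res$z - res$z[i])^2)
          d[i] <- Inf
          ante <- if (any(d < 2.0)) res$elety[which.min(d)] else NA_character_
          donors <- addAtom(donors, atom, ante)
          acceptors <- addAtom(acceptors, atom, ante)
        }
      }
    }
  }
  if (length(unknownSeen))
    message("element-based chemistry for nonstandard residue(s): ",
            paste(unique(unknownSeen), collapse = ", "))
  bindPool <- function(pool) {
    if (!length(pool)) return(data.frame())
    out <- do.call(rbind, pool); rownames(out) <- NULL; out
  }
  new("ChemistryAssignment",
      donors = bindPool(donors), acceptors = bindPool(acceptors),
      cations = cations, anions = anions, rings = rings,
      apolar = bindPool(apolar))
}

setMethod("show", "ChemistryAssignment", function(object) {
  cat("ChemistryAssignment:", nrow(object@donors), "donors,",
      nrow(object@acceptors), "acceptors,", length(object@cations),
      "cationic groups,", length(object@anions), "anionic groups,",
      length(object@rings), "aromatic rings,", nrow(object@apolar),
      "apolar atoms\n")
  invisible(object)
})
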