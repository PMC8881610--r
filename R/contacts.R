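## interactions: geometric contact detection, typing and precedence

.TYPE_PRECEDENCE <- c(salt_bridge = 1, hbond = 2, cation_pi = 3, pi_pi = 4,
                      hydrophobic = 5)

#' Geometric criteria for contact detection
#'
#' Heavy-atom criteria (deposited cryo-EM models lack hydrogens):
#' hydrogen bond = donor-heavy to acceptor-heavy distance <=
#' `hbondDistMax` and angle(antecedent, donor, acceptor) >=
#' `hbondAngleMin`; salt bridge = charged N to charged O <=
#' `saltDistMax`; hydrophobic = apolar C/S pair <= `hydrophobicDistMax`
#' (reported once per residue pair); pi-pi = ring centroid distance <=
#' `piDistMax` with inter-normal angle <= `piParallelMax` (parallel) or
#' within `[piTshapedMin, piTshapedMax]` (T-shaped); cation-pi =
#' cationic-group center to ring centroid <= `cationPiDistMax`.
#' All distances Angstrom, angles degrees.
#'
#' @param hbondDistMax,hbondAngleMin,saltDistMax,hydrophobicDistMax
#'   scalar cutoffs (see Description).
#' @param piDistMax,piParallelMax,piTshapedMin,piTshapedMax scalar
#'   cutoffs (see Description).
#' @param cationPiDistMax scalar cutoff (see Description).
#' @return Named list of criteria.
#' @export
contactCriteria <- function(hbondDistMax = 3.5, hbondAngleMin = 90,
                            saltDistMax = 4.0, hydrophobicDistMax = 4.5,
                            piDistMax = 5.5, piParallelMax = 30,
                            piTshapedMin = 60, piTshapedMax = 90,
                            cationPiDistMax = 6.0) {
  as.list(environment())
}

.emptyContacts <- function() {
  data.frame(type = character(), pep_chain = character(),
             pep_resno = integer(), pep_resid = character(),
             pep_label = character(), pep_atom = character(),
             rec_chain = character(), rec_resno = integer(),
             rec_resid = character(), rec_label = character(),
             rec_atom = character(), distance = numeric(),
             geometry = character(), dominant = logical(),
             stringsAsFactors = FALSE)
}

.contactRow <- function(type, pk, pAtom, rk, rAtom, distance, geometry = "") {
  data.frame(type = type,
             pep_chain = pk$chain, pep_resno = pk$resno, pep_resid = pk$resid,
             pep_label = ifelse(is.na(pk$label), "", pk$label),
             pep_atom = pAtom,
             rec_chain = rk$chain, rec_resno = rk$resno, rec_resid = rk$resid,
             rec_label = ifelse(is.na(rk$label), "", rk$label),
             rec_atom = rAtom, distance = distance, geometry = geometry,
             stringsAsFactors = FALSE)
}

# hydrogen bonds from donors of `chemD` to acceptors of `chemA`;
# swap=TRUE means the donor side is the receptor
.hbondPairs <- function(chemD, chemA, crit, swap) {
  don <- chemD@donors; acc <- chemA@acceptors
  if (!nrow(don) || !nrow(acc)) return(NULL)
  out <- list()
  for (i in seq_len(nrow(don))) {
    dx <- c(don$x[i], don$y[i], don$z[i])
    d <- sqrt((acc$x - dx[1])^2 + (acc$y - dx[2])^2 + (acc$z - dx[3])^2)
    hits <- which(d > 0 & d <= crit$hbondDistMax)
    for (j in hits) {
      ang <- NA_real_
      if (!is.na(don$ax[i])) {
        v1 <- c(don$ax[i], don$ay[i], don$az[i]) - dx
        v2 <- c(acc$x[j], acc$y[j], acc$z[j]) - dx
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      }
      if (!is.na(ang) && ang < crit$hbondAngleMin) next
      pk <- if (swap) acc[j, ] else don[i, ]
      rk <- if (swap) don[i, ] else acc[j, ]
      out[[length(out) + 1L]] <- .contactRow("hbond", pk,
        if (swap) acc$atom[j] else don$atom[i], rk,
        if (swap) don$atom[i] else acc$atom[j], d[j],
        sprintf("donor=%s angle=%.1f",
                paste0(if (swap) "receptor" else "peptide", ":", don$atom[i]),
                ang))
    }
  }
  out
}

.saltPairs <- function(cations, anions, crit, swap) {
  out <- list()
  for (cg in cations) for (ag in anions) {
    # charged-atom coordinates live in the parent chemistry tables; each
    # group carries its residue key, so recover coords from the group lists
    dmin <- Inf; pair <- c("", "")
    for (ca in seq_along(cg$chargedXyz[, 1])) for (an in
         seq_along(ag$chargedXyz[, 1])) {
      dd <- sqrt(sum((cg$chargedXyz[ca, ] - ag$chargedXyz[an, ])^2))
      if (dd < dmin) { dmin <- dd; pair <- c(cg$charged[ca], ag$charged[an]) }
    }
    if (dmin <= crit$saltDistMax) {
      pk <- if (swap) ag$key else cg$key
      rk <- if (swap) cg$key else ag$key
      out[[length(out) + 1L]] <- .contactRow("salt_bridge", pk,
        if (swap) pair[2] else pair[1], rk,
        if (swap) pair[1] else pair[2], dmin,
        sprintf("%s...%s", pair[1], pair[2]))
    }
  }
  out
}

.hydrophobicPairs <- function(apP, apR, crit) {
  if (!nrow(apP) || !nrow(apR)) return(NULL)
  out <- list()
  keyP <- paste(apP$chain, apP$resno, apP$insert)
  keyR <- paste(apR$chain, apR$resno, apR$insert)
  for (rp in unique(keyP)) {
    P <- apP[keyP == rp, , drop = FALSE]
    for (rr in unique(keyR)) {
      R <- apR[keyR == rr, , drop = FALSE]
      d <- outer(seq_len(nrow(P)), seq_len(nrow(R)), function(i, j)
        sqrt((P$x[i] - R$x[j])^2 + (P$y[i] - R$y[j])^2 + (P$z[i] - R$z[j])^2))
      if (min(d) <= crit$hydrophobicDistMax) {
        w <- which(d == min(d), arr.ind = TRUE)[1, ]
        out[[length(out) + 1L]] <- .contactRow("hydrophobic", P[w[1], ],
          P$atom[w[1]], R[w[2], ], R$atom[w[2]], min(d),
          "residue-level (min atom pair)")
      }
    }
  }
  out
}

.piPairs <- function(ringsP, ringsR, crit) {
  out <- list()
  for (a in ringsP) for (b in ringsR) {
    d <- sqrt(sum((a$centroid - b$centroid)^2))
    if (d > crit$piDistMax) next
    ang <- acos(pmin(1, abs(sum(a$normal * b$normal)))) * 180 / pi
    parallel <- ang <= crit$piParallelMax
    tshaped <- ang >= crit$piTshapedMin & ang <= crit$piTshapedMax
    if (!parallel && !tshaped) next
    out[[length(out) + 1L]] <- .contactRow("pi_pi", a$key, "ring", b$key,
      "ring", d, sprintf("%s normal_angle=%.1f",
                         if (parallel) "parallel" else "T-shaped", ang))
  }
  out
}

.cationPiPairs <- function(cations, rings, crit, swap) {
  out <- list()
  for (cg in cations) for (rg in rings) {
    d <- sqrt(sum((cg$center - rg$centroid)^2))
    if (d > crit$cationPiDistMax) next
    pk <- if (swap) rg$key else cg$key
    rk <- if (swap) cg$key else rg$key
    out[[length(out) + 1L]] <- .contactRow("cation_pi", pk,
      if (swap) "ring" else "group", rk, if (swap) "group" else "ring", d,
      "cation-center to ring centroid")
  }
  out
}

#' Detect typed residue-residue interactions across an interface
#'
#' Tests every peptide-receptor residue pair against the geometric
#' criteria in [contactCriteria()]; each satisfied rule emits one
#' contact, so a pair may carry several types. Salt-bridge pairs that
#' also satisfy hydrogen-bond geometry through the same charged
#' groups are reported as salt bridge only (precedence rule). Lysine
#' "stacking" interactions are picked up as cation-pi when the
#' geometry qualifies, hydrophobic otherwise. A `dominant` flag marks,
#' per residue pair, the single highest-precedence contact
#' (salt_bridge > hbond > cation_pi > pi_pi > hydrophobic); the full
#' multi-label set is always retained.
#'
#' @param model a [StructureModel-class] holding both sides.
#' @param selPeptide,selReceptor selection expressions (or sub-models)
#'   for the two sides of the interface.
#' @param criteria see [contactCriteria()].
#' @return data.frame of contacts (zero rows when none) with columns
#'   type, peptide residue (chain/resno/resid/label/atom), receptor
#'   residue, distance (Angstrom), geometry, dominant.
#' @export
detectContacts <- function(model, selPeptide, selReceptor,
                           criteria = contactCriteria()) {
  pep <- .resolveSelection(model, selPeptide)
  rec <- .resolveSelection(model, selReceptor)
  if (length(pep) == 0L || length(rec) == 0L)
    stop("selection error: empty peptide or receptor selection")
  chemP <- assignChemistry(pep)
  chemR <- assignChemistry(rec)
  attachXyz <- function(groups, m) lapply(groups, function(g) {
    a <- m@atoms
    sel <- a$chain == g$key$chain & a$resno == g$key$resno &
      a$elety %in% g$charged
    g$chargedXyz <- as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
    g$charged <- a$elety[sel]
    g
  })
  catP <- attachXyz(chemP@cations, pep); anP <- attachXyz(chemP@anions, pep)
  catR <- attachXyz(chemR@cations, rec); anR <- attachXyz(chemR@anions, rec)
  rows <- c(.hbondPairs(chemP, chemR, criteria, swap = FALSE),
            .hbondPairs(chemR, chemP, criteria, swap = TRUE),
            .saltPairs(catP, anR, criteria, swap = FALSE),
            .saltPairs(catR, anP, criteria, swap = TRUE),
            .hydrophobicPairs(chemP@apolar, chemR@apolar, criteria),
            .piPairs(chemP@rings, chemR@rings, criteria),
            .cationPiPairs(catP, chemR@rings, criteria, swap = FALSE),
            .cationPiPairs(catR, chemP@rings, criteria, swap = TRUE))
  if (!length(rows)) return(.emptyContacts())
  ct <- do.call(rbind, rows)
  ct$insert <- NULL
  pairKey <- paste(ct$pep_chain, ct$pep_resno, ct$rec_chain, ct$rec_resno)
  # precedence: drop hbond rows riding on a salt bridge's charged groups
  drop <- rep(FALSE, nrow(ct))
  for (pkk in unique(pairKey[ct$type == "salt_bridge"])) {
    sb <- ct[pairKey == pkk & ct$type == "salt_bridge", ]
    sbAtoms <- unique(c(sb$pep_atom, sb$rec_atom))
    cand <- which(pairKey == pkk & ct$type == "hbond")
    # both partner heavy atoms belong to the salt-bridging charged groups
    chargedAtoms <- unique(unlist(c(
      lapply(c(catP, catR), function(g) g$charged),
      lapply(c(anP, anR), function(g) g$charged))))
    drop[cand[ct$pep_atom[cand] %in% chargedAtoms &
                ct$rec_atom[cand] %in% chargedAtoms]] <- TRUE
  }
  ct <- ct[!drop, , drop = FALSE]
  pairKey <- pairKey[!drop]
  # deterministic order + dominant flag per residue pair
  prec <- .TYPE_PRECEDENCE[ct$type]
  ord <- order(ct$pep_resno, ct$rec_resno, prec, ct$distance,
               ct$pep_atom, ct$rec_atom)
  ct <- ct[ord, , drop = FALSE]
  pairKey <- pairKey[ord]
  ct$dominant <- !duplicated(pairKey)
  rownames(ct) <- NULL
  ct
}
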