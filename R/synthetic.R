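## synthetic_data: toy structures and assay data with known ground truth

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a private RNG stream (no global RNG state leaks out)
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

.unit <- function(v) v / sqrt(sum(v^2))

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthonormal vector perpendicular to v (deterministic choice)
.anyPerp <- function(v) {
  v <- .unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(ref - sum(ref * v) * v)
}

#' Build an idealized peptide helix
#'
#' Places backbone (N, CA, C, O) plus pseudo-side-chains on a
#' parametric alpha-helix (C-alpha radius 2.3 A), emulating the
#' single continuous helix that class B receptor agonist peptides
#' adopt. Deterministic; consecutive C-alpha spacing is ~3.8 A and
#' the i,i+4 C-alpha distance ~6.2 A at the default rise/twist. Most
#' residues carry only a C-beta, but Lys/Arg/Asp/Glu/Phe/Tyr get
#' extended pseudo-side-chains (ammonium, guanidinium, carboxylate,
#' aromatic ring) pointing radially outward, so charged and aromatic
#' interaction chemistry can anchor on the peptide. Positions listed
#' in `aibPositions` are built as Aib (alpha-aminoisobutyric acid:
#' backbone plus two methyl carbons CB1/CB2), recorded as hetero
#' residues on the peptide chain. Geometry is idealized, not
#' stereochemically refined: sufficient for the geometric operators,
#' cheap to reason about.
#'
#' @param sequence one-letter amino-acid string (length >= 4).
#' @param rise helical rise per residue, Angstrom (default 1.5).
#' @param twist helical twist per residue, degrees (default 100).
#' @param chain chain id for the peptide (default "P").
#' @param aibPositions integer positions replaced by Aib.
#' @return A [StructureModel-class].
#' @export
buildIdealHelix <- function(sequence, rise = 1.5, twist = 100, chain = "P",
                            aibPositions = integer()) {
  letters1 <- strsplit(sequence, "")[[1]]
  if (length(letters1) < 4L)
    stop("sequence error: need at least 4 residues")
  unknown <- setdiff(letters1, names(.AA1TO3))
  if (length(unknown))
    stop("sequence error: unknown residue letter(s) ",
         paste(unique(unknown), collapse = ", "))
  n <- length(letters1)
  rCA <- 2.3
  th <- (seq_len(n) - 1) * twist * pi / 180
  zz <- (seq_len(n) - 1) * rise
  ca <- cbind(rCA * cos(th), rCA * sin(th), zz)
  caExt <- rbind(2 * ca[1, ] - ca[2, ], ca, 2 * ca[n, ] - ca[n - 1, ])
  rows <- list()
  for (i in seq_len(n)) {
    resid <- if (i %in% aibPositions) "AIB" else .AA1TO3[[letters1[i]]]
    het <- i %in% aibPositions
    # N and C between consecutive C-alphas, pulled toward the axis;
    # carbonyl O along the helix axis from C
    Ni <- ca[i, ] + 0.44 * (caExt[i, ] - ca[i, ]); Ni[1:2] <- Ni[1:2] * 0.82
    Ci <- ca[i, ] + 0.42 * (caExt[i + 2, ] - ca[i, ]); Ci[1:2] <- Ci[1:2] * 0.85
    Oi <- Ci + c(0, 0, -1.23)
    out <- .unit(c(ca[i, 1], ca[i, 2], 0))
    tang <- .unit(.cross(c(0, 0, 1), out))
    add <- function(elety, xyz, element = substr(elety, 1, 1))
      data.frame(chain = chain, resno = i, resid = resid, elety = elety,
                 element = element, x = xyz[1], y = xyz[2], z = xyz[3],
                 het = het, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- add("N", Ni)
    rows[[length(rows) + 1L]] <- add("CA", ca[i, ])
    rows[[length(rows) + 1L]] <- add("C", Ci)
    rows[[length(rows) + 1L]] <- add("O", Oi)
    s <- .unit(out + c(0, 0, 0.25))  # side-chain growth direction
    p <- tang
    cb <- ca[i, ] + 1.53 * s
    sideRows <- if (resid == "AIB") {
      list(add("CB1", ca[i, ] + 1.53 * .unit(out + c(0, 0, 0.45))),
           add("CB2", ca[i, ] + 1.53 * .unit(out + 0.6 * tang)))
    } else if (resid == "GLY") {
      list()
    } else if (resid == "LYS") {
      list(add("CB", cb), add("CG", cb + 1.3 * s), add("CD", cb + 2.6 * s),
           add("CE", cb + 3.9 * s), add("NZ", cb + 5.2 * s))
    } else if (resid == "ARG") {
      ne <- cb + 3.9 * s; cz <- ne + 1.33 * s
      list(add("CB", cb), add("CG", cb + 1.3 * s), add("CD", cb + 2.6 * s),
           add("NE", ne), add("CZ", cz),
           add("NH1", cz + 1.23 * .unit(s + 0.7 * p)),
           add("NH2", cz + 1.23 * .unit(s - 0.7 * p)))
    } else if (resid == "ASP") {
      cg <- cb + 1.45 * s
      list(add("CB", cb), add("CG", cg),
           add("OD1", cg + 1.25 * .unit(s + 0.7 * p)),
           add("OD2", cg + 1.25 * .unit(s - 0.7 * p)))
    } else if (resid == "GLU") {
      cd <- cb + 2.8 * s
      list(add("CB", cb), add("CG", cb + 1.4 * s), add("CD", cd),
           add("OE1", cd + 1.25 * .unit(s + 0.7 * p)),
           add("OE2", cd + 1.25 * .unit(s - 0.7 * p)))
    } else if (resid %in% c("PHE", "TYR")) {
      cg <- cb + 1.4 * s
      centroid <- cg + 1.39 * s
      vertex <- function(angleDeg)
        centroid + 1.39 * (cos(angleDeg * pi / 180) * (-s) +
                             sin(angleDeg * pi / 180) * p)
      ring <- list(add("CG", vertex(0)), add("CD1", vertex(60)),
                   add("CE1", vertex(120)), add("CZ", vertex(180)),
                   add("CE2", vertex(-120)), add("CD2", vertex(-60)))
      if (resid == "TYR")
        ring <- c(ring, list(add("OH", vertex(180) + 1.36 * s)))
      c(list(add("CB", cb)), ring)
    } else {
      list(add("CB", cb))
    }
    rows <- c(rows, sideRows)
  }
  .newStructureModel(do.call(rbind, rows), sourceId = "ideal-helix")
}

.plantMargins <- list(dist = 0.3, angle = 10)

# classify a planted geometry against the detection acceptance region:
# "inside" (satisfies the criteria with margin; goes into the manifest),
# "outside" (clear of the criteria by the same margin; negative control,
# empty manifest), or an error in the ambiguous boundary band
.regionStatus <- function(inside, outside, what) {
  if (inside) return("inside")
  if (outside) return("outside")
  stop("construction error: requested ", what, " geometry falls in the ",
       "ambiguous band around the detection cutoff (need >= ",
       .plantMargins$dist, " A / ", .plantMargins$angle, " deg margin)")
}

# choose, among azimuth candidates, the direction whose planted point
# maximizes the clearance from all atoms except the anchor residue
.bestDirection <- function(dirs, origin, d, modelAtoms, anchorResno) {
  others <- modelAtoms[modelAtoms$resno != anchorResno, , drop = FALSE]
  score <- vapply(seq_len(ncol(dirs)), function(k) {
    pt <- origin + d * dirs[, k]
    if (!nrow(others)) return(Inf)
    min(sqrt((others$x - pt[1])^2 + (others$y - pt[2])^2 +
               (others$z - pt[3])^2))
  }, 0)
  dirs[, which.max(score)]
}

.anchorRing <- function(res) {
  ringAtoms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  if (!all(ringAtoms %in% res$elety))
    stop("construction error: ring plant expects an aromatic anchor ",
         "(PHE/TYR) at the peptide residue")
  xyz <- as.matrix(res[match(ringAtoms, res$elety), c("x", "y", "z")])
  cen <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, cen))
  normal <- sv$v[, 3]
  if (sum(normal * c(cen[1], cen[2], 0)) < 0) normal <- -normal
  list(centroid = cen, normal = .unit(normal))
}

.plantGroup <- function(type, model, peptideResno, params, recResno,
                        recChain) {
  a <- model@atoms
  res <- a[a$resno == peptideResno & a$chain != recChain, , drop = FALSE]
  if (!nrow(res))
    stop("construction error: peptide residue ", peptideResno, " not found")
  xyzOf <- function(at) {
    i <- match(at, res$elety)
    if (is.na(i)) stop("construction error: anchor atom ", at, " missing on ",
                       res$resid[1], peptideResno)
    as.numeric(res[i, c("x", "y", "z")])
  }
  mk <- function(resid, elety, xyz, element = substr(elety, 1, 1))
    data.frame(chain = recChain, resno = recResno, resid = resid,
               elety = elety, element = element,
               x = xyz[1], y = xyz[2], z = xyz[3], het = FALSE,
               stringsAsFactors = FALSE)
  crit <- contactCriteria()
  m <- .plantMargins
  if (type == "hbond") {
    d <- params$distance %||% 2.9
    ang <- params$angle %||% 160
    status <- .regionStatus(
      d <= crit$hbondDistMax - m$dist && ang >= crit$hbondAngleMin + m$angle,
      d >= crit$hbondDistMax + m$dist || ang <= crit$hbondAngleMin - m$angle,
      "hbond")
    Nx <- xyzOf("N"); CAx <- xyzOf("CA")
    u <- .unit(CAx - Nx)
    perp1 <- .anyPerp(u); perp2 <- .unit(.cross(u, perp1))
    az <- seq(0, 2 * pi, length.out = 25)[-25]
    dirs <- vapply(az, function(phi)
      cos(ang * pi / 180) * u + sin(ang * pi / 180) *
        (cos(phi) * perp1 + sin(phi) * perp2), numeric(3))
    dir <- .bestDirection(dirs, Nx, d, a, peptideResno)
    og <- Nx + d * dir
    list(atoms = rbind(mk("GLY", "O", og, "O"),
                       mk("GLY", "C", og + 1.23 * dir, "C")),
         status = status)
  } else if (type == "salt_bridge") {
    d <- params$distance %||% 3.5
    status <- .regionStatus(d <= crit$saltDistMax - m$dist,
                            d >= crit$saltDistMax + m$dist, "salt bridge")
    nz <- xyzOf("NZ")  # plant expects a lysine anchor
    dir <- .unit(nz - xyzOf("CA"))
    od1 <- nz + d * dir
    cg <- od1 + 1.25 * dir
    od2 <- cg + 1.25 * .unit(dir + 0.8 * .anyPerp(dir))
    list(atoms = rbind(mk("ASP", "OD1", od1, "O"), mk("ASP", "CG", cg, "C"),
                       mk("ASP", "OD2", od2, "O")),
         status = status)
  } else if (type == "hydrophobic") {
    d <- params$distance %||% 4.0
    status <- .regionStatus(d <= crit$hydrophobicDistMax - m$dist,
                            d >= crit$hydrophobicDistMax + m$dist,
                            "hydrophobic")
    anchorAtom <- params$anchorAtom %||% "CB"
    cb <- xyzOf(anchorAtom)
    dir <- .unit(cb - xyzOf("CA"))
    cd1 <- cb + d * dir
    list(atoms = rbind(mk("LEU", "CD1", cd1, "C"),
                       mk("LEU", "CG", cd1 + 1.53 * dir, "C"),
                       mk("LEU", "CD2",
                          cd1 + 1.53 * .unit(dir + .anyPerp(dir)), "C"),
                       mk("LEU", "CB", cd1 + 2.9 * dir, "C")),
         status = status)
  } else if (type == "pi_pi") {
    d <- params$distance %||% 5.0
    nAng <- params$normalAngle %||% 0
    insidePar <- d <= crit$piDistMax - m$dist &&
      nAng <= crit$piParallelMax - m$angle
    insideT <- d <= crit$piDistMax - m$dist &&
      nAng >= crit$piTshapedMin + m$angle && nAng <= crit$piTshapedMax
    outside <- d >= crit$piDistMax + m$dist ||
      (nAng >= crit$piParallelMax + m$angle &&
         nAng <= crit$piTshapedMin - m$angle)
    status <- .regionStatus(insidePar || insideT, outside, "pi-pi")
    anc <- .anchorRing(res)
    anc$normal <- .bestDirection(cbind(anc$normal, -anc$normal),
                                 anc$centroid, d, a, peptideResno)
    center <- anc$centroid + d * anc$normal
    n2 <- .unit(cos(nAng * pi / 180) * anc$normal +
                  sin(nAng * pi / 180) * .anyPerp(anc$normal))
    e1 <- .anyPerp(n2); e2 <- .unit(.cross(n2, e1))
    names6 <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    ring <- do.call(rbind, lapply(seq_along(names6), function(k) {
      phi <- (k - 1) * pi / 3
      mk("PHE", names6[k], center + 1.39 * (cos(phi) * e1 + sin(phi) * e2),
         "C")
    }))
    list(atoms = ring, status = status)
  } else if (type == "cation_pi") {
    d <- params$distance %||% 4.5
    status <- .regionStatus(d <= crit$cationPiDistMax - m$dist,
                            d >= crit$cationPiDistMax + m$dist, "cation-pi")
    anc <- .anchorRing(res)
    anc$normal <- .bestDirection(cbind(anc$normal, -anc$normal),
                                 anc$centroid, d, a, peptideResno)
    nz <- anc$centroid + d * anc$normal
    list(atoms = rbind(mk("LYS", "NZ", nz, "N"),
                       mk("LYS", "CE", nz + 1.49 * anc$normal, "C")),
         status = status)
  } else stop("unknown contact type: ", type)
}

#' Plant a typed interaction partner next to a peptide residue
#'
#' Places a minimal receptor-side partner group (a carbonyl acceptor,
#' an aspartate carboxylate, leucine carbons, a phenylalanine ring or
#' a lysine ammonium) at the requested geometry relative to the given
#' peptide residue, and records the planted ground truth in a
#' manifest. Geometry that satisfies the default detection criteria
#' with a margin of at least 0.3 A / 10 degrees enters the manifest;
#' geometry clear of the criteria by the same margin is placed as a
#' negative control with no manifest entry (the detector must stay
#' silent); geometry in the ambiguous band around a cutoff raises a
#' construction error. Anchors: `hbond` uses the backbone amide
#' (placement azimuth is chosen to maximize clearance from the rest
#' of the model), `salt_bridge` a lysine ammonium, `hydrophobic` an
#' apolar side-chain atom, `pi_pi`/`cation_pi` a Phe/Tyr ring.
#'
#' @param model a peptide [StructureModel-class] (see
#'   [buildIdealHelix()]), possibly already carrying planted partners.
#' @param type one of `hbond`, `salt_bridge`, `hydrophobic`, `pi_pi`,
#'   `cation_pi`.
#' @param peptideResno peptide residue number the contact anchors on.
#' @param params list of geometry parameters (`distance`, `angle`,
#'   `normalAngle`, `anchorAtom` as applicable).
#' @param receptorChain chain id for planted partners (default "R").
#' @param receptorResno residue number for the planted partner
#'   (default: next free number from 1001).
#' @return list with `model` (combined) and `manifest` (data.frame of
#'   planted in-region contacts: type, peptide_resno, receptor_chain,
#'   receptor_resno, receptor_resid; zero rows possible).
#' @export
plantContact <- function(model, type, peptideResno, params = list(),
                         receptorChain = "R", receptorResno = NULL) {
  existing <- model@atoms[model@atoms$chain == receptorChain, ]
  if (is.null(receptorResno))
    receptorResno <- if (nrow(existing)) max(existing$resno) + 1L else 1001L
  grp <- .plantGroup(type, model, peptideResno, params, receptorResno,
                     receptorChain)
  combined <- model
  combined@atoms <- rbind(combined@atoms, .newStructureModel(grp$atoms)@atoms)
  manifest <- attr(model, "manifest")
  if (is.null(manifest))
    manifest <- data.frame(type = character(), peptide_resno = integer(),
                           receptor_chain = character(),
                           receptor_resno = integer(),
                           receptor_resid = character(),
                           stringsAsFactors = FALSE)
  if (grp$status == "inside")
    manifest <- rbind(manifest, data.frame(
      type = type, peptide_resno = as.integer(peptideResno),
      receptor_chain = receptorChain,
      receptor_resno = as.integer(receptorResno),
      receptor_resid = grp$atoms$resid[1], stringsAsFactors = FALSE))
  attr(combined, "manifest") <- manifest
  list(model = combined, manifest = manifest)
}

#' Rigid-body perturbation with optional coordinate noise
#'
#' Applies an exact rotation about the model centroid, then a
#' translation, then isotropic Gaussian coordinate noise. Seeded and
#' bit-reproducible; the global RNG state is left untouched.
#'
#' @param model a [StructureModel-class].
#' @param angle rotation angle, degrees.
#' @param axis rotation axis (length 3, need not be unit).
#' @param translation length-3 translation, Angstrom.
#' @param noiseSd isotropic Gaussian noise SD per coordinate, Angstrom.
#' @param seed RNG seed for the noise.
#' @return The perturbed [StructureModel-class].
#' @export
perturbRigid <- function(model, angle = 0, axis = c(0, 0, 1),
                         translation = c(0, 0, 0), noiseSd = 0, seed = 1L) {
  stopifnot(noiseSd >= 0)
  xyz <- coords(model)
  cen <- colMeans(xyz)
  k <- .unit(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  out <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen + translation, "+")
  if (noiseSd > 0)
    out <- out + .withSeed(seed, matrix(stats::rnorm(length(out), 0, noiseSd),
                                        ncol = 3))
  model@atoms$x <- out[, 1]; model@atoms$y <- out[, 2]
  model@atoms$z <- out[, 3]
  model
}

#' Simulate logistic dose-response data
#'
#' Logistic mean (Hill slope 1) plus Gaussian noise; seeded and
#' reproducible, leaving the global RNG untouched.
#'
#' @param bottom,top,pec50 true curve parameters.
#' @param doses concentrations in molar (> 0).
#' @param nReplicates replicates per dose.
#' @param noiseSd Gaussian noise SD (response units).
#' @param seed RNG seed.
#' @param experiment experiment label stored with the data.
#' @return data.frame with columns `concentration_M`, `response`,
#'   `replicate`, `experiment`.
#' @export
simulateDoseResponse <- function(bottom, top, pec50, doses,
                                 nReplicates = 4L, noiseSd = 0, seed = 1L,
                                 experiment = 1L) {
  stopifnot(all(doses > 0), noiseSd >= 0)
  conc <- rep(doses, each = nReplicates)
  mu <- .logistic3(conc, bottom, top, pec50)
  resp <- if (noiseSd > 0)
    .withSeed(seed, mu + stats::rnorm(length(mu), 0, noiseSd)) else mu
  data.frame(concentration_M = conc, response = resp,
             replicate = rep(seq_len(nReplicates), times = length(doses)),
             experiment = experiment)
}

#' Write a self-contained fixture directory
#'
#' Emits toy inputs for an end-to-end run: a peptide helix PDB, a
#' planted peptide-receptor complex PDB with its manifest JSON, a
#' numbering-map TSV and a simulated dose-response CSV.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the simulated assay data.
#' @return `dir`, invisibly.
#' @export
writeFixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  helix <- buildIdealHelix("YAEGTFTSDLSKQL", aibPositions = 2)
  writeStructure(helix, file.path(dir, "toy_helix.pdb"))
  pl <- plantContact(helix, "hbond", 5, list(distance = 2.9, angle = 160))
  pl <- plantContact(pl$model, "salt_bridge", 12, list(distance = 3.5))
  writeStructure(pl$model, file.path(dir, "toy_complex.pdb"))
  jsonlite::write_json(pl$manifest, file.path(dir, "toy_manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  map <- data.frame(chain = "P", auth_seq = seq_len(14),
                    res_name = "", generic_label = paste0(seq_len(14), "P"),
                    region = "")
  utils::write.table(map, file.path(dir, "toy_numbering_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dr <- simulateDoseResponse(0, 100, 9, 10^seq(-12, -6, length.out = 8),
                             noiseSd = 2, seed = seed)
  utils::write.csv(dr, file.path(dir, "toy_dose_response.csv"),
                   row.names = FALSE)
  invisible(dir)
}
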