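# independent oracles and toy builders shared across tests

eulerRotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# brute-force rotation-search RMSD oracle: coarse Euler grid, then
# Nelder-Mead refinement of the best grid point; knows nothing about
# the SVD solution
oracleRmsd <- function(A, B, gridStep = pi / 6) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  f <- function(p) {
    R <- eulerRotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((Bc %*% t(R) - Ac)^2)))
  }
  best <- Inf; bp <- c(0, 0, 0)
  for (a in seq(0, 2 * pi, by = gridStep))
    for (b in seq(0, pi, by = gridStep))
      for (cc in seq(0, 2 * pi, by = gridStep)) {
        v <- f(c(a, b, cc))
        if (v < best) { best <- v; bp <- c(a, b, cc) }
      }
  o <- stats::optim(bp, f, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  o
}

# Monte-Carlo SASA oracle: uniformly random points on each probe-inflated
# sphere, independent of the golden-spiral implementation
mcSasa <- function(centers, radii, probe, n = 1e6, seed = 7) {
  set.seed(seed)
  tot <- 0
  for (i in seq_len(nrow(centers))) {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts <- sweep(v * (radii[i] + probe), 2, centers[i, ], "+")
    acc <- rep(TRUE, n)
    for (j in seq_len(nrow(centers))[-i])
      acc <- acc & (rowSums(sweep(pts, 2, centers[j, ])^2) >
                      (radii[j] + probe)^2)
    tot <- tot + 4 * pi * (radii[i] + probe)^2 * mean(acc)
  }
  tot
}

rotationMatrix <- function(angleDeg, axis) {
  k <- axis / sqrt(sum(axis^2)); th <- angleDeg * pi / 180
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rigid scaffold of reference atoms used as a superposition frame
frameScaffold <- function(chain = "R") {
  structureModel(data.frame(
    chain = chain, resno = 1:8, resid = "GLY", elety = "CA", element = "C",
    x = c(20, 25, 20, 25, 30, 30, 22, 27),
    y = c(0, 5, 10, -5, 0, 8, 13, -3),
    z = c(0, 2, 4, 6, 8, 1, 3, 5)))
}

# rotate/translate only the atoms of one chain, keeping the rest fixed
moveChain <- function(model, chain, angleDeg = 0, axis = c(1, 0, 0),
                      translation = c(0, 0, 0)) {
  a <- atoms(model)
  sel <- a$chain == chain
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  R <- rotationMatrix(angleDeg, axis)
  cen <- colMeans(xyz)
  a[sel, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen + translation, "+")
  structureModel(a, sourceId = model@sourceId)
}

carbonAtom <- function(resno, x, y = 0, z = 0, chain = "A", elety = "C",
                       element = "C") {
  data.frame(chain = chain, resno = resno, resid = "UNK", elety = elety,
             element = element, x = x, y = y, z = z)
}

# glycine-rich helix whose sparse side chains keep planted partners clear
sparsePlantHelix <- function() {
  buildIdealHelix("GGGGGGGGGKGGGGGGLGGGGGGFGGGFGG")
}
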