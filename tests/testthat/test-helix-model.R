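test_that("buildBasis is deterministic, orthonormal and branch-correct", {
  f <- buildBasis(c(0, 0, 1))
  expect_equal(f$c, c(1, 0, 0))       # near-z axis takes the +x auxiliary
  fx <- buildBasis(c(1, 0, 0))
  expect_equal(fx$c, c(0, 0, 1))
  set.seed(11)
  for (k in 1:1000) {
    n <- randUnit()
    f <- buildBasis(n)
    expect_lt(abs(sum(f$a * n)), 1e-12)
    expect_lt(abs(sum(f$b * n)), 1e-12)
    expect_lt(abs(sum(f$a * f$b)), 1e-12)
    expect_lt(abs(sqrt(sum(f$a^2)) - 1), 1e-12)
    expect_lt(abs(sqrt(sum(f$b^2)) - 1), 1e-12)
  }
  expect_identical(buildBasis(c(0, 1, 0)), buildBasis(c(0, 1, 0)))
  expect_error(buildBasis(c(0, 0, 0)), "nonzero")
  expect_error(buildBasis(c(0, 0, 2)), "unit")
})

test_that("generated coordinates follow the forward model", {
  # phase-zero residue lies on the a axis at its radius
  p <- helixParameters(P = c(0, 0, 0), n = c(0, 0, 1),
                       radii = c(1.5, 2.3, 1.7, 2.0), s = 5.4, omega = 100,
                       t = c(-0.9, 0, 1.1, 2.3), phi = c(-27, 0, 27, 20))
  x <- generateHelixCoordinates(p, frame = list(a = c(1, 0, 0),
                                                b = c(0, 1, 0), c = c(1, 0, 0)),
                                residueIndices = 0)
  expect_equal(as.numeric(x[1, "CA", ]), c(2.3, 0, 0), tolerance = 1e-12)

  # ideal alpha parameters: 1.5 A axial rise and 100 deg of phase per residue
  x <- generateHelixCoordinates(p, residueIndices = 0:17)
  expect_equal(dim(x), c(18L, 4L, 3L))
  rise <- diff(x[, "CA", ] %*% p@n)
  expect_equal(as.numeric(rise), rep(5.4 * 100 / 360, 17), tolerance = 1e-12)
  f <- buildBasis(p@n)
  ca <- sweep(x[, "CA", ], 2, p@P)
  az <- atan2(ca %*% f$b, ca %*% f$a) * 180 / pi
  expect_equal(wrapDeg(diff(az[, 1])), rep(100, 17), tolerance = 1e-9)

  expect_error(generateHelixCoordinates(p, residueIndices = integer(0)),
               "non-empty")
  expect_error(generateHelixCoordinates(p, residueIndices = c(0, 0, 1)),
               "strictly increasing")
  pBad <- p; pBad@n <- c(0, 0, 2)
  expect_error(generateHelixCoordinates(pBad, residueIndices = 0:5))
})

test_that("forward-inverse round trip recovers all parameters", {
  set.seed(42)
  for (k in 1:8) {
    p <- randomHelixParams()
    coords <- generateHelixCoordinates(p, residueIndices = 0:17)
    fit <- fitHelix(helixSegment(coords))
    expect_true(isConverged(fit))
    expect_lt(fitRMSD(fit), 1e-6)
    q <- helixParams(fit)
    expect_equal(q@omega, p@omega, tolerance = 1e-6)
    expect_equal(q@s, p@s, tolerance = 1e-6)
    expect_equal(unname(q@radii), unname(p@radii), tolerance = 1e-6)
    expect_equal(unname(q@t), unname(p@t), tolerance = 1e-6)
    expect_lt(max(abs(wrapDeg(q@phi - p@phi))), 1e-5)
    expect_lt(max(abs(as.numeric(q@n) - as.numeric(p@n))), 1e-6)
    # P recovers the axial foot of CA at residue 0 (the gauge convention)
    expect_lt(sqrt(sum((q@P - p@P)^2)), 1e-5)
  }
})

test_that("fits are gauge-deterministic across different initializations", {
  p <- idealHelixParameters("alpha", P = c(3, -2, 5), n = randUnit())
  set.seed(5)
  p@n <- randUnit()
  coords <- generateHelixCoordinates(p, residueIndices = 0:17)
  seg <- helixSegment(coords)
  fit1 <- fitHelix(seg)
  n2 <- randUnit() * 0.3 + p@n
  init2 <- helixParameters(P = p@P + c(0.5, -0.3, 0.2),
                           n = n2 / sqrt(sum(n2^2)),
                           radii = c(1.4, 2.1, 1.8, 2.1), s = 5.9, omega = 95,
                           t = c(-0.8, 0, 1.0, 2.0), phi = p@phi + 15)
  fit2 <- fitHelix(seg, init = init2)
  expect_equal(helixOmega(fit1), helixOmega(fit2), tolerance = 1e-6)
  expect_equal(helixPitch(fit1), helixPitch(fit2), tolerance = 1e-6)
  expect_equal(helixRadii(fit1), helixRadii(fit2), tolerance = 1e-6)
  expect_lt(max(abs(wrapDeg(helixPhases(fit1) - helixPhases(fit2)))), 1e-5)
  expect_lt(sqrt(sum((referencePoint(fit1) - referencePoint(fit2))^2)), 1e-5)
})

test_that("internal parameters are invariant under rigid motion", {
  set.seed(99)
  p <- randomHelixParams()
  coords <- generateHelixCoordinates(p, residueIndices = 0:17)
  fit <- fitHelix(helixSegment(coords))
  R <- rotMat(c(2, -1, 3), 71)
  tr <- c(12, -7, 4)
  fit2 <- fitHelix(helixSegment(rigidTransformCoords(coords, R, tr)))
  expect_equal(helixOmega(fit2), helixOmega(fit), tolerance = 1e-6)
  expect_equal(helixPitch(fit2), helixPitch(fit), tolerance = 1e-6)
  expect_equal(helixRadii(fit2), helixRadii(fit), tolerance = 1e-6)
  expect_equal(axialOffsets(fit2), axialOffsets(fit), tolerance = 1e-6)
  expect_equal(fitRMSD(fit2), fitRMSD(fit), tolerance = 1e-6)
  # pairwise phase differences invariant; absolute phases covariant
  expect_lt(max(abs(wrapDeg(diff(helixPhases(fit2)) - diff(helixPhases(fit))))),
            1e-5)
  # P and n transform with the rigid motion
  expect_lt(sqrt(sum((referencePoint(fit2) -
                        (R %*% referencePoint(fit) + tr))^2)), 1e-5)
  expect_lt(sqrt(sum((axisDirection(fit2) - R %*% axisDirection(fit))^2)), 1e-6)
})

test_that("reported rmsd equals independent recomputation from parameters", {
  set.seed(7)
  p <- idealHelixParameters("alpha")
  coords <- generateHelixCoordinates(p, residueIndices = 0:17)
  coords <- coords + array(rnorm(length(coords), 0, 0.15), dim(coords))
  fit <- fitHelix(helixSegment(coords))
  model <- generateHelixCoordinates(helixParams(fit),
                                    residueIndices = 0:17)
  rmsd <- sqrt(mean(apply((model - coords)^2, c(1, 2), sum)))
  expect_equal(fitRMSD(fit), rmsd, tolerance = 1e-9)
  expect_equal(fitRMSD(fit), sqrt(mean(fit@perAtomResiduals^2)),
               tolerance = 1e-9)
})

test_that("fit rejects short and degenerate segments", {
  p <- idealHelixParameters("alpha")
  coords <- generateHelixCoordinates(p, residueIndices = 0:3)
  expect_error(fitHelix(helixSegment(coords)), "segment too short")
  line <- array(0, c(6, 4, 3), dimnames = list(NULL, c("N", "CA", "C", "O"),
                                               c("x", "y", "z")))
  line[, , 3] <- seq(0, 5) + matrix(seq(0, 0.3, 0.1), 6, 4, byrow = TRUE)
  expect_error(fitHelix(helixSegment(line)), "collinear")
})

test_that("helix forms classify by nearest ideal angular turn", {
  expect_equal(classifyHelixForm(c(120, 100, 80)),
               c("three_ten", "alpha", "pi"))
  expect_equal(classifyHelixForm(110), "alpha")   # boundary resolves to alpha
  expect_equal(classifyHelixForm(90), "alpha")
  expect_equal(classifyHelixForm(c(110.01, 89.99)), c("three_ten", "pi"))
  expect_equal(classifyHelixForm(c(135, 69.9, 130, 70)),
               c("other", "other", "three_ten", "pi"))
  expect_error(classifyHelixForm(-5), "positive")
})

test_that("dihedral-to-twist map reproduces the helical calibration", {
  # dihedral sums of about -75, -105, -140 correspond to angular turns of
  # 120, 100, 80 deg/residue for 3/10, alpha, pi helices
  sums <- c(-75, -105, -140)
  target <- c(120, 100, 80)
  got <- omegaFromDihedrals((sums - 10) / 2, (sums + 10) / 2)
  expect_lt(max(abs(got - target)), 3)
  expect_equal(classifyHelixForm(got), c("three_ten", "alpha", "pi"))
  # textbook ideal dihedrals land on their forms too
  expect_equal(classifyHelixForm(omegaFromDihedrals(-49, -26)), "three_ten")
  expect_equal(classifyHelixForm(omegaFromDihedrals(-57, -47)), "alpha")
  expect_equal(classifyHelixForm(omegaFromDihedrals(-57, -70)), "pi")
  expect_error(omegaFromDihedrals(200, 0), "180")
})

test_that("twist from dihedrals agrees with twist from fitting", {
  td <- withr::local_tempdir()
  for (form in c("three_ten", "alpha", "pi")) {
    fx <- makeFixture(file.path(td, paste0(form, ".pdb")), form = form,
                      nResidues = 14)
    fit <- fitHelix(fx$segment)
    st <- readStructure(fx$file)
    dh <- computeDihedrals(st, "A")
    ok <- !is.na(dh$phi) & !is.na(dh$psi)
    expect_lt(abs(mean(omegaFromDihedrals(dh$phi[ok], dh$psi[ok])) -
                    helixOmega(fit)), 5)
  }
})

test_that("the dihedral-sum inversion is consistent with the forward map", {
  s <- idealHelixDihedralSum(c(120, 100, 80))
  expect_equal(omegaFromDihedrals((s - 10) / 2, (s + 10) / 2),
               c(120, 100, 80), tolerance = 1e-6)
})

test_that("residues per revolution is 360/omega", {
  expect_equal(residuesPerRevolution(c(100, 120, 80)), c(3.6, 3.0, 4.5))
  expect_error(residuesPerRevolution(0), "positive")
})

test_that("parameter and fit accessors expose the model quantities", {
  p <- idealHelixParameters("pi")
  expect_equal(helixDiameter(p), 2 * mean(p@radii))
  expect_equal(meanPhase(helixParameters(c(0, 0, 0), c(0, 0, 1),
                                         rep(2, 4), 5, 100, c(0, 0, 0, 0),
                                         c(170, -170, 175, -175))),
               -180, tolerance = 1e-9)  # circular mean crosses the wrap
  fit <- fitHelix(helixSegment(generateHelixCoordinates(
    p, residueIndices = 0:11)))
  expect_equal(helixOmega(fit), helixOmega(helixParams(fit)))
  expect_output(show(fit), "HelixFit")
})
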