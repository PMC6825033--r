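test_that("kinematics reproduce invariants for canonical deformations", {
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  st <- compute_kinematics(diag(3), fr)
  expect_equal(st$I1, 3)
  expect_equal(st$J, 1)
  expect_equal(st$I4, 1)
  expect_equal(st$I6, 1)

  lam <- 2
  st <- compute_kinematics(diag(c(lam, lam^-0.5, lam^-0.5)),
                           fiber_frame(c(1, 0, 0)))
  expect_equal(st$I4, 4)
  expect_equal(st$J, 1)

  # simple shear, oblique fibre: brute-force matrix oracle
  gam <- 1
  F <- diag(3); F[1, 2] <- gam
  M <- c(cos(pi / 4), sin(pi / 4), 0)
  st <- compute_kinematics(F, fiber_frame(M))
  expect_equal(st$I1, sum(diag(F %*% t(F))))
  expect_equal(st$I4, drop(crossprod(M, crossprod(F) %*% M)))
  expect_equal(st$m, drop(F %*% (M / sqrt(sum(M^2)))))

  expect_error(compute_kinematics(diag(c(-1, 1, 1)), fr), "det F")
})

test_that("isotropic energy matches its closed form and is zero at rest", {
  fr <- default_frame()
  p <- material_params(mu = 1, k1 = 0.5, k2 = 1, alpha = 10, kappa = 2)
  expect_equal(psi0_iso(compute_kinematics(diag(3), fr), p), 0)

  # isochoric shear with I1 = 4: Psi0_iso = mu/2 * (4 - 3) = 0.5
  F <- diag(3); F[1, 2] <- 1
  expect_equal(psi0_iso(compute_kinematics(F, fr), p), 0.5)

  # volumetric part is linear in kappa: isolate it by differencing
  Fd <- 1.1^(1 / 3) * diag(3)
  st <- compute_kinematics(Fd, fr)
  p2 <- material_params(mu = 1, k1 = 0.5, k2 = 1, alpha = 10, kappa = 6)
  J <- 1.1
  expect_equal(psi0_iso(st, p2) - psi0_iso(st, p),
               (6 - 2) / 4 * (J^2 - 1 - 2 * log(J)))
  expect_true(psi0_iso(st, p) >= 0)
})

test_that("fibre energy obeys the tension-only switch and its closed form", {
  p <- material_params(mu = 1, k1 = 1, k2 = 1, alpha = 45)
  fr <- fiber_frame(c(1, 0, 0), c(0, 1, 0))
  expect_equal(psi0_ani(compute_kinematics(diag(3), fr), p), 0)

  # both families shortened: no stored energy
  st_c <- compute_kinematics(diag(c(sqrt(0.8), sqrt(0.9), 1 / sqrt(0.72))), fr)
  expect_equal(st_c$I4, 0.8)
  expect_equal(st_c$I6, 0.9)
  expect_equal(psi0_ani(st_c, p), 0)
  expect_gt(psi0_ani(st_c, p, tension_only = FALSE), 0)

  # I4 = 2, I6 = 1 with k1 = k2 = 1: (1/2)(e - 1)
  st_t <- compute_kinematics(diag(c(sqrt(2), 1, 1 / sqrt(2))), fr)
  expect_equal(psi0_ani(st_t, p), 0.5 * (exp(1) - 1), tolerance = 1e-12)

  st_big <- compute_kinematics(diag(c(40, 1, 1)), fr)
  expect_error(psi0_ani(st_big, p), "overflow")
})

test_that("degradation satisfies the growth conditions", {
  expect_equal(degradation(0), 1)
  expect_equal(degradation(1), 0)
  expect_equal(degradation(0.5, 2), 0.25)
  expect_error(degradation(1.2), "\\[0, 1\\]")
  expect_error(degradation(-0.1), "\\[0, 1\\]")

  d <- seq(0, 1, length.out = 101)
  for (a in c(2, 3, 5)) {
    g <- degradation(d, a)
    expect_true(all(diff(g) <= 0))            # monotone non-increasing
    expect_equal(g[1], 1)
    expect_equal(g[101], 0)
    h <- 1e-7                                  # saturation g'(1) = 0
    expect_lt(abs((degradation(1, a) - degradation(1 - h, a)) / h), 1e-5)
  }
})

test_that("degraded energy interpolates between intact and ruptured limits", {
  p <- default_mat(); pf <- default_pf(); fr <- default_frame()
  st <- compute_kinematics(random_F(), fr)
  psi0 <- psi0_iso(st, p) + psi0_ani(st, p)
  expect_identical(degraded_energy(st, 0, p, pf), psi0)   # bitwise intact
  expect_equal(degraded_energy(st, 1, p, pf), 0)
  expect_equal(degraded_energy(st, 0.5, p, pf), 0.25 * psi0)
})

test_that("Kirchhoff stress is the energy gradient and vanishes in the limits", {
  set.seed(11)
  p <- default_mat(); pf <- default_pf(); fr <- default_frame()

  st0 <- compute_kinematics(diag(3), fr)
  for (d in c(0, 0.5, 1))
    expect_equal(kirchhoff_stress(st0, d, p, pf), matrix(0, 3, 3))
  st1 <- compute_kinematics(random_F(), fr)
  expect_equal(kirchhoff_stress(st1, 1, p, pf), matrix(0, 3, 3))

  # tau = (dPsi/dF) F' via central differences, 50 random states
  for (k in 1:50) {
    F <- random_F()
    d <- runif(1, 0, 0.9)
    st <- compute_kinematics(F, fr)
    tau <- kirchhoff_stress(st, d, p, pf)
    expect_equal(tau, t(tau))                  # symmetry
    P <- matrix(0, 3, 3); h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (degraded_energy(compute_kinematics(Fp, fr), d, p, pf) -
                  degraded_energy(compute_kinematics(Fm, fr), d, p, pf)) / (2 * h)
    }
    expect_equal(tau, P %*% t(F), tolerance = 1e-5)
  }
})

test_that("energetic force is minus the damage derivative of the energy", {
  set.seed(12)
  p <- default_mat(); pf <- default_pf(); fr <- default_frame()
  st0 <- compute_kinematics(diag(3), fr)
  expect_equal(energetic_force(st0, 0.3, p, pf), 0)   # zero energies
  st <- compute_kinematics(random_F(), fr)
  expect_equal(energetic_force(st, 1, p, pf), 0)      # saturation at d = 1

  # quadratic degradation by hand: f = 2 (1-d) (Psi0_iso + Psi0_ani)
  d <- 0.25
  expect_equal(energetic_force(st, d, p, pf),
               2 * 0.75 * (psi0_iso(st, p) + psi0_ani(st, p)))
  h <- 1e-6                                            # FD cross-check
  expect_equal(energetic_force(st, d, p, pf),
               -(degraded_energy(st, d + h, p, pf) -
                 degraded_energy(st, d - h, p, pf)) / (2 * h),
               tolerance = 1e-6)
})

test_that("spatial tangent linearises the stress and has the right limits", {
  set.seed(13)
  p <- default_mat(); pf <- default_pf(); fr <- default_frame()

  # small-strain limit, matrix only: c = kappa I x I + 2 mu IIsym
  p0 <- material_params(mu = 2, k1 = 0, k2 = 1, alpha = 0, kappa = 5)
  cc0 <- material_tangent(compute_kinematics(diag(3), fr), 0, p0, pf)
  I3 <- diag(3)
  ref <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    ref[i, j, k, l] <- 5 * I3[i, j] * I3[k, l] +
      2 * 2 * (I3[i, k] * I3[j, l] + I3[i, l] * I3[j, k]) / 2
  expect_equal(cc0, ref)

  expect_equal(material_tangent(compute_kinematics(random_F(), fr), 1, p, pf),
               array(0, c(3, 3, 3, 3)))

  # directional FD: dtau = c : sym(lv) + lv tau + tau lv'
  for (k in 1:10) {
    F <- random_F()
    d <- runif(1, 0, 0.8)
    st <- compute_kinematics(F, fr)
    tau <- kirchhoff_stress(st, d, p, pf)
    cc <- material_tangent(st, d, p, pf)
    # minor and major symmetries
    expect_equal(cc, aperm(cc, c(2, 1, 3, 4)))
    expect_equal(cc, aperm(cc, c(3, 4, 1, 2)))
    dF <- 1e-6 * matrix(rnorm(9), 3)
    dtau_fd <- (kirchhoff_stress(compute_kinematics(F + dF, fr), d, p, pf) -
                kirchhoff_stress(compute_kinematics(F - dF, fr), d, p, pf)) / 2
    lv <- dF %*% solve(F)
    sym_lv <- (lv + t(lv)) / 2
    dtau <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) dtau[i, j] <- sum(cc[i, j, , ] * sym_lv)
    dtau <- dtau + lv %*% tau + tau %*% t(lv)
    expect_equal(dtau, dtau_fd, tolerance = 1e-4)
  }
})

test_that("invariants are objective under superposed rotations", {
  set.seed(14)
  fr <- default_frame()
  for (k in 1:100) {
    F <- random_F()
    Q <- random_rotation()
    s1 <- compute_kinematics(F, fr)
    s2 <- compute_kinematics(Q %*% F, fr)
    expect_equal(c(s2$I1, s2$J, s2$I4, s2$I6),
                 c(s1$I1, s1$J, s1$I4, s1$I6), tolerance = 1e-12)
  }
})

test_that("compiled point kernel agrees with the R reference", {
  set.seed(15)
  p <- default_mat(); pf <- default_pf(); fr <- default_frame()
  for (k in 1:20) {
    F <- random_F()
    d <- runif(1)
    st <- compute_kinematics(F, fr)
    pe <- fibrocrack:::.cpp_point_eval(
      F, rbind(fr$M, fr$Mp),
      c(p$mu, p$k1, p$k2, p$kappa, pf$a_iso, pf$a_ani),
      d, TRUE, 0, TRUE)
    expect_equal(pe$tau, kirchhoff_stress(st, d, p, pf), tolerance = 1e-12)
    expect_equal(pe$psi_iso, psi0_iso(st, p), tolerance = 1e-12)
    expect_equal(pe$psi_ani, psi0_ani(st, p), tolerance = 1e-12)
  }
})
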