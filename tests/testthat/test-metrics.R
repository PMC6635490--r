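mini_rate <- function(vals, dims = c(4, 4, 2)) {
  voxvol(array(vals, dims), c(2.67, 2.67, 5), "Gy/s")
}

test_that("trapezoid integration handles constants and the analytic tail", {
  # constant rate r over [0, T] with negligible tail
  r <- mini_rate(0.5)
  d <- integrate_series(c(1e-9, 10), list(r, r), lambda_per_min = 1e9)
  expect_equal(unclass(d)[1, 1, 1], 0.5 * 600, tolerance = 1e-6)
  # tail alone: R / lambda (1 Gy/min at lambda = 0.01/min -> 100 Gy)
  r0 <- mini_rate(0)
  rl <- mini_rate(1 / 60)                          # 1 Gy/min in Gy/s
  d2 <- integrate_series(c(1, 2), list(r0, rl), lambda_per_min = 0.01,
                         head = "zero")
  tail_gy <- unclass(d2)[1, 1, 1] - (0 + 1 / 60) / 2 * 60
  expect_equal(tail_gy, 100, tolerance = 1e-10)
  expect_error(integrate_series(c(1), list(r)), ">= 2")
  expect_error(integrate_series(c(1, 2), list(r, mini_rate(-1))),
               "negative")
})

test_that("trapezoid+tail reproduces the exponential closed form within 3%", {
  tp <- c(1, 4, 7, 10, 15, 30, 46, 62)
  lam <- log(2) / GA68_HALF_LIFE_MIN                # 1/min
  r0 <- 2e-6                                        # Gy/s
  maps <- lapply(tp, function(t) mini_rate(r0 * 2^(-t / GA68_HALF_LIFE_MIN)))
  d <- integrate_series(tp, maps, lambda_per_min = lam)
  closed <- r0 / (lam / 60)                         # Gy
  expect_lt(abs(unclass(d)[1, 1, 1] - closed) / closed, 0.03)
  # refinement monotonically reduces the trapezoid error; with the head
  # zeroed and an exact exponential tail, all residual error is the
  # trapezoid's, and the closed form over [t1, inf) is r0 e^(-lam t1)/lam
  errs <- sapply(c(4, 8, 16, 32), function(n) {
    tt <- seq(1, 62, length.out = n)
    mm <- lapply(tt, function(t) mini_rate(r0 * exp(-lam * t)))
    est <- integrate_series(tt, mm, lambda_per_min = lam, head = "zero")
    abs(unclass(est)[1, 1, 1] - r0 * exp(-lam * 1) / (lam / 60))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("organ doses use mass weighting and the reference-mass correction", {
  dims <- c(3, 1, 1)
  vs <- c(10, 10, 10)                               # 1 mL voxels
  dose <- voxvol(array(c(1, 2, 4), dims), vs, "Gy")
  lab <- voxvol(array(c(1, 1, 1), dims), vs, "label")
  den <- voxvol(array(c(1.0, 0.5, 2.0), dims), vs, "g/cm3")
  refs <- data.frame(organ = "blob", reference_mass_g = 7)
  tab <- organ_doses(dose, lab, den, organ_names = c("1" = "blob"),
                     reference_masses = refs)
  # hand arithmetic: masses 1, 0.5, 2 g -> mean = (1*1+2*0.5+4*2)/3.5
  expect_equal(tab$patient_mass_g, 3.5)
  expect_equal(tab$mean_dose_gy, (1 + 1 + 8) / 3.5)
  expect_equal(tab$corrected_dose_gy, (10 / 3.5) * 3.5 / 7)
  # identity correction when patient mass equals reference mass
  refs2 <- data.frame(organ = "blob", reference_mass_g = 3.5)
  tab2 <- organ_doses(dose, lab, den, organ_names = c("1" = "blob"),
                      reference_masses = refs2)
  expect_equal(tab2$corrected_dose_gy, tab2$mean_dose_gy)
  # uniform dose over an organ equals that dose for any weighting
  dose_u <- voxvol(array(2.5, dims), vs, "Gy")
  tab3 <- organ_doses(dose_u, lab, den, organ_names = c("1" = "blob"),
                      reference_masses = refs)
  expect_equal(tab3$mean_dose_gy, 2.5)
})

test_that("voxel percentage difference matches hand arithmetic", {
  ref <- mini_rate(c(1, 2, 4, 5, rep(1, 28)))
  met <- mini_rate(c(1.1, 1.8, 4.4, 5.0, rep(1, 28)))
  mask <- array(FALSE, c(4, 4, 2)); mask[1:4] <- TRUE
  r <- voxel_percent_diff(met, ref, mask)
  expect_equal(r$mean, (10 + 10 + 10 + 0) / 4)
  expect_equal(r$n, 4L)
  # identical maps give 0 +/- 0; uniform 10% offset gives 10 +/- 0
  same <- voxel_percent_diff(ref, ref)
  expect_equal(same$mean, 0); expect_equal(same$sd, 0)
  up <- voxel_percent_diff(mini_rate(1.1), mini_rate(1))
  expect_equal(up$mean, 10, tolerance = 1e-10)
  expect_equal(up$sd, 0, tolerance = 1e-10)
  # asymmetry of the statistic
  a <- mini_rate(2); b <- mini_rate(1)
  expect_false(isTRUE(all.equal(voxel_percent_diff(a, b)$mean,
                                voxel_percent_diff(b, a)$mean)))
  expect_error(voxel_percent_diff(ref, ref, array(FALSE, c(4, 4, 2))),
               "empty mask")
})

test_that("organ percentage differences average across subjects and organs", {
  organs <- c("liver", "lung", "pancreas")
  ref <- matrix(c(2, 1, 0.1, 2, 1, 0.1), 3,
                dimnames = list(organs, NULL))
  met <- ref
  met["liver", ] <- c(2 * 1.02, 2 * 1.04)          # 2% and 4% high
  r <- organ_percent_diff(met, ref)
  expect_equal(r$per_organ$mean_pct[r$per_organ$organ == "liver"], 3)
  expect_equal(r$per_organ$mean_pct[r$per_organ$organ == "lung"], 0)
  expect_equal(r$average, mean(c(3, 0, 0)))
  expect_equal(r$average_excluding, mean(c(3, 0)))
  # identical tables -> all zeros
  z <- organ_percent_diff(ref, ref)
  expect_true(all(z$per_organ$mean_pct == 0))
  ref2 <- ref[1:2, ]
  expect_error(organ_percent_diff(met, ref2), "identical organ sets")
})

test_that("paired t-test matches closed-form arithmetic and Bonferroni threshold", {
  b <- c(10, 20, 30, 40)
  a <- b + c(1, 2, 3, 4)
  r <- paired_ttest_bonferroni(a, b, m_tests = 1)
  # t = mean(d) / (sd(d)/sqrt(n)) = 2.5 / (1.2910/2)
  expect_equal(r$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-6)
  expect_equal(r$t, 3.8730, tolerance = 1e-4)
  # m_tests = 8: raw p = 0.01 would not clear 0.05/8
  r8 <- paired_ttest_bonferroni(a, b, m_tests = 8)
  expect_equal(r8$alpha_adjusted, 0.00625)
  # degenerate: identical vectors
  rd <- paired_ttest_bonferroni(b, b, m_tests = 2)
  expect_equal(rd$status, "degenerate")
  expect_true(is.na(rd$p))
})

test_that("organ energy never exceeds whole-body energy (mass conservation)", {
  ph <- make_phantom(demo_phantom_spec("torso", c(24, 24, 12), seed = 3))
  dose <- new_like(ph$density, array(runif(prod(dim(ph$density))),
                                     dim(ph$density)), units = "Gy")
  tab <- organ_doses(dose, ph$labels, ph$density, correction = "none")
  vox_g <- unclass(ph$density) * voxel_volume_ml(ph$density)
  body_energy <- sum(unclass(dose) * vox_g)
  organ_energy <- sum(tab$mean_dose_gy * tab$patient_mass_g)
  expect_lte(organ_energy, body_energy)
})
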