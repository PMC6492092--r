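test_that("MT saturation factor behaves per the two-pool model", {
  lib <- tissue_lib()
  mt <- mt_params()

  # no RF -> no saturation
  expect_identical(
    mt_saturation_factor(lib$myocardium, mt_params(pulse_flip = 0)), 1.0)

  # no bound pool, 3000 Hz off-resonance -> essentially unattenuated
  free_only <- tissue_properties(T1 = 1550, T2 = 240, f_bound = 0)
  expect_gte(mt_saturation_factor(free_only, mt), 0.99)

  # factor in [0, 1] for every tissue in the default library
  for (tp in lib) {
    f <- mt_saturation_factor(tp, mt)
    expect_gte(f, 0); expect_lte(f, 1)
  }

  # monotonically non-increasing in pulse flip (two-pool integrator sweep)
  flips <- seq(0, 1600, by = 200)
  fac <- vapply(flips, function(fl) {
    mt_saturation_factor(lib$myocardium, mt_params(pulse_flip = fl))
  }, numeric(1))
  expect_true(all(diff(fac) <= 1e-12))

  # invalid parameters are rejected
  expect_error(mt_params(offset = -100), "offset")
  expect_error(tissue_properties(T1 = 1000, T2 = 45, f_bound = 1),
               "f_bound")
})

test_that("inversion-recovery closed forms hold for a single pass", {
  # T1 -> infinity: no recovery after inversion, Mz = -1 at TI
  frozen <- tissue_properties(T1 = 1e9, T2 = 45)
  st <- simulate_prep_cycle(frozen, seq_params("IR_BLOODNULL", TI = 140),
                            n_cycles = 1)
  expect_equal(st$Mz, -1, tolerance = 1e-6)

  # finite T1 from equilibrium: Mz(TI) = 1 - 2 exp(-TI/T1)
  tp <- tissue_properties(T1 = 900, T2 = 50)
  for (TI in c(110, 140, 360)) {
    st <- simulate_prep_cycle(tp, seq_params("IR_BLOODNULL", TI = TI),
                              n_cycles = 1)
    expect_equal(st$Mz, 1 - 2 * exp(-TI / 900), tolerance = 1e-12)
  }
})

test_that("T2 preparation penalizes venous over arterial blood", {
  lib <- tissue_lib()
  # closed-form attenuation oracle: exp(-40/T2)
  att_ven <- exp(-40 / lib$venous_blood$T2)
  att_art <- exp(-40 / lib$arterial_blood$T2)
  expect_lt(att_ven, att_art)

  ratio_for <- function(scheme) {
    sv <- simulate_prep_cycle(lib$venous_blood, seq_params(scheme),
                              n_cycles = 1)
    sa <- simulate_prep_cycle(lib$arterial_blood, seq_params(scheme),
                              n_cycles = 1)
    sv$Mxy / sa$Mxy
  }
  expect_lt(ratio_for("T2PREP_IR"), ratio_for("MTC_IR"))
})

test_that("zero-length T2 preparation equals no preparation bit-exactly", {
  tp <- tissue_lib()$liver   # non-fat tissue (fat saturation differs)
  s_t2p <- seq_params("T2PREP", t2prep_duration = 0, TI = 0, flip = 90)
  s_ref <- seq_params("REF_LOWFA", TI = 0, flip = 90)
  a <- simulate_prep_cycle(tp, s_t2p, n_cycles = 30)
  b <- simulate_prep_cycle(tp, s_ref, n_cycles = 30)
  expect_identical(a$Mz, b$Mz)
  expect_identical(a$Mxy, b$Mxy)
})

test_that("the driven steady state is a unique fixed point", {
  lib <- tissue_lib()
  for (tp in lib[c("myocardium", "fat", "liver")]) {
    mz <- vapply(c(-1, 0, 1), function(init) {
      simulate_prep_cycle(tp, seq_params("MTC_IR"), n_cycles = 200,
                          init_mz = init)$Mz
    }, numeric(1))
    expect_lt(max(mz) - min(mz), 1e-5)
  }
  expect_error(simulate_prep_cycle(lib$fat,
    structure(list(prep_scheme = "BOGUS"), class = "seq_params")),
    "prep_scheme")
})

test_that("tissue signals reproduce the intended interleaved contrast", {
  sig <- default_signals()
  odd <- sig[sig$parity == "odd", ]
  get <- function(nm) odd$signal[odd$tissue == nm]
  # bright blood, suppressed fat, near-nulled wall in the inverted beats
  expect_lt(get("arterial_blood"), 0)          # inverted blood
  expect_gt(abs(get("arterial_blood")), 5 * abs(get("fat")))
  expect_gt(get("myocardium"), 0)              # wall just past null
  expect_gt(abs(get("venous_blood")), 0.8 * abs(get("arterial_blood")))
  even <- sig[sig$parity == "even", ]
  expect_true(all(even$signal[even$tissue != "air"] >= 0))
})
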