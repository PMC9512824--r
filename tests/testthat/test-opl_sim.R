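test_that("spatial kernels realise their stated widths", {
  expect_equal(spatial_kernel(0, 300), 1)
  expect_equal(spatial_kernel(150, 300), 0.5)  # half max at FWHM/2
  # printed formula evaluated literally
  expect_equal(spatial_kernel(10, 300, "paper_literal"),
               exp(-100 / (300 / 11.09)^2))
})

test_that("photoreceptor drive follows the printed arithmetic", {
  p <- small_circuit()
  K <- kernel_matrix(p, p$fwhm_hc)
  zero <- numeric(p$n_cells)
  expect_equal(photoreceptor_drive(zero, zero, p, K), zero)
  # HC silent, light on one unit of stimulus: gain * E_VS * 1 / (0 + 1 + 1)
  d1 <- photoreceptor_drive(rep(1, p$n_cells), zero, p, K)
  expect_equal(d1, rep(0.5 * (-10) / 2, p$n_cells))
  # light always hyperpolarizes when HC is silent
  set.seed(1)
  vs <- runif(p$n_cells)
  expect_true(all(photoreceptor_drive(vs, zero, p, K)[vs > 0] < 0))
})

test_that("photoreceptor kinetics are biphasic with the exact fixed point", {
  p <- small_circuit()
  ph_A <- ph_B <- numeric(1)
  # hold drive at -1 well past the slow component's settling time
  trace <- numeric(6000)
  for (t in 1:6000) {
    st <- photoreceptor_step(ph_A, ph_B, -1, p)
    ph_A <- st$ph_A; ph_B <- st$ph_B
    trace[t] <- st$ph
  }
  expect_equal(trace[6000], -1 * (1 - p$phB_weight), tolerance = 1e-5)
  # independent oracle: literal per-step integration of the two exponentials
  a <- b <- 0
  oracle <- numeric(6000)
  for (t in 1:6000) {
    a <- a + (-1 - a) / 60
    b <- b + (-1 - b) / 400
    oracle[t] <- a - 0.8 * b
  }
  expect_equal(trace, oracle)
  # biphasic: trough before the steady state, deeper than it
  expect_lt(min(trace), -0.2)
  expect_lt(which.min(trace), 1000)
})

test_that("horizontal cells saturate and relax toward the printed target", {
  p <- small_circuit()
  Kn <- kernel_matrix(p, p$fwhm_hc, normalize = TRUE)
  n <- p$n_cells
  # spatially uniform photoreceptor signal passes the normalised kernel
  hs <- hc_step(rep(-2, n), numeric(n), p, Kn)
  expect_equal(hs$hc_inf, rep(-2, n))
  # held input converges to E_Ph * x / (x + E_Ph) = -2.5
  hc <- numeric(n)
  for (t in 1:6000) hc <- hc_step(rep(-2, n), hc, p, Kn)$hc
  expect_equal(hc, rep(10 * (-2) / (-2 + 10), n), tolerance = 1e-6)
  expect_equal(hc_step(numeric(n), numeric(n), p, Kn)$hc, numeric(n))
})

test_that("the bipolar synapse matches hand-computed values", {
  p <- small_circuit()
  K1 <- matrix(1, 1, 1)
  # printed form, single cell, transient parameters, Ph = -5
  got <- bc_synaptic_input(-5, p, "transient", K1, form = "as_printed")
  expect_equal(got, -(1 / (1 + exp(1.1 * 9)) - 1 / (1 + exp(1.1 * 4))))
  expect_gt(got, 0)
  # zero photoreceptor signal gives zero input (baseline subtraction)
  expect_equal(bc_synaptic_input(0, p, "transient", K1), 0)
  expect_equal(bc_synaptic_input(0, p, "sustained", K1, form = "as_printed"),
               0)
  # both forms: hyperpolarizing Ph -> bc_inf >= 0, monotone in |Ph|
  for (form in c("inverted", "as_printed")) {
    vals <- vapply(seq(0, -4, by = -0.5), function(v)
      bc_synaptic_input(v, p, "transient", K1, form = form), numeric(1))
    expect_true(all(vals >= 0))
    expect_true(all(diff(vals) >= 0))
  }
  # inverted form puts the transient population in its exponential regime:
  # response grows superlinearly with |Ph| near the half-activation voltage
  r2 <- bc_synaptic_input(-2, p, "transient", K1)
  r4 <- bc_synaptic_input(-4, p, "transient", K1)
  expect_gt(r4 / r2, 2)
})

test_that("bipolar membrane potential shunts with amacrine drive", {
  p <- small_circuit()
  expect_equal(bc_vm(1, 0, p), 10 * 10 / (1 + 10))
  expect_equal(bc_vm(0, 0, p), 0)
  vms <- vapply(c(0, 0.5, 1, 2), function(a) bc_vm(1, a, p), numeric(1))
  expect_true(all(diff(vms) < 0))  # E_AC = 0: pure shunting
  # temporal step
  expect_equal(bc_step(0, 1, p), 1 / p$tau_bc)
})

test_that("amacrine circuit activates uniformly for uniform drive", {
  # a narrow AC kernel so the array interior is free of edge truncation
  p <- small_circuit(ac_enabled = TRUE, fwhm_ac = 60)
  n <- p$n_cells
  as_ <- ac_step(rep(5, n), numeric(n), p)
  interior <- 12:28
  expect_lt(diff(range(as_$ac[interior])) / mean(as_$ac[interior]), 1e-4)
  expect_gt(as_$ac[15], 0)
  # the drive onto BCs is distance-normalised: uniform for uniform AC
  expect_lt(diff(range(as_$ac_drive[interior])) /
              mean(as_$ac_drive[interior]), 1e-3)
  p0 <- small_circuit(ac_syn_gain = 0)
  expect_equal(ac_step(rep(5, n), numeric(n), p0)$ac, numeric(n))
})

test_that("the full simulation is quiescent without light", {
  p <- small_circuit()
  geo <- stim_geometry(extent_um = 400, dx = 10, dt = 1, duration_ms = 300)
  z <- make_static_flash(bar_spec(bar_length = 400, contrast = 0), geo)
  s <- run_opl_simulation(z, p, record = c("ph", "hc", "bc_vm_transient",
                                           "bc_vm_sustained", "ac"))
  expect_true(all(s$ph == 0))
  expect_true(all(s$hc == 0))
  expect_true(all(s$bc_vm_transient == 0))
  expect_true(all(s$ac == 0))
})

test_that("amacrine flags are algebraically equivalent", {
  p1 <- small_circuit(ac_enabled = FALSE)
  p2 <- small_circuit(ac_enabled = TRUE, ac_syn_gain = 0)
  geo <- stim_geometry(extent_um = 400, dx = 10, dt = 1, duration_ms = 600)
  m <- make_static_flash(bar_spec(bar_length = 200, flash_duration = 300),
                         geo)
  s1 <- run_opl_simulation(m, p1)
  s2 <- run_opl_simulation(m, p2)
  expect_identical(s1$bc_vm_transient, s2$bc_vm_transient)
  expect_identical(s1$bc_vm_sustained, s2$bc_vm_sustained)
})

test_that("without horizontal feedback photoreceptor peaks lose condition
          asymmetry", {
  p <- circuit_params(hc_enabled = FALSE)
  bat <- opl_battery(p, duration_ms = 4000)
  probe <- 35  # x = 340 um, near the left mask edge
  peaks <- vapply(bat, function(m) {
    s <- run_opl_simulation(m, p, record = "ph")
    max(abs(s$ph[probe, ]))
  }, numeric(1))
  expect_lt(diff(range(peaks)) / mean(peaks), 0.01)
  expect_gt(mean(peaks), 0)  # photoreceptors still respond to light
})

test_that("emerging motion is enhanced in transient more than sustained BCs", {
  p <- circuit_params()
  bat <- opl_battery(p)
  probe <- 35  # x = 340 um: < 50 um from the mask edge, RF center visible
  res_t <- opl_condition_peaks(bat, p, trace = "bc_vm_transient")
  res_s <- opl_condition_peaks(bat, p, trace = "bc_vm_sustained")
  pk_t <- res_t$peaks[probe, ]
  pk_s <- res_s$peaks[probe, ]
  enh_t <- emerging_enhancement(pk_t["motion_right_masked"],
                                pk_t["motion_left_masked"])
  enh_s <- emerging_enhancement(pk_s["motion_right_masked"],
                                pk_s["motion_left_masked"])
  expect_gt(enh_t, enh_s)
  expect_gt(enh_s, 0)
  # emerging > continuous, exit ~ continuous (within 5%)
  expect_gt(pk_t["motion_right_masked"], pk_t["motion_right"])
  expect_lt(abs(pk_t["motion_left_masked"] / pk_t["motion_left"] - 1), 0.05)
  # flashes evoke larger peaks than continuous motion
  expect_gt(pk_t["flash_full"], pk_t["motion_right"])
  # static edge enhancement is small relative to emerging enhancement
  edge <- edge_enhancement(pk_t["flash_masked"], pk_t["flash_full"])
  expect_lt(abs(edge), abs(enh_t))
})

test_that("mirrored stimuli give mirrored circuit responses", {
  p <- small_circuit()
  geo <- stim_geometry(extent_um = 400, dx = 10, dt = 1, duration_ms = 1500)
  mr <- apply_mask(make_moving_bar(bar_spec(bar_length = 200, speed = 0.5),
                                   geo), c(0, 100))
  ml <- apply_mask(make_moving_bar(bar_spec(bar_length = 200, speed = 0.5,
                                            direction = "left"), geo),
                   c(300, 400))
  sr <- run_opl_simulation(mr, p)
  sl <- run_opl_simulation(ml, p)
  expect_equal(sl$bc_vm_transient, sr$bc_vm_transient[p$n_cells:1, ],
               tolerance = 1e-12)
})

test_that("HC initiation precedes bar arrival during continuous motion", {
  p <- circuit_params()
  m <- opl_battery(p)$motion_right
  s <- run_opl_simulation(m, p, record = c("ph", "hc"))
  hl <- hc_lead_time(s)
  interior <- which(hl$interior)
  expect_true(all(hl$lead_ms[interior] > 0))
  # halving the HC RF width shortens the maximal lead
  p2 <- circuit_params(fwhm_hc = 150)
  s2 <- run_opl_simulation(m, p2, record = c("ph", "hc"))
  expect_lt(hc_lead_time(s2)$max_lead_ms, hl$max_lead_ms)
  # a full-field flash engages HC and photoreceptors together: the HC
  # threshold crossing trails coverage only by its own integration time,
  # far smaller than the anticipatory lead during motion
  sf <- run_opl_simulation(opl_battery(p)$flash_full, p,
                           record = c("ph", "hc"))
  hf <- hc_lead_time(sf)
  flash_lag <- max(abs(hf$lead_ms[hf$interior]), na.rm = TRUE)
  expect_lt(flash_lag, 80)
  expect_lt(flash_lag, 0.3 * hl$max_lead_ms)
})
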