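#' Outer-retina circuit parameters
#'
#' All constants of the one-dimensional outer-plexiform-layer simulation:
#' photoreceptors with biphasic kinetics (difference of two first-order
#' activation functions with decay times 60 and 400 ms), horizontal cells (HC)
#' integrating photoreceptor output over a wide RF and feeding back divisively,
#' transient and sustained bipolar cells (BC) driven through a sigmoidal
#' photoreceptor-BC synapse, and an optional feed-forward amacrine circuit
#' (AC) driven by a separate "driver" BC population.
#'
#' Temporal update constants are per-millisecond divisors of literal
#' difference equations; the step is fixed at 1 ms and no dt-rescaling is
#' offered.
#'
#' @param n_cells number of cells per population (150 cells at 10-um spacing
#'   give the 1500-um array).
#' @param spacing um between cells.
#' @param tau_phA,tau_phB photoreceptor activation-function decay constants,
#'   ms (60 and 400); `phB_weight` weights the slow component in
#'   `ph = ph_A - phB_weight * ph_B`.
#' @param fwhm_hc,fwhm_bc,fwhm_ac RF widths (full width at half maximum), um.
#' @param gain_ph_hc photoreceptor-to-HC gain (1).
#' @param gain_hc_ph gain applied to the photoreceptor drive (0.5); it
#'   multiplies the whole numerator of the drive equation as printed,
#'   including the light term.
#' @param tau_hc,tau_bc,tau_ac activation time constants, ms (300, 50, 80).
#' @param E_Ph,E_HC,E_VS,E_AC driving forces, mV: photoreceptor signal (10),
#'   HC inhibitory input (2), light-induced hyperpolarization (-10), amacrine
#'   reversal (0).
#' @param v_slope_transient,v_half_transient,v_slope_sustained,
#'   v_half_sustained,v_slope_driver,v_half_driver sigmoid parameters of the
#'   photoreceptor-BC synapse for the three BC populations (mV^-1 and mV).
#' @param ac_syn_gain,ac_syn_v_slope,ac_syn_v_half BC-AC synapse gain and
#'   sigmoid parameters (1, 1.5 mV^-1, 7 mV).
#' @param ac_enabled,hc_enabled circuit flags. `hc_enabled = FALSE` silences
#'   the HC population (photoreceptor-to-HC gain forced to 0) so
#'   photoreceptors respond to light without feedback; `ac_enabled = FALSE`
#'   is equivalent to `ac_syn_gain = 0`.
#' @param kernel_mode `"normalized_fwhm"` (default; the realised full width at
#'   half maximum equals the stated value, `exp(-4 ln2 x^2 / FWHM^2)`) or
#'   `"paper_literal"` (`exp(-x^2 / (FWHM / 11.09)^2)` evaluated exactly as
#'   printed, which gives much narrower kernels).
#' @return an object of class `circuit_params`.
#' @export
circuit_params <- function(n_cells = 150, spacing = 10,
                           tau_phA = 60, tau_phB = 400, phB_weight = 0.8,
                           fwhm_hc = 300, fwhm_bc = 50, fwhm_ac = 300,
                           gain_ph_hc = 1, gain_hc_ph = 0.5,
                           tau_hc = 300, tau_bc = 50, tau_ac = 80,
                           E_Ph = 10, E_HC = 2, E_VS = -10, E_AC = 0,
                           v_slope_transient = 1.1, v_half_transient = 4,
                           v_slope_sustained = 0.1, v_half_sustained = 1,
                           v_slope_driver = 2, v_half_driver = 4,
                           ac_syn_gain = 1, ac_syn_v_slope = 1.5,
                           ac_syn_v_half = 7,
                           ac_enabled = FALSE, hc_enabled = TRUE,
                           kernel_mode = c("normalized_fwhm",
                                           "paper_literal")) {
  kernel_mode <- match.arg(kernel_mode)
  p <- as.list(environment())
  stopifnot(n_cells >= 2, spacing > 0,
            min(tau_phA, tau_phB, tau_hc, tau_bc, tau_ac) >= 1,
            gain_ph_hc >= 0, gain_hc_ph >= 0, ac_syn_gain >= 0)
  structure(p, class = "circuit_params")
}

#' Spatial interaction kernel
#'
#' Gaussian weight over cell-to-cell distance used for all RF interactions in
#' the circuit. `normalized_fwhm` realises the stated FWHM (weight 0.5 at
#' `x = fwhm/2`); `paper_literal` evaluates `exp(-x^2/(fwhm/11.09)^2)` as
#' printed (a far narrower kernel).
#'
#' @param x distance(s) from the RF center, um.
#' @param fwhm stated full width at half maximum, um.
#' @param mode `"normalized_fwhm"` or `"paper_literal"`.
#' @return weights in `(0, 1]`.
#' @export
spatial_kernel <- function(x, fwhm,
                           mode = c("normalized_fwhm", "paper_literal")) {
  mode <- match.arg(mode)
  stopifnot(fwhm > 0)
  if (mode == "normalized_fwhm") exp(-4 * log(2) * x^2 / fwhm^2)
  else exp(-x^2 / (fwhm / 11.09)^2)
}

# n x n kernel matrix over the cell lattice; optionally row-normalised
kernel_matrix <- function(params, fwhm, normalize = FALSE) {
  x <- (seq_len(params$n_cells) - 1) * params$spacing
  K <- outer(x, x, function(a, b)
    spatial_kernel(a - b, fwhm, params$kernel_mode))
  if (normalize) K / rowSums(K) else K
}

#' Photoreceptor drive
#'
#' Combines horizontal-cell feedback with visual illumination into the drive
#' onto each photoreceptor:
#' `drive_i = gain * (E_HC * hbar_i + E_VS * VS_i) /
#'            (|h|bar_i + VS_i + 1)`,
#' where `hbar_i = sum_j d_ij HC_j / sum_j d_ij` is the HC feedback
#' normalised by the distance function (and `|h|bar` the same weighted mean
#' of `|HC|`). Light (`VS > 0`) yields negative (hyperpolarizing) drive; HC
#' activation reduces the drive divisively through the denominator. With
#' `normalize = FALSE` the raw kernel sums are used instead; on a dense
#' lattice that form is regenerative (HC feedback amplified by the kernel
#' mass recruits neighbouring photoreceptors into a self-sustaining wave), so
#' the normalised form is the default.
#'
#' @param vs visual stimulus per cell (>= 0).
#' @param hc_prev HC state from the previous step, mV per cell.
#' @param params a [circuit_params()].
#' @param K_hc precomputed HC kernel matrix (defaults to building one).
#' @param normalize distance-normalise the HC feedback (default TRUE).
#' @return drive per cell, mV.
#' @export
photoreceptor_drive <- function(vs, hc_prev, params = circuit_params(),
                                K_hc = kernel_matrix(params, params$fwhm_hc),
                                normalize = TRUE) {
  stopifnot(length(vs) == params$n_cells, length(hc_prev) == params$n_cells)
  hw <- as.numeric(K_hc %*% hc_prev)
  habs <- as.numeric(K_hc %*% abs(hc_prev))
  if (normalize) {
    rs <- rowSums(K_hc)
    hw <- hw / rs
    habs <- habs / rs
  }
  den <- habs + vs + 1
  if (any(den <= 0)) stop("non-positive denominator in photoreceptor drive")
  params$gain_hc_ph * (params$E_HC * hw + params$E_VS * vs) / den
}

#' Photoreceptor kinetics step
#'
#' One 1-ms update of the biphasic photoreceptor response: two first-order
#' activation functions with decay constants `tau_phA` (60 ms) and `tau_phB`
#' (400 ms), combined as `ph = ph_A - phB_weight * ph_B`. A sustained drive D
#' settles at `ph = (1 - phB_weight) * D`.
#'
#' @param ph_A,ph_B activation-function states, mV per cell.
#' @param drive photoreceptor drive at this step (from
#'   [photoreceptor_drive()]).
#' @param params a [circuit_params()].
#' @return list with updated `ph_A`, `ph_B`, and output `ph`.
#' @export
photoreceptor_step <- function(ph_A, ph_B, drive, params = circuit_params()) {
  ph_A <- ph_A + (drive - ph_A) / params$tau_phA
  ph_B <- ph_B + (drive - ph_B) / params$tau_phB
  list(ph_A = ph_A, ph_B = ph_B, ph = ph_A - params$phB_weight * ph_B)
}

#' Horizontal-cell step
#'
#' HCs integrate photoreceptor output over their RF with distance-normalised
#' weights, `hc_inf_i = gain_ph_hc * sum_j d_ij Ph_j / sum_j d_ij`, and relax
#' toward the saturating target `E_Ph * hc_inf / (hc_inf + E_Ph)` with time
#' constant `tau_hc`.
#'
#' @param ph photoreceptor output, mV per cell.
#' @param hc_prev HC state at the previous step.
#' @param params a [circuit_params()].
#' @param K_hc_norm row-normalised HC kernel.
#' @return list with `hc` (updated state) and `hc_inf` (steady-state input).
#' @export
hc_step <- function(ph, hc_prev, params = circuit_params(),
                    K_hc_norm = kernel_matrix(params, params$fwhm_hc, TRUE)) {
  hc_inf <- params$gain_ph_hc * as.numeric(K_hc_norm %*% ph)
  if (any(abs(hc_inf + params$E_Ph) < 1e-9))
    stop("singular HC saturation (hc_inf = -E_Ph)")
  target <- params$E_Ph * hc_inf / (hc_inf + params$E_Ph)
  hc <- hc_prev + (target - hc_prev) / params$tau_hc
  list(hc = hc, hc_inf = hc_inf)
}

bc_sigmoid <- function(v, v_slope, v_half) 1 / (1 + exp(v_slope * (v_half - v)))

#' Photoreceptor-bipolar synaptic input
#'
#' Steady-state input to one BC population through the sigmoidal
#' photoreceptor-BC synapse, baseline-subtracted so zero photoreceptor output
#' yields zero input, with
#' `sigma(v) = 1 / (1 + exp(v_slope (v_half - v)))`.
#'
#' In the default `"inverted"` form the sigmoid operates on the
#' light-response amplitude `-Ph` (photoreceptors hyperpolarize to light, ON
#' bipolar cells depolarize), `bc_inf_i = sum_j d_ij [sigma(-Ph_j) -
#' sigma(0)]`. This places the half-activation voltage (4 mV for transient
#' BCs) just above the peak photoreceptor light response, so the transient
#' population sits in the sigmoid's exponential regime and amplifies
#' fluctuations around peak photoreceptor activity — the threshold behaviour
#' that makes transient BCs both more transient and more sensitive to
#' surround priming. The `"as_printed"` form,
#' `bc_inf_i = -sum_j d_ij [sigma(Ph_j) - sigma(0)]`, applies the sigmoid to
#' the signed Ph; hyperpolarizing responses then run into the sigmoid's
#' saturated tail (the whole light response is bounded by
#' `sigma(0) * kernel mass`), which flattens the transient/sustained
#' distinction. Both forms give `bc_inf >= 0`, monotone in `|Ph|`, for
#' hyperpolarizing Ph. The kernel sum is not distance-normalised.
#'
#' @param ph photoreceptor output, mV per cell.
#' @param params a [circuit_params()].
#' @param population `"transient"`, `"sustained"`, or `"driver"`.
#' @param K_bc BC kernel matrix (FWHM `fwhm_bc`).
#' @param form `"inverted"` (default) or `"as_printed"`.
#' @return steady-state synaptic input per cell.
#' @export
bc_synaptic_input <- function(ph, params = circuit_params(),
                              population = c("transient", "sustained",
                                             "driver"),
                              K_bc = kernel_matrix(params, params$fwhm_bc),
                              form = c("inverted", "as_printed")) {
  population <- match.arg(population)
  form <- match.arg(form)
  vs <- switch(population,
               transient = c(params$v_slope_transient,
                             params$v_half_transient),
               sustained = c(params$v_slope_sustained,
                             params$v_half_sustained),
               driver = c(params$v_slope_driver, params$v_half_driver))
  s0 <- bc_sigmoid(0, vs[1], vs[2])
  g <- if (form == "inverted") bc_sigmoid(-ph, vs[1], vs[2]) - s0
       else -(bc_sigmoid(ph, vs[1], vs[2]) - s0)
  as.numeric(K_bc %*% g)
}

#' Bipolar-cell temporal step and membrane potential
#'
#' `bc_step()` relaxes the synaptic activation toward its steady-state input
#' with `tau_bc`; `bc_vm()` converts synaptic activation and amacrine drive to
#' membrane potential,
#' `vm = E_Ph (E_Ph bc + E_AC ac) / (|bc| + |ac| + E_Ph)`. With `E_AC = 0`
#' the amacrine drive is purely shunting: it scales `|vm|` down without
#' changing its sign.
#'
#' @param bc_syn_prev synaptic activation at the previous step.
#' @param bc_inf steady-state input (from [bc_synaptic_input()]).
#' @param ac amacrine drive per cell (0 when the AC circuit is disabled).
#' @param params a [circuit_params()].
#' @return updated activation (`bc_step`) or membrane potential in mV
#'   (`bc_vm`).
#' @export
bc_step <- function(bc_syn_prev, bc_inf, params = circuit_params()) {
  bc_syn_prev + (bc_inf - bc_syn_prev) / params$tau_bc
}

#' @rdname bc_step
#' @param bc_syn synaptic activation at this step.
#' @export
bc_vm <- function(bc_syn, ac = 0, params = circuit_params()) {
  params$E_Ph * (params$E_Ph * bc_syn + params$E_AC * ac) /
    (abs(bc_syn) + abs(ac) + params$E_Ph)
}

#' Amacrine-cell step
#'
#' ACs sample driver-BC membrane potential through a sigmoidal BC-AC synapse
#' (gain `ac_syn_gain`, slope `ac_syn_v_slope`, half-activation
#' `ac_syn_v_half`, baseline-subtracted) over their RF and relax with
#' `tau_ac`. The drive onto BCs is the distance-normalised kernel-weighted sum
#' of AC outputs.
#'
#' @param bc_driver_vm driver-BC membrane potential, mV per cell.
#' @param ac_prev AC state at the previous step.
#' @param params a [circuit_params()].
#' @param K_ac,K_ac_norm AC kernel and its row-normalised form.
#' @return list with `ac` (updated state) and `ac_drive` (input onto BCs).
#' @export
ac_step <- function(bc_driver_vm, ac_prev, params = circuit_params(),
                    K_ac = kernel_matrix(params, params$fwhm_ac),
                    K_ac_norm = kernel_matrix(params, params$fwhm_ac, TRUE)) {
  g <- bc_sigmoid(bc_driver_vm, params$ac_syn_v_slope, params$ac_syn_v_half) -
    bc_sigmoid(0, params$ac_syn_v_slope, params$ac_syn_v_half)
  ac_inf <- params$ac_syn_gain * as.numeric(K_ac %*% g)
  ac <- ac_prev + (ac_inf - ac_prev) / params$tau_ac
  list(ac = ac, ac_drive = as.numeric(K_ac_norm %*% ac))
}

#' Run the outer-retina circuit simulation
#'
#' Integrates the full circuit over a 1-D stimulus movie at a 1-ms step.
#' Update order per step: photoreceptor drive (HC feedback from the previous
#' step) -> photoreceptor kinetics -> HC -> driver BC -> AC -> transient and
#' sustained BC. With a zero-luminance movie every state stays exactly zero.
#'
#' @param movie a 1-D [stimulus_movie()] with `dx = params$spacing` and
#'   `dt = 1` ms.
#' @param params a [circuit_params()].
#' @param record which per-population histories to keep.
#' @return an object of class `opl_sim`: list of `cells x time` matrices
#'   (`ph`, `hc`, `bc_vm_transient`, `bc_vm_sustained`, `ac`, ...), the cell
#'   positions `x_um`, the movie, and `params`.
#' @export
run_opl_simulation <- function(movie, params = circuit_params(),
                               record = c("ph", "hc", "bc_vm_transient",
                                          "bc_vm_sustained", "ac")) {
  stopifnot(inherits(movie, "stimulus_movie"))
  if (length(dim(movie$frames)) != 2L)
    stop("the circuit simulator takes 1-D movies")
  if (abs(movie$dx - params$spacing) > 1e-9)
    stop("movie dx must equal the cell spacing")
  if (abs(movie$dt - 1) > 1e-9) stop("movie dt must be 1 ms")
  n <- params$n_cells
  if (nrow(movie$frames) != n)
    stop("movie spatial samples must equal n_cells")
  if (!params$hc_enabled) params$gain_ph_hc <- 0
  if (!params$ac_enabled) params$ac_syn_gain <- 0
  nt <- ncol(movie$frames)
  K_hc <- kernel_matrix(params, params$fwhm_hc)
  K_hc_norm <- K_hc / rowSums(K_hc)
  K_bc <- kernel_matrix(params, params$fwhm_bc)
  K_ac <- kernel_matrix(params, params$fwhm_ac)
  K_ac_norm <- K_ac / rowSums(K_ac)
  # sigmoid lookup shortcuts
  pops <- c("transient", "sustained", "driver")
  ph_A <- ph_B <- ph <- hc <- ac <- numeric(n)
  bc_syn <- matrix(0, n, 3, dimnames = list(NULL, pops))
  ac_drive <- numeric(n)
  hist <- list()
  keep <- c("ph", "hc", "bc_vm_transient", "bc_vm_sustained", "bc_vm_driver",
            "ac", "drive", "hc_inf")
  record <- intersect(keep, record)
  for (nm in record) hist[[nm]] <- matrix(0, n, nt)
  for (t in seq_len(nt)) {
    vs <- movie$frames[, t]
    drive <- photoreceptor_drive(vs, hc, params, K_hc)
    st <- photoreceptor_step(ph_A, ph_B, drive, params)
    ph_A <- st$ph_A; ph_B <- st$ph_B; ph <- st$ph
    hs <- hc_step(ph, hc, params, K_hc_norm)
    hc <- hs$hc
    # driver BC feeds the amacrine circuit
    bc_inf_d <- bc_synaptic_input(ph, params, "driver", K_bc)
    bc_syn[, "driver"] <- bc_step(bc_syn[, "driver"], bc_inf_d, params)
    vm_driver <- bc_vm(bc_syn[, "driver"], 0, params)
    if (params$ac_enabled || params$ac_syn_gain > 0) {
      as_ <- ac_step(vm_driver, ac, params, K_ac, K_ac_norm)
      ac <- as_$ac; ac_drive <- as_$ac_drive
    }
    for (pop in c("transient", "sustained")) {
      bc_inf <- bc_synaptic_input(ph, params, pop, K_bc)
      bc_syn[, pop] <- bc_step(bc_syn[, pop], bc_inf, params)
    }
    vm_t <- bc_vm(bc_syn[, "transient"], ac_drive, params)
    vm_s <- bc_vm(bc_syn[, "sustained"], ac_drive, params)
    if (!is.null(hist$ph)) hist$ph[, t] <- ph
    if (!is.null(hist$hc)) hist$hc[, t] <- hc
    if (!is.null(hist$bc_vm_transient)) hist$bc_vm_transient[, t] <- vm_t
    if (!is.null(hist$bc_vm_sustained)) hist$bc_vm_sustained[, t] <- vm_s
    if (!is.null(hist$bc_vm_driver)) hist$bc_vm_driver[, t] <- vm_driver
    if (!is.null(hist$ac)) hist$ac[, t] <- ac
    if (!is.null(hist$drive)) hist$drive[, t] <- drive
    if (!is.null(hist$hc_inf)) hist$hc_inf[, t] <- hs$hc_inf
  }
  structure(c(hist,
              list(x_um = (seq_len(n) - 1) * params$spacing,
                   movie = movie, params = params)),
            class = "opl_sim")
}

#' @export
print.opl_sim <- function(x, ...) {
  cat(sprintf("<opl_sim: %d cells x %d ms (%s)>\n",
              length(x$x_um), ncol(x$ph), x$movie$condition_label))
  cat(sprintf("  HC %s, AC %s\n",
              if (x$params$hc_enabled) "on" else "off",
              if (x$params$ac_enabled) "on" else "off"))
  invisible(x)
}

#' @export
plot.opl_sim <- function(x, cell = NULL, ...) {
  if (is.null(cell)) cell <- length(x$x_um) %/% 2
  t_ms <- seq_len(ncol(x$ph)) - 1
  m <- rbind(ph = x$ph[cell, ], hc = x$hc[cell, ],
             transient = x$bc_vm_transient[cell, ],
             sustained = x$bc_vm_sustained[cell, ])
  graphics::matplot(t_ms, t(m), type = "l", lty = 1, col = 1:4,
                    xlab = "time (ms)", ylab = "mV", ...)
  graphics::legend("topright", rownames(m), col = 1:4, lty = 1, bty = "n")
  invisible(x)
}

#' Horizontal-cell lead over direct photoreceptor stimulation
#'
#' During continuous bar motion the HC signal at a cell begins to rise before
#' the bar reaches that cell, because HCs pool photoreceptor output over a
#' wide RF. Per cell the lead is
#' `(time the bar first covers the cell) - (time |HC| first exceeds
#' threshold_frac x its eventual peak)`. Cells the bar never reaches are
#' excluded; the summary maximum is taken over cells at least `margin_um`
#' from the array ends.
#'
#' @param sim an [run_opl_simulation()] result recorded with `hc`.
#' @param threshold_frac initiation threshold as a fraction of the cell's
#'   peak `|HC|` (default 0.10).
#' @param margin_um exclusion margin at the array ends, um (default 300).
#' @return list with `lead_ms` (per cell, NA where undefined), `cover_ms`,
#'   `init_ms`, `interior` (logical), and `max_lead_ms` (max over interior
#'   cells).
#' @export
hc_lead_time <- function(sim, threshold_frac = 0.10, margin_um = 300) {
  stopifnot(inherits(sim, "opl_sim"), !is.null(sim$hc))
  frames <- sim$movie$frames
  n <- nrow(frames); nt <- ncol(frames)
  t_ms <- (seq_len(nt) - 1) * sim$movie$dt
  cover <- apply(frames != 0, 1, function(r) {
    w <- which(r); if (length(w)) t_ms[w[1]] else NA_real_
  })
  init <- vapply(seq_len(n), function(i) {
    h <- abs(sim$hc[i, ])
    pk <- max(h)
    if (pk <= 0) return(NA_real_)
    w <- which(h >= threshold_frac * pk)
    t_ms[w[1]]
  }, numeric(1))
  lead <- cover - init
  x <- sim$x_um
  interior <- x >= margin_um & x <= max(x) - margin_um
  ok <- interior & !is.na(lead)
  list(lead_ms = lead, cover_ms = cover, init_ms = init,
       interior = interior,
       max_lead_ms = if (any(ok)) max(lead[ok]) else NA_real_)
}

#' Standard stimulus battery for the circuit simulator
#'
#' Builds the condition set used throughout: a full-field 2-s flash, the
#' flash with 300-um masks at both array ends (static edges), full-field
#' motion in both directions, and the masked-motion movies in which a bar
#' emerges from one mask and exits into the other.
#'
#' @param params a [circuit_params()] (sets geometry).
#' @param contrast bar amplitude (a.u.).
#' @param speed bar speed, mm/s.
#' @param bar_length moving-bar length, um.
#' @param duration_ms movie duration, ms.
#' @param pre_ms pre-stimulus baseline, ms.
#' @param mask_um depth of the masks at the array ends, um (default 300).
#' @return named list of 1-D [stimulus_movie()]s: `flash_full`,
#'   `flash_masked`, `motion_right`, `motion_left`, `motion_right_masked`,
#'   `motion_left_masked`.
#' @export
opl_battery <- function(params = circuit_params(), contrast = 1, speed = 0.5,
                        bar_length = 1000, duration_ms = 4500, pre_ms = 200,
                        mask_um = 300) {
  extent <- params$n_cells * params$spacing
  geo <- stim_geometry(extent_um = extent, dx = params$spacing, dt = 1,
                       duration_ms = duration_ms, pre_ms = pre_ms)
  masks <- list(c(0, mask_um), c(extent - mask_um, extent))
  add_masks <- function(m) {
    m <- apply_mask(m, masks[[1]])
    apply_mask(m, masks[[2]])
  }
  flash <- make_static_flash(bar_spec(bar_length = extent, contrast = contrast,
                                      flash_duration = 2000), geo)
  mr <- make_moving_bar(bar_spec(bar_length = bar_length, speed = speed,
                                 direction = "right", contrast = contrast),
                        geo)
  ml <- make_moving_bar(bar_spec(bar_length = bar_length, speed = speed,
                                 direction = "left", contrast = contrast),
                        geo)
  fm <- add_masks(flash); fm$condition_label <- "flash_masked"
  mrm <- add_masks(mr); mrm$condition_label <- "motion_emerging"
  mlm <- add_masks(ml); mlm$condition_label <- "motion_exiting"
  list(flash_full = flash, flash_masked = fm,
       motion_right = mr, motion_left = ml,
       motion_right_masked = mrm, motion_left_masked = mlm)
}

#' Peak responses of the circuit across a stimulus battery
#'
#' Runs [run_opl_simulation()] on each movie of a battery and extracts per
#' cell the signed maximum of the chosen trace within the stimulus window
#' (from movie onset to the end of the movie).
#'
#' @param battery named list of movies (see [opl_battery()]).
#' @param params a [circuit_params()].
#' @param trace which recorded trace to summarise.
#' @return list with `peaks` (matrix `cells x conditions`) and `sims` (the
#'   simulation objects).
#' @export
opl_condition_peaks <- function(battery, params = circuit_params(),
                                trace = "bc_vm_transient") {
  sims <- lapply(battery, run_opl_simulation, params = params,
                 record = unique(c(trace, "ph", "hc")))
  peaks <- vapply(sims, function(s) apply(s[[trace]], 1, max),
                  numeric(params$n_cells))
  list(peaks = peaks, sims = sims)
}
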