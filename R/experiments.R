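# ---------------------------------------------------------------------------
# Registered in-silico experiments. Each protocol drives the model through
# a configured battery of simulations and returns tidy result tables
# (one row per condition x measurement) ready for CSV export.
# ---------------------------------------------------------------------------

new_result <- function(name, config, ...) {
  structure(list(name = name, config = config, ...),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  tabs <- setdiff(names(x), c("name", "config"))
  cat(sprintf("<experiment_result> '%s'\n", x$name))
  for (tb in tabs) {
    if (is.data.frame(x[[tb]]))
      cat(sprintf("  $%s: %d rows x %d cols\n", tb, nrow(x[[tb]]),
                  ncol(x[[tb]])))
  }
  invisible(x)
}

# baseline protocol: constant drive to PYR cells of both layers plus
# optional extra named drives
baseline_stim <- function(pyr_drive = 5, extra = NULL) {
  drives <- c(PYR_sup = pyr_drive, PYR_deep = pyr_drive)
  if (!is.null(extra)) {
    for (nm in names(extra))
      drives[nm] <- (if (nm %in% names(drives)) drives[[nm]] else 0) +
        extra[[nm]]
  }
  stimulus_protocol(baseline = drives)
}

# run n_trials noisy simulations and return list(traces, mean_rates)
run_trials <- function(C, params, stim, duration, n_trials, seed) {
  traces <- vector("list", n_trials)
  for (tr in seq_len(n_trials))
    traces[[tr]] <- simulate_rates(C, params, stim, duration = duration,
                                   seed = seed + tr)
  mean_rates <- colMeans(do.call(rbind, lapply(traces, function(t)
    colMeans(t$rates))))
  list(traces = traces, mean_rates = mean_rates)
}

peaks_row <- function(traces, psd_args, G, extra = list()) {
  do.call(rbind, lapply(c("superficial", "deep"), function(lay) {
    spec <- do.call(compute_psd, c(list(traces, layer = lay), psd_args))
    pk <- find_spectral_peak(spec)
    row <- data.frame(G = G, layer = lay, frequency = pk$frequency,
                      power = pk$power, found = pk$found)
    if (length(extra)) row <- cbind(row, as.data.frame(extra))
    row
  }))
}

#' Spontaneous activity as a function of global coupling G
#'
#' For every G: noisy trials of the resting circuit (constant drive to PYR
#' cells only), time-averaged rates of all populations, and the dominant
#' LFP-proxy spectral peak of each layer from trial-averaged multitaper
#' spectra.
#'
#' @param C Unscaled [connectivity_matrix()] (G = 1); scaled internally.
#' @param G_values Coupling values to sweep.
#' @param params A [model_params()].
#' @param pyr_drive Constant drive to PYR cells (Hz, default 5).
#' @param duration Trial length (ms, default 20000).
#' @param n_trials Trials per G (default 50).
#' @param seed Base seed; trial t at the i-th G uses
#'   \code{seed + 1000 i + t}.
#' @param psd_args List of overrides passed to [compute_psd()].
#' @return \code{experiment_result} with \code{$rates} (G, population,
#'   rate) and \code{$peaks} (G, layer, frequency, power, found).
#' @export
spontaneous_g_sweep <- function(C = default_circuit(),
                                G_values = seq(50, 550, by = 100),
                                params = model_params(), pyr_drive = 5,
                                duration = 20000, n_trials = 50,
                                seed = 1, psd_args = list()) {
  stim <- baseline_stim(pyr_drive)
  rates <- NULL; peaks <- NULL
  for (i in seq_along(G_values)) {
    G <- G_values[i]
    CG <- scale_by_G(C, G)
    run <- run_trials(CG, params, stim, duration, n_trials,
                      seed + 1000L * i)
    rates <- rbind(rates, data.frame(G = G, population = POPULATIONS,
                                     rate = unname(run$mean_rates)))
    peaks <- rbind(peaks, peaks_row(run$traces, psd_args, G))
  }
  new_result("spontaneous_g_sweep",
             list(G_values = G_values, pyr_drive = pyr_drive,
                  duration = duration, n_trials = n_trials, seed = seed),
             rates = rates, peaks = peaks)
}

# SST translaminar output entries (source SST of one layer onto every
# population of the other layer)
sst_translaminar_lesions <- function() {
  les <- list()
  for (tgt in c("PYR_sup", "PV_sup", "VIP_sup"))
    les <- c(les, list(lesion_spec("remove_connection",
                                   source = "SST_deep", target = tgt)))
  for (tgt in c("PYR_deep", "PV_deep", "VIP_deep"))
    les <- c(les, list(lesion_spec("remove_connection",
                                   source = "SST_sup", target = tgt)))
  les
}

#' Standard lesion conditions of the lesion battery
#' @return Named list of lesion-spec lists.
#' @export
lesion_conditions <- function() {
  silence_class <- function(cls)
    lapply(class_pops(cls), function(p)
      lesion_spec("silence_cell", source = p))
  list(
    intact = list(),
    no_pyr_translaminar = list(
      lesion_spec("remove_connection", source = "PYR_sup",
                  target = "PYR_deep")),
    no_sst_translaminar = sst_translaminar_lesions(),
    equalized_pv = list(lesion_spec("equalize_pv_self")),
    all_three = c(
      list(lesion_spec("remove_connection", source = "PYR_sup",
                       target = "PYR_deep")),
      sst_translaminar_lesions(),
      list(lesion_spec("equalize_pv_self"))),
    silence_pv = silence_class("PV"),
    silence_sst = silence_class("SST"),
    silence_vip = silence_class("VIP")
  )
}

#' Lesion battery: connectivity manipulations under the spontaneous sweep
#'
#' Reruns the spontaneous G sweep under each lesion condition: removal of
#' the descending PYR connection, removal of translaminar SST projections,
#' equalised PV self-inhibition, the three combined, and full silencing of
#' each interneuron class in both layers. Emits the rate tables, the
#' superficial-minus-deep PYR rate difference, and the spectral peaks per
#' condition.
#'
#' @inheritParams spontaneous_g_sweep
#' @param conditions Named list of lesion-spec lists (default
#'   [lesion_conditions()]).
#' @return \code{experiment_result} with \code{$rates}, \code{$peaks}
#'   (with a \code{condition} column) and \code{$layer_diff}
#'   (condition, G, pyr rate difference).
#' @export
lesion_battery <- function(C = default_circuit(),
                           G_values = seq(50, 550, by = 100),
                           conditions = lesion_conditions(),
                           params = model_params(), pyr_drive = 5,
                           duration = 20000, n_trials = 50, seed = 1,
                           psd_args = list()) {
  rates <- NULL; peaks <- NULL
  for (cond in names(conditions)) {
    CL <- C
    for (les in conditions[[cond]]) CL <- apply_lesion(CL, les)
    res <- spontaneous_g_sweep(CL, G_values, params, pyr_drive, duration,
                               n_trials, seed, psd_args)
    rates <- rbind(rates, cbind(condition = cond, res$rates))
    peaks <- rbind(peaks, cbind(condition = cond, res$peaks))
  }
  wide <- rates[rates$population == "PYR_sup", c("condition", "G")]
  wide$diff <- rates$rate[rates$population == "PYR_sup"] -
    rates$rate[rates$population == "PYR_deep"]
  new_result("lesion_battery",
             list(G_values = G_values, conditions = names(conditions),
                  duration = duration, n_trials = n_trials, seed = seed),
             rates = rates, peaks = peaks, layer_diff = wide)
}

# switch definitions: swept targets and baseline extras
switch_setup <- function(switch, sst_baseline = 5, state_drive = 40) {
  switch(switch,
    vip = list(targets = c("VIP_sup", "VIP_deep"),
               extra = c(SST_sup = sst_baseline, SST_deep = sst_baseline)),
    pv = list(targets = c("PV_sup", "PV_deep"),
              extra = c(SST_sup = sst_baseline, SST_deep = sst_baseline)),
    sst = list(targets = c("SST_sup", "SST_deep"), extra = NULL),
    pyr_plain = list(targets = c("PYR_sup", "PYR_deep"), extra = NULL),
    pyr_vip40 = list(targets = c("PYR_sup", "PYR_deep"),
                     extra = c(VIP_sup = state_drive,
                               VIP_deep = state_drive)),
    pyr_pv40 = list(targets = c("PYR_sup", "PYR_deep"),
                    extra = c(PV_sup = state_drive,
                              PV_deep = state_drive)),
    stop(sprintf("unknown switch type '%s'", switch), call. = FALSE)
  )
}

#' Ultrasensitivity / hysteresis sweeps of the inhibitory switches
#'
#' For each switch type and each G: warm-started ascending and descending
#' input sweeps, Hill fits of the SST response curves per layer (ascending
#' branch), hysteresis areas, and optionally noisy spectral peaks at
#' selected inputs along the sweep.
#'
#' Switch types: \code{"vip"} and \code{"pv"} sweep drive to the
#' respective cells of both layers with SST cells held at a constant
#' enhancing drive; \code{"sst"} sweeps SST drive (lateral-inhibition
#' scenario); \code{"pyr_plain"}, \code{"pyr_vip40"} and \code{"pyr_pv40"}
#' sweep PYR drive with no, VIP- or PV-state background.
#'
#' @inheritParams spontaneous_g_sweep
#' @param switch One of \code{"vip"}, \code{"pv"}, \code{"sst"},
#'   \code{"pyr_plain"}, \code{"pyr_vip40"}, \code{"pyr_pv40"}.
#' @param input_grid Swept drive values (Hz), ascending (default 0-100 in
#'   1 Hz steps).
#' @param sst_baseline Constant SST drive for the VIP/PV switches (Hz).
#' @param state_drive Background drive of the VIP/PV state scenarios (Hz).
#' @param settle_ms Settling time per grid point (ms).
#' @param spectra_inputs Optional input values at which noisy spectral
#'   peaks are computed (requires \code{n_trials}, \code{duration}).
#' @param n_trials,duration Spectral trial count and length.
#' @return \code{experiment_result} with \code{$curves} (G, input,
#'   direction, population, rate), \code{$fits} (G, layer, Hill
#'   parameters), \code{$hysteresis} (G, h per layer and total) and
#'   optionally \code{$peaks}.
#' @export
switch_sweeps <- function(C = default_circuit(),
                          G_values = c(150, 300, 450),
                          switch = "vip",
                          input_grid = seq(0, 100, by = 1),
                          params = model_params(), pyr_drive = 5,
                          sst_baseline = 5, state_drive = 40,
                          settle_ms = 2000, spectra_inputs = NULL,
                          n_trials = 10, duration = 5000, seed = 1,
                          psd_args = list()) {
  setup <- switch_setup(switch, sst_baseline, state_drive)
  stim <- baseline_stim(pyr_drive, setup$extra)
  curves <- NULL; fits <- NULL; hyst <- NULL; peaks <- NULL
  for (gi in seq_along(G_values)) {
    G <- G_values[gi]
    CG <- scale_by_G(C, G)
    up <- sweep_response(CG, params, stim, setup$targets, input_grid,
                         "ascending", settle_ms = settle_ms)
    down <- sweep_response(CG, params, stim, setup$targets,
                           rev(input_grid), "descending",
                           settle_ms = settle_ms,
                           initial_rates = up$rates[nrow(up$rates), ])
    for (br in list(up, down)) {
      curves <- rbind(curves, data.frame(
        G = G, input = rep(br$input, times = 8L),
        direction = br$direction,
        population = rep(POPULATIONS, each = length(br$input)),
        rate = as.vector(br$rates)))
    }
    for (lay in c("superficial", "deep")) {
      sst <- if (lay == "superficial") "SST_sup" else "SST_deep"
      f <- fit_hill(up, population = sst)
      fits <- rbind(fits, data.frame(
        G = G, layer = lay, c = f$c, d = f$d, k = f$k, n = f$n,
        goodness = f$goodness, ok = f$ok))
    }
    h <- hysteresis_area(up, down)
    hyst <- rbind(hyst, data.frame(G = G, h_superficial = h$h_superficial,
                                   h_deep = h$h_deep,
                                   h_total = h$h_total))
    if (!is.null(spectra_inputs)) {
      for (si in seq_along(spectra_inputs)) {
        inp <- spectra_inputs[si]
        drive <- stim$baseline
        drive[pop_index(setup$targets)] <-
          drive[pop_index(setup$targets)] + inp
        st <- stimulus_protocol(setNames(drive, POPULATIONS))
        run <- run_trials(CG, params, st, duration, n_trials,
                          seed + 10000L * gi + 100L * si)
        peaks <- rbind(peaks, peaks_row(run$traces, psd_args, G,
                                        extra = list(input = inp)))
      }
    }
  }
  new_result("switch_sweeps",
             list(switch = switch, G_values = G_values,
                  input_grid = range(input_grid),
                  sst_baseline = sst_baseline, seed = seed),
             curves = curves, fits = fits, hysteresis = hyst,
             peaks = peaks)
}

#' Time-constant dependence of the switch-state oscillation frequencies
#'
#' Holds the time constant of three cell classes fixed and varies the
#' fourth, measuring the dominant oscillation frequency of the
#' SST-dominated low-input state and the PV/VIP-dominated high-input state
#' of the VIP switch. By default no extra SST drive is applied
#' (\code{sst_baseline = 0}), so the low-input state is the spontaneous
#' SST-dominated regime in which the PYR-SST loop is active and its
#' frequency can respond to the varied time constant.
#'
#' @inheritParams switch_sweeps
#' @param G Single coupling value.
#' @param varied_class \code{"PYR"}, \code{"PV"}, \code{"SST"} or
#'   \code{"VIP"}.
#' @param tau_values Time constants (ms) assigned to the varied class.
#' @param tau_fixed Time constant of the other classes (ms, default 10).
#' @param low_input,high_input VIP drive defining the two states (Hz).
#' @return \code{experiment_result} with \code{$peaks} (tau, state, layer,
#'   frequency, power).
#' @export
time_constant_sweep <- function(C = default_circuit(), G = 300,
                                varied_class = "SST",
                                tau_values = c(5, 10, 20, 40),
                                tau_fixed = 10, low_input = 0,
                                high_input = 12, params = model_params(),
                                pyr_drive = 5, sst_baseline = 0,
                                n_trials = 10, duration = 5000, seed = 1,
                                psd_args = list()) {
  varied <- pop_index(class_pops(varied_class))
  CG <- scale_by_G(C, G)
  setup <- switch_setup("vip", sst_baseline)
  stim0 <- baseline_stim(pyr_drive, setup$extra)
  peaks <- NULL
  for (ti in seq_along(tau_values)) {
    tau <- rep(tau_fixed, 8L)
    tau[varied] <- tau_values[ti]
    p <- params; p$tau <- tau
    for (state in c("low", "high")) {
      inp <- if (state == "low") low_input else high_input
      drive <- stim0$baseline
      drive[pop_index(setup$targets)] <-
        drive[pop_index(setup$targets)] + inp
      st <- stimulus_protocol(setNames(drive, POPULATIONS))
      run <- run_trials(CG, p, st, duration, n_trials,
                        seed + 10000L * ti + (state == "high") * 1000L)
      pk <- peaks_row(run$traces, psd_args, G,
                      extra = list(tau = tau_values[ti], state = state))
      peaks <- rbind(peaks, pk)
    }
  }
  new_result("time_constant_sweep",
             list(G = G, varied_class = varied_class,
                  tau_values = tau_values, tau_fixed = tau_fixed,
                  seed = seed),
             peaks = peaks)
}

# zero all outputs of `source` onto populations of the opposite layer
cut_translaminar <- function(C, source) {
  src_layer <- populations()$layer[pop_index(source)]
  tgts <- POPULATIONS[populations()$layer != src_layer]
  for (tgt in tgts)
    C <- apply_lesion(C, lesion_spec("remove_connection",
                                     source = source, target = tgt))
  C
}

#' Translaminar propagation of state changes
#'
#' Drives one inhibitory cell type in a single layer and records the PYR
#' response of the opposite layer, with each candidate translaminar
#' pathway (the cross-layer outputs of each population of the input layer)
#' removed singly and jointly.
#'
#' @inheritParams switch_sweeps
#' @param G Single coupling value.
#' @param input_class \code{"VIP"}, \code{"PV"} or \code{"SST"}.
#' @param input_layer Layer receiving the swept drive.
#' @param background Named vector of constant background drives defining
#'   the circuit state (e.g. \code{c(VIP_sup = 40, VIP_deep = 40)} for the
#'   VIP-dominated state); default: SST-enhancing drive for VIP/PV input,
#'   VIP state for SST input.
#' @return \code{experiment_result} with \code{$curves} (condition, input,
#'   rate of the opposite-layer PYR population).
#' @export
translaminar_propagation <- function(C = default_circuit(), G = 100,
                                     input_class = "VIP",
                                     input_layer = "superficial",
                                     background = NULL,
                                     input_grid = seq(0, 100, by = 2),
                                     params = model_params(),
                                     pyr_drive = 5, settle_ms = 2000) {
  input_layer <- match.arg(input_layer, c("superficial", "deep"))
  if (is.null(background)) {
    background <- if (input_class %in% c("VIP", "PV"))
      c(SST_sup = 5, SST_deep = 5)
    else c(VIP_sup = 40, VIP_deep = 40)
  }
  pops <- populations()
  target <- pops$label[pops$cell_class == input_class &
                         pops$layer == input_layer]
  if (!length(target))
    stop(sprintf("no %s population in the %s layer", input_class,
                 input_layer), call. = FALSE)
  readout <- layer_pyr(setdiff(c("superficial", "deep"), input_layer))
  sources <- pops$label[pops$layer == input_layer]
  CG <- scale_by_G(C, G)
  stim <- baseline_stim(pyr_drive, background)

  conds <- c(list(intact = CG),
             setNames(lapply(sources, function(s)
               cut_translaminar(CG, s)),
               paste0("cut_", sources)))
  all_cut <- CG
  for (s in sources) all_cut <- cut_translaminar(all_cut, s)
  conds$cut_all <- all_cut

  curves <- NULL
  for (cond in names(conds)) {
    sw <- sweep_response(conds[[cond]], params, stim, target, input_grid,
                         "ascending", settle_ms = settle_ms)
    curves <- rbind(curves, data.frame(
      condition = cond, input = input_grid, rate = sw$rates[, readout]))
  }
  new_result("translaminar_propagation",
             list(G = G, input_class = input_class,
                  input_layer = input_layer, readout = readout,
                  background = background),
             curves = curves)
}

#' Feedforward / feedback weighted drive
#'
#' Scales a scalar external drive by a per-population input-weight vector
#' (e.g. empirical feedforward or feedback innervation profiles, supplied
#' by the user as configuration data) and sweeps the drive amplitude at
#' each G, recording steady-state rates and optionally spectral peaks.
#'
#' @inheritParams switch_sweeps
#' @param weights Named per-population input-weight vector (required).
#' @param amplitudes Drive amplitudes to sweep (Hz).
#' @param baseline Constant baseline drive added on top (default none).
#' @param spectra If \code{TRUE}, add noisy spectral peaks per amplitude.
#' @return \code{experiment_result} with \code{$rates} (G, amplitude,
#'   population, rate) and optionally \code{$peaks}.
#' @export
input_weighted_drive <- function(C = default_circuit(),
                                 G_values = c(150, 300), weights,
                                 amplitudes = seq(0, 40, by = 5),
                                 baseline = 0, params = model_params(),
                                 settle_ms = 2000, spectra = FALSE,
                                 n_trials = 10, duration = 5000,
                                 seed = 1, psd_args = list()) {
  if (missing(weights) || is.null(weights))
    stop("an input-weight vector is required (feedforward/feedback ",
         "profiles are user-supplied configuration data)", call. = FALSE)
  rates <- NULL; peaks <- NULL
  for (gi in seq_along(G_values)) {
    G <- G_values[gi]
    CG <- scale_by_G(C, G)
    for (ai in seq_along(amplitudes)) {
      amp <- amplitudes[ai]
      st <- stimulus_protocol(baseline = baseline,
                              input_weights = weights, amplitude = amp)
      r <- steady_state(CG, params, st, duration = settle_ms)
      rates <- rbind(rates, data.frame(G = G, amplitude = amp,
                                       population = POPULATIONS,
                                       rate = as.numeric(r)))
      if (spectra) {
        run <- run_trials(CG, params, st, duration, n_trials,
                          seed + 10000L * gi + 100L * ai)
        peaks <- rbind(peaks, peaks_row(run$traces, psd_args, G,
                                        extra = list(amplitude = amp)))
      }
    }
  }
  new_result("input_weighted_drive",
             list(G_values = G_values, weights = weights,
                  amplitudes = range(amplitudes), seed = seed),
             rates = rates, peaks = peaks)
}

#' Inverted self-connectivity experiment
#'
#' Exchanges the recurrent self-weights of PV and SST cells in both layers
#' (SST inherits the strong self-inhibition, PV loses it) and reruns the
#' SST-, VIP- and PV-input sweeps. With the inverted scheme the roles of
#' the cell types in the switch are predicted to invert: moderate SST
#' drive disinhibits PYR cells, while VIP/PV drive suppresses everything.
#'
#' @inheritParams switch_sweeps
#' @return \code{experiment_result} with \code{$curves} (switch, G, input,
#'   direction, population, rate) from the swapped matrix.
#' @export
inverted_selfconnection_experiment <- function(C = default_circuit(),
                                               G_values = c(150, 300, 450),
                                               input_grid = seq(0, 100, by = 1),
                                               params = model_params(),
                                               pyr_drive = 5,
                                               sst_baseline = 5,
                                               settle_ms = 2000) {
  Cs <- apply_lesion(C, lesion_spec("swap_self_connections"))
  curves <- NULL
  for (sw in c("sst", "vip", "pv")) {
    res <- switch_sweeps(Cs, G_values, sw, input_grid, params, pyr_drive,
                         sst_baseline, settle_ms = settle_ms)
    curves <- rbind(curves, cbind(switch = sw, res$curves))
  }
  new_result("inverted_selfconnection",
             list(G_values = G_values, input_grid = range(input_grid)),
             curves = curves, swapped = Cs)
}

# ---------------------------------------------------------------------------
# protocol registry: new sweeps are config-only additions
# ---------------------------------------------------------------------------

protocol_table <- function() {
  list(
    spontaneous_g_sweep = spontaneous_g_sweep,
    lesion_battery = lesion_battery,
    switch_sweeps = switch_sweeps,
    time_constant_sweep = time_constant_sweep,
    translaminar_propagation = translaminar_propagation,
    input_weighted_drive = input_weighted_drive,
    inverted_selfconnection_experiment = inverted_selfconnection_experiment
  )
}

#' List the registered experiment protocols
#' @return Character vector of protocol names.
#' @export
list_protocols <- function() names(protocol_table())

#' Run a registered protocol from a configuration list
#'
#' @param name Protocol name (see [list_protocols()]).
#' @param config Named list of arguments for the protocol function.
#' @return The protocol's \code{experiment_result}.
#' @export
run_protocol <- function(name, config = list()) {
  tab <- protocol_table()
  if (!name %in% names(tab))
    stop(sprintf("unknown protocol '%s'; known protocols: %s", name,
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  do.call(tab[[name]], config)
}

#' Write the tables of an experiment result to CSV files
#'
#' @param res An \code{experiment_result}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_result_tables <- function(res, dir) {
  stopifnot(inherits(res, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (tb in setdiff(names(res), c("name", "config"))) {
    if (!is.data.frame(res[[tb]]) || !nrow(res[[tb]])) next
    p <- file.path(dir, paste0(res$name, "_", tb, ".csv"))
    write.csv(res[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
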