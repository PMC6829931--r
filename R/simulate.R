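#' Parameters of the synthetic seated-pressure generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: the seat
#' contact pattern, the per-task reaching kinematics, the three compensatory
#' effects, the noise model and the experimental design. The baseline
#' posture is modelled as two lateral pressure bumps at the ischial
#' tuberosities plus a lower-amplitude anterior thigh band, each a 2-D
#' Gaussian in grid units. Compensation perturbs this pattern over the reach
#' cycle: trunk lean-forward shifts the load toward the front rows, trunk
#' rotation shifts it laterally and loads the arm-side ischium while
#' unloading the other, and shoulder elevation produces a small ipsilateral
#' shift and loads the ipsilateral ischium through the associated pelvic
#' hike.
#'
#' Default effect sizes and noise levels place the default dataset in a
#' separable-but-noisy regime; units are arbitrary device units (only
#' relative structure reaches the features).
#'
#' @param n_rows,n_cols Grid dimensions (default 32 x 32).
#' @param sample_rate Pressure sampling rate in Hz (default 50).
#' @param duration Trial duration in seconds (default 2, one reach cycle).
#' @param n_subjects,reps Design: number of subjects (default 8) and
#'   repetitions per task per side (default 30).
#' @param tasks,sides Task and side levels of the design.
#' @param compensation_map Named map task -> dominant compensation label
#'   assigned to affected-side trials.
#' @param label_mixture Optional named probability vector over
#'   `c("TLF","TR","SE")`; when given, affected-side labels are drawn from
#'   it instead of `compensation_map` (robustness experiments).
#' @param ischial_row,ischial_cols,ischial_amp,ischial_sd Ischial bump
#'   geometry: row centre, the two column centres, peak amplitude, spread.
#' @param thigh_row,thigh_amp,thigh_sd_row,thigh_sd_col Thigh band geometry.
#' @param subj_center_sd,subj_amp_sd Between-subject SD of bump centres
#'   (sensors) and log-amplitude.
#' @param task_move_amp Baseline reach-related seat-load displacement
#'   (sensors) present in every trial of a task, compensated or not.
#' @param updown_amp_mod Global amplitude modulation of the up-and-down
#'   task.
#' @param wiggle_amp Amplitude (sensors) of the random smooth postural sway
#'   added to every trial.
#' @param tlf_forward_shift Forward (front-ward) load shift of trunk
#'   lean-forward, in rows.
#' @param tr_lateral_shift,tr_amp_asym Lateral shift (columns) and
#'   ischial loading asymmetry of trunk rotation.
#' @param se_ipsilateral_shift,se_amp_asym Small ipsilateral shift
#'   (columns) and amplitude asymmetry of shoulder elevation.
#' @param noise_add_sd,noise_mult_sd Per-sensor additive SD (device units)
#'   and multiplicative SD per frame.
#' @param trial_amp_jitter SD of the per-trial log amplitude jitter.
#' @param semg_sample_rate,semg_duration,semg_band sEMG companion signal:
#'   sampling rate (Hz), duration (s), band of the band-limited noise
#'   carrier (Hz).
#' @param semg_affected_gain Gain applied to the muscle group targeted by a
#'   compensation pattern on the affected side (default 1.5).
#' @param seed Root seed recorded with the parameters (default 42); can be
#'   overridden in [simulate_dataset()].
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_rows = 32, n_cols = 32, sample_rate = 50,
                       duration = 2,
                       n_subjects = 8, reps = 30,
                       tasks = c("back-and-forth", "side-to-side",
                                 "up-and-down"),
                       sides = c("healthy", "affected"),
                       compensation_map = c("back-and-forth" = "TLF",
                                            "side-to-side" = "TR",
                                            "up-and-down" = "SE"),
                       label_mixture = NULL,
                       ischial_row = 20, ischial_cols = c(12, 21),
                       ischial_amp = 60, ischial_sd = 3,
                       thigh_row = 9, thigh_amp = 18,
                       thigh_sd_row = 4, thigh_sd_col = 3.5,
                       subj_center_sd = 0.8, subj_amp_sd = 0.12,
                       task_move_amp = 0.8, updown_amp_mod = 0.08,
                       wiggle_amp = 0.25,
                       tlf_forward_shift = 4,
                       tr_lateral_shift = 3, tr_amp_asym = 0.25,
                       se_ipsilateral_shift = 1, se_amp_asym = 0.3,
                       noise_add_sd = 1.5, noise_mult_sd = 0.06,
                       trial_amp_jitter = 0.08,
                       semg_sample_rate = 2000, semg_duration = 2,
                       semg_band = c(20, 200), semg_affected_gain = 1.5,
                       seed = 42) {
  p <- as.list(environment())
  sds <- c(p$ischial_sd, p$thigh_sd_row, p$thigh_sd_col, p$subj_center_sd,
           p$subj_amp_sd, p$noise_add_sd, p$noise_mult_sd,
           p$trial_amp_jitter, p$wiggle_amp)
  if (any(sds < 0)) abort("All spread/noise parameters must be >= 0.")
  if (p$reps < 1) abort("`reps` must be at least 1.")
  if (p$n_subjects < 1) abort("`n_subjects` must be at least 1.")
  shifts <- c(p$tlf_forward_shift, p$tr_lateral_shift,
              p$se_ipsilateral_shift, p$task_move_amp)
  if (any(shifts < 0)) abort("Shift effect sizes must be >= 0.")
  # peaks must stay on-grid under the largest configured displacement
  max_lat <- p$task_move_amp + max(p$tr_lateral_shift,
                                   p$se_ipsilateral_shift) +
    p$wiggle_amp + 3 * p$subj_center_sd
  max_lon <- p$task_move_amp + p$tlf_forward_shift + p$wiggle_amp +
    3 * p$subj_center_sd
  if (min(p$ischial_cols) - max_lat < 1 ||
      max(p$ischial_cols) + max_lat > p$n_cols) {
    abort("Lateral shift pushes an ischial peak off-grid.")
  }
  if (p$ischial_row + max_lon > p$n_rows || p$thigh_row - max_lon < 1) {
    abort("Longitudinal shift pushes a pressure peak off-grid.")
  }
  if (!all(p$tasks %in% names(p$compensation_map)) &&
      is.null(p$label_mixture)) {
    abort("Every task needs an entry in `compensation_map`.")
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %dx%d grid @ %g Hz, %gs trials; %d subjects x %d sides x %d tasks x %d reps\n",
    x$n_rows, x$n_cols, x$sample_rate, x$duration, x$n_subjects,
    length(x$sides), length(x$tasks), x$reps))
  cat(sprintf(
    "  effects: TLF %.2g rows, TR %.2g cols (asym %.2g), SE %.2g cols (asym %.2g)\n",
    x$tlf_forward_shift, x$tr_lateral_shift, x$tr_amp_asym,
    x$se_ipsilateral_shift, x$se_amp_asym))
  cat(sprintf("  noise: additive %.2g, multiplicative %.2g; seed %s\n",
              x$noise_add_sd, x$noise_mult_sd, format(x$seed)))
  invisible(x)
}

# Per-subject anthropometric variation: a common centre offset, an overall
# amplitude factor and the affected body side.
subject_profile <- function(params) {
  list(
    d_row = rnorm(1, 0, params$subj_center_sd),
    d_col = rnorm(1, 0, params$subj_center_sd),
    amp_factor = exp(rnorm(1, 0, params$subj_amp_sd)),
    affected = sample(c("left", "right"), 1))
}

#' Simulate one labeled pressure trial
#'
#' Generates the frame stack of a single reaching repetition. A smooth reach
#' envelope `e(t) = sin^2(pi t / T)` drives both the task's baseline seat
#' displacement and the label's compensatory effect; random postural sway,
#' per-trial amplitude jitter and per-sensor noise are superimposed. The
#' random draws are identical for every label, so with all effect sizes at
#' zero a compensated trial is bit-identical to a noncompensated one at the
#' same seed.
#'
#' @param label Posture label: `"NC"`, `"TLF"`, `"TR"`, `"SE"`.
#' @param profile A subject profile (internal; `NULL` gives a nominal
#'   subject).
#' @param params A [sim_params()] object.
#' @param seed Optional seed for this trial; `NULL` continues the caller's
#'   RNG stream.
#' @param task Reaching task of the trial.
#' @param side `"healthy"` or `"affected"`.
#' @param subject Subject identifier stored in the metadata.
#' @return A [pressure_sequence()].
#' @export
simulate_trial <- function(label = "NC", profile = NULL,
                           params = sim_params(), seed = NULL,
                           task = "back-and-forth", side = "healthy",
                           subject = "S1") {
  stopifnot(inherits(params, "sim_params"))
  if (!label %in% CLASSES_4) abort("Unknown label.")
  if (is.null(profile)) {
    profile <- list(d_row = 0, d_col = 0, amp_factor = 1,
                    affected = "right")
  }
  with_seed(seed, {
    nr <- params$n_rows
    nc <- params$n_cols
    T_ <- max(2L, as.integer(round(params$duration * params$sample_rate)))
    tt <- seq_len(T_)
    env <- sin(pi * (tt - 1) / (T_ - 1))^2

    # which arm moves: the affected arm on the affected side, the other
    # arm on the healthy side; lateral direction +1 = rightward (higher x)
    arm <- if (side == "affected") profile$affected else
      setdiff(c("left", "right"), profile$affected)
    dir <- if (arm == "right") 1 else -1

    # random smooth postural sway, drawn identically for every label
    w_freq <- stats::runif(1, 0.8, 1.6)
    w_phase <- stats::runif(2, 0, 2 * pi)
    w_amp <- abs(rnorm(2, 0, params$wiggle_amp))
    g_trial <- exp(rnorm(1, 0, params$trial_amp_jitter))
    mult_noise <- rnorm(nr * nc * T_, 0, params$noise_mult_sd)
    add_noise <- rnorm(nr * nc * T_, 0, params$noise_add_sd)

    tsec <- (tt - 1) / params$sample_rate
    row_shift <- w_amp[1] * sin(2 * pi * w_freq * tsec + w_phase[1])
    col_shift <- w_amp[2] * sin(2 * pi * w_freq * tsec + w_phase[2])
    amp_mod <- rep(1, T_)   # global amplitude modulation
    asym <- rep(0, T_)      # +1 loads the right side, -1 the left

    # task-related baseline movement (present in every trial of the task)
    if (task == "back-and-forth") {
      row_shift <- row_shift - params$task_move_amp * env
    } else if (task == "side-to-side") {
      col_shift <- col_shift + dir * params$task_move_amp * env
    } else if (task == "up-and-down") {
      amp_mod <- amp_mod * (1 + params$updown_amp_mod * env)
    }

    # compensatory effects
    if (label == "TLF") {
      row_shift <- row_shift - params$tlf_forward_shift * env
    } else if (label == "TR") {
      col_shift <- col_shift + dir * params$tr_lateral_shift * env
      asym <- asym + dir * params$tr_amp_asym * env
    } else if (label == "SE") {
      # pelvic hike under shoulder elevation loads the ipsilateral ischium
      col_shift <- col_shift + dir * params$se_ipsilateral_shift * env
      asym <- asym + dir * params$se_amp_asym * env
    }

    comp <- list(  # (row, col, amp, sd_row, sd_col, body side)
      list(r = params$ischial_row, c = params$ischial_cols[1],
           a = params$ischial_amp, sr = params$ischial_sd,
           sc = params$ischial_sd, bs = -1),
      list(r = params$ischial_row, c = params$ischial_cols[2],
           a = params$ischial_amp, sr = params$ischial_sd,
           sc = params$ischial_sd, bs = 1),
      list(r = params$thigh_row, c = params$ischial_cols[1],
           a = params$thigh_amp, sr = params$thigh_sd_row,
           sc = params$thigh_sd_col, bs = -1),
      list(r = params$thigh_row, c = params$ischial_cols[2],
           a = params$thigh_amp, sr = params$thigh_sd_row,
           sc = params$thigh_sd_col, bs = 1))

    rows <- seq_len(nr)
    cols <- seq_len(nc)
    frames <- array(0, dim = c(nr, nc, T_))
    for (t in tt) {
      fr <- matrix(0, nr, nc)
      for (k in comp) {
        r_k <- k$r + profile$d_row + row_shift[t]
        c_k <- k$c + profile$d_col + col_shift[t]
        a_k <- k$a * profile$amp_factor * g_trial * amp_mod[t] *
          (1 + k$bs * asym[t])
        fr <- fr + a_k * outer(exp(-(rows - r_k)^2 / (2 * k$sr^2)),
                               exp(-(cols - c_k)^2 / (2 * k$sc^2)))
      }
      frames[, , t] <- fr
    }
    frames <- frames * (1 + array(mult_noise, dim = dim(frames))) +
      array(add_noise, dim = dim(frames))
    frames <- pmax(frames, 0)
    pressure_sequence(frames, sample_rate = params$sample_rate,
                      subject = subject, task = task, side = side,
                      label = label)
  })
}

#' Simulate a full labeled dataset of seated-pressure trials
#'
#' Generates the complete design: `n_subjects x sides x tasks x reps`
#' trials. Healthy-side trials are labeled `NC`; affected-side trials
#' receive the dominant compensation pattern of their task from
#' `compensation_map` (or draws from `label_mixture` when configured). All
#' randomness flows from one root seed, so the same seed regenerates the
#' dataset bit-identically.
#'
#' @param params A [sim_params()] object.
#' @param seed Root seed; defaults to `params$seed`.
#' @return A `sim_dataset`: list with `trials` (list of
#'   [pressure_sequence()]), `manifest` (tibble of trial, subject, task,
#'   side, label), `params` and `seed`.
#' @export
simulate_dataset <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  seed <- seed %||% params$seed
  with_seed(seed, {
    subjects <- sprintf("S%d", seq_len(params$n_subjects))
    profiles <- lapply(subjects, function(s) subject_profile(params))
    names(profiles) <- subjects

    design <- expand.grid(rep = seq_len(params$reps),
                          task = params$tasks,
                          side = params$sides,
                          subject = subjects,
                          stringsAsFactors = FALSE)
    design <- design[order(match(design$subject, subjects)), ]
    trials <- vector("list", nrow(design))
    labels <- character(nrow(design))
    for (i in seq_len(nrow(design))) {
      d <- design[i, ]
      if (d$side == "healthy") {
        lab <- "NC"
      } else if (!is.null(params$label_mixture)) {
        lab <- sample(names(params$label_mixture), 1,
                      prob = params$label_mixture)
      } else {
        lab <- unname(params$compensation_map[[d$task]])
      }
      labels[i] <- lab
      trials[[i]] <- simulate_trial(
        label = lab, profile = profiles[[d$subject]], params = params,
        seed = NULL, task = d$task, side = d$side, subject = d$subject)
    }
    manifest <- tibble::tibble(
      trial = seq_len(nrow(design)),
      subject = design$subject, task = design$task,
      side = design$side, label = labels)
    structure(list(trials = trials, manifest = manifest,
                   params = params, seed = seed),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d trials, seed %s\n",
              nrow(x$manifest), format(x$seed)))
  print(dplyr::count(x$manifest, .data$side, .data$label))
  invisible(x)
}

# Muscle groups whose activity a compensation pattern recruits: lean-forward
# engages the abdominals and thoracic erector spinae, rotation the lumbar
# erector spinae, shoulder elevation the descending trapezius.
compensation_muscles <- function(label) {
  switch(label,
         TLF = c("LRA", "RRA", "LOEA", "ROEA", "LTES", "RTES"),
         TR = c("LLES", "RLES"),
         SE = "DT",
         character(0))
}

#' Simulate a companion sEMG recording
#'
#' Nine channels of 20–200 Hz band-limited noise modulated by the reach
#' envelope. On the affected side the channels of the muscle group recruited
#' by the trial's compensation pattern are scaled by `semg_affected_gain`;
#' healthy-side recordings use unit gain everywhere.
#'
#' @param label Movement pattern (`"TLF"`, `"TR"`, `"SE"`, or `"NC"`).
#' @param side `"healthy"` or `"affected"`.
#' @param params A [sim_params()] object.
#' @param seed Optional seed; `NULL` continues the caller's stream.
#' @param subject Subject id for the metadata.
#' @param gain_scale Multiplies the affected-side gain excess (1 keeps the
#'   configured gain; 0 gives identical statistics on both sides).
#' @return An [emg_recording()].
#' @export
simulate_semg <- function(label = "TLF", side = "affected",
                          params = sim_params(), seed = NULL,
                          subject = "S1", gain_scale = 1) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, {
    fs <- params$semg_sample_rate
    n <- as.integer(round(params$semg_duration * fs))
    tt <- seq_len(n)
    env <- 0.2 + 0.8 * sin(pi * (tt - 1) / (n - 1))^2
    targeted <- compensation_muscles(label)
    gain_target <- 1 + gain_scale * (params$semg_affected_gain - 1)
    ch <- lapply(EMG_MUSCLES, function(m) {
      carrier <- butter_filtfilt(rnorm(n), params$semg_band, fs, "pass")
      carrier <- carrier / max(rms(carrier), .Machine$double.eps)
      g <- if (side == "affected" && m %in% targeted) gain_target else 1
      0.5 * g * env * carrier   # ~0.5 mV nominal amplitude
    })
    names(ch) <- EMG_MUSCLES
    emg_recording(ch, sample_rate = fs, subject = subject, side = side,
                  label = label)
  })
}

#' Simulate an sEMG study and summarise it as per-trial RMS
#'
#' Generates one recording per subject x movement x side cell, runs the
#' preprocessing chain without amplitude normalization (a side-invariant
#' reference is required for between-side amplitude comparison) and returns
#' the per-channel RMS table ready for [ave_rms()] and [paired_ttest()].
#'
#' @param params A [sim_params()] object.
#' @param seed Root seed.
#' @param movements Movement patterns to simulate (default TLF, TR, SE).
#' @param gain_scale Passed to [simulate_semg()].
#' @return A tibble: `subject`, `side`, `label`, `channel`, `rms`.
#' @export
simulate_semg_study <- function(params = sim_params(), seed = NULL,
                                movements = c("TLF", "TR", "SE"),
                                gain_scale = 1) {
  seed <- seed %||% params$seed
  with_seed(seed, {
    subjects <- sprintf("S%d", seq_len(params$n_subjects))
    grid <- expand.grid(subject = subjects, label = movements,
                        side = c("healthy", "affected"),
                        stringsAsFactors = FALSE)
    purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      rec <- simulate_semg(label = g$label, side = g$side, params = params,
                           seed = NULL, subject = g$subject,
                           gain_scale = gain_scale)
      rec <- preprocess_emg(rec, band = params$semg_band,
                            normalize = "none")
      emg_rms(rec)
    })
  })
}
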