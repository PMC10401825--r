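# Single-compartment respiratory mechanics: per-breath equation-of-motion
# fitting and maximal-compliance PEEP selection for decremental PEEP trials.

#' Breath waveform container
#'
#' One respiratory cycle of sampled airway pressure, flow and volume.
#' Volume must be consistent with the integrated flow within 2\%.
#'
#' @param time Sample times (s), strictly increasing.
#' @param pressure Airway pressure (cmH2O).
#' @param flow Airway flow (l/s).
#' @param volume Volume above end-expiration (l).
#' @return A list of class `breath_waveform`.
#' @export
breath_waveform <- function(time, pressure, flow, volume) {
  n <- length(time)
  if (n < 10L) stop("a breath needs at least 10 samples")
  if (length(pressure) != n || length(flow) != n || length(volume) != n)
    stop("channels must have equal length")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  # trapezoidal integral of flow against recorded volume
  vint <- c(0, cumsum(diff(time) * (flow[-1] + flow[-n]) / 2))
  vint <- vint - vint[1] + volume[1]
  vt <- max(volume) - min(volume)
  if (vt <= 0) stop("volume is constant over the breath")
  if (max(abs(vint - volume)) > 0.02 * vt)
    stop("volume inconsistent with integrated flow (> 2% of tidal volume)")
  structure(list(time = time, pressure = pressure, flow = flow,
                 volume = volume),
            class = "breath_waveform")
}

#' Synthesize a volume-controlled breath
#'
#' Constant inspiratory flow followed by passive exponential expiration,
#' with pressure generated by the single-compartment equation of motion
#' P = V/C + R V' + PEEP. Defaults reflect an injured surfactant-depleted
#' lung (compliance 9 ml/cmH2O, resistance 14 cmH2O/l/s).
#'
#' @param c_ml Compliance (ml/cmH2O).
#' @param r_cmh2o Resistance (cmH2O/l/s).
#' @param peep PEEP (cmH2O), the end-expiratory pressure offset.
#' @param vt_ml Tidal volume (ml).
#' @param rr Respiratory rate (breaths/min).
#' @param ie Inspiratory-to-expiratory time ratio.
#' @param fs Sampling rate (Hz).
#' @param noise_sd Gaussian pressure noise SD (cmH2O); 0 for a noiseless
#'   breath.
#' @return A [breath_waveform()].
#' @export
synth_breath <- function(c_ml = 9, r_cmh2o = 14, peep = 7, vt_ml = 172,
                         rr = 26, ie = 0.5, fs = 100, noise_sd = 0) {
  t_cycle <- 60 / rr
  t_insp <- t_cycle * ie / (1 + ie)
  tt <- seq(0, t_cycle, by = 1 / fs)
  vt <- vt_ml / 1000
  c_l <- c_ml / 1000
  tau <- r_cmh2o * c_l
  insp <- tt <= t_insp
  flow <- ifelse(insp, vt / t_insp,
                 -(vt / tau) * exp(-(tt - t_insp) / tau))
  # volume as the discrete integral of flow keeps the channels consistent
  n <- length(tt)
  vol <- c(0, cumsum(diff(tt) * (flow[-1] + flow[-n]) / 2))
  pressure <- vol / c_l + r_cmh2o * flow + peep
  if (noise_sd > 0) pressure <- pressure + stats::rnorm(length(tt), 0,
                                                        noise_sd)
  breath_waveform(tt, pressure, flow, vol)
}

#' Fit the single-compartment equation of motion
#'
#' Ordinary least squares of P(t) = V(t)/C + R V'(t) + P0 over the full
#' cycle, giving compliance, resistance and the pressure offset.
#'
#' @param breath A [breath_waveform()].
#' @return A list with `c_ml` (ml/cmH2O), `r_cmh2o` (cmH2O/l/s), `p0`
#'   (cmH2O) and `rms` residual (cmH2O).
#' @export
fit_equation_of_motion <- function(breath) {
  stopifnot(inherits(breath, "breath_waveform"))
  x <- cbind(1, breath$volume, breath$flow)
  if (qr(x)$rank < 3L)
    stop("rank-deficient design: volume and flow are collinear")
  fit <- stats::lm.fit(x, breath$pressure)
  cf <- fit$coefficients
  if (cf[2] <= 0) warning("non-positive elastance estimate")
  list(c_ml = unname(1000 / cf[2]), r_cmh2o = unname(cf[3]),
       p0 = unname(cf[1]),
       rms = sqrt(mean(fit$residuals^2)))
}

#' Decremental PEEP trial record
#'
#' @param peep PEEP levels (cmH2O), strictly decreasing.
#' @param compliance Fitted compliance per level (ml/cmH2O), positive.
#' @param resistance Optional fitted resistance per level (cmH2O/l/s).
#' @return A data frame of class `peep_trial_record`.
#' @export
peep_trial_record <- function(peep, compliance, resistance = NA_real_) {
  if (!length(peep)) stop("empty PEEP trial record")
  if (length(peep) > 1L && any(diff(peep) >= 0))
    stop("PEEP levels must be strictly decreasing")
  if (any(compliance <= 0)) stop("compliances must be positive")
  structure(data.frame(peep = peep, compliance = compliance,
                       resistance = resistance),
            class = c("peep_trial_record", "data.frame"))
}

#' Fit every breath of a PEEP trial
#'
#' Fits the equation of motion to each breath and aggregates per PEEP level
#' (mean of the per-breath estimates).
#'
#' @param df Data frame with columns `time`, `pressure`, `flow`, `volume`,
#'   `breath` (breath id) and `peep`.
#' @return A [peep_trial_record()] (levels ordered as encountered, which
#'   must be decremental).
#' @export
fit_peep_trial <- function(df) {
  stopifnot(all(c("time", "pressure", "flow", "volume", "breath", "peep")
                %in% names(df)))
  ids <- unique(df$breath)
  fits <- lapply(ids, function(b) {
    d <- df[df$breath == b, ]
    f <- fit_equation_of_motion(
      breath_waveform(d$time, d$pressure, d$flow, d$volume))
    data.frame(peep = d$peep[1], c_ml = f$c_ml, r = f$r_cmh2o)
  })
  fits <- do.call(rbind, fits)
  levels <- unique(fits$peep)
  agg_c <- vapply(levels, function(p) mean(fits$c_ml[fits$peep == p]),
                  numeric(1))
  agg_r <- vapply(levels, function(p) mean(fits$r[fits$peep == p]),
                  numeric(1))
  peep_trial_record(levels, agg_c, agg_r)
}

#' Maximal-compliance PEEP selection
#'
#' Returns the PEEP of the maximal fitted compliance along a decremental
#' trial; ties are broken toward the higher PEEP (more
#' recruitment-preserving) and logged as an attribute.
#'
#' @param trial A [peep_trial_record()].
#' @return The selected PEEP (cmH2O), with attribute `tie` when the maximum
#'   was not unique.
#' @export
select_peep_max_compliance <- function(trial) {
  stopifnot(inherits(trial, "peep_trial_record"))
  if (!nrow(trial)) stop("empty PEEP trial record")
  cmax <- max(trial$compliance)
  cand <- trial$peep[trial$compliance >= cmax - 1e-12]
  sel <- max(cand)
  if (length(cand) > 1L) attr(sel, "tie") <- cand
  sel
}
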