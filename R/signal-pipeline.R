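# Raw four-channel voltage frames -> corrected same-wavelength far/close
# spatial ratios: dark subtraction, PTFE reference normalization (applied
# exactly once), and low-SNR flagging.

#' Construct a four-channel measurement frame
#'
#' @param v_on named numeric: LED-on voltages for channels CH1..CH4 (V).
#' @param v_dark named numeric: LED-off baselines for the same channels (V).
#' @param role `"sample"` or `"reference"`.
#' @return data.frame of class `measurement_frame` with columns `channel`,
#'   `v_on`, `v_dark` and attribute `role`.
#' @export
measurement_frame <- function(v_on, v_dark, role = c("sample", "reference")) {
  role <- match.arg(role)
  chans <- channel_map()$channel
  if (!all(chans %in% names(v_on)) || !all(chans %in% names(v_dark)))
    stop_srswater("v_on and v_dark must name all channels CH1..CH4",
                  "srswater_parse_error")
  v_on <- v_on[chans]
  v_dark <- v_dark[chans]
  if (any(!is.finite(v_on)) || any(!is.finite(v_dark)))
    stop_srswater("voltages must be finite", "srswater_domain_error")
  out <- data.frame(channel = chans, v_on = as.numeric(v_on),
                    v_dark = as.numeric(v_dark), stringsAsFactors = FALSE)
  attr(out, "role") <- role
  class(out) <- c("measurement_frame", "data.frame")
  out
}

#' Average repeated frames channel-wise
#'
#' Arithmetic mean of `v_on` and `v_dark` per channel across repeated
#' frames of the same role; the replicate count is recorded as an attribute.
#'
#' @param frames list of `measurement_frame`s with identical roles.
#' @return a single averaged `measurement_frame` with attribute `n_averaged`.
#' @export
average_frames <- function(frames) {
  stopifnot(length(frames) >= 1)
  roles <- vapply(frames, function(f) attr(f, "role"), character(1))
  if (length(unique(roles)) != 1)
    stop_srswater("cannot average frames with mixed roles",
                  "srswater_domain_error")
  chans <- channel_map()$channel
  von <- rowMeans(vapply(frames, function(f)
    f$v_on[match(chans, f$channel)], numeric(4)))
  vdk <- rowMeans(vapply(frames, function(f)
    f$v_dark[match(chans, f$channel)], numeric(4)))
  out <- measurement_frame(setNames(von, chans), setNames(vdk, chans),
                           role = roles[1])
  attr(out, "n_averaged") <- length(frames)
  out
}

#' Read measurement frames from CSV
#'
#' Expected columns: `frame_id`, `role` (sample|reference), `channel`
#' (CH1..CH4), `v_on_V`, `v_dark_V`. Frames sharing a role are averaged.
#'
#' @param path CSV file path.
#' @return list with elements `sample` and `reference`
#'   (`measurement_frame`s; NULL when a role is absent).
#' @export
read_measurement_csv <- function(path) {
  if (!file.exists(path))
    stop_srswater(sprintf("measurement file not found: %s", path),
                  "srswater_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "role", "channel", "v_on_V", "v_dark_V")
  if (!all(need %in% names(df)))
    stop_srswater(paste("measurement CSV must contain columns:",
                        paste(need, collapse = ", ")),
                  "srswater_parse_error")
  per_role <- function(role) {
    d <- df[df$role == role, ]
    if (nrow(d) == 0) return(NULL)
    frames <- lapply(split(d, d$frame_id), function(fr)
      measurement_frame(setNames(fr$v_on_V, fr$channel),
                        setNames(fr$v_dark_V, fr$channel), role = role))
    average_frames(unname(frames))
  }
  list(sample = per_role("sample"), reference = per_role("reference"))
}

#' Dark-subtract a frame
#'
#' \eqn{S^{raw} = V^{on} - V^{dark}} per channel. May be non-positive; such
#' channels are flagged downstream, not here.
#'
#' @param frame a [measurement_frame()].
#' @return named numeric vector of raw signals (V) by channel.
#' @export
dark_subtract <- function(frame) {
  stopifnot(inherits(frame, "measurement_frame"))
  setNames(frame$v_on - frame$v_dark, frame$channel)
}

#' Normalize a sample signal to the PTFE reference
#'
#' \eqn{S^{norm} = S^{raw}_{sample} / S^{raw}_{ref}}.
#'
#' @param sample_S dark-subtracted sample signal (V).
#' @param reference_S dark-subtracted reference signal (V, > 0).
#' @return unitless normalized signal.
#' @export
normalize_to_reference <- function(sample_S, reference_S) {
  if (any(reference_S <= 0))
    stop_srswater("reference signal must be positive",
                  "srswater_reference_invalid")
  sample_S / reference_S
}

#' Corrected same-wavelength far/close spatial ratio
#'
#' \deqn{r^{corr}_\lambda = \frac{S^{raw}_{\lambda,\rho_f,sample}}
#'   {S^{raw}_{\lambda,\rho_c,sample}} \cdot
#'   \frac{S^{raw}_{\lambda,\rho_c,ref}}{S^{raw}_{\lambda,\rho_f,ref}}}
#' Invariant to per-channel multiplicative gains applied identically to
#' sample and reference. Any non-positive raw value flags the wavelength
#' low-SNR.
#'
#' @param frame_sample sample [measurement_frame()].
#' @param frame_reference reference [measurement_frame()].
#' @param wavelength wavelength (nm).
#' @return unitless corrected ratio.
#' @export
corrected_ratio <- function(frame_sample, frame_reference, wavelength) {
  cm <- channel_map()
  ch_far <- cm$channel[cm$wavelength_nm == wavelength &
                         cm$separation == "far"]
  ch_close <- cm$channel[cm$wavelength_nm == wavelength &
                           cm$separation == "close"]
  if (length(ch_far) != 1 || length(ch_close) != 1)
    stop_srswater(sprintf("unknown wavelength %g nm", wavelength),
                  "srswater_domain_error")
  s <- dark_subtract(frame_sample)
  r <- dark_subtract(frame_reference)
  vals <- c(sample_far = unname(s[ch_far]), sample_close = unname(s[ch_close]),
            ref_far = unname(r[ch_far]), ref_close = unname(r[ch_close]))
  if (any(vals <= 0))
    stop_srswater(sprintf(
      "low-SNR at %g nm: non-positive raw signal in %s", wavelength,
      paste(names(vals)[vals <= 0], collapse = ", ")), "srswater_low_snr")
  (vals[["sample_far"]] / vals[["sample_close"]]) *
    (vals[["ref_close"]] / vals[["ref_far"]])
}

#' Corrected ratios for all wavelengths with exclusion reasons
#'
#' @param frame_sample sample [measurement_frame()].
#' @param frame_reference reference [measurement_frame()].
#' @param wavelengths wavelengths (nm) to evaluate.
#' @return list of class `corrected_ratios`: `r_corr` (named numeric of
#'   successes) and `excluded` (named character of reasons).
#' @export
corrected_ratios <- function(frame_sample, frame_reference,
                             wavelengths = swir_wavelengths()) {
  r_corr <- numeric(0)
  excluded <- character(0)
  for (wl in wavelengths) {
    res <- tryCatch(corrected_ratio(frame_sample, frame_reference, wl),
                    srswater_low_snr = function(e) e)
    if (inherits(res, "condition"))
      excluded[as.character(wl)] <- conditionMessage(res)
    else r_corr[as.character(wl)] <- res
  }
  structure(list(r_corr = r_corr, excluded = excluded),
            class = "corrected_ratios")
}
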