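#' Per-event timing model for a bdTEM acquisition
#'
#' Collects the per-event times that determine section throughput. Defaults
#' follow the published system constants: ~37 ms average stage motion per
#' step (the mean of the 34 ms x-axis and 40 ms y-axis motion times) plus an
#' extra 10 ms of settle added to each movement, a 2.2-minute per-section
#' transition (tape advance, overview, beam centring, autofocus), and a
#' 120 ms camera exposure.
#'
#' @param exposure_s Camera exposure per tile (s).
#' @param acq_overhead_s Per-tile acquisition-software/readout overhead (s);
#'   the one per-tile constant not printed anywhere, see
#'   [fit_acq_overhead()].
#' @param stage_move_s Stage motion time per step (s).
#' @param stage_settle_s Additional settle time per stage step (s).
#' @param deflection_settle_s Settle time per beam deflection (s).
#' @param transition_s Per-section transition overhead (s).
#' @param uptime_frac Facility uptime fraction in `(0, 1]`.
#' @return An object of class `timing_model`.
#' @export
timing_model <- function(exposure_s = 0.120,
                         acq_overhead_s = 0.034,
                         stage_move_s = 0.037,
                         stage_settle_s = 0.010,
                         deflection_settle_s = 0.006,
                         transition_s = 132,
                         uptime_frac = 1.0) {
  vals <- c(exposure_s, acq_overhead_s, stage_move_s, stage_settle_s,
            deflection_settle_s, transition_s)
  if (any(vals < 0)) stop("all times must be >= 0", call. = FALSE)
  if (uptime_frac <= 0 || uptime_frac > 1)
    stop("`uptime_frac` must be in (0, 1]", call. = FALSE)
  structure(list(
    exposure_s = exposure_s, acq_overhead_s = acq_overhead_s,
    stage_move_s = stage_move_s, stage_settle_s = stage_settle_s,
    deflection_settle_s = deflection_settle_s, transition_s = transition_s,
    uptime_frac = uptime_frac
  ), class = "timing_model")
}

#' Burst imaging rate
#'
#' Pixels per second counting exposure time only: a 36-MPix camera at 40 ms
#' exposure bursts at 900 MPix/s.
#'
#' @param tile_pixels Pixels per tile.
#' @param exposure_s Exposure time (s), > 0.
#' @return Rate in MPix/s.
#' @export
burst_rate <- function(tile_pixels, exposure_s) {
  if (exposure_s <= 0) stop("`exposure_s` must be > 0", call. = FALSE)
  tile_pixels / exposure_s / 1e6
}

#' Section imaging and total times from a plan and timing model
#'
#' The linear time model:
#' \deqn{t_{imaging} = N_t (t_{exp} + t_{acq}) + N_{st} (t_{move} + t_{settle})
#'   + N_{defl} t_{defl}}
#' with \eqn{N_{defl} = (\mathrm{tiles\ per\ supertile} - 1) N_{st}} (the
#' centre subtile is acquired undeflected). Every supertile counts one stage
#' step, including the first. Total time adds the per-section transition
#' overhead.
#'
#' @param plan A [plan_montage()] object.
#' @param timing A [timing_model()] object.
#' @return List with `imaging_time_s`, `total_time_s`, and `breakdown` — a
#'   named numeric vector of each term's seconds (exposure, acq_overhead,
#'   stage, deflection, transition) and `fractions` of total time.
#' @export
section_times <- function(plan, timing) {
  stopifnot(inherits(plan, "montage_plan"), inherits(timing, "timing_model"))
  n_t <- plan$n_tiles
  n_st <- plan$n_supertiles
  tiles_per_st <- plan$spec$grid_rows * plan$spec$grid_cols
  n_defl <- (tiles_per_st - 1) * n_st
  terms <- c(
    exposure = n_t * timing$exposure_s,
    acq_overhead = n_t * timing$acq_overhead_s,
    stage = n_st * (timing$stage_move_s + timing$stage_settle_s),
    deflection = n_defl * timing$deflection_settle_s,
    transition = timing$transition_s
  )
  imaging <- sum(terms[c("exposure", "acq_overhead", "stage", "deflection")])
  total <- imaging + terms[["transition"]]
  list(imaging_time_s = imaging, total_time_s = total,
       breakdown = terms, fractions = terms / total)
}

#' Imaging-rate report from measured or modelled times
#'
#' Computes the rate hierarchy: montage rate (all acquired pixels over
#' imaging time, i.e. including stage and deflection overheads), net rate
#' (same pixels over total time including section transition), and effective
#' rate (unique pixels, overlap counted once, over total time). Displayed
#' values round half-away-from-zero to integer MPix/s; unrounded values are
#' retained.
#'
#' @param plan A [plan_montage()] object.
#' @param imaging_time_s,total_time_s Section times (s); `0 < imaging <=
#'   total`.
#' @param exposure_s Optional exposure per tile (s) so the duty cycle can be
#'   reported.
#' @return An object of class `rate_report`.
#' @export
rates_from_times <- function(plan, imaging_time_s, total_time_s,
                             exposure_s = NULL) {
  stopifnot(inherits(plan, "montage_plan"))
  if (imaging_time_s <= 0 || total_time_s < imaging_time_s)
    stop("need 0 < imaging_time_s <= total_time_s", call. = FALSE)
  tot_px <- montage_total_pixels(plan)
  uniq_px <- montage_unique_pixels(plan)
  montage <- tot_px / imaging_time_s / 1e6
  net <- tot_px / total_time_s / 1e6
  effective <- uniq_px / total_time_s / 1e6
  duty <- if (is.null(exposure_s)) NA_real_ else
    duty_cycle(plan, exposure_s, total_time_s)
  structure(list(
    total_pixels = tot_px,
    unique_pixels = uniq_px,
    imaging_time_s = imaging_time_s,
    total_time_s = total_time_s,
    montage_MPixps = montage,
    net_MPixps = net,
    effective_MPixps = effective,
    duty_cycle_frac = duty,
    display = c(montage = round(montage), net = round(net),
                effective = round(effective)),
    sections_per_day = sections_per_day(total_time_s)
  ), class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat("<rate_report>\n")
  cat(sprintf("  imaging time        %6.1f min\n", x$imaging_time_s / 60))
  cat(sprintf("  total time          %6.1f min\n", x$total_time_s / 60))
  cat(sprintf("  montage rate        %6d MPix/s\n", x$display[["montage"]]))
  cat(sprintf("  net rate            %6d MPix/s\n", x$display[["net"]]))
  cat(sprintf("  effective rate      %6d MPix/s\n", x$display[["effective"]]))
  if (!is.na(x$duty_cycle_frac))
    cat(sprintf("  duty cycle          %6.1f %%\n", 100 * x$duty_cycle_frac))
  cat(sprintf("  sections per day    %6d\n", x$sections_per_day))
  invisible(x)
}

#' Imaging duty cycle
#'
#' Fraction of total per-section time spent exposing the camera:
#' `n_tiles * exposure / total_time`. The numerator counts exposure only
#' (not readout or software overhead).
#'
#' @param plan A [plan_montage()] object.
#' @param exposure_s Exposure per tile (s).
#' @param total_time_s Total per-section time (s), > 0.
#' @return Fraction in `[0, 1]`.
#' @export
duty_cycle <- function(plan, exposure_s, total_time_s) {
  stopifnot(inherits(plan, "montage_plan"))
  if (total_time_s <= 0) stop("`total_time_s` must be > 0", call. = FALSE)
  plan$n_tiles * exposure_s / total_time_s
}

#' Sections imaged per day by one microscope
#'
#' @param total_time_s Total per-section time (s), > 0.
#' @return `floor(86400 / total_time_s)` (integer).
#' @export
sections_per_day <- function(total_time_s) {
  if (total_time_s <= 0) stop("`total_time_s` must be > 0", call. = FALSE)
  as.integer(floor(86400 / total_time_s))
}

#' Days to image a volume with an array of microscopes
#'
#' Assumes 1 mm^2 sections: a volume of depth `depth_mm` cut at
#' `section_thickness_nm` yields `depth_mm * 1e6 / thickness` sections,
#' imaged by `n_scopes` microscopes running `uptime_frac` of the time.
#' Result is rounded up to whole days.
#'
#' @param depth_mm Volume depth (mm).
#' @param section_thickness_nm Section thickness (nm), e.g. 45.
#' @param n_scopes Number of microscopes.
#' @param total_time_s Total per-section time (s).
#' @param uptime_frac Facility uptime fraction in `(0, 1]`.
#' @return Whole days (integer, `ceiling`).
#' @export
days_for_volume <- function(depth_mm, section_thickness_nm, n_scopes,
                            total_time_s, uptime_frac = 1.0) {
  if (depth_mm < 0 || section_thickness_nm <= 0 || n_scopes < 1 ||
      total_time_s <= 0 || uptime_frac <= 0 || uptime_frac > 1)
    stop("invalid argument", call. = FALSE)
  n_sections <- depth_mm * 1e6 / section_thickness_nm
  per_day <- n_scopes * (86400 / total_time_s) * uptime_frac
  as.integer(ceiling(n_sections / per_day))
}

#' Back-solve the per-tile acquisition-software overhead
#'
#' The acquisition-software/readout overhead per tile is the one per-event
#' time not directly published; given an observed section imaging time it is
#' recovered by inverting the linear model of [section_times()].
#'
#' @param plan A [plan_montage()] object.
#' @param timing A [timing_model()]; its `acq_overhead_s` is ignored.
#' @param observed_imaging_time_s Observed imaging time for the section (s).
#' @return `acq_overhead_s` (s) such that `section_times()` reproduces the
#'   observed imaging time.
#' @export
fit_acq_overhead <- function(plan, timing, observed_imaging_time_s) {
  stopifnot(inherits(plan, "montage_plan"), inherits(timing, "timing_model"))
  t0 <- timing
  t0$acq_overhead_s <- 0
  base <- section_times(plan, t0)$imaging_time_s
  if (observed_imaging_time_s < base)
    stop(sprintf(
      "infeasible: observed imaging time %.3f s is below the %.3f s floor ",
      observed_imaging_time_s, base), "set by exposure/stage/deflection",
      call. = FALSE)
  (observed_imaging_time_s - base) / plan$n_tiles
}

#' Full throughput report in the style of the published performance table
#'
#' Convenience wrapper: plan -> times -> rates, with burst rate, duty cycle
#' and volume projections.
#'
#' @param plan A [plan_montage()] object.
#' @param timing A [timing_model()] object.
#' @param n_scopes,section_thickness_nm,uptime_frac Volume projection
#'   parameters.
#' @return A list combining [section_times()] and [rates_from_times()] output
#'   plus `burst_MPixps`, `days_per_mm3`, `days_per_mm3_uptime`.
#' @export
throughput_report <- function(plan, timing, n_scopes = 4,
                              section_thickness_nm = 45,
                              uptime_frac = 0.65) {
  tm <- section_times(plan, timing)
  rr <- rates_from_times(plan, tm$imaging_time_s, tm$total_time_s,
                         exposure_s = timing$exposure_s)
  tile_px2 <- as.numeric(plan$spec$tile_px)^2
  c(tm, unclass(rr), list(
    burst_MPixps = burst_rate(tile_px2, timing$exposure_s),
    days_per_mm3 = days_for_volume(1, section_thickness_nm, n_scopes,
                                   tm$total_time_s, 1.0),
    days_per_mm3_uptime = days_for_volume(1, section_thickness_nm, n_scopes,
                                          tm$total_time_s, uptime_frac)
  ))
}
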