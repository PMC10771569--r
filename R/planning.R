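#' Pulse protocols and activation plans
#'
#' A pulse protocol is the electrical recipe of one activation: pulse
#' amplitude (V), number of pulses, pulse width (default 100 us) and
#' delivery frequency (default 1 Hz). An activation plan is the ordered
#' list of (electrode pair, protocol) activations delivered sequentially.
#'
#' @param amplitude Pulse amplitude, V (> 0).
#' @param n_pulses Number of pulses (> 0).
#' @param pulse_width Pulse width, microseconds. Default 100.
#' @param frequency Pulse delivery frequency, Hz. Default 1.
#' @return A \code{pulse_protocol}.
#' @export
pulse_protocol <- function(amplitude, n_pulses, pulse_width = 100,
                           frequency = 1) {
  vals <- c(amplitude, n_pulses, pulse_width, frequency)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all pulse-protocol parameters must be strictly positive")
  if (pulse_width / 1e6 > 1 / frequency)
    stop("pulse_width exceeds the pulse period 1/frequency")
  structure(list(amplitude = amplitude, n_pulses = n_pulses,
                 pulse_width = pulse_width, frequency = frequency),
            class = "pulse_protocol")
}

#' @rdname pulse_protocol
#' @param pairs List of length-2 electrode-label vectors (or a single
#'   pair), one per activation; recycled against \code{protocols}.
#' @param protocols A \code{pulse_protocol} or list of them, one per
#'   activation.
#' @export
activation_plan <- function(pairs, protocols) {
  if (is.character(pairs)) pairs <- list(pairs)
  if (inherits(protocols, "pulse_protocol")) protocols <- list(protocols)
  n <- max(length(pairs), length(protocols))
  pairs <- rep_len(pairs, n)
  protocols <- rep_len(protocols, n)
  stopifnot(all(vapply(pairs, length, 0L) == 2),
            all(vapply(protocols, inherits, TRUE, "pulse_protocol")))
  structure(list(activations = Map(function(p, pr)
    list(pair = as.character(p), protocol = pr), pairs, protocols)),
    class = "activation_plan")
}

#' @export
print.activation_plan <- function(x, ...) {
  cat(sprintf("<activation_plan> %d activation(s), total %g s\n",
              length(x$activations), treatment_time(x)))
  for (a in x$activations)
    cat(sprintf("  %s-%s: %g V x %d pulses (%g us @ %g Hz)\n",
                a$pair[1], a$pair[2], a$protocol$amplitude,
                a$protocol$n_pulses, a$protocol$pulse_width,
                a$protocol$frequency))
  invisible(x)
}

#' Total treatment time of a plan
#'
#' Sum over activations of n_pulses / frequency: the wall-clock pulse
#' delivery time (an 8-pulse, 1 Hz single-pair protocol takes 8 s).
#'
#' @param plan An \code{\link{activation_plan}} (may be empty).
#' @return Seconds.
#' @export
treatment_time <- function(plan) {
  stopifnot(inherits(plan, "activation_plan"))
  if (length(plan$activations) == 0) {
    warning("empty activation plan: treatment time is 0 s")
    return(0)
  }
  sum(vapply(plan$activations,
             function(a) a$protocol$n_pulses / a$protocol$frequency,
             numeric(1)))
}

#' Deliver an activation plan and superpose the fields
#'
#' Solves each activation's field independently (with the other needles
#' removed from the conductive domain) and combines the activations into
#' a cumulative exposure map: the pointwise maximum of the field
#' magnitude over the plan. Activations are sequential in time, so each
#' point's electroporation state is governed by the strongest field it
#' ever experiences, not by a vector sum of simultaneous fields.
#'
#' @param geometry,electrodes Domain and needle layout.
#' @param plan An \code{\link{activation_plan}}.
#' @param options Solver options passed to \code{\link{solve_field}}.
#' @return A \code{cumulative_field}: \code{Emag} (pointwise max, V/cm),
#'   per-activation \code{solutions} kept for audit, and references to
#'   the inputs.
#' @export
run_plan <- function(geometry, electrodes, plan, options = list()) {
  stopifnot(inherits(plan, "activation_plan"))
  if (length(plan$activations) == 0) stop("empty activation plan")
  sols <- vector("list", length(plan$activations))
  cum <- NULL
  for (i in seq_along(plan$activations)) {
    a <- plan$activations[[i]]
    sols[[i]] <- tryCatch(
      solve_field(geometry, electrodes, a$pair, a$protocol$amplitude,
                  options),
      error = function(e) stop(sprintf(
        "activation %d (%s-%s at %g V) failed: %s", i, a$pair[1],
        a$pair[2], a$protocol$amplitude, conditionMessage(e)),
        call. = FALSE))
    E <- sols[[i]]$Emag
    E[is.na(E)] <- 0        # cells occluded by this activation's holes
    cum <- if (is.null(cum)) E else pmax(cum, E)
  }
  cum[!geometry$inside] <- NA_real_
  structure(list(geometry = geometry, electrodes = electrodes, plan = plan,
                 Emag = cum, solutions = sols),
            class = "cumulative_field")
}

#' @export
print.cumulative_field <- function(x, ...) {
  cat(sprintf("<cumulative_field> %d activation(s), max |E| %.0f V/cm\n",
              length(x$solutions), max(x$Emag, na.rm = TRUE)))
  invisible(x)
}

#' Ablation sweep: threshold to ablated area/volume
#'
#' For each candidate IRE threshold, the ablated measure is the measure
#' of the set of grid cells whose cumulative field magnitude is at or
#' above the threshold (cell counting at cell centers, boundary cells
#' count as ablated): mm2 on 2D well sections, mm3 on 3D voxel domains.
#' This is the surface-integration bridge between simulated fields and
#' measured ablation.
#'
#' @param cum A \code{\link{run_plan}} result.
#' @param E_min,E_max,step Sweep range and step, V/cm. Defaults mirror
#'   the small-well protocol: 200 to 1200 V/cm in 1 V/cm steps (use a
#'   20 V/cm step for medium/large wells and tumors).
#' @param region Optional region index restricting the measure (e.g. the
#'   tumor region of a \code{\link{tumor_domain}}).
#' @return An \code{ablation_sweep} data frame with columns
#'   \code{threshold} (V/cm) and \code{ablated} (mm2 or mm3), ablated
#'   measure non-increasing in threshold; attributes \code{unit} and
#'   \code{domain_measure}.
#' @export
ablation_sweep <- function(cum, E_min = 200, E_max = 1200, step = 1,
                           region = NULL) {
  stopifnot(inherits(cum, "cumulative_field"))
  if (!(E_min < E_max) || step <= 0)
    stop("require E_min < E_max and step > 0")
  sel <- region_mask(cum$geometry, region)
  if (!any(sel)) stop("empty region")
  vals <- cum$Emag[sel]
  cell <- cell_measure(cum$geometry)
  thresholds <- seq(E_min, E_max, by = step)
  # counts via the ECDF complement: #cells with E >= t
  srt <- sort(vals)
  n_ge <- length(srt) - findInterval(thresholds, srt, left.open = TRUE)
  structure(
    data.frame(threshold = thresholds, ablated = n_ge * cell$measure),
    unit = cell$unit, domain_measure = length(vals) * cell$measure,
    class = c("ablation_sweep", "data.frame"))
}

region_mask <- function(geometry, region = NULL) {
  if (is.null(region)) geometry$inside
  else !is.na(geometry$region) & geometry$region == region
}

cell_measure <- function(geometry) {
  if (length(dim(geometry$inside)) == 3)
    list(measure = geometry$cell_volume_mm3, unit = "mm3")
  else list(measure = geometry$cell_area_mm2, unit = "mm2")
}

#' Coverage fraction at a threshold
#'
#' Ablated measure at a threshold divided by the region measure; 1 means
#' complete (100 percent) coverage of the region.
#'
#' @inheritParams ablation_sweep
#' @param threshold IRE field threshold, V/cm.
#' @return Fraction in [0, 1].
#' @export
coverage_fraction <- function(cum, threshold, region = NULL) {
  stopifnot(inherits(cum, "cumulative_field"))
  sel <- region_mask(cum$geometry, region)
  if (!any(sel)) stop("empty region")
  mean(cum$Emag[sel] >= threshold)
}

#' Tri-level IRE coverage classification
#'
#' Labels every in-domain point as \code{untreated} (below the
#' experimental threshold), \code{exp_only} (at or above the experimental
#' threshold but below the in-vivo reported one) or \code{rep} (at or
#' above the reported threshold). Defaults are the experimental Hep-G2
#' hydrogel threshold 544 V/cm and the healthy-liver in-vivo literature
#' value 800 V/cm. Ties resolve toward the higher label.
#'
#' @inheritParams ablation_sweep
#' @param exp_threshold Experimental IRE threshold, V/cm (default 544).
#' @param rep_threshold Reported in-vivo threshold, V/cm (default 800);
#'   must be >= \code{exp_threshold}.
#' @return Integer array (same shape as the grid): 0 untreated, 1
#'   exp_only, 2 rep; NA outside the domain. The three counts partition
#'   the in-domain cells.
#' @export
classify_field_map <- function(cum, exp_threshold = 544,
                               rep_threshold = 800) {
  stopifnot(inherits(cum, "cumulative_field"))
  if (exp_threshold > rep_threshold)
    stop("exp_threshold must be <= rep_threshold")
  lab <- array(NA_integer_, dim(cum$Emag))
  inside <- cum$geometry$inside
  lab[inside] <- 0L
  lab[inside & cum$Emag >= exp_threshold] <- 1L
  lab[inside & cum$Emag >= rep_threshold] <- 2L
  structure(lab, levels = c("untreated", "exp_only", "rep"))
}
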