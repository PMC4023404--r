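#' Stimulation/inhibition protocol
#'
#' A protocol is an ordered sequence of input-strength segments (PDGF dose is
#' modeled as a step change in the MEK phosphorylation rate, scaled by the
#' dimensionless input strength S), plus optional instantaneous inhibitor
#' events: U0126 (MEK catalytic block, zeroes the ERK-phosphorylation fluxes)
#' and okadaic acid (phosphatase block, zeroes all ERK- and
#' substrate-dephosphorylation fluxes).
#'
#' @param segments tibble/data.frame with columns `t_start` (min, strictly
#'   increasing, first value 0) and `S` (input strength per segment).
#' @param u0126_time,okadaic_time event times in min, or `NA` for no event.
#' @param t_end end of simulation window (min).
#' @param variant model variant tag: one of `"full"`, `"control"`,
#'   `"importin"`, `"combined"`, `"constant_mek"`.
#' @param u0126_factor,okadaic_factor residual flux fraction remaining after
#'   the corresponding inhibitor (0 = complete inhibition, the default; values
#'   in (0, 1) model partial inhibition).
#' @return An object of class `erk_protocol`.
#' @export
#' @examples
#' protocol_step(S = 1, t_end = 75)
#' protocol_u0126(t_inhibit = 46)
erk_protocol <- function(segments = tibble::tibble(t_start = 0, S = 1),
                         u0126_time = NA_real_, okadaic_time = NA_real_,
                         t_end = 75, variant = "full",
                         u0126_factor = 0, okadaic_factor = 0) {
  stopifnot(u0126_factor >= 0, u0126_factor <= 1,
            okadaic_factor >= 0, okadaic_factor <= 1)
  segments <- as_tibble(segments)
  stopifnot(all(c("t_start", "S") %in% names(segments)), nrow(segments) >= 1)
  if (segments$t_start[1] != 0) abort("first protocol segment must start at t = 0")
  if (is.unsorted(segments$t_start, strictly = TRUE)) {
    abort("segment start times must be strictly increasing")
  }
  variant <- match.arg(variant, .erk_variants)
  for (ev in c(u0126_time, okadaic_time)) {
    if (!is.na(ev) && (ev < 0 || ev > t_end)) abort("event times must lie in [0, t_end]")
  }
  if (any(segments$t_start > t_end)) abort("segment start times must lie in [0, t_end]")
  structure(
    list(segments = segments, u0126_time = as.numeric(u0126_time),
         okadaic_time = as.numeric(okadaic_time), t_end = as.numeric(t_end),
         variant = variant, u0126_factor = u0126_factor,
         okadaic_factor = okadaic_factor),
    class = "erk_protocol"
  )
}

#' @export
print.erk_protocol <- function(x, ...) {
  cat("<erk_protocol> variant:", x$variant, " t_end:", x$t_end, "min\n")
  print(x$segments)
  if (!is.na(x$u0126_time)) cat("U0126 at", x$u0126_time, "min\n")
  if (!is.na(x$okadaic_time)) cat("okadaic acid at", x$okadaic_time, "min\n")
  invisible(x)
}

#' @rdname erk_protocol
#' @param S input strength of the step applied at t = 0.
#' @export
protocol_step <- function(S = 1, t_end = 75, variant = "full") {
  erk_protocol(tibble(t_start = 0, S = S), t_end = t_end, variant = variant)
}

#' @rdname erk_protocol
#' @param t_inhibit time of inhibitor addition (min after stimulation).
#' @export
protocol_u0126 <- function(t_inhibit = 46, S = 1, t_end = 75, variant = "full") {
  erk_protocol(tibble(t_start = 0, S = S), u0126_time = t_inhibit,
               t_end = t_end, variant = variant)
}

#' @rdname erk_protocol
#' @export
protocol_okadaic <- function(t_inhibit = 46, S = 1, t_end = 75, variant = "full") {
  erk_protocol(tibble(t_start = 0, S = S), okadaic_time = t_inhibit,
               t_end = t_end, variant = variant)
}

#' @rdname erk_protocol
#' @param S1,S2 input strengths before and after the dose step-up.
#' @param t_step time of the dose increase (min).
#' @export
protocol_dose_step <- function(S1 = 0.5, S2 = 1, t_step = 30, t_end = 75,
                               variant = "full") {
  erk_protocol(tibble(t_start = c(0, t_step), S = c(S1, S2)),
               t_end = t_end, variant = variant)
}

# event/segment breakpoints of a protocol, with per-interval context
.protocol_segments <- function(protocol) {
  brk <- sort(unique(c(
    protocol$segments$t_start,
    protocol$u0126_time[!is.na(protocol$u0126_time)],
    protocol$okadaic_time[!is.na(protocol$okadaic_time)],
    protocol$t_end
  )))
  brk <- brk[brk <= protocol$t_end]
  if (max(brk) < protocol$t_end) brk <- c(brk, protocol$t_end)
  n <- length(brk) - 1L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t0 <- brk[i]
    seg_idx <- max(which(protocol$segments$t_start <= t0))
    out[[i]] <- list(
      from = t0, to = brk[i + 1L],
      u = protocol$segments$S[seg_idx],
      inh = if (!is.na(protocol$u0126_time) && t0 >= protocol$u0126_time)
        protocol$u0126_factor else 1,
      pho = if (!is.na(protocol$okadaic_time) && t0 >= protocol$okadaic_time)
        protocol$okadaic_factor else 1
    )
  }
  out
}
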