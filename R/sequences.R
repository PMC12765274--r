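# Pulse/delay sequence templates with the timing arithmetic of chirped
# SIFTER experiments.
#
# Delays are measured between pulse CENTERS. For linear chirps this makes
# the refocusing-time bookkeeping of the pathway solver exact; note that
# edge-to-edge delays are the more common lab convention.

.SEQ_TEMPLATES <- list(
  hahn_21 = list(
    ratios = c(2, 1), roles = c("pi/2", "pi"), signs = c(1, 1),
    phases = c(0, 0), pathway = "0,1;1,-1"),
  abstruse_221 = list(
    ratios = c(2, 2, 1), roles = c("pi/2", "pi", "pi"), signs = c(1, 1, 1),
    phases = c(0, 0, 0), pathway = "0,1;1,-1;-1,1"),
  refocused_222 = list(
    ratios = c(2, 2, 2), roles = c("pi/2", "pi", "pi"), signs = c(1, 1, 1),
    phases = c(0, 0, 0), pathway = "0,1;1,-1;-1,1"),
  sifter_2221 = list(
    ratios = c(2, 2, 2, 1), roles = c("pi/2", "pi", "pi/2", "pi"),
    signs = c(1, 1, 1, 1), phases = c(0, 0, pi / 2, 0),
    pathway = "0,1;1,-1;-1,-1;-1,1"),
  sifter_2263 = list(
    ratios = c(2, 2, 6, 3), roles = c("pi/2", "pi", "pi/2", "pi"),
    signs = c(1, -1, -1, -1), phases = c(0, 0, pi / 2, 0),
    pathway = "0,1;1,-1;-1,-1;-1,1",
    extra_pathways = list("0,1;1,-1;-1,1;1,-1")),
  sifter_2314 = list(
    ratios = c(2, 3, 1, 4), roles = c("pi/2", "pi", "pi/2", "pi"),
    signs = c(1, -1, 1, -1), phases = c(0, 0, pi / 2, 0),
    pathway = "0,1;1,-1;-1,-1;-1,1",
    extra_pathways = list("0,1;1,1;1,-1;-1,-1")),
  sixpulse_222232 = list(
    ratios = c(2, 2, 2, 2, 3, 2),
    roles = c("pi/2", "pi", "pi/2", "pi", "pi", "pi"),
    signs = c(1, 1, 1, 1, 1, 1), phases = c(0, 0, pi / 2, 0, 0, 0),
    pathway = "0,1;1,-1;-1,-1;-1,1;1,-1;-1,1"),
  sidre_3p = list(
    ratios = c(2, 2, 1), roles = c("pi/2", "pi", "pi"), signs = c(1, 1, 1),
    phases = c(0, 0, 0), pathway = "0,1;1,-1;-1,1", sidre_of = "sifter_2221"),
  sidre_5p = list(
    ratios = c(2, 2, 2, 3, 2), roles = c("pi/2", "pi", "pi", "pi", "pi"),
    signs = c(1, 1, 1, 1, 1), phases = c(0, 0, 0, 0, 0),
    pathway = "0,1;1,-1;-1,1;1,-1;-1,1", sidre_of = "sixpulse_222232"))

.sequence_delays <- function(name, tau1, tau2, tau3 = NULL, tau4 = NULL) {
  switch(name,
    hahn_21 = tau1,
    abstruse_221 = ,
    refocused_222 = c(tau1, tau1 + tau2),
    sifter_2221 = ,
    sifter_2263 = ,
    sifter_2314 = c(tau1, tau1, tau2),
    sidre_3p = c(tau1, tau1 + tau2),
    sixpulse_222232 = {
      if (is.null(tau3)) tau3 <- tau2
      if (is.null(tau4)) tau4 <- tau2
      c(tau1, tau1, tau2, tau2 + tau3, tau3 + tau4)
    },
    sidre_5p = {
      if (is.null(tau3)) tau3 <- tau2
      if (is.null(tau4)) tau4 <- tau2
      c(tau1, tau1 + tau2, tau2 + tau3, tau3 + tau4)
    },
    stop("no delay rule for template ", name))
}

#' Assemble a chirp pulse sequence from explicit parts
#'
#' @param ratios relative pulse lengths.
#' @param roles `"pi/2"` / `"pi"` per pulse; pi/2 pulses get the amplitude
#'   for an adiabatic flip of pi/2, pi pulses the amplitude for `q_pi`.
#' @param signs sweep signs per pulse (+1 up, -1 down).
#' @param phases pulse phases (rad): 0 for x, `pi/2` for y.
#' @param delays center-to-center delays (ns), one per pulse gap.
#' @param tp_unit length of a ratio-1 pulse (ns).
#' @param sw common sweep width (MHz).
#' @param q_pi critical adiabaticity of the pi pulses (shared, so the
#'   dynamic phase shifts of equal-Q pi pulses compensate).
#' @param n WURST steepness index.
#' @param pathway declared main coherence pathway (see [pathway()]).
#' @param extra_pathways further refocused pathways, if any.
#' @param name template name tag.
#' @return an object of class `pulse_sequence`.
#' @export
chirp_sequence <- function(ratios, roles, signs, phases, delays, tp_unit, sw,
                           q_pi = 5, n = 16, pathway = NULL,
                           extra_pathways = NULL, name = "custom") {
  np <- length(ratios)
  stopifnot(length(roles) == np, length(signs) == np, length(phases) == np,
            length(delays) == np - 1L)
  pulses <- vector("list", np)
  for (i in seq_len(np)) {
    pulses[[i]] <- if (roles[i] == "pi/2")
      chirp_pulse(tp = ratios[i] * tp_unit, sw = sw, n = n, flip = pi / 2,
                  sweep = signs[i], role = "pi/2")
    else
      chirp_pulse(tp = ratios[i] * tp_unit, sw = sw, n = n, qcrit = q_pi,
                  sweep = signs[i], role = "pi")
  }
  seq <- structure(
    list(name = name, pulses = pulses, phases = phases, delays = delays,
         ratios = ratios, roles = roles, signs = signs, tp_unit = tp_unit,
         sw = sw, q_pi = q_pi, n = n,
         pathway = if (!is.null(pathway)) .as_pathway(pathway) else NULL,
         extra_pathways = lapply(extra_pathways %||% list(), .as_pathway)),
    class = "pulse_sequence")
  .check_sequence_gaps(seq)
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_sequence_gaps <- function(seq, delays = seq$delays) {
  tp <- vapply(seq$pulses, `[[`, numeric(1), "tp")
  need <- (tp[-length(tp)] + tp[-1]) / 2
  bad <- which(delays < need - 1e-9)
  if (length(bad) > 0L)
    stop(sprintf(
      "pulses %d and %d overlap: center-to-center delay %g ns < %g ns",
      bad[1], bad[1] + 1L, delays[bad[1]], need[bad[1]]))
  invisible(TRUE)
}

#' Pulse timing of a sequence
#'
#' Start, center and end times (ns) of every pulse, with t = 0 at the center
#' of the first pulse, plus the nominal echo time (time of pathway
#' refocusing after the last pulse center, from the coherence-order
#' bookkeeping over the delays).
#'
#' @param seq a `pulse_sequence`.
#' @return a list with `table` (data frame: start, center, end per pulse),
#'   `duration` (first pulse start to nominal echo, ns) and `echo_time`
#'   (absolute, ns) when a main pathway is declared.
#' @export
sequence_timing <- function(seq) {
  tp <- vapply(seq$pulses, `[[`, numeric(1), "tp")
  centers <- cumsum(c(0, seq$delays))
  tab <- data.frame(start = centers - tp / 2, center = centers,
                    end = centers + tp / 2)
  echo <- NA_real_
  if (!is.null(seq$pathway)) {
    np <- length(tp)
    o <- seq$pathway$op
    echo <- centers[np] - sum(o[seq_len(np - 1L)] * seq$delays) / o[np]
  }
  list(table = tab, echo_time = echo,
       duration = (if (is.na(echo)) max(tab$end) else echo) - tab$start[1])
}

#' Standard 2D-SIFTER sequence with the 2:2:2:1 pulse-length ratio
#'
#' Four chirp pulses, (pi/2)x (pi)x (pi/2)y (pi)x with lengths
#' `(2,2,2,1) * tp_unit`, all up sweeps, delays tau1, tau1, tau2 between
#' pulse centers and the echo refocusing tau2 after the last pulse. Keeping
#' the two pi pulses at equal critical adiabaticity gives them the 1:sqrt(2)
#' amplitude relation.
#'
#' @param tp_unit length of the ratio-1 pulse (ns).
#' @param sw sweep width (MHz).
#' @param tau1,tau2 base delays (ns).
#' @param q_pi shared critical adiabaticity of the pi pulses.
#' @param n WURST steepness index.
#' @return a `pulse_sequence`.
#' @export
make_sifter_2221 <- function(tp_unit, sw, tau1, tau2 = tau1, q_pi = 5, n = 16) {
  make_variant("sifter_2221", tp_unit = tp_unit, sw = sw, tau1 = tau1,
               tau2 = tau2, q_pi = q_pi, n = n)
}

#' Build a named chirp sequence template
#'
#' Templates: `hahn_21` (Boehlen-Bodenhausen two-pulse echo), `abstruse_221`
#' and `refocused_222` (refocused echoes), `sifter_2221` (standard
#' four-pulse SIFTER), `sifter_2263` (dual-pathway study variant,
#' up-down-down-down), `sifter_2314` (dispersion-free solid echo,
#' up-down-up-down), `sixpulse_222232` (asymmetric Carr-Purcell SIFTER), and
#' the background references `sidre_3p` / `sidre_5p` (the corresponding
#' SIFTER template with its second pi/2 pulse left out).
#'
#' @param name template name.
#' @inheritParams make_sifter_2221
#' @param tau3,tau4 further base delays for the six-pulse templates (ns);
#'   default `tau2`.
#' @param q_pi shared critical adiabaticity of the pi pulses.
#' @param n WURST steepness index.
#' @return a `pulse_sequence`.
#' @export
make_variant <- function(name, tp_unit, sw, tau1, tau2 = tau1, tau3 = NULL,
                         tau4 = NULL, q_pi = 5, n = 16) {
  if (!name %in% names(.SEQ_TEMPLATES))
    stop("unknown template '", name, "'; available: ",
         paste(names(.SEQ_TEMPLATES), collapse = ", "))
  tmpl <- .SEQ_TEMPLATES[[name]]
  delays <- .sequence_delays(name, tau1, tau2, tau3, tau4)
  seq <- chirp_sequence(tmpl$ratios, tmpl$roles, tmpl$signs, tmpl$phases,
                        delays, tp_unit, sw, q_pi = q_pi, n = n,
                        pathway = tmpl$pathway,
                        extra_pathways = tmpl$extra_pathways, name = name)
  seq$taus <- c(tau1 = tau1, tau2 = tau2,
                tau3 = if (!is.null(tau3)) tau3 else tau2,
                tau4 = if (!is.null(tau4)) tau4 else tau2)
  seq
}

#' @export
print.pulse_sequence <- function(x, ...) {
  cat(sprintf("pulse sequence '%s': %d pulses, ratio %s, sweeps (%s)\n",
              x$name, length(x$pulses), paste(x$ratios, collapse = ":"),
              paste(ifelse(x$signs > 0, "+", "-"), collapse = "")))
  cat(sprintf("  tp_unit = %g ns, SW = %g MHz, Q(pi) = %g, delays (ns): %s\n",
              x$tp_unit, x$sw, x$q_pi, paste(x$delays, collapse = ", ")))
  invisible(x)
}

#' Two-dimensional SIFTER acquisition schedule
#'
#' Generates the per-point delay sets of a 2D-SIFTER (or six-pulse SIFTER)
#' acquisition. `dt` is the increment of the dipolar evolution time axis per
#' point. For the four-pulse templates in the recommended `tau2_up_tau1_down`
#' mode, tau2 grows by `dt/2` per point while tau1 shrinks by `dt/2`, so the
#' dipolar time `tau2 - tau1` advances by `dt`. For the six-pulse template,
#' tau1 shrinks by `dt/2` while tau2, tau3 and tau4 each grow by a third of
#' that, advancing `(tau2+tau3+tau4) - tau1` by `dt`. `symmetric` centers
#' the dipolar axis on zero.
#'
#' @param seq a SIFTER-family `pulse_sequence` from [make_variant()].
#' @param dt dipolar-time increment per point (ns).
#' @param npoints number of points.
#' @param mode `"tau2_up_tau1_down"` (default, avoids echo crossings) or
#'   `"symmetric"`.
#' @return an object of class `sifter_schedule`: `delays` (npoints x gaps
#'   matrix, ns), `dipolar_time` (ns), plus the generating sequence.
#' @export
schedule_2d <- function(seq, dt, npoints,
                        mode = c("tau2_up_tau1_down", "symmetric")) {
  mode <- match.arg(mode)
  if (is.null(seq$taus)) stop("sequence carries no base delays; build it with make_variant()")
  if (npoints < 1L) stop("'npoints' must be >= 1")
  sixp <- seq$name %in% c("sixpulse_222232", "sidre_5p")
  steps <- if (mode == "symmetric")
    (seq_len(npoints) - 1L) - (npoints - 1L) / 2 else seq_len(npoints) - 1L

  tau1 <- seq$taus[["tau1"]] - steps * dt / 2
  if (sixp) {
    tau2 <- seq$taus[["tau2"]] + steps * dt / 6
    tau3 <- seq$taus[["tau3"]] + steps * dt / 6
    tau4 <- seq$taus[["tau4"]] + steps * dt / 6
    dip <- (tau2 + tau3 + tau4) - tau1
    delays <- if (seq$name == "sixpulse_222232")
      cbind(tau1, tau1, tau2, tau2 + tau3, tau3 + tau4)
    else cbind(tau1, tau1 + tau2, tau2 + tau3, tau3 + tau4)
  } else {
    tau2 <- seq$taus[["tau2"]] + steps * dt / 2
    dip <- tau2 - tau1
    delays <- switch(seq$name,
      sifter_2221 = , sifter_2263 = , sifter_2314 = cbind(tau1, tau1, tau2),
      sidre_3p = cbind(tau1, tau1 + tau2),
      stop("no 2D schedule rule for template '", seq$name, "'"))
  }

  tp <- vapply(seq$pulses, `[[`, numeric(1), "tp")
  need <- (tp[-length(tp)] + tp[-1]) / 2
  ok <- apply(delays, 1, function(d) all(d >= need - 1e-9))
  if (!all(ok)) {
    nmax <- if (any(!ok)) which(!ok)[1] - 1L else npoints
    stop(sprintf(
      "schedule violates the minimal tau1 gap from point %d on; at most %d points are feasible with these base delays",
      which(!ok)[1], nmax))
  }
  if (npoints > 1L && any(diff(dip) <= 0))
    stop("dipolar time axis must be strictly increasing")
  structure(list(sequence = seq, delays = delays, dipolar_time = dip,
                 dt = dt, mode = mode),
            class = "sifter_schedule")
}

#' @export
print.sifter_schedule <- function(x, ...) {
  cat(sprintf("2D schedule for '%s': %d points, dt = %g ns, dipolar time [%g, %g] ns (%s)\n",
              x$sequence$name, nrow(x$delays), x$dt, min(x$dipolar_time),
              max(x$dipolar_time), x$mode))
  invisible(x)
}

#' Serialize a sequence template to structured text
#'
#' Writes/reads a simple `key: value` representation (name, tp_unit ns,
#' sw MHz, q_pi, n, ratios, roles, signs, phases, delays ns).
#'
#' @param seq a `pulse_sequence`.
#' @param path file path.
#' @return `path` (write) or a `pulse_sequence` (read).
#' @export
write_sequence_config <- function(seq, path) {
  lines <- c(
    paste("name:", seq$name),
    paste("tp_unit:", format(seq$tp_unit, digits = 12)),
    paste("sw:", format(seq$sw, digits = 12)),
    paste("q_pi:", format(seq$q_pi, digits = 12)),
    paste("n:", format(seq$n, digits = 12)),
    paste("ratios:", paste(seq$ratios, collapse = " ")),
    paste("roles:", paste(seq$roles, collapse = " ")),
    paste("signs:", paste(seq$signs, collapse = " ")),
    paste("phases:", paste(format(seq$phases, digits = 12), collapse = " ")),
    paste("delays:", paste(format(seq$delays, digits = 12), collapse = " ")))
  if (!is.null(seq$pathway))
    lines <- c(lines, paste("pathway:",
      paste(sprintf("%d,%d", seq$pathway$om, seq$pathway$op), collapse = ";")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sequence_config
#' @export
read_sequence_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":", fixed = FALSE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(seq_along(kv), function(i)
    trimws(sub("^[^:]*:", "", lines[i])), character(1))
  get <- function(k) vals[match(k, keys)]
  nums <- function(k) as.numeric(strsplit(get(k), "\\s+")[[1]])
  chirp_sequence(
    ratios = nums("ratios"),
    roles = strsplit(get("roles"), "\\s+")[[1]],
    signs = nums("signs"),
    phases = nums("phases"),
    delays = nums("delays"),
    tp_unit = as.numeric(get("tp_unit")), sw = as.numeric(get("sw")),
    q_pi = as.numeric(get("q_pi")), n = as.numeric(get("n")),
    pathway = if (!is.na(get("pathway"))) get("pathway") else NULL,
    name = get("name"))
}
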