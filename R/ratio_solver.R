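# Pulse-length-ratio solver for chirp refocusing.
#
# For a sequence of linear chirps with equal sweep width, a coherence
# pathway refocuses the offset-dependent phase roll when
#   sum_i  s_i * tp_i * (o-_i - o+_i)  =  0
# with s_i the sweep sign, tp_i the pulse length and (o-, o+) the coherence
# order before/after pulse i. Each pathway (plus any length constraints)
# contributes one linear equation; the solver works over exact rationals,
# enumerates small-integer solutions and ranks them by how short the
# amplitude-limited sequence can be made.

#' Build a coherence pathway
#'
#' A pathway records the coherence order before (`o-`) and after (`o+`) each
#' pulse. Accepts a string `"0,1;1,-1;-1,-1;-1,1"` (one `o-,o+` pair per
#' pulse, pairs separated by `;`), a two-column matrix, or a list of length-2
#' vectors.
#'
#' @param x pathway specification.
#' @param max_order largest |coherence order| allowed (default 1, the
#'   single-quantum bookkeeping of an S = 1/2 pair).
#' @return an object of class `coherence_pathway` with integer vectors
#'   `om`, `op`.
#' @examples
#' pathway("0,1;1,-1")            # Hahn echo
#' pathway("0,1;1,-1;-1,-1;-1,1") # four-pulse SIFTER, third pulse passive
#' @export
pathway <- function(x, max_order = 1L) {
  if (inherits(x, "coherence_pathway")) return(x)
  if (is.character(x)) {
    parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
    m <- t(vapply(parts, function(p) as.numeric(trimws(p)), numeric(2)))
  } else if (is.matrix(x)) {
    m <- x
  } else if (is.list(x)) {
    m <- do.call(rbind, x)
  } else stop("cannot interpret pathway specification")
  if (ncol(m) != 2L) stop("a pathway needs an (o-, o+) pair per pulse")
  if (any(m != round(m))) stop("coherence orders must be integers")
  if (any(abs(m) > max_order))
    stop(sprintf("coherence orders exceed the |o| <= %d bound", max_order))
  structure(list(om = as.integer(m[, 1]), op = as.integer(m[, 2])),
            class = "coherence_pathway")
}

#' @export
print.coherence_pathway <- function(x, ...) {
  cat("coherence pathway:",
      paste(sprintf("%d>%d", x$om, x$op), collapse = " | "), "\n")
  invisible(x)
}

#' Refocusing residual of a pulse-length assignment
#'
#' Evaluates `sum_i s_i * tp_i * (o-_i - o+_i)` for one pathway. Exact for
#' rational inputs (no rounding is introduced).
#'
#' @param lengths relative pulse lengths (positive).
#' @param signs sweep signs, one of -1/+1 per pulse.
#' @param pw a [pathway()].
#' @return the residual; 0 means the pathway refocuses without dispersion.
#' @examples
#' eq8_residual(c(2, 1), c(1, 1), pathway("0,1;1,-1"))   # 0: Hahn 2:1
#' eq8_residual(c(1, 1), c(1, 1), pathway("0,1;1,-1"))   # +1
#' @export
eq8_residual <- function(lengths, signs, pw) {
  pw <- pathway(pw)
  n <- length(pw$om)
  if (length(lengths) != n || length(signs) != n)
    stop("'lengths', 'signs' and the pathway must agree in pulse count")
  if (!all(signs %in% c(-1, 1))) stop("signs must be -1 or +1")
  sum(signs * lengths * (pw$om - pw$op))
}

# ---- exact rational Gaussian elimination -------------------------------

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}
.gcdv <- function(v) Reduce(.gcd2, abs(v))
.lcm2 <- function(a, b) a / .gcd2(a, b) * b

# Reduced row echelon form of [A | b] over exact rationals. Entries are
# stored as integer-valued doubles num/den; all inputs here are small
# integers, so double arithmetic is exact.
.rref_rat <- function(A, b) {
  m <- nrow(A); n <- ncol(A)
  num <- cbind(A, b); den <- matrix(1, m, n + 1L)
  reduce <- function(i, j) {
    g <- .gcd2(num[i, j], den[i, j])
    if (g > 0) { num[i, j] <<- num[i, j] / g; den[i, j] <<- den[i, j] / g }
    if (den[i, j] < 0) { num[i, j] <<- -num[i, j]; den[i, j] <<- -den[i, j] }
    if (num[i, j] == 0) den[i, j] <<- 1
  }
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    pr <- which(num[row:m, col] != 0)
    if (length(pr) == 0L) next
    pr <- pr[1] + row - 1L
    if (pr != row) {
      num[c(row, pr), ] <- num[c(pr, row), ]
      den[c(row, pr), ] <- den[c(pr, row), ]
    }
    # scale pivot row to 1
    pn <- num[row, col]; pd <- den[row, col]
    for (j in seq_len(n + 1L)) {
      num[row, j] <- num[row, j] * pd
      den[row, j] <- den[row, j] * pn
      reduce(row, j)
    }
    # eliminate the column from the other rows
    for (i in seq_len(m)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      for (j in seq_len(n + 1L)) {
        # row_i <- row_i - f * row_row
        a_n <- num[i, j]; a_d <- den[i, j]
        b_n <- fn * num[row, j]; b_d <- fd * den[row, j]
        num[i, j] <- a_n * b_d - b_n * a_d
        den[i, j] <- a_d * b_d
        reduce(i, j)
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  inconsistent <- any(apply(num, 1, function(r)
    all(r[seq_len(n)] == 0) && r[n + 1L] != 0))
  list(num = num, den = den, pivots = pivots,
       free = setdiff(seq_len(n), pivots), inconsistent = inconsistent)
}

# ---- solution enumeration and ranking ----------------------------------

.rank_metric <- function(lengths, roles) {
  unit <- if (!is.null(roles) && any(roles == "pi")) {
    min(lengths[roles == "pi"])
  } else min(lengths)
  sum(lengths) / unit
}

.role_feasible <- function(lengths, roles, min_pi2_frac) {
  if (is.null(roles) || !any(roles == "pi") || !any(roles == "pi/2"))
    return(TRUE)
  min(lengths[roles == "pi/2"]) >=
    min_pi2_frac * min(lengths[roles == "pi"]) - 1e-12
}

.solution_record <- function(lengths, signs, pathways, roles, homogeneous) {
  res <- vapply(pathways, function(pw) eq8_residual(lengths, signs, pw),
                numeric(1))
  int_form <- NULL
  if (all(abs(lengths - round(lengths)) < 1e-9)) {
    v <- round(lengths)
    if (homogeneous) v <- v / .gcdv(v)
    int_form <- as.integer(v)
  }
  list(lengths = lengths, signs = signs, residuals = res,
       integer_form = int_form,
       normalized_total = .rank_metric(lengths, roles))
}

#' Solve the refocusing condition for pulse-length ratios
#'
#' Builds one linear equation per coherence pathway (plus optional fixed
#' lengths and equality constraints), reduces the system with exact rational
#' arithmetic, and intersects the solution space with the positive orthant.
#'
#' With no fixed lengths the system is homogeneous and solutions are rays:
#' a one-dimensional positive ray is reported as the unique solution (in
#' smallest-integer form when one exists). Higher-dimensional families are
#' enumerated as primitive positive integer solutions with coefficients up
#' to `max_coef` and ranked by `normalized_total`: the total sequence length
#' after scaling the shortest pi-role pulse to 1, since the shortest pi
#' pulse (which needs the highest amplitude) sets the absolute time unit.
#' When `roles` are given, candidate solutions whose shortest pi/2 pulse
#' falls below `min_pi2_frac` of the shortest pi pulse are discarded: such a
#' pi/2 pulse could not keep an adequate time bandwidth product once the pi
#' pulses run at the amplitude limit.
#'
#' @param n_pulses number of pulses.
#' @param signs sweep signs, length `n_pulses`, entries -1/+1.
#' @param pathways a [pathway()] or list of pathways.
#' @param fixed named list of fixed lengths, e.g. `list(`1` = 2)` fixes
#'   pulse 1 to relative length 2 (indices as names).
#' @param equal list of index pairs forced to equal length.
#' @param roles optional character vector (`"pi"` / `"pi/2"`) per pulse,
#'   used for ranking and feasibility.
#' @param max_coef largest integer coefficient searched/accepted (default 12).
#' @param min_pi2_frac smallest tolerated ratio of the shortest pi/2 pulse
#'   to the shortest pi pulse (default 1/3); only applied when `roles` are
#'   given.
#' @return an object of class `ratio_solutions`: fields `feasible`,
#'   `unique`, `dim` (degrees of freedom of the constrained system) and
#'   `solutions`, a ranked list with elements `lengths`, `integer_form`,
#'   `residuals`, `normalized_total`.
#' @examples
#' # chirp Hahn echo, both sweeps up: unique 2:1
#' solve_ratios(2, c(1, 1), pathway("0,1;1,-1"))
#' # up/down Hahn echo: infeasible (negative lengths would be needed)
#' solve_ratios(2, c(1, -1), pathway("0,1;1,-1"))$feasible
#' @export
solve_ratios <- function(n_pulses, signs, pathways, fixed = NULL,
                         equal = NULL, roles = NULL, max_coef = 12L,
                         min_pi2_frac = 1 / 3) {
  if (length(signs) != n_pulses) stop("need one sweep sign per pulse")
  if (!all(signs %in% c(-1, 1))) stop("signs must be -1 or +1")
  if (inherits(pathways, "coherence_pathway")) pathways <- list(pathways)
  pathways <- lapply(pathways, pathway)
  if (length(pathways) == 0L) stop("at least one pathway is required")
  for (pw in pathways)
    if (length(pw$om) != n_pulses)
      stop("every pathway must have one (o-, o+) pair per pulse")
  if (!is.null(roles)) {
    if (length(roles) != n_pulses || !all(roles %in% c("pi", "pi/2")))
      stop("'roles' must be 'pi'/'pi/2' per pulse")
  }

  A <- do.call(rbind, lapply(pathways, function(pw) signs * (pw$om - pw$op)))
  b <- rep(0, length(pathways))
  if (!is.null(equal)) {
    for (pr in equal) {
      row <- rep(0, n_pulses); row[pr[1]] <- 1; row[pr[2]] <- -1
      A <- rbind(A, row); b <- c(b, 0)
    }
  }
  homogeneous <- is.null(fixed) || length(fixed) == 0L
  if (!homogeneous) {
    for (nm in names(fixed)) {
      i <- as.integer(nm)
      row <- rep(0, n_pulses); row[i] <- 1
      A <- rbind(A, row); b <- c(b, fixed[[nm]])
    }
  }

  rr <- .rref_rat(A, b)
  out <- structure(
    list(n_pulses = n_pulses, signs = signs, pathways = pathways,
         roles = roles, dim = length(rr$free), feasible = FALSE,
         unique = FALSE, solutions = list()),
    class = "ratio_solutions")
  if (rr$inconsistent) return(out)

  n <- n_pulses
  pivmap <- stats::setNames(seq_along(rr$pivots), rr$pivots)
  val <- function(i, j) rr$num[i, j] / rr$den[i, j]
  # particular solution (free vars = 0) and nullspace basis
  part <- rep(0, n)
  for (p in rr$pivots) part[p] <- val(pivmap[[as.character(p)]], n + 1L)
  basis <- matrix(0, n, length(rr$free))
  for (k in seq_along(rr$free)) {
    f <- rr$free[k]
    basis[f, k] <- 1
    for (p in rr$pivots)
      basis[p, k] <- -val(pivmap[[as.character(p)]], f)
  }

  d <- length(rr$free)
  sols <- list()
  if (d == 0L) {
    if (all(part > 0))
      sols <- list(.solution_record(part, signs, pathways, roles, homogeneous))
  } else {
    if (d > 4L)
      stop("solution family has more than 4 degrees of freedom; add constraints")
    grid <- do.call(expand.grid, rep(list(seq_len(max_coef)), d))
    seen <- character(0)
    for (r in seq_len(nrow(grid))) {
      cvec <- as.numeric(grid[r, ])
      t <- part + as.numeric(basis %*% cvec)
      if (any(t <= 1e-9)) next
      if (any(abs(t - round(t)) > 1e-9)) {
        if (!homogeneous) next
        # rescale rationals to smallest-integer form when possible
        dens <- vapply(t, function(x) {
          fr <- .as_fraction(x); fr[2]
        }, numeric(1))
        t <- t * Reduce(.lcm2, dens)
        if (any(abs(t - round(t)) > 1e-6)) next
      }
      t <- round(t)
      if (homogeneous) t <- t / .gcdv(t)
      if (max(t) > max_coef) next
      if (!.role_feasible(t, roles, min_pi2_frac)) next
      key <- paste(t, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      sols[[length(sols) + 1L]] <-
        .solution_record(t, signs, pathways, roles, homogeneous)
    }
  }

  if (length(sols) > 0L) {
    ord <- order(vapply(sols, `[[`, numeric(1), "normalized_total"),
                 vapply(sols, function(s) max(s$lengths), numeric(1)))
    sols <- sols[ord]
    out$feasible <- TRUE
    out$unique <- (d == 0L) ||
      (homogeneous && d == 1L && length(sols) == 1L)
    out$solutions <- sols
  }
  out
}

# continued-fraction rational approximation (exact for the small rationals
# produced by the rref); returns c(num, den)
.as_fraction <- function(x, max_den = 1e6) {
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0
  a <- floor(x); frac <- x - a
  h <- a * h1 + h0; k <- a * k1 + k0
  while (abs(x - h / k) > 1e-12 * max(1, x) && k < max_den) {
    x2 <- 1 / frac
    a <- floor(x2); frac <- x2 - a
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    h <- a * h1 + h0; k <- a * k1 + k0
  }
  c(sign * h, k)
}

#' @export
print.ratio_solutions <- function(x, ...) {
  cat(sprintf("refocusing ratios: %d pulses, signs (%s), %d pathway(s)\n",
              x$n_pulses, paste(ifelse(x$signs > 0, "+", "-"), collapse = ""),
              length(x$pathways)))
  if (!x$feasible) {
    cat("  infeasible: no positive pulse lengths satisfy the pathways\n")
    return(invisible(x))
  }
  cat(sprintf("  %d solution(s)%s\n", length(x$solutions),
              if (x$unique) " [unique up to scaling]" else ""))
  for (s in utils::head(x$solutions, 10L)) {
    form <- if (!is.null(s$integer_form))
      paste(s$integer_form, collapse = ":") else
        paste(signif(s$lengths, 4), collapse = ":")
    cat(sprintf("    %s   (normalized total %.3g)\n", form,
                s$normalized_total))
  }
  invisible(x)
}

#' Enumerate sweep-sign patterns and rank their refocusing solutions
#'
#' Runs [solve_ratios()] for every one of the `2^n` sweep-direction
#' patterns and returns the feasible ones with their top-ranked solution,
#' sorted by normalized total length; ties are broken by the longest single
#' pulse and then lexicographically on the signs (up before down).
#'
#' @inheritParams solve_ratios
#' @param ... passed to [solve_ratios()] (`fixed`, `equal`, `roles`, ...).
#' @return a data frame with columns `signs` (character, e.g. `"++-"`),
#'   `ratio` (colon-separated integer form), `normalized_total`, `unique`.
#' @export
enumerate_patterns <- function(n_pulses, pathways, ...) {
  if (n_pulses > 10L) stop("sign-pattern enumeration supports at most 10 pulses")
  pats <- as.matrix(do.call(expand.grid, rep(list(c(1, -1)), n_pulses)))
  rows <- list()
  for (r in seq_len(nrow(pats))) {
    signs <- as.numeric(pats[r, ])
    sol <- solve_ratios(n_pulses, signs, pathways, ...)
    if (!sol$feasible) next
    top <- sol$solutions[[1]]
    form <- if (!is.null(top$integer_form))
      paste(top$integer_form, collapse = ":") else
        paste(signif(top$lengths, 6), collapse = ":")
    rows[[length(rows) + 1L]] <- data.frame(
      signs = paste(ifelse(signs > 0, "+", "-"), collapse = ""),
      ratio = form,
      normalized_total = top$normalized_total,
      longest = max(top$lengths),
      unique = sol$unique,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(signs = character(0), ratio = character(0),
                      normalized_total = numeric(0), longest = numeric(0),
                      unique = logical(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$normalized_total, df$longest, df$signs), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Verify refocusing of several pathways and predict their echo times
#'
#' Checks the refocusing residual of each pathway for a given length/sign
#' assignment and, when inter-pulse delays are supplied, predicts the echo
#' time of each pathway after the last pulse from the coherence-order
#' bookkeeping: the offset phase accumulated over the delays,
#' `sum_j o+_j * tau_j`, must cancel against the detection period.
#'
#' @param lengths relative pulse lengths.
#' @param signs sweep signs.
#' @param pathways list of [pathway()]s (at least 2 for a dual-echo check).
#' @param delays optional numeric vector of `n_pulses - 1` center-to-center
#'   delays (ns) used for echo-time prediction.
#' @return a data frame with one row per pathway: `residual` and (when
#'   delays are given) `echo_time`, the predicted time of refocusing after
#'   the last pulse center (ns).
#' @export
verify_dual_refocusing <- function(lengths, signs, pathways, delays = NULL) {
  pathways <- lapply(pathways, pathway)
  res <- vapply(pathways, function(pw) eq8_residual(lengths, signs, pw),
                numeric(1))
  out <- data.frame(pathway = seq_along(pathways), residual = res)
  if (!is.null(delays)) {
    n <- length(lengths)
    if (length(delays) != n - 1L)
      stop("need one center-to-center delay per pulse gap")
    out$echo_time <- vapply(pathways, function(pw) {
      o_det <- pw$op[n]
      if (o_det == 0) return(NA_real_)
      -sum(pw$op[seq_len(n - 1L)] * delays) / o_det
    }, numeric(1))
  }
  out
}

#' Linear-condition pathways for SIFTER ratio design
#'
#' Two auxiliary "pathways" that encode, in the refocusing-condition
#' bookkeeping, the additional linear constraints used when designing
#' four-pulse SIFTER variants:
#'
#' * `dispersion_matching_pathway()`: the echo produced by pulses 1 and 2
#'   must have the same offset-frequency dispersion as the passage of the
#'   third pulse (the third pulse then does not affect the in-phase
#'   coherence). Encoded as orders `(0,1), (1,-1), (-1,0)` and passive
#'   afterwards, i.e. `-s1*t1 + 2*s2*t2 - s3*t3 = 0`.
#' * `solid_echo_pathway()`: pulses 1 and 3 (the two pi/2 pulses) must
#'   refocus the dipolar coupling without offset dispersion: coherence +1
#'   before the third pulse and -1 after, pulses 2 and 4 passive, i.e.
#'   `-s1*t1 + 2*s3*t3 = 0` (the 2:1 first-to-third length relation for up
#'   sweeps).
#'
#' @param n_pulses number of pulses in the sequence (>= 3).
#' @return a [pathway()].
#' @export
dispersion_matching_pathway <- function(n_pulses = 4L) {
  stopifnot(n_pulses >= 3L)
  m <- rbind(c(0, 1), c(1, -1), c(-1, 0))
  if (n_pulses > 3L)
    m <- rbind(m, matrix(0, n_pulses - 3L, 2))
  pathway(m)
}

#' @rdname dispersion_matching_pathway
#' @export
solid_echo_pathway <- function(n_pulses = 4L) {
  stopifnot(n_pulses >= 3L)
  m <- rbind(c(0, 1), c(1, 1), c(1, -1))
  if (n_pulses > 3L)
    m <- rbind(m, matrix(-1, n_pulses - 3L, 2))
  pathway(m)
}

# internal alias, usable where a formal argument shadows `pathway`
.as_pathway <- function(x, ...) pathway(x, ...)
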