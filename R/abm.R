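# Agent-based model of CA acquisition in a growing cell population.
#
# Cells occupy interphase states (normal or micronucleated). When a cell's
# cycle clock expires it enters a mitosis type - normal, laggard (lagging
# chromosome) or bridge (chromatin bridge) - or arrests, with probabilities
# conditioned on its interphase state. A division removes the parent and
# creates two daughters; with a mitosis-type-specific probability the
# division produces one micronucleated daughter, and with probability
# R(mitosis type) one daughter (chosen uniformly) acquires a heritable de
# novo CA. Arrested cells are removed. The run starts from a small founder
# population and stops exactly when the population reaches the stop size.
#
# Because every cell has the same (median) cycle duration, generations do
# not interleave: each generation is processed as one vectorized batch, in
# the order of the cells' inherited clock offsets, which reproduces the
# event-by-event dynamics of a clock-expiry queue.

MITOSIS_TYPES <- c("normal", "laggard", "bridge")

#' Agent-based model parameters
#'
#' Defaults are assembled from wild-type live-imaging frequencies: 6.2
#' percent laggard and 5.1 percent bridge mitoses; at least one
#' micronucleated daughter in 32.3 / 17.2 percent of laggard / bridge
#' mitoses; micronucleated cells 9.5 times as likely to produce a
#' micronucleated daughter and more prone to arrest. The normal-mitosis
#' daughter micronucleation probability and the arrest probabilities are
#' approximate free parameters (documented in the vignette); simulated
#' frequencies are therefore properties, not exact reproductions.
#'
#' @param p_mitosis 2 x 4 matrix of transition probabilities from the
#'   interphase states (rows `normal`, `micronucleated`) to
#'   `normal`/`laggard`/`bridge` mitosis or `arrest`; rows must sum to 1.
#' @param q_mn probability, per mitosis type, that the division yields one
#'   micronucleated daughter.
#' @param mn_mult multiplier on `q_mn` for micronucleated parents (capped
#'   at 0.95).
#' @param rates per-mitosis-type de novo CA probability per division, each
#'   in `[0, 1]`.
#' @param cycle_h median cell-cycle duration in hours (sets the time scale
#'   only).
#' @param start,stop founder and stop population sizes.
#' @return A validated list of class `sk_abm_params`.
#' @export
abm_params <- function(p_mitosis = NULL,
                       q_mn = c(normal = 0.04, laggard = 0.323, bridge = 0.172),
                       mn_mult = 9.5,
                       rates = c(normal = 0.037, laggard = 0.925, bridge = 0.844),
                       cycle_h = 18, start = 50, stop = 50000) {
  if (is.null(p_mitosis)) {
    p_mitosis <- rbind(
      normal = c(0.887, 0.062, 0.051, 0),
      micronucleated = c(0.75 * c(0.887, 0.062, 0.051), 0.25)
    )
    colnames(p_mitosis) <- c(MITOSIS_TYPES, "arrest")
  }
  if (!is.matrix(p_mitosis) || any(dim(p_mitosis) != c(2L, 4L)))
    sk_parameter_error("p_mitosis must be a 2 x 4 matrix")
  if (any(p_mitosis < 0) || any(abs(rowSums(p_mitosis) - 1) > 1e-8))
    sk_parameter_error("p_mitosis rows (including arrest) must sum to 1")
  if (length(q_mn) != 3L || any(q_mn < 0 | q_mn > 1))
    sk_parameter_error("q_mn must be three probabilities")
  if (length(rates) != 3L || any(rates < 0 | rates > 1))
    sk_parameter_error("rates must be three probabilities in [0, 1]")
  if (stop <= start) sk_parameter_error("stop population must exceed start")
  structure(list(p_mitosis = p_mitosis,
                 q_mn = setNames(as.numeric(q_mn), MITOSIS_TYPES),
                 mn_mult = mn_mult,
                 rates = setNames(as.numeric(rates), MITOSIS_TYPES),
                 cycle_h = cycle_h, start = as.integer(start),
                 stop = as.integer(stop)),
            class = "sk_abm_params")
}

#' Simulate the agent-based CA model
#'
#' @param params an [abm_params()].
#' @param seed RNG seed; a fixed seed reproduces the run exactly.
#' @param n_checkpoints number of population-size checkpoints (geometric
#'   between start and stop) at which micronucleus and CA frequencies are
#'   sampled.
#' @return list of class `sk_absim` with `freq` (named frequencies:
#'   `mn_frequency`, `ca_frequency`, `ca_freq_micronucleated`,
#'   `ca_freq_normal`, CA frequencies by parent mitosis type
#'   `ca_freq_mitosis_*`, and de novo acquisition frequencies
#'   `de_novo_freq_mitosis_*` - the fraction of live daughters of each
#'   mitosis type whose CA arose at their own birth), `final_size`,
#'   `divisions` (counts by
#'   mitosis type), `checkpoints` (size, mn_freq, ca_freq), `generations`
#'   (population size at each generation boundary) and `extinct`.
#' @export
abm_simulate <- function(params, seed = 1L, n_checkpoints = 30L) {
  stopifnot(inherits(params, "sk_abm_params"))
  with_rng_seed(seed, {
    n0 <- params$start
    mn <- rep(FALSE, n0)
    ca <- rep(FALSE, n0)
    dn <- rep(FALSE, n0)             # CA acquired at the cell's own birth
    origin <- rep(1L, n0)            # mitosis type that produced the cell
    offset <- runif(n0, 0, params$cycle_h)
    ck_sizes <- unique(round(exp(seq(log(n0 + 1), log(params$stop),
                                     length.out = n_checkpoints))))
    ck_next <- 1L
    ck <- list()
    divisions <- setNames(numeric(3L), MITOSIS_TYPES)
    gens <- integer()
    cp <- t(apply(params$p_mitosis, 1L, cumsum))
    gen <- 0L
    repeat {
      n <- length(offset)
      gens <- c(gens, n)
      if (n == 0L || n >= params$stop || gen > 5000L) break
      gen <- gen + 1L
      ord <- order(offset)
      mn <- mn[ord]; ca <- ca[ord]; dn <- dn[ord]
      origin <- origin[ord]; offset <- offset[ord]
      u <- runif(n)
      row <- ifelse(mn, 2L, 1L)
      type <- 1L + (u > cp[row, 1L]) + (u > cp[row, 2L]) + (u > cp[row, 3L])
      divided <- type <= 3L
      q <- params$q_mn[pmin(type, 3L)]
      q[mn] <- pmin(q[mn] * params$mn_mult, 0.95)
      mn_event <- divided & (runif(n) < q)
      acq <- divided & (runif(n) < params$rates[pmin(type, 3L)])
      side_mn <- runif(n) < 0.5
      side_ca <- runif(n) < 0.5
      d1_mn <- mn_event & side_mn; d2_mn <- mn_event & !side_mn
      d1_dn <- acq & side_ca; d2_dn <- acq & !side_ca
      d1_ca <- (ca | d1_dn) & divided; d2_ca <- (ca | d2_dn) & divided

      # population size after processing event i: parents drop out one by
      # one, each division adds two daughters
      sizes <- n - seq_len(n) + 2L * cumsum(divided)
      # population checkpoints crossed inside this generation
      mn_run <- sum(mn) - cumsum(mn) + cumsum(d1_mn + d2_mn)
      ca_run <- sum(ca) - cumsum(ca) + cumsum(d1_ca + d2_ca)
      while (ck_next <= length(ck_sizes) && any(sizes >= ck_sizes[ck_next])) {
        i <- which(sizes >= ck_sizes[ck_next])[1L]
        ck[[length(ck) + 1L]] <- c(size = sizes[i],
                                   mn_freq = mn_run[i] / sizes[i],
                                   ca_freq = ca_run[i] / sizes[i])
        ck_next <- ck_next + 1L
      }
      stop_at <- which(sizes >= params$stop)
      cut <- if (length(stop_at)) stop_at[1L] else n
      proc <- seq_len(cut)
      dv <- divided[proc]
      for (t in 1:3) divisions[t] <- divisions[t] + sum(type[proc] == t)
      keep <- if (cut < n) seq((cut + 1L), n) else integer()
      new_mn <- c(d1_mn[proc][dv], d2_mn[proc][dv])
      new_ca <- c(d1_ca[proc][dv], d2_ca[proc][dv])
      new_dn <- c(d1_dn[proc][dv], d2_dn[proc][dv])
      new_origin <- c(type[proc][dv], type[proc][dv])
      new_offset <- c(offset[proc][dv], offset[proc][dv])
      mn <- c(mn[keep], new_mn)
      ca <- c(ca[keep], new_ca)
      dn <- c(dn[keep], new_dn)
      origin <- c(origin[keep], new_origin)
      offset <- c(offset[keep], new_offset)
      if (length(stop_at)) { gens <- c(gens, length(offset)); break }
    }
    n <- length(offset)
    f <- function(x) if (length(x)) mean(x) else NA_real_
    freq <- c(
      mn_frequency = f(mn),
      ca_frequency = f(ca),
      ca_freq_micronucleated = f(ca[mn]),
      ca_freq_normal = f(ca[!mn]),
      ca_freq_mitosis_normal = f(ca[origin == 1L]),
      ca_freq_mitosis_laggard = f(ca[origin == 2L]),
      ca_freq_mitosis_bridge = f(ca[origin == 3L]),
      de_novo_freq_mitosis_normal = f(dn[origin == 1L]),
      de_novo_freq_mitosis_laggard = f(dn[origin == 2L]),
      de_novo_freq_mitosis_bridge = f(dn[origin == 3L])
    )
    if (n == 0L) freq[] <- NA_real_
    ckdt <- if (length(ck)) data.table::as.data.table(do.call(rbind, ck))
    else data.table::data.table(size = numeric(), mn_freq = numeric(),
                                ca_freq = numeric())
    structure(list(freq = freq, final_size = n,
                   divisions = setNames(as.numeric(divisions[MITOSIS_TYPES]),
                                        MITOSIS_TYPES),
                   checkpoints = ckdt, generations = gens,
                   extinct = n == 0L),
              class = "sk_absim")
  })
}

#' Sum of squared error between simulated and target CA frequencies
#'
#' @param sim an `sk_absim` result.
#' @param targets named numeric vector of target frequencies; names must be
#'   compartments present in `sim$freq` (default compartments in a fit are
#'   the CA frequencies of micronucleated and normal cells).
#' @return Non-negative scalar.
#' @export
abm_sse <- function(sim, targets) {
  if (is.null(names(targets)) || any(names(targets) == ""))
    sk_parameter_error("targets must be named")
  miss <- setdiff(names(targets), names(sim$freq))
  if (length(miss))
    sk_stop("sk_compartment_error",
            paste0("missing compartment(s): ", paste(miss, collapse = ", ")))
  v <- sim$freq[names(targets)]
  if (anyNA(v)) return(sum((1 - unname(targets))^2) + 1)
  sum((unname(v) - unname(targets))^2)
}

#' Estimate per-mitosis-type CA rates from target frequencies
#'
#' Multi-start, bound-constrained, derivative-free (Nelder-Mead simplex)
#' minimization of the expected SSE between simulated and target CA
#' frequencies. The objective averages the simulation over a fixed set of
#' replicate seeds (common random numbers), making it deterministic within
#' a start. Estimates from all starts are returned together with their
#' residual errors and the residual-error-weighted average.
#'
#' @param targets named numeric vector of target CA frequencies (see
#'   [abm_sse()]).
#' @param params an [abm_params()]; its `rates` entry is ignored.
#' @param n_starts number of optimization starts (>= 1).
#' @param seed RNG seed controlling start points and evaluation seeds.
#' @param reps simulation replicates averaged per objective evaluation.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return list of class `sk_rate_estimate` with `estimates` (one row per
#'   start: rates and residual SSE), `weighted` (residual-weighted average
#'   rate vector) and `weights`.
#' @export
estimate_rates <- function(targets, params, n_starts = 5L, seed = 1L,
                           reps = 4L, maxit = 150L) {
  if (n_starts < 1L) sk_parameter_error("n_starts must be >= 1")
  with_rng_seed(seed, {
    eval_seeds <- sample.int(1e6, reps)
    starts <- matrix(runif(3L * n_starts), n_starts, 3L)
    objective <- function(r) {
      pen <- sum(pmax(r - 1, 0)^2 + pmax(-r, 0)^2)
      rc <- pmin(pmax(r, 0), 1)
      p <- params
      p$rates <- setNames(rc, MITOSIS_TYPES)
      v <- vapply(eval_seeds, function(s)
        abm_sse(abm_simulate(p, seed = s), targets), numeric(1))
      mean(v) + 10 * pen
    }
    est <- lapply(seq_len(n_starts), function(k) {
      fit <- tryCatch({
        f1 <- optim(starts[k, ], objective, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-4))
        # restart the simplex from the first-round optimum: Nelder-Mead
        # simplexes collapse early on noisy piecewise-constant objectives
        optim(f1$par, objective, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-5))
      }, error = function(e) list(par = starts[k, ], value = objective(starts[k, ]),
                                  convergence = 99L))
      r <- pmin(pmax(fit$par, 0), 1)
      data.table::data.table(start = k, r_normal = r[1], r_laggard = r[2],
                             r_bridge = r[3], sse = fit$value,
                             converged = identical(fit$convergence, 0L))
    })
    est <- data.table::rbindlist(est)
    wts <- 1 / (est$sse + 1e-8)
    wts <- wts / sum(wts)
    weighted <- c(
      normal = sum(wts * est$r_normal),
      laggard = sum(wts * est$r_laggard),
      bridge = sum(wts * est$r_bridge)
    )
    structure(list(estimates = est[], weighted = weighted, weights = wts),
              class = "sk_rate_estimate")
  })
}

#' Basal CA rate from mitosis-type rates and frequencies
#'
#' The population-level per-division CA rate is the average of the
#' per-mitosis-type rates weighted by the relative frequency of each
#' mitosis type.
#'
#' @param rates per-mitosis-type CA rates (normal, laggard, bridge), on any
#'   common scale (percent in typical use).
#' @param freqs mitosis-type frequencies summing to 1.
#' @return The weighted average, on the scale of `rates`.
#' @examples
#' basal_rate(c(3.7, 92.5, 84.4), c(0.887, 0.062, 0.051))
#' @export
basal_rate <- function(rates, freqs) {
  if (length(rates) != length(freqs))
    sk_parameter_error("rates and freqs must have equal length")
  if (abs(sum(freqs) - 1) > 1e-8)
    sk_parameter_error("mitosis-type frequencies must sum to 1")
  sum(rates * freqs)
}
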