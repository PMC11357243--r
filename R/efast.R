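#' eFAST sampling design
#'
#' Extended Fourier Amplitude Sensitivity Test search-curve design (Saltelli's
#' max-frequency scheme, interference factor `M = 4`). For each replication
#' and each target factor a search curve of `n` points is generated in which
#' the target factor oscillates at the maximum admissible frequency
#' `floor((n - 1) / (2 M))` and the complementary factors at low frequencies
#' `1..floor(w_max / (2 M))`; every factor receives an independent random
#' phase per curve. Draws are mapped into the requested ranges through the
#' arcsine transform, giving the characteristic eFAST marginal.
#'
#' @param ranges Named list of `c(lower, upper)` ranges (the physiological
#'   intervals by default elsewhere).
#' @param n Points per search curve (simulated sample size).
#' @param replications Number of independent replications.
#' @param M Interference factor.
#' @param seed Seed for the phases.
#' @return `efast_design`: data frame with columns `rep`, `target`, `s_index`
#'   and one column per factor; attributes `frequencies`, `n`, `M`.
#' @export
efast_sample <- function(ranges, n = 1000, replications = 5, M = 4,
                         seed = NULL) {
  k <- length(ranges)
  stopifnot(k >= 2, !is.null(names(ranges)))
  wmax <- floor((n - 1) / (2 * M))
  if (wmax < 2 * k)
    stop("n = ", n, " is below the eFAST minimum for ", k, " factors")
  if (!is.null(seed)) set.seed(seed)
  m <- max(1, floor(wmax / (2 * M)))
  cmpl_freq <- function(n_other) {
    if (m >= n_other) unique(round(seq(1, m, length.out = n_other)))[seq_len(n_other)]
    else rep_len(seq_len(m), n_other)
  }
  s <- -pi + 2 * pi * (seq_len(n) - 0.5) / n
  fac_names <- names(ranges)
  blocks <- list(); freqs <- list()
  for (r in seq_len(replications)) {
    for (ti in seq_len(k)) {
      w <- numeric(k)
      w[ti] <- wmax
      w[-ti] <- cmpl_freq(k - 1)
      phi <- stats::runif(k, 0, 2 * pi)
      X <- sapply(seq_len(k), function(f) {
        x01 <- 0.5 + asin(sin(w[f] * s + phi[f])) / pi
        ranges[[f]][1] + x01 * (ranges[[f]][2] - ranges[[f]][1])
      })
      colnames(X) <- fac_names
      blocks[[length(blocks) + 1]] <-
        cbind(data.frame(rep = r, target = fac_names[ti], s_index = seq_len(n)),
              as.data.frame(X))
      freqs[[length(freqs) + 1]] <-
        data.frame(rep = r, target = fac_names[ti], factor = fac_names,
                   frequency = w)
    }
  }
  structure(do.call(rbind, blocks),
            frequencies = do.call(rbind, freqs), n = n, M = M,
            ranges = ranges,
            class = c("efast_design", "data.frame"))
}

fast_spectrum_indices <- function(y, wmax, M) {
  n <- length(y)
  Y <- stats::fft(y) / n
  amp2 <- 2 * Mod(Y[2:(floor((n - 1) / 2) + 1)])^2  # frequencies 1..n/2-1
  V <- sum(amp2)
  if (V < .Machine$double.eps) return(c(Si = NA_real_, STi = NA_real_))
  Vi <- sum(amp2[(1:M) * wmax])
  Vc <- sum(amp2[seq_len(floor(wmax / 2))])
  c(Si = Vi / V, STi = 1 - Vc / V)
}

#' Sobol indices from an eFAST design
#'
#' First-order indices are estimated from the spectral power at each target
#' factor's frequency and its first `M` harmonics; total-order indices from
#' the complement of the low-frequency spectrum. Indices are averaged over
#' replications and the replication spread retained.
#'
#' @param design An [efast_sample()] design.
#' @param outputs Numeric vector (one output per design row) or a matrix with
#'   one column per output (e.g. plasma potassium at several times).
#' @return `sobol_result`: data frame (output, parameter, Si, STi, Si_sd,
#'   STi_sd).
#' @export
efast_indices <- function(design, outputs) {
  stopifnot(inherits(design, "efast_design"))
  if (is.vector(outputs)) outputs <- matrix(outputs, ncol = 1)
  if (is.null(colnames(outputs)))
    colnames(outputs) <- paste0("y", seq_len(ncol(outputs)))
  if (nrow(outputs) != nrow(design))
    stop("outputs must have one row per design row")
  bad <- !is.finite(rowSums(outputs))
  if (any(bad))
    stop("non-finite model outputs in design rows: ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  n <- attr(design, "n"); M <- attr(design, "M")
  wmax <- floor((n - 1) / (2 * M))
  key <- interaction(design$rep, design$target, drop = TRUE)
  rows <- list()
  for (out_j in colnames(outputs)) {
    yj <- outputs[, out_j]
    per <- do.call(rbind, lapply(split(seq_len(nrow(design)), key), function(idx) {
      idx <- idx[order(design$s_index[idx])]
      si <- fast_spectrum_indices(yj[idx], wmax, M)
      data.frame(rep = design$rep[idx[1]], parameter = design$target[idx[1]],
                 Si = si["Si"], STi = si["STi"])
    }))
    agg <- do.call(rbind, lapply(split(per, per$parameter), function(d)
      data.frame(output = out_j, parameter = d$parameter[1],
                 Si = mean(d$Si), STi = mean(d$STi),
                 Si_sd = stats::sd(d$Si), STi_sd = stats::sd(d$STi))))
    rows[[out_j]] <- agg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sobol_result", "data.frame")
  out
}

#' Run the potassium model over an eFAST design
#'
#' Each design row sets the sampled parameters on the nominal set (without
#' re-calibration) and simulates 24 h from the nominal calibrated steady
#' state; outputs are plasma potassium at the requested times, so the
#' resulting indices are time-resolved.
#'
#' @param params Nominal `qsp_parameters`.
#' @param design [efast_sample()] design whose factor columns are model
#'   parameter names.
#' @param times Output times, minutes.
#' @return [efast_indices()] result with one output per time point.
#' @export
efast_qsp <- function(params, design,
                      times = seq(0, 1440, by = 120)) {
  fac <- setdiff(colnames(design), c("rep", "target", "s_index"))
  init <- attr(params, "steady_state")
  horizon <- max(times)
  out <- matrix(NA_real_, nrow(design), length(times),
                dimnames = list(NULL, paste0("K_t", times)))
  pv <- unlist(params)
  for (i in seq_len(nrow(design))) {
    pv2 <- pv
    pv2[fac] <- as.numeric(design[i, fac])
    sol <- deSolve::ode(
      y = init, times = times, func = "spirok_derivs", parms = pv2,
      dllname = "spirok", initfunc = "spirok_initmod",
      nout = length(qsp_output_names()), outnames = qsp_output_names(),
      method = "lsoda", rtol = 1e-8, atol = 1e-10
    )
    out[i, ] <- sol[, "K_plasma"]
  }
  efast_indices(design, out)
}

#' Monte-Carlo uncertainty envelope of potassium trajectories
#'
#' Samples parameters uniformly from the given ranges, simulates a 24-h
#' trajectory per draw starting from that draw's own drug-free steady state,
#' and summarizes plasma potassium pointwise by the median, the 95% interval
#' and the full min-max range.
#'
#' @param params Nominal `qsp_parameters` (non-sampled parameters).
#' @param ranges Named list of `c(lower, upper)`; degenerate (zero-width)
#'   ranges are allowed.
#' @param n_draws Number of Monte-Carlo draws (>= 2).
#' @param seed Seed.
#' @param horizon,dt Trajectory grid, minutes.
#' @return `uncertainty_envelope`: data frame (time_min, min, q2.5, median,
#'   q97.5, max) with attribute `n_ok` (successful draws) and `draws_K`
#'   (matrix of trajectories).
#' @export
uncertainty_mc <- function(params, ranges = param_ranges("efast"),
                           n_draws = 500, seed = NULL,
                           horizon = 1440, dt = 60) {
  stopifnot(n_draws >= 2)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, horizon, by = dt)
  draws <- sapply(ranges, function(r) stats::runif(n_draws, r[1], r[2]))
  K <- matrix(NA_real_, n_draws, length(times))
  ok <- logical(n_draws)
  for (i in seq_len(n_draws)) {
    res <- try({
      pp <- do.call(set_parameter,
                    c(list(params), as.list(draws[i, , drop = TRUE])))
      st <- steady_state_analytic(pp)
      simulate_qsp(pp, initial_state = st, horizon = horizon, dt = dt)$K_plasma
    }, silent = TRUE)
    if (!inherits(res, "try-error")) { K[i, ] <- res; ok[i] <- TRUE }
  }
  if (mean(ok) < 0.9)
    stop(sum(!ok), " of ", n_draws, " draws failed to simulate")
  Kok <- K[ok, , drop = FALSE]
  env <- data.frame(
    time_min = times,
    min = apply(Kok, 2, min),
    q2.5 = apply(Kok, 2, stats::quantile, 0.025),
    median = apply(Kok, 2, stats::median),
    q97.5 = apply(Kok, 2, stats::quantile, 0.975),
    max = apply(Kok, 2, max)
  )
  structure(env, n_ok = sum(ok), n_failed = sum(!ok), draws_K = Kok,
            class = c("uncertainty_envelope", "data.frame"))
}
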