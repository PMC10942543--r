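#' Generate pseudo-data for gating-model fitting
#'
#' Forward-model steady-state activation, time-constant, and (optionally)
#' peak I-V curves from known rate parameters, with multiplicative Gaussian
#' noise. Stands in for digitized experimental summary curves when testing
#' the fitting workflow.
#'
#' @param truth a `vsm_rate_params` object (the generating parameters).
#' @param V voltage grid (mV).
#' @param noise_sd multiplicative noise standard deviation (0 = exact).
#' @param seed RNG seed.
#' @param scale optional conductance scale (nS); if given, a peak I-V curve
#'   `scale * n_inf * (V - E_K)` is included with `E_K = -84` mV.
#' @return A `vsm_fit_data` list with `V`, `n_inf`, `tau`, optionally `iv`,
#'   and `noise_sd`.
#' @export
make_pseudo_data <- function(truth, V, noise_sd = 0, seed = 1,
                             scale = NULL) {
  stopifnot(is.numeric(V), length(V) >= 1)
  r <- rates(V, truth)
  set.seed(seed)
  jitter <- function(x) x * (1 + noise_sd * rnorm(length(x)))
  out <- list(
    V = V,
    n_inf = jitter(r$n_inf),
    tau = jitter(r$tau),
    noise_sd = noise_sd
  )
  if (!is.null(scale)) out$iv <- jitter(scale * r$n_inf * (V + 84))
  structure(out, class = "vsm_fit_data")
}

#' Read/write fitting datasets as CSV
#'
#' Long format with columns `V_mV`, `quantity` (`n_inf`, `tau` or `iv`),
#' `value`, `sd`, `source`.
#'
#' @param data a `vsm_fit_data` object.
#' @param path file path.
#' @return `path` invisibly (write); a `vsm_fit_data` (read).
#' @export
write_fit_data <- function(data, path) {
  rows <- list()
  for (q in intersect(c("n_inf", "tau", "iv"), names(data))) {
    rows[[q]] <- data.frame(
      V_mV = data$V, quantity = q, value = data[[q]],
      sd = if (is.null(data$noise_sd)) NA_real_ else data$noise_sd,
      source = "pseudo-data"
    )
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit_data
#' @export
read_fit_data <- function(path) {
  df <- utils::read.csv(path)
  need <- c("V_mV", "quantity", "value")
  if (!all(need %in% names(df))) {
    stop("read_fit_data: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  V <- sort(unique(df$V_mV))
  out <- list(V = V)
  for (q in unique(df$quantity)) {
    sub <- df[df$quantity == q, ]
    out[[q]] <- sub$value[order(sub$V_mV)]
  }
  structure(out, class = "vsm_fit_data")
}

# weighted least-squares objective over the provided curves; each curve is
# normalized by its dynamic range so fractions and pA contribute comparably
.fit_objective <- function(data, weights = NULL) {
  targets <- intersect(c("n_inf", "tau", "iv"), names(data))
  if (!length(targets)) stop("fit_gate: dataset contains no target curves")
  rng <- lapply(targets, function(q) max(diff(range(data[[q]])), 1e-12))
  names(rng) <- targets
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(targets)),
                                                   targets)
  function(par) {
    p <- list(x1 = exp(par[1]), x2 = par[2], x3 = exp(par[3]),
              x4 = par[4], x5 = exp(par[5]))
    if (abs(p$x2) < 1e-3 || abs(p$x4) < 1e-3) return(1e10)
    r <- rates(data$V, p)
    err <- 0
    if ("n_inf" %in% targets) {
      err <- err + weights[["n_inf"]] *
        sum(((r$n_inf - data$n_inf) / rng[["n_inf"]])^2)
    }
    if ("tau" %in% targets) {
      err <- err + weights[["tau"]] *
        sum(((r$tau - data$tau) / rng[["tau"]])^2)
    }
    if ("iv" %in% targets) {
      scale <- exp(par[6])
      model_iv <- scale * r$n_inf * (data$V + 84)
      err <- err + weights[["iv"]] *
        sum(((model_iv - data$iv) / rng[["iv"]])^2)
    }
    if (!is.finite(err)) 1e10 else err
  }
}

#' Fit a five-parameter gating model to summary curves
#'
#' Weighted least-squares fit of the [rates()] parameterization to
#' steady-state activation, time-constant and optionally peak-I-V curves,
#' by Nelder-Mead local search with randomized multiplicative restarts
#' (< 10% perturbation of the incumbent). Deterministic given `seed`.
#'
#' @param data a `vsm_fit_data` (see [make_pseudo_data()],
#'   [read_fit_data()]).
#' @param init initial `vsm_rate_params`.
#' @param weights optional named weights per curve (`n_inf`, `tau`, `iv`).
#' @param restarts number of restart perturbations.
#' @param seed RNG seed for the perturbations.
#' @param init_scale initial conductance scale for the I-V target (nS).
#' @return A `vsm_fit_result`: `params` (fitted `vsm_rate_params`), `scale`
#'   (if I-V fitted), `objective`, `restarts`, `trace` (objective after
#'   each accepted improvement), and `warning` flag when no restart
#'   improved on the initial fit.
#' @export
fit_gate <- function(data, init, weights = NULL, restarts = 200, seed = 1,
                     init_scale = 1) {
  obj <- .fit_objective(data, weights)
  has_iv <- "iv" %in% names(data)
  par0 <- c(log(init$x1), init$x2, log(init$x3), init$x4,
            log(max(init$x5, 1e-6)))
  if (has_iv) par0 <- c(par0, log(init_scale))
  set.seed(seed)
  fit1 <- optim(par0, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  best <- fit1
  improved <- FALSE
  trace <- fit1$value
  for (i in seq_len(restarts)) {
    pert <- best$par * (1 + runif(length(best$par), -0.1, 0.1))
    fit <- optim(pert, obj, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-14))
    if (fit$value < best$value) {
      best <- fit
      improved <- TRUE
      trace <- c(trace, fit$value)
    }
  }
  par <- best$par
  structure(list(
    params = rate_params(exp(par[1]), par[2], exp(par[3]), par[4],
                         exp(par[5])),
    scale = if (has_iv) exp(par[6]) else NULL,
    objective = best$value,
    restarts = restarts,
    trace = trace,
    warning = !improved && restarts > 0
  ), class = "vsm_fit_result")
}

#' Calibrate the male and female parameter sets from published anchors
#'
#' Reconstructs the sex-specific channel-level constants from the anchor
#' values (Kv2.1 peak current at +40 mV, steady-state Kv2.1 currents at -40
#' and -30 mV, the Kv1.5/Kv2.1 contribution split at -40 mV, and the steady
#' L-type current at -40 mV) and verifies each anchor against the
#' assembled model. The shipped parameter files are the output of this
#' routine.
#'
#' @return List with `male` and `female` (`vsm_params`, NSC conductance
#'   tuned to the sex-specific resting potential) and `report`: a data
#'   frame of anchors with target, achieved value, and relative error.
#' @export
calibrate_sex_models <- function() {
  out <- list()
  rows <- list()
  for (sex in c("male", "female")) {
    anch <- .calibration_anchors(sex)
    p <- default_parameters(sex)
    p <- tune_nsc_for_baseline(p, anch$v_rest)
    out[[sex]] <- p
    E_K <- nernst(1, p$conc$K_in, p$conc$K_out, p$const)
    peak <- p$channels$G_Kv21 * rates(40, p$gates$kv21)$n_inf * (40 - E_K)
    c40 <- steady_currents(p, -40)
    c30 <- steady_currents(p, -30)
    split <- 100 * c40$I_Kv15 / (c40$I_Kv15 + c40$I_Kv21)
    eqv <- find_equilibrium(p)$V
    achieved <- c(peak, c40$I_Kv21, c30$I_Kv21, split, abs(c40$I_Ca), eqv)
    target <- c(anch$kv21_peak_40, anch$kv21_ss_m40, anch$kv21_ss_m30,
                anch$kv_split_m40[["kv15"]], anch$ica_ss_m40, anch$v_rest)
    rows[[sex]] <- data.frame(
      sex = sex,
      anchor = c("kv21_peak_+40mV_pA", "kv21_ss_-40mV_pA",
                 "kv21_ss_-30mV_pA", "kv15_contribution_-40mV_pct",
                 "ica_ss_-40mV_pA", "resting_potential_mV"),
      target = target,
      achieved = achieved,
      rel_error = abs(achieved - target) / pmax(abs(target), 1e-12)
    )
  }
  out$report <- do.call(rbind, rows)
  rownames(out$report) <- NULL
  out
}
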