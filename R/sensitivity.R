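# Population-based sensitivity analysis: log-normal scaling of the 11
# current magnitudes, model outputs per sample, multivariable linear
# regression of standardized outputs on standardized log scale factors.

# the 11 scalable current magnitudes and the parameter each maps to
.sens_parameters <- c(
  I_Kv15 = "G_Kv15", I_Kv21 = "G_Kv21", I_BKCa = "P_BKCa", I_Kb = "G_Kb",
  I_Cav12 = "P_Ca", I_PMCA = "I_PMCAbar", I_Cab = "G_Cab", I_NCX = "P_NCX",
  I_NSC = "G_NSC", I_NaK = "I_NaKmax", I_Nab = "G_Nab"
)

#' Specification of a model population
#'
#' @param n_samples number of population members.
#' @param median log-normal median (default 1).
#' @param sd log-normal standard deviation (of the distribution itself,
#'   default 0.1).
#' @param seed RNG seed.
#' @param parameters character vector of current-magnitude names (defaults
#'   to all 11).
#' @return List of class `vsm_population_spec`.
#' @export
population_spec <- function(n_samples = 300, median = 1, sd = 0.1, seed = 1,
                            parameters = names(.sens_parameters)) {
  stopifnot(sd > 0, n_samples >= length(parameters) + 10)
  stopifnot(all(parameters %in% names(.sens_parameters)))
  structure(list(n_samples = n_samples, median = median, sd = sd,
                 seed = as.integer(seed), parameters = parameters),
            class = "vsm_population_spec")
}

#' Sample log-normal scale factors
#'
#' Each entry is log-normal with the requested median and standard
#' deviation (the `sd` of the distribution, not of the underlying normal):
#' `mu = log(median)` and `sigma` solved from
#' `sd^2 = (e^{sigma^2} - 1) e^{2 mu + sigma^2}`.
#'
#' @param spec a `vsm_population_spec`.
#' @return Matrix (samples x parameters) of scale factors.
#' @export
sample_population <- function(spec) {
  mu <- log(spec$median)
  # sd^2 = (e^{s2} - 1) e^{2 mu + s2}: quadratic in e^{s2}
  c2 <- spec$sd^2 / exp(2 * mu)
  e_s2 <- (1 + sqrt(1 + 4 * c2)) / 2
  sigma <- sqrt(log(e_s2))
  set.seed(spec$seed)
  m <- matrix(
    rlnorm(spec$n_samples * length(spec$parameters), meanlog = mu,
           sdlog = sigma),
    nrow = spec$n_samples
  )
  colnames(m) <- spec$parameters
  m
}

#' Run the model over a population of scale factors
#'
#' For each sample, scales only the maximal conductances / permeabilities /
#' transport maxima named in the population spec (kinetics untouched),
#' recomputes the
#' deterministic baseline equilibrium (noise off), and extracts the
#' requested outputs.
#'
#' @param p base `vsm_params` (NSC-tuned).
#' @param scales matrix from [sample_population()].
#' @param outputs subset of `c("baseline_V", "mean_Ca_i")`.
#' @return List with `outputs` (matrix samples x outputs) and `failed`
#'   (indices of non-convergent samples, excluded with a count reported via
#'   attribute).
#' @export
run_population <- function(p, scales,
                           outputs = c("baseline_V", "mean_Ca_i")) {
  outputs <- match.arg(outputs, several.ok = TRUE)
  res <- matrix(NA_real_, nrow(scales), length(outputs),
                dimnames = list(NULL, outputs))
  failed <- integer(0)
  for (i in seq_len(nrow(scales))) {
    pi <- p
    for (j in colnames(scales)) {
      pi <- scale_parameter(pi, .sens_parameters[[j]], scales[i, j])
    }
    eq <- tryCatch(find_equilibrium(pi), error = function(e) NULL)
    if (is.null(eq)) {
      failed <- c(failed, i)
      next
    }
    if ("baseline_V" %in% outputs) res[i, "baseline_V"] <- eq$V
    if ("mean_Ca_i" %in% outputs) {
      res[i, "mean_Ca_i"] <- eq$state[["Ca_i"]] * 1e6
    }
  }
  list(outputs = res, failed = failed)
}

#' Multivariable linear regression sensitivity coefficients
#'
#' Ordinary least squares of z-scored outputs on z-scored log scale
#' factors; the standardized coefficients measure how strongly each
#' current magnitude controls each output.
#'
#' @param scales matrix from [sample_population()].
#' @param outputs matrix from [run_population()] (`$outputs`), or any
#'   numeric matrix with one column per output.
#' @return A `vsm_regression`: `coefficients` (parameters x outputs),
#'   `r_squared` per output, and `n` (samples used).
#' @export
regress_sensitivity <- function(scales, outputs) {
  outputs <- as.matrix(outputs)
  ok <- stats::complete.cases(outputs)
  scales <- scales[ok, , drop = FALSE]
  outputs <- outputs[ok, , drop = FALSE]
  if (nrow(scales) < ncol(scales) + 10) {
    stop("regress_sensitivity: need at least ", ncol(scales) + 10,
         " complete samples")
  }
  X <- scale(log(scales))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("regress_sensitivity: collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coefs <- matrix(NA_real_, ncol(scales), ncol(outputs),
                  dimnames = list(colnames(scales), colnames(outputs)))
  r2 <- numeric(ncol(outputs))
  names(r2) <- colnames(outputs)
  for (k in seq_len(ncol(outputs))) {
    y <- as.numeric(scale(outputs[, k]))
    fit <- stats::lsfit(X, y, intercept = TRUE)
    coefs[, k] <- fit$coefficients[-1]
    r2[k] <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  structure(list(coefficients = coefs, r_squared = r2, n = nrow(scales)),
            class = "vsm_regression")
}

#' End-to-end sensitivity analysis
#'
#' @param sex `"male"` or `"female"`.
#' @param n_samples population size.
#' @param seed RNG seed.
#' @param sd log-normal standard deviation.
#' @return A `vsm_regression` with the sample spec attached.
#' @export
sensitivity_analysis <- function(sex = c("male", "female"), n_samples = 300,
                                 seed = 1, sd = 0.1) {
  sex <- match.arg(sex)
  p <- default_parameters(sex)
  p <- tune_nsc_for_baseline(p, if (sex == "male") -40 else -30)
  spec <- population_spec(n_samples = n_samples, sd = sd, seed = seed)
  scales <- sample_population(spec)
  pop <- run_population(p, scales)
  out <- regress_sensitivity(scales, pop$outputs)
  out$spec <- spec
  out$failed <- pop$failed
  out
}
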