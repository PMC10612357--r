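# Classed conditions used across the package. Every domain error carries a
# subclass ("kinstab_<what>") so callers and tests can dispatch on the cause
# rather than match message text.

ks_stop <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(paste0("kinstab_", class), "kinstab_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

ks_warn <- function(msg, class) {
  cond <- structure(
    class = c(paste0("kinstab_", class), "kinstab_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

# Gas constant in kcal mol^-1 K^-1 (1.987 cal mol^-1 K^-1), used for both the
# unfolding free-energy scale and the Arrhenius activation energy.
R_KCAL <- 1.987e-3

#' Gas constant used throughout the package
#'
#' Returns the gas constant in kcal mol^-1 K^-1 (1.987e-3), the unit
#' convention used for unfolding free energies, m values and Arrhenius
#' activation energies.
#'
#' @return A length-one numeric, kcal mol^-1 K^-1.
#' @export
gas_constant_kcal <- function() R_KCAL

# Evaluate seeded code without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    ks_stop("`seed` must be a single non-missing number", "invalid_seed")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Levenberg-Marquardt least squares via nls.lm with standard errors from the
# Gauss-Newton Hessian. Residual-based (not formula-based) so exact-fit
# (zero-residual) problems, common with noiseless synthetic data, converge
# cleanly.
ks_nls <- function(par0, resid_fun, lower = NULL, upper = NULL,
                   maxiter = 500, what = "nonlinear") {
  out <- tryCatch(
    minpack.lm::nls.lm(
      par = par0, fn = resid_fun, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)
    ),
    error = function(e) ks_stop(paste0(what, " fit failed: ",
                                       conditionMessage(e)), "fit_diverged")
  )
  if (out$info %in% c(0L, 5L)) {
    ks_stop(paste0(what, " fit did not converge: ", out$message),
            "fit_diverged")
  }
  n <- length(resid_fun(out$par))
  p <- length(out$par)
  cov <- tryCatch({
    s2 <- out$deviance / max(n - p, 1L)
    # deviance Hessian ~ 2 J'J, so J'J = hessian / 2
    cv <- s2 * solve(out$hessian / 2)
    dimnames(cv) <- list(names(par0), names(par0))
    cv
  }, error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else
    stats::setNames(rep(NA_real_, p), names(par0))
  list(par = stats::setNames(out$par, names(par0)), se = se, cov = cov,
       deviance = out$deviance, n = n, info = out$info,
       converged = TRUE)
}

stopifnot_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) ||
      (finite && any(!is.finite(x)))) {
    ks_stop(sprintf("`%s` must be finite numeric with no missing values", name),
            "invalid_input")
  }
  invisible(x)
}
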