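#' Trefone couplet binding system
#'
#' Describes the reversible binding chemistry of a Trefone couplet: the two
#' partner species (called `a` and `i` throughout the package, after the
#' a-Cell / i-Cell nomenclature) associate into a binary complex
#' `a:i` with association constant `ka` (L/mol), i.e. at equilibrium
#' `[a:i] = ka * [a]_free * [i]_free`.  An optional competitive analog of the
#' `a` species (modelled on des(1-3)IGF-I, which activates the receptor
#' normally but associates only weakly with the binding protein) binds the
#' same partner with constant `ka_analog`.
#'
#' @param ka association constant of the couplet complex, L/mol; must be > 0.
#' @param ka_analog association constant of the analog for the partner
#'   Trefone, L/mol; 0 means the analog (if dosed) never forms a complex.
#' @param analog_mimics which couplet species the analog imitates at the
#'   receptor: `"a"` (the default, the des(1-3)IGF-I configuration: the
#'   analog activates the a-receptor but binds the `i` species only weakly)
#'   or `"i"` (the mirrored configuration, where the analog binds the `a`
#'   species).
#' @param labels character vector of length 3 naming the `a` species, the `i`
#'   species and the analog (used in output only).
#' @return An object of class `ctc_binding_system`.
#' @examples
#' bs <- binding_system(ka = 1e10, ka_analog = 1e7)
#' equilibrate_with_analog(1e-8, 1e-8, 1e-8, bs)
#' @export
binding_system <- function(ka = 1e10, ka_analog = 0, analog_mimics = c("a", "i"),
                           labels = c(a = "aT", i = "iT", analog = "dT")) {
  analog_mimics <- match.arg(analog_mimics)
  if (!is.numeric(ka) || length(ka) != 1L || is.na(ka) || ka <= 0) {
    stop("binding_system: 'ka' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(ka_analog) || length(ka_analog) != 1L || is.na(ka_analog) ||
      ka_analog < 0) {
    stop("binding_system: 'ka_analog' must be a single non-negative number",
         call. = FALSE)
  }
  structure(
    list(ka = as.numeric(ka), ka_analog = as.numeric(ka_analog),
         analog_mimics = analog_mimics, labels = labels),
    class = "ctc_binding_system"
  )
}

# species the analog competes for (binds): the partner of the one it mimics
analog_binds <- function(system) {
  if (identical(system$analog_mimics, "a")) "i" else "a"
}

new_equilibrium_result <- function(free_a, free_i, free_analog = 0,
                                   complex_ai = 0, complex_di = 0) {
  structure(
    list(free_a = free_a, free_i = free_i, free_analog = free_analog,
         complex_ai = complex_ai, complex_di = complex_di),
    class = "ctc_equilibrium"
  )
}

#' @export
print.ctc_equilibrium <- function(x, ...) {
  cat("Trefone couplet equilibrium (mol/L)\n")
  cat(sprintf("  free a      : %.6g\n", x$free_a))
  cat(sprintf("  free i      : %.6g\n", x$free_i))
  cat(sprintf("  free analog : %.6g\n", x$free_analog))
  cat(sprintf("  complex a:i : %.6g\n", x$complex_ai))
  cat(sprintf("  complex d:i : %.6g\n", x$complex_di))
  invisible(x)
}

check_nonneg <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
    stop(sprintf("'%s' must be a single non-negative number (got %s)",
                 name, paste(format(value), collapse = ", ")), call. = FALSE)
  }
  invisible(as.numeric(value))
}

#' Mass-action equilibrium of one binding pair
#'
#' Solves the equilibrium of `a + i <-> a:i` given total concentrations and
#' the association constant.  With `C` the complex concentration, mass action
#' and conservation give the quadratic
#' `ka*C^2 - (ka*(A + I) + 1)*C + ka*A*I = 0`; the smaller root is the
#' physical one (`C <= min(A, I)`).  The root is computed in the
#' cancellation-free form `2*q / (b + sqrt(b^2 - 4*ka*q))` so that very large
#' `ka` (tight binding) does not lose precision.
#'
#' @param total_a,total_i total concentrations of each species, mol/L.
#' @param ka association constant, L/mol (`ka = 0` means no binding).
#' @return A `ctc_equilibrium` with analog fields set to zero.
#' @examples
#' eq <- equilibrate_pair(1e-8, 1e-8, 1e10)
#' eq$complex_ai  # ~9.05e-9: almost everything is bound at Ka = 1e10
#' @export
equilibrate_pair <- function(total_a, total_i, ka) {
  check_nonneg(total_a, "total_a")
  check_nonneg(total_i, "total_i")
  check_nonneg(ka, "ka")
  if (ka == 0 || total_a == 0 || total_i == 0) {
    return(new_equilibrium_result(free_a = total_a, free_i = total_i))
  }
  b <- ka * (total_a + total_i) + 1
  q <- ka * total_a * total_i
  disc <- b * b - 4 * ka * q
  disc <- max(disc, 0)
  cmplx <- 2 * q / (b + sqrt(disc))
  cmplx <- min(cmplx, total_a, total_i)
  new_equilibrium_result(
    free_a = total_a - cmplx,
    free_i = total_i - cmplx,
    complex_ai = cmplx
  )
}

#' Equilibrium of a couplet pair plus a competitive analog
#'
#' Simultaneous equilibrium of two complexes sharing the `i` species:
#' `a + i <-> a:i` (constant `ka`) and `analog + i <-> analog:i`
#' (constant `ka_analog`).  Solved by bisection on the free `i`
#' concentration: given `f_i`, `free_a = total_a / (1 + ka*f_i)` and
#' `free_analog = total_analog / (1 + ka_analog*f_i)`, and the residual
#' `f_i*(1 + ka*free_a + ka_analog*free_analog) - total_i` is strictly
#' increasing in `f_i`, so the root is unique on `[0, total_i]`.
#'
#' @param total_a,total_i,total_analog total concentrations, mol/L.
#' @param system a [binding_system()].
#' @param tol relative tolerance on the bracket width.
#' @param max_iter bisection iteration cap; exceeding it raises an error
#'   reporting the residual.
#' @return A `ctc_equilibrium`.  `complex_di` is always the analog complex;
#'   with `analog_mimics = "i"` it pairs the analog with the `a` species
#'   (mirror configuration) instead of the `i` species.
#' @export
equilibrate_with_analog <- function(total_a, total_i, total_analog, system,
                                    tol = 1e-13, max_iter = 200L) {
  stopifnot(inherits(system, "ctc_binding_system"))
  check_nonneg(total_a, "total_a")
  check_nonneg(total_i, "total_i")
  check_nonneg(total_analog, "total_analog")
  if (identical(analog_binds(system), "a")) {
    # mirrored configuration: solve with the roles swapped, swap back
    swapped <- system
    swapped$analog_mimics <- "a"
    eq <- equilibrate_with_analog(total_i, total_a, total_analog, swapped,
                                  tol = tol, max_iter = max_iter)
    return(new_equilibrium_result(
      free_a = eq$free_i, free_i = eq$free_a, free_analog = eq$free_analog,
      complex_ai = eq$complex_ai, complex_di = eq$complex_di))
  }
  ka <- system$ka
  kd <- system$ka_analog
  if (total_analog == 0 || kd == 0) {
    eq <- equilibrate_pair(total_a, total_i, ka)
    eq$free_analog <- total_analog
    return(eq)
  }
  if (total_i == 0) {
    return(new_equilibrium_result(free_a = total_a, free_i = 0,
                                  free_analog = total_analog))
  }
  residual <- function(fi) {
    fa <- total_a / (1 + ka * fi)
    fd <- total_analog / (1 + kd * fi)
    fi * (1 + ka * fa + kd * fd) - total_i
  }
  lo <- 0
  hi <- total_i
  iter <- 0L
  while (hi - lo > tol * total_i) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop(sprintf(
        "equilibrate_with_analog: no convergence after %d iterations (residual %g)",
        max_iter, residual((lo + hi) / 2)), call. = FALSE)
    }
    mid <- (lo + hi) / 2
    if (residual(mid) > 0) hi <- mid else lo <- mid
  }
  fi <- (lo + hi) / 2
  fa <- total_a / (1 + ka * fi)
  fd <- total_analog / (1 + kd * fi)
  new_equilibrium_result(
    free_a = fa,
    free_i = fi,
    free_analog = fd,
    complex_ai = ka * fa * fi,
    complex_di = kd * fd * fi
  )
}

#' Discretize a concentration into Lo / Mid / Hi
#'
#' Half-open bins: `Lo` for `conc < theta_lo`, `Mid` for
#' `theta_lo <= conc < theta_hi`, `Hi` for `conc >= theta_hi`.  A value equal
#' to a threshold always falls in the upper bin, which keeps the binning
#' deterministic.
#'
#' @param conc concentration, mol/L; must be non-negative.
#' @param theta_lo,theta_hi bin edges, mol/L, with `0 <= theta_lo < theta_hi`.
#' @return One of `"Lo"`, `"Mid"`, `"Hi"`.
#' @export
discretize_level <- function(conc, theta_lo, theta_hi) {
  check_nonneg(conc, "conc")
  check_nonneg(theta_lo, "theta_lo")
  if (!is.numeric(theta_hi) || length(theta_hi) != 1L || is.na(theta_hi) ||
      theta_hi <= theta_lo) {
    stop("'theta_hi' must be a single number greater than 'theta_lo'",
         call. = FALSE)
  }
  if (conc >= theta_hi) "Hi" else if (conc >= theta_lo) "Mid" else "Lo"
}
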