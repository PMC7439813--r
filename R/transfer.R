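#' Presynaptic-inhibition transfer functions
#'
#' A transfer spec describes how the release factor `p` of excitatory synapses
#' depends on the (weighted) inhibitory activity it senses. All families are
#' monotonically nonincreasing and evaluate into `[0, 1]`:
#'
#' * `"linear"`: `g(r) = 1 - beta * r`, rectified at 0 (GABA-B-like linear
#'   suppression of release with inhibitory rate).
#' * `"sigmoid"`: `g(r) = 1 / (1 + exp(beta_s * (r - r_shift)))`.
#' * `"exponential"`: `g(r) = exp(-beta_e * r)`.
#' * `"none"`: `g(r) = 1` identically -- presynaptic inhibition disabled.
#'
#' @param kind One of `"linear"`, `"sigmoid"`, `"exponential"`, `"none"`.
#' @param beta Linear slope (1/Hz). Default 0.05, the population-level scale.
#' @param beta_s Sigmoid slope (1/Hz).
#' @param r_shift Sigmoid inflection rate (Hz).
#' @param beta_e Exponential slope (1/Hz).
#' @return An object of class `transfer_spec`.
#' @examples
#' tr <- transfer_spec("linear", beta = 0.05)
#' release_factor(tr, 5)   # p = 0.75 at 5 Hz
#' @export
transfer_spec <- function(kind = c("linear", "sigmoid", "exponential", "none"),
                          beta = 0.05, beta_s = 0.2, r_shift = 5, beta_e = 0.1) {
  kind <- match.arg(kind)
  stopifnot(beta >= 0, beta_s >= 0, beta_e >= 0, r_shift >= 0)
  structure(list(kind = kind, beta = beta, beta_s = beta_s,
                 r_shift = r_shift, beta_e = beta_e),
            class = "transfer_spec")
}

#' @export
print.transfer_spec <- function(x, ...) {
  par_str <- switch(x$kind,
    linear      = sprintf("beta = %g /Hz", x$beta),
    sigmoid     = sprintf("beta_s = %g /Hz, r_shift = %g Hz", x$beta_s, x$r_shift),
    exponential = sprintf("beta_e = %g /Hz", x$beta_e),
    none        = "p identically 1")
  cat(sprintf("<transfer_spec> %s (%s)\n", x$kind, par_str))
  invisible(x)
}

#' Evaluate the release factor and its derivative
#'
#' Evaluates the transfer function of a [transfer_spec()] at rate `r`,
#' returning the release factor clipped to `[0, 1]` together with its
#' analytic derivative. On a clipped branch (linear transfer driven below 0)
#' the derivative is 0.
#'
#' @param transfer A [transfer_spec()].
#' @param r Nonnegative rate(s) (Hz). Vectorised.
#' @return A list with components `p` (release factor) and `dp_dr`
#'   (derivative, 1/Hz), each the length of `r`.
#' @export
release_factor <- function(transfer, r) {
  stopifnot(inherits(transfer, "transfer_spec"))
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("release_factor: rate `r` must be finite and nonnegative")
  }
  switch(transfer$kind,
    none = list(p = rep(1, length(r)), dp_dr = rep(0, length(r))),
    linear = {
      raw <- 1 - transfer$beta * r
      clipped <- raw <= 0
      list(p = pmin(1, pmax(0, raw)),
           dp_dr = ifelse(clipped, 0, -transfer$beta))
    },
    sigmoid = {
      z <- transfer$beta_s * (r - transfer$r_shift)
      p <- 1 / (1 + exp(z))
      list(p = p, dp_dr = -transfer$beta_s * p * (1 - p))
    },
    exponential = {
      p <- exp(-transfer$beta_e * r)
      list(p = p, dp_dr = -transfer$beta_e * p)
    },
    stop("release_factor: unknown transfer kind")
  )
}

#' Rescale a transfer spec from population to network units
#'
#' In the full rate network the release factor senses the total weighted
#' inhibitory activity summed over all inhibitory neurons, which is larger
#' than the population-level quantity by a factor `1/c` (the connection
#' probability). Slopes are therefore multiplied by `c` (and the sigmoid
#' inflection divided by `c`) so that network and mean-field transfer agree.
#'
#' @param transfer A [transfer_spec()] in population (mean-field) units.
#' @param c Connection probability.
#' @return A `transfer_spec` in network units.
#' @export
scale_transfer <- function(transfer, c) {
  stopifnot(inherits(transfer, "transfer_spec"), c > 0, c <= 1)
  transfer_spec(transfer$kind,
                beta = transfer$beta * c,
                beta_s = transfer$beta_s * c,
                r_shift = transfer$r_shift / c,
                beta_e = transfer$beta_e * c)
}
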