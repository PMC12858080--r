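#' Contact-probability model for a polymer domain
#'
#' Defines the probability that two beads separated by `s` positions along
#' the backbone are in contact. Two families are supported: a *uniform*
#' model where every eligible pair is connected with the same probability
#' `p_u`, and a *power-law* model `P_c(s) = c * s^-gamma` that mimics the
#' contact-probability decay measured inside topologically associating
#' domains. Backbone neighbours (`s == 1`) are always in contact.
#'
#' The exponent `gamma` measures compaction: small `gamma` means abundant
#' long-range contacts (a collapsed domain), `gamma = 1.5` corresponds to an
#' ideal-chain polymer and `gamma = 2.2` to a self-avoiding one. Values of
#' `c * s^-gamma` above 1 are capped at 1 when evaluated.
#'
#' `boundary_factor` scales contact probabilities of pairs that touch the
#' absorbing boundary beads (0 and `L`). The default 0 insulates the
#' boundary completely, so non-backbone bonds form only among interior
#' beads; values in (0, 1] allow progressively leakier insulation.
#'
#' @param kind `"uniform"` or `"powerlaw"`.
#' @param p_u Uniform contact probability in `[0, 1]` (uniform model only).
#' @param c Power-law prefactor, positive (power-law model only).
#' @param gamma Power-law decay exponent, `>= 0` (power-law model only).
#' @param boundary_factor Multiplier in `[0, 1]` applied to contact
#'   probabilities of pairs involving a boundary bead. Default 0.
#' @return An object of class `contact_model`.
#' @examples
#' contact_model("uniform", p_u = 1e-3)
#' contact_model("powerlaw", c = 0.0214, gamma = 0.71)
#' @export
contact_model <- function(kind = c("uniform", "powerlaw"), p_u = NULL,
                          c = NULL, gamma = NULL, boundary_factor = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(boundary_factor), length(boundary_factor) == 1,
            boundary_factor >= 0, boundary_factor <= 1)
  if (kind == "uniform") {
    if (is.null(p_u)) stop("uniform model requires `p_u`")
    stopifnot(is.numeric(p_u), length(p_u) == 1, p_u >= 0, p_u <= 1)
    if (!is.null(c) || !is.null(gamma))
      stop("`c` and `gamma` apply to the power-law model only")
  } else {
    if (is.null(c) || is.null(gamma))
      stop("power-law model requires `c` and `gamma`")
    stopifnot(is.numeric(c), length(c) == 1, c > 0,
              is.numeric(gamma), length(gamma) == 1, gamma >= 0)
    if (!is.null(p_u)) stop("`p_u` applies to the uniform model only")
  }
  structure(
    list(kind = kind, p_u = p_u, c = c, gamma = gamma,
         boundary_factor = boundary_factor),
    class = "contact_model"
  )
}

#' @export
print.contact_model <- function(x, ...) {
  if (x$kind == "uniform") {
    cat(sprintf("<contact_model> uniform, p_u = %g", x$p_u))
  } else {
    cat(sprintf("<contact_model> power law, P_c(s) = %g * s^-%g", x$c, x$gamma))
  }
  cat(sprintf(", boundary_factor = %g\n", x$boundary_factor))
  invisible(x)
}

#' Evaluate the contact probability at given separations
#'
#' Returns 1 for `s == 1` (backbone bonds are always present) and the model
#' probability, capped at 1, for `s > 1`. The boundary factor is not applied
#' here: it acts on specific pairs, not on separations.
#'
#' @param model A [contact_model()].
#' @param s Integer separations in beads, `>= 1`.
#' @return Numeric vector of probabilities, same length as `s`.
#' @examples
#' m <- contact_model("powerlaw", c = 0.0214, gamma = 0.71)
#' contact_probability(m, c(1, 10, 100))
#' @export
contact_probability <- function(model, s) {
  stopifnot(inherits(model, "contact_model"))
  if (any(s < 1) || any(s != round(s)))
    stop("separation `s` must be a positive integer")
  p <- if (model$kind == "uniform") {
    rep(model$p_u, length(s))
  } else {
    model$c * s^(-model$gamma)
  }
  p <- pmin(1, p)
  p[s == 1] <- 1
  p
}

# probabilities indexed by separation 1..L (backbone slot unused by samplers)
pc_by_separation <- function(model, L) {
  contact_probability(model, seq_len(L))
}
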