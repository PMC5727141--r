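#' Built-in and user-defined reaction models
#'
#' A reaction model bundles the local reaction kinetics `F`, its Jacobian
#' `J = dF/dX`, and the diagonal diffusion matrix of the boundary
#' reaction-diffusion system `dX/dt = F(X) + D d2X/dtheta2`.
#'
#' Two models are built in:
#' \describe{
#'   \item{`"gle"`}{the real Ginzburg-Landau equation,
#'     `F = (U - (U^2+V^2)U, V - (U^2+V^2)V)`, `D = diag(D0, D0)`, with
#'     default `D0 = 0.3`, for which the whole reduction is known in closed
#'     form.}
#'   \item{`"activator_inhibitor"`}{a two-species activator-inhibitor system,
#'     `F_U = rho_U U^2 / ((1 + kappa U^2) V) - mu_U U + sigma_U`,
#'     `F_V = rho_V U^2 - mu_V V`, `D = diag(D_U, D_V)`, defaults
#'     `rho_U = 0.01, rho_V = 0.02, mu_U = 0.01, mu_V = 0.02, sigma_U = 0,
#'     kappa = 0, D_U = 0.005, D_V = 0.2`.  Its admissible domain is
#'     `U >= 0, V > 0`; evaluation at `V <= 0` is an error (states are never
#'     silently clamped).}
#' }
#'
#' @param name `"gle"` or `"activator_inhibitor"`.
#' @param params named list of parameter overrides (see defaults above).
#' @return an object of class `reaction_model`: a list with `name`,
#'   `n_species`, `params`, `diffusion` (per-species diffusivities),
#'   `reaction(X)` and `jacobian(X)`.  `reaction` maps an `m x n_species`
#'   matrix of states to an `m x n_species` matrix of rates; `jacobian` maps
#'   it to an `m x n_species x n_species` array of partial derivatives.
#' @export
#' @examples
#' m <- make_model("gle")
#' m$reaction(matrix(c(1, 0), 1))  # fixed point on the unit circle
make_model <- function(name = c("gle", "activator_inhibitor"),
                       params = list()) {
  name <- match.arg(name)
  defaults <- switch(name,
    gle = list(D0 = 0.3),
    activator_inhibitor = list(rho_U = 0.01, rho_V = 0.02, mu_U = 0.01,
                               mu_V = 0.02, sigma_U = 0, kappa = 0,
                               D_U = 0.005, D_V = 0.2))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s) for model '", name, "': ",
         paste(unknown, collapse = ", "))
  }
  p <- utils::modifyList(defaults, params)

  if (name == "gle") {
    if (p$D0 <= 0) stop("diffusivity D0 must be positive")
    model <- register_model(
      name = "gle",
      n_species = 2L,
      reaction = function(X) {
        r2 <- X[, 1]^2 + X[, 2]^2
        cbind(X[, 1] * (1 - r2), X[, 2] * (1 - r2))
      },
      jacobian = function(X) {
        U <- X[, 1]; V <- X[, 2]
        r2 <- U^2 + V^2
        J <- array(0, c(nrow(X), 2L, 2L))
        J[, 1, 1] <- 1 - r2 - 2 * U^2
        J[, 1, 2] <- -2 * U * V
        J[, 2, 1] <- -2 * U * V
        J[, 2, 2] <- 1 - r2 - 2 * V^2
        J
      },
      diffusion = c(p$D0, p$D0),
      params = p)
  } else {
    if (p$D_U <= 0 || p$D_V <= 0) stop("diffusivities must be positive")
    model <- register_model(
      name = "activator_inhibitor",
      n_species = 2L,
      reaction = function(X) {
        U <- X[, 1]; V <- X[, 2]
        if (any(V <= 0)) {
          stop("activator_inhibitor: state left the admissible domain ",
               "(V <= 0)", call. = FALSE)
        }
        cbind(p$rho_U * U^2 / ((1 + p$kappa * U^2) * V) - p$mu_U * U +
                p$sigma_U,
              p$rho_V * U^2 - p$mu_V * V)
      },
      jacobian = function(X) {
        U <- X[, 1]; V <- X[, 2]
        if (any(V <= 0)) {
          stop("activator_inhibitor: state left the admissible domain ",
               "(V <= 0)", call. = FALSE)
        }
        s <- 1 + p$kappa * U^2
        J <- array(0, c(nrow(X), 2L, 2L))
        J[, 1, 1] <- p$rho_U * 2 * U / (s^2 * V) - p$mu_U
        J[, 1, 2] <- -p$rho_U * U^2 / (s * V^2)
        J[, 2, 1] <- 2 * p$rho_V * U
        J[, 2, 2] <- -p$mu_V
        J
      },
      diffusion = c(p$D_U, p$D_V),
      params = p)
  }
  model
}

#' Register a user-supplied reaction model
#'
#' User models plug into the same contract as the built-ins.  When
#' `jacobian` is `NULL` a central finite-difference Jacobian is generated
#' from `reaction`.
#'
#' @param name model identifier.
#' @param n_species number of chemical species.
#' @param reaction function mapping an `m x n_species` state matrix to an
#'   `m x n_species` rate matrix.
#' @param jacobian function mapping the state matrix to an
#'   `m x n_species x n_species` array, or `NULL` for finite differences.
#' @param diffusion per-species non-negative diffusivities.
#' @param params named list of parameters (stored for provenance).
#' @return a `reaction_model` object.
#' @export
register_model <- function(name, n_species, reaction, jacobian = NULL,
                           diffusion, params = list()) {
  n_species <- as.integer(n_species)
  stopifnot(n_species >= 1, length(diffusion) == n_species)
  if (any(diffusion < 0)) stop("all diffusivities must be >= 0")
  if (is.null(jacobian)) {
    jacobian <- .fd_jacobian_fn(reaction, n_species)
  }
  structure(list(name = name, n_species = n_species, reaction = reaction,
                 jacobian = jacobian, diffusion = diffusion, params = params),
            class = "reaction_model")
}

# Central finite-difference Jacobian factory (used for user models without
# an analytic Jacobian, and as the oracle in tests).
.fd_jacobian_fn <- function(reaction, n_species, h = 1e-6) {
  function(X) {
    m <- nrow(X)
    J <- array(0, c(m, n_species, n_species))
    for (j in seq_len(n_species)) {
      Xp <- X; Xm <- X
      Xp[, j] <- Xp[, j] + h
      Xm[, j] <- Xm[, j] - h
      J[, , j] <- (reaction(Xp) - reaction(Xm)) / (2 * h)
    }
    J
  }
}

#' @export
print.reaction_model <- function(x, ...) {
  cat("<reaction_model>", x$name, "\n")
  cat("  species:    ", x$n_species, "\n")
  cat("  diffusion:  ", paste(signif(x$diffusion, 6), collapse = ", "), "\n")
  cat("  params:     ",
      paste(names(x$params), signif(unlist(x$params), 6), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

# Random admissible states for a model, used by the Jacobian consistency
# checks.  GLE states live near the unit disc; activator-inhibitor states
# stay in U >= 0, V > 0.
.random_states <- function(model, m) {
  if (model$name == "activator_inhibitor") {
    cbind(stats::runif(m, 0.05, 3), stats::runif(m, 0.2, 5))
  } else {
    matrix(stats::runif(m * model$n_species, -1.5, 1.5), m)
  }
}
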