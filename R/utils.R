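#' @keywords internal
"_PACKAGE"

# Abort with a classed condition so callers/tests can distinguish
# configuration errors, degenerate inputs and plain input errors.
stop_gxe <- function(msg, class) {
  stop(structure(
    class = c(class, "gxeortho_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error     <- function(msg) stop_gxe(msg, "gxeortho_config_error")
input_error      <- function(msg) stop_gxe(msg, "gxeortho_input_error")
degenerate_error <- function(msg) stop_gxe(msg, "gxeortho_degenerate_error")

#' Standardize a numeric vector to mean 0, sd 1
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector with mean 0 and standard deviation 1.
#' @keywords internal
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12)
    degenerate_error("cannot standardize a (near) constant vector")
  (x - mean(x)) / s
}

# Residualize y on covariates plus an intercept; returns residuals.
# `covariates` may be NULL, a data.frame, or a numeric matrix.
residualize <- function(y, covariates) {
  X <- covariate_matrix(covariates, length(y))
  if (is.null(X)) return(y - mean(y))
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    input_error("covariate design is rank deficient")
  qr.resid(qrX, y)
}

# Normalize covariate input to a plain numeric matrix (or NULL if empty).
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (!is.matrix(covariates)) covariates <- matrix(covariates, ncol = 1L)
  if (ncol(covariates) == 0L) return(NULL)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n)
    input_error("covariate rows do not match the number of individuals")
  if (any(!is.finite(covariates)))
    input_error("covariates contain non-finite values")
  covariates
}

# Deterministic per-stage seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 499979 * stage) %% .Machine$integer.max)
}

is_binary01 <- function(x) all(x %in% c(0, 1))
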