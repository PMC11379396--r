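# Internal helpers shared across modules.

# Canonical matching key for item names: trimmed, case-folded.
item_key <- function(x) tolower(trimws(x))

# Off-diagonal sum of squares of a symmetric matrix.
offdiag_ss <- function(m) {
  sum(m[lower.tri(m)]^2) * 2
}

# Symmetric matrix power via eigendecomposition with an eigenvalue floor.
# Used for R^{-1/2}, Phi^{1/2} etc.; the floor guards near-singular inputs.
mat_power <- function(m, power, floor = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  e$vectors %*% diag(vals^power, nrow(m)) %*% t(e$vectors)
}

# Squared multiple correlations of each variable with the rest.
# Falls back to a ridge-regularised inverse when R is singular.
smc <- function(R, ridge = 1e-4) {
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    inv <- solve(R + diag(ridge, nrow(R)))
  }
  1 - 1 / diag(inv)
}

stopf <- function(class, msg, ...) {
  abort(sprintf(msg, ...), class = c(class, "ratefa_error"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
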