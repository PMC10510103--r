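# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(..., class = "iredpanel_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) abort(sprintf("`%s` must lie in [0, 1]", name))
  invisible(x)
}

# euclidean distances between rows of two coordinate matrices (n x 3, m x 3)
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

coords_of <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}
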