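# Internal helpers shared across modules.

#' Derive a per-cell child seed from the root seed
#'
#' Splitting rule: `(root + 1000003 * cell_index + 97 * stream) mod (2^31 - 1)`,
#' where `stream` separates independent random draws for one cell
#' (1 = shape, 2 = track, 3 = placement). Because each cell owns its child
#' seeds, adding a cell to a simulation never perturbs the cells already
#' generated.
#'
#' @param root_seed integer root seed of the simulation.
#' @param cell_index 1-based cell index.
#' @param stream integer stream id.
#' @return an integer seed.
#' @keywords internal
child_seed <- function(root_seed, cell_index, stream = 1L) {
  as.integer((as.double(root_seed) + 1000003 * cell_index + 97 * stream) %%
               2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (strict_min && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict_min && x < min) stopf("'%s' must be >= %g", name, min)
  if (x > max) stopf("'%s' must be <= %g", name, max)
  invisible(x)
}

is_binary_mask <- function(m) {
  is.matrix(m) && (is.logical(m) || all(m %in% c(0, 1)))
}

as_mask <- function(m) {
  if (!is.matrix(m)) stopf("mask must be a matrix")
  if (is.logical(m)) return(m)
  m != 0
}
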