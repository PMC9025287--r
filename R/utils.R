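# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded internals do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from (seed, tag) staying inside .Machine$integer.max.
derive_seed <- function(seed, tag) {
  (as.numeric(seed) * 7919 + as.numeric(tag) * 104729) %% 2147483579
}

stopifnot_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3D array", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}

# Multiply a 3D array along one axis by a weight matrix W (n_out x n_in).
apply_axis <- function(vol, W, axis) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- W %*% matrix(v, nrow = dv[1])
  out <- array(m, dim = c(nrow(W), dv[2], dv[3]))
  aperm(out, order(perm))
}

# 13 unique 3D direction offsets (distance-1 neighborhood, one per +/- pair).
unique_directions_3d <- function() {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- apply(offs, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  unname(offs[keep, , drop = FALSE])
}

# md5 hash of an R object (serialized to a temp file); used for run logs.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
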