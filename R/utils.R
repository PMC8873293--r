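#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Six-connected binary erosion
#'
#' @param mask logical or 0/1 3D array.
#' @return logical array: voxels whose six face neighbours (and themselves)
#'   are all inside the mask; faces at the array border count as outside.
#' @keywords internal
erode6 <- function(mask) {
  m <- mask > 0
  d <- dim(m)
  shift1 <- function(a, axis, by) {
    out <- array(FALSE, dim(a))
    idx_src <- lapply(dim(a), seq_len)
    idx_dst <- idx_src
    n <- dim(a)[axis]
    if (by > 0) {
      idx_dst[[axis]] <- seq_len(n - by) + by
      idx_src[[axis]] <- seq_len(n - by)
    } else {
      idx_dst[[axis]] <- seq_len(n + by)
      idx_src[[axis]] <- seq_len(n + by) - by
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- m
  for (axis in 1:3) {
    out <- out & shift1(m, axis, 1L) & shift1(m, axis, -1L)
  }
  out
}

#' Connected components of a binary 3D mask
#'
#' @param mask logical or 0/1 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return integer array of component labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6L, 26L))
  lab <- .cpp_label_components(as.integer(mask > 0), as.integer(dim(mask)),
                               as.integer(connectivity))
  array(lab, dim(mask))
}
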