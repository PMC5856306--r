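#' @importFrom stats coef lm median qt rnorm runif sd setNames t.test
#'   oneway.test cor.test qnorm qlnorm plnorm
#' @importFrom utils head
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label connected components in a 2D binary mask
#'
#' Flood-fill labelling of foreground pixels with 4- or 8-connectivity.
#' Slices in this package are processed independently in 2D, so a fast
#' matrix-based labeller is sufficient.
#'
#' @param m logical (or 0/1 numeric) matrix.
#' @param connectivity 8 (default, edge + corner neighbours) or 4.
#' @return Integer matrix of the same shape; 0 is background, components
#'   are numbered from 1 in scan order.
#' @keywords internal
label_components_2d <- function(m, connectivity = 8) {
  stopifnot(is.matrix(m), connectivity %in% c(4, 8))
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m != 0)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(lab)
  if (connectivity == 8) {
    di <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dj <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    di <- c(-1L, 1L, 0L, 0L)
    dj <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  for (p in fg) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    stack <- p
    lab[p] <- cur
    while (length(stack) > 0L) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- ((q - 1L) %% nr) + 1L
      j <- ((q - 1L) %/% nr) + 1L
      ni <- i + di; nj <- j + dj
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      nb <- (nj[ok] - 1L) * nr + ni[ok]
      nb <- nb[m[nb] != 0 & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

## voxel-centre physical coordinates (mm) along one axis: centre of voxel i
## (1-based) is at (i - 1) * spacing
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

## wrap angle difference to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi)
  a - pi
}

assert_scalar_pos <- function(x, name, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (x > 0) && (allow_inf || is.finite(x))
  if (!ok) stop(sprintf("'%s' must be a positive %sscalar", name,
                        if (allow_inf) "" else "finite "), call. = FALSE)
  invisible(x)
}
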