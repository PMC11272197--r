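#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rnorm runif lm pt cor var coef sd setNames p.adjust
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

# Run `code` with the RNG seeded to `seed`, restoring any pre-existing global
# RNG state afterwards. All randomness in the package flows through this so no
# function mutates the caller's RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  force(code)
}

# Otsu threshold of a numeric vector, computed on a 256-bin histogram over the
# observed range. Returns a value separating the two intensity classes.
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (r[1] == r[2]) stop("cannot threshold: zero dynamic range")
  u <- (v - r[1]) / (r[2] - r[1])
  thr <- EBImage::otsu(matrix(u, nrow = 1L), range = c(0, 1), levels = levels)
  thr * (r[2] - r[1]) + r[1]
}

# Air/tissue threshold for a T1 slice. The marginal histogram is trimodal
# (air, lean, fat) and a single Otsu split lands between fat and the rest,
# so the air level is found hierarchically: first Otsu isolates the bright
# class, a second Otsu below it separates air from lean tissue.
air_threshold <- function(v, t1 = otsu_threshold(v)) {
  lo <- v[v < t1]
  if (length(lo) < 2L || max(lo) == min(lo)) return(t1)
  otsu_threshold(lo)
}

# Type-1 (inverse ECDF) quantile; no interpolation, so clipping at these
# quantiles is exactly idempotent.
quantile1 <- function(x, p) as.numeric(quantile(x, p, type = 1, names = FALSE))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# disc-shaped structuring element of the given radius (in voxels)
disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; returns 1 when both masks are empty
#' (perfect agreement on "nothing there").
#'
#' @param a,b binary arrays of identical dimension (0/1 or logical).
#' @return A number in \[0, 1\].
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stopf("dice: masks differ in size")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
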