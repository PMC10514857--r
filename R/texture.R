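#' Local-texture score map
#'
#' Computes, for every pixel, the standard deviation of image intensity
#' over a square window of side \code{2 * textureRadiusPx + 1} centred on
#' the pixel, with edge-mirrored padding at the borders. A confluent cell
#' monolayer scores high (cells are textured under phase contrast); the
#' cell-free wound scores near the noise floor; a constant image maps to an
#' all-zero score grid. This score is the basis of wound segmentation.
#'
#' @param x a [CalibratedImage-class] or a numeric matrix.
#' @param textureRadiusPx window radius in pixels; must be >= 1 and smaller
#'   than a quarter of the smaller image dimension.
#' @return Numeric matrix of non-negative texture scores, same shape as the
#'   input.
#' @examples
#' textureMap(matrix(7, 64, 64), 3)[1, 1]   # constant image -> 0
#' @seealso [segmentWound()]
#' @name textureMap
NULL

#' @rdname textureMap
#' @export
setMethod("textureMap", "CalibratedImage", function(x, textureRadiusPx = 5L) {
    textureMap(x@pixels, textureRadiusPx)
})

#' @rdname textureMap
#' @export
setMethod("textureMap", "matrix", function(x, textureRadiusPx = 5L) {
    r <- as.integer(textureRadiusPx)
    if (r < 1L || r >= min(dim(x)) / 4)
        stop("'textureRadiusPx' must be >= 1 and < min(image dims)/4")
    .localSdMap(x, r)
})

# windowed SD via integral images on an edge-mirrored padded copy.
# The image is centred first so the squared cumulative sums do not lose
# precision to catastrophic cancellation on large frames.
.localSdMap <- function(m, r) {
    m <- m - mean(m)
    n <- nrow(m); p <- ncol(m)
    ri <- c(r:1, 1:n, n:(n - r + 1L))
    ci <- c(r:1, 1:p, p:(p - r + 1L))
    pad <- m[ri, ci]
    k <- 2L * r + 1L
    kk <- as.numeric(k) * k
    s1 <- .windowSums(pad, k)
    s2 <- .windowSums(pad * pad, k)
    v <- pmax(s2 / kk - (s1 / kk)^2, 0)
    matrix(sqrt(v), n, p)
}

# sums over all k x k windows of `pad`; returns matrix of size (dim - k + 1)
.windowSums <- function(pad, k) {
    cs <- apply(pad, 2L, cumsum)
    cs <- t(apply(cs, 1L, cumsum))
    nn <- nrow(pad); pp <- ncol(pad)
    z <- matrix(0, nn + 1L, pp + 1L)
    z[-1L, -1L] <- cs
    i <- seq_len(nn - k + 1L)
    j <- seq_len(pp - k + 1L)
    z[i + k, j + k, drop = FALSE] - z[i, j + k, drop = FALSE] -
        z[i + k, j, drop = FALSE] + z[i, j, drop = FALSE]
}
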