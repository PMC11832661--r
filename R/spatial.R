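# Graph-Laplacian spatial prior over a masked voxel grid.
#
# Adjacency is 6-connectivity (face neighbours) restricted to the mask. The
# Laplacian D has off-diagonal entries 1 for adjacent voxel pairs and
# diagonal entries minus the neighbour count (-6 for a fully connected
# interior voxel), so every row sums to zero and -D is positive
# semidefinite. The spatial log-prior of a parameter map theta is
#
#   log p(theta) = (v/2) log(alpha) - (alpha/2) theta' (-D) theta
#                = (v/2) log(alpha) - (alpha/2) sum_{(i,j) adjacent} (theta_i - theta_j)^2
#
# i.e. an (improper, translation-invariant) Gaussian Markov random field
# whose precision alpha sets the weight of the smoothing; larger alpha
# favours flatter maps. The quadratic form is evaluated with -D so that
# roughness is penalised; the (v/2) log(alpha) normalisation makes the
# data-fit / smoothing trade-off well defined when alpha is optimised.

#' Construct a masked voxel grid
#'
#' @param mask logical 3D array (or an array coercible to logical); voxels
#'   marked \code{TRUE} are included. A fully-masked grid can be built by
#'   passing dimensions via \code{shape} with \code{mask = NULL}.
#' @param shape integer dimensions, used when \code{mask} is \code{NULL}.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- voxelGrid(shape = c(5, 5, 5))
#' nVoxels(g)
#' @export
voxelGrid <- function(mask = NULL, shape = NULL) {
    if (is.null(mask)) {
        stopifnot(!is.null(shape), length(shape) == 3L)
        mask <- array(TRUE, dim = as.integer(shape))
    }
    mask <- array(as.logical(mask), dim = dim(mask))
    if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
    new("VoxelGrid", shape = as.integer(dim(mask)), mask = mask)
}

#' Number of masked voxels
#' @param x a \linkS4class{VoxelGrid} or \linkS4class{ASLDataset}.
#' @return Integer voxel count v.
#' @export
setMethod("nVoxels", "VoxelGrid", function(x) sum(x@mask))

setMethod("show", "VoxelGrid", function(object) {
    cat(
        "VoxelGrid ", paste(object@shape, collapse = " x "), ", ",
        sum(object@mask), " of ", prod(object@shape), " voxels masked in\n",
        sep = ""
    )
})

# Grid coordinates (v x 3 integer matrix) of masked voxels in raster order
# (first index fastest), the canonical voxel enumeration.
.voxelCoords <- function(grid) {
    which(grid@mask, arr.ind = TRUE)
}

#' Build the first-order graph Laplacian of a masked grid
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @return A sparse symmetric \code{v x v} \code{Matrix::dgCMatrix} D with
#'   off-diagonal 1 for 6-connected masked neighbours and diagonal minus the
#'   neighbour count.
#' @examples
#' D <- buildLaplacian(voxelGrid(shape = c(3, 3, 3)))
#' range(Matrix::rowSums(D)) # all zero
#' @export
buildLaplacian <- function(grid) {
    stopifnot(is(grid, "VoxelGrid"))
    v <- nVoxels(grid)
    index <- array(0L, dim = grid@shape)
    index[grid@mask] <- seq_len(v)
    coords <- .voxelCoords(grid)
    ii <- integer(0)
    jj <- integer(0)
    for (axis in 1:3) {
        nb <- coords
        nb[, axis] <- nb[, axis] + 1L
        ok <- nb[, axis] <= grid@shape[axis]
        if (!any(ok)) next
        to <- index[nb[ok, , drop = FALSE]]
        from <- index[coords[ok, , drop = FALSE]]
        keep <- to > 0L
        ii <- c(ii, from[keep])
        jj <- c(jj, to[keep])
    }
    deg <- tabulate(c(ii, jj), nbins = v)
    Matrix::sparseMatrix(
        i = c(ii, jj, seq_len(v)),
        j = c(jj, ii, seq_len(v)),
        x = c(rep(1, 2 * length(ii)), -deg),
        dims = c(v, v)
    )
}

#' Spatial prior log-density of a parameter map
#'
#' @param thetaMap length-v parameter map.
#' @param logAlpha log spatial precision.
#' @param D Laplacian from \code{\link{buildLaplacian}}.
#' @return \code{(v/2) log(alpha) - (alpha/2) thetaMap' (-D) thetaMap}.
#' @export
spatialLogPdf <- function(thetaMap, logAlpha, D) {
    v <- nrow(D)
    if (length(thetaMap) != v) {
        stop("thetaMap has length ", length(thetaMap), " but D is ", v, " x ", v)
    }
    alpha <- exp(logAlpha)
    rough <- -sum(thetaMap * as.numeric(D %*% thetaMap)) # theta' (-D) theta
    (v / 2) * logAlpha - (alpha / 2) * rough
}

# Roughness quadratic form theta' (-D) theta = sum over adjacent pairs of
# squared differences. Shared by the engine's gradient code and tests.
.roughness <- function(thetaMap, D) {
    -sum(thetaMap * as.numeric(D %*% thetaMap))
}

#' Gaussian log-density
#'
#' Full univariate normal log-density (including the 2*pi constant), used
#' for distributional priors such as the prior on log noise variance.
#'
#' @param x,mean,variance scalars or vectors (variance strictly positive).
#' @return Log-density values.
#' @export
normalLogPdf <- function(x, mean = 0, variance = 1) {
    if (any(variance <= 0)) stop("variance must be strictly positive")
    -0.5 * log(2 * pi * variance) - (x - mean)^2 / (2 * variance)
}

#' Write a Laplacian to Matrix Market format (debugging aid)
#' @param D sparse Laplacian.
#' @param path output .mtx path.
#' @return The path, invisibly.
#' @export
writeLaplacianMTX <- function(D, path) {
    Matrix::writeMM(as(D, "generalMatrix"), path)
    invisible(path)
}
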