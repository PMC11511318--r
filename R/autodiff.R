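#' @useDynLib ehff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm dnorm qnorm runif rnorm sd
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation over dense arrays.
#
# A "tape" records nodes in creation order; each node is an environment
# holding its value, an accumulated gradient, and a backward closure that
# pushes gradients into its parents.  Ops called with tape = NULL skip all
# recording and behave as plain numeric functions (inference mode).
# Gradients are only propagated into nodes with track = TRUE, so constant
# inputs (images, masks) cost nothing on the backward pass.
# ---------------------------------------------------------------------------

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, track = FALSE, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$track <- track
  if (!is.null(tape) && track) {
    nd$backward <- backward
    n <- tape$n + 1L
    if (n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

ad_leaf <- function(tape, value, track = FALSE) {
  ad_node(tape, value, track = track)
}

ad_accum <- function(node, g) {
  if (!node$track) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run the backward pass from a scalar loss node.
#' @noRd
ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# Context: tape + parameter store with leaf caching, so each parameter array
# is wrapped in exactly one node per forward pass.
ad_ctx <- function(params, tape = NULL) {
  cx <- new.env(parent = emptyenv())
  cx$params <- params
  cx$tape <- tape
  cx$leaves <- new.env(parent = emptyenv())
  cx
}

ctx_param <- function(ctx, name) {
  nd <- ctx$leaves[[name]]
  if (is.null(nd)) {
    v <- ctx$params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    nd <- ad_leaf(ctx$tape, v, track = !is.null(ctx$tape))
    ctx$leaves[[name]] <- nd
  }
  nd
}

# Collect gradients accumulated on parameter leaves, named as the parameters.
ctx_grads <- function(ctx) {
  nms <- ls(ctx$leaves)
  out <- vector("list", length(nms))
  names(out) <- nms
  for (nm in nms) {
    g <- ctx$leaves[[nm]]$grad
    if (!is.null(g)) out[[nm]] <- g
  }
  out[!vapply(out, is.null, logical(1))]
}

# RNG hygiene: evaluate code under a fixed seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
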