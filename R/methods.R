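## broom-style accessors and plotting for fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy covariance estimates of an AI-REML fit
#'
#' @param x a [reml_fit()] object.
#' @param scale `"covariance"` (default) or `"correlation"`; correlations are
#'   reported with the variances kept on the diagonal rows.
#' @param ... unused.
#' @return a tibble with one row per distinct covariance element: `matrix`
#'   (random term or `".residual"`), `row`, `col` (trait names), `estimate`
#'   and (when available) the AI-based `se`.
#' @export
tidy.reml_fit <- function(x, scale = c("covariance", "correlation"), ...) {
  scale <- match.arg(scale)
  q <- length(x$traits)
  ij <- which(lower.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  mats <- c(x$estimates$G, list(.residual = x$estimates$E))
  out <- dplyr::bind_rows(lapply(names(mats), function(nm) {
    S <- mats[[nm]]
    est <- S[ij]
    if (scale == "correlation") {
      Cm <- stats::cov2cor(S)
      est <- ifelse(ij[, 1L] == ij[, 2L], diag(S)[ij[, 1L]], Cm[ij])
    }
    tibble::tibble(matrix = nm, row = x$traits[ij[, 1L]],
                   col = x$traits[ij[, 2L]], estimate = est)
  }))
  if (!is.null(x$se_cov) && scale == "covariance") {
    out$se <- x$se_cov$se
  }
  out
}

#' One-row summary of an AI-REML fit
#'
#' @param x a [reml_fit()] object.
#' @param ... unused.
#' @return a one-row tibble: `-2 logL`, iterates, convergence, number of
#'   equations, structural nonzeros of the coefficient matrix and its factor,
#'   and the parameter count.
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(
    m2ll = x$m2ll, niter = x$niter, converged = x$converged,
    param = x$param, neq = x$neq,
    nnz_C = x$nnz$total, nnz_L = x$nnz_L,
    n_parameters = length(x$theta)
  )
}

#' Convergence trajectory plot for an AI-REML fit
#'
#' Shows `-2 logL` and the largest absolute gradient element across
#' iterates.
#'
#' @param object a [reml_fit()] object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot reml_fit
#' @export
autoplot.reml_fit <- function(object, ...) {
  tr <- object$trajectory
  if (is.null(tr) || !nrow(tr)) stop("fit has no recorded trajectory")
  d <- dplyr::bind_rows(
    tibble::tibble(iter = tr$iter, value = tr$m2ll, what = "-2 logL"),
    tibble::tibble(iter = tr$iter, value = tr$grad_max,
                   what = "max |gradient|")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "AI-REML iterate", y = NULL,
                  title = paste0("AI-REML convergence (",
                                 object$param, " parameterisation)")) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
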