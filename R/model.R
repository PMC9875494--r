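## Multivariate linear mixed model specification and structural accounting:
## trait/fixed/random-term descriptions, equation counts (NEQ) and parameter
## counts (NP) without assembling the mixed model equations.

#' Define a random term of the model
#'
#' @param name term name (e.g. `"direct"`, `"maternal"`, `"mpe"`).
#' @param id_col name of the data column holding the level identifier for
#'   each record (`"id"` for direct genetic effects, `"dam"` for maternal
#'   terms).
#' @param rel name of the relationship factor to use for this term, matching
#'   a name in the `rels` list passed to [build_design()]; the special value
#'   `"identity"` requests an identity relationship over the levels observed
#'   in the data (e.g. a permanent environmental term).
#' @return a `random_term` description.
#' @export
random_term <- function(name, id_col = "id", rel = "animal") {
  structure(list(name = name, id_col = id_col, rel = rel),
            class = "random_term")
}

#' Specify a multivariate animal model
#'
#' Describes the model `y = X b + Z u + e` for `q` traits: which data
#' columns are traits, which categorical factors are fitted per trait, and
#' the random terms with their relationship structures.  Genetic effects are
#' ordered traits (or principal components) within individuals.
#'
#' @param traits character vector of trait column names (`q = length`).
#' @param fixed fixed-effect factors per trait: a character vector applied to
#'   every trait, or a named list with one character vector per trait.  The
#'   name `"1"` denotes an overall mean.  Within each trait the first factor
#'   keeps all its levels and each later factor has its first level
#'   constrained to zero, so that `X` has full rank.
#' @param random list of [random_term()] descriptions; the first term is the
#'   direct additive genetic effect.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(traits, fixed = "1",
                       random = list(random_term("direct", "id", "animal"))) {
  q <- length(traits)
  stopifnot(q >= 1L, length(random) >= 1L)
  if (!is.list(fixed)) fixed <- stats::setNames(rep(list(fixed), q), traits)
  stopifnot(length(fixed) == q, all(lengths(fixed) >= 1L))
  names(fixed) <- traits
  if (inherits(random, "random_term")) random <- list(random)
  names(random) <- vapply(random, `[[`, "", "name")
  structure(list(traits = traits, q = q, fixed = fixed, random = random),
            class = "model_spec")
}

#' Number of parameters to be estimated
#'
#' One symmetric covariance matrix per random term plus the residual, each
#' contributing `q(q+1)/2` parameters at full rank.
#'
#' @param spec a [model_spec()].
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  q <- spec$q
  as.integer((length(spec$random) + 1L) * q * (q + 1L) / 2L)
}

#' Number of mixed-model equations
#'
#' Counts equations without assembling the coefficient matrix: the total
#' number of fixed-effect levels over traits (after the identifiability
#' constraint) plus `q` equations per level of each random term.  Either
#' provide the data (level counts are derived exactly as assembly would), or
#' provide the structural counts directly.
#'
#' @param spec a [model_spec()] (only needed with `data`).
#' @param data phenotype data frame (see [build_design()]).
#' @param rels named list of relationship factors (their sizes determine the
#'   level counts of the random terms); as in [build_design()].
#' @param fixed_levels alternative to `data`: vector of fixed-effect level
#'   counts, one entry per (trait, factor) combination, already reduced for
#'   any identifiability constraint.
#' @param random_levels alternative to `data`: vector of level counts, one
#'   per random term.
#' @param q number of traits (required with structural counts).
#' @return integer equation count.
#' @export
count_equations <- function(spec = NULL, data = NULL, rels = NULL,
                            fixed_levels = NULL, random_levels = NULL,
                            q = spec$q) {
  if (!is.null(fixed_levels) || !is.null(random_levels)) {
    stopifnot(!is.null(q))
    return(as.integer(sum(fixed_levels) + q * sum(random_levels)))
  }
  stopifnot(!is.null(spec), !is.null(data), !is.null(rels))
  d <- build_design(spec, data, rels, param = "mv", quiet = TRUE)
  d$neq
}
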