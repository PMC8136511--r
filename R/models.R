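# Amino-acid substitution models: general time-reversible form
# Q_ij = S_ij * pi_j (i != j), normalised to one expected substitution per
# unit branch length, with optional discrete-gamma rate heterogeneity.

#' Build a normalised amino-acid rate matrix
#'
#' Assembles the instantaneous rate matrix of a general time-reversible
#' amino-acid model from a symmetric exchangeability matrix \eqn{S} and a
#' stationary frequency vector \eqn{\pi}: \eqn{Q_{ij} \propto S_{ij}\pi_j}
#' for \eqn{i \neq j}, diagonal set so rows sum to zero, and the whole matrix
#' scaled so that the expected number of substitutions per unit time,
#' \eqn{-\sum_i \pi_i Q_{ii}}, equals 1.
#'
#' @param exchangeabilities symmetric non-negative 20 x 20 matrix (diagonal
#'   ignored).
#' @param frequencies length-20 stationary distribution (must be positive and
#'   sum to 1 within 1e-8).
#' @return 20 x 20 rate matrix with zero row sums and unit mean rate.
#' @export
build_rate_matrix <- function(exchangeabilities, frequencies) {
  S <- as.matrix(exchangeabilities)
  pi <- as.numeric(frequencies)
  if (length(pi) != nrow(S) || nrow(S) != ncol(S))
    stop("dimension mismatch between exchangeabilities and frequencies")
  if (any(pi <= 0))
    stop("all stationary frequencies must be positive")
  if (abs(sum(pi) - 1) > 1e-8)
    stop("frequencies must sum to 1")
  if (max(abs(S - t(S))) > 1e-10)
    stop("exchangeability matrix must be symmetric")
  if (any(S[row(S) != col(S)] < 0))
    stop("exchangeabilities must be non-negative")
  Q <- S * rep(pi, each = nrow(S))   # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Symmetric eigendecomposition of a reversible Q (via the pi^{1/2} similarity
# transform), so that P(t) = E exp(Lambda t) Einv with all-real factors.
decompose_q <- function(Q, pi) {
  d <- sqrt(pi)
  B <- (Q * rep(1 / d, each = length(d))) * d   # diag(d) Q diag(1/d), symmetric
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  list(E = eig$vectors / d,             # diag(1/d) V
       Einv = t(eig$vectors * d),       # t(V) diag(d)
       lambda = eig$values)
}

#' Discrete-gamma rate categories
#'
#' Mean rates of \code{k} equal-probability categories of a gamma distribution
#' with shape \code{alpha} and mean 1 (the standard "+G" discretisation).
#' Category means are computed in closed form from incomplete-gamma
#' differences, so the rates average exactly 1.
#'
#' @param alpha positive shape parameter; small values give strong
#'   among-site rate variation.
#' @param k number of categories (default 4).
#' @return increasing numeric vector of length \code{k} with mean 1.
#' @export
discrete_gamma <- function(alpha, k = 4L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive number")
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  if (k == 1L) return(1)
  q <- qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  p <- c(0, pgamma(q, shape = alpha + 1, rate = alpha), 1)
  rates <- k * diff(p)
  rates / mean(rates)  # exact unit mean despite rounding
}

# Empirical exchangeabilities + frequencies, sourced from the installed
# phangorn (PAML residue order, lower triangle stored column-wise).
empirical_aa_model <- function(name) {
  obj <- switch(name,
    LG = ".LG", WAG = ".WAG", JTT = ".JTT",
    stop("unknown empirical model: ", name))
  m <- utils::getFromNamespace(obj, "phangorn")
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- m$Q
  S <- S + t(S)
  dimnames(S) <- list(AA_ALPHABET, AA_ALPHABET)
  freq <- as.numeric(m$bf)
  freq <- freq / sum(freq)
  list(S = S, freq = setNames(freq, AA_ALPHABET))
}

#' Construct an amino-acid substitution model
#'
#' Bundles exchangeabilities, stationary frequencies, the derived normalised
#' rate matrix, its eigendecomposition, and an optional discrete-gamma rate
#' model into an \code{aa_model} object used throughout the likelihood engine.
#'
#' Available empirical matrices are LG, WAG and JTT (taken from the installed
#' \pkg{phangorn}); \code{"Poisson"} is the equal-rates, equal-frequency
#' model.
#'
#' @param name one of \code{"LG"}, \code{"WAG"}, \code{"JTT"},
#'   \code{"Poisson"}.
#' @param gamma_shape positive gamma shape for among-site rate variation, or
#'   \code{NULL} for rate homogeneity.
#' @param n_cat number of discrete gamma categories (ignored when
#'   \code{gamma_shape} is \code{NULL}).
#' @param frequencies optional length-20 frequency override.
#' @return an object of class \code{aa_model}.
#' @export
aa_model <- function(name = c("LG", "WAG", "JTT", "Poisson"),
                     gamma_shape = NULL, n_cat = 4L, frequencies = NULL) {
  name <- match.arg(name)
  if (name == "Poisson") {
    S <- matrix(1, 20, 20); diag(S) <- 0
    dimnames(S) <- list(AA_ALPHABET, AA_ALPHABET)
    freq <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  } else {
    emp <- empirical_aa_model(name)
    S <- emp$S
    freq <- emp$freq
  }
  if (!is.null(frequencies)) {
    if (length(frequencies) != 20) stop("frequencies must have length 20")
    freq <- setNames(as.numeric(frequencies) / sum(frequencies), AA_ALPHABET)
  }
  Q <- build_rate_matrix(S, freq)
  dec <- decompose_q(Q, freq)
  rates <- if (is.null(gamma_shape)) 1 else discrete_gamma(gamma_shape, n_cat)
  structure(list(name = name,
                 exchangeabilities = S,
                 frequencies = freq,
                 gamma_shape = gamma_shape,
                 n_categories = length(rates),
                 rates = rates,
                 rate_matrix = Q,
                 eigen = dec),
            class = "aa_model")
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$name,
      if (!is.null(x$gamma_shape))
        sprintf("+G%d (alpha = %.4g)", x$n_categories, x$gamma_shape)
      else "(rate-homogeneous)", "\n")
  invisible(x)
}

model_label <- function(model) {
  paste0(model$name,
         if (!is.null(model$gamma_shape)) paste0("+G", model$n_categories) else "")
}

#' Build an \code{aa_model} from custom exchangeabilities
#'
#' @param name model label.
#' @param exchangeabilities symmetric 20 x 20 matrix.
#' @param frequencies length-20 simplex.
#' @inheritParams aa_model
#' @export
custom_aa_model <- function(name, exchangeabilities, frequencies,
                            gamma_shape = NULL, n_cat = 4L) {
  S <- as.matrix(exchangeabilities)
  dimnames(S) <- list(AA_ALPHABET, AA_ALPHABET)
  freq <- setNames(as.numeric(frequencies) / sum(frequencies), AA_ALPHABET)
  Q <- build_rate_matrix(S, freq)
  rates <- if (is.null(gamma_shape)) 1 else discrete_gamma(gamma_shape, n_cat)
  structure(list(name = name, exchangeabilities = S, frequencies = freq,
                 gamma_shape = gamma_shape, n_categories = length(rates),
                 rates = rates, rate_matrix = Q,
                 eigen = decompose_q(Q, freq)),
            class = "aa_model")
}

#' Read a PAML-layout amino-acid model file
#'
#' Whitespace-separated lower triangle of the exchangeability matrix (19
#' rows) followed by the 20 stationary frequencies, residues in the standard
#' PAML order.
#'
#' @param file path to the model file.
#' @param name model label (defaults to the file name).
#' @inheritParams aa_model
#' @return an \code{aa_model}.
#' @export
read_paml_model <- function(file, name = NULL, gamma_shape = NULL,
                            n_cat = 4L) {
  vals <- scan(file, quiet = TRUE)
  if (length(vals) < 210)
    stop("expected 190 exchangeabilities + 20 frequencies, got ",
         length(vals), " numbers")
  S <- matrix(0, 20, 20)
  S[upper.tri(S)] <- vals[1:190]     # row-wise lower triangle = column-wise
  S <- S + t(S)                      # upper triangle of the transpose
  freq <- vals[191:210]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(file))
  custom_aa_model(name, S, freq, gamma_shape, n_cat)
}

#' Transition probability matrix
#'
#' \eqn{P(t) = e^{Qt}} computed by symmetric eigendecomposition of the
#' reversible rate matrix; entries are clipped to \eqn{[0, 1]} to remove
#' numerical noise, and rows sum to 1.
#'
#' @param model an \code{aa_model}.
#' @param t branch length (expected substitutions per site), \eqn{\ge 0}.
#' @return 20 x 20 stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  if (!inherits(model, "aa_model")) stop("model must be an aa_model")
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("t must be a single non-negative number")
  P <- with(model$eigen, E %*% (exp(lambda * t) * Einv))
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(model$rate_matrix)
  P
}
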