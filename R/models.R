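# Substitution model specifications.
#
# Counting corrections (p, poisson, gamma, kimura_protein, jc69, k2p) need no
# parameters beyond the gamma shape. `ml_empirical` carries a full reversible
# rate matrix built from exchangeabilities s_ij and stationary frequencies
# pi: Q_ij = s_ij * pi_j, diagonal filled so rows sum to 0, scaled so the
# expected substitution rate at equilibrium, -sum(pi_i Q_ii), equals 1 --
# branch lengths are then expected substitutions per site. Rate heterogeneity
# across sites uses the standard 4-category discrete gamma (equal
# probabilities, category rates = bin means).

MODEL_NAMES <- c("p", "poisson", "gamma", "kimura_protein", "jc69", "k2p",
                 "ml_empirical")

#' Specify a substitution model
#'
#' @param name one of `"p"`, `"poisson"`, `"gamma"`, `"kimura_protein"`,
#'   `"jc69"`, `"k2p"`, `"ml_empirical"`.
#' @param alpha gamma shape for among-site rate variation (> 0). Required for
#'   `name = "gamma"`; optional for `"ml_empirical"` (4 discrete categories);
#'   ignored otherwise.
#' @param exchangeabilities symmetric non-negative matrix of relative rates
#'   (`ml_empirical` only; diagonal ignored).
#' @param frequencies stationary frequencies summing to 1 (`ml_empirical`
#'   only). Names, if present, give the state alphabet.
#' @param states state characters (defaults to the amino-acid or nucleotide
#'   alphabet matching the frequency vector length).
#' @return object of class `substitution_model`.
#' @seealso [model_uniform()], [model_jtt()]
#' @export
substitution_model <- function(name, alpha = NULL, exchangeabilities = NULL,
                               frequencies = NULL, states = NULL) {
  name <- match.arg(name, MODEL_NAMES)
  if (!is.null(alpha) && (!is.numeric(alpha) || alpha <= 0)) {
    stop("gamma shape alpha must be > 0")
  }
  if (name == "gamma" && is.null(alpha)) alpha <- 1.0
  m <- list(name = name, alpha = alpha)
  if (name == "ml_empirical") {
    if (is.null(exchangeabilities) || is.null(frequencies)) {
      stop("ml_empirical needs exchangeabilities and frequencies")
    }
    k <- length(frequencies)
    exchangeabilities <- as.matrix(exchangeabilities)
    if (!all(dim(exchangeabilities) == k)) {
      stop("exchangeability matrix must be ", k, "x", k)
    }
    if (max(abs(exchangeabilities - t(exchangeabilities))) > 1e-9) {
      stop("exchangeability matrix must be symmetric")
    }
    if (any(exchangeabilities[upper.tri(exchangeabilities)] < 0)) {
      stop("exchangeabilities must be non-negative")
    }
    if (abs(sum(frequencies) - 1) > 1e-12) {
      stop("frequencies must sum to 1 (got ", sum(frequencies), ")")
    }
    if (any(frequencies <= 0)) stop("frequencies must be positive")
    if (is.null(states)) {
      states <- if (!is.null(names(frequencies))) toupper(names(frequencies))
                else if (k == 20) AA_STATES
                else if (k == 4) DNA_STATES
                else stop("supply state labels for a ", k, "-state model")
    }
    pi <- as.numeric(frequencies)
    Q <- exchangeabilities * rep(pi, each = k)
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    mu <- -sum(pi * diag(Q))          # expected rate at equilibrium
    Q <- Q / mu
    # reversible Q: symmetrize with sqrt(pi) for a stable eigendecomposition
    ps <- sqrt(pi)
    B <- Q * (ps %o% (1 / ps))
    B <- (B + t(B)) / 2
    eig <- eigen(B, symmetric = TRUE)
    m$frequencies <- pi
    m$states <- states
    m$Q <- Q
    m$eig <- list(values = eig$values, vectors = eig$vectors, ps = ps)
    m$rates <- if (is.null(alpha)) 1 else discrete_gamma_rates(alpha, 4L)
  }
  class(m) <- "substitution_model"
  m
}

#' Uniform (Jukes-Cantor-like) k-state model
#'
#' Equal exchangeabilities and frequencies over `nstates` states: the 20-state
#' version admits the closed form d = -(19/20) log(1 - 20 p / 19) used as an
#' analytic cross-check of the ML machinery.
#'
#' @param nstates 20 (protein) or 4 (DNA).
#' @param alpha optional gamma shape.
#' @export
model_uniform <- function(nstates = 20, alpha = NULL) {
  states <- if (nstates == 20) AA_STATES else if (nstates == 4) DNA_STATES
            else stop("nstates must be 4 or 20")
  ex <- matrix(1, nstates, nstates)
  diag(ex) <- 0
  substitution_model("ml_empirical", alpha = alpha, exchangeabilities = ex,
                     frequencies = rep(1 / nstates, nstates), states = states)
}

#' JTT empirical amino-acid model
#'
#' Exchangeabilities and stationary frequencies of the Jones-Taylor-Thornton
#' matrix, taken at run time from the phangorn package's model tables.
#'
#' @param alpha optional gamma shape (4 discrete categories).
#' @export
model_jtt <- function(alpha = NULL) {
  jtt <- get(".JTT", envir = asNamespace("phangorn"))
  states <- toupper(names(jtt$bf))
  k <- length(states)
  ex <- matrix(0, k, k)
  ex[lower.tri(ex)] <- jtt$Q        # phangorn stores the lower triangle column-wise
  ex <- ex + t(ex)
  substitution_model("ml_empirical", alpha = alpha, exchangeabilities = ex,
                     frequencies = as.numeric(jtt$bf), states = states)
}

#' Discrete gamma rate categories
#'
#' Mean-of-bin discretization of the gamma(alpha, alpha) distribution into
#' `k` equal-probability categories; the category rates average to 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # mean within each bin via the incomplete-gamma identity
  cdf1 <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  k * diff(cdf1)
}

#' Transition probability matrix P(t)
#'
#' @param model an `ml_empirical` [substitution_model()].
#' @param t branch length (expected substitutions per site at rate 1).
#' @return row-stochastic matrix with `P[i, j] = P(state j at time t | i at 0)`.
#' @export
prob_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"), model$name == "ml_empirical",
            t >= 0)
  e <- model$eig
  P <- (e$vectors * rep(exp(e$values * t), each = nrow(e$vectors))) %*% t(e$vectors)
  P <- P * ((1 / e$ps) %o% e$ps)
  P[P < 0] <- 0
  P / rowSums(P)
}

# mixture transition matrix over the discrete gamma categories
prob_matrix_mixture <- function(model, t) {
  rates <- model$rates
  if (length(rates) == 1) return(prob_matrix(model, t * rates))
  Reduce(`+`, lapply(rates, function(r) prob_matrix(model, t * r))) / length(rates)
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("substitution model:", x$name)
  if (!is.null(x$alpha)) cat(sprintf(" (gamma alpha = %g)", x$alpha))
  if (x$name == "ml_empirical") cat(sprintf(", %d states", length(x$states)))
  cat("\n")
  invisible(x)
}
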