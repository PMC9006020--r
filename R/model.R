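# Reversible amino-acid substitution models with discrete-gamma rate
# heterogeneity. State order follows the PAML/LG convention (AA_STATES).

# Fetch published exchangeability/frequency tables. LG (Le & Gascuel 2008)
# and WAG (Whelan & Goldman 2001) are taken from phangorn's model tables
# (lower triangle, column-major); Poisson is closed form.
model_tables <- function(name) {
  if (name == "Poisson") {
    s <- matrix(1, 20, 20)
    diag(s) <- 0
    return(list(s = s, freq = rep(1 / 20, 20)))
  }
  getAA <- utils::getFromNamespace("getModelAA", "phangorn")
  res <- local({
    getAA(name)
    list(Q = Q, bf = bf)
  })
  s <- matrix(0, 20, 20)
  s[lower.tri(s)] <- res$Q
  s <- s + t(s)
  dimnames(s) <- list(AA_STATES, AA_STATES)
  list(s = s, freq = res$bf)
}

#' Discrete-gamma relative rates (mean of equiprobable bins)
#'
#' Divides a Gamma(alpha, alpha) density (mean 1) into `k` equiprobable
#' bins and returns the conditional mean rate of each bin, normalized so
#' the rates average exactly 1. This is the classic discrete-gamma
#' approximation of among-site rate variation.
#'
#' @param alpha Positive gamma shape parameter; small values mean strong
#'   rate heterogeneity.
#' @param k Number of rate categories (>= 1). `k = 1` returns rate 1
#'   (rate homogeneity).
#' @return Numeric vector of `k` relative rates with mean 1.
#' @export
#' @examples
#' discrete_gamma_rates(0.5, 4)
discrete_gamma_rates <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  if (k == 1) return(1)
  edges <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # Mean of a gamma over a bin via the incomplete-gamma identity:
  # E[X; a<X<b] = P(alpha+1 bin) / P(alpha bin) with rate alpha.
  r <- k * diff(pgamma(edges, shape = alpha + 1, rate = alpha))
  r * k / sum(r)
}

#' Build an amino-acid substitution model
#'
#' Assembles a reversible 20-state rate matrix `Q[i,j] = s[i,j] * pi[j]`,
#' normalized to one expected substitution per unit branch length
#' (`-sum(pi * diag(Q)) = 1`), together with a discrete-gamma rate
#' distribution. Frequencies come from the model table (`freq_mode =
#' "model"`) or from the observed amino-acid proportions of an alignment
#' (`freq_mode = "empirical"`, the "+F" option), with zero-count states
#' floored at a small pseudo-frequency before renormalization.
#'
#' @param name One of "LG", "WAG", "Poisson".
#' @param k Number of discrete-gamma categories (>= 1).
#' @param alpha Gamma shape parameter (> 0); ignored when `k = 1`.
#' @param freq_mode "model" or "empirical" ("+F").
#' @param alignment Alignment (gene alignment, supermatrix, or character
#'   matrix) from which to count frequencies; required for
#'   `freq_mode = "empirical"`.
#' @param pseudo_freq Floor applied to unobserved states under "+F".
#' @return An object of class `aa_model`.
#' @export
#' @examples
#' m <- aa_model("Poisson", k = 1)
#' round(-sum(m$freq * diag(m$Q)), 12)  # normalization identity
aa_model <- function(name = c("LG", "WAG", "Poisson"), k = 4, alpha = 1,
                     freq_mode = c("model", "empirical"), alignment = NULL,
                     pseudo_freq = 1e-4) {
  name <- match.arg(name)
  freq_mode <- match.arg(freq_mode)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  tab <- model_tables(name)
  freq <- tab$freq
  if (freq_mode == "empirical") {
    if (is.null(alignment))
      stop("`alignment` is required when freq_mode = \"empirical\"")
    freq <- empirical_frequencies(alignment, pseudo_freq = pseudo_freq)
  }
  names(freq) <- AA_STATES
  Q <- sweep(tab$s, 2, freq, "*")
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(AA_STATES, AA_STATES)
  # Symmetrized eigendecomposition (numerically stable for reversible Q):
  # B = D^(1/2) Q D^(-1/2) is symmetric when detailed balance holds.
  d2 <- sqrt(freq)
  B <- Q * outer(d2, 1 / d2)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  eig <- list(U = e$vectors / d2, Uinv = t(e$vectors * d2), lambda = e$values)
  structure(list(
    name = name, k = as.integer(k),
    alpha = if (k > 1) alpha else NA_real_,
    rates = discrete_gamma_rates(if (k > 1) alpha else 1, k),
    freq = freq, s = tab$s, Q = Q, freq_mode = freq_mode, eig = eig
  ), class = "aa_model")
}

# Empirical amino-acid proportions of an alignment, missing characters
# excluded, unobserved states floored then renormalized.
empirical_frequencies <- function(alignment, pseudo_freq = 1e-4) {
  seq <- as_seq_matrix(alignment)
  counts <- table(factor(seq, levels = AA_STATES))
  p <- as.numeric(counts)
  if (sum(p) == 0) stop("alignment contains no unambiguous amino acids")
  p <- p / sum(p)
  p[p < pseudo_freq] <- pseudo_freq
  p <- p / sum(p)
  names(p) <- AA_STATES
  p
}

# Rebuild the gamma rates of a model for a new shape (Q/eigen unchanged).
update_alpha <- function(model, alpha) {
  model$alpha <- alpha
  model$rates <- discrete_gamma_rates(alpha, model$k)
  model
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param model An `aa_model`.
#' @param t Branch length (expected substitutions/site, >= 0).
#' @param r Relative rate multiplier (>= 0), e.g. a gamma category rate.
#' @return 20 x 20 row-stochastic matrix; tiny negative entries from the
#'   eigendecomposition are clamped at 0.
#' @export
transition_matrix <- function(model, t, r = 1) {
  stopifnot(inherits(model, "aa_model"))
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("branch length `t` must be a single finite number >= 0")
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0)
    stop("rate `r` must be a single finite number >= 0")
  P <- ptrans(model$eig, t * r)
  dimnames(P) <- list(AA_STATES, AA_STATES)
  P
}

# Bare matrix-exponential kernel used in the hot paths.
ptrans <- function(eig, tr) {
  P <- eig$U %*% (exp(eig$lambda * tr) * eig$Uinv)
  P[P < 0] <- 0
  P
}

#' Parse a model specification string
#'
#' Accepts strings in the familiar "LG+G4+F" form: a model name, an
#' optional "+G<k>" gamma term (default "+G" means 4 categories) and an
#' optional "+F" empirical-frequency term.
#'
#' @param spec Character scalar, e.g. "LG+G4+F", "Poisson+G4", "WAG".
#' @return List with elements `name`, `k`, `freq_mode`.
#' @export
parse_model_string <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  parts <- strsplit(toupper(gsub(" ", "", spec)), "+", fixed = TRUE)[[1]]
  if (length(parts) == 0) stop("empty model string")
  name <- c(LG = "LG", WAG = "WAG", POISSON = "Poisson")[parts[1]]
  if (is.na(name)) stop("unknown model name: ", parts[1])
  k <- 1L
  freq_mode <- "model"
  for (p in parts[-1]) {
    if (grepl("^G[0-9]*$", p)) {
      k <- if (p == "G") 4L else as.integer(sub("^G", "", p))
      if (k < 1) stop("invalid gamma category count in: ", p)
    } else if (p == "F") {
      freq_mode <- "empirical"
    } else stop("unrecognized model term: ", p)
  }
  list(name = unname(name), k = k, freq_mode = freq_mode)
}

#' @export
print.aa_model <- function(x, ...) {
  g <- if (x$k > 1) sprintf("+G%d (alpha = %.4g)", x$k, x$alpha) else ""
  f <- if (x$freq_mode == "empirical") "+F" else ""
  cat(sprintf("Amino-acid model %s%s%s\n", x$name, g, f))
  invisible(x)
}
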