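# Maximum-likelihood engine: Felsenstein pruning for reversible amino-acid
# models with discrete-gamma rate mixing, per-node log-scaling against
# underflow, edge-local branch-length optimization (exact coordinate
# ascent via outside/inside partials), gamma-shape optimization, posterior
# mean site rates, and NJ + NNI hill-climbing tree search.

BL_MIN <- 1e-8
BL_MAX <- 20

# ---- data preparation -------------------------------------------------

# Site-pattern data independent of any particular tree: alignment rows in
# a fixed (sorted) taxon order, compressed into unique column patterns.
prep_data <- function(aln) {
  seq <- as_seq_matrix(aln)
  taxa <- sort(rownames(seq))
  states <- encode_states(seq[taxa, , drop = FALSE])
  cp <- compress_patterns(states)
  list(taxa = taxa, pat = cp$pat, w = cp$w, site_index = cp$site_index,
       L = ncol(states), npat = ncol(cp$pat))
}

# Bind pattern data to a tree: postorder edge list, tip pattern rows in
# tip-number order, children-edge index per node.
prep_tree <- function(pd, tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo object")
  if (is.null(tree$tip.label))
    stop("tree has no tip labels (extract trees from a multiPhylo with [[)")
  missing_leaves <- setdiff(tree$tip.label, pd$taxa)
  if (length(missing_leaves) > 0)
    stop("leaf without a sequence row: ", missing_leaves[1])
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)))
    stop("branch lengths must be finite")
  if (any(tree$edge.length < 0))
    stop("branch lengths must be >= 0")
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  child_edges <- split(seq_len(nedge), tree$edge[, 1])
  list(tree = tree, edge = tree$edge, elen = tree$edge.length,
       ntip = ntip, nnode = tree$Nnode,
       root = tree$edge[nedge, 1],
       tip_pat = pd$pat[match(tree$tip.label, pd$taxa), , drop = FALSE],
       child_edges = child_edges)
}

# ---- pruning ----------------------------------------------------------

# Per-pattern, per-category log-likelihoods by postorder pruning.
# Missing tip states contribute a row of ones (marginalized).
pattern_logliks <- function(pd, pt, model, elen = pt$elen) {
  k <- model$k
  npat <- pd$npat
  eig <- model$eig
  freq <- model$freq
  E <- pt$edge
  nedge <- nrow(E)
  ntip <- pt$ntip
  M <- ntip + pt$nnode
  ll <- matrix(0, npat, k)
  for (m in seq_len(k)) {
    r <- model$rates[m]
    D <- vector("list", M)
    lsc <- vector("list", M)
    for (e in seq_len(nedge)) {
      p <- E[e, 1]; ch <- E[e, 2]
      P <- ptrans(eig, elen[e] * r)
      if (ch <= ntip) {
        s <- pt$tip_pat[ch, ]
        Em <- matrix(1, npat, 20)
        obs <- which(!is.na(s))
        if (length(obs) > 0) Em[obs, ] <- t(P)[s[obs], , drop = FALSE]
        le <- NULL
      } else {
        sc <- scale_partial(D[[ch]])
        Em <- sc$x %*% t(P)
        le <- lsc[[ch]] + sc$logs
      }
      if (is.null(D[[p]])) {
        D[[p]] <- Em
        lsc[[p]] <- le %||% 0
      } else {
        D[[p]] <- D[[p]] * Em
        lsc[[p]] <- lsc[[p]] + (le %||% 0)
      }
    }
    ll[, m] <- log(as.vector(D[[pt$root]] %*% freq)) + lsc[[pt$root]]
  }
  ll
}

scale_partial <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  mx[mx <= 0] <- 1
  list(x = x / mx, logs = log(mx))
}

# Mixture site log-likelihood per pattern (equal category weights).
# Hand-rolled log-sum-exp over the (few) category columns: this sits in
# the innermost optimization loop.
pattern_site_lnl <- function(ll, k) {
  if (k == 1) return(as.vector(ll))
  mx <- ll[, 1]
  for (m in 2:k) mx <- pmax(mx, ll[, m])
  acc <- exp(ll[, 1] - mx)
  for (m in 2:k) acc <- acc + exp(ll[, m] - mx)
  mx + log(acc) - log(k)
}

total_loglik <- function(pd, pt, model, elen = pt$elen) {
  sum(pd$w * pattern_site_lnl(pattern_logliks(pd, pt, model, elen), model$k))
}

#' Per-site log-likelihoods under a tree and model
#'
#' Felsenstein pruning with missing characters marginalized and the
#' discrete-gamma mixture averaged with equal category weights. The total
#' is accumulated as the plain left-to-right sum of the per-site vector,
#' so `sum(result$site) == result$total` holds exactly.
#'
#' @param aln Alignment (gene alignment, supermatrix, character matrix).
#' @param tree `phylo` tree with branch lengths; its leaves must all have
#'   alignment rows (extra alignment rows are ignored).
#' @param model An [aa_model()].
#' @return List with `site` (numeric vector, one log-likelihood per
#'   alignment column) and `total` (their sum).
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  pd <- prep_data(aln)
  pt <- prep_tree(pd, tree)
  ll <- pattern_logliks(pd, pt, model)
  site <- pattern_site_lnl(ll, model$k)[pd$site_index]
  list(site = site, total = sum(site))
}

# ---- branch-length optimization --------------------------------------

# Down pass retaining, per category: the edge partial E[e] (subtree
# likelihood propagated through its branch), its accumulated log-scaler,
# and the scaled node partial D[v] for internal nodes.
down_pass <- function(pd, pt, model, elen) {
  k <- model$k
  npat <- pd$npat
  eig <- model$eig
  E <- pt$edge
  nedge <- nrow(E)
  ntip <- pt$ntip
  M <- ntip + pt$nnode
  Elist <- rep(list(vector("list", nedge)), k)
  lscE <- rep(list(vector("list", nedge)), k)
  Dlist <- rep(list(vector("list", M)), k)
  lscD <- rep(list(vector("list", M)), k)
  ll <- matrix(0, npat, k)
  for (m in seq_len(k)) {
    r <- model$rates[m]
    D <- vector("list", M)
    lsc <- vector("list", M)
    for (e in seq_len(nedge)) {
      p <- E[e, 1]; ch <- E[e, 2]
      P <- ptrans(eig, elen[e] * r)
      if (ch <= ntip) {
        s <- pt$tip_pat[ch, ]
        Em <- matrix(1, npat, 20)
        obs <- which(!is.na(s))
        if (length(obs) > 0) Em[obs, ] <- t(P)[s[obs], , drop = FALSE]
        le <- NULL
      } else {
        sc <- scale_partial(D[[ch]])
        D[[ch]] <- sc$x
        lsc[[ch]] <- lsc[[ch]] + sc$logs
        Dlist[[m]][[ch]] <- sc$x
        lscD[[m]][[ch]] <- lsc[[ch]]
        Em <- sc$x %*% t(P)
        le <- lsc[[ch]]
      }
      Elist[[m]][[e]] <- Em
      lscE[[m]][[e]] <- le %||% 0
      if (is.null(D[[p]])) {
        D[[p]] <- Em
        lsc[[p]] <- le %||% 0
      } else {
        D[[p]] <- D[[p]] * Em
        lsc[[p]] <- lsc[[p]] + (le %||% 0)
      }
    }
    sc <- scale_partial(D[[pt$root]])
    Dlist[[m]][[pt$root]] <- sc$x
    lscD[[m]][[pt$root]] <- lsc[[pt$root]] + sc$logs
    ll[, m] <- log(as.vector(sc$x %*% model$freq)) + lscD[[m]][[pt$root]]
  }
  list(E = Elist, lscE = lscE, D = Dlist, lscD = lscD, ll = ll)
}

# One exact coordinate-ascent sweep over all branches. Edges are visited
# in preorder; outside partials are propagated with already-updated
# branch lengths, so every one-dimensional optimization maximizes the
# exact total log-likelihood at the current parameter values.
sweep_branches <- function(pd, pt, model, elen, brent_tol = 1e-5) {
  k <- model$k
  npat <- pd$npat
  eig <- model$eig
  rates <- model$rates
  E <- pt$edge
  nedge <- nrow(E)
  ntip <- pt$ntip
  M <- ntip + pt$nnode
  piRow <- matrix(model$freq, npat, 20, byrow = TRUE)
  dp <- down_pass(pd, pt, model, elen)
  U <- rep(list(vector("list", M)), k)
  lscU <- rep(list(vector("list", M)), k)
  ones <- matrix(1, npat, 20)
  for (m in seq_len(k)) {
    U[[m]][[pt$root]] <- ones
    lscU[[m]][[pt$root]] <- 0
  }
  lnl <- NA_real_
  for (e in rev(seq_len(nedge))) {
    u <- E[e, 1]; v <- E[e, 2]
    Gpi <- vector("list", k)
    lscG <- vector("list", k)
    sibs <- setdiff(pt$child_edges[[as.character(u)]], e)
    for (m in seq_len(k)) {
      G <- U[[m]][[u]]
      ls <- lscU[[m]][[u]]
      for (s_e in sibs) {
        G <- G * dp$E[[m]][[s_e]]
        ls <- ls + dp$lscE[[m]][[s_e]]
      }
      sc <- scale_partial(G)
      Gpi[[m]] <- sc$x * piRow
      lscG[[m]] <- ls + sc$logs
    }
    v_tip <- v <= ntip
    if (v_tip) {
      s <- pt$tip_pat[v, ]
      obs <- which(!is.na(s))
      lscDv <- rep(list(0), k)
    } else {
      lscDv <- lapply(seq_len(k), function(m) dp$lscD[[m]][[v]])
    }
    # Eigen-basis contraction: with D' = D U^-T and G' = (G pi) U, the
    # edge likelihood is rowSums(G' * D' * exp(lambda t r)) -- a cheap
    # matrix-vector product per Brent evaluation.
    tUinv <- t(eig$Uinv)
    if (v_tip) {
      DU <- matrix(rowSums(eig$Uinv), npat, 20, byrow = TRUE)
      if (length(obs) > 0) DU[obs, ] <- tUinv[s[obs], , drop = FALSE]
    }
    W <- lapply(seq_len(k), function(m) {
      DUm <- if (v_tip) DU else dp$D[[m]][[v]] %*% tUinv
      (Gpi[[m]] %*% eig$U) * DUm
    })
    obj <- function(t) {
      llm <- matrix(0, npat, k)
      for (m in seq_len(k)) {
        lik <- as.vector(W[[m]] %*% exp(eig$lambda * (t * rates[m])))
        llm[, m] <- log(pmax(lik, 1e-320)) + lscG[[m]] + lscDv[[m]]
      }
      sum(pd$w * pattern_site_lnl(llm, k))
    }
    cur <- obj(elen[e])
    # bracket around the current length; re-widen if the optimum lands on
    # a local bracket edge
    lo <- max(BL_MIN, elen[e] / 8)
    hi <- min(BL_MAX, max(elen[e] * 8, 1e-3))
    opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = brent_tol)
    if ((opt$maximum - lo < 2 * brent_tol && lo > BL_MIN) ||
        (hi - opt$maximum < 2 * brent_tol && hi < BL_MAX)) {
      opt <- optimize(obj, c(BL_MIN, BL_MAX), maximum = TRUE,
                      tol = brent_tol)
    }
    if (opt$objective > cur) {
      elen[e] <- opt$maximum
      lnl <- opt$objective
    } else {
      lnl <- cur
    }
    # refresh the edge partial and push the outside partial through the
    # (possibly updated) branch
    for (m in seq_len(k)) {
      P <- ptrans(eig, elen[e] * rates[m])
      if (v_tip) {
        Em <- ones
        if (length(obs) > 0) Em[obs, ] <- t(P)[s[obs], , drop = FALSE]
      } else {
        Em <- dp$D[[m]][[v]] %*% t(P)
      }
      dp$E[[m]][[e]] <- Em
      if (!v_tip) {
        sc <- scale_partial((Gpi[[m]] / piRow) %*% t(P))
        U[[m]][[v]] <- sc$x
        lscU[[m]][[v]] <- lscG[[m]] + sc$logs
      }
    }
  }
  list(elen = elen, loglik = lnl)
}

# Down pass plus outside (up) partials for every node, without touching
# branch lengths. Used by the NNI scorer.
updown_pass <- function(pd, pt, model, elen) {
  k <- model$k
  npat <- pd$npat
  eig <- model$eig
  E <- pt$edge
  ntip <- pt$ntip
  M <- ntip + pt$nnode
  dp <- down_pass(pd, pt, model, elen)
  U <- rep(list(vector("list", M)), k)
  lscU <- rep(list(vector("list", M)), k)
  ones <- matrix(1, npat, 20)
  for (m in seq_len(k)) {
    U[[m]][[pt$root]] <- ones
    lscU[[m]][[pt$root]] <- 0
  }
  for (e in rev(seq_len(nrow(E)))) {
    u <- E[e, 1]; v <- E[e, 2]
    if (v <= ntip) next
    for (m in seq_len(k)) {
      G <- U[[m]][[u]]
      ls <- lscU[[m]][[u]]
      for (s_e in setdiff(pt$child_edges[[as.character(u)]], e)) {
        G <- G * dp$E[[m]][[s_e]]
        ls <- ls + dp$lscE[[m]][[s_e]]
      }
      P <- ptrans(eig, elen[e] * model$rates[m])
      sc <- scale_partial(G %*% t(P))
      U[[m]][[v]] <- sc$x
      lscU[[m]][[v]] <- ls + sc$logs
    }
  }
  c(dp, list(U = U, lscU = lscU))
}

# Score both NNI rearrangements of an internal edge by Brent-optimizing
# the central branch only, reusing cached subtree partials. Returns the
# candidate scores, optimal central lengths, and the edge pair to swap.
nni_edge_scores <- function(pd, pt, model, elen, ud, e) {
  k <- model$k
  npat <- pd$npat
  eig <- model$eig
  piRow <- matrix(model$freq, npat, 20, byrow = TRUE)
  u <- pt$edge[e, 1]; v <- pt$edge[e, 2]
  sib_edges <- setdiff(pt$child_edges[[as.character(u)]], e)
  sib <- sib_edges[1]
  rest <- sib_edges[-1]
  kids <- pt$child_edges[[as.character(v)]]
  out <- vector("list", 2)
  for (ci in 1:2) {
    cc <- kids[ci]; oo <- kids[-ci]
    W <- vector("list", k)
    lsc <- vector("list", k)
    for (m in seq_len(k)) {
      G <- ud$U[[m]][[u]] * ud$E[[m]][[cc]]
      ls <- ud$lscU[[m]][[u]] + ud$lscE[[m]][[cc]]
      for (r_e in rest) {
        G <- G * ud$E[[m]][[r_e]]
        ls <- ls + ud$lscE[[m]][[r_e]]
      }
      sc <- scale_partial(G)
      Dside <- ud$E[[m]][[sib]] * ud$E[[m]][[oo]]
      sd2 <- scale_partial(Dside)
      W[[m]] <- ((sc$x * piRow) %*% eig$U) * (sd2$x %*% t(eig$Uinv))
      lsc[[m]] <- ls + sc$logs + ud$lscE[[m]][[sib]] + ud$lscE[[m]][[oo]] +
        sd2$logs
    }
    obj <- function(t) {
      llm <- matrix(0, npat, k)
      for (m in seq_len(k)) {
        lik <- as.vector(W[[m]] %*% exp(eig$lambda * (t * model$rates[m])))
        llm[, m] <- log(pmax(lik, 1e-320)) + lsc[[m]]
      }
      sum(pd$w * pattern_site_lnl(llm, k))
    }
    opt <- optimize(obj, c(BL_MIN, BL_MAX), maximum = TRUE, tol = 1e-4)
    out[[ci]] <- list(score = opt$objective, t = opt$maximum,
                      swap = c(sib, cc), edge = e)
  }
  out
}

# Apply an NNI move: exchange the subtrees hanging from two edges (their
# stem lengths travel with them) and set the central branch length.
apply_nni <- function(tree, edge_pair, central_edge, central_len) {
  tr <- tree
  a <- edge_pair[1]; b <- edge_pair[2]
  tmp <- tr$edge[a, 2]
  tr$edge[a, 2] <- tr$edge[b, 2]
  tr$edge[b, 2] <- tmp
  tmp <- tr$edge.length[a]
  tr$edge.length[a] <- tr$edge.length[b]
  tr$edge.length[b] <- tmp
  tr$edge.length[central_edge] <- central_len
  attr(tr, "order") <- NULL
  stats::reorder(tr, "postorder")
}

opt_branches_prep <- function(pd, pt, model, tol = 1e-4, max_iter = 100,
                              brent_tol = 1e-5) {
  elen <- pmin(pmax(pt$elen, BL_MIN), BL_MAX)
  lnl_prev <- -Inf
  lnl <- -Inf
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    sw <- sweep_branches(pd, pt, model, elen, brent_tol)
    elen <- sw$elen
    lnl <- sw$loglik
    if (is.finite(lnl_prev) && lnl - lnl_prev < tol) break
    lnl_prev <- lnl
  }
  list(elen = elen, loglik = lnl, sweeps = it)
}

#' Optimize branch lengths by coordinate-wise Brent search
#'
#' Cycles one-dimensional (Brent) optimizations over all branches until
#' the log-likelihood improves by less than `tol` in a full sweep or
#' `max_iter` sweeps are reached. Branch lengths are bounded in
#' [1e-8, 20]. The log-likelihood is non-decreasing across sweeps.
#'
#' @param aln Alignment.
#' @param tree `phylo` tree with (starting) branch lengths.
#' @param model An [aa_model()].
#' @param tol Minimum per-sweep log-likelihood improvement (default 1e-4).
#' @param max_iter Maximum number of sweeps (default 100).
#' @param brent_tol Brent x-tolerance for each one-dimensional search.
#' @return List with `tree` (optimized branch lengths), `logLik`, and
#'   `sweeps` performed.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-4,
                                    max_iter = 100, brent_tol = 1e-5) {
  pd <- prep_data(aln)
  pt <- prep_tree(pd, tree)
  fit <- opt_branches_prep(pd, pt, model, tol, max_iter, brent_tol)
  out <- pt$tree
  out$edge.length <- fit$elen
  list(tree = out, logLik = fit$loglik, sweeps = fit$sweeps)
}

opt_alpha_prep <- function(pd, pt, model, elen, brent_tol = 1e-3) {
  f <- function(la) {
    m2 <- update_alpha(model, exp(la))
    total_loglik(pd, pt, m2, elen)
  }
  opt <- optimize(f, c(log(0.02), log(50)), maximum = TRUE, tol = brent_tol)
  list(alpha = exp(opt$maximum), loglik = opt$objective)
}

#' Jointly optimize branch lengths and the gamma shape
#'
#' Alternates Brent optimization of `log(alpha)` on [log 0.02, log 50]
#' with branch-length sweeps until the joint improvement falls below
#' `tol`. With `k = 1` (no rate heterogeneity) alpha is reported as `NA`
#' and only branch lengths are fitted.
#'
#' @param aln Alignment.
#' @param tree `phylo` tree with starting branch lengths.
#' @param model An [aa_model()].
#' @param what Character vector naming what to optimize: any of
#'   "branches", "alpha".
#' @param tol Convergence tolerance on the joint log-likelihood gain.
#' @param max_cycles Maximum alternation cycles.
#' @param brent_tol Brent x-tolerance for branch searches.
#' @return List with `tree`, `model` (updated alpha), `logLik`, `alpha`.
#' @export
optimize_parameters <- function(aln, tree, model,
                                what = c("branches", "alpha"),
                                tol = 1e-4, max_cycles = 10,
                                brent_tol = 1e-5) {
  what <- match.arg(what, several.ok = TRUE)
  pd <- prep_data(aln)
  pt <- prep_tree(pd, tree)
  do_alpha <- "alpha" %in% what && model$k >= 2
  do_br <- "branches" %in% what
  elen <- pmin(pmax(pt$elen, BL_MIN), BL_MAX)
  lnl <- total_loglik(pd, pt, model, elen)
  for (cyc in seq_len(max_cycles)) {
    lnl_start <- lnl
    if (do_br) {
      fit <- opt_branches_prep(pd, pt, model, tol = tol, max_iter = 20,
                               brent_tol = brent_tol)
      elen <- fit$elen
      pt$elen <- elen
      lnl <- fit$loglik
    }
    if (do_alpha) {
      a <- opt_alpha_prep(pd, pt, model, elen)
      if (a$loglik > lnl) {
        model <- update_alpha(model, a$alpha)
        lnl <- a$loglik
      }
    }
    if (lnl - lnl_start < tol) break
  }
  out <- pt$tree
  out$edge.length <- elen
  list(tree = out, model = model, logLik = lnl,
       alpha = if (model$k >= 2) model$alpha else NA_real_)
}

# ---- site rates -------------------------------------------------------

#' Empirical-Bayes posterior-mean site rates
#'
#' For each alignment column, the posterior mean relative rate
#' `sum_m r_m P(m | column)` under the discrete-gamma mixture with equal
#' prior category weights, computed over the supplied tree. The ranking
#' orders sites from fastest to slowest, breaking ties by the smaller
#' column index first.
#'
#' @param aln Alignment.
#' @param tree `phylo` tree with branch lengths (typically the ML tree).
#' @param model An [aa_model()] with `k >= 2`.
#' @return Object of class `site_rates`: list with `rates` (per-column
#'   posterior means) and `ranking` (column indices, fastest first).
#' @export
estimate_site_rates <- function(aln, tree, model) {
  if (model$k < 2)
    stop("site rates undefined without heterogeneity (k must be >= 2)")
  pd <- prep_data(aln)
  pt <- prep_tree(pd, tree)
  ll <- pattern_logliks(pd, pt, model)
  post <- exp(ll - lse_rows(ll))
  post <- post / rowSums(post)
  r_pat <- as.vector(post %*% model$rates)
  rates <- r_pat[pd$site_index]
  structure(list(rates = rates,
                 ranking = order(-rates, seq_along(rates))),
            class = "site_rates")
}

#' @export
print.site_rates <- function(x, ...) {
  cat(sprintf("Site rates for %d columns: mean %.3f, range %.3f-%.3f\n",
              length(x$rates), mean(x$rates), min(x$rates), max(x$rates)))
  invisible(x)
}

# ---- distances and tree search ----------------------------------------

#' Pairwise maximum-likelihood distances
#'
#' For each taxon pair, maximizes the two-sequence likelihood under the
#' given model (gamma mixture included) over the evolutionary distance.
#' Pairs with no overlapping unambiguous sites get the maximum distance.
#'
#' @param aln Alignment.
#' @param model An [aa_model()].
#' @return A `dist` object.
#' @export
ml_pairwise_distances <- function(aln, model) {
  states <- encode_states(aln)
  n <- nrow(states)
  taxa <- rownames(states)
  k <- model$k
  freq <- model$freq
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- states[i, ]; y <- states[j, ]
      ok <- !is.na(x) & !is.na(y)
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- BL_MAX
        next
      }
      cnt <- tabulate((x[ok] - 1L) * 20L + y[ok], nbins = 400)
      use <- which(cnt > 0)
      ri <- ((use - 1L) %/% 20L) + 1L
      f <- function(t) {
        M <- 0
        for (m in seq_len(k)) M <- M + ptrans(model$eig, t * model$rates[m])
        M <- M / k
        sum(cnt[use] * log(freq[ri] * M[use]))
      }
      opt <- optimize(f, c(1e-6, BL_MAX), maximum = TRUE, tol = 1e-5)
      d[i, j] <- d[j, i] <- opt$maximum
    }
  }
  stats::as.dist(d)
}

#' Control settings for the tree search
#'
#' @param tol Log-likelihood convergence tolerance for branch sweeps.
#' @param max_sweeps Maximum branch-optimization sweeps per fit.
#' @param brent_tol Brent x-tolerance for branch searches.
#' @param nni_tol Minimum log-likelihood gain to accept an NNI move.
#' @param nni_sweeps Branch sweeps used when scoring NNI candidates.
#' @param max_nni_rounds Maximum NNI improvement rounds.
#' @param restarts Number of stochastic restarts: after the hill climb
#'   converges, the tree is perturbed by a few random NNI moves (seeded)
#'   and re-climbed; the best result is kept. Helps escape the local
#'   optima NNI-only searches are prone to when a long-branch taxon is
#'   misplaced by the starting tree.
#' @return A named list of class `search_control`.
#' @export
search_control <- function(tol = 1e-3, max_sweeps = 8, brent_tol = 1e-4,
                           nni_tol = 1e-2, nni_sweeps = 1,
                           max_nni_rounds = 30, restarts = 0) {
  structure(list(tol = tol, max_sweeps = max_sweeps, brent_tol = brent_tol,
                 nni_tol = nni_tol, nni_sweeps = nni_sweeps,
                 max_nni_rounds = max_nni_rounds, restarts = restarts),
            class = "search_control")
}

#' Fast search preset for resampling replicates
#'
#' Coarser tolerances and fewer sweeps than [search_control()]; intended
#' for bootstrap replicates and quick screening trees where thousands of
#' searches are run.
#' @export
fast_search <- function() {
  search_control(tol = 5e-2, max_sweeps = 3, brent_tol = 1e-3,
                 nni_tol = 0.1, nni_sweeps = 1, max_nni_rounds = 8)
}

#' Maximum-likelihood tree search (NJ start, NNI hill climbing)
#'
#' Builds a neighbor-joining starting tree from pairwise ML distances
#' (unless a starting `phylo` is supplied), optimizes branch lengths, and
#' hill-climbs over nearest-neighbor-interchange rearrangements: all
#' neighbors of the current tree are scored with a quick branch pass, the
#' best improving move is accepted and refitted, and the search stops
#' when no move gains more than `control$nni_tol` log-likelihood units.
#' The search is deterministic given its inputs.
#'
#' @param aln Alignment with >= 4 taxa.
#' @param model An [aa_model()].
#' @param start Either "nj" or a starting `phylo` tree.
#' @param seed Optional integer seed (the default search is fully
#'   deterministic; the seed only fixes tie-breaking in degenerate
#'   starting configurations).
#' @param control A [search_control()] list.
#' @param optimize_model Also optimize the gamma shape alpha (requires
#'   `k >= 2`).
#' @return List with `tree` (ML tree, unrooted), `logLik`, `model`.
#' @export
ml_tree_search <- function(aln, model, start = "nj", seed = NULL,
                           control = search_control(),
                           optimize_model = FALSE) {
  pd <- prep_data(aln)
  if (length(pd$taxa) < 4) stop("tree search requires at least 4 taxa")
  run <- function() {
    fit_full <- function(tr, mod) {
      pt <- prep_tree(pd, tr)
      fit <- opt_branches_prep(pd, pt, mod, tol = control$tol,
                               max_iter = control$max_sweeps,
                               brent_tol = control$brent_tol)
      out <- pt$tree
      out$edge.length <- fit$elen
      list(tree = out, loglik = fit$loglik)
    }
    fit_sweep <- function(tr, mod) {
      pt <- prep_tree(pd, tr)
      fit <- opt_branches_prep(pd, pt, mod, tol = control$tol,
                               max_iter = 1,
                               brent_tol = control$brent_tol)
      out <- pt$tree
      out$edge.length <- fit$elen
      list(tree = out, loglik = fit$loglik)
    }
    # NNI hill climb (periodic full refits, optional alpha re-fit) from
    # a given starting tree
    climb <- function(tree, model) {
      fit <- fit_full(tree, model)
      tree <- fit$tree
      lnl <- fit$loglik
      if (optimize_model && model$k >= 2) {
        op <- optimize_parameters(aln, tree, model, tol = control$tol,
                                  max_cycles = 2,
                                  brent_tol = control$brent_tol)
        tree <- op$tree; model <- op$model; lnl <- op$logLik
      }
      for (outer in 1:3) {
        lnl_outer <- lnl
        moved <- FALSE
        for (round in seq_len(control$max_nni_rounds)) {
          pt <- prep_tree(pd, tree)
          ud <- updown_pass(pd, pt, model, pt$elen)
          internal <- which(pt$edge[, 2] > pt$ntip)
          best <- NULL
          for (e in internal) {
            for (cand in nni_edge_scores(pd, pt, model, pt$elen, ud, e)) {
              if (cand$score > lnl + control$nni_tol &&
                  (is.null(best) || cand$score > best$score)) best <- cand
            }
          }
          if (is.null(best)) break
          tree <- apply_nni(pt$tree, best$swap, best$edge, best$t)
          fit <- fit_sweep(tree, model)   # quick tidy; full refit below
          tree <- fit$tree
          lnl <- fit$loglik
          moved <- TRUE
        }
        fit <- fit_full(tree, model)
        tree <- fit$tree
        lnl <- fit$loglik
        if (optimize_model && model$k >= 2) {
          op <- optimize_parameters(aln, tree, model, tol = control$tol,
                                    max_cycles = 2,
                                    brent_tol = control$brent_tol)
          tree <- op$tree; model <- op$model; lnl <- op$logLik
        }
        if (!moved || lnl - lnl_outer < max(control$tol, 1e-3)) break
      }
      list(tree = tree, logLik = lnl, model = model)
    }
    # a few seeded random NNI moves, to escape local optima
    perturb <- function(tree, r) {
      with_seed((if (is.null(seed)) 0 else seed) + 7717 * r, {
        for (i in 1:3) {
          pt <- prep_tree(pd, tree)
          internal <- which(pt$edge[, 2] > pt$ntip)
          e <- internal[sample.int(length(internal), 1)]
          u <- pt$edge[e, 1]; v <- pt$edge[e, 2]
          sib <- setdiff(pt$child_edges[[as.character(u)]], e)[1]
          kids <- pt$child_edges[[as.character(v)]]
          kid <- kids[sample.int(length(kids), 1)]
          tree <- apply_nni(pt$tree, c(sib, kid), e, pt$elen[e])
        }
        tree
      })
    }
    if (inherits(start, "phylo")) {
      tree <- start
    } else {
      tree <- ape::nj(ml_pairwise_distances(aln, model))
    }
    tree <- ape::unroot(tree)
    if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length <- pmin(pmax(tree$edge.length, BL_MIN), BL_MAX)
    res <- climb(tree, model)
    restarts <- control$restarts
    if (is.null(restarts)) restarts <- 0
    for (r in seq_len(restarts)) {
      cand <- climb(perturb(res$tree, r), res$model)
      if (cand$logLik > res$logLik + control$tol) res <- cand
    }
    res
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
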