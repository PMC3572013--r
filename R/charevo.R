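# Mk-model ancestral state reconstruction over tree samples: maximum
# likelihood rate estimation with multiple restarts, marginal state
# probabilities at the least-inclusive MRCA of a taxon set, fixed-node
# tests on the 2-log-likelihood criterion, and stochastic character
# mapping with endpoint-conditioned path sampling.

# rate matrix from a rate vector: mk2 uses c(q01, q10); mk3 uses the six
# off-diagonal rates in row order (q01, q02, q10, q12, q20, q21)
mk_Q <- function(rates, k) {
  Q <- matrix(0, k, k)
  Q[row(Q) != col(Q)] <- 0
  idx <- which(row(Q) != col(Q))
  # fill row-wise
  pos <- 1L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    Q[i, j] <- rates[pos]
    pos <- pos + 1L
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# transition probabilities for a k-state Markov chain; closed form for
# k = 2, scaling-and-squaring Taylor expansion otherwise
mk_pmat <- function(Q, t) {
  k <- nrow(Q)
  if (t <= 0) return(diag(k))
  if (k == 2) {
    a <- Q[1, 2]; b <- Q[2, 1]; s <- a + b
    if (s == 0) return(diag(2))
    e <- exp(-s * t)
    P <- matrix(c(b + a * e, a - a * e,
                  b - b * e, a + b * e) / s, 2, 2, byrow = TRUE)
    return(pmax(P, 0))
  }
  A <- Q * t
  s <- max(0L, ceiling(log2(max(1, max(abs(A)) / 0.5))))
  A <- A / 2^s
  P <- diag(k); term <- diag(k)
  for (n in 1:12) {
    term <- term %*% A / n
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P[P < 0] <- 0
  P / rowSums(P)
}

mk_root_prior <- function(Q, root_prior) {
  k <- nrow(Q)
  if (root_prior == "flat") return(rep(1 / k, k))
  # stationary distribution
  v <- Re(eigen(t(Q))$vectors[, which.min(abs(Re(eigen(t(Q))$values)))])
  v <- abs(v)
  v / sum(v)
}

# pruning log-likelihood for a k-state trait; optionally clamp an internal
# node to one state. tip_states: named integer vector in 0..k-1, NA = '?'
mk_loglik <- function(tree, tip_states, Q, root_prior = "flat",
                      clamp_node = NULL, clamp_state = NULL) {
  k <- nrow(Q)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  partial <- matrix(1, nn, k)
  st <- tip_states[tr$tip.label]
  for (i in seq_len(ntip)) {
    if (!is.na(st[i])) {
      partial[i, ] <- 0
      partial[i, st[i] + 1L] <- 1
    }
  }
  logscale <- 0
  done <- rep(FALSE, nn)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (ch > ntip && !done[ch]) stop("edge order violated") # postorder guard
    if (!is.null(clamp_node) && ch == clamp_node) {
      keep <- partial[ch, clamp_state + 1L]
      partial[ch, ] <- 0
      partial[ch, clamp_state + 1L] <- keep
    }
    P <- mk_pmat(Q, tr$edge.length[e])
    partial[p, ] <- partial[p, ] * as.numeric(P %*% partial[ch, ])
    mx <- max(partial[p, ])
    if (mx > 0 && mx < 1e-100) {
      partial[p, ] <- partial[p, ] / mx
      logscale <- logscale + log(mx)
    }
    done[p] <- TRUE
  }
  root <- tr$edge[nrow(tr$edge), 1]
  if (!is.null(clamp_node) && root == clamp_node) {
    keep <- partial[root, clamp_state + 1L]
    partial[root, ] <- 0
    partial[root, clamp_state + 1L] <- keep
  }
  prior <- mk_root_prior(Q, root_prior)
  L <- sum(prior * partial[root, ])
  if (L <= 0) return(-Inf)
  log(L) + logscale
}

n_mk_rates <- function(model) if (model == "mk2") 2L else 6L
mk_k <- function(model) if (model == "mk2") 2L else 3L

#' Fit an Mk model of discrete trait evolution by maximum likelihood
#'
#' Unrestricted transition rates (2 states: q01, q10; 3 states: six free
#' rates) are estimated by bounded quasi-Newton optimization on the log
#' scale with multiple random restarts (default 25). The root prior is
#' flat by default.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tip_states named vector of states (0-based integers; NA or '?'
#'   for missing), names matching tip labels.
#' @param model `"mk2"` (binary) or `"mk3"` (three states).
#' @param ntries number of optimization restarts.
#' @param seed integer seed for the restart draws.
#' @param root_prior `"flat"` or `"stationary"`.
#' @param clamp_node,clamp_state optionally clamp an internal node to a
#'   state during optimization (used by [fixed_state_test()]).
#' @return object of class `mk_fit`: list with `rates`, `Q`, `lnl`,
#'   `model`, `root_prior`.
#' @export
fit_mk <- function(tree, tip_states, model = c("mk2", "mk3"), ntries = 25L,
                   seed = 1L, root_prior = c("flat", "stationary"),
                   clamp_node = NULL, clamp_state = NULL) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  tip_states <- normalize_states(tip_states, mk_k(model))
  if (all(is.na(tip_states))) stop("all tip states are missing")
  set.seed(seed)
  np <- n_mk_rates(model)
  k <- mk_k(model)
  obj <- function(lr) {
    Q <- mk_Q(exp(lr), k)
    -mk_loglik(tree, tip_states, Q, root_prior, clamp_node, clamp_state)
  }
  tot <- sum(tree$edge.length)
  base_rate <- max(0.5 / tot, 1e-4)
  starts <- c(list(rep(log(base_rate), np)),
              replicate(max(0L, ntries - 1L),
                        log(base_rate) + stats::rnorm(np, 0, 2),
                        simplify = FALSE))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, obj, method = "L-BFGS-B",
                            lower = log(1e-8), upper = log(100)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("Mk optimization failed from all starts")
  rates <- exp(best$par)
  structure(list(rates = rates, Q = mk_Q(rates, k), lnl = -best$value,
                 model = model, root_prior = root_prior, k = k),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk", x$k, "-state fit: lnL =", format(x$lnl, digits = 6), "\n")
  cat("  rates:", format(signif(x$rates, 4)), "\n")
  invisible(x)
}

normalize_states <- function(x, k) {
  nm <- names(x)
  if (is.character(x)) x[x == "?"] <- NA
  x <- suppressWarnings(as.integer(x))
  names(x) <- nm
  if (any(!is.na(x) & (x < 0 | x >= k)))
    stop("states must lie in 0..", k - 1)
  x
}

# marginal state probabilities at one internal node, rates fixed:
# clamp the node to each state in turn and normalize the likelihoods
mk_node_marginal <- function(tree, tip_states, Q, root_prior, node) {
  k <- nrow(Q)
  ll <- vapply(seq_len(k) - 1L, function(s)
    mk_loglik(tree, tip_states, Q, root_prior, node, s), 0)
  w <- exp(ll - max(ll))
  list(prob = w / sum(w), lnl_fixed = ll)
}

#' Ancestral state at the least-inclusive MRCA over a tree sample
#'
#' For each tree the target node is the least-inclusive common ancestor of
#' the named taxa (which may subtend additional taxa when the set is not
#' monophyletic on that tree). Rates are estimated per tree, the marginal
#' state probability at the target node is computed by clamping, and means
#' across trees are reported. Trees missing any named taxon are skipped
#' with a warning.
#'
#' @param trees a `multiPhylo`/list of rooted trees (unrooted trees are
#'   midpoint-rooted).
#' @param taxa character vector of taxon names defining the target clade.
#' @param tip_states named state vector (see [fit_mk()]).
#' @param model `"mk2"` or `"mk3"`.
#' @param ntries optimization restarts per tree.
#' @param seed integer seed.
#' @param root_prior root prior.
#' @return object of class `asr_result`: `per_tree` data frame (tree, node,
#'   subtended tip count, state probabilities, free and fixed -lnL) and
#'   `mean_prob` (mean state probabilities across trees).
#' @export
mrca_state_probability <- function(trees, taxa, tip_states,
                                   model = c("mk2", "mk3"), ntries = 25L,
                                   seed = 1L,
                                   root_prior = c("flat", "stationary")) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  if (inherits(trees, "phylo")) trees <- list(trees)
  k <- mk_k(model)
  rows <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!all(taxa %in% tr$tip.label)) {
      warning("tree ", i, " is missing named taxa; skipped")
      next
    }
    if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
    st <- normalize_states(tip_states, k)
    fit <- fit_mk(tr, st, model, ntries, seed + i, root_prior)
    node <- if (length(taxa) == 1) {
      which(tr$tip.label == taxa)
    } else ape::getMRCA(tr, taxa)
    marg <- mk_node_marginal(tr, st, fit$Q, root_prior, node)
    nsub <- length(clade_tips(tr, node))
    rows[[length(rows) + 1L]] <- c(tree = i, node = node, ntips = nsub,
                                   stats::setNames(marg$prob,
                                                   paste0("P", 0:(k - 1))),
                                   lnl_free = fit$lnl,
                                   stats::setNames(-marg$lnl_fixed,
                                                   paste0("neg_lnl_", 0:(k - 1))))
  }
  if (length(rows) == 0) stop("no usable trees")
  per_tree <- as.data.frame(do.call(rbind, rows))
  mean_prob <- colMeans(per_tree[, paste0("P", 0:(k - 1)), drop = FALSE])
  structure(list(per_tree = per_tree, mean_prob = mean_prob, taxa = taxa,
                 model = model),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Ancestral state at least-inclusive MRCA of",
      length(x$taxa), "taxa over", nrow(x$per_tree), "trees\n")
  cat("  mean state probabilities:",
      paste(names(x$mean_prob), format(round(x$mean_prob, 4)), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge)))
    below[[tr$edge[e, 1]]] <- c(below[[tr$edge[e, 1]]], below[[tr$edge[e, 2]]])
  below[[node]]
}

#' Fixed-node support test for an ancestral state
#'
#' For each tree the target node is clamped to each state in turn, rates
#' are re-optimized under the clamp, and the means of the resulting
#' negative log-likelihoods are compared. A difference of two
#' log-likelihood units or more is taken as significant support for the
#' better state.
#'
#' @inheritParams mrca_state_probability
#' @return list with `mean_neg_lnl` (per state), `delta` (largest pairwise
#'   difference of the two best states for k = 2; max - min generally),
#'   `best_state`, `significant` (delta >= 2) and `per_tree`.
#' @export
fixed_state_test <- function(trees, taxa, tip_states,
                             model = c("mk2", "mk3"), ntries = 25L,
                             seed = 1L, root_prior = c("flat", "stationary")) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  if (inherits(trees, "phylo")) trees <- list(trees)
  k <- mk_k(model)
  res <- matrix(NA_real_, 0, k)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!all(taxa %in% tr$tip.label)) {
      warning("tree ", i, " is missing named taxa; skipped")
      next
    }
    if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
    st <- normalize_states(tip_states, k)
    node <- if (length(taxa) == 1) which(tr$tip.label == taxa)
            else ape::getMRCA(tr, taxa)
    ll <- vapply(0:(k - 1), function(s) {
      fit <- fit_mk(tr, st, model, ntries, seed + i * 131L + s, root_prior,
                    clamp_node = node, clamp_state = s)
      -fit$lnl
    }, 0)
    res <- rbind(res, ll)
  }
  if (nrow(res) == 0) stop("no usable trees")
  m <- colMeans(res)
  names(m) <- paste0("state", 0:(k - 1))
  delta <- max(m) - min(m)
  if (k > 2) {
    o <- sort(m)
    delta_best <- o[2] - o[1]
  } else delta_best <- delta
  list(mean_neg_lnl = m, delta = unname(delta_best),
       best_state = as.integer(which.min(m)) - 1L,
       significant = delta_best >= 2, per_tree = res)
}

#' Forward simulation of a discrete trait on a tree
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param Q k x k rate matrix.
#' @param seed integer seed.
#' @param root_prior `"flat"`, `"stationary"`, or a probability vector.
#' @return list with `tip_states` (named, 0-based), `node_states`,
#'   `n_changes`, `change_counts` (k x k matrix).
#' @export
simulate_mk <- function(tree, Q, seed = 1L, root_prior = "flat") {
  set.seed(seed)
  k <- nrow(Q)
  prior <- if (is.numeric(root_prior)) root_prior
           else mk_root_prior(Q, root_prior)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  states <- integer(ntip + tr$Nnode)
  states[ntip + 1L] <- sample.int(k, 1, prob = prior)
  counts <- matrix(0L, k, k)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    s <- states[p]; t_rem <- tr$edge.length[e]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      dt <- stats::rexp(1, rate)
      if (dt > t_rem) break
      t_rem <- t_rem - dt
      s_new <- sample.int(k, 1, prob = pmax(Q[s, ], 0) *
                            (seq_len(k) != s))
      counts[s, s_new] <- counts[s, s_new] + 1L
      s <- s_new
    }
    states[ch] <- s
  }
  list(tip_states = stats::setNames(states[seq_len(ntip)] - 1L, tr$tip.label),
       node_states = states[(ntip + 1L):(ntip + tr$Nnode)] - 1L,
       n_changes = sum(counts), change_counts = counts)
}

# endpoint-conditioned CTMC path: rejection sampling with a uniformization
# fallback; returns the k x k matrix of realized change counts
sample_path_counts <- function(a, b, t, Q, Pt, max_attempts = 100L) {
  k <- nrow(Q)
  for (att in seq_len(max_attempts)) {
    s <- a; t_rem <- t
    counts <- matrix(0L, k, k)
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      dt <- stats::rexp(1, rate)
      if (dt > t_rem) break
      t_rem <- t_rem - dt
      s_new <- sample.int(k, 1, prob = pmax(Q[s, ], 0) * (seq_len(k) != s))
      counts[s, s_new] <- counts[s, s_new] + 1L
      s <- s_new
    }
    if (s == b) return(counts)
  }
  sample_path_unif(a, b, t, Q, Pt)
}

sample_path_unif <- function(a, b, t, Q, Pt) {
  k <- nrow(Q)
  omega <- max(-diag(Q)) + 1e-10
  R <- diag(k) + Q / omega
  pab <- max(Pt[a, b], 1e-300)
  u <- stats::runif(1)
  Rn <- list(diag(k))
  cum <- 0; n <- -1L
  repeat {
    n <- n + 1L
    if (n > 0) Rn[[n + 1L]] <- Rn[[n]] %*% R
    pn <- stats::dpois(n, omega * t) * Rn[[n + 1L]][a, b] / pab
    cum <- cum + pn
    if (u <= cum || n >= 500L) break
  }
  counts <- matrix(0L, k, k)
  if (n == 0L) return(counts)
  states <- integer(n + 1L)
  states[1] <- a; states[n + 1L] <- b
  if (n > 1) for (i in 2:n) {
    w <- R[states[i - 1L], ] * Rn[[n - i + 2L]][, b]
    states[i] <- sample.int(k, 1, prob = pmax(w, 0))
  }
  for (i in seq_len(n)) {
    if (states[i] != states[i + 1L])
      counts[states[i], states[i + 1L]] <- counts[states[i], states[i + 1L]] + 1L
  }
  counts
}

#' Stochastic character mapping: mean numbers of state changes
#'
#' Conditional character histories are sampled on each tree (node states
#' from their joint conditional distribution, branch paths by
#' endpoint-conditioned simulation), and change counts are averaged over
#' `n_maps` mappings per tree and over trees. For a binary character the
#' 0-to-1 changes are gains and 1-to-0 changes losses. A matrix or data
#' frame of several characters (e.g. additive binary coding) is mapped
#' per character.
#'
#' @param trees rooted tree(s).
#' @param tip_states named state vector, or a matrix/data frame with one
#'   column per character.
#' @param model `"mk2"` or `"mk3"`.
#' @param n_maps mappings per tree (default 50).
#' @param seed integer seed.
#' @param rates optional fixed rate vector; when NULL rates are estimated
#'   per tree.
#' @param ntries restarts for rate estimation.
#' @param root_prior root prior.
#' @return object of class `simmap_counts`: `mean_changes` (total), `mean_counts`
#'   (k x k), and for binary models `gains` and `losses`; for multi-character
#'   input a named list of such objects.
#' @export
stochastic_map_counts <- function(trees, tip_states, model = c("mk2", "mk3"),
                                  n_maps = 50L, seed = 1L, rates = NULL,
                                  ntries = 25L,
                                  root_prior = c("flat", "stationary")) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  if (is.matrix(tip_states) || is.data.frame(tip_states)) {
    tip_states <- as.matrix(tip_states)
    out <- lapply(seq_len(ncol(tip_states)), function(j)
      stochastic_map_counts(trees, tip_states[, j], model, n_maps,
                            seed + 7919L * j, rates, ntries, root_prior))
    names(out) <- colnames(tip_states)
    return(out)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  k <- mk_k(model)
  st_all <- normalize_states(tip_states, k)
  per_tree <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
    set.seed(seed + i * 104729L)
    if (is.null(rates)) {
      fit <- fit_mk(tr, st_all, model, ntries, seed + i, root_prior)
      Q <- fit$Q
    } else Q <- mk_Q(rates, k)
    if (all(Q == 0) && length(unique(stats::na.omit(st_all))) > 1)
      stop("zero rates are incompatible with variable tip states")
    per_tree[[i]] <- simmap_one_tree(tr, st_all, Q, n_maps, root_prior)
  }
  mean_counts <- Reduce(`+`, per_tree) / length(per_tree)
  out <- list(mean_counts = mean_counts, mean_changes = sum(mean_counts),
              n_maps = n_maps, n_trees = length(per_tree))
  if (k == 2) {
    out$gains <- mean_counts[1, 2]
    out$losses <- mean_counts[2, 1]
  }
  structure(out, class = "simmap_counts")
}

#' @export
print.simmap_counts <- function(x, ...) {
  cat("Stochastic mapping:", x$n_maps, "maps x", x$n_trees, "trees; mean",
      format(round(x$mean_changes, 3)), "changes per tree\n")
  if (!is.null(x$gains))
    cat("  gains (0->1):", format(round(x$gains, 3)),
        " losses (1->0):", format(round(x$losses, 3)), "\n")
  invisible(x)
}

# mean k x k change-count matrix over n_maps mappings on one tree
simmap_one_tree <- function(tree, tip_states, Q, n_maps, root_prior) {
  k <- nrow(Q)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  # down partials (no scaling needed at these sizes; guard anyway)
  partial <- matrix(1, nn, k)
  st <- tip_states[tr$tip.label]
  for (i in seq_len(ntip)) if (!is.na(st[i])) {
    partial[i, ] <- 0; partial[i, st[i] + 1L] <- 1
  }
  nedge <- nrow(tr$edge)
  Pmats <- vector("list", nedge)
  for (e in seq_len(nedge)) {
    Pmats[[e]] <- mk_pmat(Q, tr$edge.length[e])
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    partial[p, ] <- partial[p, ] * as.numeric(Pmats[[e]] %*% partial[ch, ])
    mx <- max(partial[p, ])
    if (mx > 0) partial[p, ] <- partial[p, ] / mx
  }
  root <- tr$edge[nedge, 1]
  prior <- mk_root_prior(Q, if (is.character(root_prior)) root_prior else "flat")
  acc <- matrix(0, k, k)
  # edges in preorder for forward sampling
  pre <- rev(seq_len(nedge))
  for (m in seq_len(n_maps)) {
    node_state <- integer(nn)
    w <- prior * partial[root, ]
    node_state[root] <- sample.int(k, 1, prob = w)
    counts <- matrix(0L, k, k)
    for (e in pre) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      wch <- Pmats[[e]][node_state[p], ] * partial[ch, ]
      node_state[ch] <- sample.int(k, 1, prob = pmax(wch, 0))
      counts <- counts + sample_path_counts(node_state[p], node_state[ch],
                                            tr$edge.length[e], Q, Pmats[[e]])
    }
    acc <- acc + counts
  }
  acc / n_maps
}

#' Additive binary recoding of the three-state stipe-covering character
#'
#' State 0 ('hair-like only') becomes (1, 0); state 1 ('hairs and
#' lecythiform') becomes (1, 1); state 2 ('lecythiform only') becomes
#' (0, 1). Missing states recode to missing in both characters.
#'
#' @param states named vector with values 0, 1, 2 (NA or '?' for missing).
#' @return matrix with columns `hair` and `lecythiform` (0/1/NA).
#' @export
additive_binary_recode <- function(states) {
  st <- normalize_states(states, 3L)
  hair <- ifelse(is.na(st), NA_integer_, as.integer(st %in% c(0L, 1L)))
  lecy <- ifelse(is.na(st), NA_integer_, as.integer(st %in% c(1L, 2L)))
  cbind(hair = stats::setNames(hair, names(st)), lecythiform = lecy)
}
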