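# GY94 codon substitution site models: M7 (beta-distributed omega, neutral)
# versus M8 (beta plus a positive-selection class omega_s > 1), fitted by
# maximum likelihood on a neighbor-joining tree, compared by a df = 2
# likelihood-ratio test, with empirical-Bayes per-site selection posteriors.
#
# Numerical scheme: F3x4 codon frequencies (positional frequencies floored at
# 1e-4 and renormalized so the reversible rate matrix stays irreducible);
# beta discretized into K equal-probability classes by class-mean omega;
# transition probabilities via symmetrized eigendecomposition of the 61-state
# rate matrix; branch lengths taken from the NJ tree (JC nucleotide distances
# converted to per-codon units) and rescaled by a single jointly-optimized
# tree-scale factor; a fixed 3-point multi-start schedule makes fits
# deterministic without a seed.

.gy_env <- new.env(parent = emptyenv())

#' Neighbor-joining tree from JC-corrected nucleotide distances
#'
#' @param alignment a \code{codon_alignment} with >= 3 sequences.
#' @return an unrooted \code{ape::phylo}; negative branch lengths clamped
#'   to 0; branch lengths in nucleotide substitutions per site.
#' @export
build_nj_tree <- function(alignment) {
  m <- aln_matrix(alignment)
  if (nrow(m) < 3L) stop("insufficient-data error: NJ needs >= 3 sequences")
  d <- pairwise_diff_matrix(m) / ncol(m)
  if (any(d >= 0.75)) stop("distance error: saturated pair (p >= 3/4)")
  dd <- -0.75 * log(1 - 4 * d / 3)
  tree <- ape::nj(stats::as.dist(dd))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# --- GY94 structural tables (built once) ------------------------------------

gy94_structure <- function() {
  if (!is.null(.gy_env$struct)) return(.gy_env$struct)
  ct <- codon_table()
  sense <- sense_codons()
  n <- length(sense)
  chars <- do.call(rbind, strsplit(sense, ""))
  single <- matrix(FALSE, n, n)
  ts <- matrix(FALSE, n, n)       # transition (A<->G, C<->T)
  nonsyn <- matrix(FALSE, n, n)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(chars[i, ] != chars[j, ])
      if (length(diff) == 1L) {
        single[i, j] <- TRUE
        ts[i, j] <- purine[chars[i, diff]] == purine[chars[j, diff]]
        nonsyn[i, j] <- ct[sense[i]] != ct[sense[j]]
      }
    }
  }
  .gy_env$struct <- list(sense = sense, single = single, ts = ts,
                         nonsyn = nonsyn, n = n,
                         idx_single = which(single),
                         idx_ts = which(single & ts),
                         idx_nonsyn = which(single & nonsyn),
                         col_of = as.vector(col(single)))
  .gy_env$struct
}

#' F3x4 codon frequencies of an alignment
#'
#' Positional nucleotide frequencies (floored at 1e-4, renormalized) combined
#' multiplicatively over the three codon positions, restricted to sense
#' codons and normalized.
#'
#' @param alignment a \code{codon_alignment}.
#' @return named numeric vector over the 61 sense codons, summing to 1.
#' @export
gy94_f3x4 <- function(alignment) {
  m <- aln_matrix(alignment)
  L <- ncol(m)
  pos <- ((seq_len(L) - 1L) %% 3L) + 1L
  freq <- sapply(1:3, function(p) {
    f <- table(factor(m[, pos == p], levels = .BASES))
    f <- pmax(as.numeric(f) / sum(f), 1e-4)
    f / sum(f)
  })
  rownames(freq) <- .BASES
  st <- gy94_structure()
  chars <- do.call(rbind, strsplit(st$sense, ""))
  pi <- freq[chars[, 1], 1] * freq[chars[, 2], 2] * freq[chars[, 3], 3]
  pi <- pi / sum(pi)
  names(pi) <- st$sense
  pi
}

# unscaled GY94 rate matrix for one (omega, kappa); diag set to -rowsum
gy94_Q <- function(omega, kappa, pi) {
  st <- gy94_structure()
  Q <- matrix(0, st$n, st$n)
  Q[st$idx_single] <- 1
  Q[st$idx_ts] <- kappa
  Q[st$idx_nonsyn] <- Q[st$idx_nonsyn] * omega
  Q[st$idx_single] <- Q[st$idx_single] * pi[st$col_of[st$idx_single]]
  diag(Q) <- -rowSums(Q)
  Q
}

# eigendecomposition of a reversible Q; returns fast P(t) evaluator pieces
gy94_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))      # B = D Q D^-1, symmetric
  B <- (B + t(B)) / 2             # symmetrize numerically
  e <- eigen(B, symmetric = TRUE)
  list(vals = e$values,
       V = e$vectors / sq,        # D^-1 U  (row scaling)
       W = t(e$vectors) * rep(sq, each = length(pi)))  # U' D
}

gy94_pmat <- function(ed, t) {
  P <- ed$V %*% (exp(ed$vals * t) * ed$W)
  P[P < 0] <- 0
  P / rowSums(P)
}

# class-mean discretization of Beta(p, q) into K equal-probability bins
beta_class_means <- function(p, q, K) {
  br <- suppressWarnings(qbeta(seq(0, 1, length.out = K + 1L), p, q))
  means <- K * (p / (p + q)) * (pbeta(br[-1], p + 1, q) - pbeta(br[-(K + 1L)], p + 1, q))
  pmin(pmax(means, 1e-8), 1 - 1e-8)
}

# omega classes and weights for M7 / M8
site_model_classes <- function(model, pars, K) {
  om <- beta_class_means(pars$p, pars$q, K)
  if (model == "M7") {
    list(omega = om, weight = rep(1 / K, K))
  } else {
    list(omega = c(om, pars$omega_s),
         weight = c(rep((1 - pars$p1) / K, K), pars$p1))
  }
}

# --- likelihood machinery ----------------------------------------------------

# codon state matrix (taxa x sites, indices into sense codons) + patterns
codon_states <- function(alignment) {
  st <- gy94_structure()
  cm <- codon_matrix(alignment)
  idx <- match(cm, st$sense)
  if (anyNA(idx)) {
    bad <- which(is.na(idx), arr.ind = FALSE)[1]
    stop("translation error: stop codon '", cm[bad], "' in alignment")
  }
  s <- matrix(idx, nrow(cm), ncol(cm), dimnames = list(rownames(cm), NULL))
  key <- apply(s, 2L, paste0, collapse = ",")
  u <- !duplicated(key)
  list(states = s[, u, drop = FALSE],
       weight = as.numeric(table(key)[key[u]]),
       map = match(key, key[u]),
       n_sites = ncol(s))
}

# per-site log-likelihood under one omega class (Felsenstein pruning).
# `leaf_cols`: per tip, the state index per pattern (used to index P columns
# directly, avoiding explicit indicator matrices).  Scalar rescaling per
# edge keeps the computation in range; the same constant is added back to
# every pattern, so the result is exact.
class_site_loglik <- function(ed, tree_post, edge_len, leaf_cols, pi) {
  ntip <- length(tree_post$tip.label)
  nnode <- ntip + tree_post$Nnode
  L <- vector("list", nnode)
  logsc <- 0
  E <- tree_post$edge
  for (k in seq_len(nrow(E))) {
    child <- E[k, 2L]; parent <- E[k, 1L]
    # P %*% Lc computed in the eigenbasis: V e^{vals t} (W Lc); for leaves
    # W Lc is a column gather of W
    tmp <- if (child <= ntip) {
      ed$W[, leaf_cols[[child]], drop = FALSE]
    } else {
      ed$W %*% L[[child]]
    }
    part <- ed$V %*% (exp(ed$vals * edge_len[k]) * tmp)
    part[part < 0] <- 0
    mx <- max(part)
    if (mx <= 0) mx <- 1e-300
    part <- part / mx
    logsc <- logsc + log(mx)
    L[[parent]] <- if (is.null(L[[parent]])) part else L[[parent]] * part
  }
  root <- E[nrow(E), 1L]
  lik <- colSums(pi * L[[root]])
  log(pmax(lik, 1e-300)) + logsc
}

# full mixture log-likelihood; optionally return per-class pattern matrices
gy94_loglik <- function(pars, model, K, data, tree_post, base_len, pi,
                        details = FALSE) {
  cls <- site_model_classes(model, pars, K)
  Qs <- lapply(seq_along(cls$omega), function(k) gy94_Q(cls$omega[k], pars$kappa, pi))
  rates <- vapply(Qs, function(Q) -sum(pi * diag(Q)), 0)
  mu <- sum(cls$weight * rates)
  edge_len <- base_len * pars$scale / mu   # branch lengths in subs/codon
  npat <- length(data$weight)
  logL <- matrix(NA_real_, length(cls$omega), npat)
  for (k in seq_along(cls$omega)) {
    ed <- gy94_eigen(Qs[[k]], pi)
    logL[k, ] <- class_site_loglik(ed, tree_post, edge_len, data$leaf_cols, pi)
  }
  m <- apply(logL, 2L, max)
  site_log <- m + log(colSums(cls$weight * exp(sweep(logL, 2L, m, "-"))))
  total <- sum(site_log * data$weight)
  if (!details) return(total)
  list(loglik = total, class_loglik = logL, classes = cls,
       site_log = site_log, edge_len = edge_len)
}

# transform helpers
.sm_pack <- function(pars, model) {
  v <- c(log(pars$kappa), log(pars$p), log(pars$q), log(pars$scale))
  if (model == "M8") v <- c(v, stats::qlogis(pars$p1), log(pars$omega_s - 1))
  v
}
.sm_unpack <- function(v, model) {
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  pars <- list(kappa = clamp(exp(v[1]), 1e-3, 1e3),
               p = clamp(exp(v[2]), 0.005, 99),
               q = clamp(exp(v[3]), 0.005, 99),
               scale = clamp(exp(v[4]), 1e-6, 1e4))
  if (model == "M8") {
    pars$p1 <- stats::plogis(v[5])
    pars$omega_s <- 1 + exp(v[6])
  }
  pars
}

#' Fit a GY94 site model (M7 or M8) by maximum likelihood
#'
#' @param alignment in-frame, stop-free \code{codon_alignment}.
#' @param tree optional \code{phylo} (default: \code{build_nj_tree}); branch
#'   lengths interpreted as nucleotide substitutions/site and converted to
#'   codon units, then rescaled by a free tree-scale parameter.
#' @param model \code{"M7"} or \code{"M8"}.
#' @param K number of beta discretization classes (>= 5; default 10).
#' @param maxit optimizer iteration cap per start.
#' @return object of class \code{site_model_fit}: \code{model_label},
#'   \code{log_likelihood}, \code{parameters}, \code{omega_classes}
#'   (values/weights), \code{tree}, \code{converged}, plus internal
#'   per-site class likelihoods used by \code{\link{site_posteriors}}.
#' @export
fit_site_model <- function(alignment, tree = NULL, model = c("M8", "M7"),
                           K = 10L, maxit = 300L) {
  model <- match.arg(model)
  if (K < 5L) stop("domain error: K must be >= 5")
  if (is.null(tree)) tree <- build_nj_tree(alignment)
  tree_post <- ape::reorder.phylo(tree, "postorder")
  data <- codon_states(alignment)
  # row r of the state matrix must correspond to tip number r of the tree
  perm <- match(tree_post$tip.label, rownames(data$states))
  if (anyNA(perm)) stop("domain error: tree tips do not match allele ids")
  data$states <- data$states[perm, , drop = FALSE]
  data$leaf_cols <- lapply(seq_len(nrow(data$states)),
                           function(r) data$states[r, ])
  pi <- gy94_f3x4(alignment)
  base_len <- pmax(tree_post$edge.length * 3, 1e-8)  # nt/site -> subs/codon
  starts <- list(list(kappa = 2, p = 0.5, q = 0.5, scale = 1, p1 = 0.10, omega_s = 3),
                 list(kappa = 2, p = 2.0, q = 2.0, scale = 1, p1 = 0.30, omega_s = 6),
                 list(kappa = 5, p = 0.2, q = 1.0, scale = 0.5, p1 = 0.05, omega_s = 2))
  if (model == "M8") {
    # near-M7 start guarantees the nested optimum is reachable
    starts <- c(starts, list(list(kappa = 2, p = 0.5, q = 0.5, scale = 1,
                                  p1 = 0.01, omega_s = 1.05)))
  }
  fn <- function(v) {
    pars <- .sm_unpack(v, model)
    ll <- tryCatch(gy94_loglik(pars, model, K, data, tree_post, base_len, pi),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # coarse pass over the fixed start grid with a cheap discretization,
  # then polish the best start at full K
  K_coarse <- min(K, 5L)
  fn_coarse <- function(v) {
    pars <- .sm_unpack(v, model)
    ll <- tryCatch(gy94_loglik(pars, model, K_coarse, data, tree_post, base_len, pi),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  coarse <- list()
  for (s0 in starts) {
    v0 <- .sm_pack(s0, model)
    opt <- tryCatch(optim(v0, fn_coarse, method = "BFGS",
                          control = list(maxit = ceiling(maxit / 6), reltol = 1e-6)),
                    error = function(e) NULL)
    if (!is.null(opt)) coarse[[length(coarse) + 1L]] <- opt
  }
  if (length(coarse) == 0L) stop("convergence error: all optimizer starts failed")
  ord <- order(vapply(coarse, `[[`, 0, "value"))
  best <- NULL
  for (idx in utils::head(ord, 2L)) {
    opt <- tryCatch(optim(coarse[[idx]]$par, fn, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-9)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("convergence error: polish stage failed")
  conv <- best$convergence == 0
  if (model == "M8") {
    # boundary-aware step: when the selection-class weight collapses, BFGS
    # stalls short of the nested (M7) optimum; profile the shared
    # parameters with p1 pinned at the boundary and keep the better fit
    p1_hat <- .sm_unpack(best$par, "M8")$p1
    if (p1_hat < 1e-2) {
      fn_bound <- function(v4) {
        pars <- .sm_unpack(c(v4, stats::qlogis(1e-9), 0), "M8")
        ll <- tryCatch(gy94_loglik(pars, "M8", K, data, tree_post, base_len, pi),
                       error = function(e) -Inf)
        if (!is.finite(ll)) 1e10 else -ll
      }
      ob <- tryCatch(optim(best$par[1:4], fn_bound, method = "BFGS",
                           control = list(maxit = maxit, reltol = 1e-9)),
                     error = function(e) NULL)
      if (!is.null(ob) && ob$value < best$value) {
        best <- list(par = c(ob$par, stats::qlogis(1e-9), 0),
                     value = ob$value, convergence = ob$convergence)
        conv <- ob$convergence == 0
      }
    }
  }
  if (!conv) warning("convergence error: iteration cap reached; best-so-far fit returned")
  pars <- .sm_unpack(best$par, model)
  det <- gy94_loglik(pars, model, K, data, tree_post, base_len, pi, details = TRUE)
  fitted_tree <- tree_post
  fitted_tree$edge.length <- det$edge_len
  structure(list(model_label = model,
                 log_likelihood = det$loglik,
                 parameters = pars,
                 omega_classes = det$classes,
                 tree = fitted_tree,
                 K = as.integer(K),
                 converged = conv,
                 data_key = paste(sort(alignment$allele_ids), collapse = "|"),
                 n_codons = alignment$codon_count,
                 .class_loglik = det$class_loglik,
                 .pattern_map = data$map,
                 .pattern_weight = data$weight),
            class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.3f | kappa = %.2f, beta(p = %.3f, q = %.3f)",
              x$model_label, x$log_likelihood, x$parameters$kappa,
              x$parameters$p, x$parameters$q))
  if (x$model_label == "M8") {
    cat(sprintf(", p1 = %.3f, omega_s = %.2f", x$parameters$p1,
                x$parameters$omega_s))
  }
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio test of M8 versus M7
#'
#' @param m7,m8 \code{site_model_fit}s on the same alignment and tree.
#' @param tol negative statistics larger than \code{-tol} are clamped to 0.
#' @return object of class \code{lrt_result}: \code{statistic}, \code{df}
#'   (2), \code{p}.
#' @export
lrt <- function(m7, m8, tol = 0.1) {
  if (m7$model_label != "M7" || m8$model_label != "M8") {
    stop("domain error: lrt(m7, m8) expects an M7 and an M8 fit")
  }
  if (m7$data_key != m8$data_key) stop("domain error: fits are on different data")
  stat <- 2 * (m8$log_likelihood - m7$log_likelihood)
  if (stat < 0) {
    if (stat < -tol) {
      warning("M8 log-likelihood below M7 by more than tolerance (",
              round(stat, 4), "); clamped to 0")
    }
    stat <- 0
  }
  structure(list(statistic = stat, df = 2L,
                 p = pchisq(stat, df = 2, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT = %.3f, df = %d, p = %.3g\n", x$statistic, x$df, x$p))
  invisible(x)
}

#' Empirical-Bayes per-site positive-selection posteriors (M8)
#'
#' @param m8 a fitted M8 \code{site_model_fit}.
#' @param threshold significance level; a site is called selected when its
#'   posterior mass on omega > 1 classes is at least \code{1 - threshold}.
#' @return list with \code{posterior} (probability of the omega > 1 class per
#'   site, 1-based codon index) and \code{selected_sites}.
#' @export
site_posteriors <- function(m8, threshold = 0.05) {
  if (m8$model_label != "M8") stop("domain error: need an M8 fit")
  cls <- m8$omega_classes
  logL <- m8$.class_loglik
  wlog <- log(cls$weight) + logL
  mx <- apply(wlog, 2L, max)
  post <- exp(sweep(wlog, 2L, mx, "-"))
  post <- sweep(post, 2L, colSums(post), "/")
  sel_mass_pat <- colSums(post[cls$omega > 1, , drop = FALSE])
  sel_mass <- sel_mass_pat[m8$.pattern_map]
  selected <- which(sel_mass >= 1 - threshold)
  list(posterior = sel_mass, selected_sites = selected,
       threshold = threshold)
}

#' Simulate codon evolution under GY94 along a tree
#'
#' Root states are drawn from the stationary codon frequencies and evolved
#' along each branch with the class-specific transition matrices.  Used for
#' parameter-recovery and calibration testing.
#'
#' @param tree a \code{phylo} with branch lengths in expected nucleotide
#'   substitutions per site (converted to codon units internally).
#' @param n_codons number of codon sites.
#' @param omega_site numeric vector (length \code{n_codons} or 1) of per-site
#'   omega values.
#' @param kappa transition/transversion rate ratio.
#' @param pi codon frequencies (default uniform over sense codons).
#' @param seed RNG seed.
#' @return a \code{codon_alignment} of the tip sequences; attribute
#'   \code{omega_site} records the simulated per-site omega.
#' @export
simulate_gy94 <- function(tree, n_codons, omega_site = 1, kappa = 2,
                          pi = NULL, seed = 1L) {
  set.seed(seed)
  st <- gy94_structure()
  if (is.null(pi)) pi <- setNames(rep(1 / st$n, st$n), st$sense)
  omega_site <- rep_len(omega_site, n_codons)
  tree_post <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree_post$tip.label)
  E <- tree_post$edge
  root <- E[nrow(E), 1L]
  base_len <- pmax(tree_post$edge.length * 3, 0)
  omegas <- sort(unique(omega_site))
  # common mixture-average rate scaling (matching the fitted model): branch
  # lengths are expected substitutions per codon averaged over sites, so
  # high-omega sites genuinely evolve faster
  Qs <- lapply(omegas, function(w) gy94_Q(w, kappa, pi))
  site_w <- vapply(omegas, function(w) mean(omega_site == w), 0)
  mu_mix <- sum(site_w * vapply(Qs, function(Q) -sum(pi * diag(Q)), 0))
  eds <- lapply(Qs, function(Q) gy94_eigen(Q / mu_mix, pi))
  names(eds) <- as.character(omegas)
  nodes_seq <- matrix(NA_integer_, ntip + tree_post$Nnode, n_codons)
  nodes_seq[root, ] <- sample.int(st$n, n_codons, replace = TRUE, prob = pi)
  for (k in rev(seq_len(nrow(E)))) {   # preorder: parents before children
    parent <- E[k, 1L]; child <- E[k, 2L]
    out <- integer(n_codons)
    for (w in omegas) {
      idx <- which(omega_site == w)
      P <- gy94_pmat(eds[[as.character(w)]], base_len[k])
      cur <- nodes_seq[parent, idx]
      out[idx] <- vapply(cur, function(s) sample.int(st$n, 1L, prob = P[s, ]), 0L)
    }
    nodes_seq[child, ] <- out
  }
  seqs <- apply(nodes_seq[seq_len(ntip), , drop = FALSE], 1L,
                function(s) paste0(st$sense[s], collapse = ""))
  aln <- codon_alignment(seqs, allele_ids = tree_post$tip.label)
  attr(aln, "omega_site") <- omega_site
  aln
}
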