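# Archetypal analysis of the descriptor matrix.
#
# Finds k extreme behavioral profiles (archetypes) Z such that every
# animal's descriptor vector is approximated by a convex combination of
# them: minimize ||X - A Z||_F^2 with the rows of A (the per-animal
# composition weights) on the probability simplex, and each archetype
# itself a convex combination of the data, Z = D X with simplex rows D.
# Fitted by alternating simplex-constrained least squares with multiple
# seeded restarts.

# Lawson-Hanson active-set non-negative least squares,
# min ||b - A x|| s.t. x >= 0. Handles underdetermined systems (the
# passive set never exceeds nrow(A)); rank-deficient passive-set solves
# fall back to pivoted least squares with dropped coefficients at 0.
.nnls <- function(A, b, maxiter = NULL) {
  n <- ncol(A)
  maxiter <- maxiter %||% max(50L, 5L * n)
  tol <- 10 * .Machine$double.eps * sum(abs(A)) * max(dim(A))
  x <- numeric(n)
  P <- logical(n)
  iter <- 0
  repeat {
    w <- as.numeric(crossprod(A, b - A %*% x))
    if (all(P) || max(w[!P]) <= tol) break
    free <- which(!P)
    P[free[which.max(w[free])]] <- TRUE
    repeat {
      iter <- iter + 1
      if (iter > maxiter) return(x)
      z <- numeric(n)
      zp <- stats::lm.fit(A[, P, drop = FALSE], b)$coefficients
      zp[is.na(zp)] <- 0
      z[P] <- zp
      if (all(z[P] > 0)) { x <- z; break }
      q <- which(P & z <= 0)
      den <- x[q] - z[q]
      step <- min(ifelse(den > 0, x[q] / den, 0))
      x <- x + step * (z - x)
      x[abs(x) < 1e-14] <- 0
      P <- P & (x > 0)
    }
  }
  x
}

# min ||b - A x|| s.t. x >= 0, sum(x) = 1, via NNLS on a system augmented
# with a large sum-to-one penalty row (classical device; penalty = 200),
# then an exact projection onto the simplex face found.
.simplex_ls <- function(A, b, penalty = 200) {
  Aa <- rbind(A, rep(penalty, ncol(A)))
  ba <- c(b, penalty)
  x <- .nnls(Aa, ba)
  x[x < 0] <- 0
  s <- sum(x)
  if (s <= 0) rep(1 / length(x), length(x)) else x / s
}

.aa_alphas <- function(X, Z, penalty = 200) {
  At <- t(Z)  # m x k design: x_i ~ Z^T a_i
  out <- apply(X, 1, function(x) .simplex_ls(At, x, penalty))
  if (is.null(dim(out))) matrix(out, ncol = 1) else t(out)
}

.aa_rss <- function(X, A, Z) sum((X - A %*% Z)^2)

#' Fit k behavioral archetypes
#'
#' Alternating minimization: given archetypes `Z`, each animal's simplex
#' weights are solved by constrained least squares; given the weights, the
#' least-squares archetypes are computed and projected back onto the convex
#' hull of the data through the `delta_weights` rows. A candidate archetype
#' update is only accepted if it does not increase the residual sum of
#' squares, so RSS is non-increasing over iterations by construction. The
#' best of `n_restarts` seeded random initializations (archetypes started
#' at k distinct data rows) is returned.
#'
#' @param X numeric n x m matrix (rows = animals), typically from
#'   [descriptor_matrix()] whose scaling attributes are carried along.
#' @param k number of archetypes (3 for the Tracker/Explorer/Non-Switcher
#'   decomposition).
#' @param n_restarts seeded random restarts.
#' @param max_iter maximum alternating iterations per restart.
#' @param tol relative RSS change declaring convergence.
#' @param seed integer master seed.
#' @return an object of class `archetype_model`: `Z` (k x m),
#'   `alphas` (n x k simplex weights), `delta_weights` (k x n), `rss`,
#'   `rss_path`, `n_iter`, `converged`, `restart_index`, plus the scaling
#'   record of `X` when present.
#' @export
fit_archetypes <- function(X, k = 3, n_restarts = 10, max_iter = 200,
                           tol = 1e-8, seed = 1) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop2("X contains non-finite entries")
  n <- nrow(X); m <- ncol(X)
  if (n <= k) stop2("need more observations (", n, ") than archetypes (", k, ")")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, r))
    Z <- X[sample.int(n, k), , drop = FALSE]
    D <- NULL
    A <- .aa_alphas(X, Z)
    rss <- .aa_rss(X, A, Z)
    rss_path <- rss
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      # unconstrained least-squares archetypes given A (ridge guards rank
      # deficiency when an archetype receives no weight)
      G <- crossprod(A) + diag(1e-10, k)
      Zbar <- solve(G, crossprod(A, X))
      Dn <- t(apply(Zbar, 1, function(z) .simplex_ls(t(X), z)))
      Zn <- Dn %*% X
      An <- .aa_alphas(X, Zn)
      rss_new <- .aa_rss(X, An, Zn)
      if (rss_new > rss + 1e-12) {  # reject non-descent step, stop here
        converged <- TRUE
        break
      }
      Z <- Zn; D <- Dn; A <- An
      rss_path <- c(rss_path, rss_new)
      if (rss_new < 1e-15 || rss - rss_new < tol * max(rss, 1e-12)) {
        rss <- rss_new
        converged <- TRUE
        break
      }
      rss <- rss_new
    }
    if (is.null(D))  # no accepted update: express initial rows of X exactly
      D <- t(apply(Z, 1, function(z) .simplex_ls(t(X), z)))
    fit <- list(Z = Z, alphas = A, delta_weights = D, rss = rss,
                rss_path = rss_path, n_iter = it, converged = converged,
                restart_index = r)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  if (!best$converged) warning("no restart reached the convergence tolerance")
  dimnames(best$Z) <- list(paste0("A", seq_len(k)), colnames(X))
  colnames(best$alphas) <- rownames(best$Z)
  best$k <- k
  best$seed <- seed
  best$mouse_ids <- attr(X, "mouse_ids")
  best$scaling <- list(scaling = attr(X, "scaling"),
                       col_mins = attr(X, "col_mins"),
                       col_maxs = attr(X, "col_maxs"))
  class(best) <- "archetype_model"
  best
}

#' @export
print.archetype_model <- function(x, ...) {
  cat("<archetype_model> k =", x$k, " rss =", signif(x$rss, 6),
      " iter =", x$n_iter, " converged =", x$converged, "\n")
  print(round(x$Z, 4))
  invisible(x)
}

#' Project observations onto a fitted archetype simplex
#'
#' Solves `min ||x - Z^T a||` subject to `a >= 0`, `sum(a) = 1` for each
#' row of `x`.
#'
#' @param model an `archetype_model`.
#' @param x numeric vector of length m or an n x m matrix.
#' @return simplex weight vector (or n x k matrix).
#' @export
project_alphas <- function(model, x) {
  if (is.matrix(x)) {
    if (ncol(x) != ncol(model$Z)) stop2("dimension mismatch: expected ",
                                        ncol(model$Z), " columns")
    out <- apply(x, 1, function(r) .simplex_ls(t(model$Z), r))
    return(if (is.null(dim(out))) matrix(out, ncol = 1) else t(out))
  }
  if (length(x) != ncol(model$Z)) stop2("dimension mismatch: expected length ",
                                        ncol(model$Z))
  .simplex_ls(t(model$Z), x)
}

#' Archetypes in raw descriptor units
#'
#' Undoes the min-max column scaling recorded on the descriptor matrix.
#'
#' @param model an `archetype_model`.
#' @return k x m matrix in the original descriptor units.
#' @export
archetypes_raw <- function(model) {
  Z <- model$Z
  sc <- model$scaling
  if (identical(sc$scaling, "minmax")) {
    rng <- sc$col_maxs - sc$col_mins
    Z <- sweep(sweep(Z, 2, rng, "*"), 2, sc$col_mins, "+")
  }
  Z
}

#' Name the three archetypes Tracker / Explorer / NonSwitcher
#'
#' On the raw-unit archetype matrix: the Tracker is the archetype with the
#' highest high-value-side preference; of the remaining two, the
#' NonSwitcher has the higher side bias and the Explorer is the last. Ties
#' on preference are broken by side bias then index, with a warning.
#'
#' @param model an `archetype_model` with `k = 3` fitted on descriptor
#'   columns `pref` and `side_bias`.
#' @return character vector of length 3: label of each archetype index.
#' @export
label_archetypes <- function(model) {
  if (model$k != 3) stop2("semantic labeling is defined for k = 3 only")
  Z <- archetypes_raw(model)
  if (!all(c("pref", "side_bias") %in% colnames(Z)))
    stop2("archetype matrix lacks named descriptor columns")
  pref <- Z[, "pref"]; bias <- Z[, "side_bias"]
  if (sum(pref == max(pref)) > 1) {
    warning("tie on preference between archetypes; breaking by side bias then index")
    tr <- which(pref == max(pref))
    tr <- tr[order(-bias[tr], tr)][1]
  } else tr <- which.max(pref)
  rest <- setdiff(seq_len(3), tr)
  ns <- rest[which.max(bias[rest])]
  ex <- setdiff(rest, ns)
  labels <- character(3)
  labels[tr] <- "Tracker"; labels[ns] <- "NonSwitcher"; labels[ex] <- "Explorer"
  labels
}

#' Ternary (barycentric to Cartesian) coordinates of simplex weights
#'
#' Vertices at (0,0), (1,0) and (0.5, sqrt(3)/2) for archetypes 1..3.
#'
#' @param alphas length-3 vector or n x 3 matrix of simplex weights.
#' @return matrix with columns `x`, `y`.
#' @export
ternary_coordinates <- function(alphas) {
  A <- if (is.matrix(alphas)) alphas else matrix(alphas, nrow = 1)
  if (ncol(A) != 3) stop2("ternary coordinates require k = 3 weights")
  if (any(abs(rowSums(A) - 1) > 1e-6) || any(A < -1e-6))
    stop2("weights are off the simplex beyond tolerance 1e-6")
  cbind(x = A[, 2] + 0.5 * A[, 3], y = sqrt(3) / 2 * A[, 3])
}

#' Invert ternary coordinates back to simplex weights
#'
#' @param xy matrix with columns `x`, `y` (or length-2 vector).
#' @return n x 3 matrix of barycentric weights.
#' @export
barycentric_coordinates <- function(xy) {
  P <- if (is.matrix(xy)) xy else matrix(xy, nrow = 1)
  a3 <- P[, 2] / (sqrt(3) / 2)
  a2 <- P[, 1] - 0.5 * a3
  cbind(a1 = 1 - a2 - a3, a2 = a2, a3 = a3)
}

#' Per-animal archetypal composition table
#'
#' @param model an `archetype_model` with `k = 3`.
#' @param mouse_ids optional ids overriding the ones stored on the model.
#' @return data.frame `mouse_id`, `alpha_Tr`, `alpha_Ex`, `alpha_NS`,
#'   `nearest` (label of the max-weight archetype), `ternary_x`,
#'   `ternary_y`.
#' @export
composition_table <- function(model, mouse_ids = NULL) {
  labels <- label_archetypes(model)
  A <- model$alphas
  ids <- mouse_ids %||% model$mouse_ids %||% paste0("m", seq_len(nrow(A)))
  xy <- ternary_coordinates(A)
  nearest <- labels[max.col(A, ties.method = "first")]
  out <- data.frame(mouse_id = ids,
                    alpha_Tr = A[, which(labels == "Tracker")],
                    alpha_Ex = A[, which(labels == "Explorer")],
                    alpha_NS = A[, which(labels == "NonSwitcher")],
                    nearest = nearest,
                    ternary_x = xy[, "x"], ternary_y = xy[, "y"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
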