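#' Interaction matrix container
#'
#' Square signed matrix of per-capita interaction strengths. Entry
#' `values[i, j]` is the effect of species `j` (source) on species `i`
#' (target). Connectance is the fraction of realized off-diagonal entries;
#' the positive edge percentage (PEP) is the share of realized off-diagonal
#' entries that are positive.
#'
#' @param values square numeric matrix.
#' @param clique_size Klemm-Eguiluz clique parameter used to generate the
#'   topology (`NA` when unknown).
#' @return an object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(values, clique_size = NA_integer_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("interaction matrix must be square")
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("sp", seq_len(nrow(values)))
  }
  structure(values,
            connectance = connectance(values),
            positive_edge_percentage = positive_edge_percentage(values),
            clique_size = clique_size,
            class = c("interaction_matrix", "matrix", "array"))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %d species, connectance %.4f, PEP %s\n",
              nrow(x), connectance(x),
              ifelse(is.na(positive_edge_percentage(x)), "NA",
                     sprintf("%.1f%%", positive_edge_percentage(x)))))
  invisible(x)
}

#' Connectance of an interaction matrix
#'
#' Ratio of non-zero off-diagonal entries to `S * (S - 1)`.
#' @param A square matrix.
#' @return a number in `[0, 1]`.
#' @export
connectance <- function(A) {
  A <- as.matrix(A)
  S <- nrow(A)
  if (S < 2) return(0)
  off <- A[row(A) != col(A)]
  sum(off != 0) / (S * (S - 1))
}

#' Positive edge percentage of an interaction matrix
#'
#' Share (in percent) of non-zero off-diagonal entries that are positive;
#' `NA` when there are no realized edges.
#' @param A square matrix.
#' @return a number in `[0, 100]` or `NA`.
#' @export
positive_edge_percentage <- function(A) {
  A <- as.matrix(A)
  off <- A[row(A) != col(A)]
  nz <- off[off != 0]
  if (length(nz) == 0) return(NA_real_)
  100 * mean(nz > 0)
}

#' Generate a Klemm-Eguiluz adjacency structure
#'
#' Grows a modular, scale-free graph: an initial fully connected clique of
#' `clique_size` active nodes; every subsequent node links to each active
#' node (or, with probability `mu`, to a random node chosen by preferential
#' attachment), joins the active set, and one active node is deactivated
#' with probability inversely proportional to its degree. The undirected
#' edge set is returned as a symmetric logical matrix (each undirected edge
#' occupies both directed slots; strengths are later assigned
#' independently).
#'
#' @param n_species number of nodes.
#' @param clique_size size of the initial clique (also the size of the
#'   active set); must not exceed `n_species`.
#' @param mu probability of redirecting a link from an active node to a
#'   preferentially attached node.
#' @param seed optional RNG seed.
#' @return an `n_species` x `n_species` logical matrix, symmetric with an
#'   all-`FALSE` diagonal.
#' @export
generate_klemm_adjacency <- function(n_species, clique_size = 10, mu = 0.5,
                                     seed = NULL) {
  if (clique_size > n_species) stop("clique_size must not exceed n_species")
  if (clique_size < 1 || n_species < 1) stop("n_species and clique_size must be positive")
  .ecosig_seed(seed)
  S <- n_species
  adj <- matrix(FALSE, S, S)
  m <- clique_size
  adj[seq_len(m), seq_len(m)] <- TRUE
  diag(adj) <- FALSE
  active <- seq_len(m)
  degree <- colSums(adj)
  if (S > m) {
    for (v in (m + 1):S) {
      for (a in active) {
        target <- a
        if (runif(1) < mu) {
          # preferential attachment among all previous nodes not yet linked
          pool <- which(!adj[v, seq_len(v - 1)])
          pool <- setdiff(pool, v)
          if (length(pool) > 0) {
            w <- degree[pool] + 1e-12
            target <- pool[sample.int(length(pool), 1L, prob = w)]
          }
        }
        if (target != v && !adj[v, target]) {
          adj[v, target] <- adj[target, v] <- TRUE
          degree[v] <- degree[v] + 1L
          degree[target] <- degree[target] + 1L
        }
      }
      # activate v, deactivate one active node with probability ~ 1/degree
      active <- c(active, v)
      w <- 1 / pmax(degree[active], 1)
      drop <- sample.int(length(active), 1L, prob = w)
      active <- active[-drop]
    }
  }
  dimnames(adj) <- list(paste0("sp", seq_len(S)), paste0("sp", seq_len(S)))
  adj
}

#' Assign interaction strengths to an adjacency structure
#'
#' Diagonal entries are set to -1 (self-limitation); each directed edge gets
#' an independent strength drawn from Uniform(0, 1); absent edges are 0.
#'
#' @param adjacency square logical (or 0/1) matrix.
#' @param seed optional RNG seed.
#' @param clique_size recorded on the result (metadata only).
#' @return an [interaction_matrix()].
#' @export
assign_strengths <- function(adjacency, seed = NULL, clique_size = NA_integer_) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  .ecosig_seed(seed)
  S <- nrow(adjacency)
  A <- matrix(0, S, S, dimnames = dimnames(adjacency))
  edges <- which(adjacency != 0 & row(adjacency) != col(adjacency))
  A[edges] <- runif(length(edges))
  diag(A) <- -1
  interaction_matrix(A, clique_size = clique_size)
}

#' Adjust the connectance of an interaction matrix
#'
#' Removes realized off-diagonal entries uniformly at random (or adds new
#' ones with Uniform(0, 1) strength) until exactly
#' `round(target_c * S * (S - 1))` off-diagonal entries are non-zero.
#' The diagonal is untouched.
#'
#' @param A an [interaction_matrix()].
#' @param target_c target connectance in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return an [interaction_matrix()].
#' @export
adjust_connectance <- function(A, target_c, seed = NULL) {
  if (target_c < 0 || target_c > 1) stop("target_c must be in [0, 1]")
  .ecosig_seed(seed)
  cs <- attr(A, "clique_size")
  A <- as.matrix(A)
  S <- nrow(A)
  target_n <- round(target_c * S * (S - 1))
  offdiag <- row(A) != col(A)
  present <- which(offdiag & A != 0)
  absent <- which(offdiag & A == 0)
  if (length(present) > target_n) {
    drop <- sample(present, length(present) - target_n)
    A[drop] <- 0
  } else if (length(present) < target_n) {
    add <- sample(absent, target_n - length(present))
    A[add] <- runif(length(add))
  }
  interaction_matrix(A, clique_size = if (is.null(cs)) NA_integer_ else cs)
}

#' Stability check by noise-free Ricker simulation
#'
#' Runs a deterministic Ricker simulation from broken-stick initial
#' proportions and declares the matrix stable when no abundance exceeds
#' `explosion_bound` and no non-finite value appears within `t_test` steps.
#'
#' @param A an [interaction_matrix()] (or square matrix).
#' @param K carrying capacities; drawn from Uniform(0, 0.5) when `NULL`.
#' @param t_test number of Ricker steps.
#' @param explosion_bound abundance bound above which the run counts as an
#'   explosion.
#' @param seed optional RNG seed (controls `K` and the initial proportions).
#' @return `TRUE` when the simulation stays bounded.
#' @export
ricker_stability_check <- function(A, K = NULL, t_test = 100,
                                   explosion_bound = 1e8, seed = NULL) {
  .ecosig_seed(seed)
  A <- as.matrix(A)
  S <- nrow(A)
  if (is.null(K)) K <- runif(S, 0, 0.5)
  if (any(K <= 0)) stop("carrying capacities must be strictly positive")
  x0 <- broken_stick_proportions(S)
  res <- ricker_core(A, K, x0, sigma = 0, n_timepoints = t_test,
                     explosion_bound = explosion_bound)
  !res$exploded
}

#' Tune the positive edge percentage under a stability constraint
#'
#' Flips randomly chosen positive off-diagonal entries to negative (value
#' negated), one at a time, until the achieved PEP is at or below
#' `target_pep` *and* the matrix passes [ricker_stability_check()]. A matrix
#' that already satisfies both conditions is returned unchanged. If every
#' positive edge has been flipped and the matrix is still unstable, an error
#' with diagnostics is raised.
#'
#' @param A an [interaction_matrix()] with assigned strengths.
#' @param target_pep target positive edge percentage in `[0, 100]`.
#' @param K carrying capacities for the stability test (drawn from
#'   Uniform(0, 0.5) when `NULL`).
#' @param seed optional RNG seed.
#' @param t_test,explosion_bound stability-test controls, see
#'   [ricker_stability_check()].
#' @return an [interaction_matrix()] whose `positive_edge_percentage`
#'   attribute records the achieved PEP.
#' @export
tune_positive_edge_fraction <- function(A, target_pep, K = NULL, seed = NULL,
                                        t_test = 100, explosion_bound = 1e8) {
  if (target_pep < 0 || target_pep > 100) stop("target_pep must be in [0, 100]")
  .ecosig_seed(seed)
  cs <- attr(A, "clique_size")
  A <- as.matrix(A)
  S <- nrow(A)
  if (is.null(K)) K <- runif(S, 0, 0.5)

  stable <- function(M) ricker_stability_check(M, K = K, t_test = t_test,
                                               explosion_bound = explosion_bound)
  pep_of <- function(M) {
    p <- positive_edge_percentage(M)
    if (is.na(p)) 0 else p
  }

  finish <- function(M) {
    out <- interaction_matrix(M, clique_size = if (is.null(cs)) NA_integer_ else cs)
    attr(out, "K") <- K # the carrying capacities the matrix was verified with
    out
  }
  if (pep_of(A) <= target_pep && stable(A)) {
    return(finish(A))
  }
  repeat {
    if (pep_of(A) > target_pep || !stable(A)) {
      pos <- which(row(A) != col(A) & A > 0)
      if (length(pos) == 0) {
        stop(sprintf(paste0("no stable matrix found: all positive edges ",
                            "converted (PEP = 0, connectance = %.4f) and the ",
                            "Ricker stability test still fails"),
                     connectance(A)))
      }
      flip <- if (length(pos) == 1) pos else sample(pos, 1)
      A[flip] <- -A[flip]
    } else {
      break
    }
  }
  finish(A)
}

#' Generate a stable Klemm-Eguiluz interaction matrix
#'
#' Convenience wrapper chaining [generate_klemm_adjacency()],
#' [assign_strengths()], [adjust_connectance()] and
#' [tune_positive_edge_fraction()].
#'
#' @param n_species number of species.
#' @param connectance target connectance.
#' @param pep target positive edge percentage.
#' @param clique_size Klemm-Eguiluz clique parameter.
#' @param K carrying capacities used in the stability test (drawn from
#'   Uniform(0, 0.5) when `NULL`).
#' @param seed optional RNG seed.
#' @return an [interaction_matrix()].
#' @export
generate_interaction_matrix <- function(n_species, connectance = 0.05,
                                        pep = 16, clique_size = 10,
                                        K = NULL, seed = NULL) {
  .ecosig_seed(seed)
  adj <- generate_klemm_adjacency(n_species, clique_size = clique_size)
  A <- assign_strengths(adj, clique_size = clique_size)
  A <- adjust_connectance(A, connectance)
  tune_positive_edge_fraction(A, target_pep = pep, K = K)
}
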