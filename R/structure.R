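#' Gaussian-Markov structure matrices
#'
#' Intrinsic CAR and random-walk priors are specified through a symmetric
#' positive semi-definite *structure matrix* K: the effect vector w has
#' improper density proportional to \eqn{\exp(-w'Kw / 2\sigma^2)}. Rows of
#' an intrinsic K sum to zero and the rank deficiency equals the dimension
#' of the invariant (unpenalized) subspace.
#'
#' @name structure_matrix
NULL

new_structure_matrix <- function(entries, labels, rank_deficiency) {
  dimnames(entries) <- list(labels, labels)
  structure(list(labels = labels, entries = entries,
                 rank_deficiency = as.integer(rank_deficiency)),
            class = "structure_matrix")
}

#' @export
print.structure_matrix <- function(x, ...) {
  cat("Structure matrix:", nrow(x$entries), "x", ncol(x$entries),
      "| rank deficiency", x$rank_deficiency, "\n")
  invisible(x)
}

#' Intrinsic CAR (ICAR) structure matrix of an adjacency graph
#'
#' K = D - A with D = diag(N_i) and A the binary adjacency matrix; this is
#' the precision structure implied by the conditionals
#' \eqn{u_i | u_{-i} \sim N(\frac{1}{N_i}\sum_j a_{ij} u_j, \sigma_u^2/N_i)}.
#' Rank deficiency equals the number of connected components.
#'
#' @param graph an `adjacency_graph` with no islands.
#' @return a `structure_matrix`.
#' @export
icar_structure_matrix <- function(graph) {
  if (length(graph$islands)) {
    stop("ICAR structure undefined for island region(s): ",
         paste(graph$islands, collapse = ", "))
  }
  A <- adjacency_matrix(graph)
  K <- diag(graph$n_neighbors) - A
  new_structure_matrix(K, graph$region_ids, n_components(graph))
}

#' First-order random-walk (RW1) structure matrix
#'
#' First-difference penalty over T ordered time points:
#' diag(1, 2, ..., 2, 1) with -1 on the first off-diagonals; rank
#' deficiency 1 (constants are unpenalized).
#'
#' @param T integer number of time points, at least 2.
#' @param labels optional labels, default `t1..tT`.
#' @return a `structure_matrix`.
#' @export
rw1_structure_matrix <- function(T, labels = NULL) {
  T <- as.integer(T)
  if (is.na(T) || T < 2L) stop("RW1 structure requires T >= 2")
  D <- diff(diag(T))                       # (T-1) x T first-difference operator
  K <- crossprod(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(T))
  new_structure_matrix(K, labels, 1L)
}

#' Kronecker space-time interaction structure matrix
#'
#' The space-time interaction field delta has precision structure
#' \eqn{K_\delta = K_{space} \otimes K_{time}}: temporal trends are
#' penalized towards those of spatial neighbours. Labels are
#' `region:time`; the layout is region-major (all times of region 1, then
#' region 2, ...), matching a row-wise flattening of an n x T effect
#' matrix.
#'
#' @param K_space,K_time `structure_matrix` objects (spatial and temporal
#'   factors; identity matrices encode unstructured factors).
#' @return a `structure_matrix` of dimension `n*T` with rank deficiency
#'   `n*T - rank(K_space) * rank(K_time)`.
#' @export
interaction_structure_matrix <- function(K_space, K_time) {
  stopifnot(inherits(K_space, "structure_matrix"),
            inherits(K_time, "structure_matrix"))
  Ks <- K_space$entries; Kt <- K_time$entries
  K <- kronecker(Ks, Kt)
  n <- nrow(Ks); Tn <- nrow(Kt)
  rk <- (n - K_space$rank_deficiency) * (Tn - K_time$rank_deficiency)
  labels <- as.vector(t(outer(K_space$labels, K_time$labels, paste, sep = ":")))
  new_structure_matrix(K, labels, n * Tn - rk)
}

#' Identity structure matrix (unstructured factor)
#' @param labels index labels.
#' @return a full-rank `structure_matrix` (rank deficiency 0).
#' @export
identity_structure_matrix <- function(labels) {
  new_structure_matrix(diag(length(labels)), labels, 0L)
}

#' Export a structure matrix as coordinate-format sparse text
#'
#' Writes rows `i j value` (1-based indices, tab-separated, header line)
#' for the non-zero entries.
#' @param K a `structure_matrix`.
#' @param path output file path.
#' @export
write_structure_matrix <- function(K, path) {
  idx <- which(K$entries != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L],
                   value = K$entries[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure_matrix
#' @param labels labels for the reconstructed matrix (fixes dimension).
#' @param rank_deficiency rank deficiency to record.
#' @export
read_structure_matrix <- function(path, labels, rank_deficiency) {
  df <- utils::read.delim(path)
  n <- length(labels)
  K <- matrix(0, n, n)
  K[cbind(df$i, df$j)] <- df$value
  new_structure_matrix(K, labels, rank_deficiency)
}
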