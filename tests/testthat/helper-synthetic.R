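# Small in-code fixtures shared across test files.

make_ts <- function(t_len = 50, n = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(t_len * n), t_len, n)
    colnames(m) <- paste0("R", seq_len(n))
    m
  })
}

# Adjacency matrix from an igraph-free edge list on n nodes.
adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n, dimnames = list(paste0("R", 1:n), paste0("R", 1:n)))
  for (e in edges) {
    a[e[1], e[2]] <- a[e[2], e[1]] <- 1L
  }
  class(a) <- c("binary_graph", "matrix", "array")
  a
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n, dimnames = list(paste0("R", 1:n), paste0("R", 1:n)))
  diag(a) <- 0L
  class(a) <- c("binary_graph", "matrix", "array")
  a
}

path_graph <- function(n) {
  adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

random_adj <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
    a <- a + t(a)
    dimnames(a) <- list(paste0("R", 1:n), paste0("R", 1:n))
    class(a) <- c("binary_graph", "matrix", "array")
    a
  })
}

# All labelled simple graphs on n nodes (2^(n(n-1)/2) of them).
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    a <- matrix(0L, n, n)
    a[ut] <- bits
    a <- a + t(a)
    dimnames(a) <- list(paste0("R", 1:n), paste0("R", 1:n))
    class(a) <- c("binary_graph", "matrix", "array")
    a
  })
}

# Gaussian two-group feature table with `n_info` informative features.
make_feature_table <- function(n_per_group = 30, n_features = 20,
                               n_info = 2, shift = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    x <- matrix(rnorm(n * n_features), n, n_features)
    diagnosis <- factor(rep(c("ASD", "HC"), each = n_per_group),
      levels = c("ASD", "HC")
    )
    if (n_info > 0) {
      x[diagnosis == "ASD", seq_len(n_info)] <-
        x[diagnosis == "ASD", seq_len(n_info)] + shift
    }
    colnames(x) <- sprintf("f%03d", seq_len(n_features))
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("s%03d", 1:n), site = "SYN",
        age = runif(n, 6, 40), diagnosis = diagnosis
      ),
      tibble::as_tibble(x)
    )
  })
}
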