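# Independent oracles and small fixture builders. These are deliberately
# naive re-derivations (flood fill, all-pairs distances, normal equations)
# kept separate from the package's implementations.

# binary ugrid with 1-density p
rand_binary_grid <- function(nr, nc, p = 0.3, cell_size = 10) {
  ugrid(matrix(as.numeric(runif(nr * nc) < p), nr, nc), cell_size = cell_size)
}

uniform_grid <- function(value, nr, nc, cell_size = 10) {
  ugrid(matrix(value, nr, nc), cell_size = cell_size)
}

all_true_mask <- function(template) {
  ugrid(matrix(1, nrow(template$values), ncol(template$values)),
        cell_size = template$cell_size, origin = template$origin,
        crs_tag = template$crs_tag)
}

# stack-based flood fill labelling
oracle_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  lab[is.na(m)] <- NA_integer_
  if (connectivity == 8) {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  stack_i <- integer(nr * nc); stack_j <- integer(nr * nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (is.na(m[i, j]) || m[i, j] == 0 || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    top <- 1L; stack_i[1] <- i; stack_j[1] <- j
    lab[i, j] <- nxt
    while (top > 0L) {
      pi <- stack_i[top]; pj <- stack_j[top]; top <- top - 1L
      for (k in seq_along(dr)) {
        qi <- pi + dr[k]; qj <- pj + dc[k]
        if (qi < 1L || qi > nr || qj < 1L || qj > nc) next
        if (is.na(m[qi, qj]) || m[qi, qj] == 0 || lab[qi, qj] != 0L) next
        lab[qi, qj] <- nxt
        top <- top + 1L; stack_i[top] <- qi; stack_j[top] <- qj
      }
    }
  }
  lab
}

# all-pairs distance access flags: cell flagged iff the count of 1-cells
# within radius_cells of its centre reaches min_cells
oracle_buffer_flags <- function(m, radius_cells, min_cells) {
  nr <- nrow(m); nc <- ncol(m)
  ones <- which(!is.na(m) & m == 1, arr.ind = TRUE)
  ri <- rep(seq_len(nr), times = nc)
  cj <- rep(seq_len(nc), each = nr)
  counts <- rep(0, nr * nc)
  if (nrow(ones) > 0) {
    for (k in seq_len(nrow(ones))) {
      d2 <- (ri - ones[k, 1])^2 + (cj - ones[k, 2])^2
      counts <- counts + (d2 <= radius_cells^2 + 1e-9)
    }
  }
  flags <- matrix(as.numeric(counts >= min_cells), nr, nc)
  flags[is.na(m)] <- NA
  flags
}

# closed-form simple-regression normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       rmse = sqrt(sum(res^2) / length(y)))
}

# map labels of a to labels of b and check they induce the same partition
same_partition <- function(a, b) {
  fa <- as.vector(a); fb <- as.vector(b)
  ok <- !is.na(fa) & fa > 0
  if (!identical(which(!is.na(fa) & fa > 0), which(!is.na(fb) & fb > 0))) return(FALSE)
  length(unique(paste(fa[ok], fb[ok]))) == length(unique(fa[ok])) &&
    length(unique(fa[ok])) == length(unique(fb[ok]))
}
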