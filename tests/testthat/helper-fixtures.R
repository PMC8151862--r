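# Shared fixtures: small parameter sets and slow-path oracles used across
# test files.

# small, fast parameter set for simulation tests
small_params <- function(...) {
  model_params(domain = c(40, 40), hematocrit = 0.3, n_steps = 500L, ...)
}

# brute-force flood fill (BFS) labeling oracle for free space,
# 4-connectivity; periodic via explicit neighbor wrapping
flood_fill_labels <- function(occ, periodic) {
  ny <- nrow(occ); nx <- ncol(occ)
  lab <- matrix(0L, ny, nx)
  nxt <- 0L
  for (j0 in seq_len(ny)) {
    for (i0 in seq_len(nx)) {
      if (occ[j0, i0] != 0 || lab[j0, i0] != 0) next
      nxt <- nxt + 1L
      queue <- matrix(c(j0, i0), ncol = 2)
      lab[j0, i0] <- nxt
      while (nrow(queue) > 0) {
        j <- queue[1, 1]; i <- queue[1, 2]
        queue <- queue[-1, , drop = FALSE]
        for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
          jj <- j + d[1]; ii <- i + d[2]
          if (periodic) {
            jj <- ((jj - 1) %% ny) + 1
            ii <- ((ii - 1) %% nx) + 1
          } else if (jj < 1 || jj > ny || ii < 1 || ii > nx) next
          if (occ[jj, ii] == 0 && lab[jj, ii] == 0) {
            lab[jj, ii] <- nxt
            queue <- rbind(queue, c(jj, ii))
          }
        }
      }
    }
  }
  lab
}

# areas of labeled components, sorted (label identity is arbitrary)
sorted_component_sizes <- function(lab) {
  sort(tabulate(lab[lab > 0]))
}

# plain gradient-descent relaxation of a single ring on the same energy,
# used as an independent oracle for the L-BFGS-based constructors
gradient_descent_ring <- function(v0, params, k_bend, A0, step = 2e-5,
                                  n_iter = 20000L) {
  v <- v0
  for (i in seq_len(n_iter)) {
    g <- erythrosim:::cpp_cell_grad(v, params$k_spring, params$l0, k_bend,
                                    params$k_area, A0)
    v <- v - step * g
  }
  v
}
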