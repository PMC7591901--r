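# Grid-space rotation augmentation: the 24 proper rotations of the cube
# (axis permutations + sign flips with determinant +1) act exactly on a
# stored voxel grid and its target tensor, so training can randomize the
# orientation of every sample each epoch without re-voxelizing.

.octahedral_ops <- function() {
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  even <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  ops <- list()
  for (pi in seq_along(perms)) {
    for (m in 0:7) {
      flip <- c(bitwAnd(m, 1L) > 0, bitwAnd(m, 2L) > 0, bitwAnd(m, 4L) > 0)
      det <- (if (even[pi]) 1 else -1) * prod(ifelse(flip, -1, 1))
      if (det == 1) {
        ops[[length(ops) + 1L]] <- list(perm = perms[[pi]], flip = flip)
      }
    }
  }
  ops
}

.OCTAHEDRAL_OPS <- .octahedral_ops()

# apply one cube rotation to an (n, n, n, C) array:
# out[w] = in[v] with v[a] = flip_a(w[perm[a]])
.rotate_array <- function(g, op) {
  n <- dim(g)[1]
  idx <- lapply(1:3, function(a) if (op$flip[a]) n:1 else 1:n)
  g <- g[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  aperm(g, c(op$perm, 4L))
}

# matching transform for an 8x8x8x4 target tensor: spatial rotation plus
# remapping of the in-cell coordinate channels. .rotate_array sends
# in-axis perm[a] (flipped when flip[perm[a]]) to out-axis a, so the
# out coordinate channel a is the (possibly inverted) in channel perm[a].
.rotate_target <- function(target, op) {
  out <- .rotate_array(target, op)
  coords <- out[, , , 2:4, drop = FALSE]
  s <- out[, , , 1]
  for (a in 1:3) {
    v <- coords[, , , op$perm[a]]
    if (op$flip[op$perm[a]]) v <- 1 - v
    out[, , , 1 + a] <- v * s
  }
  out
}
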