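# Shared fixtures and oracles for the test suite.

fx <- toy_fixtures()

# reduced CV geometry to keep the suite fast; pipeline structure unchanged
quick_config <- function(repeats = 2L) cv_config(outer_repeats = repeats)

# small-tree type spec so populations generate quickly
small_type <- function(n = 8L, z_offset = 0, z_offset_sd = 10,
                       axon_depth = 4L, dendrite = list()) {
  type_spec(n = n,
            dendrite = utils::modifyList(
              list(n_stems = 2L, seg_len = 15, seg_len_sd = 5, depth = 2L),
              dendrite),
            axon = list(n_stems = 1L, seg_len = 20, seg_len_sd = 6,
                        depth = axon_depth, z_offset = z_offset,
                        z_offset_sd = z_offset_sd, lateral_extent = 60))
}

small_pop <- function(seed, z_offset_b = 0, n = 8L, ...) {
  generate_population(population_spec(
    types = list(A = small_type(n = n, z_offset = 0, ...),
                 B = small_type(n = n, z_offset = z_offset_b, ...)),
    seed = seed))
}

expect_valid_morphology <- function(m) {
  expect_true(morphrep:::validate_morphology(m))
  ts <- morphrep:::tree_structure(m)
  expect_length(ts$root, 1L)
  expect_equal(sum(is.na(ts$parent_row)), 1L)
}

# Independent persistence oracle: a tip dies at the first branch point
# (walking toward the soma) where a sibling subtree carries a strictly
# larger maximal birth (ties beat it if their tip id is smaller); the
# globally eldest tip dies at the soma.
oracle_diagram <- function(m, filter) {
  f <- morphrep:::filter_values(m, filter)
  ts <- morphrep:::tree_structure(m)
  nd <- m$nodes
  n <- nrow(nd)
  # subtree max birth (and the id of the tip achieving it) per node
  best_birth <- rep(-Inf, n); best_tip <- rep(NA_integer_, n)
  for (v in rev(seq_len(n))) {
    if (length(ts$children[[v]]) == 0L) {
      best_birth[v] <- f[v]; best_tip[v] <- nd$id[v]
    } else {
      for (k in ts$children[[v]]) {
        if (best_birth[k] > best_birth[v] ||
            (best_birth[k] == best_birth[v] && best_tip[k] < best_tip[v])) {
          best_birth[v] <- best_birth[k]; best_tip[v] <- best_tip[k]
        }
      }
    }
  }
  rows <- lapply(ts$tips, function(t0) {
    birth <- f[t0]; tid <- nd$id[t0]
    v <- t0
    repeat {
      p <- ts$parent_row[v]
      if (is.na(p)) return(data.frame(birth = birth, death = f[v] * 0,
                                      tip_id = tid))
      sibs <- setdiff(ts$children[[p]], v)
      beaten <- any(vapply(sibs, function(s)
        best_birth[s] > birth ||
          (best_birth[s] == birth && best_tip[s] < tid), TRUE))
      if (beaten) return(data.frame(birth = birth, death = f[p], tip_id = tid))
      v <- p
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$birth, out$death, out$tip_id), ]
}

sort_diagram <- function(d) {
  d <- as.data.frame(d)[, c("birth", "death", "tip_id")]
  d <- d[order(d$birth, d$death, d$tip_id), ]
  rownames(d) <- NULL
  d
}
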