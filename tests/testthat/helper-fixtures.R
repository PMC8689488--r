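# Shared fixtures: tiny in-memory stacks, fast low-resolution phantom specs,
# and simulated experiment tables. Everything is generated in code.

random_stack <- function(nr = 6L, nc = 7L, ns = 3L, channels = c("shell", "ros"),
                         bit_depth = 8L, pixel_size = NULL, id = NULL) {
  top <- 2^bit_depth - 1
  chans <- lapply(channels, function(ch)
    array(sample(0:top, nr * nc * ns, replace = TRUE), c(nr, nc, ns)))
  names(chans) <- channels
  zstack(chans, pixel_size = pixel_size, bit_depth = bit_depth, id = id)
}

# Small, quick-to-render phantom (128^2, 2 slices) for unit tests.
fast_phantom_spec <- function(...) {
  args <- list(...)
  defaults <- list(image_shape = c(128L, 128L), n_slices = 2L,
                   shell_axes = c(42, 26), ring_thickness = 5,
                   noise_sd = 3)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# Balanced nested table with known treatment/container/individual effects.
sim_table <- function(a = 3L, b = 2L, n = 4L, treat_effects = rep(0, a),
                      container_sd = 0, resid_sd = 1) {
  rows <- list()
  for (i in seq_len(a)) for (j in seq_len(b)) {
    c_off <- rnorm(1, 0, container_sd)
    y <- treat_effects[i] + c_off + rnorm(n, 0, resid_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      treatment = sprintf("t%02d", i), container = sprintf("t%02d_c%d", i, j),
      y = y)
  }
  do.call(rbind, rows)
}

# All distinct permutations of a (small) label multiset.
combinat_perms <- function(labs) {
  all_perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  m <- unique(do.call(rbind, all_perms(labs)))
  lapply(seq_len(nrow(m)), function(i) m[i, ])
}

# Explicit-loop nested sums-of-squares oracle, independent of nested_anova.
ss_oracle <- function(tab, y) {
  grand <- mean(y)
  sst <- ssc <- ssr <- 0
  for (t in unique(tab$treatment)) {
    it <- tab$treatment == t
    mt <- mean(y[it])
    sst <- sst + sum(it) * (mt - grand)^2
    for (cc in unique(tab$container[it])) {
      ic <- it & tab$container == cc
      mc <- mean(y[ic])
      ssc <- ssc + sum(ic) * (mc - mt)^2
      ssr <- ssr + sum((y[ic] - mc)^2)
    }
  }
  list(ss_treatment = sst, ss_container = ssc, ss_residual = ssr)
}
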