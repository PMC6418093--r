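# Fixture builders shared across the suite. Everything is generated in code;
# no stored binary data.

# a small, fast simulator world (160x120 frame, radius-50 arena)
smallConfig <- function(seed, nFlies = 3L, durationS = 5, ...) {
  arenaSimConfig(nFlies = nFlies, width = 160L, height = 120L,
                 durationS = durationS, seed = seed, ...)
}

# wrap scripted trajectories (array [frame, fly, 2]) as an ArenaSimulation so
# they can be rendered and ground-truthed like simulated ones
scriptedSim <- function(config, positions) {
  n <- dim(positions)[1]
  nf <- dim(positions)[2]
  moving <- matrix(FALSE, n, nf)
  if (n > 1) {
    for (i in 2:n) {
      d <- sqrt((positions[i, , 1] - positions[i - 1, , 1])^2 +
                  (positions[i, , 2] - positions[i - 1, , 2])^2)
      moving[i, ] <- d >= config@motionThreshold
    }
  }
  new("ArenaSimulation", config = config, positions = positions,
      moving = moving, walkState = moving)
}

# straight-line walkers: never revisit old ground, constant speed, fixed
# pairwise separation. ys/x0 in frame coordinates.
straightWalkers <- function(nframes, ys, x0, speed) {
  nf <- length(ys)
  pos <- array(NA_real_, c(nframes, nf, 2))
  for (i in seq_len(nframes)) {
    pos[i, , 1] <- x0 + speed * (i - 1)
    pos[i, , 2] <- ys
  }
  pos
}

# a disc mask for building synthetic foreground patterns
discMask <- function(height, width, cx, cy, r) {
  xs <- matrix(rep(seq_len(width) - 0.5, each = height), nrow = height)
  ys <- matrix(rep(seq_len(height) - 0.5, times = width), nrow = height)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# count connected components of a logical mask via the package's labeller
nComponents <- function(mask) {
  arenaActivity:::.cppComponents(mask)$n
}

# a tiny flat-gray frame
grayFrame <- function(height = 40, width = 60, level = 128L) {
  matrix(as.integer(level), nrow = height, ncol = width)
}
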