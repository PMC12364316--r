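# Shared fixtures, built in code and memoised for the test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, expr, .cache)
  get(key, .cache)
}

# default synthetic world: 3.2 A map, 60-residue solenoid, 16-atom ligand
defaultFixture <- function(seed = 0L) {
  memo(paste0("fixture", seed), makeFixture(fixtureSpec(seed = seed)))
}

defaultParams <- function() mapSimParams(3.2)

# a random blob of hetero atoms for gradient/energy oracles
randomToy <- function(n = 10L, seed = 1L, span = c(3, 9)) {
  withr::with_seed(seed, {
    Structure(data.frame(
      name = paste0("C", seq_len(n)),
      element = sample(c("C", "N", "O"), n, replace = TRUE),
      resname = "LIG", resseq = 1L,
      x = runif(n, span[1], span[2]), y = runif(n, span[1], span[2]),
      z = runif(n, span[1], span[2]), hetero = TRUE))
  })
}

# a self-avoiding chain with consecutive bonds ~1.4-1.55 A, for force-field
# oracles (steps that land within 1 A of an earlier atom are redrawn)
chainToy <- function(n = 15L, seed = 3L) {
  withr::with_seed(seed, {
    p <- matrix(0, n, 3)
    for (i in 2:n) {
      repeat {
        d <- rnorm(3)
        cand <- p[i - 1, ] + d / sqrt(sum(d^2)) * runif(1, 1.4, 1.55)
        if (min(colSums((t(p[seq_len(i - 1), , drop = FALSE]) - cand)^2)) > 1)
          break
      }
      p[i, ] <- cand
    }
    Structure(data.frame(
      name = paste0("C", seq_len(n)),
      element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
      resname = "LIG", resseq = 1L,
      x = p[, 1], y = p[, 2], z = p[, 3], hetero = TRUE))
  })
}

# minimal 3-atom PDB text (glycine-ish backbone fragment)
writeMiniPDB <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       2.400   2.100   3.200  1.00  0.00           C",
    "ATOM      3  O   GLY A   1       3.100   3.500   3.100  1.00  0.00           O",
    "END"), path)
  path
}

expect_selection_equal <- function(a, b) {
  expect_setequal(selectionIndices(a), selectionIndices(b))
}
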