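test_that("adjacency is |cor|^beta with unit diagonal", {
  set.seed(1)
  x <- matrix(rnorm(5 * 20), 5, 20,
              dimnames = list(paste0("m", 1:5), paste0("s", 1:20)))
  a <- adjacency(x, network_params(power = 6))
  expected <- abs(cor(t(x)))^6
  diag(expected) <- 1
  expect_equal(a, expected, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(unname(diag(a)), rep(1, 5))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(a, t(a))
  expect_error(adjacency(x[, 1:2]), "at least 3 samples")
  x[1, ] <- 5
  expect_error(adjacency(x), "zero-variance")
})

test_that("adjacency and TOM are permutation-equivariant", {
  set.seed(2)
  x <- matrix(rnorm(10 * 15), 10, 15,
              dimnames = list(paste0("m", 1:10), paste0("s", 1:15)))
  perm <- sample(10)
  a <- adjacency(x)
  ap <- adjacency(x[perm, ])
  expect_equal(ap, a[perm, perm], tolerance = 1e-14)
  expect_equal(tom_similarity(ap), tom_similarity(a)[perm, perm],
               tolerance = 1e-13)
})

test_that("TOM of an isolated fully-connected pair is 1", {
  a <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("m1", "m2"),
                                                   c("m1", "m2")))
  tom <- tom_similarity(a)
  expect_equal(tom["m1", "m2"], 1)
})

test_that("two planted correlated blocks are recovered as two modules", {
  set.seed(5)
  n <- 60
  block <- function(p, rho) {
    f <- rnorm(n)
    t(sapply(seq_len(p), function(i) sqrt(rho) * f +
               sqrt(1 - rho) * rnorm(n)))
  }
  x <- rbind(block(40, 0.8), block(40, 0.8))
  dimnames(x) <- list(sprintf("m%02d", 1:80), paste0("s", 1:n))
  asg <- detect_modules(x, network_params(min_module_size = 30))$assignment
  lab <- unclass(asg)
  expect_setequal(unique(lab), c("turquoise", "blue"))
  # each block maps to exactly one label
  expect_length(unique(lab[1:40]), 1L)
  expect_length(unique(lab[41:80]), 1L)
  expect_false(lab[1] == lab[41])
})

test_that("blocks below min_module_size dissolve to grey", {
  set.seed(6)
  n <- 50
  f <- rnorm(n)
  small <- t(sapply(1:20, function(i) 0.9 * f + 0.3 * rnorm(n)))
  noise <- matrix(rnorm(40 * n), 40, n)
  x <- rbind(small, noise)
  dimnames(x) <- list(sprintf("m%02d", 1:60), paste0("s", 1:n))
  asg <- detect_modules(x, network_params(min_module_size = 30))$assignment
  expect_true(all(unclass(asg) == "grey"))
})

test_that("modules with near-duplicate eigenmetabolites are merged", {
  set.seed(7)
  n <- 40
  f <- rnorm(n)
  mk <- function(p) t(sapply(seq_len(p), function(i)
    0.95 * f + 0.4 * rnorm(n)))
  labels <- setNames(rep(c("turquoise", "blue"), each = 35),
                     sprintf("m%02d", 1:70))
  x <- rbind(mk(35), mk(35))   # both modules share the same factor
  dimnames(x) <- list(names(labels), paste0("s", 1:n))
  merged <- merge_close_modules(module_assignment(labels), x,
                                merge_height = 0.25)
  expect_length(setdiff(unique(unclass(merged)), "grey"), 1L)
  expect_equal(unique(unclass(merged)), "turquoise")
})

test_that("eigenmetabolite scores are centred, sign-oriented and bounded in variance explained", {
  set.seed(8)
  x <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("m", 1:20), paste0("s", 1:12)))
  eig <- eigenmetabolite(x, rownames(x))
  expect_lt(abs(mean(eig$scores)), 1e-10)
  z <- t(scale(t(x)))
  expect_gte(cor(eig$scores, colMeans(z)), 0)
  expect_gt(eig$var_explained, 0)
  expect_lte(eig$var_explained, 1)
})

test_that("module labels are size-ordered colors with grey for unassigned", {
  set.seed(9)
  n <- 60
  mk <- function(p, rho = 0.8) {
    f <- rnorm(n)
    t(sapply(seq_len(p), function(i) sqrt(rho) * f +
               sqrt(1 - rho) * rnorm(n)))
  }
  x <- rbind(mk(50), mk(35), matrix(rnorm(40 * n), 40, n))
  dimnames(x) <- list(sprintf("m%03d", 1:125), paste0("s", 1:n))
  asg <- detect_modules(x, network_params(min_module_size = 30))$assignment
  lab <- unclass(asg)
  sizes <- table(lab)
  expect_gte(sizes[["turquoise"]], sizes[["blue"]])   # largest first
  expect_true("grey" %in% lab)
  expect_length(unique(lab[1:50]), 1L)
  expect_length(unique(lab[51:85]), 1L)
})

test_that("kME is highest for a module's own members", {
  set.seed(10)
  n <- 50
  f <- rnorm(n)
  mod <- t(sapply(1:35, function(i) 0.9 * f + 0.4 * rnorm(n)))
  noise <- matrix(rnorm(35 * n), 35, n)
  x <- rbind(mod, noise)
  dimnames(x) <- list(sprintf("m%02d", 1:70), paste0("s", 1:n))
  ms <- detect_modules(x, network_params(min_module_size = 30))
  members <- names(ms$assignment)[unclass(ms$assignment) != "grey"]
  grey <- setdiff(names(ms$assignment), members)
  expect_false(anyNA(ms$kME[members]))
  expect_true(all(is.na(ms$kME[grey])))
  expect_gt(mean(abs(ms$kME[members])), 0.7)
})
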