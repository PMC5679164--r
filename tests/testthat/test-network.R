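## nm with a transcript induced in one stimulus at a controllable level
induced_nm <- function(max_ratios, n_rep = 3, seed = 1) {
  set.seed(seed)
  n <- length(max_ratios)
  r <- matrix(1, n, 2 * n_rep)
  r[, 1:n_rep] <- max_ratios           # condition mean = the given ratio in sA
  rownames(r) <- sprintf("G%03d", seq_len(n))
  make_nm(r, stimulus = rep(c("sA", "sB"), each = n_rep),
          donor = sprintf("D%02d", seq_len(2 * n_rep)))
}

test_that("the induced-transcript pre-filter applies an inclusive two-fold rule", {
  nm <- induced_nm(c(1.9, 2.0, 4, 1.2))
  out <- prefilter_induced(nm)
  expect_setequal(rownames(out$ratios), c("G002", "G003"))
  expect_error(prefilter_induced(induced_nm(c(1.1, 1.2))), "no induced")
})

test_that("adjacency/TOM dissimilarity matches a brute-force formula oracle", {
  set.seed(20)
  tom_oracle <- function(x, beta) {
    C <- cor(t(x)); A <- abs(C)^beta; diag(A) <- 0
    n <- nrow(A)
    k <- rowSums(A)
    out <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      num <- A[i, j]
      for (u in 1:n) if (u != i && u != j) num <- num + A[i, u] * A[u, j]
      out[i, j] <- 1 - num / (min(k[i], k[j]) + 1 - A[i, j])
    }
    out
  }
  for (rep in 1:100) {
    x <- matrix(rnorm(10 * 8), 10, 8,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:8)))
    d <- adjacency_tom(x, network_config(soft_power = 6))
    o <- tom_oracle(x, 6)
    expect_equal(unname(d - diag(diag(d))), o, tolerance = 1e-10)
    expect_true(all(d >= 0 & d <= 1))
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("identical transcripts are maximally similar, independent noise nearly dissimilar", {
  set.seed(21)
  x <- matrix(rnorm(200 * 100), 200, 100,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  x[2, ] <- x[1, ]
  d <- adjacency_tom(x, network_config(soft_power = 6))
  expect_lt(d["g001", "g002"], 0.05)
  expect_gt(d["g003", "g004"], 0.9)
  ## zero-variance transcripts are excluded with a warning
  x[5, ] <- 3
  expect_warning(d2 <- adjacency_tom(x, network_config(soft_power = 6)), "zero-variance")
  expect_false("g005" %in% rownames(d2))
})

test_that("tree cut recovers planted correlation blocks and respects the size floor", {
  set.seed(22)
  x <- rbind(make_block(50, 40, 0.8, "A"), make_block(50, 40, 0.8, "B"))
  rownames(x) <- sprintf("g%03d", 1:100)
  cfg <- network_config(soft_power = 6, min_module_size = 30)
  labels <- detect_modules(adjacency_tom(x, cfg), cfg)
  truth <- rep(c("blkA", "blkB"), each = 50)
  expect_equal(length(setdiff(unique(labels), "unassigned")), 2)
  expect_gte(ari(labels, truth), 0.9)
  ## a 29-member block cannot reach the floor of 30, its 40-member
  ## neighbour can
  set.seed(23)
  x29 <- rbind(make_block(29, 40, 0.9, "A"), make_block(40, 40, 0.8, "B"))
  rownames(x29) <- sprintf("g%03d", 1:69)
  lab29 <- detect_modules(adjacency_tom(x29, cfg), cfg)
  expect_true(all(lab29[1:29] == "unassigned"))
  expect_equal(length(setdiff(unique(lab29[30:69]), "unassigned")), 1)
})

test_that("pure noise yields (near) nothing assigned", {
  set.seed(24)
  x <- matrix(rnorm(100 * 15), 100, 15,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  cfg <- network_config(soft_power = 6, min_module_size = 30)
  labels <- detect_modules(adjacency_tom(x, cfg), cfg)
  expect_lte(mean(labels != "unassigned"), 0.05)
  ## fewer transcripts than the floor: warning, all unassigned
  expect_warning(lab_small <- detect_modules(adjacency_tom(x[1:10, ], cfg), cfg),
                 "min_module_size")
  expect_true(all(lab_small == "unassigned"))
})

test_that("eigengenes summarize modules with the documented conventions", {
  set.seed(25)
  base <- rnorm(12)
  x <- rbind(g1 = base, g2 = base, g3 = base)
  x <- x + 0            # identical members: rank-1 module
  colnames(x) <- sprintf("c%02d", 1:12)
  labels <- setNames(rep("mod1", 3), rownames(x))
  eg <- module_eigengenes(x, labels)
  expect_equal(abs(cor(eg[, 1], x[1, ])), 1, tolerance = 1e-12)
  expect_equal(sum(eg[, 1]^2), 1, tolerance = 1e-12)
  ## sign convention: positively aligned with the module mean profile
  z <- scale(t(x))
  expect_gte(cor(eg[, 1], rowMeans(z)), 0)
  ## flipping every member flips the eigengene
  eg_fl <- module_eigengenes(-x, labels)
  expect_equal(unclass(eg_fl)[, 1], -unclass(eg)[, 1], tolerance = 1e-12)
})

test_that("the eigengene explains at least as much variance as any member", {
  set.seed(26)
  x <- make_block(8, 20, 0.6)
  labels <- setNames(rep("m", 8), rownames(x))
  eg <- module_eigengenes(x, labels)
  z <- scale(t(x))
  explained <- function(v) sum((t(z) %*% (v / sqrt(sum(v^2))))^2)
  e_eg <- explained(unclass(eg)[, 1])
  for (j in 1:8) expect_gte(e_eg + 1e-10, explained(z[, j]))
})

test_that("modules with near-identical eigengenes merge; distant ones do not", {
  set.seed(27)
  f <- rnorm(20)
  ## two modules driven by the same latent factor -> eigengene cor ~ 1
  x <- rbind(t(replicate(10, f + rnorm(20, sd = 0.1))),
             t(replicate(10, f + rnorm(20, sd = 0.1))),
             make_block(10, 20, 0.9, "C"))
  rownames(x) <- sprintf("g%02d", 1:30)
  colnames(x) <- sprintf("c%02d", 1:20)
  labels <- setNames(rep(c("m1", "m2", "m3"), each = 10), rownames(x))
  eg0 <- module_eigengenes(x, labels)
  expect_gt(cor(unclass(eg0))["m1", "m2"], 0.9)
  merged <- merge_close_modules(x, labels, cut_height = 0.1)
  mods <- setdiff(unique(merged$labels), "unassigned")
  expect_equal(length(mods), 2)
  expect_equal(unname(merged$labels["g01"]), unname(merged$labels["g11"]))
  ## post-merge invariant: no eigengene pair closer than the cut height
  cc <- cor(unclass(merged$eigengenes))
  expect_true(all(cc[upper.tri(cc)] <= 1 - 0.1))
  ## single module: identity
  one <- merge_close_modules(x[1:10, ], labels[1:10], 0.1)
  expect_equal(unique(unname(one$labels)), "m1")
})

test_that("kME filtering relabels weak members and recomputes eigengenes", {
  set.seed(28)
  f <- rnorm(30)
  strong <- t(replicate(15, f + rnorm(30, sd = 0.2)))
  weak <- matrix(rnorm(5 * 30), 5, 30)     # unrelated to the module
  x <- rbind(strong, weak)
  rownames(x) <- sprintf("g%02d", 1:20)
  colnames(x) <- sprintf("c%02d", 1:30)
  labels <- setNames(rep("m1", 20), rownames(x))
  eg <- module_eigengenes(x, labels)
  out <- kme_filter(x, labels, eg, min_kme = 0.7)
  kme <- cor(t(x), unclass(eg)[, 1])[, 1]
  expect_setequal(names(out$labels)[out$labels == "m1"], names(kme)[abs(kme) >= 0.7])
  ## retained members really exceed the threshold against pre-filter eigengenes
  expect_true(all(abs(kme[out$labels == "m1"]) >= 0.7))
  ## dissolving an entire module warns
  labels2 <- setNames(rep("m1", 5), rownames(x)[16:20])
  eg2 <- module_eigengenes(x[16:20, ], labels2)
  expect_warning(kme_filter(x[16:20, ], labels2, eg2, min_kme = 0.9999), "dissolved")
})

test_that("soft power selection follows its documented rule", {
  set.seed(29)
  ## heterogeneous block structure gives a hub-dominated degree distribution
  x <- rbind(make_block(40, 30, 0.85, "A"), make_block(15, 30, 0.7, "B"),
             matrix(rnorm(45 * 30), 45, 30))
  rownames(x) <- sprintf("g%03d", 1:100)
  p <- suppressWarnings(pick_soft_power(x))
  fit <- attr(p, "fit")
  ok <- fit$power[fit$rsq >= 0.8]
  if (length(ok)) {
    expect_equal(as.integer(p), min(ok))
  } else {
    expect_equal(as.integer(p), fit$power[which.max(fit$rsq)])
  }
  ## a single candidate is always returned, with its fit reported
  p6 <- suppressWarnings(pick_soft_power(x, candidates = 6))
  expect_equal(as.integer(p6), 6L)
  expect_equal(attr(p6, "fit")$power, 6)
  expect_error(pick_soft_power(x, candidates = integer()), "empty")
  xc <- matrix(5, 25, 10, dimnames = list(sprintf("g%02d", 1:25), NULL))
  expect_error(pick_soft_power(xc), "constant")
})

test_that("label permutation leaves module memberships invariant", {
  set.seed(30)
  x <- rbind(make_block(35, 25, 0.8, "A"), make_block(35, 25, 0.8, "B"))
  rownames(x) <- sprintf("g%03d", 1:70)
  cfg <- network_config(soft_power = 6, min_module_size = 30)
  lab1 <- detect_modules(adjacency_tom(x, cfg), cfg)
  perm <- sample(70)
  lab2 <- detect_modules(adjacency_tom(x[perm, ], cfg), cfg)
  expect_equal(ari(lab1[rownames(x)], lab2[rownames(x)]), 1)
})
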