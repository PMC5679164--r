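## helper: nm whose probes carry planted per-stimulus shifts
two_program_nm <- function(noise_sd = 0.2, n_samples = 6, seed = 1) {
  set.seed(seed)
  probes <- sprintf("G%03d", 1:100)
  ## program 1 induced in stimA, program 2 repressed there
  shift <- c(rep(2, 50), rep(-2, 50))
  lg <- matrix(rnorm(100 * n_samples, sd = noise_sd), 100, n_samples) + shift
  r <- 2^lg
  rownames(r) <- probes
  make_nm(r, stimulus = rep("stimA", n_samples))
}

test_that("per-stimulus clustering groups identical profiles and honours k", {
  r <- 2^rbind(a = c(1, 1, 1), b = c(1, 1, 1), c = c(-2, 0, 2), d = c(5, 5, 5))
  nm <- make_nm(r, stimulus = rep("s1", 3))
  parts <- cluster_per_stimulus(nm, k = 2, seed = 1)
  expect_equal(parts["a", 1], parts["b", 1])
  ## forced partition: one cluster per distinct profile (a and b coincide)
  parts4 <- cluster_per_stimulus(nm, k = 4, seed = 1)
  expect_equal(length(unique(parts4[, 1])), 3)
  expect_equal(parts4["a", 1], parts4["b", 1])
  ## with all-distinct profiles, k = n gives singletons
  nm_d <- make_nm(2^rbind(a = c(0, 0), b = c(1, 1), c = c(2, 0)),
                  stimulus = rep("s1", 2))
  parts_d <- cluster_per_stimulus(nm_d, k = 3, seed = 1)
  expect_equal(length(unique(parts_d[, 1])), 3)
  expect_error(cluster_per_stimulus(nm, k = 5), "exceeds")
  expect_error(cluster_per_stimulus(nm, k = 1), ">= 2")
})

test_that("clustering recovers two planted programs (ARI >= 0.9 at sd 0.3)", {
  nm <- two_program_nm(noise_sd = 0.3, seed = 4)
  parts <- cluster_per_stimulus(nm, k = 2, seed = 2)
  truth <- rep(c("p1", "p2"), each = 50)
  expect_gte(ari(parts[, 1], truth), 0.9)
})

test_that("cocluster scores count shared labels per stimulus group", {
  set.seed(5)
  labels <- matrix(sample(1:4, 6 * 15, replace = TRUE), 6, 15,
                   dimnames = list(letters[1:6], NULL))
  labels["a", ] <- 1; labels["b", ] <- 1          # together everywhere
  labels["c", ] <- 2; labels["d", ] <- 3          # never together
  labels["e", ] <- c(rep(9, 9), 2:7)              # with f in exactly 9 groups
  labels["f", ] <- c(rep(9, 9), 12:17)
  cc <- cocluster_scores(labels)
  expect_equal(cc["a", "b"], 15L)
  expect_equal(cc["c", "d"], 0L)
  expect_equal(cc["e", "f"], 9L)
  expect_equal(attr(cc, "n_groups"), 15)
})

test_that("cocluster matrices satisfy range, symmetry and diagonal invariants", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:40, 1); S <- sample(2:15, 1)
    labels <- matrix(sample(1:5, n * S, replace = TRUE), n, S,
                     dimnames = list(sprintf("t%02d", 1:n), NULL))
    cc <- cocluster_scores(labels)
    expect_true(all(cc >= 0 & cc <= S))
    expect_identical(cc, t(cc), ignore_attr = TRUE)
    expect_true(all(diag(cc) == S))
  }
})

## build a cocluster matrix directly for clique tests
make_cc <- function(n, pairs_at, S = 15, ids = letters[seq_len(n)]) {
  cc <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (p in pairs_at) cc[p[[1]], p[[2]]] <- cc[p[[2]], p[[1]]] <- as.integer(p[[3]])
  diag(cc) <- as.integer(S)
  attr(cc, "n_groups") <- S
  cc
}

test_that("clique extraction separates fully conserved groups", {
  cc <- make_cc(5, list(list("a","b",15), list("a","c",15), list("b","c",15),
                        list("d","e",15)))
  ms <- extract_modules(cc, min_size = 2, t_min = 10)
  expect_equal(length(ms), 2)
  expect_equal(ms[[1]], c("a", "b", "c"))
  expect_equal(ms[[2]], c("d", "e"))
  expect_equal(attr(ms, "unassigned"), character(0))
})

test_that("empty and complete graphs give zero and one module", {
  cc0 <- make_cc(6, list())
  ms0 <- extract_modules(cc0, min_size = 2, t_min = 1)
  expect_equal(length(ms0), 0)
  expect_equal(sort(attr(ms0, "unassigned")), letters[1:6])
  ccf <- make_cc(6, combn(letters[1:6], 2, function(p) list(p[1], p[2], 15),
                          simplify = FALSE))
  msf <- extract_modules(ccf, min_size = 3, t_min = 5)
  expect_equal(length(msf), 1)
  expect_equal(msf[[1]], letters[1:6])
})

test_that("modules are disjoint and order-invariant", {
  set.seed(7)
  for (i in 1:10) {
    n <- 30
    labels <- matrix(sample(1:3, n * 8, replace = TRUE), n, 8,
                     dimnames = list(sprintf("t%02d", 1:n), NULL))
    cc <- cocluster_scores(labels)
    ms <- extract_modules(cc, min_size = 3, t_min = 3)
    all_members <- unlist(ms)
    expect_equal(anyDuplicated(all_members), 0)
    expect_true(all(all_members %in% rownames(cc)))
    expect_setequal(c(all_members, attr(ms, "unassigned")), rownames(cc))
    ## permuting the transcript order leaves the module sets unchanged
    perm <- sample(n)
    ms2 <- extract_modules(cc[perm, perm], min_size = 3, t_min = 3)
    expect_identical(lapply(unname(unclass(ms)), sort), lapply(unname(unclass(ms2)), sort))
  }
})

test_that("consolidation reunites cores and admits only t_min-clique genes", {
  ## two perfectly conserved cores of one pattern, cross-linked at t_min;
  ## one satellite linked to every member, one linked to all but z
  pairs <- c(
    list(list("w", "x", 15), list("y", "z", 15)),
    lapply(list(c("w","y"), c("w","z"), c("x","y"), c("x","z")),
           function(p) list(p[1], p[2], 5)),
    lapply(c("w", "x", "y", "z"), function(g) list("s", g, 5)),
    lapply(c("w", "x", "y"), function(g) list("t", g, 5)))
  cc <- make_cc(6, pairs, ids = c("w", "x", "y", "z", "s", "t"))
  ms <- extract_modules(cc, min_size = 2, t_min = 5)
  expect_equal(length(ms), 1)
  expect_equal(ms[[1]], c("s", "w", "x", "y", "z"))   # t lacks an edge to z
  expect_setequal(attr(ms, "unassigned"), "t")
  ## every module is still a clique at t_min
  expect_true(all(cc[ms[[1]], ms[[1]]] >= 5))
  ## without consolidation the greedy scan leaves two separate cores
  ms0 <- extract_modules(cc, min_size = 2, t_min = 5, expand = FALSE)
  expect_equal(length(ms0), 2)
  expect_equal(ms0[[1]], c("w", "x"))
  expect_equal(ms0[[2]], c("y", "z"))
})

test_that("component mode relaxes the clique requirement", {
  ## a,b,c form a path (a-b, b-c) at score 15: no 3-clique, one component
  cc <- make_cc(4, list(list("a","b",15), list("b","c",15)))
  ms_clique <- extract_modules(cc, min_size = 3, t_min = 10)
  expect_equal(length(ms_clique), 0)
  ms_comp <- extract_modules(cc, min_size = 3, t_min = 10, mode = "components")
  expect_equal(length(ms_comp), 1)
  expect_equal(ms_comp[[1]], c("a", "b", "c"))
})

test_that("fingerprint counts two-fold responders with inclusive thresholds", {
  ratios <- c(4, 2, 2.1, 1.5, 1, 0.9, 0.5, 0.4, 0.45, 1.2)
  nm <- make_nm(cbind(s1 = ratios), stimulus = "stimA")
  ms <- list(m1 = rownames(nm$ratios))
  fp <- fingerprint(ms, nm)
  expect_equal(fp$pct_up, 30)
  expect_equal(fp$pct_down, 30)
  ## no change and saturation
  fp0 <- fingerprint(list(m = rownames(nm$ratios)), make_nm(cbind(s1 = rep(1, 10))))
  expect_equal(c(fp0$pct_up, fp0$pct_down), c(0, 0))
  fp8 <- fingerprint(list(m = rownames(nm$ratios)), make_nm(cbind(s1 = rep(8, 10))))
  expect_equal(c(fp8$pct_up, fp8$pct_down), c(100, 0))
})

test_that("fingerprint denominators include transcripts missing from the data", {
  nm <- make_nm(cbind(s1 = c(4, 4, 1)), stimulus = "stimA")
  ms <- list(m1 = c(rownames(nm$ratios), "ABSENT1", "ABSENT2"))
  fp <- fingerprint(ms, nm)
  expect_equal(fp$pct_up, 100 * 2 / 5)
  fp2 <- fingerprint(ms, nm, missing_in_denominator = FALSE)
  expect_equal(fp2$pct_up, 100 * 2 / 3)
  expect_error(fingerprint(list(m = character()), nm), "non-empty")
})

test_that("fingerprint matches a brute-force recount on random inputs", {
  set.seed(8)
  checked <- 0
  for (i in 1:250) {
    n <- sample(5:20, 1)
    nm <- make_nm(matrix(2^rnorm(n * 4, sd = 1.2), n, 4),
                  stimulus = rep(c("sA", "sB"), each = 2),
                  donor = sprintf("D%02d", 1:4))
    genes <- sample(rownames(nm$ratios), sample(2:n, 1))
    fp <- fingerprint(list(m = genes), nm, fold = 2)
    for (st in c("sA", "sB")) {
      cond <- 2^rowMeans(log2(nm$ratios[genes, nm$samples$stimulus == st, drop = FALSE]))
      up <- sum(cond >= 2); down <- sum(cond <= 0.5)
      row <- fp[fp$condition == st, ]
      expect_equal(row$pct_up, 100 * up / length(genes), tolerance = 1e-10)
      expect_equal(row$pct_down, 100 * down / length(genes), tolerance = 1e-10)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 500)
})

test_that("MDTM sums qualifying absolute fold changes", {
  ratios <- c(3, 1 / 4, 1.5, 1 / 1.9, 2)
  expect_equal(mdtm(ratios), 3 + 4 + 2)
  expect_equal(mdtm(c(1.2, 0.9, 1.9)), 0)
  ## monotone in any qualifying entry
  r2 <- ratios; r2[1] <- 3.5
  expect_gt(mdtm(r2), mdtm(ratios))
  expect_error(mdtm(c(2, 0)), "> 0")
  ## transcript subset restriction
  named <- setNames(ratios, sprintf("g%d", 1:5))
  expect_equal(mdtm(named, subset = c("g1", "g3")), 3)
})

test_that("MDTM matches a brute-force oracle on random samples", {
  set.seed(9)
  for (i in 1:1000) {
    v <- 2^rnorm(sample(3:30, 1), sd = 1.5)
    oracle <- 0
    for (x in v) {
      s <- if (x >= 1) x else 1 / x
      if (s >= 2) oracle <- oracle + s
    }
    expect_equal(mdtm(v), oracle, tolerance = 1e-10)
  }
})

test_that("per-sample MDTM agrees with the scalar definition", {
  set.seed(10)
  nm <- make_nm(matrix(2^rnorm(40, sd = 1.5), 10, 4),
                stimulus = rep("sA", 4))
  md <- mdtm_samples(nm)
  for (j in 1:4) expect_equal(md$mdtm[j], mdtm(nm$ratios[, j]))
})
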