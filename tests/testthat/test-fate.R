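paired_cm <- function(S, U, classes = NULL) {
  meta <- data.frame(species = "sim", stage = "s1",
                     class = if (is.null(classes)) NA_character_ else classes)
  list(spliced = count_matrix(S, sprintf("g%03d", seq_len(nrow(S))),
                              sprintf("c%03d", seq_len(ncol(S))), meta,
                              layer_tag = "spliced"),
       unspliced = count_matrix(U, sprintf("g%03d", seq_len(nrow(U))),
                                sprintf("c%03d", seq_len(ncol(U))), meta,
                                layer_tag = "unspliced"))
}

test_that("unspliced-fraction filter keeps the 7% boundary and drops u=0", {
  S <- matrix(c(93, 94, 50, 10, 0), 1, 5)
  U <- matrix(c(7, 6, 50, 90, 0), 1, 5)
  S <- rbind(S, 0); U <- rbind(U, 0)     # second gene all zero
  p <- paired_cm(S, U)
  out <- filter_unspliced_cells(p$spliced, p$unspliced, min_frac = 0.07)
  # fractions: 0.07 (kept, boundary), 0.06 (dropped), 0.5, 0.9, zero-total
  expect_setequal(out$spliced$cell_ids, c("c001", "c003", "c004"))
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(attr(out, "overall_frac"),
               (7 + 50 + 90) / (100 + 100 + 100))
  expect_error(filter_unspliced_cells(p$spliced, p$unspliced, min_frac = 0.99),
               "every cell")
})

test_that("shared-count gene filter is strictly greater-than", {
  S <- matrix(c(11, 10, 50, 0), 4, 1)
  U <- matrix(c(11, 50, 10, 0), 4, 1)
  p <- paired_cm(S, U)
  kept <- gene_filter_shared_counts(p$spliced, p$unspliced, min_shared = 10)
  expect_identical(kept, "g001")   # (11,11) kept; (10,50),(50,10),(0,0) not
})

test_that("moments equal brute-force neighbour averaging", {
  set.seed(40)
  n <- 20
  S <- matrix(rpois(15 * n, 8), 15, n)
  U <- matrix(rpois(15 * n, 4), 15, n)
  p <- paired_cm(S, U)
  mom <- knn_moments(p$spliced, p$unspliced, n_hvgs = 15, n_pcs = 5, k = 4)
  sf <- colSums(S) / median(colSums(S))
  Sn <- t(sweep(S, 2, sf, `/`))
  Un <- t(sweep(U, 2, sf, `/`))
  expect_equal(mom$Ms, oracle_knn_average(Sn, mom$nn), ignore_attr = TRUE)
  expect_equal(mom$Mu, oracle_knn_average(Un, mom$nn), ignore_attr = TRUE)
  # k = n-1: every neighbourhood is the whole data set
  mom_all <- knn_moments(p$spliced, p$unspliced, n_hvgs = 15, n_pcs = 5,
                         k = n - 1)
  expect_equal(mom_all$Ms, matrix(colMeans(Sn), n, 15, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(knn_moments(p$spliced, p$unspliced, k = n), "below the cell")
})

test_that("duplicated cells receive identical moment rows", {
  set.seed(41)
  S <- matrix(rpois(12 * 10, 6), 12, 10)
  S[, 2] <- S[, 1]
  U <- matrix(rpois(12 * 10, 3), 12, 10)
  U[, 2] <- U[, 1]
  p <- paired_cm(S, U)
  mom <- knn_moments(p$spliced, p$unspliced, n_hvgs = 12, n_pcs = 4, k = 3)
  # identical inputs, identical neighbourhood geometry
  expect_equal(mom$Ms[1, ], mom$Ms[2, ], tolerance = 1e-9)
})

test_that("steady-state slope is exact without noise and signs velocities", {
  set.seed(42)
  s <- runif(200, 0, 10)
  Ms <- cbind(a = s)
  Mu <- cbind(a = 0.5 * s)
  model <- fit_steady_state_gamma(Ms, Mu)
  expect_equal(unname(model$gamma["a"]), 0.5, tolerance = 1e-12)
  expect_true(all(abs(model$V) < 1e-12))
  # induction-phase cells (u above the line) have positive velocity
  Mu2 <- cbind(a = 0.5 * s + c(rep(0, 150), rep(2, 50)))
  model2 <- fit_steady_state_gamma(Ms, Mu2)
  expect_true(all(model2$V[151:200, 1] > 0))
  # all-negative-slope genes are dropped with an error when none remain
  expect_error(fit_steady_state_gamma(cbind(b = s), cbind(b = -s)),
               "positive steady-state slope")
})

test_that("gamma/beta is recovered within 10% under Poisson noise", {
  set.seed(43)
  n <- 500
  alpha <- runif(n, 1, 20)         # cells spread along the steady-state line
  u_mean <- alpha / 8              # beta = 8
  s_mean <- alpha / 4              # gamma = 4 -> gamma/beta = 0.5
  scale <- 40
  Ms <- cbind(g = rpois(n, scale * s_mean) / scale)
  Mu <- cbind(g = rpois(n, scale * u_mean) / scale)
  model <- fit_steady_state_gamma(Ms, Mu)
  expect_equal(unname(model$gamma["g"]), 0.5, tolerance = 0.1)
})

test_that("velocity kernel concentrates mass along the velocity direction", {
  # cell 1 at origin; neighbours along +x, -x, +y
  Ms <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1))
  V <- rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 0))
  nn <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  rownames(Ms) <- paste0("c", 1:4)
  model <- list(Ms = Ms, V = V)
  Tv <- velocity_kernel(model, nn, softmax_scale = 4)
  r1 <- as.matrix(Tv)[1, ]
  expect_equal(unname(which.max(r1)), 2L)      # aligned neighbour wins
  oracle <- oracle_softmax_row(c(1, 0), Ms[1, ], Ms[2:4, ], 4)
  expect_equal(unname(r1[2:4]), unname(oracle), tolerance = 1e-12)
  # zero-velocity cells get uniform rows over neighbours
  expect_equal(unname(as.matrix(Tv)[2, c(1, 3, 4)]), rep(1 / 3, 3))
  expect_equal(unname(Matrix::rowSums(Tv)), rep(1, 4))
})

test_that("kernel combination is convex and validates the weight", {
  set.seed(44)
  nn <- t(vapply(1:6, function(i) sample(setdiff(1:6, i), 3), numeric(3)))
  Ms <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("c", 1:6), NULL))
  V <- matrix(rnorm(12), 6, 2)
  Tv <- velocity_kernel(list(Ms = Ms, V = V), nn)
  A <- Matrix::sparseMatrix(i = rep(1:6, each = 3), j = as.vector(t(nn)),
                            x = 1, dims = c(6, 6))
  Tc <- connectivity_kernel(A + Matrix::t(A))
  expect_equal(as.matrix(combine_kernels(Tv, Tc, 0)), as.matrix(Tv),
               ignore_attr = TRUE)
  expect_equal(as.matrix(combine_kernels(Tv, Tc, 1)), as.matrix(Tc),
               ignore_attr = TRUE)
  mix <- combine_kernels(Tv, Tc, 0.2)
  expect_lt(max(abs(Matrix::rowSums(mix) - 1)), 1e-9)
  expect_true(all(mix@x >= 0))
  expect_error(combine_kernels(Tv, Tc, 1.4), "0, 1")
})

test_that("absorbing blocks are flagged terminal; reversal finds the source", {
  # directed chain: 1 -> 2 -> 3 with two absorbing end blocks {4,5}, {6,7}
  n <- 7
  T <- matrix(0, n, n, dimnames = list(paste0("c", 1:7), paste0("c", 1:7)))
  T[1, 2] <- 1
  T[2, c(3, 1)] <- c(0.9, 0.1)
  T[3, c(4, 6)] <- c(0.5, 0.5)
  T[4, 4:5] <- 0.5; T[5, 4:5] <- 0.5  # absorbing (aperiodic) block A
  T[6, 6:7] <- 0.5; T[7, 6:7] <- 0.5  # absorbing (aperiodic) block B
  labels <- c("root", "mid", "mid", "A", "A", "B", "B")
  st <- terminal_initial_states(Matrix::Matrix(T, sparse = TRUE), labels,
                                top_quantile = 0.5)
  expect_setequal(names(st$terminal), c("A", "B"))
  expect_equal(st$root_class, "root")
})

test_that("gambler's ruin absorption probabilities are exact", {
  # random walk on 0..4, absorbing ends, p = 1/2: P(up from k) = k/4
  n <- 5
  T <- matrix(0, n, n)
  T[1, 1] <- 1; T[5, 5] <- 1
  for (k in 2:4) T[k, c(k - 1, k + 1)] <- 0.5
  rownames(T) <- colnames(T) <- paste0("s", 0:4)
  fate <- absorption_probabilities(Matrix::Matrix(T, sparse = TRUE),
                                   list(lo = 1L, hi = 5L))
  expect_equal(unname(fate["s1", "hi"]), 1 / 4)
  expect_equal(unname(fate["s2", "hi"]), 2 / 4)
  expect_equal(unname(fate["s3", "hi"]), 3 / 4)
  # a cell already terminal is one-hot on its own lineage
  expect_equal(unname(fate["s0", ]), c(1, 0))
  expect_error(absorption_probabilities(T, list(a = 1L, b = 1L)), "disjoint")
})

test_that("absorption matches Monte-Carlo simulation on a 10-state chain", {
  set.seed(45)
  n <- 10
  P <- matrix(rexp(n * n), n, n)
  P[9, ] <- 0; P[9, 9] <- 1        # absorbing states 9 and 10
  P[10, ] <- 0; P[10, 10] <- 1
  P <- P / rowSums(P)
  rownames(P) <- colnames(P) <- paste0("s", 1:n)
  fate <- absorption_probabilities(Matrix::Matrix(P, sparse = TRUE),
                                   list(A = 9L, B = 10L))
  mc <- oracle_mc_absorption(P, c(9L, 10L), c(1L, 2L), start = 1L,
                             n_traj = 1e5)
  expect_equal(unname(fate["s1", ]), mc, tolerance = 0.01)
})

test_that("DPT is zero at the root and monotone along a path graph", {
  n <- 12
  W <- Matrix::sparseMatrix(i = 1:(n - 1), j = 2:n, x = 1, dims = c(n, n),
                            dimnames = list(paste0("c", 1:n),
                                            paste0("c", 1:n)))
  W <- W + Matrix::t(W)
  dpt <- dpt_pseudotime(W, root = 1, n_comps = 6)
  expect_equal(unname(dpt[1]), 0)
  expect_true(all(diff(dpt) > 0))
  expect_equal(max(dpt), 1)
  # disconnected cells get NA
  W2 <- Matrix::bdiag(W, Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1),
                                              x = 1, dims = c(2, 2)))
  rownames(W2) <- colnames(W2) <- paste0("c", 1:(n + 2))
  expect_warning(d2 <- dpt_pseudotime(W2, root = 1), "disconnected")
  expect_true(all(is.na(d2[(n + 1):(n + 2)])))
})

test_that("driver ranking rewards fate-correlated genes, drops flat ones", {
  set.seed(46)
  n <- 50
  fate <- cbind(L = runif(n))
  rownames(fate) <- paste0("c", 1:n)
  Ms <- cbind(copycat = fate[, 1],
              flat = rep(2, n),
              noise = rnorm(n))
  rownames(Ms) <- rownames(fate)
  dt <- rank_drivers(Ms, fate, "L", top_n = 10)
  expect_equal(dt$gene[1], "copycat")
  expect_equal(dt$correlation[1], 1)
  expect_false("flat" %in% dt$gene)
  expect_equal(dt$rank, seq_len(nrow(dt)))
})

test_that("fate-weighted trend honours weights and fits linear data", {
  set.seed(47)
  t <- seq(0, 1, length.out = 80)
  y <- 2 + 3 * t
  tr <- fit_fate_weighted_trend(y, t, rep(1, 80))
  expect_equal(tr$value, 2 + 3 * tr$grid_t, tolerance = 1e-6)
  # weight-zero cells have no influence at all
  y2 <- c(y[1:60], rnorm(20, 50))
  w <- c(rep(1, 60), rep(0, 20))
  tr2 <- fit_fate_weighted_trend(y2, t, w)
  tr3 <- fit_fate_weighted_trend(y2[1:60], t[1:60], w[1:60])
  expect_equal(tr2$value, tr3$value, tolerance = 1e-9)
  expect_error(fit_fate_weighted_trend(y, t, rep(0, 80)), "zero")
})

test_that("driver/regulator set algebra counts exact overlaps", {
  d <- list(m = list(AC = paste0("g", 1:100), PR = paste0("g", 200:299)),
            z = list(AC = paste0("g", c(1:5, 500:594)),
                     PR = paste0("g", 200:299)))
  r <- list(m = list(AC = c("g1", "g2", "g900")),
            z = list(AC = c("g500", "nope")))
  out <- driver_regulator_intersection(d, r)
  expect_equal(out$shared$AC, sort(paste0("g", 1:5)))
  expect_length(out$shared$PR, 100)
  expect_equal(out$shared_counts$n_shared[out$shared_counts$class == "AC"], 5L)
  expect_equal(out$driver_regulators$m$AC, c("g1", "g2"))
  expect_equal(out$driver_regulators$z$AC, "g500")
  # disjoint lists share nothing
  expect_length(driver_regulator_intersection(
    list(a = list(X = "g1"), b = list(X = "g2")), list())$shared$X, 0)
})

test_that("planted lineage structure is recovered end to end", {
  fp <- default_fate()
  expect_setequal(names(fp$states$terminal),
                  paste0("terminal", 1:3))
  expect_equal(fp$states$root_class, "progenitor")
  expect_lt(max(abs(Matrix::rowSums(fp$T) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(fp$fate) - 1)), 1e-9)
  kin <- default_kinetics()
  dpt <- dpt_pseudotime(fp$mom$graph, fp$states$initial[1])
  expect_gte(stats::cor(dpt, fp$t, method = "spearman"), 0.9)
})
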