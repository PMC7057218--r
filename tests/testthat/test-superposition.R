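test_that("Kabsch recovers constructed transforms and rejects degeneracy", {
  set.seed(1)
  A <- matrix(rnorm(30, sd = 5), 10, 3)
  fit0 <- kabsch_rmsd(A, A)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  R <- rotation_about_axis(c(0, 0, 1), 37)
  B <- transform_xyz(A, R, c(1, 2, 3))
  fit <- kabsch_rmsd(A, B)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation, R, tolerance = 1e-6)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # a mirror image can never be matched by a proper rotation
  M <- A
  M[, 1] <- -M[, 1]
  fitm <- kabsch_rmsd(M, A)
  expect_gt(fitm$rmsd, 0.5)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_rmsd(A[1:2, ], A[1:2, ]), "degenerate")
  L <- cbind(1:6, 0, 0)
  expect_error(kabsch_rmsd(L, L), "degenerate")
})

test_that("inverse-variance weighting downweights outliers", {
  set.seed(3)
  A <- matrix(rnorm(45, sd = 6), 15, 3)
  # noise-free pairing converges immediately
  fit0 <- weighted_refine(A, transform_xyz(A, rotation_about_axis(c(1, 1, 0), 20), c(3, 0, -1)))
  expect_lt(fit0$rmsd, 1e-9)
  expect_lte(fit0$iterations, 3)

  B <- A + matrix(rnorm(45, sd = 0.1), 15, 3)
  B[7, ] <- B[7, ] + c(5, 0, 0)   # one 5 A outlier pair
  fit <- weighted_refine(A, B)
  expect_lt(fit$weights[7], 0.1 * stats::median(fit$weights[-7]))
  expect_lte(fit$rmsd, kabsch_rmsd(A, B)$rmsd + 1e-12)

  # weighted refinement never reports a larger rmsd than the plain fit
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(36, sd = 4), 12, 3)
    Y <- X + matrix(rnorm(36, sd = 0.3), 12, 3)
    expect_lte(weighted_refine(X, Y)$rmsd, kabsch_rmsd(X, Y)$rmsd + 1e-12)
  }
})

test_that("a displaced fragment is relocated to its original site", {
  fx <- fold_fixture()
  tgt <- fx$structure
  frag <- new_structure(tgt$stretches[3])   # the helix
  set.seed(4)
  moved <- transform_structure(frag, random_rotation(), c(40, -25, 60))
  res <- superpose_fold(moved, tgt)
  expect_gte(length(res), 1)
  best <- res[[1]]
  expect_lt(best$rmsd, 0.1)
  # the match core is the fragment's original site
  expect_true(all(best$core$target_stretch == 3))
  expect_setequal(best$core$target_row, 1:9)
  # inverting the target-to-template transform relocates the fold there
  back <- sweep(moved$stretches[[1]]$xyz$CA, 2, best$translation) %*%
    best$rotation
  expect_lt(max(abs(back - tgt$stretches[[3]]$xyz$CA)), 0.1)
})

test_that("self-superposition is exact and equivariant", {
  fx <- fold_fixture()
  res <- superpose_fold(fx$structure, fx$structure)
  expect_gte(length(res), 1)
  expect_lt(res[[1]]$rmsd, 1e-9)
  expect_equal(res[[1]]$rotation, diag(3), tolerance = 1e-6)

  # equivariance: pre-rotating the target changes the recovered transform
  # by exactly the inverse of that motion (the fit maps target -> template)
  set.seed(6)
  R <- random_rotation()
  tv <- c(5, -8, 12)
  res2 <- superpose_fold(fx$structure, transform_structure(fx$structure, R, tv))
  expect_equal(res2[[1]]$rotation, t(R), tolerance = 1e-6)
  expect_equal(res2[[1]]$translation, -as.vector(t(R) %*% tv),
               tolerance = 1e-6)
})

test_that("a motif repeated at two sites yields two separate results", {
  els <- list(element("ah", 10), element("ah", 10, t = c(0, 10, 0)))
  shifted <- lapply(els, function(e) { e$t <- e$t + c(45, 0, 0); e })
  tgt <- assemble_fold(c(els, shifted))$structure
  tpl <- assemble_fold(els)$structure
  res <- superpose_fold(tpl, tgt)
  expect_length(res, 2)
  expect_equal(vapply(res, function(r) r$site_index, 1L), 1:2)
  # sites share no target residues
  ids <- lapply(res, function(r) paste(r$core$target_stretch, r$core$target_row))
  expect_length(intersect(ids[[1]], ids[[2]]), 0)
  for (r in res) expect_lt(r$rmsd, 1e-6)
})

test_that("trimming is restricted to fragments above five residues", {
  els <- list(element("ah", 5), element("ah", 5, t = c(0, 9, 0)))
  tgt <- assemble_fold(els)$structure
  res <- superpose_fold(tgt, tgt, ss_threshold = 30, tt_threshold = 30)
  expect_gte(length(res), 1)
  for (cut in res[[1]]$trimmed) expect_equal(cut, c(0L, 0L))
  expect_identical(trim_options(5), list(c(0L, 0L)))
  expect_length(trim_options(11), 16)     # all (0..3)^2 combinations
  expect_length(trim_options(7), 6)       # capped so >= 5 residues remain
})

test_that("the returned trims equal the full-enumeration argmin", {
  fx <- assemble_fold(list(element("ah", 12), element("bs", 9, t = c(0, 11, 0))))
  tgt <- fx$structure
  # bend the target helix ends so trimming pays off
  bent <- tgt
  for (r in c(1, 2, 11, 12)) {
    bent$stretches[[1]]$xyz$O[r, ] <- bent$stretches[[1]]$xyz$O[r, ] + c(0.4, 0, 0)
    for (nm in names(bent$stretches[[1]]$xyz)) {
      bent$stretches[[1]]$xyz[[nm]][r, ] <-
        bent$stretches[[1]]$xyz[[nm]][r, ] + c(0.8, -0.3, 0.2) * (r %% 3)
    }
  }
  res <- superpose_fold(tgt, bent, ss_threshold = 20, tt_threshold = 20)
  expect_gte(length(res), 1)
  best <- res[[1]]
  # independent oracle: re-enumerate every trim combination
  m <- best$match
  opts <- lapply(seq_len(nrow(m$assignment)), function(i) {
    cvnet:::trim_options(m$assignment$length[i])
  })
  ann_t <- annotate_structure(tgt)
  ann_g <- annotate_structure(bent)
  combos <- cvnet:::expand_trim_grid(opts)
  rms <- vapply(combos, function(cb) {
    pc <- cvnet:::site_pairing(ann_t, ann_g, m, cb, c("N", "CA", "C", "O"))
    weighted_refine(pc$a, pc$b)$rmsd
  }, numeric(1))
  expect_equal(best$rmsd, min(rms), tolerance = 1e-9)
})

test_that("superposed target coordinates are written per site", {
  fx <- fold_fixture()
  tgt <- fx$structure
  frag <- new_structure(tgt$stretches[3])
  set.seed(9)
  moved <- transform_structure(frag, random_rotation(), c(30, 10, -20))
  res <- superpose_fold(moved, tgt)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_superposed(tgt, res[[1]], f)
  p <- parse_structure(f)
  expect_equal(n_residues(p), n_residues(tgt))
})
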