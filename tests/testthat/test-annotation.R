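test_that("ideal elements score decisively toward their own hypothesis", {
  hx <- new_structure(list(build_ideal_element("ah", 12)))
  g <- build_cv_graph(structure_cvs(hx))
  sc <- annotate_cvs(g, hx, 0.85, 0.85)
  expect_true(all(sc$score_ah < sc$score_bs))
  expect_true(all(sc$label == "ah"))

  st <- new_structure(list(build_ideal_element("bs", 10)))
  g2 <- build_cv_graph(structure_cvs(st))
  sc2 <- annotate_cvs(g2, st, 0.5, 0.5)
  expect_true(all(sc2$score_bs < sc2$score_ah))
  expect_true(all(sc2$label == "bs"))
})

test_that("a degenerate CV takes maximal penalties on both hypotheses", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0), c(15.2, 0, 0))
  o <- ca[c(3, 2, 1, 5, 4), ]  # first window's O centroid == CA centroid
  strc <- new_structure(list(manual_stretch(ca, o)))
  g <- build_cv_graph(structure_cvs(strc))
  expect_true(g$cvs$degenerate[1])
  sc <- annotate_cvs(g, strc)
  expect_equal(sc$score_ah[1], 1)
  expect_equal(sc$score_bs[1], 1)
  expect_equal(sc$label[1], "coil")
})

test_that("strictness 0 never yields coil for non-tied CVs", {
  fx <- random_fixture(seed = 21, noise_sigma = 0.2)
  g <- build_cv_graph(structure_cvs(fx$structure))
  sc <- annotate_cvs(g, fx$structure, 0, 0)
  tied <- abs(sc$score_ah - sc$score_bs) == 0 | sc$degenerate
  expect_true(all(sc$label[!tied] != "coil"))
})

test_that("CV labels obey the argmin-under-strictness rule", {
  fx <- random_fixture(seed = 8, noise_sigma = 0.25)
  g <- build_cv_graph(structure_cvs(fx$structure))
  for (s in c(0.1, 0.4, 0.7)) {
    sc <- annotate_cvs(g, fx$structure, s, s)
    diff <- abs(sc$score_ah - sc$score_bs)
    argmin <- ifelse(sc$score_ah < sc$score_bs, "ah", "bs")
    expect_identical(sc$label[diff > s & !sc$degenerate],
                     argmin[diff > s & !sc$degenerate])
    expect_true(all(sc$label[diff <= s] == "coil"))
    expect_equal(sc$max_strictness, pmin(1, diff))
  }
})

test_that("residue rules translate CV labels as specified", {
  # synthetic CV sets with prescribed labels: 6-residue stretch, 4 CVs
  fake_cvs <- function(n) {
    st <- build_ideal_element("ah", n)
    structure_cvs(new_structure(list(st)))
  }
  fake_scores <- function(labels) {
    data.frame(score_ah = 0, score_bs = 1, label = labels,
               max_strictness = 1, degenerate = FALSE,
               stringsAsFactors = FALSE)
  }
  strc <- new_structure(list(build_ideal_element("ah", 6)))
  cvs <- fake_cvs(6)
  # rule (i): residue 3 participates in CVs 1-3, all ah
  lab <- annotate_residues(fake_scores(c("ah", "ah", "ah", "ah")), cvs, strc)
  expect_true(all(lab[[1]] == "ah"))
  # rule (ii): residue 3 in CVs (coil, ah, ah), no bs, residue 4 ah by rule
  # (i) -> residue 3 extended to ah; residue 2 (one ah CV only) stays coil
  lab2 <- annotate_residues(fake_scores(c("coil", "ah", "ah", "ah")), cvs, strc)
  expect_equal(lab2[[1]][4], "ah")
  expect_equal(lab2[[1]][3], "ah")
  expect_equal(lab2[[1]][2], "coil")
  # rule (iii): two bs CVs and no ah CV promote a coil residue to bs
  lab3 <- annotate_residues(fake_scores(c("bs", "bs", "coil", "coil")), cvs, strc)
  expect_equal(lab3[[1]][2], "bs")
  expect_equal(lab3[[1]][3], "bs")
})

test_that("ideal fixtures are recovered perfectly at default strictness", {
  fx <- fold_fixture()
  ann <- annotate_structure(fx$structure)
  for (s in seq_along(ann$labels)) {
    expect_identical(ann$labels[[s]], fx$truth$labels[[s]])
  }
  coil <- annotate_structure(new_structure(list(build_ideal_element("coil", 14))))
  expect_true(all(unlist(coil$labels) == "coil"))
  expect_length(coil$fragments, 0)
})

test_that("fragments need three residues; short runs are relabelled coil", {
  fx <- assemble_fold(list(element("ah", 8), element("coil", 5),
                           element("ah", 8)), joined = TRUE, linker_length = 4)
  ann <- annotate_structure(fx$structure)
  labs <- vapply(ann$fragments, function(f) f$label, "")
  expect_equal(sum(labs == "ah"), 2)

  cvs <- structure_cvs(new_structure(list(build_ideal_element("ah", 6))))
  sc <- data.frame(score_ah = 1, score_bs = 0,
                   label = c("bs", "bs", "coil", "coil"),
                   max_strictness = 1, degenerate = FALSE)
  grp <- group_fragments(list(c("bs", "bs", "coil", "coil", "coil", "coil")),
                         cvs)
  expect_length(grp$fragments, 0)
  expect_true(all(grp$labels[[1]] == "coil"))
})

test_that("sheet packing follows the angle-band and distance conditions", {
  ud <- assemble_fold(sheet_elements("UD", 8, spacing = 4.8))
  ann <- annotate_structure(ud$structure)
  expect_equal(ann$sheets, c(1L, 1L))

  far <- assemble_fold(list(element("bs", 8), element("bs", 8, t = c(0, 10, 0))))
  ann2 <- annotate_structure(far$structure)
  expect_equal(ann2$sheets, c(1L, 2L))

  # A-B and B-C paired, A-C not (9.6 A apart): transitive closure -> one sheet
  udu <- assemble_fold(sheet_elements("UDU", 8, spacing = 4.8))
  ann3 <- annotate_structure(udu$structure)
  ia <- ann3$fragments[[1]]$cv_idx
  ic <- ann3$fragments[[3]]$cv_idx
  expect_gte(min(ann3$graph$dist[ia, ic]), 6)  # A-C fails the distance test
  expect_equal(ann3$sheets, c(1L, 1L, 1L))
})

test_that("fragment-graph edges aggregate CV relations and weight proximity", {
  fx <- assemble_fold(list(element("ah", 5), element("ah", 5, t = c(0, 9, 0))))
  ann <- annotate_structure(fx$structure)
  fg <- ann$fragment_graph
  ia <- ann$fragments[[1]]$cv_idx
  ib <- ann$fragments[[2]]$cv_idx
  expect_length(ia, 3)
  block <- ann$graph$dist[ia, ib]
  expect_equal(fg$mean_dist[1, 2], mean(block), tolerance = 1e-9)
  expect_equal(fg$min_angle[1, 2], min(ann$graph$angle[ia, ib]), tolerance = 1e-9)
  expect_equal(fg$max_angle[1, 2], max(ann$graph$angle[ia, ib]), tolerance = 1e-9)
  # same-type factor: same fragments, same distance, one relabelled
  w_same <- fg$weight[1, 2]
  expect_equal(w_same, 2 / mean(block), tolerance = 1e-9)
  fr2 <- ann$fragments
  fr2[[2]]$label <- "bs"
  fg2 <- build_fragment_graph(fr2, ann$graph)
  expect_equal(fg2$weight[1, 2], w_same / 2, tolerance = 1e-9)

  # weights strictly decrease as the fragments move apart
  w <- vapply(c(6, 9, 14, 20), function(d) {
    fxd <- assemble_fold(list(element("ah", 5), element("ah", 5, t = c(0, d, 0))))
    annotate_structure(fxd$structure)$fragment_graph$weight[1, 2]
  }, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("the non-coil set shrinks monotonically with strictness", {
  pairs <- list(c(0.2, 0.4), c(0.3, 0.6), c(0.1, 0.8))
  for (seed in 1:50) {
    fx <- random_fixture(seed = seed, noise_sigma = runif(1, 0, 0.3))
    for (p in pairs) {
      lo <- annotate_structure(fx$structure, p[1], p[1])
      hi <- annotate_structure(fx$structure, p[2], p[2])
      non_lo <- unlist(lo$labels) != "coil"
      non_hi <- unlist(hi$labels) != "coil"
      expect_true(all(!non_hi | non_lo),
                  info = sprintf("seed %d, strictness %.1f vs %.1f",
                                 seed, p[1], p[2]))
    }
  }
})

test_that("annotation is deterministic and rigid-motion invariant", {
  fx <- random_fixture(seed = 33, noise_sigma = 0.2)
  a1 <- annotate_structure(fx$structure)
  a2 <- annotate_structure(fx$structure)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$cv_scores, a2$cv_scores)
  set.seed(12)
  moved <- transform_structure(fx$structure, random_rotation(), rnorm(3, sd = 30))
  a3 <- annotate_structure(moved)
  expect_identical(a3$labels, a1$labels)
})

test_that("per-residue strictness is high on ideal helices, low where distorted", {
  hx <- new_structure(list(build_ideal_element("ah", 16)))
  ann <- annotate_structure(hx)
  s0 <- per_residue_strictness(ann)[[1]]
  expect_true(all(s0 > 0.7))

  pert <- perturb(hx, carbonyl_rotation = 60, carbonyl_residues = 6:10)
  annp <- annotate_structure(pert)
  s1 <- per_residue_strictness(annp)[[1]]
  expect_lt(mean(s1[6:10]), mean(s1[c(1:4, 13:16)]))

  coil <- annotate_structure(new_structure(list(build_ideal_element("coil", 12))))
  sc <- per_residue_strictness(coil)[[1]]
  expect_lt(mean(sc), mean(s0))

  f <- withr::local_tempfile(fileext = ".pdb")
  write_strictness_pdb(annp, f)
  txt <- readLines(f)
  b <- as.numeric(substr(txt[grepl("^ATOM", txt)], 61, 66))
  expect_true(all(b >= 0 & b <= 100))
})

test_that("the annotation report tables mirror the geometry", {
  hx <- new_structure(list(build_ideal_element("ah", 12)))
  ann <- annotate_structure(hx)
  out <- withr::local_tempdir()
  tabs <- annotation_report(ann, out)
  expect_equal(nrow(tabs$moduli), length(ann$cvs$modulus))
  expect_true(all(abs(tabs$ca_distances$distance - 3.8) < 0.1))
  expect_true(all(file.exists(attr(tabs, "files"))))

  st <- new_structure(list(build_ideal_element("bs", 10)))
  tabs2 <- annotation_report(annotate_structure(st), out, prefix = "strand")
  expect_equal(mean(tabs2$moduli$modulus), 1.4, tolerance = 0.2 / 1.4)
})
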