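test_that("the fold matrix lays out diagonals and blocks as specified", {
  fx <- fold_fixture()
  ann <- annotate_structure(fx$structure)
  fm <- build_fold_matrix(ann)
  n <- length(ann$cvs$modulus)
  expect_length(fm$moduli, n)            # first diagonal: n entries
  expect_length(fm$labels, n)
  sec <- vapply(seq_len(n - 1), function(i) fm$angle[i, i + 1], numeric(1))
  expect_length(sec, n - 1)              # second diagonal: n - 1 relations
  expect_equal(nrow(fm$fragments), 3)    # 2 strands + 1 helix
  expect_setequal(fm$fragments$label, c("bs", "bs", "ah"))
  expect_equal(fm$angle, t(fm$angle))

  set.seed(2)
  moved <- transform_structure(fx$structure, random_rotation(), rnorm(3, sd = 15))
  fm2 <- build_fold_matrix(annotate_structure(moved))
  expect_equal(fm2$angle, fm$angle, tolerance = 1e-6)
  expect_equal(fm2$dist, fm$dist, tolerance = 1e-6)
  expect_equal(fm2$moduli, fm$moduli, tolerance = 1e-6)
})

test_that("block similarity is 100 for identical blocks and 0 out of band", {
  fx <- fold_fixture()
  fm <- build_fold_matrix(annotate_structure(fx$structure))
  idx <- which(fm$frag == 1)
  expect_equal(block_similarity(fm, idx, fm, idx)$score, 100)
  # a block shifted far out of every tolerance band
  fm2 <- fm
  fm2$angle <- fm2$angle + 90
  fm2$dist <- fm2$dist + 50
  fm2$moduli <- fm2$moduli + 10
  expect_equal(block_similarity(fm, idx, fm2, idx)$score, 0)
})

test_that("similarity degrades monotonically under increasing distortion", {
  base <- new_structure(list(build_ideal_element("ah", 12)))
  fm0 <- build_fold_matrix(annotate_structure(base))
  idx <- which(fm0$frag == 1)
  scores <- vapply(c(0, 0.3, 0.6, 1.0), function(sig) {
    p <- perturb(base, noise_sigma = sig, seed = 9)
    annp <- annotate_structure(p)
    if (length(annp$fragments) == 0) return(0)
    fmp <- build_fold_matrix(annp)
    take <- which(fmp$stretch == 1)[seq_along(idx)]
    block_similarity(fm0, idx, fmp, take)$score
  }, numeric(1))
  expect_equal(scores[1], 100)
  expect_true(all(diff(scores) <= 0))
})

test_that("self-search returns the identity match at any threshold", {
  fx <- fold_fixture()
  ann <- annotate_structure(fx$structure)
  fm <- build_fold_matrix(ann)
  for (th in list(c(0, 0), c(45, 55), c(100, 100))) {
    m <- find_fold_occurrences(fm, fm, th[1], th[2])
    expect_gte(length(m), 1)
    self <- m[[which.max(vapply(m, function(x) x$ss_score + x$tt_score, 1))]]
    expect_equal(self$ss_score, 100)
    expect_equal(self$tt_score, 100)
    mf <- apply_filters(list(self), ann, ann)
    expect_equal(mf[[1]]$rmsd_to_template, 0, tolerance = 1e-9)
  }
  # helix-only target cannot host a strand-containing template
  ho <- annotate_structure(new_structure(list(build_ideal_element("ah", 14))))
  expect_equal(length(find_fold_occurrences(fm, build_fold_matrix(ho), 45, 55)), 0)
  # a template with no fragment is unusable
  coil <- annotate_structure(new_structure(list(build_ideal_element("coil", 10))))
  expect_error(build_fold_matrix(coil), "unusable")
})

test_that("recursive search equals brute-force enumeration (completeness)", {
  fx <- fold_fixture()
  fm_t <- build_fold_matrix(annotate_structure(fx$structure))
  for (seed in c(1, 7, 23)) {
    tg <- random_search_target(seed)
    ann_g <- annotate_structure(tg$structure)
    if (length(ann_g$fragments) == 0) next
    fm_g <- build_fold_matrix(ann_g)
    for (th in list(c(45, 55), c(70, 70))) {
      got <- find_fold_occurrences(fm_t, fm_g, th[1], th[2])
      keys <- sort(vapply(got, match_key, ""))
      oracle <- brute_force_fold_search(fm_t, fm_g, th[1], th[2])
      expect_identical(keys, oracle,
                       info = sprintf("seed %d thresholds %d/%d",
                                      seed, th[1], th[2]))
    }
  }
})

test_that("a duplicated fold is found at both sites", {
  els <- c(sheet_elements("UD", length = 7, spacing = 4.8),
           list(element("ah", 9, t = c(0, 2.4, 9))))
  shifted <- lapply(els, function(e) { e$t <- e$t + c(50, 0, 0); e })
  both <- assemble_fold(c(els, shifted))
  tpl <- assemble_fold(els)
  fm_t <- build_fold_matrix(annotate_structure(tpl$structure))
  fm_g <- build_fold_matrix(annotate_structure(both$structure))
  m <- find_fold_occurrences(fm_t, fm_g, 45, 55)
  keys <- vapply(m, match_key, "")
  oracle <- brute_force_fold_search(fm_t, fm_g, 45, 55)
  expect_identical(sort(keys), oracle)
  # exactly two disjoint full-fold placements among the matches
  strands <- vapply(m, function(x) paste(sort(unique(x$assignment$target_stretch)),
                                         collapse = ","), "")
  expect_setequal(unique(strands), c("1,2,3", "4,5,6"))
})

test_that("match sets shrink as thresholds rise", {
  fx <- fold_fixture()
  fm_t <- build_fold_matrix(annotate_structure(fx$structure))
  tg <- random_search_target(12)
  fm_g <- build_fold_matrix(annotate_structure(tg$structure))
  lo <- sort(vapply(find_fold_occurrences(fm_t, fm_g, 30, 30), match_key, ""))
  mid <- sort(vapply(find_fold_occurrences(fm_t, fm_g, 60, 30), match_key, ""))
  hi <- sort(vapply(find_fold_occurrences(fm_t, fm_g, 60, 80), match_key, ""))
  expect_true(all(mid %in% lo))
  expect_true(all(hi %in% mid))
})

test_that("connectivity requirement enforces template fragment order", {
  fx <- assemble_fold(list(element("ah", 8), element("bs", 8, t = c(0, 12, 0))),
                      joined = TRUE, linker_length = 4)
  ann_t <- annotate_structure(fx$structure)
  fm_t <- build_fold_matrix(ann_t)
  # target with the two elements in reversed chain order
  rev_fx <- assemble_fold(list(element("bs", 8), element("ah", 8, t = c(0, 12, 0))),
                          joined = TRUE, linker_length = 4)
  fm_g <- build_fold_matrix(annotate_structure(rev_fx$structure))
  free <- find_fold_occurrences(fm_t, fm_g, 40, 0)
  conn <- find_fold_occurrences(fm_t, fm_g, 40, 0, require_connectivity = TRUE)
  expect_gt(length(free), 0)
  expect_length(conn, 0)
})

test_that("sequence, disulfide and r.m.s.d. filters act position-wise", {
  seqnames <- rep("ALA", 9)
  seqnames[c(4, 9)] <- "CYS"
  st <- build_ideal_element("ah", 9, resname = seqnames)
  # S-gamma atoms ~2 A apart for the disulfide test
  st$sg[4, ] <- st$xyz$CA[4, ] + c(0, 2, 0)
  st$sg[9, ] <- st$sg[4, ] + c(0, 0, 2.0)
  strc <- new_structure(list(st))
  ann <- annotate_structure(strc)
  fm <- build_fold_matrix(ann)
  m <- find_fold_occurrences(fm, fm, 45, 55)

  kept <- apply_filters(m, ann, ann, sequence_pattern = "XXXCXXXXC")
  expect_length(kept, length(m))
  expect_length(apply_filters(m, ann, ann, sequence_pattern = "XXXXXXXXC"),
                length(m))
  expect_length(apply_filters(m, ann, ann, sequence_pattern = "CXXXXXXXX"), 0)
  expect_length(apply_filters(m, ann, ann, sequence_pattern = "XXXXXXXXX"),
                length(m))
  expect_error(apply_filters(m, ann, ann, sequence_pattern = "XXX"), "length")

  expect_length(apply_filters(m, ann, ann, disulfide = TRUE), length(m))
  st2 <- st
  st2$sg[9, ] <- st2$sg[4, ] + c(0, 0, 4)   # too far for a bridge
  ann2 <- annotate_structure(new_structure(list(st2)))
  m2 <- find_fold_occurrences(fm, build_fold_matrix(ann2), 45, 55)
  expect_length(apply_filters(m2, ann, ann2, disulfide = TRUE), 0)

  expect_length(apply_filters(m, ann, ann, max_rmsd = 0), length(m))
})

test_that("the library pipeline extracts, superposes, names and clusters", {
  fx <- fold_fixture()
  td <- withr::local_tempdir()
  tpl_path <- file.path(td, "tmpl.pdb")
  write_structure(fx$structure, tpl_path)
  db <- file.path(td, "db")
  dir.create(db)
  for (i in 1:3) {
    write_structure(perturb(fx$structure, noise_sigma = 0.3, seed = 200 + i),
                    file.path(db, sprintf("fx%02d.pdb", i)))
  }
  man <- generate_library(tpl_path, db, out_dir = td, multi_chain = TRUE)
  expect_equal(nrow(man), 3)
  expect_true(all(grepl("^[a-z0-9]+_[0-9]+_[0-9]{4}\\.pdb$", man$file)))
  expect_true(all(man$rmsd_to_template < 1))
  expect_true(all(file.exists(file.path(td, "library", man$file))))
  # the common B factor is stamped on every atom
  txt <- readLines(file.path(td, "library", man$file[1]))
  expect_true(all(substr(txt[grepl("^ATOM", txt)], 61, 66) == " 25.00"))

  # lowering the tertiary threshold never shrinks the library
  man_lo <- generate_library(tpl_path, db, out_dir = file.path(td, "lo"),
                             tt_threshold = 20, multi_chain = TRUE)
  expect_gte(nrow(man_lo), nrow(man))

  # database restricted by an id list
  idf <- file.path(td, "ids.txt")
  writeLines(c("fx01", "fx03"), idf)
  man_id <- generate_library(tpl_path, db, out_dir = file.path(td, "ids"),
                             multi_chain = TRUE, id_list = idf)
  expect_setequal(unique(sub("_.*", "", man_id$file)), c("fx01", "fx03"))
})

test_that("library clustering modes behave as documented", {
  fx <- fold_fixture()
  td <- withr::local_tempdir()
  tpl_path <- file.path(td, "tmpl.pdb")
  write_structure(fx$structure, tpl_path)
  db <- file.path(td, "db")
  dir.create(db)
  # two conformer families: near-identical copies and strongly distorted ones
  for (i in 1:2) {
    write_structure(perturb(fx$structure, noise_sigma = 0.05, seed = i),
                    file.path(db, sprintf("near%02d.pdb", i)))
  }
  bent <- fx$structure
  bent$stretches[[3]] <- transform_stretch(bent$stretches[[3]],
                                           rotation_about_axis(c(0, 0, 1), 25),
                                           c(1.5, 0, 0))
  for (i in 1:2) {
    write_structure(perturb(bent, noise_sigma = 0.05, seed = 10 + i),
                    file.path(db, sprintf("bent%02d.pdb", i)))
  }
  man <- generate_library(tpl_path, db, out_dir = td, multi_chain = TRUE,
                          tt_threshold = 30, max_rmsd = 8)
  expect_equal(nrow(man), 4)
  cl <- cluster_library(file.path(td, "library"), man, "pairwise_rmsd",
                        rmsd_cut = 1.0)
  expect_equal(length(unique(cl)), 2)
  by_family <- split(cl, grepl("^near", man$file))
  expect_length(unique(by_family[["TRUE"]]), 1)
  expect_length(unique(by_family[["FALSE"]]), 1)

  bins <- cluster_library(file.path(td, "library"), man, "rmsd_range",
                          breaks = c(0, 1, Inf))
  expect_equal(sort(unique(bins)), 1:2)

  s1 <- cluster_library(file.path(td, "library"), man, "random_subset",
                        n = 2, seed = 7)
  s2 <- cluster_library(file.path(td, "library"), man, "random_subset",
                        n = 2, seed = 7)
  expect_equal(sum(!is.na(s1)), 2)
  expect_identical(s1, s2)
})
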